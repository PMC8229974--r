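amp6 <- make_amplicon(6, seed = 42)

test_that("deterministic conversion extremes show pure T/A or C/G at CpG
           sites", {
  cpg_c <- amp6$cpg_offsets + 1L
  cpg_g <- amp6$cpg_offsets + 2L
  sim0 <- simulate_reads(amp6, rep(0, 6),
    read_sim_params(n_reads = 60, conversion_rate = 1,
                    inappropriate_conversion = 0, subst_error = 0, seed = 1))
  for (i in seq_len(60)) {
    s <- sim0$reads$sequence[i]
    at <- function(pos) substring(s, pos, pos)
    if (sim0$reads$strand[i] == "top")
      expect_true(all(at(cpg_c) == "T"))
    else
      expect_true(all(at(cpg_g) == "A"))
  }
  sim1 <- simulate_reads(amp6, rep(1, 6),
    read_sim_params(n_reads = 60, conversion_rate = 1,
                    inappropriate_conversion = 0, subst_error = 0, seed = 2))
  for (i in seq_len(60)) {
    s <- sim1$reads$sequence[i]
    at <- function(pos) substring(s, pos, pos)
    if (sim1$reads$strand[i] == "top")
      expect_true(all(at(cpg_c) == "C"))
    else
      expect_true(all(at(cpg_g) == "G"))
  }
})

test_that("incomplete conversion leaves the expected fraction of CpG
           cytosines unconverted", {
  c_rate <- 0.99
  sim <- simulate_reads(amp6, rep(0, 6),
    read_sim_params(n_reads = 10000, conversion_rate = c_rate,
                    inappropriate_conversion = 0, subst_error = 0,
                    frac_top_strand = 1, seed = 3))
  cpg_c <- amp6$cpg_offsets + 1L
  bases <- t(vapply(sim$reads$sequence,
                    function(s) strsplit(s, "")[[1]][cpg_c], character(6)))
  frac_retained <- mean(bases == "C")
  expect_lt(abs(frac_retained - (1 - c_rate)),
            binom_3se(1 - c_rate, 10000 * 6))
})

test_that("read simulation is byte-identical under a fixed seed", {
  p <- read_sim_params(n_reads = 200, seed = 99)
  s1 <- simulate_reads(amp6, c(0, 0, .3, .3, .9, .94), p)
  s2 <- simulate_reads(amp6, c(0, 0, .3, .3, .9, .94), p)
  expect_identical(s1, s2)
  s3 <- simulate_reads(amp6, c(0, 0, .3, .3, .9, .94),
                       read_sim_params(n_reads = 200, seed = 100))
  expect_false(identical(s1$reads$sequence, s3$reads$sequence))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fastq(s1$reads, f1); write_fastq(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("strand fractions and truth-state frequencies match their
           generating probabilities", {
  profile <- c(0.1, 0.2, 0.5, 0.8, 0.9, 0.4)
  sim <- simulate_reads(amp6, profile,
                        read_sim_params(n_reads = 6000, frac_top_strand = 0.3,
                                        seed = 5))
  expect_lt(abs(mean(sim$truth$strand == "top") - 0.3),
            binom_3se(0.3, 6000))
  freq <- colMeans(as.matrix(sim$truth[, -(1:2)]))
  expect_true(all(abs(freq - profile) <
                    binom_3se(pmax(profile, 1e-3), 6000) + 1e-9))
})

test_that("epiallele coupling makes within-read states comonotone without
           changing marginals", {
  profile <- rep(0.5, 6)
  full <- simulate_reads(amp6, profile,
    read_sim_params(n_reads = 400, epiallele_cor = 1, seed = 55))
  st <- as.matrix(full$truth[, -(1:2)])
  # fully coupled: all sites of a read share one latent draw
  expect_true(all(apply(st, 1, function(r) all(r) || all(!r))))
  expect_lt(abs(mean(st) - 0.5), binom_3se(0.5, 400))  # reads, not cells
  indep <- simulate_reads(amp6, profile,
    read_sim_params(n_reads = 400, epiallele_cor = 0, seed = 55))
  sti <- as.matrix(indep$truth[, -(1:2)])
  expect_gt(mean(apply(sti, 1, function(r) !(all(r) || all(!r)))), 0.5)
})

test_that("FASTQ writing and reading round-trips", {
  sim <- simulate_reads(amp6, rep(0.5, 6), read_sim_params(n_reads = 10,
                                                           seed = 1))
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$reads, path)
  back <- read_fastq(path)
  expect_identical(back$read_id, sim$reads$read_id)
  expect_identical(back$sequence, sim$reads$sequence)
})

test_that("noise-free panels have expression strictly decreasing in
           methylation and closed-form inhibition", {
  p <- panel_gen_params(sigma_e = 0, sigma_t = 0, sigma_rfi = 0, seed = 8)
  panel <- simulate_panel(p)
  ord <- order(panel$dr4_pct)
  expect_true(all(diff(panel$expr_dr4[ord]) <= 0))
  ord5 <- order(panel$dr5_pct)
  expect_true(all(diff(panel$expr_dr5[ord5]) <= 0))
  expected <- trail_inhibition(panel$dr4_pct / 100, panel$dr5_pct / 100,
                               p$theta, p$s0)
  expect_equal(panel$inhibition_pct, pmin(pmax(expected, -10), 100))
  # fully methylated on both receptors: availability 0, closed form
  expect_equal(trail_inhibition(1, 1, theta = 10, s0 = 0.5),
               100 * plogis(10 * (0 - 0.5)))
})

test_that("default panels couple methylation negatively with inhibition", {
  panel <- simulate_panel(panel_gen_params(seed = 21))
  expect_identical(nrow(panel), 32L)
  expect_lt(cor(panel$dr4_pct, panel$inhibition_pct, method = "spearman"), 0)
  expect_lt(cor(panel$dr5_pct, panel$inhibition_pct, method = "spearman"), 0)
})

test_that("cohort hypermethylation frequency follows p_hyper", {
  counts <- c(A = 200L)
  p0 <- cohort_gen_params(subtype_counts = counts,
                          p_hyper = list(dr4 = c(A = 0), dr5 = c(A = 0)),
                          n_remission = 0L, n_pairs = 0L, seed = 1)
  ch0 <- simulate_array_cohort(p0)
  pct <- gene_methylation(ch0$beta, select_probes(ch0$annotation, "DR4"))
  expect_identical(sum(pct >= 10), 0L)

  p1 <- cohort_gen_params(subtype_counts = counts,
                          p_hyper = list(dr4 = c(A = 1), dr5 = c(A = 1)),
                          hyper_mean = 0.30, n_remission = 0L, n_pairs = 0L,
                          seed = 2)
  ch1 <- simulate_array_cohort(p1)
  pct1 <- gene_methylation(ch1$beta, select_probes(ch1$annotation, "DR4"))
  expect_identical(sum(pct1 >= 10), 200L)

  p3 <- cohort_gen_params(subtype_counts = counts,
                          p_hyper = list(dr4 = c(A = 0.3), dr5 = c(A = 0.3)),
                          n_remission = 0L, n_pairs = 0L, seed = 3)
  ch3 <- simulate_array_cohort(p3)
  pct3 <- gene_methylation(ch3$beta, select_probes(ch3$annotation, "DR4"))
  expect_lt(abs(mean(pct3 >= 10) - 0.3), binom_3se(0.3, 200))
  expect_identical(unname(pct3 >= 10), ch3$truth$dr4_hyper)
})

test_that("cohort generation is deterministic and betas stay in range", {
  ch1 <- simulate_array_cohort(cohort_gen_params(seed = 4))
  ch2 <- simulate_array_cohort(cohort_gen_params(seed = 4))
  expect_identical(ch1, ch2)
  expect_true(all(ch1$beta >= 0 & ch1$beta <= 1))
  expect_identical(ncol(ch1$beta), nrow(ch1$samples))
})
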