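amp <- make_amplicon(6, seed = 42)
L <- nchar(amp$sequence)
ref_chars <- strsplit(amp$sequence, "")[[1]]
n_scored_top <- sum(ref_chars != "C")

test_that("perfect converted reads align to the correct strand with full
           identity", {
  top_read <- bisulfite_convert(amp$sequence, "top")
  bottom_read <- reverse_complement(bisulfite_convert(amp$sequence, "bottom"))
  aln <- align_reads(c(top_read, bottom_read), amp)
  expect_identical(aln$strand, c("top", "bottom"))
  expect_false(any(aln$base_at_ref == "-", na.rm = TRUE))
  cc <- call_reads(aln, amp)
  expect_equal(cc$calls$identity, c(1, 1))
  expect_equal(cc$calls$conversion_efficiency, c(1, 1))
  expect_true(all(cc$states == "U"))
})

test_that("a single non-bisulfite substitution lowers identity by one scored
           position", {
  read <- bisulfite_convert(amp$sequence, "top")
  # mutate an A at a non-C reference position into G
  pos <- which(ref_chars == "A")[3]
  substr(read, pos, pos) <- "G"
  cc <- call_reads(align_reads(read, amp), amp)
  expect_equal(cc$calls$identity, (n_scored_top - 1) / n_scored_top)
})

test_that("fully methylated converted reads call all sites methylated", {
  read <- bisulfite_convert(amp$sequence, "top", profile = rep(1, 6))
  cc <- call_reads(align_reads(read, amp), amp)
  expect_true(all(cc$states == "M"))
  expect_equal(cc$calls$conversion_efficiency, 1)
})

test_that("conversion efficiency counts the unconverted non-CpG cytosines", {
  noncpg_c <- setdiff(which(ref_chars == "C"), amp$cpg_offsets + 1L)
  read <- bisulfite_convert(amp$sequence, "top")
  # un-convert half of the non-CpG C positions back to C
  k <- length(noncpg_c) %/% 2
  for (pos in noncpg_c[seq_len(k)]) substr(read, pos, pos) <- "C"
  cc <- call_reads(align_reads(read, amp), amp)
  expect_equal(cc$calls$conversion_efficiency,
               (length(noncpg_c) - k) / length(noncpg_c))
})

test_that("read filters apply in identity, conversion, length order", {
  calls <- data.frame(
    read_id = c("ok", "badconv", "badlen", "badboth"),
    strand = "top", length = c(100L, 100L, 30L, 30L),
    identity = c(0.99, 0.99, 0.99, 0.5),
    conversion_efficiency = c(0.99, 0.5, 0.99, 0.5))
  flt <- filter_reads(calls)
  expect_identical(flt$reason, c("pass", "conversion", "length", "identity"))
  expect_identical(unname(flt$report), c(1L, 1L, 1L))
  expect_identical(flt$pass, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("simulated pass rates track the binomial prediction for
           conversion filtering", {
  noncpg_c <- setdiff(which(ref_chars == "C"), amp$cpg_offsets + 1L)
  n_c <- length(noncpg_c)
  c_rate <- 0.995
  sim <- simulate_reads(amp, rep(0, 6),
    read_sim_params(n_reads = 1000, conversion_rate = c_rate,
                    inappropriate_conversion = 0, subst_error = 0,
                    frac_top_strand = 1, seed = 12))
  cc <- call_reads(align_reads(sim$reads, amp), amp)
  flt <- filter_reads(cc$calls, min_identity = 0, min_conversion = 0.9,
                      min_length = 0)
  # P(pass) = P(Binom(n_c, 1 - c) small enough that converted fraction >= .9)
  max_fail <- floor(n_c * 0.1)
  p_pass <- pbinom(max_fail, n_c, 1 - c_rate)
  expect_lt(abs(mean(flt$pass) - p_pass),
            binom_3se(p_pass, 1000) + 1e-9)
})

test_that("per-site summaries are exact tallies with coverage gating", {
  states <- rbind(matrix("M", 5, 2), matrix("U", 5, 2))
  amp2 <- amplicon_spec("two", "AATCGTTCGATT", "AAT", "AAT")
  s <- summarize_calls(states, amp2, min_coverage = 5)
  expect_equal(s$sites$percent, c(50, 50))
  expect_equal(s$sites$coverage, c(10L, 10L))
  expect_equal(s$mean_percent, 50)
  # hand-built per-site percents [0,0,30,30,90,90] -> unweighted mean 40
  states6 <- do.call(cbind, lapply(c(0, 0, .3, .3, .9, .9), function(p)
    c(rep("M", round(10 * p)), rep("U", 10 - round(10 * p)))))
  s6 <- summarize_calls(states6, amp, min_coverage = 5)
  expect_equal(s6$sites$percent, c(0, 0, 30, 30, 90, 90))
  expect_equal(s6$mean_percent, 40)
  # low-coverage sites drop out of the mean and report NA
  states_low <- states6
  states_low[3:10, 1] <- "N"
  slow <- summarize_calls(states_low, amp, min_coverage = 5)
  expect_true(is.na(slow$sites$percent[1]))
  expect_equal(slow$mean_percent, mean(c(0, 30, 30, 90, 90)))
  expect_error(summarize_calls(states6, amp, min_coverage = 99),
               "insufficient coverage")
})

test_that("error-free calling reproduces the simulator truth exactly on both
           strands", {
  for (frac in c(0, 0.5, 1)) {
    sim <- simulate_reads(amp, c(0, 0.2, 0.4, 0.6, 0.8, 1),
      read_sim_params(n_reads = 300, conversion_rate = 1,
                      inappropriate_conversion = 0, subst_error = 0,
                      frac_top_strand = frac, seed = 31))
    res <- quantify_methylation(sim$reads, amp, caller_params(min_coverage = 50))
    truth_m <- colSums(as.matrix(sim$truth[, -(1:2)]))
    expect_identical(res$sites$n_methylated, as.integer(truth_m))
    expect_identical(res$sites$coverage, rep(300L, 6))
    expect_identical(res$n_reads_pass, 300L)
  }
})

test_that("strand composition does not change the estimates when truth is
           shared", {
  p0 <- read_sim_params(n_reads = 200, conversion_rate = 1,
                        inappropriate_conversion = 0, subst_error = 0,
                        frac_top_strand = 0, seed = 17)
  p1 <- read_sim_params(n_reads = 200, conversion_rate = 1,
                        inappropriate_conversion = 0, subst_error = 0,
                        frac_top_strand = 1, seed = 17)
  profile <- c(0.1, 0.3, 0.5, 0.7, 0.9, 0.5)
  r0 <- quantify_methylation(simulate_reads(amp, profile, p0)$reads, amp,
                             caller_params(min_coverage = 50))
  r1 <- quantify_methylation(simulate_reads(amp, profile, p1)$reads, amp,
                             caller_params(min_coverage = 50))
  expect_equal(r0$sites$percent, r1$sites$percent)
})

test_that("quantify handles degenerate inputs", {
  expect_error(quantify_methylation(data.frame(), amp), "no reads")
  sim0 <- simulate_reads(amp, rep(0, 6),
    read_sim_params(n_reads = 120, conversion_rate = 1,
                    inappropriate_conversion = 0, subst_error = 0, seed = 2))
  r <- quantify_methylation(sim0$reads, amp, caller_params())
  expect_equal(r$mean_percent, 0)
  sim1 <- simulate_reads(amp, rep(1, 6),
    read_sim_params(n_reads = 120, conversion_rate = 1,
                    inappropriate_conversion = 0, subst_error = 0, seed = 2))
  r1 <- quantify_methylation(sim1$reads, amp, caller_params())
  expect_equal(r1$mean_percent, 100)
})
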