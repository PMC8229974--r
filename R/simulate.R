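#' Parameters for the bisulfite read simulator
#'
#' @param n_reads Number of reads to simulate.
#' @param conversion_rate Probability that an unmethylated cytosine (CpG or
#'   not) reads as T after bisulfite treatment. Default 0.995, a typical
#'   conversion efficiency for a commercial bisulfite kit.
#' @param inappropriate_conversion Probability that a methylated CpG cytosine
#'   nevertheless reads as T (over-conversion). Default 0.005.
#' @param subst_error Per-base substitution error rate applied after
#'   conversion. Default 0.005. Indels are not modeled.
#' @param frac_top_strand Fraction of reads drawn from the top strand.
#' @param epiallele_cor Within-read correlation of CpG methylation states:
#'   with this probability a site reuses the read's shared latent uniform
#'   instead of an independent one, so 0 (default) gives independent sites
#'   and 1 gives fully coupled epialleles. Per-site marginal frequencies are
#'   unchanged.
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @return A list of class `read_sim_params`.
#' @export
read_sim_params <- function(n_reads = 1000L, conversion_rate = 0.995,
                            inappropriate_conversion = 0.005,
                            subst_error = 0.005, frac_top_strand = 0.5,
                            epiallele_cor = 0, seed = 1L) {
  p <- list(n_reads = as.integer(n_reads), conversion_rate = conversion_rate,
            inappropriate_conversion = inappropriate_conversion,
            subst_error = subst_error, frac_top_strand = frac_top_strand,
            epiallele_cor = epiallele_cor, seed = as.integer(seed))
  rates <- unlist(p[c("conversion_rate", "inappropriate_conversion",
                      "subst_error", "frac_top_strand", "epiallele_cor")])
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (p$n_reads <= 0L) stop("n_reads must be positive", call. = FALSE)
  class(p) <- "read_sim_params"
  p
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Simulate one strand's reads as an L x n character matrix, then collapse.
# `chars` is the strand sequence (in its own 5'->3' orientation),
# `cpg_pos` the 1-based positions of CpG cytosines on that strand in
# strand-local coordinates, `meth` an n x S logical matrix of per-read
# methylation states in amplicon site order, `site_map` mapping amplicon site
# index -> strand-local CpG position.
simulate_strand_reads <- function(chars, cpg_pos, meth, params) {
  n <- nrow(meth)
  L <- length(chars)
  if (n == 0L) return(matrix(character(0), nrow = L, ncol = 0L))
  mat <- matrix(chars, nrow = L, ncol = n)
  c_pos <- which(chars == "C")
  noncpg_c <- setdiff(c_pos, cpg_pos)
  if (length(noncpg_c) && n) {
    conv <- matrix(runif(length(noncpg_c) * n) < params$conversion_rate,
                   nrow = length(noncpg_c))
    mat[noncpg_c, ][conv] <- "T"
  }
  if (length(cpg_pos) && n) {
    p_convert <- ifelse(meth, params$inappropriate_conversion,
                        params$conversion_rate)          # n x S
    conv <- matrix(runif(length(p_convert)), nrow = n) < p_convert
    for (j in seq_along(cpg_pos))
      mat[cpg_pos[j], conv[, j]] <- "T"
  }
  if (params$subst_error > 0 && n) {
    hit <- which(matrix(runif(L * n) < params$subst_error, nrow = L))
    if (length(hit)) {
      orig <- mat[hit]
      alt <- vapply(orig, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      mat[hit] <- alt
    }
  }
  mat
}

collapse_cols <- function(mat) {
  if (ncol(mat) == 0L) return(character(0))
  apply(mat, 2L, paste, collapse = "")
}

#' Simulate bisulfite amplicon reads with known truth
#'
#' Emulates targeted bisulfite sequencing of one amplicon: each read is a
#' full-length copy of the (top or bottom) strand in which every CpG
#' cytosine's methylation state is drawn independently from the site's
#' profile value, unmethylated cytosines convert to T with probability
#' `conversion_rate`, methylated CpG cytosines erroneously convert with
#' probability `inappropriate_conversion`, and uniform substitution errors
#' are applied afterwards. Bottom-strand reads are emitted in sequencing
#' orientation, i.e. the reverse complement of the converted bottom strand
#' (which aligns to the top reference with G-to-A conversions).
#'
#' @param amplicon An [amplicon_spec].
#' @param profile Numeric vector of per-site methylation fractions in
#'   `[0, 1]`, one per CpG site of the amplicon.
#' @param params A [read_sim_params] object.
#' @return A list with `reads` (data.frame: `read_id`, `sequence`, `strand`)
#'   and `truth` (data.frame: `read_id`, `strand`, and one logical
#'   `site_<i>` column per CpG site giving the drawn methylation state).
#' @export
simulate_reads <- function(amplicon, profile, params = read_sim_params()) {
  stopifnot(inherits(amplicon, "amplicon_spec"),
            inherits(params, "read_sim_params"))
  S <- length(amplicon$cpg_offsets)
  if (length(profile) != S)
    stop("profile length does not match amplicon CpG sites", call. = FALSE)
  if (any(profile < 0 | profile > 1))
    stop("profile values must lie in [0, 1]", call. = FALSE)
  set.seed(params$seed)
  n <- params$n_reads
  top_chars <- strsplit(amplicon$sequence, "", fixed = TRUE)[[1]]
  L <- length(top_chars)
  is_top <- runif(n) < params$frac_top_strand
  u <- matrix(runif(n * S), nrow = n)
  if (params$epiallele_cor > 0) {
    shared <- matrix(runif(n), nrow = n, ncol = S)
    use_shared <- matrix(runif(n * S), nrow = n) < params$epiallele_cor
    u[use_shared] <- shared[use_shared]
  }
  meth <- u < matrix(profile, nrow = n, ncol = S, byrow = TRUE)

  # top-strand CpG C at 1-based offset+1; bottom-strand C of the same site
  # sits opposite the top G (offset+2), i.e. bottom-local position L-1-offset
  top_cpg <- amplicon$cpg_offsets + 1L
  bottom_chars <- strsplit(reverse_complement(amplicon$sequence),
                           "", fixed = TRUE)[[1]]
  bottom_cpg <- L - 1L - amplicon$cpg_offsets

  seqs <- character(n)
  top_mat <- simulate_strand_reads(top_chars, top_cpg,
                                   meth[is_top, , drop = FALSE], params)
  seqs[is_top] <- collapse_cols(top_mat)
  bot_mat <- simulate_strand_reads(bottom_chars, bottom_cpg,
                                   meth[!is_top, , drop = FALSE], params)
  if (any(!is_top)) {
    # back to sequencing orientation: reverse complement of converted bottom
    rc_mat <- matrix(COMPLEMENT[bot_mat[rev(seq_len(L)), , drop = FALSE]],
                     nrow = L)
    seqs[!is_top] <- collapse_cols(rc_mat)
  }
  ids <- sprintf("read_%05d", seq_len(n))
  truth <- data.frame(read_id = ids,
                      strand = ifelse(is_top, "top", "bottom"),
                      stringsAsFactors = FALSE)
  if (S) {
    meth_df <- as.data.frame(meth)
    names(meth_df) <- sprintf("site_%d", seq_len(S))
    truth <- cbind(truth, meth_df)
  }
  list(reads = data.frame(read_id = ids, sequence = seqs,
                          strand = truth$strand, stringsAsFactors = FALSE),
       truth = truth)
}

#' Write simulated reads as a 4-line FASTQ file
#'
#' Quality strings are constant Q30 (`?`); downstream calling does not use
#' base qualities.
#'
#' @param reads Data frame with `read_id` and `sequence` columns.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$sequence),
                 function(k) strrep("?", k), character(1))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a 4-line FASTQ file into a data frame
#'
#' @param path FASTQ path (plain or gzipped).
#' @return Data frame with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- sub("\\s.*$", "", names(x))
  data.frame(read_id = ids, sequence = toupper(as.character(x)),
             stringsAsFactors = FALSE)
}

default_panel_groups <- function() {
  # emulates a 32-line BCP-ALL panel: MLL-rearranged and MEF2D-rearranged
  # lines frequently promoter-methylated, TCF3-HLF and ETV6-RUNX1 lines
  # unmethylated, the rest mixed
  data.frame(
    karyotype = c("MLLr", "BCR-ABL1", "TCF3-PBX1", "TCF3-HLF",
                  "ETV6-RUNX1", "MEF2Dr", "DUX4r"),
    n = c(9L, 6L, 7L, 4L, 2L, 2L, 2L),
    p_meth_dr4 = c(1.0, 0.33, 0.5, 0, 0, 1.0, 0.5),
    p_meth_dr5 = c(0.67, 0.33, 0.4, 0, 0, 1.0, 0.5),
    stringsAsFactors = FALSE)
}

#' Parameters for the cell-line panel generator
#'
#' @param groups Data frame with columns `karyotype`, `n`, `p_meth_dr4`,
#'   `p_meth_dr5`: per-karyotype line counts and the probability that each
#'   receptor's promoter is in the methylated mixture component.
#' @param alpha,beta Intercept and slope of the expression model:
#'   log10 relative expression = alpha - beta * methylation + noise.
#' @param sigma_e Expression noise sd (log10 scale).
#' @param theta,s0 Steepness and midpoint of the logistic link from receptor
#'   availability `s = max(1 - m_DR4, 1 - m_DR5)` to percent inhibition by
#'   rhsTRAIL at 100 ng/mL: inhibition = 100 * logistic(theta * (s - s0)).
#' @param sigma_t Inhibition noise sd (percentage points); results clipped to
#'   `[-10, 100]`.
#' @param rfi_gain Scale of the cell-surface RFI signal above the control
#'   ratio of 1.
#' @param sigma_rfi Log-normal noise sd on the RFI signal.
#' @param hyper_shape,base_shape Beta shape pairs for the methylated and
#'   unmethylated mixture components of per-gene methylation. The methylated
#'   component is dense (mean 0.8): silenced promoters in these lines are
#'   heavily methylated, which is what makes doubly hypermethylated lines
#'   TRAIL-resistant under the logistic link.
#' @param level_cor Gaussian-copula correlation of the two genes'
#'   methylation levels within a line (a line-wide silencing propensity);
#'   also couples the mixture-state draws.
#' @param seed Integer seed.
#' @return A list of class `panel_gen_params`.
#' @export
panel_gen_params <- function(groups = default_panel_groups(),
                             alpha = 0, beta = 2, sigma_e = 0.25,
                             theta = 10, s0 = 0.5, sigma_t = 5,
                             rfi_gain = 4, sigma_rfi = 0.2,
                             hyper_shape = c(8, 2), base_shape = c(0.8, 150),
                             level_cor = 0.7, seed = 1L) {
  if (sigma_e < 0 || sigma_t < 0 || sigma_rfi < 0)
    stop("noise sds must be non-negative", call. = FALSE)
  if (level_cor < 0 || level_cor > 1)
    stop("level_cor must lie in [0, 1]", call. = FALSE)
  structure(list(groups = groups, alpha = alpha, beta = beta,
                 sigma_e = sigma_e, theta = theta, s0 = s0, sigma_t = sigma_t,
                 rfi_gain = rfi_gain, sigma_rfi = sigma_rfi,
                 hyper_shape = hyper_shape, base_shape = base_shape,
                 level_cor = level_cor, seed = as.integer(seed)),
            class = "panel_gen_params")
}

# methylation level for one gene: mixture state from the shared uniform v,
# level from a quantile correlated across genes via a Gaussian copula
draw_panel_meth <- function(p_meth, v, u, params) {
  hyper <- v < p_meth
  ifelse(hyper,
         stats::qbeta(u, params$hyper_shape[1], params$hyper_shape[2]),
         stats::qbeta(u, params$base_shape[1], params$base_shape[2]))
}

#' Deterministic TRAIL-inhibition link
#'
#' Maps the two receptors' methylation fractions to expected percent
#' inhibition by rhsTRAIL through receptor availability
#' `s = max(1 - m_dr4, 1 - m_dr5)` (either death receptor suffices for
#' TRAIL-induced apoptosis): `100 * logistic(theta * (s - s0))`.
#'
#' @param m_dr4,m_dr5 Methylation fractions in `[0, 1]`. Vectorized.
#' @param theta Logistic steepness (default 10).
#' @param s0 Availability midpoint (default 0.5).
#' @return Expected percent inhibition in `(0, 100)`.
#' @export
trail_inhibition <- function(m_dr4, m_dr5, theta = 10, s0 = 0.5) {
  s <- pmax(1 - m_dr4, 1 - m_dr5)
  100 * stats::plogis(theta * (s - s0))
}

#' Simulate a TRAIL-sensitivity cell-line panel
#'
#' Generates a phenotype table for a panel of leukemia cell lines in which
#' promoter methylation of each death-receptor gene is drawn from a
#' karyotype-dependent mixture prior, relative mRNA expression decreases
#' log-linearly with methylation, cell-surface RFI tracks expression, and
#' percent inhibition by rhsTRAIL follows a logistic function of the best
#' available (least methylated) receptor.
#'
#' @param params A [panel_gen_params] object.
#' @return Data frame with one row per line: `sample_id`, `karyotype`,
#'   `dr4_pct`, `dr5_pct` (truth mean percent methylation), `expr_dr4`,
#'   `expr_dr5` (relative expression), `rfi_dr4`, `rfi_dr5`,
#'   `inhibition_pct`.
#' @export
simulate_panel <- function(params = panel_gen_params()) {
  stopifnot(inherits(params, "panel_gen_params"))
  set.seed(params$seed)
  g <- params$groups
  karyo <- rep(g$karyotype, g$n)
  n <- length(karyo)
  v <- runif(n)                       # shared mixture-state draw
  z <- rnorm(n)                       # shared level propensity
  r <- params$level_cor
  u4 <- stats::pnorm(r * z + sqrt(1 - r^2) * rnorm(n))
  u5 <- stats::pnorm(r * z + sqrt(1 - r^2) * rnorm(n))
  m4 <- draw_panel_meth(rep(g$p_meth_dr4, g$n), v, u4, params)
  m5 <- draw_panel_meth(rep(g$p_meth_dr5, g$n), v, u5, params)
  log_e4 <- params$alpha - params$beta * m4 + rnorm(n, 0, params$sigma_e)
  log_e5 <- params$alpha - params$beta * m5 + rnorm(n, 0, params$sigma_e)
  rfi4 <- 1 + params$rfi_gain * 10^log_e4 * exp(rnorm(n, 0, params$sigma_rfi))
  rfi5 <- 1 + params$rfi_gain * 10^log_e5 * exp(rnorm(n, 0, params$sigma_rfi))
  inh <- trail_inhibition(m4, m5, params$theta, params$s0) +
    rnorm(n, 0, params$sigma_t)
  inh <- pmin(pmax(inh, -10), 100)
  data.frame(sample_id = sprintf("line_%02d", seq_len(n)),
             karyotype = karyo,
             dr4_pct = 100 * m4, dr5_pct = 100 * m5,
             expr_dr4 = 10^log_e4, expr_dr5 = 10^log_e5,
             rfi_dr4 = rfi4, rfi_dr5 = rfi5,
             inhibition_pct = inh, stringsAsFactors = FALSE)
}

default_subtype_counts <- function() {
  c("high-hyperdiploid" = 187L, "ETV6-RUNX1" = 164L, "TCF3-PBX1" = 23L,
    "iAMP21" = 10L, "dic(9;20)" = 20L, "BCR-ABL1" = 19L, "MLLr" = 28L,
    "hypodiploid" = 5L, "polyploid" = 3L)
}

default_p_hyper <- function() {
  subtypes <- names(default_subtype_counts())
  dr4 <- setNames(numeric(length(subtypes)), subtypes)
  dr5 <- dr4
  dr4[c("TCF3-PBX1", "dic(9;20)", "MLLr", "hypodiploid")] <-
    c(1 / 23, 1 / 20, 2 / 28, 1 / 5)
  dr5[c("dic(9;20)", "MLLr", "hypodiploid")] <- c(5 / 20, 10 / 28, 1 / 5)
  list(dr4 = dr4, dr5 = dr5)
}

#' Parameters for the array-cohort generator
#'
#' Defaults emulate a 459-sample diagnostic BCP-ALL methylation-array cohort
#' in which promoter hypermethylation of the death-receptor genes is confined
#' to a few unfavorable karyotypes, remission samples sit at a 2-3% baseline,
#' and a minority of paired relapse samples gain methylation.
#'
#' @param subtype_counts Named integer vector of diagnostic sample counts per
#'   karyotype subtype.
#' @param p_hyper Named list with elements `dr4` and `dr5`: per-subtype
#'   probability that the gene promoter is hypermethylated.
#' @param baseline_mean,baseline_sd Gene-level beta distribution of
#'   unmethylated samples (truncated to `[0.001, 0.08]`); `baseline_sd` is
#'   the per-gene residual spread.
#' @param baseline_shared_sd Spread of a per-sample baseline propensity
#'   shared by both genes (array-wide sample effects); this is what couples
#'   the two genes' low-level methylation across a cohort. Set to 0 for
#'   fully independent genes.
#' @param hyper_mean,hyper_sd Gene-level beta distribution of hypermethylated
#'   samples (truncated to `[0.15, 0.95]`, keeping hypermethylated and
#'   baseline samples separated across the 10% reporting threshold).
#' @param probe_sd Per-probe jitter sd around the gene-level beta.
#' @param n_remission Number of remission samples.
#' @param n_pairs Number of diagnosis/relapse pairs.
#' @param p_relapse_up Probability that a gene unmethylated at diagnosis is
#'   hypermethylated at relapse within a pair.
#' @param n_decoys Number of decoy probes (other genes / non-TSS200 /
#'   non-island) added to the annotation.
#' @param share_hyper If `TRUE` (default) the two genes share one latent
#'   per-sample hypermethylation propensity, so hypermethylation co-occurs
#'   (comonotone coupling); if `FALSE` the genes are independent.
#' @param seed Integer seed.
#' @return A list of class `cohort_gen_params`.
#' @export
cohort_gen_params <- function(subtype_counts = default_subtype_counts(),
                              p_hyper = default_p_hyper(),
                              baseline_mean = 0.025, baseline_sd = 0.005,
                              baseline_shared_sd = 0.006,
                              hyper_mean = 0.30, hyper_sd = 0.10,
                              probe_sd = 0.01, n_remission = 20L,
                              n_pairs = 24L, p_relapse_up = 0.2,
                              n_decoys = 20L, share_hyper = TRUE,
                              seed = 1L) {
  stopifnot(all(subtype_counts >= 0L),
            all(unlist(p_hyper) >= 0), all(unlist(p_hyper) <= 1),
            p_relapse_up >= 0, p_relapse_up <= 1)
  structure(list(subtype_counts = subtype_counts, p_hyper = p_hyper,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 baseline_shared_sd = baseline_shared_sd,
                 hyper_mean = hyper_mean, hyper_sd = hyper_sd,
                 probe_sd = probe_sd, n_remission = as.integer(n_remission),
                 n_pairs = as.integer(n_pairs), p_relapse_up = p_relapse_up,
                 n_decoys = as.integer(n_decoys), share_hyper = share_hyper,
                 seed = as.integer(seed)),
            class = "cohort_gen_params")
}

draw_gene_beta <- function(hyper, params, shared = 0) {
  shared <- rep_len(shared, length(hyper))
  b <- numeric(length(hyper))
  b[hyper] <- pmin(pmax(rnorm(sum(hyper), params$hyper_mean,
                              params$hyper_sd), 0.15), 0.95)
  b[!hyper] <- pmin(pmax(params$baseline_mean + shared[!hyper] +
                           rnorm(sum(!hyper), 0, params$baseline_sd),
                         0.001), 0.08)
  b
}

#' Simulate a 450k-style methylation-array cohort
#'
#' Produces a probe-by-sample beta matrix, a sample table (subtype, phase,
#' pair id) and a probe annotation in which the death-receptor genes DR4 and
#' DR5 carry 6 and 5 TSS200 CpG-island probes respectively, plus decoy
#' probes that the TSS200-island selection rule must exclude.
#'
#' @param params A [cohort_gen_params] object.
#' @return List with `beta` (matrix, probes x samples), `samples`
#'   (data.frame: `sample_id`, `subtype`, `phase`, `pair_id`), `annotation`
#'   (data.frame: `probe_id`, `gene`, `feature_group`, `island_relation`),
#'   and `truth` (data.frame of per-sample gene-level hypermethylation flags
#'   and betas).
#' @export
simulate_array_cohort <- function(params = cohort_gen_params()) {
  stopifnot(inherits(params, "cohort_gen_params"))
  set.seed(params$seed)
  subtypes <- rep(names(params$subtype_counts), params$subtype_counts)
  n_diag <- length(subtypes)
  diag_ids <- sprintf("dx_%04d", seq_len(n_diag))

  u <- runif(n_diag)
  u2 <- if (params$share_hyper) u else runif(n_diag)
  hyper4 <- u < params$p_hyper$dr4[subtypes]
  hyper5 <- u2 < params$p_hyper$dr5[subtypes]
  z <- rnorm(n_diag, 0, params$baseline_shared_sd)
  beta4 <- draw_gene_beta(hyper4, params, z)
  beta5 <- draw_gene_beta(hyper5, params, z)

  samples <- data.frame(sample_id = diag_ids, subtype = subtypes,
                        phase = "diagnosis", pair_id = NA_character_,
                        stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = diag_ids, dr4_hyper = hyper4,
                      dr5_hyper = hyper5, dr4_beta = beta4, dr5_beta = beta5,
                      stringsAsFactors = FALSE)

  if (params$n_remission > 0L) {
    ids <- sprintf("rem_%03d", seq_len(params$n_remission))
    zr <- rnorm(params$n_remission, 0, params$baseline_shared_sd)
    b4 <- draw_gene_beta(rep(FALSE, params$n_remission), params, zr)
    b5 <- draw_gene_beta(rep(FALSE, params$n_remission), params, zr)
    samples <- rbind(samples,
                     data.frame(sample_id = ids, subtype = "remission",
                                phase = "remission", pair_id = NA_character_,
                                stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(sample_id = ids, dr4_hyper = FALSE,
                                     dr5_hyper = FALSE, dr4_beta = b4,
                                     dr5_beta = b5, stringsAsFactors = FALSE))
  }

  if (params$n_pairs > 0L) {
    pair_sub <- sample(names(params$subtype_counts), params$n_pairs,
                       replace = TRUE,
                       prob = params$subtype_counts / sum(params$subtype_counts))
    for (k in seq_len(params$n_pairs)) {
      pid <- sprintf("pair_%02d", k)
      up <- runif(1) < params$p_hyper$dr4[pair_sub[k]]
      up5 <- runif(1) < params$p_hyper$dr5[pair_sub[k]]
      zp <- rnorm(1, 0, params$baseline_shared_sd)
      dxb4 <- draw_gene_beta(up, params, zp)
      dxb5 <- draw_gene_beta(up5, params, zp)
      up_rel4 <- !up && runif(1) < params$p_relapse_up
      up_rel5 <- !up5 && runif(1) < params$p_relapse_up
      rlb4 <- if (up_rel4) draw_gene_beta(TRUE, params) else dxb4
      rlb5 <- if (up_rel5) draw_gene_beta(TRUE, params) else dxb5
      ids <- paste0(pid, c("_dx", "_rel"))
      samples <- rbind(samples,
                       data.frame(sample_id = ids, subtype = pair_sub[k],
                                  phase = c("diagnosis", "relapse"),
                                  pair_id = pid, stringsAsFactors = FALSE))
      truth <- rbind(truth,
                     data.frame(sample_id = ids,
                                dr4_hyper = c(up, up || up_rel4),
                                dr5_hyper = c(up5, up5 || up_rel5),
                                dr4_beta = c(dxb4, rlb4),
                                dr5_beta = c(dxb5, rlb5),
                                stringsAsFactors = FALSE))
    }
  }

  annotation <- rbind(
    data.frame(probe_id = sprintf("cg_DR4_%02d", 1:6), gene = "DR4",
               feature_group = "TSS200", island_relation = "Island",
               stringsAsFactors = FALSE),
    data.frame(probe_id = sprintf("cg_DR5_%02d", 1:5), gene = "DR5",
               feature_group = "TSS200", island_relation = "Island",
               stringsAsFactors = FALSE),
    # decoys: same genes but outside TSS200/island, plus unrelated genes
    data.frame(probe_id = c("cg_DR4_body1", "cg_DR4_shore1", "cg_DR5_ts1500"),
               gene = c("DR4", "DR4", "DR5"),
               feature_group = c("Body", "TSS200", "TSS1500"),
               island_relation = c("Island", "Shore", "Island"),
               stringsAsFactors = FALSE))
  if (params$n_decoys > 0L)
    annotation <- rbind(annotation,
      data.frame(probe_id = sprintf("cg_decoy_%03d", seq_len(params$n_decoys)),
                 gene = sprintf("GENE%d", seq_len(params$n_decoys)),
                 feature_group = sample(c("TSS200", "TSS1500", "Body"),
                                        params$n_decoys, replace = TRUE),
                 island_relation = sample(c("Island", "Shore", "Shelf",
                                            "OpenSea"),
                                          params$n_decoys, replace = TRUE),
                 stringsAsFactors = FALSE))

  n_all <- nrow(samples)
  beta <- matrix(NA_real_, nrow = nrow(annotation), ncol = n_all,
                 dimnames = list(annotation$probe_id, samples$sample_id))
  gene_beta <- rbind(DR4 = truth$dr4_beta, DR5 = truth$dr5_beta)
  target <- annotation$feature_group == "TSS200" &
    annotation$island_relation == "Island" & annotation$gene %in% c("DR4", "DR5")
  for (i in which(target)) {
    g <- annotation$gene[i]
    beta[i, ] <- pmin(pmax(gene_beta[g, ] + rnorm(n_all, 0, params$probe_sd),
                           0), 1)
  }
  for (i in which(!target))
    beta[i, ] <- pmin(pmax(rnorm(n_all, 0.05, 0.03), 0), 1)

  list(beta = beta, samples = samples, annotation = annotation, truth = truth)
}

#' Write a data frame as TSV with header
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a TSV with header
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
}
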