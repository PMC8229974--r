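# 450k-style array cohort stage: per-gene probe selection by annotation,
# per-sample mean methylation, subtype summaries and paired
# diagnosis/relapse comparison. Beta values are interpreted as fraction
# methylated; gene-level "percent methylation" is 100 x mean beta.

#' Select promoter CpG-island probes for a gene
#'
#' Keeps probes annotated to the gene with the requested feature group
#' (default TSS200, within 200 bases upstream of the transcription start
#' site) and, when `require_island` is set, relation-to-island `Island`.
#' Output order is stable by probe id.
#'
#' @param annotation Data frame with `probe_id`, `gene`, `feature_group`,
#'   `island_relation`.
#' @param gene Gene symbol.
#' @param feature_group Feature group to match (default `"TSS200"`).
#' @param require_island Require `island_relation == "Island"` (default
#'   `TRUE`).
#' @return Character vector of probe ids.
#' @export
select_probes <- function(annotation, gene, feature_group = "TSS200",
                          require_island = TRUE) {
  if (nrow(annotation) == 0L) stop("annotation is empty", call. = FALSE)
  keep <- annotation$gene == gene & annotation$feature_group == feature_group
  if (require_island) keep <- keep & annotation$island_relation == "Island"
  probes <- sort(annotation$probe_id[keep])
  if (length(probes) == 0L)
    stop("no probes for gene ", gene, " under the selection rule",
         call. = FALSE)
  probes
}

#' Per-sample gene methylation percent from a beta matrix
#'
#' 100 times the mean beta over the selected probes; missing betas are
#' excluded pairwise, and a sample is reported missing only when all its
#' probes are missing.
#'
#' @param beta_matrix Numeric matrix, probes x samples, entries in `[0, 1]`
#'   or `NA`.
#' @param probes Probe ids (subset of `rownames(beta_matrix)`).
#' @return Named numeric vector of percent methylation per sample.
#' @export
gene_methylation <- function(beta_matrix, probes) {
  if (length(probes) == 0L) stop("empty probe list", call. = FALSE)
  miss <- setdiff(probes, rownames(beta_matrix))
  if (length(miss))
    stop("probes absent from beta matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sub <- beta_matrix[probes, , drop = FALSE]
  if (any(sub < 0 | sub > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]", call. = FALSE)
  100 * colMeans(sub, na.rm = TRUE)
}

#' Per-subtype counts of samples above a methylation threshold
#'
#' @param gene_pct Named numeric vector of per-sample percent methylation
#'   (names are sample ids).
#' @param samples Sample table with `sample_id` and `subtype`.
#' @param threshold Percent threshold (default 10, counted inclusively).
#' @return List with `by_subtype` (data.frame: `subtype`, `n`, `n_above`,
#'   `fraction`) and `overall` (`n`, `n_above`, `percent`).
#' @export
subtype_summary <- function(gene_pct, samples, threshold = 10) {
  ids <- names(gene_pct)
  idx <- match(ids, samples$sample_id)
  if (anyNA(idx))
    stop("samples missing subtype: ",
         paste(head(ids[is.na(idx)], 5), collapse = ", "), call. = FALSE)
  subtype <- samples$subtype[idx]
  above <- !is.na(gene_pct) & gene_pct >= threshold
  n <- tapply(above, subtype, length)
  n_above <- tapply(above, subtype, sum)
  by_sub <- data.frame(subtype = names(n), n = as.integer(n),
                       n_above = as.integer(n_above),
                       fraction = as.numeric(n_above / n),
                       stringsAsFactors = FALSE)
  rownames(by_sub) <- NULL
  list(by_subtype = by_sub[order(by_sub$subtype), ],
       overall = list(n = length(above), n_above = sum(above),
                      percent = 100 * mean(above)))
}

#' Paired diagnosis/relapse methylation change
#'
#' One row per pair: percent methylation at diagnosis and at relapse, their
#' difference, and an upregulated flag when the gain exceeds the margin.
#'
#' @param gene_pct Named numeric vector of per-sample percent methylation.
#' @param samples Sample table with `sample_id`, `phase` and `pair_id`; each
#'   pair id must label exactly one diagnosis and one relapse sample.
#' @param margin Gain (percentage points) above which a pair is flagged
#'   upregulated (default 5).
#' @return Data frame: `pair_id`, `diagnosis_pct`, `relapse_pct`, `delta`,
#'   `upregulated`.
#' @export
paired_delta <- function(gene_pct, samples, margin = 5) {
  paired <- samples[!is.na(samples$pair_id) & samples$pair_id != "", ]
  if (nrow(paired) == 0L) stop("no paired samples", call. = FALSE)
  out <- lapply(split(paired, paired$pair_id), function(p) {
    dx <- p$sample_id[p$phase == "diagnosis"]
    rl <- p$sample_id[p$phase == "relapse"]
    if (length(dx) != 1L || length(rl) != 1L)
      stop("broken pair: ", p$pair_id[1], call. = FALSE)
    data.frame(pair_id = p$pair_id[1],
               diagnosis_pct = unname(gene_pct[dx]),
               relapse_pct = unname(gene_pct[rl]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$delta <- out$relapse_pct - out$diagnosis_pct
  out$upregulated <- out$delta > margin
  out
}

#' Correlation between two genes' methylation across a cohort
#'
#' Spearman correlation of log10-floored percent methylation; see
#' [spearman_cor()] and [log10_percent()].
#'
#' @param dr4_pct,dr5_pct Paired per-sample percent vectors.
#' @param floor Zero floor for the log transform.
#' @return A `correlation_result`.
#' @export
cohort_correlation <- function(dr4_pct, dr5_pct, floor = 0.1) {
  spearman_cor(log10_percent(dr4_pct, floor), log10_percent(dr5_pct, floor))
}

#' Read a beta-value matrix from TSV
#'
#' Expects probes as rows with a `probe_id` first column and sample ids as
#' the remaining column names.
#'
#' @param path TSV path.
#' @return Numeric matrix, probes x samples.
#' @export
read_beta_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, setdiff(names(df), "probe_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$probe_id
  m
}

#' Full cohort analysis for the two death-receptor genes
#'
#' Selects TSS200 CpG-island probes for DR4 and DR5, computes per-sample
#' gene methylation, per-subtype >= threshold counts over diagnostic
#' samples, the between-gene correlation, and the paired diagnosis/relapse
#' deltas.
#'
#' @param beta Beta matrix (probes x samples).
#' @param samples Sample table (`sample_id`, `subtype`, `phase`, `pair_id`).
#' @param annotation Probe annotation table.
#' @param genes Gene symbols to analyze (default DR4, DR5).
#' @param threshold Reporting threshold in percent (default 10).
#' @param margin Paired upregulation margin (default 5).
#' @return List with `gene_pct` (data.frame sample x genes), `summaries`
#'   (per-gene subtype summaries over diagnosis-phase samples),
#'   `correlation` and `pairs` (per-gene paired deltas, `NULL` if no pairs).
#' @export
analyze_cohort <- function(beta, samples, annotation,
                           genes = c("DR4", "DR5"), threshold = 10,
                           margin = 5) {
  pct <- lapply(genes, function(g)
    gene_methylation(beta, select_probes(annotation, g)))
  names(pct) <- genes
  gene_pct <- data.frame(sample_id = colnames(beta), stringsAsFactors = FALSE)
  for (g in genes) gene_pct[[g]] <- unname(pct[[g]][gene_pct$sample_id])

  is_dx <- samples$phase == "diagnosis" & is.na(samples$pair_id)
  dx_ids <- samples$sample_id[is_dx]
  summaries <- lapply(genes, function(g)
    subtype_summary(pct[[g]][dx_ids], samples, threshold))
  names(summaries) <- genes

  correlation <- if (length(genes) == 2L)
    cohort_correlation(pct[[genes[1]]][dx_ids], pct[[genes[2]]][dx_ids])
  else NULL

  pairs <- NULL
  if (any(!is.na(samples$pair_id) & samples$pair_id != "")) {
    pairs <- lapply(genes, function(g) paired_delta(pct[[g]], samples, margin))
    names(pairs) <- genes
  }
  list(gene_pct = gene_pct, summaries = summaries,
       correlation = correlation, pairs = pairs)
}
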