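# Rank-based association statistics used throughout the analysis:
# log-scale transformation of percents, Spearman correlation reported as
# R^2 = rho^2, Mann-Whitney U, Fisher's exact and chi-square tests.
# Two-sided tests throughout; no multiple-testing correction is applied.

#' Log10-transform a methylation percent with a zero floor
#'
#' Percents below the floor (default 0.1%) are set to the floor before
#' taking log10; at the default 100x minimum coverage, percents below
#' 1/coverage are not distinguishable from zero anyway.
#'
#' @param pct Percent in `[0, 100]`. Vectorized.
#' @param floor Positive floor (default 0.1).
#' @return log10 of the floored percent.
#' @export
log10_percent <- function(pct, floor = 0.1) {
  if (floor <= 0) stop("floor must be > 0", call. = FALSE)
  if (any(pct < 0 | pct > 100))
    stop("percent must lie in [0, 100]", call. = FALSE)
  log10(pmax(pct, floor))
}

#' Spearman rank correlation with R-squared reporting
#'
#' Rho is the Pearson correlation of average (tie-corrected) ranks; the
#' two-sided p-value uses the t-distribution approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom.
#' The squared coefficient is reported alongside, matching the convention of
#' labeling rank-correlation strength as R^2.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List of class `correlation_result`: `rho`, `r_squared`, `p_value`,
#'   `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("undefined correlation: constant vector", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, r_squared = rho^2, p_value = p, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (R^2 = %.3f), p = %.4g, n = %d\n",
              x$rho, x$r_squared, x$p_value, x$n))
  invisible(x)
}

# exact two-sided Mann-Whitney p by enumeration of all rank assignments
# (handles ties through average ranks); feasible for n1 + n2 <= ~12
mw_exact_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2L, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with average ranks for ties. The two-sided
#' p-value is exact (full enumeration of rank assignments, valid under ties)
#' when n1 + n2 <= 10, and otherwise uses the normal approximation with tie
#' and continuity corrections.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return List of class `group_test_result`: `statistic` (U for group_a),
#'   `p_value`, `n1`, `n2`, `method`.
#' @export
mann_whitney <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= 10L) {
    p <- mw_exact_p(a, b)
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    p <- if (sigma2 == 0) 1 else
      2 * stats::pnorm(-max(abs(u - n1 * n2 / 2) - 0.5, 0) / sqrt(sigma2))
    p <- min(p, 1)
    method <- "normal approximation"
  }
  structure(list(statistic = u, p_value = p, n1 = n1, n2 = n2,
                 method = method),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), p = %.4g (%s)\n",
              x$statistic, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

check_table <- function(tab, min_dim = 2L) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must contain non-negative integer counts", call. = FALSE)
  if (nrow(tab) < min_dim || ncol(tab) < min_dim)
    stop("table must be at least ", min_dim, "x", min_dim, call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: zero margin", call. = FALSE)
  tab
}

#' Fisher's exact test (two-sided) on a 2x2 table
#'
#' Two-sided p is the sum of hypergeometric probabilities of all tables with
#' the observed margins whose probability does not exceed the observed
#' table's.
#'
#' @param table_2x2 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table_2x2) {
  tab <- check_table(table_2x2)
  if (nrow(tab) != 2L || ncol(tab) != 2L)
    stop("fisher_exact expects a 2x2 table", call. = FALSE)
  stats::fisher.test(tab)$p.value
}

#' Pearson chi-square test on an r x c table
#'
#' No continuity correction; df = (r - 1)(c - 1).
#'
#' @param table_rxc Matrix of non-negative integer counts, at least 2x2.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(table_rxc) {
  tab <- check_table(table_rxc)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' Association report for a cell-line panel
#'
#' Computes, per receptor, the Spearman correlation of log10 percent
#' methylation with log10 relative expression, with cell-surface RFI and
#' with percent inhibition by rhsTRAIL, and Mann-Whitney comparisons of
#' inhibition between methylation categories (unmethylated or
#' DR4-preferentially unmethylated vs the rest, and highly methylated vs the
#' rest).
#'
#' @param panel Phenotype data frame with columns `dr4_pct`, `dr5_pct`,
#'   `expr_dr4`, `expr_dr5`, `rfi_dr4`, `rfi_dr5`, `inhibition_pct`.
#' @param floor Zero floor passed to [log10_percent()].
#' @return Tidy data frame: `comparison`, `n` (or n1/n2), `rho`, `r_squared`,
#'   `statistic`, `p_value`.
#' @export
associate_panel <- function(panel, floor = 0.1) {
  need <- c("dr4_pct", "dr5_pct", "expr_dr4", "expr_dr5", "rfi_dr4",
            "rfi_dr5", "inhibition_pct")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  rows <- list()
  add_cor <- function(label, x, y) {
    r <- spearman_cor(x, y)
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = label, n = r$n, rho = r$rho, r_squared = r$r_squared,
      statistic = NA_real_, p_value = r$p_value, stringsAsFactors = FALSE)
  }
  for (g in c("dr4", "dr5")) {
    lm <- log10_percent(panel[[paste0(g, "_pct")]], floor)
    add_cor(paste0(g, "_meth_vs_expression"),
            lm, log10(panel[[paste0("expr_", g)]]))
    add_cor(paste0(g, "_meth_vs_rfi"), lm, panel[[paste0("rfi_", g)]])
    add_cor(paste0(g, "_meth_vs_inhibition"), lm, panel$inhibition_pct)
  }
  add_cor("dr4_meth_vs_dr5_meth",
          log10_percent(panel$dr4_pct, floor),
          log10_percent(panel$dr5_pct, floor))
  cls <- classify_methylation(panel$dr4_pct, panel$dr5_pct)
  avail_unmeth <- cls$category %in% c("UNMETHYLATED", "DR4_PREF_UNMETH")
  add_mw <- function(label, sel) {
    if (!any(sel) || all(sel)) return(invisible())
    mw <- mann_whitney(panel$inhibition_pct[sel], panel$inhibition_pct[!sel])
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = label, n = mw$n1 + mw$n2, rho = NA_real_,
      r_squared = NA_real_, statistic = mw$statistic, p_value = mw$p_value,
      stringsAsFactors = FALSE)
  }
  add_mw("inhibition_dr4avail_vs_rest", avail_unmeth)
  add_mw("inhibition_highly_meth_vs_rest", cls$highly_methylated)
  do.call(rbind, rows)
}
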