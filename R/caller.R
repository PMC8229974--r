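# Bisulfite-aware global alignment and per-CpG methylation calling.
#
# A bisulfite read can come from either strand of the amplicon. Reads from
# the top strand show C->T conversions relative to the unconverted reference;
# reads from the bottom strand, once in top orientation, show G->A
# conversions. The aligner therefore scores each read (in both orientations)
# under two asymmetric substitution models and keeps the best of the four.

bisulfite_score_matrix <- function(model = c("top", "bottom")) {
  model <- match.arg(model)
  b <- c("A", "C", "G", "T", "N")
  mat <- matrix(-1, 5, 5, dimnames = list(b, b))  # mat[read, ref]
  diag(mat) <- 1
  mat["N", ] <- -1; mat[, "N"] <- -1              # N never matches
  if (model == "top") mat["T", "C"] <- 1 else mat["A", "G"] <- 1
  mat
}

# Walk one gapped global alignment (pattern = read, subject = reference) and
# return the read base observed at each reference position; "-" marks a
# deletion, NA a reference position the read does not cover.
walk_alignment <- function(pat, subj, ref_len) {
  p <- strsplit(pat, "", fixed = TRUE)[[1]]
  s <- strsplit(subj, "", fixed = TRUE)[[1]]
  keep <- s != "-"
  out <- rep(NA_character_, ref_len)
  out[cumsum(keep)[keep]] <- p[keep]
  out
}

BASES5 <- c("A", "C", "G", "T", "N")
COMPLEMENT5 <- c(4L, 3L, 2L, 1L, 5L)

#' Align bisulfite reads to an amplicon
#'
#' Globally aligns each read against the unconverted amplicon sequence under
#' four hypotheses (read as given or reverse-complemented, under a top-strand
#' model where reference C matches read C or T at no penalty, or a
#' bottom-strand model where reference G matches read G or A), and keeps the
#' highest-scoring one. Scoring is match +1, mismatch -1, linear gap penalty
#' -2. Reads whose length equals the reference are scored by the ungapped
#' (substitution-only) alignment, which is optimal for them unless they are
#' heavily mutated; length-mismatched or poorly scoring reads go through the
#' full gapped alignment.
#'
#' @param reads Data frame with `read_id` and `sequence`, or a character
#'   vector of sequences.
#' @param amplicon An [amplicon_spec].
#' @return A list with `strand` (character, `"top"`/`"bottom"` per read),
#'   `base_at_ref` (reads x reference-positions character matrix of observed
#'   read bases, `"-"` for deletion, `NA` for uncovered), `score` and
#'   `read_length`.
#' @export
align_reads <- function(reads, amplicon) {
  stopifnot(inherits(amplicon, "amplicon_spec"))
  if (is.character(reads))
    reads <- data.frame(read_id = sprintf("read_%d", seq_along(reads)),
                        sequence = reads, stringsAsFactors = FALSE)
  n <- nrow(reads)
  if (n == 0L) stop("no reads", call. = FALSE)
  L <- nchar(amplicon$sequence)
  ref_int <- match(strsplit(amplicon$sequence, "", fixed = TRUE)[[1]], BASES5)
  score_mats <- list(top = bisulfite_score_matrix("top"),
                     bottom = bisulfite_score_matrix("bottom"))
  model_of <- c("top", "bottom", "top", "bottom")
  rc_of <- c(FALSE, FALSE, TRUE, TRUE)

  strand <- character(n)
  best_score <- numeric(n)
  base_at_ref <- matrix(NA_character_, nrow = n, ncol = L,
                        dimnames = list(reads$read_id, NULL))
  read_len <- nchar(reads$sequence)

  fast <- which(read_len == L)
  slow <- which(read_len != L)
  if (length(fast)) {
    rm <- matrix(match(unlist(strsplit(reads$sequence[fast], "", fixed = TRUE)),
                       BASES5), nrow = L)
    rc <- matrix(COMPLEMENT5[rm[rev(seq_len(L)), , drop = FALSE]], nrow = L)
    ref_rep <- rep.int(ref_int, length(fast))
    sc <- sapply(seq_len(4L), function(k) {
      orient <- if (rc_of[k]) rc else rm
      colSums(matrix(score_mats[[model_of[k]]][cbind(c(orient), ref_rep)],
                     nrow = L))
    })
    if (length(fast) == 1L) sc <- matrix(sc, nrow = 1L)
    best <- max.col(sc, ties.method = "first")
    bscore <- sc[cbind(seq_along(fast), best)]
    # ungapped score below L/2 (>25% mismatches): retry with gaps allowed
    redo <- bscore < L / 2
    keep <- !redo
    if (any(keep)) {
      ki <- fast[keep]
      strand[ki] <- model_of[best[keep]]
      best_score[ki] <- bscore[keep]
      for (j in which(keep)) {
        orient <- if (rc_of[best[j]]) rc[, j] else rm[, j]
        base_at_ref[fast[j], ] <- BASES5[orient]
      }
    }
    slow <- c(slow, fast[redo])
  }

  if (length(slow)) {
    ref <- Biostrings::DNAString(amplicon$sequence)
    fwd <- Biostrings::DNAStringSet(reads$sequence[slow])
    rcs <- Biostrings::reverseComplement(fwd)
    alns <- lapply(seq_len(4L), function(k)
      Biostrings::pairwiseAlignment(
        pattern = if (rc_of[k]) rcs else fwd, subject = ref,
        substitutionMatrix = score_mats[[model_of[k]]],
        gapOpening = 0, gapExtension = 2, type = "global"))
    scores <- vapply(alns, BiocGenerics::score, numeric(length(slow)))
    if (length(slow) == 1L) scores <- matrix(scores, nrow = 1L)
    best <- max.col(scores, ties.method = "first")
    for (k in seq_len(4L)) {
      idx <- which(best == k)
      if (!length(idx)) next
      sub <- alns[[k]][idx]
      pats <- as.character(Biostrings::alignedPattern(sub))
      subs <- as.character(Biostrings::alignedSubject(sub))
      for (j in seq_along(idx))
        base_at_ref[slow[idx[j]], ] <- walk_alignment(pats[j], subs[j], L)
    }
    strand[slow] <- model_of[best]
    best_score[slow] <- scores[cbind(seq_along(slow), best)]
  }

  list(strand = strand, base_at_ref = base_at_ref, score = best_score,
       read_length = read_len, read_id = reads$read_id)
}

#' Call per-read methylation states from alignments
#'
#' For a top-strand read, the base observed at a CpG cytosine is read as
#' methylated (C), unmethylated (T) or uninformative (anything else / gap);
#' a bottom-strand read is read at the CpG guanine (G methylated, A
#' unmethylated). Conversion efficiency is the fraction of non-CpG reference
#' cytosines (top) or guanines (bottom) observed converted, among those
#' observed in either state; identity is the match fraction over aligned
#' positions whose reference base is not bisulfite-ambiguous under the
#' chosen model.
#'
#' @param alignment Result of [align_reads()].
#' @param amplicon An [amplicon_spec].
#' @return A list with `calls` (data.frame: `read_id`, `strand`, `length`,
#'   `identity`, `conversion_efficiency`) and `states` (reads x CpG-sites
#'   character matrix with values `"M"`, `"U"`, `"N"`).
#' @export
call_reads <- function(alignment, amplicon) {
  stopifnot(inherits(amplicon, "amplicon_spec"))
  ref <- strsplit(amplicon$sequence, "", fixed = TRUE)[[1]]
  L <- length(ref)
  off <- amplicon$cpg_offsets
  S <- length(off)
  n <- nrow(alignment$base_at_ref)
  cpg_c <- off + 1L          # 1-based position of CpG C
  cpg_g <- off + 2L          # 1-based position of CpG G
  noncpg_c <- setdiff(which(ref == "C"), cpg_c)
  noncpg_g <- setdiff(which(ref == "G"), cpg_g)

  states <- matrix("N", nrow = n, ncol = S,
                   dimnames = list(alignment$read_id,
                                   if (S) sprintf("site_%d", seq_len(S))))
  identity <- numeric(n)
  conv <- numeric(n)
  for (i in seq_len(n)) {
    b <- alignment$base_at_ref[i, ]
    top <- alignment$strand[i] == "top"
    if (S) {
      obs <- b[if (top) cpg_c else cpg_g]
      st <- rep("N", S)
      if (top) {
        st[!is.na(obs) & obs == "C"] <- "M"
        st[!is.na(obs) & obs == "T"] <- "U"
      } else {
        st[!is.na(obs) & obs == "G"] <- "M"
        st[!is.na(obs) & obs == "A"] <- "U"
      }
      states[i, ] <- st
    }
    qpos <- if (top) noncpg_c else noncpg_g
    qb <- b[qpos]
    conv_base <- if (top) "T" else "A"
    ret_base <- if (top) "C" else "G"
    n_conv <- sum(qb == conv_base, na.rm = TRUE)
    n_ret <- sum(qb == ret_base, na.rm = TRUE)
    conv[i] <- if (n_conv + n_ret == 0L) NA_real_ else n_conv / (n_conv + n_ret)
    amb <- if (top) "C" else "G"
    scored <- which(ref != amb & !is.na(b) & b != "-")
    identity[i] <- if (length(scored) == 0L) NA_real_ else
      mean(b[scored] == ref[scored])
  }
  list(calls = data.frame(read_id = alignment$read_id,
                          strand = alignment$strand,
                          length = alignment$read_length,
                          identity = identity,
                          conversion_efficiency = conv,
                          stringsAsFactors = FALSE),
       states = states)
}

#' Filter read calls on identity, conversion efficiency and length
#'
#' A read passes iff identity >= `min_identity`, conversion efficiency >=
#' `min_conversion` and length >= `min_length`. Each failing read is counted
#' under its first failing rule, in that order. A read with no informative
#' QC positions (NA identity or conversion) fails the corresponding rule.
#'
#' @param calls The `calls` data frame from [call_reads()].
#' @param min_identity Minimum match fraction over non-bisulfite positions
#'   (default 0.90).
#' @param min_conversion Minimum conversion efficiency (default 0.90).
#' @param min_length Minimum read length (default 50).
#' @return List with `pass` (logical vector), `reason` (character,
#'   `"pass"`/`"identity"`/`"conversion"`/`"length"`) and `report` (named
#'   integer counts).
#' @export
filter_reads <- function(calls, min_identity = 0.90, min_conversion = 0.90,
                         min_length = 50L) {
  fail_id <- is.na(calls$identity) | calls$identity < min_identity
  fail_cv <- is.na(calls$conversion_efficiency) |
    calls$conversion_efficiency < min_conversion
  fail_ln <- calls$length < min_length
  reason <- rep("pass", nrow(calls))
  reason[fail_ln] <- "length"
  reason[fail_cv] <- "conversion"
  reason[fail_id] <- "identity"     # first in precedence order wins
  pass <- reason == "pass"
  report <- c(identity = sum(reason == "identity"),
              conversion = sum(reason == "conversion"),
              length = sum(reason == "length"))
  list(pass = pass, reason = reason, report = report)
}

#' Summarize per-CpG methylation over passing reads
#'
#' Tallies methylated (M) and unmethylated (U) calls per CpG site, ignoring
#' uninformative (N) calls, and reports percent methylation per site plus
#' the unweighted mean percent over sites meeting the coverage requirement.
#'
#' @param states Reads x sites state matrix (`"M"`/`"U"`/`"N"`) of passing
#'   reads.
#' @param amplicon An [amplicon_spec].
#' @param min_coverage Minimum informative calls for a site to be reported
#'   (default 100); below it the site percent is `NA` and the site is
#'   excluded from the mean.
#' @return List with `sites` (data.frame: `site_index`, `offset`, `coverage`,
#'   `n_methylated`, `percent`) and `mean_percent` (unweighted mean over
#'   qualifying sites).
#' @export
summarize_calls <- function(states, amplicon, min_coverage = 100L) {
  stopifnot(inherits(amplicon, "amplicon_spec"))
  S <- length(amplicon$cpg_offsets)
  if (is.null(dim(states))) states <- matrix(states, ncol = S)
  n_m <- colSums(states == "M")
  n_u <- colSums(states == "U")
  coverage <- n_m + n_u
  percent <- ifelse(coverage >= min_coverage, 100 * n_m / pmax(coverage, 1L),
                    NA_real_)
  sites <- data.frame(site_index = seq_len(S),
                      offset = amplicon$cpg_offsets,
                      coverage = as.integer(coverage),
                      n_methylated = as.integer(n_m),
                      percent = percent)
  if (all(is.na(percent)))
    stop("insufficient coverage: no site reaches min_coverage", call. = FALSE)
  list(sites = sites, mean_percent = mean(percent, na.rm = TRUE))
}

#' Caller parameters
#'
#' @param min_identity,min_conversion,min_length Read filters; see
#'   [filter_reads()].
#' @param min_coverage Site coverage requirement; see [summarize_calls()].
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(min_identity = 0.90, min_conversion = 0.90,
                          min_length = 50L, min_coverage = 100L) {
  structure(list(min_identity = min_identity, min_conversion = min_conversion,
                 min_length = as.integer(min_length),
                 min_coverage = as.integer(min_coverage)),
            class = "caller_params")
}

#' Quantify amplicon methylation from bisulfite reads
#'
#' End-to-end composition of alignment, per-read calling, QC filtering and
#' per-site summarization. Percent estimates are reported raw: incomplete
#' conversion inflates unmethylated-site estimates by roughly
#' `(1 - conversion rate) * 100` percentage points, and no correction is
#' applied.
#'
#' @param reads FASTQ path or data frame with `read_id` and `sequence`.
#' @param amplicon An [amplicon_spec].
#' @param params A [caller_params] object.
#' @return An object of class `meth_result`: list with `sample` (optional
#'   label), `amplicon_name`, `sites` (per-site summary data frame),
#'   `mean_percent`, `n_reads_total`, `n_reads_pass`, `filter_counts`,
#'   `calls` and `states` of passing reads.
#' @export
quantify_methylation <- function(reads, amplicon, params = caller_params()) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  if (is.null(nrow(reads)) || nrow(reads) == 0L)
    stop("no reads", call. = FALSE)
  aln <- align_reads(reads, amplicon)
  called <- call_reads(aln, amplicon)
  flt <- filter_reads(called$calls, params$min_identity,
                      params$min_conversion, params$min_length)
  states_pass <- called$states[flt$pass, , drop = FALSE]
  summ <- summarize_calls(states_pass, amplicon, params$min_coverage)
  structure(list(amplicon_name = amplicon$name,
                 sites = summ$sites,
                 mean_percent = summ$mean_percent,
                 n_reads_total = nrow(reads),
                 n_reads_pass = sum(flt$pass),
                 filter_counts = flt$report,
                 calls = called$calls[flt$pass, , drop = FALSE],
                 states = states_pass),
            class = "meth_result")
}

#' @export
print.meth_result <- function(x, ...) {
  cat(sprintf("Methylation call for amplicon '%s'\n", x$amplicon_name))
  cat(sprintf("  reads: %d total, %d passing QC (failed: %s)\n",
              x$n_reads_total, x$n_reads_pass,
              paste(sprintf("%s %d", names(x$filter_counts),
                            x$filter_counts), collapse = ", ")))
  cat(sprintf("  mean percent methylation: %.2f%%\n", x$mean_percent))
  invisible(x)
}

#' @export
summary.meth_result <- function(object, ...) {
  print(object)
  cat("  per-site summary:\n")
  print(object$sites, row.names = FALSE)
  invisible(object$sites)
}
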