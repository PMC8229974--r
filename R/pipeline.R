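# End-to-end pipeline: simulate -> call -> classify -> associate -> cohort,
# driven by a single serializable config so a run can be reproduced exactly
# from its emitted config file.

#' Construct a synthetic amplicon with a chosen number of CpG sites
#'
#' Builds a random amplicon whose interior carries exactly `n_cpg` planted
#' CpG dinucleotides separated by spacers that contain non-CpG cytosines
#' (needed for conversion-efficiency QC) but never a CG, flanked by C-free
#' primer regions, so the bisulfite-space primers are the regions themselves
#' (no C to convert) and are guaranteed CG-free.
#'
#' @param name Amplicon name.
#' @param n_cpg Number of CpG sites.
#' @param primer_len Primer length (default 20).
#' @param spacer Spacer length between CpG sites (default 12).
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @return An [amplicon_spec].
#' @export
synthetic_amplicon <- function(name = "synthetic", n_cpg = 6L,
                               primer_len = 20L, spacer = 12L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pick <- function(k) paste(sample(c("A", "G", "T"), k, replace = TRUE),
                            collapse = "")
  # spacer: any base, but never C directly before G (no accidental CpG) and
  # never a trailing C (the next block may start with G)
  pick_spacer <- function(k) {
    ch <- character(k)
    prev <- "A"
    for (j in seq_len(k)) {
      allowed <- c("A", "C", "G", "T")
      if (prev == "C") allowed <- setdiff(allowed, "G")
      if (j == k) allowed <- setdiff(allowed, "C")
      ch[j] <- sample(allowed, 1L)
      prev <- ch[j]
    }
    paste(ch, collapse = "")
  }
  fwd_region <- pick(primer_len)
  rev_region <- pick(primer_len)
  body <- paste0(vapply(seq_len(n_cpg), function(i)
    paste0(pick_spacer(spacer), "CG"), character(1)), collapse = "")
  sequence <- paste0(fwd_region, body, pick_spacer(spacer), rev_region)
  amplicon_spec(name, sequence,
                fwd_primer = fwd_region,
                rev_primer = reverse_complement(rev_region))
}

#' Assemble a per-sample x per-site percent-methylation matrix
#'
#' One row per sample, one column per CpG site; sites below the coverage
#' requirement appear as `NA` (written as empty cells in TSV). All results
#' must come from the same amplicon.
#'
#' @param results Named list of `meth_result` objects (names are sample
#'   labels).
#' @return Numeric matrix, samples x sites.
#' @export
heatmap_matrix <- function(results) {
  if (length(results) == 0L) stop("no results", call. = FALSE)
  amps <- vapply(results, function(r) r$amplicon_name, character(1))
  ns <- vapply(results, function(r) nrow(r$sites), integer(1))
  if (length(unique(amps)) != 1L || length(unique(ns)) != 1L)
    stop("results come from different amplicons", call. = FALSE)
  mat <- t(vapply(results, function(r) r$sites$percent, numeric(ns[1])))
  rownames(mat) <- names(results)
  colnames(mat) <- sprintf("site_%d", seq_len(ns[1]))
  mat
}

#' Default pipeline configuration
#'
#' Two synthetic amplicons shaped like the DR4 (6 CpG) and DR5 (13 CpG)
#' promoter amplicons, a 32-line panel and a full array cohort.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @return A config list accepted by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    amplicons = list(
      list(name = "DR4_like", n_cpg = 6,
           profile = c(0, 0, 0.30, 0.30, 0.90, 0.94)),
      list(name = "DR5_like", n_cpg = 13,
           profile = rep(c(0.02, 0.5, 0.9), length.out = 13))),
    read_sim = list(n_reads = 400),
    caller = list(min_coverage = 50),
    panel = list(),
    cohort = list(),
    stages = list(simulate = TRUE, cohort = TRUE))
}

merge_params <- function(constructor, overrides, ...) {
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  do.call(constructor, c(overrides, list(...)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> call -> classify -> associate -> cohort
#' (optional), writing every stage's TSV/JSON outputs plus a manifest with
#' the package version, seed and config hash under `out_dir`. Any stage
#' error aborts with the stage name and reason. A run re-executed from its
#' emitted `config.json` is byte-identical.
#'
#' @param config Config list (see [default_run_config()]) or path to a JSON
#'   config file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = "amplimeth_run") {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stage <- function(nm, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", nm, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[amplimeth] stage %-9s %.2fs", nm,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  outputs <- character(0)
  emit <- function(x, fname, writer = write_tsv) {
    path <- file.path(out_dir, fname)
    writer(x, path)
    outputs <<- c(outputs, fname)
    path
  }

  amp_defs <- config$amplicons
  if (is.data.frame(amp_defs)) amp_defs <- split(amp_defs, seq_len(nrow(amp_defs)))
  amps <- list()
  fastqs <- character(0)
  panel <- NULL; cohort <- NULL
  do_sim <- isTRUE(config$stages$simulate %||% TRUE)
  if (do_sim) {
    stage("simulate", {
      for (i in seq_along(amp_defs)) {
        d <- as.list(amp_defs[[i]])
        amp <- synthetic_amplicon(d$name, as.integer(d$n_cpg),
                                  seed = seed + i)
        amps[[d$name]] <- amp
        rs <- merge_params(read_sim_params, config$read_sim %||% list(),
                           seed = seed + 100L + i)
        sim <- simulate_reads(amp, unlist(d$profile), rs)
        emit(amp, paste0(d$name, ".amplicon.json"), write_amplicon_json)
        fastqs[[d$name]] <- emit(sim$reads, paste0(d$name, ".fastq"),
                                 write_fastq)
        emit(sim$truth, paste0(d$name, ".truth.tsv"))
      }
      panel <- simulate_panel(merge_params(panel_gen_params,
                                           config$panel %||% list(),
                                           seed = seed + 200L))
      emit(panel, "panel.tsv")
      cohort <- simulate_array_cohort(merge_params(cohort_gen_params,
                                                   config$cohort %||% list(),
                                                   seed = seed + 300L))
      emit(data.frame(probe_id = rownames(cohort$beta), cohort$beta,
                      check.names = FALSE), "cohort_beta.tsv")
      emit(cohort$samples, "cohort_samples.tsv")
      emit(cohort$annotation, "cohort_annotation.tsv")
      NULL
    })
  } else {
    # externally supplied inputs: amplicon JSON + FASTQ per amplicon,
    # phenotype TSV, and optionally the three cohort tables
    for (d in amp_defs) {
      d <- as.list(d)
      amps[[d$name]] <- read_amplicon_json(d$spec)
      fastqs[[d$name]] <- d$fastq %||% ""
    }
    panel <- read_tsv(config$panel_tsv)
    if (!is.null(config$cohort_beta))
      cohort <- list(beta = read_beta_matrix(config$cohort_beta),
                     samples = read_tsv(config$cohort_samples),
                     annotation = read_tsv(config$cohort_annotation))
  }

  cp <- merge_params(caller_params, config$caller %||% list())
  calls <- stage("call", {
    res <- lapply(names(amps), function(nm) {
      fq <- fastqs[[nm]]
      if (is.null(fq) || !nzchar(fq) || !file.exists(fq))
        stop("missing FASTQ for amplicon ", nm)
      r <- quantify_methylation(fq, amps[[nm]], cp)
      emit(r$sites, paste0(nm, ".sites.tsv"))
      emit(list(amplicon = nm, mean_percent = r$mean_percent,
                n_reads_total = r$n_reads_total,
                n_reads_pass = r$n_reads_pass,
                filter_counts = as.list(r$filter_counts)),
           paste0(nm, ".summary.json"),
           function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                               digits = NA))
      r
    })
    names(res) <- names(amps)
    res
  })

  classified <- stage("classify", {
    cl <- classify_panel(panel)
    emit(cl, "panel_classified.tsv")
    cl
  })

  assoc <- stage("associate", {
    a <- associate_panel(panel)
    emit(a, "panel_associations.tsv")
    a
  })

  cohort_res <- NULL
  if (isTRUE(config$stages$cohort %||% TRUE) && !is.null(cohort)) {
    cohort_res <- stage("cohort", {
      cr <- analyze_cohort(cohort$beta, cohort$samples, cohort$annotation)
      emit(cr$gene_pct, "cohort_gene_pct.tsv")
      for (g in names(cr$summaries))
        emit(cr$summaries[[g]]$by_subtype,
             paste0("cohort_subtype_", g, ".tsv"))
      if (!is.null(cr$pairs))
        for (g in names(cr$pairs))
          emit(cr$pairs[[g]], paste0("cohort_pairs_", g, ".tsv"))
      cr
    })
  }

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    package = "amplimeth",
    version = as.character(utils::packageVersion("amplimeth")),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    stages = c(if (do_sim) "simulate", "call", "classify", "associate",
               if (!is.null(cohort_res)) "cohort"),
    outputs = sort(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(amplicons = amps, calls = calls, panel = classified,
                 associations = assoc, cohort = cohort_res,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
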