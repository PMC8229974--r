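#' @importFrom stats rbinom rnorm runif setNames median
#' @importFrom utils head tail
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

check_dna <- function(sequence, what = "sequence", allow_n = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop(what, " must be a single character string", call. = FALSE)
  allowed <- if (allow_n) "ACGTN" else "ACGT"
  bad <- gsub(sprintf("[%s]", allowed), "", sequence)
  if (nchar(bad) > 0L)
    stop(what, " contains non-DNA characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "), call. = FALSE)
  invisible(sequence)
}

#' Reverse-complement a DNA string
#'
#' @param sequence Uppercase DNA string (A/C/G/T/N).
#' @return The reverse complement as a character string; N maps to N.
#' @export
reverse_complement <- function(sequence) {
  check_dna(sequence)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Locate CpG sites in a DNA sequence
#'
#' Returns the 0-based offsets of the C of every CG dinucleotide. CpG sites
#' cannot overlap, so this is the complete, unambiguous site list. An N never
#' contributes to a CpG.
#'
#' @param sequence Uppercase DNA string (A/C/G/T/N only).
#' @return Integer vector of 0-based offsets, strictly increasing (possibly
#'   empty).
#' @examples
#' find_cpg_sites("ACGTCG")  # 1, 4
#' @export
find_cpg_sites <- function(sequence) {
  check_dna(sequence)
  if (nchar(sequence) < 2L) return(integer(0))
  m <- gregexpr("CG", sequence, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) - 1L
}

#' Check a bisulfite-PCR primer for CpG sites
#'
#' Bisulfite PCR primers must not span a CG dinucleotide: a CpG position
#' converts (or not) depending on its methylation state, so a primer covering
#' one would amplify methylation states unequally.
#'
#' @param primer DNA string in bisulfite space.
#' @return `TRUE` iff the primer contains no CG dinucleotide.
#' @export
validate_primer <- function(primer) {
  check_dna(primer, "primer")
  if (nchar(primer) == 0L) stop("primer must be non-empty", call. = FALSE)
  !grepl("CG", primer, fixed = TRUE)
}

#' In-silico bisulfite conversion
#'
#' Deterministically converts a DNA string the way complete sodium-bisulfite
#' treatment would: every cytosine outside a CpG context reads as thymine,
#' while a CpG cytosine is protected iff methylated. Stochastic
#' (incomplete/inappropriate) conversion is the read simulator's job, not
#' this function's.
#'
#' @param sequence Uppercase DNA string; for `strand = "bottom"` this is still
#'   the top strand, and the function converts its reverse complement,
#'   returning the result in bottom-strand orientation.
#' @param strand `"top"` or `"bottom"`.
#' @param profile Numeric vector of per-CpG methylation fractions in `[0, 1]`
#'   (one per element of `cpg_offsets`), or `NULL` for fully unmethylated.
#'   For this deterministic conversion a site is treated as methylated iff
#'   its profile value is >= 0.5.
#' @param cpg_offsets 0-based offsets of CpG cytosines in `sequence` (top
#'   strand coordinates). Defaults to `find_cpg_sites(sequence)`.
#' @return Converted DNA string.
#' @export
bisulfite_convert <- function(sequence, strand = c("top", "bottom"),
                              profile = NULL,
                              cpg_offsets = find_cpg_sites(sequence)) {
  strand <- match.arg(strand)
  check_dna(sequence)
  n_sites <- length(cpg_offsets)
  if (!is.null(profile)) {
    if (length(profile) != n_sites)
      stop("profile length (", length(profile),
           ") does not match number of CpG sites (", n_sites, ")",
           call. = FALSE)
    if (any(profile < 0 | profile > 1))
      stop("profile values must lie in [0, 1]", call. = FALSE)
  }
  methylated <- if (is.null(profile)) rep(FALSE, n_sites) else profile >= 0.5
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (strand == "top") {
    is_c <- chars == "C"
    protect <- rep(FALSE, L)
    if (n_sites) protect[cpg_offsets[methylated] + 1L] <- TRUE
    chars[is_c & !protect] <- "T"
    paste(chars, collapse = "")
  } else {
    bottom <- strsplit(reverse_complement(sequence), "", fixed = TRUE)[[1]]
    # bottom-strand C of CpG site at top offset o pairs with the top G at
    # o + 1, i.e. bottom-strand position L - 2 - o (0-based)
    protect <- rep(FALSE, L)
    if (n_sites) protect[(L - 1L) - (cpg_offsets[methylated] + 1L) + 1L] <- TRUE
    is_c <- bottom == "C"
    bottom[is_c & !protect] <- "T"
    paste(bottom, collapse = "")
  }
}

#' Construct an amplicon specification
#'
#' An `amplicon_spec` ties together the unconverted genomic top-strand
#' sequence of a bisulfite-PCR product (primer-inclusive), the bisulfite-space
#' primer pair that produced it, and the 0-based offsets of its CpG sites.
#'
#' @param name Identifier, e.g. `"DR4"`.
#' @param sequence Uppercase unconverted genomic top-strand DNA, including the
#'   primer-binding regions.
#' @param fwd_primer,rev_primer Bisulfite-space primer sequences; neither may
#'   contain a CG dinucleotide.
#' @param cpg_offsets 0-based offsets of CpG cytosines in `sequence`; computed
#'   from the sequence when omitted.
#' @param source_coords Optional list with `assembly`, `chrom`, `start`, `end`
#'   (0-based half-open) recording the genomic origin.
#' @return An object of class `amplicon_spec`.
#' @export
amplicon_spec <- function(name, sequence, fwd_primer, rev_primer,
                          cpg_offsets = find_cpg_sites(sequence),
                          source_coords = NULL) {
  check_dna(sequence)
  cpg_offsets <- as.integer(cpg_offsets)
  if (is.unsorted(cpg_offsets, strictly = TRUE))
    stop("cpg_offsets must be strictly increasing", call. = FALSE)
  for (o in cpg_offsets)
    if (substr(sequence, o + 1L, o + 2L) != "CG")
      stop("offset ", o, " is not a CpG site in the sequence", call. = FALSE)
  if (!validate_primer(fwd_primer)) stop("fwd_primer contains CG", call. = FALSE)
  if (!validate_primer(rev_primer)) stop("rev_primer contains CG", call. = FALSE)
  if (nchar(sequence) < nchar(fwd_primer) + nchar(rev_primer))
    stop("amplicon shorter than its primers", call. = FALSE)
  structure(
    list(name = name, sequence = sequence,
         fwd_primer = fwd_primer, rev_primer = rev_primer,
         cpg_offsets = cpg_offsets, source_coords = source_coords),
    class = "amplicon_spec")
}

#' @export
print.amplicon_spec <- function(x, ...) {
  cat(sprintf("Amplicon '%s': %d bp, %d CpG sites\n",
              x$name, nchar(x$sequence), length(x$cpg_offsets)))
  cat("  fwd primer:", x$fwd_primer, "\n")
  cat("  rev primer:", x$rev_primer, "\n")
  cat("  CpG offsets (0-based):", paste(x$cpg_offsets, collapse = ", "), "\n")
  if (!is.null(x$source_coords))
    cat(sprintf("  source: %s %s:%d-%d\n", x$source_coords$assembly,
                x$source_coords$chrom, x$source_coords$start,
                x$source_coords$end))
  invisible(x)
}

#' @rdname amplicon_spec
#' @param path File path for JSON serialization.
#' @export
write_amplicon_json <- function(name, path) {
  spec <- name
  if (!inherits(spec, "amplicon_spec")) stop("not an amplicon_spec")
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname amplicon_spec
#' @export
read_amplicon_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  amplicon_spec(x$name, x$sequence, x$fwd_primer, x$rev_primer,
                as.integer(x$cpg_offsets),
                source_coords = x$source_coords)
}

match_converted <- function(converted, pattern, max_mismatches) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                   Biostrings::DNAString(converted),
                                   max.mismatch = max_mismatches,
                                   with.indels = FALSE, fixed = TRUE)
  BiocGenerics::start(hits)
}

#' In-silico bisulfite PCR
#'
#' Finds the amplicon a bisulfite-space primer pair would produce from an
#' unconverted genomic top strand. Because valid primers contain no CG
#' dinucleotide, their binding sites convert independently of methylation, so
#' the search is performed on the fully converted top strand (every C read as
#' T). The forward primer is matched directly; the reverse primer anneals to
#' the complement of the product, so its reverse complement is matched
#' downstream. The amplicon is then mapped back to the unconverted input and
#' CpG offsets are computed there.
#'
#' @param genomic_sequence Unconverted top-strand DNA.
#' @param fwd_primer,rev_primer Bisulfite-space primers (CG-free).
#' @param max_mismatches Maximum mismatches allowed per primer site
#'   (default 0). N in the genomic sequence never matches a primer base.
#' @param max_product_size Product-size cap used to declare an amplification
#'   ambiguous when more than one product fits under it (default 2000).
#' @param name Name given to the returned amplicon.
#' @param strand `"top"` searches the given strand; `"bottom"` treats the
#'   input's reverse complement as the template strand (a primer pair
#'   designed against one strand of a locus finds the same amplicon whether
#'   that locus is supplied in either orientation, by switching the search
#'   strand). The returned amplicon is reported in the searched strand's
#'   orientation.
#' @return An [amplicon_spec].
#' @export
in_silico_pcr <- function(genomic_sequence, fwd_primer, rev_primer,
                          max_mismatches = 0L, max_product_size = 2000L,
                          name = "amplicon", strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  if (strand == "bottom")
    genomic_sequence <- reverse_complement(genomic_sequence)
  check_dna(genomic_sequence, "genomic_sequence")
  if (!validate_primer(fwd_primer)) stop("fwd_primer contains CG", call. = FALSE)
  if (!validate_primer(rev_primer)) stop("rev_primer contains CG", call. = FALSE)
  converted <- bisulfite_convert(genomic_sequence, "top", profile = NULL,
                                 cpg_offsets = integer(0))
  fwd_hits <- match_converted(converted, fwd_primer, max_mismatches)
  if (length(fwd_hits) == 0L)
    stop("primer not found: no forward-primer site", call. = FALSE)
  rev_rc <- reverse_complement(rev_primer)
  rev_hits <- match_converted(converted, rev_rc, max_mismatches)

  products <- list()
  for (f in fwd_hits) {
    down <- rev_hits[rev_hits >= f + nchar(fwd_primer)]
    if (length(down) == 0L) next
    r <- min(down)  # nearest downstream reverse site
    len <- r + nchar(rev_rc) - f
    if (len <= max_product_size)
      products[[length(products) + 1L]] <- c(start = f, len = len)
  }
  if (length(products) == 0L)
    stop("primer not found: no productive primer pair", call. = FALSE)
  # distinct products under the size cap => ambiguous amplification
  keys <- vapply(products, paste, character(1), collapse = ":")
  products <- products[!duplicated(keys)]
  if (length(products) > 1L)
    stop("ambiguous amplification: ", length(products),
         " products under the size cap", call. = FALSE)
  p <- products[[1L]]
  amp_seq <- substr(genomic_sequence, p["start"], p["start"] + p["len"] - 1L)
  amplicon_spec(name, amp_seq, fwd_primer, rev_primer)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}
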