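#' Filtering configuration for sequence refinement
#'
#' Bundles every tunable of the refinement pipeline. The canonical grid used
#' for titanium pyrosequencing reads crosses Phred cutoffs
#' `{25, 27, 30, 32}` with tolerated sub-threshold fractions `{0.10, 0.15}`;
#' a harsher published variant allows only 3\% of bases below Q27, and
#' end-trim mode truncates each read at its first sub-threshold base.
#'
#' @param q_cutoff integer Phred threshold in `[0, 40]`.
#' @param allowed_fraction fraction of bases permitted to have quality
#'   strictly below `q_cutoff` (fraction mode only).
#' @param mode `"fraction"` (keep reads whose sub-threshold fraction is at
#'   most `allowed_fraction`), `"end_trim"` (truncate at the first
#'   sub-threshold base, then drop reads that became too short) or `"none"`
#'   (skip the quality stage).
#' @param primer IUPAC nucleotide string (barcode + primer) that every read
#'   must match at its 5' end, or `NULL` to skip the primer stage.
#' @param strip_primer if `TRUE`, the matched prefix is removed from kept
#'   reads.
#' @param trim_rule `"mean_minus_sd"` (trim all reads to
#'   `floor(mean - sd)` of the raw length distribution and drop shorter
#'   reads), `"none"`, or `"fixed:<L>"` for an explicit length.
#' @param end_trim_min_len minimum surviving length in end-trim mode;
#'   `NULL` means the trim length `L` when trimming is active, else 1.
#' @return An object of class `FilterConfig`.
#' @export
filter_config <- function(q_cutoff = 27L, allowed_fraction = 0.15,
                          mode = c("fraction", "end_trim", "none"),
                          primer = NULL, strip_primer = TRUE,
                          trim_rule = "mean_minus_sd",
                          end_trim_min_len = NULL) {
  mode <- match.arg(mode)
  q_cutoff <- as.integer(q_cutoff)
  stopifnot(q_cutoff >= 0L, q_cutoff <= 40L,
            allowed_fraction >= 0, allowed_fraction <= 1)
  if (!(identical(trim_rule, "mean_minus_sd") || identical(trim_rule, "none") ||
        grepl("^fixed:[0-9]+$", trim_rule)))
    stop("trim_rule must be 'mean_minus_sd', 'none' or 'fixed:<L>'")
  structure(list(q_cutoff = q_cutoff, allowed_fraction = allowed_fraction,
                 mode = mode, primer = primer, strip_primer = strip_primer,
                 trim_rule = trim_rule, end_trim_min_len = end_trim_min_len),
            class = "FilterConfig")
}

#' Length-trimming threshold: one standard deviation below the mean
#'
#' Computes `floor(mean(length) - sd(length))` over the raw read lengths,
#' the length to which all reads are trimmed (reads shorter than it are
#' removed). The sample standard deviation (n-1 denominator) is used; for a
#' single read the standard deviation is taken as 0.
#'
#' @param rs a non-empty [ReadSet].
#' @return Integer trim length.
#' @export
compute_trim_length <- function(rs) {
  len <- read_lengths(rs)
  if (!length(len)) stop("cannot compute a trim length for an empty ReadSet")
  s <- if (length(len) > 1) stats::sd(len) else 0
  as.integer(floor(mean(len) - s))
}

#' Trim reads to a common length
#'
#' Reads shorter than `L` are removed and counted; the rest are truncated to
#' exactly `L` bases (and quality values) from the 5' end.
#'
#' @param rs a [ReadSet].
#' @param L target length, `>= 1`.
#' @return A list with elements `reads` (the trimmed [ReadSet]) and
#'   `removed_count`.
#' @export
trim_reads <- function(rs, L) {
  stopifnot(inherits(rs, "ReadSet"), L >= 1)
  len <- read_lengths(rs)
  keep <- len >= L
  out <- rs[which(keep)]
  out$bases <- substr(out$bases, 1L, L)
  out$quals <- lapply(out$quals, function(q) q[seq_len(L)])
  out <- note_provenance(out, paste0("trimmed to ", L, " nt"))
  list(reads = out, removed_count = sum(!keep))
}

#' Quality filter: tolerated fraction of sub-threshold bases
#'
#' A read is kept iff the number of positions with quality strictly below
#' `q_cutoff`, divided by its length, is at most `allowed_fraction`
#' (boundary inclusive). With all reads at a common trimmed length the
#' fraction is interchangeable with an absolute base count.
#'
#' @param rs a [ReadSet].
#' @param q_cutoff integer Phred threshold.
#' @param allowed_fraction maximum tolerated fraction in `[0, 1]`.
#' @return A list with elements `reads` (kept reads) and `removed_count`.
#' @export
quality_filter_fraction <- function(rs, q_cutoff, allowed_fraction) {
  stopifnot(inherits(rs, "ReadSet"))
  frac <- vapply(rs$quals, function(q) {
    if (!length(q)) return(0)
    sum(q < q_cutoff) / length(q)
  }, numeric(1))
  keep <- frac <= allowed_fraction
  list(reads = rs[which(keep)], removed_count = sum(!keep))
}

#' Quality filter: end trimming at the first sub-threshold base
#'
#' Each read is truncated at its first (5'-most) position with quality
#' strictly below `q_cutoff`, excluding that position, so that every
#' surviving base has quality at or above the cutoff. Reads whose truncated
#' length falls below `min_length` are removed and counted.
#'
#' @param rs a [ReadSet].
#' @param q_cutoff integer Phred threshold.
#' @param min_length minimum surviving read length.
#' @return A list with elements `reads` and `removed_count`.
#' @export
quality_end_trim <- function(rs, q_cutoff, min_length = 1L) {
  stopifnot(inherits(rs, "ReadSet"))
  cut_at <- vapply(rs$quals, function(q) {
    i <- which(q < q_cutoff)
    if (length(i)) i[1] - 1L else length(q)
  }, integer(1))
  keep <- which(cut_at >= min_length)
  out <- rs[keep]
  out$bases <- substr(out$bases, 1L, cut_at[keep])
  out$quals <- Map(function(q, n) q[seq_len(n)], out$quals, cut_at[keep])
  out <- note_provenance(out, paste0("end-trimmed at Q", q_cutoff))
  list(reads = out, removed_count = length(rs) - length(keep))
}

#' Remove reads containing ambiguous bases
#'
#' @param rs a [ReadSet].
#' @return A list with elements `reads` (reads free of `N`) and
#'   `removed_count`.
#' @export
ambiguous_filter <- function(rs) {
  stopifnot(inherits(rs, "ReadSet"))
  keep <- !grepl("N", rs$bases, fixed = TRUE)
  list(reads = rs[which(keep)], removed_count = sum(!keep))
}

# one logical vector per primer position: does read char match IUPAC code?
iupac_prefix_match <- function(bases, primer) {
  map <- Biostrings::IUPAC_CODE_MAP
  primer <- toupper(primer)
  pl <- nchar(primer)
  ok <- nchar(bases) >= pl
  pchars <- strsplit(primer, "")[[1]]
  prefix <- substr(bases, 1L, pl)
  for (j in seq_len(pl)) {
    allowed <- strsplit(map[[pchars[j]]], "")[[1]]
    ok <- ok & substr(prefix, j, j) %in% allowed
  }
  ok
}

#' Remove reads with primer errors
#'
#' A read is kept iff its 5' prefix matches the primer position-by-position
#' under IUPAC degeneracy (e.g. `M = {A,C}`, `N = {A,C,G,T}`), with zero
#' mismatches tolerated; comparison is case-insensitive. Reads shorter than
#' the primer count as primer errors. Reads are assumed to be in primer
#' orientation, as in 454 amplicon runs; no reverse-complement search is
#' performed.
#'
#' @param rs a [ReadSet].
#' @param primer_iupac non-empty IUPAC nucleotide string (barcode + primer).
#' @param strip if `TRUE`, the matched prefix is removed from kept reads
#'   (bases and quality values).
#' @return A list with elements `reads` and `removed_count`.
#' @export
primer_filter <- function(rs, primer_iupac, strip = TRUE) {
  stopifnot(inherits(rs, "ReadSet"), nzchar(primer_iupac))
  if (!length(rs)) return(list(reads = rs, removed_count = 0L))
  ok <- iupac_prefix_match(rs$bases, primer_iupac)
  out <- rs[which(ok)]
  if (strip && length(out)) {
    pl <- nchar(primer_iupac)
    out$bases <- substr(out$bases, pl + 1L, nchar(out$bases))
    out$quals <- lapply(out$quals, function(q) q[-seq_len(pl)])
    out <- note_provenance(out, "primer stripped")
  }
  list(reads = out, removed_count = sum(!ok))
}

#' Run the full refinement pipeline with per-stage accounting
#'
#' Stages are applied in the fixed order length -> quality -> ambiguous ->
#' primer, the order in which removals are conventionally tabulated; a read
#' failing several criteria is counted once, at the earliest stage. With
#' `mode = "none"` the quality stage is skipped (a "trimmed, no quality
#' check" baseline) and with `trim_rule = "none"` trimming is skipped (a
#' "full length" baseline).
#'
#' @param rs a [ReadSet].
#' @param config a [filter_config()] object.
#' @return A list with elements `reads` (the refined [ReadSet]) and
#'   `ledger` (a `RemovalLedger`).
#' @export
run_refinement <- function(rs, config) {
  stopifnot(inherits(rs, "ReadSet"), inherits(config, "FilterConfig"))
  raw <- length(rs)
  removed <- c(length = 0L, quality = 0L, ambiguous = 0L, primer = 0L)

  L <- NULL
  if (config$trim_rule != "none" && raw > 0) {
    L <- if (startsWith(config$trim_rule, "fixed:"))
      as.integer(sub("^fixed:", "", config$trim_rule))
    else compute_trim_length(rs)
    tr <- trim_reads(rs, L)
    rs <- tr$reads
    removed["length"] <- tr$removed_count
  }

  if (config$mode == "fraction") {
    qf <- quality_filter_fraction(rs, config$q_cutoff, config$allowed_fraction)
    rs <- qf$reads
    removed["quality"] <- qf$removed_count
  } else if (config$mode == "end_trim") {
    ml <- config$end_trim_min_len
    if (is.null(ml)) ml <- if (is.null(L)) 1L else L
    qf <- quality_end_trim(rs, config$q_cutoff, min_length = ml)
    rs <- qf$reads
    removed["quality"] <- qf$removed_count
  }

  af <- ambiguous_filter(rs)
  rs <- af$reads
  removed["ambiguous"] <- af$removed_count

  if (!is.null(config$primer)) {
    pf <- primer_filter(rs, config$primer, strip = config$strip_primer)
    rs <- pf$reads
    removed["primer"] <- pf$removed_count
  }

  ledger <- removal_ledger(raw_count = raw, stage_removals = removed,
                           remaining = length(rs))
  list(reads = rs, ledger = ledger, trim_length = L)
}

#' Per-stage removal ledger
#'
#' Records how many reads each refinement stage removed, in stage order
#' (length, quality, ambiguous, primer), together with the raw count, the
#' number remaining and the fraction removed. Conservation always holds:
#' `raw_count == remaining + sum(stage removals)`.
#'
#' @param raw_count number of reads entering the pipeline.
#' @param stage_removals named integer vector in stage order.
#' @param remaining number of reads surviving all stages.
#' @return An object of class `RemovalLedger`.
#' @export
removal_ledger <- function(raw_count, stage_removals, remaining) {
  raw_count <- as.integer(raw_count)
  stage_removals <- vapply(stage_removals, as.integer, integer(1))
  remaining <- as.integer(remaining)
  if (raw_count != remaining + sum(stage_removals))
    stop("ledger violates conservation: raw ", raw_count, " != remaining ",
         remaining, " + removed ", sum(stage_removals))
  structure(list(raw_count = raw_count,
                 stage_removals = stage_removals,
                 remaining = remaining,
                 percent_removed = if (raw_count > 0) 1 - remaining / raw_count else 0),
            class = "RemovalLedger")
}

#' @export
print.RemovalLedger <- function(x, ...) {
  cat("RemovalLedger (", x$raw_count, " raw reads)\n", sep = "")
  for (s in names(x$stage_removals))
    cat(sprintf("  %-10s %d\n", s, x$stage_removals[[s]]))
  cat(sprintf("  %-10s %d\n", "remaining", x$remaining))
  cat(sprintf("  %% removed  %.1f%%\n", 100 * x$percent_removed))
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.RemovalLedger <- function(x, ...) {
  data.frame(stage = c(names(x$stage_removals), "remaining"),
             count = c(unname(x$stage_removals), x$remaining),
             stringsAsFactors = FALSE)
}

#' Mean of per-read mean quality
#'
#' The per-read arithmetic mean of the Phred values, averaged (unweighted)
#' across reads. On raw titanium data this typically sits in the high 20s
#' and rises by several units after trimming away the low-quality 3' tails.
#'
#' @param rs a non-empty [ReadSet].
#' @return Numeric scalar.
#' @export
quality_summary <- function(rs) {
  stopifnot(inherits(rs, "ReadSet"))
  if (!length(rs)) stop("quality_summary of an empty ReadSet is undefined")
  mean(vapply(rs$quals, mean, numeric(1)))
}
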