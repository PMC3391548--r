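#' Maximal homopolymer runs in a sequence
#'
#' Scans a nucleotide string for maximal single-base runs of at least
#' `min_len` bases. A run is reported exactly once at its full length (a
#' run of eight A's is one 8-mer, not also a 4-mer), and `N` never forms a
#' run. Homopolymers are the dominant source of pyrosequencing indel
#' errors, so their incidence is tabulated alongside the quality analysis.
#'
#' @param sequence nucleotide string.
#' @param min_len minimum reported run length (default 4).
#' @return A data frame with columns `base`, `length`, `start` (0-based
#'   offset of the run).
#' @export
#' @examples
#' find_runs("AAAATTTTTGG")  # one A 4-mer, one T 5-mer
find_runs <- function(sequence, min_len = 4L) {
  stopifnot(length(sequence) == 1)
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (!length(chars))
    return(data.frame(base = character(), length = integer(), start = integer(),
                      stringsAsFactors = FALSE))
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths       # 0-based
  keep <- r$lengths >= min_len & r$values %in% c("A", "C", "G", "T")
  data.frame(base = r$values[keep], length = r$lengths[keep],
             start = starts[keep], stringsAsFactors = FALSE)
}

#' Tabulate homopolymer occurrence by base and length bin
#'
#' Aggregates [find_runs()] over every read of a set into the conventional
#' occurrence table: rows `A, T, G, C`, columns for run lengths 4 through 8
#' with everything longer pooled into a `>8` bin. Runs are counted per
#' occurrence across reads, not per unique sequence.
#'
#' @param rs a [ReadSet].
#' @param min_len minimum run length counted (default 4).
#' @return An object of class `HomopolymerTable`: an integer matrix with
#'   rownames `A, T, G, C` and colnames `4mers ... 8mers, >8mers`.
#' @export
tabulate_homopolymers <- function(rs, min_len = 4L) {
  stopifnot(inherits(rs, "ReadSet"))
  bases <- c("A", "T", "G", "C")
  bins <- c("4mers", "5mers", "6mers", "7mers", "8mers", ">8mers")
  tab <- matrix(0L, nrow = 4, ncol = 6, dimnames = list(bases, bins))
  for (s in rs$bases) {
    runs <- find_runs(s, min_len = min_len)
    if (!nrow(runs)) next
    bin <- ifelse(runs$length > 8L, ">8mers", paste0(runs$length, "mers"))
    for (k in seq_len(nrow(runs)))
      tab[runs$base[k], bin[k]] <- tab[runs$base[k], bin[k]] + 1L
  }
  structure(tab, class = c("HomopolymerTable", "matrix", "array"))
}

#' @export
print.HomopolymerTable <- function(x, ...) {
  cat("Homopolymer occurrence (maximal runs):\n")
  print(unclass(x))
  invisible(x)
}
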