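#' Read amplicon reads from paired FASTA and QUAL files
#'
#' The native output of 454-style instruments is a FASTA file of base calls
#' accompanied by a `.qual` file holding one whitespace-separated list of
#' integer Phred scores per record. Records must appear in the same order
#' with identical identifiers in both files.
#'
#' @param fasta_path path to the FASTA file (plain or gzipped).
#' @param qual_path path to the matching QUAL file (plain or gzipped).
#' @return A [ReadSet].
#' @export
read_fasta_qual <- function(fasta_path, qual_path) {
  seqs <- Biostrings::readBStringSet(fasta_path, format = "fasta")
  q <- parse_qual_file(qual_path)
  ids_f <- first_word(names(seqs))
  if (length(seqs) != length(q$id))
    stop("FASTA has ", length(seqs), " records but QUAL has ", length(q$id))
  mism <- which(ids_f != q$id)
  if (length(mism))
    stop("identifier mismatch between FASTA and QUAL at record ", mism[1],
         ": '", ids_f[mism[1]], "' vs '", q$id[mism[1]], "'")
  ReadSet(id = ids_f, bases = as.character(seqs), quals = q$quals,
          provenance = paste0("read_fasta_qual(", fasta_path, ")"))
}

#' Read amplicon reads from a FASTQ file
#'
#' Assumes the Sanger/Phred+33 quality encoding. Decoded values outside the
#' pyrosequencing range `[0, 40]` are rejected rather than clipped, since
#' out-of-range values almost always signal a different FASTQ dialect and
#' silent clipping would corrupt downstream quality filtering.
#'
#' @param path path to a four-line-per-record FASTQ file (plain or gzipped).
#' @return A [ReadSet].
#' @export
read_fastq <- function(path) {
  # Biostrings emits a harmless mcols-dropped warning on FASTQ ingestion
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  quals <- suppressWarnings(
    lapply(as.character(Biostrings::quality(x)), function(s) utf8ToInt(s) - 33L))
  bad <- which(vapply(quals, function(q) length(q) && (min(q) < 0L || max(q) > 40L),
                      logical(1)))
  if (length(bad))
    stop("quality values outside [0, 40] after Phred+33 decoding (record '",
         first_word(names(x))[bad[1]], "'); wrong FASTQ dialect suspected")
  ReadSet(id = first_word(names(x)), bases = suppressWarnings(as.character(x)),
          quals = quals,
          provenance = paste0("read_fastq(", path, ")"))
}

#' Write a ReadSet as paired FASTA and QUAL files
#'
#' Round-trip property: reading the written pair back with
#' [read_fasta_qual()] reproduces the ids, bases and quality values exactly.
#' Quality lists are written as a single whitespace-separated line per
#' record; readers accept arbitrary wrapping.
#'
#' @param rs a [ReadSet].
#' @param fasta_path,qual_path output paths.
#' @return Invisibly, `rs`.
#' @export
write_fasta_qual <- function(rs, fasta_path, qual_path) {
  stopifnot(inherits(rs, "ReadSet"))
  seqs <- Biostrings::BStringSet(rs$bases)
  names(seqs) <- rs$id
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  con <- file(qual_path, "w")
  on.exit(close(con))
  for (i in seq_along(rs$id)) {
    writeLines(paste0(">", rs$id[i]), con)
    writeLines(paste(rs$quals[[i]], collapse = " "), con)
  }
  invisible(rs)
}

#' Write a ReadSet as FASTQ (Phred+33)
#'
#' @param rs a [ReadSet].
#' @param path output path.
#' @return Invisibly, `rs`.
#' @export
write_fastq <- function(rs, path) {
  stopifnot(inherits(rs, "ReadSet"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(rs$id)) {
    writeLines(c(paste0("@", rs$id[i]), rs$bases[i], "+",
                 intToUtf8(rs$quals[[i]] + 33L)), con)
  }
  invisible(rs)
}

# 454-style QUAL: FASTA-like headers, whitespace-separated integers below,
# possibly wrapped over several lines. No dedicated parser exists in the
# installed stack, so this one is hand-rolled.
parse_qual_file <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- startsWith(lines, ">")
  if (!length(lines)) return(list(id = character(), quals = list()))
  if (!hdr[1]) stop("QUAL file does not start with a '>' header: ", path)
  rec <- cumsum(hdr)
  ids <- first_word(sub("^>", "", lines[hdr]))
  quals <- lapply(split(lines[!hdr], rec[!hdr]), function(body) {
    v <- suppressWarnings(as.integer(strsplit(paste(body, collapse = " "),
                                              "[[:space:]]+")[[1]]))
    v <- v[!is.na(v)]
    v
  })
  out <- rep(list(integer()), length(ids))
  present <- as.integer(names(quals))
  out[present] <- quals
  list(id = ids, quals = out)
}

first_word <- function(x) sub("[[:space:]].*$", "", x)
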