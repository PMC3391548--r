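#' Construct a set of quality-scored amplicon reads
#'
#' A `ReadSet` is the package's central container: an ordered collection of
#' reads, each carrying a nucleotide string and one integer Phred quality
#' score (0--40) per base, with optional ground-truth annotation (template of
#' origin, taxon label) used by the simulator and the bias module.
#'
#' Internally the container is columnar: parallel vectors over reads, with
#' the per-base qualities held as a list of integer vectors. Bases are stored
#' uppercase; the alphabet is `A`, `C`, `G`, `T`, `N`.
#'
#' @param id character vector of unique read identifiers.
#' @param bases character vector of nucleotide strings (case-insensitive on
#'   input; stored uppercase).
#' @param quals list of integer vectors, one per read, each the same length
#'   as the corresponding `bases` string, values in `[0, 40]`.
#' @param taxon optional character vector of taxon labels (`NA` allowed).
#' @param template_id optional character vector of ground-truth template
#'   identifiers (`NA` allowed).
#' @param provenance free-text description of origin and prior processing.
#'
#' @return An object of class `ReadSet`.
#' @export
#' @examples
#' rs <- ReadSet(id = c("r1", "r2"),
#'               bases = c("acgt", "GGGG"),
#'               quals = list(c(30L, 30L, 12L, 40L), rep(35L, 4)))
#' length(rs)
ReadSet <- function(id = character(), bases = character(), quals = list(),
                    taxon = NULL, template_id = NULL, provenance = "") {
  id <- as.character(id)
  bases <- toupper(as.character(bases))
  quals <- lapply(quals, function(q) as.integer(round(q)))
  n <- length(id)
  if (length(bases) != n || length(quals) != n)
    stop("id, bases and quals must have one entry per read")
  if (anyDuplicated(id))
    stop("duplicate read ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  if (n > 0) {
    bl <- nchar(bases)
    ql <- lengths(quals)
    bad <- which(bl != ql)
    if (length(bad))
      stop("base/quality length mismatch for read '", id[bad[1]], "' (",
           bl[bad[1]], " bases vs ", ql[bad[1]], " quality values)")
    rng <- range(unlist(quals, use.names = FALSE), 0L)
    if (rng[1] < 0L || rng[2] > 40L)
      stop("Phred quality values must lie in [0, 40]; observed range [",
           rng[1], ", ", rng[2], "]")
    if (any(grepl("[^ACGTN]", bases)))
      stop("bases must be over {A,C,G,T,N}")
  }
  taxon <- if (is.null(taxon)) rep(NA_character_, n) else as.character(taxon)
  template_id <- if (is.null(template_id)) rep(NA_character_, n) else as.character(template_id)
  if (length(taxon) != n || length(template_id) != n)
    stop("taxon and template_id must have one entry per read")
  structure(
    list(id = id, bases = bases, quals = quals,
         taxon = taxon, template_id = template_id,
         provenance = as.character(provenance)[1]),
    class = "ReadSet")
}

#' @export
length.ReadSet <- function(x) length(x$id)

#' Subset a ReadSet
#'
#' @param x a `ReadSet`.
#' @param i integer, logical or character (read id) index.
#' @param ... ignored.
#' @return A `ReadSet` containing the selected reads, in index order.
#' @export
`[.ReadSet` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$id)
  ReadSet(id = x$id[i], bases = x$bases[i], quals = x$quals[i],
          taxon = x$taxon[i], template_id = x$template_id[i],
          provenance = x$provenance)
}

#' @export
print.ReadSet <- function(x, ...) {
  cat("ReadSet with", length(x), "reads\n")
  if (length(x)) {
    rng <- range(nchar(x$bases))
    cat("  lengths:", rng[1], "-", rng[2], "nt\n")
    if (any(!is.na(x$taxon)))
      cat("  taxon labels present for", sum(!is.na(x$taxon)), "reads\n")
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.ReadSet <- function(x, ...) {
  data.frame(id = x$id, bases = x$bases,
             length = if (length(x)) nchar(x$bases) else integer(),
             mean_q = vapply(x$quals, function(q) if (length(q)) mean(q) else NA_real_,
                             numeric(1)),
             taxon = x$taxon, template_id = x$template_id,
             stringsAsFactors = FALSE)
}

# note a processing stage on the provenance string
note_provenance <- function(rs, msg) {
  rs$provenance <- if (nzchar(rs$provenance)) paste(rs$provenance, msg, sep = "; ") else msg
  rs
}

#' Read lengths of a ReadSet
#' @param rs a `ReadSet`.
#' @return Integer vector of read lengths.
#' @export
read_lengths <- function(rs) {
  stopifnot(inherits(rs, "ReadSet"))
  if (!length(rs)) return(integer())
  nchar(rs$bases)
}
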