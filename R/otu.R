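#' Pairwise alignment distance between two sequences
#'
#' Distance used for OTU clustering: the sequences are globally aligned
#' (Needleman-Wunsch; match +2, mismatch -4, gap -5 per base, compiled),
#' terminal gap columns are excluded, and the distance is
#' `(mismatches + internal gap columns) / columns`, where `columns` counts
#' alignment columns excluding terminal gaps. Length overhangs at either
#' end therefore do not contribute to the distance, while internal indels
#' count as differences. A position involving `N` counts as a mismatch
#' unless both characters are equal.
#'
#' @param seq_a,seq_b non-empty nucleotide strings.
#' @return Distance in `[0, 1]`; symmetric in its arguments.
#' @export
#' @examples
#' pairwise_distance("AAAA", "AAAT")  # 0.25
pairwise_distance <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  align_dist_cpp(toupper(seq_a), toupper(seq_b))
}

# distance from one pair of aligned (gapped) strings; used by tests as an
# independent route from alignment strings to a distance
dist_from_alignment <- function(p, s) {
  pc <- strsplit(p, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  gap <- pc == "-" | sc == "-"
  # terminal gap runs: leading/trailing columns where either string is gapped
  nong <- which(!gap)
  if (!length(nong)) return(1)
  core <- nong[1]:nong[length(nong)]
  pc <- pc[core]; sc <- sc[core]
  gapc <- pc == "-" | sc == "-"
  mism <- sum(!gapc & pc != sc)
  (mism + sum(gapc)) / length(core)
}

#' All-vs-all distance matrix
#'
#' Computes the symmetric [pairwise_distance()] matrix for a set of
#' sequences. Quadratic in the number of sequences; intended for desk-scale
#' inputs (up to a few thousand reads). Identical sequences are aligned only
#' once.
#'
#' @param seqs character vector of nucleotide strings.
#' @param ids identifiers for rows/columns (defaults to names or indices).
#' @return A list of class `DistanceMatrix` with elements `ids` and `d`
#'   (symmetric numeric matrix, zero diagonal).
#' @export
distance_matrix <- function(seqs, ids = NULL) {
  seqs <- toupper(seqs)
  if (is.null(ids)) ids <- if (!is.null(names(seqs))) names(seqs) else as.character(seq_along(seqs))
  stopifnot(length(ids) == length(seqs), !anyDuplicated(ids))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n >= 2) {
    uniq <- unique(seqs)
    du <- dist_matrix_cpp(uniq)
    ix <- match(seqs, uniq)
    d <- du[ix, ix, drop = FALSE]
    dimnames(d) <- list(ids, ids)
  }
  structure(list(ids = ids, d = d), class = "DistanceMatrix")
}

#' Complete-linkage clustering at a distance threshold
#'
#' Agglomerative complete-linkage clustering cut at `threshold`: clusters
#' are merged in order of smallest maximum inter-cluster distance while that
#' distance is at most the threshold. Every output cluster therefore has a
#' maximum intra-cluster pairwise distance at most the threshold. Merge ties
#' are broken towards the pair with the lexicographically smallest member
#' ids, making the partition independent of input order. The conventional
#' OTU definition at 97\% similarity corresponds to `threshold = 0.03`.
#'
#' @param dm a [distance_matrix()] result, or a plain symmetric matrix with
#'   dimnames.
#' @param threshold distance cutoff (default 0.03).
#' @return An object of class `Clustering`: `assignment` (named character
#'   vector, read id -> OTU id), `threshold`, and `otu_sizes` (named integer
#'   vector).
#' @export
complete_linkage <- function(dm, threshold = 0.03) {
  if (inherits(dm, "DistanceMatrix")) {
    d <- dm$d; ids <- dm$ids
  } else {
    d <- as.matrix(dm)
    ids <- rownames(d)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(d)))
  }
  n <- length(ids)
  if (n == 0)
    return(new_clustering(character(), threshold))
  members <- as.list(ids)
  D <- d
  diag(D) <- Inf
  active <- rep(TRUE, n)
  repeat {
    if (sum(active) < 2) break
    Da <- D
    Da[!active, ] <- Inf
    Da[, !active] <- Inf
    mn <- min(Da)
    if (!is.finite(mn) || mn > threshold) break
    cand <- which(Da <= mn + 1e-12 & upper.tri(Da), arr.ind = TRUE)
    # deterministic tie-break: smallest (min id, other min id) pair
    keys <- apply(cand, 1, function(rc) {
      a <- min(members[[rc[1]]]); b <- min(members[[rc[2]]])
      paste(sort(c(a, b)), collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    members[[i]] <- c(members[[i]], members[[j]])
    newrow <- pmax(D[i, ], D[j, ])
    D[i, ] <- newrow
    D[, i] <- newrow
    D[i, i] <- Inf
    active[j] <- FALSE
  }
  clusters <- members[active]
  # stable OTU labels: clusters ordered by smallest member id
  clusters <- clusters[order(vapply(clusters, min, character(1)))]
  assignment <- character(n)
  names(assignment) <- ids
  for (k in seq_along(clusters))
    assignment[clusters[[k]]] <- sprintf("OTU_%04d", k)
  new_clustering(assignment, threshold)
}

new_clustering <- function(assignment, threshold) {
  sizes <- if (length(assignment)) table(assignment) else table(character())
  structure(list(assignment = assignment, threshold = threshold,
                 otu_sizes = stats::setNames(as.integer(sizes), names(sizes))),
            class = "Clustering")
}

#' @export
print.Clustering <- function(x, ...) {
  cat("Clustering of", length(x$assignment), "reads into",
      length(x$otu_sizes), "OTUs at distance threshold", x$threshold, "\n")
  invisible(x)
}

#' Cluster the reads of a ReadSet into OTUs
#'
#' Convenience wrapper: computes the all-vs-all alignment distance matrix
#' for the read sequences and applies [complete_linkage()]. Duplicate
#' sequences are collapsed before alignment (they sit at distance zero and
#' always co-cluster), which makes clustering of refined pyrosequencing
#' read sets far cheaper.
#'
#' @param rs a [ReadSet].
#' @param threshold distance cutoff (default 0.03, i.e. 97\% similarity).
#' @return A `Clustering` over the read ids of `rs`.
#' @export
cluster_reads <- function(rs, threshold = 0.03) {
  stopifnot(inherits(rs, "ReadSet"))
  if (!length(rs)) return(new_clustering(character(), threshold))
  uniq <- unique(rs$bases)
  rep_ids <- rs$id[match(uniq, rs$bases)]
  dm <- distance_matrix(uniq, ids = rep_ids)
  cl <- complete_linkage(dm, threshold)
  assignment <- cl$assignment[rep_ids[match(rs$bases, uniq)]]
  names(assignment) <- rs$id
  new_clustering(assignment, threshold)
}

#' Descending OTU abundance vector
#'
#' @param clustering a `Clustering`.
#' @return Integer vector of OTU sizes sorted in descending order.
#' @export
abundance_vector <- function(clustering) {
  stopifnot(inherits(clustering, "Clustering"))
  sort(unname(clustering$otu_sizes), decreasing = TRUE)
}

#' Write a clustering as a two-column mapping
#'
#' @param clustering a `Clustering`.
#' @param path output path for a tab-delimited (read_id, otu_id) table.
#' @return Invisibly, the written data frame.
#' @export
write_clustering <- function(clustering, path) {
  df <- data.frame(read_id = names(clustering$assignment),
                   otu_id = unname(clustering$assignment),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
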