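#' Per-taxon fractions before and after filtering
#'
#' Compares the taxon composition of a read set before and after quality
#' filtering. Fractions are computed within each set over the union of taxa
#' seen in either set; a taxon absent from one set gets fraction 0 there.
#' The post-filter set must be a subset (by read id) of the pre-filter set.
#'
#' @param pre_set,post_set [ReadSet]s whose reads carry taxon labels.
#' @return An object of class `TaxonDistribution`: a data frame with
#'   columns `taxon`, `pre_fraction`, `post_fraction`.
#' @export
taxon_fractions <- function(pre_set, post_set) {
  stopifnot(inherits(pre_set, "ReadSet"), inherits(post_set, "ReadSet"))
  if (!all(post_set$id %in% pre_set$id))
    stop("post-filter set contains reads absent from the pre-filter set")
  for (s in list(pre_set, post_set)) {
    miss <- which(is.na(s$taxon))
    if (length(miss))
      stop("read '", s$id[miss[1]], "' carries no taxon label")
  }
  taxa <- sort(unique(c(pre_set$taxon, post_set$taxon)))
  frac <- function(s) {
    tb <- table(factor(s$taxon, levels = taxa))
    as.numeric(tb) / max(1L, length(s))
  }
  out <- data.frame(taxon = taxa,
                    pre_fraction = frac(pre_set),
                    post_fraction = frac(post_set),
                    stringsAsFactors = FALSE)
  class(out) <- c("TaxonDistribution", class(out))
  out
}

#' Goodness of fit to the identity line y = x
#'
#' `R^2 = 1 - sum((y - x)^2) / sum((y - mean(y))^2)`: the residuals are
#' taken to the fixed line `y = x` (no fitted slope or intercept), the
#' denominator is the total sum of squares about the mean of `y`. Values
#' near 1 mean filtering left the composition unchanged; the statistic can
#' be negative (fit worse than the horizontal mean line) and is reported
#' unclamped.
#'
#' @param points a two-column matrix/data frame of `(x, y)` points, or a
#'   `TaxonDistribution` (uses `pre_fraction` as x, `post_fraction` as y).
#' @return Numeric scalar.
#' @export
r_squared_identity <- function(points) {
  if (inherits(points, "TaxonDistribution"))
    points <- cbind(points$pre_fraction, points$post_fraction)
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("at least two points are required")
  x <- points[, 1]; y <- points[, 2]
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("all y values identical: R^2 against y = x is undefined")
  1 - sum((y - x)^2) / ss_tot
}

#' Attribute removed reads to their pre-filter clusters
#'
#' Given a clustering of the reads before quality filtering and the ids of
#' the reads the quality stage removed, reports for each pre-filter cluster
#' the fraction of all removed reads that it contributed, in descending
#' cluster-size order. Used to ask whether removal concentrates in the
#' largest and smallest clusters.
#'
#' @param pre_clustering a `Clustering` of the pre-filter reads.
#' @param removed_ids character vector of removed read ids (must all be in
#'   the clustering).
#' @return An object of class `ClusterRemovalProfile`: a data frame with
#'   columns `otu_id`, `cluster_size`, `removed`,
#'   `fraction_of_total_removed`, ordered by descending `cluster_size`.
#'   Empty when nothing was removed.
#' @export
removal_by_cluster <- function(pre_clustering, removed_ids) {
  stopifnot(inherits(pre_clustering, "Clustering"))
  absent <- setdiff(removed_ids, names(pre_clustering$assignment))
  if (length(absent))
    stop("removed read '", absent[1], "' is absent from the pre-filter clustering")
  if (!length(removed_ids)) {
    out <- data.frame(otu_id = character(), cluster_size = integer(),
                      removed = integer(),
                      fraction_of_total_removed = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    sizes <- pre_clustering$otu_sizes
    rem <- table(factor(pre_clustering$assignment[removed_ids],
                        levels = names(sizes)))
    out <- data.frame(otu_id = names(sizes),
                      cluster_size = as.integer(sizes),
                      removed = as.integer(rem),
                      stringsAsFactors = FALSE)
    out$fraction_of_total_removed <- out$removed / length(removed_ids)
    out <- out[order(-out$cluster_size, out$otu_id), ]
    rownames(out) <- NULL
  }
  class(out) <- c("ClusterRemovalProfile", class(out))
  out
}
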