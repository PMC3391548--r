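# independent oracles used to validate implementation routes

# brute-force per-read keep decision for the fraction-mode quality filter
oracle_fraction_keep <- function(quals, q_cutoff, allowed_fraction) {
  vapply(quals, function(q) {
    below <- 0
    for (v in q) if (v < q_cutoff) below <- below + 1
    below / length(q) <= allowed_fraction
  }, logical(1))
}

# exhaustive rarefaction: enumerate every n-subset of the N reads
oracle_rarefaction_enum <- function(counts, n) {
  reads <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(reads), n)
  mean(apply(subs, 2, function(ix) length(unique(reads[ix]))))
}

# Monte-Carlo rarefaction
oracle_rarefaction_mc <- function(counts, n, reps = 10000) {
  reads <- rep(seq_along(counts), counts)
  v <- replicate(reps, length(unique(sample(reads, n))))
  c(mean = mean(v), se = stats::sd(v) / sqrt(reps))
}

# hierarchical complete-linkage oracle: stats::hclust cut at the threshold.
# Valid for tie-free dissimilarities (random continuous draws).
oracle_complete_linkage <- function(d, threshold) {
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  stats::cutree(hc, h = threshold)
}

# same partition up to relabeling?
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# regex-based maximal homopolymer scan
oracle_runs <- function(s, min_len = 4) {
  m <- gregexpr("(A+|C+|G+|T+)", toupper(s))[[1]]
  if (m[1] == -1) return(data.frame(base = character(), length = integer()))
  len <- attr(m, "match.length")
  base <- substring(toupper(s), m, m)
  keep <- len >= min_len
  data.frame(base = base[keep], length = len[keep])
}

# random symmetric distance matrix with zero diagonal
random_dist <- function(n, max_d = 0.06) {
  d <- matrix(0, n, n)
  v <- stats::runif(n * (n - 1) / 2, 0, max_d)
  d[upper.tri(d)] <- v
  d <- d + t(d)
  rownames(d) <- colnames(d) <- sprintf("s%02d", seq_len(n))
  d
}
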