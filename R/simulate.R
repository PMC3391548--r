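#' Configuration of the synthetic pyrosequencing community
#'
#' Describes a mock amplicon community and a 454-titanium-like error model:
#' reads of variable length whose Phred quality declines along the read,
#' substitution errors drawn per base with probability `10^(-Q/10)`,
#' homopolymer run-length errors (the dominant pyrosequencing indel mode),
#' a barcoded degenerate primer prepended to every template, and a
#' sub-population of globally degraded reads that quality filtering is
#' expected to remove. All randomness derives from the single `seed`.
#'
#' @param n_templates number of template sequences (true richness).
#' @param template_length template length in nt, including the primer.
#' @param min_template_divergence lower bound on pairwise template distance
#'   (rejection sampling); keep it above the clustering threshold when OTU
#'   recovery is to be tested.
#' @param abundance_model `"geometric"` (template i has weight
#'   `abundance_ratio^(i-1)`) or `"uniform"`.
#' @param abundance_ratio ratio of the geometric abundance series.
#' @param n_reads number of reads to simulate.
#' @param primer IUPAC string (barcode + primer) starting every template;
#'   degenerate positions are resolved to a concrete base per template.
#' @param q_start mean Phred score at the first base.
#' @param q_slope mean per-base decline of the quality trajectory.
#' @param q_noise_sd per-base Gaussian jitter of the quality (clipped to
#'   `[0, 40]` and rounded).
#' @param q_read_sd per-read Gaussian offset of the whole trajectory,
#'   emulating read-to-read quality heterogeneity of real runs.
#' @param homopolymer_indel_rate per-run probability of a +-1 length error,
#'   scaled by `(run_length - 3)` for runs of four or more bases.
#' @param length_sd standard deviation of the read-length jitter.
#' @param frac_bad_reads fraction of reads whose whole trajectory is
#'   degraded by `bad_q_penalty`, so they fail typical quality filters.
#' @param bad_q_penalty Phred units subtracted from `q_start` for bad reads.
#' @param taxon_labels label set assigned to templates round-robin.
#' @param chimera_rate accepted for interface compatibility; must be 0
#'   (chimera simulation is out of scope).
#' @param seed integer seed governing all randomness.
#' @return An object of class `SimulationConfig`.
#' @export
simulation_config <- function(n_templates = 10L,
                              template_length = 300L,
                              min_template_divergence = 0.10,
                              abundance_model = c("geometric", "uniform"),
                              abundance_ratio = 0.8,
                              n_reads = 500L,
                              primer = "tagtgtagatGTGCCAGCMGCNGCGG",
                              q_start = 34,
                              q_slope = 0.02,
                              q_noise_sd = 2,
                              q_read_sd = 4,
                              homopolymer_indel_rate = 0.01,
                              length_sd = 10,
                              frac_bad_reads = 0.2,
                              bad_q_penalty = 20,
                              taxon_labels = c("Proteobacteria", "Firmicutes",
                                               "Bacteroidetes", "Actinobacteria",
                                               "Chloroflexi", "Cyanobacteria",
                                               "Thermotogae", "Nitrospirae"),
                              chimera_rate = 0,
                              seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  stopifnot(n_templates >= 1, n_reads >= 0,
            min_template_divergence >= 0, min_template_divergence <= 1,
            frac_bad_reads >= 0, frac_bad_reads <= 1,
            homopolymer_indel_rate >= 0, homopolymer_indel_rate <= 1,
            chimera_rate == 0,
            template_length > nchar(primer))
  structure(as.list(environment()), class = "SimulationConfig")
}

#' Generate divergent template sequences
#'
#' Draws `n_templates` random sequences of `template_length` nt, each
#' starting with a concrete realization of the (degenerate) primer, and
#' rejects candidates closer than `min_template_divergence` to any accepted
#' template (alignment distance of [pairwise_distance()]). Taxon labels are
#' assigned round-robin from `taxon_labels`.
#'
#' @param config a [simulation_config()].
#' @return A list with `templates` (named character vector,
#'   `T001, T002, ...`) and `taxa` (named character vector, same names).
#' @export
generate_templates <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  map <- Biostrings::IUPAC_CODE_MAP
  pchars <- strsplit(toupper(config$primer), "")[[1]]
  body_len <- config$template_length - length(pchars)
  templates <- character(0)
  tries <- 0L
  cap <- 200L * config$n_templates
  while (length(templates) < config$n_templates) {
    tries <- tries + 1L
    if (tries > cap)
      stop("template rejection sampling exceeded ", cap, " iterations; ",
           "lower min_template_divergence or n_templates")
    primer_real <- vapply(pchars, function(ch) {
      allowed <- strsplit(map[[ch]], "")[[1]]
      if (length(allowed) == 1) allowed else sample(allowed, 1)
    }, character(1))
    cand <- paste(c(primer_real,
                    sample(c("A", "C", "G", "T"), body_len, replace = TRUE)),
                  collapse = "")
    ok <- all(vapply(templates, function(t)
      pairwise_distance(cand, t) >= config$min_template_divergence, logical(1)))
    if (ok) templates <- c(templates, cand)
  }
  names(templates) <- sprintf("T%03d", seq_along(templates))
  taxa <- rep(config$taxon_labels, length.out = config$n_templates)
  names(taxa) <- names(templates)
  list(templates = templates, taxa = taxa)
}

# apply +-1 length errors to homopolymer runs of a character vector
apply_homopolymer_errors <- function(chars, rate) {
  if (rate <= 0) return(list(chars = chars, n_indels = 0L))
  runs <- find_runs(paste(chars, collapse = ""), min_len = 4L)
  if (!nrow(runs)) return(list(chars = chars, n_indels = 0L))
  hit <- stats::runif(nrow(runs)) < pmin(1, rate * (runs$length - 3))
  n <- 0L
  # rightmost first so earlier offsets stay valid
  for (k in rev(which(hit))) {
    pos <- runs$start[k] + 1L   # 1-based first base of the run
    if (stats::runif(1) < 0.5 && length(chars) > 1) {
      chars <- chars[-pos]                        # run shrinks by one
    } else {
      chars <- append(chars, runs$base[k], after = pos - 1L)
    }
    n <- n + 1L
  }
  list(chars = chars, n_indels = n)
}

#' Simulate 454-style reads from templates
#'
#' For each read a template is drawn from the abundance model; a read
#' length is drawn around the template length; homopolymer runs may gain or
#' lose one base; a per-base Phred trajectory is drawn as
#' `round(clip(q_start + read_offset - q_slope * pos + noise))`; and a
#' substitution is planted at every position independently with probability
#' `10^(-Q/10)` -- the link between low quality and error is purely
#' probabilistic, which is exactly the assumption underlying quality
#' filtering. Inserted bases inherit the local quality trajectory.
#'
#' @param templates result of [generate_templates()] (or a compatible list).
#' @param config the same [simulation_config()].
#' @return A list with `reads` (a [ReadSet] with `taxon` and `template_id`
#'   filled in) and `truth` (a `GroundTruth` list: per-read table,
#'   `true_richness`, `true_abundance`).
#' @export
simulate_reads <- function(templates, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  tnames <- names(templates$templates)
  k <- length(tnames)
  w <- switch(config$abundance_model,
              geometric = config$abundance_ratio^(seq_len(k) - 1),
              uniform = rep(1, k))
  w <- w / sum(w)
  n <- config$n_reads
  tmpl_chars <- lapply(templates$templates, function(t) strsplit(t, "")[[1]])

  ids <- sprintf("read_%05d", seq_len(n))
  pick <- if (n > 0) sample.int(k, n, replace = TRUE, prob = w) else integer()
  is_bad <- stats::runif(n) < config$frac_bad_reads
  bases <- character(n)
  quals <- vector("list", n)
  n_subs <- integer(n)
  n_indels <- integer(n)
  alphabet <- c("A", "C", "G", "T")

  for (i in seq_len(n)) {
    tc <- tmpl_chars[[pick[i]]]
    len <- min(length(tc),
               max(50L, as.integer(round(stats::rnorm(1, length(tc),
                                                      config$length_sd)))))
    chars <- tc[seq_len(len)]
    he <- apply_homopolymer_errors(chars, config$homopolymer_indel_rate)
    chars <- he$chars
    L <- length(chars)
    q0 <- config$q_start - if (is_bad[i]) config$bad_q_penalty else 0
    q0 <- q0 + stats::rnorm(1, 0, config$q_read_sd)
    q <- q0 - config$q_slope * (seq_len(L) - 1) +
      stats::rnorm(L, 0, config$q_noise_sd)
    q <- as.integer(round(pmin(40, pmax(0, q))))
    perr <- 10^(-q / 10)
    sub_at <- which(stats::runif(L) < perr)
    for (p in sub_at)
      chars[p] <- sample(setdiff(alphabet, chars[p]), 1)
    bases[i] <- paste(chars, collapse = "")
    quals[[i]] <- q
    n_subs[i] <- length(sub_at)
    n_indels[i] <- he$n_indels
  }

  reads <- ReadSet(id = ids, bases = bases, quals = quals,
                   taxon = templates$taxa[tnames[pick]],
                   template_id = tnames[pick],
                   provenance = paste0("simulated (seed ", config$seed, ")"))
  abund <- table(factor(tnames[pick], levels = tnames))
  truth <- structure(list(
    reads = data.frame(read_id = ids,
                       template_id = tnames[pick],
                       taxon = unname(templates$taxa[tnames[pick]]),
                       n_subs = n_subs, n_indels = n_indels,
                       bad = is_bad, stringsAsFactors = FALSE),
    true_richness = sum(abund > 0),
    true_abundance = stats::setNames(as.integer(abund), tnames)),
    class = "GroundTruth")
  list(reads = reads, truth = truth)
}

#' Generate templates and simulate reads in one call
#'
#' @param config a [simulation_config()].
#' @return As [simulate_reads()], plus `templates` and `taxa`.
#' @export
simulate_community <- function(config) {
  tp <- generate_templates(config)
  sim <- simulate_reads(tp, config)
  c(sim, tp)
}

#' Write ground truth as a delimited table
#'
#' @param truth a `GroundTruth`.
#' @param path output path (tab-delimited).
#' @return Invisibly, the per-read table.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "GroundTruth"))
  utils::write.table(truth$reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(truth$reads)
}
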