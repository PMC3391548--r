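test_that("template generation respects divergence, primer, and determinism", {
  cfg <- simulation_config(n_templates = 5L, template_length = 150L,
                           min_template_divergence = 0.10, seed = 7L)
  tp <- generate_templates(cfg)
  expect_length(tp$templates, 5)
  expect_true(all(nchar(tp$templates) == 150))
  # every pairwise distance at or above the floor
  pairs <- utils::combn(5, 2)
  d <- apply(pairs, 2, function(ij)
    pairwise_distance(tp$templates[ij[1]], tp$templates[ij[2]]))
  expect_true(all(d >= 0.10))
  # each template starts with a realization of the degenerate primer
  prefix_ok <- vapply(tp$templates, function(t)
    length(primer_filter(mk_rs(t), cfg$primer)$reads) == 1, logical(1))
  expect_true(all(prefix_ok))
  # round-robin taxon labels
  expect_identical(unname(tp$taxa), cfg$taxon_labels[c(1:5)])
  # same seed, same templates
  expect_identical(generate_templates(cfg)$templates, tp$templates)

  cfg1 <- simulation_config(n_templates = 1L, template_length = 100L, seed = 3L)
  expect_length(generate_templates(cfg1)$templates, 1)

  tight <- simulation_config(n_templates = 30L, template_length = 40L,
                             primer = "ACGTACGTACGTACGTACGTACGTACGTACG",
                             min_template_divergence = 0.9, seed = 4L)
  expect_error(generate_templates(tight), "rejection sampling")
})

test_that("identical configs give byte-identical FASTA/QUAL output", {
  cfg <- simulation_config(n_templates = 4L, template_length = 120L,
                           n_reads = 40L, seed = 9L)
  fa1 <- withr::local_tempfile(); qu1 <- withr::local_tempfile()
  fa2 <- withr::local_tempfile(); qu2 <- withr::local_tempfile()
  write_fasta_qual(simulate_community(cfg)$reads, fa1, qu1)
  write_fasta_qual(simulate_community(cfg)$reads, fa2, qu2)
  expect_identical(readLines(fa1), readLines(fa2))
  expect_identical(readLines(qu1), readLines(qu2))
})

test_that("error-free limit: reads are template prefixes and richness is exact", {
  cfg <- simulation_config(n_templates = 5L, template_length = 150L,
                           n_reads = 80L, q_start = 40, q_slope = 0,
                           q_noise_sd = 0, q_read_sd = 0,
                           homopolymer_indel_rate = 0, frac_bad_reads = 0,
                           length_sd = 0, seed = 13L)
  sim <- simulate_community(cfg)
  # at the Q40 cap the substitution channel still has P = 1e-4, so a
  # handful of substitutions remain; reads without planted errors must be
  # exact template prefixes, and recovery must be exact regardless
  expect_lte(sum(sim$truth$reads$n_subs), 10)
  clean <- sim$truth$reads$n_subs == 0 & sim$truth$reads$n_indels == 0
  prefix_ok <- mapply(function(b, t) startsWith(t, b),
                      sim$reads$bases[clean],
                      sim$templates[sim$reads$template_id[clean]])
  expect_true(all(prefix_ok))
  expect_identical(sim$truth$true_richness, 5L)
  expect_identical(sum(sim$truth$true_abundance), 80L)

  cl <- cluster_reads(sim$reads, 0.03)
  expect_length(cl$otu_sizes, 5)
  counts <- abundance_vector(cl)
  if (all(counts >= 3))                       # no singletons/doubletons
    expect_equal(chao1(counts)$estimate, 5)
})

test_that("substitution load matches the analytic Phred error budget", {
  cfg <- simulation_config(n_templates = 3L, template_length = 200L,
                           n_reads = 150L, q_start = 20, q_slope = 0,
                           q_noise_sd = 0, q_read_sd = 0,
                           homopolymer_indel_rate = 0, frac_bad_reads = 0,
                           length_sd = 0, seed = 17L)
  sim <- simulate_community(cfg)
  expected <- sum(vapply(sim$reads$quals, function(q) sum(10^(-q / 10)),
                         numeric(1)))
  observed <- sum(sim$truth$reads$n_subs)
  expect_lt(abs(observed - expected), 3 * sqrt(expected))
})

test_that("planted bad reads fail the quality filter at the planted rate", {
  cfg <- simulation_config(n_templates = 4L, template_length = 150L,
                           n_reads = 400L, q_start = 38, q_slope = 0,
                           q_noise_sd = 1, q_read_sd = 0,
                           frac_bad_reads = 0.3, bad_q_penalty = 20,
                           length_sd = 0, seed = 19L)
  sim <- simulate_community(cfg)
  qf <- quality_filter_fraction(sim$reads, 27L, 0.10)
  frac_failed <- qf$removed_count / length(sim$reads)
  expect_lt(abs(frac_failed - 0.3), 3 * sqrt(0.3 * 0.7 / 400))
  # the failures are the planted bad reads
  bad_ids <- sim$truth$reads$read_id[sim$truth$reads$bad]
  expect_true(all(setdiff(sim$reads$id, qf$reads$id) %in% bad_ids))
})

test_that("homopolymer indels hit runs at the configured, length-scaled rate", {
  cfg <- simulation_config(n_templates = 2L, template_length = 150L,
                           n_reads = 200L, q_start = 40, q_slope = 0,
                           q_noise_sd = 0, q_read_sd = 0,
                           homopolymer_indel_rate = 0.2, frac_bad_reads = 0,
                           length_sd = 0, seed = 23L)
  sim <- simulate_community(cfg)
  runs_per_template <- vapply(sim$templates, function(t)
    sum(pmin(1, 0.2 * (find_runs(t)$length - 3))), numeric(1))
  expected <- sum(runs_per_template[sim$reads$template_id])
  observed <- sum(sim$truth$reads$n_indels)
  if (expected > 0) {
    expect_lt(abs(observed - expected), 4 * sqrt(expected))
    expect_gt(observed, 0)
  } else {
    expect_identical(observed, 0L)
  }
  # indels change read length by exactly +-1 per event
  delta <- nchar(sim$reads$bases) - 150L
  expect_true(all(abs(delta) <= sim$truth$reads$n_indels))
})

test_that("with errors on and filtering off, observed richness is inflated", {
  sim <- std_sim("noisy_small",
                 simulation_config(n_templates = 6L, template_length = 200L,
                                   n_reads = 150L, seed = 29L))
  ref <- run_refinement(sim$reads,
                        filter_config(mode = "none",
                                      primer = "tagtgtagatGTGCCAGCMGCNGCGG"))
  cl <- cluster_reads(ref$reads, 0.03)
  expect_gt(length(cl$otu_sizes), sim$truth$true_richness)
})
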