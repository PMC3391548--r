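test_that("compute_trim_length is floor(mean - sample sd) of raw lengths", {
  expect_identical(compute_trim_length(mk_rs(strrep("A", c(250, 250, 250)))), 250L)
  # lengths (300, 250, 200): mean 250, sample sd 50 -> 200
  expect_identical(compute_trim_length(mk_rs(strrep("A", c(300, 250, 200)))), 200L)
  expect_identical(compute_trim_length(mk_rs(strrep("A", 42))), 42L)  # sd = 0
  expect_error(compute_trim_length(ReadSet()), "empty")
})

test_that("trim_reads truncates from the 5' end and drops short reads", {
  rs <- mk_rs(c("ACGTA", "ACGTACGTAC"))
  tr <- trim_reads(rs, 6L)
  expect_identical(tr$removed_count, 1L)
  expect_identical(read_lengths(tr$reads), 6L)

  tr0 <- trim_reads(rs, 4L)
  expect_identical(tr0$removed_count, 0L)
  expect_true(all(read_lengths(tr0$reads) == 4L))

  rs2 <- mk_rs("ACGTACGT", quals = list(rep(30L, 8)))
  tr2 <- trim_reads(rs2, 4L)
  expect_identical(tr2$reads$bases, "ACGT")
  expect_identical(tr2$reads$quals[[1]], rep(30L, 4))
})

test_that("fraction-mode quality filter uses strict < with inclusive allowance", {
  q1 <- c(rep(26L, 10), rep(40L, 90))
  rs <- mk_rs(strrep("A", 100), quals = list(q1))
  expect_length(quality_filter_fraction(rs, 27, 0.10)$reads, 1)  # 10/100 <= 0.10
  expect_length(quality_filter_fraction(rs, 27, 0.09)$reads, 0)  # 0.10 > 0.09
  # all quals equal to the cutoff: strict < counts zero bases
  rs2 <- mk_rs("ACGT", quals = list(rep(27L, 4)))
  expect_length(quality_filter_fraction(rs2, 27, 0)$reads, 1)
})

test_that("fraction-mode filter agrees with a brute-force oracle", {
  withr::local_seed(21)
  for (rep in 1:5) {
    rs <- random_readset(30)
    q <- sample(20:35, 1); f <- stats::runif(1, 0, 0.5)
    kept <- quality_filter_fraction(rs, q, f)$reads$id
    expect_identical(kept, rs$id[oracle_fraction_keep(rs$quals, q, f)])
  }
})

test_that("end trimming truncates at the first sub-threshold base", {
  rs <- mk_rs("ACGT", quals = list(c(40L, 40L, 20L, 40L)))
  et <- quality_end_trim(rs, 27, min_length = 2)
  expect_identical(et$removed_count, 0L)
  expect_identical(et$reads$bases, "AC")
  expect_identical(et$reads$quals[[1]], c(40L, 40L))

  rs2 <- mk_rs("ACGT", quals = list(c(20L, 40L, 40L, 40L)))
  expect_identical(quality_end_trim(rs2, 27, min_length = 1)$removed_count, 1L)

  rs3 <- mk_rs("ACGT", quals = list(rep(30L, 4)))
  expect_identical(quality_end_trim(rs3, 27)$reads$bases, "ACGT")
})

test_that("ambiguous filter removes exactly the N-containing reads", {
  af <- ambiguous_filter(mk_rs(c("ACGT", "ACNT")))
  expect_identical(af$removed_count, 1L)
  expect_identical(af$reads$bases, "ACGT")
  expect_identical(ambiguous_filter(ReadSet())$removed_count, 0L)
})

test_that("primer filter applies IUPAC degeneracy with zero mismatches", {
  primer <- "tagtgtagatGTGCCAGCMGCNGCGG"
  good <- paste0("TAGTGTAGATGTGCCAGCAGCTGCGG", "ACGTACGT")  # A in M, T in N
  bad  <- paste0("TAGTGTAGATGTGCCAGCGGCTGCGG", "ACGTACGT")  # G not in M={A,C}
  rs <- mk_rs(c(good, bad))
  pf <- primer_filter(rs, primer, strip = FALSE)
  expect_identical(pf$removed_count, 1L)
  expect_identical(pf$reads$id, "r1")

  ps <- primer_filter(mk_rs(good), primer, strip = TRUE)
  expect_identical(nchar(ps$reads$bases), nchar(good) - nchar(primer))
  expect_identical(lengths(ps$reads$quals), nchar(good) - nchar(primer))

  # read shorter than the primer counts as a primer error
  expect_identical(primer_filter(mk_rs("TAGT"), primer)$removed_count, 1L)
})

test_that("run_refinement on the planted fixture yields ledger (5,4,2,1) and 8 kept", {
  fx <- planted_fixture()
  res <- run_refinement(fx$reads, fx$config)
  expect_identical(unname(res$ledger$stage_removals),
                   c(5L, 4L, 2L, 1L))
  expect_identical(res$ledger$remaining, 8L)
  expect_identical(res$ledger$raw_count, 20L)
  expect_equal(res$ledger$percent_removed, 12 / 20)
})

test_that("identity pipeline removes nothing", {
  withr::local_seed(22)
  rs <- random_readset(10)
  res <- run_refinement(rs, filter_config(mode = "none", trim_rule = "none"))
  expect_identical(unname(res$ledger$stage_removals), rep(0L, 4))
  expect_identical(res$ledger$remaining, length(rs))
})

test_that("conservation holds for random configs; ledger rejects violations", {
  withr::local_seed(23)
  for (rep in 1:8) {
    rs <- random_readset(40)
    cfg <- filter_config(q_cutoff = sample(20:35, 1),
                         allowed_fraction = stats::runif(1, 0, 0.3),
                         mode = sample(c("fraction", "end_trim", "none"), 1),
                         trim_rule = sample(c("mean_minus_sd", "none", "fixed:70"), 1))
    res <- run_refinement(rs, cfg)
    expect_identical(res$ledger$raw_count,
                     res$ledger$remaining + sum(res$ledger$stage_removals))
  }
  expect_error(removal_ledger(10, c(length = 1L, quality = 1L), 9), "conservation")
})

test_that("remaining reads are monotone in filter stringency", {
  withr::local_seed(24)
  rs <- random_readset(80, q_min = 15, q_max = 40)
  remaining <- function(q, f) {
    run_refinement(rs, filter_config(q_cutoff = q, allowed_fraction = f,
                                     trim_rule = "fixed:60"))$ledger$remaining
  }
  for (f in c(0.10, 0.15)) {
    r <- vapply(c(25L, 27L, 30L, 32L), remaining, integer(1), f = f)
    expect_true(all(diff(r) <= 0))
  }
  for (q in c(25L, 30L)) {
    expect_gte(remaining(q, 0.15), remaining(q, 0.10))
  }
})

test_that("refinement is idempotent at a fixed trim length", {
  fx <- planted_fixture()
  first <- run_refinement(fx$reads, fx$config)
  cfg2 <- filter_config(q_cutoff = 27L, allowed_fraction = 0.15,
                        primer = NULL,   # primer already stripped
                        trim_rule = paste0("fixed:", first$trim_length - nchar(fx$primer)))
  second <- run_refinement(first$reads, cfg2)
  expect_identical(sum(second$ledger$stage_removals), 0L)
  expect_identical(second$reads$bases, first$reads$bases)
})

test_that("quality_summary averages per-read means, unweighted", {
  expect_equal(quality_summary(mk_rs("AC", quals = list(c(30L, 30L)))), 30)
  rs <- mk_rs(c("ACGT", "AC"), quals = list(rep(20L, 4), rep(40L, 2)))
  expect_equal(quality_summary(rs), 30)   # lengths do not weight the mean
  expect_error(quality_summary(ReadSet()), "empty")

  # trimming off a lowest-Q 3' tail cannot decrease the summary
  withr::local_seed(25)
  for (rep in 1:5) {
    L <- 80L
    qv <- lapply(1:10, function(i) c(sample(30:40, L - 20, TRUE),
                                     sample(5:15, 20, TRUE)))
    rs <- mk_rs(vapply(rep(L, 10), random_seq, ""), quals = qv)
    trimmed <- trim_reads(rs, L - 20L)$reads
    expect_gte(quality_summary(trimmed), quality_summary(rs))
  }
})
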