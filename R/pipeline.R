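#' Run the refinement grid and downstream analyses
#'
#' Runs the full pipeline -- refinement, OTU clustering, alpha diversity --
#' for every condition of a quality-filter grid: the cross product of
#' `q_cutoffs` and `fractions` (fraction mode), plus the two no-quality
#' baselines `full_noQ` (no trimming, no quality stage) and `trim_noQ`
#' (trimmed, no quality stage). Conditions are named `Q<cutoff>_<pct>` in
#' the conventional subscript notation, e.g. `Q27_15`.
#'
#' @param x a [ReadSet], or a [simulation_config()] (the community is then
#'   simulated first).
#' @param q_cutoffs integer vector of Phred cutoffs (default
#'   `c(25, 27, 30, 32)`).
#' @param fractions tolerated sub-threshold fractions (default
#'   `c(0.10, 0.15)`).
#' @param threshold clustering distance cutoff (default 0.03).
#' @param primer IUPAC primer to enforce/strip, or `NULL`.
#' @param strip_primer passed to [filter_config()].
#' @param do_cluster set `FALSE` to skip clustering and diversity (ledger
#'   accounting only).
#' @param rarefaction_step passed to [diversity_estimate()].
#' @return An object of class `RunManifest`: `conditions` (named list, one
#'   entry per condition with `ledger`, `reads`, `clustering`, `diversity`),
#'   `trim_length`, `seed`/`config` when simulated, and the input summary.
#' @export
run_grid <- function(x, q_cutoffs = c(25L, 27L, 30L, 32L),
                     fractions = c(0.10, 0.15),
                     threshold = 0.03, primer = NULL, strip_primer = TRUE,
                     do_cluster = TRUE, rarefaction_step = NULL) {
  config <- NULL
  if (inherits(x, "SimulationConfig")) {
    config <- x
    sim <- simulate_community(config)
    rs <- sim$reads
    if (is.null(primer)) primer <- config$primer
  } else if (inherits(x, "ReadSet")) {
    rs <- x
  } else stop("x must be a ReadSet or a SimulationConfig")

  conds <- list(full_noQ = filter_config(mode = "none", trim_rule = "none",
                                         primer = primer, strip_primer = strip_primer),
                trim_noQ = filter_config(mode = "none", primer = primer,
                                         strip_primer = strip_primer))
  for (f in sort(fractions, decreasing = TRUE)) {
    for (q in sort(q_cutoffs)) {
      nm <- sprintf("Q%d_%d", q, round(100 * f))
      conds[[nm]] <- filter_config(q_cutoff = q, allowed_fraction = f,
                                   mode = "fraction", primer = primer,
                                   strip_primer = strip_primer)
    }
  }

  out <- vector("list", length(conds))
  names(out) <- names(conds)
  trim_length <- NA_integer_
  for (nm in names(conds)) {
    res <- tryCatch({
      ref <- run_refinement(rs, conds[[nm]])
      if (nm == "trim_noQ" && !is.null(ref$trim_length))
        trim_length <- ref$trim_length
      cl <- div <- NULL
      if (do_cluster && length(ref$reads)) {
        cl <- cluster_reads(ref$reads, threshold = threshold)
        div <- diversity_estimate(abundance_vector(cl),
                                  rarefaction_step = rarefaction_step)
      }
      list(ledger = ref$ledger, reads = ref$reads, clustering = cl,
           diversity = div, error = NULL)
    }, error = function(e) {
      message("condition ", nm, " failed: ", conditionMessage(e))
      list(ledger = NULL, reads = NULL, clustering = NULL, diversity = NULL,
           error = conditionMessage(e))
    })
    out[[nm]] <- res
  }
  structure(list(conditions = out, input = rs, config = config,
                 threshold = threshold, trim_length = trim_length,
                 seed = if (!is.null(config)) config$seed else NA_integer_),
            class = "RunManifest")
}

#' @export
print.RunManifest <- function(x, ...) {
  cat("RunManifest with", length(x$conditions), "conditions\n")
  print(grid_summary(x))
  invisible(x)
}

#' Condition-level summary of a grid run
#'
#' @param manifest a `RunManifest`.
#' @return A data frame with one row per condition: remaining reads,
#'   percent removed, observed OTUs, Chao1 (+CI), Shannon H, evenness.
#' @export
grid_summary <- function(manifest) {
  stopifnot(inherits(manifest, "RunManifest"))
  rows <- lapply(names(manifest$conditions), function(nm) {
    cc <- manifest$conditions[[nm]]
    data.frame(
      condition = nm,
      remaining = if (!is.null(cc$ledger)) cc$ledger$remaining else NA_integer_,
      pct_removed = if (!is.null(cc$ledger)) 100 * cc$ledger$percent_removed else NA_real_,
      s_obs = if (!is.null(cc$diversity)) cc$diversity$s_obs else NA_integer_,
      chao1 = if (!is.null(cc$diversity)) cc$diversity$chao1 else NA_real_,
      chao1_lo = if (!is.null(cc$diversity)) cc$diversity$chao1_ci[1] else NA_real_,
      chao1_hi = if (!is.null(cc$diversity)) cc$diversity$chao1_ci[2] else NA_real_,
      shannon_h = if (!is.null(cc$diversity)) cc$diversity$shannon_h else NA_real_,
      evenness = if (!is.null(cc$diversity)) cc$diversity$evenness else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

fmt6 <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- signif(df[[j]], 6)
  df
}

write_tsv <- function(df, path) {
  utils::write.table(fmt6(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write the report tables of a grid run
#'
#' Emits plain tab-delimited tables under `out_dir`: the per-condition
#' removal ledgers, the diversity summary, the long-format rarefaction
#' table, cluster-removal and taxon-bias tables (when taxon labels are
#' present), and the homopolymer occurrence matrix of the trimmed
#' (no-quality) reads. Re-running on the same manifest overwrites
#' byte-identical files.
#'
#' @param manifest a `RunManifest`.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the character vector of files written.
#' @export
report <- function(manifest, out_dir) {
  stopifnot(inherits(manifest, "RunManifest"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()

  led <- do.call(rbind, lapply(names(manifest$conditions), function(nm) {
    l <- manifest$conditions[[nm]]$ledger
    if (is.null(l)) return(NULL)
    cbind(condition = nm, as.data.frame(l))
  }))
  f <- file.path(out_dir, "removal_ledgers.tsv")
  write_tsv(led, f); written <- c(written, f)

  f <- file.path(out_dir, "diversity.tsv")
  write_tsv(grid_summary(manifest), f); written <- c(written, f)

  rar <- do.call(rbind, lapply(names(manifest$conditions), function(nm) {
    d <- manifest$conditions[[nm]]$diversity
    if (is.null(d)) return(NULL)
    cbind(condition = nm, d$rarefaction)
  }))
  if (!is.null(rar)) {
    f <- file.path(out_dir, "rarefaction.tsv")
    write_tsv(rar, f); written <- c(written, f)
  }

  trim <- manifest$conditions[["trim_noQ"]]
  if (!is.null(trim$reads)) {
    f <- file.path(out_dir, "homopolymers.tsv")
    tab <- tabulate_homopolymers(trim$reads)
    utils::write.table(cbind(base = rownames(tab), as.data.frame(unclass(tab))),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
  }

  if (length(manifest$input) && any(!is.na(manifest$input$taxon))) {
    bias_rows <- do.call(rbind, lapply(names(manifest$conditions), function(nm) {
      cc <- manifest$conditions[[nm]]
      if (is.null(cc$reads) || nm %in% c("full_noQ", "trim_noQ") ||
          length(cc$reads) < 1) return(NULL)
      td <- taxon_fractions(manifest$input, cc$reads)
      r2 <- tryCatch(r_squared_identity(td), error = function(e) NA_real_)
      cbind(condition = nm, td, r_squared = r2)
    }))
    if (!is.null(bias_rows)) {
      f <- file.path(out_dir, "taxon_bias.tsv")
      write_tsv(bias_rows, f); written <- c(written, f)
    }
  }

  if (!is.null(trim$clustering)) {
    rem_rows <- do.call(rbind, lapply(names(manifest$conditions), function(nm) {
      cc <- manifest$conditions[[nm]]
      if (is.null(cc$reads) || nm %in% c("full_noQ", "trim_noQ")) return(NULL)
      removed <- setdiff(names(trim$clustering$assignment), cc$reads$id)
      prof <- removal_by_cluster(trim$clustering, removed)
      if (!nrow(prof)) return(NULL)
      cbind(condition = nm, as.data.frame(prof))
    }))
    if (!is.null(rem_rows)) {
      f <- file.path(out_dir, "cluster_removal.tsv")
      write_tsv(rem_rows, f); written <- c(written, f)
    }
  }
  invisible(written)
}
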