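# shared fixture builders -- everything is generated in code

# quick ReadSet: constant quality unless per-read vectors are given
mk_rs <- function(bases, quals = NULL, q = 35L, ids = NULL, taxon = NULL) {
  n <- length(bases)
  if (is.null(ids)) ids <- sprintf("r%d", seq_len(n))
  if (is.null(quals)) quals <- lapply(nchar(bases), function(L) rep(as.integer(q), L))
  ReadSet(id = ids, bases = bases, quals = quals, taxon = taxon)
}

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                  collapse = "")

random_readset <- function(n, len_min = 60, len_max = 120, q_min = 10, q_max = 40) {
  lens <- sample(len_min:len_max, n, TRUE)
  mk_rs(vapply(lens, random_seq, ""),
        quals = lapply(lens, function(L) sample(q_min:q_max, L, TRUE)))
}

# 20-read fixture with non-overlapping planted defects:
# 5 short, 4 low-quality, 2 N-containing, 1 primer mutant, 8 clean.
# Raw lengths: 15 x 100 and 5 x 50 -> mean 87.5, sd 22.2 -> trim L = 65.
planted_fixture <- function() {
  primer <- "ACGTACGTAC"
  set.seed(77)
  body <- random_seq(90)
  full <- paste0(primer, body)               # 100 nt
  bases <- character(20)
  quals <- vector("list", 20)
  good_q <- function() rep(35L, 100)
  for (i in 1:8) { bases[i] <- full; quals[[i]] <- good_q() }          # clean
  for (i in 9:13) {                                                    # short
    bases[i] <- substr(full, 1, 50); quals[[i]] <- rep(35L, 50)
  }
  for (i in 14:17) {                                                   # low Q
    bases[i] <- full
    qv <- good_q(); qv[21:45] <- 20L                                   # 25/65 < Q27
    quals[[i]] <- qv
  }
  for (i in 18:19) {                                                   # N inside
    bases[i] <- paste0(substr(full, 1, 29), "N", substr(full, 31, 100))
    quals[[i]] <- good_q()
  }
  bases[20] <- paste0("T", substr(full, 2, 100))                       # primer error
  quals[[20]] <- good_q()
  list(reads = mk_rs(bases, quals = quals),
       primer = primer,
       config = filter_config(q_cutoff = 27L, allowed_fraction = 0.15,
                              mode = "fraction", primer = primer,
                              trim_rule = "mean_minus_sd"))
}

# standard simulated worlds shared across test files (computed lazily, once)
.sim_cache <- new.env(parent = emptyenv())
std_sim <- function(name, config) {
  if (is.null(.sim_cache[[name]]))
    .sim_cache[[name]] <- simulate_community(config)
  .sim_cache[[name]]
}
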