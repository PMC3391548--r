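#' Analytic rarefaction: expected richness in a subsample
#'
#' The hypergeometric expectation of the number of OTUs observed in a
#' uniform random subsample of `n` of the `N` reads:
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))`.
#' Binomial coefficients are evaluated in log space, so communities with
#' `N` up to about `1e6` reads pose no overflow problem.
#'
#' @param counts positive integer OTU abundances.
#' @param n subsample size, `0 <= n <= sum(counts)`.
#' @return Expected richness (numeric scalar).
#' @export
rarefaction_expected <- function(counts, n) {
  counts <- check_counts(counts)
  N <- sum(counts)
  if (n < 0 || n > N) stop("subsample size n must satisfy 0 <= n <= ", N)
  if (n == 0) return(0)
  # lchoose(N - Ni, n) = -Inf when n > N - Ni, giving the term value 1
  sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
}

#' Rarefaction curve
#'
#' Evaluates [rarefaction_expected()] on the grid `step, 2*step, ..., N`,
#' always including the endpoint `n = N` (where the expectation equals the
#' observed richness).
#'
#' @param counts positive integer OTU abundances.
#' @param step grid spacing, `>= 1`.
#' @return A data frame with columns `n` and `expected_richness`.
#' @export
rarefaction_curve <- function(counts, step = 1L) {
  counts <- check_counts(counts)
  stopifnot(step >= 1)
  N <- sum(counts)
  grid <- unique(c(seq(step, N, by = step), N))
  data.frame(n = grid,
             expected_richness = vapply(grid, function(n)
               rarefaction_expected(counts, n), numeric(1)))
}

#' Chao1 richness estimate with a 95\% confidence interval
#'
#' With `F1` singleton and `F2` doubleton OTUs the point estimate is
#' `S_obs + F1^2 / (2 F2)` when `F2 > 0` and the bias-corrected
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` otherwise. The confidence interval
#' uses the classic variance of the estimated number of unseen species
#' `T = chao1 - S_obs` -- for `F2 > 0`,
#' `var(T) = F2 (r^2/2 + r^3 + r^4/4)` with `r = F1/F2`; for `F2 = 0`,
#' `var(T) = F1(F1-1)/2 + F1(2F1-1)^2/4 - F1^4/(4 chao1)` -- combined with
#' the log-normal construction
#' `K = exp(z sqrt(log(1 + var/T^2)))`, CI `= (S_obs + T/K, S_obs + T K)`
#' at `z = 1.96`. With no singletons (or `T = 0`) the estimate equals
#' `S_obs` and the interval collapses to a point.
#'
#' @param counts positive integer OTU abundances.
#' @return A list with elements `estimate`, `ci_lower`, `ci_upper`,
#'   `s_obs`, `f1`, `f2`.
#' @export
chao1 <- function(counts) {
  counts <- check_counts(counts)
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) {
    est <- s_obs + f1^2 / (2 * f2)
    r <- f1 / f2
    v <- f2 * (r^2 / 2 + r^3 + r^4 / 4)
  } else {
    est <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    v <- if (f1 > 0)
      f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 - f1^4 / (4 * est)
    else 0
  }
  T <- est - s_obs
  if (T <= 0 || v <= 0) {
    ci <- c(est, est)
  } else {
    K <- exp(1.96 * sqrt(log(1 + v / T^2)))
    ci <- c(s_obs + T / K, s_obs + T * K)
  }
  list(estimate = est, ci_lower = ci[1], ci_upper = ci[2],
       s_obs = s_obs, f1 = f1, f2 = f2)
}

#' Shannon diversity and Pielou evenness
#'
#' `H = -sum p_i log(p_i)` with natural logarithms and `p_i = N_i / N`;
#' evenness is Pielou's `J = H / log(S_obs)`, taken to be 1 for a single
#' OTU (the limit convention: a one-OTU community is perfectly even).
#'
#' @param counts positive integer OTU abundances.
#' @return A list with elements `shannon_h` and `evenness`.
#' @export
shannon_evenness <- function(counts) {
  counts <- check_counts(counts)
  p <- counts / sum(counts)
  h <- -sum(p * log(p))
  s <- length(counts)
  list(shannon_h = h, evenness = if (s > 1) h / log(s) else 1)
}

#' All alpha-diversity statistics for one abundance vector
#'
#' @param counts positive integer OTU abundances.
#' @param rarefaction_step grid spacing of the rarefaction curve; `NULL`
#'   picks roughly 50 grid points.
#' @return An object of class `DiversityEstimate` with fields `s_obs`,
#'   `chao1`, `chao1_ci`, `shannon_h`, `evenness` and `rarefaction`.
#' @export
diversity_estimate <- function(counts, rarefaction_step = NULL) {
  counts <- check_counts(counts)
  N <- sum(counts)
  if (is.null(rarefaction_step)) rarefaction_step <- max(1L, N %/% 50L)
  c1 <- chao1(counts)
  se <- shannon_evenness(counts)
  structure(list(s_obs = length(counts),
                 chao1 = c1$estimate,
                 chao1_ci = c(c1$ci_lower, c1$ci_upper),
                 shannon_h = se$shannon_h,
                 evenness = se$evenness,
                 rarefaction = rarefaction_curve(counts, rarefaction_step)),
            class = "DiversityEstimate")
}

#' @export
print.DiversityEstimate <- function(x, ...) {
  cat(sprintf("DiversityEstimate: S_obs %d, Chao1 %.2f [%.2f, %.2f], H %.3f, J %.3f\n",
              x$s_obs, x$chao1, x$chao1_ci[1], x$chao1_ci[2],
              x$shannon_h, x$evenness))
  invisible(x)
}

check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (!length(counts)) stop("abundance vector is empty")
  if (any(counts <= 0) || any(counts != floor(counts)))
    stop("abundances must be positive integers")
  counts
}
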