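#' Pair-approximation kernels for the structure coefficients
#'
#' `psi_kernel()` and `phi_kernel()` are the two combinatorial kernels entering
#' the closed-form structure coefficients for death-birth updating on random
#' regular graphs of degree `k`:
#' \deqn{\Psi(k,i,l) = \binom{l}{k-1-i}\frac{1}{(k-2)(k-1)^l}
#'   + \binom{k-1-l}{k-i}\frac{1}{(k-1)^{k-1-l}}}
#' \deqn{\Phi(k,i,l) = \binom{l}{k-i}\frac{1}{(k-1)^l}
#'   + \binom{k-1-l}{k-1-i}\frac{1}{(k-2)(k-1)^{k-1-l}}}
#' with the convention that a binomial coefficient \eqn{\binom{a}{b}} vanishes
#' whenever `b < 0` or `b > a` (R's `choose()` already implements this).
#' The two kernels are reflections of one another:
#' `phi_kernel(k, i, l) == psi_kernel(k, i, k - 1 - l)`.
#'
#' @param k Degree, integer `>= 3`.
#' @param i Number of A-players among the `k` co-players, `0 <= i <= k`.
#' @param l Summation index, `0 <= l <= k` (vectorised).
#' @return Numeric vector of kernel values.
#' @export
psi_kernel <- function(k, i, l) {
  if (k < 3) stop("psi/phi kernels require k >= 3", call. = FALSE)
  choose(l, k - 1 - i) / ((k - 2) * (k - 1)^l) +
    choose(k - 1 - l, k - i) / (k - 1)^(k - 1 - l)
}

#' @rdname psi_kernel
#' @export
phi_kernel <- function(k, i, l) {
  if (k < 3) stop("psi/phi kernels require k >= 3", call. = FALSE)
  choose(l, k - i) / (k - 1)^l +
    choose(k - 1 - l, k - 1 - i) / ((k - 2) * (k - 1)^(k - 1 - l))
}

# Scalar part of sigma that depends on the configuration only through
# S = sum(s): sigma_{s} = sigma_total(k, S) * hypergeometric(s | S).
sigma_total_S <- function(k, S) {
  l <- 0:k
  pref <- (k - 2)^(k - S) / (k^2 * (k + 1) * (k + 2))
  pref * sum((k - l) * ((2 * k + (k - 2) * l) * psi_kernel(k, S, l) +
                        (k^2 - (k - 2) * l) * phi_kernel(k, S, l)))
}

#' Closed-form structure coefficient of one configuration
#'
#' Computes the structure coefficient \eqn{\sigma_{s_1 \cdots s_n}} for
#' death-birth updating on a large random regular graph with degree profile
#' `(k; g)`, under weak selection and pair approximation:
#' \deqn{\sigma_{s_1\cdots s_n} = \frac{(k-2)^{k-S}}{k^2(k+1)(k+2)}
#'   \frac{\prod_j \binom{g_j}{s_j}}{\binom{k}{S}}
#'   \sum_{l=0}^{k}(k-l)\left\{[2k+(k-2)l]\Psi(k,S,l)
#'   + [k^2-(k-2)l]\Phi(k,S,l)\right\}}
#' where \eqn{S = \sum_j s_j}. The multivariate hypergeometric factor
#' \eqn{\prod_j\binom{g_j}{s_j}/\binom{k}{S}} is the probability of the typed
#' configuration given its total, so edge diversity factorises out of the
#' structure coefficient: \eqn{\sigma_{s}} is the degree-only coefficient
#' \eqn{\sigma_S} times the chance of seeing that split of `S` A-neighbours
#' across types.
#'
#' All coefficients are strictly positive and the full table sums to one, so
#' the table is a probability distribution over configurations; its mean obeys
#' \eqn{\sum_s \sigma_s s_i = g_i(k+1)/(2k)}.
#'
#' @param profile A [degree_profile()].
#' @param s Integer configuration vector (`0 <= s[i] <= g[i]`).
#' @return A single positive number.
#' @seealso [sigma_table()] for the whole lattice at once.
#' @examples
#' sigma_coefficient(degree_profile(5, c(3, 2)), c(1, 1))
#' @export
sigma_coefficient <- function(profile, s) {
  profile <- as_profile(profile)
  s <- validate_config(profile, s)
  S <- sum(s)
  hyp <- prod(choose(profile$g, s)) / choose(profile$k, S)
  hyp * sigma_total_S(profile$k, S)
}

#' Table of all structure coefficients for a degree profile
#'
#' @param profile A [degree_profile()].
#' @return An object of class `"sigma_table"`: a data frame with the `n`
#'   configuration columns `s1 ... sn` followed by a `sigma` column, one row
#'   per configuration in the order of [config_grid()]. The profile is
#'   attached as attribute `"profile"`.
#' @examples
#' st <- sigma_table(degree_profile(5, c(3, 2)))
#' sum(st$sigma)  # 1
#' @export
sigma_table <- function(profile) {
  profile <- as_profile(profile)
  grid <- config_grid(profile)
  S <- rowSums(grid)
  totals <- vapply(0:profile$k, function(i) sigma_total_S(profile$k, i),
                   numeric(1))
  hyp <- apply(grid, 1L, function(s) prod(choose(profile$g, s))) /
    choose(profile$k, S)
  out <- as.data.frame(grid)
  out$sigma <- hyp * totals[S + 1L]
  attr(out, "profile") <- profile
  class(out) <- c("sigma_table", "data.frame")
  out
}

#' @export
print.sigma_table <- function(x, ...) {
  p <- attr(x, "profile")
  cat("Structure coefficients for k =", p$k, " g = (",
      paste(p$g, collapse = ", "), ")  [", nrow(x), "configurations ]\n")
  print.data.frame(x, row.names = FALSE, ...)
  cat("sum =", format(sum(x$sigma), digits = 15), "\n")
  invisible(x)
}

#' Marginal structure coefficients
#'
#' Sums a sigma table down to a vector indexed by a single count. With
#' `mode = "total"` the marginal is over the total number of A-neighbours
#' `S = sum(s)` (defined for any profile and equal to the single-type table at
#' the same `k`). With `mode = "first"` it is over the first coordinate,
#' \eqn{\tilde\sigma_s = \sum_{s_2}\cdots\sum_{s_n} \sigma_{s s_2 \cdots s_n}},
#' the object entering the reduced rule for diverse multiplayer games with
#' equal group sizes.
#'
#' @param table A [sigma_table()].
#' @param mode `"total"` or `"first"`.
#' @return Named numeric vector `sigma~_0 ... sigma~_max`; sums to the same
#'   total as the table (one).
#' @export
marginal_sigma <- function(table, mode = c("total", "first")) {
  mode <- match.arg(mode)
  profile <- attr(table, "profile")
  n <- profile$n
  scols <- as.matrix(table[, seq_len(n), drop = FALSE])
  key <- if (mode == "total") rowSums(scols) else scols[, 1L]
  upper <- if (mode == "total") profile$k else profile$g[1L]
  out <- vapply(0:upper, function(v) sum(table$sigma[key == v]), numeric(1))
  names(out) <- 0:upper
  out
}

#' Mean configuration under the structure coefficients
#'
#' Viewing the sigma table as a probability distribution over configurations,
#' returns the per-type means `E[s_i] = sum(sigma * s_i)`. These obey the
#' identity `E[s_i] = g_i (k + 1) / (2 k)`, the workhorse behind the reduction
#' of edge-dependent pairwise games to a single averaged game.
#'
#' @param table A [sigma_table()].
#' @return Numeric vector of length `n`.
#' @export
expected_config <- function(table) {
  profile <- attr(table, "profile")
  scols <- as.matrix(table[, seq_len(profile$n), drop = FALSE])
  as.numeric(crossprod(scols, table$sigma))
}
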