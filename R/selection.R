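#' Left side of the sigma rule
#'
#' Under weak selection, strategy A fixates more readily than B
#' (`rho_A > rho_B`) exactly when the expected "gains from flipping" are
#' positive:
#' \deqn{\sum_{s_1=0}^{g_1}\cdots\sum_{s_n=0}^{g_n}
#'   \sigma_{s_1\cdots s_n}\,(a_{s_1\cdots s_n} -
#'   b_{(g_1-s_1)\cdots(g_n-s_n)}) > 0.}
#' This function returns that left-hand side. The flipped index `g - s` is the
#' payoff a focal B-player would earn if every player in the neighbourhood
#' simultaneously switched strategy.
#'
#' @param table A [sigma_table()].
#' @param tensor A [payoff_tensor()] on the same profile.
#' @return A single number; positive favours A, negative favours B.
#' @export
sigma_rule_lhs <- function(table, tensor) {
  profile <- attr(table, "profile")
  tp <- tensor$profile
  if (profile$k != tp$k || !identical(profile$g, tp$g))
    stop("sigma table and payoff tensor are on different profiles",
         call. = FALSE)
  flip <- flip_permutation(profile)
  sum(table$sigma * (tensor$a - tensor$b[flip]))
}

# index permutation sending configuration s to g - s
flip_permutation <- function(profile) {
  grid <- config_grid(profile)
  gmat <- matrix(profile$g, nrow(grid), profile$n, byrow = TRUE)
  apply(gmat - grid, 1L, function(s) config_index(profile, s))
}

#' Selection verdict under weak selection
#'
#' Wraps the sign of the sigma-rule left side together with the predicted
#' weak-selection fixation-probability difference `rho_A - rho_B = omega *
#' lhs`.
#'
#' @param lhs Left side of the sigma rule, as from [sigma_rule_lhs()].
#' @param omega Selection intensity, `0 < omega << 1`.
#' @param neutral_band Absolute values of `lhs` below this count as neutral
#'   (float noise near criticality); default `1e-12`.
#' @return An object of class `"selection_verdict"`: list with `lhs`,
#'   `favored` (`"A"`, `"B"` or `"neutral"`), `omega` and `predicted_diff`.
#' @export
selection_verdict <- function(lhs, omega = 0.01, neutral_band = 1e-12) {
  if (omega <= 0) stop("'omega' must be positive", call. = FALSE)
  favored <- if (abs(lhs) < neutral_band) "neutral" else if (lhs > 0) "A" else "B"
  structure(list(lhs = lhs, favored = favored, omega = omega,
                 predicted_diff = omega * lhs),
            class = "selection_verdict")
}

#' @export
print.selection_verdict <- function(x, ...) {
  cat("sigma rule lhs:", format(x$lhs, digits = 8), "-> favors", x$favored,
      "\npredicted rho_A - rho_B at omega =", x$omega, ":",
      format(x$predicted_diff, digits = 8), "\n")
  invisible(x)
}

#' Critical benefit-to-cost ratio of a benefit-parameterised family
#'
#' For game families whose sigma-rule left side is affine in the benefit
#' parameter (true of every family in this package), the critical ratio where
#' selection is exactly neutral is found in closed form from two evaluations
#' of the rule, at benefits 1 and 2, with the cost held fixed.
#'
#' @param make_tensor Function of one argument `B` returning the family's
#'   [payoff_tensor()] at benefit `B` and the fixed cost.
#' @param profile A [degree_profile()].
#' @param cost The fixed cost at which `make_tensor` operates (default 1), so
#'   the returned value is the ratio `(B/C)*`.
#' @param table Optional precomputed [sigma_table()] for `profile`.
#' @return The critical ratio `(B/C)*`; `Inf` if the benefit cannot turn
#'   selection in favour of A (cooperation never favoured).
#' @examples
#' pr <- degree_profile(5, c(3, 2))
#' critical_ratio(function(B) donation_tensor(pr, c(B, B), c(1, 1)), pr)  # k
#' @export
critical_ratio <- function(make_tensor, profile, cost = 1,
                           table = sigma_table(profile)) {
  profile <- as_profile(profile)
  l1 <- sigma_rule_lhs(table, make_tensor(1))
  l2 <- sigma_rule_lhs(table, make_tensor(2))
  slope <- l2 - l1
  l0 <- l1 - slope  # affine extrapolation to benefit 0
  if (abs(slope) < 1e-14)
    stop("sigma-rule lhs does not depend on the benefit parameter",
         call. = FALSE)
  if (slope < 0) return(Inf)
  (-l0 / slope) / cost
}

#' Critical ratios for the division-of-labour threshold games
#'
#' Evaluates the closed-form critical benefit-to-cost ratios for the
#' two-role threshold public goods game directly from the structure
#' coefficients. With labor division (accumulative goods):
#' \deqn{(B/C)^* = 1 / \left[\sum_{s_1=0}^{g_1}\sum_{s_2=1}^{g_2}
#'   (s_1+s_2+1)\sigma_{s_1 s_2} - \sum_{s_1=0}^{g_1-1}\sum_{s_2=0}^{g_2-1}
#'   (k-s_1-s_2)\sigma_{s_1 s_2}\right]}
#' and without labor division (single threshold 2):
#' \deqn{(B/C)^* = 1 / \left[\sum_{s=1}^{k}(s+1)\sigma_s -
#'   \sum_{s=0}^{k-2}(k-s)\sigma_s\right].}
#' The non-accumulative counterparts drop the `(s1+s2+1)` / `(k-s1-s2)`
#' multipliers. A non-positive denominator means no finite benefit favours
#' cooperation and `Inf` is returned.
#'
#' @param k Total degree.
#' @param g1,g2 Same-role and cross-role degrees, `g1 + g2 = k` (ignored when
#'   `labor_division = FALSE`).
#' @param labor_division Logical; `FALSE` gives the single-threshold
#'   comparison case.
#' @param accumulative Logical; whether goods grow with each cooperator above
#'   threshold.
#' @return The critical ratio `(B/C)*` (possibly `Inf`).
#' @export
critical_dol <- function(k, g1 = NULL, g2 = NULL, labor_division = TRUE,
                         accumulative = TRUE) {
  if (labor_division) {
    if (is.null(g1) || is.null(g2) || g1 + g2 != k)
      stop("need g1 + g2 = k for the division-of-labour case", call. = FALSE)
    profile <- degree_profile(k, c(g1, g2))
    st <- sigma_table(profile)
    s1 <- st$s1
    s2 <- st$s2
    w_gain <- if (accumulative) s1 + s2 + 1 else 1
    w_loss <- if (accumulative) k - s1 - s2 else 1
    denom <- sum((st$sigma * w_gain)[s2 >= 1]) -
      sum((st$sigma * w_loss)[s1 <= g1 - 1 & s2 <= g2 - 1])
  } else {
    st <- marginal_sigma(sigma_table(degree_profile(k, k)), "total")
    s <- 0:k
    w_gain <- if (accumulative) s + 1 else rep(1, k + 1)
    w_loss <- if (accumulative) k - s else rep(1, k + 1)
    denom <- sum((st * w_gain)[s >= 1]) - sum((st * w_loss)[s <= k - 2])
  }
  if (denom <= 0) Inf else 1 / denom
}

#' Critical-ratio scan over the division of labour
#'
#' Reproduces the division-of-labour comparison: for each `g1` the critical
#' `(B/C)*` with labour division (`g2 = k - g1`) next to the fixed
#' no-division value at the same `k`.
#'
#' @param k Total degree (default 40).
#' @param g1 Vector of same-role degrees to scan (default `1:(k - 1)`).
#' @param accumulative Logical.
#' @return Data frame with columns `g1`, `bc_dol`, `bc_ndol`.
#' @export
dol_scan <- function(k = 40, g1 = seq_len(k - 1), accumulative = TRUE) {
  bc_ndol <- critical_dol(k, labor_division = FALSE,
                          accumulative = accumulative)
  bc_dol <- vapply(g1, function(g) critical_dol(k, g, k - g,
                                                accumulative = accumulative),
                   numeric(1))
  data.frame(g1 = g1, bc_dol = bc_dol, bc_ndol = bc_ndol)
}

#' Reduced selection condition for edge-dependent pairwise games
#'
#' For pairwise games played across each edge type, the sigma rule collapses
#' to the single-coefficient condition
#' \deqn{\frac{k+1}{k-1}\bar\alpha + \bar\beta > \bar\gamma +
#'   \frac{k+1}{k-1}\bar\theta}
#' where the bars are degree-weighted means over types, e.g.
#' `alphabar = sum(g * alpha) / k`. The structure coefficient of the averaged
#' game is `(k + 1) / (k - 1)`, the familiar single-type value. The full
#' sigma-rule left side equals `(k - 1) / 2` times this reduced left side.
#'
#' @param profile A [degree_profile()].
#' @param alpha,beta,gamma,theta Per-type 2x2 payoff entries.
#' @param omega Selection intensity for the verdict.
#' @return A [selection_verdict()] whose `lhs` is the reduced left side.
#' @export
pairwise_condition <- function(profile, alpha, beta, gamma, theta,
                               omega = 0.01) {
  profile <- as_profile(profile)
  if (any(lengths(list(alpha, beta, gamma, theta)) != profile$n))
    stop("need one 2x2 matrix per edge type", call. = FALSE)
  k <- profile$k
  wbar <- function(v) sum(profile$g * v) / k
  lhs <- (k + 1) / (k - 1) * wbar(alpha) + wbar(beta) -
    wbar(gamma) - (k + 1) / (k - 1) * wbar(theta)
  selection_verdict(lhs, omega)
}

#' Number of structure coefficients needed for a profile
#'
#' Let `m` be the number of distinct per-type degrees among `g` and `n_i` the
#' multiplicity of each distinct value `g_i`. A general payoff structure needs
#' `prod(choose(g_i + n_i, n_i))` coefficients, while additive diverse
#' multiplayer games need only `sum(g_i + 1)`. Without edge diversity
#' (`m = 1`, `g = k`) both reduce to the classic `k + 1`.
#'
#' @param profile A [degree_profile()].
#' @param payoff_class `"general"` or `"diverse-additive"`.
#' @return An integer count.
#' @export
coefficient_count <- function(profile,
                              payoff_class = c("general", "diverse-additive")) {
  profile <- as_profile(profile)
  payoff_class <- match.arg(payoff_class)
  tab <- table(profile$g)
  gvals <- as.integer(names(tab))
  mult <- as.integer(tab)
  if (payoff_class == "general")
    as.integer(round(prod(choose(gvals + mult, mult))))
  else
    as.integer(sum(gvals + 1L))
}
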