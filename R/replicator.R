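#' Pair-approximation replicator equation on edge-typed regular graphs
#'
#' In the infinite-population limit the frequency `x` of A-players obeys
#' \deqn{\dot x = \frac{\omega (k-2)}{k^2} x (1-x) f(x)}
#' where `f(x)` mixes the payoff drifts `Lambda_a - Lambda_b` over binomially
#' distributed neighbourhood configurations:
#' \deqn{f(x) = \sum_{s} \prod_j \binom{g_j}{s_j} x^{s_j}(1-x)^{g_j-s_j}
#'   \,(\Lambda_a(s) - \Lambda_b(s)).}
#' `Lambda_a(s)` averages, over a binomial `Binom(g_j - s_j, z)` thinning of
#' the focal's B-neighbours with `z = 1/(k-1)`, the terms
#' \deqn{\sum_j (s_j + r_j)\, a_{s+r} + \left(z s_j + \frac{r_j}{z}\right)
#'   a_{s+r-\delta_j}}
#' and `Lambda_b(s)` is its mirror image (thinning the A-neighbours, payoffs
#' `b`, coefficient `z (g_j - s_j) + r_j / z`, index shifted up by
#' `delta_j`). Shifted terms whose index would leave the lattice carry a zero
#' coefficient and are dropped.
#'
#' The replicator model is consistent with the finite-population sigma rule:
#' integrating the drift gives
#' `integrate(f, 0, 1) == k^2 / (k - 1) * sigma_rule_lhs(...)` exactly, so the
#' infinite-population flow and the fixation comparison always agree on which
#' strategy is favoured on average.
#'
#' @param tensor A [payoff_tensor()].
#' @param omega Selection intensity.
#' @return An object of class `"replicator_model"`: list with `profile`,
#'   `tensor`, `omega` and the derived constant `z = 1/(k-1)`.
#' @export
replicator_model <- function(tensor, omega = 0.01) {
  if (!inherits(tensor, "payoff_tensor"))
    stop("'tensor' must be a payoff_tensor", call. = FALSE)
  if (omega <= 0) stop("'omega' must be positive", call. = FALSE)
  profile <- tensor$profile
  structure(list(profile = profile, tensor = tensor, omega = omega,
                 z = 1 / (profile$k - 1)),
            class = "replicator_model")
}

# enumerate r-lattice 0..lim (vector) as matrix, reusing config machinery
r_grid <- function(lim) {
  if (all(lim == 0L)) return(matrix(0L, 1L, length(lim)))
  cols <- rev(expand.grid(rev(lapply(lim, function(m) 0:m)),
                          KEEP.OUT.ATTRS = FALSE))
  m <- as.matrix(cols)
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

#' Payoff drift terms of the replicator equation
#'
#' @param model A [replicator_model()].
#' @param s Integer configuration.
#' @return `lambda_a()` and `lambda_b()` each return a single number.
#' @rdname lambda
#' @export
lambda_a <- function(model, s) {
  p <- model$profile
  s <- validate_config(p, s)
  z <- model$z
  a <- model$tensor$a
  rs <- r_grid(p$g - s)
  tot <- 0
  for (row in seq_len(nrow(rs))) {
    r <- rs[row, ]
    w <- prod(choose(p$g - s, r) * z^r * (1 - z)^(p$g - s - r))
    inner <- 0
    sr <- s + r
    base_idx <- config_index(p, sr)
    for (j in seq_len(p$n)) {
      inner <- inner + (s[j] + r[j]) * a[base_idx]
      if (sr[j] >= 1L) {
        shifted <- sr
        shifted[j] <- shifted[j] - 1L
        inner <- inner + (z * s[j] + r[j] / z) * a[config_index(p, shifted)]
      } else if (z * s[j] + r[j] / z != 0) {
        stop("internal consistency error: nonzero coefficient for ",
             "out-of-range shifted configuration", call. = FALSE)
      }
    }
    tot <- tot + w * inner
  }
  tot
}

#' @rdname lambda
#' @export
lambda_b <- function(model, s) {
  p <- model$profile
  s <- validate_config(p, s)
  z <- model$z
  b <- model$tensor$b
  rs <- r_grid(s)
  tot <- 0
  for (row in seq_len(nrow(rs))) {
    r <- rs[row, ]
    w <- prod(choose(s, r) * z^r * (1 - z)^(s - r))
    inner <- 0
    sr <- s - r
    base_idx <- config_index(p, sr)
    for (j in seq_len(p$n)) {
      inner <- inner + (p$g[j] - s[j] + r[j]) * b[base_idx]
      if (sr[j] <= p$g[j] - 1L) {
        shifted <- sr
        shifted[j] <- shifted[j] + 1L
        inner <- inner + (z * (p$g[j] - s[j]) + r[j] / z) *
          b[config_index(p, shifted)]
      } else if (z * (p$g[j] - s[j]) + r[j] / z != 0) {
        stop("internal consistency error: nonzero coefficient for ",
             "out-of-range shifted configuration", call. = FALSE)
      }
    }
    tot <- tot + w * inner
  }
  tot
}

#' Replicator drift f(x) and velocity xdot(x)
#'
#' @param model A [replicator_model()].
#' @param x Frequency of A-players in `[0, 1]` (vectorised).
#' @return Numeric vector.
#' @rdname f_of_x
#' @export
f_of_x <- function(model, x) {
  if (any(x < 0 | x > 1)) stop("'x' must lie in [0, 1]", call. = FALSE)
  p <- model$profile
  grid <- config_grid(p)
  dl <- vapply(seq_len(nrow(grid)), function(i) {
    s <- grid[i, ]
    lambda_a(model, s) - lambda_b(model, s)
  }, numeric(1))
  cg <- apply(grid, 1L, function(s) prod(choose(p$g, s)))
  S <- rowSums(grid)
  vapply(x, function(xx) {
    wt <- cg * xx^S * (1 - xx)^(p$k - S)
    sum(wt * dl)
  }, numeric(1))
}

#' @rdname f_of_x
#' @export
xdot <- function(model, x) {
  p <- model$profile
  model$omega * (p$k - 2) / p$k^2 * x * (1 - x) * f_of_x(model, x)
}

#' Interior equilibria of the replicator dynamics
#'
#' Scans `f` for sign changes on a uniform grid over `(0, 1)` and refines
#' each bracket by bisection. The boundary fixed points 0 and 1 are always
#' present and not reported. A drift that is identically zero (neutral game)
#' is reported as degenerate.
#'
#' @param model A [replicator_model()].
#' @param grid_step Scan resolution (default `1e-3`).
#' @param tol Bisection tolerance on the root location (default `1e-10`).
#' @return A data frame with columns `x` and `stable` (logical: `f` crosses
#'   from positive to negative), zero rows if `f` has no interior sign change.
#'   Degenerate (neutral) dynamics return the data frame with attribute
#'   `degenerate = TRUE`.
#' @export
equilibria <- function(model, grid_step = 1e-3, tol = 1e-10) {
  # coarse values of f on a cached polynomial basis (f is a polynomial in x)
  xs <- seq(0, 1, by = grid_step)
  fs <- f_of_x(model, xs)
  out <- data.frame(x = numeric(0), stable = logical(0))
  if (all(abs(fs) < 1e-12)) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  roots <- numeric(0)
  stable <- logical(0)
  for (i in seq_len(length(xs) - 1L)) {
    if (fs[i] == 0 || sign(fs[i]) == sign(fs[i + 1L])) next
    lo <- xs[i]; hi <- xs[i + 1L]; flo <- fs[i]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      fm <- f_of_x(model, mid)
      if (fm == 0) { lo <- mid; hi <- mid; break }
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    root <- (lo + hi) / 2
    if (root > 0 && root < 1) {
      roots <- c(roots, root)
      stable <- c(stable, fs[i] > 0)
    }
  }
  data.frame(x = roots, stable = stable)
}

#' Integrate the replicator trajectory
#'
#' Numerically integrates `xdot` from `x0` with an adaptive solver, clipping
#' to `[0, 1]`.
#'
#' @param model A [replicator_model()].
#' @param x0 Initial frequency in `(0, 1)`.
#' @param horizon Final time.
#' @param step Output time step.
#' @return Data frame with columns `t` and `x`.
#' @export
trajectory <- function(model, x0, horizon, step = horizon / 200) {
  if (x0 <= 0 || x0 >= 1) stop("'x0' must lie in (0, 1)", call. = FALSE)
  # xdot is a polynomial in x; evaluate it through a precomputed coefficient
  # cache rather than re-deriving the lambdas at every solver step
  p <- model$profile
  grid <- config_grid(p)
  dl <- vapply(seq_len(nrow(grid)), function(i)
    lambda_a(model, grid[i, ]) - lambda_b(model, grid[i, ]), numeric(1))
  cg <- apply(grid, 1L, function(s) prod(choose(p$g, s)))
  S <- rowSums(grid)
  pref <- model$omega * (p$k - 2) / p$k^2
  rhs <- function(t, y, parms) {
    x <- min(max(y[1L], 0), 1)
    f <- sum(cg * x^S * (1 - x)^(p$k - S) * dl)
    list(pref * x * (1 - x) * f)
  }
  times <- seq(0, horizon, by = step)
  sol <- deSolve::ode(y = c(x = x0), times = times, func = rhs, parms = NULL,
                      atol = 1e-9, rtol = 1e-8)
  data.frame(t = sol[, 1L], x = pmin(pmax(sol[, 2L], 0), 1))
}

#' Large-degree mean payoffs with and without division of labour
#'
#' Closed-form average payoffs in an infinite population at cooperator
#' frequency `p`, for the non-accumulative threshold public goods game with
#' large degree `k`, writing \eqn{r = (k-2)/(k-1)}:
#' \deqn{\pi_A^{ndol} = [1 - r^k (1-p)^k] B - C}
#' \deqn{\pi_B^{ndol} = [1 - (1 - r p)^{k-1} (1 + k p - 2 p)] B}
#' \deqn{\pi_A^{dol} = [1 - r^{g_2} (1-p)^{g_2}] B - C}
#' \deqn{\pi_B^{dol} = [1 - (1 - r p)^{g_1}][1 - (1 - r p)^{g_2}] B}
#' Division of labour makes provision harder, so for `0 < p < 1` both
#' strategies transiently earn less: `pi_A_dol < pi_A_ndol` and
#' `pi_B_dol < pi_B_ndol`.
#'
#' @param p Cooperator frequency in `[0, 1]` (vectorised).
#' @param B,C Benefit and cost.
#' @param k Total degree.
#' @param g1,g2 Same-role and cross-role degrees with `g1 + g2 = k`.
#' @return Data frame with columns `p`, `pi_A_ndol`, `pi_B_ndol`, `pi_A_dol`,
#'   `pi_B_dol`.
#' @export
dol_mean_payoffs <- function(p, B, C, k, g1, g2) {
  if (g1 + g2 != k) stop("need g1 + g2 = k", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]", call. = FALSE)
  r <- (k - 2) / (k - 1)
  data.frame(
    p = p,
    pi_A_ndol = (1 - r^k * (1 - p)^k) * B - C,
    pi_B_ndol = (1 - (1 - r * p)^(k - 1) * (1 + k * p - 2 * p)) * B,
    pi_A_dol = (1 - r^g2 * (1 - p)^g2) * B - C,
    pi_B_dol = (1 - (1 - r * p)^g1) * (1 - (1 - r * p)^g2) * B)
}

#' Compare payoff ratios with and without division of labour
#'
#' Computes `pi_A / pi_B` under both regimes on a frequency grid and reports
#' which regime gives cooperators the better relative standing at each point.
#' Grid points where a `pi_B` vanishes are excluded (noted in the
#' `"excluded"` attribute).
#'
#' @param p Frequency grid, a vector inside `(0, 1)`.
#' @inheritParams dol_mean_payoffs
#' @return Data frame with columns `p`, `ratio_dol`, `ratio_ndol` and
#'   `dol_advantages_A` (logical).
#' @export
payoff_ratio_compare <- function(p, B, C, k, g1, g2) {
  if (any(p <= 0 | p >= 1)) stop("'p' grid must lie inside (0, 1)",
                                 call. = FALSE)
  mp <- dol_mean_payoffs(p, B, C, k, g1, g2)
  ok <- mp$pi_B_dol != 0 & mp$pi_B_ndol != 0
  out <- data.frame(p = mp$p[ok],
                    ratio_dol = mp$pi_A_dol[ok] / mp$pi_B_dol[ok],
                    ratio_ndol = mp$pi_A_ndol[ok] / mp$pi_B_ndol[ok])
  out$dol_advantages_A <- out$ratio_dol > out$ratio_ndol
  attr(out, "excluded") <- mp$p[!ok]
  out
}
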