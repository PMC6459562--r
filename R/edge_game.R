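#' Fit an evolutionary game model on an edge-typed regular graph
#'
#' `edge_game()` is the package's central constructor: it couples a payoff
#' tensor on a degree profile with a selection intensity, computes the
#' structure-coefficient table and the sigma rule, and returns a model object
#' with the usual methods (`print`, `summary`, `coef`, `predict`, `plot`,
#' `simulate`).
#'
#' @param tensor A [payoff_tensor()] (see the family constructors
#'   [pairwise_tensor()], [additive_tensor()], [dol_tensor()], ...).
#' @param omega Selection intensity, `0 < omega << 1` (default 0.01).
#' @return An object of class `"edge_game"`: list with `profile`, `tensor`,
#'   `omega`, `sigma` (the [sigma_table()]), `lhs` and `verdict`.
#' @examples
#' pr <- degree_profile(6, c(3, 3))
#' gm <- edge_game(additive_tensor(pr, list(volunteers_table(3, 5.55, 1),
#'                                          volunteers_table(3, 5.55, 1))))
#' gm
#' coef(gm)[1:5]
#' predict(gm)
#' @export
edge_game <- function(tensor, omega = 0.01) {
  if (!inherits(tensor, "payoff_tensor"))
    stop("'tensor' must be a payoff_tensor", call. = FALSE)
  if (omega <= 0) stop("'omega' must be positive", call. = FALSE)
  st <- sigma_table(tensor$profile)
  lhs <- sigma_rule_lhs(st, tensor)
  structure(list(profile = tensor$profile, tensor = tensor, omega = omega,
                 sigma = st, lhs = lhs,
                 verdict = selection_verdict(lhs, omega)),
            class = "edge_game")
}

#' @export
print.edge_game <- function(x, ...) {
  p <- x$profile
  cat("Evolutionary multiplayer game on an edge-typed regular graph\n")
  cat("  profile: k =", p$k, " g = (", paste(p$g, collapse = ", "), ")\n")
  cat("  selection intensity omega =", x$omega, "\n")
  cat("  sigma-rule lhs =", format(x$lhs, digits = 8),
      "-> natural selection favors",
      if (x$verdict$favored == "neutral") "neither strategy"
      else paste0("strategy ", x$verdict$favored), "\n")
  invisible(x)
}

#' @export
summary.edge_game <- function(object, ...) {
  eq <- equilibria(replicator_model(object$tensor, object$omega))
  structure(list(game = object, equilibria = eq),
            class = "summary.edge_game")
}

#' @export
print.summary.edge_game <- function(x, ...) {
  print(x$game)
  cat("  predicted rho_A - rho_B =",
      format(x$game$verdict$predicted_diff, digits = 8), "\n")
  if (isTRUE(attr(x$equilibria, "degenerate"))) {
    cat("  replicator dynamics: neutral (f identically zero)\n")
  } else if (nrow(x$equilibria) == 0L) {
    cat("  replicator dynamics: no interior equilibrium\n")
  } else {
    cat("  interior equilibria:\n")
    print(x$equilibria, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.edge_game <- function(object, ...) {
  st <- object$sigma
  n <- object$profile$n
  nm <- apply(as.matrix(st[, seq_len(n), drop = FALSE]), 1L, paste,
              collapse = ",")
  stats::setNames(st$sigma, paste0("sigma[", nm, "]"))
}

#' Predictions from a fitted edge game
#'
#' With `x = NULL`, returns the weak-selection [selection_verdict()]
#' (which strategy is favoured, and the predicted fixation-probability
#' difference `omega * lhs`). With a vector `x` of A-frequencies, returns the
#' infinite-population replicator velocity `xdot` at those frequencies.
#'
#' @param object An [edge_game()].
#' @param x Optional numeric vector of frequencies in `[0, 1]`.
#' @param ... Unused.
#' @export
predict.edge_game <- function(object, x = NULL, ...) {
  if (is.null(x)) return(object$verdict)
  xdot(replicator_model(object$tensor, object$omega), x)
}

#' Simulate the finite-population death-birth process of a fitted game
#'
#' Generates a random edge-typed regular graph realising the model's profile
#' and runs the compiled Monte Carlo engine.
#'
#' @param object An [edge_game()].
#' @param nsim Number of replicate runs per batch.
#' @param seed Optional integer master seed.
#' @param N Population size (default 500).
#' @param mode `"fixation"` (default) for [estimate_fixation()] or `"drift"`
#'   for [estimate_delta_p()].
#' @param ... Passed on to the estimator (e.g. `p_grid`, `max_generations`).
#' @return A `"fixation_estimate"` or the drift data frame.
#' @export
simulate.edge_game <- function(object, nsim = 1000L, seed = NULL, N = 500L,
                               mode = c("fixation", "drift"), ...) {
  mode <- match.arg(mode)
  gseed <- if (is.null(seed)) NULL else seed + 1000L
  graph <- generate_typed_graph(N, object$profile, seed = gseed)
  if (mode == "fixation")
    estimate_fixation(graph, object$tensor, object$omega, runs = nsim,
                      seed = seed, ...)
  else
    estimate_delta_p(graph, object$tensor, object$omega, reps = nsim,
                     seed = seed, ...)
}

#' Plot the replicator drift of a fitted edge game
#'
#' Draws `f(x)` (the sign of which drives the infinite-population dynamics)
#' over `[0, 1]` and marks interior equilibria: filled points are stable,
#' open points unstable.
#'
#' @param x An [edge_game()].
#' @param npoints Curve resolution.
#' @param ... Passed to [plot()].
#' @export
plot.edge_game <- function(x, npoints = 201L, ...) {
  model <- replicator_model(x$tensor, x$omega)
  xs <- seq(0, 1, length.out = npoints)
  fs <- f_of_x(model, xs)
  plot(xs, fs, type = "l", xlab = "frequency of A-players (x)",
       ylab = "replicator drift f(x)", ...)
  graphics::abline(h = 0, lty = 3)
  eq <- equilibria(model)
  if (nrow(eq) > 0L)
    graphics::points(eq$x, rep(0, nrow(eq)),
                     pch = ifelse(eq$stable, 19, 1), cex = 1.3)
  invisible(x)
}
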