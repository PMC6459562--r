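#' Per-node payoffs of a strategy assignment
#'
#' Every node plays one multiplayer game with its `k` neighbours: a node
#' playing A in neighbourhood configuration `s` earns `a_s`, a node playing B
#' earns `b_s`.
#'
#' @param graph A `typed_graph`.
#' @param strategies Logical or 0/1 vector over nodes (1 = A).
#' @param tensor A [payoff_tensor()] on the graph's profile.
#' @return Numeric vector of payoffs, one per node.
#' @export
evaluate_payoffs <- function(graph, strategies, tensor) {
  check_graph_tensor(graph, tensor)
  strategies <- as.integer(as.logical(strategies))
  vapply(seq_len(graph$N), function(v) {
    i <- config_index(graph$profile, neighborhood_config(graph, v, strategies))
    if (strategies[v] == 1L) tensor$a[i] else tensor$b[i]
  }, numeric(1))
}

check_graph_tensor <- function(graph, tensor) {
  gp <- graph$profile
  tp <- tensor$profile
  if (gp$k != tp$k || !identical(gp$g, tp$g))
    stop("payoff tensor profile does not match the graph profile",
         call. = FALSE)
  invisible(NULL)
}

check_fitness_positive <- function(tensor, omega) {
  worst <- 1 - omega + omega * min(tensor$a, tensor$b)
  if (worst <= 0)
    stop("fitness positivity violated: 1 - omega + omega * min(payoff) = ",
         format(worst), "; reduce omega", call. = FALSE)
  invisible(NULL)
}

graph_cpp_args <- function(graph, tensor) {
  list(nbr = graph$nbr - 1L, typ = graph$typ - 1L,
       g = as.integer(graph$profile$g), a = tensor$a, b = tensor$b)
}

#' One elementary death-birth event
#'
#' A uniformly random individual reconsiders its strategy and adopts the
#' strategy of neighbour `j` with probability proportional to `j`'s fitness
#' `F_j = 1 - omega + omega * payoff_j`.
#'
#' @param graph A `typed_graph`.
#' @param strategies 0/1 strategy vector (1 = A).
#' @param tensor A [payoff_tensor()].
#' @param omega Selection intensity.
#' @return The updated strategy vector.
#' @export
death_birth_step <- function(graph, strategies, tensor, omega = 0.01) {
  check_graph_tensor(graph, tensor)
  check_fitness_positive(tensor, omega)
  strategies <- as.integer(as.logical(strategies))
  i <- sample.int(graph$N, 1L)
  probs <- adoption_probabilities(graph, strategies, tensor, omega, i)
  j <- sample.int(graph$profile$k, 1L, prob = probs)
  strategies[i] <- strategies[graph$nbr[i, j]]
  strategies
}

#' Adoption probabilities at one node
#'
#' The probability that a death-birth event at `node` copies each of its
#' neighbours, `F_j / sum(F)`.
#'
#' @inheritParams death_birth_step
#' @param node The focal (dying) node.
#' @return Numeric vector of length `k` summing to one, aligned with
#'   `graph$nbr[node, ]`.
#' @export
adoption_probabilities <- function(graph, strategies, tensor, omega, node) {
  strategies <- as.integer(as.logical(strategies))
  pays <- evaluate_payoffs(graph, strategies, tensor)
  F <- 1 - omega + omega * pays[graph$nbr[node, ]]
  if (any(F <= 0))
    stop("non-positive fitness encountered", call. = FALSE)
  F / sum(F)
}

#' Monte Carlo fixation probabilities under death-birth updating
#'
#' Estimates `rho_A` (a single A-mutant in a B population takes over) and
#' `rho_B` (a single B-mutant in an A population takes over) from independent
#' runs, each started at a uniformly random node and iterated until
#' absorption or the generation cap. The two batches use paired seeds derived
#' from `seed`.
#'
#' @param graph A `typed_graph`.
#' @param tensor A [payoff_tensor()].
#' @param omega Selection intensity (default 0.01).
#' @param runs Replicates per batch.
#' @param seed Optional integer master seed.
#' @param max_generations Cap in generations of `N` elementary events per run
#'   (default `1e4`).
#' @return Object of class `"fixation_estimate"`: list with `rho_A`, `rho_B`,
#'   `se_A`, `se_B`, `runs`, `capped_A`, `capped_B`, `omega`. A warning is
#'   attached when more than 1% of runs hit the cap.
#' @export
estimate_fixation <- function(graph, tensor, omega = 0.01, runs = 1000L,
                              seed = NULL, max_generations = 1e4) {
  check_graph_tensor(graph, tensor)
  check_fitness_positive(tensor, omega)
  if (runs < 1L) stop("'runs' must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
  }
  args <- graph_cpp_args(graph, tensor)
  max_steps <- max_generations * graph$N
  if (!is.null(seed)) set.seed(seed)
  resA <- .cpp_fixation(args$nbr, args$typ, args$g, args$a, args$b,
                        omega, as.integer(runs), 1L, max_steps)
  if (!is.null(seed)) set.seed(seed + 1L)
  resB <- .cpp_fixation(args$nbr, args$typ, args$g, args$a, args$b,
                        omega, as.integer(runs), 0L, max_steps)
  rho_A <- resA[1L] / runs
  rho_B <- resB[1L] / runs
  out <- structure(list(
    rho_A = rho_A, rho_B = rho_B,
    se_A = sqrt(rho_A * (1 - rho_A) / runs),
    se_B = sqrt(rho_B * (1 - rho_B) / runs),
    runs = runs, capped_A = resA[2L], capped_B = resB[2L], omega = omega),
    class = "fixation_estimate")
  if ((resA[2L] + resB[2L]) / (2 * runs) > 0.01)
    warning("more than 1% of runs hit the generation cap; estimates may be ",
            "biased", call. = FALSE)
  out
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf("rho_A = %.5g (SE %.2g)   rho_B = %.5g (SE %.2g)   [%d runs, omega = %g]\n",
              x$rho_A, x$se_A, x$rho_B, x$se_B, x$runs, x$omega))
  cat(sprintf("rho_A - rho_B = %.5g\n", x$rho_A - x$rho_B))
  invisible(x)
}

#' Mean one-generation frequency change
#'
#' For each frequency `p` on the grid, draws `reps` independent Bernoulli(p)
#' strategy initialisations, runs one generation (`N` elementary death-birth
#' events) and averages the change in the frequency of A-players.
#'
#' @param graph A `typed_graph`.
#' @param tensor A [payoff_tensor()].
#' @param omega Selection intensity.
#' @param p_grid Frequencies inside `(0, 1)`.
#' @param reps Replicates per grid point.
#' @param seed Optional integer seed.
#' @return Data frame with columns `p`, `delta_p` (mean change) and `se`.
#' @export
estimate_delta_p <- function(graph, tensor, omega = 0.01,
                             p_grid = seq(0.1, 0.9, by = 0.1),
                             reps = 500L, seed = NULL) {
  check_graph_tensor(graph, tensor)
  check_fitness_positive(tensor, omega)
  if (any(p_grid <= 0 | p_grid >= 1))
    stop("'p_grid' must lie inside (0, 1)", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  args <- graph_cpp_args(graph, tensor)
  res <- lapply(p_grid, function(p) {
    d <- .cpp_drift(args$nbr, args$typ, args$g, args$a, args$b, omega, p,
                    as.integer(reps), graph$N)
    c(mean(d), stats::sd(d) / sqrt(length(d)))
  })
  m <- do.call(rbind, res)
  data.frame(p = p_grid, delta_p = m[, 1L], se = m[, 2L])
}

#' Exact fixation probabilities on a tiny graph
#'
#' Builds the full death-birth transition matrix over all `2^N` strategy
#' assignments, solves the absorption system exactly, and averages over the
#' `N` single-mutant starting states. Only feasible for `N <= 12`.
#'
#' @param graph A `typed_graph` with at most 12 nodes.
#' @param tensor A [payoff_tensor()].
#' @param omega Selection intensity (`omega = 0` gives neutral drift, for
#'   which `rho_A = rho_B = 1/N` exactly on any regular graph).
#' @return List with exact `rho_A` and `rho_B`.
#' @export
exact_fixation <- function(graph, tensor, omega = 0.01) {
  check_graph_tensor(graph, tensor)
  if (omega > 0) check_fitness_positive(tensor, omega)
  N <- graph$N
  if (N > 12L) stop("exact solver limited to N <= 12 (state space 2^N)",
                    call. = FALSE)
  nstates <- 2L^N
  P <- matrix(0, nstates, nstates)
  bits <- function(state) as.integer(intToBits(state)[1:N])
  for (state in 0:(nstates - 1L)) {
    strat <- bits(state)
    row <- state + 1L
    if (sum(strat) == 0L || sum(strat) == N) {
      P[row, row] <- 1
      next
    }
    pays <- evaluate_payoffs(graph, strat, tensor)
    F <- 1 - omega + omega * pays
    if (any(F <= 0)) stop("non-positive fitness encountered", call. = FALSE)
    for (i in seq_len(N)) {
      nbrs <- graph$nbr[i, ]
      w <- F[nbrs] / sum(F[nbrs])
      for (j in seq_along(nbrs)) {
        new_strat <- strat
        new_strat[i] <- strat[nbrs[j]]
        new_state <- sum(new_strat * 2^(seq_len(N) - 1L))
        P[row, new_state + 1L] <- P[row, new_state + 1L] + w[j] / N
      }
    }
  }
  allA <- nstates  # state with every bit set, 1-based row index
  transient <- setdiff(seq_len(nstates), c(1L, allA))
  Q <- P[transient, transient, drop = FALSE]
  r <- P[transient, allA]
  h <- solve(diag(length(transient)) - Q, r)
  habs <- numeric(nstates)
  habs[allA] <- 1
  habs[transient] <- h
  single_A <- 2^(seq_len(N) - 1L) + 1L
  single_B <- (nstates - 1L) - 2^(seq_len(N) - 1L) + 1L
  list(rho_A = mean(habs[single_A]), rho_B = mean(1 - habs[single_B]))
}
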