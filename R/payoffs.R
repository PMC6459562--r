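#' Payoff tensor over neighbourhood configurations
#'
#' A payoff tensor assigns to every configuration `(s1, ..., sn)` the payoff
#' `a` of a focal A-player and the payoff `b` of a focal B-player whose
#' neighbourhood contains `s[i]` A-players along type-`i` edges. Tensors are
#' stored as flat vectors in the row order of [config_grid()], so a single
#' sigma-rule evaluator serves every game family.
#'
#' @param profile A [degree_profile()].
#' @param a,b Numeric vectors of length `prod(g + 1)` in [config_grid()]
#'   order, all finite.
#' @return An object of class `"payoff_tensor"`.
#' @export
payoff_tensor <- function(profile, a, b) {
  profile <- as_profile(profile)
  len <- prod(profile$g + 1L)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != len || length(b) != len)
    stop("payoff vectors must cover all ", len, " configurations",
         call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("payoff values must be finite", call. = FALSE)
  structure(list(profile = profile, a = a, b = b), class = "payoff_tensor")
}

#' @export
print.payoff_tensor <- function(x, ...) {
  p <- x$profile
  cat("Payoff tensor on profile k =", p$k, " g = (",
      paste(p$g, collapse = ", "), "):", length(x$a), "configurations\n")
  df <- as.data.frame(config_grid(p))
  df$a <- x$a
  df$b <- x$b
  print(utils::head(df, 12L), row.names = FALSE)
  if (nrow(df) > 12L) cat("... (", nrow(df) - 12L, "more rows )\n")
  invisible(x)
}

#' Look up payoffs of a single configuration
#'
#' @param tensor A [payoff_tensor()].
#' @param s Integer configuration.
#' @return Named numeric vector `c(a = ..., b = ...)`.
#' @export
tensor_payoff <- function(tensor, s) {
  i <- config_index(tensor$profile, s)
  c(a = tensor$a[i], b = tensor$b[i])
}

#' Edge-dependent pairwise games as a payoff tensor
#'
#' Each edge type `i` carries its own 2x2 game with entries
#' `alpha[i]` (A vs A), `beta[i]` (A vs B), `gamma[i]` (B vs A) and
#' `theta[i]` (B vs B); a focal player accumulates payoffs over its `k`
#' pairwise interactions:
#' `a_s = sum_i s_i alpha_i + (g_i - s_i) beta_i`,
#' `b_s = sum_i s_i gamma_i + (g_i - s_i) theta_i`.
#'
#' For donation games on every type (`alpha = B - C`, `beta = -C`,
#' `gamma = B`, `theta = 0`) the sigma rule reduces to the averaged-benefit
#' rule `Bbar / Cbar > k`.
#'
#' @param profile A [degree_profile()].
#' @param alpha,beta,gamma,theta Numeric vectors, one entry per edge type.
#' @return A [payoff_tensor()].
#' @export
pairwise_tensor <- function(profile, alpha, beta, gamma, theta) {
  profile <- as_profile(profile)
  n <- profile$n
  if (any(lengths(list(alpha, beta, gamma, theta)) != n))
    stop("need one 2x2 matrix (alpha, beta, gamma, theta) per edge type",
         call. = FALSE)
  grid <- config_grid(profile)
  gmat <- matrix(profile$g, nrow(grid), n, byrow = TRUE)
  a <- as.numeric(grid %*% alpha + (gmat - grid) %*% beta)
  b <- as.numeric(grid %*% gamma + (gmat - grid) %*% theta)
  payoff_tensor(profile, a, b)
}

#' Donation-game pairwise tensor
#'
#' Convenience wrapper for [pairwise_tensor()] with per-type benefits `B` and
#' costs `C`: a cooperator pays `C_i` to hand `B_i` to the partner across a
#' type-`i` edge.
#'
#' @param profile A [degree_profile()].
#' @param B,C Numeric vectors of per-type benefits and costs.
#' @return A [payoff_tensor()].
#' @export
donation_tensor <- function(profile, B, C) {
  pairwise_tensor(profile, alpha = B - C, beta = -C, gamma = B,
                  theta = rep(0, as_profile(profile)$n))
}

#' Per-type multiplayer game tables
#'
#' A per-type game is the pair of payoff vectors `(a_0...a_g, b_0...b_g)` of a
#' `(g + 1)`-player game indexed by the number `s` of opposing A-players.
#'
#' @param a,b Numeric vectors of equal length `g + 1`.
#' @return An object of class `"game_table"` with elements `a`, `b` and `g`.
#' @export
game_table <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 2L)
    stop("'a' and 'b' must have equal length g + 1 >= 2", call. = FALSE)
  structure(list(a = a, b = b, g = length(a) - 1L), class = "game_table")
}

#' Additive tensor of diverse multiplayer games
#'
#' Each focal individual plays one multiplayer game per edge type with the
#' neighbours of that type, and accumulates payoffs:
#' `a_s = sum_j a^(j)_{s_j}` and `b_s = sum_j b^(j)_{s_j}`.
#'
#' @param profile A [degree_profile()].
#' @param games List of `n` [game_table()]s; table `j` must have length
#'   `g[j] + 1`.
#' @return A [payoff_tensor()].
#' @export
additive_tensor <- function(profile, games) {
  profile <- as_profile(profile)
  if (length(games) != profile$n)
    stop("need one game table per edge type", call. = FALSE)
  for (j in seq_len(profile$n)) {
    if (!inherits(games[[j]], "game_table") ||
        games[[j]]$g != profile$g[j])
      stop("game table ", j, " must be a game_table of size g[", j, "] + 1 = ",
           profile$g[j] + 1L, call. = FALSE)
  }
  grid <- config_grid(profile)
  a <- numeric(nrow(grid))
  b <- numeric(nrow(grid))
  for (j in seq_len(profile$n)) {
    a <- a + games[[j]]$a[grid[, j] + 1L]
    b <- b + games[[j]]$b[grid[, j] + 1L]
  }
  payoff_tensor(profile, a, b)
}

#' Average several same-size games into one unified game
#'
#' For equal group sizes the sigma rule for diverse multiplayer games is `n`
#' times the rule for the single averaged game
#' `abar_s = mean_j a^(j)_s`, `bbar_s = mean_j b^(j)_s`; evolutionary
#' predictions under diverse games coincide with those under this unified
#' game.
#'
#' @param games List of [game_table()]s with a common `g`.
#' @return A single [game_table()].
#' @export
average_game <- function(games) {
  gs <- vapply(games, function(x) x$g, integer(1))
  if (length(unique(gs)) != 1L)
    stop("averaging requires equal group sizes g", call. = FALSE)
  game_table(rowMeans(vapply(games, `[[`, numeric(gs[1] + 1L), "a")),
             rowMeans(vapply(games, `[[`, numeric(gs[1] + 1L), "b")))
}

#' Volunteer's dilemma game table
#'
#' One volunteer suffices: a cooperator always pays `Cv` and everyone receives
#' `Bv` as soon as at least one of the `g + 1` participants cooperates. Hence
#' `a_s = Bv - Cv` for all `s`, `b_s = Bv` for `s > 0` and `b_0 = 0`.
#'
#' @param g Number of co-players (group size minus one), `>= 1`.
#' @param Bv,Cv Benefit and cost, both positive.
#' @return A [game_table()].
#' @export
volunteers_table <- function(g, Bv, Cv) {
  if (g < 1) stop("'g' must be >= 1", call. = FALSE)
  if (Bv <= 0 || Cv <= 0) stop("'Bv' and 'Cv' must be positive", call. = FALSE)
  game_table(rep(Bv - Cv, g + 1L), c(0, rep(Bv, g)))
}

#' Linear public goods game table
#'
#' Each cooperator invests `Cp`, producing a benefit `Bp` that is shared
#' evenly among all `g + 1` participants of the group:
#' `a_s = (s + 1) Bp / (g + 1) - Cp`, `b_s = s Bp / (g + 1)`.
#'
#' @param g Number of co-players, `>= 1`.
#' @param Bp,Cp Benefit produced per cooperator and its cost.
#' @return A [game_table()].
#' @export
pgg_table <- function(g, Bp, Cp) {
  if (g < 1) stop("'g' must be >= 1", call. = FALSE)
  s <- 0:g
  game_table((s + 1) * Bp / (g + 1) - Cp, s * Bp / (g + 1))
}

#' Scale per-type games by edge weights
#'
#' On weighted graphs every payoff entry of the type-`j` game is multiplied by
#' the weight `zeta[j]` of type-`j` edges (interaction rate). Critical
#' benefit-to-cost ratios are invariant under any positive `zeta`.
#'
#' @param games List of [game_table()]s.
#' @param zeta Positive numeric vector, one weight per game.
#' @return List of weighted [game_table()]s.
#' @export
weighted_tables <- function(games, zeta) {
  if (length(zeta) != length(games))
    stop("need one weight per game", call. = FALSE)
  if (any(zeta <= 0)) stop("edge weights must be positive", call. = FALSE)
  Map(function(gm, z) game_table(z * gm$a, z * gm$b), games, zeta)
}

#' Division-of-labour threshold public goods tensor (two roles)
#'
#' Two kinds of individuals must both contribute before any benefit exists:
#' type-1 edges link same-role neighbours, type-2 edges link the other role.
#' A focal cooperator covers its own role, so it only needs a cooperator
#' across a type-2 edge; a focal defector needs cooperators along both types.
#' With accumulative goods each cooperator above threshold adds `B`:
#' `a_{s1 s2} = (s1 + s2 + 1) B - C` if `s2 >= 1` else `-C`;
#' `b_{s1 s2} = (s1 + s2) B` if `s1 >= 1` and `s2 >= 1` else `0`.
#' Without accumulation the provided good is flat: `a = B - C` / `b = B` under
#' the same threshold conditions.
#'
#' @param profile A [degree_profile()] with exactly two edge types.
#' @param B,C Benefit per (accumulative) cooperator and cost, both positive.
#' @param accumulative Logical; see above.
#' @return A [payoff_tensor()].
#' @export
dol_tensor <- function(profile, B, C, accumulative = TRUE) {
  profile <- as_profile(profile)
  if (profile$n != 2L)
    stop("division-of-labour tensor requires exactly two edge types",
         call. = FALSE)
  if (B <= 0 || C <= 0) stop("'B' and 'C' must be positive", call. = FALSE)
  grid <- config_grid(profile)
  s1 <- grid[, 1L]
  s2 <- grid[, 2L]
  if (accumulative) {
    a <- ifelse(s2 >= 1L, (s1 + s2 + 1) * B - C, -C)
    b <- ifelse(s1 >= 1L & s2 >= 1L, (s1 + s2) * B, 0)
  } else {
    a <- ifelse(s2 >= 1L, B - C, -C)
    b <- ifelse(s1 >= 1L & s2 >= 1L, B, 0)
  }
  payoff_tensor(profile, a, b)
}

#' Threshold public goods table without division of labour
#'
#' The single-type counterpart of [dol_tensor()] with provision threshold 2
#' (counting the focal cooperator): with accumulative goods
#' `a_s = (s + 1) B - C` if `s >= 1` else `-C`; `b_s = s B` if `s >= 2` else
#' `0`. Without accumulation the benefit is flat `B` under the same
#' thresholds.
#'
#' @param k Group size minus one (total degree), `>= 3`.
#' @param B,C Benefit and cost, positive.
#' @param accumulative Logical.
#' @return A [game_table()] of length `k + 1`.
#' @export
ndol_table <- function(k, B, C, accumulative = TRUE) {
  if (k < 3) stop("'k' must be >= 3", call. = FALSE)
  s <- 0:k
  if (accumulative) {
    a <- ifelse(s >= 1, (s + 1) * B - C, -C)
    b <- ifelse(s >= 2, s * B, 0)
  } else {
    a <- ifelse(s >= 1, B - C, -C)
    b <- ifelse(s >= 2, B, 0)
  }
  game_table(a, b)
}

#' Embed a single-type game table as a payoff tensor
#'
#' @param table A [game_table()] with `g = k`.
#' @return A [payoff_tensor()] on the single-type profile `(k; k)`.
#' @export
table_tensor <- function(table) {
  profile <- degree_profile(table$g, table$g)
  payoff_tensor(profile, table$a, table$b)
}

#' Gaussian-sampled per-interaction game tables
#'
#' Draws independent benefits and costs for each of `n_games` interactions
#' from Gaussian distributions (truncated below at `floor` to keep them
#' positive) and builds the corresponding volunteer's-dilemma or public-goods
#' tables. Emulates settings where every group interaction carries its own
#' randomly perturbed payoff structure.
#'
#' @param n_games Number of tables to draw.
#' @param g Number of co-players per game.
#' @param mean_benefit,var_benefit Mean and variance of the benefit draws.
#' @param mean_cost,var_cost Mean and variance of the cost draws.
#' @param family `"vd"` or `"pgg"`.
#' @param seed Optional integer seed (local to this call).
#' @param floor Lower truncation bound, default `1e-6`.
#' @return List of `n_games` [game_table()]s with the drawn `benefit` and
#'   `cost` attached as attributes.
#' @export
sampled_game_tables <- function(n_games, g, mean_benefit, var_benefit,
                                mean_cost, var_cost,
                                family = c("vd", "pgg"), seed = NULL,
                                floor = 1e-6) {
  family <- match.arg(family)
  if (mean_benefit <= 0 || mean_cost <= 0)
    stop("mean benefit and cost must be positive", call. = FALSE)
  if (var_benefit < 0 || var_cost < 0)
    stop("variances must be non-negative", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  Bs <- pmax(stats::rnorm(n_games, mean_benefit, sqrt(var_benefit)), floor)
  Cs <- pmax(stats::rnorm(n_games, mean_cost, sqrt(var_cost)), floor)
  lapply(seq_len(n_games), function(i) {
    tab <- if (family == "vd") volunteers_table(g, Bs[i], Cs[i])
           else pgg_table(g, Bs[i], Cs[i])
    attr(tab, "benefit") <- Bs[i]
    attr(tab, "cost") <- Cs[i]
    tab
  })
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Read or write a payoff tensor as TSV
#'
#' The format has a header comment naming the profile, then a header row
#' `s1 ... sn a b` and one row per configuration.
#'
#' @param tensor A [payoff_tensor()].
#' @param path File path.
#' @return `read_payoff_tensor()` returns a [payoff_tensor()];
#'   `write_payoff_tensor()` returns `path` invisibly.
#' @export
write_payoff_tensor <- function(tensor, path) {
  p <- tensor$profile
  df <- as.data.frame(config_grid(p))
  df$a <- tensor$a
  df$b <- tensor$b
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#edgegames-tensor v1 k=%d g=%s", p$k,
                     paste(p$g, collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_payoff_tensor
#' @export
read_payoff_tensor <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#edgegames-tensor"))
    stop("not a payoff tensor file (missing #edgegames-tensor header)",
         call. = FALSE)
  hdr <- parse_header_fields(lines[1L])
  profile <- degree_profile(hdr$k, hdr$g)
  df <- utils::read.table(text = lines[-1L], header = TRUE, sep = "\t")
  need <- c(paste0("s", seq_len(profile$n)), "a", "b")
  if (!all(need %in% names(df)))
    stop("tensor file must have columns ", paste(need, collapse = " "),
         call. = FALSE)
  if (nrow(df) != prod(profile$g + 1L))
    stop("tensor file must have one row per configuration", call. = FALSE)
  idx <- apply(df[, seq_len(profile$n), drop = FALSE], 1L,
               function(s) config_index(profile, s))
  a <- numeric(nrow(df))
  b <- numeric(nrow(df))
  a[idx] <- df$a
  b[idx] <- df$b
  payoff_tensor(profile, a, b)
}

parse_header_fields <- function(line) {
  toks <- strsplit(line, "[ \t]+")[[1L]]
  kv <- toks[grepl("=", toks, fixed = TRUE)]
  fields <- list()
  for (t in kv) {
    parts <- strsplit(t, "=", fixed = TRUE)[[1L]]
    fields[[parts[1L]]] <- parts[2L]
  }
  list(N = if (!is.null(fields$N)) as.integer(fields$N) else NULL,
       k = as.integer(fields$k),
       g = as.integer(strsplit(fields$g, ",", fixed = TRUE)[[1L]]))
}
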