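# Independent oracles used across the suite. Everything here is deliberately
# written from first principles (unsimplified sums, exact rational
# arithmetic), not by calling the package's own code paths.

# --- exact rational arithmetic on integer-valued doubles (safe below 2^53) --

rat <- function(num, den = 1) {
  num <- unname(num); den <- unname(den)
  stopifnot(den != 0)
  if (den < 0) { num <- -num; den <- -den }
  g <- rat_gcd(abs(num), den)
  if (g > 1) { num <- num / g; den <- den / g }
  c(num = num, den = den)
}

rat_gcd <- function(a, b) {
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }
  max(a, 1)
}

rat_add <- function(x, y) rat(x[1] * y[2] + y[1] * x[2], x[2] * y[2])
rat_mul <- function(x, y) rat(x[1] * y[1], x[2] * y[2])
rat_num <- function(x) unname(x[1] / x[2])

# --- unsimplified closed-form sigma, exact rationals, valid for k <= 8 ------

oracle_psi <- function(k, i, l) {
  rat_add(rat(choose(l, k - 1 - i), (k - 2) * (k - 1)^l),
          rat(choose(k - 1 - l, k - i), (k - 1)^(k - 1 - l)))
}

oracle_phi <- function(k, i, l) {
  rat_add(rat(choose(l, k - i), (k - 1)^l),
          rat(choose(k - 1 - l, k - 1 - i), (k - 2) * (k - 1)^(k - 1 - l)))
}

oracle_sigma <- function(k, g, s) {
  S <- sum(s)
  acc <- rat(0)
  for (l in 0:k) {
    term <- rat_add(rat_mul(rat(2 * k + (k - 2) * l), oracle_psi(k, S, l)),
                    rat_mul(rat(k^2 - (k - 2) * l), oracle_phi(k, S, l)))
    acc <- rat_add(acc, rat_mul(rat(k - l), term))
  }
  pref <- rat((k - 2)^(k - S), k^2 * (k + 1) * (k + 2))
  hyp <- rat(prod(choose(g, s)), choose(k, S))
  rat_num(rat_mul(rat_mul(pref, hyp), acc))
}

# --- brute-force tensor constructions ---------------------------------------

enumerate_configs <- function(g) {
  grids <- rev(expand.grid(rev(lapply(g, function(gi) 0:gi)),
                           KEEP.OUT.ATTRS = FALSE))
  m <- as.matrix(grids)
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

brute_additive <- function(g, tables, which = c("a", "b")) {
  which <- match.arg(which)
  cfg <- enumerate_configs(g)
  apply(cfg, 1, function(s)
    sum(vapply(seq_along(g), function(j) tables[[j]][[which]][s[j] + 1],
               numeric(1))))
}

brute_sigma_rule <- function(sig_df, a, b, g) {
  cfg <- enumerate_configs(g)
  flip_idx <- apply(cfg, 1, function(s) {
    fs <- g - s
    idx <- 0
    for (j in seq_along(g)) idx <- idx * (g[j] + 1) + fs[j]
    idx + 1
  })
  sum(sig_df$sigma * (a - b[flip_idx]))
}

# small deterministic typed graph helpers ------------------------------------

k4_graph <- function() {
  # complete graph on 4 nodes, one edge type
  generate_typed_graph(4, degree_profile(3, 3), seed = 1)
}
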