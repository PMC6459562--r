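test_that("sigma rule vanishes for constant games and matches brute force", {
  p <- degree_profile(5, c(3, 2))
  st <- sigma_table(p)
  m <- prod(p$g + 1)
  const <- payoff_tensor(p, rep(1.7, m), rep(1.7, m))
  expect_equal(sigma_rule_lhs(st, const), 0, tolerance = 1e-12)

  set.seed(5)
  tn <- payoff_tensor(p, runif(m), runif(m))
  expect_equal(sigma_rule_lhs(st, tn),
               brute_sigma_rule(st, tn$a, tn$b, p$g), tolerance = 1e-12)

  expect_error(sigma_rule_lhs(st, payoff_tensor(degree_profile(4, c(3, 1)),
                                                rep(1, 8), rep(1, 8))),
               "different profiles")
})

test_that("edge-dependent donation games are neutral exactly at Bbar/Cbar = k", {
  # mixed per-type benefits/costs whose degree-weighted ratio equals k
  cases <- list(
    list(g = c(3, 2), B = c(6, 3.5), C = c(1, 1)),       # Bbar = 5 = k
    list(g = c(2, 1), B = c(3, 3), C = c(1, 1)),          # k = 3
    list(g = c(2, 2), B = c(2, 6), C = c(1, 1)),          # Bbar = 4 = k
    list(g = c(4, 4), B = c(8, 8), C = c(0.5, 1.5)))      # Cbar = 1, k = 8
  for (cs in cases) {
    k <- sum(cs$g)
    p <- degree_profile(k, cs$g)
    st <- sigma_table(p)
    expect_equal(sigma_rule_lhs(st, donation_tensor(p, cs$B, cs$C)), 0,
                 tolerance = 1e-9)
  }
})

test_that("volunteer's dilemma lhs simplifies to Bv * sigma~_g - Cv", {
  p <- degree_profile(6, c(3, 3))
  st <- sigma_table(p)
  sg <- marginal_sigma(st, "first")
  for (Bv in c(1.05, 5.55, 10.05)) {
    tn <- additive_tensor(p, list(volunteers_table(3, Bv, 1),
                                  volunteers_table(3, Bv, 1)))
    # additive lhs is n x the averaged-game lhs
    expect_equal(sigma_rule_lhs(st, tn), 2 * (Bv * sg[["3"]] - 1),
                 tolerance = 1e-9)
  }
})

test_that("verdicts report the favored strategy and scale linearly in omega", {
  v <- selection_verdict(0.5, omega = 0.01)
  expect_identical(v$favored, "A")
  expect_equal(v$predicted_diff, 0.005)
  expect_identical(selection_verdict(-2, 0.01)$favored, "B")
  expect_identical(selection_verdict(1e-14, 0.01)$favored, "neutral")
  expect_equal(selection_verdict(0.5, 0.02)$predicted_diff,
               2 * selection_verdict(0.5, 0.01)$predicted_diff)
  expect_error(selection_verdict(1, omega = 0), "positive")
})

test_that("critical ratio of the donation family is k for arbitrary mixes", {
  set.seed(8)
  for (k in c(3, 4, 5, 8)) {
    n <- sample(1:min(k - 1, 3), 1)
    cuts <- sort(sample(seq_len(k - 1), n - 1))
    g <- diff(c(0, cuts, k))
    p <- degree_profile(k, g)
    st <- sigma_table(p)
    # uniform benefit B against unit costs: critical B equals k
    bc <- critical_ratio(function(B) donation_tensor(p, rep(B, n), rep(1, n)),
                         p, table = st)
    expect_equal(bc, k, tolerance = 1e-9)
    # re-substituting the root gives a neutral rule
    expect_equal(sigma_rule_lhs(st, donation_tensor(p, rep(bc, n), rep(1, n))),
                 0, tolerance = 1e-9)
  }
})

test_that("critical volunteer's-dilemma ratio is 1 / sigma~_g", {
  p <- degree_profile(6, c(3, 3))
  st <- sigma_table(p)
  sg <- marginal_sigma(st, "first")
  bc <- critical_ratio(function(B) additive_tensor(
    p, list(volunteers_table(3, B, 1), volunteers_table(3, B, 1))), p,
    table = st)
  expect_equal(bc, 1 / sg[["3"]], tolerance = 1e-9)
})

test_that("the printed division-of-labour formulas agree with the tensor route", {
  st8 <- sigma_table(degree_profile(8, c(3, 5)))
  for (acc in c(TRUE, FALSE)) {
    direct <- critical_dol(8, 3, 5, labor_division = TRUE, accumulative = acc)
    p <- degree_profile(8, c(3, 5))
    via_tensor <- critical_ratio(function(B) dol_tensor(p, B, 1, acc), p,
                                 table = st8)
    expect_equal(direct, via_tensor, tolerance = 1e-9)

    nd <- critical_dol(8, labor_division = FALSE, accumulative = acc)
    p1 <- degree_profile(8, 8)
    via_t1 <- critical_ratio(function(B)
      table_tensor(ndol_table(8, B, 1, acc)), p1)
    expect_equal(nd, via_t1, tolerance = 1e-9)
  }
})

test_that("pairwise reduction agrees in sign with the full sigma rule", {
  set.seed(13)
  for (k in c(3, 4, 5)) {
    g <- if (k == 3) c(2, 1) else if (k == 4) c(3, 1) else c(3, 2)
    p <- degree_profile(k, g)
    st <- sigma_table(p)
    for (rep in 1:100) {
      alpha <- rnorm(2); beta <- rnorm(2); gamma <- rnorm(2); theta <- rnorm(2)
      full <- sigma_rule_lhs(st, pairwise_tensor(p, alpha, beta, gamma, theta))
      reduced <- pairwise_condition(p, alpha, beta, gamma, theta)$lhs
      # the two routes are proportional with constant (k - 1) / 2
      expect_equal(full, (k - 1) / 2 * reduced, tolerance = 1e-9)
    }
  }
  # all-equal entries are neutral
  p <- degree_profile(4, c(3, 1))
  expect_identical(pairwise_condition(p, c(1, 1), c(1, 1), c(1, 1),
                                      c(1, 1))$favored, "neutral")
  # donation games: favored A iff Bbar/Cbar > k
  expect_identical(pairwise_condition(p, c(5, 5) - 1, c(-1, -1), c(5, 5),
                                      c(0, 0))$favored, "A")
  expect_identical(pairwise_condition(p, c(3, 3) - 1, c(-1, -1), c(3, 3),
                                      c(0, 0))$favored, "B")
})

test_that("the additive lhs is n times the averaged-game lhs for equal sizes", {
  set.seed(17)
  for (n in 2:3) {
    g <- rep(3, n)
    p <- degree_profile(sum(g), g)
    st <- sigma_table(p)
    tabs <- lapply(seq_len(n), function(i) game_table(runif(4), runif(4)))
    lhs_add <- sigma_rule_lhs(st, additive_tensor(p, tabs))
    avg <- average_game(tabs)
    sg <- marginal_sigma(st, "first")
    lhs_avg <- sum(sg * (avg$a - rev(avg$b)))
    expect_equal(lhs_add, n * lhs_avg, tolerance = 1e-12)
  }
})

test_that("critical ratios are invariant under positive edge weights", {
  set.seed(19)
  p <- degree_profile(6, c(3, 3))
  st <- sigma_table(p)
  base_bc <- critical_ratio(function(B) additive_tensor(
    p, list(volunteers_table(3, B, 1), volunteers_table(3, B, 1))), p,
    table = st)
  for (rep in 1:5) {
    zeta <- runif(2, 0.2, 4)
    bc <- critical_ratio(function(B) additive_tensor(
      p, weighted_tables(list(volunteers_table(3, B, 1),
                              volunteers_table(3, B, 1)), zeta)), p,
      table = st)
    expect_equal(bc, base_bc, tolerance = 1e-9)
    # while the lhs scales by the mean weight
    lhs_w <- sigma_rule_lhs(st, additive_tensor(
      p, weighted_tables(list(volunteers_table(3, 7, 1),
                              volunteers_table(3, 7, 1)), zeta)))
    lhs_1 <- sigma_rule_lhs(st, additive_tensor(
      p, list(volunteers_table(3, 7, 1), volunteers_table(3, 7, 1))))
    expect_equal(lhs_w, mean(zeta) * lhs_1, tolerance = 1e-9)
  }
})

test_that("coefficient counts follow the m distinct group sizes", {
  expect_equal(coefficient_count(degree_profile(5, 5), "general"), 6L)
  expect_equal(coefficient_count(degree_profile(5, 5), "diverse-additive"), 6L)
  # all g equal: C(g + n, n); n = 2, g = 3 -> 10
  expect_equal(coefficient_count(degree_profile(6, c(3, 3)), "general"), 10L)
  expect_equal(coefficient_count(degree_profile(6, c(3, 3)),
                                 "diverse-additive"), 4L)
  # all distinct: product / sum of (g_i + 1)
  p <- degree_profile(6, c(1, 2, 3))
  expect_equal(coefficient_count(p, "general"), 2L * 3L * 4L)
  expect_equal(coefficient_count(p, "diverse-additive"), 2L + 3L + 4L)
})
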