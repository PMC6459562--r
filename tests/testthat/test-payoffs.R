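test_that("pairwise tensors accumulate per-edge payoffs", {
  p <- degree_profile(3, c(2, 1))
  # donation entries: alpha = B - C, beta = -C, gamma = B, theta = 0
  tn <- donation_tensor(p, B = c(2, 4), C = c(1, 1))
  # hand summation at s = (1, 0): (1*1 + 1*(-1)) + (0*3 + 1*(-1)) = -1
  expect_equal(unname(tensor_payoff(tn, c(1, 0))["a"]), -1)
  expect_equal(unname(tensor_payoff(tn, c(1, 0))["b"]), 2)

  # identical matrices across types: payoffs depend on S = sum(s) only
  p2 <- degree_profile(5, c(3, 2))
  tn2 <- pairwise_tensor(p2, alpha = c(2, 2), beta = c(-1, -1),
                         gamma = c(3, 3), theta = c(0.5, 0.5))
  cfg <- config_grid(p2)
  S <- rowSums(cfg)
  for (Sv in unique(S)) {
    expect_lt(diff(range(tn2$a[S == Sv])), 1e-12)
    expect_lt(diff(range(tn2$b[S == Sv])), 1e-12)
  }
  expect_error(pairwise_tensor(p2, 1, 1, 1, 1), "per edge type")
})

test_that("tensor builders are linear in their payoff inputs", {
  set.seed(11)
  p <- degree_profile(5, c(3, 2))
  a1 <- runif(2); b1 <- runif(2); g1 <- runif(2); t1 <- runif(2)
  a2 <- runif(2); b2 <- runif(2); g2 <- runif(2); t2 <- runif(2)
  sum12 <- pairwise_tensor(p, a1 + a2, b1 + b2, g1 + g2, t1 + t2)
  part1 <- pairwise_tensor(p, a1, b1, g1, t1)
  part2 <- pairwise_tensor(p, a2, b2, g2, t2)
  expect_equal(sum12$a, part1$a + part2$a)
  expect_equal(sum12$b, part1$b + part2$b)

  tabs1 <- list(game_table(runif(4), runif(4)), game_table(runif(3), runif(3)))
  tabs2 <- list(game_table(runif(4), runif(4)), game_table(runif(3), runif(3)))
  tsum <- additive_tensor(p, Map(function(x, y)
    game_table(x$a + y$a, x$b + y$b), tabs1, tabs2))
  expect_equal(tsum$a, additive_tensor(p, tabs1)$a + additive_tensor(p, tabs2)$a)
})

test_that("additive tensors equal brute-force per-configuration sums", {
  set.seed(3)
  for (g in list(c(3, 3), c(2, 1), c(2, 2, 1))) {
    p <- degree_profile(sum(g), g)
    tabs <- lapply(g, function(gi) game_table(runif(gi + 1), runif(gi + 1)))
    tn <- additive_tensor(p, tabs)
    expect_equal(tn$a, brute_additive(g, tabs, "a"))
    expect_equal(tn$b, brute_additive(g, tabs, "b"))
  }
  p <- degree_profile(4, c(3, 1))
  expect_error(additive_tensor(p, list(game_table(1:3, 1:3),
                                       game_table(1:2, 1:2))),
               "game_table")
})

test_that("averaging diverse games gives the unified game", {
  vd1 <- volunteers_table(3, 1.05, 1)
  vd2 <- volunteers_table(3, 10.05, 1)
  avg <- average_game(list(vd1, vd2))
  unified <- volunteers_table(3, (1.05 + 10.05) / 2, 1)
  expect_equal(avg$a, unified$a)
  expect_equal(avg$b, unified$b)
  # identical games average to themselves
  same <- average_game(list(vd1, vd1, vd1))
  expect_equal(same$a, vd1$a)
  expect_error(average_game(list(vd1, volunteers_table(4, 2, 1))),
               "equal group sizes")
})

test_that("volunteer's dilemma tables provide on the first volunteer", {
  tab <- volunteers_table(3, 1.05, 1)
  expect_length(tab$a, 4)
  expect_equal(tab$a, rep(0.05, 4))
  expect_equal(tab$b, c(0, 1.05, 1.05, 1.05))
  expect_equal(volunteers_table(2, 1, 1)$a, rep(0, 3))
})

test_that("public goods tables share benefits over all g + 1 participants", {
  tab <- pgg_table(3, 5.1, 1)
  expect_equal(tab$b[1], 0)            # lone defector earns nothing
  expect_equal(tab$a[4], 5.1 - 1)      # full provision: Bp - Cp
  expect_equal(tab$a[3], 3 * 5.1 / 4 - 1)  # s = 2: (s+1) Bp/(g+1) - Cp
})

test_that("edge weights scale per-type games entrywise", {
  vd <- volunteers_table(3, 2, 1)
  same <- weighted_tables(list(vd, vd), c(1, 1))
  expect_equal(same[[1]]$a, vd$a)
  doubled <- weighted_tables(list(vd, vd), c(2, 2))
  expect_equal(doubled[[2]]$b, 2 * vd$b)
  expect_error(weighted_tables(list(vd), 0), "positive")
})

test_that("division-of-labour tensors implement the two-threshold payoffs", {
  p <- degree_profile(5, c(3, 2))
  acc <- dol_tensor(p, B = 2, C = 1, accumulative = TRUE)
  expect_equal(unname(tensor_payoff(acc, c(0, 0))["a"]), -1)
  expect_equal(unname(tensor_payoff(acc, c(0, 1))["a"]), 3)
  expect_equal(unname(tensor_payoff(acc, c(1, 1))["b"]), 4)
  expect_equal(unname(tensor_payoff(acc, c(1, 0))["b"]), 0)
  # b vanishes whenever the cross-role threshold is unmet
  for (s1 in 0:3) {
    expect_equal(unname(tensor_payoff(acc, c(s1, 0))["b"]), 0)
    expect_equal(unname(tensor_payoff(dol_tensor(p, 2, 1, FALSE),
                                      c(s1, 0))["b"]), 0)
  }
  flat <- dol_tensor(p, 2, 1, accumulative = FALSE)
  expect_equal(unname(tensor_payoff(flat, c(3, 2))["a"]), 1)
  expect_equal(unname(tensor_payoff(flat, c(3, 2))["b"]), 2)
  expect_error(dol_tensor(degree_profile(3, 3), 2, 1), "two edge types")
})

test_that("single-threshold tables mirror the no-division case", {
  acc <- ndol_table(5, 2, 1, accumulative = TRUE)
  expect_equal(acc$a[1], -1)
  expect_equal(acc$b[1], 0)
  expect_equal(acc$b[2], 0)  # threshold 2 unmet with one cooperator
  flat <- ndol_table(5, 2, 1, accumulative = FALSE)
  expect_equal(flat$b[2], 0)
  expect_equal(flat$a[6], 1)   # s = k: B - C
  expect_equal(flat$b[6], 2)   # s = k: B
})

test_that("sampled game tables reduce to the mean game at zero variance and are reproducible", {
  zero <- sampled_game_tables(5, 3, 5.05, 0, 1, 0, family = "vd", seed = 1)
  ref <- volunteers_table(3, 5.05, 1)
  for (tab in zero) expect_equal(tab$a, ref$a)

  s1 <- sampled_game_tables(10, 3, 5.05, 1.5, 1, 0.25, family = "vd", seed = 9)
  s2 <- sampled_game_tables(10, 3, 5.05, 1.5, 1, 0.25, family = "vd", seed = 9)
  expect_equal(vapply(s1, attr, numeric(1), "benefit"),
               vapply(s2, attr, numeric(1), "benefit"))

  many <- sampled_game_tables(1e4, 3, 5.05, 1.5, 1, 0.25, family = "pgg",
                              seed = 2)
  bs <- vapply(many, attr, numeric(1), "benefit")
  expect_lt(abs(mean(bs) - 5.05), 3 * sqrt(1.5 / 1e4))
})

test_that("payoff tensors round-trip through TSV", {
  p <- degree_profile(4, c(3, 1))
  tn <- dol_tensor(degree_profile(4, c(2, 2)), 2, 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_payoff_tensor(tn, path)
  back <- read_payoff_tensor(path)
  expect_equal(back$a, tn$a)
  expect_equal(back$b, tn$b)
  expect_identical(back$profile$g, tn$profile$g)
  expect_error(read_payoff_tensor(textConnection("x")), ".")
})
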