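test_that("larger-vs-dove break-even solves y^2 + y - x = 0", {
  y1 <- breakeven_larger_vs_dove(1)
  expect_equal(y1, 0.6180339887, tolerance = 1e-9)   # golden section
  expect_equal(breakeven_larger_vs_dove(6), 2)       # exact integer case
  expect_equal(breakeven_larger_vs_dove(2), 1)       # (-1 + sqrt 9)/2
  for (x in c(0.3, 1, 2, 6, 17.5)) {
    y <- breakeven_larger_vs_dove(x)
    expect_equal(y^2 + y - x, 0, tolerance = 1e-12)
  }
  # strictly increasing in x
  xs <- seq(0.1, 50, length.out = 200)
  expect_true(all(diff(vapply(xs, breakeven_larger_vs_dove, 0)) > 0))
  expect_error(breakeven_larger_vs_dove(0), "positive")
  expect_error(breakeven_larger_vs_dove(-1), "positive")
})

test_that("larger-vs-hawk break-even solves y (x - y)^2 = 1 beyond x", {
  y1 <- breakeven_larger_vs_hawk(1)
  expect_equal(signif(y1, 4), 1.755)
  expect_equal(round(y1, 2), 1.75)
  # defining cubic at x = 1
  expect_equal(y1^3 - 2 * y1^2 + y1 - 1, 0, tolerance = 1e-10)
  # frozen two-stage grid-search oracle values
  expect_equal(y1, 1.754877666, tolerance = 1e-8)
  y2 <- breakeven_larger_vs_hawk(2)
  expect_equal(y2, 2.618033989, tolerance = 1e-8)
  expect_gt(y2, 2)
  expect_equal(y2 * (2 - y2)^2, 1, tolerance = 1e-10)
})

test_that("smaller-vs-dove break-even is the Fibonacci mark at x = 1", {
  y <- breakeven_smaller_vs_dove(1)
  expect_equal(y, 0.3819660113, tolerance = 1e-9)
  expect_equal(y^2 - 3 * y + 1, 0, tolerance = 1e-12)
  expect_equal(y, 1 - breakeven_larger_vs_dove(1), tolerance = 1e-12)
  # the non-extraneous root lies in (0, x)
  for (x in c(0.5, 1, 2, 10)) {
    r <- breakeven_smaller_vs_dove(x)
    expect_gt(r, 0)
    expect_lt(r, x)
    expect_equal(r^2 - (x^2 + 2 * x) * r + x^2, 0, tolerance = 1e-9)
  }
})

test_that("smaller-vs-hawk break-even solves x^2 (x - y) = 1", {
  expect_identical(breakeven_smaller_vs_hawk(1), 0)
  expect_equal(breakeven_smaller_vs_hawk(2), 1.75)
  expect_equal(2^2 * (2 - 1.75), 1)
  # below the break-even the resistance payoff 1 dominates surrender
  for (rho in c(0.1, 0.5, 0.9)) expect_lt(1^2 * (1 - rho), 1)
})

test_that("threshold constants satisfy their defining identities", {
  th <- conflict_thresholds()
  expect_equal(th$phi, (sqrt(5) - 1) / 2, tolerance = 1e-12)
  expect_equal(th$fib_mark, 1 - th$phi, tolerance = 1e-12)
  expect_equal(th$hawk_shift * (1 - th$hawk_shift)^2, 1, tolerance = 1e-10)
  expect_identical(th$surrender_point, 0)
  # the "reverse surpass by 75%" restatement
  expect_equal(signif(th$hawk_shift - 1, 4), 0.7549)
})

test_that("strategy predictions follow the documented thresholds", {
  expect_equal(predict_strategy(size_pair(1, 0.5), "larger", "dove")$decision,
               "aggress")
  expect_equal(predict_strategy(0.7, "larger", "dove")$decision, "cooperate")
  expect_equal(predict_strategy(0.9, "larger", "hawk")$decision, "aggress")
  expect_equal(predict_strategy(0.1, "larger", "hawk")$decision, "aggress")
  expect_equal(predict_strategy(0.5, "smaller", "hawk")$decision, "resist")
  # smaller vs dove: the payoff argmax switches at the Fibonacci mark
  expect_equal(predict_strategy(0.3, "smaller", "dove")$decision, "cheat")
  expect_equal(predict_strategy(0.5, "smaller", "dove")$decision, "cooperate")
  # exact threshold ties resolve to the cooperative branch
  th <- conflict_thresholds()
  expect_equal(predict_strategy(th$phi, "larger", "dove")$decision, "cooperate")
  expect_equal(predict_strategy(th$fib_mark, "smaller", "dove")$decision,
               "cooperate")
  expect_error(predict_strategy(1.2, "larger", "dove"), "between 0 and 1")
})

test_that("strategy decisions equal the reward-matrix argmax and report both payoffs", {
  rhos <- withr::with_seed(11, stats::runif(500, 0.01, 0.99))
  for (rho in rhos[1:50]) {
    m <- relativized_matrix(size_pair(1, rho))
    d <- predict_strategy(rho, "larger", "dove")
    expect_equal(d$payoff_chosen, max(m$e_dd, m$e_hd))
    expect_equal(d$payoff_rejected, min(m$e_dd, m$e_hd))
    expect_equal(d$decision == "cooperate", m$e_dd >= m$e_hd)
    d2 <- predict_strategy(rho, "smaller", "dove")
    expect_equal(d2$decision == "cooperate", m$e_dd >= m$e_dh)
    d3 <- predict_strategy(rho, "larger", "hawk")
    expect_equal(d3$decision == "aggress", m$e_hh >= m$e_dh)
    d4 <- predict_strategy(rho, "smaller", "hawk")
    expect_equal(d4$decision == "resist", m$e_hh >= m$e_hd)
  }
})

test_that("competing payoffs are equal at each returned break-even", {
  # larger vs dove at x = 1: rho^2 vs 1 - rho
  phi <- breakeven_larger_vs_dove(1)
  expect_equal(phi^2, 1 - phi, tolerance = 1e-9)
  # smaller vs dove: rho^2 vs rho (1 - rho)^2
  fib <- breakeven_smaller_vs_dove(1)
  expect_equal(fib^2, fib * (1 - fib)^2, tolerance = 1e-9)
  # larger vs hawk: rho (1 - rho)^2 vs 1 at the (out-of-range) root
  hs <- breakeven_larger_vs_hawk(1)
  expect_equal(hs * (1 - hs)^2, 1, tolerance = 1e-9)
  # smaller vs hawk: 1 - rho vs 1 at rho = 0
  expect_equal(1 - breakeven_smaller_vs_hawk(1), 1)
})

test_that("decide_dyads vectorizes over a dyad table", {
  tr <- data.frame(id = c("a", "b", "c"), trait = c(10, 7, 3))
  dy <- decide_dyads(pairwise_descriptors(tr), "larger", "dove")
  expect_equal(nrow(dy), 3L)
  expect_equal(dy$decision[dy$id_x == "a" & dy$id_y == "b"], "cooperate")  # 0.7 > phi
  expect_equal(dy$decision[dy$id_x == "a" & dy$id_y == "c"], "aggress")    # 0.3 < phi
  expect_true(all(dy$payoff_chosen >= dy$payoff_rejected))
})
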