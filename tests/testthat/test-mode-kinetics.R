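test_that("global fit identifies all four generating modes with exact Ki", {
  for (md in c("competitive", "noncompetitive", "uncompetitive", "mixed")) {
    g <- exact_grid(md, ki = 2, alpha = 3,
                    inhibitors = c(0, 1, 2, 4))
    f <- fit_global_inhibition(g)
    expect_identical(f$mode, md)
    expect_equal(f$ki, 2, tolerance = 1e-6)
    expect_equal(f$km, 100, tolerance = 1e-6)
    expect_equal(f$vmax, 200, tolerance = 1e-6)
    if (md == "mixed") expect_equal(f$alpha, 3, tolerance = 1e-6)
  }
})

test_that("published-constant grids classify correctly", {
  f1 <- fit_global_inhibition(exact_grid("competitive", ki = 0.17))
  expect_identical(f1$mode, "competitive")
  expect_equal(f1$ki, 0.17, tolerance = 1e-6)
  f4 <- fit_global_inhibition(
    exact_grid("noncompetitive", ki = 4.2, inhibitors = c(0, 1.9, 3.8, 7.6)))
  expect_identical(f4$mode, "noncompetitive")
  expect_equal(f4$ki, 4.2, tolerance = 1e-6)
})

test_that("a grid without inhibition is flagged degenerate", {
  g <- expand.grid(substrate = c(50, 100, 200), inhibitor = c(0, 1, 2, 4))
  g$velocity <- mm_velocity(g$substrate, 0, 100, 200, "none")
  f <- fit_global_inhibition(rate_grid(g))
  expect_true(f$degenerate)
  expect_identical(f$mode, "none")
  expect_identical(f$ki, Inf)
})

test_that("Lineweaver-Burk geometry matches the rate-law algebra", {
  expect_error(exact_grid("none", ki = Inf, inhibitors = c(0, 0, 0)),
               "3 inhibitor")  # degenerate design rejected
  lb <- lineweaver_burk(exact_grid("competitive", ki = 0.17))
  # competitive: shared y-intercept 1/Vmax
  expect_equal(lb$lines$y_intercept, rep(1 / 200, 4), tolerance = 1e-9)
  expect_lt(lb$dispersion[["y_intercept"]], 1e-9)
  # uninhibited line: x-intercept -1/Km
  expect_equal(lb$lines$x_intercept[lb$lines$inhibitor == 0], -1 / 100,
               tolerance = 1e-9)
  lbn <- lineweaver_burk(exact_grid("noncompetitive", ki = 4.2,
                                    inhibitors = c(0, 1.9, 3.8, 7.6)))
  expect_equal(lbn$lines$x_intercept, rep(-1 / 100, 4), tolerance = 1e-9)
  expect_lt(lbn$dispersion[["x_intercept"]], 1e-9)
  bad <- exact_grid("competitive", ki = 0.17)
  bad$velocity[1] <- 0
  expect_error(lineweaver_burk(bad), "positive")
})

test_that("Dixon intersections recover Ki and detect degenerate patterns", {
  d <- dixon_ki(exact_grid("competitive", ki = 0.17))
  expect_equal(d$ki, 0.17, tolerance = 1e-6)
  dn <- dixon_ki(exact_grid("noncompetitive", ki = 4.2,
                            inhibitors = c(0, 1.9, 3.8, 7.6)))
  expect_equal(dn$ki, 4.2, tolerance = 1e-6)
  # noncompetitive intersection sits on the [I]-axis (1/v = 0)
  expect_equal(max(abs(dn$intersections$y)), 0, tolerance = 1e-9)
  # uncompetitive Dixon lines are parallel: no intersection
  expect_error(dixon_ki(exact_grid("uncompetitive", ki = 2,
                                   inhibitors = c(0, 1, 2, 4))),
               "parallel")
})

test_that("Dixon and global-fit Ki agree within 1% on noiseless grids", {
  for (md in c("competitive", "noncompetitive")) {
    g <- exact_grid(md, ki = 1.3, inhibitors = c(0, 0.65, 1.3, 2.6))
    kg <- fit_global_inhibition(g)$ki
    kd <- dixon_ki(g)$ki
    expect_lt(abs(kd / kg - 1), 0.01)
  }
})

test_that("Cheng-Prusoff consistency links IC50 and Ki", {
  # competitive, [S] = Km: IC50 = Ki (1 + S/Km) = 2 Ki
  ki <- 0.17
  inhib <- c(0, ki * 2^(-2:5))
  v0 <- mm_velocity(100, 0, 100, 200, "competitive", ki)
  v <- mm_velocity(100, inhib, 100, 200, "competitive", ki)
  f <- fit_ic50(inhib, percent_inhibition(v0, v))
  expect_equal(f$ic50, 2 * ki, tolerance = 1e-4)
  # pure noncompetitive: IC50 = Ki at any substrate
  ki <- 4.2
  inhib <- c(0, ki * 2^(-2:5))
  v0 <- mm_velocity(100, 0, 100, 200, "noncompetitive", ki)
  v <- mm_velocity(100, inhib, 100, 200, "noncompetitive", ki)
  f <- fit_ic50(inhib, percent_inhibition(v0, v))
  expect_equal(f$ic50, ki, tolerance = 1e-4)
})

test_that("reversibility verdicts follow the intercepts", {
  tr <- assay_truth(mode = "noncompetitive", ki = 2, ic50 = 2)
  d <- simulate_reversibility(tr, inhibitor_levels = c(0, 1, 2, 4))
  r <- reversibility_test(d)
  expect_identical(r$verdict, "reversible")
  expect_equal(max(abs(r$lines$intercept)), 0, tolerance = 1e-9)
  # slopes shrink with [I] by the rate-law factor 1/(1 + I/Ki)
  s <- r$lines$slope[order(r$lines$inhibitor)]
  expect_equal(s / s[1], 1 / (1 + c(0, 1, 2, 4) / 2), tolerance = 1e-9)
  # constant offset forces an irreversible-like verdict
  d2 <- d
  d2$velocity <- d2$velocity + 20
  ns <- noise_spec(cv = 0.01, replicates = 1, seed = 7)
  d2$velocity <- d2$velocity * (1 + stats::rnorm(nrow(d2), 0, 0.002))
  expect_identical(reversibility_test(d2)$verdict, "irreversible-like")
  expect_error(reversibility_test(data.frame(enzyme = c(1, 2),
                                             inhibitor = 0,
                                             velocity = c(1, 2))),
               "3 enzyme")
})

test_that("noisy grids classify the true mode in at least 95% of seeds", {
  # shortened screen of the full acceptance sweep (deeper run in acceptance)
  trc <- truth_competitive()
  ok <- vapply(1:60, function(i) {
    g <- simulate_rate_grid(trc, inhibitors = c(0, 0.19, 0.38, 0.76),
                            noise = noise_spec(0.02, 3, seed = 9000 + i))
    fit_global_inhibition(g)$mode == "competitive"
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})
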