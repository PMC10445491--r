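test_that("progress traces follow the mode-specific rate laws exactly", {
  tr <- assay_truth(km = 100, vmax = 200, mode = "none")
  tl <- simulate_progress_trace(tr, substrate = 100)[[1]]
  # at S = Km the uninhibited velocity is Vmax/2
  expect_equal(unname(stats::coef(stats::lm(tl$rfu ~ tl$times))[2]), 100,
               tolerance = 1e-12)

  trc <- assay_truth(km = 100, vmax = 200, mode = "competitive", ki = 0.5)
  tl <- simulate_progress_trace(trc, substrate = 100, inhibitor = 0.5)[[1]]
  # [I] = Ki, [S] = Km: v = Vmax Km / (2 Km + Km) = Vmax/3
  expect_equal(diff(tl$rfu[1:2]), 200 / 3, tolerance = 1e-12)

  trn <- assay_truth(km = 100, vmax = 200, mode = "noncompetitive", ki = 2)
  for (s in c(30, 100, 350)) {
    v0 <- mm_velocity(s, 0, 100, 200, "noncompetitive", 2)
    ti <- simulate_progress_trace(trn, substrate = s, inhibitor = 2)[[1]]
    expect_equal(diff(ti$rfu[1:2]), v0 / 2, tolerance = 1e-12)
  }
})

test_that("trace generation validates parameters and scales with enzyme", {
  tr <- assay_truth(mode = "competitive", ki = 1)
  expect_error(simulate_progress_trace(tr, substrate = -1), "substrate")
  expect_error(simulate_progress_trace(tr, substrate = 100, enzyme = 0),
               "enzyme")
  expect_error(mm_velocity(100, 1, km = 100, vmax = 200,
                           mode = "competitive", ki = -1), "ki")
  t1 <- simulate_progress_trace(tr, 100, enzyme = 0.02)[[1]]
  t2 <- simulate_progress_trace(tr, 100, enzyme = 0.04)[[1]]
  expect_equal(t2$rfu, 2 * t1$rfu, tolerance = 1e-12)
})

test_that("generators are deterministic under a fixed seed", {
  tr <- truth_competitive()
  ns <- noise_spec(cv = 0.05, replicates = 3, seed = 42)
  a <- simulate_dose_response(tr, c(0, 0.1, 0.4, 1.6, 6.4), ns)
  b <- simulate_dose_response(tr, c(0, 0.1, 0.4, 1.6, 6.4), ns)
  expect_identical(a, b)
  s1 <- simulate_slow_binding(tr, noise = ns)
  s2 <- simulate_slow_binding(tr, noise = ns)
  expect_identical(s1, s2)
  q1 <- simulate_quenching(tr, "double_log", noise = ns)
  q2 <- simulate_quenching(tr, "double_log", noise = ns)
  expect_identical(q1, q2)
})

test_that("dose-response generator matches the logistic definition", {
  tr <- assay_truth(ic50 = 1, hill = 1)
  d <- simulate_dose_response(tr, c(0, 1, 3))
  expect_equal(d$inhibition[d$concentration == 1], 0.5)
  expect_equal(d$inhibition[d$concentration == 0], 0)
  expect_equal(d$inhibition[d$concentration == 3], 0.75)
  expect_error(simulate_dose_response(tr, c(1, 2, 4)), "control")
})

test_that("reversibility generator gives lines through the origin", {
  tr <- assay_truth(mode = "noncompetitive", ki = 2, ic50 = 2)
  d <- simulate_reversibility(tr, inhibitor_levels = c(0, 2))
  v0 <- d$velocity[d$inhibitor == 0]
  expect_equal(v0 / v0[1], c(1, 2, 4), tolerance = 1e-12)
  # [I] = Ki halves the slope for a noncompetitive inhibitor
  expect_equal(d$velocity[d$inhibitor == 2], v0 / 2, tolerance = 1e-12)
})

test_that("slow-binding generator follows the exponential decay law", {
  tr <- assay_truth(k3 = 0.1410, k4 = 0.0203)
  d <- simulate_slow_binding(tr, inhibitors = c(0, 0.2, 0.8))
  expect_equal(d$v_over_v0[d$preincubation == 0], rep(1, 3))
  # [I] = 0: Kobs = k4
  i0 <- d[d$inhibitor == 0, ]
  expect_equal(i0$v_over_v0, exp(-0.0203 * i0$preincubation),
               tolerance = 1e-12)
  # printed-constants check: Kobs = k4 (1 + I / (k4/k3))
  i8 <- d[d$inhibitor == 0.8, ]
  kobs <- 0.0203 * (1 + 0.8 / (0.0203 / 0.1410))
  expect_equal(i8$v_over_v0, exp(-kobs * i8$preincubation), tolerance = 1e-12)
  expect_error(simulate_slow_binding(assay_truth(k3 = -1)), "k3")
  expect_error(simulate_slow_binding(tr, preincubation_times = c(2, 4, 6)),
               "include 0")
})

test_that("noiseless velocity is strictly decreasing in inhibitor", {
  for (md in c("competitive", "noncompetitive", "uncompetitive", "mixed")) {
    v <- mm_velocity(100, seq(0, 10, by = 0.5), 100, 200, md, ki = 2,
                     alpha = 3)
    expect_true(all(diff(v) < 0), info = md)
  }
})

test_that("quenching spectra peak near 340 nm and follow the chosen model", {
  tr <- assay_truth(ksv = 0.15792, f0 = 1000)
  sp <- simulate_quenching(tr, "stern_volmer", quencher = c(0, 3.2))
  s0 <- sp[sp$quencher == 0, ]
  expect_equal(max(s0$intensity), 1000)
  expect_equal(s0$wavelength[which.max(s0$intensity)], 340)
  s3 <- sp[sp$quencher == 3.2, ]
  expect_equal(max(s0$intensity) / max(s3$intensity), 1 + 0.15792 * 3.2,
               tolerance = 1e-12)
  # with n = 1 and KA = KSV the two generating models coincide
  tr2 <- assay_truth(ksv = 0.2, ka = 0.2, n_sites = 1)
  a <- simulate_quenching(tr2, "stern_volmer")
  b <- simulate_quenching(tr2, "double_log")
  expect_equal(a$intensity, b$intensity, tolerance = 1e-12)
  expect_error(simulate_quenching(tr, quencher = c(-1, 0)), "quencher")
})
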