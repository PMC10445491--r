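test_that("peak extraction handles peaked, flat, and invalid spectra", {
  wl <- seq(300, 400, by = 2)
  y <- 1000 * exp(-(wl - 340)^2 / 800)
  p <- extract_peak(wl, y)
  expect_equal(p$peak, 1000)
  expect_equal(p$wavelength, 340)
  flat <- extract_peak(wl, rep(7, length(wl)))
  expect_equal(flat$peak, 7)
  expect_equal(flat$wavelength, 300)
  expect_true(flat$flat)
  expect_error(extract_peak(numeric(0), numeric(0)), "empty|10 wavelength")
})

test_that("Stern-Volmer fit recovers the published constant exactly", {
  q <- c(0, 0.2, 0.4, 0.8, 1.6, 3.2)
  f0 <- 1000
  tt <- data.frame(quencher = q, f = f0 / (1 + 0.15792 * q))
  f <- fit_stern_volmer(tt)
  expect_equal(f$ksv, 0.15792, tolerance = 1e-9)
  expect_equal(f$ksv_per_molar, 1.5792e5, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  # unquenched series gives ksv = 0
  expect_equal(fit_stern_volmer(data.frame(quencher = q,
                                           f = rep(f0, 6)))$ksv, 0)
  # halving all [Q] at fixed F doubles the fitted slope
  tt2 <- tt; tt2$quencher <- tt2$quencher / 2
  expect_equal(fit_stern_volmer(tt2)$ksv, 2 * 0.15792, tolerance = 1e-9)
})

test_that("double-log fit recovers (KA, n) and matches the grid oracle", {
  q <- c(0, 0.2, 0.4, 0.8, 1.6, 3.2)
  f0 <- 1000
  ka <- 0.24434; n <- 1.2897
  tt <- data.frame(quencher = q, f = f0 / (1 + ka * q^n))
  f <- fit_double_log(tt)
  expect_equal(f$ka, ka, tolerance = 1e-9)
  expect_equal(f$n_sites, n, tolerance = 1e-9)
  # brute-force 2-D minimization of squared log-residuals agrees
  qq <- q[q > 0]
  or <- grid_search_double_log(qq, f0 / (1 + ka * qq^n), f0,
                               la_range = log10(ka) + c(-1, 1) * 1e-5,
                               n_range = n + c(-1, 1) * 1e-5, n = 2001)
  expect_equal(or$ka, f$ka, tolerance = 1e-6)
  expect_equal(or$n_sites, f$n_sites, tolerance = 1e-6)
})

test_that("double-log and Stern-Volmer coincide when n = 1", {
  q <- c(0, 0.2, 0.4, 0.8, 1.6, 3.2)
  tt <- data.frame(quencher = q, f = 1000 / (1 + 0.2 * q))
  expect_equal(fit_double_log(tt)$ka, fit_stern_volmer(tt)$ksv,
               tolerance = 1e-9)
  expect_equal(fit_double_log(tt)$n_sites, 1, tolerance = 1e-9)
})

test_that("points with F >= F0 are excluded with a warning", {
  q <- c(0, 0.2, 0.4, 0.8, 1.6, 3.2)
  f <- 1000 / (1 + 0.2 * q)
  f[2] <- 1001
  expect_warning(res <- fit_double_log(data.frame(quencher = q, f = f)),
                 "excluded")
  expect_equal(res$excluded, 1)
  f[3:5] <- 1001
  expect_error(suppressWarnings(
    fit_double_log(data.frame(quencher = q, f = f))), "fewer than 3")
})

test_that("end-to-end spectra recovery hits the generating parameters", {
  tr <- assay_truth(ksv = 0.15792, ka = 0.24434, n_sites = 1.2897)
  sv <- titration_from_sim(simulate_quenching(tr, "stern_volmer"))
  expect_equal(fit_stern_volmer(sv)$ksv, 0.15792, tolerance = 1e-6)
  dl <- titration_from_sim(simulate_quenching(tr, "double_log"))
  f <- fit_double_log(dl)
  expect_equal(f$ka, 0.24434, tolerance = 1e-6)
  expect_equal(f$n_sites, 1.2897, tolerance = 1e-6)
})

test_that("fitted KA ranking reproduces the published affinity order", {
  # published (KA, n) pairs for the four spectra-characterized inhibitors
  truths <- list(c1 = c(0.24434, 1.2897), c4 = c(0.05545, 0.7819),
                 c6 = c(0.00180, 0.4337), c2 = c(0.00002, 0.1796))
  kas <- vapply(truths, function(p) {
    tr <- assay_truth(ka = p[1], n_sites = p[2])
    fit_double_log(titration_from_sim(
      simulate_quenching(tr, "double_log")))$ka
  }, 0)
  expect_identical(names(sort(kas, decreasing = TRUE)),
                   c("c1", "c4", "c6", "c2"))
})

test_that("micromolar/molar conversion round-trips exactly", {
  x <- c(0.15792, 1e-5, 42)
  expect_identical(per_molar_to_per_uM(per_uM_to_per_molar(x)), x)
})
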