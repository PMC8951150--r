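test_that("mono-exponential fit is exact on noiseless input and errors on degenerate input", {
  t <- seq(0, 20, length.out = 100)
  y <- 3e-9 * (1 - exp(-0.5 * t))
  fit <- fit_monoexponential(t, y)
  expect_equal(fit$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$amplitude, 3e-9, tolerance = 1e-10)
  expect_equal(fit$offset, 0, tolerance = 1e-19)
  expect_lt(fit$rss, 1e-30)
  # initial-rate identity: beta * (amplitude - offset) = slope at t = 0
  slope0 <- (y[2] - y[1]) / (t[2] - t[1])
  expect_equal(fit$beta * (fit$amplitude - fit$offset), slope0,
               tolerance = 0.1)

  expect_error(fit_monoexponential(t[1:4], y[1:4]),
               class = "permkin_fit_error")
  expect_error(fit_monoexponential(rev(t), y), class = "permkin_fit_error")
  expect_error(fit_monoexponential(t, rep(1, 100)),
               class = "permkin_fit_error")
})

test_that("beta is recovered from a noisy synthetic trace within its uncertainty", {
  fx <- generate_fixture(beta = 0.2, amplitude = 1, n_points = 200,
                         noise_sd = 0.01, seed = 42)
  fit <- fit_monoexponential(fx$t, fx$y)
  expect_lt(abs(fit$beta - 0.2), 3 * fit$stderr_beta)
  expect_gt(fit$stderr_beta, 0)
})

test_that("the fitted rate is insensitive to doubling the fit window", {
  g <- std_geom()
  sim <- simulate_weak_acid(g, std_weak_acid(1, 1, 7, g),
                            proton_environment(PT = 1e-5), nST_std,
                            n_points = 150)
  b10 <- fit_monoexponential(sim$t_s, sim$nSi, window = 10)$beta
  b20 <- fit_monoexponential(sim$t_s, sim$nSi, window = 20)$beta
  expect_lt(abs(b20 - b10) / b10, 5e-3)
})

test_that("the general estimator is size-invariant for a non-lipophilic solute", {
  papps <- vapply(c(100, 500, 2000, 5000), function(r) {
    g <- std_geom(r)
    estimate_permeability(simulate_neutral(g, std_neutral(1, g), nST_std,
                                           n_points = 100))$Papp
  }, numeric(1))
  expect_lt(diff(range(papps)) / mean(papps), 0.02)
  expect_equal(mean(papps), 2e-8, tolerance = 0.05)
})

test_that("the radius-based estimator deviates at both size extremes for KP = 1e4", {
  est <- lapply(c(25, 5000), function(r) {
    g <- std_geom(r)
    estimate_permeability(simulate_neutral(g, std_neutral(1e4, g), nST_std,
                                           n_points = 100))
  })
  # Pappr grows by over two orders of magnitude from 25 nm to 5000 nm
  expect_gt(est[[2]]$Pappr / est[[1]]$Pappr, 100)
  # while Papp varies far less (factor < 3)
  expect_lt(est[[2]]$Papp / est[[1]]$Papp, 3)
})

test_that("aqueous-only permeability: direct bookkeeping equals the closed form", {
  for (KP in c(1, 100)) {
    g <- std_geom(100)
    p <- std_neutral(KP, g)
    est <- estimate_permeability(simulate_neutral(g, p, nST_std,
                                                  n_points = 100))
    closed <- papp_w_from_papp(est$Papp, KP,
                               fVwD = g$Vwo / g$VT, fVlD = g$Vlo / g$VT,
                               fVwA = g$Vwi / g$VT, fVlA = g$Vli / g$VT)
    expect_equal(est$Pappw, closed, tolerance = 1e-10)
  }
})

test_that("volume-corrected radius estimator approaches the plain one for small acceptors", {
  b <- 0.05; r <- 1e-6
  expect_equal(papp_rV(b, r, VA = 1e-9, VT = 1), papp_r(b, r),
               tolerance = 1e-8)
  expect_lt(papp_rV(b, r, VA = 0.3, VT = 1), papp_r(b, r))
})

test_that("the hybrid estimator equals the intrinsic permeability and is linear in KP", {
  kps <- c(1, 10, 100, 1000, 1e4)
  est <- lapply(kps, function(KP) {
    g <- std_geom(100)
    estimate_permeability(simulate_neutral(g, std_neutral(KP, g), nST_std,
                                           n_points = 100))
  })
  pw_star <- vapply(est, `[[`, numeric(1), "Pappw_star")
  p_int <- vapply(est, `[[`, numeric(1), "P_intrinsic")
  expect_equal(pw_star, p_int, tolerance = 0.03)
  # log-log slope 1
  slope <- coef(lm(log10(pw_star) ~ log10(kps)))[[2]]
  expect_equal(slope, 1, tolerance = 0.01)
  # Papp saturates instead: sublinear in KP and well below Pappw* at high KP
  papp <- vapply(est, `[[`, numeric(1), "Papp")
  expect_lt(papp[5] / pw_star[5], 0.3)
  slope_high <- log10(papp[5] / papp[4]) / log10(kps[5] / kps[4])
  expect_lt(slope_high, 0.7)
  expect_equal(papp, vapply(est, `[[`, numeric(1), "Pobs"), tolerance = 0.04)
})

test_that("intrinsic permeability matches the simulated general estimator for KP = 1", {
  g <- std_geom(100)
  est <- estimate_permeability(simulate_neutral(g, std_neutral(1, g),
                                                nST_std, n_points = 100))
  expect_equal(p_intrinsic_neutral(1, 1, g$h / 2), est$Papp, tolerance = 0.03)
  expect_equal(p_intrinsic_neutral(1, 0, g$h / 2), 0)
})

test_that("sequestration-corrected and intrinsic forms order correctly", {
  h <- 1.975e-8
  expect_equal(p_obs_neutral(1, 1, h, fVwD = 1, fVlD = 0),
               p_intrinsic_neutral(1, 1, h))
  expect_lt(p_obs_neutral(1, 1e4, h, fVwD = 0.993, fVlD = 3.9e-4),
            p_intrinsic_neutral(1, 1e4, h))
})

test_that("weak-acid intrinsic forms: protonation limit and pKa = pH halving", {
  h <- 1.975e-8
  # fully protonated limit reduces to the non-ionisable form
  expect_equal(p_obs_weak_acid(1, 10, 1, 1e-7, H = 1, h, 0.99, 1e-4),
               p_obs_neutral(1, 10, h, 0.99, 10 * 1e-4 / 10), tolerance = 1e-4)
  # negligible lipid, pH = pKa: half the non-ionisable value
  expect_equal(p_obs_weak_acid(1, 1, 1, 1e-7, H = 1e-7, h, 1, 0),
               0.5 * p_intrinsic_neutral(1, 1, h), tolerance = 1e-12)
  expect_equal(p_intrinsic_weak_acid(1, 1, 1e-7, 1e-7, h),
               0.5 * p_intrinsic_neutral(1, 1, h), tolerance = 1e-12)
})

test_that("Meyer-Overton with D = kflip h^2 reproduces the intrinsic permeability", {
  h <- 1.975e-8
  expect_equal(meyer_overton(50, D = 1 * h^2, h = h),
               p_intrinsic_neutral(1, 50, h), tolerance = 1e-12)
  expect_equal(meyer_overton(100, 1e-16, 1e-8),
               2 * meyer_overton(50, 1e-16, 1e-8))
  expect_equal(meyer_overton(0, 1e-16, 1e-8), 0)
})

test_that("estimator guards reject unusable inputs", {
  expect_error(papp_general(0.1, 1e-9, 0, 1, 1),
               class = "permkin_estimator_error")
  expect_error(papp_w(0.1, 1e-9, 1e-9, 1, 0),
               class = "permkin_estimator_error")
  expect_error(p_obs_neutral(1, 1, 1e-8, 0.8, 0.5),
               class = "permkin_estimator_error")
})
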