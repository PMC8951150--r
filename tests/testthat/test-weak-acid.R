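test_that("microreversibility fixes the membrane acidity constant", {
  g <- std_geom()
  p <- std_weak_acid(KPSH = 100, KPSD = 10, pKaSw = 7, geom = g)
  expect_equal(p$KaSl, p$KaSw * p$KPSD / p$KPSH, tolerance = 1e-12)
  expect_equal(-log10(p$KaSl), 8) # pKa shifts up one unit for KPSD = 0.1 KPSH
  expect_equal(p$klioSH, p$kloiSH * g$Vlo / g$Vli, tolerance = 1e-12)
})

test_that("outer speciation splits by the clamped pH and both partition coefficients", {
  g <- std_geom()
  env <- proton_environment()
  # pKa = pHo: equal aqueous split
  p <- std_weak_acid(1, 1, 7, g)
  o <- speciate_outer(nST_std, g, p, env)
  expect_equal(o$SHwo, o$SDwo, tolerance = 1e-12)
  # KPSD = 0.1 KPSH: the membrane-bound solute is mostly protonated
  p2 <- std_weak_acid(100, 10, 7, g)
  o2 <- speciate_outer(nST_std, g, p2, env)
  expect_equal(o2$SHlo / (o2$SHlo + o2$SDlo), 10 / 11, tolerance = 1e-12)
  # no partition -> no membrane-bound solute, all solute aqueous
  p0 <- weak_acid_params(0, 0, 7, klioSH = 1)
  o0 <- speciate_outer(nST_std, g, p0, env)
  expect_equal(o0$SHlo + o0$SDlo, 0)
  expect_equal((o0$SHwo + o0$SDwo) * g$Vwo, nST_std, tolerance = 1e-12)
})

test_that("inner speciation satisfies all equilibria and round-trips the conserved totals", {
  g <- std_geom()
  env <- proton_environment(PT = 1e-5)
  p <- std_weak_acid(100, 10, 7, g)
  set.seed(11)
  for (k in 1:10) {
    nSi <- runif(1, 1e-12, 5e-9)
    nHi <- .Machine$double.xmin + runif(1, 1e-10, 5e-9)
    sp <- solve_inner_speciation(nSi, nHi, g, p, env)
    # equilibrium relations
    expect_equal(sp$SDwi / sp$SHwi, p$KaSw / sp$Hwi, tolerance = 1e-9)
    expect_equal(sp$SHli / sp$SHwi, p$KPSH, tolerance = 1e-9)
    expect_equal(sp$SDli / sp$SDwi, p$KPSD, tolerance = 1e-9)
    expect_equal(sp$SDli / sp$SHli, p$KaSl / sp$Hwi, tolerance = 1e-9)
    expect_equal(sp$PHwi / env$PT, sp$Hwi / (sp$Hwi + env$KaP),
                 tolerance = 1e-9)
    # conserved totals recovered from the speciation
    nSi_back <- g$Vwi * (sp$SHwi + sp$SDwi) + g$Vli * (sp$SHli + sp$SDli)
    nHi_back <- g$Vwi * (sp$Hwi + sp$PHwi + sp$SHwi) + g$Vli * sp$SHli
    expect_equal(nSi_back, nSi, tolerance = 1e-9)
    expect_equal(nHi_back, nHi, tolerance = 1e-9)
  }
})

test_that("an unperturbed lumen keeps its initial pH", {
  g <- std_geom()
  env <- proton_environment(PT = 1e-4, pHi0 = 7)
  p <- std_weak_acid(1, 1, 7, g)
  nHi0 <- g$Vwi * (1e-7 + env$PT * 0.5)
  sp <- solve_inner_speciation(0, nHi0, g, p, env)
  expect_equal(sp$pHi, 7, tolerance = 1e-9)
})

test_that("a concentrated probe clamps the inner pH shift below 0.01", {
  g <- std_geom()
  p <- std_weak_acid(1, 1, 7, g)
  eq <- equilibrium_weak_acid(g, p, proton_environment(PT = 1e-4), nST_std)
  expect_lt(abs(eq$dpHi), 0.01)
})

test_that("equilibrium balances the neutral-species flux and orders the anion gradient", {
  g <- std_geom()
  p <- std_weak_acid(1, 1, 7, g)
  env <- proton_environment(PT = 0)
  eq <- equilibrium_weak_acid(g, p, env, nST_std)
  # equal protonated concentrations inside and outside (detailed balance)
  expect_equal(eq$SHwi, eq$SHwo, tolerance = 1e-6)
  # the anion equilibrates at a lower inner concentration when pHi drops
  expect_lt(eq$dpHi, 0)
  expect_lt(eq$SDwi, eq$SDwo)
  # simulation plateau agrees with the root-found equilibrium
  sim <- simulate_weak_acid(g, p, env, nST_std)
  expect_equal(sim$nSi[nrow(sim)], eq$nSi_inf, tolerance = 1e-3)
})

test_that("an overwhelming internal buffer restores full concentration equalisation", {
  g <- std_geom()
  p <- std_weak_acid(1, 1, 7, g)
  eq_buf <- equilibrium_weak_acid(g, p, proton_environment(PT = 1), nST_std)
  eq_neutral <- equilibrium_neutral(g, std_neutral(1, g), nST_std)
  expect_equal(eq_buf$nSi_inf, attr(eq_neutral, "nSi_inf"), tolerance = 1e-3)
})

test_that("solute and labile protons are conserved along the trace; pHi only falls", {
  g <- std_geom()
  p <- std_weak_acid(1, 1, 7, g)
  env <- proton_environment(PT = 1e-6)
  sim <- simulate_weak_acid(g, p, env, nST_std, n_points = 120)
  nSo <- (sim$SHwo + sim$SDwo) * g$Vwo + (sim$SHlo + sim$SDlo) * g$Vlo
  nSi <- (sim$SHwi + sim$SDwi) * g$Vwi + (sim$SHli + sim$SDli) * g$Vli
  expect_equal(nSo + nSi, rep(nST_std, nrow(sim)), tolerance = 1e-9)
  nHi <- (sim$Hwi + sim$PHwi + sim$SHwi) * g$Vwi + sim$SHli * g$Vli
  expect_equal(nHi, sim$nHi, tolerance = 1e-9)
  expect_equal(diff(sim$nHi), diff(sim$nSi), tolerance = 1e-12)
  expect_true(all(diff(sim$pHi) <= 1e-9))
})

test_that("the weak-acid model reduces to the neutral model when pKa >> pH", {
  g <- std_geom()
  p_acid <- std_weak_acid(1, 1, pKaSw = 12, geom = g)
  p_neutral <- std_neutral(1, g)
  sim_a <- simulate_weak_acid(g, p_acid, proton_environment(PT = 0), nST_std,
                              n_points = 120)
  beta_a <- fit_monoexponential(sim_a$t_s, sim_a$nSi)$beta
  expect_equal(beta_a, beta_analytic_neutral(g, p_neutral), tolerance = 5e-3)
  # traces match pointwise on a shared grid
  sim_n <- simulate_neutral(g, p_neutral, nST_std, t_grid = sim_a$t_s)
  expect_lt(max(abs(sim_a$nSi - sim_n$nSi)) / max(sim_n$nSi), 5e-3)
})

test_that("the pH shift shrinks monotonically as the probe concentration rises", {
  g <- std_geom()
  p <- std_weak_acid(1, 1, 7, g)
  dpH <- vapply(c(0, 1e-6, 1e-5, 1e-4), function(PT)
    abs(equilibrium_weak_acid(g, p, proton_environment(PT = PT), nST_std)$dpHi),
    numeric(1))
  expect_true(all(diff(dpH) < 0))
})

test_that("probe signal follows Henderson-Hasselbalch and inverts cleanly", {
  env <- proton_environment(KaP = 1e-7)
  expect_equal(probe_signal(7, env), 0.5)
  expect_equal(probe_signal(6, env), 10 / 11)
  # inverse map: pHi = pKaP - log10(f/(1-f))
  f <- probe_signal(c(5.5, 6.5, 7.5), env)
  expect_equal(7 - log10(f / (1 - f)), c(5.5, 6.5, 7.5), tolerance = 1e-12)
})
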