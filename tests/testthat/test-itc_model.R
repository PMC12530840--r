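test_that("direct simulation conserves total heat in the tight-binding limit", {
  # a huge first injection saturates everything at once; total heat then
  # equals dH * N * P0 * V0 up to the material expelled by that injection
  sch <- injection_schedule(syringe_conc = 10e-3, cell_protein_conc = 20e-6,
                            injection_volumes = c(1e-6, rep(1e-6, 5)))
  params <- binding_parameters(kd = 1e-12, dh = -50, n = 0.9)
  tg <- simulate_direct(params, sch)
  expected_uJ <- params$dh * params$n * 20e-6 * 200e-6 * 1e9
  expect_equal(sum(tg$heats), expected_uJ, tolerance = 0.02)
})

test_that("per-injection heats follow the dilution-corrected complex increments", {
  sch <- schedule_displacement(preload = 0)
  params <- binding_parameters(kd = 2.9e-7, dh = -50, n = 0.9)
  tg <- simulate_direct(params, sch)
  comp <- protonbind:::cell_composition(sch)
  cx_prev <- 0
  for (i in seq_len(nrow(comp))) {
    cx <- solve_single_site(params$n * comp$protein[i], comp$titrant[i],
                            params$kd)$complex
    q <- params$dh * 200e-6 * (cx - cx_prev * comp$dilution[i]) * 1e9
    expect_equal(tg$heats[i], q, tolerance = 1e-9)
    cx_prev <- cx
  }
  # normalized heats are heats over moles injected
  expect_equal(tg$normalized,
               tg$heats * 1e-9 / (sch$syringe_conc * sch$injection_volumes))
})

test_that("zero enthalpy gives zero heat and the low-c direct titration is featureless", {
  sch <- schedule_direct_lowc()
  expect_true(all(simulate_direct(binding_parameters(1e-3, dh = 0), sch)$heats == 0))
  # c = 0.14 regime of the direct fragment titration: a shallow, nearly
  # featureless curve. The per-injection amplitude is capped by the bound
  # fraction of the injectant, P/(P + Kd) ~ 12% of |dH|, and the curve decays
  # monotonically with no sigmoidal transition.
  tg <- simulate_direct(binding_parameters(kd = 1e-3, dh = -40, n = 1), sch)
  expect_lt(max(abs(tg$normalized)), 40 * 140e-6 / (140e-6 + 1e-3) * 1.01)
  expect_true(all(diff(abs(tg$normalized[-1])) < 0))
  expect_lt(as.numeric(c_value(140e-6, 1e-3)), 1)
})

test_that("noiseless fit recovers the generating parameters to high precision", {
  sch <- injection_schedule(syringe_conc = 300e-6, cell_protein_conc = 20e-6)
  truth <- binding_parameters(kd = 2.9e-7, dh = -50, n = 0.9)
  fit <- fit_one_site(simulate_direct(truth, sch))
  expect_true(fit$converged)
  expect_equal(fit$params$n, 0.9, tolerance = 1e-6)
  expect_equal(fit$params$kd, 2.9e-7, tolerance = 1e-6)
  expect_equal(fit$params$dh, -50, tolerance = 1e-6)
  expect_true(all(fit$se >= 0, na.rm = TRUE))
})

test_that("noiseless round-trip identity holds across a random sweep inside the c window", {
  set.seed(11)
  p0 <- 20e-6
  for (i in 1:25) {
    cval <- 10^runif(1, 0.1, 2.9)          # c in ~[1.26, 800]
    kd <- p0 / cval
    n <- runif(1, 0.7, 1.3)
    dh <- runif(1, -80, -10)
    sch <- injection_schedule(syringe_conc = 25 * p0, cell_protein_conc = p0)
    fit <- suppressWarnings(fit_one_site(simulate_direct(
      binding_parameters(kd = kd, dh = dh, n = n), sch)))
    expect_true(fit$converged)
    expect_lt(abs(fit$params$kd - kd) / kd, 1e-6)
    expect_lt(abs(fit$params$n - n) / n, 1e-6)
    expect_lt(abs(fit$params$dh - dh) / abs(dh), 1e-6)
  }
})

test_that("fit flags unreliable c values and degenerate thermograms", {
  sch <- schedule_direct_lowc()
  tg <- simulate_direct(binding_parameters(kd = 1e-3, dh = -40), sch)
  expect_warning(fit_one_site(tg), "c value")
  # all-zero thermogram: never a silent confident fit
  tg0 <- simulate_direct(binding_parameters(kd = 1e-3, dh = 0), sch)
  fit0 <- suppressWarnings(fit_one_site(tg0))
  expect_true(!fit0$converged || abs(fit0$params$dh) < 1e-6 ||
                any(!is.finite(fit0$se)) || any(fit0$se > 1))
})

test_that("displacement simulation reduces to direct titration without a competitor", {
  strong <- binding_parameters(kd = 2.9e-7, dh = -50, n = 0.9)
  weak <- binding_parameters(kd = 1e-3, dh = -5)
  sch0 <- schedule_displacement(preload = 0)
  expect_equal(simulate_displacement(strong, weak, sch0)$heats,
               simulate_direct(strong, sch0)$heats, tolerance = 1e-12)
  # inert weak ligand: pointwise equality despite nonzero preload
  inert <- binding_parameters(kd = Inf, dh = 0)
  schp <- schedule_displacement()
  expect_equal(simulate_displacement(strong, inert, schp)$heats,
               simulate_direct(strong, sch0)$heats, tolerance = 1e-6)
})

test_that("displacement shifts the apparent Kd by the competition factor", {
  strong <- binding_parameters(kd = 2.9e-7, dh = -50, n = 0.9)
  weak <- binding_parameters(kd = 1e-3, dh = 0)
  tg <- simulate_displacement(strong, weak, schedule_displacement())
  fit <- suppressWarnings(fit_one_site(tg))
  kd_apparent_expected <- strong$kd * (1 + 4.2e-3 / weak$kd)
  expect_equal(fit$params$kd, kd_apparent_expected, tolerance = 0.1)
  expect_gt(fit$params$kd, strong$kd * 3)
})

test_that("displacing an exothermic weak ligand attenuates the net heats without flipping them", {
  # displacement endothermically breaks the weak complex, so when both
  # ligands bind exothermically the net signal shrinks; a measurable
  # displacement experiment needs the two enthalpies to differ
  strong <- binding_parameters(kd = 2.9e-7, dh = -50, n = 1)
  weak_same <- binding_parameters(kd = 1e-3, dh = -50)
  weak_silent <- binding_parameters(kd = 1e-3, dh = 0)
  sch <- schedule_displacement()
  tg_same <- simulate_displacement(strong, weak_same, sch)
  tg_sil <- simulate_displacement(strong, weak_silent, sch)
  early <- 2:8  # before the equivalence point
  expect_true(all(abs(tg_same$heats[early]) < abs(tg_sil$heats[early])))
  expect_true(all(sign(tg_same$heats[early]) == sign(tg_sil$heats[early])))
  # equal enthalpies on both sites make the displacement nearly silent
  # relative to the reference; opposite-sign enthalpies amplify it
  weak_opp <- binding_parameters(kd = 1e-3, dh = +50)
  tg_opp <- simulate_displacement(strong, weak_opp, sch)
  expect_true(all(abs(tg_opp$heats[early]) > abs(tg_sil$heats[early])))
})

test_that("weighted mean fragment concentration sits between final and preload values", {
  sch <- schedule_displacement()
  strong <- binding_parameters(kd = 2.9e-7, dh = -50, n = 0.9)
  tg <- simulate_displacement(strong, binding_parameters(1e-3, dh = 0), sch)
  m_unw <- mean_fragment_conc(sch)
  m_w <- mean_fragment_conc(sch, weights = tg)
  comp <- protonbind:::cell_composition(sch)
  expect_gt(m_unw, min(comp$preload))
  expect_lt(m_unw, 4.2e-3)
  expect_gt(m_w, m_unw)  # heat-weighting favours early, less-diluted injections
  expect_lt(m_w, 4.2e-3)
  expect_error(mean_fragment_conc(schedule_displacement(preload = 0)), "preload")
})
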