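# Fitting tests use a coarse grid and few starts where exactness is not the
# point, to keep the suite quick; the parameter-recovery tests use the full
# protocol.

test_that("the loss is zero at the generating truth, quadratic in the
           residuals, and order-invariant", {
  m <- build_matrix()
  pp <- ref_params()
  ds <- generate_dataset(pp, m, times = c(0.5, 2, 10), noise = noise_free())
  truth <- list(h = 0.04, V = 92, K = 1129)

  expect_lt(carrier_loss(truth, ds, m), 1e-10)

  ds2 <- ds
  ds2$mean_uptake_pmol_per_mg <- ds2$mean_uptake_pmol_per_mg * 2
  off <- list(h = 0.04, V = 92, K = 1129)
  base <- carrier_loss(off, ds2, m)
  ds4 <- ds
  ds4$mean_uptake_pmol_per_mg <- ds4$mean_uptake_pmol_per_mg * 3
  expect_equal(carrier_loss(off, ds4, m), 4 * base, tolerance = 1e-8)

  shuffled <- ds[sample(nrow(ds)), ]
  expect_equal(carrier_loss(truth, shuffled, m), carrier_loss(truth, ds, m))

  bad <- ds; bad$condition_id[1] <- "99"
  expect_error(carrier_loss(truth, bad, m), "not in matrix")
})

test_that("noise-free parameter recovery is exact for both variants across
           generator sets", {
  m <- build_matrix()
  gens <- list(c(h = 0.04, V = 92, K = 1129),
               c(h = 0.16, V = 92, K = 1129),
               c(h = 0.5, V = 40, K = 300))
  for (g in gens) {
    ds <- generate_dataset(serine_params(g["h"], g["V"], g["K"]), m,
                           noise = noise_free())
    fit <- fit_carrier(ds, m, fit_spec("mixed", multistart = 2))
    expect_equal(fit$par$h, unname(g["h"]), tolerance = 0.01)
    expect_equal(fit$par$V, unname(g["V"]), tolerance = 0.01)
    expect_equal(fit$par$K, unname(g["K"]), tolerance = 0.01)
    expect_lt(fit$ssr, 1e-8)
    expect_equal(fit$r_squared, 1, tolerance = 1e-8)
  }

  # obligate variant: recover the endogenous interior concentration
  for (endo in c(10, 80)) {
    ds <- generate_dataset(serine_params(h = 0), m, noise = noise_free(),
                           endo_int = endo)
    fit <- fit_carrier(ds, m, fit_spec("obligate", multistart = 2))
    expect_equal(fit$par$endo_int, endo, tolerance = 0.01)
    expect_equal(fit$par$V, 92, tolerance = 0.01)
    expect_equal(fit$par$K, 1129, tolerance = 0.01)
  }
})

test_that("fits are deterministic and report coherent diagnostics", {
  m <- build_matrix()
  ds <- generate_dataset(ref_params(h = 0.16), m,
                         noise = noise_model(0.1, 0.3, 5, seed = 4))
  f1 <- fit_carrier(ds, m, fit_spec("mixed", multistart = 3))
  f2 <- fit_carrier(ds, m, fit_spec("mixed", multistart = 3))
  expect_identical(f1$par, f2$par)
  expect_identical(f1$ssr, f2$ssr)
  expect_equal(f1$ssr, min(f1$starts$ssr))
  expect_true(all(f1$starts$ssr >= f1$ssr - 1e-9))
  expect_gte(f1$r_squared, 0.9)        # truth-in-family fit on noisy data
  expect_true(all(is.finite(f1$se)) && all(f1$se >= 0))
})

test_that("R-squared scores against the grand-mean null as defined", {
  m <- build_matrix()
  ds <- generate_dataset(ref_params(), m, times = c(0.5, 2, 10),
                         noise = noise_free())
  fit <- fit_carrier(ds, m, fit_spec("mixed", multistart = 1))
  expect_equal(r_squared(fit, ds), 1, tolerance = 1e-8)

  # a deliberately wrong model scores below a flat line through the mean
  wrong <- fit
  wrong$par <- list(h = 5, V = 5000, K = 10, endo_int = 0)
  expect_lt(r_squared(wrong, ds), 0)

  flat <- ds
  flat$mean_uptake_pmol_per_mg <- 3
  expect_error(r_squared(fit, flat), "SST = 0")
})

test_that("weighted loss honours inverse-sem weights", {
  m <- build_matrix()
  ds <- generate_dataset(ref_params(), m, times = c(1, 5),
                         noise = noise_model(0.1, 0.3, 6, seed = 9))
  p <- list(h = 0.1, V = 50, K = 800)
  unw <- carrier_loss(p, ds, m, weighting = "none")
  wtd <- carrier_loss(p, ds, m, weighting = "sem")
  expect_false(isTRUE(all.equal(unw, wtd)))
  ds0 <- ds; ds0$sem[1] <- 0
  expect_error(carrier_loss(p, ds0, m, weighting = "sem"), "positive sem")
})

test_that("the mixed family nests the obligate optimum", {
  m <- build_matrix()
  # data generated by an obligate truth with no endogenous substrate can be
  # matched by the mixed family at h -> 0
  ds <- generate_dataset(serine_params(h = 0), m, noise = noise_free())
  mixed <- fit_carrier(ds, m, fit_spec("mixed", multistart = 4))
  obligate <- fit_carrier(ds, m, fit_spec("obligate", multistart = 4))
  expect_lte(mixed$ssr, obligate$ssr + 1e-6)
})

test_that("discrimination prefers the generating mechanism", {
  m <- build_matrix()
  ds <- generate_dataset(ref_params(h = 0.16), m,
                         noise = noise_model(0.1, 0.3, 5, seed = 21))
  d1 <- discriminate(ds, m, multistart = 2)
  expect_s3_class(d1, "carrier_discrimination")
  expect_equal(d1$verdict, "mixed-preferred")
  expect_equal(d1$delta_r2,
               d1$mixed$r_squared - d1$obligate$r_squared)
  # identical dataset in -> identical report out
  d2 <- discriminate(ds, m, multistart = 2)
  expect_identical(d1$mixed$par, d2$mixed$par)
  expect_identical(d1$verdict, d2$verdict)
})

test_that("obligate fits of mixed-generated data underpredict late
           zero-trans uptake", {
  m <- build_matrix()
  ds <- generate_dataset(ref_params(h = 0.16), m, noise = noise_free())
  obl <- fit_carrier(ds, m, fit_spec("obligate", multistart = 4))
  resid <- uptake_to_conc(ds$mean_uptake_pmol_per_mg) - predict(obl, ds)
  late <- ds$time_min == 10 & ds$condition_id %in% c("2", "5")
  expect_true(all(resid[late] > 0))
})
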