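test_that("fold assignment is balanced, deterministic, and errors when too small", {
  f <- make_folds(10, 5, seed = 1)
  expect_equal(as.integer(sort(table(f))), c(2L, 2L, 2L, 2L, 2L))
  expect_identical(f, make_folds(10, 5, seed = 1))
  expect_false(identical(f, make_folds(10, 5, seed = 2)))
  f2 <- make_folds(11, 5, seed = 1)
  expect_lte(diff(range(table(f2))), 1)
  expect_error(make_folds(3, 5), class = "cocoanir_validation_error")
})

test_that("k-fold CV predicts each sample out-of-fold; LOO matches an explicit loop", {
  toy <- make_linear_toy(n = 8, noise = 0.1)
  # determinism
  p1 <- kfold_cv(toy$X, toy$y, "PLS", n_factors = 2, k_folds = 4, seed = 9)
  p2 <- kfold_cv(toy$X, toy$y, "PLS", n_factors = 2, k_folds = 4, seed = 9)
  expect_identical(p1, p2)
  # leave-one-out vs hand-rolled loop
  loo <- kfold_cv(toy$X, toy$y, "PLS", n_factors = 2, k_folds = 8, seed = 1)
  byhand <- vapply(seq_len(8), function(i) {
    m <- fit_pls(toy$X[-i, ], toy$y[-i], 2)
    predict(m, toy$X[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(loo, byhand, tolerance = 1e-10)
})

test_that("metrics follow the SEC/SECV/R2/RPD definitions", {
  y <- c(1, 2, 3, 4, 5)
  perfect <- compute_metrics(y, y, y, n_factors = 1)
  expect_equal(perfect$sec, 0)
  expect_equal(perfect$secv, 0)
  expect_equal(perfect$r2cv, 1)
  expect_true(perfect$rpd_flagged)

  # constant CV prediction at the mean: R2cv = 0 and RPD = SD/SD = 1
  cvm <- compute_metrics(y, y, rep(mean(y), 5), n_factors = 0)
  expect_equal(cvm$r2cv, 0)
  expect_equal(cvm$rpd, 1, tolerance = 1e-12)

  # titratable acidity table row: SD 3.86, SECV 1.43 gives RPD 2.70
  expect_equal(round(3.86 / 1.43, 2), 2.70)

  withr::with_seed(20, {
    y <- rnorm(20); fit <- y + rnorm(20, 0, 0.3); cv <- y + rnorm(20, 0, 0.5)
    m <- compute_metrics(y, fit, cv, n_factors = 3)
    expect_equal(m$sec, sqrt(sum((fit - y)^2) / (20 - 1 - 3)))
    expect_equal(m$secv, sqrt(sum((cv - y)^2) / 19))
    expect_equal(m$rpd, sd(y) / m$secv)
  })
  expect_error(compute_metrics(rep(1, 5), rnorm(5), rnorm(5)),
               class = "cocoanir_validation_error")
})

test_that("the 2.5 SD outlier rule removes only planted outliers", {
  withr::with_seed(21, {
    y <- rnorm(20)
    pred <- y + rnorm(20, 0, 0.1)
    clean <- remove_outliers(y, pred)
    expect_length(clean$removed, 0)
    expect_length(clean$retained, 20)

    # plant one gross error
    pred2 <- pred
    pred2[7] <- y[7] + 10 * sd(pred - y)
    out <- remove_outliers(y, pred2)
    expect_equal(out$removed, 7L)
    expect_equal(length(out$retained) + length(out$removed), 20)

    # two-pass behaviour matches a hand-rolled loop on the same rule
    pred3 <- pred
    pred3[3] <- y[3] + 30 * sd(pred - y)
    pred3[11] <- y[11] + 5 * sd(pred - y)
    keep <- seq_along(y)
    for (pass in 1:2) {
      r <- pred3[keep] - y[keep]
      t_i <- abs(r) / sd(r)
      drop <- keep[t_i > 2.5]
      if (length(drop) == 0) break
      keep <- setdiff(keep, drop)
    }
    got <- remove_outliers(y, pred3)
    got2 <- remove_outliers(y[got$retained], pred3[got$retained])
    expect_setequal(got$retained[got2$retained], keep)
  })
  # large shared offset with tiny spread: every T statistic explodes
  expect_error(
    remove_outliers(rep(0, 5), c(100, 100.1, 99.9, 100.05, 99.95)),
    class = "cocoanir_validation_error")
})

test_that("interpretation bands follow the published cut-offs", {
  top <- interpret_performance(0.91, 3.40)
  expect_equal(top$accuracy, "excellent")
  expect_equal(top$rpd_class, "adequate")
  expect_equal(interpret_performance(0.65, 2)$accuracy, "poor")
  expect_equal(interpret_performance(0.82, 2)$accuracy, "good")
  expect_equal(interpret_performance(0.66, 2)$accuracy, "approximate")
  # unstated gaps resolve to the lower band
  expect_equal(interpret_performance(0.905, 2)$accuracy, "good")
  expect_equal(interpret_performance(0.815, 2)$accuracy, "approximate")
  expect_equal(interpret_performance(0.5, 1.49)$rpd_class, "unsatisfactory")
  expect_equal(interpret_performance(0.5, 2.51)$rpd_class, "adequate")
  expect_equal(interpret_performance(0.5, 2.0)$rpd_class, "intermediate")
})

test_that("factor selection is parsimonious and capped", {
  # noiseless single-component data needs exactly one factor
  wl <- seq_len(30)
  withr::with_seed(22, {
    conc <- runif(15, 1, 2)
    X <- outer(conc, exp(-((wl - 15)^2) / 18))
    sel <- select_n_factors(X, 3 * conc, "PLS", max_k = 5, seed = 1)
    expect_equal(sel$k, 1)

    # pure-noise response: nothing beats the mean by much
    yn <- rnorm(15)
    Xn <- matrix(rnorm(15 * 30), 15)
    seln <- select_n_factors(Xn, yn, "PLS", max_k = 5, seed = 1)
    expect_lte(seln$k, 1)
    # chosen k never exceeds the argmin
    expect_lte(sel$k, which.min(sel$secv_path$secv) - 1)
  })
})

test_that("the single-cell calibration pipeline accounts for every sample", {
  ds <- make_toy_dataset(n = 26, seed = 30)
  ev <- calibrate_constituent(ds, "protein",
                              math_treatment("SNV_DT", "1,4,4,1"),
                              seed = 77)
  r <- ev$report
  expect_equal(r$n + r$n_removed, 26)
  expect_equal(r$rpd, r$sd / r$secv, tolerance = 1e-12)
  expect_identical(sort(c(ev$cv$sample_id, ev$removed_ids)),
                   sort(ds$sample_ids))
  # reproducible end to end
  ev2 <- calibrate_constituent(ds, "protein",
                               math_treatment("SNV_DT", "1,4,4,1"),
                               seed = 77)
  expect_equal(ev$report, ev2$report)
})

test_that("outlier culling does not worsen the calibration fit", {
  ds <- make_toy_dataset(n = 24, seed = 31)
  # corrupt one reference value to plant an outlier
  refs <- ds$references
  refs$fat[5] <- refs$fat[5] + 12 * sd(refs$fat)
  ds2 <- spectral_dataset(ds$wavelengths, ds$absorbance, ds$sample_ids,
                          references = refs, preparation = "ground")
  ev <- calibrate_constituent(ds2, "fat", math_treatment("NONE", "0,0,1,1"),
                              seed = 3)
  expect_true(ds$sample_ids[5] %in% ev$removed_ids)
  # SEC on the culled set beats a no-culling run
  ev_keep <- calibrate_constituent(ds2, "fat",
                                   math_treatment("NONE", "0,0,1,1"),
                                   seed = 3, max_outlier_passes = 0)
  expect_lte(ev$report$sec, ev_keep$report$sec)
})

test_that("grid search covers 9 cells and its winner minimizes SECV", {
  ds <- make_toy_dataset(n = 20, seed = 32)
  gs <- grid_search(ds, "dm", max_factors = 6, seed = 5)
  expect_equal(nrow(gs$grid), 9)
  expect_equal(nrow(dplyr::distinct(gs$grid, scatter, math_treatment)), 9)
  expect_lte(gs$best$secv, min(gs$grid$secv) + 1e-12)
  # every emitted row satisfies the RPD identity at rounding precision
  expect_true(all(abs(gs$grid$rpd - gs$grid$sd / gs$grid$secv) < 5e-3))
})

test_that("scatter-correcting treatments win on scatter-corrupted spectra", {
  spec <- synthetic_spec(n_samples = 24, seed = 33)
  comp <- generate_compositions(spec)
  clean <- generate_spectra(comp, spec, "ground", nir_portable())
  withr::with_seed(33, {
    a <- rnorm(24, 0, 0.15); b <- rnorm(24, 0, 0.05)
  })
  corrupted <- spectral_dataset(clean$wavelengths,
                                clean$absorbance * (1 + a) + b,
                                clean$sample_ids, references = comp,
                                preparation = "ground")
  # a modest factor budget: given enough latent factors PLS can absorb
  # affine scatter itself, which is exactly what scatter correction is
  # meant to spare
  cell <- function(sc) {
    calibrate_constituent(corrupted, "fat", math_treatment(sc, "0,0,1,1"),
                          seed = 2, max_factors = 3)$report
  }
  none <- cell("NONE"); mscr <- cell("MSC"); snv <- cell("SNV_DT")
  expect_lt(min(mscr$secv, snv$secv), none$secv)
  expect_gte(max(mscr$r2cv, snv$r2cv) - none$r2cv, 0.1)
})
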