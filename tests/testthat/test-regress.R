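test_that("PLS at full rank reproduces ordinary least squares", {
  withr::with_seed(10, {
    X <- matrix(rnorm(8 * 4), 8, 4)
    y <- rnorm(8)
    ols <- lm.fit(cbind(1, X), y)
    for (fitter in list(fit_pls, fit_mpls)) {
      m <- fitter(X, y, 4)
      expect_equal(predict(m, X), as.numeric(cbind(1, X) %*% ols$coefficients),
                   tolerance = 1e-8)
    }
    m <- fit_pcr(X, y, 4)
    expect_equal(predict(m, X), as.numeric(cbind(1, X) %*% ols$coefficients),
                 tolerance = 1e-8)
  })
})

test_that("PLS with one factor on a single column is simple regression", {
  withr::with_seed(11, {
    x <- rnorm(15)
    y <- 2 + 3 * x + rnorm(15, 0, 0.2)
    m <- fit_pls(matrix(x, ncol = 1), y, 1)
    slope <- cov(x, y) / var(x)
    expect_equal(m$coefficients, slope, tolerance = 1e-10,
                 ignore_attr = TRUE)
  })
})

test_that("NIPALS agrees with an independent SIMPLS implementation", {
  withr::with_seed(12, {
    X <- matrix(rnorm(6 * 4), 6, 4)
    y <- rnorm(6)
    for (k in 1:2) {
      m <- fit_pls(X, y, k)
      oracle <- simpls_oracle(X, y, k)
      expect_equal(predict(m, X), oracle$predict(X), tolerance = 1e-6)
    }
  })
})

test_that("modified PLS equals PLS at one factor and stays exact on noiseless data", {
  toy <- make_linear_toy(noise = 0)
  m1 <- fit_mpls(toy$X, toy$y, 1)
  p1 <- fit_pls(toy$X, toy$y, 1)
  expect_equal(m1$coefficients, p1$coefficients, tolerance = 1e-12)

  # one latent component, noiseless: one MPLS factor explains everything
  single <- make_linear_toy(noise = 0)
  y1 <- 4 * single$conc[, 1]
  X1 <- single$conc[, 1, drop = FALSE] %*%
    matrix(exp(-((single$wl - 1100)^2) / (2 * 30^2)), nrow = 1)
  ms <- fit_mpls(X1, y1, 1)
  expect_gt(ms$training_stats$r2cal, 1 - 1e-8)
})

test_that("MPLS and PLS cross-validate within a common envelope", {
  # compared on scatter-corrected spectra, where channel scales are
  # comparable; on raw spectra the per-factor standardization amplifies
  # information-free channels and the engines legitimately diverge
  ds <- make_toy_dataset(n = 56, seed = 21)
  proc <- apply_treatment(ds, math_treatment("SNV_DT", "1,4,4,1"))
  ref <- constituent_values(proc, "fat")
  X <- proc$absorbance[ref$row, ]
  y <- ref$value
  secv_of <- function(engine) {
    preds <- kfold_cv(X, y, engine, n_factors = 4, seed = 1)
    sqrt(sum((preds - y)^2) / (length(y) - 1))
  }
  s_pls <- secv_of("PLS"); s_mpls <- secv_of("MPLS")
  expect_lt(abs(s_mpls - s_pls) / s_pls, 0.2)
})

test_that("PCR components match the SVD and k = 0 predicts the mean", {
  withr::with_seed(13, {
    X <- matrix(rnorm(10 * 6), 10, 6)
    y <- rnorm(10)
    m <- fit_pcr(X, y, 3)
    sv <- svd(scale(X, scale = FALSE))
    for (a in 1:3) {
      v <- sv$v[, a]
      got <- extract_loadings(m, a)$loading
      if (sum(got * v) < 0) v <- -v
      expect_equal(got, v, tolerance = 1e-8)
    }
    # successive PCR loadings are orthogonal
    L <- t(sapply(1:3, function(a) extract_loadings(m, a)$loading))
    expect_equal(tcrossprod(L), diag(3), tolerance = 1e-8)
    m0 <- fit_pcr(X, y, 0)
    expect_equal(predict(m0, X), rep(mean(y), 10))
  })
})

test_that("rank overreach errors name the achievable rank", {
  withr::with_seed(14, {
    X <- matrix(rnorm(8), 8, 1) %*% matrix(rnorm(5), 1, 5)  # rank 1
    y <- rnorm(8)
    expect_error(fit_pls(X, y, 3), "1", class = "cocoanir_rank_error")
    expect_error(fit_pcr(X, y, 3), "1", class = "cocoanir_rank_error")
    expect_error(fit_pls(X, y, 12), class = "cocoanir_rank_error")
  })
})

test_that("prediction is consistent batch vs per-row and on training rows", {
  toy <- make_linear_toy(noise = 0.01)
  m <- fit_mpls(toy$X, toy$y, 3)
  batch <- predict(m, toy$X)
  rows <- vapply(seq_len(nrow(toy$X)), function(i)
    predict(m, toy$X[i, , drop = FALSE]), numeric(1))
  expect_equal(batch, rows, tolerance = 1e-12)
  expect_equal(batch, m$training_stats$fitted, tolerance = 1e-10)
  expect_error(predict(m, toy$X[, 1:10]), class = "cocoanir_grid_error")
})

test_that("loadings are unit-norm and peak at the informative band", {
  # single constituent driven by one Gaussian band at 1210 nm
  withr::with_seed(15, {
    wl <- seq(900, 1680, by = 2)
    conc <- runif(20, 1, 3)
    band <- exp(-((wl - 1210)^2) / (2 * 20^2))
    X <- outer(conc, band) + matrix(rnorm(20 * length(wl), 0, 1e-4), 20)
    m <- fit_pls(X, conc, 2, wavelengths = wl)
    l1 <- extract_loadings(m, 1)
    expect_equal(sum(l1$loading^2), 1, tolerance = 1e-10)
    peak <- l1$wavelength_nm[which.max(abs(l1$loading))]
    expect_lte(abs(peak - 1210), 4)  # within 2 grid steps
    expect_error(extract_loadings(m, 5), class = "cocoanir_validation_error")
  })
})

test_that("engine invariances hold: y-shift, SSE monotonicity, wavelength permutation", {
  toy <- make_linear_toy(noise = 0.05)
  m <- fit_mpls(toy$X, toy$y, 3)
  m_shift <- fit_mpls(toy$X, toy$y + 100, 3)
  expect_equal(predict(m_shift, toy$X), predict(m, toy$X) + 100,
               tolerance = 1e-8)

  for (fitter in list(fit_pls, fit_mpls, fit_pcr)) {
    sse <- vapply(0:4, function(k) {
      f <- fitter(toy$X, toy$y, k)
      sum((predict(f, toy$X) - toy$y)^2)
    }, numeric(1))
    expect_true(all(diff(sse) < 1e-8))
  }

  withr::with_seed(16, {
    perm <- sample(ncol(toy$X))
    m_p <- fit_mpls(toy$X[, perm], toy$y, 3)
    expect_equal(predict(m_p, toy$X[, perm]), predict(m, toy$X),
                 tolerance = 1e-8)
    expect_equal(m_p$coefficients, m$coefficients[perm], tolerance = 1e-8)
  })
})
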