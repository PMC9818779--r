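test_that("SNV centers and scales each spectrum", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  withr::with_seed(1, {
    x <- rnorm(50)
    out <- snv(x)
    expect_equal(mean(out), 0, tolerance = 1e-12)
    expect_equal(sd(out), 1, tolerance = 1e-12)
    # affine invariance: a * x + b maps to the same output
    expect_equal(snv(3.7 * x + 11), out, tolerance = 1e-10)
  })
  expect_error(snv(rep(2, 10)), class = "cocoanir_preprocess_error")
  expect_error(snv(1), class = "cocoanir_preprocess_error")
})

test_that("detrend removes quadratic baselines and is idempotent", {
  wl <- seq(900, 1680, by = 2)
  base <- 0.3 + 1e-4 * wl + 2e-7 * wl^2
  expect_equal(detrend(base, wl), rep(0, length(wl)), tolerance = 1e-10)
  withr::with_seed(2, {
    x <- rnorm(length(wl))
    once <- detrend(x, wl)
    expect_equal(detrend(once, wl), once, tolerance = 1e-10)
    # residual orthogonal to the quadratic basis
    basis <- cbind(1, wl, wl^2)
    basis <- sweep(basis, 2, sqrt(colSums(basis^2)), "/")
    expect_lt(max(abs(crossprod(basis, once))), 1e-8)
  })
  expect_error(detrend(c(1, 2), c(1, 2)), class = "cocoanir_preprocess_error")
})

test_that("MSC inverts affine scatter against the reference", {
  withr::with_seed(3, {
    ref <- rnorm(60)
    expect_equal(msc(2 * ref + 1, ref), ref, tolerance = 1e-12)
    expect_equal(msc(ref, ref), ref, tolerance = 1e-12)
    x <- ref + rnorm(60, 0, 0.3)
    out <- msc(x, ref)
    # refitting the corrected spectrum on the reference gives a = 0, b = 1
    fit <- lm(out ~ ref)
    expect_equal(unname(coef(fit)[1]), 0, tolerance = 1e-10)
    expect_equal(unname(coef(fit)[2]), 1, tolerance = 1e-10)
  })
  expect_error(msc(rnorm(5), rep(1, 5)), class = "cocoanir_preprocess_error")
})

test_that("gap-segment derivative matches closed forms and the stencil oracle", {
  # code 0,0,1,1 is the identity on the full grid
  x <- rnorm(30); wl <- seq_len(30)
  id <- gap_derivative(x, wl, 0, 0, 1, 1)
  expect_equal(id$values, x)
  expect_equal(id$wavelengths, wl)

  # linear ramp, slope m, unit grid: first gap-4 difference is 2 * 4 * m
  m <- 3
  r <- gap_derivative(m * (1:40), 1:40, 1, 4, 4, 1)
  expect_true(all(abs(r$values - 8 * m) < 1e-10))

  # quadratic x[i] = i^2: second gap-5 difference is 2 * (2 * 5)^2 / 2 = 200
  q <- gap_derivative((1:40)^2, 1:40, 2, 5, 5, 1)
  expect_true(all(abs(q$values - 200) < 1e-8))

  # random spectrum vs brute-force loop oracle, all three grid codes
  withr::with_seed(4, {
    x <- rnorm(60); wl <- seq(900, 900 + 2 * 59, by = 2)
    for (code in list(c(0, 0, 1, 1), c(1, 4, 4, 1), c(2, 5, 5, 1))) {
      got <- gap_derivative(x, wl, code[1], code[2], code[3], code[4])
      want <- gap_derivative_oracle(x, wl, code[1], code[2], code[3], code[4])
      expect_equal(got$values, want$values, tolerance = 1e-10)
      expect_equal(got$wavelengths, want$wavelengths)
    }
  })

  # linearity: D(a x + b y) = a D(x) + b D(y)
  withr::with_seed(5, {
    x <- rnorm(50); y <- rnorm(50); wl <- seq_len(50)
    dx <- gap_derivative(x, wl, 1, 4, 4, 1)$values
    dy <- gap_derivative(y, wl, 1, 4, 4, 1)$values
    dxy <- gap_derivative(2 * x - 3 * y, wl, 1, 4, 4, 1)$values
    expect_equal(dxy, 2 * dx - 3 * dy, tolerance = 1e-10)
  })

  expect_error(gap_derivative(rnorm(5), 1:5, 2, 5, 5, 1),
               class = "cocoanir_preprocess_error")
})

test_that("apply_treatment composes scatter then derivative with grid bookkeeping", {
  ds <- make_toy_dataset(n = 8)
  # identity cell leaves the data untouched
  same <- apply_treatment(ds, math_treatment("NONE", "0,0,1,1"))
  expect_equal(same$absorbance, ds$absorbance, ignore_attr = TRUE)

  # SNV_DT is idempotent
  t_snv <- math_treatment("SNV_DT", "0,0,1,1")
  once <- apply_treatment(ds, t_snv)
  twice <- apply_treatment(once, t_snv)
  expect_equal(twice$absorbance, once$absorbance, tolerance = 1e-8,
               ignore_attr = TRUE)

  # scatter corrections exactly undo planted affine scatter
  withr::with_seed(6, {
    a <- runif(8, 0.7, 1.3); b <- rnorm(8, 0, 0.2)
    corrupted <- ds
    corrupted$absorbance <- ds$absorbance * a + b
    for (sc in c("SNV_DT", "MSC")) {
      tr <- math_treatment(sc, "1,4,4,1")
      clean <- apply_treatment(ds, tr)
      fixed <- apply_treatment(corrupted, tr,
                               msc_reference = colMeans(ds$absorbance))
      expect_equal(fixed$absorbance, clean$absorbance, tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
  })

  # MSC freezes its reference: a scaled copy of a training spectrum maps to
  # the same processed spectrum
  tr <- math_treatment("MSC", "0,0,1,1")
  proc <- apply_treatment(ds, tr)
  ref <- attr(proc, "msc_reference")
  copy <- subset_one <- ds
  copy$absorbance <- ds$absorbance * 1.5 + 0.1
  proc2 <- apply_treatment(copy, tr, msc_reference = ref)
  expect_equal(proc2$absorbance, proc$absorbance, tolerance = 1e-8,
               ignore_attr = TRUE)

  # treatments are row-wise: permuting samples commutes
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  tr <- math_treatment("SNV_DT", "2,5,5,1")
  direct <- apply_treatment(ds, tr)$absorbance[perm, ]
  ds_p <- spectral_dataset(ds$wavelengths, ds$absorbance[perm, ],
                           ds$sample_ids[perm], preparation = "ground")
  permuted <- apply_treatment(ds_p, tr)$absorbance
  expect_equal(permuted, direct, ignore_attr = TRUE)

  # derivative codes shrink and report the retained grid
  der <- apply_treatment(ds, math_treatment("NONE", "1,4,4,1"))
  expect_lt(length(der$wavelengths), length(ds$wavelengths))
  expect_true(all(der$wavelengths %in% ds$wavelengths))
})

test_that("math treatment codes validate and render like the field writes them", {
  t <- math_treatment("SNV_DT", "1,4,4,1")
  expect_equal(format(t), "SNV_DT 1,4,4,1")
  expect_error(math_treatment("NONE", c(3, 1, 1, 1)),
               class = "cocoanir_treatment_error")
  expect_error(math_treatment("NONE", c(1, 0, 1, 1)),
               class = "cocoanir_treatment_error")
  expect_error(math_treatment("NONE", c(0, 0, 0, 1)),
               class = "cocoanir_treatment_error")
})
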