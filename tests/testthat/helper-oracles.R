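# Independent oracle implementations and small data builders. These must
# stay separate from the package's own algorithm paths: SIMPLS vs NIPALS,
# explicit loops vs vectorized code, naive stencils vs index arithmetic.

# SIMPLS (de Jong) for a single response; algorithmically distinct from the
# package's NIPALS/deflation implementation but equivalent for PLS1.
simpls_oracle <- function(X, y, k) {
  X <- as.matrix(X)
  x_mean <- colMeans(X)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - mean(y)
  p <- ncol(X)
  s <- crossprod(Xc, yc)
  R <- matrix(0, p, k); V <- matrix(0, p, k); q <- numeric(k)
  for (a in seq_len(k)) {
    r <- s
    t <- as.numeric(Xc %*% r)
    t <- t - mean(t)
    nt <- sqrt(sum(t^2))
    t <- t / nt; r <- r / nt
    pl <- as.numeric(crossprod(Xc, t))
    q[a] <- sum(yc * t)
    v <- pl
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - as.numeric(Vp %*% crossprod(Vp, pl))
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v * as.numeric(crossprod(v, s))
    R[, a] <- r; V[, a] <- v
  }
  b <- as.numeric(R %*% q)
  list(coefficients = b,
       predict = function(Xn) mean(y) + as.numeric(sweep(as.matrix(Xn), 2, x_mean) %*% b))
}

# brute-force gap-segment stencil: loops, no cumsum tricks
gap_derivative_oracle <- function(x, wl, d, g, s1, s2) {
  vals <- x
  for (rep in seq_len(d)) {
    n <- length(vals)
    out <- numeric(0); ow <- numeric(0)
    for (i in (g + 1):(n - g)) {
      out <- c(out, vals[i + g] - vals[i - g])
      ow <- c(ow, wl[i])
    }
    vals <- out; wl <- ow
  }
  smooth_once <- function(v, w, s) {
    if (s <= 1) return(list(values = v, wavelengths = w))
    n <- length(v)
    out <- numeric(0); ow <- numeric(0)
    for (i in seq_len(n)) {
      lo <- if (s %% 2 == 1) i - (s - 1) / 2 else i - s / 2
      hi <- if (s %% 2 == 1) i + (s - 1) / 2 else i + s / 2 - 1
      if (lo >= 1 && hi <= n) {
        out <- c(out, mean(v[lo:hi]))
        ow <- c(ow, w[i])
      }
    }
    list(values = out, wavelengths = ow)
  }
  sm <- smooth_once(vals, wl, s1)
  smooth_once(sm$values, sm$wavelengths, s2)
}

# small exactly-linear spectral problem: y is a noiseless linear function of
# the spectra, spectra are mixtures of two Gaussian bands
make_linear_toy <- function(n = 12, p = 40, seed = 99, noise = 0.02) {
  withr::with_seed(seed, {
    wl <- seq(1000, 1390, length.out = p)
    conc <- cbind(runif(n, 1, 3), runif(n, 0.5, 2))
    bands <- rbind(exp(-((wl - 1100)^2) / (2 * 30^2)),
                   exp(-((wl - 1300)^2) / (2 * 25^2)))
    X <- conc %*% bands + matrix(rnorm(n * p, 0, noise), n, p)
    y <- 2 * conc[, 1] - conc[, 2]
    list(X = X, y = y, wl = wl, conc = conc)
  })
}

make_toy_dataset <- function(n = 16, seed = 5) {
  spec <- synthetic_spec(n_samples = n, seed = seed)
  comp <- generate_compositions(spec)
  generate_spectra(comp, spec, "ground", nir_portable())
}
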