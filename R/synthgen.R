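#' Reference distribution of cocoa bean constituents
#'
#' Published descriptive statistics (mean, SD, range) of the nine measured
#' constituents of commercial dried fermented cocoa beans, used as the
#' default composition distribution of the synthetic generator. Units:
#' shell, fat, protein, dm, ash in percent; tpc in mg gallic acid
#' equivalents per g dry defatted powder; ta in mmol NaOH per 100 g; fi is
#' the A460/A530 ratio; ph is unitless.
#'
#' @return A tibble with `constituent`, `minimum`, `maximum`, `mean`, `sd`,
#'   `unit`.
#' @export
cocoa_constituent_stats <- function() {
  tibble::tribble(
    ~constituent, ~minimum, ~maximum, ~mean,  ~sd,   ~unit,
    "shell",      11.13,    18.34,    13.25,  1.54,  "%",
    "fat",        36.96,    48.39,    44.72,  1.94,  "%",
    "protein",     8.32,    15.43,    13.85,  1.13,  "%",
    "tpc",        32.58,    98.04,    56.42, 13.32,  "mg/g dry defatted",
    "ph",          4.84,     6.47,     5.58,  0.36,  "",
    "ta",          8.20,    26.81,    17.19,  4.22,  "mmol NaOH/100 g",
    "fi",          0.57,     2.24,     1.29,  0.49,  "A460/A530",
    "dm",         93.30,    95.76,    94.51,  0.59,  "%",
    "ash",         2.34,     3.66,     2.99,  0.30,  "%")
}

#' Near-infrared band library of the synthetic generator
#'
#' Gaussian absorption bands per spectrally active component. Centers follow
#' standard NIR band assignments for cocoa: lipid C-H overtones (1210, 1725,
#' 1744 nm) and CH2 combinations (2320 nm); water O-H (1450, 1930 nm);
#' protein N-H/amide bands (1500, 2057, 2130 nm); a weak phenolic O-H band
#' (1420 nm); carbohydrate C-H/O-H combinations (2100 nm); plus weak bands
#' carrying the indirect signals of acids (930, 1395 nm), pH (910 nm), ash
#' (2180 nm) and the pigment-related fermentation index (1480 nm). Widths
#' and per-unit intensities are generator design values tuned to give
#' realistic smooth broad-band cocoa spectra -- they are configuration, not
#' claims about true extinction coefficients.
#'
#' @return A tibble with `component`, `center_nm`, `sigma_nm`, `intensity`
#'   (absorbance units per concentration unit of the component).
#' @export
cocoa_band_library <- function() {
  tibble::tribble(
    ~component,     ~center_nm, ~sigma_nm, ~intensity,
    "fat",          1210,       30,        0.006,
    "fat",          1725,       15,        0.005,
    "fat",          1744,       15,        0.005,
    "fat",          2320,       20,        0.005,
    "water",        1450,       40,        0.030,
    "water",        1930,       40,        0.040,
    "protein",      1500,       25,        0.010,
    "protein",      2057,       20,        0.010,
    "protein",      2130,       20,        0.010,
    "polyphenol",   1420,       60,        0.00030,
    "carbohydrate", 2100,       40,        0.006,
    "acid",          930,       25,        0.0010,
    "acid",         1395,       20,        0.0015,
    "ph",            910,       20,        0.015,
    "ash",          2180,       25,        0.012,
    "fi",           1480,       30,        0.010)
}

default_correlations <- function() {
  # fat dilutes the non-fat solids where polyphenols sit; FI rises as
  # anthocyanin-related phenolics fall; pH and titratable acidity oppose
  list(c("fat", "tpc", -0.3),
       c("fi", "tpc", -0.4),
       c("ph", "ta", -0.7))
}

#' Synthetic cocoa study specification
#'
#' Bundles everything the generator needs: sample count, composition
#' distributions (defaults: the published constituent table), constituent
#' correlations, the band library, noise level, and whole-bean degradation
#' parameters (per-sample multiplicative/additive scatter, wavelength slope,
#' and an uncorrelated broadband shell-interference component).
#'
#' @param n_samples Number of samples (default 56, the study size emulated).
#' @param seed Integer seed; all draws derive from it.
#' @param noise_sd Absorbance noise SD in ground mode (default 0.002 AU).
#' @param whole_noise_sd Absorbance noise SD in whole-bean mode.
#' @param scatter List with `multiplicative_sd`, `additive_sd`, `slope_sd`
#'   (whole mode only).
#' @param shell_interference Amplitude SD of the broadband interference
#'   component (whole mode only).
#' @param composition_stats Tibble as [cocoa_constituent_stats()].
#' @param correlations List of `c(name_a, name_b, rho)` triples.
#' @param bands Band library tibble as [cocoa_band_library()].
#' @return A `synthetic_spec` configuration object.
#' @export
synthetic_spec <- function(n_samples = 56, seed = 1, noise_sd = 0.002,
                           whole_noise_sd = 0.004,
                           scatter = list(multiplicative_sd = 0.15,
                                          additive_sd = 0.05,
                                          slope_sd = 5e-5),
                           shell_interference = 0.05,
                           composition_stats = cocoa_constituent_stats(),
                           correlations = default_correlations(),
                           bands = cocoa_band_library()) {
  stopifnot(n_samples >= 2, noise_sd >= 0, shell_interference >= 0)
  structure(
    list(n_samples = n_samples, seed = as.integer(seed),
         noise_sd = noise_sd, whole_noise_sd = whole_noise_sd,
         scatter = scatter, shell_interference = shell_interference,
         composition_stats = composition_stats,
         correlations = correlations, bands = bands),
    class = "synthetic_spec")
}

# derived sub-seed so each stochastic block has its own stream and adding a
# constituent or mode does not perturb the others; kept below 2^31
derive_seed <- function(seed, block) {
  (as.numeric(seed) * 7919 + block * 104729) %% 2147483647
}

correlation_matrix <- function(stats, correlations) {
  k <- nrow(stats)
  R <- diag(k)
  rownames(R) <- colnames(R) <- stats$constituent
  for (tr in correlations) {
    a <- tr[1]; b <- tr[2]; rho <- as.numeric(tr[3])
    if (a %in% rownames(R) && b %in% rownames(R)) {
      R[a, b] <- R[b, a] <- rho
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop_cocoa("Constituent correlation matrix is not positive semi-definite.",
               "cocoanir_validation_error")
  }
  R
}

#' Draw a synthetic constituent table
#'
#' Samples from a correlated normal with the configured means/SDs, truncated
#' to the configured `[min, max]` ranges (out-of-range draws are clipped to
#' the bound). Each constituent's underlying standard-normal stream has its
#' own derived seed, so adding a constituent leaves the others' draws
#' unchanged.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with `sample_id` plus one column per constituent.
#' @export
generate_compositions <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  stats <- spec$composition_stats
  k <- nrow(stats); n <- spec$n_samples
  Z <- matrix(0, n, k)
  for (j in seq_len(k)) {
    Z[, j] <- withr::with_seed(derive_seed(spec$seed, j), rnorm(n))
  }
  R <- correlation_matrix(stats, spec$correlations)
  L <- chol(R + diag(1e-10, k))
  X <- Z %*% L
  out <- tibble(sample_id = sprintf("S%02d", seq_len(n)))
  for (j in seq_len(k)) {
    v <- stats$mean[j] + stats$sd[j] * X[, j]
    out[[stats$constituent[j]]] <- pmin(pmax(v, stats$minimum[j]),
                                        stats$maximum[j])
  }
  out
}

component_concentrations <- function(comp) {
  water <- 100 - comp$dm
  tibble(fat = comp$fat, water = water, protein = comp$protein,
         polyphenol = comp$tpc,
         carbohydrate = pmax(100 - comp$fat - comp$protein - water -
                               comp$ash, 0),
         acid = comp$ta, ph = comp$ph, ash = comp$ash, fi = comp$fi)
}

band_matrix <- function(bands, wl) {
  comps <- unique(bands$component)
  B <- matrix(0, length(comps), length(wl),
              dimnames = list(comps, NULL))
  for (i in seq_len(nrow(bands))) {
    B[bands$component[i], ] <- B[bands$component[i], ] +
      bands$intensity[i] *
      exp(-((wl - bands$center_nm[i])^2) / (2 * bands$sigma_nm[i]^2))
  }
  B
}

#' Generate synthetic NIR spectra for a composition table
#'
#' Spectra are Beer--Lambert linear mixtures of the component band spectra
#' plus a fixed smooth baseline and i.i.d. absorbance noise. In
#' `mode = "whole"` each sample additionally receives multiplicative and
#' additive scatter, a wavelength slope, a smooth uncorrelated broadband
#' shell-interference component, and larger noise -- emulating intact beans
#' whose shell scatters the incident light. `mode = "ground"` is the clean
#' de-husked powder condition.
#'
#' @param compositions Tibble from [generate_compositions()].
#' @param spec A [synthetic_spec()].
#' @param mode `"ground"` or `"whole"`.
#' @param instrument An [instrument_profile()].
#' @return A [spectral_dataset()] with the composition table attached as
#'   references; the noiseless signal matrix is stored in attribute
#'   `"ground_truth"`.
#' @export
generate_spectra <- function(compositions, spec,
                             mode = c("ground", "whole"),
                             instrument = nir_benchtop()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mode <- match.arg(mode)
  wl <- wavelength_grid(instrument)
  conc <- component_concentrations(compositions)
  B <- band_matrix(spec$bands, wl)
  conc_m <- as.matrix(conc[, rownames(B), drop = FALSE])
  # fixed gentle baseline typical of diffuse-reflectance log(1/R) spectra
  baseline <- 0.35 + 2e-4 * (wl - min(wl))
  signal <- conc_m %*% B
  signal <- sweep(signal, 2, baseline, "+")
  n <- nrow(signal)

  mode_block <- if (mode == "ground") 100 else 200
  if (mode == "whole") {
    sc <- spec$scatter
    a <- withr::with_seed(derive_seed(spec$seed, mode_block + 1),
                          rnorm(n, 0, sc$multiplicative_sd))
    b <- withr::with_seed(derive_seed(spec$seed, mode_block + 2),
                          rnorm(n, 0, sc$additive_sd))
    slope <- withr::with_seed(derive_seed(spec$seed, mode_block + 3),
                              rnorm(n, 0, sc$slope_sd))
    # broadband interference: smooth random curves uncorrelated with the
    # composition, spanning the full range
    centers <- seq(min(wl), max(wl), length.out = 4)
    shapes <- vapply(centers, function(cc)
      exp(-((wl - cc)^2) / (2 * 150^2)), numeric(length(wl)))
    U <- matrix(withr::with_seed(derive_seed(spec$seed, mode_block + 4),
                                 rnorm(n * 4, 0, spec$shell_interference)),
                n, 4)
    interference <- U %*% t(shapes)
    out <- signal * (1 + a) + outer(b, rep(1, length(wl))) +
      outer(slope, wl - mean(wl)) + interference
    noise_sd <- spec$whole_noise_sd
  } else {
    out <- signal
    noise_sd <- spec$noise_sd
  }
  if (noise_sd > 0) {
    noise <- matrix(withr::with_seed(derive_seed(spec$seed, mode_block + 5),
                                     rnorm(n * length(wl), 0, noise_sd)),
                    n, length(wl))
    out <- out + noise
  }
  ds <- spectral_dataset(wl, out, compositions$sample_id,
                         references = compositions,
                         instrument = instrument, preparation =
                           if (mode == "ground") "ground" else "whole")
  attr(ds, "ground_truth") <- signal
  ds
}

#' Build the bundled synthetic study fixture
#'
#' A deterministic n = 56 study: one composition table and spectra for both
#' instrument profiles in both preparation modes, reproducible byte-for-byte
#' from the seed.
#'
#' @param seed Integer seed (default 20221220).
#' @param n_samples Sample count (default 56).
#' @return A list with `compositions`, `benchtop_ground`, `benchtop_whole`,
#'   `portable_ground`, `portable_whole`, and the `spec` used.
#' @export
make_fixture <- function(seed = 20221220, n_samples = 56) {
  spec <- synthetic_spec(n_samples = n_samples, seed = seed)
  comp <- generate_compositions(spec)
  list(
    compositions = comp,
    benchtop_ground = generate_spectra(comp, spec, "ground", nir_benchtop()),
    benchtop_whole = generate_spectra(comp, spec, "whole", nir_benchtop()),
    portable_ground = generate_spectra(comp, spec, "ground", nir_portable()),
    portable_whole = generate_spectra(comp, spec, "whole", nir_portable()),
    spec = spec)
}
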