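#' Fermentation index from anthocyanin absorbances
#'
#' FI is the absorbance ratio A460/A530 of an acidified-methanol cocoa
#' extract; the anthocyanins lost during fermentation absorb at 530 nm, so
#' the ratio rises as fermentation progresses. An FI strictly greater than 1
#' classifies the beans as well-fermented (valid for Forastero and, with
#' caution, Trinitario material).
#'
#' @param a460,a530 Absorbances at 460 and 530 nm (vectorized; `a530 > 0`).
#' @return A tibble with `fi` and `fermentation` class.
#' @examples
#' fermentation_index(1.2, 0.6)  # FI 2, well-fermented
#' @export
fermentation_index <- function(a460, a530) {
  if (any(a460 < 0) || any(a530 <= 0)) {
    stop_cocoa("Absorbances must be >= 0 and A530 > 0.",
               "cocoanir_assay_error")
  }
  fi <- a460 / a530
  tibble(fi = fi,
         fermentation = ifelse(fi > 1, "well-fermented", "under-fermented"))
}

#' Kjeldahl protein from total nitrogen
#'
#' @param nitrogen_pct Total nitrogen, percent w/w (>= 0, vectorized).
#' @param factor Nitrogen-to-protein conversion factor (6.25 for cocoa).
#' @return Protein, percent w/w.
#' @export
protein_from_nitrogen <- function(nitrogen_pct, factor = 6.25) {
  if (any(nitrogen_pct < 0)) {
    stop_cocoa("Nitrogen content cannot be negative.", "cocoanir_assay_error")
  }
  factor * nitrogen_pct
}

#' Gallic acid standard curve for the Folin-Ciocalteu assay
#'
#' Ordinary least squares of absorbance at 765 nm on standard concentration
#' (the assay standards are 0, 50, 100, 150, 200 and 250 mg/L gallic acid).
#'
#' @param standards Data frame with columns `conc_mg_l` and `absorbance`
#'   (>= 2 distinct standards).
#' @return A `gallic_line` with `slope` (absorbance per mg/L), `intercept`
#'   and `r2`.
#' @export
fit_gallic_line <- function(standards) {
  standards <- as_tibble(standards)
  if (nrow(standards) < 2 || sd(standards$conc_mg_l) < .var_tol) {
    stop_cocoa("Need at least 2 distinct standards.", "cocoanir_assay_error")
  }
  fit <- lm(absorbance ~ conc_mg_l, data = standards)
  sst <- sum((standards$absorbance - mean(standards$absorbance))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else NA_real_
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), r2 = r2,
                 standards = standards),
            class = "gallic_line")
}

#' @export
print.gallic_line <- function(x, ...) {
  cat(sprintf(
    "<gallic_line> A765 = %.5g + %.5g * C(mg/L), r2 = %.4f (%d standards)\n",
    x$intercept, x$slope, x$r2, nrow(x$standards)))
  invisible(x)
}

#' @method tidy gallic_line
#' @export
tidy.gallic_line <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' Total phenolic content from Folin-Ciocalteu absorbance
#'
#' Converts the 765 nm absorbance of the assay mixture to gallic acid
#' equivalents per gram of dry defatted powder. The default dilution
#' geometry matches the assay as run: 0.05 g defatted powder extracted in
#' 10 mL methanol-water, 0.1 mL extract in a 4.6 mL assay mixture (3 mL
#' water + 0.5 mL reagent + 1 mL sodium carbonate), so
#' `TPC = C * (4.6 / 0.1) * 0.010 / 0.05` with C in mg/L from the standard
#' curve.
#'
#' @param a765 Assay absorbance at 765 nm (vectorized).
#' @param line A [fit_gallic_line()] calibration.
#' @param extract_volume_ml Extraction volume, mL.
#' @param aliquot_ml Extract aliquot pipetted into the assay, mL.
#' @param assay_volume_ml Total assay mixture volume, mL.
#' @param mass_g Defatted powder mass extracted, g.
#' @return TPC in mg gallic acid equivalents per g dry defatted mass.
#' @export
tpc_from_absorbance <- function(a765, line, extract_volume_ml = 10,
                                aliquot_ml = 0.1, assay_volume_ml = 4.6,
                                mass_g = 0.05) {
  stopifnot(inherits(line, "gallic_line"))
  if (any(mass_g <= 0) || any(aliquot_ml <= 0)) {
    stop_cocoa("Masses and volumes must be positive.", "cocoanir_assay_error")
  }
  conc <- (a765 - line$intercept) / line$slope
  if (any(conc < -.var_tol)) {
    stop_cocoa("Absorbance below the calibration intercept gives a negative concentration.",
               "cocoanir_assay_error")
  }
  conc <- pmax(conc, 0)
  dilution <- assay_volume_ml / aliquot_ml
  conc * dilution * (extract_volume_ml / 1000) / mass_g
}

#' Titratable acidity from an NaOH titration
#'
#' `TA = M * V * (extract / aliquot) * (100 / powder)` in mmol NaOH per
#' 100 g powder; at the assay defaults (0.05 M NaOH, 25 mL aliquot of a
#' 100 mL extract of 5 g powder, titrated to pH 8.1) this reduces to
#' `TA = 4 * V`. The equivalent percent acetic acid (60.05 g/mol, 1:1
#' stoichiometry) is reported alongside.
#'
#' @param v_naoh_ml Titrant volume, mL (vectorized).
#' @param molarity NaOH molarity, mol/L.
#' @param aliquot_ml Titrated aliquot, mL.
#' @param extract_ml Total extract volume, mL.
#' @param powder_g Powder mass extracted, g.
#' @return A tibble with `ta_mmol_100g` and `acetic_acid_pct`.
#' @examples
#' titratable_acidity(4.30)  # 17.2 mmol NaOH / 100 g
#' @export
titratable_acidity <- function(v_naoh_ml, molarity = 0.05, aliquot_ml = 25,
                               extract_ml = 100, powder_g = 5) {
  if (any(c(molarity, aliquot_ml, extract_ml, powder_g) <= 0) ||
      any(v_naoh_ml < 0)) {
    stop_cocoa("Titration quantities must be positive.",
               "cocoanir_assay_error")
  }
  ta <- molarity * v_naoh_ml * (extract_ml / aliquot_ml) * (100 / powder_g)
  tibble(ta_mmol_100g = ta, acetic_acid_pct = ta * 60.05 / 1000)
}

#' Dry matter and moisture from oven drying
#'
#' Moisture is the gravimetric loss on drying as a percentage of the wet
#' mass; dry matter is its complement (`DM + moisture = 100` exactly).
#'
#' @param wet_g,dry_g Sample mass before and after drying, g
#'   (`0 < dry_g <= wet_g`, vectorized).
#' @return A tibble with `dm_pct` and `moisture_pct`.
#' @export
dry_matter <- function(wet_g, dry_g) {
  if (any(wet_g <= 0) || any(dry_g <= 0)) {
    stop_cocoa("Masses must be positive.", "cocoanir_assay_error")
  }
  if (any(dry_g > wet_g)) {
    stop_cocoa("Dry mass cannot exceed wet mass.", "cocoanir_assay_error")
  }
  moisture <- 100 * (wet_g - dry_g) / wet_g
  tibble(dm_pct = 100 - moisture, moisture_pct = moisture)
}

#' Shell percentage from de-husking weights
#'
#' @param peel_g,nib_g Peel (shell) and nib masses from a de-husked aliquot,
#'   g (both >= 0, sum > 0; vectorized).
#' @return Shell fraction, percent of whole-bean mass.
#' @examples
#' shell_fraction(2.65, 17.35)  # 13.25 %
#' @export
shell_fraction <- function(peel_g, nib_g) {
  if (any(peel_g < 0) || any(nib_g < 0) || any(peel_g + nib_g <= 0)) {
    stop_cocoa("Need non-negative masses with a positive total.",
               "cocoanir_assay_error")
  }
  100 * peel_g / (peel_g + nib_g)
}

#' Descriptive statistics table
#'
#' Minimum, maximum, mean, SD (denominator n - 1) and coefficient of
#' variation `CV = 100 * SD / mean` for each numeric column -- the shape of
#' a constituent summary table.
#'
#' @param data A data frame; non-numeric columns (e.g. `sample_id`) are
#'   ignored.
#' @return A tibble with one row per constituent.
#' @export
descriptive_stats <- function(data) {
  data <- as_tibble(data)
  num <- data[vapply(data, is.numeric, logical(1))]
  if (ncol(num) == 0) {
    stop_cocoa("No numeric columns to summarize.", "cocoanir_assay_error")
  }
  purrr::map_dfr(names(num), function(nm) {
    v <- num[[nm]][!is.na(num[[nm]])]
    if (length(v) < 2) {
      stop_cocoa(sprintf("Need n >= 2 for '%s'.", nm), "cocoanir_assay_error")
    }
    m <- mean(v); s <- sd(v)
    if (abs(m) < .var_tol && s > 0) {
      stop_cocoa(sprintf("CV undefined for '%s' (zero mean).", nm),
                 "cocoanir_assay_error")
    }
    tibble(constituent = nm, minimum = min(v), maximum = max(v),
           mean = m, sd = s,
           cv_pct = if (s == 0) 0 else 100 * s / m)
  })
}
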