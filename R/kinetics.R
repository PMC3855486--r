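# Enzyme kinetics for the NMN deamidase assays: Michaelis-Menten and Hill
# rate laws, nonlinear least-squares fitting, conversion of the coupled
# glutamate-dehydrogenase (GDH) absorbance signal to activity units, and
# ligand-efficiency arithmetic.

# NADPH molar extinction coefficient at 360 nm used by the coupled assay.
EPSILON_NADPH_360 <- 4320   # M^-1 cm^-1

# Subunit molecular weight of the O. iheyensis enzyme by mass spectrometry,
# used to derive kcat when the enzyme amount is given as a mass.
OIPNCC_MW_KDA <- 47.32

#' Michaelis-Menten rate law
#'
#' `v = kcat * E0 * S / (Km + S)`. With `E0 = 1`, `kcat` plays the role of
#' `Vmax`.
#'
#' @param S Substrate concentration(s), same units as `Km`.
#' @param Km Michaelis constant.
#' @param kcat Turnover number.
#' @param E0 Enzyme concentration (default 1, i.e. rates per enzyme).
#' @return Rate(s).
#' @export
mm_rate <- function(S, Km, kcat, E0 = 1) {
  stopifnot(all(S >= 0), Km > 0, kcat > 0, E0 > 0)
  kcat * E0 * S / (Km + S)
}

#' Hill rate law
#'
#' `v = Vmax * S^nH / (S50^nH + S^nH)`; at `nH = 1` this is the
#' Michaelis-Menten form, `nH > 1` gives the sigmoidal profile of
#' cooperative enzymes.
#'
#' @param S Substrate concentration(s).
#' @param S50 Half-saturation concentration (S_0.5).
#' @param nH Hill coefficient (> 0).
#' @param Vmax Limiting rate.
#' @return Rate(s).
#' @export
hill_rate <- function(S, S50, nH, Vmax) {
  stopifnot(all(S >= 0), S50 > 0, nH > 0, Vmax > 0)
  Vmax * S^nH / (S50^nH + S^nH)
}

#' Convert a coupled-assay absorbance slope to a reaction rate
#'
#' In the coupled GDH assay the ammonia released by the deamidase drives
#' NADPH oxidation, observed as an absorbance decline at 360 nm. The molar
#' rate is `dA/dt / (epsilon * l)`; scaled by the assay volume it gives
#' µmol/min, and one enzyme unit is 1 µmol NADPH consumed per minute.
#'
#' @param dA360_per_min Absolute absorbance change per minute.
#' @param epsilon Molar extinction coefficient (default 4320 M^-1 cm^-1 for
#'   NADPH at 360 nm).
#' @param path_cm Optical path length in cm.
#' @param volume_L Assay volume in liters.
#' @param enzyme_mg Optional enzyme mass, to also report U/mg.
#' @return List with `umol_per_min` (= units) and, when `enzyme_mg` is
#'   given, `units_per_mg`.
#' @export
absorbance_to_rate <- function(dA360_per_min, epsilon = EPSILON_NADPH_360,
                               path_cm = 1, volume_L, enzyme_mg = NULL) {
  if (epsilon <= 0) stop("extinction coefficient must be positive")
  stopifnot(path_cm > 0, volume_L > 0)
  umol <- abs(dA360_per_min) / (epsilon * path_cm) * volume_L * 1e6
  out <- list(umol_per_min = umol)
  if (!is.null(enzyme_mg)) out$units_per_mg <- umol / enzyme_mg
  out
}

validate_rate_table <- function(rates) {
  stopifnot(is.data.frame(rates), all(c("conc", "rate") %in% names(rates)),
            all(rates$conc >= 0))
  if (length(unique(rates$conc)) < 4) {
    stop("rate table needs at least 4 distinct substrate concentrations")
  }
  rates
}

#' Fit the Michaelis-Menten model to an initial-rate table
#'
#' Nonlinear least squares on `v = Vmax * S / (Km + S)`, initialized from
#' the double-reciprocal (Lineweaver-Burk) linearization. When the enzyme
#' concentration is supplied the turnover number `kcat = Vmax / E0` and the
#' specificity constant `kcat/Km` are derived; an enzyme mass plus molecular
#' weight may be given instead of a molar concentration.
#'
#' @param rates `data.frame` with `conc`, `rate` (and optionally
#'   `replicate`); at least 4 distinct concentrations.
#' @param E0 Enzyme concentration, in the units that make `Vmax / E0` a
#'   rate per enzyme (e.g. both per-second).
#' @param enzyme_mg,volume_L,mw_kda Alternative enzyme specification as mass
#'   in the assay volume; `E0` is derived as `mg / (MW * V)` µM with the
#'   default MW 47.32 kDa.
#' @return An `mm_fit`: `Km`, `Vmax` (with standard errors), `kcat`,
#'   `kcat_over_Km` (when `E0` known) and the underlying `nls` fit.
#' @export
fit_mm <- function(rates, E0 = NULL, enzyme_mg = NULL, volume_L = NULL,
                   mw_kda = OIPNCC_MW_KDA) {
  rates <- validate_rate_table(rates)
  if (is.null(E0) && !is.null(enzyme_mg) && !is.null(volume_L)) {
    E0 <- enzyme_mg * 1e-3 / (mw_kda * 1e3) / volume_L * 1e6   # µM
  }
  pos <- rates$rate > 0 & rates$conc > 0
  lb <- stats::lm(I(1 / rate) ~ I(1 / conc), data = rates[pos, ])
  Vmax0 <- unname(1 / stats::coef(lb)[1])
  Km0 <- unname(stats::coef(lb)[2] * Vmax0)
  if (!is.finite(Vmax0) || Vmax0 <= 0) Vmax0 <- max(rates$rate)
  if (!is.finite(Km0) || Km0 <= 0) Km0 <- stats::median(rates$conc)
  fit <- tryCatch(
    minpack.lm::nlsLM(rate ~ Vmax * conc / (Km + conc), data = rates,
                      start = list(Vmax = Vmax0, Km = Km0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Michaelis-Menten fit did not converge (start Vmax=",
                             signif(Vmax0, 4), ", Km=", signif(Km0, 4), "): ",
                             conditionMessage(e)))
  est <- summary(fit)$coefficients
  out <- list(Km = est["Km", "Estimate"], Km_se = est["Km", "Std. Error"],
              Vmax = est["Vmax", "Estimate"],
              Vmax_se = est["Vmax", "Std. Error"],
              E0 = E0, fit = fit)
  if (!is.null(E0)) {
    out$kcat <- out$Vmax / E0
    out$kcat_se <- out$Vmax_se / E0
    out$kcat_over_Km <- out$kcat / out$Km
  }
  structure(out, class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> Km = %.4g +/- %.2g, Vmax = %.4g +/- %.2g",
              x$Km, x$Km_se, x$Vmax, x$Vmax_se))
  if (!is.null(x$kcat)) {
    cat(sprintf(", kcat = %.4g +/- %.2g, kcat/Km = %.3g",
                x$kcat, x$kcat_se, x$kcat_over_Km))
  }
  cat("\n")
  invisible(x)
}

#' Fit the Hill model to an initial-rate table
#'
#' Nonlinear least squares on `v = Vmax * S^nH / (S50^nH + S^nH)`,
#' initialized from the Hill-plot linearization
#' `log(v / (Vmax - v)) ~ nH * log(S) - nH * log(S50)`.
#'
#' @inheritParams fit_mm
#' @return A `hill_fit`: `S50`, `nH`, `Vmax` with standard errors, the
#'   underlying `nls` fit, and `kcat` when `E0` is given.
#' @export
fit_hill <- function(rates, E0 = NULL) {
  rates <- validate_rate_table(rates)
  Vmax0 <- max(rates$rate) * 1.05
  ok <- rates$rate > 0 & rates$rate < Vmax0 & rates$conc > 0
  hp <- stats::lm(log(rate / (Vmax0 - rate)) ~ log(conc), data = rates[ok, ])
  nH0 <- unname(stats::coef(hp)[2])
  S500 <- unname(exp(-stats::coef(hp)[1] / nH0))
  if (!is.finite(nH0) || nH0 <= 0) nH0 <- 1
  if (!is.finite(S500) || S500 <= 0) S500 <- stats::median(rates$conc)
  fit <- tryCatch(
    minpack.lm::nlsLM(rate ~ Vmax * conc^nH / (S50^nH + conc^nH),
                      data = rates,
                      start = list(Vmax = Vmax0, S50 = S500, nH = nH0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Hill fit did not converge (start Vmax=",
                             signif(Vmax0, 4), ", S50=", signif(S500, 4),
                             ", nH=", signif(nH0, 3), "): ",
                             conditionMessage(e)))
  est <- summary(fit)$coefficients
  out <- list(S50 = est["S50", "Estimate"], S50_se = est["S50", "Std. Error"],
              nH = est["nH", "Estimate"], nH_se = est["nH", "Std. Error"],
              Vmax = est["Vmax", "Estimate"],
              Vmax_se = est["Vmax", "Std. Error"],
              E0 = E0, fit = fit)
  if (!is.null(E0)) out$kcat <- out$Vmax / E0
  structure(out, class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> S50 = %.4g +/- %.2g, nH = %.3g +/- %.2g, Vmax = %.4g +/- %.2g\n",
              x$S50, x$S50_se, x$nH, x$nH_se, x$Vmax, x$Vmax_se))
  invisible(x)
}

#' Heavy-atom count of a molecular formula
#'
#' Counts all non-hydrogen atoms in a Hill-style molecular formula string.
#'
#' @param formula E.g. `"C11H15N2O8P"` (NMN).
#' @return Integer heavy-atom count.
#' @examples
#' heavy_atom_count("C11H15N2O8P")       # 22
#' heavy_atom_count("C15H23N5O14P2")     # 36
#' @export
heavy_atom_count <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  total <- 0L
  for (t in toks) {
    el <- gsub("[0-9]", "", t)
    cnt <- gsub("[^0-9]", "", t)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (el != "H") total <- total + cnt
  }
  total
}

#' Ligand constants for the docking arithmetic
#'
#' Molecular formulas and heavy-atom counts for the ligands whose docking
#' scores feed the ligand-efficiency calculation.
#'
#' @return `data.frame` with `ligand`, `formula`, `heavy_atoms`.
#' @export
ligand_constants <- function() {
  data.frame(
    ligand = c("NMN", "ADP-ribose"),
    formula = c("C11H15N2O8P", "C15H23N5O14P2"),
    heavy_atoms = c(heavy_atom_count("C11H15N2O8P"),
                    heavy_atom_count("C15H23N5O14P2")),
    stringsAsFactors = FALSE)
}

#' Ligand efficiency (LE1)
#'
#' Docking score divided by the ligand's heavy (non-hydrogen) atom count,
#' reported to 3 decimals (round half to even).
#'
#' @param score Docking score (kcal/mol).
#' @param heavy_atoms Heavy-atom count (>= 1).
#' @return LE1, rounded to 3 decimals.
#' @examples
#' ligand_efficiency(-122.053, 22)   # -5.548
#' @export
ligand_efficiency <- function(score, heavy_atoms) {
  if (any(heavy_atoms < 1)) stop("heavy-atom count must be at least 1")
  round(score / heavy_atoms, 3)
}
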