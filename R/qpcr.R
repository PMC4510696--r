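#' Construct a qPCR measurement
#'
#' Bundles technical-replicate Ct values for a target miRNA and the U6
#' snRNA reference in one condition. Replicates are averaged before any
#' delta computation; any Ct above `max_ct` (QC bound 30) rejects the
#' measurement.
#'
#' @param target_ct numeric vector of target Ct replicates.
#' @param reference_ct numeric vector of reference (U6) Ct replicates.
#' @param label condition label.
#' @param max_ct QC upper bound on every Ct (default 30).
#' @return an `exo_qpcr` list with averaged `target_ct`, `reference_ct`.
#' @export
qpcr_measurement <- function(target_ct, reference_ct, label = "",
                             max_ct = 30) {
  if (!length(target_ct) || !length(reference_ct)) {
    abort("replicate Ct lists must be non-empty")
  }
  cts <- c(target_ct, reference_ct)
  if (any(!is.finite(cts)) || any(cts <= 0)) {
    abort("Ct values must be positive and finite")
  }
  if (any(cts > max_ct)) {
    abort(sprintf("measurement rejected: Ct > %g fails QC", max_ct))
  }
  structure(list(target_ct = mean(target_ct),
                 reference_ct = mean(reference_ct),
                 label = label), class = "exo_qpcr")
}

#' Delta-delta-Ct fold change
#'
#' `dCt = Ct_target - Ct_reference` within each condition,
#' `ddCt = dCt_treated - dCt_control`, and `FC = 2^-ddCt`. A fold change
#' above 1 means the target is more abundant in the treated condition
#' (e.g. exosomes when contrasting exosome vs cell).
#'
#' @param treated,control `exo_qpcr` measurements (see
#'   [qpcr_measurement()]).
#' @return tibble: `delta_treated`, `delta_control`, `ddct`,
#'   `fold_change`.
#' @export
ddct_fold_change <- function(treated, control) {
  stopifnot(inherits(treated, "exo_qpcr"), inherits(control, "exo_qpcr"))
  d_t <- treated$target_ct - treated$reference_ct
  d_c <- control$target_ct - control$reference_ct
  ddct <- d_t - d_c
  tibble(delta_treated = d_t, delta_control = d_c, ddct = ddct,
         fold_change = 2^(-ddct))
}

#' Fit a qPCR standard curve from a dilution series
#'
#' Ordinary least squares of mean Ct on log10(copies/ul) over a synthetic
#' oligonucleotide dilution series (the assay uses nine twofold dilutions
#' from 50 pM). Reports slope (Ct per log10 copies), intercept, r-squared
#' and the amplification efficiency `10^(-1/slope) - 1` (1 = perfect
#' doubling per cycle).
#'
#' @param dilutions tibble with `copies_per_ul` and `ct` (replicate rows
#'   allowed; Cts are averaged per concentration first).
#' @return an `exo_std_curve`; [tidy()] gives the coefficient table,
#'   [glance()] the fit summary.
#' @export
fit_standard_curve <- function(dilutions) {
  stopifnot(all(c("copies_per_ul", "ct") %in% names(dilutions)))
  if (any(dilutions$copies_per_ul <= 0)) {
    abort("concentrations must be > 0")
  }
  tab <- dilutions |>
    dplyr::group_by(copies_per_ul) |>
    dplyr::summarise(mean_ct = mean(ct), .groups = "drop") |>
    dplyr::mutate(log10_copies = log10(copies_per_ul))
  if (nrow(tab) < 3) abort("need at least 3 distinct concentrations")
  if (length(unique(tab$log10_copies)) < 2) {
    abort("identical concentrations: design matrix is rank deficient")
  }
  fit <- lm(mean_ct ~ log10_copies, data = tab)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((tab$mean_ct - mean(tab$mean_ct))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  eff <- if (abs(slope) < sqrt(.Machine$double.eps)) NA_real_
         else 10^(-1 / slope) - 1
  if (is.na(eff)) warn("flat dilution series: efficiency undefined")
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency = eff, dilution_table = tab, fit = fit),
            class = "exo_std_curve")
}

#' @export
print.exo_std_curve <- function(x, ...) {
  cat(sprintf(
    "<exo_std_curve> Ct = %.4f * log10(copies/ul) + %.4f; r^2 = %.4f; efficiency = %s\n",
    x$slope, x$intercept, x$r_squared,
    ifelse(is.na(x$efficiency), "undefined", sprintf("%.1f%%", 100 * x$efficiency))))
  invisible(x)
}

#' @export
tidy.exo_std_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.exo_std_curve <- function(x, ...) {
  tibble(r_squared = x$r_squared, efficiency = x$efficiency,
         n_dilutions = nrow(x$dilution_table))
}

#' Predict Ct from a standard curve
#'
#' @param curve an `exo_std_curve`.
#' @param copies_per_ul copies per microliter.
#' @return predicted mean Ct.
#' @export
predict_ct <- function(curve, copies_per_ul) {
  curve$intercept + curve$slope * log10(copies_per_ul)
}

#' Absolute copy number from a Ct value
#'
#' Inverts the standard curve: `copies/ul = 10^((Ct - intercept) /
#' slope)`. Ct values outside the fitted dilution range trigger an
#' extrapolation warning.
#'
#' @param ct mean Ct value(s).
#' @param curve an `exo_std_curve`.
#' @return copies per microliter.
#' @export
absolute_copies <- function(ct, curve) {
  if (abs(curve$slope) < sqrt(.Machine$double.eps)) {
    abort("standard curve slope is zero; cannot invert")
  }
  rng <- range(curve$dilution_table$mean_ct)
  if (any(ct < rng[1] - 1e-9 | ct > rng[2] + 1e-9)) {
    warn("Ct outside the fitted dilution range: extrapolating")
  }
  10^((ct - curve$intercept) / curve$slope)
}

#' Percent increase of absolute copies over a baseline
#'
#' `((CP_condition - CP_baseline) / CP_baseline) * 100`, the conventional
#' relative change in absolute copy number. SEMs, when given, are
#' propagated by the first-order delta method.
#'
#' @param cp_condition,cp_baseline absolute copy numbers.
#' @param sem_condition,sem_baseline optional SEMs.
#' @return percent increase, or a tibble with `percent_increase` and
#'   `sem` when SEMs are supplied.
#' @export
percent_increase <- function(cp_condition, cp_baseline,
                             sem_condition = NULL, sem_baseline = NULL) {
  if (any(cp_baseline <= 0)) abort("baseline copy number must be > 0")
  pct <- (cp_condition - cp_baseline) / cp_baseline * 100
  if (is.null(sem_condition) && is.null(sem_baseline)) return(pct)
  sem_condition <- sem_condition %||0% 0
  sem_baseline <- sem_baseline %||0% 0
  sem <- 100 * sqrt((sem_condition / cp_baseline)^2 +
                      (cp_condition * sem_baseline / cp_baseline^2)^2)
  tibble(percent_increase = pct, sem = sem)
}

`%||0%` <- function(x, y) if (is.null(x)) y else x

#' Reporter normalization (Luc / beta-Gal)
#'
#' Luciferase signal normalized to co-transfected beta-galactosidase,
#' expressed relative to the scrambled-control reporter ratio; the fold
#' repression is its reciprocal. Vectors of technical replicates yield
#' the mean and its delta-method SEM.
#'
#' @param luc luciferase signal(s), > 0.
#' @param bgal beta-galactosidase signal(s), > 0.
#' @param control_ratio normalized Luc/beta-Gal of the control reporter,
#'   > 0.
#' @return tibble: `relative_expression`, `fold_repression`, and `sem`
#'   when replicates are given.
#' @export
reporter_normalize <- function(luc, bgal, control_ratio) {
  if (any(luc <= 0) || any(bgal <= 0)) abort("signals must be > 0")
  if (control_ratio <= 0) abort("control ratio must be > 0")
  rel <- (luc / bgal) / control_ratio
  if (length(rel) == 1) {
    return(tibble(relative_expression = rel, fold_repression = 1 / rel))
  }
  m <- mean(rel)
  sem <- sd(rel) / sqrt(length(rel))
  tibble(relative_expression = m, fold_repression = 1 / m,
         sem = sem, fold_repression_sem = sem / m^2)
}

#' Convert a molar concentration to copies per microliter
#'
#' Avogadro-based arithmetic for building synthetic dilution series:
#' `copies/ul = pM * 1e-12 mol/L * N_A / 1e6`.
#'
#' @param pm concentration in picomolar.
#' @return copies per microliter.
#' @export
pm_to_copies_per_ul <- function(pm) {
  pm * 1e-12 * 6.02214076e23 / 1e6
}
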