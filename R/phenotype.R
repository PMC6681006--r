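# Selection-phenotype arithmetic: drug intake in mg/kg, two-bottle preference
# ratio, realized heritability from the selection response, and relative qPCR
# expression (delta-delta-Ct).

#' Drug intake in mg per kg body weight
#'
#' concentration (mg/L) x volume consumed (mL, converted to L) / body weight
#' (kg). Linear in concentration and volume, inverse in weight.
#'
#' @param ma_volume_ml volume of drug solution consumed, mL (>= 0).
#' @param water_volume_ml volume of water consumed, mL (unused here; accepted
#'   so one record can feed both intake and preference).
#' @param ma_concentration_mg_l drug concentration, mg/L.
#' @param body_weight_kg body weight, kg (> 0).
#' @return Intake in mg/kg.
#' @export
ma_intake_mg_per_kg <- function(ma_volume_ml, ma_concentration_mg_l,
                                body_weight_kg, water_volume_ml = NULL) {
  if (any(ma_volume_ml < 0) || any(ma_concentration_mg_l < 0))
    abort("volumes and concentration must be >= 0")
  if (any(body_weight_kg <= 0)) abort("body weight must be > 0")
  ma_concentration_mg_l * (ma_volume_ml / 1000) / body_weight_kg
}

#' Two-bottle preference ratio
#'
#' Drug solution consumed (mL) divided by total fluid consumed from both
#' tubes. NA (with a warning) when nothing was drunk.
#'
#' @param ma_volume_ml volume of drug solution consumed, mL.
#' @param water_volume_ml volume of water consumed, mL.
#' @return Preference in \[0, 1\], NA where total is 0.
#' @export
preference_ratio <- function(ma_volume_ml, water_volume_ml) {
  if (any(ma_volume_ml < 0) || any(water_volume_ml < 0))
    abort("volumes must be >= 0")
  tot <- ma_volume_ml + water_volume_ml
  out <- ifelse(tot > 0, ma_volume_ml / tot, NA_real_)
  if (anyNA(out)) warn("zero total fluid for %d record(s); preference is NA",
                       sum(is.na(out)))
  out
}

#' Realized heritability from selection records
#'
#' Cumulative selection response R_t = offspring mean of generation t minus
#' the founder population mean; cumulative selection differential S_t = sum up
#' to t of (selected-parent mean - population mean). Realized h^2 is the
#' least-squares slope of R on S (breeder's equation R = h^2 S), with the
#' intercept fitted and reported by default.
#'
#' @param records data frame with columns `generation`, `population_mean`,
#'   `selected_parent_mean`, `offspring_mean`, ordered by generation (row t:
#'   population t is phenotyped, parents are selected from it, and
#'   `offspring_mean` is the mean of generation t+1).
#' @param through_origin fit without intercept (default FALSE).
#' @return list: `h2` (slope), `intercept` (0 when `through_origin`),
#'   `r_squared`, `response` and `differential` (the cumulative series).
#' @export
realized_heritability <- function(records, through_origin = FALSE) {
  need <- c("population_mean", "selected_parent_mean", "offspring_mean")
  if (!all(need %in% names(records)))
    abort("records must have columns: generation, %s",
          paste(need, collapse = ", "))
  if (nrow(records) < 2L) abort("need at least 2 generations")
  if (!is.null(records$generation) &&
      is.unsorted(records$generation, strictly = TRUE))
    abort("records must be ordered by generation")
  S <- cumsum(records$selected_parent_mean - records$population_mean)
  R <- records$offspring_mean - records$population_mean[1]
  if (all(S == 0))
    abort("zero cumulative selection differential; h2 is undefined")
  fit <- if (through_origin) stats::lm(R ~ S - 1) else stats::lm(R ~ S)
  co <- stats::coef(fit)
  # exact (noise-free) records give a perfect fit; that is fine here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(h2 = unname(co[["S"]]),
       intercept = if (through_origin) 0 else unname(co[["(Intercept)"]]),
       r_squared = r2,
       response = R, differential = S)
}

#' Relative expression by the delta-delta-Ct method
#'
#' For control-gene-adjusted cycle thresholds (delta Ct = target Ct - control
#' Ct), the per-sample fold value is 2^(reference-group mean - sample value):
#' a sample one cycle *below* the reference mean (more transcript) scores
#' fold 2, a sample at the reference mean scores fold 1, and folds are
#' strictly decreasing in delta Ct.
#'
#' @param delta_ct named numeric vector of per-sample delta Ct values.
#' @param reference_ids sample ids (or logical/integer index into `delta_ct`)
#'   forming the reference group whose mean anchors fold = 1.
#' @return Named numeric vector of fold values, with attribute
#'   `reference_mean`.
#' @export
ddct_relative_expression <- function(delta_ct, reference_ids) {
  if (is.character(reference_ids)) {
    if (!all(reference_ids %in% names(delta_ct)))
      abort("reference sample(s) not found in delta_ct")
    ref <- delta_ct[reference_ids]
  } else {
    ref <- delta_ct[reference_ids]
  }
  if (!length(ref)) abort("reference group is empty")
  m <- mean(ref)
  out <- 2^(m - delta_ct)
  attr(out, "reference_mean") <- m
  out
}
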