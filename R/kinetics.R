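#' Assemble an enzyme-kinetics dataset
#'
#' Initial-velocity measurements over a substrate grid, optionally at several
#' inhibitor concentrations (0 = control), with replicate ids.
#'
#' @param substrate Substrate concentrations (uM), positive.
#' @param velocity Velocities (arbitrary activity units), non-negative.
#' @param inhibitor Inhibitor concentrations (uM), 0 for control.
#' @param replicate Replicate identifiers.
#' @return Data frame of class `kinetics_dataset`.
#' @export
kinetics_dataset <- function(substrate, velocity, inhibitor = 0,
                             replicate = 1L) {
  d <- data.frame(substrate = as.numeric(substrate),
                  velocity = as.numeric(velocity),
                  inhibitor = as.numeric(inhibitor),
                  replicate = replicate)
  if (any(!is.finite(d$substrate)) || any(d$substrate <= 0))
    stop("substrate concentrations must be positive and finite")
  if (any(!is.finite(d$velocity)) || any(d$velocity < 0))
    stop("velocities must be non-negative and finite")
  class(d) <- c("kinetics_dataset", "data.frame")
  d
}

#' Read a kinetics CSV (columns substrate_uM, inhibitor_uM, replicate, velocity)
#' @param path CSV path.
#' @return A [kinetics_dataset].
#' @export
read_kinetics_csv <- function(path) {
  d <- utils::read.csv(path)
  needed <- c("substrate_uM", "inhibitor_uM", "replicate", "velocity")
  missing <- setdiff(needed, names(d))
  if (length(missing))
    stop("kinetics CSV is missing column(s): ", paste(missing, collapse = ", "))
  kinetics_dataset(d$substrate_uM, d$velocity, d$inhibitor_uM, d$replicate)
}

condition_subset <- function(d, condition) {
  sub <- d[abs(d$inhibitor - condition) < 1e-12, , drop = FALSE]
  if (length(unique(sub$substrate)) < 3L)
    stop("need >= 3 distinct substrate concentrations at [I] = ", condition)
  sub
}

mmfit <- function(Km, Vmax, se_Km, se_Vmax, method, inhibitor, n) {
  if (!is.finite(Km) || Km <= 0) stop("fitted Km is not positive (", Km, ")")
  if (!is.finite(Vmax) || Vmax <= 0)
    stop("fitted Vmax is not positive (", Vmax, ")")
  structure(list(Km = Km, Vmax = Vmax, se_Km = se_Km, se_Vmax = se_Vmax,
                 method = method, inhibitor = inhibitor, n = n),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<MM fit (%s), [I]=%g uM: Km = %.4g uM, Vmax = %.4g AU>\n",
              x$method, x$inhibitor, x$Km, x$Vmax))
  invisible(x)
}

#' Fit Michaelis-Menten parameters by the double-reciprocal (Lineweaver-Burk) plot
#'
#' Ordinary least squares of 1/v on 1/S: `Vmax = 1/intercept`,
#' `Km = slope/intercept`. Requires strictly positive velocities; a
#' non-positive intercept (unphysical Vmax) is an error.
#'
#' @param d A [kinetics_dataset].
#' @param condition Inhibitor concentration (uM) selecting the curve to fit.
#' @return An `mm_fit` (Km in uM, Vmax in activity units, delta-method
#'   standard errors).
#' @export
fit_lineweaver_burk <- function(d, condition = 0) {
  sub <- condition_subset(d, condition)
  if (any(sub$velocity <= 0))
    stop("Lineweaver-Burk requires strictly positive velocities")
  inv_v <- 1 / sub$velocity
  inv_s <- 1 / sub$substrate
  fit <- stats::lm(inv_v ~ inv_s)
  b0 <- unname(coef(fit)[1])   # intercept = 1/Vmax
  b1 <- unname(coef(fit)[2])   # slope = Km/Vmax
  if (!is.finite(b0) || b0 <= 0)
    stop("non-positive double-reciprocal intercept; Vmax would be unphysical")
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  Vmax <- 1 / b0
  Km <- b1 / b0
  # first-order (delta-method) error propagation
  se_Vmax <- se[1] / b0^2
  se_Km <- abs(Km) * sqrt((se[2] / b1)^2 + (se[1] / b0)^2)
  mmfit(Km, Vmax, unname(se_Km), unname(se_Vmax), "lineweaver_burk",
        condition, nrow(sub))
}

#' Fit Michaelis-Menten parameters by nonlinear least squares
#'
#' Levenberg-Marquardt fit of `v = Vmax * S / (Km + S)`, initialised from the
#' Lineweaver-Burk estimate (falling back to a heuristic start if the linear
#' fit fails).
#'
#' @inheritParams fit_lineweaver_burk
#' @return An `mm_fit`.
#' @export
fit_mm_nonlinear <- function(d, condition = 0) {
  sub <- condition_subset(d, condition)
  start <- tryCatch({
    lb <- fit_lineweaver_burk(d, condition)
    list(Km = lb$Km, Vmax = lb$Vmax)
  }, error = function(e)
    list(Km = stats::median(sub$substrate), Vmax = max(sub$velocity) * 1.2))
  fit <- tryCatch(
    minpack.lm::nlsLM(velocity ~ Vmax * substrate / (Km + substrate),
                      data = sub, start = start,
                      lower = c(Km = 1e-12, Vmax = 1e-12),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) stop("Michaelis-Menten fit failed at [I] = ",
                             condition, ": ", conditionMessage(e)))
  cf <- coef(fit)
  se <- tryCatch(suppressWarnings(sqrt(diag(stats::vcov(fit)))),
                 error = function(e) c(Km = NA_real_, Vmax = NA_real_))
  mmfit(unname(cf["Km"]), unname(cf["Vmax"]), unname(se["Km"]),
        unname(se["Vmax"]), "nonlinear", condition, nrow(sub))
}

#' Classify the inhibition mode from control and inhibited fits
#'
#' Computes the mean relative shifts over inhibited conditions,
#' `r_Km = Km_i/Km_0 - 1` and `r_V = 1 - Vmax_i/Vmax_0`, and calls the mode:
#' competitive when the apparent Km rises by more than `km_threshold` with
#' Vmax essentially unchanged; noncompetitive when Vmax falls by more than
#' `vmax_threshold` with Km essentially unchanged; mixed when both shifts
#' exceed their thresholds; none otherwise. Ki is estimated by least squares
#' on the linearised apparent-parameter relation (through the origin):
#' `Km_i = Km_0 (1 + [I]/Ki)` for competitive,
#' `Vmax_i = Vmax_0 / (1 + [I]/Ki)` for noncompetitive (also used for mixed).
#'
#' The thresholds are this package's operational reading of "no significant
#' change"; both are tunable.
#'
#' @param control `mm_fit` at `[I] = 0`.
#' @param inhibited List of `mm_fit`s at `[I] > 0` (their `inhibitor` fields
#'   supply the concentrations).
#' @param km_threshold Relative Km shift called significant (default 0.25).
#' @param vmax_threshold Relative Vmax drop called significant (default 0.15).
#' @return Object of class `inhibition_call`: `mode`, `Ki` (uM, `NA` for mode
#'   "none"), the shifts, thresholds and fits used.
#' @export
classify_inhibition <- function(control, inhibited, km_threshold = 0.25,
                                vmax_threshold = 0.15) {
  if (inherits(inhibited, "mm_fit")) inhibited <- list(inhibited)
  if (!length(inhibited)) stop("need at least one inhibited-condition fit")
  conc <- vapply(inhibited, function(f) f$inhibitor, 0)
  if (any(conc <= 0)) stop("inhibited fits must have [I] > 0")
  r_km <- mean(vapply(inhibited, function(f) f$Km / control$Km - 1, 0))
  r_v <- mean(vapply(inhibited, function(f) 1 - f$Vmax / control$Vmax, 0))
  km_up <- r_km > km_threshold
  v_down <- r_v > vmax_threshold
  mode <- if (km_up && v_down) "mixed"
    else if (km_up && abs(r_v) < vmax_threshold) "competitive"
    else if (v_down && abs(r_km) < km_threshold) "noncompetitive"
    else "none"
  Ki <- NA_real_
  if (mode == "competitive") {
    y <- vapply(inhibited, function(f) f$Km / control$Km - 1, 0)
    Ki <- sum(conc^2) / sum(conc * y)
  } else if (mode %in% c("noncompetitive", "mixed")) {
    y <- vapply(inhibited, function(f) control$Vmax / f$Vmax - 1, 0)
    Ki <- sum(conc^2) / sum(conc * y)
  }
  if (!is.na(Ki) && Ki <= 0)
    stop("Ki estimate is non-positive; shifts are inconsistent with the mode")
  structure(list(mode = mode, Ki = Ki, r_Km = r_km, r_Vmax = r_v,
                 km_threshold = km_threshold, vmax_threshold = vmax_threshold,
                 control = control, inhibited = inhibited),
            class = "inhibition_call")
}

#' @export
print.inhibition_call <- function(x, ...) {
  cat(sprintf("<inhibition call: %s%s (r_Km = %+.2f, r_Vmax = %+.2f)>\n",
              x$mode,
              if (is.na(x$Ki)) "" else sprintf(", Ki = %.4g uM", x$Ki),
              x$r_Km, x$r_Vmax))
  invisible(x)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Levenberg-Marquardt fit of
#' `response = bottom + (top - bottom) / (1 + (dose/IC50)^hill)`.
#' The fit is normalised so that `top > bottom` (the equivalent
#' reparameterisation flips the sign of the hill slope).
#'
#' @param dose Dose vector (uM), positive, at least 4 distinct values.
#' @param response Response vector (same length).
#' @return Object of class `dose_response_fit`: `IC50` (uM), `hill`, `top`,
#'   `bottom`, `rss`.
#' @export
fit_ic50 <- function(dose, response) {
  if (length(dose) != length(response)) stop("dose/response length mismatch")
  if (any(dose <= 0)) stop("doses must be positive")
  if (length(unique(dose)) < 4L)
    stop("need at least 4 distinct doses spanning the transition")
  if (diff(range(response)) <= 0)
    stop("degenerate response span; cannot fit a transition")
  top0 <- max(response); bot0 <- min(response)
  mid <- (top0 + bot0) / 2
  ic0 <- exp(stats::approx(response[order(dose)],
                           log(sort(dose)), xout = mid, ties = mean,
                           rule = 2)$y)
  if (!is.finite(ic0)) ic0 <- exp(mean(log(dose)))
  hill0 <- if (stats::cor(log(dose), response) < 0) 1 else -1
  df <- data.frame(dose = dose, response = response)
  span <- top0 - bot0
  # a start sitting exactly on the data can give a singular initial Jacobian;
  # offset starts are tried in order until one converges
  starts <- list(
    list(bottom = bot0 - 0.02 * span, top = top0 + 0.02 * span, IC50 = ic0,
         hill = hill0),
    list(bottom = bot0, top = top0, IC50 = ic0, hill = hill0),
    list(bottom = bot0 - 0.1 * span, top = top0 + 0.1 * span,
         IC50 = ic0 * 2, hill = hill0 * 1.5),
    list(bottom = bot0, top = top0, IC50 = exp(mean(log(dose))),
         hill = hill0))
  fit <- NULL
  last_err <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        response ~ bottom + (top - bottom) / (1 + (dose / IC50)^hill),
        data = df, start = st,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) { last_err <<- conditionMessage(e); NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("4PL fit failed: ", last_err)
  cf <- as.list(coef(fit))
  if (cf$top < cf$bottom) {   # equivalent curve with top/bottom swapped
    tmp <- cf$top; cf$top <- cf$bottom; cf$bottom <- tmp
    cf$hill <- -cf$hill
  }
  if (cf$IC50 <= 0) stop("fitted IC50 is non-positive")
  structure(list(IC50 = cf$IC50, hill = cf$hill, top = cf$top,
                 bottom = cf$bottom,
                 rss = sum(stats::resid(fit)^2), n = length(dose)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<4PL fit: IC50 = %.4g uM, hill = %.3g, top = %.4g, bottom = %.4g>\n",
    x$IC50, x$hill, x$top, x$bottom))
  invisible(x)
}

#' Normalise inhibition against each enzyme variant's own control
#'
#' Mutant enzymes can have reduced intrinsic activity; inhibition is therefore
#' expressed within each variant as
#' `100 * (1 - activity_with / activity_without)`, so that the mutation's own
#' effect on turnover cancels.
#'
#' @param activity_with Activity with ligand, per variant.
#' @param activity_without Control activity without ligand, per variant
#'   (must be positive).
#' @param variant Variant names (defaults to names of `activity_with` or
#'   V1, V2, ...).
#' @return Data frame with `variant`, `inhibition_pct`.
#' @export
normalize_mutant_inhibition <- function(activity_with, activity_without,
                                        variant = NULL) {
  if (length(activity_with) != length(activity_without))
    stop("with/without activity vectors differ in length")
  if (is.null(variant))
    variant <- names(activity_with) %||%
      paste0("V", seq_along(activity_with))
  bad <- which(!is.finite(activity_without) | activity_without <= 0)
  if (length(bad))
    stop("non-positive control activity for variant(s): ",
         paste(variant[bad], collapse = ", "))
  data.frame(variant = variant,
             inhibition_pct = 100 * (1 - activity_with / activity_without))
}
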