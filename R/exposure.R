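#' Exposure metrics over the dosing interval
#'
#' Computes the peak concentration and the area under the concentration-time
#' curve from a simulated profile.  Cmax is the grid maximum; the AUC is the
#' trapezoidal integral over the profile's time span (336 h, the two-week
#' dosing interval, for default profiles).
#'
#' @param profile A `pk_profile` from [simulate_profile()].
#' @param interval Required time span `c(start, end)` in h; the profile must
#'   cover it.  Default `c(0, 336)`.
#' @return An object of class `exposure_metrics`: list with `cmax` (ug/mL),
#'   `auc_2w` (ug.h/mL) and `subject_id`.
#' @examples
#' ind <- realize_individual(pop_params(), 70.5, eta = rep(0, 5))
#' compute_exposure(simulate_profile(ind, infusion_schedule(20, 70.5)))
#' @export
compute_exposure <- function(profile, interval = c(0, 336)) {
  stopifnot(inherits(profile, "pk_profile"))
  t <- profile$time; y <- profile$conc
  if (min(t) > interval[1] + 1e-9 || max(t) < interval[2] - 1e-9)
    stop(sprintf("profile does not cover [%g, %g] h", interval[1], interval[2]))
  keep <- t >= interval[1] - 1e-9 & t <= interval[2] + 1e-9
  t <- t[keep]; y <- y[keep]
  structure(list(cmax = max(y),
                 auc_2w = trapz(t, y),
                 subject_id = attr(profile, "subject_id")),
            class = "exposure_metrics")
}

# trapezoidal quadrature on an arbitrary (sorted) grid
trapz <- function(t, y) sum(diff(t) * (y[-length(y)] + y[-1L]) / 2)

#' Bodyweight-normalized apparent clearance
#'
#' `CL/WT = Dose / (AUC_2W x bodyweight)`, the apparent clearance per kg
#' implied by a subject's dose and two-week exposure.  In this model it
#' decreases with age in pediatric subjects because clearance scales less
#' than proportionally with weight.
#'
#' @param dose_total Administered dose, mg.
#' @param auc_2w Area under the curve over the dosing interval, ug.h/mL.
#' @param wt Bodyweight, kg.
#' @return Apparent clearance in L/h/kg.
#' @export
apparent_clearance <- function(dose_total, auc_2w, wt) {
  if (any(dose_total <= 0) || any(wt <= 0))
    stop("'dose_total' and 'wt' must be positive")
  if (any(auc_2w <= 0)) stop("'auc_2w' must be positive")
  dose_total / (auc_2w * wt)
}

#' @export
print.exposure_metrics <- function(x, ...) {
  cat(sprintf("Cmax %.4g ug/mL, AUC_2W %.5g ug.h/mL\n", x$cmax, x$auc_2w))
  invisible(x)
}

#' Write concentration profiles or exposure metrics to CSV
#'
#' @param x A `pk_profile`, `exposure_metrics`, or a data frame of either.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(x, path) {
  if (inherits(x, "pk_profile"))
    x <- data.frame(subject_id = attr(x, "subject_id"),
                    time_h = x$time, conc_ug_ml = x$conc)
  else if (inherits(x, "exposure_metrics"))
    x <- data.frame(subject_id = x$subject_id, cmax = x$cmax,
                    auc_2w = x$auc_2w)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
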