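#' Population pharmacokinetic parameters
#'
#' Constructs the fixed- and random-effects parameter set of the
#' avalglucosidase alfa population model: a concatenated three-compartment
#' disposition model with parallel linear (`cl`) and Michaelis-Menten
#' (`vmax`, `km`) elimination from the central compartment, two-way
#' intercompartmental clearance `q2` between the central volume `v1` and the
#' first peripheral volume `v2`, one-way clearance `q3` from `v2` into the
#' second peripheral volume `v3`, and a slow return clearance `q_pc` from
#' `v3` back to the central compartment.  Bodyweight enters through power-law
#' (allometric) scaling of `cl`, `v1` and `vmax` around the reference weight
#' `wt_ref`.  Inter-individual variability is log-normal on
#' \{CL, V1, Vmax, Km, Qpc\} with variances `omega2`; residual error is
#' proportional with variance `sigma2`.
#'
#' Defaults are the published population estimates for avalglucosidase alfa
#' (reference weight 70.5 kg, the dataset median).  `q2`, `v2`, `q3` and `v3`
#' are fixed (not estimated) in that reference fit.
#'
#' @param cl Linear clearance, L/h.
#' @param v1 Central volume of distribution, L.
#' @param vmax Maximal rate of the saturable elimination pathway, mg/h.
#' @param km Concentration of half-maximal saturable elimination, ug/mL.
#' @param q2 Two-way intercompartmental clearance V1 <-> V2, L/h.
#' @param v2 First peripheral volume, L.
#' @param q3 One-way intercompartmental clearance V2 -> V3, L/h.
#' @param v3 Second peripheral volume, L.
#' @param q_pc Slow return clearance V3 -> V1, L/h.
#' @param exp_cl,exp_v1,exp_vmax Allometric exponents on CL, V1 and Vmax.
#' @param wt_ref Reference (median) bodyweight, kg.
#' @param omega2 Named numeric vector of log-normal inter-individual variances
#'   for `cl`, `v1`, `vmax`, `km`, `q_pc` (dimensionless).
#' @param sigma2 Proportional residual error variance (dimensionless).
#' @param fixed Character vector naming parameters held fixed during
#'   estimation.
#'
#' @return An object of class `pop_params` (a named list).
#' @examples
#' pop <- pop_params()
#' typical_values(pop, wt = 68.1)
#' @export
pop_params <- function(cl = 0.808, v1 = 3.37, vmax = 12, km = 0.541,
                       q2 = 0.254, v2 = 296, q3 = 1.87, v3 = 1.31,
                       q_pc = 0.0157,
                       exp_cl = 0.896, exp_v1 = 0.661, exp_vmax = 0.463,
                       wt_ref = 70.5,
                       omega2 = c(cl = 0.0907, v1 = 0.0184, vmax = 0.118,
                                  km = 0.243, q_pc = 1.23),
                       sigma2 = 0.12,
                       fixed = c("q2", "v2", "q3", "v3")) {
  omega2 <- omega2[eta_names]
  if (anyNA(omega2))
    stop("'omega2' must contain entries named ",
         paste(eta_names, collapse = ", "))
  p <- list(cl = cl, v1 = v1, vmax = vmax, km = km,
            q2 = q2, v2 = v2, q3 = q3, v3 = v3, q_pc = q_pc,
            exp_cl = exp_cl, exp_v1 = exp_v1, exp_vmax = exp_vmax,
            wt_ref = wt_ref, omega2 = omega2, sigma2 = sigma2,
            fixed = fixed)
  validate_pop_params(p)
  structure(p, class = "pop_params")
}

# order of the per-subject random-effect vector throughout the package
eta_names <- c("cl", "v1", "vmax", "km", "q_pc")

validate_pop_params <- function(p) {
  pos <- c("cl", "v1", "vmax", "km", "q2", "v2", "q3", "v3", "q_pc",
           "wt_ref", "sigma2")
  for (nm in pos)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0)
      stop("parameter '", nm, "' must be a single positive number")
  if (any(p$omega2 < 0)) stop("'omega2' entries must be non-negative")
  invisible(p)
}

#' Read population parameters from a key-value file
#'
#' Reads a flat YAML (or JSON-compatible YAML) file with keys `cl`, `v1`,
#' `vmax`, `km`, `q2`, `v2`, `q3`, `v3`, `q_pc`, `exp_cl`, `exp_v1`,
#' `exp_vmax`, `wt_ref`, `omega2_cl` ... `omega2_q_pc` and `sigma2`.  The
#' packaged default parameter file is
#' `system.file("extdata", "avalglucosidase_poppk.yaml", package = "avalpk")`.
#'
#' @param path Path to the parameter file.
#' @return A [pop_params] object.
#' @export
read_pop_params <- function(path) {
  kv <- yaml::read_yaml(path)
  om <- paste0("omega2_", eta_names)
  miss <- setdiff(c("cl", "v1", "vmax", "km", "q2", "v2", "q3", "v3", "q_pc",
                    "exp_cl", "exp_v1", "exp_vmax", "wt_ref", om, "sigma2"),
                  names(kv))
  if (length(miss))
    stop("parameter file is missing keys: ", paste(miss, collapse = ", "))
  omega2 <- stats::setNames(as.numeric(kv[om]), eta_names)
  pop_params(cl = kv$cl, v1 = kv$v1, vmax = kv$vmax, km = kv$km,
             q2 = kv$q2, v2 = kv$v2, q3 = kv$q3, v3 = kv$v3, q_pc = kv$q_pc,
             exp_cl = kv$exp_cl, exp_v1 = kv$exp_v1, exp_vmax = kv$exp_vmax,
             wt_ref = kv$wt_ref, omega2 = omega2, sigma2 = kv$sigma2,
             fixed = if (is.null(kv$fixed)) c("q2", "v2", "q3", "v3")
                     else as.character(kv$fixed))
}

#' Write population parameters to a key-value file
#'
#' @param pop A [pop_params] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pop_params <- function(pop, path) {
  stopifnot(inherits(pop, "pop_params"))
  kv <- pop[c("cl", "v1", "vmax", "km", "q2", "v2", "q3", "v3", "q_pc",
              "exp_cl", "exp_v1", "exp_vmax", "wt_ref")]
  kv <- c(kv, stats::setNames(as.list(unname(pop$omega2)),
                              paste0("omega2_", eta_names)),
          list(sigma2 = pop$sigma2, fixed = pop$fixed))
  yaml::write_yaml(kv, path, precision = 15L)
  invisible(path)
}

#' Allometric typical values at a given bodyweight
#'
#' Computes the typical (population) parameter values at bodyweight `wt`
#' using power-law scaling around the reference weight:
#' `TV(P) = theta_P * (wt / wt_ref)^exp_P` for CL, V1 and Vmax.  Km and the
#' slow return clearance Qpc carry no allometric factor, nor do the fixed
#' peripheral parameters.
#'
#' @param pop A [pop_params] object.
#' @param wt Bodyweight in kg (vectorised).
#' @return For scalar `wt`, an object of class `typical_values`; for vector
#'   `wt`, a data frame with one row per weight.
#' @examples
#' typical_values(pop_params(), wt = 70.5)  # identical to the thetas
#' @export
typical_values <- function(pop, wt) {
  stopifnot(inherits(pop, "pop_params"))
  if (!is.numeric(wt) || any(!is.finite(wt)) || any(wt <= 0))
    stop("'wt' must be positive and finite")
  r <- wt / pop$wt_ref
  out <- data.frame(tv_cl = pop$cl * r^pop$exp_cl,
                    tv_v1 = pop$v1 * r^pop$exp_v1,
                    tv_vmax = pop$vmax * r^pop$exp_vmax,
                    tv_km = rep(pop$km, length(wt)),
                    tv_qpc = rep(pop$q_pc, length(wt)),
                    evaluated_wt = wt)
  if (length(wt) == 1L) {
    out <- as.list(out)
    class(out) <- "typical_values"
  }
  out
}

#' Realize individual parameters from the population model
#'
#' Draws (or accepts) a per-subject vector of log-scale random effects
#' `eta = (eta_CL, eta_V1, eta_Vmax, eta_Km, eta_Qpc)` and returns the
#' individual parameters `P_i = TV(P; wt) * exp(eta_P)`.  The fixed
#' peripheral parameters (`q2`, `v2`, `q3`, `v3`) are copied unchanged.
#'
#' @param pop A [pop_params] object.
#' @param wt Bodyweight in kg at which the allometric typical values are
#'   evaluated.
#' @param eta Optional numeric 5-vector of log-scale deviations in the order
#'   CL, V1, Vmax, Km, Qpc.  When `NULL`, independent normal deviates with
#'   variances `pop$omega2` are drawn from the current RNG stream.
#' @param subject_id Optional subject identifier carried on the result.
#' @return An object of class `ind_params`.
#' @examples
#' realize_individual(pop_params(), wt = 70.5, eta = rep(0, 5))
#' @export
realize_individual <- function(pop, wt, eta = NULL, subject_id = NA) {
  stopifnot(inherits(pop, "pop_params"))
  if (is.null(eta)) {
    eta <- stats::rnorm(5L, 0, sqrt(pop$omega2))
  }
  if (length(eta) != 5L || any(!is.finite(eta)))
    stop("'eta' must be a finite numeric 5-vector (cl, v1, vmax, km, q_pc)")
  eta <- stats::setNames(as.numeric(eta), eta_names)
  tv <- typical_values(pop, wt)
  structure(list(cl = tv$tv_cl * exp(eta[["cl"]]),
                 v1 = tv$tv_v1 * exp(eta[["v1"]]),
                 vmax = tv$tv_vmax * exp(eta[["vmax"]]),
                 km = tv$tv_km * exp(eta[["km"]]),
                 q_pc = tv$tv_qpc * exp(eta[["q_pc"]]),
                 q2 = pop$q2, v2 = pop$v2, q3 = pop$q3, v3 = pop$v3,
                 eta = eta, wt = wt, subject_id = subject_id),
            class = "ind_params")
}

#' Piecewise-constant bodyweight trajectory
#'
#' Represents a subject's time-varying bodyweight as last-observation-carried-
#' forward (LOCF) between breakpoints: the weight at time `t` is the value at
#' the latest breakpoint not after `t` (the first value before the first
#' breakpoint).
#'
#' @param time Breakpoint times, h, non-decreasing.
#' @param wt Bodyweights at the breakpoints, kg, positive.
#' @return An object of class `weight_trajectory`; evaluate with
#'   [eval_weight()].
#' @export
weight_trajectory <- function(time, wt) {
  if (length(time) != length(wt) || length(wt) < 1L)
    stop("'time' and 'wt' must be equal-length, non-empty")
  if (is.unsorted(time)) stop("'time' must be non-decreasing")
  if (any(wt <= 0)) stop("weights must be positive")
  structure(list(time = as.numeric(time), wt = as.numeric(wt)),
            class = "weight_trajectory")
}

#' Evaluate a bodyweight trajectory
#'
#' @param traj A [weight_trajectory] (a single weight is promoted to a
#'   constant trajectory).
#' @param t Times, h.
#' @return Bodyweights at `t`, kg (LOCF).
#' @export
eval_weight <- function(traj, t) {
  if (is.numeric(traj) && length(traj) == 1L)
    traj <- weight_trajectory(0, traj)
  stopifnot(inherits(traj, "weight_trajectory"))
  idx <- findInterval(t, traj$time)
  traj$wt[pmax(idx, 1L)]
}

#' @export
print.pop_params <- function(x, ...) {
  cat("Population PK parameters (avalglucosidase alfa model)\n")
  cat(sprintf("  CL %.4g L/h, V1 %.4g L, Vmax %.4g mg/h, Km %.4g ug/mL\n",
              x$cl, x$v1, x$vmax, x$km))
  cat(sprintf("  Q2 %.4g, V2 %.4g, Q3 %.4g, V3 %.4g, Qpc %.4g  (fixed: %s)\n",
              x$q2, x$v2, x$q3, x$v3, x$q_pc, paste(x$fixed, collapse = ", ")))
  cat(sprintf("  allometry: CL^%.3g V1^%.3g Vmax^%.3g around %.3g kg\n",
              x$exp_cl, x$exp_v1, x$exp_vmax, x$wt_ref))
  cat(sprintf("  IIV omega2: %s\n",
              paste(sprintf("%s %.3g (%.1f%%)", eta_names, x$omega2,
                            omega2_to_cv(x$omega2)), collapse = ", ")))
  cat(sprintf("  residual sigma2 %.3g (%.1f%% CV, proportional)\n",
              x$sigma2, sigma2_to_cv(x$sigma2)))
  invisible(x)
}

#' @export
print.ind_params <- function(x, ...) {
  cat(sprintf("Individual PK parameters (subject %s, wt %.3g kg)\n",
              as.character(x$subject_id), x$wt))
  cat(sprintf("  CL %.4g L/h, V1 %.4g L, Vmax %.4g mg/h, Km %.4g, Qpc %.4g\n",
              x$cl, x$v1, x$vmax, x$km, x$q_pc))
  cat(sprintf("  eta: %s\n", paste(sprintf("%.3g", x$eta), collapse = ", ")))
  invisible(x)
}

#' @export
print.typical_values <- function(x, ...) {
  cat(sprintf(
    "Typical values at %.4g kg: CL %.4g L/h, V1 %.4g L, Vmax %.4g mg/h\n",
    x$evaluated_wt, x$tv_cl, x$tv_v1, x$tv_vmax))
  invisible(x)
}
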