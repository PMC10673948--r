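#' Right-hand side of the disposition model
#'
#' Pure-R evaluation of the model's ordinary differential equations, mainly
#' for inspection and testing (simulation uses the compiled equivalent).
#' With central, first- and second-peripheral amounts `A = (A1, A2, A3)` in
#' mg and concentrations `Ck = Ak/Vk`:
#' \deqn{dA1/dt = R(t) - CL.C1 - Vmax.C1/(Km + C1) - Q2.C1 + Q2.C2 + Qpc.C3}
#' \deqn{dA2/dt = Q2.C1 - Q2.C2 - Q3.C2}
#' \deqn{dA3/dt = Q3.C2 - Qpc.C3}
#' Each intercompartmental clearance acts on its source compartment's
#' concentration, the only mass-conserving reading of the one-way V2 -> V3
#' flow with back redistribution V3 -> V1.
#'
#' @param state Numeric 3-vector of compartment amounts (mg), non-negative.
#' @param t Time, h.
#' @param ind An `ind_params` object (see [realize_individual()]).
#' @param rate_fn Function of time returning the infusion rate in mg/h, or a
#'   single number for a constant rate.
#' @return Numeric 3-vector of derivatives, mg/h.
#' @examples
#' ind <- realize_individual(pop_params(), wt = 70.5, eta = rep(0, 5))
#' pk_rhs(c(10, 5, 1), 0, ind, rate_fn = 0)
#' @export
pk_rhs <- function(state, t, ind, rate_fn = 0) {
  stopifnot(inherits(ind, "ind_params"))
  if (length(state) != 3L || anyNA(state) || any(!is.finite(state)))
    stop("'state' must be a finite numeric 3-vector")
  r <- if (is.function(rate_fn)) rate_fn(t) else rate_fn
  c1 <- state[1] / ind$v1
  c2 <- state[2] / ind$v2
  c3 <- state[3] / ind$v3
  c(r - ind$cl * c1 - ind$vmax * c1 / (ind$km + c1) -
      ind$q2 * c1 + ind$q2 * c2 + ind$q_pc * c3,
    ind$q2 * c1 - ind$q2 * c2 - ind$q3 * c2,
    ind$q3 * c2 - ind$q_pc * c3)
}

# Integrate the compiled model over piecewise-constant segments.
# `segments`: list with numeric vectors t0, t1, rate and a 9-column matrix
# `pars` (cl, v1, vmax, km, q2, v2, q3, v3, q_pc), one row per contiguous,
# ordered segment.  `times`: sorted output times within [t0[1], t1[n]].
# Integration restarts at every segment boundary so rate/parameter
# discontinuities are honored exactly.  Returns list(time, a (3-col amount
# matrix), v1 (central volume in force at each time), final_state).
integrate_segments <- function(segments, times, init = c(0, 0, 0),
                               rtol = 1e-8, atol = 1e-8) {
  state <- init
  nseg <- length(segments$t0)
  nt <- length(times)
  out_t <- numeric(nt); out_a <- matrix(NA_real_, nt, 3L); out_v1 <- numeric(nt)
  pos <- 0L
  if (nt && times[1] == segments$t0[1]) {
    pos <- 1L
    out_t[1] <- times[1]; out_a[1, ] <- state; out_v1[1] <- segments$pars[1L, 2L]
    times <- times[-1L]
  }
  for (i in seq_len(nseg)) {
    t0 <- segments$t0[i]; t1 <- segments$t1[i]
    if (t1 - t0 <= 0) next
    sel <- times[times > t0 & times <= t1]
    tt <- c(t0, sel)
    if (!length(sel) || sel[length(sel)] < t1) tt <- c(tt, t1)
    sol <- deSolve::lsoda(y = state, times = tt, func = "pk_derivs",
                          parms = c(segments$pars[i, ], segments$rate[i]),
                          dllname = "avalpk", initfunc = "pk_initmod",
                          rtol = rtol, atol = atol, maxsteps = 20000)
    if (attr(sol, "istate")[1L] < 0)
      stop(sprintf("ODE integration failed in segment %d (t = %.4g..%.4g h)",
                   i, t0, t1))
    ns <- length(sel)
    if (ns) {
      idx <- pos + seq_len(ns)
      keep <- match(sel, sol[, 1L])
      out_t[idx] <- sel
      out_a[idx, ] <- sol[keep, 2:4, drop = FALSE]
      out_v1[idx] <- segments$pars[i, 2L]
      pos <- pos + ns
    }
    state <- as.numeric(sol[nrow(sol), 2:4])
  }
  list(time = out_t[seq_len(pos)], a = out_a[seq_len(pos), , drop = FALSE],
       v1 = out_v1[seq_len(pos)], final_state = state)
}

# combined rate over contiguous interval starts/ends from a dose list
segment_rates <- function(doses, t0, t1) {
  rate <- numeric(length(t0))
  for (d in doses) {
    s <- d$segments
    for (j in seq_len(nrow(s))) {
      on <- t0 >= s$start[j] - 1e-12 & t1 <= s$start[j] + s$duration[j] + 1e-12
      rate[on] <- rate[on] + s$rate[j]
    }
  }
  rate
}

# Build contiguous integration segments for one subject with realized,
# time-constant parameters.
pk_segments <- function(ind, doses, horizon) {
  bounds <- 0
  for (d in doses) {
    s <- d$segments
    bounds <- c(bounds, s$start, s$start + s$duration)
  }
  bounds <- sort(unique(c(bounds[bounds < horizon - 1e-9], horizon)))
  bounds <- bounds[c(TRUE, diff(bounds) > 1e-9)]   # merge near-duplicates
  t0 <- bounds[-length(bounds)]; t1 <- bounds[-1L]
  n <- length(t0)
  pars <- matrix(c(ind$cl, ind$v1, ind$vmax, ind$km, ind$q2, ind$v2,
                   ind$q3, ind$v3, ind$q_pc),
                 n, 9L, byrow = TRUE)
  list(t0 = t0, t1 = t1, rate = segment_rates(doses, t0, t1), pars = pars)
}

# Segments with piecewise-constant (LOCF) time-varying weight: typical values
# are re-evaluated at every dose/weight breakpoint and held constant between.
pk_segments_tv <- function(pop, eta, doses, wt_traj, horizon) {
  if (is.numeric(wt_traj) && length(wt_traj) == 1L)
    wt_traj <- weight_trajectory(0, wt_traj)
  bounds <- c(0, wt_traj$time)
  for (d in doses) {
    s <- d$segments
    bounds <- c(bounds, s$start, s$start + s$duration)
  }
  bounds <- sort(unique(c(bounds[bounds >= 0 & bounds < horizon - 1e-9],
                          horizon)))
  bounds <- bounds[c(TRUE, diff(bounds) > 1e-9)]   # merge near-duplicates
  t0 <- bounds[-length(bounds)]; t1 <- bounds[-1L]
  n <- length(t0)
  r <- eval_weight(wt_traj, t0) / pop$wt_ref
  e <- exp(eta)
  pars <- cbind(pop$cl * r^pop$exp_cl * e[1L],
                pop$v1 * r^pop$exp_v1 * e[2L],
                pop$vmax * r^pop$exp_vmax * e[3L],
                rep(pop$km * e[4L], n),
                rep(pop$q2, n), rep(pop$v2, n), rep(pop$q3, n),
                rep(pop$v3, n),
                rep(pop$q_pc * e[5L], n))
  list(t0 = t0, t1 = t1, rate = segment_rates(doses, t0, t1), pars = pars)
}

#' Simulate a concentration-time profile
#'
#' Integrates the disposition model for one subject under a stepped infusion
#' and returns the central concentration on a uniform grid.  The integrator
#' (`lsoda`, stiff-capable, compiled right-hand side) is restarted at every
#' infusion-rate breakpoint so the discontinuities are handled exactly.
#'
#' @param ind An `ind_params` object.
#' @param schedule An [infusion_schedule] (or a list of them for repeated
#'   dosing).
#' @param horizon Simulation horizon, h.  Default 336 h (the two-week dosing
#'   interval).
#' @param dt Output grid spacing, h.  Default 0.1 h.
#' @param rtol,atol Integrator tolerances.
#' @return An object of class `pk_profile`: a data frame with columns `time`
#'   (h) and `conc` (ug/mL), with the subject id and dosing record as
#'   attributes.
#' @examples
#' ind <- realize_individual(pop_params(), wt = 70.5, eta = rep(0, 5))
#' prof <- simulate_profile(ind, infusion_schedule(20, 70.5))
#' compute_exposure(prof)
#' @export
simulate_profile <- function(ind, schedule, horizon = 336, dt = 0.1,
                             rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(ind, "ind_params"))
  if (inherits(schedule, "infusion_schedule")) schedule <- list(schedule)
  times <- seq(0, horizon, by = dt)
  segs <- pk_segments(ind, schedule, horizon)
  sim <- integrate_segments(segs, times, rtol = rtol, atol = atol)
  conc <- pmax(sim$a[, 1L] / sim$v1, 0)
  structure(data.frame(time = sim$time, conc = conc),
            class = c("pk_profile", "data.frame"),
            subject_id = ind$subject_id,
            dose = vapply(schedule, function(d) d$total_dose, 0))
}

# model prediction at arbitrary observation times under time-varying weight;
# workhorse for estimation, VPC and study generation
predict_conc <- function(pop, eta, doses, wt_traj, times,
                         rtol = 1e-6, atol = 1e-6) {
  if (!length(times)) return(numeric(0))
  horizon <- max(times, vapply(doses, function(d)
    if (nrow(d$segments)) max(d$segments$start + d$segments$duration) else 0,
    0)) + 1e-6
  segs <- pk_segments_tv(pop, eta, doses, wt_traj, horizon)
  ut <- unique(sort(times))
  conc <- fast_conc(segs, ut, rtol, atol)
  conc[match(times, ut)]
}

# central concentration at sorted unique times via the compiled piecewise
# Dormand-Prince solver; falls back to the (stiff-capable) lsoda path if the
# explicit integrator gives up
fast_conc <- function(segs, ut, rtol = 1e-6, atol = 1e-6) {
  a <- tryCatch(
    .Call(pk_sim_c, segs$t0, segs$t1, segs$rate, segs$pars, ut,
          c(0, 0, 0), rtol, atol),
    error = function(e) NULL)
  if (is.null(a)) {
    sim <- integrate_segments(segs, ut, rtol = rtol, atol = atol)
    return(sim$a[, 1L] / sim$v1)
  }
  v1 <- segs$pars[pmax(findInterval(ut, segs$t0), 1L), 2L]
  a[seq_along(ut), 1L] / v1
}

#' @export
print.pk_profile <- function(x, ...) {
  cat(sprintf(
    "Concentration profile: %d points over %.4g h, Cmax %.4g ug/mL\n",
    nrow(x), max(x$time), max(x$conc)))
  invisible(x)
}

#' @export
plot.pk_profile <- function(x, log = "", xlab = "Time (h)",
                            ylab = "Concentration (ug/mL)", type = "l", ...) {
  graphics::plot(x$time, x$conc, type = type, log = log,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
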