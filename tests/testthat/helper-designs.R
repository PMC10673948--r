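# shared fixtures built in code: designs, oracles, tiny datasets

# single-dose, richly sampled adult arm for estimation tests
rich_design <- function(n = 10, dose = 20) {
  study_design(list(list(
    label = "rich", n = n, dose = dose, duration_weeks = 2,
    demographics = list(type = "adult", age_min = 18, age_max = 70,
                        wt_mean = 75.9, wt_sd = 20.1, wt_lo = 38, wt_hi = 129),
    sampling = list(weeks = 1, predose = FALSE, eoi = TRUE,
                    offsets_h = c(1, 2, 4, 8, 16, 24, 48, 96, 168, 332)))))
}

# one-subject design list for direct likelihood/MAP work
make_subject <- function(pop, eta, wt = 75, dose = 20,
                         offsets = c(1, 2, 4, 8, 16, 24, 48, 96, 168, 332),
                         dv = NULL, seed = NULL) {
  sch <- infusion_schedule(dose, wt)
  tt <- sch$total_duration + offsets
  f <- avalpk:::predict_conc(pop, eta, list(sch), wt, tt,
                             rtol = 1e-10, atol = 1e-10)
  if (is.null(dv)) dv <- f
  list(id = 1L, doses = list(sch), obs_time = tt, obs_dv = dv,
       obs_blq = rep(FALSE, length(tt)),
       wt_traj = weight_trajectory(0, wt),
       covariates = data.frame(WT = wt), lloq = 0.0125)
}

# independent fixed-step classical RK4 on the full piecewise problem;
# brute-force oracle for the adaptive solvers
rk4_oracle <- function(ind, schedule, horizon, h = 0.001, out_dt = 0.1) {
  rate_at <- function(t) infusion_rate(schedule, t)
  deriv <- function(y, t) {
    c1 <- y[1] / ind$v1; c2 <- y[2] / ind$v2; c3 <- y[3] / ind$v3
    mm <- if (c1 > 0) ind$vmax * c1 / (ind$km + c1) else 0
    c(rate_at(t) - ind$cl * c1 - mm - ind$q2 * c1 + ind$q2 * c2 +
        ind$q_pc * c3,
      ind$q2 * c1 - ind$q2 * c2 - ind$q3 * c2,
      ind$q3 * c2 - ind$q_pc * c3)
  }
  # align steps with rate breakpoints so the step function is exact
  brk <- with(schedule$segments, sort(unique(c(0, start, start + duration,
                                               horizon))))
  brk <- brk[brk <= horizon]
  out_t <- seq(0, horizon, by = out_dt)
  out_y <- matrix(NA_real_, length(out_t), 3L)
  y <- c(0, 0, 0)
  oi <- 1L
  out_y[1L, ] <- y; oi <- 2L
  for (b in seq_len(length(brk) - 1L)) {
    t <- brk[b]; tend <- brk[b + 1L]
    nst <- max(1L, ceiling((tend - t) / h))
    hh <- (tend - t) / nst
    for (s in seq_len(nst)) {
      k1 <- deriv(y, t)
      k2 <- deriv(y + hh / 2 * k1, t + hh / 2)
      k3 <- deriv(y + hh / 2 * k2, t + hh / 2)
      k4 <- deriv(y + hh * k3, t + hh)
      y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- brk[b] + s * hh
      while (oi <= length(out_t) && out_t[oi] <= t + 1e-9) {
        out_y[oi, ] <- y; oi <- oi + 1L
      }
    }
  }
  list(time = out_t, conc = out_y[, 1L] / ind$v1, a = out_y)
}

typical_subject <- function(pop = pop_params(), wt = 70.5)
  realize_individual(pop, wt, eta = rep(0, 5))
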