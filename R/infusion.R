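#' Stepped intravenous infusion schedule
#'
#' Builds the ramped infusion used for avalglucosidase alfa dosing: the rate
#' is increased stepwise at 1, 3 and 5 mg/kg/h for 30 minutes each, then held
#' at 7 mg/kg/h until the planned weight-based dose has been delivered.  For
#' doses of at most 4.5 mg/kg (the amount the three fixed steps deliver) the
#' ladder is truncated as soon as the cumulative delivered amount reaches the
#' dose.
#'
#' @param dose_per_kg Planned dose, mg/kg.
#' @param wt Bodyweight, kg (converts per-kg rates to absolute mg/h).
#' @param start Start time of the infusion, h.
#' @param step_rates Per-kg step rates, mg/kg/h.
#' @param step_durations Durations of all but the last step, h.
#' @return An object of class `infusion_schedule`: a list with `segments`
#'   (data frame of `start`, `rate` mg/h, `duration` h), `total_dose` (mg)
#'   and `total_duration` (h).
#' @examples
#' sch <- infusion_schedule(20, wt = 70.5)
#' sch$total_duration  # 3.71 h
#' @export
infusion_schedule <- function(dose_per_kg, wt, start = 0,
                              step_rates = c(1, 3, 5, 7),
                              step_durations = c(0.5, 0.5, 0.5)) {
  if (!is.numeric(dose_per_kg) || dose_per_kg <= 0)
    stop("'dose_per_kg' must be positive")
  if (!is.numeric(wt) || wt <= 0) stop("'wt' must be positive")
  nstep <- length(step_rates)
  if (length(step_durations) != nstep - 1L)
    stop("'step_durations' must have one entry fewer than 'step_rates'")

  remaining <- dose_per_kg                      # mg/kg still to deliver
  seg_rate <- numeric(0)
  seg_dur <- numeric(0)
  for (k in seq_len(nstep)) {
    if (remaining <= 1e-12) break
    dur_k <- if (k < nstep) step_durations[k] else remaining / step_rates[k]
    amt_k <- step_rates[k] * dur_k
    if (amt_k >= remaining) {                   # truncate within this step
      dur_k <- remaining / step_rates[k]
      amt_k <- remaining
    }
    seg_rate <- c(seg_rate, step_rates[k])
    seg_dur <- c(seg_dur, dur_k)
    remaining <- remaining - amt_k
  }
  seg_start <- start + cumsum(c(0, seg_dur[-length(seg_dur)]))
  segments <- data.frame(start = seg_start,
                         rate = seg_rate * wt,
                         duration = seg_dur)
  structure(list(segments = segments,
                 total_dose = dose_per_kg * wt,
                 total_duration = sum(seg_dur),
                 dose_per_kg = dose_per_kg, wt = wt, start = start),
            class = "infusion_schedule")
}

#' Zero-dose schedule (no drug input)
#'
#' @param start Nominal start time, h.
#' @return An `infusion_schedule` with no segments and zero dose.
#' @export
zero_schedule <- function(start = 0) {
  structure(list(segments = data.frame(start = numeric(0), rate = numeric(0),
                                       duration = numeric(0)),
                 total_dose = 0, total_duration = 0,
                 dose_per_kg = 0, wt = NA_real_, start = start),
            class = "infusion_schedule")
}

#' Infusion rate as a function of time
#'
#' @param schedule An [infusion_schedule].
#' @param t Times, h.
#' @return Rates in mg/h at `t` (zero outside all segments).
#' @export
infusion_rate <- function(schedule, t) {
  stopifnot(inherits(schedule, "infusion_schedule"))
  r <- numeric(length(t))
  seg <- schedule$segments
  for (i in seq_len(nrow(seg))) {
    on <- t >= seg$start[i] & t < seg$start[i] + seg$duration[i]
    r[on] <- seg$rate[i]
  }
  r
}

#' @export
print.infusion_schedule <- function(x, ...) {
  cat(sprintf(
    "Stepped infusion: %.4g mg total over %.4g h (%d segments)\n",
    x$total_dose, x$total_duration, nrow(x$segments)))
  if (nrow(x$segments)) print(x$segments, row.names = FALSE)
  invisible(x)
}
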