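#' Study design for synthetic PK data generation
#'
#' A study design is a list of arms, each with a size, a weight-based dose,
#' a duration, demographics and a sampling template, plus the assay's lower
#' limit of quantitation.  Packaged templates emulating the four
#' avalglucosidase alfa trials (every-two-week dosing; rich sampling around
#' selected dosing weeks) are available through [study_templates()].
#'
#' @param arms List of arm specifications; each a list with `label`, `n`,
#'   `dose` (mg/kg), `duration_weeks`, `demographics` (list: `type`
#'   "adult"/"pediatric", `age_min`, `age_max`, `wt_mean`, `wt_sd`, `wt_lo`,
#'   `wt_hi`, and for pediatric `growth_kg_per_year`), `sampling` (list:
#'   `weeks`, `predose`, `eoi`, `offsets_h` after end of infusion), optional
#'   `sparse_sampling` in the same form, and optional `switch` (list `week`,
#'   `dose`) for ascending-dose arms.
#' @param lloq Lower limit of quantitation, ug/mL.
#' @return An object of class `study_design`.
#' @export
study_design <- function(arms, lloq = 0.0125) {
  stopifnot(length(arms) >= 1L, lloq > 0)
  for (a in arms) {
    stopifnot(a$n > 0, a$dose > 0, a$duration_weeks > 0)
    smax <- max(unlist(c(a$sampling$weeks, a$sparse_sampling$weeks)))
    if (smax > a$duration_weeks)
      stop("sampling week ", smax, " beyond study duration in arm ", a$label)
  }
  structure(list(arms = arms, lloq = lloq), class = "study_design")
}

#' Packaged study-design templates
#'
#' @param name One of `"study1_lopd_phase1"`, `"study2_lopd_phase12"`,
#'   `"study3_lopd_phase3"`, `"study4_iopd_phase2"`; `NULL` lists the names.
#' @param path Optional alternative YAML file in the packaged format.
#' @return A [study_design], or a character vector of template names.
#' @export
study_templates <- function(name = NULL,
                            path = system.file("extdata",
                                               "study_templates.yaml",
                                               package = "avalpk")) {
  all <- yaml::read_yaml(path)
  if (is.null(name)) return(names(all))
  if (!name %in% names(all))
    stop("unknown template '", name, "'; available: ",
         paste(names(all), collapse = ", "))
  tpl <- all[[name]]
  study_design(tpl$arms, lloq = tpl$lloq)
}

# sample times for one dose event given its template block
template_times <- function(block, dose_start, eoi) {
  tt <- numeric(0)
  if (isTRUE(block$predose)) tt <- c(tt, max(dose_start - 0.1, 0))
  if (isTRUE(block$eoi)) tt <- c(tt, eoi)
  tt <- c(tt, eoi + unlist(block$offsets_h))
  tt
}

#' Generate a synthetic PK study dataset
#'
#' Draws demographics per arm, realizes log-normal inter-individual
#' variability, builds the stepped infusion for every scheduled dose at the
#' subject's current bodyweight (pediatric subjects gain weight linearly over
#' study time, exercising the time-varying-weight pathway), simulates the
#' model at the template sampling times, applies proportional residual error
#' `y = f (1 + e)`, `e ~ N(0, sigma2)`, and flags observations below the
#' limit of quantitation.  Fully reproducible under `seed`.
#'
#' @param design A [study_design].
#' @param pop A [pop_params] object.
#' @param seed Integer seed.
#' @param disease Label written to the `DISEASE` column for adult
#'   (`"LOPD"`) and pediatric (`"IOPD"`) arms.
#' @param ada_rate,pretreat_rate Bernoulli rates for the antidrug-antibody
#'   and prior-treatment covariate columns (labels only; no PK effect).
#' @return A `pkdata` data frame (see [read_pkdata()]) with `WT`, `AGE`,
#'   `SEX`, `DISEASE`, `PRETREAT`, `ADA` covariate columns.
#' @examples
#' \donttest{
#' d <- generate_study(study_templates("study1_lopd_phase1"), pop_params(),
#'                     seed = 1)
#' }
#' @export
generate_study <- function(design, pop = pop_params(), seed = NULL,
                           disease = NULL, ada_rate = 0.3,
                           pretreat_rate = 0.5) {
  stopifnot(inherits(design, "study_design"), inherits(pop, "pop_params"))
  if (!is.null(seed)) set.seed(seed)
  recs <- list()
  sid <- 0L
  for (arm in design$arms) {
    demo <- arm$demographics
    pediatric <- identical(demo$type, "pediatric")
    for (s in seq_len(arm$n)) {
      sid <- sid + 1L
      age <- stats::runif(1, demo$age_min, demo$age_max)
      wt0 <- rtrunc_norm(1, demo$wt_mean, demo$wt_sd, demo$wt_lo, demo$wt_hi)
      sex <- if (stats::runif(1) < 0.5) "M" else "F"
      ada <- as.integer(stats::runif(1) < ada_rate)
      pretreat <- as.integer(stats::runif(1) < pretreat_rate)
      eta <- stats::rnorm(5L, 0, sqrt(pop$omega2))

      dose_weeks <- seq(1, arm$duration_weeks, by = 2)
      dose_times <- (dose_weeks - 1) * 168
      growth <- if (pediatric && !is.null(demo$growth_kg_per_year))
        demo$growth_kg_per_year else 0
      wt_at <- function(t) wt0 + growth * t / (24 * 365.25)
      wt_traj <- weight_trajectory(dose_times, wt_at(dose_times))

      doses <- vector("list", length(dose_times))
      dose_mgkg <- rep(arm$dose, length(dose_weeks))
      if (!is.null(arm$switch))
        dose_mgkg[dose_weeks >= arm$switch$week] <- arm$switch$dose
      for (j in seq_along(dose_times))
        doses[[j]] <- infusion_schedule(dose_mgkg[j],
                                        wt_at(dose_times[j]),
                                        start = dose_times[j])

      obs_t <- numeric(0)
      for (block in list(arm$sampling, arm$sparse_sampling)) {
        if (is.null(block)) next
        for (w in block$weeks) {
          j <- match(w, dose_weeks)
          if (is.na(j)) j <- max(which(dose_weeks <= w))
          eoi <- dose_times[j] + doses[[j]]$total_duration
          obs_t <- c(obs_t, template_times(block, dose_times[j], eoi))
        }
      }
      obs_t <- sort(unique(obs_t))
      horizon <- arm$duration_weeks * 168
      if (max(obs_t) > horizon)
        stop("sampling time beyond simulation horizon in arm ", arm$label)

      f <- predict_conc(pop, eta, doses, wt_traj, obs_t)
      eps <- stats::rnorm(length(f), 0, sqrt(pop$sigma2))
      y <- f * (1 + eps)
      blq <- as.integer(y < design$lloq)

      dose_recs <- do.call(rbind, lapply(doses, function(d) {
        s <- d$segments
        data.frame(TIME = s$start, AMT = s$rate * s$duration, RATE = s$rate,
                   DV = NA_real_, EVID = 1L, MDV = 1L, BLQ = 0L)
      }))
      obs_recs <- data.frame(TIME = obs_t, AMT = NA_real_, RATE = NA_real_,
                             DV = y, EVID = 0L, MDV = 0L, BLQ = blq)
      rec <- rbind(dose_recs, obs_recs)
      rec <- rec[order(rec$TIME, -rec$EVID), ]
      rec <- cbind(ID = sid, rec)
      rec$WT <- eval_weight(wt_traj, rec$TIME)
      rec$AGE <- age
      rec$SEX <- sex
      rec$DISEASE <- if (!is.null(disease)) disease
                     else if (pediatric) "IOPD" else "LOPD"
      rec$PRETREAT <- pretreat
      rec$ADA <- ada
      rec$ARM <- arm$label
      recs[[sid]] <- rec
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  suppressWarnings(as_pkdata(out, lloq = design$lloq))
}

#' Inject multiplicative outliers into a dataset
#'
#' Multiplies a random subset of quantified observations by `magnitude` and
#' records the originals in an `OUTLIER` audit column (0 for untouched rows,
#' the pre-injection value for modified rows), so exclusion workflows can be
#' exercised and reversed exactly.
#'
#' @param data A `pkdata` data frame.
#' @param rate Fraction of observation records to perturb, in `[0, 1)`.
#' @param magnitude Multiplicative factor applied to the selected `DV`s.
#' @param seed Integer seed.
#' @return The modified `pkdata` with an `OUTLIER` column.
#' @export
inject_outliers <- function(data, rate, magnitude = 10, seed = NULL) {
  stopifnot(inherits(data, "pkdata"), rate >= 0, rate < 1)
  if (!is.null(seed)) set.seed(seed)
  out <- data
  out$OUTLIER <- 0
  if (rate > 0) {
    obs <- which(out$EVID == 0L & out$MDV == 0L)
    hit <- obs[stats::runif(length(obs)) < rate]
    out$OUTLIER[hit] <- out$DV[hit]
    out$DV[hit] <- out$DV[hit] * magnitude
  }
  out
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design: %d arm(s), LLOQ %g ug/mL\n",
              length(x$arms), x$lloq))
  for (a in x$arms)
    cat(sprintf("  %-16s n=%-3d %g mg/kg q2w, %g weeks\n",
                a$label, a$n, a$dose, a$duration_weeks))
  invisible(x)
}
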