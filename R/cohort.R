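#' Read a growth-percentile fixture
#'
#' Loads a CSV of weight-for-age percentiles with columns `sex` (`M`/`F`),
#' `age_years`, `p5_kg`, `p50_kg`, `p95_kg`.  The packaged default
#' (`growth_percentiles_synthetic.csv`) is a constructed stand-in with
#' plausible magnitudes for CDC-style weight-for-age charts; any user fixture
#' in the same format is accepted, and no result in the package depends on
#' the exact percentile values — only on the truncation contract.
#'
#' @param path Fixture path; default is the packaged file.
#' @return A data frame with the columns above.
#' @export
read_growth_fixture <- function(path = system.file(
    "extdata", "growth_percentiles_synthetic.csv", package = "avalpk")) {
  fx <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_years", "p5_kg", "p50_kg", "p95_kg")
  if (!all(need %in% names(fx)))
    stop("growth fixture must have columns ", paste(need, collapse = ", "))
  if (any(fx$p5_kg >= fx$p95_kg) || any(fx$p50_kg <= 0))
    stop("growth fixture percentiles must satisfy 0 < p5 < p95")
  fx
}

# inverse-CDF draw from N(mean, sd) truncated to [lo, hi]
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Sample bodyweight for age and sex from a growth fixture
#'
#' Draws weights from a normal distribution centered at the fixture's median
#' (P50) with standard deviation `(P95 - P5) / (2 * z_0.95)` (so that the
#' untruncated distribution would place its 5th and 95th percentiles at the
#' fixture values), truncated to `[P5, P95]`.
#'
#' @param age Age in years; must match a fixture row exactly.
#' @param sex `"M"` or `"F"`.
#' @param fixture A growth fixture (see [read_growth_fixture()]).
#' @param n Number of draws.
#' @return Numeric vector of weights, kg, all within `[P5, P95]`.
#' @export
sample_weight <- function(age, sex, fixture = read_growth_fixture(), n = 1L) {
  row <- fixture[fixture$sex == sex & fixture$age_years == age, , drop = FALSE]
  if (nrow(row) != 1L)
    stop(sprintf("no unique fixture row for sex %s, age %g y", sex, age))
  sd <- (row$p95_kg - row$p5_kg) / (2 * stats::qnorm(0.95))
  rtrunc_norm(n, row$p50_kg, sd, row$p5_kg, row$p95_kg)
}

#' Virtual cohort specification
#'
#' @param age_bands Data frame with columns `label`, `age_min`, `age_max`
#'   (years) and `n`.  Default: the four pediatric bands used for the
#'   bodyweight cut-off analysis (1 to <2 y n=1002, 2 to <6 y n=1000,
#'   6 to <12 y n=1008, 12 to <18 y n=1008) plus 1000 adults.
#' @param sex_split Fraction male per cell grid, default 0.5.
#' @param adult_weight Adult weight distribution: list with `mean`, `sd`,
#'   `lower`, `upper` in kg (default: moments of the adult study population,
#'   75.9 (20.1) kg truncated to [38, 129]).
#' @param fixture Growth-percentile fixture for pediatric weights.
#' @param scale Multiplies every band size (rounded, min 1); `scale = 0.1`
#'   gives a ten-percent cohort for quick runs.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(age_bands = default_age_bands(),
                        sex_split = 0.5,
                        adult_weight = list(mean = 75.9, sd = 20.1,
                                            lower = 38, upper = 129),
                        fixture = read_growth_fixture(),
                        scale = 1) {
  stopifnot(is.data.frame(age_bands),
            all(c("label", "age_min", "age_max", "n") %in% names(age_bands)),
            all(age_bands$n > 0), sex_split >= 0, sex_split <= 1,
            adult_weight$lower < adult_weight$upper)
  if (scale != 1) age_bands$n <- pmax(1L, as.integer(round(age_bands$n * scale)))
  structure(list(age_bands = age_bands, sex_split = sex_split,
                 adult_weight = adult_weight, fixture = fixture),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_age_bands <- function() {
  data.frame(label = c("1 to <2 y", "2 to <6 y", "6 to <12 y", "12 to <18 y",
                       ">=18 y"),
             age_min = c(1, 2, 6, 12, 18),
             age_max = c(2, 6, 12, 18, NA),
             n = c(1002L, 1000L, 1008L, 1008L, 1000L))
}

# staggered age grid for one band, matching the fixture's resolution
band_age_grid <- function(age_min, age_max) {
  if (age_min < 2) c(1, 1.5) else seq(age_min, age_max - 1)
}

#' Build a virtual cohort
#'
#' Generates virtual subjects for each age band.  Within a band, ages are
#' staggered on an even grid crossed with sex, and band sizes are honored
#' exactly (cell sizes as even as possible).  Pediatric weights are sampled
#' per (age, sex) from the growth fixture's truncated normal; adult weights
#' from the spec's adult truncated normal.  Each subject receives
#' IIV-realized individual parameters.
#'
#' @param spec A [cohort_spec].
#' @param pop A [pop_params] object.
#' @param seed Integer seed; the build is fully reproducible under it.
#' @return An object of class `virtual_cohort`: a data frame with one row per
#'   subject (`subject_id`, `band`, `age`, `sex`, `wt`, `eta_*` columns).
#' @export
build_cohorts <- function(spec = cohort_spec(), pop = pop_params(),
                          seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(pop, "pop_params"))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  sid <- 0L
  for (b in seq_len(nrow(spec$age_bands))) {
    band <- spec$age_bands[b, ]
    adult <- is.na(band$age_max) || band$age_min >= 18
    ages <- if (adult) NA_real_ else band_age_grid(band$age_min, band$age_max)
    cells <- expand.grid(age = ages, sex = c("M", "F"),
                         stringsAsFactors = FALSE)
    # even split with remainder spread over the first cells
    base <- band$n %/% nrow(cells)
    extra <- band$n %% nrow(cells)
    cells$n <- base + (seq_len(nrow(cells)) <= extra)
    # honor sex_split when not 0.5 by reweighting whole cells
    if (spec$sex_split != 0.5) {
      nm <- round(band$n * spec$sex_split)
      m_cells <- cells$sex == "M"
      cells$n[m_cells] <- even_split(nm, sum(m_cells))
      cells$n[!m_cells] <- even_split(band$n - nm, sum(!m_cells))
    }
    cells <- cells[cells$n > 0L, , drop = FALSE]
    for (k in seq_len(nrow(cells))) {
      nk <- cells$n[k]
      wt <- if (adult)
        rtrunc_norm(nk, spec$adult_weight$mean, spec$adult_weight$sd,
                    spec$adult_weight$lower, spec$adult_weight$upper)
      else
        sample_weight(cells$age[k], cells$sex[k], spec$fixture, n = nk)
      eta <- matrix(stats::rnorm(5L * nk, 0, rep(sqrt(pop$omega2), each = nk)),
                    nrow = nk)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid + seq_len(nk), band = band$label,
        age = cells$age[k], sex = cells$sex[k], wt = wt,
        eta_cl = eta[, 1L], eta_v1 = eta[, 2L], eta_vmax = eta[, 3L],
        eta_km = eta[, 4L], eta_q_pc = eta[, 5L])
      sid <- sid + nk
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("virtual_cohort", "data.frame"), pop = pop)
}

even_split <- function(n, k) {
  base <- n %/% k
  base + (seq_len(k) <= n %% k)
}

#' Run a bodyweight cut-off dosing scenario
#'
#' Assigns 40 mg/kg to pediatric subjects below the weight cut-off and
#' 20 mg/kg to pediatric subjects at or above it (the `>=` rule) and to all
#' adults, simulates every subject's single-dose concentration profile over
#' 336 h (grid 0.1 h) with the stepped infusion, and summarizes Cmax and
#' AUC_2W per band.
#'
#' @param cohort A `virtual_cohort` from [build_cohorts()].
#' @param cutoff Bodyweight cut-off in kg (scan values of interest: 25, 30,
#'   35, 40).  `cutoff = 0` doses every pediatric subject at the adult level.
#' @param pop A [pop_params] object.
#' @param dose_low,dose_high Doses (mg/kg) at/above and below the cut-off.
#' @param dt Simulation output grid, h.
#' @param horizon Simulation horizon, h.
#' @return An object of class `scenario_result`: list with `cutoff`,
#'   `exposures` (per-subject data frame with `cmax`, `auc_2w`,
#'   `assigned_dose`) and `summary` (per-band 10/25/50/75/90 percentiles).
#' @export
run_cutoff_scenario <- function(cohort, cutoff, pop = attr(cohort, "pop"),
                                dose_low = 20, dose_high = 40,
                                dt = 0.1, horizon = 336) {
  stopifnot(inherits(cohort, "virtual_cohort"))
  adult <- grepl("^>=18", cohort$band) | (!is.na(cohort$age) & cohort$age >= 18)
  dose <- ifelse(!adult & cohort$wt < cutoff, dose_high, dose_low)
  n <- nrow(cohort)
  cmax <- numeric(n); auc <- numeric(n)
  eta_m <- as.matrix(cohort[, paste0("eta_", eta_names)])
  for (i in seq_len(n)) {
    ind <- realize_individual(pop, cohort$wt[i], eta = eta_m[i, ],
                              subject_id = cohort$subject_id[i])
    prof <- simulate_profile(ind, infusion_schedule(dose[i], cohort$wt[i]),
                             horizon = horizon, dt = dt)
    ex <- compute_exposure(prof, interval = c(0, horizon))
    cmax[i] <- ex$cmax; auc[i] <- ex$auc_2w
  }
  exposures <- data.frame(subject_id = cohort$subject_id, band = cohort$band,
                          age = cohort$age, sex = cohort$sex, wt = cohort$wt,
                          assigned_dose = dose, cmax = cmax, auc_2w = auc)
  structure(list(cutoff = cutoff, exposures = exposures,
                 summary = summarize_exposures(exposures)),
            class = "scenario_result")
}

summarize_exposures <- function(exposures) {
  qs <- c(0.10, 0.25, 0.50, 0.75, 0.90)
  out <- lapply(split(exposures, exposures$band), function(d) {
    data.frame(band = d$band[1L], n = nrow(d),
               metric = rep(c("cmax", "auc_2w"), each = length(qs)),
               percentile = rep(100 * qs, 2L),
               value = c(stats::quantile(d$cmax, qs, names = FALSE),
                         stats::quantile(d$auc_2w, qs, names = FALSE)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Scan bodyweight cut-offs
#'
#' Runs [run_cutoff_scenario()] for each cut-off and collects the per-band
#' exposure summaries for comparison against the adult reference band.
#'
#' @param cohort A `virtual_cohort`.
#' @param cutoffs Numeric vector of cut-offs, kg. Default `c(25, 30, 35, 40)`.
#' @param ... Passed to [run_cutoff_scenario()].
#' @return A list of `scenario_result`, named by cut-off.
#' @export
cutoff_scan <- function(cohort, cutoffs = c(25, 30, 35, 40), ...) {
  stats::setNames(lapply(cutoffs, function(co)
    run_cutoff_scenario(cohort, co, ...)), paste0("cutoff_", cutoffs))
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Cut-off scenario: %g kg (40 mg/kg below, 20 mg/kg at/above)\n",
              x$cutoff))
  med <- x$summary[x$summary$percentile == 50 & x$summary$metric == "auc_2w", ]
  for (i in seq_len(nrow(med)))
    cat(sprintf("  %-12s n=%4d  median AUC_2W %.0f ug.h/mL\n",
                med$band[i], med$n[i], med$value[i]))
  invisible(x)
}

#' @export
print.virtual_cohort <- function(x, ...) {
  cat(sprintf("Virtual cohort: %d subjects\n", nrow(x)))
  tb <- table(x$band)
  for (nm in names(tb)) cat(sprintf("  %-12s n=%d\n", nm, tb[[nm]]))
  invisible(x)
}

#' @export
summary.virtual_cohort <- function(object, ...) {
  do.call(rbind, lapply(split(object, object$band), function(d)
    data.frame(band = d$band[1L], n = nrow(d),
               wt_min = min(d$wt), wt_median = stats::median(d$wt),
               wt_max = max(d$wt))))
}
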