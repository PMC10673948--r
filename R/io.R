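#' Read a longitudinal PK dataset (NONMEM-convention CSV)
#'
#' Mandatory columns: `ID`, `TIME` (h since first dose), `AMT` (mg), `RATE`
#' (mg/h), `DV` (ug/mL), `EVID` (0 observation, 1 dose), `MDV`.  Optional:
#' `BLQ` (below-limit flag), `WT` (kg at record time), `AGE`, `SEX`, and any
#' further covariate columns, which are carried through untouched.  Infusions
#' are encoded through `RATE`; the infusion duration is `AMT / RATE`.
#'
#' Validation enforces: times non-decreasing within subject; dose records
#' carry positive `AMT` and `RATE`; observation records carry `DV`; every
#' subject has at least one dose; a warning is issued for quantified
#' observations below the limit of quantitation (`lloq`, default the assay's
#' 0.0125 ug/mL) that are not flagged `BLQ`.
#'
#' @param path CSV path.
#' @param lloq Lower limit of quantitation, ug/mL.
#' @return A data frame of class `pkdata` (attribute `lloq` attached).
#' @export
read_pkdata <- function(path, lloq = 0.0125) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_pkdata(d, lloq = lloq)
}

#' @rdname read_pkdata
#' @param d A data frame with the columns above.
#' @export
as_pkdata <- function(d, lloq = 0.0125) {
  need <- c("ID", "TIME", "AMT", "RATE", "DV", "EVID", "MDV")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("dataset is missing mandatory columns: ", paste(miss, collapse = ", "))
  if (!"BLQ" %in% names(d)) d$BLQ <- 0L
  for (id in unique(d$ID)) {
    rows <- d[d$ID == id, ]
    if (is.unsorted(rows$TIME))
      stop("non-monotone TIME within subject ", id)
    if (!any(rows$EVID == 1L))
      stop("subject ", id, " has no dose record (orphan observations)")
    bad <- rows$EVID == 1L & (is.na(rows$AMT) | rows$AMT <= 0 |
                                is.na(rows$RATE) | rows$RATE <= 0)
    if (any(bad))
      stop("subject ", id, ": dose records must carry positive AMT and RATE")
  }
  obs <- d$EVID == 0L & d$MDV == 0L
  low <- obs & !is.na(d$DV) & d$DV < lloq & d$BLQ == 0L
  if (any(low))
    warning(sum(low), " observation(s) below the LLOQ (", lloq,
            " ug/mL) are not flagged BLQ")
  structure(d, class = c("pkdata", "data.frame"), lloq = lloq)
}

#' Write a PK dataset to CSV
#'
#' Full double precision; round-trips losslessly through [read_pkdata()].
#'
#' @param data A `pkdata` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pkdata <- function(data, path) {
  df <- as.data.frame(data)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# split a pkdata into per-subject design lists used by estimation/VPC:
# doses as infusion_schedule objects, observation times/values, LOCF weight
subject_designs <- function(data) {
  stopifnot(inherits(data, "pkdata"))
  lloq <- attr(data, "lloq")
  lapply(split(as.data.frame(data), data$ID), function(d) {
    dose_rows <- d[d$EVID == 1L, , drop = FALSE]
    doses <- lapply(seq_len(nrow(dose_rows)), function(j) {
      dur <- dose_rows$AMT[j] / dose_rows$RATE[j]
      structure(list(segments = data.frame(start = dose_rows$TIME[j],
                                           rate = dose_rows$RATE[j],
                                           duration = dur),
                     total_dose = dose_rows$AMT[j], total_duration = dur,
                     dose_per_kg = NA_real_,
                     wt = if ("WT" %in% names(d)) dose_rows$WT[j] else NA_real_,
                     start = dose_rows$TIME[j]),
                class = "infusion_schedule")
    })
    obs <- d[d$EVID == 0L & d$MDV == 0L, , drop = FALSE]
    wt_traj <- if ("WT" %in% names(d) && !anyNA(d$WT))
      weight_trajectory(d$TIME, d$WT)
    else NULL
    list(id = d$ID[1L], doses = doses,
         obs_time = obs$TIME, obs_dv = obs$DV,
         obs_blq = obs$BLQ == 1L, wt_traj = wt_traj,
         covariates = d[1L, setdiff(names(d),
             c("ID", "TIME", "AMT", "RATE", "DV", "EVID", "MDV", "BLQ")),
             drop = FALSE],
         lloq = lloq)
  })
}

#' Time after end of most recent infusion
#'
#' Derives TAD (the visual-predictive-check time axis) for every record:
#' time since the end of the latest infusion that finished at or before the
#' record's time (time since start of first dose before any infusion ends).
#'
#' @param data A `pkdata` data frame.
#' @return Numeric vector of TAD values, h, aligned with `data` rows.
#' @export
tad <- function(data) {
  stopifnot(inherits(data, "pkdata"))
  out <- numeric(nrow(data))
  for (id in unique(data$ID)) {
    sel <- data$ID == id
    d <- data[sel, ]
    ends <- d$TIME[d$EVID == 1L] + d$AMT[d$EVID == 1L] / d$RATE[d$EVID == 1L]
    ends <- sort(ends)
    idx <- findInterval(d$TIME, ends)
    out[sel] <- ifelse(idx == 0L, d$TIME, d$TIME - ends[pmax(idx, 1L)])
  }
  out
}
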