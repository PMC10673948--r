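#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("Population PK fit (%s): %d subjects, %d observations\n",
              x$method, x$n_subjects, x$n_obs))
  cat(sprintf("  OFV %.3f  (%s)\n", x$ofv,
              if (x$converged) "converged" else "NOT converged"))
  cat("  estimated:", paste(sprintf("%s = %.4g", x$free,
                                    unlist(x$estimates[x$free])),
                            collapse = ", "), "\n")
  if (length(x$betas))
    cat("  covariate effects:",
        paste(sprintf("%s = %.4g", names(x$betas), x$betas),
              collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.pk_fit <- function(object, ...) {
  c(stats::setNames(unlist(object$estimates[object$free]), object$free),
    object$betas)
}

#' @export
logLik.pk_fit <- function(object, ...) {
  structure(-object$ofv / 2, df = length(object$free) + length(object$betas),
            nobs = object$n_obs, class = "logLik")
}

#' @export
summary.pk_fit <- function(object, ...) {
  est <- object$estimates
  tab <- data.frame(
    parameter = c("cl", "v1", "vmax", "km", "q_pc"),
    estimate = unlist(est[c("cl", "v1", "vmax", "km", "q_pc")]),
    estimated = c("cl", "v1", "vmax", "km", "q_pc") %in% object$free)
  iiv <- data.frame(parameter = eta_names, omega2 = as.numeric(est$omega2),
                    cv_pct = omega2_to_cv(as.numeric(est$omega2)),
                    eta_shrinkage_pct = 100 * (1 -
                      apply(object$eta_hats, 2, stats::sd) /
                        sqrt(pmax(est$omega2, 1e-12))))
  out <- list(fit = object, fixed_effects = tab, iiv = iiv,
              sigma2 = est$sigma2, betas = object$betas)
  class(out) <- "summary.pk_fit"
  out
}

#' @export
print.summary.pk_fit <- function(x, ...) {
  print(x$fit)
  cat("\nFixed effects:\n")
  print(x$fixed_effects, row.names = FALSE, digits = 4)
  cat("\nInter-individual variability (MAP eta spread vs omega):\n")
  print(x$iiv, row.names = FALSE, digits = 3)
  cat(sprintf("\nResidual: sigma2 %.4g (%.1f%% CV, proportional)\n",
              x$sigma2, sigma2_to_cv(x$sigma2)))
  invisible(x)
}

#' Predictions from a fitted population model
#'
#' @param object A `pk_fit`.
#' @param newdata Optional `pkdata`; defaults to the fitted dataset.
#' @param type `"population"` (eta = 0; PRED) or `"individual"` (MAP eta;
#'   IPRED, only for the fitted dataset).
#' @param ... Unused.
#' @return Data frame `ID`, `TIME`, `DV`, `BLQ`, `pred` over quantified and
#'   BLQ observation records.
#' @export
predict.pk_fit <- function(object, newdata = NULL,
                           type = c("population", "individual"), ...) {
  type <- match.arg(type)
  data <- if (is.null(newdata)) object$data else newdata
  if (is.null(data)) stop("fit carries no data; supply 'newdata'")
  designs <- subject_designs(data)
  if (type == "individual" && !is.null(newdata))
    stop("individual predictions are only defined for the fitted subjects")
  out <- lapply(seq_along(designs), function(i) {
    des <- designs[[i]]
    eta <- if (type == "individual") object$eta_hats[i, ] else rep(0, 5L)
    f <- predict_conc_mult(object$estimates, eta, des)
    data.frame(ID = des$id, TIME = des$obs_time, DV = des$obs_dv,
               BLQ = as.integer(des$obs_blq), pred = f)
  })
  do.call(rbind, out)
}

#' Residuals of a fitted population model
#'
#' Individual weighted residuals `IWRES = (DV - IPRED)/(sigma IPRED)` (the
#' package's substitute for conditional weighted residuals) or first-order
#' population residuals `(DV - PRED)/(sigma PRED)`.
#'
#' @param object A `pk_fit`.
#' @param type `"iwres"` or `"population"`.
#' @param ... Unused.
#' @return Data frame with `ID`, `TIME` and the residual column.
#' @export
residuals.pk_fit <- function(object, type = c("iwres", "population"), ...) {
  type <- match.arg(type)
  p <- predict.pk_fit(object,
                      type = if (type == "iwres") "individual"
                             else "population")
  keep <- p$BLQ == 0L
  p <- p[keep, ]
  s <- sqrt(object$estimates$sigma2)
  data.frame(ID = p$ID, TIME = p$TIME,
             res = (p$DV - p$pred) / (s * p$pred))
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws new inter-individual and residual variability on the fitted
#' dataset's design (same doses, times, weights) -- the building block of
#' the visual predictive check.
#'
#' @param object A `pk_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List of `nsim` data frames (`ID`, `TIME`, `DV`).
#' @export
simulate.pk_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  designs <- subject_designs(object$data)
  pop <- object$estimates
  lapply(seq_len(nsim), function(r) {
    do.call(rbind, lapply(designs, function(des) {
      eta <- stats::rnorm(5L, 0, sqrt(pop$omega2))
      f <- predict_conc_mult(pop, eta, des)
      eps <- stats::rnorm(length(f), 0, sqrt(pop$sigma2))
      data.frame(ID = des$id, TIME = des$obs_time, DV = f * (1 + eps))
    }))
  })
}

#' Goodness-of-fit plot for a fitted model
#'
#' Observed versus population and individual predictions on the log scale
#' with the identity line.
#'
#' @param x A `pk_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pk_fit <- function(x, ...) {
  pp <- predict.pk_fit(x, type = "population")
  pi <- predict.pk_fit(x, type = "individual")
  keep <- pp$BLQ == 0L & pp$DV > 0 & pp$pred > 0 & pi$pred > 0
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (d in list(list(p = pp, lab = "PRED"), list(p = pi, lab = "IPRED"))) {
    graphics::plot(d$p$pred[keep], d$p$DV[keep], log = "xy",
                   xlab = paste(d$lab, "(ug/mL)"),
                   ylab = "Observed (ug/mL)", ...)
    graphics::abline(0, 1, col = "firebrick")
  }
  invisible(x)
}
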