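# proportional-error Gaussian -2 log-likelihood for one subject's
# quantified observations: sum_j [ ln(2 pi sigma2 f_j^2) + (y_j - f_j)^2 /
# (sigma2 f_j^2) ]
prop_neg2ll <- function(y, f, sigma2) {
  if (any(f <= 0))
    stop("model prediction <= 0 at an observation time; the proportional ",
         "error model is undefined there")
  v <- sigma2 * f^2
  sum(log(2 * pi * v) + (y - f)^2 / v)
}

#' Individual -2 log-likelihood under the proportional error model
#'
#' Simulates the subject's predictions at the quantified observation times
#' (observations flagged below the limit of quantitation are excluded) and
#' evaluates the Gaussian -2 log-likelihood with variance `sigma2 * f^2`.
#'
#' @param ind An `ind_params` object.
#' @param data The subject's records: a `pkdata` data frame containing a
#'   single subject.
#' @param sigma2 Proportional residual variance.
#' @return The -2 log-likelihood contribution (dimensionless).
#' @export
neg2ll_individual <- function(ind, data, sigma2) {
  stopifnot(inherits(ind, "ind_params"))
  des <- one_subject_design(data)
  keep <- !des$obs_blq
  if (!any(keep)) return(0)
  tt <- des$obs_time[keep]
  segs <- pk_segments(ind, des$doses, max(tt) + 1e-6)
  ut <- sort(unique(tt))
  sim <- integrate_segments(segs, ut, rtol = 1e-7, atol = 1e-7)
  f <- (sim$a[, 1L] / sim$v1)[match(tt, sim$time)]
  prop_neg2ll(des$obs_dv[keep], f, sigma2)
}

one_subject_design <- function(data) {
  if (is.list(data) && !is.data.frame(data) && !is.null(data$obs_time))
    return(data)
  stopifnot(inherits(data, "pkdata"))
  des <- subject_designs(data)
  if (length(des) != 1L) stop("'data' must contain exactly one subject")
  des[[1L]]
}

# MAP objective: -2 log posterior kernel for eta given a subject design.
# Outside +/- 6 prior SDs (physiologically absurd, needlessly stiff ODEs)
# the objective continues as a steep quadratic in the excess, keeping it
# smooth for line searches.
map_objective <- function(eta, des, pop, omega_inv, pop_mult = NULL) {
  cap <- pmin(6 / sqrt(pmax(diag(omega_inv), 1e-12)), 4.6)
  pen <- 0
  if (any(abs(eta) > cap)) {
    pen <- 1e4 * sum(pmax(abs(eta) - cap, 0)^2)
    eta <- pmin(pmax(eta, -cap), cap)
  }
  keep <- !des$obs_blq
  f <- try(predict_conc_mult(pop, eta, des, pop_mult), silent = TRUE)
  if (inherits(f, "try-error") || any(!is.finite(f)) || any(f[keep] <= 0))
    return(1e10)
  prop_neg2ll(des$obs_dv[keep], f[keep], pop$sigma2) +
    drop(eta %*% omega_inv %*% eta) + pen
}

# gradient of map_objective via prediction sensitivities (finite differences
# on f, chain rule on the proportional-error deviance)
map_gradient <- function(eta, des, pop, omega_inv, pop_mult = NULL,
                         h = 1e-5) {
  cap <- pmin(6 / sqrt(pmax(diag(omega_inv), 1e-12)), 4.6)
  dpen <- 2e4 * sign(eta) * pmax(abs(eta) - cap, 0)
  eta_c <- pmin(pmax(eta, -cap), cap)
  g <- tryCatch({
    keep <- !des$obs_blq
    f0 <- predict_conc_mult(pop, eta_c, des, pop_mult)[keep]
    if (any(!is.finite(f0)) || any(f0 <= 0)) stop("invalid prediction")
    y <- des$obs_dv[keep]
    s2 <- pop$sigma2
    J <- vapply(seq_along(eta), function(k) {
      ek <- replace(eta_c, k, eta_c[k] + h)
      (predict_conc_mult(pop, ek, des, pop_mult)[keep] - f0) / h
    }, numeric(length(f0)))
    dldf <- 2 / f0 - 2 * (y - f0) / (s2 * f0^2) -
      2 * (y - f0)^2 / (s2 * f0^3)
    as.numeric(crossprod(J, dldf)) + 2 * as.numeric(omega_inv %*% eta_c) +
      dpen
  }, error = function(e) NULL)
  if (!is.null(g) && all(is.finite(g))) return(g)
  # integration failed along this direction: fall back to a guarded
  # finite-difference gradient of the (failure-capped) objective
  g0 <- map_objective(eta, des, pop, omega_inv, pop_mult)
  vapply(seq_along(eta), function(k) {
    (map_objective(replace(eta, k, eta[k] + 1e-4), des, pop, omega_inv,
                   pop_mult) - g0) / 1e-4
  }, 0)
}

# inner MAP solve: BFGS with the sensitivity gradient
map_solve <- function(start, des, pop, omega_inv, pop_mult = NULL,
                      maxit = 100) {
  stats::optim(unname(start), map_objective, gr = map_gradient, des = des,
               pop = pop, omega_inv = omega_inv, pop_mult = pop_mult,
               method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-9))
}

# prediction at the subject's quantified times with optional per-subject
# multiplicative covariate effects on the thetas
predict_conc_mult <- function(pop, eta, des, pop_mult = NULL) {
  p <- pop
  if (!is.null(pop_mult))
    for (nm in names(pop_mult)) p[[nm]] <- p[[nm]] * pop_mult[[nm]]
  wt <- if (!is.null(des$wt_traj)) des$wt_traj else pop$wt_ref
  tt <- des$obs_time
  f <- predict_conc(p, eta, des$doses, wt, tt)
  f
}

#' Maximum a posteriori (empirical Bayes) estimate of a subject's random
#' effects
#'
#' Minimizes the penalized deviance
#' `neg2ll_individual + eta' Omega^-1 eta` over the 5-vector of log-scale
#' random effects.  Optimization starts from `eta = 0` with one seeded
#' random restart; the better optimum is kept.  A subject without quantified
#' observations returns the prior mode `eta = 0`.
#'
#' @param data One subject's records (`pkdata` with a single ID, or an
#'   internal subject-design list).
#' @param pop A [pop_params] object (supplies `omega2` and `sigma2`).
#' @param start Optional starting value (warm start).
#' @param restarts Number of random restarts (default 1).
#' @param seed Optional seed for the restarts.
#' @return Named eta 5-vector with attributes `objective` and `converged`.
#' @export
map_estimate <- function(data, pop, start = NULL, restarts = 1L,
                         seed = NULL) {
  des <- one_subject_design(data)
  omega2 <- pmax(pop$omega2, 1e-10)
  omega_inv <- diag(1 / omega2, 5L)
  if (!any(!des$obs_blq)) {
    eta <- stats::setNames(rep(0, 5L), eta_names)
    attr(eta, "objective") <- 0; attr(eta, "converged") <- TRUE
    return(eta)
  }
  if (!is.null(seed)) set.seed(seed)
  starts <- list(if (is.null(start)) rep(0, 5L) else as.numeric(start))
  for (r in seq_len(restarts))
    starts[[r + 1L]] <- stats::rnorm(5L, 0, sqrt(omega2) / 2)
  best <- NULL
  for (s0 in starts) {
    fit <- map_solve(s0, des, pop, omega_inv, maxit = 200)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  eta <- stats::setNames(best$par, eta_names)
  attr(eta, "objective") <- best$value
  attr(eta, "converged") <- best$convergence == 0L
  eta
}

# Laplace per-subject OFV contribution around the MAP eta.  The curvature
# of the -2 log joint is approximated by the Gauss-Newton form
# 2 J' V^-1 J + 2 Omega^-1 built from the sensitivities J = df/deta
# (finite differences, one extra model evaluation per random effect), the
# standard approximation in conditional-estimation engines.
laplace_ofv_i <- function(eta_hat, des, pop, omega_inv, pop_mult = NULL,
                          h = 1e-4) {
  keep <- !des$obs_blq
  f0 <- predict_conc_mult(pop, eta_hat, des, pop_mult)[keep]
  if (any(f0 <= 0) || any(!is.finite(f0))) return(1e10)
  y <- des$obs_dv[keep]
  g0 <- prop_neg2ll(y, f0, pop$sigma2) +
    drop(eta_hat %*% omega_inv %*% eta_hat)
  k <- length(eta_hat)
  J <- matrix(0, length(f0), k)
  for (j in seq_len(k)) {
    ej <- replace(eta_hat, j, eta_hat[j] + h)
    J[, j] <- (predict_conc_mult(pop, ej, des, pop_mult)[keep] - f0) / h
  }
  V <- pop$sigma2 * f0^2
  H <- 2 * crossprod(J, J / V) + 2 * omega_inv
  ld <- determinant(H / 2, logarithm = TRUE)
  if (ld$sign <= 0) return(1e10)
  g0 + as.numeric(ld$modulus) - k * log(2 * pi) +
    sum(log(2 * pi * pmax(1 / diag(omega_inv), 1e-300)))
}

#' Likelihood-ratio threshold for covariate selection
#'
#' Chi-square quantile at level `1 - alpha` with `df` degrees of freedom:
#' the drop in objective function value (-2 log-likelihood) a nested model
#' must achieve to be significant.  The stepwise procedure uses alpha 0.05
#' forward (3.84 for 1 df) and 0.001 backward (10.83 for 1 df).
#'
#' @param alpha Significance level, in (0, 1).
#' @param df Degrees of freedom added by the candidate, >= 1.
#' @return The OFV-drop threshold.
#' @export
lrt_threshold <- function(alpha, df = 1L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("invalid 'alpha'")
  if (df < 1) stop("'df' must be >= 1")
  stats::qchisq(1 - alpha, df)
}

#' Covariate candidate for stepwise selection
#'
#' Continuous covariates enter as a power on the median-normalized value,
#' `theta * (x / ref)^beta` (mirroring the bodyweight convention);
#' categorical covariates as a proportional shift `theta * (1 + beta * I)`.
#'
#' @param name Covariate column name in the dataset.
#' @param param Target structural parameter (`"cl"`, `"v1"`, `"vmax"`,
#'   `"km"` or `"q_pc"`).
#' @param form `"power"` (continuous) or `"proportional"` (categorical/0-1).
#' @param ref Normalization constant for `"power"`; defaults to the dataset
#'   median at fit time.
#' @return An object of class `covariate_candidate` (df = 1).
#' @export
covariate_candidate <- function(name, param,
                                form = c("power", "proportional"),
                                ref = NULL) {
  form <- match.arg(form)
  stopifnot(param %in% eta_names)
  structure(list(name = name, param = param, form = form, ref = ref, df = 1L),
            class = "covariate_candidate")
}

# multiplicative covariate factor on one subject's theta
cov_multiplier <- function(cand, beta, xval) {
  if (cand$form == "power") (xval / cand$ref)^beta else 1 + beta * xval
}

# per-subject covariate values, encoded jointly across the dataset so that
# categorical levels map consistently (first sorted level = 0)
cov_values <- function(cand, designs) {
  v <- vapply(designs, function(des) {
    x <- des$covariates[[cand$name]]
    if (is.null(x)) stop("covariate '", cand$name, "' not in dataset")
    as.character(x[1L])
  }, "")
  num <- suppressWarnings(as.numeric(v))
  if (anyNA(num)) as.numeric(factor(v, sort(unique(v)))) - 1 else num
}

#' Fit the population model
#'
#' Estimates selected fixed-effect parameters by minimizing an approximate
#' marginal -2 log-likelihood over the dataset.  Methods:
#' \describe{
#'   \item{`laplace`}{Laplace approximation around each subject's MAP eta
#'     (the default): per-subject penalized deviance at the inner optimum
#'     plus the log-determinant curvature correction.  Inner MAP problems are
#'     warm-started across outer iterations.}
#'   \item{`naive-pooled`}{All etas fixed at zero; pure pooled fit.}
#'   \item{`two-stage`}{Single pass: MAP etas under the initial values, then
#'     each free theta is multiplied by `exp(mean(eta_hat))`.  Cheap, used
#'     for resampling-heavy workflows.}
#' }
#' Objective function values are comparable between this package's own fits
#' (same data, same method), not to other estimation engines.
#'
#' @param data A `pkdata` dataset (>= 2 subjects for a population fit).
#' @param init Initial [pop_params]; fixed parameters (`init$fixed`) are
#'   never estimated.
#' @param method Estimation method, see above.
#' @param free Character vector of structural parameters to estimate
#'   (subset of cl, v1, vmax, km, q_pc and the exponents exp_cl, exp_v1,
#'   exp_vmax).
#' @param candidates List of selected [covariate_candidate]s whose
#'   coefficients are estimated jointly with the thetas.
#' @param control List: `maxit` (outer iterations, default 150), `reltol`
#'   (outer relative tolerance, default 1e-5), `restarts` (inner MAP random
#'   restarts, default 0 during the outer search).
#' @param seed Seed for the (deterministic, multi-start) inner strategy.
#' @return An object of class `pk_fit` with `estimates` (a [pop_params]),
#'   `betas` (covariate coefficients), `ofv`, `converged`, `eta_hats`
#'   (subjects x 5 matrix) and bookkeeping fields.  Methods: `print`,
#'   `summary`, `coef`, `logLik`, `predict`, `residuals`, `simulate`,
#'   `plot`.
#' @export
fit_population <- function(data, init = pop_params(),
                           method = c("laplace", "naive-pooled", "two-stage"),
                           free = c("cl", "v1"),
                           candidates = list(),
                           control = list(), seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(data, "pkdata"), inherits(init, "pop_params"))
  designs <- subject_designs(data)
  if (length(designs) < 2L && method != "naive-pooled")
    stop("population fit needs at least 2 subjects")
  bad <- intersect(free, init$fixed)
  if (length(bad))
    stop("cannot estimate fixed parameters: ", paste(bad, collapse = ", "))
  ctl <- modifyList(list(maxit = 150L, reltol = 1e-5, restarts = 0L), control)
  omega2 <- pmax(init$omega2, 1e-10)
  omega_inv <- diag(1 / omega2, 5L)

  # resolve covariate references and per-subject values once
  cand_x <- lapply(candidates, function(cand) {
    x <- cov_values(cand, designs)
    if (cand$form == "power" && is.null(cand$ref)) cand$ref <- stats::median(x)
    list(cand = cand, x = x)
  })

  mult_for <- function(betas, i) {
    if (!length(cand_x)) return(NULL)
    m <- list()
    for (k in seq_along(cand_x)) {
      cand <- cand_x[[k]]$cand
      f <- cov_multiplier(cand, betas[k], cand_x[[k]]$x[i])
      m[[cand$param]] <- if (is.null(m[[cand$param]])) f else m[[cand$param]] * f
    }
    m
  }

  warm <- matrix(0, length(designs), 5L)      # warm-start etas
  n_beta <- length(candidates)

  make_pop <- function(par) {
    p <- init
    for (j in seq_along(free)) p[[free[j]]] <- exp(par[j])
    p
  }

  objective <- function(par) {
    p <- make_pop(par)
    betas <- if (n_beta) par[length(free) + seq_len(n_beta)] else numeric(0)
    total <- 0
    for (i in seq_along(designs)) {
      des <- designs[[i]]
      pm <- mult_for(betas, i)
      if (method == "naive-pooled") {
        total <- total + map_objective(rep(0, 5L), des, p, omega_inv * 0, pm)
      } else {
        opt <- map_solve(warm[i, ], des, p, omega_inv, pm, maxit = 80)
        warm[i, ] <<- opt$par
        total <- total + if (method == "laplace")
          laplace_ofv_i(opt$par, des, p, omega_inv, pm)
        else opt$value
      }
      if (!is.finite(total)) return(1e10)
    }
    total
  }

  set.seed(seed)
  par0 <- c(log(unlist(init[free])), rep(0, n_beta))
  if (length(par0) == 1L) {
    opt <- stats::optim(par0, objective, method = "Brent",
                        lower = par0 - 3, upper = par0 + 3)
    opt$convergence <- 0L
  } else {
    opt <- stats::optim(par0, objective, method = "Nelder-Mead",
                        control = list(maxit = ctl$maxit,
                                       reltol = ctl$reltol))
  }

  est <- make_pop(opt$par)
  betas <- if (n_beta) stats::setNames(
    opt$par[length(free) + seq_len(n_beta)],
    vapply(candidates, function(cc) paste(cc$param, cc$name, sep = "~"), ""))
  else numeric(0)

  # final per-subject MAP at the optimum (with restart for robustness)
  eta_hats <- matrix(0, length(designs), 5L,
                     dimnames = list(names(designs), eta_names))
  if (method != "naive-pooled") {
    final_betas <- if (n_beta) opt$par[length(free) + seq_len(n_beta)]
                   else numeric(0)
    for (i in seq_along(designs)) {
      opt_i <- map_solve(warm[i, ], designs[[i]], est, omega_inv,
                         mult_for(final_betas, i), maxit = 200)
      eta_hats[i, ] <- opt_i$par
    }
  }
  if (method == "two-stage")
    for (nm in intersect(free, eta_names)) {
      est[[nm]] <- est[[nm]] * exp(mean(eta_hats[, match(nm, eta_names)]))
    }

  structure(list(estimates = est, betas = betas, ofv = opt$value,
                 converged = opt$convergence == 0L,
                 eta_hats = eta_hats, method = method, free = free,
                 candidates = candidates, init = init,
                 n_subjects = length(designs),
                 n_obs = sum(vapply(designs,
                                    function(d) sum(!d$obs_blq), 0L)),
                 data = data),
            class = "pk_fit")
}

#' Memoising single-pass two-stage fitter
#'
#' Returns a fitting function (for use with [bootstrap()]) implementing the
#' single-pass two-stage estimator: per-subject MAP random effects under
#' `pop`, then `theta_P * exp(mean(eta_hat_P))` for each free parameter.
#' Because the estimator depends on the data only through per-subject
#' statistics, the MAP step is memoised by (original) subject id, which
#' makes case-resampling bootstraps cheap.
#'
#' @param pop A [pop_params] object (initial values and variances).
#' @param free Structural parameters to update from the mean random effect.
#' @return A function `pkdata -> pk_fit`.
#' @export
two_stage_fitter <- function(pop, free = "cl") {
  cache <- new.env(parent = emptyenv())
  function(data) {
    designs <- subject_designs(data)
    etas <- t(vapply(designs, function(des) {
      src <- des$covariates$SRCID        # original id under case resampling
      key <- paste0("s", if (!is.null(src)) src else des$id)
      if (is.null(cache[[key]]))
        cache[[key]] <- as.numeric(map_estimate(des, pop))
      cache[[key]]
    }, numeric(5L)))
    est <- pop
    for (nm in free)
      est[[nm]] <- est[[nm]] * exp(mean(etas[, match(nm, eta_names)]))
    structure(list(estimates = est, betas = numeric(0), ofv = NA_real_,
                   converged = TRUE, eta_hats = etas, method = "two-stage",
                   free = free, candidates = list(), init = pop,
                   n_subjects = length(designs), n_obs = NA_integer_,
                   data = NULL),
              class = "pk_fit")
  }
}

#' Stepwise covariate selection
#'
#' Greedy forward inclusion followed by backward elimination on the
#' likelihood-ratio scale: at each forward step the candidate with the
#' largest significant OFV drop (threshold `lrt_threshold(forward_alpha,
#' df)`) is added; afterwards each retained candidate is removed unless its
#' deletion raises the OFV by more than the stricter
#' `lrt_threshold(backward_alpha, df)`.
#'
#' @param data A `pkdata` dataset.
#' @param init Initial [pop_params].
#' @param candidates List of [covariate_candidate]s.
#' @param forward_alpha,backward_alpha Significance levels (defaults 0.05
#'   and 0.001).
#' @param ... Passed to [fit_population()] (`method`, `free`, `control`...).
#' @return List with `selected` (candidate list), `final` (the final
#'   `pk_fit`) and `trace` (data frame auditing every tested step with its
#'   OFV change); fit failures are recorded in the trace, not fatal.
#' @export
stepwise_select <- function(data, init = pop_params(), candidates,
                            forward_alpha = 0.05, backward_alpha = 0.001,
                            ...) {
  base <- fit_population(data, init, candidates = list(), ...)
  trace <- data.frame(step = character(0), candidate = character(0),
                      ofv = numeric(0), delta_ofv = numeric(0),
                      action = character(0))
  cand_label <- function(cc) paste(cc$param, cc$name, sep = "~")
  selected <- list()
  remaining <- candidates
  current <- base
  repeat {
    if (!length(remaining)) break
    dofv <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (k in seq_along(remaining)) {
      f <- try(fit_population(data, init,
                              candidates = c(selected, remaining[k]), ...),
               silent = TRUE)
      if (inherits(f, "try-error")) {
        trace <- rbind(trace, data.frame(step = "forward",
                                         candidate = cand_label(remaining[[k]]),
                                         ofv = NA, delta_ofv = NA,
                                         action = "fit failed"))
        next
      }
      fits[[k]] <- f
      dofv[k] <- current$ofv - f$ofv
      trace <- rbind(trace, data.frame(step = "forward",
                                       candidate = cand_label(remaining[[k]]),
                                       ofv = f$ofv, delta_ofv = dofv[k],
                                       action = "tested"))
    }
    thr <- vapply(remaining, function(cc) lrt_threshold(forward_alpha, cc$df),
                  0)
    ok <- which(!is.na(dofv) & dofv > thr)
    if (!length(ok)) break
    pick <- ok[which.max(dofv[ok])]
    trace <- rbind(trace, data.frame(step = "forward",
                                     candidate = cand_label(remaining[[pick]]),
                                     ofv = fits[[pick]]$ofv,
                                     delta_ofv = dofv[pick],
                                     action = "included"))
    selected <- c(selected, remaining[pick])
    current <- fits[[pick]]
    remaining <- remaining[-pick]
  }
  # backward elimination at the stricter threshold
  repeat {
    if (!length(selected)) break
    drop_dofv <- rep(NA_real_, length(selected))
    drop_fits <- vector("list", length(selected))
    for (k in seq_along(selected)) {
      f <- try(fit_population(data, init, candidates = selected[-k], ...),
               silent = TRUE)
      if (inherits(f, "try-error")) next
      drop_fits[[k]] <- f
      drop_dofv[k] <- f$ofv - current$ofv   # penalty for removal
      trace <- rbind(trace, data.frame(step = "backward",
                                       candidate = cand_label(selected[[k]]),
                                       ofv = f$ofv, delta_ofv = drop_dofv[k],
                                       action = "tested"))
    }
    thr <- vapply(selected, function(cc) lrt_threshold(backward_alpha, cc$df),
                  0)
    weak <- which(!is.na(drop_dofv) & drop_dofv < thr)
    if (!length(weak)) break
    out <- weak[which.min(drop_dofv[weak])]
    trace <- rbind(trace, data.frame(step = "backward",
                                     candidate = cand_label(selected[[out]]),
                                     ofv = drop_fits[[out]]$ofv,
                                     delta_ofv = drop_dofv[out],
                                     action = "removed"))
    current <- drop_fits[[out]]
    selected <- selected[-out]
  }
  list(selected = selected, final = current, trace = trace, base = base)
}
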