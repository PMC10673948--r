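test_that("the individual -2 log-likelihood matches direct arithmetic", {
  pop <- pop_params()
  des <- make_subject(pop, eta = rep(0, 5))
  ind <- typical_subject(pop, 75)
  # zero residuals leave only the normalization terms
  n2 <- neg2ll_individual(ind, des, pop$sigma2)
  f <- des$obs_dv
  expect_equal(n2, sum(log(2 * pi * pop$sigma2 * f^2)), tolerance = 1e-6)
  # single observation, f = 1, sigma2 = 1/(2*pi): contribution (y-1)^2 * 2pi
  expect_equal(avalpk:::prop_neg2ll(1.3, 1, 1 / (2 * pi)),
               log(1) + (0.3)^2 * 2 * pi)
  # three handcrafted points, term-by-term spreadsheet evaluation
  y <- c(2.0, 0.8, 5.5); fv <- c(1.9, 1.0, 5.0); s2 <- 0.12
  manual <- sum(log(2 * pi * s2 * fv^2) + (y - fv)^2 / (s2 * fv^2))
  expect_equal(avalpk:::prop_neg2ll(y, fv, s2), manual)
  expect_error(avalpk:::prop_neg2ll(1, -1, 0.1), "undefined")
})

test_that("the likelihood grows monotonically in the residual size", {
  vals <- vapply(c(0, 0.1, 0.3, 0.9), function(d)
    avalpk:::prop_neg2ll(1 + d, 1, 0.12), 0)
  expect_true(all(diff(vals) > 0))
})

test_that("MAP returns the prior mode without observations", {
  pop <- pop_params()
  des <- make_subject(pop, eta = rep(0, 5))
  des$obs_blq <- rep(TRUE, length(des$obs_blq))
  eh <- map_estimate(des, pop)
  expect_equal(as.numeric(eh), rep(0, 5))
})

test_that("MAP inverts noiseless rich data when the prior is weak", {
  pop <- pop_params(sigma2 = 1e-4)
  pop$omega2 <- pop$omega2 * 10       # weak prior
  eta_true <- c(0.3, -0.1, 0.2, -0.2, 0.5)
  des <- make_subject(pop, eta = eta_true,
                      offsets = c(1, 2, 4, 8, 16, 24, 36, 48, 72, 96, 120,
                                  168, 216, 264, 300, 332))
  eh <- map_estimate(des, pop, restarts = 1L, seed = 4)
  # clearance, central volume and the slow return clearance are sharply
  # identified; the Vmax/Km pair trades off along a nearly flat direction
  # under a single-dose design and recovers only coarsely
  expect_equal(as.numeric(eh)[c(1, 2, 5)], eta_true[c(1, 2, 5)],
               tolerance = 2e-2)
  expect_equal(as.numeric(eh), eta_true, tolerance = 0.25)
})

test_that("inflating the prior variance moves MAP toward the ML optimum", {
  base <- pop_params()
  des <- make_subject(base, eta = c(0.25, 0, 0, 0, 0))
  ml <- base
  ml$omega2 <- base$omega2 * 1e6        # effectively pure likelihood
  eta_ml <- as.numeric(map_estimate(des, ml))
  dist <- vapply(c(1, 4, 16), function(k) {
    p <- base
    p$omega2 <- base$omega2 * k
    sqrt(sum((as.numeric(map_estimate(des, p)) - eta_ml)^2))
  }, 0)
  expect_lt(dist[2], dist[1])
  expect_lt(dist[3], dist[2])
})

test_that("MAP is invariant to observation ordering", {
  pop <- pop_params()
  des <- make_subject(pop, eta = c(0.2, 0, -0.1, 0, 0))
  set.seed(1)
  des$obs_dv <- des$obs_dv * (1 + rnorm(length(des$obs_dv), 0, 0.2))
  o <- sample(length(des$obs_time))
  des2 <- des
  des2$obs_time <- des$obs_time[o]
  des2$obs_dv <- des$obs_dv[o]
  des2$obs_blq <- des$obs_blq[o]
  oi <- diag(1 / pop$omega2, 5)
  # the objective itself is permutation-invariant ...
  for (eta in list(rep(0, 5), c(0.2, -0.1, 0.1, 0, 0.3)))
    expect_equal(avalpk:::map_objective(eta, des, pop, oi),
                 avalpk:::map_objective(eta, des2, pop, oi),
                 tolerance = 1e-12)
  # ... and so is the attained optimum (the arg-min may slide along nearly
  # flat directions, the value may not)
  e1 <- map_estimate(des, pop)
  e2 <- map_estimate(des2, pop)
  expect_equal(attr(e1, "objective"), attr(e2, "objective"),
               tolerance = 1e-4)
})

test_that("likelihood-ratio thresholds are the chi-square quantiles", {
  expect_equal(lrt_threshold(0.05, 1), 3.841, tolerance = 1e-3)
  expect_equal(lrt_threshold(0.001, 1), 10.828, tolerance = 1e-3)
  expect_lt(lrt_threshold(0.9999, 1), 1e-4)
  expect_error(lrt_threshold(1.2, 1), "alpha")
  expect_error(lrt_threshold(0.05, 0), "df")
})

test_that("a deterministic one-parameter inverse problem is solved exactly", {
  pop0 <- pop_params(sigma2 = 1e-8)
  pop0$omega2[] <- 1e-12              # no inter-individual variability
  design <- rich_design(n = 3)
  d <- generate_study(design, pop0, seed = 21)
  init <- pop0
  init$cl <- 1.2                      # start away from the generating value
  fit <- fit_population(d, init, method = "naive-pooled", free = "cl")
  expect_equal(coef(fit)[["cl"]], 0.808, tolerance = 1e-3)
})

test_that("modelling the true weight effect lowers the pooled OFV", {
  pop0 <- pop_params(sigma2 = 1e-4)
  pop0$omega2[] <- 1e-12
  # weight-heterogeneous arm so allometry matters
  des <- study_design(list(list(
    label = "mixedwt", n = 8, dose = 20, duration_weeks = 2,
    demographics = list(type = "adult", age_min = 18, age_max = 70,
                        wt_mean = 60, wt_sd = 30, wt_lo = 15, wt_hi = 120),
    sampling = list(weeks = 1, predose = FALSE, eoi = TRUE,
                    offsets_h = c(2, 8, 24, 96, 240)))))
  d <- generate_study(des, pop0, seed = 31)
  with_allo <- fit_population(d, pop0, method = "naive-pooled", free = "cl")
  no_allo <- pop0
  no_allo$exp_cl <- 1e-12; no_allo$exp_v1 <- 1e-12; no_allo$exp_vmax <- 1e-12
  without <- fit_population(d, no_allo, method = "naive-pooled", free = "cl")
  expect_lt(with_allo$ofv, without$ofv)
})

test_that("stepwise selection finds an injected covariate and nothing else", {
  pop0 <- pop_params(sigma2 = 1e-4)
  pop0$omega2[] <- 1e-12
  design <- rich_design(n = 12)
  d <- generate_study(design, pop0, seed = 41)
  # inject a strong sex effect on clearance into the observations:
  # male concentrations correspond to CL multiplied by 1.6
  df <- as.data.frame(d)
  male_ids <- unique(df$ID[df$SEX == "M"])
  expect_gt(length(male_ids), 1)
  pop_m <- pop0; pop_m$cl <- pop0$cl * 1.6
  for (id in male_ids) {
    des_i <- avalpk:::subject_designs(
      avalpk:::as_pkdata(df[df$ID == id, ]))[[1]]
    f <- avalpk:::predict_conc_mult(pop_m, rep(0, 5), des_i)
    df$DV[df$ID == id & df$EVID == 0] <- f
  }
  d2 <- suppressWarnings(as_pkdata(df))
  cand <- list(
    covariate_candidate("SEX", "cl", form = "proportional"),
    covariate_candidate("ADA", "cl", form = "proportional"))
  sel <- stepwise_select(d2, pop0, cand, method = "naive-pooled",
                         free = "cl", control = list(maxit = 120))
  picked <- vapply(sel$selected, function(cc) cc$name, "")
  expect_true("SEX" %in% picked)
  expect_false("ADA" %in% picked)
  expect_true(all(c("step", "candidate", "delta_ofv", "action") %in%
                    names(sel$trace)))
})

test_that("no candidate is selected when none clears the threshold", {
  pop0 <- pop_params(sigma2 = 1e-4)
  pop0$omega2[] <- 1e-12
  d <- generate_study(rich_design(n = 6), pop0, seed = 51)
  sel <- stepwise_select(d, pop0,
                         list(covariate_candidate("ADA", "cl",
                                                  form = "proportional")),
                         method = "naive-pooled", free = "cl",
                         control = list(maxit = 80))
  expect_length(sel$selected, 0)
})

test_that("recovery improves with more subjects (two-stage estimator)", {
  pop <- pop_params()
  err_at <- function(n, seed) {
    d <- generate_study(rich_design(n = n), pop, seed = seed)
    fit <- fit_population(d, pop, method = "two-stage", free = "cl")
    abs(log(coef(fit)[["cl"]] / pop$cl))
  }
  # bias/error shrinks with n in expectation; average a few replicates
  seeds <- c(61, 62, 63)
  small <- mean(vapply(seeds, function(s) err_at(4, s), 0))
  large <- mean(vapply(seeds, function(s) err_at(24, s), 0))
  expect_lt(large, small)
})

test_that("fit methods expose the standard modelling interface", {
  pop <- pop_params()
  d <- generate_study(rich_design(n = 4), pop, seed = 71)
  fit <- fit_population(d, pop, method = "two-stage", free = "cl")
  expect_s3_class(fit, "pk_fit")
  expect_named(coef(fit), "cl")
  expect_output(print(fit), "Population PK fit")
  s <- summary(fit)
  expect_s3_class(s, "summary.pk_fit")
  p <- predict(fit, type = "individual")
  expect_true(all(c("ID", "TIME", "pred") %in% names(p)))
  expect_true(all(p$pred > 0))
  r <- residuals(fit)
  expect_true(is.numeric(r$res))
  sim <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sim, 2L)
  expect_false(isTRUE(all.equal(sim[[1]]$DV, sim[[2]]$DV)))
  ll <- logLik(fit)
  expect_true(is.finite(as.numeric(ll)) || is.na(as.numeric(ll)))
})
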