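test_that("variability conversions reproduce the published CV pairs", {
  expect_equal(omega2_to_cv(0.0907), 30.8, tolerance = 1e-3)
  expect_equal(omega2_to_cv(1.23), 156, tolerance = 5e-3)
  expect_equal(sigma2_to_cv(0.12), 34.6, tolerance = 2e-3)
  expect_equal(omega2_to_cv(0), 0)
  expect_equal(sigma2_to_cv(0), 0)
  expect_equal(sigma2_to_cv(0.04), 20)
  expect_error(omega2_to_cv(-0.1), "non-negative")
})

test_that("conversion curves are monotone with the log-normal above", {
  x <- seq(0.01, 2, by = 0.05)
  expect_true(all(diff(omega2_to_cv(x)) > 0))
  expect_true(all(diff(sigma2_to_cv(x)) > 0))
  expect_true(all(omega2_to_cv(x) >= sigma2_to_cv(x)))
})

test_that("absolute average fold error follows its definition", {
  obs <- c(1, 2, 4, 8)
  expect_equal(aafe(obs, obs), 1)
  expect_equal(aafe(2 * obs, obs), 2)
  expect_equal(aafe(c(2, 0.5, 2, 0.5), c(1, 1, 1, 1)), 2)
  expect_equal(aafe(c(2, 0.5), c(1, 1)), aafe(c(1, 1), c(2, 0.5)))
  expect_error(aafe(c(1, -1), c(1, 1)), "positive")
})

test_that("goodness-of-fit criteria match direct formula evaluation", {
  g0 <- gof_metrics(c(1, 2), c(1, 2), c(1, 2))
  expect_equal(g0$bias_pct, c(0, 0))
  expect_equal(g0$precision_pct, c(0, 0))
  expect_equal(g0$aafe, c(1, 1))
  g1 <- gof_metrics(1.1 * c(1, 5, 20), c(1, 5, 20), c(1, 5, 20))
  expect_equal(g1$bias_pct[1], 10, tolerance = 1e-9)
  expect_equal(g1$precision_pct[1], 10, tolerance = 1e-9)
  set.seed(12)
  obs <- exp(rnorm(100, 1, 0.7))
  pred <- obs * exp(rnorm(100, 0, 0.3))
  ipred <- obs * exp(rnorm(100, 0, 0.1))
  g <- gof_metrics(pred, ipred, obs)
  pe <- (pred - obs) / obs
  expect_equal(g$bias_pct[1], 100 * mean(pe))
  expect_equal(g$precision_pct[1], 100 * sqrt(mean(pe^2)))
  expect_equal(g$mae_pct[1], 100 * mean(abs(pe)))
  expect_equal(g$aafe[1], 10^mean(abs(log10(pred / obs))))
  expect_equal(g$r_log[1], cor(log(pred), log(obs)))
  expect_error(gof_metrics(1:3, 1:3, 1:4), "mismatch")
})

test_that("condition numbers are eigenvalue ratios", {
  expect_equal(condition_number(diag(5)), 1)
  expect_equal(condition_number(diag(c(4, 1))), 4)
  # SPD matrix with known spectrum via an orthogonal rotation
  th <- 0.6
  q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  m <- q %*% diag(c(9, 2)) %*% t(q)
  expect_equal(condition_number(m), 4.5)
  set.seed(5)
  a <- crossprod(matrix(rnorm(25), 5))
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(condition_number(a), max(ev) / min(ev))
  expect_error(condition_number(matrix(1:4, 2)), "symmetric")
})

test_that("VPC bands collapse onto the data when variability vanishes", {
  pop0 <- pop_params(sigma2 = 1e-12)
  pop0$omega2[] <- 1e-14
  d <- generate_study(rich_design(n = 5), pop0, seed = 15)
  v <- vpc(d, pop0, n_reps = 20, bins = 4, seed = 2)
  expect_equal(v$bins$sim_median, v$bins$observed, tolerance = 1e-4)
  expect_equal(v$bins$sim_lo, v$bins$sim_hi, tolerance = 1e-4)
})

test_that("prediction correction is a no-op for identical subjects", {
  pop <- pop_params()
  d <- generate_study(rich_design(n = 1), pop, seed = 16)
  # clone one subject's design so every subject shares dose, weight and
  # sampling times; with one bin per distinct time the correction factor
  # is exactly 1
  df1 <- as.data.frame(d)
  df <- do.call(rbind, lapply(1:6, function(i) {
    x <- df1; x$ID <- i; x
  }))
  d2 <- suppressWarnings(as_pkdata(df))
  ntimes <- length(unique(tad(d2)[d2$EVID == 0]))
  vs <- vpc(d2, pop, n_reps = 30, bins = ntimes, mode = "standard", seed = 3)
  vp <- vpc(d2, pop, n_reps = 30, bins = ntimes, mode = "pc", seed = 3)
  expect_equal(vp$bins$observed, vs$bins$observed, tolerance = 1e-10)
  expect_equal(vp$bins$sim_median, vs$bins$sim_median, tolerance = 1e-10)
})

test_that("VPC orders percentiles within every bin", {
  pop <- pop_params()
  d <- generate_study(rich_design(n = 8), pop, seed = 17)
  v <- vpc(d, pop, n_reps = 40, bins = 5, seed = 4)
  b <- v$bins
  expect_true(all(b$sim_lo <= b$sim_median + 1e-12))
  expect_true(all(b$sim_median <= b$sim_hi + 1e-12))
  for (bin in unique(b$bin)) {
    m <- b$observed[b$bin == bin][order(b$percentile[b$bin == bin])]
    expect_true(!is.unsorted(m))
  }
})

test_that("bootstrap on a single subject is degenerate at the estimate", {
  pop <- pop_params()
  d <- generate_study(rich_design(n = 1), pop, seed = 18)
  bs <- bootstrap(d, two_stage_fitter(pop), n = 5, seed = 1)
  expect_equal(bs$n_converged, 5L)
  expect_equal(bs$table$lower, bs$table$upper, tolerance = 1e-12)
})

test_that("bootstrap resamples preserve the subject count", {
  pop <- pop_params()
  d <- generate_study(rich_design(n = 6), pop, seed = 19)
  counts <- integer(0)
  fn <- function(dd) {
    counts <<- c(counts, length(unique(dd$ID)))
    two_stage_fitter(pop)(dd)
  }
  bs <- bootstrap(d, fn, n = 8, seed = 2)
  expect_true(all(counts == 6L))
  expect_true(all(bs$table$lower <= bs$table$median + 1e-12))
  expect_true(all(bs$table$median <= bs$table$upper + 1e-12))
})

test_that("stratified resampling preserves stratum counts", {
  pop <- pop_params()
  d <- generate_study(rich_design(n = 8), pop, seed = 20)
  df <- as.data.frame(d)
  df$DISEASE <- ifelse(df$ID <= 4, "IOPD", "LOPD")
  d2 <- suppressWarnings(as_pkdata(df))
  strata <- list()
  fn <- function(dd) {
    tb <- table(vapply(split(dd$DISEASE, dd$ID), `[`, "", 1))
    strata[[length(strata) + 1L]] <<- tb
    two_stage_fitter(pop)(dd)
  }
  invisible(bootstrap(d2, fn, n = 5, seed = 3, stratify_by = "DISEASE"))
  for (tb in strata) {
    expect_equal(unname(tb[["IOPD"]]), 4L)
    expect_equal(unname(tb[["LOPD"]]), 4L)
  }
})
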