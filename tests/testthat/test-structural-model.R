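test_that("typical values reduce to the thetas at the reference weight", {
  pop <- pop_params()
  tv <- typical_values(pop, wt = pop$wt_ref)
  expect_equal(tv$tv_cl, pop$cl)
  expect_equal(tv$tv_v1, pop$v1)
  expect_equal(tv$tv_vmax, pop$vmax)
  expect_equal(tv$tv_km, pop$km)
  expect_equal(tv$tv_qpc, pop$q_pc)
})

test_that("typical values at 68.1 kg match the reported typical patient", {
  tv <- typical_values(pop_params(), wt = 68.1)
  expect_equal(tv$tv_cl, 0.783, tolerance = 1e-3)
  expect_equal(tv$tv_v1, 3.29, tolerance = 2e-3)
  expect_equal(tv$tv_vmax, 11.8, tolerance = 1e-2)
})

test_that("allometric scaling is a power law (homogeneity property)", {
  pop <- pop_params()
  for (k in c(0.5, 2, 3.7)) {
    for (w in c(20, 70.5, 110)) {
      expect_equal(typical_values(pop, k * w)$tv_cl,
                   typical_values(pop, w)$tv_cl * k^pop$exp_cl)
      expect_equal(typical_values(pop, k * w)$tv_v1,
                   typical_values(pop, w)$tv_v1 * k^pop$exp_v1)
    }
  }
  # Km and Qpc carry no weight effect
  expect_equal(typical_values(pop, 12)$tv_km, pop$km)
  expect_equal(typical_values(pop, 12)$tv_qpc, pop$q_pc)
  expect_error(typical_values(pop, -5), "positive")
})

test_that("individual parameters are log-normal around the typical values", {
  pop <- pop_params()
  ind0 <- realize_individual(pop, 55, eta = rep(0, 5))
  tv <- typical_values(pop, 55)
  expect_equal(ind0$cl, tv$tv_cl)
  expect_equal(ind0$v1, tv$tv_v1)
  expect_equal(ind0$km, pop$km)
  # eta_cl = ln 2 exactly doubles clearance, touches nothing else
  ind2 <- realize_individual(pop, 55, eta = c(log(2), 0, 0, 0, 0))
  expect_equal(ind2$cl, 2 * ind0$cl)
  expect_equal(ind2$v1, ind0$v1)
  # fixed peripheral parameters are copied unchanged
  expect_equal(ind2$q2, pop$q2)
  expect_equal(ind2$v2, pop$v2)
  expect_error(realize_individual(pop, 55, eta = c(0, 0)), "5-vector")
})

test_that("Monte-Carlo CV of realized clearance matches the log-normal identity", {
  pop <- pop_params()
  set.seed(42)
  eta <- rnorm(1e5, 0, sqrt(pop$omega2[["cl"]]))
  cl <- pop$cl * exp(eta)
  cv <- 100 * sd(cl) / mean(cl)
  expect_equal(cv, 30.8, tolerance = 0.01)    # 30.8% from omega2 = 0.0907
})

test_that("stepped infusion reproduces the published total durations", {
  expect_equal(infusion_schedule(20, 70.5)$total_duration, 3.71,
               tolerance = 0.002)
  expect_equal(infusion_schedule(40, 70.5)$total_duration, 6.57,
               tolerance = 0.002)
  # boundary: the three fixed steps deliver exactly 4.5 mg/kg in 1.5 h
  expect_equal(infusion_schedule(4.5, 50)$total_duration, 1.5)
})

test_that("infusion segments always integrate to the planned dose", {
  for (d in c(0.3, 1.2, 3, 4.5, 5, 20, 40)) {
    for (w in c(9.9, 29.2, 70.5, 129)) {
      sch <- infusion_schedule(d, w)
      expect_equal(sum(sch$segments$rate * sch$segments$duration),
                   d * w, tolerance = 1e-9)
      expect_true(all(sch$segments$rate >= 0))
      # contiguous, non-overlapping segments
      s <- sch$segments
      if (nrow(s) > 1L)
        expect_equal(s$start[-1L], (s$start + s$duration)[-nrow(s)])
    }
  }
  # sub-4.5 mg/kg doses truncate the ladder at the right point:
  # 3 mg/kg = 0.5 + 1.5 mg/kg in the first two steps, then 1 mg/kg at 5
  sch3 <- infusion_schedule(3, 10)
  expect_equal(sch3$total_duration, 0.5 + 0.5 + 1 / 5)
  expect_error(infusion_schedule(-1, 70), "positive")
})

test_that("infusion_rate is the piecewise-constant schedule", {
  sch <- infusion_schedule(20, 70.5)
  expect_equal(infusion_rate(sch, 0.25), 1 * 70.5)
  expect_equal(infusion_rate(sch, 0.75), 3 * 70.5)
  expect_equal(infusion_rate(sch, 1.25), 5 * 70.5)
  expect_equal(infusion_rate(sch, 2), 7 * 70.5)
  expect_equal(infusion_rate(sch, 10), 0)
})

test_that("weight trajectories evaluate LOCF and validate inputs", {
  tr <- weight_trajectory(c(0, 336, 672), c(10, 10.5, 11))
  expect_equal(eval_weight(tr, c(-5, 0, 100, 336, 500, 1e4)),
               c(10, 10, 10, 10.5, 10.5, 11))
  expect_error(weight_trajectory(c(10, 0), c(1, 1)), "non-decreasing")
  expect_error(weight_trajectory(0, -3), "positive")
})

test_that("the ODE right-hand side matches a hand-computed evaluation", {
  ind <- typical_subject()
  # empty system at rest
  expect_equal(pk_rhs(c(0, 0, 0), 0, ind, 0), c(0, 0, 0))
  # half-saturation: A1 = Km*V1 gives exactly -Vmax/2 with CL = Q2 = 0
  ind0 <- ind; ind0$cl <- 0; ind0$q2 <- 1e-300
  d <- pk_rhs(c(ind$km * ind$v1, 0, 0), 0, ind0, 0)
  expect_equal(d[1], -ind$vmax / 2, tolerance = 1e-12)
  # arithmetic oracle: evaluate the three flow equations term by term
  a <- c(10, 5, 1)
  c1 <- a[1] / 3.37; c2 <- a[2] / 296; c3 <- a[3] / 1.31
  exp1 <- 0 - 0.808 * c1 - 12 * c1 / (0.541 + c1) -
    0.254 * c1 + 0.254 * c2 + 0.0157 * c3
  exp2 <- 0.254 * c1 - 0.254 * c2 - 1.87 * c2
  exp3 <- 1.87 * c2 - 0.0157 * c3
  expect_equal(pk_rhs(a, 0, ind, 0), c(exp1, exp2, exp3), tolerance = 1e-12)
  # intercompartmental flows conserve mass: the sum of the equations is
  # input minus the two elimination routes
  for (r in c(0, 150)) {
    d <- pk_rhs(a, 0, ind, r)
    expect_equal(sum(d), r - ind$cl * c1 - ind$vmax * c1 / (ind$km + c1),
                 tolerance = 1e-12)
  }
  expect_error(pk_rhs(c(NA, 0, 0), 0, ind), "finite")
})

test_that("Michaelis-Menten elimination is monotone and bounded by Vmax", {
  ind <- typical_subject()
  conc <- c(0.01, 0.1, 0.5, 1, 5, 50, 500)
  mm <- ind$vmax * conc / (ind$km + conc)
  expect_true(all(diff(mm) > 0))
  expect_true(all(mm < ind$vmax))
})

test_that("parameter files round-trip and ship correct packaged defaults", {
  pop <- read_pop_params(system.file("extdata", "avalglucosidase_poppk.yaml",
                                     package = "avalpk"))
  expect_equal(unclass(pop)[names(unclass(pop_params()))],
               unclass(pop_params())[names(unclass(pop_params()))])
  tmp <- tempfile(fileext = ".yaml")
  custom <- pop_params(cl = 1.1, omega2 = c(cl = 0.2, v1 = 0.1, vmax = 0.3,
                                            km = 0.2, q_pc = 1))
  write_pop_params(custom, tmp)
  back <- read_pop_params(tmp)
  expect_equal(back$cl, 1.1)
  expect_equal(back$omega2, custom$omega2)
})

test_that("parameter validation rejects impossible values", {
  expect_error(pop_params(cl = -1), "positive")
  expect_error(pop_params(km = 0), "positive")
  expect_error(pop_params(sigma2 = 0), "positive")
  expect_error(pop_params(omega2 = c(cl = -0.1, v1 = 0.1, vmax = 0.1,
                                     km = 0.1, q_pc = 0.1)), "non-negative")
})

test_that("the optional renal adjustment reproduces the reported endpoints", {
  # exponent back-derived from the covariate-run clearance span
  expect_equal(renal_cl_adjustment(0.812, 161), 0.812)
  expect_equal(renal_cl_adjustment(0.812, 528), 0.843, tolerance = 1e-3)
  expect_equal(renal_cl_adjustment(0.812, 50.2), 0.781, tolerance = 5e-3)
})

test_that("the fixed-exponent sensitivity variant uses 0.75 / 1", {
  p <- fixed_allometry(pop_params())
  expect_equal(c(p$exp_cl, p$exp_v1, p$exp_vmax), c(0.75, 1, 0.75))
  expect_equal(p$cl, pop_params()$cl)
})
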