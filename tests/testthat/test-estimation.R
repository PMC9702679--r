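# Crude initial rates, the maximum-likelihood fit, and Wald inference.

test_that("crude initial intensities are events over exposure", {
  # every pair stays good over 2 years: no events, all good-exit rates at floor
  ids <- paste0("s", 1:6)
  quiet <- do.call(rbind, lapply(ids, function(i)
    make_panel(i, c(0, 2), c(1, 1))))
  quiet <- rbind(quiet, make_panel("p1", c(0, 2), c(2, 2)))
  init <- crude_initial_intensities(quiet)
  expect_equal(unname(exp(init$logq0[c("good-poor", "good-dead")])),
               c(1e-3, 1e-3))

  # 10 pairs starting good, 20 person-years, 4 deteriorations -> 0.2/yr
  states2 <- c(rep(2, 4), rep(1, 6))
  det <- do.call(rbind, lapply(1:10, function(i)
    make_panel(paste0("d", i), c(0, 2), c(1, states2[i]))))
  det <- rbind(det, make_panel("p1", c(0, 2), c(2, 2)))
  init2 <- crude_initial_intensities(det)
  expect_equal(unname(exp(init2$logq0["good-poor"])), 0.2)

  # doubling every elapsed time halves every crude rate
  det_slow <- det
  det_slow$time <- det_slow$time * 2
  init3 <- crude_initial_intensities(det_slow)
  expect_equal(unname(exp(init3$logq0["good-poor"])), 0.1)

  # a live state never at the start of a pair is rejected by name
  good_only <- do.call(rbind, lapply(1:3, function(i)
    make_panel(paste0("g", i), c(0, 2), c(1, 1))))
  expect_error(crude_initial_intensities(good_only), "poor")
})

test_that("fit with a single covariate pattern matches a direct
           4-parameter baseline fit", {
  cfg <- small_sim_config(n = 500, seed = 21)
  # restrict the generator to the reference profile
  pg <- profile_grid()$profiles
  comp <- setNames(as.numeric(pg$education == "high" &
                                pg$cohort == "1950-1962" &
                                pg$region == "central"), pg$key)
  cfg$composition$F <- comp
  sim <- generate_cohort(cfg, genders = "F")
  fit <- fit_model(sim$panel)

  # covariate columns never vary, so all betas are reported fixed at zero
  expect_true(all(fit$fixed[-(1:4)]))
  expect_true(all(fit$theta[-(1:4)] == 0))

  # direct maximization over the (free) baselines of the same likelihood
  prep <- panelmsm:::prepare_likelihood(sim$panel)
  free_b <- which(!fit$fixed[1:4])
  nll4 <- function(lq) {
    full <- fit$theta
    full[free_b] <- lq
    -panelmsm:::loglik_prepared(full, prep)
  }
  opt <- optim(fit$theta[free_b], nll4, method = "BFGS",
               control = list(reltol = 1e-12))
  expect_equal(unname(fit$theta[free_b]), unname(opt$par), tolerance = 1e-4)
  expect_gte(fit$loglik$value, -opt$value - 1e-6)
})

test_that("the fitted likelihood improves on the crude initial values", {
  sim <- generate_cohort(small_sim_config(n = 400, seed = 22), genders = "M")
  fit <- fit_model(sim$panel)
  expect_true(fit$converged)
  expect_gt(fit$loglik$value, fit$loglik_initial)
  # covariance is symmetric positive semi-definite
  expect_equal(fit$vcov, t(fit$vcov))
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("refitting the same data gives identical estimates", {
  sim <- generate_cohort(small_sim_config(n = 250, seed = 23), genders = "F")
  f1 <- fit_model(sim$panel)
  f2 <- fit_model(sim$panel)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$loglik$value, f2$loglik$value)
})

test_that("hazard ratios exponentiate coefficients with Wald intervals", {
  params <- default_true_params("F")
  # null coefficient with SE 0.1
  p0 <- model_params(params$logq0, matrix(0, 4, 7))
  fit <- fake_fit(p0, vcov = diag(0.1^2, 32))
  hr <- hazard_ratios(fit)
  expect_identical(nrow(hr), 28L)
  expect_true(all(hr$hr == 1))
  expect_equal(hr$ci_low, rep(exp(-qnorm(0.975) * 0.1), 28))
  expect_equal(hr$ci_high, rep(exp(qnorm(0.975) * 0.1), 28))
  expect_equal(round(hr$ci_low[1], 2), 0.82)
  expect_equal(round(hr$ci_high[1], 2), 1.22)

  # log 2 with SE 0.05
  b <- matrix(0, 4, 7); b[1, 1] <- log(2)
  fit2 <- fake_fit(model_params(params$logq0, b), vcov = diag(0.05^2, 32))
  hr2 <- hazard_ratios(fit2)
  row <- hr2[hr2$transition == "good-poor" & hr2$term == "edu_low", ]
  expect_equal(row$hr, 2)
  expect_true(row$p < 1e-10)

  # a non-converged fit is rejected
  bad <- fit; bad$converged <- FALSE
  expect_error(hazard_ratios(bad), "converged")
})

test_that("fit recovers generating parameters on a moderate sample", {
  sim <- generate_cohort(small_sim_config(n = 1500, seed = 24),
                         genders = "F")
  fit <- fit_model(sim$panel)
  expect_true(fit$converged)
  truth <- panelmsm:::pack_params(default_true_params("F"))
  se <- sqrt(diag(fit$vcov))
  z <- abs(fit$theta - truth) / se
  # at n = 1500 nearly all parameters should sit within 3 SE of truth
  expect_gte(mean(z < 3), 0.9)
})
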