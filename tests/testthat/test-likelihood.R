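# Transition probabilities and the panel likelihood, checked against
# closed forms, an ODE integration oracle, and a Padé matrix exponential.

ode_tpm <- function(Q, t) {
  # forward equations dP/dt = P Q, integrated row by row
  deriv <- function(tt, y, parms) list(as.vector(matrix(y, 3, 3) %*% Q))
  y0 <- as.vector(diag(3))
  sol <- deSolve::ode(y0, c(0, t), deriv, parms = NULL,
                      rtol = 1e-12, atol = 1e-12)
  matrix(sol[2, -1], 3, 3)
}

test_that("P(0) is the identity and negative intervals are rejected", {
  Q <- two_state_Q()
  expect_equal(unname(transition_probability_matrix(Q, 0)), diag(3),
               ignore_attr = TRUE)
  expect_error(transition_probability_matrix(Q, -1), "non-negative")
})

test_that("two-live-state reduction matches the closed form", {
  P <- transition_probability_matrix(two_state_Q(), 2)
  expect_equal(P[1, 1], 1 / 3 + (2 / 3) * exp(-0.6), tolerance = 1e-12)
  expect_equal(P[1, 2], 1 - two_state_p11(2), tolerance = 1e-12)
  expect_equal(P[1, 3], 0)
})

test_that("P(t) agrees with forward-ODE integration and Pade expm", {
  set.seed(202)
  for (i in 1:10) {
    Q <- random_Q()
    t <- stats::runif(1, 0.1, 8)
    P <- transition_probability_matrix(Q, t)
    expect_lt(max(abs(P - ode_tpm(Q, t))), 1e-8)
    expect_lt(max(abs(P - as.matrix(Matrix::expm(Q * t)))), 1e-12)
  }
})

test_that("transition matrices are row-stochastic with absorbing death row", {
  set.seed(203)
  for (i in 1:25) {
    P <- transition_probability_matrix(random_Q(), stats::runif(1, 0, 10))
    expect_true(all(P >= 0 & P <= 1))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_equal(unname(P[3, ]), c(0, 0, 1))
  }
})

test_that("Chapman-Kolmogorov holds: P(s+t) = P(s) P(t)", {
  set.seed(204)
  for (i in 1:25) {
    Q <- random_Q()
    s <- stats::runif(1, 0.01, 10); t <- stats::runif(1, 0.01, 10)
    lhs <- transition_probability_matrix(Q, s + t)
    rhs <- transition_probability_matrix(Q, s) %*%
      transition_probability_matrix(Q, t)
    expect_lt(max(abs(lhs - rhs)), 1e-8)
  }
})

test_that("small-interval expansion: P(t) = I + tQ + O(t^2)", {
  set.seed(205)
  for (i in 1:10) {
    Q <- random_Q()
    for (t in c(1e-3, 5e-4, 1e-4)) {
      err <- max(abs(transition_probability_matrix(Q, t) - (diag(3) + t * Q)))
      expect_lt(err, 2 * max(abs(Q))^2 * t^2)
    }
  }
})

test_that("death probability is non-decreasing in the interval length", {
  set.seed(206)
  for (i in 1:10) {
    Q <- random_Q()
    ts <- sort(stats::runif(20, 0, 15))
    p13 <- vapply(ts, function(t)
      transition_probability_matrix(Q, t)[1, 3], numeric(1))
    p23 <- vapply(ts, function(t)
      transition_probability_matrix(Q, t)[2, 3], numeric(1))
    expect_true(all(diff(p13) >= -1e-12))
    expect_true(all(diff(p23) >= -1e-12))
  }
})

test_that("panel contributions read the right matrix entry", {
  P <- transition_probability_matrix(two_state_Q(), 0)
  expect_equal(panel_contribution(P, STATE_GOOD, STATE_GOOD), 1)
  expect_equal(panel_contribution(P, STATE_GOOD, STATE_POOR), 0)
  P2 <- transition_probability_matrix(two_state_Q(), 2)
  expect_equal(panel_contribution(P2, STATE_GOOD, STATE_POOR),
               1 - two_state_p11(2), tolerance = 1e-12)
  expect_error(panel_contribution(P, STATE_DEAD, STATE_DEAD), "absorbing")
})

test_that("exact-death density matches its limiting and derivative forms", {
  # no path to death
  expect_equal(exact_death_contribution(two_state_Q(), 1.3, STATE_GOOD), 0)

  set.seed(207)
  Q <- random_Q()
  # t -> 0+ limit collapses to the direct death intensity
  expect_equal(exact_death_contribution(Q, 1e-9, STATE_GOOD), Q[1, 3],
               tolerance = 1e-6)
  expect_equal(exact_death_contribution(Q, 1e-9, STATE_POOR), Q[2, 3],
               tolerance = 1e-6)
  # the density is the time derivative of the cumulative death probability
  for (t in c(0.5, 1.3, 4)) {
    h <- 1e-6
    for (from in c(STATE_GOOD, STATE_POOR)) {
      dnum <- (transition_probability_matrix(Q, t + h)[from, 3] -
               transition_probability_matrix(Q, t - h)[from, 3]) / (2 * h)
      expect_equal(exact_death_contribution(Q, t, from), dnum,
                   tolerance = 1e-6)
    }
  }
  expect_error(exact_death_contribution(Q, 0, STATE_GOOD), "positive")
  expect_error(exact_death_contribution(Q, 1, STATE_DEAD), "dead")
})

test_that("subject histories are validated", {
  prof <- covariate_profile("high", "1950-1962", "central", "F")
  expect_error(subject_history("a", prof, 1, 1), "at least two")
  expect_error(subject_history("a", prof, c(0, 0), c(1, 1)),
               "strictly increasing")
  expect_error(subject_history("a", prof, c(0, 2, 4), c(1, 3, 1)),
               "follow death")
})

test_that("subject log-likelihood matches hand computation", {
  prof <- covariate_profile("high", "1950-1962", "central", "F")

  # zero intensities: staying put has probability one
  p0 <- model_params(rep(log(1e-300), 4))  # effectively zero rates
  h <- subject_history("a", prof, c(0, 2), c(1, 1))
  expect_equal(subject_log_likelihood(p0, h)$value, 0, tolerance = 1e-12)

  # deterioration over the two-state worked example
  p <- model_params(log(c(0.2, 0.1, 1e-300, 1e-300)))
  h2 <- subject_history("a", prof, c(0, 2), c(1, 2))
  expect_equal(subject_log_likelihood(p, h2)$value,
               log(1 - two_state_p11(2)), tolerance = 1e-9)

  # Markov factorization: three observations = sum of the two pairs
  h3 <- subject_history("a", prof, c(0, 2, 5), c(1, 2, 1))
  ha <- subject_history("a", prof, c(0, 2), c(1, 2))
  hb <- subject_history("a", prof, c(2, 5), c(2, 1))
  expect_equal(subject_log_likelihood(p, h3)$value,
               subject_log_likelihood(p, ha)$value +
                 subject_log_likelihood(p, hb)$value)
})

test_that("total log-likelihood is additive and cache-invariant", {
  params <- default_true_params("F")
  sim <- generate_cohort(small_sim_config(n = 80, seed = 11), genders = "F")
  panel <- sim$panel

  empty <- panel[0, ]
  expect_equal(total_log_likelihood(params, empty)$value, 0)
  expect_identical(total_log_likelihood(params, empty)$n_pairs, 0L)

  multi_id <- names(which(table(panel$id) >= 2))[1]
  one <- panel[panel$id == multi_id, ]
  h1 <- panel_to_histories(one)[[1]]
  expect_equal(total_log_likelihood(params, one)$value,
               subject_log_likelihood(params, h1)$value)

  # duplicating every subject exactly doubles the value
  dup <- panel
  dup$id <- paste0(dup$id, "x")
  both <- rbind(panel, dup)
  expect_equal(total_log_likelihood(params, both)$value,
               2 * total_log_likelihood(params, panel)$value,
               tolerance = 1e-12)

  # grouped vectorised evaluation equals the per-subject loop exactly
  expect_equal(total_log_likelihood(params, panel, cache = TRUE)$value,
               total_log_likelihood(params, panel, cache = FALSE)$value,
               tolerance = 1e-12)

  # mixed genders are rejected
  zz <- make_panel("zz", c(0, 2), c(1, 1), gender = "M")
  zz$wave <- NA_integer_
  expect_error(total_log_likelihood(params, rbind(panel, zz)), "gender")
})

test_that("exact-death and panel-death likelihood terms differ as densities
           vs probabilities", {
  params <- default_true_params("F")
  prof <- covariate_profile("low", "1920-1939", "eastern", "F")
  h <- subject_history("a", prof, c(0, 2, 3.4), c(1, 2, 3),
                       exact = c(FALSE, FALSE, TRUE))
  Q <- build_intensity_matrix(params, prof)
  ll_exact <- subject_log_likelihood(params, h, exact_death = TRUE)$value
  ll_panel <- subject_log_likelihood(params, h, exact_death = FALSE)$value
  P1 <- transition_probability_matrix(Q, 2)
  expect_equal(ll_exact,
               log(P1[1, 2]) + log(exact_death_contribution(Q, 1.4, 2)))
  expect_equal(ll_panel,
               log(P1[1, 2]) +
                 log(transition_probability_matrix(Q, 1.4)[2, 3]))
})
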