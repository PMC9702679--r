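# Shared fixtures: small intensity matrices, random parameter draws, and a
# reduced simulation configuration for fast unit tests.

# Two live states only (no deaths): deterioration 0.2/yr, recovery 0.1/yr.
# P[good,good](t) has the closed form mu/(l+m) + l/(l+m) exp(-(l+m) t).
two_state_Q <- function() {
  matrix(c(-0.2, 0.2, 0,
           0.1, -0.1, 0,
           0, 0, 0),
         3L, 3L, byrow = TRUE,
         dimnames = list(c("good", "poor", "dead"),
                         c("good", "poor", "dead")))
}

two_state_p11 <- function(t, lambda = 0.2, mu = 0.1) {
  mu / (lambda + mu) + lambda / (lambda + mu) * exp(-(lambda + mu) * t)
}

# Random valid intensity matrix with all four transitions active.
random_Q <- function() {
  q <- stats::runif(4, 0.02, 0.6)
  p <- model_params(log(q))
  build_intensity_matrix(p, covariate_profile("high", "1950-1962", "central"))
}

# Random full parameter set (moderate hazard ratios).
random_params <- function() {
  model_params(
    logq0 = log(stats::runif(4, 0.02, 0.5)),
    beta = matrix(stats::rnorm(28, 0, 0.4), 4, 7)
  )
}

random_profile <- function() {
  covariate_profile(
    sample(c("low", "medium", "high"), 1),
    sample(c("1920-1939", "1940-1949", "1950-1962"), 1),
    sample(c("central", "northern", "southern", "eastern"), 1)
  )
}

# Reduced-size generator settings for unit tests.
small_sim_config <- function(n = 400L, seed = 1L, ...) {
  sim_config(n_subjects = c(F = n, M = n), seed = seed, ...)
}

# A fit object with known parameters and a given covariance, for exercising
# the prediction stage without an optimization run.
fake_fit <- function(params, vcov = diag(1e-10, 32), gender = "F") {
  theta <- panelmsm:::pack_params(params)
  nm <- names(theta)
  dimnames(vcov) <- list(nm, nm)
  structure(
    list(params_hat = params, theta = theta, vcov = vcov,
         fixed = stats::setNames(rep(FALSE, 32), nm),
         loglik = list(value = 0, n_pairs = 0L),
         n_subjects = 0L, n_pairs = 0L, gender = gender,
         converged = TRUE,
         diagnostics = list(grad_norm = 0, iterations = 0L),
         config = fit_config()),
    class = "panelmsm_fit"
  )
}

# Minimal hand-built panel data.frame.
make_panel <- function(id, time, state, gender = "F", education = "high",
                       cohort = "1950-1962", region = "central",
                       birth_year = 1955L, exact_death = NULL) {
  n <- length(time)
  if (is.null(exact_death)) exact_death <- as.integer(state == 3L)
  data.frame(
    id = rep_len(id, n), gender = rep_len(gender, n),
    education = rep_len(education, n), cohort = rep_len(cohort, n),
    region = rep_len(region, n), birth_year = rep_len(birth_year, n),
    time = time, state = as.integer(state),
    exact_death = as.integer(exact_death),
    stringsAsFactors = FALSE
  )
}
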