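# Covariate-specific transition probabilities with simulation-based
# confidence intervals — the headline output surface of the analysis.

# Draw B parameter vectors from the asymptotic normal of a fit, via the
# eigendecomposition of the covariance (tiny negative eigenvalues from the
# numerical Hessian are clipped at zero, so rank-deficient covariances —
# e.g. fixed parameters — are handled). Draws yielding a non-finite
# intensity matrix for any design vector in `Z` are redrawn (counted).
draw_parameters <- function(fit, B, Z, max_redraw = 10L) {
  eg <- eigen((fit$vcov + t(fit$vcov)) / 2, symmetric = TRUE)
  rt <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  sample_draws <- function(n) {
    z <- matrix(stats::rnorm(n * N_PARAMS), n, N_PARAMS)
    sweep(z %*% rt, 2L, fit$theta, "+")
  }
  bad_rows <- function(draws) {
    bad <- !apply(is.finite(draws), 1L, all)
    for (k in seq_len(4L)) {
      cols <- 4L + (k - 1L) * N_DESIGN + seq_len(N_DESIGN)
      lp <- draws[, k, drop = TRUE] + draws[, cols, drop = FALSE] %*% t(Z)
      # intensities beyond exp(300)/year overflow downstream arithmetic
      bad <- bad | apply(lp >= 300, 1L, any)
    }
    bad
  }
  draws <- sample_draws(B)
  n_redraws <- 0L
  bad <- bad_rows(draws)
  while (any(bad) && n_redraws < max_redraw * B) {
    draws[bad, ] <- sample_draws(sum(bad))
    n_redraws <- n_redraws + sum(bad)
    bad <- bad_rows(draws)
  }
  if (any(bad)) {
    warning(sum(bad), " parameter draw(s) remained invalid and were dropped")
    draws <- draws[!bad, , drop = FALSE]
  }
  attr(draws, "n_redraws") <- n_redraws
  draws
}

# B x 4 matrix of intensities for one design vector z, from a B x 32 draw
# matrix laid out as pack_params().
draw_intensities <- function(draws, z) {
  out <- matrix(0, nrow(draws), 4L, dimnames = list(NULL, TRANSITIONS))
  for (k in seq_len(4L)) {
    cols <- 4L + (k - 1L) * N_DESIGN + seq_len(N_DESIGN)
    out[, k] <- exp(draws[, k] + as.vector(draws[, cols] %*% z))
  }
  out
}

#' Predicted transition probabilities for a covariate profile
#'
#' Point estimate P(t) = exp(t Q(profile)) at the fitted parameters, with
#' percentile confidence intervals from `B` draws of the parameter vector
#' from its asymptotic normal distribution (mean = estimates, covariance =
#' the fit's covariance matrix). The point estimate does not depend on the
#' CI seed.
#'
#' @param fit A converged `panelmsm_fit`.
#' @param profile A `covariate_profile`.
#' @param t Prediction interval in years (default 2, the modal wave gap).
#' @param B Number of parameter draws for the interval.
#' @param seed Seed for the draws (recorded in the result).
#' @param level Confidence level.
#' @return List of class `msm_prediction`: `estimate`, `ci_low`, `ci_high`
#'   (3 x 3 matrices), `t`, `B`, `seed`, `n_redraws`, `profile`.
#' @export
predict_transition_probabilities <- function(fit, profile, t = 2,
                                             B = 1000L, seed = 1L,
                                             level = 0.95) {
  stopifnot(inherits(fit, "panelmsm_fit"))
  if (!isTRUE(fit$converged)) stop("prediction requires a converged fit")
  if (t <= 0) stop("prediction interval t must be positive")
  Q <- build_intensity_matrix(fit$params_hat, profile)
  P <- transition_probability_matrix(Q, t)
  if (!is.null(seed)) set.seed(seed)
  z <- encode_covariates(profile)
  draws <- draw_parameters(fit, B, Z = matrix(z, nrow = 1L))
  qd <- draw_intensities(draws, z)
  lp <- live_probs(qd[, 1L], qd[, 2L], qd[, 3L], qd[, 4L], t)
  probs <- cbind(
    lp$p11, lp$p12, pmax(1 - lp$p11 - lp$p12, 0),
    lp$p21, lp$p22, pmax(1 - lp$p21 - lp$p22, 0)
  )
  alpha <- (1 - level) / 2
  qs <- apply(probs, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  lo <- matrix(c(qs[1L, ], 0, 0, 1), 3L, 3L, byrow = TRUE,
               dimnames = dimnames(P))
  hi <- matrix(c(qs[2L, ], 0, 0, 1), 3L, 3L, byrow = TRUE,
               dimnames = dimnames(P))
  structure(
    list(estimate = P, ci_low = lo, ci_high = hi, t = t, B = B,
         seed = seed, n_redraws = attr(draws, "n_redraws"),
         profile = profile),
    class = "msm_prediction"
  )
}

#' @export
print.msm_prediction <- function(x, ...) {
  cat(sprintf("transition probabilities over %.3g years:\n", x$t))
  print(round(x$estimate, 4))
  cat(sprintf("(%d parameter draws for the intervals, seed %s)\n",
              x$B, format(x$seed)))
  invisible(x)
}

#' Transition-probability grid over all covariate profiles
#'
#' One row per covariate profile and transition type (36 x 4 = 144 rows per
#' gender stratum): the probability over the interval `t` of deterioration
#' (good to poor), recovery (poor to good), and death from each live state,
#' with percentile confidence intervals from a single set of parameter
#' draws. Deterministic given the fit and the seed.
#'
#' @param fit A converged `panelmsm_fit`.
#' @param t Interval in years.
#' @param B Number of parameter draws.
#' @param seed Seed for the draws.
#' @param level Confidence level.
#' @return data.frame with columns gender, education, cohort, region,
#'   transition, interval, estimate, ci_low, ci_high.
#' @export
probability_grid <- function(fit, t = 2, B = 1000L, seed = 1L,
                             level = 0.95) {
  stopifnot(inherits(fit, "panelmsm_fit"))
  if (!isTRUE(fit$converged)) stop("prediction requires a converged fit")
  pg <- profile_grid()
  if (!is.null(seed)) set.seed(seed)
  draws <- draw_parameters(fit, B, Z = pg$design)
  alpha <- (1 - level) / 2
  out <- vector("list", 36L)
  params <- fit$params_hat
  for (k in seq_len(36L)) {
    z <- pg$design[k, ]
    q <- intensity_vector(params, z)
    lp <- live_probs(q[1L], q[2L], q[3L], q[4L], t)
    est <- c(lp$p12, lp$p21, max(1 - lp$p11 - lp$p12, 0),
             max(1 - lp$p21 - lp$p22, 0))
    qd <- draw_intensities(draws, z)
    lpd <- live_probs(qd[, 1L], qd[, 2L], qd[, 3L], qd[, 4L], t)
    pd <- cbind(lpd$p12, lpd$p21,
                pmax(1 - lpd$p11 - lpd$p12, 0),
                pmax(1 - lpd$p21 - lpd$p22, 0))
    qs <- apply(pd, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE)
    out[[k]] <- data.frame(
      gender = fit$gender,
      education = pg$profiles$education[k],
      cohort = pg$profiles$cohort[k],
      region = pg$profiles$region[k],
      transition = c("good-poor", "poor-good", "good-dead", "poor-dead"),
      interval = t,
      estimate = est, ci_low = qs[1L, ], ci_high = qs[2L, ],
      row.names = NULL
    )
  }
  grid <- do.call(rbind, out)
  attr(grid, "B") <- B
  attr(grid, "seed") <- seed
  attr(grid, "n_redraws") <- attr(draws, "n_redraws")
  grid
}

#' Small-multiples plot of a probability grid
#'
#' For one transition type, plots the predicted probability with its
#' interval by cohort, education panels crossed with country group —
#' the layout used to read education and cohort gradients at a glance.
#'
#' @param grid Output of [probability_grid()].
#' @param transition One of "good-poor", "poor-good", "good-dead",
#'   "poor-dead".
#' @return A ggplot object.
#' @export
plot_probability_grid <- function(grid, transition = "good-poor") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_probability_grid requires the ggplot2 package")
  }
  d <- grid[grid$transition == transition, ]
  ggplot2::ggplot(
    d, ggplot2::aes(x = .data$cohort, y = .data$estimate,
                    group = .data$education, colour = .data$education)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.4)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0.2, position = ggplot2::position_dodge(0.4)) +
    ggplot2::facet_wrap(~region, nrow = 1) +
    ggplot2::labs(
      y = sprintf("P(%s) over %.3g years", transition, d$interval[1]),
      x = "birth cohort", colour = "education") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
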