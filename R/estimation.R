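# Maximum-likelihood estimation of the 32-parameter proportional-intensity
# model, per gender stratum, with Wald inference from the numerical Hessian.

#' Crude initial intensities from observed state changes
#'
#' For each allowed transition i -> h, the crude rate is the number of
#' observed i -> h changes across consecutive observation pairs divided by
#' the total elapsed years across pairs starting in state i. Transitions
#' never observed get a small floor rate. Covariate coefficients start at 0.
#'
#' @param panel Long-format panel data.frame.
#' @param floor Rate (events/year) assigned to never-observed transitions.
#' @return An `msm_params` with `attr(, "n_events")` holding the transition
#'   counts.
#' @export
crude_initial_intensities <- function(panel, floor = 1e-3) {
  validate_panel(panel)
  if (nrow(panel) == 0L) stop("dataset is empty")
  panel <- panel[order(panel$id, panel$time), , drop = FALSE]
  n <- nrow(panel)
  same <- panel$id[-1L] == panel$id[-n]
  i1 <- which(same); i2 <- i1 + 1L
  from <- panel$state[i1]; to <- panel$state[i2]
  dt <- panel$time[i2] - panel$time[i1]
  exposure <- c(good = sum(dt[from == 1L]), poor = sum(dt[from == 2L]))
  for (s in c(1L, 2L)) {
    if (!any(from == s)) {
      stop("no observation pairs begin in state ", STATE_LABELS[s])
    }
  }
  n_events <- stats::setNames(integer(4L), TRANSITIONS)
  rate <- numeric(4L)
  for (k in seq_along(TRANSITIONS)) {
    n_events[k] <- sum(from == TRANSITION_FROM[k] & to == TRANSITION_TO[k])
    rate[k] <- if (n_events[k] > 0L) {
      n_events[k] / exposure[TRANSITION_FROM[k]]
    } else {
      floor
    }
  }
  out <- model_params(logq0 = log(rate))
  attr(out, "n_events") <- n_events
  out
}

#' Estimation settings
#'
#' @param exact_death Use the exact-death density for exact-flagged deaths.
#' @param max_iter Maximum BFGS iterations.
#' @param grad_tol Relative gradient tolerance declaring convergence: the
#'   max-norm of the score must fall below `grad_tol * max(1, |loglik|)`.
#' @param reltol Relative function tolerance passed to the optimizer.
#' @param hessian_step Relative step for the central-difference Hessian.
#' @param floor Intensity floor (events/year) for never-observed transitions,
#'   whose baselines are held fixed rather than estimated.
#' @param polish Maximum Newton refinement steps after BFGS.
#' @return List of settings.
#' @export
fit_config <- function(exact_death = TRUE, max_iter = 500L,
                       grad_tol = 1e-6, reltol = 1e-10,
                       hessian_step = 1e-4, floor = 1e-3, polish = 2L) {
  list(exact_death = exact_death, max_iter = as.integer(max_iter),
       grad_tol = grad_tol, reltol = reltol, hessian_step = hessian_step,
       floor = floor, polish = as.integer(polish))
}

# Central-difference gradient; step scaled to the parameter magnitude.
num_grad <- function(f, x, step = 1e-5) {
  vapply(seq_along(x), function(j) {
    h <- step * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Central-difference Hessian (symmetric by construction).
num_hessian <- function(f, x, step = 1e-4) {
  p <- length(x)
  h <- step * pmax(1, abs(x))
  f0 <- f(x)
  H <- matrix(0, p, p)
  fp <- numeric(p); fm <- numeric(p)
  for (j in seq_len(p)) {
    xp <- x; xp[j] <- x[j] + h[j]
    xm <- x; xm[j] <- x[j] - h[j]
    fp[j] <- f(xp); fm[j] <- f(xm)
    H[j, j] <- (fp[j] + fm[j] - 2 * f0) / h[j]^2
  }
  if (p > 1L) {
    for (j in seq_len(p - 1L)) {
      for (k in seq((j + 1L), p)) {
        xpp <- x; xpp[j] <- x[j] + h[j]; xpp[k] <- x[k] + h[k]
        xpm <- x; xpm[j] <- x[j] + h[j]; xpm[k] <- x[k] - h[k]
        xmp <- x; xmp[j] <- x[j] - h[j]; xmp[k] <- x[k] + h[k]
        xmm <- x; xmm[j] <- x[j] - h[j]; xmm[k] <- x[k] - h[k]
        H[j, k] <- H[k, j] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[j] * h[k])
      }
    }
  }
  H
}

#' Fit the three-state panel model to one gender stratum
#'
#' Maximizes the interval-censored panel log-likelihood (with exact-death
#' density terms) over the 32-parameter vector — 4 baseline log-intensities
#' plus 4 x 7 log hazard ratios — by BFGS from crude initial rates, followed
#' by Newton refinement using the central-difference Hessian. The covariance
#' matrix is the inverse of the negative Hessian at the optimum, with a
#' pseudo-inverse fallback (and a warning) if it is ill-conditioned.
#'
#' Baselines of transitions never observed in the data are held at the floor
#' rate; coefficients of design columns with no variation in the data are
#' held at 0. Both appear in the `fixed` flag vector of the result.
#'
#' @param panel Long-format panel data.frame, one gender.
#' @param config Settings from [fit_config()].
#' @return Object of class `panelmsm_fit`: `params_hat`, `theta`, `vcov`
#'   (32 x 32), `loglik`, `converged`, `fixed`, counts, gender, diagnostics.
#' @export
fit_model <- function(panel, config = fit_config()) {
  prep <- prepare_likelihood(panel, exact_death = config$exact_death)
  init <- crude_initial_intensities(panel, floor = config$floor)
  n_events <- attr(init, "n_events")
  theta0 <- pack_params(init)

  fixed <- stats::setNames(rep(FALSE, N_PARAMS), theta_names())
  unseen <- n_events == 0L
  if (any(unseen)) {
    warning("transition(s) never observed, baseline held at floor: ",
            paste(TRANSITIONS[unseen], collapse = ", "))
    fixed[seq_len(4L)][unseen] <- TRUE
  }
  # design columns constant across observed intervals are unidentifiable
  zmat <- do.call(rbind, lapply(prep$groups, `[[`, "z"))
  wts <- vapply(prep$groups, function(g) length(g$t), numeric(1))
  varying <- vapply(seq_len(N_DESIGN), function(j) {
    vals <- zmat[, j][wts > 0]
    length(unique(vals)) > 1L
  }, logical(1))
  for (j in which(!varying)) {
    fixed[4L + (seq_len(4L) - 1L) * N_DESIGN + j] <- TRUE
  }
  # betas of floor-fixed transitions are unidentifiable too
  for (k in which(unseen)) {
    fixed[4L + (k - 1L) * N_DESIGN + seq_len(N_DESIGN)] <- TRUE
  }

  free <- !fixed
  embed <- function(th_free) { th <- theta0; th[free] <- th_free; th }
  negll <- function(th_free) {
    v <- -loglik_prepared(embed(th_free), prep)
    # finite ceiling keeps finite-difference gradients defined when the
    # optimizer probes a zero-probability region
    if (!is.finite(v)) 1e10 else v
  }

  opt <- stats::optim(
    par = theta0[free], fn = negll, method = "BFGS",
    control = list(maxit = config$max_iter, reltol = config$reltol)
  )
  th_free <- opt$par
  ll <- -opt$value

  # Newton refinement: drives the score to numerical zero and yields the
  # Hessian used for the covariance matrix.
  H <- NULL
  for (it in seq_len(max(config$polish, 1L))) {
    g <- num_grad(negll, th_free)
    H <- num_hessian(negll, th_free, step = config$hessian_step)
    step_dir <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step_dir) || !all(is.finite(step_dir))) break
    scale <- 1
    improved <- FALSE
    for (half in 0:4) {
      cand <- th_free - scale * step_dir
      val <- negll(cand)
      if (is.finite(val) && val <= -ll + 1e-12) {
        th_free <- cand; ll <- -val; improved <- TRUE; break
      }
      scale <- scale / 2
    }
    if (!improved || max(abs(g)) < config$grad_tol * max(1, abs(ll))) break
  }
  g <- num_grad(negll, th_free)
  grad_norm <- max(abs(g))
  if (is.null(H) || any(!is.finite(H))) {
    H <- num_hessian(negll, th_free, step = config$hessian_step)
  }

  vcov_free <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(vcov_free) || any(!is.finite(vcov_free)) ||
      any(diag(vcov_free) < 0)) {
    warning("Hessian ill-conditioned; using pseudo-inverse covariance")
    vcov_free <- MASS::ginv(H)
  }
  vcov_free <- (vcov_free + t(vcov_free)) / 2

  theta_hat <- embed(th_free)
  vcov <- matrix(0, N_PARAMS, N_PARAMS,
                 dimnames = list(theta_names(), theta_names()))
  vcov[free, free] <- vcov_free

  converged <- opt$convergence == 0 &&
    grad_norm < config$grad_tol * max(1, abs(ll))

  structure(
    list(
      params_hat = unpack_params(theta_hat),
      theta = theta_hat,
      vcov = vcov,
      fixed = fixed,
      loglik = list(value = ll, n_pairs = prep$n_pairs),
      loglik_initial = -negll(theta0[free]),
      n_subjects = prep$n_subjects,
      n_pairs = prep$n_pairs,
      n_events = n_events,
      gender = prep$gender,
      converged = converged,
      diagnostics = list(
        grad_norm = grad_norm,
        iterations = opt$counts[["function"]],
        optim_convergence = opt$convergence
      ),
      config = config
    ),
    class = "panelmsm_fit"
  )
}

#' @export
print.panelmsm_fit <- function(x, ...) {
  cat(sprintf(
    "three-state panel model fit (gender %s): %d subjects, %d intervals\n",
    x$gender, x$n_subjects, x$n_pairs))
  cat(sprintf("log-likelihood %.3f, converged: %s (max |score| %.2e)\n",
              x$loglik$value, x$converged, x$diagnostics$grad_norm))
  cat("baseline intensities (events/year):\n")
  print(round(exp(x$params_hat$logq0), 4))
  invisible(x)
}

#' Hazard-ratio table with Wald inference
#'
#' Exponentiated covariate coefficients per transition, with normal-theory
#' confidence intervals exp(beta +/- z * SE), Wald z statistics and p-values.
#' Coefficients held fixed during estimation are omitted.
#'
#' @param fit A converged `panelmsm_fit`.
#' @param level Confidence level (default 0.95).
#' @return data.frame with columns transition, term, loghr, se, hr, ci_low,
#'   ci_high, z, p.
#' @export
hazard_ratios <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "panelmsm_fit"))
  if (!isTRUE(fit$converged)) {
    stop("hazard ratios require a converged fit")
  }
  zq <- stats::qnorm(1 - (1 - level) / 2)
  idx <- which(!fit$fixed & seq_len(N_PARAMS) > 4L)
  if (!length(idx)) return(data.frame())
  nm <- theta_names()[idx]
  parts <- regmatches(nm, regexpr("^[a-z]+-[a-z]+", nm))
  term <- sub("^[a-z]+-[a-z]+\\.", "", nm)
  est <- fit$theta[idx]
  se <- sqrt(diag(fit$vcov)[idx])
  z <- est / se
  data.frame(
    transition = parts, term = term,
    loghr = unname(est), se = unname(se),
    hr = unname(exp(est)),
    ci_low = unname(exp(est - zq * se)),
    ci_high = unname(exp(est + zq * se)),
    z = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))),
    row.names = NULL
  )
}

#' Parameter-recovery simulation study
#'
#' Repeatedly simulates SHARE-like cohorts from known true parameters,
#' fits the model, and records estimates, standard errors, Wald-interval
#' coverage of the truth, and bias — the central verification surface of
#' the pipeline.
#'
#' @param n_replicates Number of simulated datasets.
#' @param config A [sim_config()]; its `true_params` are the truth.
#' @param genders Gender strata to cycle over across replicates.
#' @param fit_cfg Settings from [fit_config()].
#' @param seed Root seed; replicate r uses `seed + r`.
#' @param level Wald confidence level for the coverage bookkeeping.
#' @return List with `detail` (one row per free parameter per replicate:
#'   estimate, se, truth, covered), `coverage` (pooled), `bias` (per
#'   parameter), and `n_converged`.
#' @export
recovery_study <- function(n_replicates = 10L, config = sim_config(),
                           genders = c("F", "M"), fit_cfg = fit_config(),
                           seed = 1L, level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  rows <- vector("list", n_replicates)
  n_conv <- 0L
  for (r in seq_len(n_replicates)) {
    g <- genders[((r - 1L) %% length(genders)) + 1L]
    cfg <- config
    cfg$seed <- seed + r
    sim <- generate_cohort(cfg, genders = g)
    fit <- fit_model(sim$panel, config = fit_cfg)
    n_conv <- n_conv + as.integer(fit$converged)
    truth <- pack_params(config$true_params[[g]])
    idx <- which(!fit$fixed)
    se <- sqrt(diag(fit$vcov)[idx])
    rows[[r]] <- data.frame(
      replicate = r, gender = g,
      param = theta_names()[idx],
      truth = unname(truth[idx]),
      estimate = unname(fit$theta[idx]),
      se = unname(se),
      covered = unname(abs(fit$theta[idx] - truth[idx]) <= zq * se),
      converged = fit$converged,
      row.names = NULL
    )
  }
  detail <- do.call(rbind, rows)
  bias <- stats::aggregate(
    cbind(bias = estimate - truth) ~ param, data = detail, FUN = mean)
  bias$mc_se <- stats::aggregate(
    (detail$estimate - detail$truth) ~ detail$param,
    FUN = function(x) stats::sd(x) / sqrt(length(x)))[[2]]
  list(
    detail = detail,
    coverage = mean(detail$covered),
    bias = bias,
    n_converged = n_conv,
    n_replicates = n_replicates
  )
}
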