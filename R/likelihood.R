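# Transition probabilities and the interval-censored panel likelihood.
#
# Live states are observed only at interview dates; death dates are exact.
# Under time-homogeneity P(t) = exp(tQ). Because death is absorbing, only
# the 2 x 2 live-state block A of Q evolves: A = [[-(a+c), a], [b, -(b+d)]]
# with a = q12, b = q21, c = q13, d = q23. Its eigenvalues are always real
# (discriminant (a+c-b-d)^2 + 4ab >= 0), so exp(tA) has an exact spectral
# closed form, which is what the likelihood evaluates — vectorised over
# intervals. The death column follows from row-stochasticity.

# exp(tA) entries for live states, vectorised over (a, b, c, d, t).
# Returns a list with components p11, p12, p21, p22.
live_probs <- function(a, b, c, d, t) {
  A11 <- -(a + c)
  A22 <- -(b + d)
  tr <- A11 + A22
  disc <- (A11 - A22)^2 + 4 * a * b
  sq <- sqrt(pmax(disc, 0))
  degen <- sq < 1e-9
  sq_safe <- ifelse(degen, 1, sq)
  l1 <- (tr + sq) / 2
  l2 <- (tr - sq) / 2
  e1 <- exp(l1 * t)
  e2 <- exp(l2 * t)
  # distinct-eigenvalue branch
  p11 <- (e1 * (A11 - l2) - e2 * (A11 - l1)) / sq_safe
  p22 <- (e1 * (A22 - l2) - e2 * (A22 - l1)) / sq_safe
  p12 <- a * (e1 - e2) / sq_safe
  p21 <- b * (e1 - e2) / sq_safe
  if (any(degen)) {
    # coincident eigenvalues: exp(tA) = e^{lt} (I + t (A - l I))
    l <- tr / 2
    el <- exp(l * t)
    p11 <- ifelse(degen, el * (1 + t * (A11 - l)), p11)
    p22 <- ifelse(degen, el * (1 + t * (A22 - l)), p22)
    p12 <- ifelse(degen, el * t * a, p12)
    p21 <- ifelse(degen, el * t * b, p21)
  }
  clamp <- function(p) pmin(pmax(p, 0), 1)
  list(p11 = clamp(p11), p12 = clamp(p12), p21 = clamp(p21), p22 = clamp(p22))
}

#' Transition probability matrix P(t) = exp(tQ)
#'
#' Probability of occupying each state after an elapsed time `t`, given the
#' current state, for a time-homogeneous process with intensity matrix `Q`.
#' Computed from the exact spectral form of the 2 x 2 live-state block (its
#' eigenvalues are always real for this model class); the death column is
#' the row-stochastic complement.
#'
#' @param Q 3 x 3 intensity matrix (see [build_intensity_matrix()]).
#' @param t Elapsed time in years, a single value >= 0.
#' @return 3 x 3 row-stochastic matrix with attribute `interval = t`;
#'   the death row is (0, 0, 1).
#' @examples
#' Q <- matrix(c(-0.3, 0.2, 0.1, 0.1, -0.25, 0.15, 0, 0, 0), 3, byrow = TRUE)
#' transition_probability_matrix(Q, 2)
#' @export
transition_probability_matrix <- function(Q, t) {
  validate_intensity_matrix(Q)
  if (length(t) != 1L || !is.finite(t) || t < 0) {
    stop("t must be a single non-negative number of years")
  }
  lp <- live_probs(Q[1, 2], Q[2, 1], Q[1, 3], Q[2, 3], t)
  P <- matrix(c(
    lp$p11, lp$p12, 1 - lp$p11 - lp$p12,
    lp$p21, lp$p22, 1 - lp$p21 - lp$p22,
    0, 0, 1
  ), 3L, 3L, byrow = TRUE, dimnames = list(STATE_LABELS, STATE_LABELS))
  P[P < 0] <- 0
  attr(P, "interval") <- t
  P
}

#' Panel likelihood contribution of one interval
#'
#' For a live state observed at the start of an interval and any state
#' observed at its end, the contribution is the corresponding entry of the
#' transition probability matrix.
#'
#' @param P Transition probability matrix for the interval.
#' @param from State at the interval start (must be a live state).
#' @param to State at the interval end.
#' @return The probability `P[from, to]`.
#' @export
panel_contribution <- function(P, from, to) {
  from <- as.integer(from); to <- as.integer(to)
  if (from == STATE_DEAD) {
    stop("no panel contribution from the absorbing death state")
  }
  stopifnot(from %in% c(1L, 2L), to %in% 1:3)
  P[from, to]
}

#' Likelihood density for an exactly observed death time
#'
#' When the death date is known exactly, the interval from the last interview
#' to death contributes a density, not a panel probability: the probability
#' of being in some live state h just before the death instant times the
#' instantaneous death intensity from h, summed over the two live states:
#' sum_h P(t)[from, h] * q_{h,dead}.
#'
#' @param Q 3 x 3 intensity matrix.
#' @param t Time in years from the last interview to the death date (> 0).
#' @param from Live state at the last interview.
#' @return Density value (per year).
#' @export
exact_death_contribution <- function(Q, t, from) {
  validate_intensity_matrix(Q)
  from <- as.integer(from)
  if (from == STATE_DEAD) stop("death cannot be observed from the dead state")
  if (length(t) != 1L || !is.finite(t) || t <= 0) {
    stop("t must be a single positive number of years")
  }
  lp <- live_probs(Q[1, 2], Q[2, 1], Q[1, 3], Q[2, 3], t)
  if (from == STATE_GOOD) {
    lp$p11 * Q[1, 3] + lp$p12 * Q[2, 3]
  } else {
    lp$p21 * Q[1, 3] + lp$p22 * Q[2, 3]
  }
}

#' A subject's observed history
#'
#' Time-ordered observations of one subject: interview times (decimal years,
#' any origin), observed states, and an exact-time flag that may be TRUE
#' only for a terminal death observation with a known date.
#'
#' @param id Subject identifier.
#' @param profile A `covariate_profile` (with gender for stratified fits).
#' @param times Strictly increasing numeric vector, length >= 2.
#' @param states Integer states (1/2/3); death, if present, must be last.
#' @param exact Logical vector; TRUE only where `states == 3`.
#' @return Object of class `subject_history`.
#' @export
subject_history <- function(id, profile, times, states,
                            exact = states == STATE_DEAD) {
  stopifnot(inherits(profile, "covariate_profile"))
  times <- as.numeric(times); states <- as.integer(states)
  exact <- as.logical(exact)
  n <- length(times)
  if (n < 2L) stop("a subject history needs at least two observations")
  if (length(states) != n || length(exact) != n) {
    stop("times, states and exact must have equal length")
  }
  if (any(diff(times) <= 0)) {
    stop("observation times must be strictly increasing (no duplicate dates)")
  }
  if (!all(states %in% 1:3)) stop("states must be coded 1, 2, 3")
  if (any(states[-n] == STATE_DEAD)) {
    stop("no observation may follow death")
  }
  if (any(exact & states != STATE_DEAD)) {
    stop("exact-time flags are only meaningful for death observations")
  }
  structure(
    list(id = id, profile = profile, times = times, states = states,
         exact = exact),
    class = "subject_history"
  )
}

#' Log-likelihood of one subject's history
#'
#' Markov factorisation over consecutive observation pairs: each pair
#' contributes the log transition probability for its interval, except a
#' pair ending in an exact-time death, which contributes the log of the
#' exact death density. The intensity matrix is built once per subject from
#' its covariate profile.
#'
#' @param params An `msm_params` object.
#' @param history A `subject_history`.
#' @param exact_death If FALSE, treat even exact-flagged deaths as panel
#'   observations (pure interval-censored term).
#' @return List with `value` (log-likelihood) and `n_pairs`. A zero
#'   contribution yields `-Inf` (optimizer-safe) with attribute
#'   `zero_contribution = TRUE`.
#' @export
subject_log_likelihood <- function(params, history, exact_death = TRUE) {
  stopifnot(inherits(history, "subject_history"))
  Q <- build_intensity_matrix(params, history$profile)
  n <- length(history$times)
  ll <- 0
  zero <- FALSE
  for (j in seq_len(n - 1L)) {
    from <- history$states[j]
    to <- history$states[j + 1L]
    dt <- history$times[j + 1L] - history$times[j]
    contrib <- if (to == STATE_DEAD && exact_death && history$exact[j + 1L]) {
      exact_death_contribution(Q, dt, from)
    } else {
      panel_contribution(transition_probability_matrix(Q, dt), from, to)
    }
    if (contrib <= 0) { zero <- TRUE; ll <- -Inf; break }
    ll <- ll + log(contrib)
  }
  out <- list(value = ll, n_pairs = n - 1L)
  attr(out, "zero_contribution") <- zero
  out
}

# ---- dataset-level likelihood -------------------------------------------

# Collapse a long panel data.frame into the per-profile interval groups the
# fast likelihood evaluates: for each of the 36 covariate profiles present,
# the vectors of interval lengths, start/end states and exact-death flags.
prepare_likelihood <- function(panel, exact_death = TRUE) {
  validate_panel(panel)
  g <- unique(panel$gender)
  if (length(g) > 1L) {
    stop("dataset mixes genders; fit each stratum separately")
  }
  panel <- panel[order(panel$id, panel$time), , drop = FALSE]
  id <- panel$id
  n <- nrow(panel)
  same <- id[-1L] == id[-n]
  i1 <- which(same)        # row index of interval start
  i2 <- i1 + 1L            # row index of interval end
  t <- panel$time[i2] - panel$time[i1]
  from <- panel$state[i1]
  to <- panel$state[i2]
  exact <- exact_death & (to == STATE_DEAD) & (panel$exact_death[i2] == 1)
  key <- profile_key(panel$education[i1], panel$cohort[i1], panel$region[i1])
  pg <- profile_grid()
  kidx <- match(key, pg$profiles$key)
  groups <- lapply(which(tabulate(kidx, 36L) > 0L), function(k) {
    sel <- which(kidx == k)
    list(z = pg$design[k, ], t = t[sel], from = from[sel], to = to[sel],
         exact = exact[sel], key = pg$profiles$key[k])
  })
  list(groups = groups, n_pairs = length(t),
       n_subjects = length(unique(id)), gender = g)
}

# Fast total log-likelihood over a prepared dataset, for a packed theta.
loglik_prepared <- function(theta, prep) {
  params <- unpack_params(theta)
  total <- 0
  for (grp in prep$groups) {
    q <- intensity_vector(params, grp$z)
    if (any(!is.finite(q))) return(-Inf)
    a <- q[1L]; b <- q[2L]; cc <- q[3L]; d <- q[4L]
    lp <- live_probs(a, b, cc, d, grp$t)
    contrib <- numeric(length(grp$t))
    f1 <- grp$from == 1L; f2 <- !f1
    panel3 <- (grp$to == 3L) & !grp$exact
    sel <- f1 & grp$to == 1L; contrib[sel] <- lp$p11[sel]
    sel <- f1 & grp$to == 2L; contrib[sel] <- lp$p12[sel]
    sel <- f2 & grp$to == 1L; contrib[sel] <- lp$p21[sel]
    sel <- f2 & grp$to == 2L; contrib[sel] <- lp$p22[sel]
    sel <- f1 & panel3; contrib[sel] <- 1 - lp$p11[sel] - lp$p12[sel]
    sel <- f2 & panel3; contrib[sel] <- 1 - lp$p21[sel] - lp$p22[sel]
    sel <- f1 & grp$exact; contrib[sel] <- lp$p11[sel] * cc + lp$p12[sel] * d
    sel <- f2 & grp$exact; contrib[sel] <- lp$p21[sel] * cc + lp$p22[sel] * d
    if (any(!is.finite(contrib) | contrib <= 0)) return(-Inf)
    total <- total + sum(log(contrib))
  }
  total
}

#' Total log-likelihood of a gender stratum
#'
#' Sum of per-subject log-likelihoods over a long-format panel dataset.
#' The default path groups intervals by covariate profile and evaluates the
#' closed-form transition probabilities vectorised over interval lengths;
#' `cache = FALSE` instead loops over subjects via
#' [subject_log_likelihood()] (the two agree exactly).
#'
#' @param params An `msm_params` object.
#' @param panel Long-format panel data.frame (see [read_panel()] for the
#'   column contract).
#' @param exact_death Use the exact-death density for exact-flagged deaths.
#' @param cache Use the grouped vectorised evaluation (default).
#' @return List with `value` and `n_pairs`.
#' @export
total_log_likelihood <- function(params, panel, exact_death = TRUE,
                                 cache = TRUE) {
  if (nrow(panel) == 0L) return(list(value = 0, n_pairs = 0L))
  if (cache) {
    prep <- prepare_likelihood(panel, exact_death = exact_death)
    list(value = loglik_prepared(pack_params(params), prep),
         n_pairs = prep$n_pairs)
  } else {
    hists <- panel_to_histories(panel)
    vals <- lapply(hists, function(h)
      subject_log_likelihood(params, h, exact_death = exact_death))
    list(value = sum(vapply(vals, `[[`, numeric(1), "value")),
         n_pairs = sum(vapply(vals, `[[`, integer(1), "n_pairs")))
  }
}

#' Split a long panel data.frame into subject histories
#'
#' Subjects with fewer than two observations carry no interval information
#' and are dropped.
#'
#' @param panel Validated long-format panel data.frame.
#' @return Named list of `subject_history` objects.
#' @export
panel_to_histories <- function(panel) {
  validate_panel(panel)
  panel <- panel[order(panel$id, panel$time), , drop = FALSE]
  n_obs <- table(panel$id)
  panel <- panel[panel$id %in% names(n_obs)[n_obs >= 2L], , drop = FALSE]
  lapply(split(panel, panel$id, drop = TRUE), function(d) {
    subject_history(
      id = d$id[1L],
      profile = covariate_profile(d$education[1L], d$cohort[1L],
                                  d$region[1L], d$gender[1L]),
      times = d$time, states = d$state,
      exact = d$exact_death == 1 & d$state == STATE_DEAD
    )
  })
}
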