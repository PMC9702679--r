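# Synthetic SHARE-like panel data with known truth.
#
# The generator emulates the observation process of a multi-country ageing
# panel: a seven-wave schedule (2004, 2007, 2009, 2011, 2013, 2015, 2017 —
# a three-year gap after the first wave, two-year gaps after), interview
# dates jittered around wave years, skipped waves, permanent attrition,
# staggered country-group entry (Eastern countries join at wave 2), gendered
# age windows (men sampled from 50, women from 50), and exact death dates
# between waves. Latent health trajectories follow the three-state model
# exactly, so the fitted model is correctly specified by construction.

#' Published sample margins of the SHARE-based working sample
#'
#' Counts and column percentages by education, birth cohort and country
#' group per gender, plus the mean number of survey participations, for the
#' pooled seven-wave working sample the model is designed for. Used as the
#' default covariate composition of the synthetic generator and for
#' arithmetic consistency checks.
#'
#' @return data.frame with columns gender, block, level, count, percent.
#' @export
share_margins <- function() {
  path <- system.file("extdata", "share_table_margins.csv",
                      package = "panelmsm")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default true parameters of the synthetic truth
#'
#' Plausible per-gender intensities and hazard ratios encoding the
#' gradients the model is meant to detect: worse deterioration and
#' mortality for lower education, older cohorts, and Eastern countries;
#' better recovery for higher education and Northern countries; higher
#' mortality for men, more poor health for women.
#'
#' @param gender "F" or "M".
#' @return An `msm_params`.
#' @export
default_true_params <- function(gender = c("F", "M")) {
  gender <- match.arg(gender)
  if (gender == "F") {
    logq0 <- log(c(0.09, 0.25, 0.008, 0.045))
    beta <- log(rbind(
      c(2.0, 1.45, 1.8, 1.3, 0.8, 1.3, 1.6),    # deterioration
      c(0.60, 0.80, 0.70, 0.85, 1.2, 0.8, 0.7), # recovery
      c(1.30, 1.15, 2.5, 1.5, 0.9, 1.0, 1.3),   # good -> death
      c(1.20, 1.10, 2.2, 1.4, 0.9, 1.0, 1.2)    # poor -> death
    ))
  } else {
    logq0 <- log(c(0.08, 0.28, 0.012, 0.06))
    beta <- log(rbind(
      c(1.9, 1.40, 1.7, 1.25, 0.8, 1.25, 1.7),
      c(0.65, 0.85, 0.7, 0.85, 1.15, 0.85, 0.7),
      c(1.35, 1.15, 2.4, 1.5, 0.9, 1.0, 1.35),
      c(1.25, 1.10, 2.1, 1.4, 0.9, 1.05, 1.25)
    ))
  }
  model_params(logq0, beta)
}

# Joint profile probabilities from independent margins (the published table
# prints margins only, not the joint distribution).
default_composition <- function(gender = c("F", "M")) {
  gender <- match.arg(gender)
  m <- share_margins()
  m <- m[m$gender == gender & m$level != "total", ]
  marg <- function(block, levels) {
    x <- m[m$block == block, ]
    p <- x$count[match(levels, x$level)]
    p / sum(p)
  }
  p_edu <- marg("education", EDUCATION_LEVELS)
  p_coh <- marg("cohort", COHORT_LEVELS)
  p_reg <- marg("region", REGION_LEVELS)
  pg <- profile_grid()$profiles
  p <- p_edu[match(pg$education, EDUCATION_LEVELS)] *
    p_coh[match(pg$cohort, COHORT_LEVELS)] *
    p_reg[match(pg$region, REGION_LEVELS)]
  stats::setNames(p / sum(p), pg$key)
}

# Initial poor-health prevalence per profile: regional base levels mimic
# the wave-1 ordering (Northern lowest, Southern/Eastern highest), scaled
# by education and cohort multipliers.
default_initial_poor <- function(gender = c("F", "M")) {
  gender <- match.arg(gender)
  base <- if (gender == "F") {
    c(central = 0.26, northern = 0.15, southern = 0.40, eastern = 0.48)
  } else {
    c(central = 0.23, northern = 0.11, southern = 0.26, eastern = 0.46)
  }
  edu_m <- c(low = 1.4, medium = 1.0, high = 0.55)
  coh_m <- c("1920-1939" = 1.3, "1940-1949" = 1.0, "1950-1962" = 0.75)
  pg <- profile_grid()$profiles
  p <- base[pg$region] * edu_m[pg$education] * coh_m[pg$cohort]
  stats::setNames(pmin(pmax(p, 0.02), 0.9), pg$key)
}

#' Configuration of the synthetic-data generator
#'
#' Defaults define the study conditions: per-gender samples of 4000
#' subjects, the seven-wave 2004-2017 schedule, interview dates jittered
#' by up to 0.3 years, a 10% chance of skipping any scheduled wave, 12%
#' per-wave permanent attrition, covariate composition from the published
#' sample margins, Eastern countries entering at wave 2, and age windows
#' of 50-79 for men and 50-84 for women.
#'
#' @param n_subjects Named vector, subjects per gender.
#' @param true_params Named list of `msm_params` per gender.
#' @param composition Named list of 36 profile probabilities per gender
#'   (keys as in [profile_grid()]); NULL for the margins-based default.
#' @param wave_schedule Strictly increasing wave years.
#' @param gap_jitter Half-width (years) of the uniform interview-date
#'   jitter; must be below half the smallest wave gap.
#' @param p_skip_wave Probability of missing any scheduled wave.
#' @param p_dropout Per-wave permanent attrition probability.
#' @param p_initial_poor Named 36-vector per gender of initial poor-health
#'   probabilities; NULL for the default.
#' @param age_window Named list of c(lower, upper) ages per gender.
#' @param region_entry_wave Named integer vector: first wave index at which
#'   each country group is sampled.
#' @param seed Integer seed making the generated dataset reproducible.
#' @return List of settings (class `sim_config`).
#' @export
sim_config <- function(n_subjects = c(F = 4000L, M = 4000L),
                       true_params = list(F = default_true_params("F"),
                                          M = default_true_params("M")),
                       composition = NULL,
                       wave_schedule = c(2004, 2007, 2009, 2011, 2013,
                                         2015, 2017),
                       gap_jitter = 0.3,
                       p_skip_wave = 0.10,
                       p_dropout = 0.12,
                       p_initial_poor = NULL,
                       age_window = list(F = c(50, 84), M = c(50, 79)),
                       region_entry_wave = c(central = 1L, northern = 1L,
                                             southern = 1L, eastern = 2L),
                       seed = NULL) {
  if (is.null(composition)) {
    composition <- list(F = default_composition("F"),
                        M = default_composition("M"))
  }
  if (is.null(p_initial_poor)) {
    p_initial_poor <- list(F = default_initial_poor("F"),
                           M = default_initial_poor("M"))
  }
  if (any(diff(wave_schedule) <= 0)) {
    stop("wave years must be strictly increasing")
  }
  if (gap_jitter < 0 || gap_jitter >= min(diff(wave_schedule)) / 2) {
    stop("gap_jitter must be in [0, half the smallest wave gap)")
  }
  for (p in c(p_skip_wave, p_dropout)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  for (g in names(composition)) {
    cmp <- composition[[g]]
    if (any(cmp < 0) || abs(sum(cmp) - 1) > 1e-8) {
      stop("composition for gender ", g, " must be a probability vector")
    }
    pip <- p_initial_poor[[g]]
    if (any(pip < 0 | pip > 1)) {
      stop("p_initial_poor for gender ", g, " must lie in [0, 1]")
    }
  }
  structure(
    list(n_subjects = n_subjects, true_params = true_params,
         composition = composition, wave_schedule = wave_schedule,
         gap_jitter = gap_jitter, p_skip_wave = p_skip_wave,
         p_dropout = p_dropout, p_initial_poor = p_initial_poor,
         age_window = age_window, region_entry_wave = region_entry_wave,
         seed = seed),
    class = "sim_config"
  )
}

#' Simulate one continuous-time trajectory
#'
#' Competing-exponentials simulation of the latent process: the holding
#' time in a live state i is Exponential(-Q[i,i]) and the next state is
#' drawn proportionally to the off-diagonal intensities. The path ends at
#' death or at `t_max`; event times are exact.
#'
#' @param Q 3 x 3 intensity matrix.
#' @param start_state Initial live state (1 or 2).
#' @param t_max Follow-up horizon in years.
#' @return List with `times` (state entry times, starting at 0), `states`,
#'   `death_time` (NA if alive at `t_max`), and `t_max`.
#' @export
simulate_trajectory <- function(Q, start_state, t_max) {
  validate_intensity_matrix(Q)
  s <- as.integer(start_state)
  if (s == STATE_DEAD) stop("cannot start a trajectory in the absorbing state")
  stopifnot(s %in% c(1L, 2L), t_max > 0)
  times <- 0
  states <- s
  death_time <- NA_real_
  t <- 0
  repeat {
    rate <- -Q[s, s]
    if (rate <= 0) break
    t <- t + stats::rexp(1L, rate)
    if (t > t_max) break
    s <- sample.int(3L, 1L, prob = Q[s, ] * (Q[s, ] > 0))
    times <- c(times, t)
    states <- c(states, s)
    if (s == STATE_DEAD) { death_time <- t; break }
  }
  list(times = times, states = states, death_time = death_time,
       t_max = t_max)
}

# State occupied at time t (t on the trajectory's own clock).
state_at <- function(path, t) {
  idx <- findInterval(t, path$times)
  path$states[pmax(idx, 1L)]
}

#' Observe a trajectory at survey waves
#'
#' Reads the latent state at jittered wave dates, applying wave skipping
#' and permanent attrition. The first wave anchors the subject's clock
#' (jitter applies to the gaps that follow). If the subject dies after at
#' least one interview, before being lost to attrition and within the
#' study period, a final exact-time death observation is appended.
#'
#' @param path A trajectory from [simulate_trajectory()], with time 0 at
#'   the first scheduled wave.
#' @param schedule Wave years the subject is scheduled for.
#' @param config A [sim_config()] (uses gap_jitter, p_skip_wave, p_dropout).
#' @return List with `times` (years since the first scheduled wave),
#'   `states`, `exact`, `wave` (schedule index; NA for the death record),
#'   and `keep` (TRUE when at least two observations resulted).
#' @export
observe_at_waves <- function(path, schedule, config) {
  m <- length(schedule)
  u <- c(0, stats::runif(m - 1L, -config$gap_jitter, config$gap_jitter))
  rel <- schedule - schedule[1L] + u
  times <- numeric(0); states <- integer(0); waves <- integer(0)
  dropout_rel <- Inf
  dropped <- FALSE
  for (i in seq_len(m)) {
    if (dropped) { dropout_rel <- rel[i]; break }
    skip <- stats::runif(1L) < config$p_skip_wave
    if (skip) next
    s <- state_at(path, rel[i])
    if (s == STATE_DEAD) break
    times <- c(times, rel[i])
    states <- c(states, s)
    waves <- c(waves, i)
    if (stats::runif(1L) < config$p_dropout) dropped <- TRUE
  }
  exact <- rep(FALSE, length(times))
  dt <- path$death_time
  if (!is.na(dt) && length(times) >= 1L && dt > times[length(times)] &&
      dt < dropout_rel && dt <= rel[m]) {
    times <- c(times, dt)
    states <- c(states, STATE_DEAD)
    waves <- c(waves, NA_integer_)
    exact <- c(exact, TRUE)
  }
  list(times = times, states = states, exact = exact, wave = waves,
       keep = length(times) >= 2L)
}

#' Generate a synthetic SHARE-like cohort
#'
#' Draws covariate profiles from the configured composition, simulates
#' latent trajectories under the per-gender true parameters from each
#' subject's entry wave (the first wave at which their country group is
#' sampled and they are past the lower age bound), observes them at waves,
#' and assembles a long-format panel plus a truth manifest. Subjects with a
#' single resulting observation are emitted (the minimum-interview filter
#' is applied downstream); the exclusion fraction is recorded.
#'
#' @param config A [sim_config()].
#' @param genders Which strata to generate.
#' @return List with `panel` (long-format data.frame, extra `wave` column)
#'   and `manifest` (true parameters, seed, config echo, exclusion
#'   fractions).
#' @export
generate_cohort <- function(config = sim_config(), genders = c("F", "M")) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ws <- config$wave_schedule
  pg <- profile_grid()$profiles
  cohort_range <- list("1920-1939" = c(1920, 1939),
                       "1940-1949" = c(1940, 1949),
                       "1950-1962" = c(1950, 1962))
  acc <- list()
  excl <- stats::setNames(numeric(length(genders)), genders)
  for (g in genders) {
    n <- as.integer(config$n_subjects[[g]])
    if (n == 0L) { excl[g] <- 0; next }
    comp <- config$composition[[g]]
    pidx <- sample.int(36L, n, replace = TRUE, prob = comp[pg$key])
    params <- config$true_params[[g]]
    Qs <- lapply(seq_len(36L), function(k) {
      build_intensity_matrix(params, covariate_profile(
        pg$education[k], pg$cohort[k], pg$region[k]))
    })
    age_lo <- config$age_window[[g]][1L]
    n_excluded <- 0L
    rows_id <- character(0); rows_t <- numeric(0); rows_s <- integer(0)
    rows_e <- integer(0); rows_w <- integer(0); rows_p <- integer(0)
    rows_b <- integer(0)
    for (i in seq_len(n)) {
      k <- pidx[i]
      cr <- cohort_range[[pg$cohort[k]]]
      by <- sample(seq(cr[1L], cr[2L]), 1L)
      first_idx <- config$region_entry_wave[[pg$region[k]]]
      eligible <- which(seq_along(ws) >= first_idx & ws - by >= age_lo)
      if (!length(eligible)) { n_excluded <- n_excluded + 1L; next }
      sched <- ws[eligible[1L]:length(ws)]
      start <- if (stats::runif(1L) <
                   config$p_initial_poor[[g]][pg$key[k]]) STATE_POOR
               else STATE_GOOD
      horizon <- sched[length(sched)] - sched[1L] + config$gap_jitter + 1
      path <- simulate_trajectory(Qs[[k]], start, horizon)
      obs <- observe_at_waves(path, sched, config)
      if (!obs$keep) n_excluded <- n_excluded + 1L
      n_obs <- length(obs$times)
      if (n_obs == 0L) next
      rows_id <- c(rows_id, rep(sprintf("%s%05d", g, i), n_obs))
      rows_t <- c(rows_t, sched[1L] + obs$times)
      rows_s <- c(rows_s, obs$states)
      rows_e <- c(rows_e, as.integer(obs$exact))
      rows_w <- c(rows_w, obs$wave + eligible[1L] - 1L)
      rows_p <- c(rows_p, rep(k, n_obs))
      rows_b <- c(rows_b, rep(by, n_obs))
    }
    excl[g] <- n_excluded / n
    if (length(rows_id)) {
      acc[[g]] <- data.frame(
        id = rows_id, gender = g,
        education = pg$education[rows_p], cohort = pg$cohort[rows_p],
        region = pg$region[rows_p], birth_year = rows_b,
        time = rows_t, state = rows_s, exact_death = rows_e,
        wave = rows_w, stringsAsFactors = FALSE
      )
    }
  }
  panel <- if (length(acc)) do.call(rbind, acc) else data.frame(
    id = character(0), gender = character(0), education = character(0),
    cohort = character(0), region = character(0),
    birth_year = integer(0), time = numeric(0), state = integer(0),
    exact_death = integer(0), wave = integer(0)
  )
  rownames(panel) <- NULL
  manifest <- list(
    true_params = lapply(config$true_params[genders], pack_params),
    seed = config$seed,
    genders = genders,
    n_subjects = as.list(config$n_subjects[genders]),
    exclusion_fraction = as.list(excl),
    wave_schedule = ws,
    gap_jitter = config$gap_jitter,
    p_skip_wave = config$p_skip_wave,
    p_dropout = config$p_dropout
  )
  list(panel = panel, manifest = manifest)
}
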