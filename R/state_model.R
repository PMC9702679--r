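# State space, covariate coding, and intensity-matrix construction for the
# three-state illness-death model with recovery:
#   1 = good health, 2 = poor health, 3 = dead (absorbing).
# Allowed transitions: 1->2 (deterioration), 2->1 (recovery), 1->3, 2->3.

#' @export
STATE_GOOD <- 1L
#' @export
STATE_POOR <- 2L
#' @export
STATE_DEAD <- 3L

STATE_LABELS <- c("good", "poor", "dead")

# Transition codes, in the fixed order used throughout the package.
TRANSITIONS <- c("good-poor", "poor-good", "good-dead", "poor-dead")
TRANSITION_FROM <- c(1L, 2L, 1L, 2L)
TRANSITION_TO <- c(2L, 1L, 3L, 3L)

EDUCATION_LEVELS <- c("low", "medium", "high")
COHORT_LEVELS <- c("1920-1939", "1940-1949", "1950-1962")
REGION_LEVELS <- c("central", "northern", "southern", "eastern")
GENDER_LEVELS <- c("F", "M")

# Dummy-coding columns. Reference levels: education = high (tertiary),
# cohort = 1950-1962 (youngest), region = central (largest group).
DESIGN_NAMES <- c(
  "edu_low", "edu_medium",
  "cohort_1920_1939", "cohort_1940_1949",
  "region_northern", "region_southern", "region_eastern"
)
N_DESIGN <- length(DESIGN_NAMES)
N_PARAMS <- length(TRANSITIONS) * (1L + N_DESIGN)

#' Allowed transition structure of the illness-death model
#'
#' Returns the set of permitted instantaneous transitions and the absorbing
#' states. Death (state 3) is absorbing: it has no outgoing transitions.
#'
#' @return A list with elements `allowed` (4 x 2 integer matrix of
#'   from/to state pairs) and `absorbing` (integer vector).
#' @export
transition_structure <- function() {
  list(
    allowed = cbind(from = TRANSITION_FROM, to = TRANSITION_TO),
    absorbing = STATE_DEAD
  )
}

#' Dichotomize a five-category self-perceived health response
#'
#' Collapses the standard five-point self-perceived health scale into the
#' binary good/poor classification used by the model: excellent, very good
#' and good map to good health; fair and poor map to poor health. Matching
#' is case-insensitive after trimming surrounding whitespace.
#'
#' @param category Character vector of responses among "excellent",
#'   "very good", "good", "fair", "poor".
#' @return Integer vector of states (`STATE_GOOD` or `STATE_POOR`).
#' @examples
#' dichotomize_srh(c("excellent", "fair"))
#' @export
dichotomize_srh <- function(category) {
  x <- tolower(trimws(as.character(category)))
  out <- integer(length(x))
  good <- x %in% c("excellent", "very good", "good")
  poor <- x %in% c("fair", "poor")
  bad <- !(good | poor)
  if (any(bad)) {
    stop("unknown self-perceived health category: ",
         paste(sQuote(unique(category[bad])), collapse = ", "))
  }
  out[good] <- STATE_GOOD
  out[poor] <- STATE_POOR
  out
}

#' Construct a covariate profile
#'
#' A profile holds the three design covariates (education, birth cohort,
#' country group) plus the gender stratum. Gender never enters the design
#' vector: it selects which of the two stratified models applies.
#'
#' @param education One of "low", "medium", "high".
#' @param cohort One of "1920-1939", "1940-1949", "1950-1962".
#' @param region One of "central", "northern", "southern", "eastern".
#' @param gender Optional, "F" or "M".
#' @return An object of class `covariate_profile`.
#' @export
covariate_profile <- function(education, cohort, region, gender = NULL) {
  education <- match.arg(as.character(education), EDUCATION_LEVELS)
  cohort <- match.arg(as.character(cohort), COHORT_LEVELS)
  region <- match.arg(as.character(region), REGION_LEVELS)
  if (!is.null(gender)) gender <- match.arg(as.character(gender), GENDER_LEVELS)
  structure(
    list(education = education, cohort = cohort, region = region,
         gender = gender),
    class = "covariate_profile"
  )
}

#' @export
print.covariate_profile <- function(x, ...) {
  cat("covariate profile:",
      if (!is.null(x$gender)) paste0("gender=", x$gender) else "",
      paste0("education=", x$education),
      paste0("cohort=", x$cohort),
      paste0("region=", x$region), "\n")
  invisible(x)
}

#' Encode a covariate profile as a 0/1 design vector
#'
#' Dummy coding with reference levels education = high, cohort = 1950-1962,
#' region = central; the reference profile maps to the all-zero vector.
#'
#' @param profile A `covariate_profile`.
#' @return Named numeric vector of length 7.
#' @export
encode_covariates <- function(profile) {
  stopifnot(inherits(profile, "covariate_profile"))
  z <- stats::setNames(numeric(N_DESIGN), DESIGN_NAMES)
  if (profile$education == "low") z["edu_low"] <- 1
  if (profile$education == "medium") z["edu_medium"] <- 1
  if (profile$cohort == "1920-1939") z["cohort_1920_1939"] <- 1
  if (profile$cohort == "1940-1949") z["cohort_1940_1949"] <- 1
  if (profile$region == "northern") z["region_northern"] <- 1
  if (profile$region == "southern") z["region_southern"] <- 1
  if (profile$region == "eastern") z["region_eastern"] <- 1
  z
}

#' Grid of all covariate profiles
#'
#' All 36 education x cohort x region combinations, in a fixed order, with
#' the corresponding 36 x 7 design matrix.
#'
#' @return A list with `profiles` (data.frame with columns education, cohort,
#'   region and key) and `design` (36 x 7 matrix).
#' @export
profile_grid <- function() {
  g <- expand.grid(
    education = EDUCATION_LEVELS, cohort = COHORT_LEVELS,
    region = REGION_LEVELS,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g$key <- profile_key(g$education, g$cohort, g$region)
  design <- t(vapply(
    seq_len(nrow(g)),
    function(i) encode_covariates(
      covariate_profile(g$education[i], g$cohort[i], g$region[i])
    ),
    numeric(N_DESIGN)
  ))
  rownames(design) <- g$key
  list(profiles = g, design = design)
}

profile_key <- function(education, cohort, region) {
  paste(education, cohort, region, sep = "|")
}

#' Model parameters of the proportional-intensity model
#'
#' Holds the four baseline log-intensities (log events/year, at the reference
#' profile) and, per transition, seven log hazard ratios for the covariate
#' indicators: 4 + 4 x 7 = 32 free parameters.
#'
#' @param logq0 Numeric vector of length 4 (order: good-poor, poor-good,
#'   good-dead, poor-dead), baseline log-intensities.
#' @param beta 4 x 7 numeric matrix of log hazard ratios (rows = transitions,
#'   columns = design indicators); defaults to all zeros.
#' @return An object of class `msm_params`.
#' @export
model_params <- function(logq0, beta = NULL) {
  logq0 <- as.numeric(logq0)
  if (length(logq0) != 4L) stop("logq0 must have length 4")
  if (is.null(beta)) beta <- matrix(0, 4L, N_DESIGN)
  beta <- matrix(as.numeric(beta), 4L, N_DESIGN)
  if (!all(is.finite(logq0)) || !all(is.finite(beta))) {
    stop("model parameters must be finite")
  }
  names(logq0) <- TRANSITIONS
  dimnames(beta) <- list(TRANSITIONS, DESIGN_NAMES)
  structure(list(logq0 = logq0, beta = beta), class = "msm_params")
}

#' @export
print.msm_params <- function(x, ...) {
  cat("three-state model parameters (baseline intensities, events/year):\n")
  print(round(exp(x$logq0), 4))
  cat("log hazard ratios:\n")
  print(round(x$beta, 4))
  invisible(x)
}

# Flatten parameters to the 32-vector used by the optimizer and vcov:
# first the 4 baseline log-intensities, then the betas grouped by transition.
pack_params <- function(params) {
  stopifnot(inherits(params, "msm_params"))
  theta <- c(params$logq0, as.vector(t(params$beta)))
  names(theta) <- theta_names()
  theta
}

unpack_params <- function(theta) {
  stopifnot(length(theta) == N_PARAMS)
  model_params(
    logq0 = theta[1:4],
    beta = matrix(theta[-(1:4)], 4L, N_DESIGN, byrow = TRUE)
  )
}

theta_names <- function() {
  c(
    paste0("logq0.", TRANSITIONS),
    paste0(rep(TRANSITIONS, each = N_DESIGN), ".", rep(DESIGN_NAMES, 4L))
  )
}

# Per-profile transition intensities q_ih = exp(logq0_ih + beta_ih . z),
# returned as a vector in TRANSITIONS order.
intensity_vector <- function(params, z) {
  exp(params$logq0 + as.vector(params$beta %*% z))
}

#' Build the 3 x 3 transition-intensity matrix for a covariate profile
#'
#' Each allowed off-diagonal entry is the baseline intensity multiplied by
#' exp(beta . z) for the profile's design vector z; diagonal entries are
#' minus the row sums, and the death row is all zeros (absorbing state).
#'
#' @param params An `msm_params` object.
#' @param profile A `covariate_profile`.
#' @return 3 x 3 intensity matrix (events/year) with state dimnames.
#' @export
build_intensity_matrix <- function(params, profile) {
  z <- encode_covariates(profile)
  q <- intensity_vector(params, z)
  if (!all(is.finite(q))) {
    stop("non-finite intensity for transition ",
         paste(TRANSITIONS[!is.finite(q)], collapse = ", "))
  }
  Q <- matrix(0, 3L, 3L, dimnames = list(STATE_LABELS, STATE_LABELS))
  Q[cbind(TRANSITION_FROM, TRANSITION_TO)] <- q
  diag(Q) <- -rowSums(Q)
  Q
}

# Validity check used by the probability and simulation code.
validate_intensity_matrix <- function(Q) {
  if (!is.matrix(Q) || any(dim(Q) != 3L) || !all(is.finite(Q))) {
    stop("Q must be a finite 3 x 3 matrix")
  }
  off <- Q[cbind(TRANSITION_FROM, TRANSITION_TO)]
  if (any(off < 0)) stop("off-diagonal intensities must be non-negative")
  if (any(abs(Q[3L, ]) > 0)) stop("death row of Q must be zero (absorbing)")
  if (Q[1L, 1L] != -(Q[1L, 2L] + Q[1L, 3L]) ||
      Q[2L, 2L] != -(Q[2L, 1L] + Q[2L, 3L])) {
    if (max(abs(rowSums(Q))) > 1e-12) stop("rows of Q must sum to zero")
  }
  invisible(Q)
}
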