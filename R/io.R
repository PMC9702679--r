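# Long-format panel interchange: one row per subject-interview (plus one row
# for an exact death date). CSV with header; comma separated; UTF-8.
#
# Columns: id, gender (F/M), education (low/medium/high),
# cohort (1920-1939/1940-1949/1950-1962),
# region (central/northern/southern/eastern), birth_year (integer),
# time (decimal calendar year), state (1/2/3 or a five-category
# self-perceived health label), exact_death (0/1).

PANEL_COLUMNS <- c("id", "gender", "education", "cohort", "region",
                   "birth_year", "time", "state", "exact_death")

# Structural validation shared by the likelihood and descriptive code.
# Collects all failures (with offending subjects/rows) before rejecting.
validate_panel <- function(panel) {
  if (!is.data.frame(panel)) stop("panel must be a data.frame")
  missing_cols <- setdiff(setdiff(PANEL_COLUMNS, "birth_year"),
                          names(panel))
  if (length(missing_cols)) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(panel) == 0L) return(invisible(panel))
  problems <- character(0)
  bad_state <- !(panel$state %in% 1:3)
  if (any(bad_state)) {
    problems <- c(problems, paste0(
      "invalid state codes in rows ",
      paste(utils::head(which(bad_state), 5L), collapse = ", ")))
  }
  bad_lvl <- !(panel$gender %in% GENDER_LEVELS) |
    !(panel$education %in% EDUCATION_LEVELS) |
    !(panel$cohort %in% COHORT_LEVELS) |
    !(panel$region %in% REGION_LEVELS)
  if (any(bad_lvl)) {
    problems <- c(problems, paste0(
      "invalid covariate levels in rows ",
      paste(utils::head(which(bad_lvl), 5L), collapse = ", ")))
  }
  ord <- order(panel$id, panel$time)
  p <- panel[ord, , drop = FALSE]
  same <- p$id[-1L] == p$id[-nrow(p)]
  if (any(same)) {
    i1 <- which(same); i2 <- i1 + 1L
    dup <- p$time[i2] - p$time[i1] <= 0
    if (any(dup)) {
      problems <- c(problems, paste0(
        "non-increasing interview times for subject(s) ",
        paste(unique(utils::head(p$id[i1][dup], 5L)), collapse = ", ")))
    }
    post_death <- p$state[i1] == STATE_DEAD
    if (any(post_death)) {
      problems <- c(problems, paste0(
        "observation after death for subject(s) ",
        paste(unique(utils::head(p$id[i1][post_death], 5L)),
              collapse = ", ")))
    }
    drift <- p$education[i1] != p$education[i2] |
      p$cohort[i1] != p$cohort[i2] | p$region[i1] != p$region[i2] |
      p$gender[i1] != p$gender[i2]
    if (any(drift)) {
      problems <- c(problems, paste0(
        "covariates change within subject(s) ",
        paste(unique(utils::head(p$id[i1][drift], 5L)), collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop("invalid panel dataset:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  invisible(panel)
}

#' Read a long-format panel CSV
#'
#' Parses and validates a panel file. The `state` column may hold integer
#' codes 1/2/3 or five-category self-perceived health labels, which are
#' dichotomized via [dichotomize_srh()]; a label of "dead" (or code 3) marks
#' death. Validation failures are reported together with the subjects and
#' rows concerned, and reject the whole file.
#'
#' @param path Path to a CSV file with the panel column contract.
#' @return Validated panel data.frame with integer states.
#' @export
read_panel <- function(path) {
  # gender must never be parsed as a logical column (a file of all "F")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(gender = "character"))
  missing_cols <- setdiff(setdiff(PANEL_COLUMNS, "birth_year"), names(raw))
  if (length(missing_cols)) {
    stop("panel file ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  st <- raw$state
  if (is.character(st)) {
    stl <- tolower(trimws(st))
    num <- suppressWarnings(as.integer(stl))
    is_num <- !is.na(num)
    out <- integer(length(st))
    out[is_num] <- num[is_num]
    dead <- !is_num & stl == "dead"
    out[dead] <- STATE_DEAD
    lab <- !is_num & !dead
    if (any(lab)) out[lab] <- dichotomize_srh(st[lab])
    raw$state <- out
  } else {
    raw$state <- as.integer(st)
  }
  raw$id <- as.character(raw$id)
  raw$time <- as.numeric(raw$time)
  raw$exact_death <- as.integer(raw$exact_death)
  validate_panel(raw)
  raw
}

#' Write a panel dataset to CSV
#'
#' @param panel Panel data.frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  cols <- intersect(c(PANEL_COLUMNS, "wave"), names(panel))
  utils::write.csv(panel[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' Writes the parameter estimates, covariance matrix, log-likelihood and
#' diagnostics so the prediction stage can run from a file.
#'
#' @param fit A `panelmsm_fit`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "panelmsm_fit"))
  doc <- list(
    package = "panelmsm", version = "0.1.0",
    gender = fit$gender,
    theta = as.list(fit$theta),
    vcov = fit$vcov,
    fixed = as.list(fit$fixed),
    loglik = fit$loglik$value, n_pairs = fit$loglik$n_pairs,
    n_subjects = fit$n_subjects,
    converged = fit$converged,
    grad_norm = fit$diagnostics$grad_norm,
    iterations = fit$diagnostics$iterations,
    config = fit$config[c("exact_death", "grad_tol", "max_iter",
                          "hessian_step", "floor")]
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path JSON file written by [write_fit()].
#' @return A `panelmsm_fit` object.
#' @export
read_fit <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta <- unlist(doc$theta)
  vcov <- matrix(as.numeric(doc$vcov), N_PARAMS, N_PARAMS,
                 dimnames = list(theta_names(), theta_names()))
  structure(
    list(
      params_hat = unpack_params(theta),
      theta = stats::setNames(as.numeric(theta), theta_names()),
      vcov = vcov,
      fixed = stats::setNames(unlist(doc$fixed), theta_names()),
      loglik = list(value = doc$loglik, n_pairs = doc$n_pairs),
      n_subjects = doc$n_subjects,
      n_pairs = doc$n_pairs,
      converged = doc$converged,
      gender = doc$gender,
      diagnostics = list(grad_norm = doc$grad_norm,
                         iterations = doc$iterations),
      config = doc$config
    ),
    class = "panelmsm_fit"
  )
}
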