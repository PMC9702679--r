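# Eligibility filtering and descriptive tables: sample composition by
# covariate group and poor-health prevalence per wave.

#' Eligibility rules of the working sample
#'
#' At least two interviews per subject, and gendered age windows checked at
#' each interview (men 50-79, women 50-84; age = interview year minus birth
#' year). Rules are identical across genders except the upper age bound.
#'
#' @param min_interviews Minimum number of interviews (live observations).
#' @param age_window Named list of c(lower, upper) ages per gender.
#' @return List of rules.
#' @export
eligibility_rules <- function(min_interviews = 2L,
                              age_window = list(F = c(50, 84),
                                                M = c(50, 79))) {
  list(min_interviews = as.integer(min_interviews),
       age_window = age_window)
}

#' Apply eligibility filters to a panel dataset
#'
#' Drops subjects with a missing birth year ("incomplete"), drops individual
#' interviews outside the gendered age window, and then drops subjects left
#' with fewer than the minimum number of interviews. Exact-death records are
#' exempt from the age-window row check (they are not interviews) but are
#' removed together with an excluded subject. Applying the filters twice is
#' the same as applying them once.
#'
#' @param panel Long-format panel data.frame with birth_year.
#' @param rules From [eligibility_rules()].
#' @return List with `panel` (filtered) and `report` (data.frame of
#'   exclusion counts by reason and gender, plus dropped-interview counts).
#' @export
apply_eligibility_filters <- function(panel, rules = eligibility_rules()) {
  validate_panel(panel)
  if (nrow(panel) == 0L) {
    report <- data.frame(gender = character(0), reason = character(0),
                         n = integer(0))
    return(list(panel = panel, report = report))
  }
  if (is.null(panel$birth_year)) panel$birth_year <- NA_integer_
  counts <- list()
  bump <- function(gender, reason, n) {
    counts[[length(counts) + 1L]] <<- data.frame(
      gender = gender, reason = reason, n = n, stringsAsFactors = FALSE)
  }

  # subjects with unknown birth year: data incomplete
  by_subject <- !duplicated(panel$id)
  na_by <- unique(panel$id[is.na(panel$birth_year)])
  for (g in unique(panel$gender[by_subject])) {
    n <- length(unique(panel$id[panel$id %in% na_by & panel$gender == g]))
    if (n > 0L) bump(g, "incomplete", n)
  }
  panel <- panel[!(panel$id %in% na_by), , drop = FALSE]

  if (nrow(panel) > 0L) {
    # interviews outside the age window (death records exempt)
    age <- panel$time - panel$birth_year
    win <- do.call(rbind, rules$age_window[panel$gender])
    out_of_window <- panel$state != STATE_DEAD &
      (age < win[, 1L] | age > win[, 2L])
    for (g in unique(panel$gender)) {
      n <- sum(out_of_window & panel$gender == g)
      if (n > 0L) bump(g, "interview-outside-age-window", n)
    }
    panel <- panel[!out_of_window, , drop = FALSE]
  }

  if (nrow(panel) > 0L) {
    # minimum interview count on what remains
    live <- panel$state != STATE_DEAD
    n_int <- tapply(live, panel$id, sum)
    few <- names(n_int)[n_int < rules$min_interviews]
    if (length(few)) {
      g_of <- panel$gender[match(few, panel$id)]
      for (g in unique(g_of)) {
        bump(g, "too-few-interviews", sum(g_of == g))
      }
    }
    panel <- panel[!(panel$id %in% few), , drop = FALSE]
  }

  report <- if (length(counts)) do.call(rbind, counts) else {
    data.frame(gender = character(0), reason = character(0), n = integer(0))
  }
  rownames(panel) <- NULL
  list(panel = panel, report = report)
}

#' Sample-characteristics table
#'
#' Per gender: subject counts and column percentages (1 decimal) by
#' education, birth cohort and country group, plus the mean number of
#' interviews per subject (2 decimals) — the composition table of the
#' working sample.
#'
#' @param panel Filtered long-format panel data.frame.
#' @return List of class `msm_table1` with `composition` (gender, block,
#'   level, n, percent) and `participation` (gender, mean_interviews).
#' @export
sample_characteristics <- function(panel) {
  validate_panel(panel)
  subj <- panel[!duplicated(panel$id),
                c("id", "gender", "education", "cohort", "region")]
  live <- panel[panel$state != STATE_DEAD, , drop = FALSE]
  comp <- list()
  for (g in unique(subj$gender)) {
    sg <- subj[subj$gender == g, ]
    total <- nrow(sg)
    for (block in c("education", "cohort", "region")) {
      levels <- switch(block, education = EDUCATION_LEVELS,
                       cohort = COHORT_LEVELS, region = REGION_LEVELS)
      n <- vapply(levels, function(l) sum(sg[[block]] == l), integer(1))
      comp[[length(comp) + 1L]] <- data.frame(
        gender = g, block = block, level = levels, n = unname(n),
        percent = round(100 * unname(n) / total, 1),
        stringsAsFactors = FALSE)
    }
  }
  participation <- do.call(rbind, lapply(unique(subj$gender), function(g) {
    ids <- subj$id[subj$gender == g]
    n_int <- table(live$id[live$gender == g])
    data.frame(gender = g,
               n_subjects = length(ids),
               mean_interviews = round(sum(n_int) / length(ids), 2))
  }))
  structure(list(composition = do.call(rbind, comp),
                 participation = participation),
            class = "msm_table1")
}

#' @export
print.msm_table1 <- function(x, ...) {
  for (g in unique(x$composition$gender)) {
    cat(sprintf("== gender %s ==\n", g))
    d <- x$composition[x$composition$gender == g, ]
    for (b in unique(d$block)) {
      cat(sprintf("%s:\n", b))
      db <- d[d$block == b, ]
      for (i in seq_len(nrow(db))) {
        cat(sprintf("  %-12s %8d  %5.1f%%\n",
                    db$level[i], db$n[i], db$percent[i]))
      }
    }
    p <- x$participation[x$participation$gender == g, ]
    cat(sprintf("mean interviews per subject: %.2f (n = %d)\n",
                p$mean_interviews, p$n_subjects))
  }
  invisible(x)
}

#' Poor-health prevalence per wave
#'
#' Percentage of attended interviews reporting poor health, per wave, by
#' gender crossed with education, cohort and country group, plus per-gender
#' totals. Cells with no attendees are NA (e.g. country groups not yet
#' sampled at a wave). Dead subjects contribute to denominators only at
#' waves they attended alive.
#'
#' @param panel Filtered panel data.frame; wave indices are taken from a
#'   `wave` column if present, otherwise assigned by nearest wave year.
#' @param wave_schedule Wave years, required when `panel` has no `wave`
#'   column.
#' @return data.frame of class `msm_table2`: gender, block, level, wave,
#'   n_interviews, prevalence (percent, 1 decimal; NA when unobserved).
#' @export
prevalence_table <- function(panel, wave_schedule = NULL) {
  validate_panel(panel)
  live <- panel[panel$state != STATE_DEAD, , drop = FALSE]
  if (is.null(live$wave) || all(is.na(live$wave))) {
    if (is.null(wave_schedule)) {
      stop("panel has no wave column; supply wave_schedule")
    }
    live$wave <- vapply(live$time,
                        function(t) which.min(abs(wave_schedule - t)),
                        integer(1))
  }
  waves <- sort(unique(live$wave))
  rows <- list()
  cell <- function(d, g, block, level, w) {
    n <- nrow(d)
    rows[[length(rows) + 1L]] <<- data.frame(
      gender = g, block = block, level = level, wave = w,
      n_interviews = n,
      prevalence = if (n > 0L)
        round(100 * mean(d$state == STATE_POOR), 1) else NA_real_,
      stringsAsFactors = FALSE)
  }
  for (g in unique(live$gender)) {
    lg <- live[live$gender == g, ]
    for (w in waves) {
      lw <- lg[lg$wave == w, ]
      for (block in c("education", "cohort", "region")) {
        levels <- switch(block, education = EDUCATION_LEVELS,
                         cohort = COHORT_LEVELS, region = REGION_LEVELS)
        for (l in levels) cell(lw[lw[[block]] == l, ], g, block, l, w)
      }
      cell(lw, g, "total", "total", w)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("msm_table2", class(out))
  out
}

#' @export
print.msm_table2 <- function(x, ...) {
  waves <- sort(unique(x$wave))
  for (g in unique(x$gender)) {
    cat(sprintf("== poor-health prevalence (%%), gender %s ==\n", g))
    cat(sprintf("%-12s", "group"),
        sprintf(" w%-5d", waves), "\n", sep = "")
    d <- x[x$gender == g, ]
    for (b in unique(d$block)) {
      for (l in unique(d$level[d$block == b])) {
        v <- vapply(waves, function(w) {
          p <- d$prevalence[d$block == b & d$level == l & d$wave == w]
          if (length(p) == 0L || is.na(p)) "  -  " else sprintf("%5.1f", p)
        }, character(1))
        cat(sprintf("%-12s", l), sprintf(" %s", v), "\n", sep = "")
      }
    }
  }
  invisible(x)
}
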