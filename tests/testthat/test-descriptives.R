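# Eligibility filtering and the composition / prevalence tables.

test_that("eligibility filters drop the documented cases", {
  # single interview: excluded with reason
  lone <- make_panel("a", 0 + 2010, 1)
  two <- make_panel("b", c(2010, 2012), c(1, 1))
  filt <- apply_eligibility_filters(rbind(lone, two))
  expect_identical(sort(unique(filt$panel$id)), "b")
  expect_true(any(filt$report$reason == "too-few-interviews" &
                    filt$report$n == 1))

  # woman aged 84 at interview retained; aged 85 that interview dropped
  w84 <- make_panel("c", c(2000, 2004), c(1, 1), birth_year = 1920L)
  f84 <- apply_eligibility_filters(w84)          # ages 80 and 84
  expect_identical(nrow(f84$panel), 2L)
  w85 <- make_panel("d", c(2000, 2003, 2005), c(1, 1, 1),
                    birth_year = 1920L)          # ages 80, 83, 85
  f85 <- apply_eligibility_filters(w85)
  expect_identical(nrow(f85$panel), 2L)
  expect_true(any(f85$report$reason == "interview-outside-age-window"))
  # the male window is tighter: same ages drop a man entirely
  m83 <- make_panel("e", c(2000, 2003), c(1, 1), gender = "M",
                    birth_year = 1920L)          # ages 80, 83
  fm <- apply_eligibility_filters(m83)
  expect_identical(nrow(fm$panel), 0L)

  # missing birth year: excluded as incomplete
  nb <- make_panel("f", c(2010, 2012), c(1, 1))
  nb$birth_year <- NA_integer_
  fnb <- apply_eligibility_filters(nb)
  expect_identical(nrow(fnb$panel), 0L)
  expect_true(any(fnb$report$reason == "incomplete"))

  # empty dataset: empty output, zero-count report
  fe <- apply_eligibility_filters(two[0, ])
  expect_identical(nrow(fe$panel), 0L)
  expect_identical(nrow(fe$report), 0L)
})

test_that("filtering is idempotent", {
  sim <- generate_cohort(small_sim_config(n = 300, seed = 51))
  once <- apply_eligibility_filters(sim$panel)
  twice <- apply_eligibility_filters(once$panel)
  expect_identical(once$panel, twice$panel)
  expect_identical(nrow(twice$report), 0L)
})

test_that("sample characteristics reproduce counts and percentages", {
  sim <- generate_cohort(small_sim_config(n = 400, seed = 52))
  panel <- apply_eligibility_filters(sim$panel)$panel
  tab <- sample_characteristics(panel)
  for (g in c("F", "M")) {
    d <- tab$composition[tab$composition$gender == g, ]
    total <- sum(d$n[d$block == "education"])
    # blocks partition the same subjects
    expect_identical(sum(d$n[d$block == "cohort"]), total)
    expect_identical(sum(d$n[d$block == "region"]), total)
    # percentages per block close under rounding
    for (b in unique(d$block)) {
      expect_lt(abs(sum(d$percent[d$block == b]) - 100), 0.2)
    }
    # recomputation of one cell
    row <- d[d$block == "education" & d$level == "low", ]
    expect_equal(row$percent, round(100 * row$n / total, 1))
  }
  # single-category dataset shows 100%
  one <- make_panel("z", c(2010, 2012), c(1, 1))
  t1 <- sample_characteristics(one)
  expect_equal(
    t1$composition$percent[t1$composition$block == "education" &
                             t1$composition$level == "high"], 100)
})

test_that("mean participations count live interviews only", {
  p <- rbind(
    make_panel("a", c(2010, 2012, 2014), c(1, 2, 1)),
    make_panel("b", c(2010, 2012, 2013.3), c(1, 2, 3))
  )
  tab <- sample_characteristics(p)
  # subject a: 3 interviews; subject b: 2 interviews + exact death record
  expect_equal(tab$participation$mean_interviews, 2.5)
})

test_that("prevalence table does the arithmetic and flags empty cells", {
  ws <- c(2004, 2007)
  # wave 1: 8 interviews, 2 poor -> 25.0%; wave 2 all good -> 0.0%
  p <- do.call(rbind, lapply(1:8, function(i)
    make_panel(paste0("s", i), c(2004, 2007), c(ifelse(i <= 2, 2, 1), 1))))
  p$wave <- ifelse(p$time == 2004, 1L, 2L)
  tab <- prevalence_table(p)
  tot <- tab[tab$block == "total", ]
  expect_equal(tot$prevalence[tot$wave == 1], 25.0)
  expect_equal(tot$prevalence[tot$wave == 2], 0.0)
  # no northern subjects: NA cell
  nor <- tab[tab$block == "region" & tab$level == "northern", ]
  expect_true(all(is.na(nor$prevalence)))

  # subgroup prevalences average (attendance-weighted) to the total
  sim <- generate_cohort(small_sim_config(n = 500, seed = 53),
                         genders = "F")
  tab2 <- prevalence_table(sim$panel)
  for (w in unique(tab2$wave)) {
    d <- tab2[tab2$wave == w & tab2$gender == "F", ]
    tot_w <- d[d$block == "total", ]
    edu <- d[d$block == "education" & d$n_interviews > 0, ]
    avg <- sum(edu$prevalence * edu$n_interviews) / sum(edu$n_interviews)
    expect_equal(avg, tot_w$prevalence, tolerance = 0.11)
    expect_true(all(d$prevalence[!is.na(d$prevalence)] >= 0 &
                      d$prevalence[!is.na(d$prevalence)] <= 100))
  }
})

test_that("configured regional ordering appears in wave-one prevalence", {
  sim <- generate_cohort(small_sim_config(n = 3000, seed = 54),
                         genders = "F")
  tab <- prevalence_table(sim$panel)
  w1 <- tab[tab$wave == 1 & tab$block == "region", ]
  n_prev <- w1$prevalence[w1$level == "northern"]
  s_prev <- w1$prevalence[w1$level == "southern"]
  expect_lt(n_prev, s_prev)
  # Eastern countries unobserved at wave 1 (entry at wave 2)
  expect_true(is.na(w1$prevalence[w1$level == "eastern"]))
})
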