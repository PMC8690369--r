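aj_rows <- function(exit, event, entry = 0) {
  tibble::tibble(entry = rep(entry, length.out = length(exit)),
                 exit = exit, event = event)
}

test_that("Aalen-Johansen reproduces hand-executed product-limit recursions", {
  ## 4 subjects: relapses at 1 and 3, death at 2, censored at 4
  cif <- aalen_johansen(aj_rows(c(1, 2, 3, 4),
                                c("relapse", "death", "relapse", "censored")))
  expect_equal(cif$cif_relapse, c(0, 0.25, 0.25, 0.50))
  expect_equal(cif$cif_death, c(0, 0, 0.25, 0.25))
  expect_equal(cif$surv, c(1, 0.75, 0.50, 0.25))

  ## one subject: the incidence jumps from 0 to 1
  cif1 <- aalen_johansen(aj_rows(5, "relapse"))
  expect_equal(cif1$cif_relapse, c(0, 1))
  expect_equal(cif1$time, c(0, 5))

  expect_error(aalen_johansen(aj_rows(c(1, 2), c("relapse", "relapse"),
                                      entry = c(0, 2))),
               "entry must precede exit")
})

test_that("without deaths the estimator equals one minus Kaplan-Meier", {
  withr::local_seed(101)
  for (i in 1:25) {
    n <- sample(2:40, 1)
    exit <- round(rexp(n, 1), 3) + 0.001
    event <- sample(c("relapse", "censored"), n, replace = TRUE, prob = c(.7, .3))
    cif <- aalen_johansen(aj_rows(exit, event))
    km <- survival::survfit(survival::Surv(exit, event == "relapse") ~ 1)
    km_at <- summary(km, times = cif$time[-1])$surv
    expect_equal(cif$cif_relapse[-1], 1 - km_at, tolerance = 1e-12)
  }
})

test_that("estimator agrees with the brute-force risk-set enumerator and survfit", {
  withr::local_seed(102)
  for (i in 1:60) {
    d <- random_aj_instance()
    if (!any(d$event != "censored")) next
    cif <- aalen_johansen(d)
    orc <- aj_oracle(d$entry, d$exit, d$event)
    expect_equal(cif$time[-1], orc$time, tolerance = 1e-12)
    expect_equal(cif$cif_relapse[-1], orc$cif_relapse, tolerance = 1e-12)
    expect_equal(cif$cif_death[-1], orc$cif_death, tolerance = 1e-12)
    expect_equal(cif$surv[-1], orc$surv, tolerance = 1e-12)
  }

  ## independent library cross-check (multistate survfit), no delayed entry
  withr::local_seed(103)
  d <- data.frame(exit = round(rexp(200, 1), 2) + 0.01,
                  event = sample(c("censored", "relapse", "death"), 200, TRUE))
  cif <- aalen_johansen(aj_rows(d$exit, d$event))
  sf <- survival::survfit(survival::Surv(exit, factor(event, c("censored", "relapse", "death"))) ~ 1,
                          data = d)
  sfs <- summary(sf, times = cif$time[-1])
  i_rel <- match("relapse", sf$states)
  expect_equal(cif$cif_relapse[-1], sfs$pstate[, i_rel], tolerance = 1e-10)
})

test_that("surv + cif_relapse + cif_death conserve probability", {
  withr::local_seed(104)
  for (i in 1:40) {
    d <- random_aj_instance(30)
    cif <- aalen_johansen(d)
    expect_lt(max(abs(cif$surv + cif$cif_relapse + cif$cif_death - 1)), 1e-10)
    expect_true(all(diff(cif$cif_relapse) >= 0))
    expect_true(all(diff(cif$cif_death) >= 0))
    expect_true(all(diff(cif$surv) <= 0))
  }
})

test_that("with constant competing hazards the limit incidence is the hazard share", {
  withr::local_seed(105)
  n <- 5000; l_rel <- 1; l_dth <- 0.5
  T1 <- rexp(n, l_rel); T2 <- rexp(n, l_dth)
  d <- aj_rows(pmin(T1, T2), ifelse(T1 <= T2, "relapse", "death"))
  cif <- aalen_johansen(d)
  p_hat <- max(cif$cif_relapse)
  p_true <- l_rel / (l_rel + l_dth)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("median extraction follows the first-crossing rule", {
  curve <- structure(
    tibble::tibble(time = c(0, 1, 2), n_risk = c(10, 10, 7),
                   d_relapse = c(0L, 3L, 3L), d_death = c(0L, 0L, 0L),
                   surv = c(1, .7, .45), cif_relapse = c(0, .3, .55),
                   cif_death = c(0, 0, 0)),
    class = c("cif_curve", "tbl_df", "tbl", "data.frame"))
  expect_equal(median_from_cif(curve), 2)
  ## a plateau below p leaves the median undefined
  curve$cif_relapse <- c(0, .3, .4)
  expect_true(is.na(median_from_cif(curve)))
  ## an exact hit at p counts (>= rule)
  curve$cif_relapse <- c(0, .5, .6); curve$time <- c(0, 1.52, 3)
  expect_equal(median_from_cif(curve), 1.52)
  expect_error(median_from_cif(curve, p = 1.2), "probability")
})

## minimal counting_data-like rows for fit_cox, with inert extra covariates
cox_rows <- function(exit, status, group, entry = 0) {
  tibble::tibble(
    patient_id = sprintf("S%04d", seq_along(exit)),
    stratum = group,
    entry = rep(entry, length.out = length(exit)), exit = exit,
    event = factor(ifelse(status == 1, "relapse", "censored"),
                   levels = c("censored", "relapse", "death")),
    prior_relapses = factor(group, levels = 0:10),
    age_class = age_class(rep(30, length(exit))),
    gender = factor("F", levels = c("F", "M")),
    calendar_year = factor(2010)
  )
}

test_that("relabelling symmetry forces a hazard ratio of exactly one", {
  exit <- c(1, 2, 3, 4, 5)
  rows <- dplyr::bind_rows(cox_rows(exit, 1, 0), cox_rows(exit, 1, 1))
  fit <- fit_cox(rows)
  expect_lt(abs(fit$strata$coef), 1e-8)
  expect_equal(fit$strata$hr, 1, tolerance = 1e-8)
})

test_that("coefficient matches a brute-force partial-likelihood maximisation", {
  withr::local_seed(106)
  ## non-monotone covariate orderings keep the maximum finite
  for (pattern in list(c(1, 0, 1), c(0, 1, 0))) {
    for (i in 1:3) {
      exit <- sort(runif(3, 1, 10)) + cumsum(runif(3, 0.01, 0.1)) # distinct times
      rows <- cox_rows(exit, 1, pattern)
      fit <- fit_cox(rows)
      b_oracle <- cox_pl_oracle(exit, rep(1, 3), pattern)
      expect_equal(fit$strata$coef, b_oracle, tolerance = 1e-6)
    }
  }
})

test_that("the Wald interval covers a true rate ratio of 2 at its nominal level", {
  withr::local_seed(107)
  hits <- 0
  for (rep in 1:100) {
    t0 <- rexp(200, 1); t1 <- rexp(200, 2)
    rows <- dplyr::bind_rows(cox_rows(t0, 1, 0), cox_rows(t1, 1, 1))
    fit <- fit_cox(rows)
    s <- fit$strata
    hits <- hits + (s$conf_low <= 2 && 2 <= s$conf_high)
  }
  expect_gte(hits, 90)
})

test_that("hazard ratios are invariant to a change of time unit", {
  withr::local_seed(108)
  exit <- rexp(60, 1); x <- rep(0:1, 30)
  rows <- cox_rows(exit, 1, x)
  rows2 <- dplyr::mutate(rows, exit = exit * 365.25)
  f1 <- fit_cox(rows); f2 <- fit_cox(rows2)
  expect_equal(f1$strata$hr, f2$strata$hr, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected or trimmed with a warning", {
  rows <- cox_rows(c(1, 2, 3), 0, c(0, 1, 1)) # no events at all
  expect_error(fit_cox(rows), "no relapse events")
})

test_that("tidy and glance expose the fit in broom style", {
  withr::local_seed(109)
  rows <- dplyr::bind_rows(cox_rows(rexp(50, 1), 1, 0), cox_rows(rexp(50, 2), 1, 1))
  fit <- fit_cox(rows)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "hr", "conf.low", "conf.high") %in% names(td)))
  gl <- glance(fit)
  expect_identical(gl$n_events, 100L)
  expect_identical(nrow(gl), 1L)
})
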