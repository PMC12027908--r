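test_that("median dichotomization splits strictly above the cutoff", {
  md <- median_dichotomize(c(1, 2, 3))
  expect_identical(md$cutoff, 2)
  expect_identical(md$indicator, c(0L, 0L, 1L))
  expect_error(median_dichotomize(c(5, 5, 5)), "degenerate")
  expect_error(median_dichotomize(3), "at least 2")
  set.seed(6)
  co <- simulate_cohort(cohort_config(n = 1e4, seed = 6))
  expect_lt(abs(median_dichotomize(co$nt_probnp_pg_ml)$cutoff - 104) / 104,
            0.10)
})

test_that("Kaplan-Meier matches the hand product-limit estimator", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 0))
  ev <- km[km$n_event > 0, ]
  expect_equal(ev$survival, c(0.75, 0.50, 0.25))
  # all censored: flat at 1
  km0 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$survival == 1))
  # no censoring: equals empirical survivor fraction; random data vs oracle
  set.seed(10)
  t <- rexp(60)
  km1 <- kaplan_meier(t, rep(1, 60))
  expect_equal(km1$survival, 1 - seq_len(60) / 60, tolerance = 1e-12)
  t2 <- rexp(100); e2 <- rbinom(100, 1, 0.6)
  km2 <- kaplan_meier(t2, e2)
  oracle <- hand_km(t2, e2)
  expect_equal(km2$survival[km2$n_event > 0], oracle$survival,
               tolerance = 1e-12)
})

test_that("Cox fit recovers known hazard ratios", {
  set.seed(21)
  # light censoring so nearly all 2000 subjects contribute events
  d <- sim_exp_ph(2000, log(2), base_rate = 0.5, cens = c(4, 10))
  f <- fit_cox(data.frame(x = d$x), d$times, d$events)
  expect_gt(unname(f$hazard_ratios), 1.8)
  expect_lt(unname(f$hazard_ratios), 2.2)
  dn <- sim_exp_ph(2000, 0, base_rate = 0.5, cens = c(4, 10))
  fn <- fit_cox(data.frame(x = dn$x), dn$times, dn$events)
  expect_gt(unname(fn$hazard_ratios), 0.85)
  expect_lt(unname(fn$hazard_ratios), 1.18)
})

test_that("Cox degenerate and separated inputs raise errors", {
  set.seed(22)
  d <- sim_exp_ph(50, log(2))
  expect_error(fit_cox(data.frame(x = rep(1, 50)), d$times, d$events),
               "degeneracy")
  # perfect separation: covariate is the reverse rank of untied event times
  t <- 1:20
  x <- rev(seq_along(t))
  expect_error(fit_cox(data.frame(x = x), t, rep(1, 20)), "monotone")
})

test_that("maximised log partial likelihood matches brute-force enumeration", {
  set.seed(23)
  for (r in 1:10) {
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n * 2), n)
    times <- sample(seq_len(50), n)  # untied
    events <- rbinom(n, 1, 0.7)
    if (sum(events) < 1) events[1] <- 1
    f <- try(fit_cox(as.data.frame(x), times, events), silent = TRUE)
    if (inherits(f, "try-error")) next  # separation in a tiny draw
    expect_equal(f$loglik,
                 brute_force_cox_loglik(f$coefficients, x, times, events),
                 tolerance = 1e-10)
    expect_equal(f$loglik_null,
                 brute_force_cox_loglik(c(0, 0), x, times, events),
                 tolerance = 1e-10)
  }
})

test_that("bootstrap CI is percentile-based, seeded and uses B resamples", {
  const <- data.frame(v = rep(4.2, 30))
  ci <- bootstrap_ci(function(d) mean(d$v), const, B = 100, seed = 1)
  expect_equal(unname(ci[1, ]), c(4.2, 4.2))
  calls <- new.env(); calls$n <- 0L
  dat <- data.frame(v = rnorm(50))
  ci1 <- bootstrap_ci(function(d) { calls$n <- calls$n + 1L; mean(d$v) },
                      dat, seed = 9)
  expect_identical(calls$n, 1000L)
  ci2 <- bootstrap_ci(function(d) mean(d$v), dat, seed = 9)
  expect_identical(ci1, ci2)  # bit-reproducible under a fixed seed
  expect_error(bootstrap_ci(function(d) stop("no"), dat, B = 10),
               "bootstrap error")
})

test_that("bootstrap interval for a mean has near-nominal coverage", {
  set.seed(31)
  hits <- 0
  for (r in 1:300) {
    d <- data.frame(v = rnorm(200))
    ci <- bootstrap_ci(function(dd) mean(dd$v), d, B = 200)
    hits <- hits + (ci[1, "lower"] <= 0 && 0 <= ci[1, "upper"])
  }
  expect_gt(hits / 300, 0.90)
  expect_lt(hits / 300, 0.99)
})

test_that("stepwise BIC keeps one copy of duplicated candidates and a falling trajectory", {
  set.seed(41)
  d <- sim_exp_ph(800, log(3))
  cand <- data.frame(a = d$x, b = d$x, noise = rnorm(800))
  # the duplicate column is collinear once 'a' enters; it is skipped with a
  # warning and cannot be selected
  m <- suppressWarnings(stepwise_bic(cand, d$times, d$events))
  expect_identical(m$selected, "a")  # earliest duplicate wins the tie
  expect_true(all(diff(m$bic_trajectory) < 0))
  expect_s3_class(m$fit, "cox_fit")
  expect_gt(m$c_statistic, 0.5)
})

test_that("Harrell's C handles perfect, tied and null rankings", {
  expect_identical(harrell_c(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_identical(harrell_c(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 0)
  expect_identical(harrell_c(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1)), 0.5)
  expect_error(harrell_c(c(1, 2), c(5, 3), c(0, 0)), "no usable pairs")
  set.seed(51)
  d <- sim_exp_ph(2000, 0)
  cnull <- harrell_c(rnorm(2000), d$times, d$events)
  expect_lt(abs(cnull - 0.5), 0.03)
})

test_that("Harrell's C is antisymmetric and matches the survival package", {
  set.seed(52)
  d <- sim_exp_ph(300, log(2))
  risk <- rnorm(300) + d$x
  c1 <- harrell_c(risk, d$times, d$events)
  expect_equal(c1 + harrell_c(-risk, d$times, d$events), 1, tolerance = 1e-12)
  ref <- survival::concordance(survival::Surv(d$times, d$events) ~ risk,
                               reverse = TRUE)$concordance
  expect_equal(c1, ref, tolerance = 1e-10)
})

test_that("descriptive comparison routes tests by normality and type", {
  set.seed(61)
  n <- 120
  co <- data.frame(
    normal_var = rnorm(n, 10, 2),
    skewed_var = rlnorm(n, 0, 1.2),
    binary_var = rbinom(n, 1, 0.3),
    follow_up_years = runif(n, 0.2, 3),
    event = 0L)
  co$event[1:12] <- 1L
  co$follow_up_years[1:12] <- 0.5
  tab <- compare_descriptives(co)
  expect_identical(tab$test[tab$variable == "normal_var"], "t")
  expect_identical(tab$test[tab$variable == "skewed_var"], "mann-whitney")
  expect_identical(tab$test[tab$variable == "binary_var"], "fisher")
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
})

test_that("Fisher routing reproduces the hypergeometric enumeration exactly", {
  # 110 patients: 12/100 exposed among 1-year survivors, 8/10 among deaths
  group <- c(rep(FALSE, 100), rep(TRUE, 10))
  x <- c(rep(1, 12), rep(0, 88), rep(1, 8), rep(0, 2))
  co <- data.frame(valvular = x,
                   follow_up_years = ifelse(group, 0.5, 2), event = as.integer(group))
  tab <- compare_descriptives(co, variables = "valvular")
  expect_equal(tab$p_value,
               enum_fisher_p(rbind(c(12, 88), c(8, 2))), tolerance = 1e-12)
})

test_that("identical groups give p near 1 and tiny groups are skipped", {
  base <- data.frame(m = c(rnorm(30, 5), rnorm(30, 5)),
                     b = rep(c(0, 1), 30))
  g <- rep(c(FALSE, TRUE), each = 30)
  base$m[31:60] <- base$m[1:30]  # group 1 duplicates group 0
  base$b[31:60] <- base$b[1:30]
  tab <- compare_descriptives(base, group = g, variables = c("m", "b"))
  expect_true(all(tab$p_value > 0.95))
  expect_warning(
    compare_descriptives(data.frame(v = rnorm(10)),
                         group = c(rep(FALSE, 9), TRUE), variables = "v"),
    "skipped")
})
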