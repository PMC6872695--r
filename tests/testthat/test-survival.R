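test_that("Kaplan-Meier handles hand-computable cases", {
  # all censored: flat at 1
  km <- km_estimate(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km$survival == 1))
  # three events: 2/3, 1/3, 0
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # one event among n at risk: step to (n-1)/n
  km <- km_estimate(c(4, 7, 9, 11), c(1, 0, 0, 0))
  expect_equal(km$survival[km$time == 4], 3 / 4)
  expect_true(all(diff(km$survival) <= 0))
})

test_that("Kaplan-Meier matches survfit and ignores record order", {
  withr::with_seed(21, {
    for (i in 1:10) {
      n <- 60
      time <- ceiling(rexp(n, 0.01))   # day resolution forces ties
      event <- rbinom(n, 1, 0.7)
      km <- km_estimate(time, event)
      sf <- survival::survfit(survival::Surv(time, event) ~ 1)
      sf_at <- summary(sf, times = km$time)
      expect_equal(km$survival, sf_at$surv, tolerance = 1e-12)
      o <- sample(n)
      expect_identical(km, km_estimate(time[o], event[o]))
    }
  })
})

test_that("log-rank of a group against its own copy is null", {
  time <- c(3, 5, 8, 12, 17)
  event <- c(1, 0, 1, 1, 0)
  res <- logrank_test(c(time, time), c(event, event),
                      rep(c("a", "b"), each = 5))
  expect_equal(res$chi_square, 0)
  expect_equal(res$p_value, 1)
})

test_that("log-rank matches the survdiff oracle and is symmetric", {
  withr::with_seed(22, {
    for (i in 1:30) {
      n <- 80
      g <- rbinom(n, 1, 0.5)
      time <- ceiling(rexp(n, 0.01 * exp(0.4 * g)))
      event <- rbinom(n, 1, 0.75)
      res <- logrank_test(time, event, g)
      expect_equal(res$chi_square, oracle_logrank_chi(time, event, g),
                   tolerance = 1e-9)
      swapped <- logrank_test(time, event, 1 - g)
      expect_equal(res$chi_square, swapped$chi_square, tolerance = 1e-12)
    }
  })
})

test_that("log-rank without any events is an error", {
  expect_error(logrank_test(c(1, 2, 3, 4), c(0, 0, 0, 0), c(1, 1, 2, 2)),
               class = "hetpet_undefined_test")
})

test_that("Cox recovers a null and a planted effect", {
  withr::with_seed(23, {
    d0 <- sim_surv(1000, beta = 0)
    f0 <- cox_fit(d0, covariates = "x")
    expect_lt(abs(tidy(f0)$estimate), 3 * tidy(f0)$std_error)
    betas <- replicate(20, {
      d <- sim_surv(600, beta = 0.7)
      tidy(cox_fit(d, covariates = "x"))$estimate
    })
    expect_lt(abs(mean(betas) - 0.7), 0.08)
  })
  expect_true(f0$converged)
  expect_equal(tidy(f0)$hazard_ratio, exp(tidy(f0)$estimate))
  td <- tidy(f0)
  expect_true(td$ci95_low < td$hazard_ratio & td$hazard_ratio < td$ci95_high)
})

test_that("Cox estimates are stable under duplication and centering", {
  withr::with_seed(24, {
    d <- sim_surv(300, beta = 0.5)
  })
  b <- tidy(cox_fit(d, covariates = "x"))$estimate
  d2 <- rbind(d, d)
  b2 <- tidy(cox_fit(d2, covariates = "x"))$estimate
  expect_equal(b, b2, tolerance = 0.02)   # identical up to Efron ties
  dc <- d; dc$x <- dc$x - mean(dc$x)
  expect_equal(tidy(cox_fit(dc, covariates = "x"))$estimate, b,
               tolerance = 1e-6)
})

test_that("log-rank direction agrees with the Cox coefficient sign", {
  withr::with_seed(25, {
    d <- sim_surv(400, beta = 0.8)
  })
  res <- logrank_test(d$time, d$event, d$x)
  fit <- tidy(cox_fit(d, covariates = "x"))
  # group coded 1 has elevated hazard: positive log-HR, significant split
  expect_gt(fit$estimate, 0)
  expect_gt(res$chi_square, qchisq(0.95, 1))
})

test_that("Cox validates degenerate inputs", {
  d <- data.frame(time = c(5, 6, 7, 8), event = c(1, 1, 0, 1),
                  x = c(1, 1, 1, 1))
  expect_error(cox_fit(d, covariates = "x"), class = "hetpet_input_error")
  d2 <- data.frame(time = c(5, 6, 7, 8), event = c(0, 0, 0, 1),
                   x = c(1, 2, 3, 4), y = c(2, 1, 4, 3))
  expect_error(cox_fit(d2, covariates = c("x", "y")),
               class = "hetpet_insufficient_data")
  expect_error(cox_fit(d2, covariates = "z"), class = "hetpet_input_error")
})

test_that("categorical covariates are reference-coded", {
  withr::with_seed(26, {
    n <- 300
    stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE)
    lam <- 0.002 * exp(c(I = 0, II = 0.2, III = 0.5, IV = 0.9)[stage])
    d <- data.frame(time = rexp(n, lam), event = 1, stage = stage)
  })
  fit <- cox_fit(d, covariates = "stage")
  td <- tidy(fit)
  expect_equal(td$term, c("stageII", "stageIII", "stageIV"))
  expect_gt(td$estimate[3], td$estimate[1])
})

test_that("clinical tables read with tolerant headers and listwise deletion", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "Case_ID,OS_Days,Vital_Status,AGE,Gender,Tumor_Stage,GlycoS",
    "P1,100,Dead,61,male,III,0.9",
    "P2,450,Alive,55,female,II,0.7",
    "P3,NA,Alive,70,male,IV,1.1"
  ), path)
  expect_message(cl <- read_clinical(path), "dropped")
  expect_equal(nrow(cl), 2)
  expect_equal(cl$event, c(1L, 0L))
  expect_named(cl, c("patient_id", "os_days", "event", "age", "sex",
                     "stage", "glycos"), ignore.order = TRUE)
})
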