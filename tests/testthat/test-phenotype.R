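test_that("conditional expectation of a censored normal is exact and
           monotone", {
  # at the mean, E[Y | Y > mu] = mu + sigma * sqrt(2/pi)
  expect_equal(conditional_expectation_censored(120, 120, 15),
               120 + 15 * sqrt(2 / pi), tolerance = 1e-10)
  # quadrature oracle: truncated-normal mean by numerical integration
  tn_mean <- function(y, mu, sig) {
    stats::integrate(function(x) x * dnorm(x, mu, sig), y, Inf,
                     rel.tol = 1e-12)$value /
      pnorm(y, mu, sig, lower.tail = FALSE)
  }
  for (case in list(c(140, 120, 15), c(100, 120, 15), c(125, 120, 2))) {
    expect_equal(conditional_expectation_censored(case[1], case[2], case[3]),
                 tn_mean(case[1], case[2], case[3]), tolerance = 1e-8)
  }
  # always exceeds the observed value; tail contraction as sigma -> 0
  expect_gt(conditional_expectation_censored(140, 120, 15), 140)
  expect_warning(y_small <- conditional_expectation_censored(140, 120, 0.5),
                 "clipped")   # alpha = 40 is deep in the tail
  expect_equal(y_small, 140, tolerance = 1e-3)
  # monotone increasing in y_obs and in mu
  ys <- conditional_expectation_censored(seq(110, 150, 5), 120, 15)
  expect_true(all(diff(ys) > 0))
  mus <- conditional_expectation_censored(130, seq(100, 140, 5), 15)
  expect_true(all(diff(mus) > 0))
  # degenerate tail is clipped with a warning
  expect_warning(yc <- conditional_expectation_censored(200, 100, 1),
                 "clipped")
  expect_gt(yc, 200)
  expect_error(conditional_expectation_censored(120, 120, -1), "positive")
})

test_that("with no censoring the fit reduces to an ordinary linear mixed
           model", {
  cfg <- sim_config(n_pedigrees = 30, sibship = 3, n_marry = 1, h2 = 0,
                    tau_ped = 5, sigma_total = 15, n_exams = 1,
                    censoring = list(enabled = FALSE), seed = 4)
  peds <- simulate_pedigrees(cfg)
  rec <- simulate_phenotypes(peds, cfg, seed = 4)$records
  f <- fit_censored_exam(rec)
  lm <- lme4::lmer(sbp ~ I(sex == "male") + age + I(smoke == "yes") +
                     (1 | fam), data = rec, REML = FALSE)
  ref <- c(lme4::fixef(lm), sigma(lm))
  est <- c(f$coefficients, f$sigma)
  expect_lt(max(abs(est - ref) / abs(ref)), 1e-4)
  # the random-intercept scale is compared absolutely: near a boundary a
  # relative criterion on a tiny variance is meaningless
  expect_lt(abs(f$tau - sqrt(unlist(lme4::VarCorr(lm)))), 1e-3)
  expect_equal(f$loglik, as.numeric(logLik(lm)), tolerance = 1e-6)
})

test_that("with no pedigree variation the fit approaches a single-level
           tobit", {
  cfg <- sim_config(n_pedigrees = 40, sibship = 3, n_marry = 1, h2 = 0,
                    tau_ped = 0, sigma_total = 15, n_exams = 1, seed = 6)
  peds <- simulate_pedigrees(cfg)
  rec <- simulate_phenotypes(peds, cfg, seed = 6)$records
  f <- fit_censored_exam(rec)
  sv <- survival::survreg(
    survival::Surv(sbp, med == "no") ~ I(sex == "male") + age +
      I(smoke == "yes"),
    data = rec, dist = "gaussian")
  # mixed censored model nests the tobit, so its likelihood dominates
  expect_gte(f$loglik, as.numeric(logLik(sv)) - 1e-6)
  # tau near the boundary relative to the residual scale
  expect_lt(f$tau, 0.25 * f$sigma)
  expect_lt(max(abs(f$coefficients - coef(sv))), 0.5)
  expect_lt(abs(f$sigma - sv$scale), 0.5)
})

test_that("degenerate designs and inputs are rejected", {
  rec <- data.frame(id = c("a", "b"), fam = c("f1", "f2"), exam = 1,
                    sbp = c(120, 130), age = c(40, 50),
                    sex = c("male", "female"), smoke = c("no", "no"),
                    med = c("no", "no"))
  bad <- rec
  bad$sbp[1] <- -5
  expect_error(fit_censored_exam(bad), "positive")
  two_exams <- rbind(rec, transform(rec, exam = 2))
  expect_error(fit_censored_exam(two_exams), "single exam")
  dup <- rbind(rec, rec[1, ])
  expect_error(fit_censored_exam(dup), "duplicate")
})

# hand-built fit objects let the residual arithmetic be checked exactly
fake_fit <- function(mu, sigma, fams) {
  structure(list(coefficients = c(intercept = mu, sexmale = 0, age = 0,
                                  smokeyes = 0),
                 sigma = sigma, tau = 0,
                 ranef = setNames(rep(0, length(fams)), fams),
                 loglik = NA_real_, convergence = 0L, boundary_tau = FALSE,
                 n = NA_integer_, n_censored = 0L, exam = NA_integer_),
            class = "censored_fit")
}

test_that("adjusted phenotype averages residuals over exams 1-3", {
  fams <- "f1"
  fits <- list("1" = fake_fit(100, 10, fams), "2" = fake_fit(100, 10, fams),
               "3" = fake_fit(100, 10, fams))
  rec <- data.frame(id = rep(c("a", "b", "c", "d"), times = c(3, 3, 1, 1)),
                    fam = "f1",
                    exam = c(1, 2, 3, 1, 2, 3, 2, 4),
                    sbp = c(105, 95, 100, 110, 110, 110, 108, 120),
                    age = 0, sex = "female", smoke = "no", med = "no")
  rec$med[rec$id == "b" & rec$exam == 2] <- "yes"
  adj <- build_adjusted_phenotype(fits, rec)
  # residuals +5, -5, 0 average to zero
  expect_equal(adj$R[adj$id == "a"], 0)
  expect_equal(adj$n_exams_used[adj$id == "a"], 3L)
  # the medicated exam uses Y* > Y, so R exceeds the naive mean residual
  naive_b <- mean(c(110, 110, 110) - 100)
  expect_gt(adj$R[adj$id == "b"], naive_b)
  # individual measured only at exam 2
  expect_equal(adj$R[adj$id == "c"], 8)
  expect_equal(adj$n_exams_used[adj$id == "c"], 1L)
  # exam-4-only individuals are excluded and reported
  expect_false("d" %in% adj$id)
  expect_equal(attr(adj, "skipped"), "d")
})

test_that("the conditional-expectation correction restores the overall
           residual mean under exact censoring", {
  # under Type-I censoring the unmedicated subset is selected toward low
  # values, so only the mean over ALL individuals (with Y* for the
  # medicated) is centred at zero
  cfg <- sim_config(n_pedigrees = 40, sibship = 3, n_marry = 1, h2 = 0,
                    tau_ped = 5, sigma_total = 15, n_exams = 3,
                    censoring = list(enabled = TRUE, threshold_q = 0.7,
                                     p_med = 1, p_base = 0,
                                     observed = "threshold"), seed = 12)
  peds <- simulate_pedigrees(cfg)
  rec <- simulate_phenotypes(peds, cfg, seed = 12)$records
  fits <- lapply(1:3, function(e)
    fit_censored_exam(rec[rec$exam == e, ]))
  names(fits) <- as.character(1:3)
  adj <- build_adjusted_phenotype(fits, rec)
  expect_lt(abs(mean(adj$R)), 3 * sd(adj$R) / sqrt(nrow(adj)))
  # and the unmedicated residual mean is negative, as selection implies
  never_med <- setdiff(adj$id, rec$id[rec$med == "yes"])
  expect_lt(mean(adj$R[adj$id %in% never_med]), 0)
})
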