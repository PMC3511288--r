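test_that("degenerate mixing reproduces the analytic MNL log-likelihood", {
  pd <- preset_data(n = 60L)
  ds <- pd$data
  attrs <- names(pd$preset$design$factors)
  spec_mix <- mixed_logit_spec(attrs, mixing = c(cost = "normal",
                                                 regimen = "normal"),
                               n_draws = 25, seed = 1)
  mu <- c(0.1, -0.08, -0.01, -0.02, -0.03, -0.01, 0, -0.05, -0.02)
  ll_mix <- panel_simulated_loglik(spec_mix, ds, c(mu, 0, 0))
  # analytic conditional-logit log-likelihood computed directly
  ch <- ds$choices
  X <- cbind(asc = as.numeric(ch$alt == 1L), as.matrix(ch[, attrs]))
  v <- drop(X %*% mu)
  vc <- v[ch$chosen == 1L]; vo <- v[ch$chosen == 0L]
  ll_direct <- sum(vc - log(exp(vc) + exp(vo)))
  expect_equal(ll_mix, ll_direct, tolerance = 1e-10)
})

test_that("one task with identical alternatives has log-likelihood log(1/2)", {
  ds <- hand_dataset(xa = 1, xb = 1,
                     chosen_a = matrix(TRUE, 1, 1))
  spec <- mixed_logit_spec("x", include_asc = FALSE, n_draws = 1)
  expect_equal(panel_simulated_loglik(spec, ds, 0.7), log(0.5))
})

test_that("simulated likelihood matches a hand-enumerated draw average", {
  # 2 respondents x 2 tasks, 1 attribute, normal mixing, R = 3 Halton draws
  ds <- hand_dataset(xa = c(1, 2), xb = c(0, 1),
                     chosen_a = rbind(c(TRUE, FALSE), c(TRUE, TRUE)))
  spec <- mixed_logit_spec("x", mixing = c(x = "normal"),
                           include_asc = FALSE, n_draws = 3)
  mu <- 0.4; sd <- 0.9
  # independent oracle: base-2 radical inverse written out digit by digit
  rad2 <- function(i) {
    out <- 0; f <- 0.5
    while (i > 0) { out <- out + f * (i %% 2); i <- i %/% 2; f <- f / 2 }
    out
  }
  u <- vapply(10L + 1:6, rad2, numeric(1))  # 10 discarded points
  beta <- mu + sd * qnorm(u)
  # chosen-minus-other attribute difference per respondent x task
  chosen_a <- rbind(c(TRUE, FALSE), c(TRUE, TRUE))
  dxa <- c(1, 1)  # A-minus-B differences of the two tasks
  ll <- 0
  for (i in 1:2) {
    b <- beta[(i - 1) * 3 + 1:3]
    d_i <- dxa * ifelse(chosen_a[i, ], 1, -1)
    pr <- sapply(b, function(bb) prod(plogis(d_i * bb)))
    ll <- ll + log(mean(pr))
  }
  expect_equal(panel_simulated_loglik(spec, ds, c(mu, sd)), ll,
               tolerance = 1e-12)
})

test_that("spread-zero fit matches an independent conditional logit", {
  skip_if_not_installed("survival")
  library(survival)
  pd <- preset_data()
  ds <- pd$data
  attrs <- names(pd$preset$design$factors)
  f <- fit_mixed_logit(mixed_logit_spec(attrs, n_draws = 1), ds)
  ch <- ds$choices
  ch$asc <- as.numeric(ch$alt == 1L)
  ch$strat <- paste(ch$resp_id, ch$task_id)
  fml <- stats::as.formula(paste("chosen ~",
                                 paste(c("asc", attrs), collapse = "+"),
                                 "+ strata(strat)"))
  cl <- survival::clogit(fml, data = ch)
  nm <- c("asc", attrs)
  expect_lt(max(abs(stats::coef(cl)[nm] - f$coefficients[nm])), 1e-4)
  expect_lt(abs(cl$loglik[2] - f$loglik), 1e-6)
  expect_true(f$converged)
})

test_that("non-varying attributes raise an identification error naming them", {
  pd <- preset_data(n = 30L)
  ds <- pd$data
  ds$choices$flatline <- 1
  spec <- mixed_logit_spec(c("cost", "flatline"), n_draws = 1)
  expect_error(fit_mixed_logit(spec, ds), "flatline")
})

test_that("refitting from the optimum is an immediate fixed point", {
  pd <- preset_data(n = 50L)
  spec <- mixed_logit_spec(names(pd$preset$design$factors), n_draws = 1)
  f1 <- fit_mixed_logit(spec, pd$data)
  f2 <- fit_mixed_logit(spec, pd$data, start = f1$theta)
  expect_lte(f2$iterations, 2L)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-6)
})

test_that("interaction terms validate covariates and identification", {
  pd <- preset_data(n = 40L)
  ds <- pd$data
  spec <- mixed_logit_spec(names(pd$preset$design$factors), n_draws = 1)
  expect_error(add_interactions(spec, ds, list(c("cost", "nope"))),
               "missing from the dataset")
  ds_na <- ds
  ds_na$covariates$PHI[3] <- NA
  expect_error(add_interactions(spec, ds_na, list(c("cost", "PHI"))),
               "missing values")
  ds0 <- ds
  ds0$covariates$PHI <- 0L
  sp0 <- add_interactions(spec, ds0, list(c("cost", "PHI")))
  expect_error(fit_mixed_logit(sp0, ds0), "identification")
})

test_that("cost-interaction and group-specific-cost fits reach the same optimum", {
  pd <- preset_data(n = 120L, seed = 21L)
  ds <- pd$data
  attrs <- names(pd$preset$design$factors)
  spec_ia <- add_interactions(mixed_logit_spec(attrs, n_draws = 1), ds,
                              list(c("cost", "PHI")))
  f_ia <- fit_mixed_logit(spec_ia, ds)
  # reparameterization: separate cost slopes per insurance group
  ds2 <- ds
  phi <- ds$covariates$PHI[match(ds$choices$resp_id,
                                 ds$covariates$resp_id)]
  ds2$choices$cost_phi <- ds$choices$cost * phi
  ds2$choices$cost_nophi <- ds$choices$cost * (1 - phi)
  attrs2 <- c(setdiff(attrs, "cost"), "cost_nophi", "cost_phi")
  f_grp <- fit_mixed_logit(mixed_logit_spec(attrs2, n_draws = 1), ds2)
  expect_equal(f_grp$loglik, f_ia$loglik, tolerance = 1e-6)
  expect_equal(unname(f_grp$coefficients["cost_nophi"]),
               unname(f_ia$coefficients["cost"]), tolerance = 1e-4)
  expect_equal(unname(f_grp$coefficients["cost_phi"] -
                        f_grp$coefficients["cost_nophi"]),
               unname(f_ia$coefficients["cost_x_PHI"]), tolerance = 1e-4)
})

test_that("a simulated cost-by-insurance effect is recovered", {
  p <- study_emulation_preset()
  pop <- population_spec(
    p$pop$means, mixing = list(),
    covariate_model = list(prevalence = c(PHI = 0.5),
                           interactions = list(list(attribute = "cost",
                                                    covariate = "PHI",
                                                    beta = 0.004))),
    n_respondents = 800L, seed = 31L)
  ds <- simulate_study(pop, p$design)
  spec <- add_interactions(
    mixed_logit_spec(names(p$design$factors), n_draws = 1), ds,
    list(c("cost", "PHI")))
  f <- fit_mixed_logit(spec, ds)
  est <- f$coefficients[["cost_x_PHI"]]
  se <- f$se[["cost_x_PHI"]]
  expect_lt(abs(est - 0.004), 3 * se)
})

test_that("stepwise selection obeys its thresholds", {
  pd <- preset_data(n = 80L, seed = 41L)
  ds <- pd$data
  spec <- mixed_logit_spec(names(pd$preset$design$factors), n_draws = 1)
  # alpha_in = 0: nothing can enter
  sw0 <- stepwise_covariates(spec, ds, c("PHI", "HC"), alpha_in = 0,
                             se = "hessian")
  expect_length(sw0$spec$interactions, 0L)
  expect_error(stepwise_covariates(spec, ds, "nope"), "not in the dataset")
})

test_that("stepwise keeps a real interaction and ignores pure noise", {
  p <- study_emulation_preset()
  pop <- population_spec(
    p$pop$means, mixing = list(),
    covariate_model = list(
      prevalence = c(PHI = 0.5, noise1 = 0.5),
      interactions = list(list(attribute = "cost", covariate = "PHI",
                               beta = 0.008))),
    n_respondents = 600L, seed = 51L)
  ds <- simulate_study(pop, p$design)
  spec <- mixed_logit_spec(names(p$design$factors), n_draws = 1)
  sw <- stepwise_covariates(spec, ds, c("PHI", "noise1"))
  selected <- vapply(sw$spec$interactions, `[`, character(1), 2L)
  expect_true("PHI" %in% selected)
  expect_false("noise1" %in% selected)
})

test_that("simulated likelihood stabilizes as the draw count grows", {
  pd <- preset_data(n = 50L)
  ds <- pd$data
  attrs <- names(pd$preset$design$factors)
  par <- c(0.05, -0.1, -0.014, -0.02, -0.035, -0.012, -0.005, -0.094,
           -0.02, 0.06, 0.022)
  ll_at <- function(R) {
    spec <- mixed_logit_spec(attrs,
                             mixing = c(side_effect_severity = "normal",
                                        death_risk = "normal"),
                             n_draws = R, seed = 1)
    panel_simulated_loglik(spec, ds, par)
  }
  ref <- ll_at(2000)
  errs <- abs(vapply(c(50, 200, 1000), ll_at, numeric(1)) - ref)
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.05)
})

test_that("triangular draws keep the sign of the mean everywhere", {
  u <- seq(1e-6, 1 - 1e-6, length.out = 2001)
  t01 <- dcemix:::qtriangular01(u)
  expect_true(all(t01 >= 0 & t01 <= 2))
  for (mu in c(-3, -0.01, 0.02, 5)) {
    expect_true(all(sign(mu * t01) == sign(mu)))
  }
})

test_that("log-likelihood is invariant to shuffling respondent rows", {
  pd <- preset_data(n = 40L)
  ds <- pd$data
  set.seed(6)
  perm <- sample.int(nrow(ds$choices))
  ds2 <- choice_dataset(ds$choices[perm, ], ds$covariates)
  attrs <- names(pd$preset$design$factors)
  spec <- mixed_logit_spec(attrs, mixing = c(cost = "triangular"),
                           n_draws = 50, seed = 2)
  par <- c(0.1, -0.1, -0.014, -0.02, -0.035, -0.012, -0.005, -0.094, -0.02)
  expect_identical(panel_simulated_loglik(spec, ds, par),
                   panel_simulated_loglik(spec, ds2, par))
})
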