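# A minimal mml_fit stub lets the analytics be tested against hand
# constructions without running the optimizer.
stub_fit <- function(spec, theta, loglik = -1, n_parameters = length(theta)) {
  structure(list(spec = spec, theta = theta,
                 coefficients = theta[seq_along(coef_names_of(spec))],
                 loglik = loglik, n_parameters = n_parameters),
            class = "mml_fit")
}
coef_names_of <- function(spec) dcemix:::coef_names(spec)

test_that("fit statistics follow their closed forms", {
  pd <- preset_data(n = 50L)
  spec <- mixed_logit_spec(names(pd$preset$design$factors), n_draws = 1)
  f <- fit_mixed_logit(spec, pd$data)
  fs <- fit_statistics(f, pd$data)
  # null log-likelihood by direct summation over chosen rows
  chosen <- pd$data$choices[pd$data$choices$chosen == 1L, ]
  share_a <- mean(chosen$alt == 1L)
  ll0 <- sum(log(ifelse(chosen$alt == 1L, share_a, 1 - share_a)))
  expect_equal(fs$loglik_null, ll0)
  expect_equal(fs$aic, 2 * f$n_parameters - 2 * f$loglik)
  expect_equal(fs$mcfadden_r2, 1 - f$loglik / ll0)
  expect_equal(fs$lr_chisq, 2 * (f$loglik - ll0))
  expect_gt(fs$mcfadden_r2, 0)
  # a model no better than the shares null: LR = 0, p = 1
  f0 <- stub_fit(spec, f$theta, loglik = ll0, n_parameters = 2L)
  fs0 <- fit_statistics(f0, pd$data)
  expect_equal(fs0$lr_chisq, 0)
  expect_equal(fs0$p_value, 1)
  expect_equal(fs0$mcfadden_r2, 0)
  # 50/50 shares: LL0 = n log(1/2)
  even <- hand_dataset(xa = c(1, 2), xb = c(0, 0),
                       chosen_a = rbind(c(TRUE, FALSE), c(FALSE, TRUE)))
  sp1 <- mixed_logit_spec("x", include_asc = FALSE, n_draws = 1)
  fs_even <- fit_statistics(stub_fit(sp1, c(x = 0), loglik = 4 * log(0.5)),
                            even)
  expect_equal(fs_even$loglik_null, 4 * log(0.5))
})

test_that("hit rate ties at one half and saturates for deterministic choosers", {
  f1 <- factor_set(factor_spec("x", c(0, 1), +1))
  A <- cbind(x = c(1, 1)); B <- cbind(x = c(1, 1))
  d_same <- manual_design(f1, A, B)
  beta <- matrix(2, 50, 1, dimnames = list(NULL, "x"))
  ds_same <- simulate_choices(d_same, beta, seed = 2)
  sp <- mixed_logit_spec("x", include_asc = FALSE, n_draws = 1)
  expect_equal(hit_rate(stub_fit(sp, c(x = 2)), ds_same), 0.5)

  # near-deterministic simulated choosers, model at the true coefficients
  pd <- preset_data()
  p <- pd$preset
  big <- population_spec(p$pop$means * 50, n_respondents = 300L, seed = 6L)
  ds_big <- simulate_study(big, p$design)
  spec <- mixed_logit_spec(names(p$design$factors), n_draws = 1)
  fr_names <- c("asc", names(p$design$factors))
  f_stub <- stub_fit(spec, setNames(50 * p$pop$means[fr_names], fr_names))
  expect_gte(hit_rate(f_stub, ds_big), 0.999)

  # moderate signal: strictly between chance and certainty
  f_fit <- fit_mixed_logit(spec, pd$data)
  hr <- hit_rate(f_fit, pd$data)
  expect_gt(hr, 0.5); expect_lt(hr, 1)
  # and it beats the null share-only predictor, which scores exactly 1/2
  # under the tie rule when shares are near even
  f_null <- stub_fit(spec, setNames(rep(0, 9), fr_names))
  expect_gt(hr, hit_rate(f_null, pd$data))
})

test_that("relative importance normalizes, scales out, and flags degeneracy", {
  imp <- relative_importance(c(a = -0.1, b = 0.05),
                             factor_ranges = c(a = 3, b = 10))
  expect_equal(imp$importance, c(0.3, 0.5))
  expect_equal(imp$share_pct, c(37.5, 62.5))
  expect_equal(sum(imp$share_pct), 100)
  # one nonzero coefficient takes the whole share
  one <- relative_importance(c(a = 0, b = -2), c(a = 5, b = 1))
  expect_equal(one$share_pct, c(0, 100))
  # rescaling all coefficients leaves shares unchanged
  imp2 <- relative_importance(c(a = -0.2, b = 0.1), c(a = 3, b = 10))
  expect_equal(imp2$share_pct, imp$share_pct)
  expect_error(relative_importance(c(a = 0, b = 0), c(a = 1, b = 1)),
               "degenerate")
  # matrix input: every row sums to 100
  m <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  ri <- relative_importance(m, c(a = 1, b = 2, c = 3))
  expect_equal(unname(rowSums(ri$share_pct)), rep(100, 10))
})

test_that("conditional coefficients collapse to the mean without heterogeneity", {
  ds <- hand_dataset(xa = c(1, 2), xb = c(0, 1),
                     chosen_a = rbind(c(TRUE, FALSE), c(TRUE, TRUE)))
  spec <- mixed_logit_spec("x", mixing = c(x = "normal"),
                           include_asc = FALSE, n_draws = 50)
  cc <- conditional_individual_coefficients(
    stub_fit(spec, c(x = 0.7, sd.x = 0)), ds)
  expect_equal(cc$x, c(0.7, 0.7))
})

test_that("conditional coefficients average back to the population mean", {
  pd <- preset_data(n = 300L, seed = 71L)
  spec <- mixed_logit_spec(names(pd$preset$design$factors),
                           mixing = preset_mixing, n_draws = 300, seed = 3)
  truth <- pd$preset$pop$means
  nm <- c("asc", names(pd$preset$design$factors))
  theta <- c(setNames(truth[nm], nm),
             sd.side_effect_severity = 0.06, sd.future_risk = 0.009,
             sd.symptom_frequency = 0.013, sd.death_risk = 0.022)
  cc <- conditional_individual_coefficients(stub_fit(spec, theta), pd$data)
  for (a in c("side_effect_severity", "death_risk")) {
    se_mc <- sd(cc[[a]]) / sqrt(nrow(cc))
    expect_lt(abs(mean(cc[[a]]) - truth[[a]]), 5 * se_mc + 0.003)
  }
  # conditional means shrink toward the population mean as variance drops
  theta_small <- theta
  theta_small[c("sd.side_effect_severity", "sd.future_risk",
                "sd.symptom_frequency", "sd.death_risk")] <- 1e-4
  cc_small <- conditional_individual_coefficients(stub_fit(spec, theta_small),
                                                  pd$data)
  expect_lt(sd(cc_small$side_effect_severity), sd(cc$side_effect_severity))
})

test_that("conditional coefficients separate opposite preference groups", {
  f1 <- factor_set(factor_spec("x", c(0, 1), 0))
  set.seed(13)
  A <- cbind(x = rep(1, 8)); B <- cbind(x = rep(0, 8))
  d <- manual_design(f1, A, B)
  n <- 200
  group <- rep(c(-1, 1), each = n / 2)
  beta <- matrix(group * 1.5, n, 1, dimnames = list(NULL, "x"))
  ds <- simulate_choices(d, beta, seed = 14)
  spec <- mixed_logit_spec("x", mixing = c(x = "normal"),
                           include_asc = FALSE, n_draws = 200, seed = 4)
  fhat <- fit_mixed_logit(spec, ds, se = "none")
  cc <- conditional_individual_coefficients(fhat, ds)
  # AUC of conditional means for recovering the true group
  r <- rank(cc$x)
  n1 <- sum(group > 0)
  auc <- (sum(r[group > 0]) - n1 * (n1 + 1) / 2) / (n1 * (n - n1))
  expect_gt(auc, 0.9)
})

test_that("harm-benefit classification counts known subpopulations", {
  grouping <- medication_harm_benefit_groups()
  ranges <- c(side_effect_severity = 9, future_risk = 45,
              symptom_frequency = 24, death_risk = 30)
  # all respondents identical, harms dominant
  harmy <- matrix(rep(c(-0.2, -0.02, -0.01, -0.01), each = 5), 5, 4,
                  dimnames = list(NULL, names(ranges)))
  ri <- relative_importance(harmy, ranges)
  hb <- classify_harm_benefit(ri$importance, grouping)
  expect_equal(hb$pct[hb$comparison == "harms_gt_benefits"], 100)
  # configuration errors
  no_benefit <- grouping
  no_benefit$benefit_immediate <- character(0)
  no_benefit$benefit_longterm <- character(0)
  expect_error(classify_harm_benefit(ri$importance, no_benefit),
               "empty harm or benefit")
  bad <- cbind(ri$importance, extra = 1)
  expect_error(classify_harm_benefit(bad, grouping), "untagged")
  # two-population mixture with known proportions
  set.seed(15)
  n <- 2000
  harm_dom <- runif(n) < 0.65
  coefs <- cbind(
    side_effect_severity = ifelse(harm_dom, -0.2, -0.05),
    future_risk = -0.002,
    symptom_frequency = -0.002,
    death_risk = ifelse(harm_dom, -0.01, -0.06))
  ri2 <- relative_importance(coefs, ranges)
  hb2 <- classify_harm_benefit(ri2$importance, grouping)
  got <- hb2$pct[hb2$comparison == "harms_gt_benefits"] / 100
  expect_lt(abs(got - mean(harm_dom)), 3 * sqrt(0.65 * 0.35 / n))
})

test_that("trade-off arithmetic and MRS invariances hold", {
  cf <- c(regimen = -0.0937, future_risk = -0.0141, cost = -0.012)
  tr <- tradeoff(cf, "regimen", -3, "future_risk")
  expect_equal(tr$delta_u, 0.2811)
  expect_equal(tr$compensating_move, 0.2811 / 0.0141)
  # a ~20-point future-risk reduction offsets the regimen gain
  expect_equal(tr$compensating_move, 19.9, tolerance = 0.005)
  # same factor: the compensating move undoes the move exactly
  same <- tradeoff(cf, "cost", 7, "cost")
  expect_equal(same$compensating_move, -7)
  # doubling all coefficients leaves the trade-off unchanged
  tr2 <- tradeoff(cf * 2, "regimen", -3, "future_risk")
  expect_equal(tr2$compensating_move, tr$compensating_move)
  expect_error(tradeoff(c(a = 1, b = 0), "a", 1, "b"), "undefined MRS")
})

test_that("AIC orders nested fits by penalized likelihood", {
  pd <- preset_data(n = 80L, seed = 81L)
  ds <- pd$data
  attrs <- names(pd$preset$design$factors)
  f_small <- fit_mixed_logit(mixed_logit_spec(attrs[1:4], n_draws = 1), ds)
  f_big <- fit_mixed_logit(mixed_logit_spec(attrs, n_draws = 1), ds)
  expect_gte(f_big$loglik, f_small$loglik)
  aic <- function(f) 2 * f$n_parameters - 2 * f$loglik
  gain <- f_big$loglik - f_small$loglik
  penalty <- f_big$n_parameters - f_small$n_parameters
  expect_equal(aic(f_big) < aic(f_small), gain > penalty)
})
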