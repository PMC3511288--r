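# Post-estimation analytics: fit statistics, predictive hit rate, attribute
# relative importance, individual-level (conditional) coefficients,
# harm-vs-benefit classification and trade-off arithmetic.

#' Goodness-of-fit statistics
#'
#' AIC, McFadden's pseudo R-squared and the likelihood-ratio test of the
#' fitted model against the average-utility null that predicts every choice
#' with the choice shares observed in the dataset.
#'
#' @param result An `mml_fit`.
#' @param data The [choice_dataset()] the model was fitted on.
#' @return List with `loglik`, `loglik_null`, `aic`, `mcfadden_r2`,
#'   `lr_chisq`, `df`, `p_value`.
#' @export
fit_statistics <- function(result, data) {
  stopifnot(inherits(result, "mml_fit"), inherits(data, "choice_dataset"))
  ll <- result$loglik
  if (ll > 0) stop("inconsistent input: log-likelihood > 0", call. = FALSE)
  ch <- data$choices
  chosen <- ch[ch$chosen == 1L, ]
  share_a <- mean(chosen$alt == 1L)
  ll0 <- sum(log(ifelse(chosen$alt == 1L, share_a, 1 - share_a)))
  if (ll < ll0 - 1e-6)
    stop("inconsistent input: fitted log-likelihood below the choice-share ",
         "null", call. = FALSE)
  k <- result$n_parameters
  lr <- 2 * (ll - ll0)
  list(loglik = ll, loglik_null = ll0,
       aic = 2 * k - 2 * ll,
       mcfadden_r2 = 1 - ll / ll0,
       lr_chisq = lr, df = k,
       p_value = stats::pchisq(lr, k, lower.tail = FALSE))
}

#' Predictive hit rate
#'
#' Share of respondent-task observations whose predicted choice probability
#' favors the alternative actually chosen; ties at probability 1/2 count as
#' half a hit, so an uninformative model scores exactly 50%. Probabilities
#' are either unconditional (mixing integral averaged over draws, default)
#' or evaluated at each respondent's conditional coefficient means.
#'
#' @param result An `mml_fit`.
#' @param data The fitted [choice_dataset()].
#' @param coefficients `"unconditional"` or `"conditional"`.
#' @return The hit rate (scalar in `[0, 1]`).
#' @export
hit_rate <- function(result, data,
                     coefficients = c("unconditional", "conditional")) {
  coefficients <- match.arg(coefficients)
  fr <- msl_frame(result$spec, data)
  if (coefficients == "unconditional") {
    p <- rowMeans(stats::plogis(delta_v(result$theta * fr$theta_scale, fr)))
  } else {
    bc <- conditional_individual_coefficients(result, data)
    beta <- as.matrix(bc[, fr$cn, drop = FALSE])
    beta <- sweep(beta, 2L, fr$col_scale, "*")  # match preconditioned D
    p <- stats::plogis(rowSums(fr$D * beta[fr$resp_task, , drop = FALSE]))
  }
  mean((p > 0.5) + 0.5 * (p == 0.5))
}

#' Conditional (individual-level) coefficients
#'
#' Simulation-based conditional means of each respondent's coefficients
#' given their observed choices:
#' `E[beta_i | choices_i] = sum_r beta^(r) P_i(r) / sum_r P_i(r)` where
#' `P_i(r)` is the probability of respondent i's choice sequence under draw
#' r. Fixed coefficients are returned at their point estimates.
#'
#' @param result An `mml_fit` with at least one random coefficient.
#' @param data The fitted [choice_dataset()].
#' @return Data frame: `resp_id` plus one column per coefficient.
#' @export
conditional_individual_coefficients <- function(result, data) {
  fr <- msl_frame(result$spec, data)
  if (!length(fr$rc))
    stop("model has no random coefficients", call. = FALSE)
  th <- split_theta(result$theta, fr)  # natural units for the draws below
  dv <- delta_v(result$theta * fr$theta_scale, fr)
  logp <- stats::plogis(dv, log.p = TRUE)
  logP <- rowsum(logp, fr$resp_task)
  m <- apply(logP, 1L, max)
  W <- exp(logP - m)
  sw <- rowSums(W)
  if (any(!is.finite(sw)) || any(sw <= 0))
    stop("numeric underflow in conditional weights; increase n_draws",
         call. = FALSE)
  W <- W / sw
  out <- matrix(rep(th$mu, each = fr$n), fr$n, length(fr$cn),
                dimnames = list(NULL, fr$cn))
  for (j in seq_along(fr$rc)) {
    k <- fr$rc[j]
    nm <- fr$cn[k]
    B <- if (fr$mx[k] == "normal") {
      sidx <- match(k, fr$rc_norm)
      th$mu[k] + th$sigma[sidx] * fr$draws[[nm]]
    } else {
      th$mu[k] * fr$draws[[nm]]
    }
    out[, nm] <- rowSums(W * B)
  }
  cbind(data.frame(resp_id = fr$resp_ids), as.data.frame(out))
}

#' Attribute ranges of a design
#'
#' @param design A `choice_design`.
#' @return Named vector of `max(level) - min(level)` per factor.
#' @export
design_ranges <- function(design) {
  vapply(design$factors, function(f) diff(range(f$levels)), numeric(1))
}

#' Relative importance of attributes
#'
#' Importance of a factor is `|coefficient| * (level range)`; shares are
#' normalized to sum to 100%. At the population level pass the coefficient
#' means; at the individual level pass the matrix of conditional individual
#' coefficients (one row per respondent), yielding a per-respondent share
#' matrix.
#'
#' @param coefficients Named numeric vector, a coefficient matrix with named
#'   columns, or an `mml_fit` (its means are used).
#' @param factor_ranges Named vector of level ranges (see
#'   [design_ranges()]); its names select the factors scored.
#' @return For a vector: a data frame (`factor`, `coefficient`, `range`,
#'   `importance`, `share_pct`). For a matrix: a list with `importance` and
#'   `share_pct` matrices (rows sum to 100).
#' @export
relative_importance <- function(coefficients, factor_ranges) {
  if (inherits(coefficients, "mml_fit"))
    coefficients <- coefficients$coefficients
  fn <- names(factor_ranges)
  if (is.matrix(coefficients) || is.data.frame(coefficients)) {
    cf <- as.matrix(as.data.frame(coefficients)[, fn, drop = FALSE])
    imp <- abs(cf) * rep(factor_ranges, each = nrow(cf))
    tot <- rowSums(imp)
    if (any(tot <= 0))
      stop("degenerate model: zero total importance for some respondent",
           call. = FALSE)
    list(importance = imp, share_pct = 100 * imp / tot)
  } else {
    miss <- setdiff(fn, names(coefficients))
    if (length(miss))
      stop("no coefficient for factor(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    imp <- abs(coefficients[fn]) * factor_ranges
    if (sum(imp) <= 0)
      stop("degenerate model: zero total importance", call. = FALSE)
    data.frame(factor = fn, coefficient = unname(coefficients[fn]),
               range = unname(factor_ranges),
               importance = unname(imp),
               share_pct = unname(100 * imp / sum(imp)))
  }
}

#' Harm-versus-benefit classification of individual preferences
#'
#' Counts respondents whose summed harm-factor importance exceeds their
#' summed benefit-factor importance, plus the immediate-versus-long-term
#' splits within harms and within benefits.
#'
#' @param importance Per-respondent importance matrix (respondents x
#'   factors), e.g. the `importance` element of [relative_importance()] on
#'   conditional coefficients.
#' @param grouping Named list with character vectors `harm_immediate`,
#'   `harm_longterm`, `benefit_immediate`, `benefit_longterm` (see
#'   [medication_harm_benefit_groups()]).
#' @return Data frame with `comparison`, `n`, `pct`.
#' @export
classify_harm_benefit <- function(importance, grouping) {
  need <- c("harm_immediate", "harm_longterm",
            "benefit_immediate", "benefit_longterm")
  miss <- setdiff(need, names(grouping))
  if (length(miss))
    stop("grouping is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  harms <- c(grouping$harm_immediate, grouping$harm_longterm)
  benefits <- c(grouping$benefit_immediate, grouping$benefit_longterm)
  if (!length(harms) || !length(benefits))
    stop("configuration error: empty harm or benefit factor set",
         call. = FALSE)
  importance <- as.matrix(importance)
  untagged <- setdiff(colnames(importance), c(harms, benefits))
  if (length(untagged))
    stop("configuration error: untagged factor(s): ",
         paste(untagged, collapse = ", "), call. = FALSE)
  miss2 <- setdiff(c(harms, benefits), colnames(importance))
  if (length(miss2))
    stop("importance matrix lacks factor(s): ",
         paste(miss2, collapse = ", "), call. = FALSE)
  sum_of <- function(cols) rowSums(importance[, cols, drop = FALSE])
  n <- nrow(importance)
  cmp <- c("harms_gt_benefits" =
             sum(sum_of(harms) > sum_of(benefits)),
           "harms_immediate_gt_longterm" =
             sum(sum_of(grouping$harm_immediate) >
                   sum_of(grouping$harm_longterm)),
           "benefits_immediate_gt_longterm" =
             sum(sum_of(grouping$benefit_immediate) >
                   sum_of(grouping$benefit_longterm)))
  data.frame(comparison = names(cmp), n = unname(cmp),
             pct = unname(100 * cmp / n))
}

#' Attribute trade-off (marginal rate of substitution)
#'
#' Utility change for a stated move in one attribute, and the compensating
#' move in a second attribute that leaves utility unchanged
#' (`-beta_a * move_a / beta_b`).
#'
#' @param result An `mml_fit` or a named coefficient vector.
#' @param factor_a Attribute being moved.
#' @param move_a Size of the move, in `factor_a`'s units.
#' @param factor_b Compensating attribute.
#' @return List of class `"tradeoff_result"` with `delta_u` and
#'   `compensating_move`.
#' @export
tradeoff <- function(result, factor_a, move_a, factor_b) {
  cf <- if (inherits(result, "mml_fit")) result$coefficients else result
  for (f in c(factor_a, factor_b))
    if (!f %in% names(cf))
      stop("no coefficient named '", f, "'", call. = FALSE)
  if (cf[[factor_b]] == 0)
    stop("undefined MRS: coefficient of '", factor_b, "' is zero",
         call. = FALSE)
  du <- cf[[factor_a]] * move_a
  structure(list(factor_a = factor_a, move_a = move_a, factor_b = factor_b,
                 delta_u = du,
                 compensating_move = -du / cf[[factor_b]],
                 mrs = cf[[factor_a]] / cf[[factor_b]]),
            class = "tradeoff_result")
}

#' @export
print.tradeoff_result <- function(x, ...) {
  cat(sprintf("Moving %s by %+g changes utility by %+.4f;\ncompensated by moving %s by %+.4f\n",
              x$factor_a, x$move_a, x$delta_u, x$factor_b,
              x$compensating_move))
  invisible(x)
}
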