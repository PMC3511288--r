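# Panel mixed multinomial logit by maximum simulated likelihood.
#
# The simulated log-likelihood is
#   LL = sum_i log[ (1/R) sum_r prod_t P_it(chosen | beta_i^(r)) ]
# with beta_i^(r) the r-th quasi-random draw for respondent i, transformed
# per coefficient: normal as mean + sd * qnorm(u), constrained triangular as
# mean * T(u) with T symmetric triangular on [0,2] (spread tied to |mean|,
# sign-preserving). With two alternatives every task reduces to a logistic
# probability of the chosen-minus-other utility difference, so the whole
# likelihood is built from one difference matrix D (tasks x coefficients)
# and per-draw offset matrices A_k = D[,k] * draws, which are fixed across
# the optimization; both LL and its analytic gradient are then dense matrix
# arithmetic.

#' Specify a panel mixed logit model
#'
#' @param attributes Character vector of attribute column names entering
#'   utility linearly.
#' @param mixing Named character vector tagging coefficients as `"fixed"`,
#'   `"normal"` or `"triangular"` (constrained triangular, spread tied to
#'   the mean); unlisted coefficients are fixed. The tag name `"asc"` refers
#'   to the alternative-specific constant.
#' @param include_asc Include an alternative-specific constant on
#'   alternative A (captures left-right bias).
#' @param interactions List of `c(attribute, covariate)` pairs; each adds a
#'   fixed coefficient on `attribute x covariate`.
#' @param n_draws Draws per respondent for the mixing integral.
#' @param draw_type `"halton"` (low-discrepancy, default) or
#'   `"pseudo_random"`.
#' @param seed Seed for pseudo-random draws (and Halton permutation when
#'   enabled).
#' @return An object of class `"mixed_logit_spec"`.
#' @export
mixed_logit_spec <- function(attributes, mixing = character(0),
                             include_asc = TRUE, interactions = list(),
                             n_draws = 1000L,
                             draw_type = c("halton", "pseudo_random"),
                             seed = 1L) {
  draw_type <- match.arg(draw_type)
  if (length(attributes) == 0L)
    stop("at least one attribute is required", call. = FALSE)
  if (n_draws < 1L) stop("n_draws must be >= 1", call. = FALSE)
  mixing <- vapply(mixing, as.character, character(1))
  bad <- setdiff(mixing, c("fixed", "normal", "triangular"))
  if (length(bad))
    stop("unknown mixing tag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(names(mixing), c(attributes, "asc"))
  if (length(unknown))
    stop("mixing tags for unknown coefficient(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(attributes = attributes, mixing = mixing,
                 include_asc = isTRUE(include_asc),
                 interactions = interactions,
                 n_draws = as.integer(n_draws), draw_type = draw_type,
                 seed = as.integer(seed)),
            class = "mixed_logit_spec")
}

#' Add attribute-by-covariate interaction terms to a model spec
#'
#' Each pair appends a fixed coefficient on the product of an attribute
#' column and a respondent covariate, measuring the covariate group's
#' deviation in sensitivity to that attribute.
#'
#' @param spec A [mixed_logit_spec()].
#' @param data A [choice_dataset()] (used to validate covariate presence and
#'   completeness; the product columns are built at estimation time).
#' @param pairs List of `c(attribute, covariate)` character pairs.
#' @return The expanded spec.
#' @export
add_interactions <- function(spec, data, pairs) {
  stopifnot(inherits(spec, "mixed_logit_spec"),
            inherits(data, "choice_dataset"))
  for (p in pairs) {
    if (!p[[1L]] %in% spec$attributes)
      stop("interaction attribute '", p[[1L]], "' is not in the spec",
           call. = FALSE)
    if (is.null(data$covariates) || !p[[2L]] %in% names(data$covariates))
      stop("covariate '", p[[2L]], "' missing from the dataset",
           call. = FALSE)
    if (anyNA(data$covariates[[p[[2L]]]]))
      stop("covariate '", p[[2L]], "' has missing values; no silent ",
           "imputation is performed", call. = FALSE)
    spec$interactions <- c(spec$interactions, list(c(p[[1L]], p[[2L]])))
  }
  spec
}

# ---- internal model frame ---------------------------------------------------

coef_names <- function(spec) {
  inter <- vapply(spec$interactions, function(p) paste0(p[1L], "_x_", p[2L]),
                  character(1))
  c(if (spec$include_asc) "asc", spec$attributes, inter)
}

coef_mixing <- function(spec) {
  cn <- coef_names(spec)
  mx <- setNames(rep("fixed", length(cn)), cn)
  for (nm in names(spec$mixing)) mx[nm] <- spec$mixing[[nm]]
  mx
}

# Build the estimation frame: difference matrix D (chosen minus other, one
# row per respondent-task), respondent index per task, mixing layout, and
# the per-coefficient draw offset matrices.
msl_frame <- function(spec, data, check_identification = FALSE) {
  ch <- data$choices
  miss <- setdiff(spec$attributes, names(ch))
  if (length(miss))
    stop("dataset lacks attribute column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  resp_ids <- unique(ch$resp_id)
  n <- length(resp_ids)
  cn <- coef_names(spec)
  X <- matrix(0, nrow(ch), length(cn), dimnames = list(NULL, cn))
  if (spec$include_asc) X[, "asc"] <- as.numeric(ch$alt == 1L)
  for (a in spec$attributes) X[, a] <- ch[[a]]
  for (p in spec$interactions) {
    cv <- data$covariates[[p[2L]]][match(ch$resp_id, data$covariates$resp_id)]
    if (anyNA(cv))
      stop("covariate '", p[2L], "' has missing values", call. = FALSE)
    X[, paste0(p[1L], "_x_", p[2L])] <- ch[[p[1L]]] * cv
  }
  chosen <- ch$chosen == 1L
  # rows are sorted resp_id, task_id, alt with 2 alternatives per task
  D <- X[chosen, , drop = FALSE] - X[!chosen, , drop = FALSE]
  resp_task <- match(ch$resp_id[chosen], resp_ids)

  varies <- apply(D != 0, 2L, any)
  if (check_identification && !all(varies))
    stop("identification error: coefficient(s) with no variation across ",
         "alternatives: ", paste(cn[!varies], collapse = ", "),
         call. = FALSE)

  # precondition: standardize each difference column to unit RMS so the
  # optimizer sees comparably scaled parameters regardless of attribute
  # units; estimates are mapped back to natural units on exit
  col_scale <- ifelse(varies, sqrt(colMeans(D^2)), 1)
  D <- sweep(D, 2L, col_scale, "/")

  mx <- coef_mixing(spec)
  rc <- which(mx != "fixed")
  R <- if (length(rc)) spec$n_draws else 1L
  draws <- NULL
  if (length(rc)) {
    if (spec$draw_type == "halton") {
      u <- halton_draws(length(rc), R, n, discard = 10L)
    } else {
      u <- with_seed(spec$seed,
                     array(stats::runif(n * R * length(rc)),
                           c(n, R, length(rc))))
    }
    draws <- vector("list", length(rc))
    names(draws) <- cn[rc]
    for (j in seq_along(rc)) {
      uu <- u[, , j, drop = FALSE][, , 1L, drop = TRUE]
      uu <- matrix(uu, n, R)  # n x R even when n or R is 1
      draws[[j]] <- if (mx[rc[j]] == "normal") stats::qnorm(uu)
                    else qtriangular01(uu)
    }
  }
  # precompute A_k = D[,k] * draw_k[resp_task, ]
  A <- lapply(seq_along(rc), function(j)
    D[, rc[j]] * draws[[j]][resp_task, , drop = FALSE])
  names(A) <- cn[rc]

  norm_names <- cn[rc][mx[rc] == "normal"]
  theta_names <- c(cn, if (length(norm_names)) paste0("sd.", norm_names))
  rc_norm <- rc[mx[rc] == "normal"]
  list(D = D, resp_task = resp_task, n = n, R = R, cn = cn, mx = mx,
       rc = rc, rc_norm = rc_norm,
       rc_tri = rc[mx[rc] == "triangular"], A = A, draws = draws,
       col_scale = col_scale,
       theta_scale = c(col_scale, col_scale[rc_norm]),
       theta_names = theta_names, n_obs = nrow(D), resp_ids = resp_ids)
}

# Split theta into means (mu) and normal spreads (sigma).
split_theta <- function(theta, fr) {
  K <- length(fr$cn)
  list(mu = theta[seq_len(K)],
       sigma = if (length(fr$rc_norm)) theta[K + seq_along(fr$rc_norm)]
               else numeric(0))
}

# Utility-difference matrix (tasks x draws) at theta.
delta_v <- function(theta, fr) {
  th <- split_theta(theta, fr)
  nontri <- setdiff(seq_along(fr$cn), fr$rc_tri)
  base <- drop(fr$D[, nontri, drop = FALSE] %*% th$mu[nontri])
  dv <- matrix(base, fr$n_obs, fr$R)
  for (j in seq_along(fr$rc_norm)) {
    nm <- fr$cn[fr$rc_norm[j]]
    dv <- dv + th$sigma[j] * fr$A[[nm]]
  }
  for (k in fr$rc_tri) {
    nm <- fr$cn[k]
    dv <- dv + th$mu[k] * fr$A[[nm]]
  }
  dv
}

LOG_FLOOR <- log(1e-300)

msl_loglik_core <- function(theta, fr, want_grad = FALSE,
                            per_respondent = FALSE) {
  dv <- delta_v(theta, fr)
  logp <- stats::plogis(dv, log.p = TRUE)
  n_floor <- sum(logp < LOG_FLOOR)
  if (n_floor) logp[logp < LOG_FLOOR] <- LOG_FLOOR
  logP <- rowsum(logp, fr$resp_task)               # n x R
  m <- apply(logP, 1L, max)
  W <- exp(logP - m)
  sw <- rowSums(W)
  ll_i <- m + log(sw / fr$R)
  out <- list(loglik = sum(ll_i), ll_i = ll_i, n_floor = n_floor)
  if (want_grad || per_respondent) {
    Wn <- W / sw                                   # weights per respondent
    G <- Wn[fr$resp_task, , drop = FALSE] * stats::plogis(-dv)
    rs <- rowSums(G)
    nontri <- setdiff(seq_along(fr$cn), fr$rc_tri)
    if (per_respondent) {
      # score contribution of each respondent for each parameter (BHHH)
      Smat <- matrix(0, fr$n, length(fr$theta_names),
                     dimnames = list(NULL, fr$theta_names))
      Smat[, nontri] <- rowsum(fr$D[, nontri, drop = FALSE] * rs,
                               fr$resp_task)
      for (k in fr$rc_tri)
        Smat[, k] <- rowsum(rowSums(G * fr$A[[fr$cn[k]]]), fr$resp_task)
      for (j in seq_along(fr$rc_norm)) {
        nm <- fr$cn[fr$rc_norm[j]]
        Smat[, length(fr$cn) + j] <-
          rowsum(rowSums(G * fr$A[[nm]]), fr$resp_task)
      }
      out$scores <- Smat
      out$grad <- colSums(Smat)
    } else {
      g <- numeric(length(fr$theta_names))
      names(g) <- fr$theta_names
      g[nontri] <- drop(crossprod(fr$D[, nontri, drop = FALSE], rs))
      for (k in fr$rc_tri) g[k] <- sum(G * fr$A[[fr$cn[k]]])
      for (j in seq_along(fr$rc_norm)) {
        nm <- fr$cn[fr$rc_norm[j]]
        g[length(fr$cn) + j] <- sum(G * fr$A[[nm]])
      }
      out$grad <- g
    }
  }
  out
}

#' Panel simulated log-likelihood
#'
#' Evaluates the maximum-simulated-likelihood objective at a given parameter
#' vector: per respondent, the product of logit choice probabilities over
#' their tasks is averaged over the mixing draws before taking logs, which
#' is what ties a respondent's repeated tasks to a single preference draw
#' (the panel structure).
#'
#' @param spec A [mixed_logit_spec()].
#' @param data A [choice_dataset()].
#' @param params Parameter vector: coefficient means in
#'   `c(asc, attributes, interactions)` order followed by the spreads of the
#'   normally mixed coefficients.
#' @return The log-likelihood (scalar).
#' @export
panel_simulated_loglik <- function(spec, data, params) {
  fr <- msl_frame(spec, data)
  if (length(params) != length(fr$theta_names))
    stop("`params` must have length ", length(fr$theta_names), " (",
         paste(fr$theta_names, collapse = ", "), ")", call. = FALSE)
  msl_loglik_core(as.numeric(params) * fr$theta_scale, fr)$loglik
}

#' Fit a panel mixed logit by maximum simulated likelihood
#'
#' Quasi-Newton (BFGS) maximization with an analytic gradient, followed by
#' Newton polishing steps until the gradient norm drops below `gtol` (or no
#' further improvement is possible). Standard errors come from the inverse
#' numerical Hessian by default, or from the BHHH outer product of
#' per-respondent scores. The same spec, data and seed always reproduce the
#' same result.
#'
#' @param spec A [mixed_logit_spec()].
#' @param data A [choice_dataset()].
#' @param start Optional starting parameter vector (defaults to zero means
#'   and spreads of 0.1).
#' @param se `"hessian"`, `"bhhh"` or `"none"`.
#' @param gtol Gradient sup-norm declaring convergence.
#' @param maxit Maximum BFGS iterations.
#' @return An object of class `"mml_fit"`.
#' @export
fit_mixed_logit <- function(spec, data, start = NULL,
                            se = c("hessian", "bhhh", "none"),
                            gtol = 1e-5, maxit = 500L) {
  se <- match.arg(se)
  stopifnot(inherits(spec, "mixed_logit_spec"),
            inherits(data, "choice_dataset"))
  fr <- msl_frame(spec, data, check_identification = TRUE)
  np <- length(fr$theta_names)
  if (is.null(start)) {
    start <- numeric(np)
    if (length(fr$rc_norm)) start[length(fr$cn) + seq_along(fr$rc_norm)] <- 0.1
  }
  if (length(start) != np)
    stop("`start` must have length ", np, call. = FALSE)
  start <- as.numeric(start) * fr$theta_scale  # to preconditioned space

  negll <- function(th) -msl_loglik_core(th, fr)$loglik
  neggr <- function(th) -msl_loglik_core(th, fr, want_grad = TRUE)$grad

  opt <- stats::optim(start, negll, neggr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  theta <- opt$par
  res <- msl_loglik_core(theta, fr, want_grad = TRUE)
  gnorm <- max(abs(res$grad))
  iters <- max(opt$counts[["gradient"]] - 1L, 0L)
  H <- NULL

  # BFGS restarts reset the inverse-Hessian approximation, which often
  # breaks a stall; then damped-Newton polish toward the gradient-norm
  # criterion (ridge added when spread parameters sit in flat directions)
  restarts <- 0L
  while (gnorm > gtol && restarts < 4L) {
    opt2 <- stats::optim(theta, negll, neggr, method = "BFGS",
                         control = list(maxit = maxit, reltol = 1e-14))
    r2 <- msl_loglik_core(opt2$par, fr, want_grad = TRUE)
    restarts <- restarts + 1L
    if (r2$loglik < res$loglik) break
    gained <- r2$loglik > res$loglik + 1e-10 || max(abs(r2$grad)) < gnorm
    theta <- opt2$par; res <- r2; gnorm <- max(abs(r2$grad))
    if (!gained) break
  }
  polish <- 0L
  while (gnorm > gtol && polish < 15L) {
    H <- stats::optimHess(theta, negll, neggr)
    ridge <- 1e-8 * max(1, max(abs(diag(H))))
    improved <- FALSE
    for (damp in 0:6) {
      Hd <- H + (ridge * 10^damp) * diag(nrow(H))
      step <- tryCatch(solve(Hd, res$grad), error = function(e) NULL)
      if (is.null(step)) next
      lam <- 1
      for (h in 1:6) {
        cand <- theta + lam * step
        r2 <- msl_loglik_core(cand, fr, want_grad = TRUE)
        if (is.finite(r2$loglik) &&
            (r2$loglik > res$loglik + 1e-12 ||
             (r2$loglik > res$loglik - 1e-10 &&
              max(abs(r2$grad)) < 0.9 * gnorm))) {
          theta <- cand; res <- r2; gnorm <- max(abs(r2$grad))
          improved <- TRUE
          break
        }
        lam <- lam / 2
      }
      if (improved) break
    }
    polish <- polish + 1L
    if (!improved) break
  }

  K <- length(fr$cn)

  vcov <- se_vec <- NULL
  if (se == "hessian") {
    if (is.null(H)) H <- stats::optimHess(theta, negll, neggr)
    vcov <- tryCatch(solve(H), error = function(e) NULL)
  } else if (se == "bhhh") {
    sc <- msl_loglik_core(theta, fr, per_respondent = TRUE)$scores
    vcov <- tryCatch(solve(crossprod(sc)), error = function(e) NULL)
  }
  # back to natural units
  theta <- theta / fr$theta_scale
  names(theta) <- fr$theta_names
  if (!is.null(vcov)) {
    vcov <- vcov / tcrossprod(fr$theta_scale)
    dg <- diag(vcov)
    se_vec <- ifelse(dg > 0, sqrt(pmax(dg, 0)), NA_real_)
    dimnames(vcov) <- list(fr$theta_names, fr$theta_names)
    names(se_vec) <- fr$theta_names
  }

  mu <- theta[seq_len(K)]
  # the likelihood is symmetric in each spread's sign; report the magnitude
  # ($theta keeps the raw optimizer so the simulated optimum is preserved)
  sig <- if (length(fr$rc_norm)) abs(theta[K + seq_along(fr$rc_norm)]) else
    numeric(0)
  names(sig) <- fr$cn[fr$rc_norm]
  z <- if (!is.null(se_vec)) c(mu, sig) / se_vec else rep(NA_real_, np)
  p <- 2 * stats::pnorm(-abs(z))

  structure(list(
    coefficients = mu,
    spreads = sig,
    se = if (!is.null(se_vec)) se_vec[seq_len(K)] else
      setNames(rep(NA_real_, K), fr$cn),
    se_spreads = if (!is.null(se_vec) && length(fr$rc_norm))
      setNames(se_vec[K + seq_along(fr$rc_norm)], fr$cn[fr$rc_norm]) else
      setNames(rep(NA_real_, length(fr$rc_norm)), fr$cn[fr$rc_norm]),
    z = z, p_values = p,
    theta = theta, vcov = vcov,
    loglik = res$loglik,
    gradient_norm = gnorm,
    converged = gnorm < gtol,
    iterations = iters,
    newton_steps = polish,
    prob_floor_count = res$n_floor,
    n_obs = fr$n_obs, n_respondents = fr$n,
    n_parameters = np,
    mixing = fr$mx,
    draw_settings = list(n_draws = fr$R, draw_type = spec$draw_type,
                         seed = spec$seed),
    spec = spec),
    class = "mml_fit")
}

#' @export
print.mml_fit <- function(x, ...) {
  cat(sprintf("Panel mixed logit (MSL, %d %s draws)\n",
              x$draw_settings$n_draws, x$draw_settings$draw_type))
  cat(sprintf("Log-likelihood %.4f on %d parameters; %d respondents, %d choices; %s\n",
              x$loglik, x$n_parameters, x$n_respondents, x$n_obs,
              if (x$converged) "converged" else
                sprintf("NOT converged (|g| = %.3g)", x$gradient_norm)))
  print(coef_table(x), digits = 4)
  invisible(x)
}

#' Coefficient table of a fitted model
#'
#' @param x An `mml_fit`.
#' @return Data frame with estimate, SE, z, p per coefficient (means first,
#'   then mixing spreads).
#' @export
coef_table <- function(x) {
  stopifnot(inherits(x, "mml_fit"))
  nm <- names(x$theta)
  data.frame(term = nm,
             kind = c(rep("mean", length(x$coefficients)),
                      rep("sd", length(x$spreads))),
             estimate = unname(c(x$coefficients, x$spreads)),
             se = unname(if (is.null(x$vcov)) rep(NA_real_, length(nm)) else
               c(x$se, x$se_spreads)),
             z = unname(x$z), p = unname(x$p_values))
}

#' @export
coef.mml_fit <- function(object, ...) object$coefficients

#' @export
logLik.mml_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_parameters, class = "logLik")
}

#' @export
vcov.mml_fit <- function(object, ...) object$vcov

#' Forward-stepwise addition and backward elimination of covariate terms
#'
#' Candidate covariates enter as fixed interaction terms with a chosen
#' attribute (cost by default). Forward passes add, one at a time, the
#' candidate that most improves the log-likelihood, provided its
#' coefficient's p-value is below `alpha_in`; backward passes then drop any
#' selected term whose p-value exceeds `alpha_out`. The trace records every
#' step's log-likelihood and AIC.
#'
#' @param base_spec A [mixed_logit_spec()].
#' @param data A [choice_dataset()].
#' @param candidates Character vector of covariate names.
#' @param alpha_in,alpha_out Entry / exit p-value thresholds.
#' @param attribute Attribute the covariates interact with.
#' @param ... Passed to [fit_mixed_logit()].
#' @return List with `spec` (final), `fit` (final fit), and `trace`.
#' @export
stepwise_covariates <- function(base_spec, data, candidates,
                                alpha_in = 0.05, alpha_out = 0.10,
                                attribute = "cost", ...) {
  for (cv in candidates)
    if (is.null(data$covariates) || !cv %in% names(data$covariates))
      stop("candidate covariate '", cv, "' not in the dataset", call. = FALSE)
  spec <- base_spec
  cur <- fit_mixed_logit(spec, data, ...)
  trace <- data.frame(step = 0L, action = "base", term = NA_character_,
                      loglik = cur$loglik,
                      aic = 2 * cur$n_parameters - 2 * cur$loglik,
                      p = NA_real_, accepted = TRUE)
  inmodel <- character(0)
  step <- 0L
  repeat {
    pool <- setdiff(candidates, inmodel)
    if (!length(pool) || alpha_in <= 0) break
    best <- NULL
    for (cv in pool) {
      sp2 <- add_interactions(spec, data, list(c(attribute, cv)))
      f2 <- tryCatch(fit_mixed_logit(sp2, data, ...),
                     error = function(e) NULL)
      if (is.null(f2)) next
      if (is.null(best) || f2$loglik > best$fit$loglik)
        best <- list(cv = cv, spec = sp2, fit = f2)
    }
    if (is.null(best)) break
    term <- paste0(attribute, "_x_", best$cv)
    pval <- best$fit$p_values[[term]]
    step <- step + 1L
    accepted <- is.finite(pval) && pval < alpha_in
    trace <- rbind(trace, data.frame(
      step = step, action = "forward", term = term,
      loglik = best$fit$loglik,
      aic = 2 * best$fit$n_parameters - 2 * best$fit$loglik,
      p = pval, accepted = accepted))
    if (!accepted) break
    spec <- best$spec; cur <- best$fit; inmodel <- c(inmodel, best$cv)
  }
  # backward elimination
  repeat {
    if (!length(inmodel)) break
    terms <- paste0(attribute, "_x_", inmodel)
    pv <- cur$p_values[terms]
    worst <- which.max(pv)
    if (pv[worst] <= alpha_out) break
    drop_cv <- inmodel[worst]
    inmodel <- setdiff(inmodel, drop_cv)
    spec$interactions <- Filter(function(p)
      !(p[1L] == attribute && p[2L] == drop_cv), spec$interactions)
    cur <- fit_mixed_logit(spec, data, ...)
    step <- step + 1L
    trace <- rbind(trace, data.frame(
      step = step, action = "backward", term = terms[worst],
      loglik = cur$loglik,
      aic = 2 * cur$n_parameters - 2 * cur$loglik,
      p = pv[worst], accepted = TRUE))
  }
  list(spec = spec, fit = cur, trace = trace)
}
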