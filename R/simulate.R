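# Panel choice simulation under the linear-additive utility model:
# V = asc * 1[alt A] + sum_k (beta_ik + sum interactions) * x_k, with the
# observed choice following logit probabilities. The logit noise is applied
# as a single logistic comparison of V_A - V_B (the Gumbel-difference form),
# which is distributionally identical to independent Gumbel errors per
# alternative but needs one uniform draw per task.

#' Construct / validate a choice dataset
#'
#' A choice dataset is a long-format table (one row per respondent x task x
#' alternative) plus a respondent covariate table. Validation enforces:
#' exactly two alternatives per task, exactly one chosen row per
#' respondent-task, numeric attribute columns, and each respondent confined
#' to a single block.
#'
#' @param choices Data frame with columns `resp_id`, `block`, `task_id`,
#'   `role`, `alt`, `chosen`, plus one numeric column per attribute.
#' @param covariates Data frame with `resp_id` plus covariate columns, or
#'   `NULL`.
#' @param attributes Character vector naming the attribute columns; defaults
#'   to every column not among the structural ones.
#' @param provenance Optional list (seed, spec hash) recorded when simulated.
#' @return An object of class `"choice_dataset"`.
#' @export
choice_dataset <- function(choices, covariates = NULL, attributes = NULL,
                           provenance = NULL) {
  structural <- c("resp_id", "block", "task_id", "role", "alt", "chosen")
  miss <- setdiff(structural, names(choices))
  if (length(miss))
    stop("choice table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(attributes))
    attributes <- setdiff(names(choices), c(structural, "repeat_of"))
  for (a in attributes)
    if (!is.numeric(choices[[a]]))
      stop("attribute column '", a, "' is not numeric", call. = FALSE)
  key <- interaction(choices$resp_id, choices$task_id, drop = TRUE)
  n_alt <- tapply(choices$alt, key, length)
  if (any(n_alt != 2L))
    stop("task(s) without exactly 2 alternatives: ",
         paste(utils::head(names(n_alt)[n_alt != 2L]), collapse = ", "),
         call. = FALSE)
  n_ch <- tapply(choices$chosen, key, sum)
  if (any(n_ch != 1L))
    stop("respondent-task(s) without exactly one chosen alternative: ",
         paste(utils::head(names(n_ch)[n_ch != 1L]), collapse = ", "),
         call. = FALSE)
  n_blk <- tapply(choices$block, choices$resp_id,
                  function(b) length(unique(b)))
  if (any(n_blk != 1L))
    stop("respondent(s) spanning more than one block", call. = FALSE)
  o <- order(choices$resp_id, choices$task_id, choices$alt)
  choices <- choices[o, , drop = FALSE]
  rownames(choices) <- NULL
  if (!is.null(covariates)) {
    if (!"resp_id" %in% names(covariates))
      stop("covariate table needs a resp_id column", call. = FALSE)
    if (!all(unique(choices$resp_id) %in% covariates$resp_id))
      stop("covariate table is missing respondents", call. = FALSE)
  }
  structure(list(choices = choices, covariates = covariates,
                 attributes = attributes, provenance = provenance),
            class = "choice_dataset")
}

#' @export
print.choice_dataset <- function(x, ...) {
  ch <- x$choices
  cat(sprintf("<choice_dataset> %d respondents x %d tasks, %d attributes\n",
              length(unique(ch$resp_id)),
              length(unique(ch$task_id[ch$resp_id == ch$resp_id[1L]])),
              length(x$attributes)))
  invisible(x)
}

#' Simulate panel choices over a design
#'
#' Each respondent is assigned one block and answers all of its tasks with a
#' single coefficient vector (the panel structure); the alternative-specific
#' constant, if present as an `asc` column of `coefficients`, attaches to
#' alternative A. Interactions shift the attribute coefficient by
#' `beta * covariate` for each respondent.
#'
#' @param design A `choice_design`.
#' @param coefficients `n x K` matrix from [draw_individual_coefficients()]
#'   (columns named after attributes, plus optionally `asc`).
#' @param covariates Respondent covariate data frame (needed when
#'   `interactions` is non-empty).
#' @param interactions List of `list(attribute=, covariate=, beta=)`.
#' @param seed Integer seed.
#' @return A [choice_dataset()].
#' @export
simulate_choices <- function(design, coefficients, covariates = NULL,
                             interactions = list(), seed = 1L) {
  stopifnot(inherits(design, "choice_design"))
  fn <- names(design$factors)
  if (!all(fn %in% colnames(coefficients)))
    stop("coefficient matrix must have one column per design factor",
         call. = FALSE)
  n <- nrow(coefficients)
  beta <- coefficients[, fn, drop = FALSE]
  asc <- if ("asc" %in% colnames(coefficients)) coefficients[, "asc"] else
    rep(0, n)
  for (ia in interactions) {
    if (is.null(covariates) || !ia$covariate %in% names(covariates))
      stop("interaction covariate '", ia$covariate,
           "' missing from covariate table", call. = FALSE)
    if (!ia$attribute %in% fn)
      stop("interaction attribute '", ia$attribute,
           "' is not a design factor", call. = FALSE)
    beta[, ia$attribute] <- beta[, ia$attribute] +
      ia$beta * covariates[[ia$covariate]]
  }

  m <- design_matrices(design, roles = c("design", "repeat", "dominance"))
  D <- m$A - m$B  # task x K differences (A minus B)

  with_seed(seed, {
    block_of <- sample(rep_len(seq_len(design$n_blocks), n))
    rows <- vector("list", n)
    ro <- design$tasks$repeat_of[match(m$task_id, design$tasks$task_id)]
    for (i in seq_len(n)) {
      tix <- which(m$block == block_of[i])
      dv <- asc[i] + drop(D[tix, , drop = FALSE] %*% beta[i, ])
      p_a <- stats::plogis(dv)
      pick_a <- stats::runif(length(tix)) < p_a
      nt <- length(tix)
      rows[[i]] <- data.frame(
        resp_id = i,
        block = block_of[i],
        task_id = rep(m$task_id[tix], each = 2L),
        role = rep(m$role[tix], each = 2L),
        repeat_of = rep(ro[tix], each = 2L),
        alt = rep(c(1L, 2L), nt),
        chosen = as.integer(as.vector(rbind(pick_a, !pick_a))))
    }
    ch <- do.call(rbind, rows)
    # attach level columns by task/alt lookup
    idxA <- match(ch$task_id, m$task_id)
    levmat <- matrix(NA_real_, nrow(ch), length(fn),
                     dimnames = list(NULL, fn))
    isA <- ch$alt == 1L
    levmat[isA, ] <- m$A[idxA[isA], , drop = FALSE]
    levmat[!isA, ] <- m$B[idxA[!isA], , drop = FALSE]
    ch <- cbind(ch, as.data.frame(levmat))
    choice_dataset(ch, covariates, attributes = fn,
                   provenance = list(seed = as.integer(seed)))
  })
}

#' Simulate a full study: coefficients, covariates, choices
#'
#' Convenience wrapper drawing individual coefficients and covariates from a
#' [population_spec()] and simulating choices over a design. All randomness
#' derives deterministically from `seed`.
#'
#' @param pop A [population_spec()].
#' @param design A `choice_design`.
#' @param n Number of respondents (default `pop$n_respondents`).
#' @param seed Integer seed (default `pop$seed`).
#' @return A [choice_dataset()] whose provenance records the seed, the
#'   population hash and the true coefficient matrix (as attribute
#'   `"true_coefficients"` of the provenance list, for recovery checks).
#' @export
simulate_study <- function(pop, design, n = pop$n_respondents,
                           seed = pop$seed) {
  beta <- draw_individual_coefficients(pop, n, derive_seed(seed, "beta"))
  cov <- draw_covariates(pop, n, derive_seed(seed, "cov"))
  ds <- simulate_choices(design, beta, cov,
                         interactions = pop$covariate_model$interactions,
                         seed = derive_seed(seed, "choices"))
  ds$provenance <- list(seed = as.integer(seed),
                        pop_hash = config_hash(unclass(pop)),
                        true_coefficients = beta)
  ds
}
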