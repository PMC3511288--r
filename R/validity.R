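# Response-validity scoring from the embedded dominance and repeat tasks.

# Locate, per block, the dominance task and its dominant alternative.
dominance_tasks <- function(design) {
  m <- design_matrices(design, roles = "dominance")
  if (length(m$task_id) == 0L)
    stop("design has no dominance-role tasks", call. = FALSE)
  dom_alt <- integer(length(m$task_id))
  for (i in seq_along(m$task_id)) {
    if (dominates(m$A[i, ], m$B[i, ], design$factors)) dom_alt[i] <- 1L
    else if (dominates(m$B[i, ], m$A[i, ], design$factors)) dom_alt[i] <- 2L
    else stop("dominance task ", m$task_id[i],
              " has no dominant alternative", call. = FALSE)
  }
  data.frame(task_id = m$task_id, block = m$block, dominant_alt = dom_alt)
}

#' Monotonicity (dominance) test
#'
#' A respondent passes when they choose the dominant alternative of their
#' block's dominance task — the alternative that is at least as good on
#' every attribute with a stated preference direction and strictly better
#' on at least one.
#'
#' @param data A [choice_dataset()].
#' @param design The `choice_design` the data were collected/simulated on.
#' @return List with `pass` (named logical per respondent) and `rate`.
#' @export
monotonicity_test <- function(data, design) {
  dom <- dominance_tasks(design)
  blocks_seen <- unique(data$choices$block)
  miss <- setdiff(blocks_seen, dom$block)
  if (length(miss))
    stop("missing validity task: block(s) ", paste(miss, collapse = ", "),
         " have no dominance task", call. = FALSE)
  ch <- data$choices
  sel <- ch$role == "dominance" & ch$chosen == 1L
  picked <- ch[sel, c("resp_id", "task_id", "alt")]
  pass <- picked$alt == dom$dominant_alt[match(picked$task_id, dom$task_id)]
  names(pass) <- picked$resp_id
  list(pass = pass, rate = mean(pass))
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed agreement and
#' `p_e` the agreement expected from the marginals.
#'
#' @param tab 2x2 contingency table (first answer in rows, second in
#'   columns).
#' @return Kappa in `[-1, 1]`; `NA` when the marginals are degenerate
#'   (`p_e = 1`).
#' @export
cohen_kappa <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2L, ncol(tab) == 2L)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 100) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Repeat-task consistency and kappa
#'
#' Compares each respondent's answer to the repeated choice set with their
#' answer to its original. If the repeated task presented the alternatives
#' in swapped order (detected by comparing attribute profiles), the second
#' answer is mapped back before comparison. Cohen's kappa is computed on
#' the pooled first-vs-repeat 2x2 table.
#'
#' @inheritParams monotonicity_test
#' @return List with `pass`, `pass_rate`, `kappa`, and the agreement
#'   `table`.
#' @export
repeat_consistency <- function(data, design) {
  m <- design_matrices(design, roles = "repeat")
  if (length(m$task_id) == 0L)
    stop("design has no repeat-role tasks", call. = FALSE)
  tt <- design$tasks
  ro <- tt$repeat_of[match(m$task_id, tt$task_id)]
  if (anyNA(ro))
    stop("pairing error: repeat task(s) without a repeat_of source",
         call. = FALSE)
  orig <- design_matrices(design, roles = "design")
  swap <- logical(length(m$task_id))
  for (i in seq_along(m$task_id)) {
    j <- match(ro[i], orig$task_id)
    if (is.na(j))
      stop("pairing error: repeat task ", m$task_id[i],
           " points to unknown task ", ro[i], call. = FALSE)
    if (all(m$A[i, ] == orig$A[j, ]) && all(m$B[i, ] == orig$B[j, ]))
      swap[i] <- FALSE
    else if (all(m$A[i, ] == orig$B[j, ]) && all(m$B[i, ] == orig$A[j, ]))
      swap[i] <- TRUE
    else stop("pairing error: repeat task ", m$task_id[i],
              " does not duplicate task ", ro[i], call. = FALSE)
  }
  ch <- data$choices
  sel <- ch$chosen == 1L
  picked <- ch[sel, c("resp_id", "task_id", "alt")]
  key <- paste(picked$resp_id, picked$task_id)
  rix <- match(picked$task_id, m$task_id)
  rep_rows <- which(!is.na(rix))
  i <- rix[rep_rows]
  orig_row <- match(paste(picked$resp_id[rep_rows], ro[i]), key)
  if (anyNA(orig_row))
    stop("pairing error: respondent(s) lack an answer to the original of ",
         "their repeated task", call. = FALSE)
  first <- picked$alt[orig_row]
  second <- ifelse(swap[i], 3L - picked$alt[rep_rows], picked$alt[rep_rows])
  pass <- first == second
  names(pass) <- picked$resp_id[rep_rows]
  tab <- table(factor(first, 1:2, c("A", "B")),
               factor(second, 1:2, c("A", "B")))
  list(pass = pass, pass_rate = mean(pass), kappa = cohen_kappa(tab),
       table = tab)
}

#' Full response-validity report
#'
#' @inheritParams monotonicity_test
#' @return A list of class `"validity_report"` with the monotonicity pass
#'   rate, repeat pass rate, kappa, and per-respondent flags.
#' @export
validity_report <- function(data, design) {
  mono <- monotonicity_test(data, design)
  rep <- repeat_consistency(data, design)
  structure(list(monotonicity_pass_rate = mono$rate,
                 repeat_pass_rate = rep$pass_rate,
                 kappa = rep$kappa,
                 monotonicity_pass = mono$pass,
                 repeat_pass = rep$pass,
                 table = rep$table),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("<validity_report> monotonicity pass %.1f%%, repeat pass %.1f%%, kappa %.3f\n",
              100 * x$monotonicity_pass_rate, 100 * x$repeat_pass_rate,
              x$kappa))
  invisible(x)
}

# Restrict a choice dataset to a set of respondents.
subset_respondents <- function(data, ids) {
  ch <- data$choices[data$choices$resp_id %in% ids, , drop = FALSE]
  cov <- if (!is.null(data$covariates))
    data$covariates[data$covariates$resp_id %in% ids, , drop = FALSE]
  choice_dataset(ch, cov, attributes = data$attributes,
                 provenance = data$provenance)
}

#' Refit excluding respondents flagged by a validity test
#'
#' Fits the model on the full sample and on the sample with failing
#' respondents removed, and reports a side-by-side coefficient table with
#' sign agreement and agreement of the rank order of coefficient
#' magnitudes.
#'
#' @param data A [choice_dataset()].
#' @param pass Named logical vector of per-respondent pass flags (names are
#'   respondent ids); failing respondents are excluded.
#' @param spec A [mixed_logit_spec()].
#' @param min_respondents Minimum respondents the exclusion must leave.
#' @param ... Passed to [fit_mixed_logit()].
#' @return List with `full`, `excluded` (both `mml_fit`) and `comparison`.
#' @export
refit_excluding <- function(data, pass, spec, min_respondents = 30L, ...) {
  keep <- names(pass)[pass]
  keep_ids <- unique(data$choices$resp_id)
  keep_ids <- keep_ids[as.character(keep_ids) %in% keep]
  if (length(keep_ids) < min_respondents)
    stop("insufficient sample: exclusion leaves ", length(keep_ids),
         " respondents (< ", min_respondents, ")", call. = FALSE)
  full <- fit_mixed_logit(spec, data, ...)
  excl <- if (all(pass)) full else
    fit_mixed_logit(spec, subset_respondents(data, keep_ids), ...)
  cf <- full$coefficients; ce <- excl$coefficients
  comparison <- data.frame(
    term = names(cf),
    full = unname(cf), excluded = unname(ce),
    sign_agree = sign(cf) == sign(ce),
    rank_full = rank(-abs(cf)), rank_excluded = rank(-abs(ce)))
  comparison$rank_agree <- comparison$rank_full == comparison$rank_excluded
  list(full = full, excluded = excl, comparison = comparison)
}
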