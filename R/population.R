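# Synthetic respondent populations: heterogeneous preference coefficients
# drawn from per-coefficient mixing distributions, plus binary covariates.

# Inverse CDF of the symmetric triangular distribution on [0, 2], mode 1.
# Multiplying by the coefficient mean gives the "constrained triangular"
# mixing whose spread equals |mean|, so every draw shares the mean's sign.
qtriangular01 <- function(u) {
  ifelse(u < 0.5, sqrt(2 * u), 2 - sqrt(2 * (1 - u)))
}

#' Specify a synthetic preference population
#'
#' @param means Named numeric vector of coefficient means: one per attribute
#'   plus optionally `asc`, the alternative-specific constant attached to
#'   alternative A (left option).
#' @param mixing Named list giving the mixing distribution per coefficient:
#'   `list(type = "fixed")`, `list(type = "normal", sd = s)` or
#'   `list(type = "triangular")` (spread tied to `|mean|`). Coefficients not
#'   listed are fixed.
#' @param covariate_model List with `prevalence`, a named vector of Bernoulli
#'   prevalences in `[0, 1]` for binary respondent covariates, and
#'   `interactions`, a list of `list(attribute=, covariate=, beta=)` terms
#'   shifting an attribute coefficient for covariate carriers.
#' @param n_respondents Default panel size.
#' @param seed Default seed.
#' @return An object of class `"population_spec"`.
#' @export
population_spec <- function(means, mixing = list(),
                            covariate_model = list(prevalence = numeric(0),
                                                   interactions = list()),
                            n_respondents = 100L, seed = 1L) {
  if (is.null(names(means)) || any(!nzchar(names(means))))
    stop("`means` must be a fully named numeric vector", call. = FALSE)
  for (nm in names(mixing)) {
    m <- mixing[[nm]]
    if (!nm %in% names(means))
      stop("mixing given for unknown coefficient '", nm, "'", call. = FALSE)
    if (!m$type %in% c("fixed", "normal", "triangular"))
      stop("invalid mixing type '", m$type, "' for '", nm, "'", call. = FALSE)
    if (m$type == "normal") {
      if (is.null(m$sd) || m$sd < 0)
        stop("invalid distribution: normal mixing for '", nm,
             "' needs sd >= 0", call. = FALSE)
    }
  }
  prev <- covariate_model$prevalence %||% numeric(0)
  if (length(prev) && (any(prev < 0) || any(prev > 1)))
    stop("covariate prevalences must lie in [0, 1]", call. = FALSE)
  for (ia in covariate_model$interactions %||% list()) {
    if (!ia$attribute %in% names(means))
      stop("interaction attribute '", ia$attribute, "' not in `means`",
           call. = FALSE)
    if (!ia$covariate %in% names(prev))
      stop("interaction covariate '", ia$covariate,
           "' has no prevalence", call. = FALSE)
  }
  structure(list(means = means, mixing = mixing,
                 covariate_model = list(
                   prevalence = prev,
                   interactions = covariate_model$interactions %||% list()),
                 n_respondents = as.integer(n_respondents),
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> %d respondents, %d coefficients (%d random)\n",
              x$n_respondents, length(x$means),
              sum(vapply(x$mixing, function(m) m$type != "fixed", logical(1)))))
  invisible(x)
}

#' Draw per-respondent coefficient vectors
#'
#' Normal coefficients are drawn `N(mean, sd^2)`; constrained-triangular
#' coefficients as `mean * T` with `T` symmetric triangular on `[0, 2]`
#' (support `[0, 2 mean]`, or `[2 mean, 0]` for negative means, so the sign
#' of the mean is preserved); fixed coefficients are constant.
#'
#' @param pop A [population_spec()].
#' @param n Number of respondents (default `pop$n_respondents`).
#' @param seed Seed (default `pop$seed`).
#' @return An `n x K` matrix with one named column per coefficient.
#' @export
draw_individual_coefficients <- function(pop, n = pop$n_respondents,
                                         seed = pop$seed) {
  stopifnot(inherits(pop, "population_spec"))
  K <- length(pop$means)
  with_seed(seed, {
    out <- matrix(rep(pop$means, each = n), n, K,
                  dimnames = list(NULL, names(pop$means)))
    for (nm in names(pop$mixing)) {
      m <- pop$mixing[[nm]]
      if (m$type == "normal" && m$sd > 0)
        out[, nm] <- stats::rnorm(n, pop$means[[nm]], m$sd)
      else if (m$type == "triangular")
        out[, nm] <- pop$means[[nm]] * qtriangular01(stats::runif(n))
    }
    out
  })
}

#' Draw a respondent covariate table
#'
#' Binary covariates are independent Bernoulli draws at the prevalences in
#' the population spec; `age` and `male` descriptive columns are included
#' when the spec carries them (they do not enter utilities unless an
#' interaction names them).
#'
#' @inheritParams draw_individual_coefficients
#' @return A data frame with `resp_id` and one column per covariate.
#' @export
draw_covariates <- function(pop, n = pop$n_respondents, seed = pop$seed) {
  stopifnot(inherits(pop, "population_spec"))
  prev <- pop$covariate_model$prevalence
  with_seed(derive_seed(seed, "covariates"), {
    df <- data.frame(resp_id = seq_len(n))
    for (nm in names(prev))
      df[[nm]] <- as.integer(stats::runif(n) < prev[[nm]])
    df
  })
}

#' Preset emulating the medication-adherence study conditions
#'
#' Returns a seeded population and design matching the study structure this
#' package is built around: 161 respondents over 4 survey versions of 10
#' pairwise tasks each (8 D-efficient design tasks plus one repeated and one
#' dominated task), 8 linear medication attributes, normally mixed harm and
#' benefit coefficients, a sign-constrained triangular cost coefficient, a
#' cost-by-private-health-insurance interaction of +0.004, and covariate
#' prevalences of 0.48 (private health insurance), 0.61 (concession card)
#' and 0.37 (low income). Coefficient magnitudes are illustrative defaults
#' chosen to give the qualitative importance ordering reported for such
#' panels (risk of death most important, regimen least among significant
#' factors); the true study coefficients are not public.
#'
#' @param seed Integer seed controlling design search and all draws.
#' @return A list with elements `pop` ([population_spec()]) and `design`
#'   (`choice_design`).
#' @examples
#' p <- study_emulation_preset()
#' p$pop$n_respondents  # 161
#' @export
study_emulation_preset <- function(seed = 20120620L) {
  factors <- medication_factors()
  design <- generate_efficient_design(factors, n_tasks = 32L, n_blocks = 4L,
                                      n_iter = 2000L,
                                      seed = derive_seed(seed, "design"))
  design <- add_validity_tasks(design, seed = derive_seed(seed, "validity"))
  means <- c(asc = 0.05,
             side_effect_severity = -0.10,
             future_risk = -0.0141,
             symptom_frequency = -0.02,
             death_risk = -0.035,
             cost = -0.012,
             symptom_severity = -0.005,
             regimen = -0.0937,
             alcohol = -0.02)
  mixing <- list(
    side_effect_severity = list(type = "normal", sd = 0.06),
    future_risk = list(type = "normal", sd = 0.009),
    symptom_frequency = list(type = "normal", sd = 0.013),
    death_risk = list(type = "normal", sd = 0.022),
    cost = list(type = "triangular"))
  pop <- population_spec(
    means, mixing,
    covariate_model = list(
      prevalence = c(PHI = 0.48, HC = 0.61, low_income = 0.37),
      interactions = list(list(attribute = "cost", covariate = "PHI",
                               beta = 0.004))),
    n_respondents = 161L, seed = seed)
  list(pop = pop, design = design)
}

#' Harm/benefit grouping of the default medication attributes
#'
#' Tags each harm/benefit attribute as harm vs benefit and immediate vs
#' long-term, the grouping used by [classify_harm_benefit()].
#'
#' @return A named list of character vectors.
#' @export
medication_harm_benefit_groups <- function() {
  list(harm_immediate = "side_effect_severity",
       harm_longterm = "future_risk",
       benefit_immediate = "symptom_frequency",
       benefit_longterm = "death_risk")
}
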