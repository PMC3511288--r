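#' Define a choice attribute (factor)
#'
#' A factor is one characteristic of a hypothetical alternative — e.g. the
#' out-of-pocket monthly cost of a medication — together with the discrete
#' levels it can take in the experiment and the direction in which utility is
#' expected to move as the level increases.
#'
#' @param name Short identifier (used as a column name in choice data).
#' @param levels Strictly increasing numeric vector of at least two level
#'   values, in the attribute's natural units.
#' @param direction Expected preference direction: `+1` if higher levels are
#'   preferred, `-1` if lower levels are preferred, `0` for no prior.
#' @param description Free-text description.
#' @param unit Unit label for the levels (e.g. `"$AU/month"`).
#'
#' @return An object of class `"factor_spec"`.
#' @examples
#' factor_spec("cost", c(5, 20, 35, 50), direction = -1, unit = "$AU/month")
#' @export
factor_spec <- function(name, levels, direction = 0, description = name,
                        unit = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string", call. = FALSE)
  levels <- as.numeric(levels)
  if (length(levels) < 2L || anyNA(levels))
    stop("factor '", name, "' needs >= 2 numeric levels", call. = FALSE)
  if (any(diff(levels) <= 0))
    stop("levels of factor '", name, "' must be strictly increasing",
         call. = FALSE)
  if (!direction %in% c(-1, 0, 1))
    stop("`direction` must be -1, 0 or +1", call. = FALSE)
  structure(
    list(name = name, description = description, unit = unit,
         levels = levels, direction = as.integer(direction)),
    class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  dir <- c("-1" = "lower preferred", "0" = "no prior",
           "1" = "higher preferred")[as.character(x$direction)]
  cat(sprintf("<factor> %s [%s]: levels %s (%s)\n", x$name, x$unit,
              paste(x$levels, collapse = ", "), dir))
  invisible(x)
}

#' Bundle factors into a named factor set
#'
#' @param ... `factor_spec` objects (or a single list of them).
#' @return A named list of class `"factor_set"`.
#' @export
factor_set <- function(...) {
  fs <- list(...)
  if (length(fs) == 1L && !inherits(fs[[1L]], "factor_spec")) fs <- fs[[1L]]
  if (length(fs) == 0L)
    stop("empty factor list: at least one factor is required", call. = FALSE)
  ok <- vapply(fs, inherits, logical(1), "factor_spec")
  if (!all(ok)) stop("all elements must be factor_spec objects", call. = FALSE)
  nms <- vapply(fs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate factor names", call. = FALSE)
  names(fs) <- nms
  structure(fs, class = "factor_set")
}

#' @export
print.factor_set <- function(x, ...) {
  cat(sprintf("<factor_set> %d factors\n", length(x)))
  for (f in x) print(f)
  invisible(x)
}

#' Default medication-attribute registry
#'
#' Eight attributes describing a hypothetical long-term medication, covering
#' immediate and long-term harms and benefits, cost, regimen, disease symptom
#' severity and alcohol restrictions. The level values are a configurable
#' default registry: cost levels are centred about typical Australian
#' prescription co-payments, risks are 10-year percentages, severities are
#' 0-10 scores, regimen is doses per day. Override any entry by building your
#' own [factor_set()].
#'
#' @return A [factor_set()] of 8 factors.
#' @examples
#' medication_factors()
#' @export
medication_factors <- function() {
  factor_set(
    factor_spec("side_effect_severity", c(1, 4, 7, 10), -1,
                "current side effect severity", "score 0-10"),
    factor_spec("future_risk", c(5, 20, 35, 50), -1,
                "chance of future unwanted medication effects", "% over 10y"),
    factor_spec("symptom_frequency", c(2, 10, 18, 26), -1,
                "days with symptoms while on medication", "days/month"),
    factor_spec("death_risk", c(5, 15, 25, 35), -1,
                "chance of early death from illness while on medication",
                "% over 10y"),
    factor_spec("cost", c(5, 20, 35, 50), -1,
                "out of pocket monthly cost", "$AU/month"),
    factor_spec("symptom_severity", c(1, 4, 7, 10), -1,
                "severity of daily disease symptoms", "score 0-10"),
    factor_spec("regimen", c(1, 2, 3, 4), -1,
                "doses per day", "doses/day"),
    factor_spec("alcohol", c(0, 1), -1,
                "alcohol restriction while on medication", "0/1"))
}

#' Does one attribute profile dominate another?
#'
#' Profile `a` weakly dominates `b` when, for every factor with a stated
#' preference direction, `a` is at least as good as `b`, with at least one
#' strict improvement. Factors with `direction = 0` carry no prior and are
#' ignored.
#'
#' @param a,b Named numeric vectors, one level value per factor.
#' @param factors A [factor_set()].
#' @return `TRUE` if `a` strictly dominates `b` (in the weak-dominance,
#'   at-least-one-strict sense), else `FALSE`.
#' @export
dominates <- function(a, b, factors) {
  dirs <- vapply(factors, `[[`, integer(1), "direction")
  nms <- names(dirs)[dirs != 0L]
  if (length(nms) == 0L) return(FALSE)
  d <- dirs[nms] * (as.numeric(a[nms]) - as.numeric(b[nms]))
  all(d >= 0) && any(d > 0)
}
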