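#' Halton quasi-random draws
#'
#' Low-discrepancy sequences used in place of pseudo-random numbers for
#' maximum simulated likelihood: each mixing dimension gets the radical
#' inverse sequence in a distinct prime base (the first K primes, in
#' coefficient order), the first `discard` points are dropped to avoid the
#' correlated start of the sequence, and each respondent receives their own
#' contiguous sub-sequence so that draws are independent-looking across
#' respondents but identical across re-runs.
#'
#' @param dimension Number of mixing dimensions (max 25).
#' @param n_draws Draws per respondent.
#' @param n_respondents Number of respondents.
#' @param discard Leading points to drop (default 10).
#' @param permute_seed Optional integer; if supplied, the draw order within
#'   each respondent is randomly permuted per dimension (seeded).
#' @return A 3-d array `[n_respondents, n_draws, dimension]` with all values
#'   strictly in (0, 1).
#' @examples
#' halton_draws(1, 3, 1, discard = 0)[1, , 1]  # 1/2 1/4 3/4
#' @export
halton_draws <- function(dimension, n_draws, n_respondents = 1L,
                         discard = 10L, permute_seed = NULL) {
  primes <- c(2L, 3L, 5L, 7L, 11L, 13L, 17L, 19L, 23L, 29L, 31L, 37L, 41L,
              43L, 47L, 53L, 59L, 61L, 67L, 71L, 73L, 79L, 83L, 89L, 97L)
  if (dimension < 1L || dimension > length(primes))
    stop("unsupported dimension: need 1..", length(primes), call. = FALSE)
  if (n_draws < 1L) stop("n_draws must be >= 1", call. = FALSE)
  n <- n_draws * n_respondents
  idx <- seq_len(n) + discard
  out <- array(NA_real_, c(n_respondents, n_draws, dimension))
  for (d in seq_len(dimension)) {
    h <- radical_inverse(idx, primes[d])
    m <- matrix(h, nrow = n_draws, ncol = n_respondents)  # contiguous per resp
    if (!is.null(permute_seed)) {
      m <- with_seed(derive_seed(permute_seed, paste0("halton", d)), {
        apply(m, 2L, sample)
      })
    }
    out[, , d] <- t(m)
  }
  out
}

# Vectorized radical inverse of integer indices in a given base.
radical_inverse <- function(idx, base) {
  out <- numeric(length(idx))
  f <- 1 / base
  i <- as.numeric(idx)
  while (any(i > 0)) {
    out <- out + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  out
}
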