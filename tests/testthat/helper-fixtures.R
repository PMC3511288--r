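# Shared fixtures: tiny factor sets, hand-built designs and datasets.

tiny_factors <- function() {
  factor_set(
    factor_spec("price", c(1, 2, 3), direction = -1),
    factor_spec("quality", c(0, 5, 10), direction = +1))
}

# Build a choice_design directly from level matrices (bypasses the search).
manual_design <- function(factors, A, B, blocks = 1L,
                          roles = rep("design", nrow(A))) {
  tasks <- dcemix:::tasks_frame(factors, A, B, seq_len(nrow(A)),
                                rep_len(blocks, nrow(A)), roles)
  dcemix:::new_choice_design(factors, tasks, max(blocks))
}

# Independent D-error oracle: assemble the MNL information matrix from the
# generic sum_j p_j (x_j - xbar)(x_j - xbar)' formula, task by task.
d_error_oracle <- function(design, priors) {
  m <- dcemix:::design_matrices(design)
  K <- ncol(m$A)
  info <- matrix(0, K, K)
  for (t in seq_len(nrow(m$A))) {
    X <- rbind(m$A[t, ], m$B[t, ])
    v <- X %*% priors
    p <- exp(v) / sum(exp(v))
    xbar <- colSums(p[, 1] * X)
    for (j in 1:2)
      info <- info + p[j] * tcrossprod(X[j, ] - xbar)
  }
  det(solve(info))^(1 / K)
}

# One-attribute panel dataset built by hand (n respondents x tasks),
# each task contrasting attribute values xa vs xb; `chosen_a` is a
# respondents x tasks logical matrix.
hand_dataset <- function(xa, xb, chosen_a) {
  n <- nrow(chosen_a); tt <- ncol(chosen_a)
  rows <- expand.grid(alt = 1:2, task_id = seq_len(tt),
                      resp_id = seq_len(n))
  rows$block <- 1L
  rows$role <- "design"
  rows$x <- ifelse(rows$alt == 1L, xa[rows$task_id], xb[rows$task_id])
  picked_a <- chosen_a[cbind(rows$resp_id, rows$task_id)]
  rows$chosen <- as.integer(ifelse(rows$alt == 1L, picked_a, !picked_a))
  choice_dataset(rows, attributes = "x")
}

# The preset plus a simulated dataset at chosen scale, reused across tests.
preset_data <- local({
  cache <- new.env()
  function(n = 161L, seed = 7L) {
    key <- paste0("n", n, "s", seed)
    if (is.null(cache[[key]])) {
      p <- study_emulation_preset()
      cache[[key]] <- list(preset = p,
                           data = simulate_study(p$pop, p$design,
                                                 n = n, seed = seed))
    }
    cache[[key]]
  }
})

preset_mixing <- c(side_effect_severity = "normal", future_risk = "normal",
                   symptom_frequency = "normal", death_risk = "normal",
                   cost = "triangular")
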