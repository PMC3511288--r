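#' Enumerate the full factorial of attribute profiles
#'
#' @param factors A [factor_set()].
#' @return A data frame with one row per profile and one column per factor;
#'   the number of rows is the product of the level counts.
#' @examples
#' nrow(enumerate_full_factorial(medication_factors()))
#' @export
enumerate_full_factorial <- function(factors) {
  if (!inherits(factors, "factor_set")) factors <- factor_set(factors)
  grid <- expand.grid(lapply(factors, `[[`, "levels"),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names(factors)
  grid
}

# Extract the per-alternative level matrices of a design's tasks.
# Returns list(A = n_tasks x K, B = n_tasks x K, task_id, block, role).
design_matrices <- function(design, roles = "design") {
  tt <- design$tasks
  tt <- tt[tt$role %in% roles, , drop = FALSE]
  fn <- names(design$factors)
  a <- tt[tt$alt == 1L, , drop = FALSE]
  b <- tt[tt$alt == 2L, , drop = FALSE]
  stopifnot(identical(a$task_id, b$task_id))
  list(A = as.matrix(a[, fn, drop = FALSE]),
       B = as.matrix(b[, fn, drop = FALSE]),
       task_id = a$task_id, block = a$block, role = a$role)
}

# MNL Fisher information of a paired design at coefficient vector `priors`.
design_information <- function(A, B, priors) {
  va <- drop(A %*% priors)
  pa <- stats::plogis(va - drop(B %*% priors))
  # sum_tasks sum_j p_j (x_j - xbar)(x_j - xbar)'; with 2 alternatives this
  # collapses to sum p(1-p) d d' with d = x_A - x_B
  d <- A - B
  w <- pa * (1 - pa)
  crossprod(d * sqrt(w))
}

#' D-error of a paired choice design
#'
#' The D-error is `det(I(beta)^-1)^(1/K)` where `I` is the Fisher information
#' of a multinomial logit model over the design's design-role tasks and `K`
#' the number of coefficients; smaller is better. With zero priors the choice
#' probabilities are 1/2 and the criterion reduces to the classical
#' utility-neutral D-error.
#'
#' @param design A `choice_design`.
#' @param priors Named (or positionally matched) coefficient vector, one per
#'   factor; defaults to all zeros.
#' @return A positive scalar.
#' @export
d_error <- function(design, priors = NULL) {
  stopifnot(inherits(design, "choice_design"))
  K <- length(design$factors)
  if (is.null(priors)) priors <- rep(0, K)
  if (length(priors) != K)
    stop("`priors` must have one value per factor (", K, ")", call. = FALSE)
  if (!is.null(names(priors))) priors <- priors[names(design$factors)]
  m <- design_matrices(design)
  if (nrow(m$A) == 0L) stop("design has no design-role tasks", call. = FALSE)
  info <- design_information(m$A, m$B, as.numeric(priors))
  ld <- determinant(info, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus) ||
      rcond(info) < .Machine$double.eps * 1e3)
    stop("singular design: information matrix is not positive definite ",
         "(an attribute may be constant across all alternatives)",
         call. = FALSE)
  exp(-as.numeric(ld$modulus) / K)
}

#' Level-balance report for a design
#'
#' Counts how often each level of each factor appears across the
#' design-role tasks (both alternatives pooled) and flags factors whose
#' level counts deviate from perfect balance by more than one occurrence.
#'
#' @param design A `choice_design`.
#' @return A data frame with columns `factor`, `level`, `count`, `expected`,
#'   `flag`.
#' @export
level_balance <- function(design) {
  m <- design_matrices(design)
  out <- list()
  for (f in names(design$factors)) {
    lv <- design$factors[[f]]$levels
    x <- c(m$A[, f], m$B[, f])
    cnt <- vapply(lv, function(l) sum(x == l), numeric(1))
    exp_cnt <- length(x) / length(lv)
    out[[f]] <- data.frame(factor = f, level = lv, count = cnt,
                           expected = exp_cnt,
                           flag = abs(cnt - exp_cnt) > 1)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

new_choice_design <- function(factors, tasks, n_blocks, d_err = NA_real_,
                              d_err_initial = NA_real_) {
  structure(list(factors = factors, tasks = tasks,
                 n_blocks = as.integer(n_blocks),
                 d_error = d_err, d_error_initial = d_err_initial),
            class = "choice_design")
}

#' @export
print.choice_design <- function(x, ...) {
  tt <- x$tasks
  nd <- sum(tt$role == "design" & tt$alt == 1L)
  nr <- sum(tt$role == "repeat" & tt$alt == 1L)
  nm <- sum(tt$role == "dominance" & tt$alt == 1L)
  cat(sprintf("<choice_design> %d factors, %d tasks (%d design / %d repeat / %d dominance) in %d block(s)\n",
              length(x$factors), nd + nr + nm, nd, nr, nm, x$n_blocks))
  if (is.finite(x$d_error))
    cat(sprintf("  D-error %.6g (random start %.6g)\n",
                x$d_error, x$d_error_initial))
  invisible(x)
}

# Draw one random task (two distinct profiles) as a 2 x K level matrix.
random_task <- function(factors) {
  K <- length(factors)
  repeat {
    prof <- vapply(factors, function(f)
      f$levels[sample.int(length(f$levels), 2L, replace = TRUE)],
      numeric(2))
    if (!all(prof[1L, ] == prof[2L, ])) return(prof)
  }
}

tasks_frame <- function(factors, A, B, task_id, block, role,
                        repeat_of = NA_integer_) {
  fn <- names(factors)
  n <- length(task_id)
  df <- data.frame(task_id = rep(task_id, each = 2L),
                   block = rep(as.integer(block), each = 2L),
                   role = rep(role, each = 2L),
                   alt = rep(c(1L, 2L), n),
                   repeat_of = rep(as.integer(repeat_of), each = 2L))
  lev <- matrix(NA_real_, 2L * n, length(fn), dimnames = list(NULL, fn))
  lev[seq(1L, 2L * n, by = 2L), ] <- A
  lev[seq(2L, 2L * n, by = 2L), ] <- B
  cbind(df, as.data.frame(lev))
}

#' Generate a D-efficient, level-balanced, blocked paired design
#'
#' Starts from a uniformly random design and improves it by coordinate
#' swaps (a modified Fedorov search): at each iteration one level of one
#' alternative of one task is replaced by another admissible level and the
#' change is kept only if the D-error decreases. The search is seeded and
#' deterministic. Tasks are then assigned to blocks so that per-block level
#' counts are as even as possible (greedy in task order, ties broken by
#' block index).
#'
#' @param factors A [factor_set()].
#' @param n_tasks Total number of design tasks (must be divisible by
#'   `n_blocks` and at least the number of coefficients).
#' @param n_blocks Number of survey versions.
#' @param priors Coefficient priors for the D-error (default zeros).
#' @param n_iter Number of candidate swaps to evaluate.
#' @param seed Integer seed; the same seed reproduces the design exactly.
#' @return A `choice_design` with `d_error` (final) and `d_error_initial`
#'   (random start) filled in.
#' @examples
#' d <- generate_efficient_design(medication_factors(), 32, 4, seed = 1)
#' d$d_error <= d$d_error_initial
#' @export
generate_efficient_design <- function(factors, n_tasks, n_blocks = 1L,
                                      priors = NULL, n_iter = 2000L,
                                      seed = 1L) {
  if (!inherits(factors, "factor_set")) factors <- factor_set(factors)
  K <- length(factors)
  if (n_tasks %% n_blocks != 0L)
    stop("`n_tasks` must be divisible by `n_blocks`", call. = FALSE)
  if (n_tasks < K)
    stop("under-identified design: ", n_tasks, " tasks cannot identify ",
         K, " coefficients", call. = FALSE)
  if (is.null(priors)) priors <- rep(0, K)
  priors <- as.numeric(priors)

  with_seed(seed, {
    # random start, regenerated until non-singular
    for (attempt in 1:50) {
      A <- matrix(NA_real_, n_tasks, K, dimnames = list(NULL, names(factors)))
      B <- A
      for (t in seq_len(n_tasks)) {
        pr <- random_task(factors)
        A[t, ] <- pr[1L, ]; B[t, ] <- pr[2L, ]
      }
      info <- design_information(A, B, priors)
      if (rcond(info) > .Machine$double.eps * 1e3) break
    }
    obj <- function(A, B) {
      info <- design_information(A, B, priors)
      if (rcond(info) < .Machine$double.eps * 1e3) return(Inf)
      ld <- determinant(info, logarithm = TRUE)
      if (ld$sign <= 0) return(Inf)
      exp(-as.numeric(ld$modulus) / K)
    }
    cur <- obj(A, B)
    d_init <- cur

    for (it in seq_len(n_iter)) {
      t <- sample.int(n_tasks, 1L)
      f <- sample.int(K, 1L)
      side <- sample.int(2L, 1L)
      lv <- factors[[f]]$levels
      old <- if (side == 1L) A[t, f] else B[t, f]
      new <- sample(lv[lv != old], 1L)
      A2 <- A; B2 <- B
      if (side == 1L) A2[t, f] <- new else B2[t, f] <- new
      if (all(A2[t, ] == B2[t, ])) next  # keep alternatives distinct
      cand <- obj(A2, B2)
      if (cand < cur) { A <- A2; B <- B2; cur <- cand }
    }

    blocks <- assign_blocks(A, B, factors, n_blocks)
    tasks <- tasks_frame(factors, A, B, seq_len(n_tasks), blocks, "design")
    des <- new_choice_design(factors, tasks, n_blocks, cur, d_init)
    des$balance <- level_balance(des)
    des
  })
}

# Greedy block assignment equalizing per-block level counts; tasks taken in
# index order, ties broken by block index.
assign_blocks <- function(A, B, factors, n_blocks) {
  n_tasks <- nrow(A)
  per_block <- n_tasks / n_blocks
  # per block, per factor-level occurrence counts
  lev_index <- lapply(names(factors), function(f)
    cbind(match(A[, f], factors[[f]]$levels),
          match(B[, f], factors[[f]]$levels)))
  counts <- lapply(names(factors), function(f)
    matrix(0L, n_blocks, length(factors[[f]]$levels)))
  sizes <- integer(n_blocks)
  blocks <- integer(n_tasks)
  for (t in seq_len(n_tasks)) {
    open <- which(sizes < per_block)
    score <- vapply(open, function(b) {
      s <- 0
      for (k in seq_along(counts)) {
        cnt <- counts[[k]][b, ]
        cnt[lev_index[[k]][t, 1L]] <- cnt[lev_index[[k]][t, 1L]] + 1L
        cnt[lev_index[[k]][t, 2L]] <- cnt[lev_index[[k]][t, 2L]] + 1L
        s <- s + sum((cnt - mean(cnt))^2)
      }
      s
    }, numeric(1))
    b <- open[which.min(score)]
    blocks[t] <- b
    sizes[b] <- sizes[b] + 1L
    for (k in seq_along(counts)) {
      counts[[k]][b, lev_index[[k]][t, 1L]] <-
        counts[[k]][b, lev_index[[k]][t, 1L]] + 1L
      counts[[k]][b, lev_index[[k]][t, 2L]] <-
        counts[[k]][b, lev_index[[k]][t, 2L]] + 1L
    }
  }
  blocks
}

#' Add a repeated and a dominated choice task to every block
#'
#' Each block gains (i) a repeat of one randomly chosen design task of that
#' block, used to score choice consistency, and (ii) a constructed dominance
#' task in which alternative A takes the direction-best level of every
#' factor with a stated preference direction, so that choosing B signals
#' non-monotone responding. Existing design tasks are never altered.
#'
#' @param design A `choice_design` with design-role tasks.
#' @param seed Integer seed for the random task picks.
#' @return The augmented `choice_design`.
#' @export
add_validity_tasks <- function(design, seed = 1L) {
  stopifnot(inherits(design, "choice_design"))
  factors <- design$factors
  dirs <- vapply(factors, `[[`, integer(1), "direction")
  if (all(dirs == 0L))
    stop("cannot construct a dominance task: every factor has direction 0",
         call. = FALSE)
  fn <- names(factors)
  m <- design_matrices(design)
  next_id <- max(design$tasks$task_id) + 1L

  with_seed(seed, {
    extra <- list()
    for (b in seq_len(design$n_blocks)) {
      in_b <- which(m$block == b)
      if (length(in_b) == 0L)
        stop("block ", b, " has no design tasks", call. = FALSE)
      # repeated task: exact copy of a random design task of this block
      src <- in_b[sample.int(length(in_b), 1L)]
      extra[[length(extra) + 1L]] <-
        tasks_frame(factors, m$A[src, , drop = FALSE],
                    m$B[src, , drop = FALSE],
                    next_id, b, "repeat", repeat_of = m$task_id[src])
      next_id <- next_id + 1L
      # dominance task: B random (not already direction-best everywhere),
      # A at the direction-best level of every directed factor
      best <- vapply(fn, function(f) {
        lv <- factors[[f]]$levels
        if (dirs[f] >= 0L) lv[length(lv)] else lv[1L]
      }, numeric(1))
      repeat {
        bprof <- vapply(factors, function(f)
          f$levels[sample.int(length(f$levels), 1L)], numeric(1))
        aprof <- ifelse(dirs != 0L, best, bprof)
        names(aprof) <- fn
        if (dominates(aprof, bprof, factors)) break
      }
      extra[[length(extra) + 1L]] <-
        tasks_frame(factors, matrix(aprof, 1L, dimnames = list(NULL, fn)),
                    matrix(bprof, 1L, dimnames = list(NULL, fn)),
                    next_id, b, "dominance")
      next_id <- next_id + 1L
    }
    design$tasks <- rbind(design$tasks, do.call(rbind, extra))
    design
  })
}

#' Write / read a design as JSON
#'
#' The JSON carries the factor registry (names, units, levels, directions)
#' and the long-format task table, so a design round-trips exactly.
#'
#' @param design A `choice_design`.
#' @param path File path.
#' @return `design_to_json()` returns `path` invisibly; `design_from_json()`
#'   returns the `choice_design`.
#' @export
design_to_json <- function(design, path) {
  stopifnot(inherits(design, "choice_design"))
  obj <- list(
    factors = lapply(unname(design$factors), function(f)
      list(name = f$name, description = f$description, unit = f$unit,
           levels = f$levels, direction = f$direction)),
    n_blocks = design$n_blocks,
    d_error = design$d_error,
    d_error_initial = design$d_error_initial,
    tasks = design$tasks)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname design_to_json
#' @export
design_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fs <- factor_set(lapply(seq_len(nrow(obj$factors)), function(i)
    factor_spec(obj$factors$name[i], obj$factors$levels[[i]],
                obj$factors$direction[i], obj$factors$description[i],
                obj$factors$unit[i])))
  tasks <- as.data.frame(obj$tasks)
  tasks$task_id <- as.integer(tasks$task_id)
  tasks$block <- as.integer(tasks$block)
  tasks$alt <- as.integer(tasks$alt)
  tasks$repeat_of <- as.integer(tasks$repeat_of)
  new_choice_design(fs, tasks, obj$n_blocks,
                    obj$d_error %||% NA_real_,
                    obj$d_error_initial %||% NA_real_)
}

#' Export a design as CSV (one row per task x alternative)
#'
#' @param design A `choice_design`.
#' @param path File path.
#' @export
design_to_csv <- function(design, path) {
  utils::write.csv(design$tasks, path, row.names = FALSE)
  invisible(path)
}
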