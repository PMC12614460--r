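#' Declare a bounded hyperparameter search space
#'
#' @param name Character vector of dimension names.
#' @param lower,upper Numeric bounds with `lower < upper` elementwise.
#' @param kind `"integer"` or `"continuous"` per dimension (recycled).
#' @return A `search_space` tibble with columns `name`, `lower`, `upper`,
#'   `kind`.
#' @export
#' @examples
#' search_space(c("x", "y"), -5, 5, "continuous")
search_space <- function(name, lower, upper, kind = "continuous") {
  sp <- tibble::tibble(name = name,
                       lower = rep_len(as.numeric(lower), length(name)),
                       upper = rep_len(as.numeric(upper), length(name)),
                       kind = rep_len(kind, length(name)))
  if (any(sp$lower >= sp$upper)) {
    stop("Every dimension needs lower < upper.", call. = FALSE)
  }
  if (!all(sp$kind %in% c("integer", "continuous"))) {
    stop("`kind` must be 'integer' or 'continuous'.", call. = FALSE)
  }
  class(sp) <- c("search_space", class(sp))
  sp
}

#' Exploration-to-exploitation coefficient schedule
#'
#' The leader-step coefficient `c1 = 2 * exp(-(4 t / T)^2)`: 2 at the first
#' iteration (wide exploration), decaying smoothly to ~2.25e-7 at `t = T`
#' (fine exploitation). Strictly decreasing in `t`.
#'
#' @param t Current iteration, `0 <= t <= T`.
#' @param T_max Iteration horizon, positive.
#' @return The coefficient value.
#' @export
#' @examples
#' compute_c1(0, 50)    # 2
#' compute_c1(25, 50)   # 2 * exp(-4)
compute_c1 <- function(t, T_max) {
  if (T_max <= 0) stop("`T_max` must be positive.", call. = FALSE)
  2 * exp(-(4 * t / T_max)^2)
}

#' Leader salp position update
#'
#' Moves the leader around the food source (best-so-far position) `food`:
#' per dimension `j`, with fresh uniforms `c2`, `c3`, the new coordinate is
#' `F_j + c1 * ((ub_j - lb_j) * c2 + lb_j)` when `c3 < 0.5` and
#' `F_j - c1 * ((ub_j - lb_j) * c2 + lb_j)` otherwise, clamped to the box.
#'
#' @param food Numeric vector, the food-source position (within bounds).
#' @param space A `search_space`.
#' @param c1 Non-negative step coefficient from [compute_c1()].
#' @param c2,c3 Optional uniform draws (recycled per dimension), exposed for
#'   deterministic checks; drawn fresh per dimension when `NULL`.
#' @return Updated leader position, clamped to bounds.
#' @export
update_leader <- function(food, space, c1, c2 = NULL, c3 = NULL) {
  d <- nrow(space)
  if (length(food) != d) stop("Dimension mismatch.", call. = FALSE)
  c2 <- if (is.null(c2)) stats::runif(d) else rep_len(c2, d)
  c3 <- if (is.null(c3)) stats::runif(d) else rep_len(c3, d)
  step <- c1 * ((space$upper - space$lower) * c2 + space$lower)
  x <- ifelse(c3 < 0.5, food + step, food - step)
  pmin(pmax(x, space$lower), space$upper)
}

#' Follower chain update
#'
#' Each follower moves to the midpoint of itself and its predecessor in the
#' chain. The sweep is sequential by default (row `i` averages with the
#' already-updated row `i - 1`); set `sequential = FALSE` for the simultaneous
#' variant that averages with the predecessor's pre-update position.
#'
#' @param positions Numeric matrix, one salp per row, leader in row 1.
#' @param space Optional `search_space` for clamping.
#' @param sequential Use the sequential sweep (default `TRUE`).
#' @return Updated position matrix (row 1 unchanged).
#' @export
update_followers <- function(positions, space = NULL, sequential = TRUE) {
  n <- nrow(positions)
  if (n < 2) stop("Need at least 2 salps.", call. = FALSE)
  if (sequential) {
    for (i in 2:n) positions[i, ] <- (positions[i, ] + positions[i - 1, ]) / 2
  } else {
    old <- positions
    for (i in 2:n) positions[i, ] <- (old[i, ] + old[i - 1, ]) / 2
  }
  if (!is.null(space)) {
    positions <- pmin(pmax(positions,
                           matrix(space$lower, n, nrow(space), byrow = TRUE)),
                      matrix(space$upper, n, nrow(space), byrow = TRUE))
  }
  positions
}

#' Decode a swarm position into a named hyperparameter assignment
#'
#' Integer dimensions are rounded half away from zero then clamped to their
#' bounds; continuous dimensions pass through.
#'
#' @param position Numeric vector within the box.
#' @param space A `search_space`.
#' @return Named list mapping dimension names to values.
#' @export
decode_position <- function(position, space) {
  if (length(position) != nrow(space)) {
    stop("Position length does not match the search space.", call. = FALSE)
  }
  vals <- purrr::pmap(list(position, space$lower, space$upper, space$kind),
                      function(x, lo, hi, kind) {
                        if (kind == "integer") {
                          as.integer(min(max(round_half_up(x), lo), hi))
                        } else {
                          min(max(x, lo), hi)
                        }
                      })
  stats::setNames(vals, space$name)
}

#' Salp Swarm Algorithm optimization
#'
#' Minimizes `fitness` over the box defined by `space` with a salp chain:
#' positions are initialized uniformly in the bounds (the first leader can
#' instead start from a supplied position); each iteration evaluates all
#' salps, updates the food source to the best position seen so far (elitism),
#' then moves the leading half of the chain around the food source with the
#' [compute_c1()] schedule and sweeps the trailing half (the followers)
#' toward their predecessors. The leader count follows the reference
#' formulation of the algorithm (half the population); set `n_leaders = 1`
#' for the strict single-leader chain.
#'
#' @param fitness Function taking a numeric position vector and returning a
#'   scalar to minimize. An error in `fitness` aborts with the iteration and
#'   position attached.
#' @param space A `search_space`.
#' @param n_salps Swarm size (default 20, minimum 2).
#' @param n_iter Iteration horizon `T` (default 50, minimum 1).
#' @param seed Integer seed.
#' @param n_leaders Number of leading salps updated around the food source
#'   (default `ceiling(n_salps / 2)`, the reference formulation).
#' @param leader_init Optional starting position for the first leader (e.g. a
#'   known default configuration).
#' @param sequential Follower sweep variant, see [update_followers()].
#' @return An `ssa_result`: list with `best_position`, `best_assignment`
#'   (decoded), `best_fitness`, `trace` (tibble `iteration`, `best_fitness`;
#'   non-increasing), `n_evaluations`, and the call settings.
#' @export
#' @examples
#' sp <- search_space(c("x", "y"), -5, 5)
#' res <- ssa_optimize(function(p) sum(p^2), sp, n_salps = 10, n_iter = 30,
#'                     seed = 1)
#' res$best_fitness
ssa_optimize <- function(fitness, space, n_salps = 20, n_iter = 50, seed = 1,
                         n_leaders = NULL, leader_init = NULL,
                         sequential = TRUE) {
  if (n_salps < 2) stop("`n_salps` must be at least 2.", call. = FALSE)
  if (n_iter < 1) stop("`n_iter` must be at least 1.", call. = FALSE)
  n_leaders <- n_leaders %||% ceiling(n_salps / 2)
  if (n_leaders < 1 || n_leaders >= n_salps) {
    stop("`n_leaders` must lie in [1, n_salps - 1].", call. = FALSE)
  }
  d <- nrow(space)

  eval_safe <- function(pos, iter) {
    val <- tryCatch(fitness(pos), error = function(e) {
      stop("Fitness evaluation failed at iteration ", iter, " for position (",
           paste(signif(pos, 6), collapse = ", "), "): ", conditionMessage(e),
           call. = FALSE)
    })
    as.numeric(val)
  }

  withr::with_seed(seed, {
    positions <- matrix(stats::runif(n_salps * d, min = rep(space$lower, each = n_salps),
                                     max = rep(space$upper, each = n_salps)),
                        nrow = n_salps)
    if (!is.null(leader_init)) {
      if (length(leader_init) != d) stop("`leader_init` has wrong length.", call. = FALSE)
      positions[1, ] <- pmin(pmax(leader_init, space$lower), space$upper)
    }
    food <- positions[1, ]
    best_fit <- Inf
    trace <- numeric(n_iter)
    n_eval <- 0L

    for (t in seq_len(n_iter)) {
      fits <- vapply(seq_len(n_salps),
                     function(i) eval_safe(positions[i, ], t), numeric(1))
      n_eval <- n_eval + n_salps
      it_best <- which.min(fits)
      if (fits[it_best] < best_fit) {
        best_fit <- fits[it_best]
        food <- positions[it_best, ]
      }
      trace[t] <- best_fit

      c1 <- compute_c1(t, n_iter)
      for (i in seq_len(n_leaders)) {
        positions[i, ] <- update_leader(food, space, c1)
      }
      # followers chain from the last leader; row n_leaders is the anchor
      tail_rows <- n_leaders:n_salps
      positions[tail_rows, ] <- update_followers(
        positions[tail_rows, , drop = FALSE], space, sequential = sequential)
    }
  })

  structure(list(
    best_position = stats::setNames(food, space$name),
    best_assignment = decode_position(food, space),
    best_fitness = best_fit,
    trace = tibble::tibble(iteration = seq_len(n_iter), best_fitness = trace),
    n_evaluations = n_eval,
    n_salps = n_salps, n_iter = n_iter, seed = seed, space = space
  ), class = "ssa_result")
}

#' @export
print.ssa_result <- function(x, ...) {
  cat("<ssa_result> ", x$n_salps, " salps x ", x$n_iter, " iterations; best fitness ",
      signif(x$best_fitness, 6), "\n", sep = "")
  cat("best assignment:\n")
  print(tibble::as_tibble(lapply(x$best_assignment, identity)))
  invisible(x)
}

#' Tidy an SSA run into its convergence trace
#'
#' @param x An `ssa_result`.
#' @param ... Unused.
#' @return Tibble with `iteration` and `best_fitness`.
#' @export
tidy.ssa_result <- function(x, ...) x$trace

#' One-row summary of an SSA run
#'
#' @param x An `ssa_result`.
#' @param ... Unused.
#' @return One-row tibble with the budget and the final best fitness.
#' @export
glance.ssa_result <- function(x, ...) {
  tibble::tibble(n_salps = x$n_salps, n_iter = x$n_iter,
                 n_evaluations = x$n_evaluations,
                 best_fitness = x$best_fitness)
}

#' Convergence-curve plot of an SSA run
#'
#' @param object An `ssa_result`.
#' @param ... Unused.
#' @return A ggplot of best fitness versus iteration.
#' @export
autoplot.ssa_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Iteration", y = "Best fitness (minimized)",
                  title = "Salp swarm convergence") +
    ggplot2::theme_minimal()
}
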