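#' Logarithmic-spiral moth update
#'
#' The position update of moth-flame optimization: each coordinate of a
#' moth spirals toward the corresponding flame coordinate along a
#' logarithmic helix,
#' \deqn{new_k = L_k\, e^{b t_k} \cos(2\pi t_k) + flame_k,}
#' where \eqn{L_k = |flame_k - moth_k|} is the moth-to-flame distance,
#' \eqn{b} is the helix shape constant, and \eqn{t_k \in [r, 1]} is the
#' path coefficient (\eqn{t = -1} is the closest spiral point, \eqn{t = 1}
#' the farthest).
#'
#' @param moth,flame Numeric position vectors of equal length.
#' @param b Spiral shape constant (default 1).
#' @param t Path coefficient, scalar or per-dimension vector.
#' @return The updated position vector.
#' @examples
#' spiral_step(moth = 0, flame = 1, b = 1, t = -1)  # 1 + exp(-1)*cos(-2*pi)
#' @export
spiral_step <- function(moth, flame, b = 1, t) {
  l <- abs(flame - moth)
  l * exp(b * t) * cos(2 * pi * t) + flame
}

#' Flame-count schedule
#'
#' The number of flames shrinks linearly over the run so that late
#' iterations exploit around the single best solution:
#' \eqn{round(N - l (N-1)/T)}, clamped to at least 1.
#'
#' @param iteration Current iteration \eqn{l} (1-based).
#' @param max_iterations Total iterations \eqn{T}.
#' @param n_agents Population size \eqn{N}.
#' @return Integer number of flames in `[1, N]`.
#' @export
flame_count <- function(iteration, max_iterations, n_agents) {
  k <- round(n_agents - iteration * (n_agents - 1) / max_iterations)
  as.integer(max(1, min(n_agents, k)))
}

#' Moth-flame optimization
#'
#' Minimizes `objective` over a box by the moth-flame algorithm: a
#' population of moths spirals toward a sorted elite of flames
#' ([spiral_step()]), the flame count shrinking over iterations
#' ([flame_count()]). Flames are the best `n_agents` positions among the
#' previous flames and current moths (merge and sort); moth \eqn{i} spirals
#' toward flame \eqn{\min(i, n\_flames)}. The path coefficient \eqn{t} is
#' drawn per dimension, uniform in \eqn{[r, 1]} with \eqn{r} decreasing
#' linearly from -1 to -2 over the run. Positions are clipped to the box
#' after every move.
#'
#' @param objective Function of a numeric position vector returning a
#'   finite scalar to minimize.
#' @param dimension Search-space dimension \eqn{D}.
#' @param lower,upper Box bounds, scalars or length-`D` vectors.
#' @param n_agents Population size \eqn{N} (default 50).
#' @param max_iterations Iteration count \eqn{T} (default 1000). Each
#'   iteration evaluates all `n_agents` positions.
#' @param b Spiral shape constant (default 1).
#' @param seed Integer seed; runs are deterministic given it.
#' @param init_positions Optional matrix (rows = positions) seeding the
#'   first rows of the initial population, e.g. a known-good start.
#' @return An object of class `"mfo_result"`: `best_position`,
#'   `best_fitness`, `trace` (best-so-far fitness per iteration,
#'   non-increasing), `evaluations`, and the configuration.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- mfo_optimize(sphere, dimension = 2, lower = -5, upper = 5,
#'                     n_agents = 10, max_iterations = 50, seed = 1)
#' res$best_fitness
#' @export
mfo_optimize <- function(objective, dimension, lower = -100, upper = 100,
                         n_agents = 50, max_iterations = 1000, b = 1,
                         seed = 1, init_positions = NULL) {
  dimension <- as.integer(dimension)
  n_agents <- as.integer(n_agents)
  max_iterations <- as.integer(max_iterations)
  stopifnot(dimension >= 1, n_agents >= 2, max_iterations >= 1)
  lb <- rep_len(as.numeric(lower), dimension)
  ub <- rep_len(as.numeric(upper), dimension)
  if (any(lb >= ub)) stop_dmelm("lower bound must be below upper bound")

  eval_obj <- function(pos) {
    f <- objective(pos)
    if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) {
      stop_dmelm("objective returned a non-finite value at position (%s)",
                 paste(signif(pos, 4), collapse = ", "))
    }
    f
  }

  with_seed(seed, {
    moths <- matrix(stats::runif(n_agents * dimension), n_agents, dimension)
    moths <- sweep(sweep(moths, 2, ub - lb, `*`), 2, lb, `+`)
    if (!is.null(init_positions)) {
      init_positions <- matrix(as.numeric(init_positions), ncol = dimension)
      k <- min(nrow(init_positions), n_agents)
      for (i in seq_len(k)) {
        moths[i, ] <- clip_box(init_positions[i, ], lb, ub)
      }
    }

    flames <- NULL       # positions sorted by ascending fitness
    flame_fit <- NULL
    trace <- numeric(max_iterations)
    evaluations <- 0L

    for (l in seq_len(max_iterations)) {
      fit <- apply(moths, 1, eval_obj)
      evaluations <- evaluations + n_agents

      if (is.null(flames)) {
        ord <- order(fit)
        flames <- moths[ord, , drop = FALSE]
        flame_fit <- fit[ord]
      } else {
        pool <- rbind(flames, moths)
        pool_fit <- c(flame_fit, fit)
        ord <- order(pool_fit)[seq_len(n_agents)]
        flames <- pool[ord, , drop = FALSE]
        flame_fit <- pool_fit[ord]
      }
      trace[l] <- flame_fit[1]

      n_flames <- flame_count(l, max_iterations, n_agents)
      r <- -1 - l / max_iterations    # shrinks from -1 toward -2
      for (i in seq_len(n_agents)) {
        j <- min(i, n_flames)
        t_vec <- (r - 1) * stats::runif(dimension) + 1
        moths[i, ] <- clip_box(spiral_step(moths[i, ], flames[j, ], b, t_vec),
                               lb, ub)
      }
    }

    structure(list(best_position = flames[1, ], best_fitness = flame_fit[1],
                   trace = trace, evaluations = evaluations,
                   n_agents = n_agents, max_iterations = max_iterations,
                   dimension = dimension, lower = lb, upper = ub, b = b,
                   seed = seed),
              class = "mfo_result")
  })
}

#' @export
print.mfo_result <- function(x, ...) {
  cat(sprintf("MFO result: best fitness %.6g after %d evaluations\n",
              x$best_fitness, x$evaluations))
  cat(sprintf("  %d agents, %d iterations, D = %d, seed %d\n",
              x$n_agents, x$max_iterations, x$dimension, x$seed))
  invisible(x)
}

#' Plot an MFO convergence trace
#'
#' @param x An `"mfo_result"`.
#' @param ... Passed to [plot.default()].
#' @export
plot.mfo_result <- function(x, ...) {
  plot(seq_along(x$trace), x$trace, type = "l", xlab = "iteration",
       ylab = "best-so-far fitness", main = "MFO convergence", ...)
  invisible(x)
}

#' Write a convergence trace as CSV
#'
#' @param result An `"mfo_result"` (or `"dmelm"` fit, whose trace is used).
#' @param path Output CSV path with columns `iteration`, `best_fitness`.
#' @export
write_trace <- function(result, path) {
  tr <- if (inherits(result, "dmelm")) result$optimization$trace else result$trace
  utils::write.csv(data.frame(iteration = seq_along(tr), best_fitness = tr),
                   path, row.names = FALSE)
  invisible(path)
}
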