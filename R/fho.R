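#' Box-constrained search space
#'
#' @param lower,upper Numeric vectors of equal length with
#'   `upper > lower` element-wise.
#' @return List of class `search_space` with `lower`, `upper`, `dim`.
#' @export
search_space <- function(lower, upper) {
  assert_finite(lower, "lower bounds"); assert_finite(upper, "upper bounds")
  if (length(lower) != length(upper) || any(upper <= lower)) {
    abort("need upper > lower element-wise", class = "nutriclass_config_error")
  }
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 dim = length(lower)), class = "search_space")
}

#' Fire Hawk Optimizer configuration
#'
#' @param pop_size Population size `n` (>= 4).
#' @param max_iters Number of iterations of the main loop.
#' @param hawk_count_cap Maximum hawk fraction of the population, in
#'   (0, 0.5].  Each iteration the hawk count is
#'   `clamp(round(|g| * n * cap), 1, floor(n/2))` with `g` standard normal,
#'   reflecting the Gaussian (Brownian) draw that sets the number of
#'   leading candidates.
#' @param seed Integer seed; a fixed seed gives a bit-identical run.
#' @return List of class `fho_config`.
#' @export
fho_config <- function(pop_size = 30L, max_iters = 100L,
                       hawk_count_cap = 0.25, seed = 1L) {
  if (pop_size < 4) abort("pop_size must be >= 4", class = "nutriclass_config_error")
  if (max_iters < 1) abort("max_iters must be >= 1", class = "nutriclass_config_error")
  if (hawk_count_cap <= 0 || hawk_count_cap > 0.5) {
    abort("hawk_count_cap must be in (0, 0.5]", class = "nutriclass_config_error")
  }
  structure(list(pop_size = as.integer(pop_size),
                 max_iters = as.integer(max_iters),
                 hawk_count_cap = hawk_count_cap,
                 seed = as.integer(seed)),
            class = "fho_config")
}

clamp_box <- function(x, space) pmin(space$upper, pmax(space$lower, x))

#' Initialize an FHO population
#'
#' Each coordinate is drawn as `lower + r * (upper - lower)` with `r`
#' uniform on (0, 1), consuming the current RNG stream.
#'
#' @param space A [search_space()].
#' @param n Population size (>= 4).
#' @return An `n x dim` matrix of positions, one candidate per row.
#' @export
fho_init_population <- function(space, n) {
  if (n < 4) abort("population size must be >= 4", class = "nutriclass_config_error")
  r <- matrix(runif(n * space$dim), n, space$dim)
  sweep(sweep(r, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
}

#' Split a population into hawks and prey
#'
#' The hawk count is `clamp(round(|g| * n * cap), 1, floor(n/2))`; hawks
#' are the candidates with the lowest objective values (the elite that
#' leads the search), the rest are prey.
#'
#' @param fitness Numeric vector of evaluated objective values.
#' @param hawk_count_cap Maximum hawk fraction, see [fho_config()].
#' @param g Standard-normal draw; defaults to consuming the RNG stream.
#' @return List with integer index vectors `hawks` (ascending fitness)
#'   and `prey`.
#' @export
fho_select_hawks <- function(fitness, hawk_count_cap = 0.25, g = rnorm(1)) {
  if (anyNA(fitness)) abort("fitness not evaluated", class = "nutriclass_state_error")
  n <- length(fitness)
  s <- max(1L, min(n %/% 2L, as.integer(round(abs(g) * n * hawk_count_cap))))
  ord <- order(fitness)
  list(hawks = ord[seq_len(s)], prey = sort(ord[-seq_len(s)]))
}

#' Assign prey territories to hawks
#'
#' Hawks are processed in ascending fitness order; each greedily claims
#' its nearest `ceiling(q/s)` unclaimed prey by Euclidean distance (ties
#' broken by lower prey index), so every prey belongs to exactly one
#' territory.
#'
#' @param hawk_idx Hawk indices in ascending fitness order.
#' @param prey_idx Prey indices.
#' @param positions Full population position matrix.
#' @return Named list mapping each hawk index to an integer vector of
#'   prey indices (possibly empty).
#' @export
fho_assign_territories <- function(hawk_idx, prey_idx, positions) {
  q <- length(prey_idx); s <- length(hawk_idx)
  terr <- setNames(vector("list", s), as.character(hawk_idx))
  if (q == 0L) { terr[] <- list(integer(0)); return(terr) }
  quota <- ceiling(q / s)
  unclaimed <- prey_idx
  for (h in hawk_idx) {
    if (!length(unclaimed)) { terr[[as.character(h)]] <- integer(0); next }
    d <- sqrt(colSums((t(positions[unclaimed, , drop = FALSE]) -
                         positions[h, ])^2))
    take <- unclaimed[order(d, unclaimed)][seq_len(min(quota, length(unclaimed)))]
    terr[[as.character(h)]] <- take
    unclaimed <- setdiff(unclaimed, take)
  }
  # any remainder (can only happen with rounding) goes to the best hawk
  if (length(unclaimed)) {
    terr[[1L]] <- c(terr[[1L]], unclaimed)
  }
  terr
}

#' Hawk position update
#'
#' `Fh_new = Fh + rand1 * GB - rand2 * Fh_near`, followed by a boundary
#' clamp: the hawk moves toward the global best while being repelled from
#' a neighbouring hawk.
#'
#' @param hawk,global_best,other_hawk Position vectors.
#' @param space A [search_space()].
#' @param rand Two uniforms on (0,1); defaults to consuming the RNG stream.
#' @return Updated position vector.
#' @export
fho_update_hawk <- function(hawk, global_best, other_hawk, space,
                            rand = runif(2)) {
  clamp_box(hawk + rand[1] * global_best - rand[2] * other_hawk, space)
}

#' Safe places (prey congregation points)
#'
#' `fho_safe_place_within()` is the mean position of a territory's prey
#' (falling back to the owner hawk's position when the territory is
#' empty); `fho_safe_place_global()` is the mean over all prey (falling
#' back to the global best when there is no prey).
#'
#' @param prey_positions Matrix of prey positions (rows), possibly empty.
#' @param fallback Position vector used when no prey exist.
#' @return Position vector.
#' @export
fho_safe_place_within <- function(prey_positions, fallback) {
  if (is.null(prey_positions) || nrow(prey_positions) == 0L) return(fallback)
  colMeans(prey_positions)
}

#' @rdname fho_safe_place_within
#' @export
fho_safe_place_global <- fho_safe_place_within

#' Prey position update
#'
#' With probability 1/2 the prey moves within its territory,
#' `Kp + rand3 * Fh - rand4 * Sa_within`, otherwise it moves relative to
#' another hawk and the global safe place,
#' `Kp + rand5 * Fh_vary - rand6 * Sa_global`; either way the result is
#' clamped to the box.
#'
#' @param prey,owner_hawk,other_hawk,safe_within,safe_global Position
#'   vectors.
#' @param space A [search_space()].
#' @param within Logical; which of the two moves to take.  Defaults to a
#'   fair coin from the RNG stream.
#' @param rand Two uniforms on (0,1) for the chosen move.
#' @return Updated position vector.
#' @export
fho_update_prey <- function(prey, owner_hawk, other_hawk, safe_within,
                            safe_global, space,
                            within = runif(1) < 0.5, rand = runif(2)) {
  new <- if (within) {
    prey + rand[1] * owner_hawk - rand[2] * safe_within
  } else {
    prey + rand[1] * other_hawk - rand[2] * safe_global
  }
  clamp_box(new, space)
}

#' Minimize an objective with the Fire Hawk Optimizer
#'
#' Population metaheuristic over a box: candidates are split each
#' iteration into hawks (the current elite) and prey; hawks move toward
#' the global best, prey move relative to their territory's hawk and the
#' "safe places" (prey mean positions).  New positions replace old ones
#' unconditionally; elitism lives in the archived global best, whose
#' per-iteration trace is returned as `history` (monotone non-increasing).
#'
#' @param objective Function from a numeric position vector to a finite
#'   scalar (minimized).
#' @param space A [search_space()].
#' @param config An [fho_config()].
#' @param init Optional matrix of warm-start positions (rows) injected
#'   into the initial population (replacing its first rows).
#' @param refine Optional local-search hook: a function
#'   `position -> list(position, fitness)` applied to every candidate at
#'   evaluation time (used by the clustering front-end for its k-means
#'   move).  When supplied, `objective` may be omitted for refined
#'   evaluations but is still used to validate finiteness.
#' @return Object of class `fho_fit`: list with `par` (best position),
#'   `value` (best fitness), `history` (best fitness per iteration),
#'   `config`, `space`, `evaluations`.
#' @export
#' @examples
#' sp <- search_space(rep(-5, 2), rep(5, 2))
#' fit <- fho_minimize(function(x) sum(x^2), sp,
#'                     fho_config(pop_size = 20, max_iters = 50, seed = 1))
#' fit$value
fho_minimize <- function(objective, space, config = fho_config(),
                         init = NULL, refine = NULL) {
  n <- config$pop_size
  evals <- 0L
  eval_one <- function(x) {
    if (!is.null(refine)) {
      res <- refine(x)
      evals <<- evals + 1L
      if (!is.finite(res$fitness)) {
        abort(paste0("objective returned a non-finite value at position [",
                     paste(signif(res$position, 6), collapse = ", "), "]"),
              class = "nutriclass_optim_error")
      }
      return(res)
    }
    f <- objective(x)
    evals <<- evals + 1L
    if (!is.finite(f)) {
      abort(paste0("objective returned a non-finite value at position [",
                   paste(signif(x, 6), collapse = ", "), "]"),
            class = "nutriclass_optim_error")
    }
    list(position = x, fitness = f)
  }
  withr::with_seed(config$seed, {
    pos <- fho_init_population(space, n)
    if (!is.null(init)) {
      init <- matrix(init, ncol = space$dim)
      k <- min(nrow(init), n)
      pos[seq_len(k), ] <- clamp_box_mat(init[seq_len(k), , drop = FALSE], space)
    }
    fit <- numeric(n)
    for (j in seq_len(n)) {
      r <- eval_one(pos[j, ]); pos[j, ] <- r$position; fit[j] <- r$fitness
    }
    gb_idx <- which.min(fit)
    gb_pos <- pos[gb_idx, ]; gb_val <- fit[gb_idx]
    history <- numeric(config$max_iters)
    for (it in seq_len(config$max_iters)) {
      sel <- fho_select_hawks(fit, config$hawk_count_cap)
      terr <- fho_assign_territories(sel$hawks, sel$prey, pos)
      all_prey_pos <- pos[sel$prey, , drop = FALSE]
      sa_global <- fho_safe_place_global(all_prey_pos, gb_pos)
      new_pos <- pos
      for (m in seq_along(sel$hawks)) {
        h <- sel$hawks[m]
        other <- if (length(sel$hawks) > 1L) {
          sel$hawks[sample(setdiff(seq_along(sel$hawks), m), 1L)]
        } else h
        new_pos[h, ] <- fho_update_hawk(pos[h, ], gb_pos, pos[other, ], space)
        p_idx <- terr[[as.character(h)]]
        if (length(p_idx)) {
          sa_within <- fho_safe_place_within(pos[p_idx, , drop = FALSE],
                                             pos[h, ])
          for (p in p_idx) {
            other_h <- if (length(sel$hawks) > 1L) {
              sel$hawks[sample(setdiff(seq_along(sel$hawks), m), 1L)]
            } else h
            new_pos[p, ] <- fho_update_prey(pos[p, ], pos[h, ], pos[other_h, ],
                                            sa_within, sa_global, space)
          }
        }
      }
      pos <- new_pos
      for (j in seq_len(n)) {
        r <- eval_one(pos[j, ]); pos[j, ] <- r$position; fit[j] <- r$fitness
      }
      if (min(fit) < gb_val) {
        gb_val <- min(fit); gb_pos <- pos[which.min(fit), ]
      }
      history[it] <- gb_val
    }
  })
  structure(list(par = gb_pos, value = gb_val, history = history,
                 config = config, space = space, evaluations = evals),
            class = "fho_fit")
}

clamp_box_mat <- function(m, space) {
  t(pmin(space$upper, pmax(space$lower, t(m))))
}

#' @export
print.fho_fit <- function(x, ...) {
  cat("Fire Hawk Optimizer fit\n")
  cat("  dimension:", x$space$dim, " population:", x$config$pop_size,
      " iterations:", x$config$max_iters, "\n")
  cat("  best value:", format(x$value, digits = 6), "\n")
  invisible(x)
}

#' @export
tidy.fho_fit <- function(x, ...) {
  tibble(iteration = seq_along(x$history), best_fitness = x$history)
}

#' @export
glance.fho_fit <- function(x, ...) {
  tibble(best_fitness = x$value, iterations = x$config$max_iters,
         pop_size = x$config$pop_size, evaluations = x$evaluations)
}

#' Convergence plot for an FHO run
#'
#' @param object An `fho_fit`.
#' @param ... Unused.
#' @return A ggplot of the best objective value per iteration.
#' @export
autoplot.fho_fit <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = .data$iteration, y = .data$best_fitness)) +
    geom_line() +
    labs(x = "Iteration", y = "Best objective value",
         title = "Fire Hawk Optimizer convergence")
}
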