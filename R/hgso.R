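# Henry Gas Solubility Optimization (HGSO).
#
# A population ("gases") is split into clusters that share a Henry constant
# H_j. Solubility S_ij = K * H_j * P_ij (Henry's law: solubility proportional
# to partial pressure) pulls each agent toward the global best while an
# interaction term pulls it toward its cluster best; H_j decays with an
# annealing temperature T(t) = exp(-t / max_iter), and each iteration a
# random 10-20% of the worst agents are re-seeded uniformly in the bounds to
# escape local optima. Minimization convention throughout (the fitness used
# for hyperparameter tuning is a misclassification percentage).

#' HGSO configuration
#'
#' Constants follow the standard formulation: initialization scales
#' `l1 = 5e-2` (Henry constants), `l2 = 100` (partial pressures),
#' `l3 = 1e-2` (per-cluster exponents); reference temperature
#' `T_theta = 298`; interaction floor `epsilon = 0.05`; worst-agent
#' fractions `C1 = 0.1`, `C2 = 0.2`; `alpha = 1`; `K` and `beta` default 1.
#'
#' @param population_size Number of agents `N` (>= 4, divisible by
#'   `n_clusters`).
#' @param n_clusters Number of gas clusters (default 5).
#' @param max_iter Number of iterations (default 100).
#' @param l1,l2,l3 Initialization constants (see above).
#' @param K Solubility constant.
#' @param alpha Global-attraction weight.
#' @param beta Cluster-interaction weight.
#' @param epsilon Fitness-ratio floor.
#' @param T_theta Reference temperature.
#' @param C1,C2 Lower/upper worst-agent fractions (`C1 < C2`).
#' @param seed Optional integer seed; if given, [hgso_minimize()] runs are
#'   reproducible.
#' @return An `hgso_config` list.
#' @export
hgso_config <- function(population_size = 30L, n_clusters = 5L,
                        max_iter = 100L, l1 = 5e-2, l2 = 100, l3 = 1e-2,
                        K = 1, alpha = 1, beta = 1, epsilon = 0.05,
                        T_theta = 298, C1 = 0.1, C2 = 0.2, seed = NULL) {
  check_number(population_size, "population_size", min = 4, integer = TRUE)
  check_number(n_clusters, "n_clusters", min = 1, integer = TRUE)
  if (population_size %% n_clusters != 0L) {
    stop_invalid("`population_size` (%d) must be divisible by `n_clusters` (%d)",
                 population_size, n_clusters)
  }
  check_number(max_iter, "max_iter", min = 1, integer = TRUE)
  for (nm in c("l1", "l2", "l3", "K", "alpha", "beta", "epsilon", "T_theta")) {
    check_number(get(nm), nm, min = 1e-300)
  }
  check_number(C1, "C1", min = 0); check_number(C2, "C2", min = 0)
  if (C1 >= C2) stop_invalid("`C1` must be < `C2`")
  if (!is.null(seed)) check_number(seed, "seed", integer = TRUE)
  structure(list(population_size = as.integer(population_size),
                 n_clusters = as.integer(n_clusters),
                 max_iter = as.integer(max_iter),
                 l1 = l1, l2 = l2, l3 = l3, K = K, alpha = alpha, beta = beta,
                 epsilon = epsilon, T_theta = T_theta, C1 = C1, C2 = C2,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "hgso_config")
}

#' Search-space bounds
#'
#' @param lower,upper Numeric vectors of equal length with
#'   `lower < upper` componentwise.
#' @return A `search_bounds` list.
#' @export
search_bounds <- function(lower, upper) {
  if (length(lower) != length(upper) || !all(is.finite(lower)) ||
      !all(is.finite(upper)) || !all(lower < upper)) {
    stop_invalid("`lower` and `upper` must be finite, equal-length, with lower < upper")
  }
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "search_bounds")
}

clip_bounds <- function(x, bounds) {
  x <- pmax(x, matrix(bounds$lower, nrow(x), ncol(x), byrow = TRUE))
  pmin(x, matrix(bounds$upper, nrow(x), ncol(x), byrow = TRUE))
}

#' Initialize the HGSO population
#'
#' Positions are uniform in the bounds; each cluster draws one Henry
#' constant `H_j = l1 * u` and one exponent `C_j = l3 * u`; each agent draws
#' a partial pressure `P_ij = l2 * u`, with all `u ~ U(0,1)`. Initial
#' solubilities are `K * H_j * P_ij`. All agents of a cluster share `H_j`.
#'
#' @param bounds A [search_bounds()].
#' @param config An [hgso_config()].
#' @param u Optional list of pre-drawn uniforms (`pos` N x d, `H`, `C`
#'   length-`n_clusters`, `P` length-N) for deterministic testing; drawn from
#'   the current RNG when omitted.
#' @return An `hgso_state` list: `positions`, `cluster`, `H`, `C`, `P`, `S`.
#' @export
initialize_population <- function(bounds, config, u = NULL) {
  n <- config$population_size
  d <- length(bounds$lower)
  nc <- config$n_clusters
  if (is.null(u)) {
    u <- list(pos = matrix(runif(n * d), n, d), H = runif(nc),
              C = runif(nc), P = runif(n))
  }
  positions <- sweep(sweep(u$pos, 2L, bounds$upper - bounds$lower, "*"),
                     2L, bounds$lower, "+")
  cluster <- rep(seq_len(nc), each = n %/% nc)
  H <- config$l1 * u$H
  C <- config$l3 * u$C
  P <- config$l2 * u$P
  structure(list(positions = positions, cluster = cluster, H = H, C = C,
                 P = P, S = config$K * H[cluster] * P, fitness = rep(NA_real_, n)),
            class = "hgso_state")
}

#' Per-cluster and global best agents
#'
#' Minimization convention; ties are broken by the lowest agent index.
#'
#' @param fitness Numeric vector of evaluated fitnesses.
#' @param cluster Integer cluster index per agent.
#' @return A list: `cluster_best_index` (one per cluster), `best_index`.
#' @export
rank_and_select_best <- function(fitness, cluster) {
  if (anyNA(fitness)) stop_invalid("all fitnesses must be evaluated")
  nc <- max(cluster)
  cbi <- vapply(seq_len(nc), function(j) {
    idx <- which(cluster == j)
    idx[which.min(fitness[idx])]
  }, integer(1))
  list(cluster_best_index = cbi, best_index = which.min(fitness))
}

#' Henry-coefficient annealing update
#'
#' `H_j <- H_j * exp(-C_j * (1/T(t) - 1/T_theta))` with
#' `T(t) = exp(-t / max_iter)`. Since `T(t) < 1 << T_theta` the exponent is
#' negative whenever `C_j > 0`, so `H_j` strictly decreases each iteration.
#'
#' @param H Numeric vector of Henry constants (one per cluster).
#' @param C Numeric vector of per-cluster exponents.
#' @param t Iteration index in `[1, max_iter]`.
#' @param config An [hgso_config()].
#' @return The updated `H`.
#' @export
update_henry_coefficient <- function(H, C, t, config) {
  check_number(t, "t", min = 1, max = config$max_iter, integer = TRUE)
  Tt <- exp(-t / config$max_iter)
  H * exp(-C * (1 / Tt - 1 / config$T_theta))
}

#' Solubility update (Henry's law)
#'
#' `S_ij = K * H_j * P_ij`.
#'
#' @param H Per-cluster Henry constants (after the iteration's update).
#' @param P Per-agent partial pressures.
#' @param cluster Cluster index per agent.
#' @param config An [hgso_config()].
#' @return Per-agent solubilities.
#' @export
update_solubility <- function(H, P, cluster, config) {
  config$K * H[cluster] * P
}

#' Position update
#'
#' Each agent moves toward its cluster best with interaction strength
#' `gamma = beta * exp(-(F_best + eps) / (F_ij + eps))` and toward the
#' solubility-scaled global best with weight `alpha`, each term carrying a
#' fresh `U(0,1)` draw and a random direction flag `F in {-1, +1}`; the
#' result is clipped to the bounds.
#'
#' @param state An `hgso_state` with current `fitness` evaluated.
#' @param bests The output of [rank_and_select_best()] applied to `state`,
#'   or a list with `cluster_best_index`/`best_index`.
#' @param best_position,best_fitness Global best (may be the best-so-far
#'   record rather than a population member).
#' @param bounds A [search_bounds()].
#' @param config An [hgso_config()].
#' @param rand Optional stubbed randoms: list `F` (length-N vector of +/-1),
#'   `r1`, `r2` (N x d matrices in \[0,1\]).
#' @return The state with updated, clipped `positions`.
#' @export
update_positions <- function(state, bests, best_position, best_fitness,
                             bounds, config, rand = NULL) {
  x <- state$positions
  n <- nrow(x); d <- ncol(x)
  if (is.null(rand)) {
    rand <- list(F = sample(c(-1, 1), n, replace = TRUE),
                 r1 = matrix(runif(n * d), n, d),
                 r2 = matrix(runif(n * d), n, d))
  }
  gamma <- config$beta *
    exp(-(best_fitness + config$epsilon) / (state$fitness + config$epsilon))
  cb <- state$positions[bests$cluster_best_index[state$cluster], , drop = FALSE]
  xb <- matrix(best_position, n, d, byrow = TRUE)
  step <- rand$F * rand$r1 * gamma * (cb - x) +
    rand$F * rand$r2 * config$alpha * (state$S * xb - x)
  state$positions <- clip_bounds(x + step, bounds)
  state
}

#' Number of worst agents to re-seed
#'
#' `Nw = round(N * (u * (C2 - C1) + C1))` with `u ~ U(0,1)`, rounded half to
#' even and clamped to `[1, N]`; always within `[floor(C1*N), ceiling(C2*N)]`.
#'
#' @param N Population size.
#' @param config An [hgso_config()].
#' @param u Optional stubbed uniform draw.
#' @return An integer count.
#' @export
count_worst_agents <- function(N, config, u = runif(1)) {
  check_number(N, "N", min = 1, integer = TRUE)
  # snap away float residue so N*(u*(C2-C1)+C1) rounds as the printed
  # arithmetic does (e.g. 30 * 0.15 -> 4.5 -> 4, half to even)
  nw <- round(signif(N * (u * (config$C2 - config$C1) + config$C1), 12))
  as.integer(min(max(nw, 1L), N))
}

#' Re-seed the worst agents uniformly in the bounds
#'
#' The `Nw` agents with the highest fitness get fresh uniform positions;
#' all others are untouched. Their fitnesses are marked stale (`NA`).
#'
#' @param state An `hgso_state`.
#' @param Nw Number of agents to re-seed (`0 <= Nw <= N`).
#' @param bounds A [search_bounds()].
#' @param u Optional `Nw x d` matrix of stubbed uniforms.
#' @return The updated state; re-seeded agent indices in attribute
#'   `"reseeded"`.
#' @export
reinitialize_worst <- function(state, Nw, bounds, u = NULL) {
  n <- nrow(state$positions)
  check_number(Nw, "Nw", min = 0, max = n, integer = TRUE)
  if (Nw == 0L) {
    attr(state, "reseeded") <- integer(0)
    return(state)
  }
  worst <- order(state$fitness, decreasing = TRUE)[seq_len(Nw)]
  d <- ncol(state$positions)
  if (is.null(u)) u <- matrix(runif(Nw * d), Nw, d)
  state$positions[worst, ] <- sweep(
    sweep(u, 2L, bounds$upper - bounds$lower, "*"), 2L, bounds$lower, "+")
  state$fitness[worst] <- NA_real_
  attr(state, "reseeded") <- worst
  state
}

evaluate_agents <- function(state, objective, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(state$positions))
  for (i in idx) {
    f <- objective(state$positions[i, ])
    if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) {
      stop_eval("objective returned a non-finite value for agent %d", i,
                data = list(position = state$positions[i, ]))
    }
    state$fitness[i] <- f
  }
  state
}

#' Minimize a bounded black-box objective with HGSO
#'
#' Runs the full loop: evaluate, update positions, re-evaluate, anneal the
#' Henry coefficients, update solubilities, re-seed the worst agents, and
#' refresh the cluster/global bests, for `max_iter` iterations. The reported
#' history is the best-so-far fitness per iteration (monotone
#' non-increasing).
#'
#' @param objective A function taking a position vector, returning a finite
#'   scalar to minimize.
#' @param bounds A [search_bounds()].
#' @param config An [hgso_config()].
#' @return An `hgso_result`: `best_position`, `best_fitness`, `history`
#'   tibble (`iteration`, `best_fitness`), `n_evaluations`, `config`.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- hgso_minimize(sphere, search_bounds(c(-5, -5), c(5, 5)),
#'                      hgso_config(population_size = 10, n_clusters = 2,
#'                                  max_iter = 20, seed = 1))
#' res$best_fitness
hgso_minimize <- function(objective, bounds, config = hgso_config()) {
  stopifnot(inherits(bounds, "search_bounds"), inherits(config, "hgso_config"))
  run <- function() {
    state <- initialize_population(bounds, config)
    state <- evaluate_agents(state, objective)
    n_eval <- nrow(state$positions)
    bests <- rank_and_select_best(state$fitness, state$cluster)
    best_fit <- state$fitness[bests$best_index]
    best_pos <- state$positions[bests$best_index, ]
    history <- numeric(config$max_iter)
    for (t in seq_len(config$max_iter)) {
      state <- update_positions(state, bests, best_pos, best_fit, bounds, config)
      state <- evaluate_agents(state, objective)
      n_eval <- n_eval + nrow(state$positions)
      state$H <- update_henry_coefficient(state$H, state$C, t, config)
      state$S <- update_solubility(state$H, state$P, state$cluster, config)
      nw <- count_worst_agents(nrow(state$positions), config)
      state <- reinitialize_worst(state, nw, bounds)
      stale <- attr(state, "reseeded")
      state <- evaluate_agents(state, objective, idx = stale)
      n_eval <- n_eval + length(stale)
      bests <- rank_and_select_best(state$fitness, state$cluster)
      if (state$fitness[bests$best_index] < best_fit) {
        best_fit <- state$fitness[bests$best_index]
        best_pos <- state$positions[bests$best_index, ]
      }
      history[t] <- best_fit
    }
    structure(list(best_position = best_pos, best_fitness = best_fit,
                   history = tibble::tibble(iteration = seq_len(config$max_iter),
                                            best_fitness = history),
                   n_evaluations = n_eval, config = config),
              class = "hgso_result")
  }
  if (!is.null(config$seed)) with_seed(config$seed, run()) else run()
}

#' Misclassification percentage
#'
#' `100 * misclassified / total` — the fitness minimized during
#' hyperparameter tuning.
#'
#' @param truth,estimate Equal-length label vectors.
#' @return A percentage in \[0, 100\].
#' @export
misclassification_rate <- function(truth, estimate) {
  if (length(truth) != length(estimate) || length(truth) == 0L) {
    stop_invalid("`truth` and `estimate` must be non-empty and equal length")
  }
  100 * mean(truth != estimate)
}

#' @export
print.hgso_result <- function(x, ...) {
  cat(sprintf("<hgso_result> best fitness %.6g after %d evaluations (%d iterations)\n",
              x$best_fitness, x$n_evaluations, nrow(x$history)))
  invisible(x)
}
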