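# Hybrid GA-PSO cooperative-coevolution multi-objective optimizer:
# NSGA-II machinery (nondominated sorting, crowding, tournament, SBX,
# polynomial mutation), a PSO population guided from a shared Pareto
# archive, periodic migration, rate adaptation, Tchebycheff scalarization
# and exact hypervolume (2-D sweep, 3-D slicing).

#' Hybrid GA-PSO configuration
#'
#' Defaults follow the published optimizer configuration: GA population 50,
#' crossover probability 0.8, mutation probability 0.02, tournament k = 3;
#' swarm size 30, inertia 0.9 -> 0.4 (linear decay), c1 = c2 = 2.0.
#' Operator forms (SBX eta_c = 15, polynomial mutation eta_m = 20),
#' migration (interval 10, count 5), velocity clamp (20% of each range) and
#' archive capacity are package design choices.
#'
#' @param ga_pop_size,crossover_p,mutation_p,tournament_k GA settings.
#' @param swarm_size,inertia_max,inertia_min,c1,c2 PSO settings.
#' @param eta_c,eta_m SBX / polynomial-mutation distribution indices.
#' @param migration_interval,migration_count migration schedule.
#' @param max_iters iteration budget.
#' @param v_max_frac velocity clamp as a fraction of each variable's range.
#' @param archive_capacity Pareto archive capacity.
#' @param mutation_cap,crossover_floor adaptation limits.
#' @param diversity_threshold mean-crowding level below which crossover is
#'   reduced.
#' @param stagnation_tol relative hypervolume change regarded as stagnant.
#' @param rng_seed root seed.
#' @return An object of class `hybrid_config`.
#' @export
hybrid_config <- function(ga_pop_size = 50, crossover_p = 0.8,
                          mutation_p = 0.02, tournament_k = 3,
                          swarm_size = 30, inertia_max = 0.9,
                          inertia_min = 0.4, c1 = 2.0, c2 = 2.0,
                          eta_c = 15, eta_m = 20,
                          migration_interval = 10, migration_count = 5,
                          max_iters = 100, v_max_frac = 0.2,
                          archive_capacity = 200,
                          mutation_cap = 0.2, crossover_floor = 0.6,
                          diversity_threshold = 0.05,
                          stagnation_tol = 1e-6, rng_seed = 1) {
  stopifnot(crossover_p >= 0, crossover_p <= 1, mutation_p >= 0,
            mutation_p <= 1, ga_pop_size >= 2, swarm_size >= 2,
            tournament_k >= 1, migration_interval >= 1, migration_count >= 0,
            max_iters >= 0)
  structure(as.list(environment()), class = "hybrid_config")
}

#' Pareto dominance
#'
#' `a` dominates `b` (minimization) iff `a <= b` in every component and
#' `a < b` in at least one.
#'
#' @param a,b objective vectors of equal length.
#' @return Logical scalar.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) stop("objective vectors must have equal length")
  all(a <= b) && any(a < b)
}

# n x n dominance matrix for an objective matrix (rows = individuals):
# dom[i, j] is TRUE iff row i dominates row j.
dominance_matrix <- function(F) {
  n <- nrow(F)
  le <- matrix(TRUE, n, n)
  lt <- matrix(FALSE, n, n)
  for (j in seq_len(ncol(F))) {
    le <- le & outer(F[, j], F[, j], "<=")
    lt <- lt | outer(F[, j], F[, j], "<")
  }
  le & lt
}

#' Fast nondominated sorting
#'
#' Partitions a population into Pareto fronts: front 1 is the nondominated
#' set; members of front j are dominated only by members of earlier fronts.
#'
#' @param F numeric matrix of objective values (rows = individuals,
#'   minimization).
#' @return A list with `fronts` (list of row-index vectors) and `rank`
#'   (integer vector, 1-based front index per row).
#' @export
nondominated_sort <- function(F) {
  F <- as.matrix(F)
  if (nrow(F) == 0) stop("population must be nonempty")
  if (any(!is.finite(F))) stop("unevaluated or non-finite member")
  dom <- dominance_matrix(F)
  n_dom <- colSums(dom)
  rank <- integer(nrow(F))
  fronts <- list()
  remaining <- rep(TRUE, nrow(F))
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    idx <- which(remaining & n_dom == 0)
    if (length(idx) == 0) stop("cyclic dominance: invalid objectives")
    rank[idx] <- k
    fronts[[k]] <- idx
    remaining[idx] <- FALSE
    if (any(remaining)) {
      n_dom <- n_dom - colSums(dom[idx, , drop = FALSE])
    }
  }
  list(fronts = fronts, rank = rank)
}

#' Crowding distance within a front
#'
#' Boundary solutions per objective get `+Inf`; interior solutions get the
#' sum over objectives of the normalized gap between their neighbours.
#'
#' @param F objective matrix of the front members (rows).
#' @return Numeric vector of crowding distances (same order as rows).
#' @export
crowding_distance <- function(F) {
  F <- as.matrix(F)
  n <- nrow(F)
  if (n < 3) return(rep(Inf, n))
  d <- numeric(n)
  for (j in seq_len(ncol(F))) {
    o <- order(F[, j])
    rng <- F[o[n], j] - F[o[1], j]
    d[o[c(1, n)]] <- Inf
    if (rng > 0) {
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (F[o[3:n], j] - F[o[1:(n - 2)], j]) / rng
    }
  }
  d
}

# Rank + crowding for a whole population.
rank_and_crowd <- function(F) {
  ns <- nondominated_sort(F)
  crowd <- numeric(nrow(F))
  for (idx in ns$fronts) crowd[idx] <- crowding_distance(F[idx, , drop = FALSE])
  list(rank = ns$rank, crowding = crowd)
}

#' Tournament selection
#'
#' Best of `k` uniform draws under the NSGA-II partial order: lower rank
#' wins, ties broken by larger crowding distance (remaining ties by draw
#' order).
#'
#' @param rank,crowding per-individual rank and crowding vectors.
#' @param k tournament size.
#' @return The selected row index.
#' @export
tournament_select <- function(rank, crowding, k = 3) {
  n <- length(rank)
  if (k > n) stop("tournament size exceeds population")
  cand <- sample.int(n, k, replace = FALSE)
  best <- cand[1]
  for (i in cand[-1]) {
    if (rank[i] < rank[best] ||
        (rank[i] == rank[best] && crowding[i] > crowding[best])) {
      best <- i
    }
  }
  best
}

#' Simulated binary crossover (SBX)
#'
#' With probability `1 - prob` returns parent copies. Otherwise each gene
#' recombines with probability 0.5 using the SBX spread with distribution
#' index `eta_c`; children are clipped into the box bounds. Per gene the
#' child mean equals the parent midpoint in expectation.
#'
#' @param p1,p2 parent vectors (within bounds).
#' @param prob crossover probability.
#' @param eta_c distribution index.
#' @param lower,upper box bounds.
#' @return A list with children `c1` and `c2`.
#' @export
sbx_crossover <- function(p1, p2, prob = 0.8, eta_c = 15,
                          lower, upper) {
  c1 <- p1; c2 <- p2
  if (stats::runif(1) < prob) {
    for (g in seq_along(p1)) {
      if (stats::runif(1) < 0.5 && abs(p1[g] - p2[g]) > 1e-14) {
        u <- stats::runif(1)
        beta <- if (u <= 0.5) (2 * u)^(1 / (eta_c + 1)) else
          (1 / (2 * (1 - u)))^(1 / (eta_c + 1))
        x1 <- 0.5 * ((1 + beta) * p1[g] + (1 - beta) * p2[g])
        x2 <- 0.5 * ((1 - beta) * p1[g] + (1 + beta) * p2[g])
        if (stats::runif(1) < 0.5) { tmp <- x1; x1 <- x2; x2 <- tmp }
        c1[g] <- x1; c2[g] <- x2
      }
    }
    c1 <- clip_box(c1, lower, upper)
    c2 <- clip_box(c2, lower, upper)
  }
  list(c1 = c1, c2 = c2)
}

#' Polynomial mutation
#'
#' Each gene is perturbed with probability `prob` using Deb's bounded
#' polynomial mutation with distribution index `eta_m`; the result stays
#' within bounds.
#'
#' @param x decision vector (within bounds).
#' @param prob per-gene mutation probability.
#' @param eta_m distribution index.
#' @param lower,upper box bounds.
#' @return The mutated vector.
#' @export
polynomial_mutation <- function(x, prob = 0.02, eta_m = 20, lower, upper) {
  for (g in seq_along(x)) {
    if (stats::runif(1) < prob) {
      rng <- upper[g] - lower[g]
      if (rng <= 0) next
      u <- stats::runif(1)
      d1 <- (x[g] - lower[g]) / rng
      d2 <- (upper[g] - x[g]) / rng
      if (u < 0.5) {
        delta <- (2 * u + (1 - 2 * u) * (1 - d1)^(eta_m + 1))^(1 / (eta_m + 1)) - 1
      } else {
        delta <- 1 - (2 * (1 - u) + 2 * (u - 0.5) * (1 - d2)^(eta_m + 1))^(1 / (eta_m + 1))
      }
      x[g] <- x[g] + delta * rng
    }
  }
  clip_box(x, lower, upper)
}

#' One particle-swarm update
#'
#' Linearly decayed inertia `w(iter) = w_max - (w_max - w_min) iter/max_iter`,
#' velocity `v' = w v + c1 r1 (pbest - x) + c2 r2 (guide - x)` with
#' per-dimension uniform `r1, r2`, velocity clamped componentwise to
#' `v_max`, and the position clipped into the bounds.
#'
#' @param x,v position and velocity vectors.
#' @param pbest personal best position.
#' @param guide global/archive guide position.
#' @param iter,max_iter current and maximum iteration.
#' @param cfg a [hybrid_config()].
#' @param lower,upper box bounds.
#' @return A list with updated `x` and `v`.
#' @export
pso_step <- function(x, v, pbest, guide, iter, max_iter, cfg, lower, upper) {
  stopifnot(iter <= max_iter)
  w <- cfg$inertia_max - (cfg$inertia_max - cfg$inertia_min) * iter / max_iter
  r1 <- stats::runif(length(x))
  r2 <- stats::runif(length(x))
  v_new <- w * v + cfg$c1 * r1 * (pbest - x) + cfg$c2 * r2 * (guide - x)
  v_max <- cfg$v_max_frac * (upper - lower)
  v_new <- clip_box(v_new, -v_max, v_max)
  x_new <- clip_box(x + v_new, lower, upper)
  list(x = x_new, v = v_new)
}

#' Scalar fitness configuration (weighted normalized aggregation)
#'
#' @param weights objective weights, summing to 1.
#' @param f_min,f_max per-objective normalization bounds (`f_max > f_min`).
#' @return An object of class `scalar_fitness_config`.
#' @export
scalar_fitness_config <- function(weights, f_min, f_max) {
  stopifnot(abs(sum(weights) - 1) < 1e-9, all(f_max > f_min),
            length(weights) == length(f_min),
            length(weights) == length(f_max))
  structure(list(weights = weights, f_min = f_min, f_max = f_max),
            class = "scalar_fitness_config")
}

#' Comprehensive scalar fitness
#'
#' `F = sum_i w_i (f_max_i - f_i) / (f_max_i - f_min_i)`; in \[0, 1\] when
#' the weights sum to 1 and objectives lie inside the bounds (values are
#' clipped into the bounds first). Larger is better.
#'
#' @param objs objective vector (or matrix, rows = individuals).
#' @param cfg a [scalar_fitness_config()].
#' @return Fitness value(s).
#' @export
scalar_fitness <- function(objs, cfg) {
  stopifnot(inherits(cfg, "scalar_fitness_config"))
  if (any(cfg$f_max == cfg$f_min)) stop("degenerate normalization bounds")
  if (is.matrix(objs)) {
    objs <- sweep(sweep(objs, 2, cfg$f_min, pmax), 2, cfg$f_max, pmin)
    drop(sweep(sweep(objs, 2, cfg$f_max, function(f, m) m - f), 2,
               cfg$f_max - cfg$f_min, "/") %*% cfg$weights)
  } else {
    f <- clip_box(objs, cfg$f_min, cfg$f_max)
    sum(cfg$weights * (cfg$f_max - f) / (cfg$f_max - cfg$f_min))
  }
}

#' Weight vector for Tchebycheff decomposition
#'
#' @param lambda nonnegative simplex weights (sum 1).
#' @param z_star reference (ideal) point.
#' @return An object of class `weight_vector`.
#' @export
weight_vector <- function(lambda, z_star) {
  stopifnot(all(lambda >= 0), abs(sum(lambda) - 1) < 1e-9,
            length(lambda) == length(z_star))
  structure(list(lambda = lambda, z_star = z_star), class = "weight_vector")
}

#' Tchebycheff aggregation
#'
#' `g_te(x | lambda, z*) = max_i lambda_i |f_i(x) - z*_i|`.
#'
#' @param objs objective vector.
#' @param wv a [weight_vector()].
#' @return Scalar aggregation value.
#' @export
tchebycheff <- function(objs, wv) {
  stopifnot(inherits(wv, "weight_vector"))
  max(wv$lambda * abs(objs - wv$z_star))
}

#' Adaptive controller for the recursive parameter update
#'
#' @param alpha,beta adaptation coefficients (>= 0); defaults 0.7 / 0.3.
#' @param window sliding-window history length (>= 1).
#' @return An object of class `adaptive_controller`.
#' @export
adaptive_controller <- function(alpha = 0.7, beta = 0.3, window = 10) {
  stopifnot(alpha >= 0, beta >= 0, window >= 1)
  structure(list(alpha = alpha, beta = beta, window = window),
            class = "adaptive_controller")
}

#' Recursive adaptive parameter update
#'
#' `x_{t+1} = x_t + alpha dx_opt + beta dx_feedback`, clipped into the box
#' bounds so the protocol always stays physically meaningful.
#'
#' @param x_t current parameter vector.
#' @param delta_opt optimization-driven change.
#' @param delta_feedback feedback-based change.
#' @param ctrl an [adaptive_controller()].
#' @param lower,upper box bounds.
#' @return The updated, clipped parameter vector.
#' @export
adaptive_update <- function(x_t, delta_opt, delta_feedback, ctrl,
                            lower, upper) {
  stopifnot(inherits(ctrl, "adaptive_controller"),
            length(x_t) == length(delta_opt),
            length(x_t) == length(delta_feedback))
  clip_box(x_t + ctrl$alpha * delta_opt + ctrl$beta * delta_feedback,
           lower, upper)
}

#' Self-tuning of operator rates
#'
#' If archive hypervolume stagnated over the sliding window (relative
#' change below `stagnation_tol`), mutation probability is raised by 50%
#' (capped) and the inertia floor is raised to keep the swarm exploring;
#' if archive diversity (mean finite crowding) fell below the threshold,
#' crossover probability is reduced by 0.05 (floored).
#'
#' @param history data frame with at least `hypervolume` and `diversity`
#'   columns, one row per iteration (most recent last).
#' @param cfg a [hybrid_config()] carrying the current rates.
#' @param window sliding-window length (default 10).
#' @return A list with updated `crossover_p`, `mutation_p`, `c1`, `c2` and
#'   `inertia_min`.
#' @export
adapt_rates <- function(history, cfg, window = 10) {
  stopifnot(nrow(history) >= 1)
  rates <- list(crossover_p = cfg$crossover_p, mutation_p = cfg$mutation_p,
                c1 = cfg$c1, c2 = cfg$c2, inertia_min = cfg$inertia_min)
  if (nrow(history) > window) {
    hv <- utils::tail(history$hypervolume, window + 1)
    rel <- abs(hv[length(hv)] - hv[1]) / max(abs(hv[1]), 1e-12)
    if (rel < cfg$stagnation_tol) {
      rates$mutation_p <- min(rates$mutation_p * 1.5, cfg$mutation_cap)
      rates$inertia_min <- min(rates$inertia_min + 0.05, cfg$inertia_max)
    }
  }
  div <- utils::tail(history$diversity, 1)
  if (is.finite(div) && div < cfg$diversity_threshold) {
    rates$crossover_p <- max(rates$crossover_p - 0.05, cfg$crossover_floor)
  }
  rates
}

# --- hypervolume -----------------------------------------------------------

# 2-D sweep over a (possibly dominated) point set; minimization.
hv2 <- function(F, ref) {
  keep <- F[, 1] < ref[1] & F[, 2] < ref[2]
  F <- F[keep, , drop = FALSE]
  if (nrow(F) == 0) return(0)
  o <- order(F[, 1], F[, 2])
  F <- F[o, , drop = FALSE]
  # sweep left to right keeping the 2-D staircase of nondominated points
  best_f2 <- Inf
  stair_x <- numeric(0); stair_y <- numeric(0)
  for (i in seq_len(nrow(F))) {
    if (F[i, 2] < best_f2) {
      stair_x <- c(stair_x, F[i, 1]); stair_y <- c(stair_y, F[i, 2])
      best_f2 <- F[i, 2]
    }
  }
  widths <- c(stair_x[-1], ref[1]) - stair_x
  sum(widths * (ref[2] - stair_y))
}

# 3-D hypervolume by slicing along the third objective.
hv3 <- function(F, ref) {
  keep <- F[, 1] < ref[1] & F[, 2] < ref[2] & F[, 3] < ref[3]
  F <- F[keep, , drop = FALSE]
  if (nrow(F) == 0) return(0)
  zs <- sort(unique(F[, 3]))
  bounds <- c(zs, ref[3])
  hv <- 0
  for (i in seq_along(zs)) {
    thick <- bounds[i + 1] - bounds[i]
    if (thick <= 0) next
    active <- F[F[, 3] <= zs[i], c(1, 2), drop = FALSE]
    hv <- hv + hv2(active, ref[1:2]) * thick
  }
  hv
}

#' Exact hypervolume of a front
#'
#' Lebesgue measure of the objective-space region dominated by the front
#' and bounded by the reference point (minimization). Exact sweep for two
#' objectives, recursive slicing for three. Dominated members contribute
#' nothing; every member must strictly dominate the reference point.
#'
#' @param F objective matrix (rows = front members) or vector for a single
#'   point.
#' @param ref reference point.
#' @return The hypervolume.
#' @export
hypervolume <- function(F, ref) {
  if (!is.matrix(F)) F <- matrix(F, nrow = 1)
  if (ncol(F) != length(ref)) stop("reference point dimension mismatch")
  if (nrow(F) == 0) return(0)
  if (any(apply(F, 1, function(f) all(f >= ref)))) {
    stop("front member does not dominate the reference point")
  }
  switch(as.character(ncol(F)),
         "2" = hv2(F, ref),
         "3" = hv3(F, ref),
         stop("hypervolume implemented for 2 or 3 objectives"))
}

# --- archive ---------------------------------------------------------------

#' Pareto archive
#'
#' Mutually nondominated set of (decision vector, objective vector) pairs
#' with a capacity; when over capacity the archive is truncated by
#' crowding distance (boundary members are always kept, the most crowded
#' interior members dropped first).
#'
#' @param X,F decision and objective matrices (may be empty).
#' @param ref_point hypervolume reference point (may be `NULL` until set).
#' @param capacity maximum size.
#' @return An object of class `pareto_archive`.
#' @export
pareto_archive <- function(X = NULL, F = NULL, ref_point = NULL,
                           capacity = 200) {
  a <- structure(list(X = X, F = F, ref_point = ref_point,
                      capacity = capacity),
                 class = "pareto_archive")
  if (!is.null(X)) a <- archive_update(a, X, F)
  a
}

#' @rdname pareto_archive
#' @param archive a `pareto_archive`.
#' @param X_new,F_new candidate decision/objective matrices.
#' @export
archive_update <- function(archive, X_new, F_new) {
  X <- rbind(archive$X, X_new)
  F <- rbind(archive$F, F_new)
  # deduplicate identical objective vectors to keep the archive minimal
  dup <- duplicated(F)
  X <- X[!dup, , drop = FALSE]; F <- F[!dup, , drop = FALSE]
  ns <- nondominated_sort(F)
  keep <- ns$fronts[[1]]
  X <- X[keep, , drop = FALSE]; F <- F[keep, , drop = FALSE]
  if (nrow(F) > archive$capacity) {
    # one-pass crowding-distance truncation: boundary members (Inf) are
    # always retained, the most crowded interior members dropped
    cd <- crowding_distance(F)
    keep2 <- order(-cd)[seq_len(archive$capacity)]
    X <- X[keep2, , drop = FALSE]; F <- F[keep2, , drop = FALSE]
  }
  archive$X <- X; archive$F <- F
  archive
}

# --- problem construction --------------------------------------------------

#' Seed-treatment optimization problem
#'
#' Bundles a variety profile and hardware models into the three-objective
#' minimization problem used by the optimizer: (negative germination gain
#' from the calibrated dose-response, electrical energy cost in joules,
#' processing time in seconds) as a function of the six-variable treatment
#' protocol.
#'
#' @param profile a [variety_profile()].
#' @param mech a [seed_mechanics()]; defaults to the profile's.
#' @param coil a [coil_spec()].
#' @param losses a [power_model()].
#' @return A list with `fn(x)`, `lower`, `upper`, `m = 3`, and the
#'   bundled models.
#' @export
make_problem <- function(profile, mech = profile_mechanics(profile),
                         coil = coil_spec(), losses = power_model()) {
  b <- protocol_bounds()
  fn <- function(x) evaluate_objectives(x, profile, mech, coil, losses)
  list(fn = fn, lower = b$lower, upper = b$upper, m = 3L,
       profile = profile, mech = mech, coil = coil, losses = losses)
}

#' Evaluate the three treatment objectives at a decision vector
#'
#' @param x decision vector (six protocol variables, within bounds).
#' @param profile,mech,coil,losses models as in [make_problem()].
#' @return Numeric objective vector `(-delta_g, energy_J, duration_s)`.
#' @export
evaluate_objectives <- function(x, profile, mech, coil, losses) {
  b <- protocol_bounds()
  if (any(x < b$lower - 1e-9) || any(x > b$upper + 1e-9)) {
    stop("decision vector violates the box constraints")
  }
  protocol <- vector_to_protocol(x, check = FALSE)
  dose <- effective_dose(protocol, profile, mech)
  dr <- dose_response(dose, profile)
  c(-dr$delta_g,
    protocol_energy_cost(protocol, coil, losses),
    protocol$duration_s)
}

# --- run loops -------------------------------------------------------------

# Uniform random population within bounds (rows = individuals).
init_population <- function(n, lower, upper) {
  d <- length(lower)
  X <- matrix(stats::runif(n * d), n, d)
  sweep(sweep(X, 2, upper - lower, "*"), 2, lower, "+")
}

evaluate_matrix <- function(X, fn) {
  t(apply(X, 1, fn))
}

# NSGA-II environmental selection: keep n best by (rank, crowding).
environmental_selection <- function(X, F, n) {
  ns <- nondominated_sort(F)
  sel <- integer(0)
  for (front in ns$fronts) {
    if (length(sel) + length(front) <= n) {
      sel <- c(sel, front)
    } else {
      cd <- crowding_distance(F[front, , drop = FALSE])
      sel <- c(sel, front[order(-cd)][seq_len(n - length(sel))])
      break
    }
  }
  list(X = X[sel, , drop = FALSE], F = F[sel, , drop = FALSE])
}

#' Migrate elite solutions between populations
#'
#' The `count` archive members with the largest crowding distance replace
#' the worst-ranked GA members and the worst personal bests in the swarm;
#' the archive itself is unchanged.
#'
#' @param ga list with `X`, `F`, `rank`, `crowding`.
#' @param swarm list with `X`, `V`, `pbest_X`, `pbest_F`.
#' @param archive a [pareto_archive()].
#' @param count number of migrants.
#' @return List with updated `ga` and `swarm`.
#' @export
migrate <- function(ga, swarm, archive, count) {
  if (count == 0 || nrow(archive$F) == 0) return(list(ga = ga, swarm = swarm))
  count <- min(count, nrow(archive$F), nrow(ga$X), nrow(swarm$X))
  cd <- crowding_distance(archive$F)
  top <- order(-cd)[seq_len(count)]
  # worst GA members by (rank desc, crowding asc)
  worst_ga <- order(-ga$rank, ga$crowding)[seq_len(count)]
  ga$X[worst_ga, ] <- archive$X[top, , drop = FALSE]
  ga$F[worst_ga, ] <- archive$F[top, , drop = FALSE]
  rc <- rank_and_crowd(ga$F)
  ga$rank <- rc$rank; ga$crowding <- rc$crowding
  # worst personal bests by rank within the pbest set
  rc_p <- rank_and_crowd(swarm$pbest_F)
  worst_p <- order(-rc_p$rank, rc_p$crowding)[seq_len(count)]
  swarm$pbest_X[worst_p, ] <- archive$X[top, , drop = FALSE]
  swarm$pbest_F[worst_p, ] <- archive$F[top, , drop = FALSE]
  list(ga = ga, swarm = swarm)
}

#' Run the hybrid GA-PSO cooperative-coevolution optimizer
#'
#' Per iteration: a GA generation (tournament selection, SBX, polynomial
#' mutation, evaluation, NSGA-II environmental selection), a PSO sweep
#' with guides drawn from the shared Pareto archive by crowding-biased
#' roulette and personal bests updated on Pareto dominance, archive
#' update, migration every `migration_interval` iterations and rate
#' adaptation. History records per-iteration hypervolume (fixed reference
#' point), archive diversity and the current rates. Fully reproducible
#' for a given `cfg$rng_seed`.
#'
#' @param problem a [make_problem()]-style list (`fn`, `lower`, `upper`,
#'   `m`).
#' @param cfg a [hybrid_config()].
#' @param ctrl an [adaptive_controller()] (its `window` drives
#'   [adapt_rates()]).
#' @param ref_point optional fixed hypervolume reference point; default
#'   1.1 x the per-objective worst over the initial populations.
#' @return A list with `archive` (a [pareto_archive()]), `history`
#'   (data frame) and `ref_point`.
#' @export
run_hybrid <- function(problem, cfg = hybrid_config(),
                       ctrl = adaptive_controller(), ref_point = NULL) {
  old <- local_seed(substream_seed(cfg$rng_seed, "hybrid"))
  on.exit(restore_seed(old), add = TRUE)
  lower <- problem$lower; upper <- problem$upper

  ga <- list(X = init_population(cfg$ga_pop_size, lower, upper))
  ga$F <- evaluate_matrix(ga$X, problem$fn)
  rc <- rank_and_crowd(ga$F)
  ga$rank <- rc$rank; ga$crowding <- rc$crowding

  swarm <- list(X = init_population(cfg$swarm_size, lower, upper),
                V = matrix(0, cfg$swarm_size, length(lower)))
  swarm$F <- evaluate_matrix(swarm$X, problem$fn)
  swarm$pbest_X <- swarm$X; swarm$pbest_F <- swarm$F
  # the swarm decomposes the problem Tchebycheff-style: particles cycle
  # through a lattice of weight vectors (on running-normalized
  # objectives), sweeping the whole front over the run
  lam_all <- pmax(simplex_weights(4 * cfg$swarm_size, problem$m), 1e-3)
  n_lam <- nrow(lam_all)
  f_lo <- apply(rbind(ga$F, swarm$F), 2, min)
  f_hi <- apply(rbind(ga$F, swarm$F), 2, max)
  g_te <- function(f, l) {
    max(l * (f - f_lo) / pmax(f_hi - f_lo, 1e-12))
  }

  if (is.null(ref_point)) {
    worst <- apply(rbind(ga$F, swarm$F), 2, max)
    ref_point <- worst + 0.1 * pmax(abs(worst), 1)
  }
  archive <- pareto_archive(capacity = cfg$archive_capacity,
                            ref_point = ref_point)
  archive <- archive_update(archive, rbind(ga$X, swarm$X),
                            rbind(ga$F, swarm$F))

  rates <- list(crossover_p = cfg$crossover_p, mutation_p = cfg$mutation_p,
                c1 = cfg$c1, c2 = cfg$c2, inertia_min = cfg$inertia_min)
  history <- data.frame()
  record <- function(iter) {
    Fc <- sweep(archive$F, 2, ref_point, pmin)
    cd <- crowding_distance(archive$F)
    data.frame(iter = iter,
               hypervolume = hypervolume(Fc, ref_point),
               diversity = mean(cd[is.finite(cd)], na.rm = TRUE),
               crossover_p = rates$crossover_p,
               mutation_p = rates$mutation_p,
               c1 = rates$c1, c2 = rates$c2)
  }
  history <- record(0L)

  iter <- 0L
  while (iter < cfg$max_iters) {
    iter <- iter + 1L
    # --- GA generation
    n <- cfg$ga_pop_size
    off <- matrix(0, n, length(lower))
    i <- 1L
    while (i <= n) {
      a <- tournament_select(ga$rank, ga$crowding, cfg$tournament_k)
      b <- tournament_select(ga$rank, ga$crowding, cfg$tournament_k)
      ch <- sbx_crossover(ga$X[a, ], ga$X[b, ], rates$crossover_p,
                          cfg$eta_c, lower, upper)
      off[i, ] <- polynomial_mutation(ch$c1, rates$mutation_p, cfg$eta_m,
                                      lower, upper)
      if (i + 1L <= n) {
        off[i + 1L, ] <- polynomial_mutation(ch$c2, rates$mutation_p,
                                             cfg$eta_m, lower, upper)
      }
      i <- i + 2L
    }
    off_F <- evaluate_matrix(off, problem$fn)
    # cooperative sharing: the swarm's current positions compete in the
    # GA's environmental selection alongside parents and offspring
    env <- environmental_selection(rbind(ga$X, off, swarm$X),
                                   rbind(ga$F, off_F, swarm$F), n)
    ga$X <- env$X; ga$F <- env$F
    rc <- rank_and_crowd(ga$F)
    ga$rank <- rc$rank; ga$crowding <- rc$crowding
    f_lo <- pmin(f_lo, apply(off_F, 2, min))
    f_hi <- pmax(f_hi, apply(off_F, 2, max))

    # --- PSO sweep: each particle chases its own scalarized subproblem,
    # guided by the archive member best on that subproblem
    cfg_iter <- cfg
    cfg_iter$c1 <- rates$c1; cfg_iter$c2 <- rates$c2
    cfg_iter$inertia_min <- rates$inertia_min
    Fa_n <- sweep(sweep(archive$F, 2, f_lo), 2,
                  pmax(f_hi - f_lo, 1e-12), "/")
    for (p in seq_len(cfg$swarm_size)) {
      lam_p <- lam_all[((iter - 1) * cfg$swarm_size + p - 1) %% n_lam + 1, ]
      g_arch <- apply(sweep(Fa_n, 2, lam_p, "*"), 1, max)
      guide <- archive$X[which.min(g_arch), ]
      st <- pso_step(swarm$X[p, ], swarm$V[p, ], swarm$pbest_X[p, ], guide,
                     iter, cfg$max_iters, cfg_iter, lower, upper)
      swarm$X[p, ] <- st$x; swarm$V[p, ] <- st$v
      f_new <- problem$fn(st$x)
      swarm$F[p, ] <- f_new
      f_lo <- pmin(f_lo, f_new); f_hi <- pmax(f_hi, f_new)
      if (g_te(f_new, lam_p) < g_te(swarm$pbest_F[p, ], lam_p)) {
        swarm$pbest_X[p, ] <- st$x
        swarm$pbest_F[p, ] <- f_new
      }
    }

    archive <- archive_update(archive, rbind(off, swarm$X),
                              rbind(off_F, swarm$F))

    if (cfg$migration_count > 0 && iter %% cfg$migration_interval == 0) {
      mg <- migrate(ga, swarm, archive, cfg$migration_count)
      ga <- mg$ga; swarm <- mg$swarm
    }

    history <- rbind(history, record(iter))
    cfg_rates <- cfg
    cfg_rates$crossover_p <- rates$crossover_p
    cfg_rates$mutation_p <- rates$mutation_p
    cfg_rates$c1 <- rates$c1; cfg_rates$c2 <- rates$c2
    cfg_rates$inertia_min <- rates$inertia_min
    rates <- adapt_rates(history, cfg_rates, ctrl$window)
  }
  list(archive = archive, history = history, ref_point = ref_point)
}

#' Run a plain NSGA-II baseline
#'
#' Standard NSGA-II with the same operators (tournament, SBX, polynomial
#' mutation) and the same per-iteration evaluation budget as the hybrid
#' when `pop_size = ga_pop_size + swarm_size`.
#'
#' @param problem a [make_problem()]-style list.
#' @param pop_size population size.
#' @param max_iters generations.
#' @param cfg a [hybrid_config()] for operator settings.
#' @param ref_point optional fixed hypervolume reference point.
#' @return Same structure as [run_hybrid()].
#' @export
run_nsga2 <- function(problem, pop_size = 80, max_iters = 100,
                      cfg = hybrid_config(), ref_point = NULL) {
  old <- local_seed(substream_seed(cfg$rng_seed, "nsga2"))
  on.exit(restore_seed(old), add = TRUE)
  lower <- problem$lower; upper <- problem$upper
  X <- init_population(pop_size, lower, upper)
  F <- evaluate_matrix(X, problem$fn)
  rc <- rank_and_crowd(F)
  if (is.null(ref_point)) {
    worst <- apply(F, 2, max)
    ref_point <- worst + 0.1 * pmax(abs(worst), 1)
  }
  archive <- pareto_archive(capacity = cfg$archive_capacity,
                            ref_point = ref_point)
  archive <- archive_update(archive, X, F)
  history <- data.frame()
  for (iter in seq_len(max_iters)) {
    off <- matrix(0, pop_size, length(lower))
    i <- 1L
    while (i <= pop_size) {
      a <- tournament_select(rc$rank, rc$crowding, cfg$tournament_k)
      b <- tournament_select(rc$rank, rc$crowding, cfg$tournament_k)
      ch <- sbx_crossover(X[a, ], X[b, ], cfg$crossover_p, cfg$eta_c,
                          lower, upper)
      off[i, ] <- polynomial_mutation(ch$c1, cfg$mutation_p, cfg$eta_m,
                                      lower, upper)
      if (i + 1L <= pop_size) {
        off[i + 1L, ] <- polynomial_mutation(ch$c2, cfg$mutation_p,
                                             cfg$eta_m, lower, upper)
      }
      i <- i + 2L
    }
    off_F <- evaluate_matrix(off, problem$fn)
    env <- environmental_selection(rbind(X, off), rbind(F, off_F), pop_size)
    X <- env$X; F <- env$F
    rc <- rank_and_crowd(F)
    archive <- archive_update(archive, off, off_F)
    Fc <- sweep(archive$F, 2, ref_point, pmin)
    cd <- crowding_distance(archive$F)
    history <- rbind(history, data.frame(
      iter = iter, hypervolume = hypervolume(Fc, ref_point),
      diversity = mean(cd[is.finite(cd)], na.rm = TRUE),
      crossover_p = cfg$crossover_p, mutation_p = cfg$mutation_p,
      c1 = cfg$c1, c2 = cfg$c2))
  }
  list(archive = archive, history = history, ref_point = ref_point)
}

#' Run a Tchebycheff-decomposition (MOEA/D-style) baseline
#'
#' Minimal decomposition solver: a set of simplex-lattice weight vectors,
#' Tchebycheff aggregation against a running ideal point, mating within a
#' T-neighbourhood, SBX + polynomial mutation.
#'
#' @param problem a [make_problem()]-style list.
#' @param n_weights number of subproblems.
#' @param max_iters generations.
#' @param neighborhood neighbourhood size T.
#' @param cfg a [hybrid_config()] for operator settings.
#' @param ref_point optional fixed hypervolume reference point.
#' @return Same structure as [run_hybrid()].
#' @export
run_moead <- function(problem, n_weights = 80, max_iters = 100,
                      neighborhood = 10, cfg = hybrid_config(),
                      ref_point = NULL) {
  old <- local_seed(substream_seed(cfg$rng_seed, "moead"))
  on.exit(restore_seed(old), add = TRUE)
  m <- problem$m
  lambda <- simplex_weights(n_weights, m)
  n <- nrow(lambda)
  D <- as.matrix(stats::dist(lambda))
  B <- t(apply(D, 1, function(d) order(d)[seq_len(min(neighborhood, n))]))
  lower <- problem$lower; upper <- problem$upper
  X <- init_population(n, lower, upper)
  F <- evaluate_matrix(X, problem$fn)
  z <- apply(F, 2, min)
  if (is.null(ref_point)) {
    worst <- apply(F, 2, max)
    ref_point <- worst + 0.1 * pmax(abs(worst), 1)
  }
  archive <- pareto_archive(capacity = cfg$archive_capacity,
                            ref_point = ref_point)
  archive <- archive_update(archive, X, F)
  history <- data.frame()
  g_te <- function(f, lam) max(pmax(lam, 1e-6) * abs(f - z))
  for (iter in seq_len(max_iters)) {
    for (i in seq_len(n)) {
      nb <- B[i, ]
      pr <- sample(nb, 2)
      ch <- sbx_crossover(X[pr[1], ], X[pr[2], ], cfg$crossover_p, cfg$eta_c,
                          lower, upper)
      y <- polynomial_mutation(ch$c1, max(cfg$mutation_p, 1 / length(lower)),
                               cfg$eta_m, lower, upper)
      fy <- problem$fn(y)
      z <- pmin(z, fy)
      for (j in nb) {
        if (g_te(fy, lambda[j, ]) < g_te(F[j, ], lambda[j, ])) {
          X[j, ] <- y; F[j, ] <- fy
        }
      }
      archive <- archive_update(archive, matrix(y, 1), matrix(fy, 1))
    }
    Fc <- sweep(archive$F, 2, ref_point, pmin)
    cd <- crowding_distance(archive$F)
    history <- rbind(history, data.frame(
      iter = iter, hypervolume = hypervolume(Fc, ref_point),
      diversity = mean(cd[is.finite(cd)], na.rm = TRUE),
      crossover_p = cfg$crossover_p, mutation_p = cfg$mutation_p,
      c1 = cfg$c1, c2 = cfg$c2))
  }
  list(archive = archive, history = history, ref_point = ref_point)
}

# Simplex-lattice weight vectors for m objectives (about n vectors).
simplex_weights <- function(n, m) {
  if (m == 2) {
    w1 <- seq(0, 1, length.out = n)
    return(cbind(w1, 1 - w1))
  }
  H <- 1
  while (choose(H + m - 1, m - 1) < n) H <- H + 1
  combs <- utils::combn(H + m - 1, m - 1)
  W <- t(apply(combs, 2, function(cc) diff(c(0, cc, H + m)) - 1)) / H
  W
}

#' First iteration at which the optimizer has converged
#'
#' The first index `i` (0-based, `0` = initial state) after which the
#' hypervolume changes by less than `tol` for `patience` consecutive
#' iterations; `Inf` if that never happens.
#'
#' @param hv hypervolume trace (one value per iteration, oldest first), or
#'   a history data frame with a `hypervolume` column.
#' @param tol absolute change tolerance.
#' @param patience number of consecutive quiet iterations required.
#' @return Iteration index, or `Inf`.
#' @export
convergence_iteration <- function(hv, tol = 1e-6, patience = 5) {
  if (is.data.frame(hv)) hv <- hv$hypervolume
  if (length(hv) == 0) stop("history must be nonempty")
  n <- length(hv)
  if (n == 1) return(0)
  if (n - 1 < patience) return(Inf)
  d <- abs(diff(hv))
  quiet <- d < tol
  for (i in 0:(n - 1 - patience)) {
    if (all(quiet[(i + 1):(i + patience)])) return(i)
  }
  Inf
}
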