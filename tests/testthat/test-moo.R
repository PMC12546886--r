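# Optimizer machinery: dominance, sorting, crowding, operators, PSO,
# scalarizations, hypervolume, migration, adaptation, full runs.

test_that("dominates is the strict Pareto relation", {
  expect_true(dominates(c(1, 1), c(2, 2)))
  expect_false(dominates(c(1, 2), c(2, 1)))
  expect_false(dominates(c(2, 1), c(1, 2)))
  expect_false(dominates(c(1, 2), c(1, 2)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "length")
})

test_that("nondominated_sort agrees with the brute-force oracle", {
  F <- rbind(c(1, 2), c(2, 1), c(3, 3))
  ns <- nondominated_sort(F)
  expect_equal(ns$fronts, list(c(1L, 2L), 3L))
  expect_equal(nondominated_sort(matrix(1, 4, 2))$fronts[[1]], 1:4)
  chain <- rbind(c(1, 1), c(2, 2), c(3, 3))
  expect_equal(lengths(nondominated_sort(chain)$fronts), c(1, 1, 1))
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(3:50, 1); m <- sample(2:3, 1)
    F <- matrix(sample(1:8, n * m, replace = TRUE), n, m)
    ns <- nondominated_sort(F)
    expect_equal(lapply(ns$fronts, sort), brute_fronts(F))
  }
})

test_that("crowding_distance boundary and interior values", {
  expect_equal(crowding_distance(rbind(c(1, 2), c(2, 1))), c(Inf, Inf))
  F <- rbind(c(1, 3), c(2, 2), c(3, 1))
  expect_equal(crowding_distance(F), c(Inf, 2, Inf))
  # permutation invariance
  set.seed(7)
  F2 <- cbind(runif(12), runif(12), runif(12))
  d <- crowding_distance(F2)
  perm <- sample(12)
  expect_equal(crowding_distance(F2[perm, ])[order(perm)], d)
})

test_that("tournament_select honours rank/crowding and uniformity", {
  # identical fitness -> uniform selection (chi-square over 1e4 draws)
  set.seed(11)
  draws <- replicate(1e4, tournament_select(rep(1, 5), rep(Inf, 5), k = 3))
  expect_gt(chisq.test(table(draws))$p.value, 0.001)
  # k = n always returns the single best-ranked individual
  rank <- c(3, 1, 2, 4); crowd <- c(1, 1, 1, 1)
  set.seed(2)
  expect_true(all(replicate(50, tournament_select(rank, crowd, 4)) == 2))
  expect_error(tournament_select(rep(1, 3), rep(1, 3), k = 5), "exceeds")
  # reproducible winner sequence
  s1 <- with(list(), {set.seed(3); replicate(20, tournament_select(rank, crowd, 2))})
  s2 <- with(list(), {set.seed(3); replicate(20, tournament_select(rank, crowd, 2))})
  expect_identical(s1, s2)
})

test_that("SBX crossover is copy-at-prob-0, degenerate at equal parents, mean-preserving", {
  lo <- rep(0, 3); hi <- rep(10, 3)
  p1 <- c(2, 5, 8); p2 <- c(4, 5, 1)
  set.seed(5)
  ch <- sbx_crossover(p1, p2, prob = 0, lower = lo, upper = hi)
  expect_identical(ch, list(c1 = p1, c2 = p2))
  ch2 <- sbx_crossover(p1, p1, prob = 1, lower = lo, upper = hi)
  expect_equal(ch2$c1, p1); expect_equal(ch2$c2, p1)
  # Monte-Carlo mean preservation per gene (bounds wide enough that the
  # clipping contract never engages)
  set.seed(6)
  wide_lo <- rep(-100, 3); wide_hi <- rep(100, 3)
  sums <- matrix(0, 1e4, 3)
  for (i in 1:1e4) {
    ch <- sbx_crossover(p1, p2, prob = 1, lower = wide_lo, upper = wide_hi)
    sums[i, ] <- (ch$c1 + ch$c2) / 2
  }
  mid <- (p1 + p2) / 2
  se <- apply(sums, 2, sd) / sqrt(1e4)
  expect_true(all(abs(colMeans(sums) - mid) <= 3 * pmax(se, 1e-12)))
})

test_that("polynomial mutation respects bounds and target rate", {
  lo <- rep(0, 10); hi <- rep(1, 10)
  set.seed(8)
  x <- runif(10)
  expect_identical(polynomial_mutation(x, prob = 0, lower = lo, upper = hi),
                   x)
  at_bound <- c(rep(0, 5), rep(1, 5))
  for (i in 1:50) {
    y <- polynomial_mutation(at_bound, prob = 1, lower = lo, upper = hi)
    expect_true(all(y >= 0 & y <= 1))
  }
  # empirical mutation frequency ~ 0.02 over 1e5 genes
  set.seed(9)
  n_mut <- 0
  for (i in 1:10000) {
    y <- polynomial_mutation(x, prob = 0.02, lower = lo, upper = hi)
    n_mut <- n_mut + sum(y != x)
  }
  freq <- n_mut / 1e5
  expect_lt(abs(freq - 0.02), 3 * sqrt(0.02 * 0.98 / 1e5))
})

test_that("pso_step linear inertia and degenerate updates", {
  cfg <- hybrid_config()
  lo <- rep(0, 2); hi <- rep(10, 2)
  # c1 = c2 = 0 keeps v (up to inertia); at iter 0 w = 0.9
  cfg0 <- hybrid_config(c1 = 0, c2 = 0, inertia_max = 1, inertia_min = 1)
  st <- pso_step(c(5, 5), c(1, -1), c(0, 0), c(9, 9), iter = 3,
                 max_iter = 10, cfg0, lo, hi)
  expect_equal(st$v, c(1, -1))
  expect_equal(st$x, c(6, 4))
  # x = pbest = gbest -> v' = w v
  set.seed(1)
  st2 <- pso_step(c(5, 5), c(0.4, 0.2), c(5, 5), c(5, 5), iter = 5,
                  max_iter = 10, cfg, lo, hi)
  w_mid <- 0.9 - (0.9 - 0.4) * 0.5
  expect_equal(st2$v, w_mid * c(0.4, 0.2))
  expect_equal(w_mid, 0.65)
})

test_that("scalar_fitness normalizes and weights objectives", {
  cfg <- scalar_fitness_config(weights = c(0.6, 0.4), f_min = c(0, 0),
                               f_max = c(10, 10))
  expect_equal(scalar_fitness(c(0, 0), cfg), 1)
  expect_equal(scalar_fitness(c(10, 10), cfg), 0)
  # normalized positions (0.5, 0.25) from the top
  expect_equal(scalar_fitness(c(5, 7.5), cfg), 0.6 * 0.5 + 0.4 * 0.25)
  expect_error(scalar_fitness_config(c(1), f_min = 0, f_max = 0), "f_max")
})

test_that("tchebycheff matches enumeration of a discrete front", {
  wv <- weight_vector(c(1, 0), c(0, 0))
  expect_equal(tchebycheff(c(3, 9), wv), 3)
  wv2 <- weight_vector(c(0.5, 0.5), c(0, 0))
  expect_equal(tchebycheff(c(2, 4), wv2), 2)
  set.seed(14)
  F <- cbind(runif(30), runif(30))
  z <- apply(F, 2, min)
  for (i in 1:10) {
    lam <- runif(2); lam <- lam / sum(lam)
    wv_i <- weight_vector(lam, z)
    g <- apply(F, 1, tchebycheff, wv = wv_i)
    brute <- apply(F, 1, function(f) max(lam * abs(f - z)))
    expect_equal(which.min(g), which.min(brute))
  }
})

test_that("adaptive_update applies coefficients and clips to bounds", {
  ctrl <- adaptive_controller(alpha = 0.7, beta = 0.3)
  lo <- c(0, 0); hi <- c(10, 10)
  x <- c(5, 5)
  expect_equal(adaptive_update(x, c(1, 1), c(2, 2),
                               adaptive_controller(0, 0), lo, hi), x)
  expect_equal(adaptive_update(c(9.8, 5), c(10, 0), c(0, 0), ctrl, lo, hi),
               c(10, 5))
  # beta = 0 is a damped step of length alpha |dx|
  ctrl_a <- adaptive_controller(alpha = 0.5, beta = 0)
  d <- c(3, 4)
  out <- adaptive_update(x, d, c(99, 99), ctrl_a, lo, hi)
  expect_equal(sqrt(sum((out - x)^2)), 0.5 * 5)
})

test_that("adapt_rates fires its rules and stays within limits", {
  cfg <- hybrid_config()
  improving <- data.frame(hypervolume = cumsum(rep(1, 15)),
                          diversity = rep(1, 15))
  r <- adapt_rates(improving, cfg)
  expect_equal(r$mutation_p, cfg$mutation_p)
  expect_equal(r$crossover_p, cfg$crossover_p)
  flat <- data.frame(hypervolume = rep(5, 15), diversity = rep(1, 15))
  r2 <- adapt_rates(flat, cfg)
  expect_gt(r2$mutation_p, cfg$mutation_p)
  # fuzzed histories never push rates outside [floor, cap]
  set.seed(99)
  rates <- cfg
  for (i in 1:200) {
    h <- data.frame(hypervolume = cumsum(abs(rnorm(12, 0, 0.001))),
                    diversity = runif(12, 0, 0.2))
    r <- adapt_rates(h, rates)
    expect_gte(r$crossover_p, cfg$crossover_floor)
    expect_lte(r$mutation_p, cfg$mutation_cap)
    rates$crossover_p <- r$crossover_p
    rates$mutation_p <- r$mutation_p
  }
})

test_that("hypervolume matches rectangle decomposition and Monte-Carlo", {
  expect_equal(hypervolume(c(2, 2), c(4, 4)), 4)
  F <- rbind(c(1, 3), c(2, 2), c(3, 1))
  expect_equal(hypervolume(F, c(4, 4)), 6)
  # dominated points contribute nothing
  expect_equal(hypervolume(rbind(F, c(3, 3)), c(4, 4)), 6)
  expect_error(hypervolume(rbind(c(1, 1), c(5, 5)), c(4, 4)), "reference")
  # random 2-D / 3-D fronts vs Monte-Carlo within 3 SE
  set.seed(17)
  for (i in 1:25) {
    m <- if (i %% 2 == 0) 2 else 3
    F <- matrix(runif(7 * m), 7, m)
    ref <- rep(1.2, m)
    hv <- hypervolume(F, ref)
    mc <- mc_hypervolume(F, ref, 40000)
    expect_lt(abs(hv - mc$hv), 3 * mc$se + 1e-9)
  }
})

test_that("migrate moves elites into both populations and is a no-op at 0", {
  set.seed(23)
  X <- matrix(runif(30), 10, 3); F <- matrix(runif(30), 10, 3)
  rc <- vibroseed:::rank_and_crowd(F)
  ga <- list(X = X, F = F, rank = rc$rank, crowding = rc$crowding)
  swarm <- list(X = X + 1, V = X * 0, pbest_X = X + 1, pbest_F = F + 1)
  archive <- pareto_archive(X - 1, F - 1, ref_point = rep(3, 3))
  out0 <- migrate(ga, swarm, archive, 0)
  expect_identical(out0$ga$X, ga$X)
  out <- migrate(ga, swarm, archive, 2)
  cd <- crowding_distance(archive$F)
  top <- order(-cd)[1:2]
  for (i in top) {
    expect_true(any(apply(out$ga$X, 1, identical, archive$X[i, ])))
    expect_true(any(apply(out$swarm$pbest_X, 1, identical, archive$X[i, ])))
  }
})

test_that("archive stays mutually nondominated with nondecreasing HV", {
  problem <- test_problem()
  res <- run_hybrid(problem, hybrid_config(max_iters = 15, rng_seed = 31))
  F <- res$archive$F
  dom <- vibroseed:::dominance_matrix(F)
  expect_false(any(dom))
  hv <- res$history$hypervolume
  # minimal-contribution trimming of a capped archive may cost a sliver
  expect_true(all(diff(hv) >= -1e-3 * max(hv)))
  expect_lte(nrow(F), hybrid_config()$archive_capacity)
})

test_that("run_hybrid is reproducible and handles a zero budget", {
  problem <- test_problem()
  r1 <- run_hybrid(problem, hybrid_config(max_iters = 4, rng_seed = 12))
  r2 <- run_hybrid(problem, hybrid_config(max_iters = 4, rng_seed = 12))
  expect_identical(r1$history, r2$history)
  expect_identical(r1$archive$F, r2$archive$F)
  r0 <- run_hybrid(problem, hybrid_config(max_iters = 0, rng_seed = 12))
  expect_equal(nrow(r0$history), 1)
  # archive equals the nondominated subset of the initial populations
  dom <- vibroseed:::dominance_matrix(r0$archive$F)
  expect_false(any(dom))
})

test_that("evaluate_objectives passes duration through and flags violations", {
  v <- default_varieties()
  p1 <- v[[1]]
  coil <- coil_spec(); losses <- power_model()
  x <- protocol_to_vector(treatment_protocol(2.5, 300, 30))
  f <- evaluate_objectives(x, p1, profile_mechanics(p1), coil, losses)
  expect_equal(f[[3]], 30)
  x_bad <- x; x_bad[1] <- 10
  expect_error(evaluate_objectives(x_bad, p1, profile_mechanics(p1), coil,
                                   losses), "constraint")
  # the dose achieving d_opt minimizes objective 1 over a duration grid
  durations <- seq(30, 300, by = 5)
  obj1 <- vapply(durations, function(d) {
    evaluate_objectives(protocol_to_vector(
      treatment_protocol(3.5, p1$f_n, d)), p1, profile_mechanics(p1),
      coil, losses)[1]
  }, 0)
  best_d <- durations[which.min(obj1)]
  dose_best <- effective_dose(treatment_protocol(3.5, p1$f_n, best_d), p1)
  expect_lt(abs(dose_best - p1$d_opt) / p1$d_opt, 0.05)
})

test_that("convergence_iteration finds the plateau", {
  expect_equal(convergence_iteration(rep(5, 10), tol = 1e-6, patience = 3), 0)
  expect_equal(convergence_iteration(1:10, tol = 1e-6, patience = 3), Inf)
  hv <- c(seq(0, 4, length.out = 41), rep(4, 20))
  expect_equal(convergence_iteration(hv, tol = 1e-6, patience = 5), 40)
})
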