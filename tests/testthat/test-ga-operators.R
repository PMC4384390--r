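test_that("initial population respects the K range and is seed-reproducible", {
  set.seed(10)
  pop <- init_population(5, ga_config(pop_size = 100))
  Ks <- vapply(pop, `[[`, integer(1), "K")
  expect_true(all(Ks >= 2 & Ks <= 4))
  expect_true(all(vapply(pop, function(c) !anyDuplicated(c$medoids),
                         logical(1))))
  set.seed(99); p1 <- init_population(30, ga_config(pop_size = 20))
  set.seed(99); p2 <- init_population(30, ga_config(pop_size = 20))
  expect_identical(p1, p2)
  expect_error(init_population(3, ga_config()), "at least 4")
})

test_that("assignment matches brute force and breaks ties low", {
  set.seed(11)
  for (i in 1:10) {
    D <- rand_dist(sample(5:9, 1))
    med <- sort(sample.int(nrow(D), sample(2:4, 1)))
    expect_identical(assign_to_medoids(D, med), bf_assign(D, med))
  }
  # motif 1 equidistant from medoids 3 and 5 -> assigned to 3
  D <- matrix(0, 5, 5)
  D[1, 3] <- D[3, 1] <- 0.4
  D[1, 5] <- D[5, 1] <- 0.4
  D[1, c(2, 4)] <- D[c(2, 4), 1] <- 0.9
  expect_equal(assign_to_medoids(D, c(5, 3))[1], 3)
  # degenerate single-medoid call assigns everything to it
  expect_true(all(assign_to_medoids(rand_dist(4), 2) == 2))
})

test_that("total cost sums distances to owning medoids", {
  D <- matrix(c(0, 1, 4, 5,
                1, 0, 3, 6,
                4, 3, 0, 2,
                5, 6, 2, 0) / 10, 4, byrow = TRUE)
  labels <- assign_to_medoids(D, c(1, 3))
  # hand sum: m1 -> 0, m2 -> D[2,1]=.1, m3 -> 0, m4 -> D[4,3]=.2
  expect_equal(total_cost(D, c(1, 3), labels), 0.3)
  expect_equal(total_cost(D, c(3, 1)), 0.3)   # order-invariant
  expect_equal(total_cost(matrix(0, 3, 3), 1), 0)
})

test_that("one k-medoids round never increases cost and finds committed swaps", {
  set.seed(12)
  for (i in 1:15) {
    D <- rand_dist(sample(5:9, 1))
    med <- sample.int(nrow(D), sample(2:4, 1))
    out <- kmedoids_one_round(D, med)
    expect_lte(total_cost(D, out$medoids), total_cost(D, med) + 1e-12)
    expect_false(anyDuplicated(out$medoids) > 0)
  }
})

test_that("a 1-swap-optimal configuration passes through unchanged", {
  set.seed(13)
  for (i in 1:10) {
    D <- rand_dist(6)
    # exhaustively find the best 2-medoid set: no single swap can improve it
    sets <- utils::combn(6, 2)
    costs <- apply(sets, 2, function(s) total_cost(D, s))
    best <- sets[, which.min(costs)]
    out <- kmedoids_one_round(D, best)
    expect_setequal(out$medoids, best)
  }
})

test_that("one round escapes a bad start on two well-separated triplets", {
  # points 1-3 and 4-6 are tight triplets far apart; both medoids start in
  # the first triplet
  D <- matrix(0.9, 6, 6)
  D[1:3, 1:3] <- 0.05
  D[4:6, 4:6] <- 0.05
  diag(D) <- 0
  out <- kmedoids_one_round(D, c(1, 2))
  expect_lt(total_cost(D, out$medoids), total_cost(D, c(1, 2)))
  # verify against exhaustive single-greedy-pass expectation: one medoid in
  # each triplet is the only way to reach the low cost
  expect_equal(sort((out$medoids - 1) %/% 3), c(0, 1))
})

test_that("silhouette matches the brute-force double loop and its closed cases", {
  # two clusters, within distance 0, between distance 1 -> all s = 1
  D <- matrix(1, 6, 6); D[1:3, 1:3] <- 0; D[4:6, 4:6] <- 0; diag(D) <- 0
  s <- silhouette_scores(D, c(1, 1, 1, 2, 2, 2))
  expect_equal(s$s, rep(1, 6))
  expect_equal(s$mean, 1)
  # a(i) = b(i) -> s(i) = 0
  De <- matrix(0.5, 4, 4); diag(De) <- 0
  se <- silhouette_scores(De, c(1, 1, 2, 2))
  expect_equal(se$s, rep(0, 4))
  # random matrices against the oracle
  set.seed(14)
  for (i in 1:10) {
    D <- rand_dist(8)
    labels <- sample(1:3, 8, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(silhouette_scores(D, labels)$s, bf_silhouette(D, labels),
                 tolerance = 1e-9)
  }
  expect_error(silhouette_scores(rand_dist(4), rep(1, 4)), "single cluster")
})

test_that("singleton clusters score zero silhouette", {
  set.seed(15)
  D <- rand_dist(5)
  s <- silhouette_scores(D, c(1, 1, 1, 1, 2))
  expect_equal(s$s[5], 0)
})

test_that("fitness evaluation improves medoids and is deterministic", {
  D <- matrix(0.9, 6, 6); D[1:3, 1:3] <- 0.05; D[4:6, 4:6] <- 0.05
  diag(D) <- 0
  cand <- list(K = 2L, medoids = c(1L, 2L), labels = NULL, sil = NULL,
               fitness = NA_real_)
  ev <- evaluate_fitness(cand, D)
  start_sil <- silhouette_scores(D, assign_to_medoids(D, c(1, 2)))$mean
  expect_gte(ev$fitness, start_sil)
  expect_equal(ev$fitness, mean(ev$sil), tolerance = 1e-9)
  expect_lte(total_cost(D, ev$medoids), total_cost(D, c(1, 2)))
  expect_identical(evaluate_fitness(cand, D), ev)
  # medoids at the planted exemplars give the planted partition's silhouette
  ev2 <- evaluate_fitness(list(K = 2L, medoids = c(2L, 5L)), D)
  expect_equal(ev2$fitness, mean(bf_silhouette(D, c(1, 1, 1, 2, 2, 2))),
               tolerance = 1e-9)
})

test_that("linear ranking weights follow the closed form", {
  w <- rank_selection_weights(c(0.1, 0.2, 0.3, 0.4), 1.5)
  expect_equal(w, c(0.125, 0.125 + 1 / 12, 0.125 + 2 / 12, 0.375),
               tolerance = 1e-12)
  expect_equal(sum(w), 1)
  # SP = 2, N = 2: all weight on the best
  expect_equal(rank_selection_weights(c(1, 2), 2), c(0, 1))
  # SP -> 1 limit approaches uniform
  w1 <- rank_selection_weights(c(1, 2, 3), 1 + 1e-9)
  expect_equal(w1, rep(1 / 3, 3), tolerance = 1e-8)
  # ties share averaged rank weight
  wt <- rank_selection_weights(c(0.5, 0.5, 0.9), 1.5)
  expect_equal(wt[1], wt[2])
  expect_equal(sum(wt), 1)
  expect_error(rank_selection_weights(c(1, 2), 2.5), "selective_pressure")
})

test_that("mate selection restricts the second parent to equal K", {
  set.seed(16)
  pop <- list(list(K = 7L, medoids = 1:7, fitness = 0.9),
              list(K = 3L, medoids = 1:3, fitness = 0.5),
              list(K = 3L, medoids = 2:4, fitness = 0.4))
  w <- rank_selection_weights(vapply(pop, `[[`, numeric(1), "fitness"), 1.5)
  for (i in 1:50) {
    pair <- select_mate_pair(pop, w)
    if (pair$i1 == 1L) expect_true(is.na(pair$i2))
    else expect_true(pair$i2 %in% c(2L, 3L) && pair$i2 != pair$i1)
  }
})

test_that("uniform crossover preserves K and repairs duplicates", {
  p1 <- list(K = 3L, medoids = c(1L, 2L, 3L), fitness = 0.5)
  p2 <- list(K = 3L, medoids = c(4L, 5L, 6L), fitness = 0.6)
  set.seed(17)
  ch <- uniform_crossover(p1, p2, 10)
  for (c in ch) {
    expect_equal(c$K, 3L)
    expect_false(anyDuplicated(c$medoids) > 0)
    expect_true(all(c$medoids %in% 1:6))
  }
  # disjoint parents: each slot's genes partition the parents' genes
  for (s in 1:3)
    expect_setequal(c(ch[[1]]$medoids[s], ch[[2]]$medoids[s]),
                    c(p1$medoids[s], p2$medoids[s]))
  # identical parents reproduce the parent
  ch2 <- uniform_crossover(p1, p1, 10)
  expect_equal(sort(ch2[[1]]$medoids), 1:3)
  # overlapping parents can collide; repair must keep children duplicate-free
  p3 <- list(K = 2L, medoids = c(1L, 2L), fitness = 0.1)
  p4 <- list(K = 2L, medoids = c(2L, 3L), fitness = 0.2)
  for (i in 1:20) {
    ch3 <- uniform_crossover(p3, p4, 5)
    for (c in ch3) expect_false(anyDuplicated(c$medoids) > 0)
  }
  expect_error(uniform_crossover(p1, p3, 10), "equal K")
})

test_that("duplicate repair redraws only the colliding slots", {
  set.seed(18)
  for (i in 1:20) {
    out <- repair_duplicates(list(K = 3L, medoids = c(1L, 2L, 2L),
                                  fitness = 0.2), 5)
    expect_equal(out$medoids[1:2], c(1L, 2L))
    expect_true(out$medoids[3] %in% c(3L, 4L, 5L))
  }
  ok <- list(K = 2L, medoids = c(4L, 1L), fitness = NA_real_)
  expect_equal(repair_duplicates(ok, 5)$medoids, c(4L, 1L))
  forced <- repair_duplicates(list(K = 4L, medoids = rep(1L, 4)), 4)
  expect_setequal(forced$medoids, 1:4)
  expect_error(repair_duplicates(list(K = 5L, medoids = rep(1L, 5)), 4),
               "more medoids")
})

test_that("mutation respects the K guards and the rate", {
  set.seed(19)
  c2 <- list(K = 2L, medoids = c(1L, 2L), fitness = 0.3)
  for (i in 1:20) {
    out <- mutate_k(c2, 6, rate = 1)
    expect_equal(out$K, 3L)     # K = 2 can only add
  }
  cmax <- list(K = 5L, medoids = 1:5, fitness = 0.3)
  for (i in 1:20) {
    out <- mutate_k(cmax, 6, rate = 1)
    expect_equal(out$K, 4L)     # K = n - 1 can only remove
  }
  expect_identical(mutate_k(c2, 6, rate = 0), c2)
})
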