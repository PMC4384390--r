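test_that("retrieval accuracy on separable classes is perfect", {
  # two classes of mutually identical motifs, positive cross-class distance
  D <- matrix(0.8, 6, 6)
  D[1:3, 1:3] <- 0; D[4:6, 4:6] <- 0; diag(D) <- 0
  dimnames(D) <- list(paste0("m", 1:6), paste0("m", 1:6))
  classes <- setNames(rep(c("X", "Y"), each = 3), rownames(D))
  rep <- retrieval_accuracy(D, classes)
  expect_equal(rep$overall_accuracy, 1)
  expect_equal(unname(rep$per_class_accuracy), c(1, 1))
  expect_equal(unname(rep$n_per_class), c(3, 3))
})

test_that("one motif per class forces zero retrieval accuracy", {
  set.seed(40)
  D <- rand_dist(4)
  classes <- setNames(paste0("c", 1:4), rownames(D))
  expect_equal(retrieval_accuracy(D, classes)$overall_accuracy, 0)
})

test_that("retrieval matches a brute-force nearest-neighbour table", {
  set.seed(41)
  pf <- planted_families(2, 3, motif_length = 9, concentration = 40)
  D <- build_distance_matrix(pf$motifs)
  rep <- retrieval_accuracy(D, pf$labels)
  hits <- vapply(seq_len(nrow(D)), function(i) {
    d <- D[i, ]; d[i] <- Inf
    pf$labels[[which.min(d)]] == pf$labels[[i]]
  }, logical(1))
  expect_equal(rep$overall_accuracy, mean(hits))
  # order invariance: permuting the matrix leaves accuracies unchanged
  perm <- sample(nrow(D))
  rep2 <- retrieval_accuracy(D[perm, perm], pf$labels)
  expect_equal(rep2$overall_accuracy, rep$overall_accuracy)
  expect_equal(rep2$per_class_accuracy[names(rep$per_class_accuracy)],
               rep$per_class_accuracy)
  expect_error(retrieval_accuracy(D, pf$labels[-1]), "missing class")
})

make_solution <- function(labels, medoids, ids = NULL) {
  # hand-built solution object for report tests
  n <- length(labels)
  if (is.null(ids)) ids <- paste0("m", seq_len(n))
  structure(list(ids = ids, K = length(medoids), medoids = medoids,
                 medoid_ids = ids[medoids], labels = medoids[labels],
                 silhouette = setNames(rep(0.5, n), ids), fitness = 0.5,
                 seed = 1L, generations = 0L),
            class = "cluster_solution")
}

test_that("homogeneity accounting categorises and weights correctly", {
  # clusters: {A,A,B} het, {C,C} hom, {B} singleton
  sol <- make_solution(c(1, 1, 1, 2, 2, 3), medoids = c(1L, 4L, 6L))
  classes <- setNames(c("A", "A", "B", "C", "C", "B"), sol$ids)
  hr <- homogeneity_report(sol, classes)
  expect_equal(hr$n_homogeneous, 1)
  expect_equal(hr$n_heterogeneous, 1)
  expect_equal(hr$n_singleton, 1)
  expect_equal(nrow(hr$clusters), sol$K)
  expect_equal(hr$clusters$purity[hr$clusters$cluster_id == 1], 2 / 3)
  expect_equal(hr$weighted_purity, (3 * (2 / 3) + 2 * 1 + 1 * 1) / 6)
  expect_false(hr$degenerate)
  # all pure, none singleton
  sol2 <- make_solution(c(1, 1, 2, 2), medoids = c(1L, 3L))
  hr2 <- homogeneity_report(sol2, setNames(c("A", "A", "B", "B"), sol2$ids))
  expect_equal(hr2$n_homogeneous, 2)
  expect_equal(hr2$weighted_purity, 1)
  # everything singleton is flagged degenerate
  sol3 <- make_solution(1:4, medoids = 1:4)
  hr3 <- homogeneity_report(sol3, setNames(rep("A", 4), sol3$ids))
  expect_equal(hr3$n_singleton, 4)
  expect_equal(hr3$weighted_purity, 1)
  expect_true(hr3$degenerate)
})

test_that("LOOCV is perfect on clusters of identical motifs", {
  set.seed(42)
  base1 <- rand_motif("b1", 8); base2 <- rand_motif("b2", 8)
  # force the two cluster archetypes well apart
  motifs <- c(lapply(1:3, function(i) motif(paste0("a", i), base1$matrix)),
              lapply(1:3, function(i) motif(paste0("b", i), base2$matrix)))
  D <- build_distance_matrix(motifs, ic_threshold = 0)
  sol <- make_solution(c(1, 1, 1, 2, 2, 2), medoids = c(1L, 4L),
                       ids = vapply(motifs, `[[`, character(1), "id"))
  lo <- loocv_stability(motifs, sol, D, ic_threshold = 0)
  expect_equal(lo$accuracy, 1)
  expect_equal(lo$n_eligible, 6)
})

test_that("LOOCV excludes singletons and rebuilds per fold", {
  set.seed(43)
  pf <- planted_families(2, 3, motif_length = 10, concentration = 80)
  motifs <- c(pf$motifs, list(rand_motif("lone", 10)))
  D <- build_distance_matrix(motifs)
  sol <- make_solution(c(1, 1, 1, 2, 2, 2, 3), medoids = c(1L, 4L, 7L),
                       ids = vapply(motifs, `[[`, character(1), "id"))
  lo <- loocv_stability(motifs, sol, D)
  expect_equal(lo$n_eligible, 6)              # singleton is not a fold
  expect_false("lone" %in% lo$folds$motif_id)
  # all-singleton solution has nothing to validate
  sol_bad <- make_solution(1:4, medoids = 1:4,
                           ids = vapply(motifs[1:4], `[[`, character(1),
                                        "id"))
  expect_error(loocv_stability(motifs[1:4], sol_bad, D[1:4, 1:4]),
               "singleton")
})

test_that("a two-member cluster's fold reduces to the remaining member", {
  set.seed(44)
  pf <- planted_families(2, 2, motif_length = 10, concentration = 100)
  D <- build_distance_matrix(pf$motifs)
  sol <- make_solution(c(1, 1, 2, 2), medoids = c(1L, 3L),
                       ids = vapply(pf$motifs, `[[`, character(1), "id"))
  lo <- loocv_stability(pf$motifs, sol, D)
  expect_equal(lo$accuracy, 1)
})

test_that("convergence study canonicalises partitions and sums to one", {
  set.seed(45)
  pf <- planted_families(3, 4, motif_length = 10, concentration = 100)
  D <- build_distance_matrix(pf$motifs)
  cfg <- ga_config(pop_size = 30, generations = 40, seed = 100)
  tab <- convergence_study(D, cfg, n_runs = 5)
  expect_equal(sum(tab$frequency), 1)
  expect_equal(nrow(tab), 1)                 # unique easy optimum
  expect_equal(tab$frequency[1], 1)
  expect_equal(tab$K[1], 3)
  tab1 <- convergence_study(D, cfg, n_runs = 1)
  expect_equal(nrow(tab1), 1)
  expect_equal(tab1$frequency, 1)
})

test_that("partition signatures ignore which members are the medoids", {
  ids <- paste0("m", 1:4)
  s1 <- motifclust:::.partition_signature(ids, c(1, 1, 3, 3))
  s2 <- motifclust:::.partition_signature(ids, c(2, 2, 4, 4))
  expect_identical(s1, s2)
  s3 <- motifclust:::.partition_signature(ids, c(1, 1, 1, 4))
  expect_false(identical(s1, s3))
})
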