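#' Configuration for the genetic k-medoids engine
#'
#' Defaults follow the published protocol where one is stated: population
#' 100, 300 generations, mutation rate 0.05, diversity threshold 0.8,
#' bottom-5% steady-state replacement. The boosted mutation rate and the
#' linear-ranking selective pressure are engine choices exposed here.
#'
#' @param pop_size Population size (>= 2).
#' @param generations Number of steady-state iterations.
#' @param mutation_rate Per-offspring probability of a K-perturbing mutation.
#' @param boosted_mutation_rate Mutation rate used while population diversity
#'   (largest fraction sharing one K) exceeds `diversity_threshold`.
#' @param diversity_threshold Fraction triggering the mutation boost.
#' @param replace_fraction Fraction of the population replaced per
#'   generation (worst individuals).
#' @param selective_pressure Linear-ranking pressure in (1, 2].
#' @param seed Optional integer seed; a run with a seed is fully
#'   reproducible.
#' @return A `"ga_config"` list.
#' @export
ga_config <- function(pop_size = 100, generations = 300,
                      mutation_rate = 0.05, boosted_mutation_rate = 0.25,
                      diversity_threshold = 0.8, replace_fraction = 0.05,
                      selective_pressure = 1.5, seed = NULL) {
  stopifnot(pop_size >= 2, generations >= 0)
  for (r in c(mutation_rate, boosted_mutation_rate, diversity_threshold,
              replace_fraction))
    if (r < 0 || r > 1) stop("rates and thresholds must lie in [0, 1]")
  if (selective_pressure <= 1 || selective_pressure > 2)
    stop("selective_pressure must lie in (1, 2]")
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 boosted_mutation_rate = boosted_mutation_rate,
                 diversity_threshold = diversity_threshold,
                 replace_fraction = replace_fraction,
                 selective_pressure = selective_pressure,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "ga_config")
}

.new_candidate <- function(medoids) {
  list(K = length(medoids), medoids = as.integer(medoids),
       labels = NULL, sil = NULL, fitness = NA_real_)
}

#' Random initial population
#'
#' Each candidate draws its cluster count K uniformly from `{2 .. n-1}` and
#' its K medoids uniformly without replacement. Uses the current RNG state;
#' seed via [ga_config()]/[ga_cluster()] or `set.seed()` for reproducibility.
#'
#' @param n Number of motifs (>= 4).
#' @param config A [ga_config()].
#' @return List of unevaluated candidates.
#' @export
init_population <- function(n, config = ga_config()) {
  if (n < 4) stop("need at least 4 motifs (K must range over {2..n-1})")
  lapply(seq_len(config$pop_size), function(i) {
    K <- sample(2:(n - 1L), 1L)
    .new_candidate(sample.int(n, K))
  })
}

#' Assign motifs to their nearest medoid
#'
#' Ties are broken towards the lowest medoid index; each medoid is assigned
#' to itself (the diagonal of the distance matrix is zero).
#'
#' @param D Distance matrix.
#' @param medoids Integer vector of distinct motif indices (1-based).
#' @return Integer labels: for each motif, the motif index of its medoid.
#' @export
assign_to_medoids <- function(D, medoids) {
  medoids <- as.integer(medoids)
  if (anyDuplicated(medoids)) stop("medoids must be distinct")
  .assign_cpp(D, medoids - 1L) + 1L
}

#' Total configuration cost
#'
#' Sum over motifs of the distance to the owning medoid.
#'
#' @param D Distance matrix.
#' @param medoids Integer medoid indices.
#' @param labels Optional labels from [assign_to_medoids()]; computed if
#'   missing.
#' @return Nonnegative total cost.
#' @export
total_cost <- function(D, medoids, labels = NULL) {
  if (is.null(labels)) labels <- assign_to_medoids(D, medoids)
  sum(D[cbind(seq_len(nrow(D)), labels)])
}

#' One greedy swap pass of k-medoids
#'
#' Visits medoid slots in ascending order of their medoid index at the start
#' of the pass; each current non-medoid (ascending index) is tried as a
#' replacement and a swap is kept immediately whenever it strictly lowers
#' the total cost. A single pass only; the final assignment is recomputed at
#' the end. Never increases the cost.
#'
#' @param D Distance matrix.
#' @param medoids Integer medoid indices.
#' @return List with elements `medoids` and `labels`.
#' @export
kmedoids_one_round <- function(D, medoids) {
  medoids <- as.integer(medoids)
  if (anyDuplicated(medoids)) stop("medoids must be distinct")
  out <- .one_round_cpp(D, medoids - 1L) + 1L
  list(medoids = out, labels = assign_to_medoids(D, out))
}

#' Per-motif silhouette values and their mean
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where `a(i)` is the mean
#' distance of motif i to the other members of its cluster and `b(i)` the
#' smallest mean distance to another cluster. Members of singleton clusters
#' get `s(i) = 0`.
#'
#' @param D Distance matrix.
#' @param labels Cluster labels (any vector; >= 2 distinct clusters).
#' @return List with `s` (per-motif values in `[-1, 1]`) and `mean`.
#' @export
silhouette_scores <- function(D, labels) {
  codes <- as.integer(factor(labels))
  K <- max(codes)
  if (K < 2L) stop("silhouette undefined for a single cluster")
  s <- .silhouette_cpp(D, codes - 1L, K)
  list(s = as.numeric(s), mean = mean(s))
}

#' Evaluate a candidate's fitness
#'
#' Runs one k-medoids swap pass from the candidate's medoids, assigns all
#' motifs, and scores the assignment by mean silhouette. Deterministic given
#' the candidate and the distance matrix.
#'
#' @param candidate Candidate list (`K`, `medoids`).
#' @param D Distance matrix.
#' @return The candidate with improved `medoids`, cached `labels`, per-motif
#'   `sil` and `fitness`.
#' @export
evaluate_fitness <- function(candidate, D) {
  r <- kmedoids_one_round(D, candidate$medoids)
  sil <- silhouette_scores(D, r$labels)
  candidate$medoids <- r$medoids
  candidate$K <- length(r$medoids)
  candidate$labels <- r$labels
  candidate$sil <- sil$s
  candidate$fitness <- sil$mean
  candidate
}

#' Linear-ranking selection weights
#'
#' With ranks `r = 0` (worst) to `N-1` (best),
#' `w(r) = (2 - SP)/N + 2 r (SP - 1) / (N (N - 1))`. Tied fitnesses receive
#' the average of their tied ranks, hence averaged weights.
#'
#' @param fitnesses Numeric vector (length >= 2).
#' @param selective_pressure SP in (1, 2].
#' @return Probability vector summing to 1, increasing with fitness.
#' @export
rank_selection_weights <- function(fitnesses, selective_pressure = 1.5) {
  N <- length(fitnesses)
  if (N < 2L) stop("need at least 2 individuals")
  sp <- selective_pressure
  if (sp <= 1 || sp > 2) stop("selective_pressure must lie in (1, 2]")
  r <- rank(fitnesses, ties.method = "average") - 1
  (2 - sp) / N + 2 * r * (sp - 1) / (N * (N - 1))
}

#' Roulette-wheel mate selection constrained to equal K
#'
#' The first parent is drawn by roulette over the whole population; the
#' second is drawn (renormalised roulette) from the individuals sharing the
#' first parent's K, excluding the first parent. If none exists, no mate is
#' returned and crossover is skipped for this pairing.
#'
#' @param population List of evaluated candidates.
#' @param weights Selection probabilities from [rank_selection_weights()].
#' @return List with integer `i1` and `i2` (`i2` is `NA` when no mate
#'   shares K).
#' @export
select_mate_pair <- function(population, weights) {
  N <- length(population)
  i1 <- sample.int(N, 1L, prob = weights)
  K1 <- population[[i1]]$K
  pool <- setdiff(which(vapply(population, `[[`, integer(1), "K") == K1), i1)
  if (!length(pool)) return(list(i1 = i1, i2 = NA_integer_))
  i2 <- pool[sample.int(length(pool), 1L, prob = weights[pool])]
  list(i1 = i1, i2 = i2)
}

#' Uniform crossover of two same-K candidates
#'
#' Each medoid slot is sent to child 1 from parent 1 and to child 2 from
#' parent 2, or vice versa, by an independent fair coin; both children are
#' then passed through [repair_duplicates()].
#'
#' @param p1,p2 Candidates with equal `K`.
#' @param n Number of motifs (for repair).
#' @return List of two unevaluated children.
#' @export
uniform_crossover <- function(p1, p2, n) {
  if (p1$K != p2$K) stop("uniform crossover requires equal K")
  coin <- runif(p1$K) < 0.5
  c1 <- ifelse(coin, p1$medoids, p2$medoids)
  c2 <- ifelse(coin, p2$medoids, p1$medoids)
  list(repair_duplicates(.new_candidate(c1), n),
       repair_duplicates(.new_candidate(c2), n))
}

#' Replace duplicate medoids with fresh random ones
#'
#' The first occurrence of each medoid is kept; every later duplicate slot is
#' redrawn uniformly from the motif indices not currently used by the
#' candidate. K is unchanged.
#'
#' @param candidate Candidate list.
#' @param n Number of motifs.
#' @return A valid candidate with distinct medoids.
#' @export
repair_duplicates <- function(candidate, n) {
  if (candidate$K > n) stop("cannot have more medoids than motifs")
  med <- candidate$medoids
  for (s in seq_along(med)) {
    if (s > 1L && med[s] %in% med[seq_len(s - 1L)]) {
      free <- setdiff(seq_len(n), med)
      med[s] <- free[sample.int(length(free), 1L)]
    }
  }
  candidate$medoids <- as.integer(med)
  candidate$fitness <- NA_real_
  candidate$labels <- candidate$sil <- NULL
  candidate
}

#' K-perturbing mutation
#'
#' With probability `rate` the candidate either gains a cluster (one unused
#' motif appended as a medoid, allowed while `K + 1 <= n - 1`) or loses one
#' (a uniformly chosen medoid deleted, allowed while `K - 1 >= 2`); a fair
#' coin picks the direction when both are legal. Cached fitness is
#' invalidated.
#'
#' @param candidate Candidate list.
#' @param n Number of motifs.
#' @param rate Mutation probability.
#' @return Possibly mutated candidate.
#' @export
mutate_k <- function(candidate, n, rate) {
  if (rate <= 0 || runif(1) >= rate) return(candidate)
  can_add <- candidate$K + 1L <= n - 1L
  can_remove <- candidate$K - 1L >= 2L
  if (!can_add && !can_remove) return(candidate)
  add <- if (can_add && can_remove) runif(1) < 0.5 else can_add
  med <- candidate$medoids
  if (add) {
    free <- setdiff(seq_len(n), med)
    med <- c(med, free[sample.int(length(free), 1L)])
  } else {
    med <- med[-sample.int(length(med), 1L)]
  }
  out <- .new_candidate(med)
  out
}

#' Cluster motifs with the genetic k-medoids engine
#'
#' Steady-state loop: every generation the population's diversity (largest
#' fraction sharing one K) sets the effective mutation rate (boosted above
#' the diversity threshold), `ceiling(replace_fraction * pop_size)` offspring
#' are bred by linear-ranking roulette selection, same-K uniform crossover
#' (or cloning when no mate shares K), mutation and repair, each offspring is
#' evaluated (one k-medoids pass + mean silhouette), and the offspring
#' replace the worst individuals. The best candidate ever evaluated is
#' returned; with `pop_size >= 2 / replace_fraction` it is never evicted.
#'
#' @param D Distance matrix from [build_distance_matrix()] (n >= 4).
#' @param config A [ga_config()]; its `seed`, when set, makes the run
#'   deterministic.
#' @return A `"cluster_solution"`: `ids`, `K`, `medoids` (indices),
#'   `medoid_ids`, `labels` (owning-medoid index per motif), per-motif
#'   `silhouette`, `fitness` (mean silhouette), `seed`, `generations`.
#' @export
ga_cluster <- function(D, config = ga_config()) {
  n <- nrow(D)
  if (is.null(n) || n < 4) stop("need a distance matrix over >= 4 motifs")
  if (config$pop_size < 2) stop("pop_size must be >= 2")
  if (!is.null(config$seed)) set.seed(config$seed)

  pop <- init_population(n, config)
  pop <- lapply(pop, evaluate_fitness, D = D)
  best <- pop[[which.max(vapply(pop, `[[`, numeric(1), "fitness"))]]
  n_off <- as.integer(ceiling(config$replace_fraction * config$pop_size))
  n_off <- max(1L, min(n_off, config$pop_size - 1L))

  for (gen in seq_len(config$generations)) {
    fit <- vapply(pop, `[[`, numeric(1), "fitness")
    Ks <- vapply(pop, `[[`, integer(1), "K")
    diversity <- max(tabulate(Ks)) / length(pop)
    rate <- if (diversity > config$diversity_threshold)
      config$boosted_mutation_rate else config$mutation_rate
    weights <- rank_selection_weights(fit, config$selective_pressure)

    offspring <- vector("list", n_off)
    for (o in seq_len(n_off)) {
      pair <- select_mate_pair(pop, weights)
      child <- if (is.na(pair$i2)) {
        .new_candidate(pop[[pair$i1]]$medoids)
      } else {
        uniform_crossover(pop[[pair$i1]], pop[[pair$i2]], n)[[1L]]
      }
      child <- repair_duplicates(mutate_k(child, n, rate), n)
      offspring[[o]] <- evaluate_fitness(child, D)
    }

    worst <- order(fit)[seq_len(n_off)]
    pop[worst] <- offspring
    gen_best <- pop[[which.max(vapply(pop, `[[`, numeric(1), "fitness"))]]
    if (gen_best$fitness > best$fitness) best <- gen_best
  }

  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(list(ids = ids, K = best$K,
                 medoids = sort(best$medoids),
                 medoid_ids = ids[sort(best$medoids)],
                 labels = best$labels,
                 silhouette = setNames(best$sil, ids),
                 fitness = best$fitness,
                 seed = config$seed,
                 generations = config$generations),
            class = "cluster_solution")
}

#' Tabulate a clustering solution
#'
#' @param solution A `"cluster_solution"` from [ga_cluster()].
#' @return `data.frame` with columns `motif_id`, `cluster_id` (1..K, ordered
#'   by medoid index), `is_medoid`, `silhouette`.
#' @export
cluster_assignments <- function(solution) {
  cluster_id <- match(solution$labels, solution$medoids)
  data.frame(motif_id = solution$ids,
             cluster_id = cluster_id,
             is_medoid = seq_along(solution$ids) %in% solution$medoids,
             silhouette = as.numeric(solution$silhouette),
             stringsAsFactors = FALSE)
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster solution: %d motifs in K = %d clusters, fitness %.4f\n",
              length(x$ids), x$K, x$fitness))
  sizes <- table(match(x$labels, x$medoids))
  cat("cluster sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  invisible(x)
}
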