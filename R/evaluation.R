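#' Nearest-neighbour retrieval accuracy by structural class
#'
#' For every query motif the nearest other motif in the distance matrix is
#' retrieved (ties to the lowest index); the query scores a hit when the
#' neighbour shares its structural class. Accuracy is reported per class and
#' overall (the size-weighted mean).
#'
#' @param D Distance matrix with motif ids as dimnames.
#' @param classes Named character vector mapping every id to its class.
#' @return `"retrieval_report"`: `per_class_accuracy`, `overall_accuracy`,
#'   `n_per_class`.
#' @export
retrieval_accuracy <- function(D, classes) {
  ids <- rownames(D)
  n <- length(ids)
  if (n < 2) stop("need at least 2 motifs")
  missing <- setdiff(ids, names(classes))
  if (length(missing))
    stop("missing class label(s) for: ", paste(missing, collapse = ", "))
  cls <- classes[ids]
  hit <- logical(n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    hit[i] <- cls[which.min(d)] == cls[i]   # which.min takes the lowest index
  }
  per <- tapply(hit, cls, mean)
  nper <- tapply(hit, cls, length)
  structure(list(per_class_accuracy = setNames(as.numeric(per), names(per)),
                 overall_accuracy = mean(hit),
                 n_per_class = setNames(as.integer(nper), names(nper))),
            class = "retrieval_report")
}

#' Structural homogeneity accounting of a clustering
#'
#' Each cluster's purity is the fraction of its members carrying the majority
#' class. Clusters are categorised as homogeneous (size >= 2, purity 1),
#' singleton (size 1), or heterogeneous. The weighted purity (the cluster
#' structural homogeneity score used by the noise benchmark) is the
#' size-weighted mean purity.
#'
#' @param solution A `"cluster_solution"` from [ga_cluster()].
#' @param classes Named character vector id -> class.
#' @return `"homogeneity_report"`: per-cluster `clusters` data frame,
#'   category counts, `weighted_purity`, and `degenerate` (TRUE when every
#'   cluster is a singleton).
#' @export
homogeneity_report <- function(solution, classes) {
  ids <- solution$ids
  missing <- setdiff(ids, names(classes))
  if (length(missing))
    stop("missing class label(s) for: ", paste(missing, collapse = ", "))
  cl <- match(solution$labels, solution$medoids)
  rows <- lapply(sort(unique(cl)), function(c) {
    members <- classes[ids[cl == c]]
    tab <- sort(table(members), decreasing = TRUE)
    size <- length(members)
    purity <- as.integer(tab[1]) / size
    data.frame(cluster_id = c, size = size,
               majority_class = names(tab)[1], purity = purity,
               category = if (size == 1L) "singleton"
                          else if (purity == 1) "homogeneous"
                          else "heterogeneous",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(clusters = tab,
                 n_homogeneous = sum(tab$category == "homogeneous"),
                 n_heterogeneous = sum(tab$category == "heterogeneous"),
                 n_singleton = sum(tab$category == "singleton"),
                 weighted_purity = sum(tab$size * tab$purity) / length(ids),
                 degenerate = all(tab$size == 1L)),
            class = "homogeneity_report")
}

# canonical, medoid-independent key for a partition: clusters as sorted id
# strings, sorted among themselves
.partition_signature <- function(ids, labels) {
  groups <- split(ids, labels)
  paste(sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
                    character(1))), collapse = " | ")
}

#' Leave-one-out cross-validation of FBP stability
#'
#' Every motif belonging to a non-singleton cluster is held out in turn; the
#' FBPs of all clusters are rebuilt from the remaining motifs (the held-out
#' motif's cluster loses one member; a cluster emptied by the removal is
#' dropped for that fold; if the medoid itself was removed, the remaining
#' member with the smallest summed within-cluster distance re-anchors the
#' profile) and the held-out motif is re-classified with
#' [classify_to_fbps()]. Accuracy is the fraction of held-out motifs returned
#' to their original cluster; singleton-cluster motifs are excluded from the
#' denominator.
#'
#' @param motifs List of [motif()] objects matching `solution$ids`.
#' @param solution A `"cluster_solution"`.
#' @param D Distance matrix used for the clustering (rebuilt if omitted).
#' @param coverage_fraction,min_overlap FBP parameters, see [build_fbp()].
#' @param k,ic_threshold,min_core,strand_policy Feature parameters.
#' @return List: `accuracy`, `n_eligible`, `n_correct`, per-fold `folds`
#'   data frame.
#' @export
loocv_stability <- function(motifs, solution, D = NULL,
                            coverage_fraction = 0.5, min_overlap = 4,
                            k = 4, ic_threshold = 0.3, min_core = 4,
                            strand_policy = "both") {
  ids <- vapply(motifs, `[[`, character(1), "id")
  if (!setequal(ids, solution$ids))
    stop("motifs do not match the solution's ids")
  motifs <- motifs[match(solution$ids, ids)]
  trimmed <- lapply(motifs, trim_motif, ic_threshold = ic_threshold,
                    min_core = min_core)
  if (is.null(D))
    D <- build_distance_matrix(motifs, k, ic_threshold, min_core,
                               strand_policy)
  cl <- match(solution$labels, solution$medoids)
  sizes <- table(cl)
  eligible <- which(cl %in% as.integer(names(sizes)[sizes > 1L]))
  if (!length(eligible))
    stop("all clusters are singletons; nothing to cross-validate")

  fold_results <- lapply(eligible, function(i) {
    fbps <- list()
    for (c in sort(unique(cl))) {
      members <- setdiff(which(cl == c), i)
      if (!length(members)) next
      anchor_idx <- solution$medoids[c]
      if (anchor_idx == i) {
        within <- D[members, members, drop = FALSE]
        anchor_idx <- members[which.min(rowSums(within))]
      }
      fbps[[length(fbps) + 1L]] <-
        build_fbp(trimmed[members], trimmed[[anchor_idx]],
                  coverage_fraction, min_overlap, cluster_id = c)
    }
    hit <- classify_to_fbps(trimmed[[i]], fbps, k, ic_threshold, min_core,
                            strand_policy)
    data.frame(motif_id = solution$ids[i], true_cluster = cl[i],
               assigned_cluster = as.integer(hit$cluster_id),
               correct = hit$cluster_id == cl[i],
               stringsAsFactors = FALSE)
  })
  folds <- do.call(rbind, fold_results)
  list(accuracy = mean(folds$correct), n_eligible = nrow(folds),
       n_correct = sum(folds$correct), folds = folds)
}

#' Convergence profile over repeated runs
#'
#' Runs the engine `n_runs` times with distinct derived seeds and tallies
#' the distinct partitions found (keyed by a canonical medoid-independent
#' signature). The mean silhouette of a partition does not depend on which
#' members are medoids, so each signature carries a single fitness.
#'
#' @param D Distance matrix.
#' @param config A [ga_config()]; its seed is the master seed the run seeds
#'   are derived from (seed + run index).
#' @param n_runs Number of independent runs (>= 1).
#' @return `data.frame` (`signature`, `K`, `frequency`, `fitness`, `runs`)
#'   sorted by decreasing frequency; frequencies sum to 1.
#' @export
convergence_study <- function(D, config = ga_config(), n_runs = 10) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  base <- if (is.null(config$seed)) 0L else config$seed
  ids <- rownames(D)
  recs <- lapply(seq_len(n_runs), function(r) {
    cfg <- config
    cfg$seed <- (base + r) %% .Machine$integer.max
    sol <- ga_cluster(D, cfg)
    data.frame(signature = .partition_signature(sol$ids, sol$labels),
               K = sol$K, fitness = sol$fitness, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, recs)
  agg <- do.call(rbind, lapply(split(all, all$signature), function(g)
    data.frame(signature = g$signature[1], K = g$K[1],
               frequency = nrow(g) / n_runs, fitness = g$fitness[1],
               runs = nrow(g), stringsAsFactors = FALSE)))
  agg <- agg[order(-agg$frequency, agg$signature), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
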