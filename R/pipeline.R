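#' End-to-end clustering pipeline
#'
#' Trims the motifs, builds the KFV cosine-distance matrix, runs the genetic
#' k-medoids engine, constructs one FBP per cluster (from the trimmed
#' members, anchored on the medoid), and writes `clusters.tsv`, the FBP file
#' and a reproducibility log to `out_dir`.
#'
#' @param motifs List of [motif()] objects (>= 4).
#' @param out_dir Output directory (created if missing).
#' @param config A [ga_config()].
#' @param k,ic_threshold,min_core,strand_policy Feature parameters.
#' @param coverage_fraction,min_overlap FBP parameters.
#' @param fbp_format Format for the FBP export (`"jaspar_pfm"` or
#'   `"transfac"`).
#' @return Invisibly, list with `solution`, `fbps`, `distance_matrix`, and
#'   the written `paths`.
#' @export
cmd_cluster <- function(motifs, out_dir, config = ga_config(), k = 4,
                        ic_threshold = 0.3, min_core = 4,
                        strand_policy = "both", coverage_fraction = 0.5,
                        min_overlap = 4, fbp_format = "jaspar_pfm") {
  if (length(motifs) < 4)
    stop("need at least 4 motifs to cluster (K ranges over {2..n-1})")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  D <- build_distance_matrix(motifs, k, ic_threshold, min_core,
                             strand_policy)
  solution <- ga_cluster(D, config)

  trimmed <- lapply(motifs, trim_motif, ic_threshold = ic_threshold,
                    min_core = min_core)
  cl <- match(solution$labels, solution$medoids)
  fbps <- lapply(sort(unique(cl)), function(c)
    build_fbp(trimmed[cl == c], trimmed[[solution$medoids[c]]],
              coverage_fraction, min_overlap, cluster_id = c))

  clusters_path <- file.path(out_dir, "clusters.tsv")
  utils::write.table(cluster_assignments(solution), clusters_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ext <- if (fbp_format == "jaspar_pfm") "pfm" else "transfac"
  fbp_path <- file.path(out_dir, paste0("fbps.", ext))
  write_motifs(lapply(fbps, function(f)
    motif(sprintf("cluster_%d", f$cluster_id), f$matrix)),
    fbp_path, fbp_format)

  log_path <- file.path(out_dir, "run.log")
  writeLines(c(
    sprintf("n_motifs: %d", length(motifs)),
    sprintf("seed: %s", if (is.null(config$seed)) "none" else config$seed),
    sprintf("pop_size: %d  generations: %d", config$pop_size,
            config$generations),
    sprintf("mutation_rate: %g  boosted: %g  diversity_threshold: %g",
            config$mutation_rate, config$boosted_mutation_rate,
            config$diversity_threshold),
    sprintf("replace_fraction: %g  selective_pressure: %g",
            config$replace_fraction, config$selective_pressure),
    sprintf("k: %d  ic_threshold: %g  min_core: %d  strand: %s",
            k, ic_threshold, min_core, strand_policy),
    sprintf("coverage_fraction: %g  min_overlap: %d", coverage_fraction,
            min_overlap),
    sprintf("best_K: %d  best_fitness: %.6f", solution$K,
            solution$fitness)), log_path)

  invisible(list(solution = solution, fbps = fbps, distance_matrix = D,
                 paths = c(clusters = clusters_path, fbps = fbp_path,
                           log = log_path)))
}

#' Retrieval-accuracy pipeline
#'
#' Builds the distance matrix and writes the per-class and overall
#' nearest-neighbour retrieval accuracies to `retrieval.tsv`.
#'
#' @inheritParams cmd_cluster
#' @param classes Named character vector id -> structural class.
#' @return Invisibly, the [retrieval_accuracy()] report and path.
#' @export
cmd_retrieval <- function(motifs, classes, out_dir, k = 4,
                          ic_threshold = 0.3, min_core = 4,
                          strand_policy = "both") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  D <- build_distance_matrix(motifs, k, ic_threshold, min_core,
                             strand_policy)
  rep <- retrieval_accuracy(D, classes)
  tab <- data.frame(class = c(names(rep$per_class_accuracy), "overall"),
                    n = c(as.integer(rep$n_per_class), nrow(D)),
                    accuracy = c(rep$per_class_accuracy,
                                 rep$overall_accuracy))
  path <- file.path(out_dir, "retrieval.tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(report = rep, path = path))
}

#' Noise-robustness benchmark
#'
#' Generates noise-convolved replicate datasets at each signal weight,
#' clusters every replicate, scores it against the class labels with
#' [homogeneity_report()], and writes one row per (weight, replicate) to
#' `noise.tsv`.
#'
#' @inheritParams cmd_retrieval
#' @param weights Signal fractions (descending, in `(0, 1]`).
#' @param replicates Replicates per weight.
#' @param config A [ga_config()]; the master seed derives the per-replicate
#'   generation and clustering seeds.
#' @return Invisibly, the results `data.frame` and path.
#' @export
cmd_noise_benchmark <- function(motifs, classes, out_dir,
                                weights = c(0.9, 0.8, 0.7, 0.6, 0.5),
                                replicates = 10, config = ga_config(),
                                k = 4, ic_threshold = 0.3, min_core = 4,
                                strand_policy = "both") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- if (is.null(config$seed)) 0L else config$seed
  set.seed(base)
  series <- noise_series(motifs, weights, replicates)
  orig_ids <- vapply(motifs, `[[`, character(1), "id")
  rows <- list()
  run <- 0L
  for (w in names(series)) {
    for (r in seq_along(series[[w]])) {
      run <- run + 1L
      cfg <- config
      cfg$seed <- (base + run) %% .Machine$integer.max
      noisy <- series[[w]][[r]]
      # convolved ids carry a weight suffix; classes follow the input order
      cls <- setNames(classes[orig_ids],
                      vapply(noisy, `[[`, character(1), "id"))
      D <- build_distance_matrix(noisy, k, ic_threshold,
                                 min_core, strand_policy)
      sol <- ga_cluster(D, cfg)
      hr <- homogeneity_report(sol, cls)
      rows[[run]] <- data.frame(weight = as.numeric(w), replicate = r,
                                K = sol$K, fitness = sol$fitness,
                                weighted_purity = hr$weighted_purity,
                                n_homogeneous = hr$n_homogeneous,
                                n_heterogeneous = hr$n_heterogeneous,
                                n_singleton = hr$n_singleton)
    }
  }
  tab <- do.call(rbind, rows)
  path <- file.path(out_dir, "noise.tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(results = tab, path = path))
}

#' Convergence-profile pipeline
#'
#' Clusters the same motif set `n_runs` times with derived seeds and writes
#' the distribution of distinct partitions to `convergence.tsv`.
#'
#' @inheritParams cmd_cluster
#' @param n_runs Number of repeated runs.
#' @return Invisibly, the [convergence_study()] table and path.
#' @export
cmd_convergence <- function(motifs, out_dir, n_runs = 10,
                            config = ga_config(), k = 4,
                            ic_threshold = 0.3, min_core = 4,
                            strand_policy = "both") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  D <- build_distance_matrix(motifs, k, ic_threshold, min_core,
                             strand_policy)
  tab <- convergence_study(D, config, n_runs)
  out <- cbind(signature_hash =
                 vapply(tab$signature, function(s)
                   sprintf("%08x", sum(utf8ToInt(s) *
                                       seq_along(utf8ToInt(s))) %% 0xffffffff),
                   character(1), USE.NAMES = FALSE),
               tab[, c("K", "frequency", "fitness", "runs")])
  path <- file.path(out_dir, "convergence.tsv")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(results = tab, path = path))
}
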