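#' Pool of motif columns
#'
#' Stacks the position rows of a motif set into one matrix, the sampling
#' pool for random (noise) motif generation.
#'
#' @param motifs List of [motif()] objects.
#' @return `N x 4` matrix of probability rows.
#' @export
column_pool <- function(motifs) {
  .check_motif_list(motifs)
  do.call(rbind, lapply(motifs, `[[`, "matrix"))
}

#' Random motif from a column pool
#'
#' Draws `length` columns i.i.d. uniformly with replacement from the pool.
#' Uses the current RNG state.
#'
#' @param pool Matrix from [column_pool()] (or any `N x 4` stochastic
#'   matrix).
#' @param length Number of positions.
#' @param id Identifier for the generated motif.
#' @return A [motif()].
#' @export
random_motif_from_pool <- function(pool, length, id = "random") {
  pool <- as.matrix(pool)
  if (!nrow(pool)) stop("empty column pool")
  motif(id, pool[sample.int(nrow(pool), length, replace = TRUE), ,
                 drop = FALSE])
}

#' Convolve a motif with a noise motif
#'
#' Entrywise convex combination `w * signal + (1 - w) * noise`; rows stay
#' stochastic. The id gains a weight suffix.
#'
#' @param signal,noise Equal-length [motif()] objects.
#' @param w Signal fraction in `[0, 1]`.
#' @return The blended [motif()] (class label of the signal preserved).
#' @export
convolve_motifs <- function(signal, noise, w) {
  validate_motif(signal); validate_motif(noise)
  if (motif_length(signal) != motif_length(noise))
    stop("signal and noise motifs must have equal length")
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  motif(sprintf("%s_w%g", signal$id, w),
        w * signal$matrix + (1 - w) * noise$matrix,
        name = signal$name, structural_class = signal$structural_class)
}

#' Noise-convolved replicate datasets
#'
#' For each signal weight and each replicate, every input motif is blended
#' with a fresh noise motif of its own length sampled from the pool of all
#' input columns. Defaults follow the robustness protocol: signal fractions
#' 0.9 down to 0.5, ten replicates per fraction.
#'
#' @param motifs Input motif list.
#' @param weights Signal fractions, sorted descending, each in `(0, 1]`.
#' @param replicates Replicate datasets per weight.
#' @return Named list (one element per weight, names like `"0.9"`), each a
#'   list of `replicates` motif lists.
#' @export
noise_series <- function(motifs, weights = c(0.9, 0.8, 0.7, 0.6, 0.5),
                         replicates = 10) {
  .check_motif_list(motifs)
  if (any(weights <= 0 | weights > 1)) stop("weights must lie in (0, 1]")
  if (is.unsorted(rev(weights))) stop("weights must be sorted descending")
  pool <- column_pool(motifs)
  out <- lapply(weights, function(w)
    lapply(seq_len(replicates), function(r)
      lapply(motifs, function(m)
        convolve_motifs(m, random_motif_from_pool(pool, motif_length(m),
                                                  paste0(m$id, "_noise")),
                        w))))
  names(out) <- as.character(weights)
  out
}

# one Dirichlet draw with shape alpha (length 4)
.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Planted motif families with known ground truth
#'
#' Per family a seed motif of sharply peaked random columns is drawn
#' (Dirichlet(0.2) columns); seed sets are resampled until all pairwise KFV
#' cosine distances exceed `separation_floor`. Members perturb every seed
#' column with a Dirichlet draw centred on it (`concentration` times the
#' seed column; larger = tighter; `Inf` copies the seed exactly) and are
#' optionally shifted by up to `max_shift` positions with uniform-column
#' padding. The family is recorded as the member's `structural_class`.
#'
#' @param n_families Number of families (>= 2).
#' @param members_per_family Members per family (>= 1).
#' @param motif_length Positions per motif.
#' @param concentration Within-family tightness (> 0, or `Inf`).
#' @param max_shift Maximum absolute shift in positions.
#' @param separation_floor Minimum pairwise seed KFV cosine distance.
#' @param k Word length for the separation check.
#' @return List with `motifs` (list of [motif()], ids `F<f>_M<j>`),
#'   `labels` (named character, id -> family), `seeds` (the family seed
#'   motifs).
#' @export
planted_families <- function(n_families = 3, members_per_family = 8,
                             motif_length = 10, concentration = 50,
                             max_shift = 0, separation_floor = 0.5, k = 4) {
  if (n_families < 2) stop("need at least 2 families")
  if (members_per_family < 1) stop("need at least 1 member per family")
  if (concentration <= 0) stop("concentration must be > 0")

  draw_seed <- function(f) {
    mat <- t(vapply(seq_len(motif_length),
                    function(i) .rdirichlet1(rep(0.2, 4)), numeric(4)))
    motif(sprintf("F%d_seed", f), mat)
  }
  seeds <- NULL
  for (attempt in seq_len(1000L)) {
    cand <- lapply(seq_len(n_families), draw_seed)
    kfvs <- lapply(cand, kfv, k = k)
    ok <- TRUE
    for (a in seq_len(n_families - 1L))
      for (b in (a + 1L):n_families)
        if (cosine_distance(kfvs[[a]], kfvs[[b]]) <= separation_floor)
          ok <- FALSE
    if (ok) { seeds <- cand; break }
  }
  if (is.null(seeds))
    stop("could not draw ", n_families, " seeds with pairwise KFV distance > ",
         separation_floor, " in 1000 attempts; try longer motifs")

  motifs <- list()
  labels <- character()
  for (f in seq_len(n_families)) {
    for (j in seq_len(members_per_family)) {
      mat <- if (is.infinite(concentration)) seeds[[f]]$matrix else
        t(apply(seeds[[f]]$matrix, 1L, function(col)
          .rdirichlet1(concentration * col + 1e-3)))
      if (max_shift > 0) {
        s <- sample(seq.int(-max_shift, max_shift), 1L)
        if (s != 0) {
          uni <- matrix(0.25, abs(s), 4L)
          mat <- if (s > 0) rbind(uni, mat[seq_len(nrow(mat) - s), ,
                                           drop = FALSE])
                 else rbind(mat[(1 - s):nrow(mat), , drop = FALSE], uni)
        }
      }
      id <- sprintf("F%d_M%d", f, j)
      fam <- sprintf("F%d", f)
      motifs[[length(motifs) + 1L]] <-
        motif(id, mat, structural_class = fam)
      labels[id] <- fam
    }
  }
  list(motifs = motifs, labels = labels, seeds = seeds)
}
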