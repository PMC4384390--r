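#' Best ungapped placement of one motif against an anchor
#'
#' Slides the member across the anchor in both orientations and scores every
#' placement with at least `min_overlap` overlapping columns by the sum of
#' per-column Pearson correlations between the two probability 4-vectors.
#' Columns where either profile has zero variance (e.g. the uniform column)
#' contribute 0. The highest-scoring placement wins; ties prefer the smaller
#' absolute offset, then the forward orientation.
#'
#' @param member,anchor [motif()] objects.
#' @param min_overlap Minimum number of shared columns (default 4).
#' @return List (class `"member_alignment"`): `member_id`, `offset` (member
#'   start relative to anchor start, 0-based), `reversed`, `score`.
#' @export
align_pair <- function(member, anchor, min_overlap = 4) {
  validate_motif(member); validate_motif(anchor)
  lm <- nrow(member$matrix); la <- nrow(anchor$matrix)
  if (min(lm, la) < min_overlap)
    stop(sprintf("no placement of '%s' on '%s' reaches overlap %d",
                 member$id, anchor$id, min_overlap))
  offsets <- seq.int(-(lm - min_overlap), la - min_overlap)
  best <- NULL
  for (rev_flag in c(FALSE, TRUE)) {
    mm <- if (rev_flag) .rc_matrix(member$matrix) else member$matrix
    for (off in offsets) {
      a_cols <- max(1L, off + 1L):min(la, off + lm)
      m_cols <- a_cols - off
      score <- 0
      for (t in seq_along(a_cols)) {
        x <- mm[m_cols[t], ]; y <- anchor$matrix[a_cols[t], ]
        if (stats::sd(x) > 0 && stats::sd(y) > 0)
          score <- score + stats::cor(x, y)
      }
      cand <- list(score = score, offset = off, reversed = rev_flag)
      if (is.null(best) ||
          score > best$score + 1e-12 ||
          (abs(score - best$score) <= 1e-12 &&
           (abs(off) < abs(best$offset) ||
            (abs(off) == abs(best$offset) && best$reversed && !rev_flag))))
        best <- cand
    }
  }
  structure(list(member_id = member$id, offset = as.integer(best$offset),
                 reversed = best$reversed, score = best$score),
            class = "member_alignment")
}

#' Build a familial binding profile for one cluster
#'
#' Star-aligns every member to the medoid with [align_pair()], lays the
#' oriented members out on the padded common frame, and averages the
#' probabilities of the members covering each column. End columns covered by
#' fewer than `coverage_fraction` of the members are dropped (comparison is
#' `>=`, so exactly the fraction is kept); interior low-coverage columns are
#' retained and flagged so the frame stays contiguous.
#'
#' @param cluster_members List of [motif()] objects (the medoid among them).
#' @param medoid The anchor [motif()].
#' @param coverage_fraction Minimum member coverage for edge columns
#'   (default 0.5).
#' @param min_overlap Passed to [align_pair()].
#' @param cluster_id Optional identifier stored in the profile.
#' @return Object of class `"fbp"`: `cluster_id`, `matrix` (row-stochastic),
#'   `members` (list of alignments), `support` (per-column coverage counts),
#'   `low_coverage` (logical flags for retained interior columns below the
#'   threshold).
#' @export
build_fbp <- function(cluster_members, medoid, coverage_fraction = 0.5,
                      min_overlap = 4, cluster_id = NA) {
  if (!length(cluster_members)) stop("cluster has no members")
  sig <- vapply(cluster_members, function(m)
    paste(m$id, paste(signif(m$matrix, 12), collapse = ",")), character(1))
  cluster_members <- cluster_members[!duplicated(sig)]
  alns <- lapply(cluster_members, align_pair, anchor = medoid,
                 min_overlap = min_overlap)
  lens <- vapply(cluster_members, motif_length, integer(1))
  offs <- vapply(alns, `[[`, integer(1), "offset")
  lo <- min(offs)
  hi <- max(offs + lens - 1L)
  width <- hi - lo + 1L
  nmem <- length(cluster_members)

  acc <- matrix(0, width, 4L)
  cov <- integer(width)
  for (i in seq_len(nmem)) {
    mm <- if (alns[[i]]$reversed) .rc_matrix(cluster_members[[i]]$matrix)
          else cluster_members[[i]]$matrix
    rows <- (offs[i] - lo + 1L):(offs[i] - lo + lens[i])
    acc[rows, ] <- acc[rows, ] + mm
    cov[rows] <- cov[rows] + 1L
  }
  prof <- acc / cov
  ok <- cov >= coverage_fraction * nmem
  keep_lo <- 1L
  while (keep_lo < width && !ok[keep_lo]) keep_lo <- keep_lo + 1L
  keep_hi <- width
  while (keep_hi > keep_lo && !ok[keep_hi]) keep_hi <- keep_hi - 1L
  keep <- keep_lo:keep_hi
  prof <- prof[keep, , drop = FALSE]
  colnames(prof) <- ALPHABET
  structure(list(cluster_id = cluster_id,
                 matrix = prof,
                 members = alns,
                 support = cov[keep],
                 low_coverage = !ok[keep]),
            class = "fbp")
}

#' @export
print.fbp <- function(x, ...) {
  cat(sprintf("FBP '%s': %d columns from %d members\n",
              as.character(x$cluster_id), nrow(x$matrix), length(x$members)))
  invisible(x)
}

#' Assign a motif to its nearest familial binding profile
#'
#' Each FBP's matrix is treated as a motif, trimmed, and embedded as a KFV;
#' the query motif (same treatment) is assigned to the FBP with the smallest
#' cosine distance, ties to the earliest profile in the list.
#'
#' @param m Query [motif()].
#' @param fbps List of `"fbp"` objects.
#' @param k,ic_threshold,min_core,strand_policy Feature parameters, as used
#'   for clustering.
#' @return List with `cluster_id` (of the winning FBP), `index` (position in
#'   `fbps`) and `distance`.
#' @export
classify_to_fbps <- function(m, fbps, k = 4, ic_threshold = 0.3,
                             min_core = 4, strand_policy = "both") {
  if (!length(fbps)) stop("no FBPs supplied")
  q <- kfv(trim_motif(m, ic_threshold, min_core), k, strand_policy)
  d <- vapply(seq_along(fbps), function(i) {
    fm <- motif(paste0("fbp_", i), fbps[[i]]$matrix)
    cosine_distance(q, kfv(trim_motif(fm, ic_threshold, min_core), k,
                           strand_policy))
  }, numeric(1))
  best <- which.min(d)
  list(cluster_id = fbps[[best]]$cluster_id, index = best,
       distance = d[best])
}
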