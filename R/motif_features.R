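#' Information content of one motif column, in bits
#'
#' `I = 2 + sum_j p_j log2(p_j)` with the convention `0 log2(0) = 0`. A
#' uniform column scores 0 bits, a pure column 2 bits.
#'
#' @param column Numeric 4-vector of probabilities summing to 1.
#' @return Value in `[0, 2]`.
#' @examples
#' information_content(c(0.25, 0.25, 0.25, 0.25))  # 0
#' information_content(c(1, 0, 0, 0))              # 2
#' @export
information_content <- function(column) {
  if (length(column) != 4L || anyNA(column) ||
      any(column < -1e-12) || any(column > 1 + 1e-12) ||
      abs(sum(column) - 1) > 1e-6)
    stop("column must be a 4-vector of probabilities summing to 1")
  p <- column[column > 0]
  max(0, min(2, 2 + sum(p * log2(p))))
}

# per-position IC of a motif matrix
.column_ic <- function(mat) apply(mat, 1L, information_content)

#' Trim uninformative motif edges
#'
#' Repeatedly removes the end column (first or last position) whose
#' information content is the lower of the two, while that IC is below
#' `ic_threshold` and the motif is longer than `min_core`; ties between the
#' two ends remove the left end. Motifs of length `<= min_core` are returned
#' unchanged. Only edge columns are ever removed, so the surviving span is
#' contiguous.
#'
#' @param m A [motif()].
#' @param ic_threshold IC cutoff in bits (default 0.3).
#' @param min_core Minimum retained length (default 4).
#' @return The trimmed motif (class label and id preserved).
#' @export
trim_motif <- function(m, ic_threshold = 0.3, min_core = 4) {
  validate_motif(m)
  lo <- 1L
  hi <- nrow(m$matrix)
  if (hi - lo + 1L <= min_core) return(m)
  ic <- .column_ic(m$matrix)
  while (hi - lo + 1L > min_core) {
    end <- if (ic[lo] <= ic[hi]) "l" else "r"   # tie -> trim the left end
    worst <- min(ic[lo], ic[hi])
    if (worst >= ic_threshold) break
    if (end == "l") lo <- lo + 1L else hi <- hi - 1L
  }
  if (lo == 1L && hi == nrow(m$matrix)) return(m)
  m$matrix <- m$matrix[lo:hi, , drop = FALSE]
  m$source_counts <- if (!is.null(m$source_counts))
    m$source_counts[lo:hi, , drop = FALSE] else NULL
  m
}

#' All k-mers in lexicographic order (A < C < G < T)
#'
#' @param k Word length.
#' @return Character vector of length `4^k`.
#' @export
kmer_names <- function(k) {
  words <- ""
  for (j in seq_len(k))
    words <- as.vector(t(outer(words, ALPHABET, paste0)))
  words
}

# expected counts of all 4^k words across the windows of a probability
# matrix, forward strand only; index varies last letter fastest
.kfv_forward <- function(mat, k) {
  l <- nrow(mat)
  v <- numeric(4^k)
  for (i in seq_len(l - k + 1L)) {
    p <- mat[i, ]
    for (j in seq_len(k - 1L))
      p <- rep(p, each = 4L) * rep.int(mat[i + j, ], length(p))
    v <- v + p
  }
  v
}

#' k-mer frequency vector of a motif
#'
#' Embeds a motif as the vector of expected k-mer counts under the
#' per-position independence model: for each word `w` and each length-`k`
#' window the product of the matching matrix entries, summed over windows.
#' Under the default both-strand policy the forward vector of the motif is
#' added to the forward vector of its reverse complement, making the
#' embedding strand-invariant. The entries sum to
#' `strands * (l - k + 1)` exactly.
#'
#' @param m A [motif()] (normally trimmed first).
#' @param k Word length (default 4).
#' @param strand_policy `"both"` (default) or `"forward"`.
#' @return Object of class `"kfv"`: list with `motif_id`, `k`, and `values`
#'   (named numeric of length `4^k`, lexicographic A < C < G < T order).
#' @export
kfv <- function(m, k = 4, strand_policy = c("both", "forward")) {
  strand_policy <- match.arg(strand_policy)
  validate_motif(m)
  if (k < 1) stop("k must be >= 1")
  if (nrow(m$matrix) < k)
    stop(sprintf("motif '%s' has length %d < k = %d; lower k or skip trimming",
                 m$id, nrow(m$matrix), k))
  v <- .kfv_forward(m$matrix, k)
  if (strand_policy == "both")
    v <- v + .kfv_forward(.rc_matrix(m$matrix), k)
  structure(list(motif_id = m$id, k = k,
                 values = setNames(v, kmer_names(k))),
            class = "kfv")
}

.kfv_values <- function(x) {
  if (inherits(x, "kfv")) x$values else as.numeric(x)
}

#' Cosine distance between two k-mer frequency vectors
#'
#' `d = 1 - a.b / (|a| |b|)`; 0 for identical directions, 1 for orthogonal
#' supports. Defined for nonnegative nonzero vectors, hence bounded in
#' `[0, 1]`.
#'
#' @param a,b `"kfv"` objects (or bare numeric vectors) of the same length.
#' @return Distance in `[0, 1]`.
#' @export
cosine_distance <- function(a, b) {
  va <- .kfv_values(a); vb <- .kfv_values(b)
  if (length(va) != length(vb))
    stop("vectors have different lengths (mismatched k?)")
  na <- sqrt(sum(va * va)); nb <- sqrt(sum(vb * vb))
  if (na == 0 || nb == 0) stop("cosine distance undefined for a zero vector")
  min(1, max(0, 1 - sum(va * vb) / (na * nb)))
}

#' Pairwise cosine-distance matrix over a motif set
#'
#' Trims each motif, computes its KFV, and fills the symmetric matrix of
#' pairwise cosine distances. The matrix is computed once up front and never
#' updated during clustering.
#'
#' @param motifs List of [motif()] objects (at least 2, unique ids).
#' @param k Word length (default 4).
#' @param ic_threshold,min_core Trimming parameters, see [trim_motif()].
#' @param strand_policy See [kfv()].
#' @return Symmetric `n x n` numeric matrix with motif ids as dimnames, zero
#'   diagonal, entries in `[0, 1]`; attribute `"k"` records the word length.
#' @export
build_distance_matrix <- function(motifs, k = 4, ic_threshold = 0.3,
                                  min_core = 4,
                                  strand_policy = c("both", "forward")) {
  strand_policy <- match.arg(strand_policy)
  if (length(motifs) < 2L) stop("need at least 2 motifs")
  ids <- .check_motif_list(motifs)
  kfvs <- lapply(motifs, function(m)
    kfv(trim_motif(m, ic_threshold, min_core), k, strand_policy)$values)
  V <- do.call(rbind, kfvs)
  norms <- sqrt(rowSums(V * V))
  if (any(norms == 0)) stop("zero KFV for motif(s): ",
                            paste(ids[norms == 0], collapse = ", "))
  S <- (V %*% t(V)) / outer(norms, norms)
  D <- 1 - S
  D[D < 0] <- 0
  D[D > 1] <- 1
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  attr(D, "k") <- k
  D
}

#' Export a distance matrix as TSV
#'
#' @param D Matrix from [build_distance_matrix()].
#' @param path Output file: a header row of ids then the square numeric body.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  utils::write.table(as.data.frame(D), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Export KFVs as TSV
#'
#' One row per motif; columns are `motif_id` then the `4^k` k-mers.
#'
#' @param kfvs List of `"kfv"` objects with a common `k`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_kfvs <- function(kfvs, path) {
  tab <- data.frame(motif_id = vapply(kfvs, `[[`, character(1), "motif_id"),
                    do.call(rbind, lapply(kfvs, `[[`, "values")),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
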