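#' Construct a motif
#'
#' A motif is a position probability matrix over the DNA alphabet together
#' with an identifier and an optional structural-class label. The matrix has
#' one row per position and four columns in fixed order A, C, G, T; every row
#' is a probability distribution.
#'
#' @param id Character scalar, unique identifier.
#' @param matrix Numeric `l x 4` matrix of per-position probabilities
#'   (columns A, C, G, T). Each row must sum to 1 within `1e-6`.
#' @param name Optional display name.
#' @param structural_class Optional structural-class label (e.g. `"bHLH"`,
#'   `"C2H2"`); used only by the evaluation harnesses.
#' @param source_counts Optional `l x 4` nonnegative count matrix the
#'   probabilities were derived from.
#' @return An object of class `"motif"`.
#' @examples
#' m <- motif("ex1", rbind(c(1, 0, 0, 0), c(0, 0.5, 0.5, 0)))
#' motif_length(m)
#' @export
motif <- function(id, matrix, name = NULL, structural_class = NULL,
                  source_counts = NULL) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  colnames(matrix) <- ALPHABET
  rownames(matrix) <- NULL
  m <- structure(
    list(id = as.character(id), name = name,
         structural_class = structural_class,
         matrix = matrix, source_counts = source_counts),
    class = "motif"
  )
  validate_motif(m)
  m
}

#' Validate a motif object
#'
#' Checks the motif invariants: at least one position, entries in `[0, 1]`,
#' rows summing to 1 within `1e-6`.
#'
#' @param m A `"motif"` object.
#' @return `m`, invisibly; errors on violation.
#' @export
validate_motif <- function(m) {
  if (!inherits(m, "motif")) stop("not a motif object")
  mat <- m$matrix
  if (!is.matrix(mat) || ncol(mat) != 4L || nrow(mat) < 1L)
    stop(sprintf("motif '%s': matrix must be l x 4 with l >= 1", m$id))
  if (anyNA(mat) || any(mat < -1e-12) || any(mat > 1 + 1e-12))
    stop(sprintf("motif '%s': probabilities must lie in [0, 1]", m$id))
  rs <- rowSums(mat)
  if (any(abs(rs - 1) > 1e-6))
    stop(sprintf("motif '%s': row(s) %s do not sum to 1",
                 m$id, paste(which(abs(rs - 1) > 1e-6), collapse = ", ")))
  invisible(m)
}

#' Motif length (number of positions)
#'
#' @param m A `"motif"` object.
#' @return Integer number of matrix rows.
#' @export
motif_length <- function(m) nrow(m$matrix)

#' @export
print.motif <- function(x, ...) {
  cls <- if (is.null(x$structural_class)) "" else
    sprintf(" [%s]", x$structural_class)
  cat(sprintf("motif '%s'%s, %d positions\n", x$id, cls, motif_length(x)))
  mat <- t(x$matrix)
  colnames(mat) <- seq_len(ncol(mat))
  print(round(mat, 3))
  invisible(x)
}

#' Reverse complement of a motif
#'
#' Reverses the position order and swaps the complementary nucleotide
#' columns (A with T, C with G). Applying it twice returns the original
#' motif.
#'
#' @param m A `"motif"` object.
#' @return A `"motif"` with the reverse-complemented matrix; the id gains no
#'   suffix (strand handling is internal to feature extraction and
#'   alignment).
#' @examples
#' m <- motif("a", rbind(c(1, 0, 0, 0)))        # "A"
#' reverse_complement(m)$matrix                 # "T"
#' @export
reverse_complement <- function(m) {
  validate_motif(m)
  # complement = swap columns A<->T, C<->G; reverse = flip row order
  mat <- m$matrix[rev(seq_len(nrow(m$matrix))), c(4L, 3L, 2L, 1L),
                  drop = FALSE]
  colnames(mat) <- ALPHABET
  m$matrix <- mat
  m$source_counts <- NULL
  m
}

# internal: reverse-complement a bare probability matrix
.rc_matrix <- function(mat) {
  out <- mat[rev(seq_len(nrow(mat))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(out) <- ALPHABET
  out
}

# internal: stop unless x is a list of motifs with unique ids
.check_motif_list <- function(motifs) {
  if (!length(motifs)) return(invisible(character()))
  if (!all(vapply(motifs, inherits, logical(1), "motif")))
    stop("expected a list of motif objects")
  ids <- vapply(motifs, function(m) m$id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate motif id(s): ", paste(dup, collapse = ", "))
  invisible(ids)
}
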