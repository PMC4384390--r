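#' Convert a count matrix to a probability matrix
#'
#' Normalises per-position nucleotide counts to probabilities with an
#' optional pseudocount: `p[i, j] = (counts[i, j] + pc) / (rowsum_i + 4 pc)`.
#'
#' @param counts Numeric `l x 4` matrix of nonnegative counts.
#' @param pseudocount Nonnegative real added to every cell before
#'   normalisation. Default 0: published matrices are used as-is.
#' @return `l x 4` row-stochastic matrix.
#' @examples
#' counts_to_probabilities(rbind(c(3, 1, 0, 0)), pseudocount = 1)
#' @export
counts_to_probabilities <- function(counts, pseudocount = 0) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L) stop("counts must have 4 columns (A, C, G, T)")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be nonnegative")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  tot <- rowSums(counts) + 4 * pseudocount
  if (any(tot == 0))
    stop("all-zero count row(s) ",
         paste(which(tot == 0), collapse = ", "),
         " cannot be normalised with pseudocount 0")
  out <- (counts + pseudocount) / tot
  colnames(out) <- ALPHABET
  rownames(out) <- NULL
  out
}

#' Read motifs from a JASPAR PFM or TRANSFAC flat file
#'
#' JASPAR PFM records are a `>id name` header followed by four count rows in
#' A, C, G, T order, with or without the `A [ ... ]` bracket decoration.
#' TRANSFAC records are blocks terminated by `//` carrying `AC`/`ID` fields
#' and numbered `P0`/`PO` position rows with counts in A, C, G, T column
#' order. Counts are converted to probabilities via
#' [counts_to_probabilities()].
#'
#' @param path Input file.
#' @param format `"jaspar_pfm"` or `"transfac"`.
#' @param pseudocount Passed to [counts_to_probabilities()].
#' @param class_file Optional sidecar TSV (no header, columns: motif id,
#'   structural class) populating `structural_class`.
#' @return List of [motif()] objects in file order (empty list, with a
#'   warning, for an empty file).
#' @export
read_motifs <- function(path, format = c("jaspar_pfm", "transfac"),
                        pseudocount = 0, class_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  motifs <- switch(format,
    jaspar_pfm = .parse_jaspar(lines, pseudocount),
    transfac   = .parse_transfac(lines, pseudocount)
  )
  if (!length(motifs)) {
    warning("no motif records found in ", path)
    return(list())
  }
  .check_motif_list(motifs)
  if (!is.null(class_file)) {
    classes <- read_class_labels(class_file)
    motifs <- lapply(motifs, function(m) {
      if (m$id %in% names(classes)) m$structural_class <- classes[[m$id]]
      m
    })
  }
  motifs
}

#' Read a structural-class sidecar TSV
#'
#' @param path Two-column tab-separated file, no header: motif id, class.
#' @return Named character vector mapping id to class.
#' @export
read_class_labels <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) < 2L) stop("class file must have two tab-separated columns")
  setNames(tab[[2L]], tab[[1L]])
}

.parse_count_row <- function(line, id, lineno) {
  body <- sub("^\\s*[ACGTacgt]\\s*\\[", "", line)
  body <- sub("\\]\\s*$", "", body)
  vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
  if (anyNA(vals))
    stop(sprintf("record '%s', line %d: non-numeric count", id, lineno))
  if (any(vals < 0))
    stop(sprintf("record '%s', line %d: negative count", id, lineno))
  vals
}

.parse_jaspar <- function(lines, pseudocount) {
  headers <- grep("^>", lines)
  motifs <- vector("list", length(headers))
  for (h in seq_along(headers)) {
    start <- headers[h]
    end <- if (h < length(headers)) headers[h + 1] - 1L else length(lines)
    hdr <- strsplit(sub("^>\\s*", "", lines[start]), "\\s+")[[1]]
    id <- hdr[1]
    name <- if (length(hdr) > 1) paste(hdr[-1], collapse = " ") else NULL
    body <- which(nzchar(trimws(lines[start:end]))) + start - 1L
    body <- setdiff(body, start)
    if (length(body) != 4L)
      stop(sprintf("record '%s': expected 4 count rows, found %d",
                   id, length(body)))
    rows <- lapply(seq_along(body),
                   function(i) .parse_count_row(lines[body[i]], id, body[i]))
    widths <- lengths(rows)
    if (length(unique(widths)) != 1L)
      stop(sprintf("record '%s': count rows have unequal widths (%s)",
                   id, paste(widths, collapse = ", ")))
    counts <- t(do.call(rbind, rows))  # positions x 4, rows were A,C,G,T
    mat <- tryCatch(counts_to_probabilities(counts, pseudocount),
                    error = function(e)
                      stop(sprintf("record '%s': %s", id, conditionMessage(e)),
                           call. = FALSE))
    motifs[[h]] <- motif(id, mat, name = name, source_counts = counts)
  }
  motifs
}

.parse_transfac <- function(lines, pseudocount) {
  motifs <- list()
  ac <- id_field <- NULL
  rows <- list()
  row_lines <- integer()
  flush <- function() {
    if (is.null(ac) && is.null(id_field) && !length(rows)) return(NULL)
    rid <- if (!is.null(ac)) ac else id_field
    if (is.null(rid)) stop("TRANSFAC block without AC or ID field")
    if (!length(rows))
      stop(sprintf("record '%s': no matrix rows", rid))
    widths <- lengths(rows)
    if (any(widths != 4L))
      stop(sprintf("record '%s', line %d: expected 4 counts per position row",
                   rid, row_lines[which(widths != 4L)[1]]))
    counts <- do.call(rbind, rows)  # positions x 4 already (A C G T columns)
    mat <- tryCatch(counts_to_probabilities(counts, pseudocount),
                    error = function(e)
                      stop(sprintf("record '%s': %s", rid,
                                   conditionMessage(e)), call. = FALSE))
    motif(rid, mat,
          name = if (!is.null(ac) && !is.null(id_field)) id_field else NULL,
          source_counts = counts)
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (grepl("^//", line)) {
      m <- flush()
      if (!is.null(m)) motifs[[length(motifs) + 1L]] <- m
      ac <- id_field <- NULL; rows <- list(); row_lines <- integer()
    } else if (grepl("^AC\\s", line)) {
      ac <- trimws(sub("^AC\\s+", "", line))
    } else if (grepl("^ID\\s", line)) {
      id_field <- trimws(sub("^ID\\s+", "", line))
    } else if (grepl("^[0-9]+\\s", trimws(line))) {
      toks <- strsplit(trimws(line), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(toks[-1]))
      # trailing consensus letter is optional
      if (length(vals) >= 5L && is.na(vals[length(vals)]))
        vals <- vals[-length(vals)]
      if (anyNA(vals))
        stop(sprintf("line %d: non-numeric count in position row", i))
      if (any(vals < 0))
        stop(sprintf("line %d: negative count in position row", i))
      rows[[length(rows) + 1L]] <- vals
      row_lines <- c(row_lines, i)
    }
  }
  m <- flush()  # tolerate a final block missing its // terminator
  if (!is.null(m)) motifs[[length(motifs) + 1L]] <- m
  motifs
}

#' Write motifs to a JASPAR PFM or TRANSFAC flat file
#'
#' Writes `source_counts` when present, otherwise the probability matrix
#' itself (both dialects accept real-valued matrices), so that
#' `read_motifs(write_motifs(x))` reproduces matrices within `1e-6` and ids
#' exactly.
#'
#' @param motifs List of [motif()] objects (may be empty).
#' @param path Output file.
#' @param format `"jaspar_pfm"` or `"transfac"`.
#' @return `path`, invisibly.
#' @export
write_motifs <- function(motifs, path, format = c("jaspar_pfm", "transfac")) {
  format <- match.arg(format)
  .check_motif_list(motifs)
  fmt_row <- function(v) paste(format(v, digits = 12, trim = TRUE,
                                      scientific = FALSE), collapse = " ")
  out <- character()
  for (m in motifs) {
    vals <- if (!is.null(m$source_counts)) m$source_counts else m$matrix
    if (format == "jaspar_pfm") {
      hdr <- if (is.null(m$name)) paste0(">", m$id)
             else paste0(">", m$id, " ", m$name)
      out <- c(out, hdr,
               vapply(1:4, function(j)
                 paste0(ALPHABET[j], " [ ", fmt_row(vals[, j]), " ]"),
                 character(1)))
    } else {
      out <- c(out,
               paste("AC", m$id), "XX",
               paste("ID", if (is.null(m$name)) m$id else m$name), "XX",
               "P0      A      C      G      T",
               vapply(seq_len(nrow(vals)), function(i)
                 paste(sprintf("%02d", i), fmt_row(vals[i, ])),
                 character(1)),
               "XX", "//")
    }
  }
  writeLines(out, path)
  invisible(path)
}
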