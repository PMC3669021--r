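#' Read a phenotype matrix from a delimited text file
#'
#' Expected layout: the first row holds resource names (its first cell is
#' ignored, conventionally blank), every following row starts with a strain
#' name followed by one cell per resource. Tokens are trimmed of surrounding
#' whitespace; empty trailing lines are ignored. Parse errors name the
#' offending row and column so bad cells can be located in a spreadsheet.
#'
#' @param path path to a CSV (or, with `sep = "\t"`, TSV) file.
#' @param sep single-character field separator, default `","`.
#' @return [read_binary_matrix()] a `phenotype_matrix`;
#'   [read_continuous_matrix()] a `continuous_matrix`.
#' @export
read_binary_matrix <- function(path, sep = ",") {
  p <- parse_matrix_file(path, sep)
  vals <- matrix(0L, nrow(p$cells), ncol(p$cells))
  for (j in seq_len(ncol(p$cells))) {
    tok <- p$cells[, j]
    bad <- !(tok %in% c("0", "1"))
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf(
        "cell '%s' at row %d ('%s'), column %d ('%s') is not 0 or 1",
        tok[i], i, p$strains[i], j, p$resources[j]), call. = FALSE)
    }
    vals[, j] <- as.integer(tok)
  }
  phenotype_matrix(vals, p$strains, p$resources)
}

#' @rdname read_binary_matrix
#' @export
read_continuous_matrix <- function(path, sep = ",") {
  p <- parse_matrix_file(path, sep)
  vals <- matrix(0, nrow(p$cells), ncol(p$cells))
  for (j in seq_len(ncol(p$cells))) {
    v <- suppressWarnings(as.numeric(p$cells[, j]))
    bad <- is.na(v) | v < 0
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf(
        "cell '%s' at row %d ('%s'), column %d ('%s') is not a non-negative number",
        p$cells[i, j], i, p$strains[i], j, p$resources[j]), call. = FALSE)
    }
    vals[, j] <- v
  }
  continuous_matrix(vals, p$strains, p$resources)
}

# Shared tokenizer for the header-row/header-column layout. Cell-level error
# locations are part of the contract, hence the manual split rather than
# read.csv (which reports line numbers only).
parse_matrix_file <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(is.character(sep), nchar(sep) == 1L)
  lines <- readLines(path, warn = FALSE)
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) < 2L) stop("no data rows in ", path, call. = FALSE)
  split1 <- function(s) trimws(strsplit(s, sep, fixed = TRUE)[[1L]])
  header <- split1(lines[1L])
  resources <- header[-1L]
  if (length(resources) < 1L) stop("header row has no resource names",
                                   call. = FALSE)
  body <- lapply(lines[-1L], split1)
  width <- length(resources) + 1L
  ragged <- which(vapply(body, length, 1L) != width)
  if (length(ragged))
    stop(sprintf("ragged row %d: expected %d fields, got %d",
                 ragged[1L] + 1L, width, length(body[[ragged[1L]]])),
         call. = FALSE)
  strains <- vapply(body, `[[`, "", 1L)
  cells <- do.call(rbind, lapply(body, `[`, -1L))
  list(strains = strains, resources = resources, cells = cells)
}

#' Write a matrix back to delimited text
#'
#' Inverse of the readers: reading the written file recovers the names and
#' values exactly.
#'
#' @param m a `phenotype_matrix` or `continuous_matrix`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path, sep = ",") {
  header <- paste(c("", colnames(m)), collapse = sep)
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], format(m[i, ], trim = TRUE, digits = 15)),
          collapse = sep), "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Binarize optical-density measurements at a fraction of the global maximum
#'
#' The threshold is `fraction` times the largest value in the whole matrix;
#' cells strictly greater than the threshold become 1, all others 0. The
#' default fraction of 0.10 selects unequivocal growth signals and avoids
#' false positives from near-blank wells. Equality with the threshold maps to
#' 0: "above" is read strictly, so a reading exactly at 10% of the maximum
#' does not count as growth.
#'
#' @param m a `continuous_matrix`.
#' @param fraction fraction of the global maximum used as threshold, in
#'   (0, 1]; default 0.10.
#' @return a `phenotype_matrix` with attribute `"threshold"` recording the
#'   cutoff actually applied. An all-zero input yields an all-zero result and
#'   a warning (threshold 0).
#' @examples
#' od <- continuous_matrix(rbind(a = c(x = 1.0, y = 0.5),
#'                               b = c(0.09, 0.11)))
#' b <- binarize(od)          # threshold 0.1
#' attr(b, "threshold")
#' @export
binarize <- function(m, fraction = 0.10) {
  stopifnot(inherits(m, "continuous_matrix"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be a single number in (0, 1]", call. = FALSE)
  t <- fraction * max(m)
  if (max(m) == 0)
    warning("all measurements are zero; binarized matrix is all zeros")
  out <- phenotype_matrix((unclass(m) > t) * 1L, rownames(m), colnames(m))
  attr(out, "threshold") <- t
  out
}
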