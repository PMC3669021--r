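#' Binary strain x resource phenotype matrix
#'
#' The central container of the package: a named binary relation between
#' strain isolates (rows) and resources (columns). Resources are whatever the
#' assay measures -- hydrolytic enzymes on an API ZYM strip, carbon substrates
#' on a Biolog PM plate, genes, network features. Cells are exactly 0 or 1.
#'
#' @param values numeric or integer matrix with all cells in \{0, 1\}.
#' @param strain_names,resource_names optional character vectors overriding
#'   `dimnames(values)`; must be unique and non-empty.
#' @return an integer matrix of class `"phenotype_matrix"` with row and
#'   column names set.
#' @examples
#' m <- phenotype_matrix(rbind(a = c(x = 1, y = 0), b = c(1, 1)))
#' strain_names(m)
#' @export
phenotype_matrix <- function(values, strain_names = rownames(values),
                             resource_names = colnames(values)) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("a phenotype matrix needs at least one strain and one resource",
         call. = FALSE)
  if (is.null(strain_names))
    strain_names <- paste0("S", seq_len(nrow(values)))
  if (is.null(resource_names))
    resource_names <- paste0("R", seq_len(ncol(values)))
  check_names(strain_names, nrow(values), "strain")
  check_names(resource_names, ncol(values), "resource")
  if (!is.numeric(values) || anyNA(values) || !all(values %in% c(0, 1)))
    stop("phenotype matrix cells must all be 0 or 1", call. = FALSE)
  storage.mode(values) <- "integer"
  dimnames(values) <- list(strain_names, resource_names)
  structure(values, class = c("phenotype_matrix", "matrix", "array"))
}

#' Continuous (optical density) measurement matrix
#'
#' Non-negative absorbance readings with the same naming rules as
#' [phenotype_matrix()]. Typically binarized with [binarize()] before any
#' downstream analysis.
#'
#' @inheritParams phenotype_matrix
#' @param values numeric matrix, all cells finite and >= 0.
#' @return a double matrix of class `"continuous_matrix"`.
#' @export
continuous_matrix <- function(values, strain_names = rownames(values),
                              resource_names = colnames(values)) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("a measurement matrix needs at least one strain and one resource",
         call. = FALSE)
  if (is.null(strain_names))
    strain_names <- paste0("S", seq_len(nrow(values)))
  if (is.null(resource_names))
    resource_names <- paste0("R", seq_len(ncol(values)))
  check_names(strain_names, nrow(values), "strain")
  check_names(resource_names, ncol(values), "resource")
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    stop("measurement cells must be finite numbers", call. = FALSE)
  if (any(values < 0))
    stop("measurement cells must be non-negative", call. = FALSE)
  storage.mode(values) <- "double"
  dimnames(values) <- list(strain_names, resource_names)
  structure(values, class = c("continuous_matrix", "matrix", "array"))
}

check_names <- function(x, n, what) {
  x <- as.character(x)
  if (length(x) != n)
    stop(sprintf("expected %d %s names, got %d", n, what, length(x)),
         call. = FALSE)
  if (anyNA(x) || any(!nzchar(x)))
    stop(sprintf("%s names must be non-empty", what), call. = FALSE)
  if (anyDuplicated(x))
    stop(sprintf("duplicate %s name: '%s'", what, x[duplicated(x)][1L]),
         call. = FALSE)
  invisible(x)
}

#' @rdname phenotype_matrix
#' @param m a phenotype or continuous matrix.
#' @export
strain_names <- function(m) rownames(m)

#' @rdname phenotype_matrix
#' @export
resource_names <- function(m) colnames(m)

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat(sprintf("phenotype_matrix: %d strains x %d resources (%d positive cells)\n",
              nrow(x), ncol(x), sum(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.continuous_matrix <- function(x, ...) {
  cat(sprintf("continuous_matrix: %d strains x %d resources (max %.4g)\n",
              nrow(x), ncol(x), max(x)))
  print(unclass(x), ...)
  invisible(x)
}
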