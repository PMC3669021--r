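#' Normalized Hamming distance matrix between phenotype profiles
#'
#' The distance between two profiles is the number of positions at which they
#' differ divided by the profile length, i.e. the fraction of resources
#' (axis `"strains"`) or strains (axis `"resources"`) on which the pair
#' disagrees. Values lie in \[0, 1\]; identical profiles are at distance 0 and
#' complementary profiles at distance 1.
#'
#' @param m a [phenotype_matrix()].
#' @param axis compare strain rows (`"strains"`, default) or resource columns.
#' @return a symmetric numeric matrix of class `"distance_matrix"` with zero
#'   diagonal and dimnames set to the entity names.
#' @export
hamming_distance_matrix <- function(m, axis = c("strains", "resources")) {
  stopifnot(inherits(m, "phenotype_matrix"))
  axis <- match.arg(axis)
  x <- if (axis == "strains") unclass(m) else t(unclass(m))
  d <- as.matrix(stats::dist(x, method = "manhattan")) / ncol(x)
  distance_matrix(d)
}

#' Square distance matrix container
#'
#' Validates symmetry, zero diagonal and the \[0, 1\] range used throughout
#' the package. External distances (e.g. phylogenetic) can be wrapped for use
#' with [distance_correlation()]; values above 1 are allowed there but the
#' Hamming-based workflow stays in the unit interval.
#'
#' @param d square numeric matrix with dimnames.
#' @param check_unit require entries in \[0, 1\] (default TRUE).
#' @return `d` with class `"distance_matrix"`.
#' @export
distance_matrix <- function(d, check_unit = TRUE) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(d))) {
    nm <- paste0("E", seq_len(nrow(d)))
    dimnames(d) <- list(nm, nm)
  }
  if (is.null(colnames(d)) || !identical(rownames(d), colnames(d)))
    stop("distance matrix needs identical row and column names", call. = FALSE)
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric",
                                       call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero",
                                      call. = FALSE)
  if (check_unit && (any(d < -1e-12) || any(d > 1 + 1e-12)))
    stop("distance entries must lie in [0, 1]", call. = FALSE)
  structure(d, class = c("distance_matrix", "matrix", "array"))
}

#' Similarity matrix from a normalized distance matrix
#'
#' Entry-wise `1 - d`; the diagonal becomes all ones. This similarity, rather
#' than a Pearson correlation between profiles, is the input to the ordination
#' because it is the direct complement of an explicit metric on binary
#' strings.
#'
#' @param d a `distance_matrix` with entries in \[0, 1\].
#' @return a symmetric numeric matrix with unit diagonal.
#' @export
similarity_matrix <- function(d) {
  stopifnot(inherits(d, "distance_matrix"))
  if (any(d > 1 + 1e-12))
    stop("similarity is only defined for distances in [0, 1]", call. = FALSE)
  s <- 1 - unclass(d)
  diag(s) <- 1
  s
}

#' Principal component analysis of a similarity matrix
#'
#' The n x n similarity matrix is treated as an observations x features data
#' matrix: its columns are mean-centered and a singular value decomposition
#' yields component coordinates (row scores) and variance-explained fractions
#' `sigma_k^2 / sum(sigma^2)`. Entities with identical profiles receive
#' identical coordinates on every component, which is what lets class members
#' share a single vertical position in the four-tiered layout.
#'
#' Component sign is arbitrary in any PCA; here each component is oriented so
#' that the first entity (in input order) has a non-negative coordinate, ties
#' broken by the next entity with a non-zero coordinate.
#'
#' An alternative classical principal-coordinates mode (`method = "pcoa"`,
#' metric scaling of the distance matrix via [stats::cmdscale()]) is offered
#' for comparison; the centered-SVD-of-similarity mode is the default and the
#' one the four-tiered layout uses.
#'
#' @param s symmetric similarity matrix (from [similarity_matrix()]), or for
#'   `method = "pcoa"` a `distance_matrix`.
#' @param n_components number of components to return (default all).
#' @param method `"similarity-pca"` (default) or `"pcoa"`.
#' @return an object of class `"ordination"`: list with `coordinates`
#'   (entities x components, zero column means), `variance_explained`
#'   (non-negative, non-increasing fractions summing to <= 1), `method`.
#' @export
pca_on_similarity <- function(s, n_components = NULL,
                              method = c("similarity-pca", "pcoa")) {
  method <- match.arg(method)
  s <- as.matrix(s)
  n <- nrow(s)
  if (n < 2L) stop("ordination undefined for fewer than 2 entities",
                   call. = FALSE)
  if (nrow(s) != ncol(s) || any(abs(s - t(s)) > 1e-8))
    stop("input must be a square symmetric matrix", call. = FALSE)
  nm <- rownames(s)
  if (is.null(nm)) nm <- paste0("E", seq_len(n))
  if (is.null(n_components)) n_components <- n
  n_components <- min(n_components, n)

  if (method == "pcoa") {
    fit <- suppressWarnings(
      stats::cmdscale(stats::as.dist(s), k = min(n - 1L, n_components),
                      eig = TRUE))
    coords <- as.matrix(fit$points)
    pos <- pmax(fit$eig, 0)
    ve <- if (sum(pos) > 0) pos / sum(pos) else rep(0, length(pos))
    ve <- ve[seq_len(ncol(coords))]
  } else {
    xc <- scale(s, center = TRUE, scale = FALSE)
    sv <- svd(xc)
    tot <- sum(sv$d^2)
    if (tot < 1e-24) {
      warning("zero total variance: all profiles identical; coordinates set to 0")
      coords <- matrix(0, n, n_components)
      ve <- rep(0, n_components)
    } else {
      coords <- sv$u %*% diag(sv$d, length(sv$d))
      ve <- sv$d^2 / tot
      coords <- coords[, seq_len(n_components), drop = FALSE]
      ve <- ve[seq_len(n_components)]
    }
  }
  coords <- fix_component_signs(coords)
  dimnames(coords) <- list(nm, paste0("PC", seq_len(ncol(coords))))
  structure(list(coordinates = coords, variance_explained = ve,
                 method = method), class = "ordination")
}

# Orient each component so the first entity with a non-zero coordinate
# (in input order) is positive.
fix_component_signs <- function(coords) {
  for (k in seq_len(ncol(coords))) {
    v <- coords[, k]
    i <- which(abs(v) > 1e-12)
    if (length(i) && v[i[1L]] < 0) coords[, k] <- -v
  }
  coords
}

#' One-call ordination of a phenotype matrix
#'
#' Convenience wrapper: Hamming distance, similarity, then
#' [pca_on_similarity()].
#'
#' @inheritParams hamming_distance_matrix
#' @inheritParams pca_on_similarity
#' @return an `"ordination"` object.
#' @export
ordinate <- function(m, axis = c("strains", "resources"), n_components = NULL,
                     method = c("similarity-pca", "pcoa")) {
  method <- match.arg(method)
  d <- hamming_distance_matrix(m, axis = match.arg(axis))
  if (method == "pcoa") pca_on_similarity(d, n_components, method = "pcoa")
  else pca_on_similarity(similarity_matrix(d), n_components)
}

#' @export
print.ordination <- function(x, ...) {
  ve <- x$variance_explained
  cat(sprintf("ordination (%s) of %d entities; PC1 %.1f%%, PC2 %s of variance\n",
              x$method, nrow(x$coordinates), 100 * ve[1L],
              if (length(ve) > 1L) sprintf("%.1f%%", 100 * ve[2L]) else "-"))
  invisible(x)
}
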