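#' Summary counts of a phenotype matrix
#'
#' Per-strain counts of resources used, per-resource counts of strains using
#' it, the universal resources (used by every strain), the unused resources
#' (used by none) and, if strain group labels are given (e.g. genus), the mean
#' resource count per group. These are the headline counts reported alongside
#' a four-tiered graph.
#'
#' @param m a [phenotype_matrix()].
#' @param groups optional named character vector mapping every strain in `m`
#'   to a group label.
#' @return an object of class `"profile_summary"`: list with
#'   `per_strain` (named integer), `per_resource` (named integer),
#'   `universal` (character), `unused` (character), `group_means` (named
#'   numeric or NULL).
#' @export
summarize_profiles <- function(m, groups = NULL) {
  stopifnot(inherits(m, "phenotype_matrix"))
  per_strain <- stats::setNames(as.integer(rowSums(m)), rownames(m))
  per_resource <- stats::setNames(as.integer(colSums(m)), colnames(m))
  group_means <- NULL
  if (!is.null(groups)) {
    unknown <- setdiff(names(groups), rownames(m))
    if (length(unknown))
      stop("unknown strain in groups map: ", unknown[1L], call. = FALSE)
    missing <- setdiff(rownames(m), names(groups))
    if (length(missing))
      stop("groups map does not cover strain: ", missing[1L], call. = FALSE)
    group_means <- tapply(per_strain[names(groups)], groups, mean)
    group_means <- stats::setNames(as.numeric(group_means),
                                   names(group_means))
  }
  structure(list(
    per_strain = per_strain,
    per_resource = per_resource,
    universal = colnames(m)[per_resource == nrow(m)],
    unused = colnames(m)[per_resource == 0L],
    group_means = group_means
  ), class = "profile_summary")
}

#' @export
print.profile_summary <- function(x, ...) {
  cat(sprintf(
    "profile summary: %d strains, %d resources; %d universal, %d unused\n",
    length(x$per_strain), length(x$per_resource),
    length(x$universal), length(x$unused)))
  cat(sprintf("resources per strain: min %d (%s), max %d (%s)\n",
              min(x$per_strain), names(which.min(x$per_strain)),
              max(x$per_strain), names(which.max(x$per_strain))))
  if (!is.null(x$group_means))
    cat("group means:",
        paste(sprintf("%s=%.1f", names(x$group_means), x$group_means),
              collapse = ", "), "\n")
  invisible(x)
}

# Row-major upper-triangle (i < j) vectorization, shared by the correlation
# code so both matrices pair entries identically.
upper_vec <- function(d) t(d)[lower.tri(d)]

#' Pearson correlation between two distance matrices
#'
#' Correlates the strict upper triangles of two pairwise distance matrices
#' over their shared entities. The parametric p-value treats the n(n-1)/2
#' pairs as independent observations (Student t with n_pairs - 2 df) -- this
#' is the conventional report but distance entries are not independent, so a
#' Mantel-style permutation p (rows and columns of the second matrix
#' relabeled jointly) is also computed when `permutations > 0` and is the
#' recommended significance measure.
#'
#' @param d1,d2 `distance_matrix` objects. If the entity sets differ, the
#'   intersection is used with a warning; at least 3 shared entities needed.
#' @param permutations number of Mantel permutations (0 = parametric only).
#' @param seed optional integer seed for the permutations.
#' @param alternative for the permutation test: `"two.sided"` (default, on
#'   |r|), `"greater"` or `"less"`.
#' @return an object of class `"correlation_result"`: list with `rho`,
#'   `p_parametric`, `p_permutation` (NA if `permutations == 0`), `n`,
#'   `n_pairs`, `permutations`.
#' @export
distance_correlation <- function(d1, d2, permutations = 0L, seed = NULL,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  stopifnot(inherits(d1, "distance_matrix"), inherits(d2, "distance_matrix"))
  alternative <- match.arg(alternative)
  shared <- intersect(rownames(d1), rownames(d2))
  if (!setequal(rownames(d1), rownames(d2)))
    warning(sprintf("entity sets differ; using the %d shared entities",
                    length(shared)))
  n <- length(shared)
  if (n < 3L) stop("need at least 3 shared entities", call. = FALSE)
  a <- unclass(d1)[shared, shared]
  b <- unclass(d2)[shared, shared]
  v1 <- upper_vec(a); v2 <- upper_vec(b)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("correlation undefined: a distance triangle has zero variance",
         call. = FALSE)
  r <- stats::cor(v1, v2)
  np <- length(v1)
  tstat <- r * sqrt((np - 2) / (1 - r^2))
  p_par <- 2 * stats::pt(-abs(tstat), df = np - 2)
  p_perm <- NA_real_
  if (permutations > 0L) {
    if (!is.null(seed)) set.seed(seed)
    rp <- vapply(seq_len(permutations), function(i) {
      p <- sample.int(n)
      stats::cor(v1, upper_vec(b[p, p]))
    }, 0)
    p_perm <- switch(alternative,
      two.sided = (1 + sum(abs(rp) >= abs(r) - 1e-12)) / (permutations + 1),
      greater   = (1 + sum(rp >= r - 1e-12)) / (permutations + 1),
      less      = (1 + sum(rp <= r + 1e-12)) / (permutations + 1))
  }
  structure(list(rho = r, p_parametric = p_par, p_permutation = p_perm,
                 n = n, n_pairs = np, permutations = permutations,
                 alternative = alternative),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "distance correlation over %d entities (%d pairs): rho = %.3f\n",
    x$n, x$n_pairs, x$rho))
  cat(sprintf("  parametric p (pairs treated as independent, as conventionally reported) = %.3g\n",
              x$p_parametric))
  if (!is.na(x$p_permutation))
    cat(sprintf("  Mantel permutation p (%d permutations, %s) = %.3g\n",
                x$permutations, x$alternative, x$p_permutation))
  invisible(x)
}

#' Two-group comparison: KS normality check plus Wilcoxon rank-sum test
#'
#' For two groups of values (e.g. per-strain resource counts for two genera,
#' or pairwise distances split by group), first checks each group for
#' normality with a Kolmogorov-Smirnov test against a normal with the group's
#' estimated mean and sd, then runs a two-sided Wilcoxon rank-sum test.
#' For combined sample sizes up to `exact_max` the Wilcoxon p is computed by
#' exhaustive enumeration of all group assignments (midranks for ties);
#' beyond that a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param values numeric vector of observations.
#' @param labels vector of exactly two distinct labels, same length as
#'   `values`.
#' @param exact_max largest combined n for exact enumeration (default 12).
#' @return an object of class `"group_comparison"`: list with `groups`
#'   (names), `n` (sizes), `ks` (per-group KS statistic and p, NA when a
#'   group's sd is 0), `w` (rank-sum of the first group), `p` (two-sided),
#'   `method` ("exact" or "normal approximation").
#' @export
compare_groups <- function(values, labels, exact_max = 12L) {
  if (length(values) != length(labels))
    stop("values and labels must have the same length", call. = FALSE)
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L) stop("exactly two groups required", call. = FALSE)
  x <- values[labels == lev[1L]]
  y <- values[labels == lev[2L]]
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  ks <- lapply(list(x, y), function(g) {
    if (length(g) < 2L || stats::sd(g) == 0)
      return(list(statistic = NA_real_, p = NA_real_))
    k <- suppressWarnings(
      stats::ks.test(g, "pnorm", mean = mean(g), sd = stats::sd(g)))
    list(statistic = unname(k$statistic), p = k$p.value)
  })
  names(ks) <- lev
  res <- wilcoxon_ranksum(x, y, exact_max)
  structure(c(list(groups = lev, n = c(length(x), length(y)), ks = ks), res),
            class = "group_comparison")
}

# Two-sided Wilcoxon rank-sum on midranks. Exact path enumerates every
# choose(n, n1) assignment of ranks to group 1, so it is valid under ties
# (conditional on the observed midranks).
wilcoxon_ranksum <- function(x, y, exact_max) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n <= exact_max) {
    sets <- utils::combn(n, n1)
    ws <- colSums(matrix(r[sets], nrow = n1))
    mu <- n1 * (n + 1) / 2
    dev <- abs(w - mu)
    p <- min(1, sum(abs(ws - mu) >= dev - 1e-9) / ncol(sets))
    list(w = w, p = p, method = "exact")
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    list(w = w, p = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal approximation")
  }
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s (n=%d) vs %s (n=%d)\n",
              x$groups[1L], x$n[1L], x$groups[2L], x$n[2L]))
  for (g in x$groups)
    cat(sprintf("  KS normality %s: D = %.3f, p = %.3g\n", g,
                x$ks[[g]]$statistic, x$ks[[g]]$p))
  cat(sprintf("  Wilcoxon rank-sum W = %.1f, two-sided p = %.4g (%s)\n",
              x$w, x$p, x$method))
  invisible(x)
}

#' Read an externally computed square distance matrix from CSV
#'
#' For correlating phenotypic distances with distances produced elsewhere
#' (e.g. a phylogenetic distance matrix): square CSV with matching header
#' names in the first row and first column.
#'
#' @param path CSV path.
#' @param check_unit require entries in \[0, 1\] (FALSE by default here:
#'   external distances are often unbounded).
#' @return a `distance_matrix`.
#' @export
read_distance_matrix <- function(path, check_unit = FALSE) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  d <- as.matrix(df)
  if (!identical(rownames(d), colnames(d)))
    stop("row and column names of the distance CSV must match", call. = FALSE)
  distance_matrix(d, check_unit = check_unit)
}
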