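# Fixtures and independent oracles shared across the suite. Oracles are
# deliberately naive (nested loops, exhaustive enumeration) so they cannot
# share a bug with the implementation they check.

random_pm <- function(n, m, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phenotype_matrix(matrix(rbinom(n * m, 1, p), n, m),
                   sprintf("s%02d", seq_len(n)), sprintf("r%02d", seq_len(m)))
}

# all-pairs equality oracle: membership vector of identical-row classes,
# classes numbered by first occurrence
brute_force_row_classes <- function(x) {
  n <- nrow(x)
  member <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    assigned <- FALSE
    for (j in seq_len(i - 1L)) {
      if (all(x[i, ] == x[j, ])) { member[i] <- member[j]; assigned <- TRUE; break }
    }
    if (!assigned) { next_id <- next_id + 1L; member[i] <- next_id }
  }
  member
}

# positional-comparison oracle for the normalized Hamming distance
brute_force_hamming <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    diffs <- 0L
    for (p in seq_len(ncol(x))) if (x[i, p] != x[j, p]) diffs <- diffs + 1L
    d[i, j] <- diffs / ncol(x)
  }
  d
}

# checks d[i,j] <= d[i,k] + d[k,j] for every ordered triple
triangle_holds <- function(d, tol = 1e-12) {
  n <- nrow(d)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
    if (d[i, j] > d[i, k] + d[k, j] + tol) return(FALSE)
  TRUE
}

write_tmp_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
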