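test_that("profile summary matches a direct nested-loop count", {
  set.seed(141)
  m <- random_pm(4, 6)
  s <- summarize_profiles(m)
  x <- unclass(m)
  for (i in seq_len(nrow(x)))
    expect_identical(unname(s$per_strain[i]), sum(x[i, ]))
  for (j in seq_len(ncol(x)))
    expect_identical(unname(s$per_resource[j]), sum(x[, j]))
  expect_identical(s$universal,
                   colnames(x)[apply(x, 2, function(c) all(c == 1))])
  expect_identical(s$unused,
                   colnames(x)[apply(x, 2, function(c) all(c == 0))])
  # conservation: both margins sum to the 1-cell count
  expect_identical(sum(s$per_strain), sum(m))
  expect_identical(sum(s$per_resource), sum(m))
  expect_length(intersect(s$universal, s$unused), 0)
})

test_that("all-ones matrix is fully universal", {
  s <- summarize_profiles(phenotype_matrix(matrix(1, 3, 4)))
  expect_length(s$universal, 4)
  expect_length(s$unused, 0)
  expect_true(all(s$per_strain == 4))
})

test_that("group means follow the labels and bad maps error", {
  m <- phenotype_matrix(rbind(a = c(1, 1, 0), b = c(1, 0, 0),
                              c = c(1, 1, 1)))
  groups <- c(a = "Pseudomonas", b = "Pseudomonas", c = "Serratia")
  s <- summarize_profiles(m, groups)
  expect_equal(unname(s$group_means["Pseudomonas"]), 1.5)
  expect_equal(unname(s$group_means["Serratia"]), 3)
  expect_error(summarize_profiles(m, c(groups, z = "X")), "unknown strain")
  expect_error(summarize_profiles(m, groups[1:2]), "does not cover")
})

test_that("distance correlation hits the exact endpoints", {
  d <- hamming_distance_matrix(random_pm(6, 9, seed = 151))
  expect_equal(distance_correlation(d, d)$rho, 1)
  anti <- 1 - unclass(d); diag(anti) <- 0
  expect_equal(distance_correlation(d, distance_matrix(anti))$rho, -1)
})

test_that("correlation agrees with vegan's Mantel statistic", {
  set.seed(161)
  d1 <- hamming_distance_matrix(random_pm(10, 12))
  d2 <- hamming_distance_matrix(random_pm(10, 15,
                                          seed = NULL))
  rownames(d2) <- colnames(d2) <- rownames(d1)
  res <- distance_correlation(d1, d2, permutations = 199, seed = 5)
  ref <- vegan::mantel(as.dist(unclass(d1)), as.dist(unclass(d2)),
                       permutations = 0)
  expect_equal(res$rho, unname(ref$statistic), tolerance = 1e-12)
  expect_identical(res$n_pairs, 45L)
  # symmetric in its arguments
  swapped <- distance_correlation(d2, d1)
  expect_equal(swapped$rho, res$rho)
  # invariant under joint reordering of both matrices
  p <- sample(10)
  dp1 <- distance_matrix(unclass(d1)[p, p])
  dp2 <- distance_matrix(unclass(d2)[p, p])
  expect_equal(distance_correlation(dp1, dp2)$rho, res$rho)
})

test_that("correlation recovers a planted association", {
  set.seed(171)
  n <- 20
  v <- runif(n * (n - 1) / 2, 0.2, 0.8)
  d1 <- matrix(0, n, n); d1[lower.tri(d1)] <- v; d1 <- d1 + t(d1)
  dimnames(d1) <- list(paste0("e", 1:n), paste0("e", 1:n))
  target_r <- 0.7
  sigma <- sd(v) * sqrt(1 / target_r^2 - 1)
  noise <- matrix(0, n, n)
  noise[lower.tri(noise)] <- rnorm(length(v), 0, sigma)
  d2 <- pmin(pmax(d1 + noise + t(noise), 0), 1); diag(d2) <- 0
  res <- distance_correlation(distance_matrix(d1), distance_matrix(d2))
  expect_lt(abs(res$rho - target_r), 0.15)
})

test_that("correlation input contracts are enforced", {
  d3 <- distance_matrix(matrix(c(0, .1, .2, .1, 0, .3, .2, .3, 0), 3))
  small <- distance_matrix(matrix(c(0, .1, .1, 0), 2))
  expect_error(distance_correlation(small, small), "at least 3")
  flat <- distance_matrix(matrix(0.5, 4, 4) - diag(0.5, 4))
  expect_error(distance_correlation(flat, flat), "zero variance")
  m4 <- hamming_distance_matrix(random_pm(4, 6, seed = 6))
  rownames(m4) <- colnames(m4) <- c("E1", "E2", "E3", "E9")
  expect_warning(distance_correlation(d3, m4), "shared entities")
})

test_that("fully separated 3 vs 3 groups give exact two-sided p = 0.1", {
  res <- compare_groups(c(1, 2, 3, 10, 11, 12), rep(c("g1", "g2"), each = 3))
  expect_identical(res$method, "exact")
  expect_equal(res$w, 6)       # ranks 1+2+3
  expect_equal(res$p, 0.1)     # 2 of the 20 assignments are as extreme
})

test_that("identical groups sit at the null expectation with p = 1", {
  res <- compare_groups(c(5, 5, 5, 5), c("a", "a", "b", "b"))
  expect_equal(res$w, 5)       # n1(n+1)/2
  expect_equal(res$p, 1)
})

test_that("swapping group labels leaves the p-value unchanged", {
  set.seed(181)
  v <- rnorm(10)
  lab <- rep(c("x", "y"), each = 5)
  a <- compare_groups(v, lab)
  b <- compare_groups(v, rev(lab))
  expect_equal(a$p, b$p)
})

test_that("exact enumeration agrees with the stats::wilcox.test oracle", {
  set.seed(191)
  for (rep in 1:10) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    v <- round(rnorm(n1 + n2), 3)       # ties essentially impossible
    res <- compare_groups(v, rep(c("a", "b"), c(n1, n2)))
    ref <- wilcox.test(v[1:n1], v[-(1:n1)], exact = TRUE)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large samples fall back to a tie-corrected normal approximation", {
  set.seed(201)
  v <- c(rnorm(100), rnorm(100, 0.4))
  lab <- rep(c("a", "b"), each = 100)
  res <- compare_groups(v, lab)
  expect_identical(res$method, "normal approximation")
  ref <- wilcox.test(v[lab == "a"], v[lab == "b"], exact = FALSE,
                     correct = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  # spot-check agreement of exact and approximate paths at moderate n
  v10 <- rnorm(10)
  ex <- compare_groups(v10, rep(c("a", "b"), 5), exact_max = 12L)
  ap <- compare_groups(v10, rep(c("a", "b"), 5), exact_max = 0L)
  expect_lt(abs(ex$p - ap$p), 0.08)
})

test_that("empty or mislabeled groups are rejected", {
  expect_error(compare_groups(1:3, c("a", "a", "a")), "exactly two")
  expect_error(compare_groups(1:3, c("a", "a", "b", "b")), "same length")
})

test_that("external distance CSVs round-trip through the reader", {
  d <- hamming_distance_matrix(random_pm(5, 8, seed = 211))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(unclass(d), path)
  expect_equal(unclass(read_distance_matrix(path, check_unit = TRUE)),
               unclass(d))
})
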