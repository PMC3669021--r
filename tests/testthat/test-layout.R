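test_that("spread_overlaps matches the hand-computed cases", {
  expect_equal(spread_overlaps(c(-0.5, 0.5), 0.01), c(-0.5, 0.5),
               ignore_attr = TRUE)
  expect_equal(spread_overlaps(c(0.10, 0.10, 0.50), 0.02),
               c(0.09, 0.11, 0.50), ignore_attr = TRUE)
  expect_equal(spread_overlaps(0.3, 0.05), 0.3, ignore_attr = TRUE)
  expect_error(spread_overlaps(c(0, 1), 0), "positive")
  expect_error(spread_overlaps(c(0, 1), -1), "positive")
})

test_that("spread_overlaps separates runs while preserving geometry", {
  set.seed(61)
  for (rep in 1:30) {
    y <- sort(runif(sample(2:15, 1), 0, 1))
    eps <- runif(1, 0.005, 0.2)
    out <- spread_overlaps(y, eps)
    runs <- attr(out, "runs")
    expect_true(!is.unsorted(out))
    if (length(out) > 1) expect_gte(min(diff(out)), eps * (1 - 1e-9))
    for (r in unique(runs)) {
      idx <- which(runs == r)
      if (length(idx) == 1) {
        # classes outside any run keep their raw coordinate unchanged
        expect_identical(out[idx], y[idx])
      } else {
        # members re-spaced exactly epsilon apart, centered on the run mean
        expect_equal(unname(diff(out[idx])), rep(eps, length(idx) - 1))
        expect_equal(mean(out[idx]), mean(y[idx]))
      }
    }
    # hence inter-run geometry (sum/mean of coordinates) is preserved
    expect_equal(sum(out), sum(y))
  }
})

test_that("strain classes follow PC1 order with epsilon separation", {
  set.seed(71)
  for (rep in 1:15) {
    m <- random_pm(sample(4:10, 1), sample(3:8, 1), p = runif(1, 0.3, 0.7))
    sp <- compute_strain_classes(m)
    if (length(sp$ids) < 2) next
    ord <- ordinate(m)
    eps <- 0.01 * diff(range(ord$coordinates[, 1])) + 1e-6
    y <- place_strain_classes(ord, sp, eps)
    expect_setequal(names(y), sp$ids)
    expect_true(!is.unsorted(unname(y)))
    expect_gte(min(diff(unname(y))), eps * (1 - 1e-9))
    # vertical order equals PC1 order (ties broken by class index)
    raw <- vapply(sp$members, function(mem) ord$coordinates[mem[1], 1], 0)
    names(raw) <- sp$ids
    expect_identical(names(y), sp$ids[order(raw, seq_along(raw))])
    # distances between classes in singleton runs are raw PC1 differences
    runs <- attr(y, "runs")
    solo <- which(runs %in% names(which(table(runs) == 1)))
    if (length(solo) > 1)
      expect_equal(diff(unname(y[solo])), unname(diff(sort(raw)[solo])))
  }
})

test_that("resource classes sit at the barycenter of their predecessors", {
  m <- phenotype_matrix(rbind(s1 = c(1, 1, 0), s2 = c(1, 0, 0),
                              s3 = c(0, 0, 0)),
                        resource_names = c("a", "b", "z"))
  sp <- compute_strain_classes(m); rp <- compute_resource_classes(m)
  cg <- build_class_graph(sp, rp, m)
  sy <- setNames(c(0, 2, -1), sp$ids)
  ry <- place_resource_classes(cg, sy)
  # column a is used by classes of s1 and s2 -> mean of their y
  ca <- rp$ids[rp$membership[["a"]]]
  expect_equal(unname(ry[ca]), mean(c(sy[sp$ids[sp$membership[["s1"]]]],
                                      sy[sp$ids[sp$membership[["s2"]]]])))
  # column b only by s1's class
  cb <- rp$ids[rp$membership[["b"]]]
  expect_equal(unname(ry[cb]), unname(sy[sp$ids[sp$membership[["s1"]]]]))
  # unused column z: fallback at the midpoint, flagged
  cz <- rp$ids[rp$membership[["z"]]]
  expect_equal(unname(ry[cz]), mean(range(sy)))
  expect_true(attr(ry, "fallback")[match(cz, rp$ids)])
})

test_that("outer tiers stack members at epsilon spacing around the class", {
  p <- structure(list(kind = "strain", ids = c("B1", "B2"),
                      members = list("solo", c("m1", "m2", "m3")),
                      profiles = list(1L, 0L),
                      membership = setNames(c(1L, 2L, 2L, 2L),
                                            c("solo", "m1", "m2", "m3"))),
                 class = "partition")
  y <- place_outer_tier(p, c(B1 = 0.2, B2 = 0), 0.02)
  expect_equal(unname(y["solo"]), 0.2)
  expect_equal(unname(y[c("m1", "m2", "m3")]), c(0.02, 0, -0.02))
})

test_that("node and edge counts are conserved", {
  id3 <- phenotype_matrix(diag(3))
  g <- build_tiered_graph(id3)
  expect_identical(nrow(g$nodes), 12L)  # 3 + 3 + 3 + 3
  expect_identical(nrow(g$edges), 9L)   # 3 + 3 + 3

  ones <- phenotype_matrix(matrix(1, 4, 5))
  # all profiles identical -> zero-variance ordination, still a valid graph
  g2 <- suppressWarnings(build_tiered_graph(ones))
  expect_identical(nrow(g2$nodes), 11L) # 4 + 1 + 1 + 5
  expect_identical(nrow(g2$edges), 10L) # 4 + 1 + 5
})

test_that("tiered graph invariants hold on random matrices", {
  set.seed(91)
  for (rep in 1:10) {
    m <- random_pm(sample(5:10, 1), sample(4:8, 1), p = runif(1, 0.3, 0.7))
    g <- build_tiered_graph(m)
    expect_silent(validate_tiered_graph(g))
    nd <- g$nodes
    # barycenter identity on every tier-3 node with in-degree >= 1
    cg <- g$class_graph
    for (j in seq_along(cg$resource_partition$ids)) {
      pred <- cg$links[cg$links[, 2] == j, 1]
      if (length(pred) == 0) next
      yj <- nd$y[nd$id == cg$resource_partition$ids[j]]
      ypred <- nd$y[match(cg$strain_partition$ids[pred], nd$id)]
      expect_equal(yj, mean(ypred), tolerance = 1e-12)
    }
    # min tier-2 gap
    y2 <- sort(nd$y[nd$tier == 2])
    if (length(y2) > 1) expect_gte(min(diff(y2)), g$epsilon * (1 - 1e-9))
    # every strain and resource appears exactly once on the outer tiers
    expect_setequal(nd$label[nd$tier == 1], rownames(m))
    expect_setequal(nd$label[nd$tier == 4], colnames(m))
    # tier-2/3 edges reproduce the class-graph links
    e23 <- g$edges[g$edges$from %in% cg$strain_partition$ids &
                     g$edges$to %in% cg$resource_partition$ids, ]
    expect_identical(nrow(e23), nrow(cg$links))
  }
})

test_that("association matrix blocks exactly match the edge list", {
  m <- random_pm(10, 8, seed = 97)
  g <- build_tiered_graph(m)
  a <- association_matrix(g)
  expect_identical(sum(a), nrow(g$edges))
  nd <- g$nodes[match(rownames(a), g$nodes$id), ]
  for (i in seq_len(nrow(a))) for (j in which(a[i, ] == 1L)) {
    expect_identical(nd$tier[j] - nd$tier[i], 1L)
    expect_true(any(g$edges$from == rownames(a)[i] &
                      g$edges$to == colnames(a)[j]))
  }
  # nodes ordered by tier, top-to-bottom within tier
  expect_true(!is.unsorted(nd$tier))
  for (t in 1:4) expect_true(!is.unsorted(-nd$y[nd$tier == t]))
})

test_that("GraphML round-trips and rejects invalid graphs", {
  m <- random_pm(6, 5, seed = 113)
  g <- build_tiered_graph(m)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, path)
  rt <- read_graphml(path)
  expect_identical(nrow(rt$nodes), nrow(g$nodes))
  expect_identical(nrow(rt$edges), nrow(g$edges))
  key <- function(nd) sort(paste(nd$tier, nd$label))
  expect_identical(key(rt$nodes), key(g$nodes))
  ord <- match(g$nodes$id, rt$nodes$id)
  expect_equal(rt$nodes$y[ord], g$nodes$y, tolerance = 1e-12)
  expect_identical(rt$nodes$degree[ord], g$nodes$degree)
  expect_setequal(paste(rt$edges$from, rt$edges$to),
                  paste(g$edges$from, g$edges$to))

  # independent parser oracle: igraph reads the same graph
  ig <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(ig), nrow(g$nodes))
  expect_equal(igraph::ecount(ig), nrow(g$edges))
  expect_setequal(igraph::vertex_attr(ig, "label"), g$nodes$label)
  expect_equal(sort(igraph::vertex_attr(ig, "y")), sort(g$nodes$y),
               tolerance = 1e-12)

  # a backwards (tier 3 -> tier 2) edge is rejected before writing
  bad <- g
  i <- which(g$nodes$tier[match(g$edges$from, g$nodes$id)] == 2L)[1]
  bad$edges[i, ] <- bad$edges[i, 2:1]
  expect_error(write_graphml(bad, path), "tier t to tier t\\+1")
})

test_that("yEd-compatible output carries yFiles geometry", {
  g <- build_tiered_graph(random_pm(4, 4, seed = 127))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, path, yed_compat = TRUE)
  doc <- xml2::read_xml(path)
  geom <- xml2::xml_find_all(
    doc, ".//y:Geometry", c(y = "http://www.yworks.com/xml/graphml"))
  expect_length(geom, nrow(g$nodes))
})

test_that("profile table mirrors the graph ordering", {
  m <- random_pm(6, 7, seed = 131)
  g <- build_tiered_graph(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  cells <- write_profile_table(m, g, path)
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t")[[1]]
  strains <- vapply(strsplit(lines[-(1:2)], "\t"), `[[`, "", 1)
  # row/column orders are permutations of the input names
  expect_setequal(header[-(1:2)], colnames(m))
  expect_setequal(strains, rownames(m))
  # ordered by vertical position, top first
  t1 <- g$nodes[g$nodes$tier == 1, ]
  expect_identical(strains, t1$label[order(-t1$y)])
  # mark count equals the number of 1-cells
  expect_identical(sum(cells == "X"), sum(m))
  # mismatched inputs are refused
  expect_error(write_profile_table(random_pm(5, 7, seed = 1), g, path),
               "same data")
})
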