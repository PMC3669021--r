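#' Separate vertically overlapping coordinates by a minimal spacing
#'
#' Core placement rule of the four-tiered layout. Input coordinates (already
#' in display order, ascending) are scanned for maximal runs of consecutive
#' values closer than `epsilon`; each run is re-spaced at exactly `epsilon`
#' apart, centered on the mean of the run's raw coordinates. Values outside
#' any run are untouched, so distances between non-overlapping nodes are
#' preserved. Because spreading a long run can push it into its neighbours,
#' runs are merged transitively until every consecutive gap is at least
#' `epsilon`; the merged run is still centered on the mean of all its raw
#' coordinates, so inter-run geometry is preserved exactly.
#'
#' @param y numeric vector, sorted ascending.
#' @param epsilon minimal spacing, > 0.
#' @return numeric vector of adjusted coordinates, same length and order,
#'   non-decreasing with consecutive gaps >= `epsilon` (up to rounding); the
#'   integer attribute `"runs"` labels which run each coordinate ended in
#'   (singleton runs are untouched values).
#' @export
spread_overlaps <- function(y, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a single positive number", call. = FALSE)
  n <- length(y)
  if (n <= 1L) return(y)
  if (is.unsorted(y)) stop("coordinates must be sorted ascending", call. = FALSE)
  tol <- epsilon * 1e-9
  # stack of clusters: each holds the sum and count of its raw coordinates;
  # a cluster of size c spans (c-1)*epsilon centered on its raw mean
  sums <- numeric(n); cnts <- integer(n); top <- 0L
  lo <- function(i) sums[i] / cnts[i] - (cnts[i] - 1L) * epsilon / 2
  hi <- function(i) sums[i] / cnts[i] + (cnts[i] - 1L) * epsilon / 2
  for (i in seq_len(n)) {
    top <- top + 1L
    sums[top] <- y[i]; cnts[top] <- 1L
    while (top > 1L && lo(top) - hi(top - 1L) < epsilon - tol) {
      sums[top - 1L] <- sums[top - 1L] + sums[top]
      cnts[top - 1L] <- cnts[top - 1L] + cnts[top]
      top <- top - 1L
    }
  }
  out <- numeric(n); pos <- 1L
  for (i in seq_len(top)) {
    c <- cnts[i]
    out[pos:(pos + c - 1L)] <-
      sums[i] / c + (seq_len(c) - (c + 1) / 2) * epsilon
    pos <- pos + c
  }
  attr(out, "runs") <- rep(seq_len(top), cnts[seq_len(top)])
  out
}

#' Vertical placement of strain classes along the first principal component
#'
#' Classes are sorted by their coordinate on the chosen component (all members
#' of a class share one coordinate, which becomes the class coordinate), ties
#' broken by class id for determinism, and overlapping classes are separated
#' with [spread_overlaps()].
#'
#' @param ord an [ordinate()] result over the strains of the matrix the
#'   partition came from.
#' @param classes strain [compute_strain_classes()] partition.
#' @param epsilon minimal vertical spacing, > 0.
#' @param component which component orders the axis (default 1).
#' @return named numeric vector: class id -> y, ordered by ascending
#'   component coordinate.
#' @export
place_strain_classes <- function(ord, classes, epsilon, component = 1L) {
  stopifnot(inherits(ord, "ordination"), inherits(classes, "partition"))
  coords <- ord$coordinates[, component]
  raw <- vapply(seq_along(classes$ids), function(i) {
    v <- coords[classes$members[[i]]]
    if (diff(range(v)) > 1e-8)
      stop("members of class ", classes$ids[i],
           " do not share an ordination coordinate", call. = FALSE)
    v[[1L]]
  }, 0)
  o <- order(raw, seq_along(raw))       # ties broken by class index
  y <- spread_overlaps(raw[o], epsilon)
  stats::setNames(y, classes$ids[o])
}

#' Barycenter placement of resource classes
#'
#' Each resource class sits at the arithmetic mean of the vertical positions
#' of the strain classes that link to it. A resource class used by no strain
#' (in-degree 0) has no barycenter; it is placed at the midpoint of the
#' occupied vertical range and flagged in the `"fallback"` attribute.
#'
#' @param cg a [build_class_graph()].
#' @param strain_y named vector from [place_strain_classes()].
#' @return named numeric vector resource class id -> y, in partition order,
#'   with logical attribute `"fallback"`.
#' @export
place_resource_classes <- function(cg, strain_y) {
  stopifnot(inherits(cg, "class_graph"))
  ids <- cg$resource_partition$ids
  sids <- cg$strain_partition$ids
  y <- numeric(length(ids))
  fb <- logical(length(ids))
  mid <- mean(range(strain_y))
  for (j in seq_along(ids)) {
    pred <- cg$links[cg$links[, 2L] == j, 1L]
    if (length(pred) == 0L) { y[j] <- mid; fb[j] <- TRUE }
    else y[j] <- mean(strain_y[sids[pred]])
  }
  structure(stats::setNames(y, ids), fallback = fb)
}

#' Stack class members on the outer tiers
#'
#' Members of each class are placed at `epsilon` spacing centered on their
#' class's vertical position, in input order (first member on top). Overlaps
#' between neighbouring stacks are then resolved with the same run-spreading
#' rule as for the classes themselves.
#'
#' @param partition the strain or resource [compute_strain_classes()]
#'   partition being expanded.
#' @param class_y named vector class id -> y for that partition's classes.
#' @param epsilon minimal vertical spacing, > 0.
#' @return named numeric vector member name -> y.
#' @export
place_outer_tier <- function(partition, class_y, epsilon) {
  stopifnot(inherits(partition, "partition"))
  names_out <- character(0); target <- numeric(0); ord <- integer(0)
  pos <- 0L
  for (i in seq_along(partition$ids)) {
    mem <- partition$members[[i]]
    cy <- class_y[[partition$ids[i]]]
    k <- length(mem)
    # first member on top: offsets descend with member index
    off <- ((k + 1) / 2 - seq_len(k)) * epsilon
    names_out <- c(names_out, mem)
    target <- c(target, cy + off)
    ord <- c(ord, pos + seq_len(k)); pos <- pos + k
  }
  o <- order(target, ord)
  target[o] <- spread_overlaps(target[o], epsilon)
  stats::setNames(target, names_out)
}

#' Build the four-tiered graph
#'
#' Orchestrates the full pipeline on a binary phenotype matrix: equivalence
#' classes of strains and resources, ordination of strains by PCA on the
#' Hamming-similarity matrix, vertical placement (component coordinate with
#' overlap separation for strain classes, barycenters for resource classes,
#' member stacks on the outer tiers) and assembly of the directed layered
#' graph strains (tier 1) -> strain classes (tier 2) -> resource classes
#' (tier 3) -> resources (tier 4). Links run left to right only between
#' adjacent tiers. Larger first-component coordinates are drawn higher up.
#'
#' @param m a [phenotype_matrix()].
#' @param epsilon minimal vertical spacing, or `"auto"` (default): 1% of the
#'   range of the class coordinates on the ordering component (0.01 if the
#'   range is degenerate).
#' @param component ordination component used for the vertical axis.
#' @param method ordination method, see [pca_on_similarity()].
#' @param tier_x x coordinates of the four tiers, strictly increasing.
#' @return an object of class `"tiered_graph"`: list with
#'   `nodes` (data.frame: id, label, tier, x, y, size, degree),
#'   `edges` (data.frame: from, to), `epsilon`, plus the intermediate
#'   `class_graph` and `ordination` objects.
#' @examples
#' m <- phenotype_matrix(diag(3), paste0("s", 1:3), paste0("r", 1:3))
#' g <- build_tiered_graph(m)
#' nrow(g$nodes)  # 3 strains + 3 classes + 3 resource classes + 3 resources
#' @export
build_tiered_graph <- function(m, epsilon = "auto", component = 1L,
                               method = c("similarity-pca", "pcoa"),
                               tier_x = c(0, 1, 2, 3)) {
  stopifnot(inherits(m, "phenotype_matrix"))
  if (length(tier_x) != 4L || is.unsorted(tier_x, strictly = TRUE))
    stop("tier_x must be four strictly increasing values", call. = FALSE)
  sp <- compute_strain_classes(m)
  rp <- compute_resource_classes(m)
  cg <- build_class_graph(sp, rp, m)
  ord <- ordinate(m, axis = "strains", method = match.arg(method))

  class_raw <- vapply(sp$members,
                      function(mem) ord$coordinates[mem[[1L]], component], 0)
  if (identical(epsilon, "auto")) {
    rng <- diff(range(class_raw))
    epsilon <- if (rng > 0) 0.01 * rng else 0.01
  }
  sy <- place_strain_classes(ord, sp, epsilon, component)
  ry <- place_resource_classes(cg, sy)
  t1 <- place_outer_tier(sp, sy, epsilon)
  t4 <- place_outer_tier(rp, ry, epsilon)

  nodes <- rbind(
    data.frame(id = paste0("strain:", names(t1)), label = names(t1),
               tier = 1L, x = tier_x[1L], y = unname(t1), size = 1L,
               degree = 1L, stringsAsFactors = FALSE),
    data.frame(id = names(sy), label = names(sy), tier = 2L, x = tier_x[2L],
               y = unname(sy),
               size = lengths(sp$members)[match(names(sy), sp$ids)],
               degree = cg$out_degree[match(names(sy), sp$ids)],
               stringsAsFactors = FALSE),
    data.frame(id = names(ry), label = names(ry), tier = 3L, x = tier_x[3L],
               y = unname(ry),
               size = lengths(rp$members)[match(names(ry), rp$ids)],
               degree = cg$in_degree[match(names(ry), rp$ids)],
               stringsAsFactors = FALSE),
    data.frame(id = paste0("resource:", names(t4)), label = names(t4),
               tier = 4L, x = tier_x[4L], y = unname(t4), size = 1L,
               degree = 1L, stringsAsFactors = FALSE)
  )
  edges <- rbind(
    data.frame(from = paste0("strain:", names(sp$membership)),
               to = sp$ids[sp$membership], stringsAsFactors = FALSE),
    data.frame(from = sp$ids[cg$links[, 1L]], to = rp$ids[cg$links[, 2L]],
               stringsAsFactors = FALSE),
    data.frame(from = rp$ids[rp$membership],
               to = paste0("resource:", names(rp$membership)),
               stringsAsFactors = FALSE)
  )
  g <- structure(list(nodes = nodes, edges = edges, epsilon = epsilon,
                      class_graph = cg, ordination = ord),
                 class = "tiered_graph")
  validate_tiered_graph(g)
  g
}

#' Validate the structural invariants of a tiered graph
#'
#' Checks: x constant within a tier and increasing with tier; every edge runs
#' from tier t to tier t + 1; every tier-1 node has exactly one outgoing edge
#' and every tier-4 node exactly one incoming edge; no two tier-2 nodes
#' vertically closer than `epsilon`.
#'
#' @param g a `tiered_graph`.
#' @return `g` invisibly; errors on violation.
#' @export
validate_tiered_graph <- function(g) {
  stopifnot(inherits(g, "tiered_graph"))
  nd <- g$nodes; ed <- g$edges
  if (anyDuplicated(nd$id)) stop("duplicate node ids", call. = FALSE)
  xs <- tapply(nd$x, nd$tier, unique)
  if (any(lengths(xs) != 1L) || is.unsorted(unlist(xs), strictly = TRUE))
    stop("tier x coordinates must be constant per tier and increasing",
         call. = FALSE)
  ft <- nd$tier[match(ed$from, nd$id)]
  tt <- nd$tier[match(ed$to, nd$id)]
  if (anyNA(ft) || anyNA(tt)) stop("edge references unknown node",
                                   call. = FALSE)
  if (any(tt - ft != 1L))
    stop("edges must run from tier t to tier t+1 only", call. = FALSE)
  t1 <- nd$id[nd$tier == 1L]
  if (!all(table(factor(ed$from, levels = t1)) == 1L))
    stop("every tier-1 node needs exactly one outgoing edge", call. = FALSE)
  t4 <- nd$id[nd$tier == 4L]
  if (!all(table(factor(ed$to, levels = t4)) == 1L))
    stop("every tier-4 node needs exactly one incoming edge", call. = FALSE)
  y2 <- sort(nd$y[nd$tier == 2L])
  if (length(y2) > 1L && min(diff(y2)) < g$epsilon * (1 - 1e-6))
    stop("tier-2 nodes closer than epsilon", call. = FALSE)
  invisible(g)
}

#' Directed association matrix over all four tiers
#'
#' Adjacency of the tiered graph with nodes ordered by tier and, within a
#' tier, from top (largest y) to bottom. Non-zero blocks appear only between
#' adjacent tiers, which is the block structure the layout consumes.
#'
#' @param g a `tiered_graph`.
#' @return square 0/1 integer matrix with node ids as dimnames.
#' @export
association_matrix <- function(g) {
  stopifnot(inherits(g, "tiered_graph"))
  nd <- g$nodes[order(g$nodes$tier, -g$nodes$y), ]
  n <- nrow(nd)
  a <- matrix(0L, n, n, dimnames = list(nd$id, nd$id))
  a[cbind(match(g$edges$from, nd$id), match(g$edges$to, nd$id))] <- 1L
  a
}

#' @export
print.tiered_graph <- function(x, ...) {
  tn <- table(factor(x$nodes$tier, levels = 1:4))
  cat(sprintf(
    "tiered_graph: %d strains | %d strain classes | %d resource classes | %d resources; %d edges (epsilon %.4g)\n",
    tn[1L], tn[2L], tn[3L], tn[4L], nrow(x$edges), x$epsilon))
  invisible(x)
}
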