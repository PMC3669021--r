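#' Equivalence classes of identical phenotype profiles
#'
#' Two strains belong to the same class when their profiles agree at every
#' resource; dually, two resources share a class when exactly the same strains
#' use them. Classes are ordered by the input position of their first member,
#' and named `B1..Bk` (strains) or `R1..Rl` (resources), keeping provenance to
#' the source file rather than imposing an alphabetical order.
#'
#' @param m a [phenotype_matrix()].
#' @return an object of class `"partition"`: a list with elements
#'   \describe{
#'     \item{kind}{`"strain"` or `"resource"`}
#'     \item{ids}{class identifiers, `B1..` / `R1..`}
#'     \item{members}{list of character vectors, the names in each class}
#'     \item{profiles}{list of integer canonical profiles (the shared row or
#'       column)}
#'     \item{membership}{named integer vector mapping each entity to its
#'       class index}
#'   }
#' @examples
#' m <- phenotype_matrix(rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1)))
#' compute_strain_classes(m)$members
#' @export
compute_strain_classes <- function(m) {
  stopifnot(inherits(m, "phenotype_matrix"))
  make_partition(unclass(m), rownames(m), "strain", "B")
}

#' @rdname compute_strain_classes
#' @export
compute_resource_classes <- function(m) {
  stopifnot(inherits(m, "phenotype_matrix"))
  make_partition(t(unclass(m)), colnames(m), "resource", "R")
}

make_partition <- function(x, names, kind, prefix) {
  keys <- apply(x, 1L, paste, collapse = "")
  first <- !duplicated(keys)
  levels <- keys[first]                    # first-member input order
  idx <- match(keys, levels)
  members <- split(names, idx)
  structure(list(
    kind = kind,
    ids = paste0(prefix, seq_along(levels)),
    members = unname(members),
    profiles = lapply(which(first), function(i) unname(x[i, ])),
    membership = stats::setNames(idx, names)
  ), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition of %d %ss into %d equivalence classes\n",
              length(x$membership), x$kind, length(x$ids)))
  sizes <- lengths(x$members)
  for (i in seq_along(x$ids))
    cat(sprintf("  %s (n=%d): %s\n", x$ids[i], sizes[i],
                paste(x$members[[i]], collapse = ", ")))
  invisible(x)
}

#' Reduced bipartite graph between strain classes and resource classes
#'
#' A strain class X links to a resource class Y when every strain in X uses
#' every resource in Y. Because classes collapse identical rows and columns,
#' the relation between a strain class and a resource class is all-or-none;
#' this is asserted, not assumed. Each strain class is annotated with its
#' out-degree (number of resource classes it links to) and each resource class
#' with its in-degree (number of strain classes linking to it) -- the counts
#' displayed beside class nodes in the four-tiered graph.
#'
#' @param sp,rp strain and resource partitions computed from `m` with
#'   [compute_strain_classes()] / [compute_resource_classes()].
#' @param m the [phenotype_matrix()] both partitions were computed from.
#' @return an object of class `"class_graph"`: list with `strain_partition`,
#'   `resource_partition`, `links` (two-column integer matrix of class index
#'   pairs strain -> resource), `out_degree`, `in_degree`.
#' @export
build_class_graph <- function(sp, rp, m) {
  stopifnot(inherits(sp, "partition"), sp$kind == "strain",
            inherits(rp, "partition"), rp$kind == "resource",
            inherits(m, "phenotype_matrix"))
  if (!identical(sort(names(sp$membership)), sort(rownames(m))) ||
      !identical(sort(names(rp$membership)), sort(colnames(m))))
    stop("partitions do not match the matrix names", call. = FALSE)
  k <- length(sp$ids); l <- length(rp$ids)
  links <- matrix(integer(0), 0L, 2L,
                  dimnames = list(NULL, c("strain_class", "resource_class")))
  for (i in seq_len(k)) {
    prof <- sp$profiles[[i]]
    for (j in seq_len(l)) {
      cols <- match(rp$members[[j]], colnames(m))
      vals <- prof[cols]
      if (length(unique(vals)) > 1L)
        stop("class relation is not all-or-none; partitions inconsistent with matrix",
             call. = FALSE)
      if (vals[1L] == 1L)
        links <- rbind(links, c(i, j))
    }
  }
  structure(list(
    strain_partition = sp,
    resource_partition = rp,
    links = links,
    out_degree = tabulate(links[, 1L], nbins = k),
    in_degree = tabulate(links[, 2L], nbins = l)
  ), class = "class_graph")
}

#' @export
print.class_graph <- function(x, ...) {
  cat(sprintf("class_graph: %d strain classes, %d resource classes, %d links\n",
              length(x$strain_partition$ids), length(x$resource_partition$ids),
              nrow(x$links)))
  invisible(x)
}

#' Export a partition listing as TSV
#'
#' One line per class: id, comma-separated members, canonical profile string,
#' and the class degree from a [build_class_graph()] if supplied.
#'
#' @param p a `partition`.
#' @param path output path.
#' @param degrees optional integer vector of per-class degrees.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(p, path, degrees = NULL) {
  stopifnot(inherits(p, "partition"))
  df <- data.frame(
    class = p$ids,
    members = vapply(p$members, paste, "", collapse = ","),
    profile = vapply(p$profiles, paste, "", collapse = ""),
    stringsAsFactors = FALSE
  )
  if (!is.null(degrees)) df$degree <- degrees
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
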