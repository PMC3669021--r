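#' Write a tiered graph to GraphML
#'
#' Emits standard GraphML 1.0 with per-node data keys `label` (string),
#' `tier` (int, 1-4), `x`, `y` (double), `size` (class cardinality) and
#' `degree` (the annotated connection count); edges are directed and run left
#' to right between adjacent tiers. With `yed_compat = TRUE` the file
#' additionally carries yFiles node-graphics elements (geometry and label) so
#' it opens fully positioned in the yEd editor; without the flag the output
#' sticks to plain attribute keys for maximum portability.
#'
#' The graph is validated with [validate_tiered_graph()] before anything is
#' written.
#'
#' @param g a [build_tiered_graph()] result.
#' @param path output file path.
#' @param yed_compat also emit yFiles geometry/label extensions.
#' @param scale multiplier from abstract layout units to yFiles pixels
#'   (only used with `yed_compat`).
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path, yed_compat = FALSE, scale = 150) {
  validate_tiered_graph(g)
  ns_y <- "http://www.yworks.com/xml/graphml"
  root <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns",
    "xmlns:xsi" = "http://www.w3.org/2001/XMLSchema-instance",
    "xsi:schemaLocation" = paste(
      "http://graphml.graphdrawing.org/xmlns",
      "http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd"))
  if (yed_compat) xml2::xml_set_attr(root, "xmlns:y", ns_y)

  keys <- list(
    c("d_label", "label", "string"), c("d_tier", "tier", "int"),
    c("d_x", "x", "double"), c("d_y", "y", "double"),
    c("d_size", "size", "int"), c("d_degree", "degree", "int"))
  for (k in keys)
    xml2::xml_add_child(root, "key", id = k[1L], "for" = "node",
                        "attr.name" = k[2L], "attr.type" = k[3L])
  if (yed_compat)
    xml2::xml_add_child(root, "key", id = "d_graphics", "for" = "node",
                        "yfiles.type" = "nodegraphics")

  graph <- xml2::xml_add_child(root, "graph", id = "G",
                               edgedefault = "directed")
  nd <- g$nodes
  for (i in seq_len(nrow(nd))) {
    node <- xml2::xml_add_child(graph, "node", id = nd$id[i])
    add_data <- function(key, value)
      xml2::xml_add_child(node, "data", value, key = key)
    add_data("d_label", nd$label[i])
    add_data("d_tier", as.character(nd$tier[i]))
    add_data("d_x", format(nd$x[i], digits = 15))
    add_data("d_y", format(nd$y[i], digits = 15))
    add_data("d_size", as.character(nd$size[i]))
    add_data("d_degree", as.character(nd$degree[i]))
    if (yed_compat) {
      data <- xml2::xml_add_child(node, "data", key = "d_graphics")
      shape <- xml2::xml_add_child(data, "y:ShapeNode")
      # yFiles y grows downward; flip so larger PC1 stays on top
      xml2::xml_add_child(shape, "y:Geometry", height = "20", width = "40",
                          x = format(nd$x[i] * scale, digits = 10),
                          y = format(-nd$y[i] * scale, digits = 10))
      xml2::xml_add_child(shape, "y:NodeLabel", nd$label[i])
    }
  }
  for (i in seq_len(nrow(g$edges)))
    xml2::xml_add_child(graph, "edge", id = paste0("e", i),
                        source = g$edges$from[i], target = g$edges$to[i])
  xml2::write_xml(root, path)
  invisible(path)
}

#' Read back a GraphML file written by [write_graphml()]
#'
#' Parses nodes with their attribute keys and the directed edge list; used to
#' verify serialization round-trips and to post-process layouts.
#'
#' @param path GraphML file path.
#' @return list with `nodes` (data.frame: id, label, tier, x, y, size,
#'   degree) and `edges` (data.frame: from, to).
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
  keydefs <- xml2::xml_find_all(doc, ".//g:key[@attr.name]", ns)
  keymap <- stats::setNames(xml2::xml_attr(keydefs, "attr.name"),
                            xml2::xml_attr(keydefs, "id"))
  nodes_xml <- xml2::xml_find_all(doc, ".//g:graph/g:node", ns)
  rows <- lapply(nodes_xml, function(node) {
    data <- xml2::xml_find_all(node, "./g:data", ns)
    keys <- keymap[xml2::xml_attr(data, "key")]
    vals <- stats::setNames(xml2::xml_text(data), keys)
    vals <- vals[!is.na(keys)]
    data.frame(id = xml2::xml_attr(node, "id"),
               label = vals[["label"]], tier = as.integer(vals[["tier"]]),
               x = as.numeric(vals[["x"]]), y = as.numeric(vals[["y"]]),
               size = as.integer(vals[["size"]]),
               degree = as.integer(vals[["degree"]]),
               stringsAsFactors = FALSE)
  })
  edges_xml <- xml2::xml_find_all(doc, ".//g:graph/g:edge", ns)
  list(nodes = do.call(rbind, rows),
       edges = data.frame(from = xml2::xml_attr(edges_xml, "source"),
                          to = xml2::xml_attr(edges_xml, "target"),
                          stringsAsFactors = FALSE))
}

#' Write the profile table ordered to match the graph
#'
#' A companion table to the four-tiered graph: strains as rows ordered by
#' their tier-1 vertical position (top first), resources as columns ordered by
#' tier-4 position, a mark (`X`) wherever the matrix cell is 1. The second and
#' third header columns / rows carry the equivalence-class ids, making class
#' boundaries visible.
#'
#' @param m the [phenotype_matrix()] the graph was built from.
#' @param g the matching [build_tiered_graph()].
#' @param path output TSV path.
#' @param mark string used for positive cells.
#' @return invisibly, the reordered character matrix that was written.
#' @export
write_profile_table <- function(m, g, path, mark = "X") {
  stopifnot(inherits(m, "phenotype_matrix"), inherits(g, "tiered_graph"))
  nd <- g$nodes
  t1 <- nd[nd$tier == 1L, ]; t4 <- nd[nd$tier == 4L, ]
  if (!setequal(t1$label, rownames(m)) || !setequal(t4$label, colnames(m)))
    stop("matrix and graph were not built from the same data", call. = FALSE)
  row_order <- t1$label[order(-t1$y)]
  col_order <- t4$label[order(-t4$y)]
  sp <- g$class_graph$strain_partition
  rp <- g$class_graph$resource_partition
  cells <- ifelse(unclass(m)[row_order, col_order, drop = FALSE] == 1L,
                  mark, "")
  out <- c(
    paste(c("strain", "class", col_order), collapse = "\t"),
    paste(c("", "", rp$ids[rp$membership[col_order]]), collapse = "\t"),
    vapply(seq_along(row_order), function(i)
      paste(c(row_order[i], sp$ids[sp$membership[row_order[i]]],
              cells[i, ]), collapse = "\t"), "")
  )
  writeLines(out, path)
  invisible(cells)
}
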