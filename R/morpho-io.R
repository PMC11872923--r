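# SWC input/output and the Morphology container.
#
# A morphology is a data.frame of nodes (id, type, x, y, z, radius, parent)
# with class "morphology". Types follow SWC semantics: 1 = soma, 2 = axon,
# 3 = dendrite. The soma root has parent -1. Coordinates are micrometres.

SWC_TYPES <- c(soma = 1L, axon = 2L, dendrite = 3L)

#' Construct a morphology from a node table
#'
#' @param nodes data.frame with columns `id`, `type` (integer SWC code or one
#'   of `"soma"`, `"axon"`, `"dendrite"`), `x`, `y`, `z`, `radius`, `parent`.
#' @return An object of class `morphology` (a validated node data.frame).
#' @export
morphology <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes)))
    stopf("morphology nodes need columns: %s", paste(need, collapse = ", "))
  if (is.character(nodes$type) || is.factor(nodes$type)) {
    code <- SWC_TYPES[as.character(nodes$type)]
    if (anyNA(code)) stopf("unknown compartment type")
    nodes$type <- unname(code)
  }
  nodes$type <- as.integer(nodes$type)
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  validate_morphology(nodes)
  structure(nodes, class = c("morphology", "data.frame"))
}

validate_morphology <- function(nodes) {
  if (anyDuplicated(nodes$id))
    stopf("duplicate node id(s): %s",
          paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (!all(is.finite(as.matrix(nodes[, c("x", "y", "z")]))))
    stopf("non-finite coordinates")
  if (any(nodes$radius < 0)) stopf("negative radius")
  roots <- which(nodes$parent == -1L)
  if (length(roots) != 1L) stopf("morphology must have exactly one root")
  known <- c(-1L, nodes$id)
  bad <- which(!(nodes$parent %in% known))
  if (length(bad))
    stopf("node %d (line %d) references missing parent %d",
          nodes$id[bad[1]], bad[1], nodes$parent[bad[1]])
  # cycle check: walk up from every node; a tree walk terminates at the root
  idx <- match(nodes$parent, nodes$id)
  for (i in seq_len(nrow(nodes))) {
    seen <- integer(0); j <- i
    while (!is.na(idx[j])) {
      if (j %in% seen) stopf("cycle detected at node id %d", nodes$id[j])
      seen <- c(seen, j); j <- idx[j]
      if (length(seen) > nrow(nodes)) stopf("cycle detected")
    }
  }
  invisible(nodes)
}

#' Read an SWC morphology file
#'
#' @param con Path or connection to a 7-column SWC file (`#` comments allowed).
#' @return A [morphology()] object.
#' @export
read_swc <- function(con) {
  lines <- readLines(con)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stopf("SWC stream contains no data lines")
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nfield <- lengths(fields)
  if (any(nfield != 7L))
    stopf("malformed SWC line %d: expected 7 columns, got %d",
          which(keep)[which(nfield != 7L)[1]], nfield[nfield != 7L][1])
  m <- matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE)
  if (anyNA(m)) stopf("non-numeric field in SWC data")
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5],
                      radius = m[, 6], parent = as.integer(m[, 7]))
  morphology(nodes)
}

#' Write a morphology as SWC
#'
#' @param m A [morphology()].
#' @param con Path or connection; omit to return the lines invisibly.
#' @export
write_swc <- function(m, con = NULL) {
  stopifnot(inherits(m, "morphology"))
  fmt <- function(v) formatC(v, format = "g", digits = 15)
  lines <- paste(m$id, m$type, fmt(m$x), fmt(m$y), fmt(m$z),
                 fmt(m$radius), m$parent)
  lines <- c("# SWC exported by synplastkit", lines)
  if (!is.null(con)) writeLines(lines, con)
  invisible(lines)
}

soma_node <- function(m) {
  i <- which(m$parent == -1L)
  m[i, , drop = FALSE]
}

# Edge table (parent -> child) with endpoint coordinates; `types` filters on
# the child node's type name(s).
morpho_edges <- function(m, types = NULL) {
  idx <- match(m$parent, m$id)
  child <- which(!is.na(idx))
  if (!is.null(types)) {
    code <- SWC_TYPES[types]
    child <- child[m$type[child] %in% code]
  }
  par <- idx[child]
  data.frame(
    x0 = m$x[par], y0 = m$y[par], z0 = m$z[par],
    x1 = m$x[child], y1 = m$y[child], z1 = m$z[child],
    child_id = m$id[child], parent_id = m$id[par])
}

edge_lengths <- function(e) {
  sqrt((e$x1 - e$x0)^2 + (e$y1 - e$y0)^2 + (e$z1 - e$z0)^2)
}

#' Total path length of a morphology
#' @param m A [morphology()].
#' @param types Optional compartment filter, e.g. `"dendrite"`.
#' @return Length in micrometres.
#' @export
total_path_length <- function(m, types = NULL) {
  sum(edge_lengths(morpho_edges(m, types)))
}
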