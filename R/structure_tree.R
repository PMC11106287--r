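# Atlas region ontology: a rooted tree of brain regions (Allen-structure-graph
# style), plus compilation of custom hierarchy levels where each fine region is
# absorbed into a selected ancestor.

#' Construct and validate a structure tree
#'
#' A structure tree is the region ontology of an annotation volume: a set of
#' nodes `{id, name, acronym, parent_id}` forming a single rooted tree. Region
#' id 0 is reserved for background and may never be a node.
#'
#' @param nodes A data frame with columns `id` (positive integer), `name`,
#'   `acronym` (character) and `parent_id` (integer, `NA` for the root).
#' @return An object of class `structure_tree`: the validated node table with
#'   a `root` attribute.
#' @examples
#' tr <- structure_tree(data.frame(
#'   id = c(1, 2, 3), name = c("root", "A", "B"),
#'   acronym = c("R", "A", "B"), parent_id = c(NA, 1, 1)))
#' @export
structure_tree <- function(nodes) {
  req <- c("id", "name", "acronym", "parent_id")
  if (!is.data.frame(nodes) || !all(req %in% names(nodes))) {
    stopf("nodes must be a data frame with columns %s", paste(req, collapse = ", "))
  }
  nodes <- nodes[, req]
  nodes$id <- as.integer(nodes$id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  if (anyNA(nodes$id) || any(nodes$id <= 0L)) {
    stopf("region ids must be positive integers (0 is reserved for background)")
  }
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup)) stopf("duplicate region id(s): %s", paste(unique(dup), collapse = ", "))
  roots <- nodes$id[is.na(nodes$parent_id)]
  if (length(roots) == 0L) stopf("tree has no root (no node with missing parent_id)")
  if (length(roots) > 1L) {
    stopf("multiple roots: %s", paste(roots, collapse = ", "))
  }
  dangling <- setdiff(nodes$parent_id[!is.na(nodes$parent_id)], nodes$id)
  if (length(dangling)) {
    stopf("dangling parent_id(s) not present in tree: %s",
          paste(dangling, collapse = ", "))
  }
  # acyclicity: walk every node to the root, bounded by node count
  parent <- stats::setNames(nodes$parent_id, nodes$id)
  n <- nrow(nodes)
  for (id in nodes$id) {
    cur <- id
    steps <- 0L
    while (!is.na(parent[[as.character(cur)]])) {
      cur <- parent[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > n) stopf("parent links contain a cycle (reached from id %d)", id)
    }
  }
  structure(nodes, class = c("structure_tree", "data.frame"), root = roots)
}

#' @export
print.structure_tree <- function(x, ...) {
  cat(sprintf("structure_tree: %d regions, root id %d\n", nrow(x), attr(x, "root")))
  invisible(x)
}

#' Read a structure tree from a hierarchy JSON file
#'
#' The file is a JSON array of objects `{"id", "name", "acronym",
#' "parent_id"}`, with the root's `parent_id` null.
#'
#' @param path Path to the hierarchy file.
#' @return A [structure_tree].
#' @export
load_structure_tree <- function(path) {
  if (!file.exists(path)) stopf("hierarchy file not found: %s", path)
  nodes <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.data.frame(nodes)) stopf("hierarchy file must be a JSON array of node objects")
  if (!"parent_id" %in% names(nodes)) nodes$parent_id <- NA_integer_
  structure_tree(nodes)
}

#' Write a structure tree to a hierarchy JSON file
#' @param tree A [structure_tree].
#' @param path Output path.
#' @export
write_structure_tree <- function(tree, path) {
  df <- as.data.frame(tree)
  jsonlite::write_json(df, path, dataframe = "rows", na = "null", auto_unbox = TRUE)
  invisible(path)
}

tree_parent_vec <- function(tree) {
  stats::setNames(tree$parent_id, tree$id)
}

# ancestors of id, nearest first, excluding id itself
tree_ancestors <- function(parent, id) {
  out <- integer(0)
  cur <- parent[[as.character(id)]]
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- parent[[as.character(cur)]]
  }
  out
}

#' Compile a custom hierarchy level
#'
#' Maps every region of the tree to its nearest ancestor-or-self among
#' `selected_ids`; regions with no selected ancestor map to [UNASSIGNED].
#' This is the "intermediate hierarchy" operation: a custom atlas granularity
#' where each fine region is absorbed into a selected coarser region.
#'
#' @param tree A [structure_tree].
#' @param selected_ids Integer vector of selected region ids. No selected id
#'   may be an ancestor of another selected id.
#' @return An object of class `hierarchy_mapping` with elements
#'   `selected_ids` and `map` (named integer vector over all tree ids).
#' @examples
#' tr <- structure_tree(data.frame(
#'   id = 1:5, name = c("R", "A", "B", "a1", "a2"),
#'   acronym = c("R", "A", "B", "a1", "a2"),
#'   parent_id = c(NA, 1, 1, 2, 2)))
#' h <- compile_hierarchy(tr, c(2, 3))
#' h$map[["4"]]  # a1 -> A
#' @export
compile_hierarchy <- function(tree, selected_ids) {
  stopifnot(inherits(tree, "structure_tree"))
  selected_ids <- as.integer(selected_ids)
  bad <- setdiff(selected_ids, tree$id)
  if (length(bad)) stopf("selected id(s) not in tree: %s", paste(bad, collapse = ", "))
  parent <- tree_parent_vec(tree)
  sel <- unique(selected_ids)
  # nested-selection check
  for (s in sel) {
    anc <- intersect(tree_ancestors(parent, s), sel)
    if (length(anc)) {
      stopf("nested selection: selected id %d is a descendant of selected id %d",
            s, anc[1])
    }
  }
  map <- vapply(tree$id, function(id) {
    chain <- c(id, tree_ancestors(parent, id))
    hit <- chain[chain %in% sel]
    if (length(hit)) hit[1] else UNASSIGNED
  }, integer(1))
  names(map) <- tree$id
  structure(list(selected_ids = sel, map = map), class = "hierarchy_mapping")
}

#' @export
print.hierarchy_mapping <- function(x, ...) {
  cat(sprintf("hierarchy_mapping: %d selected regions over %d tree ids (%d unassigned)\n",
              length(x$selected_ids), length(x$map), sum(x$map == UNASSIGNED)))
  invisible(x)
}

#' Look up the custom id for one or more region ids
#'
#' Background (0) maps to 0 and [UNASSIGNED] maps to itself; any other id
#' absent from the mapping is an error (tree/volume mismatch).
#'
#' @param h A `hierarchy_mapping`.
#' @param ids Integer vector of region ids.
#' @return Integer vector of custom ids.
#' @export
hierarchy_lookup <- function(h, ids) {
  stopifnot(inherits(h, "hierarchy_mapping"))
  ids <- as.integer(ids)
  out <- ids
  special <- ids == 0L | ids == UNASSIGNED
  todo <- !special
  if (any(todo)) {
    idx <- match(as.character(ids[todo]), names(h$map))
    if (anyNA(idx)) {
      missing <- unique(ids[todo][is.na(idx)])
      stopf("region id(s) absent from hierarchy mapping: %s",
            paste(missing, collapse = ", "))
    }
    out[todo] <- unname(h$map[idx])
  }
  out
}

#' Read/write a custom hierarchy selection file
#'
#' The custom-hierarchy file is JSON `{"selected_ids": [...]}`.
#'
#' @param path File path.
#' @return `read_hierarchy_selection` returns an integer vector of ids.
#' @export
read_hierarchy_selection <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$selected_ids)) stopf("file %s has no selected_ids field", path)
  as.integer(obj$selected_ids)
}

#' @rdname read_hierarchy_selection
#' @param selected_ids Integer vector of selected region ids.
#' @export
write_hierarchy_selection <- function(selected_ids, path) {
  jsonlite::write_json(list(selected_ids = as.integer(selected_ids)), path)
  invisible(path)
}
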