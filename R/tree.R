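#' Construct a clone tree
#'
#' A clone tree is a rooted tree whose root is the normal diploid clone
#' (literal ID `"diploid"`), whose single child is the MRCA of all tumour
#' clones, and whose remaining nodes are tumour clones.
#'
#' @param edges data.frame with character columns `parent` and `child`, one row
#'   per directed edge.
#' @return An object of class `clone_tree` with components `nodes` (all clone
#'   IDs in depth-first preorder from the root), `edges`, `root`, `parent`
#'   (named vector, `NA` for the root) and `children` (named list).
#' @export
clone_tree <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("parent", "child") %in% names(edges)))
  edges <- data.frame(parent = as.character(edges$parent),
                      child  = as.character(edges$child),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(edges$child))
    stop("clone tree: node(s) with more than one parent: ",
         paste(unique(edges$child[duplicated(edges$child)]), collapse = ", "))
  nodes <- unique(c(edges$parent, edges$child))
  roots <- setdiff(edges$parent, edges$child)
  if (length(roots) != 1L)
    stop("clone tree: expected exactly one root, found: ",
         paste(roots, collapse = ", "))
  root <- roots
  if (root != "diploid")
    stop("clone tree: the root must be the normal clone with ID 'diploid', got '",
         root, "'")
  children <- split(edges$child, factor(edges$parent, levels = nodes))
  if (length(children[[root]]) != 1L)
    stop("clone tree: the diploid root must have exactly one child (the MRCA)")
  parent <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  parent[edges$child] <- edges$parent
  ## depth-first preorder; also detects cycles / disconnected nodes
  order <- character(0)
  stack <- root
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    order <- c(order, v)
    kids <- children[[v]]
    if (length(kids)) stack <- c(kids, stack)
    if (length(order) > length(nodes)) stop("clone tree: cycle detected")
  }
  if (length(order) != length(nodes))
    stop("clone tree: disconnected nodes: ",
         paste(setdiff(nodes, order), collapse = ", "))
  structure(list(nodes = order, edges = edges, root = root,
                 parent = parent, children = children),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("clone_tree:", length(x$nodes) - 1L, "tumour clones, root =", x$root,
      ", MRCA =", mrca_clone(x), "\n")
  invisible(x)
}

#' Tumour clones of a tree in depth-first preorder (root excluded)
#' @param tree a `clone_tree`
#' @export
tumour_clones <- function(tree) setdiff(tree$nodes, tree$root)

#' The MRCA clone (single child of the diploid root)
#' @param tree a `clone_tree`
#' @export
mrca_clone <- function(tree) tree$children[[tree$root]]

#' Descendants of a clone
#' @param tree a `clone_tree`
#' @param node clone ID
#' @param include_self include `node` itself
#' @export
tree_descendants <- function(tree, node, include_self = FALSE) {
  stopifnot(node %in% tree$nodes)
  out <- character(0)
  stack <- tree$children[[node]]
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    out <- c(out, v)
    stack <- c(tree$children[[v]], stack)
  }
  if (include_self) c(node, out) else out
}

#' Ancestors of a clone, nearest first (root last)
#' @param tree a `clone_tree`
#' @param node clone ID
#' @export
tree_ancestors <- function(tree, node) {
  out <- character(0)
  p <- tree$parent[[node]]
  while (!is.na(p)) { out <- c(out, p); p <- tree$parent[[p]] }
  out
}

#' Read a clone tree from file
#'
#' Accepts either a two-column TSV (`parent<TAB>child`, with header) or a
#' Newick file with named internal nodes (parsed with \pkg{ape} and converted
#' to an edge list).
#'
#' @param path file path
#' @return a `clone_tree`
#' @export
read_tree <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\\(", first)) {
    phy <- ape::read.tree(path)
    if (is.null(phy$node.label) || any(phy$node.label == ""))
      stop("Newick clone trees must have named internal nodes")
    labs <- c(phy$tip.label, phy$node.label)
    edges <- data.frame(parent = labs[phy$edge[, 1L]],
                        child  = labs[phy$edge[, 2L]],
                        stringsAsFactors = FALSE)
  } else {
    edges <- utils::read.delim(path, colClasses = "character")
    if (!all(c("parent", "child") %in% names(edges)))
      stop("tree TSV must have columns 'parent' and 'child'")
  }
  clone_tree(edges)
}

#' Write a clone tree as a two-column TSV
#' @param tree a `clone_tree`
#' @param path output path
#' @export
write_tree_tsv <- function(tree, path) {
  utils::write.table(tree$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
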