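#' Rooted phylogenetic trees with exact branch lengths
#'
#' A `rooted_tree` stores a rooted phylogenetic X-tree: a distinguished
#' root, directed edges away from it, uniquely labelled leaves, and a
#' strictly positive length on every edge (the root itself carries none).
#' Vertices are integer ids `1..n_node`; the edge above vertex `v` is
#' identified by `v` (its child endpoint), a convention used throughout.
#' Lengths are [rational] (or [epslen] during reversal constructions).
#'
#' Structural invariants enforced by [validate_tree()]:
#' * exactly one vertex (the root) has in-degree 0, all others in-degree 1;
#' * every non-root, non-leaf vertex has out-degree >= 2 (no suppressed
#'   unifurcations are stored);
#' * leaf labels are unique and non-empty;
#' * every edge length, when present, is strictly positive.
#'
#' @param parent integer vector, `parent[v]` is the parent of `v`
#'   (`NA` at the root).
#' @param children list of integer vectors in stored (input) order.
#' @param label character vector of vertex labels (`NA` where unnamed);
#'   every leaf must be labelled.
#' @param lengths optional [rational]/[epslen] vector of edge lengths
#'   indexed by child vertex.
#' @return an object of class `rooted_tree`.
#' @seealso [parse_newick()], [write_newick()]
#' @export
rooted_tree <- function(parent, children, label, lengths = NULL) {
  tr <- structure(
    list(parent = as.integer(parent), children = children,
         label = as.character(label), length = lengths,
         root = which(is.na(parent))[1]),
    class = "rooted_tree")
  validate_tree(tr)
  tr
}

#' @rdname rooted_tree
#' @param tree a `rooted_tree`.
#' @export
validate_tree <- function(tree) {
  p <- tree$parent
  n <- length(p)
  if (sum(is.na(p)) != 1L) stop("tree must have exactly one root")
  root <- which(is.na(p))
  if (tree$root != root) stop("root slot inconsistent")
  for (v in seq_len(n)) {
    kids <- tree$children[[v]]
    if (length(kids) && !all(p[kids] == v)) stop("parent/children mismatch")
    if (v != root && length(kids) == 1L)
      stop("vertex ", v, " has out-degree 1; unifurcations must be suppressed")
  }
  # note: the root MAY have out-degree 1 (it is never suppressed when
  # pruning); newly parsed trees are rejected in parse_newick() instead
  lv <- leaves(tree)
  labs <- tree$label[lv]
  if (anyNA(labs) || any(labs == "")) stop("every leaf needs a non-empty label")
  if (anyDuplicated(labs)) stop("duplicate leaf label: ",
                                labs[duplicated(labs)][1])
  if (!is.null(tree$length)) {
    len <- tree$length
    idx <- setdiff(seq_len(n), root)
    ok <- if (is_epslen(len)) ep_positive(len[idx])
          else len[idx] > rational("0")
    if (!all(ok)) stop("all edge lengths must be strictly positive")
  }
  invisible(tree)
}

#' @export
print.rooted_tree <- function(x, ...) {
  cat("<rooted_tree> ", n_leaves(x), " leaves, ",
      length(x$parent), " vertices",
      if (is.null(x$length)) ", no lengths" else "", "\n", sep = "")
  cat(write_newick(x), "\n")
  invisible(x)
}

#' Basic structural queries
#'
#' @param tree a [rooted_tree].
#' @return `leaves()`: integer vertex ids; `leaf_labels()`: taxon names
#'   (in vertex-id order); `n_leaves()`: count; `tree_edges()`: integer
#'   child ids identifying each edge; `preorder()`: vertices in preorder.
#' @name tree-queries
NULL

#' @rdname tree-queries
#' @export
leaves <- function(tree) {
  which(lengths(tree$children) == 0L)
}

#' @rdname tree-queries
#' @export
leaf_labels <- function(tree) tree$label[leaves(tree)]

#' @rdname tree-queries
#' @export
n_leaves <- function(tree) length(leaves(tree))

#' @rdname tree-queries
#' @export
tree_edges <- function(tree) setdiff(seq_along(tree$parent), tree$root)

#' @rdname tree-queries
#' @export
preorder <- function(tree) {
  out <- integer(length(tree$parent))
  k <- 0L
  stack <- tree$root
  while (length(stack)) {
    v <- stack[[1]]
    stack <- stack[-1]
    k <- k + 1L
    out[k] <- v
    stack <- c(tree$children[[v]], stack)
  }
  out
}

#' Resolve a vertex by label
#'
#' @param tree a [rooted_tree].
#' @param label vertex label (leaf taxon name or interior annotation).
#' @return integer vertex id.
#' @export
node_id <- function(tree, label) {
  id <- match(label, tree$label)
  if (anyNA(id)) stop("no vertex labelled '", label[is.na(id)][1], "'")
  id
}

#' Cluster of an edge
#'
#' The set of taxa descended from the terminal (child) vertex of an edge.
#'
#' @param tree a [rooted_tree].
#' @param edge the edge's child vertex: an integer id or a vertex label.
#' @return character vector of taxon names.
#' @examples
#' tr <- parse_newick("((a:1,b:1)m:1,c:2);")
#' cluster(tr, "m")
#' @export
cluster <- function(tree, edge) {
  v <- if (is.character(edge)) node_id(tree, edge) else as.integer(edge)
  if (is.na(v) || v < 1L || v > length(tree$parent))
    stop("unknown edge: ", edge)
  if (v == tree$root) stop("the root has no incoming edge")
  sort_taxa(tree$label[descendant_leaves(tree, v)])
}

descendant_leaves <- function(tree, v) {
  out <- integer()
  stack <- v
  while (length(stack)) {
    u <- stack[[1]]
    stack <- stack[-1]
    kids <- tree$children[[u]]
    if (!length(kids)) out <- c(out, u) else stack <- c(kids, stack)
  }
  out
}

n_descendant_leaves <- function(tree, v) length(descendant_leaves(tree, v))

#' m-cherries of a tree
#'
#' An m-cherry is a maximal set of m >= 2 leaves sharing a parent that has
#' no non-leaf children.  In binary trees every m-cherry is an ordinary
#' cherry (m = 2).
#'
#' @param tree a [rooted_tree].
#' @return a list with one entry per m-cherry: `list(parent = id,
#'   leaves = taxon names)`.
#' @export
m_cherries <- function(tree) {
  out <- list()
  for (v in seq_along(tree$parent)) {
    kids <- tree$children[[v]]
    if (length(kids) >= 2L && all(lengths(tree$children[kids]) == 0L)) {
      out[[length(out) + 1L]] <-
        list(parent = v, leaves = sort(tree$label[kids]))
    }
  }
  out
}

#' Isolated leaves
#'
#' A leaf x with parent v != root is isolated when x lies in no m-cherry
#' and no vertex strictly inside the root-to-v path is itself the parent
#' of a leaf.  Isolated leaves are the extra extinctions that rigid
#' interior indices require before a complete ranking reversal is possible.
#'
#' @param tree a [rooted_tree].
#' @return character vector of taxon names (sorted).
#' @examples
#' isolated_leaves(fig3_tree())  # x5 and x8
#' @export
isolated_leaves <- function(tree) {
  root <- tree$root
  in_mcherry <- unlist(lapply(m_cherries(tree), `[[`, "leaves"))
  out <- character()
  for (x in leaves(tree)) {
    v <- tree$parent[x]
    if (is.na(v) || v == root) next
    if (tree$label[x] %in% in_mcherry) next
    ok <- TRUE
    u <- tree$parent[v]
    while (!is.na(u) && u != root) {
      if (any(lengths(tree$children[tree$children[[u]]]) == 0L)) {
        ok <- FALSE
        break
      }
      u <- tree$parent[u]
    }
    # the root endpoint is excluded from the test by definition
    if (ok) out <- c(out, tree$label[x])
  }
  sort(out)
}

#' Canonical shape key of a pendant subtree
#'
#' Encodes the rooted unlabelled shape below `vertex` as a string:
#' a leaf is `"L"`, an interior vertex is the parenthesised, lexically
#' sorted concatenation of its children's keys.  Two vertices receive the
#' same key iff their pendant subtrees are isomorphic as rooted shapes.
#'
#' @param tree a [rooted_tree].
#' @param vertex integer id or vertex label.
#' @return a character scalar.
#' @export
shape_key <- function(tree, vertex = tree$root) {
  v <- if (is.character(vertex)) node_id(tree, vertex) else as.integer(vertex)
  shape_key_int(tree, v)
}

shape_key_int <- function(tree, v) {
  kids <- tree$children[[v]]
  if (!length(kids)) return("L")
  keys <- vapply(kids, function(k) shape_key_int(tree, k), character(1))
  paste0("(", paste(sort(keys), collapse = ","), ")")
}

shape_keys_all <- function(tree) {
  # keys for every vertex in one postorder pass
  n <- length(tree$parent)
  keys <- character(n)
  for (v in rev(preorder(tree))) {
    kids <- tree$children[[v]]
    keys[v] <- if (!length(kids)) "L" else
      paste0("(", paste(sort(keys[kids]), collapse = ","), ")")
  }
  keys
}

#' Shape-equivalence classes of interior vertices
#'
#' Non-root interior vertices are grouped by the multiset of their child
#' subtree shapes.  A class is *singular* when that multiset contains the
#' single-vertex shape (i.e. the representative parents a leaf); its
#' *breadth* is the number of descendant leaves of a representative.
#'
#' @param tree a [rooted_tree].
#' @return a list of classes, each `list(representative, member_vertices,
#'   child_shape_multiset, breadth, singular)`.
#' @export
equivalence_classes <- function(tree) {
  keys <- shape_keys_all(tree)
  cand <- setdiff(which(lengths(tree$children) > 0L), tree$root)
  class_key <- vapply(cand, function(v) {
    paste(sort(keys[tree$children[[v]]]), collapse = "|")
  }, character(1))
  out <- list()
  for (k in unique(class_key)) {
    members <- cand[class_key == k]
    v <- members[1]
    child_keys <- sort(keys[tree$children[[v]]])
    out[[length(out) + 1L]] <- list(
      representative = v,
      member_vertices = members,
      child_shape_multiset = child_keys,
      breadth = n_descendant_leaves(tree, v),
      singular = any(child_keys == "L"))
  }
  out
}

#' Is an edge length assignment ultrametric?
#'
#' TRUE iff all root-to-leaf distances are exactly equal (exact rational
#' comparison; no tolerance).
#'
#' @param tree a [rooted_tree] with rational lengths.
#' @return logical scalar.
#' @export
is_ultrametric <- function(tree) {
  stopifnot(!is.null(tree$length))
  if (is_epslen(tree$length))
    stop("ultrametric test expects rational lengths")
  d <- root_depths(tree)
  lv <- leaves(tree)
  if (length(lv) <= 1L) return(TRUE)
  all(d[lv] == d[lv][1])
}

root_depths <- function(tree) {
  n <- length(tree$parent)
  d <- rep(rational("0"), n)
  for (v in preorder(tree)) {
    if (v == tree$root) next
    d[v] <- d[[tree$parent[v]]] + tree$length[[v]]
  }
  d
}

#' Total edge length
#'
#' @param tree a [rooted_tree] with lengths.
#' @return a [rational] (or [epslen]) scalar.
#' @export
total_length <- function(tree) {
  idx <- tree_edges(tree)
  if (is_epslen(tree$length)) ep_sum(tree$length[idx]) else sum(tree$length[idx])
}

#' Replace edge lengths
#'
#' @param tree a [rooted_tree].
#' @param lengths a named [rational]/[epslen] vector: names are leaf or
#'   interior vertex labels identifying each edge by its child vertex, or
#'   an unnamed vector indexed by child vertex id (root slot ignored).
#' @param unit convenience: set every edge length to 1.
#' @return the tree with lengths installed.
#' @export
set_lengths <- function(tree, lengths = NULL, unit = FALSE) {
  n <- length(tree$parent)
  if (unit) {
    len <- rep(rational("1"), n)
    tree$length <- len
    return(validate_tree(tree))
  }
  nms <- names(lengths)
  if (!is.null(nms)) {
    full <- if (is_epslen(lengths)) epslen(rep(rational("1"), n), 0)
            else rep(rational("1"), n)
    ids <- node_id(tree, nms)
    missing_edges <- setdiff(tree_edges(tree), ids)
    if (length(missing_edges))
      stop("no length given for edge above vertex ",
           missing_edges[1],
           if (!is.na(tree$label[missing_edges[1]]))
             paste0(" ('", tree$label[missing_edges[1]], "')"))
    if (is_epslen(lengths)) {
      a <- unclass(full$a); b <- unclass(full$b)
      a[ids] <- unclass(lengths$a); b[ids] <- unclass(lengths$b)
      tree$length <- epslen(new_rational(a), new_rational(b))
    } else {
      v <- unclass(full)
      v[ids] <- unclass(lengths)
      tree$length <- new_rational(v)
    }
  } else {
    stopifnot(length(lengths) == n)
    if (!is_epslen(lengths)) lengths <- rational(lengths)
    tree$length <- lengths
  }
  validate_tree(tree)
}
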