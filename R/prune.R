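#' Extinction events
#'
#' An extinction event partitions the taxon set into extinct taxa and
#' survivors.  Survivors must be non-empty.
#'
#' @param tree a [rooted_tree].
#' @param extinct character vector of taxon names that go extinct.
#' @return `list(extinct, survivors)` of class `extinction_event`.
#' @export
extinction_event <- function(tree, extinct) {
  taxa <- sort(leaf_labels(tree))
  extinct <- unique(as.character(extinct))
  unknown <- setdiff(extinct, taxa)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  survivors <- setdiff(taxa, extinct)
  if (!length(survivors)) stop("an extinction event must leave survivors")
  structure(list(extinct = sort_taxa(extinct), survivors = sort_taxa(survivors)),
            class = "extinction_event")
}

#' Induced tree after an extinction event
#'
#' Restricts the tree to the minimal subtree spanning the survivors and
#' the root, then suppresses every resulting out-degree-1 vertex except
#' the root, summing the lengths of its two incident edges.  The root is
#' never deleted: if only one maximal pendant subtree retains survivors
#' the root keeps a single (merged) edge below it.
#'
#' The result carries an `edge_map` attribute: for each edge of the
#' induced tree (keyed by its child vertex id) the ordered original child
#' vertex ids whose edges were merged into it, and a `node_map` attribute
#' giving, for each new vertex, the original vertex id.  Both are used by
#' the symbolic fixed-leaf test.
#'
#' @param tree a [rooted_tree].
#' @param event an [extinction_event()] or a character vector of extinct
#'   taxon names.
#' @return a [rooted_tree] on the survivors.
#' @examples
#' tr <- parse_newick("((a:1,b:2)v:3,c:4);")
#' prune_and_suppress(tr, "b")   # edge to a merges with edge to v
#' @export
prune_and_suppress <- function(tree, event) {
  if (!inherits(event, "extinction_event")) event <- extinction_event(tree, event)
  keep_leaf <- leaves(tree)[tree$label[leaves(tree)] %in% event$survivors]

  n <- length(tree$parent)
  keep <- rep(FALSE, n)
  for (x in keep_leaf) {
    v <- x
    while (!is.na(v) && !keep[v]) {
      keep[v] <- TRUE
      v <- tree$parent[v]
    }
  }
  keep[tree$root] <- TRUE

  # children lists restricted to kept vertices (stored order preserved)
  kept_children <- lapply(seq_len(n), function(v) {
    if (!keep[v]) return(integer())
    tree$children[[v]][keep[tree$children[[v]]]]
  })

  # walk from the root; collapse chains of out-degree-1 vertices (root kept)
  has_len <- !is.null(tree$length)
  use_ep <- has_len && is_epslen(tree$length)

  new_parent <- integer()
  new_children <- list()
  new_label <- character()
  new_orig <- integer()       # new id -> original id (edge child endpoint)
  edge_map <- list()          # new id -> original child ids merged
  len_chr_a <- character()
  len_chr_b <- character()

  add_node <- function(orig, parent_new, merged) {
    id <- length(new_parent) + 1L
    new_parent[id] <<- parent_new
    new_children[[id]] <<- integer()
    new_label[id] <<- tree$label[orig]
    new_orig[id] <<- orig
    edge_map[[id]] <<- merged
    if (has_len) {
      if (length(merged)) {
        if (use_ep) {
          tot <- ep_sum(tree$length[merged])
          len_chr_a[id] <<- unclass(tot$a)
          len_chr_b[id] <<- unclass(tot$b)
        } else {
          len_chr_a[id] <<- unclass(sum(tree$length[merged]))
        }
      } else {
        len_chr_a[id] <<- NA_character_
        if (use_ep) len_chr_b[id] <<- NA_character_
      }
    }
    if (!is.na(parent_new))
      new_children[[parent_new]] <<- c(new_children[[parent_new]], id)
    id
  }

  build <- function(orig, parent_new, merged_so_far) {
    kids <- kept_children[[orig]]
    if (length(kids) == 1L && orig != tree$root) {
      # suppress: pass through, accumulating the merged edge
      build(kids[[1]], parent_new, c(merged_so_far, kids[[1]]))
    } else {
      id <- add_node(orig, parent_new, merged_so_far)
      for (k in kids) build(k, id, k)
      id
    }
  }
  build(tree$root, NA_integer_, integer())

  lens <- NULL
  if (has_len) {
    lens <- if (use_ep) {
      la <- len_chr_a; lb <- len_chr_b
      la[is.na(la)] <- "0"; lb[is.na(lb)] <- "0"
      epslen(new_rational(la), new_rational(lb))
    } else {
      la <- len_chr_a
      la[is.na(la)] <- "0"
      new_rational(la)
    }
  }
  out <- rooted_tree(new_parent, new_children, new_label, lens)
  attr(out, "edge_map") <- edge_map
  attr(out, "node_map") <- new_orig
  attr(out, "event") <- event
  out
}
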