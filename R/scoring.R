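#' Shape features of every pendant subtree
#'
#' One postorder pass computing, for each vertex, the descriptor consumed
#' by allocation rules: canonical shape key, leaf count, number of
#' m-cherry parents and number of interior vertices parenting exactly one
#' leaf (vertex itself included in the latter two).
#'
#' @param tree a [rooted_tree].
#' @return a list of descriptors indexed by vertex id.
#' @keywords internal
vertex_features <- function(tree) {
  n <- length(tree$parent)
  keys <- shape_keys_all(tree)
  n_leaf <- integer(n)
  n_cherry <- integer(n)
  n_single <- integer(n)
  for (v in rev(preorder(tree))) {
    kids <- tree$children[[v]]
    if (!length(kids)) {
      n_leaf[v] <- 1L
      next
    }
    leaf_kids <- sum(lengths(tree$children[kids]) == 0L)
    n_leaf[v] <- sum(n_leaf[kids])
    n_cherry[v] <- sum(n_cherry[kids]) +
      as.integer(length(kids) >= 2L && leaf_kids == length(kids))
    n_single[v] <- sum(n_single[kids]) + as.integer(leaf_kids == 1L)
  }
  lapply(seq_len(n), function(v)
    list(key = keys[v], n_leaves = n_leaf[v],
         n_cherries = n_cherry[v], n_single_parent = n_single[v]))
}

#' Ratios of allocations at every non-root interior vertex
#'
#' @param tree a [rooted_tree].
#' @param rule an [allocation_rule].
#' @param include_root also compute the (never-allocated-to) root ratio.
#' @return a list keyed by vertex id: `list(vertex, terms)` with `terms`
#'   a [rational] vector aligned to the stored child order.
#' @export
vertex_ratios <- function(tree, rule, include_root = FALSE) {
  feats <- vertex_features(tree)
  vs <- which(lengths(tree$children) > 0L)
  if (!include_root) vs <- setdiff(vs, tree$root)
  out <- vector("list", length(tree$parent))
  for (v in vs) {
    # an out-degree-1 vertex (retained root of a pruned tree, or a
    # partially assembled subtree) passes its full share through
    out[[v]] <- if (length(tree$children[[v]]) == 1L) rational("1")
                else apply_rule(rule, feats[tree$children[[v]]])
  }
  out
}

#' Coefficient table gamma(x, e) of an index on a tree
#'
#' In consistent form the coefficient of leaf x for an ancestral edge e is
#' the product, over the interior vertices strictly below e's start on the
#' path to x, of the ratio term for the child subtree containing x.
#' Coefficients are 0 off the descent (descent condition), 1 on the
#' pendant edge, and sum to 1 over each edge's cluster, so scores
#' partition total edge length.
#'
#' @param tree a [rooted_tree].
#' @param rule an [allocation_rule].
#' @return a character matrix of canonical rationals with rows = taxa,
#'   columns = edges (named by child vertex id).
#' @export
coefficients_table <- function(tree, rule) {
  ratios <- vertex_ratios(tree, rule)
  lv <- leaves(tree)
  edges <- tree_edges(tree)
  out <- matrix("0", nrow = length(lv), ncol = length(edges),
                dimnames = list(tree$label[lv], as.character(edges)))
  for (i in seq_along(lv)) {
    x <- lv[i]
    gam <- rational("1")
    v <- x
    while (v != tree$root) {
      out[i, as.character(v)] <- unclass(gam)
      u <- tree$parent[v]
      # multiply in the term at u for the child branch containing x
      if (u != tree$root)
        gam <- gam * ratios[[u]][match(v, tree$children[[u]])]
      v <- u
    }
  }
  out
}

#' Diversity index scores
#'
#' The score of leaf x is `sum_e gamma(x, e) * l(e)`.  Works with exact
#' rational lengths and with symbolic infinitesimal ([epslen]) lengths;
#' the conservation identity `sum of scores == total edge length` holds
#' exactly in both cases.
#'
#' @param tree a [rooted_tree] with lengths.
#' @param rule an [allocation_rule].
#' @return a named [rational] (or [epslen]) vector over the taxa, sorted
#'   by taxon name.
#' @examples
#' tr <- set_lengths(fig3_tree(), unit = TRUE)
#' rat_decimal(scores(tr, builtin_rule("fp"))["x3"], 2)  # "1.88"
#' @export
scores <- function(tree, rule) {
  stopifnot(!is.null(tree$length))
  ratios <- vertex_ratios(tree, rule)
  lv <- leaves(tree)
  use_ep <- is_epslen(tree$length)
  la <- if (use_ep) tree$length$a else tree$length
  lb <- if (use_ep) tree$length$b else NULL

  sc_a <- character(length(lv))
  sc_b <- character(length(lv))
  for (i in seq_along(lv)) {
    x <- lv[i]
    acc_a <- rational("0")
    acc_b <- rational("0")
    gam <- rational("1")
    v <- x
    while (v != tree$root) {
      acc_a <- acc_a + gam * la[[v]]
      if (use_ep) acc_b <- acc_b + gam * lb[[v]]
      u <- tree$parent[v]
      if (u != tree$root)
        gam <- gam * ratios[[u]][match(v, tree$children[[u]])]
      v <- u
    }
    sc_a[i] <- unclass(acc_a)
    if (use_ep) sc_b[i] <- unclass(acc_b)
  }
  nms <- tree$label[lv]
  o <- order_taxa(nms)
  if (use_ep) {
    out <- epslen(new_rational(sc_a[o]), new_rational(sc_b[o]))
    names(out) <- nms[o]
    out
  } else {
    new_rational(sc_a[o], nms[o])
  }
}

#' Direct Fair Proportion score (independent of the rule framework)
#'
#' `FP(x) = sum over root-path edges of l(e) / |cluster(e)|`.  Kept as a
#' closed-form oracle against which the consistent-coefficient framework
#' is tested.
#'
#' @param tree a [rooted_tree] with rational lengths.
#' @param taxon a leaf label.
#' @return a [rational] scalar.
#' @export
fp_score_direct <- function(tree, taxon) {
  x <- node_id(tree, taxon)
  sizes <- integer(length(tree$parent))
  for (v in rev(preorder(tree))) {
    kids <- tree$children[[v]]
    sizes[v] <- if (!length(kids)) 1L else sum(sizes[kids])
  }
  acc <- rational("0")
  v <- x
  while (!is.na(tree$parent[v])) {
    acc <- acc + tree$length[[v]] / rational(sizes[v])
    v <- tree$parent[v]
  }
  acc
}

#' Direct Equal-Splits score (independent of the rule framework)
#'
#' `ES(x) = sum over root-path edges of l(e) / pi(e, x)` where `pi(e, x)`
#' is the product of the out-degrees of the interior vertices on the path
#' from e's child endpoint down to x (1 for the pendant edge).
#'
#' @inheritParams fp_score_direct
#' @return a [rational] scalar.
#' @export
es_score_direct <- function(tree, taxon) {
  x <- node_id(tree, taxon)
  acc <- tree$length[[x]]
  if (is.na(tree$parent[x])) return(rational("0")) # single-vertex tree
  pi_prod <- rational("1")
  v <- tree$parent[x]
  while (!is.na(tree$parent[v])) {
    pi_prod <- pi_prod * rational(length(tree$children[[v]]))
    acc <- acc + tree$length[[v]] / pi_prod
    v <- tree$parent[v]
  }
  acc
}

#' Natural taxon ordering
#'
#' Orders taxon names alphabetically but with embedded integers compared
#' numerically, so `x2` precedes `x10`.  Used wherever a deterministic
#' "smallest label" choice is needed.
#'
#' @param x character vector of taxon names.
#' @return an integer permutation.
#' @export
order_taxa <- function(x) {
  stem <- sub("([0-9]+)$", "", x)
  num <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1", x)))
  num[stem == x] <- NA_integer_
  order(stem, num, x, na.last = FALSE)
}

#' @rdname order_taxa
#' @export
sort_taxa <- function(x) x[order_taxa(x)]
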