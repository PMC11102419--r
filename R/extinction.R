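#' Extinctions necessary before a complete ranking reversal
#'
#' For *any* diversity index, a strict reversible ranking requires the
#' extinction of at least all but one of the leaves adjacent to each
#' interior vertex (leaves sharing a parent keep their relative order
#' otherwise).  Rigid indices additionally require the extinction of all
#' but one isolated leaf — or *all* isolated leaves when some maximal
#' pendant subtree is a single (root-adjacent, hence score-fixed) leaf.
#'
#' @param tree a [rooted_tree] with at least 3 leaves.
#' @param rigid apply the stronger requirement for rigid indices.
#' @return a list with
#'   `constraints` (per interior vertex: its adjacent leaves and how many
#'   must go), `isolated` (the isolated-leaf constraint, when `rigid`),
#'   `min_deletions`, and `witness` — one minimal deletion set, formed by
#'   keeping the natural-order smallest label of each group.
#' @examples
#' necessary_extinctions(fig3_tree(), rigid = TRUE)$witness
#' @export
necessary_extinctions <- function(tree, rigid = FALSE) {
  if (n_leaves(tree) < 3) stop("need at least 3 leaves")
  constraints <- list()
  witness <- character()
  for (v in which(lengths(tree$children) > 0L)) {
    kids <- tree$children[[v]]
    leaf_kids <- kids[lengths(tree$children[kids]) == 0L]
    if (length(leaf_kids) >= 2L) {
      labs <- sort_taxa(tree$label[leaf_kids])
      constraints[[length(constraints) + 1L]] <-
        list(vertex = v, leaves = labs, delete_at_least = length(labs) - 1L)
      witness <- c(witness, labs[-1])
    }
  }
  iso_con <- NULL
  if (rigid) {
    iso <- sort_taxa(isolated_leaves(tree))
    if (length(iso)) {
      root_kids <- tree$children[[tree$root]]
      single_leaf_mps <- any(lengths(tree$children[root_kids]) == 0L)
      need <- if (single_leaf_mps) length(iso) else length(iso) - 1L
      iso_con <- list(leaves = iso, delete_at_least = need,
                      all_required = single_leaf_mps)
      extra <- if (single_leaf_mps) iso else iso[-1]
      witness <- union(witness, extra)
    }
  }
  list(constraints = constraints, isolated = iso_con,
       min_deletions = sum(vapply(constraints, `[[`, integer(1),
                                  "delete_at_least")) +
                       (if (is.null(iso_con)) 0L else iso_con$delete_at_least),
       witness = sort_taxa(unique(witness)))
}

#' The default reversal extinction event
#'
#' All but one leaf per interior vertex (the survivor is the
#' natural-order smallest label of each group).  With `rigid = TRUE`
#' *all* isolated leaves are additionally deleted: that is the event the
#' rigid-index sufficiency construction is proved for (the necessity
#' bound of [necessary_extinctions()] is weaker — all but one isolated
#' leaf — but an un-deleted isolated leaf can be score-fixed under a
#' rigid index, which would block the construction).
#'
#' @param tree a [rooted_tree].
#' @param rigid include the isolated-leaf deletions.
#' @return an [extinction_event()].
#' @export
reversal_event <- function(tree, rigid = FALSE) {
  if (n_leaves(tree) < 3) {
    # a lone cherry: delete all but the natural-order smallest leaf
    labs <- sort_taxa(leaf_labels(tree))
    return(extinction_event(tree, labs[-1]))
  }
  extinct <- necessary_extinctions(tree, rigid = FALSE)$witness
  if (rigid) extinct <- union(extinct, isolated_leaves(tree))
  extinction_event(tree, sort_taxa(extinct))
}

#' Fixed leaves of an extinction event (symbolic test)
#'
#' A leaf is *fixed* when its score is unchanged by the event for every
#' edge length assignment.  Because scores are linear in lengths with
#' shape-determined coefficients, this holds iff for every edge e on the
#' leaf's root path the original coefficient equals the coefficient of
#' the merged edge that e becomes in the induced tree.  The test is
#' exact and symbolic — no length sampling.
#'
#' @param tree a [rooted_tree] (lengths not required).
#' @param rule an [allocation_rule].
#' @param event an [extinction_event()] or character vector of extinct
#'   taxa (empty vector: every leaf is trivially fixed).
#' @return character vector of fixed surviving taxa (natural order).
#' @export
fixed_leaves <- function(tree, rule, event) {
  if (!inherits(event, "extinction_event")) {
    if (!length(event)) return(sort_taxa(leaf_labels(tree)))
    event <- extinction_event(tree, event)
  }
  work <- tree
  if (is.null(work$length)) work <- set_lengths(work, unit = TRUE)
  induced <- prune_and_suppress(work, event)
  emap <- attr(induced, "edge_map")
  gam_T <- coefficients_table(tree, rule)
  gam_I <- coefficients_table(induced, rule)
  out <- character()
  for (x in event$survivors) {
    fixed <- TRUE
    for (ei in tree_edges(induced)) {
      gi <- rational(gam_I[x, as.character(ei)])
      for (orig in emap[[ei]]) {
        if (rational(gam_T[x, as.character(orig)]) != gi) {
          fixed <- FALSE
          break
        }
      }
      if (!fixed) break
    }
    if (fixed) out <- c(out, x)
  }
  sort_taxa(out)
}

#' Robustness of Equal-Splits on caterpillar trees
#'
#' On the caterpillar `Cat_n` (taxa `x1..xn`, cherry `{x1, x2}`, `xn`
#' root-adjacent), no extinction of a proper subset of
#' `{x1, ..., x_{n-2}}` can make a strict Equal-Splits ranking reverse:
#' such an event leaves the scores of `x_{n-1}` and `xn` untouched, so
#' that pair cannot flip.  `can_reverse = FALSE` is returned for exactly
#' these excluded subsets; `TRUE` means "not excluded by this
#' criterion", not a guarantee of reversibility.
#'
#' With `n_random > 0` the verdict is additionally brute-force checked:
#' that many seeded random length assignments are scored exactly and an
#' error is raised if any produces a strict reversal (none can).
#'
#' @param n number of caterpillar leaves (>= 4).
#' @param subset character vector of taxa proposed for extinction
#'   (a proper subset of the taxa).
#' @param n_random number of random length assignments to verify with.
#' @param seed seed for the verification draws.
#' @return logical `can_reverse`.
#' @export
caterpillar_es_robustness <- function(n, subset, n_random = 0, seed = 1) {
  if (n < 4) stop("need n >= 4")
  taxa <- paste0("x", seq_len(n))
  subset <- unique(as.character(subset))
  stopifnot(all(subset %in% taxa), length(subset) < n)
  lower <- paste0("x", seq_len(n - 2))
  excluded <- all(subset %in% lower) && length(subset) < length(lower)
  if (excluded && n_random > 0 && length(subset)) {
    es <- builtin_rule("es")
    for (k in seq_len(n_random)) {
      tr <- synthetic_tree(n, seed = seed * 10000L + k, mode = "caterpillar")
      cmp <- compare_rankings(scores(tr, es),
                              scores(prune_and_suppress(tr, subset), es))
      if (cmp$reversed_strict)
        stop("internal error: excluded subset produced a reversal")
    }
  }
  !excluded
}
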