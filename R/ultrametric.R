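#' The reversible ultrametric family U
#'
#' For even `n >= 6`, a clock-like (ultrametric) rooted binary tree with
#' `m = n/2` nested cherries in which deleting every even-indexed leaf
#' reverses the Fair Proportion and Equal-Splits rankings of the
#' survivors in the relaxed (tie-tolerant) sense.  Construction: a spine
#' of vertices `v_1 (root), ..., v_{m-1}` joined by unit edges; `v_i`
#' carries cherry i (the i-th from the root) on a stem of length
#' `n - 2i` with pendant lengths `i`; the deepest vertex `v_{m-1}`
#' carries both cherry `m-1` and cherry m, the latter on a stem of
#' length `n - 2(m-1)` with pendants `m - 1`.  Cherry i from the root
#' holds taxa `{x_{n-2i+1}, x_{n-2i+2}}`, so the deepest cherry is
#' `{x1, x2}` and `{x_{n-1}, x_n}` sits nearest the root.  Every
#' root-to-leaf distance equals `n - 1`.
#'
#' The internal lengths (spine 1, stems `n - 2i`) are a reconstruction
#' pinned by the published 12-leaf instance's score table, which the test
#' suite reproduces cell by cell.
#'
#' @param n an even integer >= 6.
#' @return a [rooted_tree] with rational lengths; `is_ultrametric()` is
#'   `TRUE` by construction.
#' @examples
#' u <- generate_U(12)
#' rat_decimal(fp_score_direct(u, "x1"), 3)  # "6.642"
#' @export
generate_U <- function(n) {
  n <- as.integer(n)
  if (n < 6L || n %% 2L != 0L) stop("n must be an even integer >= 6")
  m <- n %/% 2L
  cherry <- function(i) {
    t1 <- n - 2L * i + 1L
    sprintf("(x%d:%d,x%d:%d):%d", t1, i, t1 + 1L, i, n - 2L * i)
  }
  # deepest level: cherries m-1 and m side by side (stems n - 2(m-1))
  deep <- sprintf("((x1:%d,x2:%d):%d,(x3:%d,x4:%d):%d)",
                  m - 1L, m - 1L, n - 2L * (m - 1L),
                  m - 1L, m - 1L, n - 2L * (m - 1L))
  s <- deep
  if (m >= 3L) for (i in (m - 2L):1L)
    s <- sprintf("(%s:1,%s)", s, cherry(i))
  tr <- parse_newick(paste0(s, ";"))
  stopifnot(is_ultrametric(tr))
  tr
}

#' Necessary condition for an ultrametric FP reversal (per-leaf check)
#'
#' On an ultrametric binary tree, a leaf x outside every cherry strictly
#' out-scores, under Fair Proportion, any leaf y below its parent v, and
#' after any extinction both survive `FP(x) >= FP(y)` persists.  So a
#' (relaxed) reversal is only possible if, whenever x survives, all of
#' `cluster(v) \ {x}` goes extinct.  This check scans every surviving
#' non-cherry leaf and reports the first violation.
#'
#' @param tree an ultrametric binary [rooted_tree].
#' @param event an [extinction_event()] or character vector of extinct
#'   taxa.
#' @return `list(passes = TRUE)` or `list(passes = FALSE, witness =
#'   c(leaf, surviving_member_of_A))`.
#' @export
check_prop10 <- function(tree, event) {
  if (!is_ultrametric(tree)) stop("tree is not ultrametric")
  deg <- lengths(tree$children)
  if (any(deg[deg > 0L] != 2L)) stop("tree is not binary")
  if (!inherits(event, "extinction_event"))
    event <- extinction_event(tree, event)
  in_cherry <- unlist(lapply(m_cherries(tree), `[[`, "leaves"))
  for (x in setdiff(event$survivors, in_cherry)) {
    v <- tree$parent[node_id(tree, x)]
    A <- setdiff(tree$label[descendant_leaves(tree, v)], x)
    alive <- intersect(A, event$survivors)
    if (length(alive))
      return(list(passes = FALSE, witness = c(x, sort_taxa(alive)[1])))
  }
  list(passes = TRUE, witness = NULL)
}

#' Necessary condition for a one-per-cherry ultrametric FP reversal
#'
#' `TRUE` iff every leaf belongs to a cherry.  A leaf outside every
#' cherry survives any one-per-cherry event, and by the per-leaf
#' condition ([check_prop10()]) blocks the reversal; caterpillar trees
#' (one cherry) fail this immediately.
#'
#' @param tree a binary [rooted_tree] (lengths not needed).
#' @return logical scalar.
#' @examples
#' check_cor11(u12_tree())            # TRUE
#' check_cor11(caterpillar_tree(8))   # FALSE
#' @export
check_cor11 <- function(tree) {
  deg <- lengths(tree$children)
  if (any(deg[deg > 0L] != 2L)) stop("tree is not binary")
  in_cherry <- unlist(lapply(m_cherries(tree), `[[`, "leaves"))
  all(leaf_labels(tree) %in% in_cherry)
}

#' Relaxed reversal report on an ultrametric tree
#'
#' Ultrametric cherries force score ties, so strict reversal is the
#' wrong yardstick; this reports the relaxed comparison (every strictly
#' ordered pair must flip, ties are unconstrained, at least one pair
#' must flip).
#'
#' @param tree an ultrametric [rooted_tree] with lengths.
#' @param rule an [allocation_rule].
#' @param event an [extinction_event()] or character vector of extinct
#'   taxa.
#' @return a `ranking_comparison` (see [compare_rankings()]).
#' @examples
#' u <- u12_tree()
#' ev <- paste0("x", seq(2, 12, by = 2))
#' ultrametric_reversal_report(u, builtin_rule("fp"), ev)$reversed_relaxed
#' @export
ultrametric_reversal_report <- function(tree, rule, event) {
  if (!is_ultrametric(tree)) stop("tree is not ultrametric")
  if (!inherits(event, "extinction_event"))
    event <- extinction_event(tree, event)
  before <- scores(tree, rule)
  after <- scores(prune_and_suppress(tree, event), rule)
  compare_rankings(before, after, event$survivors)
}
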