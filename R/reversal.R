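#' The F edge set of the rigid-index construction
#'
#' `F_iso` contains the edges whose terminal vertex is the parent of an
#' isolated leaf; `F_ch` the edges whose terminal vertex is the parent of
#' the leaves of an m-cherry, except edges below some `F_iso` edge.
#' Their union `F = {f_1, ..., f_t}` is ordered by preorder index of the
#' terminal vertex (any fixed order works: the `k * eps` increments only
#' serve to separate the score differences).
#'
#' @param tree a [rooted_tree].
#' @return `list(F_iso, F_ch, F)` of edge child-vertex ids, with `F` in
#'   construction order.
#' @examples
#' f <- build_F(fig3_tree())
#' fig3_tree()$label[f$F]  # q, t, u
#' @export
build_F <- function(tree) {
  iso <- isolated_leaves(tree)
  iso_parents <- unique(tree$parent[node_id(tree, iso)])
  F_iso <- iso_parents[!is.na(tree$parent[iso_parents])] # edge above parent
  cherry_parents <- vapply(m_cherries(tree), `[[`, integer(1), "parent")
  F_ch <- integer()
  for (v in cherry_parents) {
    if (is.na(tree$parent[v])) next # cherry at the root: no edge above
    # exclude when an F_iso edge lies on the path from the root to the
    # edge's start vertex
    u <- tree$parent[v]
    blocked <- FALSE
    w <- u
    while (!is.na(w)) {
      if (w %in% F_iso) { blocked <- TRUE; break }
      w <- tree$parent[w]
    }
    if (!blocked) F_ch <- c(F_ch, v)
  }
  pre <- preorder(tree)
  Fall <- c(F_iso, F_ch)
  Fall <- Fall[order(match(Fall, pre))]
  list(F_iso = F_iso, F_ch = F_ch, F = Fall)
}

#' Recompute and certify a reversal from scratch
#'
#' Scores the tree before and after the event using the index framework
#' only (never construction-side bookkeeping), compares the rankings and
#' returns a certificate.  Works with rational or symbolic infinitesimal
#' lengths.
#'
#' @param tree a [rooted_tree] (topology source).
#' @param lengths a full edge length vector ([rational] or [epslen]
#'   indexed by child vertex id), or `NULL` to use `tree$length`.
#' @param rule an [allocation_rule].
#' @param event an [extinction_event()] or character vector of extinct
#'   taxa.
#' @param relaxed certify the relaxed (tie-tolerant) reversal notion
#'   instead of the strict one.
#' @return a `reversal_certificate`: list with the tree, lengths, event,
#'   rule name, `before`/`after` score vectors, `comparison` and `valid`.
#' @export
verify_reversal <- function(tree, lengths = NULL, rule, event,
                            relaxed = FALSE) {
  if (!is.null(lengths)) tree <- set_lengths(tree, lengths)
  stopifnot(!is.null(tree$length))
  if (!inherits(event, "extinction_event"))
    event <- extinction_event(tree, event)
  before <- scores(tree, rule)
  induced <- prune_and_suppress(tree, event)
  after <- scores(induced, rule)
  comparison <- compare_rankings(before, after, event$survivors)
  structure(list(tree = tree, lengths = tree$length, event = event,
                 rule = rule$name, before = before, after = after,
                 comparison = comparison,
                 valid = if (relaxed) comparison$reversed_relaxed
                         else comparison$reversed_strict),
            class = "reversal_certificate")
}

#' @export
print.reversal_certificate <- function(x, ...) {
  cat("<reversal_certificate> rule:", x$rule,
      "| extinct:", paste(x$event$extinct, collapse = ","), "\n")
  fmt <- function(s) if (is_epslen(s)) format(s) else
    paste0(as.character(s), "")
  surv <- x$event$survivors
  cat("  before:", paste(surv, "=", fmt(x$before[surv]), collapse = "  "), "\n")
  cat("  after: ", paste(surv, "=", fmt(x$after[surv]), collapse = "  "), "\n")
  cat("  valid:", x$valid, "\n")
  invisible(x)
}

#' Reversal construction for rigid (and any) interior indices
#'
#' Implements the direct two-stage construction: assign `l'` giving each
#' F edge length `M + k*eps` and every other edge `eps`; compute each
#' survivor's score difference `Delta = after - before` and midpoint
#' `c_i`; then reassign survivor pendant edges to `c - c_i + eps` where
#' `c = max c_i`.  The resulting scores satisfy, exactly,
#' `before_i = c - Delta_i/2` and `after_i = c + Delta_i/2`, so the
#' survivor ranking reverses completely.
#'
#' The extinction event is all isolated leaves plus all but one leaf per
#' interior vertex (survivor: natural-order smallest label, overridable).
#' `M` must be large enough that no non-root-adjacent survivor is score-
#' fixed; with `M = "auto"` it starts at twice the edge count and doubles
#' until the (symbolic) check passes.
#'
#' @param tree a [rooted_tree]; lengths are ignored and replaced.
#' @param rule an interior [allocation_rule] (boundary rules error).
#' @param M a positive rational, or `"auto"`.
#' @param event optional override of the extinction event.
#' @return a list of class `theorem9_workings`: `F_iso`, `F_ch`, `F`,
#'   `M`, `event`, `lengths` ([epslen], indexed by child vertex id),
#'   `delta`, `c_map`, `c`, `pendant_lengths` and `certificate`.
#' @examples
#' w <- theorem9_construct(fig3_tree(), builtin_rule("es"), M = 32)
#' w$certificate$valid
#' @export
theorem9_construct <- function(tree, rule, M = "auto", event = NULL) {
  if (is.null(event)) event <- reversal_event(tree, rigid = TRUE)
  if (!inherits(event, "extinction_event"))
    event <- extinction_event(tree, event)
  cls <- classify_interior(rule, tree)
  if (cls$class == "boundary")
    stop("rule '", rule$name, "' is boundary on this tree (zero term at ",
         "vertex ", cls$witness$vertex, "); the construction requires an ",
         "interior index")

  Fs <- build_F(tree)
  n <- length(tree$parent)
  auto <- identical(M, "auto")
  M_cur <- if (auto) rational(2L * (n - 1L)) else rational(M)
  root_kids <- tree$children[[tree$root]]

  pre <- preorder(tree)
  for (attempt in 1:60) {
    # l': F edges M + k*eps, everything else eps.  On trees with exactly
    # mirrored survivor positions (symmetric cherries below a blocked
    # region) the k*eps increments cannot separate the Delta values; the
    # retry then uses a distinct eps coefficient (a power of two by
    # preorder index) on every edge, which changes nothing at eps -> 0.
    a <- rep(rational("0"), n)
    b <- if (attempt == 1L) rep(rational("1"), n) else {
      bb <- rep(rational("1"), n)
      pw <- rational("1")
      for (v in pre) {
        bb[v] <- pw
        pw <- pw * rational("2")
      }
      bb
    }
    for (k in seq_along(Fs$F)) {
      a[Fs$F[k]] <- M_cur
      if (attempt == 1L) b[Fs$F[k]] <- rational(k)
    }
    lp <- epslen(a, b)
    work <- tree
    work$length <- lp
    before <- scores(work, rule)
    induced <- prune_and_suppress(work, event)
    after <- scores(induced, rule)
    surv <- event$survivors
    delta <- ep_sub(after[surv], before[surv])
    names(delta) <- surv

    # at most one Delta may vanish, and only for a root-adjacent survivor
    zero <- which(unclass(delta$a) == "0" & unclass(delta$b) == "0")
    ok <- TRUE
    if (length(zero) > 1L) ok <- FALSE
    if (length(zero) == 1L) {
      v <- node_id(tree, surv[zero])
      if (!(tree$parent[v] %in% tree$root)) ok <- FALSE
    }
    tied_pair <- NULL
    if (ok) {
      # pairwise distinct Delta values
      o <- ep_order(delta)
      for (i in seq_along(o)[-1])
        if (ep_cmp(delta[o[i]], delta[o[i - 1]]) == 0L) {
          ok <- FALSE
          tied_pair <- surv[o[c(i - 1, i)]]
          break
        }
    }
    if (ok) break
    if (attempt >= 2L && !is.null(tied_pair)) {
      # with generically distinct eps coefficients on every edge, an exact
      # Delta tie means the two survivors' score differences agree as
      # linear functionals of the lengths: the pair can never strictly
      # flip under this event (isomorphic sibling subtrees with survivors
      # in corresponding positions), for any choice of M
      stop(structure(class = c("divindex_inseparable", "error", "condition"),
                     list(message = paste0(
        "survivors ", tied_pair[1], " and ", tied_pair[2], " are ",
        "inseparable under rule '", rule$name, "': their score changes ",
        "coincide for every edge length assignment, so no lengths make ",
        "this ranking strictly reversible for the prescribed event"),
        call = sys.call(-1))))
    }
    if (attempt >= 2L) {
      if (!auto)
        stop("M = ", as.character(M_cur), " leaves a fixed or tied ",
             "survivor; increase M or use M = \"auto\"")
      M_cur <- M_cur * rational("2")
    }
    if (attempt == 60) stop("auto-M failed to separate survivors")
  }

  c_map <- ep_scale(ep_add(before[surv], after[surv]), "1/2")
  names(c_map) <- surv
  c_val <- ep_max(c_map)
  # pendant reassignment: l(e_i) = c - c_i + (the pendant's own eps term),
  # so that the scores land exactly on c -/+ Delta/2
  ids <- node_id(tree, surv)
  pend <- ep_add(ep_sub(c_val, c_map), epslen(0, lp$b[ids]))
  names(pend) <- surv
  lens <- lp
  la <- unclass(lens$a); lb <- unclass(lens$b)
  la[ids] <- unclass(pend$a); lb[ids] <- unclass(pend$b)
  lens <- epslen(new_rational(la), new_rational(lb))

  cert <- verify_reversal(tree, lens, rule, event)
  # closed-form identities (exact, including eps coefficients)
  half_d <- ep_scale(ep_sub(cert$after[surv], cert$before[surv]), "1/2")
  for (i in seq_along(surv)) {
    lhs <- ep_add(cert$before[surv][i], half_d[i])
    rhs <- ep_sub(cert$after[surv][i], half_d[i])
    if (ep_cmp(lhs, c_val) != 0L || ep_cmp(rhs, c_val) != 0L)
      stop("internal error: closed-form identity violated for ", surv[i])
  }
  if (!cert$valid)
    stop("internal error: constructed lengths failed verification")

  structure(list(F_iso = Fs$F_iso, F_ch = Fs$F_ch, F = Fs$F,
                 M = M_cur, event = event, lengths = lens,
                 lprime = lp, before_lprime = before, after_lprime = after,
                 delta = delta, c_map = c_map, c = c_val,
                 pendant_lengths = pend, certificate = cert),
            class = "theorem9_workings")
}

#' @export
print.theorem9_workings <- function(x, ...) {
  cat("<theorem9_workings> M =", as.character(x$M),
      "| F =", paste(x$F, collapse = ","), "\n")
  print(x$certificate)
  invisible(x)
}

#' Realize symbolic infinitesimal lengths as exact rationals
#'
#' Picks a concrete rational `eps = 2^-k`, small enough that the realized
#' numeric lengths are positive and the certificate recomputed with them
#' reaches the same verdict and the same before/after orderings as the
#' symbolic one.
#'
#' @param tree a [rooted_tree].
#' @param lengths an [epslen] length vector for `tree`.
#' @param rule an [allocation_rule].
#' @param event the extinction event the lengths were built for.
#' @return `list(eps, lengths, certificate)` with rational lengths.
#' @export
realize_epsilon <- function(tree, lengths, rule, event) {
  if (!inherits(event, "extinction_event"))
    event <- extinction_event(tree, event)
  sym <- verify_reversal(tree, lengths, rule, event)
  surv <- event$survivors
  ord_b <- surv[ep_order(sym$before[surv])]
  ord_a <- surv[ep_order(sym$after[surv])]
  eps <- rational("1/2")
  for (k in 1:200) {
    num <- ep_realize(lengths, eps)
    idx <- tree_edges(tree)
    if (all(num[idx] > rational("0"))) {
      cert <- verify_reversal(tree, num, rule, event)
      same_order <-
        identical(surv[rat_order(cert$before[surv])], ord_b) &&
        identical(surv[rat_order(cert$after[surv])], ord_a)
      if (same_order && cert$valid == sym$valid)
        return(list(eps = eps, lengths = num, certificate = cert))
    }
    eps <- eps * rational("1/2")
  }
  stop("failed to realize eps after 200 halvings")
}

# ---- non-rigid construction (recursive interleaving) ----

# standalone copy of the subtree rooted at r, restricted (optionally) to a
# subset of r's child branches; lengths taken from `lens` (full rational
# vector indexed by global child vertex).  Attr "map": new id -> global id.
subtree_at <- function(tree, r, lens, kids_subset = NULL) {
  kids <- tree$children[[r]]
  if (!is.null(kids_subset)) kids <- kids[kids %in% kids_subset]
  ids <- integer()
  walk <- function(v) {
    ids <<- c(ids, v)
    for (k in tree$children[[v]]) walk(k)
  }
  ids <- r
  for (k in kids) walk(k)
  new_of <- match(seq_along(tree$parent), ids)
  parent <- new_of[tree$parent[ids]]
  parent[ids == r] <- NA_integer_
  children <- lapply(ids, function(v) {
    kk <- tree$children[[v]]
    if (v == r) kk <- kids
    as.integer(new_of[kk])
  })
  lvec <- rep(rational("1"), length(ids))
  for (i in seq_along(ids)) if (ids[i] != r) lvec[i] <- lens[[ids[i]]]
  out <- rooted_tree(parent, children, tree$label[ids], lvec)
  attr(out, "map") <- ids
  out
}

# product of ratio terms from the root down to each leaf's parent
# (the coefficient a hypothetical edge above the root would have)
root_coefs <- function(tree, rule) {
  ratios <- vertex_ratios(tree, rule, include_root = TRUE)
  lv <- leaves(tree)
  out <- rep(rational("1"), length(lv))
  for (i in seq_along(lv)) {
    g <- rational("1")
    v <- lv[i]
    while (!is.na(tree$parent[v])) {
      u <- tree$parent[v]
      g <- g * ratios[[u]][match(v, tree$children[[u]])]
      v <- u
    }
    out[i] <- g
  }
  names(out) <- tree$label[lv]
  out
}

# before/after survivor scores of the standalone subtree at r under the
# current global length assignment
block_scores <- function(tree, r, lens, rule, extinct, kids_subset = NULL) {
  sub <- subtree_at(tree, r, lens, kids_subset)
  ext <- intersect(extinct, leaf_labels(sub))
  before <- scores(sub, rule)
  after <- if (length(ext)) scores(prune_and_suppress(sub, ext), rule)
           else before
  list(sub = sub, before = before, after = after,
       survivors = setdiff(sort_taxa(leaf_labels(sub)), ext))
}

min_positive_gap <- function(vals) {
  v <- rat_sort(vals)
  best <- NULL
  for (i in seq_along(v)[-1]) {
    d <- v[i] - v[i - 1]
    if (d > rational("0") && (is.null(best) || d < best)) best <- d
  }
  best
}

has_collision <- function(vals) {
  v <- rat_sort(vals)
  any(vapply(seq_along(v)[-1],
             function(i) unclass(v[i]) == unclass(v[i - 1]), logical(1)))
}

#' Separate coinciding before/after scores (edge-extension perturbation)
#'
#' Given lengths under which the survivors of `event` already form a
#' strict reversible pair of rankings on `tree`, extends edges by
#' exactly-computed small amounts until all `2m` combined before/after
#' scores are pairwise distinct, preserving both orderings.
#' A self-collision (a survivor scoring equally before and after) is
#' broken by extending an edge on the leaf's root path whose coefficient
#' differs between the two trees — this is where non-rigidity is used,
#' and an error is raised when no such edge exists.  A cross-collision is
#' broken by extending the leaf's pendant edge.  Candidate extensions are
#' halved until they create no new coincidence and break no ordering.
#'
#' @param tree a [rooted_tree] with rational lengths.
#' @param rule a non-rigid interior [allocation_rule].
#' @param event an [extinction_event()] or character vector of extinct
#'   taxa.
#' @return the adjusted [rational] length vector (full, indexed by child
#'   vertex id).
#' @export
lemma4_perturb <- function(tree, rule, event) {
  if (!inherits(event, "extinction_event"))
    event <- extinction_event(tree, event)
  lens <- tree$length
  for (round in 1:200) {
    st <- perturb_state(tree, lens, rule, event)
    col <- find_collision(st)
    if (is.null(col)) return(lens)
    lens <- break_collision(tree, lens, rule, event, st, col)
  }
  stop("lemma4_perturb: failed to separate scores after 200 rounds")
}

perturb_state <- function(tree, lens, rule, event) {
  work <- tree
  work$length <- lens
  before <- scores(work, rule)
  after <- scores(prune_and_suppress(work, event), rule)
  surv <- event$survivors
  list(before = before[surv], after = after[surv], survivors = surv)
}

find_collision <- function(st) {
  m <- length(st$survivors)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) {
      if (unclass(st$before[i]) == unclass(st$after[i]))
        return(list(type = "self", i = i))
    } else if (unclass(st$before[i]) == unclass(st$after[j])) {
      return(list(type = "cross", i = i, j = j))
    }
  }
  # also guard plain duplicates within each side (must stay strict)
  for (side in c("before", "after")) {
    v <- st[[side]]
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i < j && unclass(v[i]) == unclass(v[j]))
        return(list(type = "dup", i = i, j = j, side = side))
    }
  }
  NULL
}

break_collision <- function(tree, lens, rule, event, st, col) {
  x <- st$survivors[col$i]
  xid <- node_id(tree, x)
  target <- if (col$type == "self") {
    # an edge on x's root path whose coefficient changes after pruning
    coefficient_changing_edge(tree, lens, rule, event, x)
  } else xid  # cross/dup: extend the pendant edge of x
  if (is.null(target))
    stop("lemma4_perturb: no coefficient-changing edge for '", x,
         "'; the rule behaves rigidly here and the perturbation ",
         "cannot take effect")
  base_vals <- c(st$before, st$after)
  gap <- min_positive_gap(base_vals)
  if (is.null(gap)) gap <- rational("1")
  t <- gap * rational("1/2")
  orig <- collision_count(st)
  for (k in 1:80) {
    trial <- lens
    trial[target] <- trial[[target]] + t
    st2 <- perturb_state(tree, trial, rule, event)
    # strict orders must survive; ties are allowed to break (that is the
    # purpose of the perturbation)
    ok <- collision_count(st2) < orig &&
      strict_orders_preserved(st, st2)
    if (ok) return(trial)
    t <- t * rational("1/2")
  }
  stop("lemma4_perturb: could not break a collision (rule may be rigid)")
}

strict_orders_preserved <- function(st, st2) {
  m <- length(st$survivors)
  if (m < 2) return(TRUE)
  for (side in c("before", "after")) {
    v1 <- st[[side]]
    v2 <- st2[[side]]
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      c1 <- score_cmp(v1[i], v1[j])
      if (c1 != 0L && score_cmp(v2[i], v2[j]) != c1) return(FALSE)
    }
  }
  TRUE
}

collision_count <- function(st) {
  vals <- unclass(c(st$before, st$after))
  sum(duplicated(vals))
}

coefficient_changing_edge <- function(tree, lens, rule, event, x) {
  work <- tree
  work$length <- lens
  induced <- prune_and_suppress(work, event)
  emap <- attr(induced, "edge_map")
  gam_T <- coefficients_table(tree, rule)
  gam_I <- coefficients_table(induced, rule)
  # walk x's root path from parent edge upward
  xid <- node_id(tree, x)
  v <- xid
  while (!is.na(tree$parent[v])) {
    # find the induced edge containing original edge v
    for (ei in tree_edges(induced)) {
      if (v %in% emap[[ei]]) {
        if (rational(gam_T[x, as.character(v)]) !=
            rational(gam_I[x, as.character(ei)]))
          return(v)
        break
      }
    }
    v <- tree$parent[v]
  }
  NULL
}

#' Reversal construction for non-rigid interior indices
#'
#' Recursive interleaving construction.  The extinction event is the
#' minimum required of every index: all but one leaf adjacent to each
#' interior vertex (survivor: natural-order smallest label).  Edge
#' lengths are assembled bottom-up: at each vertex the first child
#' block's combined before/after survivor scores are made pairwise
#' distinct (via [lemma4_perturb()]-style extensions), the gap between
#' their lower and upper halves is computed, and each subsequent child
#' block (a possibly-single-leaf block last) is uniformly scaled to fit
#' inside the gap and shifted there by adding a constant to its pendant
#' edges.  Deleted leaves receive pendant lengths smaller than their
#' surviving sibling's, then a final pass halves dead pendants until all
#' leaf scores are pairwise distinct, so the pre-extinction ranking is
#' strict on all of X and its top species survives.
#'
#' @param tree a [rooted_tree] (lengths ignored and replaced).
#' @param rule a non-rigid interior [allocation_rule].
#' @param check_rigid probe the rule and refuse a rigid witness.
#' @return a `reversal_certificate` (see [verify_reversal()]) whose
#'   `lengths` are exact rationals; carries the event in `$event`.
#' @examples
#' cert <- theorem5_construct(balanced4_tree(), builtin_rule("fp"))
#' cert$valid
#' @export
theorem5_construct <- function(tree, rule, check_rigid = TRUE) {
  if (n_leaves(tree) < 2) stop("need at least 2 leaves")
  event <- reversal_event(tree, rigid = FALSE)
  cls <- classify_interior(rule, tree)
  if (cls$class == "boundary")
    stop("rule '", rule$name, "' is boundary on this tree; the ",
         "construction requires a non-rigid interior index")
  if (check_rigid && is_rigid(rule, max_breadth = max(3L, n_leaves(tree))))
    stop("rule '", rule$name, "' is rigid: use theorem9_construct(), ",
         "which additionally deletes the isolated leaves")

  n <- length(tree$parent)
  lens <- rep(rational("1"), n)
  lens <- thm5_vertex(tree, tree$root, lens, rule, event)
  lens <- separate_dead_leaves(tree, lens, rule, event)
  cert <- verify_reversal(tree, lens, rule, event)
  if (!cert$valid)
    stop("internal error: construction failed verification")
  # the theorem additionally promises the top pre-extinction scorer survives
  top <- names(cert$before)[rat_order(cert$before, decreasing = TRUE)[1]]
  if (!top %in% event$survivors)
    stop("internal error: top scorer '", top, "' did not survive")
  cert
}

thm5_vertex <- function(tree, r, lens, rule, event) {
  kids <- tree$children[[r]]
  internal_kids <- kids[lengths(tree$children[kids]) > 0L]
  leaf_kids <- kids[lengths(tree$children[kids]) == 0L]
  leaf_labs <- tree$label[leaf_kids]
  surv_leaf <- leaf_kids[leaf_labs %in% event$survivors]
  dead_leaf <- setdiff(leaf_kids, surv_leaf)

  # recurse into internal children first
  for (c1 in internal_kids) lens <- thm5_vertex(tree, c1, lens, rule, event)

  # order blocks: internal children by decreasing survivor count, then the
  # surviving leaf child (whose standalone before == after) last
  n_surv <- vapply(internal_kids, function(c1) {
    sum(tree$label[descendant_leaves(tree, c1)] %in% event$survivors)
  }, integer(1))
  blocks <- internal_kids[order(-n_surv)]
  if (length(surv_leaf)) blocks <- c(blocks, surv_leaf)
  if (!length(blocks)) stop("internal error: vertex with no surviving block")

  processed <- integer()
  for (bi in seq_along(blocks)) {
    cb <- blocks[bi]
    is_last <- bi == length(blocks)
    if (bi == 1L) {
      lens <- attach_first_block(tree, r, cb, lens, rule, event,
                                 need_distinct = !is_last)
    } else {
      lens <- attach_next_block(tree, r, cb, processed, lens, rule, event,
                                need_distinct = !is_last)
    }
    processed <- c(processed, cb)
  }

  # dead leaf children: smaller than the surviving leaf sibling's pendant
  # (or than any assigned length when no leaf survives here -- impossible
  # by construction of the event, but kept safe)
  if (length(dead_leaf)) {
    ref <- if (length(surv_leaf)) lens[[surv_leaf]] else rational("1")
    for (k in seq_along(dead_leaf))
      lens[dead_leaf[k]] <- ref * rational(paste0(k, "/", 2L * (length(dead_leaf) + 1L)))
  }
  lens
}

# first block: choose its stem small enough to preserve the block's
# internal orders, then (if required) separate its combined scores
attach_first_block <- function(tree, r, cb, lens, rule, event,
                               need_distinct) {
  if (!length(tree$children[[cb]])) {
    # single surviving leaf as the only block: any positive pendant works
    lens[cb] <- rational("1")
    return(lens)
  }
  # standalone values of the child subtree (without the stem)
  sub0 <- subtree_at(tree, cb, lens)
  ext <- intersect(event$extinct, leaf_labels(sub0))
  vals0 <- c(scores(sub0, rule),
             if (length(ext)) scores(prune_and_suppress(sub0, ext), rule))
  gap <- min_positive_gap(vals0)
  stem <- if (is.null(gap)) rational("1") else gap * rational("1/2")
  lens[cb] <- stem
  if (!need_distinct) return(lens)
  separate_block(tree, r, cb, lens, rule, event)
}

# make the partial tree's combined survivor scores pairwise distinct,
# trying stem halving first, then lemma4-style edge extensions
separate_block <- function(tree, r, cb, lens, rule, event) {
  for (round in 1:200) {
    bs <- block_scores(tree, r, lens, rule, event$extinct,
                       kids_subset = cb)
    vals <- c(bs$before[bs$survivors], bs$after[bs$survivors])
    if (!has_collision(vals)) return(lens)
    # try halving the stem: collisions are crossings of lines linear in
    # the stem length, so at most finitely many stem values are bad
    trial <- lens
    trial[cb] <- lens[[cb]] * rational("1/2")
    bs2 <- block_scores(tree, r, trial, rule, event$extinct,
                        kids_subset = cb)
    vals2 <- c(bs2$before[bs2$survivors], bs2$after[bs2$survivors])
    if (sum(duplicated(unclass(vals2))) < sum(duplicated(unclass(vals)))) {
      lens <- trial
      next
    }
    # otherwise perturb inside the partial tree
    sub <- bs$sub
    ev_sub <- extinction_event(sub, intersect(event$extinct,
                                              leaf_labels(sub)))
    adj <- lemma4_perturb(sub, rule, ev_sub)
    map <- attr(sub, "map")
    for (i in seq_along(map))
      if (!is.na(sub$parent[i])) lens[map[i]] <- adj[[i]]
  }
  stop("separate_block: failed to reach distinct combined scores")
}

attach_next_block <- function(tree, r, cb, processed, lens, rule, event,
                              need_distinct) {
  # gap of the processed chain
  ch <- block_scores(tree, r, lens, rule, event$extinct,
                     kids_subset = processed)
  vals <- rat_sort(c(ch$before[ch$survivors], ch$after[ch$survivors]))
  m2 <- length(vals)
  lo <- vals[m2 / 2]
  hi <- vals[m2 / 2 + 1]
  if (!(hi > lo)) stop("internal error: chain gap is empty")
  delta <- hi - lo

  # provisional block lengths (stem included)
  if (!length(tree$children[[cb]])) {
    lens[cb] <- rational("1")
    block_nodes <- cb
    pendants <- cb
  } else {
    lens <- attach_first_block(tree, r, cb, lens, rule, event,
                               need_distinct = need_distinct)
    if (need_distinct) lens <- separate_block(tree, r, cb, lens, rule, event)
    sub <- subtree_at(tree, cb, lens)
    map <- attr(sub, "map")
    block_nodes <- map
    pendants <- map[leaves(sub)]
  }

  # scale the whole block (stem included) into half the gap
  bs <- block_scores(tree, r, lens, rule, event$extinct, kids_subset = cb)
  allvals <- c(bs$before, bs$after) # all leaves incl. dead: keep them inside
  mx <- max(allvals)
  scale <- delta / (rational("2") * mx)
  for (v in block_nodes) lens[v] <- lens[[v]] * scale
  # shift into the gap: add lo to every pendant edge of the block
  for (p in pendants) lens[p] <- lens[[p]] + lo
  lens
}

# final pass: all leaves of T must carry pairwise distinct scores; dead
# pendant halvings only move the dead leaf's own score
separate_dead_leaves <- function(tree, lens, rule, event) {
  dead_ids <- node_id(tree, event$extinct)
  for (round in 1:400) {
    work <- tree
    work$length <- lens
    sc <- scores(work, rule)
    dup_vals <- unclass(sc)[duplicated(unclass(sc))]
    if (!length(dup_vals)) return(lens)
    moved <- FALSE
    for (d in dead_ids) {
      lab <- tree$label[d]
      if (unclass(sc[lab]) %in% dup_vals ||
          any(unclass(sc[lab]) == unclass(sc)[duplicated(unclass(sc),
                                                         fromLast = TRUE)])) {
        lens[d] <- lens[[d]] * rational("1/2")
        moved <- TRUE
      }
    }
    if (!moved)
      stop("separate_dead_leaves: residual tie not involving a dead leaf")
  }
  stop("separate_dead_leaves: failed after 400 rounds")
}
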