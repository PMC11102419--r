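#' Allocation rules: how an index splits ancestral edge length
#'
#' A phylogenetic diversity index (in consistent form) is determined by a
#' *ratio of allocations* at every interior vertex: the proportions in
#' which the length of each ancestral edge is shared among the vertex's
#' child subtrees.  An `allocation_rule` encodes this as a function of the
#' child subtree *shapes* only (never of edge lengths), which is exactly
#' the neutrality requirement: identical child shapes must receive equal
#' terms.
#'
#' `ratio_fn(children)` receives one descriptor per child subtree, a list
#' with fields `key` (canonical shape key), `n_leaves`, `n_cherries`
#' (m-cherry parents in the subtree, its root included) and
#' `n_single_parent` (interior vertices of the subtree, its root included,
#' that parent exactly one leaf).  It must return a [rational] vector of
#' non-negative terms summing to 1, one per child, in the order given.
#'
#' @param name rule name (for printing and reports).
#' @param ratio_fn the ratio function described above.
#' @param binary_only reject vertices of out-degree other than 2.  The
#'   example indices alpha..eta are defined on binary trees only.
#' @return an object of class `allocation_rule`.
#' @seealso [builtin_rule()], [table_rule()], [scores()]
#' @export
allocation_rule <- function(name, ratio_fn, binary_only = FALSE) {
  stopifnot(is.character(name), is.function(ratio_fn))
  structure(list(name = name, ratio_fn = ratio_fn,
                 binary_only = isTRUE(binary_only)),
            class = "allocation_rule")
}

#' @export
print.allocation_rule <- function(x, ...) {
  cat("<allocation_rule> ", x$name,
      if (x$binary_only) " (binary trees only)", "\n", sep = "")
  invisible(x)
}

# validated application of a rule at one vertex
apply_rule <- function(rule, children) {
  d <- length(children)
  if (rule$binary_only && d != 2L)
    stop("rule '", rule$name, "' is defined for binary vertices only ",
         "(got out-degree ", d, ")")
  r <- rule$ratio_fn(children)
  if (!is_rational(r) || length(r) != d)
    stop("rule '", rule$name, "' returned a malformed ratio (arity ",
         length(r), ", expected ", d, ")")
  zero <- rational("0"); one <- rational("1")
  if (!all(r >= zero & r <= one) || sum(r) != one)
    stop("rule '", rule$name, "' returned terms outside [0,1] or not ",
         "summing to 1")
  keys <- vapply(children, `[[`, character(1), "key")
  for (k in unique(keys[duplicated(keys)])) {
    idx <- which(keys == k)
    if (!all(r[idx] == r[idx][1]))
      stop("rule '", rule$name, "' violates neutrality: unequal terms ",
           "for identical child shapes")
  }
  r
}

half <- function() rational("1/2")

# proportional-split helper with an all-zero fallback of equal shares
prop_ratio <- function(weights) {
  tot <- sum(weights)
  if (tot == rational("0"))
    return(rep(rational("1") / rational(length(weights)), length(weights)))
  weights / tot
}

# fixed share to the child maximising `value`, ties -> equal split
top_share_ratio <- function(values, share) {
  stopifnot(length(values) == 2L)
  if (values[1] == values[2]) return(rep(half(), 2L))
  s <- rational(share)
  if (values[1] > values[2]) c(s, rational("1") - s)
  else c(rational("1") - s, s)
}

#' Built-in diversity indices
#'
#' * `fp` — Fair Proportion: terms proportional to child leaf counts.
#' * `es` — Equal-Splits: equal terms `1/d`.
#' * `alpha` — `2/3` to the more populous child subtree, `1/2:1/2` on ties.
#' * `beta` — all (`1:0`) to the more populous subtree; boundary index.
#' * `gamma_min` — all to the *less* populous subtree; boundary index.
#' * `delta_cherry` — `3/4` to the child subtree with more cherries.
#' * `epsilon_singleparent` — proportional to the number of interior
#'   vertices (subtree root included) parenting exactly one leaf;
#'   `1/2:1/2` when neither side has any.
#' * `zeta_squares` — proportional to squared leaf counts.
#' * `eta_hybrid` — Equal-Splits at vertices with five or more descendant
#'   leaves, Fair Proportion elsewhere.
#'
#' `alpha`..`eta` are defined on binary vertices only.  The `share`
#' constants of `alpha` (2/3) and `delta_cherry` (3/4) are conventional
#' choices from \code{[0,1]} and can be overridden.
#'
#' @param name one of `"fp"`, `"es"`, `"alpha"`, `"beta"`, `"gamma_min"`,
#'   `"delta_cherry"`, `"epsilon_singleparent"`, `"zeta_squares"`,
#'   `"eta_hybrid"` (short aliases `"gamma"`, `"delta"`, `"epsilon"`,
#'   `"zeta"`, `"eta"` are accepted).
#' @param share override for the fixed share used by `alpha` /
#'   `delta_cherry`.
#' @return an [allocation_rule].
#' @examples
#' scores(set_lengths(fig3_tree(), unit = TRUE), builtin_rule("fp"))
#' @export
builtin_rule <- function(name, share = NULL) {
  name <- switch(name, gamma = "gamma_min", delta = "delta_cherry",
                 epsilon = "epsilon_singleparent", zeta = "zeta_squares",
                 eta = "eta_hybrid", name)
  nl <- function(ch) rational(vapply(ch, `[[`, numeric(1), "n_leaves"))
  switch(name,
    fp = allocation_rule("fp", function(ch) prop_ratio(nl(ch))),
    es = allocation_rule("es", function(ch) {
      d <- length(ch)
      rep(rational("1") / rational(d), d)
    }),
    alpha = allocation_rule("alpha", function(ch)
      top_share_ratio(nl(ch), share %||% "2/3"), binary_only = TRUE),
    beta = allocation_rule("beta", function(ch)
      top_share_ratio(nl(ch), "1"), binary_only = TRUE),
    gamma_min = allocation_rule("gamma_min", function(ch)
      top_share_ratio(nl(ch), "0"), binary_only = TRUE),
    delta_cherry = allocation_rule("delta_cherry", function(ch) {
      nc <- rational(vapply(ch, `[[`, numeric(1), "n_cherries"))
      top_share_ratio(nc, share %||% "3/4")
    }, binary_only = TRUE),
    epsilon_singleparent = allocation_rule("epsilon_singleparent",
      function(ch) {
        cnt <- rational(vapply(ch, `[[`, numeric(1), "n_single_parent"))
        prop_ratio(cnt)
      }, binary_only = TRUE),
    zeta_squares = allocation_rule("zeta_squares", function(ch) {
      n <- nl(ch)
      prop_ratio(n * n)
    }, binary_only = TRUE),
    eta_hybrid = allocation_rule("eta_hybrid", function(ch) {
      n <- nl(ch)
      breadth <- sum(as.numeric(n))
      if (breadth >= 5) rep(half(), 2L) else prop_ratio(n)
    }, binary_only = TRUE),
    stop("unknown builtin rule '", name, "'")
  )
}

#' Index defined by an explicit ratio table
#'
#' Defines an index by assigning a ratio of allocations to each
#' shape-equivalence class.  Each assignment binds the *sorted* child
#' shape keys of a class to a vector of terms in that sorted order;
#' at application time the terms are permuted back to the vertex's stored
#' child order.  Identical child shapes must carry equal terms
#' (neutrality), which also makes the permutation unambiguous.
#'
#' @param assignments a list; each element is
#'   `list(children = <character shape keys>, terms = <ratio>)`.  `terms`
#'   is coerced with [rational()].
#' @param name rule name.
#' @param default_equal fall back to an equal split for classes not in
#'   the table (otherwise unknown classes are an error).
#' @param binary_only restrict to binary vertices.
#' @return an [allocation_rule].
#' @export
table_rule <- function(assignments, name = "table",
                       default_equal = FALSE, binary_only = FALSE) {
  entries <- lapply(assignments, function(a) {
    stopifnot(is.character(a$children))
    o <- order(a$children)
    keys <- a$children[o]
    terms <- rational(a$terms)[o]
    if (length(terms) != length(keys))
      stop("assignment arity mismatch")
    if (sum(terms) != rational("1") ||
        !all(terms >= rational("0") & terms <= rational("1")))
      stop("invalid ratio in table_rule assignment")
    for (k in unique(keys[duplicated(keys)])) {
      idx <- which(keys == k)
      if (!all(terms[idx] == terms[idx][1]))
        stop("table_rule assignment violates neutrality for shape ", k)
    }
    list(class_id = paste(keys, collapse = "|"), keys = keys, terms = terms)
  })
  ids <- vapply(entries, `[[`, character(1), "class_id")
  allocation_rule(name, function(ch) {
    keys <- vapply(ch, `[[`, character(1), "key")
    o <- order(keys)
    id <- paste(keys[o], collapse = "|")
    hit <- match(id, ids)
    if (is.na(hit)) {
      if (default_equal)
        return(rep(rational("1") / rational(length(ch)), length(ch)))
      stop("table_rule '", name, "': no assignment for class ", id)
    }
    terms_sorted <- entries[[hit]]$terms
    out <- terms_sorted
    out[o] <- terms_sorted
    out
  }, binary_only = binary_only)
}
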