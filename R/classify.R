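#' Interior / boundary classification of an index on a tree
#'
#' An index is *boundary* when some term in a ratio of allocations equals
#' zero — some species is cut off from a share of an ancestral edge — and
#' *interior* otherwise.  The classification is made concretely on the
#' supplied tree: every non-root interior vertex's ratio is computed and
#' scanned for zero terms.
#'
#' @param rule an [allocation_rule].
#' @param tree a [rooted_tree].
#' @return `list(class = "interior"|"boundary", witness)`; `witness` is
#'   `list(vertex, term)` (vertex id and term position) when boundary.
#' @examples
#' classify_interior(builtin_rule("beta"), fig3_tree())$class  # boundary
#' @export
classify_interior <- function(rule, tree) {
  ratios <- vertex_ratios(tree, rule)
  for (v in seq_along(ratios)) {
    r <- ratios[[v]]
    if (is.null(r)) next
    z <- which(unclass(r) == "0")
    if (length(z))
      return(list(class = "boundary",
                  witness = list(vertex = v, term = z[1])))
  }
  list(class = "interior", witness = NULL)
}

#' Probe an index for rigidity
#'
#' A *rigid* index assigns the same ratio of allocations to two singular
#' shape-equivalence classes of different breadth on some tree.  The
#' probe enumerates the caterpillar-type singular classes — a vertex with
#' children (leaf, caterpillar of b-1 leaves) for breadths b = 2, 3, ...,
#' `max_breadth` — and searches for a pair of different breadth with
#' identical ratio (compared as multisets of exact rationals).
#'
#' A witness proves rigidity.  Absence of a witness up to the bound does
#' not prove non-rigidity (the property quantifies over all trees), so
#' the negative result is reported as `"no_witness_up_to_bound"`.
#'
#' @param rule an [allocation_rule].
#' @param max_breadth largest breadth probed (>= 3).
#' @return `list(status = "rigid_witness"|"no_witness_up_to_bound",
#'   witness)`; `witness` is `list(breadths, ratio)` when found.
#' @examples
#' rigidity_probe(builtin_rule("es"))$status  # rigid_witness
#' rigidity_probe(builtin_rule("fp"))$status  # no witness at any bound
#' @export
rigidity_probe <- function(rule, max_breadth = 8L) {
  stopifnot(max_breadth >= 3L)
  seen <- list() # breadth -> sorted ratio (character)
  for (b in 2:max_breadth) {
    # a singular class of breadth b: children (caterpillar_{b-1}, leaf)
    probe <- if (b == 2L) star_tree(2L) else {
      tr <- caterpillar_tree(b)
      tr
    }
    feats <- vertex_features(probe)
    kids <- probe$children[[probe$root]]
    ratio <- tryCatch(apply_rule(rule, feats[kids]),
                      error = function(e) NULL)
    if (is.null(ratio)) next  # rule undefined there (e.g. non-binary)
    key <- paste(sort(unclass(ratio)), collapse = ":")
    hit <- which(vapply(seen, `[[`, character(1), "key") == key)
    if (length(hit))
      return(list(status = "rigid_witness",
                  witness = list(breadths = c(seen[[hit[1]]]$breadth, b),
                                 ratio = ratio)))
    seen[[length(seen) + 1L]] <- list(key = key, breadth = b)
  }
  list(status = "no_witness_up_to_bound", witness = NULL,
       max_breadth = max_breadth)
}

#' @rdname rigidity_probe
#' @export
is_rigid <- function(rule, max_breadth = 8L) {
  rigidity_probe(rule, max_breadth)$status == "rigid_witness"
}
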