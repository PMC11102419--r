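#' The 11-leaf example tree
#'
#' The rooted binary tree used throughout to compare index behaviour:
#' topology
#' `((((((x1,x2)w,x3)v,x4)s,x5)q,(((x6,x7)y,x8)t,(x9,x10)u)r)p,x11)`
#' with interior vertices annotated p,q,r,s,t,u,v,w,y.  Reconstructed from
#' its published ratio table and score columns; the test suite pins every
#' cell of those tables against this fixture.
#'
#' @param unit_lengths install unit edge lengths.
#' @return a [rooted_tree] (topology-only unless `unit_lengths`).
#' @export
fig3_tree <- function(unit_lengths = FALSE) {
  tr <- parse_newick(
    "((((((x1,x2)w,x3)v,x4)s,x5)q,(((x6,x7)y,x8)t,(x9,x10)u)r)p,x11);",
    lengths_required = FALSE)
  if (unit_lengths) tr <- set_lengths(tr, unit = TRUE)
  tr
}

#' The arbitrary table-defined index on the example tree
#'
#' A deliberately non-biological index whose ratios were fixed by sampling
#' small integers as left-hand numerators over 8 at the six labelled
#' vertex classes of [fig3_tree()].  It is bound to the shape classes of
#' that tree (plus the forced 1/2:1/2 cherry class) and errors elsewhere.
#'
#' @return an [allocation_rule].
#' @export
theta_rule <- function() {
  tr <- fig3_tree()
  keys <- shape_keys_all(tr)
  key_of <- function(lab) keys[node_id(tr, lab)]
  kids_keys <- function(lab) keys[tr$children[[node_id(tr, lab)]]]
  entry <- function(lab, left_num) {
    # terms follow the drawn (stored) child order, then are re-sorted by
    # table_rule; both children of each labelled vertex here have
    # distinct shapes, so orientation is unambiguous
    ch <- kids_keys(lab)
    terms <- c(paste0(left_num, "/8"), paste0(8 - left_num, "/8"))
    o <- order(ch)
    list(children = ch[o], terms = terms[o])
  }
  table_rule(
    c(lapply(list(list("p", 4), list("q", 8), list("r", 5),
                  list("s", 0), list("t", 2), list("v", 2)),
             function(e) entry(e[[1]], e[[2]])),
      list(list(children = c("L", "L"), terms = c("1/2", "1/2")))),
    name = "theta", binary_only = TRUE)
}

#' Constructed edge lengths for the rigid-index reversal example
#'
#' The edge length assignment (with `M = 32`) that makes the Equal-Splits
#' ranking on [fig3_tree()] reverse completely after the extinction of
#' x2, x5, x7, x8 and x10.  Lengths are symbolic `a + b*eps` ([epslen]);
#' the published table reads off the `eps -> 0` limits.
#'
#' @return a named [epslen] vector keyed by edge child vertex label,
#'   suitable for [set_lengths()].
#' @export
fig7_lengths <- function() {
  w <- theorem9_construct(fig3_tree(), builtin_rule("es"), M = 32)
  w$lengths
}

#' The 12-leaf reversible ultrametric tree
#'
#' `generate_U(12)`: six nested cherries, every root-to-leaf distance 11.
#' Deleting the even-indexed leaves reverses both the Fair Proportion and
#' Equal-Splits rankings of the survivors (in the relaxed, tie-tolerant
#' sense appropriate to ultrametric trees).
#'
#' @return a [rooted_tree] with rational lengths.
#' @export
u12_tree <- function() generate_U(12L)

#' Deterministic structured tree builders
#'
#' `caterpillar_tree(n)` builds the rooted caterpillar on taxa
#' `x1..xn`: the unique cherry is `{x1, x2}`, `x_{n}` is adjacent to the
#' root, and `x_{n-1}` is its only isolated leaf.  `star_tree(n)` builds
#' the rooted star (all leaves adjacent to the root).  `balanced4_tree()`
#' is the 4-leaf balanced binary tree.  Lengths, when requested, are unit.
#'
#' @param n number of leaves.
#' @param unit_lengths install unit edge lengths.
#' @return a [rooted_tree].
#' @export
caterpillar_tree <- function(n, unit_lengths = FALSE) {
  stopifnot(n >= 2)
  s <- "(x1,x2)"
  if (n >= 3) for (i in 3:n) s <- paste0("(", s, ",x", i, ")")
  tr <- parse_newick(paste0(s, ";"), lengths_required = FALSE)
  if (unit_lengths) tr <- set_lengths(tr, unit = TRUE)
  tr
}

#' @rdname caterpillar_tree
#' @export
star_tree <- function(n, unit_lengths = FALSE) {
  stopifnot(n >= 2)
  tr <- parse_newick(
    paste0("(", paste0("x", seq_len(n), collapse = ","), ");"),
    lengths_required = FALSE)
  if (unit_lengths) tr <- set_lengths(tr, unit = TRUE)
  tr
}

#' @rdname caterpillar_tree
#' @export
balanced4_tree <- function(unit_lengths = FALSE) {
  tr <- parse_newick("((x1,x2),(x3,x4));", lengths_required = FALSE)
  if (unit_lengths) tr <- set_lengths(tr, unit = TRUE)
  tr
}

#' Seeded synthetic trees
#'
#' Reproducible random trees for property tests.  Modes:
#' * `binary` — uniform random sequence of leaf attachments (each new
#'   leaf subdivides a uniformly chosen pendant-or-internal edge);
#' * `multifurcating` — random binary tree whose internal edges are then
#'   each contracted independently with probability 1/3;
#' * `caterpillar` — the deterministic caterpillar shape;
#' * `ultrametric` — random binary topology with integer node heights
#'   (every root-to-leaf distance equal by construction).
#'
#' Edge lengths are positive rationals with small numerators and
#' denominators (1..36 over 1..4), emulating the order-unity branch
#' lengths of the published examples; `ultrametric` mode draws integer
#' height increments instead.
#'
#' @param n number of leaves (>= 2).
#' @param seed integer seed; the same seed always returns the same tree.
#' @param mode one of `"binary"`, `"multifurcating"`, `"caterpillar"`,
#'   `"ultrametric"`.
#' @return a [rooted_tree] with rational lengths.
#' @export
synthetic_tree <- function(n, seed,
                           mode = c("binary", "multifurcating",
                                    "caterpillar", "ultrametric")) {
  mode <- match.arg(mode)
  stopifnot(n >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))

  if (mode == "caterpillar") {
    tr <- caterpillar_tree(n)
    return(set_lengths(tr, random_rational_lengths(tr)))
  }

  topo <- random_binary_topology(n)
  if (mode == "multifurcating" && n >= 3) topo <- random_contract(topo)
  if (mode == "ultrametric") return(set_lengths_clock(topo))
  set_lengths(topo, random_rational_lengths(topo))
}

random_binary_topology <- function(n) {
  # grow a newick string: start from a cherry, repeatedly pick a random
  # current leaf and split it into (leaf, new leaf)
  labs <- paste0("x", seq_len(n))
  parts <- labs[1]
  if (n >= 2) {
    parts <- c(labs[1], labs[2])
    s_parts <- list(labs[1], labs[2])
    # represent the tree as nested lists; insert each new leaf at a
    # uniformly chosen existing leaf position
    node <- list(labs[1], labs[2])
    for (k in seq_len(n)[-(1:2)]) {
      path <- integer()
      cur <- node
      repeat {
        if (is.character(cur)) break
        i <- sample.int(length(cur), 1L)
        path <- c(path, i)
        cur <- cur[[i]]
      }
      node <- insert_at(node, path, list(cur, labs[k]))
    }
    parts <- deparse_nested(node)
  }
  parse_newick(paste0(parts, ";"), lengths_required = FALSE)
}

insert_at <- function(node, path, value) {
  if (!length(path)) return(value)
  node[[path[1]]] <- insert_at(node[[path[1]]], path[-1], value)
  node
}

deparse_nested <- function(node) {
  if (is.character(node)) return(node)
  paste0("(", paste(vapply(node, deparse_nested, character(1)),
                    collapse = ","), ")")
}

random_contract <- function(tree) {
  # contract each internal non-root-incident edge with probability 1/3
  internal <- setdiff(which(lengths(tree$children) > 0L), tree$root)
  drop <- internal[runif(length(internal)) < 1 / 3]
  if (!length(drop)) return(tree)
  s <- contract_vertices(tree, drop)
  parse_newick(paste0(s, ";"), lengths_required = FALSE)
}

contract_vertices <- function(tree, drop) {
  rec <- function(v) {
    kids <- tree$children[[v]]
    if (!length(kids)) return(tree$label[v])
    parts <- character()
    for (k in kids) {
      sub <- rec(k)
      if (k %in% drop && length(tree$children[[k]]) > 0L) {
        # splice grandchildren into this vertex
        parts <- c(parts, substr(sub, 2L, nchar(sub) - 1L))
      } else parts <- c(parts, sub)
    }
    paste0("(", paste(parts, collapse = ","), ")")
  }
  rec(tree$root)
}

random_rational_lengths <- function(tree) {
  edges <- tree_edges(tree)
  num <- sample.int(36L, length(edges), replace = TRUE)
  den <- sample.int(4L, length(edges), replace = TRUE)
  lens <- rational(paste0(num, "/", den))
  names(lens) <- as.character(edges)
  full <- rep(rational("1"), length(tree$parent))
  v <- unclass(full)
  v[edges] <- unclass(lens)
  tree$length <- new_rational(v)
  validate_tree(tree)
  tree$length
}

set_lengths_clock <- function(tree) {
  # integer heights: leaves 0, parent = max(child heights) + U{1..5}
  n <- length(tree$parent)
  h <- integer(n)
  for (v in rev(preorder(tree))) {
    kids <- tree$children[[v]]
    h[v] <- if (!length(kids)) 0L else max(h[kids]) + sample.int(5L, 1L)
  }
  lens <- rep(rational("1"), n)
  for (v in tree_edges(tree))
    lens[v] <- rational(h[tree$parent[v]] - h[v])
  tree$length <- lens
  validate_tree(tree)
  tree
}
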