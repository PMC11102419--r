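#' Read a rooted tree from Newick text
#'
#' Standard rooted Newick with two extensions needed for exactness:
#' branch lengths may be written as decimals (`:0.25`, converted exactly)
#' or as rationals (`:1/3`).  Interior node labels are preserved as vertex
#' annotations.  A length on the root position is ignored with a warning.
#'
#' Inputs with suppressed-degree-one vertices (including a root of
#' out-degree 1) are rejected: the data model stores none, and silently
#' merging edges would alter the shape the caller supplied.
#'
#' @param text a Newick string (terminating `;` optional), or the path of
#'   a file containing one (when `file = TRUE`).
#' @param file interpret `text` as a file path.
#' @param lengths_required error when any non-root edge lacks a length
#'   (default). With `FALSE`, a topology-only tree is returned.
#' @return a [rooted_tree].
#' @examples
#' parse_newick("((a:1,b:2)v:1/2,c:0.75);")
#' @export
parse_newick <- function(text, file = FALSE, lengths_required = TRUE) {
  if (file) text <- paste(readLines(text, warn = FALSE), collapse = "")
  s <- gsub("[ \t\r\n]", "", text)
  if (!nzchar(s)) stop("empty Newick string")
  if (endsWith(s, ";")) s <- substr(s, 1L, nchar(s) - 1L)

  pos <- 1L
  n_chars <- nchar(s)
  peek <- function() if (pos > n_chars) "" else substr(s, pos, pos)
  take_token <- function() {
    # label or length token: up to one of ( ) , : ;
    start <- pos
    while (pos <= n_chars && !substr(s, pos, pos) %in% c("(", ")", ",", ":"))
      pos <<- pos + 1L
    substr(s, start, pos - 1L)
  }

  parent <- integer()
  children <- list()
  label <- character()
  len_str <- character()
  new_node <- function() {
    parent[length(parent) + 1L] <<- NA_integer_
    children[[length(parent)]] <<- integer()
    label[length(parent)] <<- NA_character_
    len_str[length(parent)] <<- NA_character_
    length(parent)
  }

  parse_clade <- function() {
    v <- new_node()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        child <- parse_clade()
        parent[child] <<- v
        children[[v]] <<- c(children[[v]], child)
        ch <- peek()
        if (ch == ",") { pos <<- pos + 1L; next }
        if (ch == ")") { pos <<- pos + 1L; break }
        stop("Newick syntax error at position ", pos, ": expected ',' or ')'")
      }
    }
    lab <- take_token()
    if (nzchar(lab)) label[v] <<- lab
    if (peek() == ":") {
      pos <<- pos + 1L
      len_str[v] <<- take_token()
      if (!nzchar(len_str[v])) stop("missing length after ':'")
    }
    v
  }

  root <- parse_clade()
  if (pos <= n_chars) stop("trailing characters in Newick string: '",
                           substr(s, pos, n_chars), "'")
  if (!is.na(len_str[root])) {
    warning("length on the root position ignored")
    len_str[root] <- NA_character_
  }

  deg <- lengths(children)
  uni <- which(deg == 1L)
  if (length(uni))
    stop("vertex of out-degree 1 in input (vertex ", uni[1],
         "); suppressed-degree-two chains are not accepted")

  is_leaf <- deg == 0L
  if (anyNA(label[is_leaf]) || any(label[is_leaf] == ""))
    stop("every leaf needs a label")
  if (anyDuplicated(label[is_leaf]))
    stop("duplicate leaf label: ", label[is_leaf][duplicated(label[is_leaf])][1])

  lens <- NULL
  non_root <- setdiff(seq_along(parent), root)
  if (any(!is.na(len_str[non_root]))) {
    if (anyNA(len_str[non_root])) {
      if (lengths_required)
        stop("edge without a branch length (vertex ",
             non_root[is.na(len_str[non_root])][1], ")")
    } else {
      vals <- rep("0", length(parent))
      vals[non_root] <- len_str[non_root]
      lens <- rational(vals)
      if (!all(lens[non_root] > rational("0")))
        stop("non-positive branch length")
    }
  } else if (lengths_required && length(non_root)) {
    stop("tree has no branch lengths (use lengths_required = FALSE ",
         "for a topology-only tree)")
  }

  rooted_tree(parent, children, label, lens)
}

#' Write a tree as Newick text
#'
#' Rational lengths are emitted in exact `p/q` notation by default so that
#' `parse_newick(write_newick(tree))` round-trips losslessly; `digits`
#' switches to fixed-point decimal output (rounded half away from zero).
#'
#' @param tree a [rooted_tree].
#' @param digits `NULL` for exact `p/q` output, otherwise decimal places.
#' @param file optional path to write to.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, digits = NULL, file = NULL) {
  has_len <- !is.null(tree$length)
  if (has_len && is_epslen(tree$length))
    stop("realize infinitesimal lengths first (see realize_epsilon)")
  fmt_len <- function(v) {
    if (!has_len) return("")
    l <- tree$length[[v]]
    paste0(":", if (is.null(digits)) as.character(l) else rat_decimal(l, digits))
  }
  rec <- function(v) {
    kids <- tree$children[[v]]
    lab <- if (is.na(tree$label[v])) "" else tree$label[v]
    core <- if (!length(kids)) lab else
      paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","),
             ")", lab)
    if (v == tree$root) core else paste0(core, fmt_len(v))
  }
  out <- paste0(rec(tree$root), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Convert to an ape "phylo" object
#'
#' Lossy: exact rational lengths become doubles.  Useful for plotting and
#' for cross-checking topology against an independent parser.
#'
#' @param tree a [rooted_tree] with rational lengths (or none).
#' @return an `ape::phylo` object.
#' @export
as_phylo <- function(tree) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for as_phylo()")
  ape::read.tree(text = write_newick(tree, digits = 12L))
}
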