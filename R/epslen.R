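#' Infinitesimal edge lengths a + b*eps
#'
#' The rigid-index reversal construction assigns lengths of the form
#' `M + k*eps` and `eps`, where `eps` is an arbitrarily small positive
#' infinitesimal.  Rather than picking a small float (and then tuning
#' tolerances), lengths are kept symbolic: a pair of exact rationals
#' `(a, b)` representing `a + b*eps`.  Comparison is lexicographic on
#' `(a, b)`, which is the correct order for all sufficiently small
#' `eps > 0`.  Scores are linear in edge lengths, so only
#' rational-by-epslen products ever arise; `eps^2` terms never occur.
#'
#' @param a constant part, coerced with [rational()].
#' @param b eps coefficient, coerced with [rational()].
#' @return an object of class `epslen`.
#' @examples
#' epslen(32, 1)           # M + eps with M = 32
#' ep_cmp(epslen(1, 5), epslen(1, 7))  # -1: equal constants, eps decides
#' @export
epslen <- function(a, b = 0) {
  a <- rational(a)
  b <- rational(b)
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n)
  bb <- rep(b, length.out = n)
  structure(list(a = a, b = bb), class = "epslen",
            names_ = names(a))
}

#' @rdname epslen
#' @export
is_epslen <- function(x) inherits(x, "epslen")

#' @rdname epslen
#' @param x an `epslen` vector.
#' @export
ep_const <- function(x) {
  stopifnot(is_epslen(x))
  out <- x$a
  names(out) <- attr(x, "names_")
  out
}

#' @rdname epslen
#' @export
ep_epscoef <- function(x) {
  stopifnot(is_epslen(x))
  out <- x$b
  names(out) <- attr(x, "names_")
  out
}

as_epslen <- function(x) {
  if (is_epslen(x)) return(x)
  epslen(rational(x), 0)
}

#' @export
length.epslen <- function(x) length(x$a)

#' @export
names.epslen <- function(x) attr(x, "names_")

#' @export
`names<-.epslen` <- function(x, value) {
  attr(x, "names_") <- value
  x
}

#' @export
`[.epslen` <- function(x, i) {
  nm <- attr(x, "names_")
  if (is.character(i)) i <- match(i, nm)
  structure(list(a = x$a[i], b = x$b[i]), class = "epslen",
            names_ = if (is.null(nm)) NULL else nm[i])
}

#' @export
`[[.epslen` <- function(x, i) x[i]

#' @export
c.epslen <- function(...) {
  parts <- lapply(list(...), as_epslen)
  a <- do.call(c, lapply(parts, function(p) p$a))
  b <- do.call(c, lapply(parts, function(p) p$b))
  nms <- unlist(lapply(parts, function(p) {
    n <- attr(p, "names_")
    if (is.null(n)) rep("", length(p$a)) else n
  }))
  if (all(nms == "")) nms <- NULL
  structure(list(a = a, b = b), class = "epslen", names_ = nms)
}

#' @export
format.epslen <- function(x, ...) {
  a <- as.character(x$a)
  b <- as.character(x$b)
  out <- ifelse(b == "0", a,
         ifelse(a == "0", paste0(b, "*eps"), paste0(a, " + ", b, "*eps")))
  out <- gsub("\\+ -", "- ", out)
  names(out) <- attr(x, "names_")
  out
}

#' @export
print.epslen <- function(x, ...) {
  cat("<epslen>\n")
  print(format(x), quote = FALSE, ...)
  invisible(x)
}

# -- explicit arithmetic helpers (no Ops: mixed-class dispatch is fragile) --

#' Arithmetic and comparison for infinitesimal lengths
#'
#' @param x,y `epslen` (or rational, promoted) vectors.
#' @param r a [rational] scalar or vector multiplier.
#' @name epslen-arith
NULL

#' @rdname epslen-arith
#' @export
ep_add <- function(x, y) {
  x <- as_epslen(x); y <- as_epslen(y)
  structure(list(a = x$a + y$a, b = x$b + y$b), class = "epslen",
            names_ = attr(x, "names_") %||% attr(y, "names_"))
}

#' @rdname epslen-arith
#' @export
ep_sub <- function(x, y) {
  x <- as_epslen(x); y <- as_epslen(y)
  structure(list(a = x$a - y$a, b = x$b - y$b), class = "epslen",
            names_ = attr(x, "names_") %||% attr(y, "names_"))
}

#' @rdname epslen-arith
#' @export
ep_scale <- function(x, r) {
  x <- as_epslen(x); r <- rational(r)
  structure(list(a = x$a * r, b = x$b * r), class = "epslen",
            names_ = attr(x, "names_"))
}

#' @rdname epslen-arith
#' @export
ep_sum <- function(x) {
  x <- as_epslen(x)
  epslen(sum(x$a), sum(x$b))
}

#' @rdname epslen-arith
#' @return `ep_cmp`: integer vector in \{-1, 0, 1\} (lexicographic on (a, b)).
#' @export
ep_cmp <- function(x, y) {
  x <- as_epslen(x); y <- as_epslen(y)
  ca <- .rat_cmp(unclass(x$a), unclass(y$a))
  cb <- .rat_cmp(unclass(x$b), unclass(y$b))
  ifelse(ca != 0L, ca, cb)
}

#' @rdname epslen-arith
#' @export
ep_max <- function(x) {
  x <- as_epslen(x)
  best <- 1L
  for (i in seq_len(length(x))[-1]) {
    if (ep_cmp(x[i], x[best]) > 0L) best <- i
  }
  x[best]
}

#' @rdname epslen-arith
#' @export
ep_order <- function(x, decreasing = FALSE) {
  x <- as_epslen(x)
  n <- length(x)
  oa <- .rat_order(unclass(x$a))
  # stable refine by eps coefficient within equal constants
  key_a <- integer(n)
  key_a[oa] <- cumsum(c(1L, .rat_cmp(unclass(x$a)[oa[-1]],
                                     unclass(x$a)[oa[-n]]) != 0L))[seq_len(n)]
  ob <- .rat_order(unclass(x$b))
  key_b <- integer(n)
  key_b[ob] <- cumsum(c(1L, .rat_cmp(unclass(x$b)[ob[-1]],
                                     unclass(x$b)[ob[-n]]) != 0L))[seq_len(n)]
  o <- order(key_a, key_b)
  if (decreasing) rev(o) else o
}

#' @rdname epslen-arith
#' @param eps_value a positive [rational] value substituted for eps.
#' @export
ep_realize <- function(x, eps_value) {
  x <- as_epslen(x)
  out <- x$a + x$b * rational(eps_value)
  names(out) <- attr(x, "names_")
  out
}

#' @rdname epslen-arith
#' @export
ep_positive <- function(x) {
  # positivity of a + b*eps for arbitrarily small eps > 0
  x <- as_epslen(x)
  zero <- rational("0")
  (x$a > zero) | (x$a == zero & x$b > zero)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
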