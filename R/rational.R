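#' Exact rational numbers
#'
#' Vectors of arbitrary-precision rational numbers, stored as canonical
#' strings `"n"` or `"n/d"` (`d > 0`, fully reduced) and backed by a
#' compiled big-integer kernel.  All arithmetic and comparisons are exact;
#' this is what makes strictness and reversal verdicts reliable, since a
#' ranking tie must be a true tie and not a floating-point accident.
#'
#' `rational()` accepts integers, integer-valued doubles, and strings in
#' integer (`"7"`), fraction (`"-3/4"`) or decimal (`"2.25"`) notation.
#' Decimal strings are converted exactly.
#'
#' @param x object to convert.
#' @return an object of class `rational`.
#' @examples
#' rational("1/3") + rational("1/6")   # "1/2"
#' sum(rational(c("1/2", "1/3", "1/6")))
#' @export
rational <- function(x = character()) {
  if (inherits(x, "rational")) return(x)
  if (is.numeric(x)) {
    bad <- is.finite(x) & x != trunc(x)
    if (any(bad))
      stop("non-integer doubles are not converted implicitly; ",
           "pass a string such as \"1/3\" or \"0.25\"")
    x <- sprintf("%.0f", x)
  }
  if (!is.character(x)) stop("cannot convert ", class(x)[1], " to rational")
  out <- .rat_canon(x)
  names(out) <- names(x)
  structure(out, class = "rational")
}

#' @rdname rational
#' @export
as_rational <- rational

#' @rdname rational
#' @export
is_rational <- function(x) inherits(x, "rational")

new_rational <- function(x, nms = NULL) {
  # internal fast path: x already canonical character
  if (!is.null(nms)) names(x) <- nms
  structure(x, class = "rational")
}

#' @export
format.rational <- function(x, ...) format(unclass(x), ...)

#' @export
print.rational <- function(x, ...) {
  cat("<rational>\n")
  print(unclass(x), quote = FALSE, ...)
  invisible(x)
}

#' @export
as.character.rational <- function(x, ...) unclass(x)

#' @export
as.numeric.rational <- function(x, ...) {
  out <- .rat_dbl(unclass(x))
  names(out) <- names(x)
  out
}

#' @export
as.double.rational <- as.numeric.rational

#' @export
`[.rational` <- function(x, i) new_rational(unclass(x)[i])

#' @export
`[[.rational` <- function(x, i) new_rational(unclass(x)[[i]])

#' @export
`[<-.rational` <- function(x, i, value) {
  y <- unclass(x)
  y[i] <- unclass(rational(value))
  new_rational(y)
}

#' @export
c.rational <- function(...) {
  parts <- lapply(list(...), function(p) unclass(rational(p)))
  new_rational(unlist(parts))
}

#' @export
rep.rational <- function(x, ...) new_rational(rep(unclass(x), ...))

#' @export
length.rational <- function(x) length(unclass(x))

#' @export
Ops.rational <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(rational("0") - e1)
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for rationals")
  }
  a <- unclass(rational(e1))
  b <- unclass(rational(e2))
  nms <- if (!is.null(names(a)) && length(a) >= length(b)) names(a) else names(b)
  if (.Generic %in% c("+", "-", "*", "/"))
    return(new_rational(.rat_arith(.Generic, a, b), nms))
  if (.Generic %in% c("==", "!=", "<", ">", "<=", ">=")) {
    cmp <- .rat_cmp(a, b)
    out <- switch(.Generic,
      "==" = cmp == 0L, "!=" = cmp != 0L,
      "<" = cmp < 0L, ">" = cmp > 0L,
      "<=" = cmp <= 0L, ">=" = cmp >= 0L)
    names(out) <- nms
    return(out)
  }
  stop(.Generic, " not defined for rationals")
}

#' @export
Summary.rational <- function(..., na.rm = FALSE) {
  x <- do.call(c, lapply(list(...), rational))
  v <- unclass(x)
  switch(.Generic,
    sum = new_rational(.rat_sum(v)),
    max = new_rational(v[[.rat_order(v)[length(v)]]]),
    min = new_rational(v[[.rat_order(v)[1L]]]),
    range = new_rational(v[.rat_order(v)[c(1L, length(v))]]),
    stop(.Generic, " not defined for rationals"))
}

#' @export
abs.rational <- function(x) {
  neg <- startsWith(unclass(x), "-")
  y <- unclass(x)
  y[neg] <- substring(y[neg], 2L)
  new_rational(y, names(x))
}

#' Sort order of a rational vector
#'
#' @param x a [rational] vector.
#' @param decreasing sort direction.
#' @return an integer permutation (stable within ties), as [order()].
#' @export
rat_order <- function(x, decreasing = FALSE) {
  o <- .rat_order(unclass(rational(x)))
  if (decreasing) rev(o) else o
}

#' @rdname rat_order
#' @export
rat_sort <- function(x, decreasing = FALSE) x[rat_order(x, decreasing)]

#' Exact decimal rendering of rationals
#'
#' Rounds half away from zero at the requested number of decimal places,
#' computed in integer arithmetic (no double-precision detour).
#'
#' @param x a [rational] vector.
#' @param digits decimal places to keep.
#' @return character vector of fixed-point decimal strings.
#' @examples
#' rat_decimal(rational("113/60"), 2)  # "1.88"
#' @export
rat_decimal <- function(x, digits = 3L) {
  out <- .rat_decimal(unclass(rational(x)), as.integer(digits))
  names(out) <- names(x)
  out
}
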