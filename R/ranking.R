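#' Ranking of taxa by score
#'
#' Higher scores rank earlier.  Ties are recorded as groups; a ranking is
#' *strict* when no two scores are exactly equal (exact rational or
#' lexicographic infinitesimal comparison — never floating point).
#'
#' @param score_vec a named [rational] or [epslen] vector of scores.
#' @return `list(ordered_taxa, groups, strict)` of class `ranking`.
#' @export
ranking <- function(score_vec) {
  nms <- names(score_vec)
  stopifnot(!is.null(nms))
  o <- score_order(score_vec, decreasing = TRUE)
  sorted <- score_vec[o]
  n <- length(o)
  grp <- integer(n)
  g <- 1L
  grp[1] <- 1L
  if (n > 1) for (i in 2:n) {
    if (score_cmp(sorted[i], sorted[i - 1L]) != 0L) g <- g + 1L
    grp[i] <- g
  }
  structure(list(ordered_taxa = nms[o],
                 groups = split(nms[o], grp),
                 strict = g == n),
            class = "ranking")
}

#' @export
print.ranking <- function(x, ...) {
  cat("<ranking>", if (x$strict) "(strict)" else "(ties present)", "\n")
  cat(paste(vapply(x$groups, paste, character(1), collapse = " = "),
            collapse = " > "), "\n")
  invisible(x)
}

# unified exact comparison / ordering over rational and epslen vectors
score_cmp <- function(x, y) {
  if (is_epslen(x) || is_epslen(y)) ep_cmp(as_epslen(x), as_epslen(y))
  else .rat_cmp(unclass(rational(x)), unclass(rational(y)))
}

score_order <- function(x, decreasing = FALSE) {
  if (is_epslen(x)) ep_order(x, decreasing = decreasing)
  else rat_order(x, decreasing = decreasing)
}

#' Compare a ranking before and after an extinction event
#'
#' Exact pairwise comparison of two score vectors over the survivors.
#' Two reversal notions are reported:
#' * `reversed_strict` — both rankings strict and every pair discordant
#'   (the surviving species end up in the exact opposite order);
#' * `reversed_relaxed` — every pair strictly ordered before is strictly
#'   ordered the opposite way after, and at least one such pair exists.
#'   This is the appropriate notion under the ultrametric constraint,
#'   where cherry mates are forced to tie.
#'
#' Also reports concordant/discordant pair counts and the Kendall
#' rank correlation `tau` (as an exact rational; pairs tied on either
#' side count to neither side).
#'
#' @param before scores on the original tree (restricted to survivors).
#' @param after scores on the induced tree.
#' @param survivors taxon names to compare (default: names of `after`).
#' @return an object of class `ranking_comparison`.
#' @export
compare_rankings <- function(before, after, survivors = names(after)) {
  stopifnot(all(survivors %in% names(before)),
            all(survivors %in% names(after)))
  b <- before[survivors]
  a <- after[survivors]
  m <- length(survivors)
  conc <- 0L
  disc <- 0L
  flipped <- TRUE
  any_strict_pair <- FALSE
  if (m > 1) for (i in 1:(m - 1)) for (j in (i + 1):m) {
    cb <- score_cmp(b[i], b[j])
    ca <- score_cmp(a[i], a[j])
    if (cb != 0L && ca != 0L) {
      if (cb == ca) conc <- conc + 1L else disc <- disc + 1L
    }
    if (cb != 0L) {
      any_strict_pair <- TRUE
      if (ca != -cb) flipped <- FALSE
    }
  }
  rb <- ranking(b)
  ra <- ranking(a)
  npairs <- m * (m - 1) / 2
  tau <- if (npairs > 0)
    rational(conc - disc) / rational(npairs) else rational("1")
  structure(list(
    # a single survivor is trivially in reversed (strict) order
    reversed_strict = rb$strict && ra$strict && disc == npairs,
    reversed_relaxed = flipped && any_strict_pair,
    concordant_pairs = conc,
    discordant_pairs = disc,
    tau = tau,
    before_ranking = rb,
    after_ranking = ra), class = "ranking_comparison")
}

#' @export
print.ranking_comparison <- function(x, ...) {
  cat("<ranking_comparison>\n")
  cat("  reversed (strict): ", x$reversed_strict, "\n", sep = "")
  cat("  reversed (relaxed): ", x$reversed_relaxed, "\n", sep = "")
  cat("  concordant/discordant pairs: ", x$concordant_pairs, "/",
      x$discordant_pairs, "  tau = ", as.character(x$tau), "\n", sep = "")
  invisible(x)
}
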