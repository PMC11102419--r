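# necessary extinctions, fixed leaves, ranking comparison

test_that("necessary extinction counts", {
  # nonbinary example: a 4-leaf group and two cherries need 3+1+1 deletions
  grp <- parse_newick("((a1,a2,a3,a4),(b1,b2),(c1,c2));",
                      lengths_required = FALSE)
  ne <- necessary_extinctions(grp)
  expect_identical(ne$min_deletions, 5L)
  expect_identical(length(ne$witness), 5L)
  # caterpillar: a single deletion (one cherry leaf)
  expect_identical(necessary_extinctions(caterpillar_tree(9))$min_deletions,
                   1L)
  # rigid case on the example tree: one per cherry (3) plus both isolated
  # leaves (x11 is a single-leaf maximal pendant subtree)
  ne3 <- necessary_extinctions(fig3_tree(), rigid = TRUE)
  expect_identical(ne3$min_deletions, 5L)
  expect_identical(ne3$witness, c("x2", "x5", "x7", "x8", "x10"))
  expect_true(ne3$isolated$all_required)
  expect_error(necessary_extinctions(parse_newick("(a:1,b:1);")), "3 leaves")
})

test_that("the default reversal events", {
  ev <- reversal_event(fig3_tree(), rigid = TRUE)
  expect_identical(ev$extinct, c("x2", "x5", "x7", "x8", "x10"))
  expect_identical(ev$survivors, c("x1", "x3", "x4", "x6", "x9", "x11"))
  # non-rigid: cherry deletions only
  expect_identical(reversal_event(fig3_tree())$extinct,
                   c("x2", "x7", "x10"))
})

test_that("fixed leaves: symbolic coefficient identity", {
  es <- builtin_rule("es")
  ev <- c("x2", "x5", "x7", "x8", "x10")
  expect_identical(fixed_leaves(fig3_tree(), es, ev), "x11")
  # empty event: every leaf is fixed
  expect_identical(fixed_leaves(fig3_tree(), es, character(0)),
                   sort_taxa(leaf_labels(fig3_tree())))
  # beta on caterpillars: every survivor except the three leaves furthest
  # from the root is fixed
  beta <- builtin_rule("beta")
  for (n in c(6L, 8L)) for (ext in list("x1", c("x2", "x4"))) {
    tr <- caterpillar_tree(n)
    fx <- fixed_leaves(tr, beta, ext)
    surv <- setdiff(paste0("x", 1:n), ext)
    expect_identical(fx, sort_taxa(setdiff(surv, c("x1", "x2", "x3"))),
                     info = paste(n, paste(ext, collapse = ",")))
  }
  # FP oracle: a survivor is fixed iff no ancestral cluster of its root
  # path loses a member (coefficients are 1/|cluster|)
  fp <- builtin_rule("fp")
  for (s in 1:10) {
    tr <- synthetic_tree(6 + (s %% 5), seed = 400 + s, mode = "binary")
    ch <- m_cherries(tr)[[1]]
    ext <- ch$leaves[1]
    fx <- fixed_leaves(tr, fp, ext)
    surv <- setdiff(leaf_labels(tr), ext)
    unchanged <- vapply(surv, function(x) {
      v <- node_id(tr, x)
      while (!is.na(tr$parent[v])) {
        if (ext %in% cluster(tr, v)) return(FALSE)
        v <- tr$parent[v]
      }
      TRUE
    }, logical(1))
    expect_identical(fx, sort_taxa(surv[unchanged]), info = s)
  }
})

test_that("ranking comparison semantics", {
  b <- rational(c(x1 = "3", x2 = "2", x3 = "1"))
  a_rev <- rational(c(x1 = "1", x2 = "2", x3 = "5"))
  cmp <- compare_rankings(b, a_rev, names(b))
  expect_true(cmp$reversed_strict)
  expect_true(cmp$reversed_relaxed)
  expect_rat_equal(cmp$tau, "-1")
  # identical vectors: tau 1, no reversal
  cmp2 <- compare_rankings(b, b, names(b))
  expect_false(cmp2$reversed_strict)
  expect_false(cmp2$reversed_relaxed)
  expect_rat_equal(cmp2$tau, 1)
  # relaxed but not strict: one tie, other pairs flipped
  b3 <- rational(c(x = "1", y = "1", z = "3"))
  a3 <- rational(c(x = "5", y = "5", z = "2"))
  cmp3 <- compare_rankings(b3, a3, names(b3))
  expect_false(cmp3$reversed_strict)
  expect_true(cmp3$reversed_relaxed)
  # antisymmetry: swapping before/after preserves the reversal flags
  set.seed(5)
  for (k in 1:20) {
    v1 <- rational(sample(1:8, 5, replace = TRUE))
    v2 <- rational(sample(1:8, 5, replace = TRUE))
    names(v1) <- names(v2) <- paste0("t", 1:5)
    c12 <- compare_rankings(v1, v2, names(v1))
    c21 <- compare_rankings(v2, v1, names(v1))
    expect_identical(c12$reversed_strict, c21$reversed_strict)
    expect_identical(c12$reversed_relaxed, c21$reversed_relaxed)
    expect_identical(c12$discordant_pairs, c21$discordant_pairs)
  }
})

test_that("caterpillar ES robustness checker", {
  expect_false(caterpillar_es_robustness(5, "x1"))
  expect_false(caterpillar_es_robustness(4, character(0)))
  expect_false(caterpillar_es_robustness(7, c("x2", "x4")))
  expect_true(caterpillar_es_robustness(5, c("x1", "x4")))
  expect_true(caterpillar_es_robustness(5, c("x1", "x2", "x3")))
  expect_error(caterpillar_es_robustness(3, "x1"), "n >= 4")
  # brute-force verification path runs clean
  expect_false(caterpillar_es_robustness(5, c("x1", "x2"), n_random = 10,
                                         seed = 3))
})

test_that("surviving sibling pairs block strict reversals (all indices)", {
  set.seed(11)
  rules <- all_rules()[c("fp", "es", "alpha", "zeta")]
  for (k in 1:40) {
    tr <- synthetic_tree(5 + (k %% 8), seed = 500 + k, mode = "binary")
    ch <- m_cherries(tr)[[1]]          # both cherry leaves survive
    others <- setdiff(leaf_labels(tr), ch$leaves)
    ext <- sample(others, sample.int(max(1, length(others) - 1), 1))
    for (rule in rules) {
      cert <- verify_reversal(tr, NULL, rule, ext)
      expect_false(cert$comparison$reversed_strict,
                   info = paste(rule$name, k))
    }
  }
})
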