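# index framework: ratios, coefficients, scores, classification

fig3 <- fig3_tree()
fig3u <- set_lengths(fig3_tree(), unit = TRUE)

test_that("the published ratio table is reproduced exactly", {
  # rows: index; columns: vertices p q r s t v (t and v share a class)
  expected <- list(
    fp      = c(p = "1/2:1/2", q = "4/5:1/5", r = "3/5:2/5",
                s = "3/4:1/4", t = "2/3:1/3", v = "2/3:1/3"),
    es      = c(p = "1/2:1/2", q = "1/2:1/2", r = "1/2:1/2",
                s = "1/2:1/2", t = "1/2:1/2", v = "1/2:1/2"),
    alpha   = c(p = "1/2:1/2", q = "2/3:1/3", r = "2/3:1/3",
                s = "2/3:1/3", t = "2/3:1/3", v = "2/3:1/3"),
    beta    = c(p = "1/2:1/2", q = "1:0", r = "1:0",
                s = "1:0", t = "1:0", v = "1:0"),
    gamma   = c(p = "1/2:1/2", q = "0:1", r = "0:1",
                s = "0:1", t = "0:1", v = "0:1"),
    delta   = c(p = "1/4:3/4", q = "3/4:1/4", r = "1/2:1/2",
                s = "3/4:1/4", t = "3/4:1/4", v = "3/4:1/4"),
    epsilon = c(p = "3/4:1/4", q = "1:0", r = "1:0",
                s = "1:0", t = "1/2:1/2", v = "1/2:1/2"),
    zeta    = c(p = "1/2:1/2", q = "16/17:1/17", r = "9/13:4/13",
                s = "9/10:1/10", t = "4/5:1/5", v = "4/5:1/5"),
    eta     = c(p = "1/2:1/2", q = "1/2:1/2", r = "1/2:1/2",
                s = "3/4:1/4", t = "2/3:1/3", v = "2/3:1/3"))
  rules <- all_rules()
  for (nm in names(expected)) for (vtx in names(expected[[nm]])) {
    expect_identical(ratio_at(fig3, rules[[nm]], vtx),
                     expected[[nm]][[vtx]],
                     info = paste(nm, "at", vtx))
  }
  # theta's table (left-hand numerators 4,8,5,0,2 over 8)
  th <- theta_rule()
  expect_identical(ratio_at(fig3, th, "p"), "1/2:1/2")
  expect_identical(ratio_at(fig3, th, "q"), "1:0")
  expect_identical(ratio_at(fig3, th, "r"), "5/8:3/8")
  expect_identical(ratio_at(fig3, th, "s"), "0:1")
  expect_identical(ratio_at(fig3, th, "t"), "1/4:3/4")
  expect_identical(ratio_at(fig3, th, "v"), "1/4:3/4")
  # cherry-parent vertices are forced to 1/2:1/2 by neutrality
  for (nm in names(rules))
    expect_identical(ratio_at(fig3, rules[[nm]], "w"), "1/2:1/2")
})

test_that("worked unit-length scores of x3 match the printed values", {
  printed <- c(fp = "1.88", es = "1.94", alpha = "1.78", beta = "1.00",
               gamma = "2.00", delta = "1.61", epsilon = "2.88",
               zeta = "1.63", eta = "1.77")
  rules <- all_rules()
  for (nm in names(printed))
    expect_identical(rat_decimal(scores(fig3u, rules[[nm]])["x3"], 2),
                     c(x3 = printed[[nm]]), info = nm)
  expect_identical(rat_decimal(scores(fig3u, theta_rule())["x3"], 2),
                   c(x3 = "1.75"))
  expect_rat_equal(scores(fig3u, rules$fp)["x3"], "113/60")
  expect_rat_equal(scores(fig3u, rules$es)["x3"], "31/16")
})

test_that("coefficient tables satisfy the allocation-function axioms", {
  for (rule in list(builtin_rule("fp"), builtin_rule("es"), theta_rule())) {
    gam <- coefficients_table(fig3, rule)
    for (e in colnames(gam)) {
      col <- rational(gam[, e])
      expect_rat_equal(sum(col), 1)                   # cluster sum = 1
      inside <- cluster(fig3, as.integer(e))
      expect_true(all(col[setdiff(rownames(gam), inside)] ==
                      rational("0")))                 # descent condition
    }
    for (x in leaf_labels(fig3))
      expect_rat_equal(gam[x, as.character(node_id(fig3, x))], 1)
  }
  # alpha coefficient from the worked example: x3 gets 1/3 at v
  gam <- coefficients_table(fig3, builtin_rule("alpha"))
  expect_rat_equal(gam["x3", as.character(node_id(fig3, "v"))], "1/3")
  # fp coefficient on the root edge collapses to 1/|cluster|
  gam_fp <- coefficients_table(fig3, builtin_rule("fp"))
  expect_rat_equal(gam_fp["x3", as.character(node_id(fig3, "p"))], "1/10")
})

test_that("consistency: Gamma vectors align with each vertex's ratio", {
  for (rule in list(builtin_rule("fp"), builtin_rule("delta_cherry"))) {
    gam <- coefficients_table(fig3, rule)
    ratios <- vertex_ratios(fig3, rule)
    for (vlab in c("q", "s", "r", "t")) {
      v <- node_id(fig3, vlab)
      kids <- fig3$children[[v]]
      # every edge on the root-to-v path (child-endpoint convention)
      f <- v
      while (!is.na(fig3$parent[f])) {
        Gf <- lapply(kids, function(k) {
          inside <- fig3$label[descendant_leaves(fig3, k)]
          sum(rational(gam[inside, as.character(f)]))
        })
        # proportionality: Gf[i] * ratio[j] == Gf[j] * ratio[i]
        r <- ratios[[v]]
        for (i in seq_along(kids)) for (j in seq_along(kids))
          expect_rat_equal(Gf[[i]] * r[j], Gf[[j]] * r[i])
        f <- fig3$parent[f]
      }
    }
  }
})

test_that("conservation and the FP/ES closed-form oracles agree", {
  rules <- all_rules()
  for (s in 1:40) {
    mode <- if (s %% 4 == 0) "multifurcating" else "binary"
    tr <- synthetic_tree(2 + (s %% 11), seed = 300 + s, mode = mode)
    use <- if (is_binary_tree(tr)) rules else rules[c("fp", "es")]
    for (nm in names(use)) {
      sc <- scores(tr, use[[nm]])
      expect_rat_equal(sum(sc), total_length(tr))
    }
    for (x in leaf_labels(tr)) {
      expect_rat_equal(scores(tr, rules$fp)[x], fp_score_direct(tr, x))
      expect_rat_equal(scores(tr, rules$es)[x], es_score_direct(tr, x))
    }
  }
})

test_that("neutrality: mirrored leaves in isomorphic subtrees score equally", {
  tr <- parse_newick("(((a:3,b:5)A:2,(c:3,d:5)B:2)C:1,e:4);")
  for (rule in all_rules()) {
    sc <- scores(tr, rule)
    expect_rat_equal(sc["a"], sc["c"])
    expect_rat_equal(sc["b"], sc["d"])
  }
})

test_that("binary-only rules reject multifurcations; fp/es accept them", {
  tr <- parse_newick("((a:1,b:1,c:1):1,d:1);")
  expect_error(scores(tr, builtin_rule("alpha")), "binary")
  expect_rat_equal(scores(tr, builtin_rule("es"))["a"],
                   rational("1") + rational("1/3"))
  expect_rat_equal(scores(tr, builtin_rule("fp"))["d"], 1)
  expect_error(builtin_rule("nope"), "unknown")
})

test_that("table rules: defaults, neutrality violations, ES equivalence", {
  expect_error(table_rule(list(list(children = c("L", "L"),
                                    terms = c("2/3", "1/3")))),
               "neutrality")
  expect_error(table_rule(list(list(children = c("L", "L"),
                                    terms = c("2/3", "2/3")))),
               "invalid ratio")
  # an all-1/2 table on a binary tree reproduces Equal-Splits
  tr <- synthetic_tree(6, seed = 11, mode = "binary")
  keys <- shape_keys_all(tr)
  classes <- unique(lapply(setdiff(which(lengths(tr$children) > 0),
                                   integer(0)),
                           function(v) sort(keys[tr$children[[v]]])))
  tb <- table_rule(lapply(classes, function(k)
    list(children = k, terms = c("1/2", "1/2"))), name = "half")
  expect_true(all(scores(tr, tb) == scores(tr, builtin_rule("es"))))
  # missing class errors unless default_equal
  th <- theta_rule()
  # the 7-leaf caterpillar has a non-root class outside theta's table
  expect_error(scores(set_lengths(caterpillar_tree(7), unit = TRUE), th),
               "no assignment")
})

test_that("interior/boundary classification", {
  expect_identical(classify_interior(builtin_rule("es"), fig3)$class,
                   "interior")
  expect_identical(classify_interior(builtin_rule("fp"), fig3)$class,
                   "interior")
  b <- classify_interior(builtin_rule("beta"), fig3)
  expect_identical(b$class, "boundary")
  expect_identical(fig3$label[b$witness$vertex], "q")
  expect_identical(classify_interior(builtin_rule("gamma_min"), fig3)$class,
                   "boundary")
})

test_that("rigidity probe finds witnesses exactly where expected", {
  expect_identical(rigidity_probe(builtin_rule("es"))$status, "rigid_witness")
  expect_identical(sort(rigidity_probe(builtin_rule("es"))$witness$breadths),
                   c(2L, 3L))
  expect_identical(rigidity_probe(builtin_rule("fp"), 12L)$status,
                   "no_witness_up_to_bound")
  expect_identical(rigidity_probe(builtin_rule("zeta_squares"), 12L)$status,
                   "no_witness_up_to_bound")
  for (nm in c("alpha", "beta", "gamma_min", "delta_cherry",
               "epsilon_singleparent", "eta_hybrid"))
    expect_identical(rigidity_probe(builtin_rule(nm))$status,
                     "rigid_witness", info = nm)
  expect_error(rigidity_probe(builtin_rule("fp"), 2L))
})
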