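# rooted tree data model, Newick I/O and structural queries

test_that("parse_newick handles the basic contract", {
  tr <- parse_newick("(a:1,b:2);")
  expect_identical(n_leaves(tr), 2L)
  expect_identical(length(tr$children[[tr$root]]), 2L)
  expect_rat_equal(total_length(tr), 3)
  expect_error(parse_newick("(a:1,b:-2);"), "non-positive")
  expect_error(parse_newick("(a:1,b:0);"), "non-positive")
  expect_error(parse_newick("(a:1,a:2);"), "duplicate")
  expect_error(parse_newick("((a:1):1,b:2);"), "out-degree 1")
  expect_error(parse_newick("(a:1,b:2"), "syntax|expected")
  expect_error(parse_newick("(a:1,b:2);", lengths_required = TRUE), NA)
  expect_error(parse_newick("(a,b);"), "length")
  expect_warning(parse_newick("(a:1,b:2):5;"), "root")
  # rational and exact-decimal lengths
  tr2 <- parse_newick("(a:1/3,b:0.25);")
  expect_rat_equal(tr2$length[node_id(tr2, "a")], "1/3")
  expect_rat_equal(tr2$length[node_id(tr2, "b")], "1/4")
})

test_that("newick round-trips exactly, and ape agrees on the topology", {
  for (s in 1:25) {
    tr <- synthetic_tree(2 + (s %% 9), seed = s,
                         mode = if (s %% 4 == 0) "multifurcating" else "binary")
    txt <- write_newick(tr)
    tr2 <- parse_newick(txt)
    expect_identical(write_newick(tr2), txt)
    expect_identical(leaf_labels(tr2), leaf_labels(tr))
    expect_true(all(rational(tr2$length[tree_edges(tr2)]) ==
                    rational(tr$length[tree_edges(tr)])))
  }
  skip_if_not_installed("ape")
  tr <- fig3_tree(unit_lengths = TRUE)
  ph <- as_phylo(tr)
  expect_identical(sort(ph$tip.label), sort(leaf_labels(tr)))
  expect_identical(ph$Nnode, 10L)
})

test_that("cluster returns the leaves below an edge", {
  tr <- fig3_tree()
  expect_identical(cluster(tr, "q"), paste0("x", 1:5))
  expect_identical(cluster(tr, "x7"), "x7")
  two <- parse_newick("(a:1,b:1);")
  expect_identical(cluster(two, "a"), "a")
  expect_error(cluster(tr, "nope"), "no vertex")
  expect_error(cluster(tr, tr$root), "root")
})

test_that("m-cherries, caterpillars and stars", {
  tr <- fig3_tree()
  ch <- m_cherries(tr)
  expect_setequal(vapply(ch, function(m) paste(m$leaves, collapse = "+"),
                         character(1)),
                  c("x1+x2", "x6+x7", "x10+x9"))
  expect_identical(length(m_cherries(caterpillar_tree(8))), 1L)
  st <- m_cherries(star_tree(5))
  expect_identical(length(st), 1L)
  expect_identical(length(st[[1]]$leaves), 5L)
})

test_that("isolated leaves", {
  expect_identical(isolated_leaves(caterpillar_tree(7)), "x6")
  expect_identical(isolated_leaves(fig3_tree()), c("x5", "x8"))
  expect_identical(isolated_leaves(star_tree(6)), character(0))
  # never intersects m-cherry leaves nor root-adjacent leaves
  for (s in 1:20) {
    tr <- synthetic_tree(3 + (s %% 10), seed = 100 + s, mode = "binary")
    iso <- isolated_leaves(tr)
    chl <- unlist(lapply(m_cherries(tr), `[[`, "leaves"))
    expect_length(intersect(iso, chl), 0L)
    root_adj <- tr$label[intersect(tr$children[[tr$root]], leaves(tr))]
    expect_length(intersect(iso, root_adj), 0L)
  }
})

test_that("prune_and_suppress merges lengths and keeps the root", {
  tr <- set_lengths(fig3_tree(), unit = TRUE)
  ind <- prune_and_suppress(tr, c("x2", "x5", "x7", "x8", "x10"))
  # q suppressed: edge from p towards x4's side has length l(p,q)+l(q,s)
  expect_rat_equal(ind$length[node_id(ind, "s")], 2)
  expect_identical(sort_taxa(leaf_labels(ind)),
                   c("x1", "x3", "x4", "x6", "x9", "x11"))
  # two-leaf tree minus b: root retains a single unmerged edge
  two <- parse_newick("(a:1,b:2);")
  ind2 <- prune_and_suppress(two, "b")
  expect_identical(leaf_labels(ind2), "a")
  expect_rat_equal(total_length(ind2), 1)
  # pruning nothing is the identity
  ind3 <- prune_and_suppress(tr, extinction_event(tr, character(0)))
  expect_identical(write_newick(ind3), write_newick(tr))
  expect_error(extinction_event(tr, leaf_labels(tr)), "survivors")
})

test_that("pruning conserves the spanning-subtree length", {
  set.seed(7)
  for (s in 1:20) {
    tr <- synthetic_tree(4 + (s %% 9), seed = 200 + s,
                         mode = if (s %% 3 == 0) "multifurcating" else "binary")
    labs <- leaf_labels(tr)
    extinct <- sample(labs, sample.int(length(labs) - 1L, 1L))
    ind <- prune_and_suppress(tr, extinct)
    # oracle: sum of lengths over the union of survivors' root paths
    keep <- rep(FALSE, length(tr$parent))
    for (x in setdiff(labs, extinct)) {
      v <- node_id(tr, x)
      while (!is.na(v)) { keep[v] <- TRUE; v <- tr$parent[v] }
    }
    span <- sum(rational(unclass(tr$length)[keep &
      !is.na(tr$parent)]))
    expect_rat_equal(total_length(ind), span)
  }
})

test_that("shape keys encode rooted shape isomorphism", {
  tr <- fig3_tree()
  expect_identical(shape_key(tr, "w"), shape_key(tr, "y"))
  expect_identical(shape_key(tr, "w"), shape_key(tr, "u"))
  expect_false(shape_key(tr, "t") == shape_key(tr, "u"))
  expect_identical(shape_key(tr, "x1"), "L")
  # invariance under child reordering
  a <- parse_newick("((a:1,b:1):1,c:1);")
  b <- parse_newick("(c:1,(b:1,a:1):1);")
  expect_identical(shape_key(a), shape_key(b))
})

test_that("equivalence classes, breadth and singularity", {
  tr <- fig3_tree()
  ec <- equivalence_classes(tr)
  members <- lapply(ec, function(e) sort(tr$label[e$member_vertices]))
  # q, s, v in distinct singular classes
  for (lab in c("q", "s")) {
    cl <- ec[[which(vapply(members, function(m) lab %in% m, logical(1)))]]
    expect_true(cl$singular)
    expect_identical(length(cl$member_vertices), 1L)
  }
  # w and y (and u) share the cherry-parent class
  wcl <- ec[[which(vapply(members, function(m) "w" %in% m, logical(1)))]]
  expect_true(all(c("w", "y", "u") %in% tr$label[wcl$member_vertices]))
  # breadth = sum of child-shape leaf counts; refines shape equality
  keys <- vapply(seq_along(tr$parent), function(v) shape_key(tr, v),
                 character(1))
  for (cl in ec) {
    expect_identical(cl$breadth,
                     length(descendant_leaves(tr, cl$representative)))
    expect_identical(length(unique(keys[cl$member_vertices])), 1L)
  }
  b4 <- balanced4_tree()
  ec4 <- equivalence_classes(b4)
  expect_identical(length(ec4), 1L)
  expect_identical(ec4[[1]]$breadth, 2L)
  expect_true(ec4[[1]]$singular)
})

test_that("ultrametric test is exact", {
  expect_true(is_ultrametric(u12_tree()))
  expect_false(is_ultrametric(set_lengths(fig3_tree(), unit = TRUE)))
  expect_true(is_ultrametric(parse_newick("(a:1,(b:1/2,c:0.5):1/2);")))
  expect_false(is_ultrametric(parse_newick("(a:1,(b:1/2,c:0.500001):1/2);")))
  for (s in 1:10)
    expect_true(is_ultrametric(synthetic_tree(6, seed = s,
                                              mode = "ultrametric")))
})
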