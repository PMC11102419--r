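# shared helpers: exact-value expectations and rule inventories

expect_rat_equal <- function(x, expected) {
  x <- rational(x)
  expected <- rational(expected)
  expect_true(all(x == expected),
              info = paste("got", paste(as.character(x), collapse = ","),
                           "expected",
                           paste(as.character(expected), collapse = ",")))
}

# every builtin rule; alpha..eta are binary-only
all_rules <- function() {
  list(fp = builtin_rule("fp"),
       es = builtin_rule("es"),
       alpha = builtin_rule("alpha"),
       beta = builtin_rule("beta"),
       gamma = builtin_rule("gamma_min"),
       delta = builtin_rule("delta_cherry"),
       epsilon = builtin_rule("epsilon_singleparent"),
       zeta = builtin_rule("zeta_squares"),
       eta = builtin_rule("eta_hybrid"))
}

binary_only <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta")

is_binary_tree <- function(tree) {
  deg <- lengths(tree$children)
  all(deg[deg > 0L] == 2L)
}

ratio_at <- function(tree, rule, label) {
  r <- vertex_ratios(tree, rule)[[node_id(tree, label)]]
  paste(as.character(r), collapse = ":")
}
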