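test_that("unrooted gene trees are rooted and mapped correctly", {
  U <- parse_newick("(b1:2,c1:2,a1:4)y;", rooted = FALSE)
  res <- reconcile_unrooted_gene(input_history(U, fix_S(), fix_mu()))
  expect_equal(res$status, "reconciled")
  h <- res$history
  expect_true(tree_equal(h$G, fix_G()))  # rooted 1 above y, 3 above a1
  lblS <- h$S$labels[h$phi]
  names(lblS) <- h$G$labels
  expect_equal(unname(lblS["y"]), "x")
  expect_equal(unname(lblS["Q"]), "r")
  ## matches the rooted algorithm on the known rooted version
  r2 <- reconcile_rooted(input_history(fix_G(), fix_S(), fix_mu()))
  expect_true(history_equal(h, r2$history))
})

test_that("undefined triangulation rejects the input", {
  U <- parse_newick("(b1:1,c1:2,a1:4)y;", rooted = FALSE)
  res <- reconcile_unrooted_gene(input_history(U, fix_S(), fix_mu()))
  expect_equal(res$status, "irreconcilable")
  res2 <- reconcile_per_edge(input_history(U, fix_S(), fix_mu()))
  expect_equal(res2$status, "irreconcilable")
})

test_that("root placement on an edge follows the lca/eps rule", {
  S <- fix_S()
  idx <- build_index(S)
  lbl <- function(l) isorec:::node_by_label(S, l)
  ## edge (y, a1): lambda = r, eps = (4 - 1 - 3)/2 = 0, lambda differs from
  ## both images -> candidate at offset 1 mapping to r
  pr <- place_root_on_edge(idx, rat(4), tp(lbl("x")), tp(lbl("A")))
  expect_equal(pr$kind, "candidate")
  expect_equal(pr$offset, rat(1))
  expect_true(tp_eq(pr$q_img, tp(lbl("r"))))
  ## both genes in B at distance 4: lambda = B, eps = 2 > 0
  pr2 <- place_root_on_edge(idx, rat(4), tp(lbl("B")), tp(lbl("B")))
  expect_equal(pr2$kind, "candidate")
  expect_equal(pr2$offset, rat(2))
  expect_true(tp_eq(pr2$q_img, tp(lbl("x"))))
  ## one endpoint already the ancestor at the full distance: no root here
  pr3 <- place_root_on_edge(idx, rat(1), tp(lbl("x")), tp(lbl("B"), rat(1)))
  expect_equal(pr3$kind, "none")
})

test_that("two-leaf gene trees are rooted at the implied midpoint", {
  G2 <- itree(c("g1", "g2"), matrix(c(1L, 2L), ncol = 2), list(rat(4)),
              rooted = FALSE)
  res <- reconcile_unrooted_gene(input_history(G2, fix_S(),
                                               leafmap(g1 = "B", g2 = "B")))
  expect_equal(res$status, "reconciled")
  h <- res$history
  root <- isorec:::rooted_form(h$G)$root
  expect_equal(h$S$labels[h$phi[root]], "x")
  ## the induced history is a duplication coincident with the speciation:
  ## accepted here, but not expandable into a positive simple history
  expect_true(is_inferable(h))
  expect_false(admits_positive_simple(h))
  ## a two-leaf gene tree whose edge admits no root is irreconcilable
  G3 <- itree(c("g1", "g2"), matrix(c(1L, 2L), ncol = 2), list(rat(3)),
              rooted = FALSE)
  res3 <- reconcile_unrooted_gene(input_history(G3, fix_S(),
                                                leafmap(g1 = "B", g2 = "C")))
  expect_equal(res3$status, "irreconcilable")
})

test_that("stage-2 processing order never changes the mapping", {
  hi <- sim_inferable(6, n_species = 5, min_genes = 4)
  iph <- derive_input(hi, unroot_gene = TRUE)
  ref <- reconcile_unrooted_gene(iph)
  expect_equal(ref$status, "reconciled")
  set.seed(42)
  for (k in 1:50) {
    res <- reconcile_unrooted_gene(iph, pop_policy = "random")
    expect_true(history_equal(res$history, ref$history))
  }
})

test_that("the per-edge algorithm is equivalent to the stage algorithm", {
  for (s in 1:40) {
    hi <- sim_inferable(s, n_species = 2 + (s %% 5), min_genes = 2)
    iph <- derive_input(hi, unroot_gene = TRUE)
    r1 <- reconcile_unrooted_gene(iph)
    r2 <- reconcile_per_edge(iph)
    expect_equal(r1$status, r2$status)
    if (r1$status == "reconciled")
      expect_true(history_equal(r1$history, r2$history))
    ## mutate one gene edge length: the two algorithms must still agree
    ## (a lengthened edge may stay reconcilable when it hosts the root)
    Gm <- iph$G
    Gm$elen[[1]] <- rat_add(Gm$elen[[1]], rat(1))
    iphm <- input_history(Gm, iph$S, iph$mu)
    m1 <- reconcile_unrooted_gene(iphm)
    m2 <- reconcile_per_edge(iphm)
    expect_equal(m1$status, m2$status)
    if (m1$status == "reconciled")
      expect_true(history_equal(m1$history, m2$history))
  }
})

test_that("a too-short edge fails the distance check in both algorithms", {
  ## y maps to x from b1/c1, but the edge to b2 is shorter than d(x, B)
  G <- parse_newick("(b1:2,c1:2,b2:1)y;", rooted = FALSE)
  mu <- leafmap(b1 = "B", c1 = "C", b2 = "B")
  expect_equal(reconcile_per_edge(input_history(G, fix_S(), mu))$status,
               "irreconcilable")
  expect_equal(reconcile_unrooted_gene(input_history(G, fix_S(), mu))$status,
               "irreconcilable")
})

test_that("round trip: unrooting and reconciling recovers the history", {
  for (s in 1:40) {
    hi <- sim_inferable(s + 100, n_species = 2 + (s %% 6), min_genes = 2)
    iph <- derive_input(hi, unroot_gene = TRUE)
    res <- reconcile_unrooted_gene(iph)
    expect_equal(res$status, "reconciled")
    expect_true(history_equal(res$history, hi))
  }
})

test_that("rooted and unrooted runs agree on reconcilability", {
  for (s in 1:20) {
    hi <- sim_inferable(s, n_species = 2 + (s %% 4), min_genes = 2)
    iph_r <- derive_input(hi)
    iph_u <- derive_input(hi, unroot_gene = TRUE)
    r <- reconcile_rooted(iph_r)
    u <- reconcile_unrooted_gene(iph_u)
    expect_equal(r$status, u$status)
    if (r$status == "reconciled")
      expect_true(history_equal(r$history, u$history))
  }
})
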