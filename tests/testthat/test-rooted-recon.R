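test_that("rooted reconciliation recovers the expected mapping", {
  res <- reconcile_rooted(input_history(fix_G(), fix_S(), fix_mu()))
  expect_equal(res$status, "reconciled")
  h <- res$history
  lblS <- h$S$labels[h$phi]
  names(lblS) <- h$G$labels
  expect_equal(unname(lblS["y"]), "x")
  expect_equal(unname(lblS["q"]), "r")
  ## species tree unchanged
  expect_true(tree_equal(h$S, fix_S()))
})

test_that("incompatible distances are rejected as irreconcilable", {
  G2 <- parse_newick("((b1:2,c1:2)y:0.5,a1:3)q;", rooted = TRUE)
  res <- reconcile_rooted(input_history(G2, fix_S(), fix_mu()))
  expect_equal(res$status, "irreconcilable")
  ## invalid input is a contract error, not an algorithm answer
  G3 <- parse_newick("(((b1:2)w:1,c1:3)y:1,a1:4)q;", rooted = TRUE)
  expect_error(reconcile_rooted(input_history(G3, fix_S(), fix_mu())),
               "invalid input")
})

test_that("single-leaf gene trees reconcile trivially", {
  G1 <- parse_newick("b1;", rooted = TRUE)
  res <- reconcile_rooted(input_history(G1, fix_S(), leafmap(b1 = "B")))
  expect_equal(res$status, "reconciled")
  expect_equal(res$history$S$labels[res$history$phi[1]], "B")
})

test_that("materialization subdivides edges, chains above the root, dedups", {
  S <- fix_S()
  lbl <- function(l) isorec:::node_by_label(S, l)
  m1 <- materialize_species_tree(S, list(tp(lbl("x"), rat(1, 2))))
  expect_equal(tree_n(m1$S), 6L)
  expect_equal(m1$S$labels[m1$ids[1]], "D1")
  ## above-root chain: r-1-D1-1-D2, D2 the new top
  m2 <- materialize_species_tree(S, list(tp(lbl("r"), rat(1)),
                                         tp(lbl("r"), rat(2))))
  rf <- isorec:::rooted_form(m2$S)
  expect_equal(m2$S$labels[rf$root], "D2")
  expect_equal(m2$S$labels[rf$parent[lbl("r")]], "D1")
  expect_equal(rf$plen[[lbl("r")]], rat(1))
  ## duplicate points collapse to one node
  m3 <- materialize_species_tree(S, list(tp(lbl("B"), rat(1)),
                                         tp(lbl("B"), rat(1))))
  expect_equal(tree_n(m3$S), 6L)
  expect_equal(m3$ids[1], m3$ids[2])
})

test_that("materialization never changes leaf-to-leaf distances", {
  for (s in c(2, 7, 12)) {
    hi <- sim_inferable(s, n_species = 5)
    S <- derive_input(hi)$S
    idx <- build_index(S)
    pts <- list(tp(tree_leaves(S)[1], rat(1, 8)),
                tp(isorec:::rooted_form(S)$root, rat(3, 4)))
    m <- materialize_species_tree(S, pts)
    lv <- tree_leaves(S)
    for (i in seq_along(lv)) for (j in seq_len(i - 1L)) {
      a <- S$labels[lv[i]]; b <- S$labels[lv[j]]
      expect_equal(naive_dist(S, lv[i], lv[j]),
                   naive_dist(m$S, isorec:::node_by_label(m$S, a),
                              isorec:::node_by_label(m$S, b)))
    }
  }
})

test_that("verify_isometric rejects a root-distance-preserving non-history", {
  ## parent mapped at the right depth but to a non-ancestor of its child
  S <- parse_newick("((A:2)D1:1,(B:2,C:2)x:1)r;", rooted = TRUE)
  G <- parse_newick("((b1:2,c1:2)xg:1,a1:3)q;", rooted = TRUE)
  phi <- integer(tree_n(G))
  lbl <- function(t, l) isorec:::node_by_label(t, l)
  phi[lbl(G, "q")] <- lbl(S, "r")
  phi[lbl(G, "xg")] <- lbl(S, "D1")  # depth 1, but not above B or C
  phi[lbl(G, "a1")] <- lbl(S, "A")
  phi[lbl(G, "b1")] <- lbl(S, "B")
  phi[lbl(G, "c1")] <- lbl(S, "C")
  chk <- verify_isometric(history(G, S, phi))
  expect_false(chk$ok)
  expect_equal(sort(G$labels[chk$edge])[1], "b1")
})

test_that("perturbing one image breaks isometry on the incident edge", {
  res <- reconcile_rooted(input_history(fix_G(), fix_S(), fix_mu()))
  h <- res$history
  expect_true(verify_isometric(h)$ok)
  h2 <- h
  h2$phi[isorec:::node_by_label(h$G, "y")] <-
    isorec:::node_by_label(h$S, "r")
  chk <- verify_isometric(h2)
  expect_false(chk$ok)
})

test_that("leaf-choice policy never changes the result", {
  for (s in 1:20) {
    hi <- sim_inferable(s, n_species = 2 + (s %% 5), min_genes = 2)
    iph <- derive_input(hi)
    r1 <- reconcile_rooted(iph, leaf_choice = "min")
    r2 <- reconcile_rooted(iph, leaf_choice = "max")
    expect_equal(r1$status, r2$status)
    expect_true(history_equal(r1$history, r2$history))
  }
})

test_that("is_ultrametric is exact", {
  expect_true(is_ultrametric(fix_S()))
  expect_false(is_ultrametric(parse_newick("((B:2,C:3)x:1,A:3)r;",
                                           rooted = TRUE)))
  expect_true(is_ultrametric(parse_newick("A;", rooted = TRUE)))
})

test_that("unique-alpha scaling pins and verifies the only factor", {
  S <- parse_newick("((B:2,C:3)x:1,A:3)r;", rooted = TRUE)
  G <- parse_newick("((b1:4,c1:6)y:2,a1:6)q;", rooted = TRUE)
  res <- reconcile_scaled(input_history(G, S, fix_mu()))
  expect_equal(res$status, "reconciled")
  expect_equal(res$certificate$case, "unique-alpha")
  expect_equal(res$certificate$alpha, rat(1, 2))
  lblS <- res$history$S$labels[res$history$phi]
  names(lblS) <- res$history$G$labels
  expect_equal(unname(lblS["y"]), "x")
  expect_equal(unname(lblS["q"]), "r")
})

test_that("both-ultrametric scaling returns the threshold certificate", {
  res <- reconcile_scaled(input_history(fix_G(), fix_S(), fix_mu()))
  expect_equal(res$certificate$case, "threshold")
  expect_equal(res$certificate$alpha_star, rat(1))
  expect_equal(res$status, "reconciled")
})

test_that("mixed ultrametricity admits no scaling factor", {
  S <- parse_newick("((B:2,C:3)x:1,A:3)r;", rooted = TRUE)
  res <- reconcile_scaled(input_history(fix_G(), S, fix_mu()))
  expect_equal(res$status, "irreconcilable")
  expect_equal(res$certificate$case, "none")
})

test_that("unique-alpha instances recover the simulated factor exactly", {
  n_done <- 0L
  for (s in 1:12) {
    hi <- sim_inferable(s, n_species = 4, dup = 0.2, loss = 0.2,
                        mode = "jitter")
    iph <- derive_input(hi)
    if (is_ultrametric(iph$G)) next
    alpha0 <- rat(3, 2)
    scaled <- input_history(tree_scale(iph$G, rat(2, 3)), iph$S, iph$mu)
    res <- reconcile_scaled(scaled)
    expect_equal(res$status, "reconciled")
    expect_equal(res$certificate$alpha, alpha0)
    expect_true(history_equal(res$history, hi))
    ## wrong factors fail
    for (k in c(-3, -1, 1, 2, 5)) {
      awrong <- rat_add(alpha0, rat(k, 16))
      rw <- reconcile_rooted(input_history(tree_scale(scaled$G, awrong),
                                           iph$S, iph$mu))
      expect_equal(rw$status, "irreconcilable")
    }
    n_done <- n_done + 1L
  }
  expect_gte(n_done, 5L)
})
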