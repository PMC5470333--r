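test_that("the simulator is deterministic and event-pure", {
  p <- sim_params(n_species = 4, dup_rate = 0.4, loss_rate = 0.4, seed = 11)
  h1 <- simulate_simple_history(p)
  h2 <- simulate_simple_history(p)
  expect_identical(write_newick(h1$G), write_newick(h2$G))
  expect_identical(write_newick(h1$S), write_newick(h2$S))
  expect_identical(h1$phi, h2$phi)
  ## every species node is a single event (no "other") across seeds
  for (s in 1:15) {
    h <- simulate_simple_history(sim_params(n_species = 2 + (s %% 5),
                                            dup_rate = 0.4, loss_rate = 0.4,
                                            seed = s, min_genes = 1))
    cls <- vapply(seq_len(tree_n(h$S)), function(v)
      classify_species_node(h, v), "")
    expect_false(any(cls == "other"))
  }
})

test_that("a zero-rate simulation mirrors the species tree", {
  h <- simulate_simple_history(sim_params(n_species = 4, dup_rate = 0,
                                          loss_rate = 0, seed = 5,
                                          min_genes = 1))
  expect_equal(tree_n(h$G), tree_n(h$S))
  ## gene tree isomorphic to species tree with matching lengths
  Gr <- h$G; Gr$labels <- h$S$labels[h$phi]
  expect_true(tree_equal(Gr, h$S))
})

test_that("the loss guard keeps a minimum number of extant genes", {
  h <- simulate_simple_history(sim_params(n_species = 3, dup_rate = 0.1,
                                          loss_rate = 1.5, seed = 9,
                                          min_genes = 1))
  expect_gte(length(isorec:::.extant_leaves(h)), 1L)
})

test_that("extended inverse finds exactly the bypassing edge points", {
  h <- bypass_history()
  x <- isorec:::node_by_label(h$S, "x")
  ext <- extended_inverse(h, x)
  expect_length(ext, 2L)
  labs <- sort(h$G$labels[vapply(ext, function(p) p$node, 0L)])
  expect_equal(labs, c("c1", "c2"))
  for (p in ext) expect_equal(p$h, rat(2))
  ## no spanning edges at the root: extended inverse equals the preimage
  r <- isorec:::node_by_label(h$S, "r")
  extr <- extended_inverse(h, r)
  expect_length(extr, 1L)
  expect_equal(extr[[1]]$h, rat(0))
})

test_that("classification distinguishes the event types", {
  h <- bypass_history()
  lbl <- function(l) isorec:::node_by_label(h$S, l)
  expect_equal(classify_species_node(h, lbl("A")), "sample")
  expect_equal(classify_species_node(h, lbl("e")), "duplication")
  expect_equal(classify_species_node(h, lbl("r")), "speciation")
  ## bypassed two-child node: generalized but not strict
  expect_equal(classify_species_node(h, lbl("x")), "generalized_speciation")
})

test_that("inferable_version prunes losses and is the identity otherwise", {
  for (s in 1:10) {
    h <- simulate_simple_history(sim_params(n_species = 4, dup_rate = 0.4,
                                            loss_rate = 0.4, seed = s,
                                            min_genes = 2))
    hi <- inferable_version(h)
    expect_true(is_inferable(hi))
    expect_true(admits_positive_simple(hi))
  }
  ## no losses, binary events: nothing changes
  h0 <- simulate_simple_history(sim_params(n_species = 4, dup_rate = 0.3,
                                           loss_rate = 0, seed = 3,
                                           min_genes = 1))
  hi0 <- inferable_version(h0)
  expect_true(history_equal(h0, hi0))
})

test_that("a pre-speciation duplication leaves a one-child node atop S", {
  ## find a simulated history with an event on the stem branch
  found <- FALSE
  for (s in 1:60) {
    h <- simulate_simple_history(sim_params(n_species = 3, dup_rate = 0.8,
                                            loss_rate = 0.1, seed = s,
                                            min_genes = 2))
    hi <- inferable_version(h)
    rfs <- isorec:::rooted_form(hi$S)
    if (length(rfs$children[[rfs$root]]) == 1L) {
      expect_true(any(hi$phi == rfs$root))  # the duplication maps there
      expect_equal(classify_species_node(hi, rfs$root), "duplication")
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("loss leaves and zero-length edges disqualify inferability", {
  h <- simulate_simple_history(sim_params(n_species = 3, dup_rate = 0.5,
                                          loss_rate = 0.8, seed = 2,
                                          min_genes = 1))
  ## the raw simple history contains loss leaves -> not inferable
  if (length(isorec:::.extant_leaves(h)) < tree_n(h$G) - 1)
    expect_false(is_inferable(h))
  hi <- inferable_version(h)
  expect_true(is_inferable(hi))
})

test_that("expand_to_simple round-trips through inferable_version", {
  for (s in 1:30) {
    hi <- sim_inferable(s, n_species = 2 + (s %% 5), dup = 0.35, loss = 0.35,
                        min_genes = 2)
    hs <- expand_to_simple(hi)
    cls <- vapply(seq_len(tree_n(hs$S)), function(v)
      classify_species_node(hs, v), "")
    expect_true(all(cls %in% c("sample", "speciation", "duplication", "loss")))
    expect_true(history_equal(inferable_version(hs), hi))
  }
})

test_that("expansion of a bypassed speciation adds losses and chains", {
  hi <- bypass_history()
  expect_true(is_inferable(hi))
  expect_true(admits_positive_simple(hi))
  hs <- expand_to_simple(hi)
  cls <- vapply(seq_len(tree_n(hs$S)), function(v)
    classify_species_node(hs, v), "")
  expect_true(all(cls %in% c("sample", "speciation", "duplication", "loss")))
  expect_true(any(cls == "loss"))   # the bypass forces loss leaves
  expect_true(history_equal(inferable_version(hs), hi))
})

test_that("positive-simple expandability matches the classifier", {
  ## coincident duplication+speciation: classifier says no, and indeed the
  ## history is not the inferable version of a positive simple history
  G2 <- itree(c("g1", "g2"), matrix(c(1L, 2L), ncol = 2), list(rat(4)),
              rooted = FALSE)
  res <- reconcile_unrooted_gene(input_history(G2, fix_S(),
                                               leafmap(g1 = "B", g2 = "B")))
  expect_false(admits_positive_simple(res$history))
  ## simulated inferable histories always qualify
  for (s in 1:10)
    expect_true(admits_positive_simple(sim_inferable(s, min_genes = 2)))
})

test_that("derive_input inverts the reconciliation-output transformations", {
  for (s in 1:10) {
    hi <- sim_inferable(s, n_species = 4, min_genes = 2)
    iph <- derive_input(hi)
    expect_length(validate_input(iph), 0L)
    ## no-duplication history: species input equals the history's tree
    h0 <- inferable_version(simulate_simple_history(
      sim_params(n_species = 4, dup_rate = 0, loss_rate = 0, seed = s,
                 min_genes = 1)))
    iph0 <- derive_input(h0)
    expect_true(tree_equal(iph0$S, h0$S))
  }
  ## unrooting keeps a multifurcating root as an ordinary node
  hi <- sim_inferable(4, n_species = 4, min_genes = 3)
  iphu <- derive_input(hi, unroot_gene = TRUE)
  rfg <- isorec:::rooted_form(hi$G)
  nkids <- length(rfg$children[[rfg$root]])
  expect_equal(tree_n(iphu$G),
               tree_n(derive_input(hi)$G) - (nkids == 2))
})
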