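## species fixture for parametric tests: x_a and x_b joined by an edge of
## length 5, two leaves hanging off each end
param_fixture <- function() {
  ## l1 -1- xa -5- xb -2- m1 ; xa -2- l2 ; xb -3- m2
  itree(c("l1", "l2", NA, NA, "m1", "m2"),
        matrix(c(3L, 1L, 3L, 2L, 3L, 4L, 4L, 5L, 4L, 6L), ncol = 2,
               byrow = TRUE),
        list(rat(1), rat(2), rat(5), rat(2), rat(3)),
        rooted = FALSE)
}

test_that("param_anc distinguishes fixed, parametric and split cases", {
  S <- param_fixture()
  ctx <- isorec:::.make_edge_ctx(S, 3L)   # the xa-xb edge, length 5
  expect_equal(ctx$L, rat(5))
  l1 <- isorec:::node_by_label(S, "l1")   # at distance 1 from xa
  ## query distance 4 over the whole edge: the answer crosses the root at
  ## rho = 3, so the interval splits there
  sp <- tryCatch(param_anc(ctx, l1, rat(4), rat(0), rat(5)),
                 interval_split = function(e) e$rho)
  expect_equal(sp, rat(3))
  ## on (0,3) the answer is above every root: parametric pt(r, 3 - rho)
  pp <- param_anc(ctx, l1, rat(4), rat(0), rat(3))
  expect_equal(pp$k, "p")
  expect_equal(pp$lf$d, rat(3))
  expect_equal(pp$lf$c, rat(-1))
  ## on (3,5) it is a fixed point of the host edge, 3 from xa
  pf <- param_anc(ctx, l1, rat(4), rat(3), rat(5))
  expect_equal(pf$k, "f")
  expect_equal(pf$side, 1L)
  expect_equal(pf$pt$h, rat(3))
  ## instantiate rho = 1 on the parametric branch: exact anc agrees
  Sx <- root_species_at(S, ei = 3L, rho = rat(1))
  idx <- build_index(Sx)
  got <- idx_anc(idx, tp(isorec:::node_by_label(Sx, "l1")), rat(4))
  expect_true(tp_eq(got, tp(isorec:::rooted_form(Sx)$root, rat(2))))
})

test_that("mirrored queries from the far side use slope +1", {
  S <- param_fixture()
  ctx <- isorec:::.make_edge_ctx(S, 3L)
  m1 <- isorec:::node_by_label(S, "m1")   # distance 2 from xb
  ## d = 4: t' = 2; fixed iff rho <= 3, parametric on (3,5)
  pp <- param_anc(ctx, m1, rat(4), rat(3), rat(5))
  expect_equal(pp$k, "p")
  expect_equal(pp$lf$d, rat(-3))   # t' - L = 2 - 5
  expect_equal(pp$lf$c, rat(1))
  sp <- tryCatch(param_anc(ctx, m1, rat(4), rat(0), rat(5)),
                 interval_split = function(e) e$rho)
  expect_equal(sp, rat(3))
})

test_that("breakpoints solve linear crossings inside the interval only", {
  expect_equal(solve_breakpoint(rat(3), rat(-1), rat(1), rat(1),
                                rat(0), rat(5)), rat(1))
  expect_null(solve_breakpoint(rat(3), rat(-1), rat(1), rat(1),
                               rat(2), rat(5)))
  ## touching at the boundary is not a split
  expect_null(solve_breakpoint(rat(2), rat(-1), rat(2), rat(1),
                               rat(0), rat(5)))
})

test_that("sampling inside accepted intervals reproduces fixed-root runs", {
  for (s in c(3, 7, 13, 21)) {
    hi <- sim_inferable(s, n_species = 4, min_genes = 3, max_genes = 10)
    if (tree_n(hi$S) < 2) next
    iph <- derive_input(hi, unroot_gene = TRUE, unroot_species = TRUE)
    for (ei in seq_len(nrow(iph$S$edge))) {
      sim <- simulate_interval(iph, ei)
      for (pc in sim$pieces) {
        if (!is.null(pc$reject)) next
        width <- rat_sub(pc$hi, pc$lo)
        for (num in c(1, 2, 3)) {
          rho <- rat_add(pc$lo, rat_mul(width, rat(num, 4)))
          h <- evaluate_at(pc$ph, rho)
          expect_true(verify_isometric(h)$ok)
          Sx <- root_species_at(iph$S, ei = ei, rho = rho)
          ref <- reconcile_unrooted_gene(input_history(iph$G, Sx, iph$mu))
          expect_equal(ref$status, "reconciled")
          expect_true(history_equal(h, ref$history))
        }
      }
    }
  }
})

test_that("instantiations at two offsets differ only in branch lengths", {
  hi <- sim_inferable(3, n_species = 4, min_genes = 3)
  iph <- derive_input(hi, unroot_gene = TRUE, unroot_species = TRUE)
  done <- FALSE
  for (ei in seq_len(nrow(iph$S$edge))) {
    sim <- simulate_interval(iph, ei)
    for (pc in sim$pieces) {
      if (!is.null(pc$reject)) next
      w <- rat_sub(pc$hi, pc$lo)
      h1 <- evaluate_at(pc$ph, rat_add(pc$lo, rat_mul(w, rat(1, 3))))
      h2 <- evaluate_at(pc$ph, rat_add(pc$lo, rat_mul(w, rat(2, 3))))
      ## same shapes when lengths are hidden
      strip <- function(t) { t$elen <- lapply(t$elen, function(x) rat(1)); t }
      expect_true(tree_equal(strip(h1$G), strip(h2$G)))
      expect_true(tree_equal(strip(h1$S), strip(h2$S)))
      done <- TRUE
    }
    if (done) break
  }
  expect_true(done)
  ## boundary instantiation is a contract error
  pc <- NULL
  for (e in simulate_interval(iph, 1L)$pieces)
    if (is.null(e$reject)) pc <- e
  if (!is.null(pc))
    expect_error(evaluate_at(pc$ph, pc$lo), "outside|strictly")
})

test_that("the solution set matches fixed-root runs at probes and nodes", {
  for (s in c(2, 9, 17, 23, 31)) {
    hi <- sim_inferable(s, n_species = 3 + (s %% 3), min_genes = 3,
                        max_genes = 12)
    if (tree_n(hi$S) < 2) next
    iph <- derive_input(hi, unroot_gene = TRUE, unroot_species = TRUE)
    ss <- reconcile_both_unrooted(iph)
    for (ei in seq_along(ss$edges)) {
      e <- ss$edges[[ei]]
      probes <- lapply(e$boundaries, function(b) b$rho)
      for (pc in e$pieces)
        probes[[length(probes) + 1L]] <- rat_half(rat_add(pc$lo, pc$hi))
      for (rho in probes) {
        if (rat_sign(rho) <= 0 || rat_cmp(rho, e$L) >= 0) next
        Sx <- root_species_at(iph$S, ei = ei, rho = rho)
        ref <- reconcile_unrooted_gene(input_history(iph$G, Sx, iph$mu))
        expect_equal(ref$status == "reconciled",
                     solution_accepts(ss, edge = ei, rho = rho))
      }
    }
    for (nd in ss$nodes) {
      Sx <- root_species_at(iph$S, node = nd$node)
      ref <- reconcile_unrooted_gene(input_history(iph$G, Sx, iph$mu))
      expect_equal(ref$status, nd$result$status)
    }
  }
})

test_that("two-leaf trees admit a continuum of root positions", {
  S2 <- itree(c("a", "b"), matrix(c(1L, 2L), ncol = 2), list(rat(4)),
              rooted = FALSE)
  G2 <- itree(c("a1", "b1"), matrix(c(1L, 2L), ncol = 2), list(rat(4)),
              rooted = FALSE)
  ss <- reconcile_both_unrooted(input_history(G2, S2, leafmap(a1 = "a",
                                                              b1 = "b")))
  acc <- Filter(function(p) is.null(p$reject), ss$edges[[1]]$pieces)
  expect_gte(length(acc), 1L)
  ## total accepted length is positive
  tot <- rat(0)
  for (p in acc) tot <- rat_add(tot, rat_sub(p$hi, p$lo))
  expect_gt(rat_sign(tot), 0)
})

test_that("duplication-only families accept rootings verified by the oracle", {
  S3 <- itree(c("a", "b"), matrix(c(1L, 2L), ncol = 2), list(rat(6)),
              rooted = FALSE)
  G3 <- itree(c("a1", "a2"), matrix(c(1L, 2L), ncol = 2), list(rat(2)),
              rooted = FALSE)
  iph <- input_history(G3, S3, leafmap(a1 = "a", a2 = "a"))
  ss <- reconcile_both_unrooted(iph)
  e <- ss$edges[[1]]
  for (pc in e$pieces) {
    mid <- rat_half(rat_add(pc$lo, pc$hi))
    Sx <- root_species_at(S3, ei = 1L, rho = mid)
    ref <- reconcile_unrooted_gene(input_history(G3, Sx, iph$mu))
    expect_equal(ref$status == "reconciled", is.null(pc$reject))
  }
})

test_that("adjacent agreeing solutions merge into maximal root sets", {
  S3 <- itree(c("a", "b"), matrix(c(1L, 2L), ncol = 2), list(rat(6)),
              rooted = FALSE)
  G3 <- itree(c("a1", "a2"), matrix(c(1L, 2L), ncol = 2), list(rat(2)),
              rooted = FALSE)
  ss <- reconcile_both_unrooted(input_history(G3, S3,
                                              leafmap(a1 = "a", a2 = "a")))
  merged <- ss$edges[[1]]$merged
  expect_length(merged, 1L)
  expect_equal(merged[[1]]$lo, rat(0))
  expect_equal(merged[[1]]$hi, rat(6))
  expect_false(merged[[1]]$lo_closed)  # endpoints are leaves
  expect_false(merged[[1]]$hi_closed)
})

test_that("the simulated root position always lies in the solution set", {
  for (s in 1:15) {
    hi <- sim_inferable(s, n_species = 3 + (s %% 3), min_genes = 3,
                        max_genes = 12)
    if (tree_n(hi$S) < 3) next
    iph <- derive_input(hi, unroot_gene = TRUE, unroot_species = TRUE)
    tr <- find_true_root(hi, iph)
    ss <- reconcile_both_unrooted(iph)
    if (tr$type == "node") {
      found <- FALSE
      for (nd in ss$nodes)
        if (nd$result$status == "reconciled" &&
            history_equal(nd$result$history, hi)) found <- TRUE
      expect_true(found)
    } else {
      expect_true(solution_accepts(ss, edge = tr$ei, rho = tr$rho))
      e <- ss$edges[[tr$ei]]
      hrec <- NULL
      for (b in e$boundaries)
        if (rat_eq(b$rho, tr$rho)) hrec <- b$result$history
      if (is.null(hrec)) for (pc in e$pieces) {
        if (is.null(pc$reject) && isorec:::rat_lt(pc$lo, tr$rho) &&
            isorec:::rat_lt(tr$rho, pc$hi))
          hrec <- evaluate_at(pc$ph, tr$rho)
      }
      expect_true(!is.null(hrec) && history_equal(hrec, hi))
    }
  }
})
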