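## Reconciliation when both trees are unrooted: every internal species node
## and every point inside a species edge is a potential root. Internal
## nodes and interval boundaries are checked by exact fixed-root runs; for
## the open intervals the per-edge algorithm is simulated parametrically,
## splitting candidate intervals at every root offset where an intermediate
## decision changes, until each interval is unequivocal and carries a
## single parametric reconciliation (or a rejection).

## piecewise application: f(piece) returns the updated piece, or raises an
## interval_split / interval_reject condition; splits are resolved by
## re-running f on both halves
.apply_piecewise <- function(pieces, f) {
  out <- list(); eps <- list()
  stack <- pieces
  while (length(stack) > 0) {
    p <- stack[[1]]; stack <- stack[-1]
    if (!is.null(p$reject)) { out[[length(out) + 1L]] <- p; next }
    r <- tryCatch(f(p),
                  interval_split = function(e) e,
                  interval_reject = function(e) e)
    if (inherits(r, "interval_split")) {
      eps[[length(eps) + 1L]] <- r$rho
      p1 <- p; p1$hi <- r$rho
      p2 <- p; p2$lo <- r$rho
      stack <- c(list(p1, p2), stack)
    } else if (inherits(r, "interval_reject")) {
      p$reject <- r$reason
      out[[length(out) + 1L]] <- p
    } else out[[length(out) + 1L]] <- r
  }
  list(pieces = out, endpoints = eps)
}

## preparation shared by all species edges of one input
.gene_prep <- function(G, S, mu) {
  nG <- tree_n(G)
  pairs <- .leaf_pairs(G)
  adj <- tree_adj(G)
  deg <- tree_degree(G)
  leaf_sid <- integer(nG)
  for (l in tree_leaves(G))
    leaf_sid[l] <- node_by_label(S, mu[[G$labels[l]]])
  pairinfo <- vector("list", nG)
  for (x in seq_len(nG)) {
    if (deg[x] <= 1L) next
    dl <- tree_dist_all(G, x, adj)
    l1 <- node_by_label(G, pairs[[x]][1]); l2 <- node_by_label(G, pairs[[x]][2])
    pairinfo[[x]] <- list(l1 = leaf_sid[l1], d1 = dl[[l1]],
                          l2 = leaf_sid[l2], d2 = dl[[l2]])
  }
  list(G = G, nG = nG, deg = deg, leaf_sid = leaf_sid, pairinfo = pairinfo)
}

.inst_slope <- function(inst, c) {
  if (!is.null(inst)) inst$slopes[[paste0(c[1], "/", c[2])]] <- c
  invisible(NULL)
}
.inst_max <- function(inst, field, val) {
  if (!is.null(inst) && val > inst[[field]]) inst[[field]] <- val
  invisible(NULL)
}

## Step A: map gene node x on every piece (triangulation from its fixed
## leaf pair); returns pieces + endpoint count, instrumenting per-node
## splits
.mapA_node <- function(ctx, gp, x, field, pieces, inst) {
  if (gp$deg[x] <= 1L) {
    sid <- gp$leaf_sid[x]
    side <- ctx$side_of[sid]
    s <- if (side == 1L) ctx$A else ctx$B
    ppt <- pp_fixed(side, tp(s$g2l[sid]))
    for (i in seq_along(pieces))
      if (is.null(pieces[[i]]$reject)) pieces[[i]][[field]] <- ppt
    return(list(pieces = pieces, nsplit = 0L))
  }
  pi <- gp$pairinfo[[x]]
  r1 <- .apply_piecewise(pieces, function(p) {
    p$.t1 <- param_anc(ctx, pi$l1, pi$d1, p$lo, p$hi); p
  })
  r2 <- .apply_piecewise(r1$pieces, function(p) {
    p$.t2 <- param_anc(ctx, pi$l2, pi$d2, p$lo, p$hi); p
  })
  r3 <- .apply_piecewise(r2$pieces, function(p) {
    xu <- p$.t1; xv <- p$.t2
    if (pp_is_anc(ctx, xu, xv, p$lo, p$hi)) p[[field]] <- xv
    else if (pp_is_anc(ctx, xv, xu, p$lo, p$hi)) p[[field]] <- xu
    else .reject("triangulation undefined")
    p$.t1 <- NULL; p$.t2 <- NULL
    p
  })
  n <- length(r1$endpoints) + length(r2$endpoints) + length(r3$endpoints)
  .inst_max(inst, "t1", n)
  list(pieces = r3$pieces, nsplit = n)
}

## lf equality check over a piece: TRUE, FALSE, or split
.lf_equal <- function(a, b, lo, hi) {
  d <- lf_sub(a, b)
  if (rat_sign(d$c) == 0L) return(rat_sign(d$d) == 0L)
  s <- lf_sign(d, lo, hi)   # splits at an interior crossing
  s == 0L
}

## Steps A-C for one gene edge over the whole candidate interval (lo, hi);
## returns the edge's partition with per-piece state
.edge_ABC <- function(ctx, gp, ei, lo, hi, inst) {
  G <- gp$G
  u <- G$edge[ei, 1]; v <- G$edge[ei, 2]
  len <- G$elen[[ei]]
  pieces <- list(list(lo = lo, hi = hi))
  ru <- .mapA_node(ctx, gp, u, "ppu", pieces, inst)
  rv <- .mapA_node(ctx, gp, v, "ppv", ru$pieces, inst)
  .inst_max(inst, "t2", ru$nsplit + rv$nsplit)
  .inst_max(inst, "t3", length(rv$pieces))
  ## Step B: potential root on this edge
  rb <- .apply_piecewise(rv$pieces, function(p) {
    lam <- pp_lca(ctx, p$ppu, p$ppv, p$lo, p$hi)
    d1 <- pp_dist(ctx, lam, p$ppu)
    d2 <- pp_dist(ctx, lam, p$ppv)
    eps <- lf_half(lf_sub(lf_const(len), lf_add(d1, d2)))
    .inst_slope(inst, eps$c)
    in_set <- pp_eq(lam, p$ppu) || pp_eq(lam, p$ppv)
    s <- lf_sign(eps, p$lo, p$hi)
    if (s > 0L || !in_set) {
      if (s < 0L) .reject("no isometric root placement on a gene edge")
      qpp <- if (lam$k == "p") pp_param(lf_add(lam$lf, eps))
      else {
        if (rat_sign(eps$c) != 0L) stop("internal: parametric eps at a fixed lca")
        pp_anc(ctx, lam, eps$d, p$lo, p$hi)
      }
      p$cand <- list(offset = lf_add(d1, eps), q = qpp)
    } else p$cand <- NULL
    p
  })
  ## Step C: distance checks
  rc <- .apply_piecewise(rb$pieces, function(p) {
    if (!is.null(p$cand)) {
      okA <- pp_is_anc(ctx, p$cand$q, p$ppu, p$lo, p$hi) &&
        .lf_equal(pp_dist(ctx, p$cand$q, p$ppu), p$cand$offset, p$lo, p$hi)
      okB <- pp_is_anc(ctx, p$cand$q, p$ppv, p$lo, p$hi) &&
        .lf_equal(pp_dist(ctx, p$cand$q, p$ppv),
                  lf_sub(lf_const(len), p$cand$offset), p$lo, p$hi)
      if (!okA || !okB) .reject("edge length check failed at the root candidate")
    } else {
      ok <- if (pp_is_anc(ctx, p$ppu, p$ppv, p$lo, p$hi))
        .lf_equal(pp_dist(ctx, p$ppu, p$ppv), lf_const(len), p$lo, p$hi)
      else if (pp_is_anc(ctx, p$ppv, p$ppu, p$lo, p$hi))
        .lf_equal(pp_dist(ctx, p$ppv, p$ppu), lf_const(len), p$lo, p$hi)
      else FALSE
      if (!ok) .reject("edge fails the distance check")
    }
    p
  })
  list(pieces = rc$pieces,
       endpoints = c(unlist(lapply(list(rb, rc), function(r) r$endpoints),
                            recursive = FALSE)))
}

## find the piece of a partition covering the open interval (lo, hi)
.covering_piece <- function(pieces, lo, hi) {
  mid <- rat_half(rat_add(lo, hi))
  for (p in pieces)
    if (rat_cmp(p$lo, mid) < 0 && rat_cmp(mid, p$hi) < 0) return(p)
  stop("internal: no covering piece")
}

## Stage 5 + 6 on one refined piece: choose the root, orient the gene tree,
## verify isometry parametrically
.stage56 <- function(ctx, gp, p) {
  G <- gp$G; nG <- gp$nG
  images <- p$images
  if (!is.null(p$cand)) {
    rootspec <- list(type = "edge", ei = p$cand_ei, cand = p$cand)
  } else {
    params <- which(vapply(images, function(x) x$k == "p", TRUE))
    if (length(params) > 0) {
      top <- images[[params[1]]]
      for (i in params[-1])
        if (lf_cmp(images[[i]]$lf, top$lf, p$lo, p$hi) > 0L) top <- images[[i]]
    } else {
      sides <- vapply(images, function(x) x$side, 0L)
      if (length(unique(sides)) > 1)
        .reject("images on both sides of the host edge with no root candidate")
      sideidx <- if (sides[1] == 1L) ctx$A$idx else ctx$B$idx
      top <- images[[1]]
      for (i in seq_len(nG))
        if (idx_is_anc(sideidx, images[[i]]$pt, top$pt)) top <- images[[i]]
      for (i in seq_len(nG))
        if (!idx_is_anc(sideidx, top$pt, images[[i]]$pt))
          .reject("no single topmost image exists")
    }
    pre <- which(vapply(seq_len(nG), function(i)
      gp$deg[i] >= 3L && pp_eq(images[[i]], top), TRUE))
    if (length(pre) == 0)
      .reject("root position is not an internal gene node and no edge hosts it")
    rootspec <- list(type = "node", node = pre[1])
  }
  ## orient the gene tree and verify every edge
  check_edge <- function(pp_par, pp_chi, len_lf) {
    if (!pp_is_anc(ctx, pp_par, pp_chi, p$lo, p$hi))
      .reject("isometry violated (ancestry)")
    if (!.lf_equal(pp_dist(ctx, pp_par, pp_chi), len_lf, p$lo, p$hi))
      .reject("isometry violated (distance)")
  }
  if (rootspec$type == "node") {
    rf <- rooted_form(G, root = rootspec$node)
    for (x in seq_len(nG)) {
      if (x == rootspec$node) next
      check_edge(images[[rf$parent[x]]], images[[x]], lf_const(rf$plen[[x]]))
    }
  } else {
    ei <- rootspec$ei
    a <- G$edge[ei, 1]; b <- G$edge[ei, 2]
    len <- G$elen[[ei]]
    q <- rootspec$cand$q
    check_edge(q, images[[a]], rootspec$cand$offset)
    check_edge(q, images[[b]], lf_sub(lf_const(len), rootspec$cand$offset))
    orient <- function(start) {
      ## parents pointing away from the root edge
      adj <- tree_adj(G)
      seen <- logical(nG); seen[c(a, b)] <- TRUE
      queue <- start; qi <- 1L
      while (qi <= length(queue)) {
        x <- queue[qi]; qi <- qi + 1L
        for (j in seq_along(adj$nb[[x]])) {
          if (adj$ei[[x]][j] == ei) next
          w <- adj$nb[[x]][j]
          if (!seen[w]) {
            seen[w] <- TRUE
            check_edge(images[[x]], images[[w]],
                       lf_const(G$elen[[adj$ei[[x]][j]]]))
            queue <- c(queue, w)
          }
        }
      }
    }
    orient(a); orient(b)
  }
  p$root <- rootspec
  p
}

#' Parametric simulation of the per-edge algorithm over one species edge
#'
#' Treats every point of species edge \code{edge} as a potential root
#' position: partitions the open interval (0, L) (or a sub-interval) into
#' unequivocal intervals, on each of which the per-edge reconciliation
#' algorithm makes uniform decisions, and returns for each a parametric
#' reconciliation or a rejection. Interval endpoints discovered on the way
#' are root positions where decisions change; they are returned so they can
#' be checked by exact fixed-root runs.
#'
#' @param iph input partial history, both trees unrooted.
#' @param edge index of the species edge hosting the root.
#' @param lo,hi optional rational sub-interval bounds (defaults: the edge).
#' @param instrument optional environment collecting split-count maxima
#'   (\code{t1}, \code{t2}, \code{t3}) and epsilon slopes
#'   (\code{slopes}).
#' @return list with \code{pieces} (each \code{lo}, \code{hi}, and either a
#'   \code{ph} parametric history or a \code{reject} reason) and
#'   \code{endpoints} (rationals strictly inside the edge).
#' @export
simulate_interval <- function(iph, edge, lo = NULL, hi = NULL,
                              instrument = NULL) {
  ctx <- .make_edge_ctx(iph$S, edge)
  gp <- .gene_prep(iph$G, iph$S, iph$mu)
  if (is.null(lo)) lo <- RAT0
  if (is.null(hi)) hi <- ctx$L
  .simulate_edge(ctx, gp, lo, hi, instrument)
}

.simulate_edge <- function(ctx, gp, lo, hi, inst) {
  G <- gp$G
  nE <- nrow(G$edge)
  if (gp$nG == 1) {
    ## a single gene maps to its species leaf; every rooting works
    ph <- list(ctx = ctx, gp = gp, lo = lo, hi = hi,
               root = list(type = "node", node = 1L),
               images = list(local_leaf_pp(ctx, gp, 1L)))
    class(ph) <- "param_history"
    return(list(pieces = list(list(lo = lo, hi = hi, ph = ph)),
                endpoints = list()))
  }
  edge_parts <- vector("list", nE)
  endpoints <- list()
  for (ei in seq_len(nE)) {
    r <- .edge_ABC(ctx, gp, ei, lo, hi, inst)
    edge_parts[[ei]] <- r$pieces
    for (p in r$pieces) {
      if (rat_cmp(p$lo, lo) > 0) endpoints[[length(endpoints) + 1L]] <- p$lo
    }
    for (e in r$endpoints) endpoints[[length(endpoints) + 1L]] <- e
  }
  ## common refinement over the pooled endpoints
  eplist <- list()
  if (length(endpoints) > 0) {
    seen <- character(0)
    for (e in endpoints) {
      key <- paste0(e[1], "/", e[2])
      if (!(key %in% seen)) { seen <- c(seen, key); eplist[[length(eplist) + 1L]] <- e }
    }
    o <- order(vapply(eplist, rat_to_double, 0))
    eplist <- eplist[o]
  }
  bounds <- c(list(lo), eplist, list(hi))
  pieces <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    plo <- bounds[[i]]; phi_ <- bounds[[i + 1L]]
    piece <- list(lo = plo, hi = phi_)
    images <- vector("list", gp$nG)
    cand <- NULL; cand_ei <- NA_integer_
    for (ei in seq_len(nE)) {
      ep <- .covering_piece(edge_parts[[ei]], plo, phi_)
      if (!is.null(ep$reject)) { piece$reject <- ep$reject; break }
      a <- G$edge[ei, 1]; b <- G$edge[ei, 2]
      if (is.null(images[[a]])) images[[a]] <- ep$ppu
      if (is.null(images[[b]])) images[[b]] <- ep$ppv
      if (!is.null(ep$cand)) {
        if (!is.null(cand)) {
          piece$reject <- "more than one gene edge hosts a potential root"
          break
        }
        cand <- ep$cand; cand_ei <- ei
      }
    }
    if (is.null(piece$reject)) {
      piece$images <- images
      piece$cand <- cand
      piece$cand_ei <- cand_ei
    }
    pieces[[length(pieces) + 1L]] <- piece
  }
  r56 <- .apply_piecewise(pieces, function(p) .stage56(ctx, gp, p))
  for (e in r56$endpoints) eplist[[length(eplist) + 1L]] <- e
  out <- list()
  for (p in r56$pieces) {
    if (is.null(p$reject)) {
      ph <- list(ctx = ctx, gp = gp, lo = p$lo, hi = p$hi,
                 root = p$root, images = p$images, cand = p$cand)
      class(ph) <- "param_history"
      out[[length(out) + 1L]] <- list(lo = p$lo, hi = p$hi, ph = ph)
    } else out[[length(out) + 1L]] <- list(lo = p$lo, hi = p$hi,
                                           reject = p$reject)
  }
  if (length(eplist) > 1) {
    o <- order(vapply(eplist, rat_to_double, 0))
    eplist <- eplist[o]
    keep <- list(eplist[[1]])
    for (e in eplist[-1])
      if (!rat_eq(e, keep[[length(keep)]])) keep[[length(keep) + 1L]] <- e
    eplist <- keep
  }
  list(pieces = out, endpoints = eplist)
}

local_leaf_pp <- function(ctx, gp, leaf) {
  sid <- gp$leaf_sid[leaf]
  side <- ctx$side_of[sid]
  s <- if (side == 1L) ctx$A else ctx$B
  pp_fixed(side, tp(s$g2l[sid]))
}
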