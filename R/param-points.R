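## Parametric machinery for reconciliation with an unrooted species tree.
##
## When the species root is an unknown point at distance rho from x_a
## inside edge (x_a, x_b), positions above the root are linear forms
## d + c*rho. Within a candidate interval (lo, hi) of root positions, every
## point arising in the per-edge algorithm is either "fixed" (a point of a
## side subtree, or on the host edge at a height that stays below the root
## throughout the interval) or "parametric" pt(r, d + c*rho). Comparisons
## whose outcome changes inside the interval raise a split condition
## carrying the breakpoint; the driver subdivides there and re-runs.

## ---- linear forms d + c*rho (exact rational coefficients) ----
lf <- function(d, c = RAT0) list(d = d, c = c)
lf_const <- function(x) list(d = x, c = RAT0)
lf_add <- function(a, b) list(d = rat_add(a$d, b$d), c = rat_add(a$c, b$c))
lf_sub <- function(a, b) list(d = rat_sub(a$d, b$d), c = rat_sub(a$c, b$c))
lf_neg <- function(a) list(d = rat_neg(a$d), c = rat_neg(a$c))
lf_half <- function(a) list(d = rat_half(a$d), c = rat_half(a$c))
lf_eval <- function(a, rho) rat_add(a$d, rat_mul(a$c, rho))
lf_identical <- function(a, b) rat_eq(a$d, b$d) && rat_eq(a$c, b$c)

## split/reject conditions
.split <- function(rho) {
  stop(structure(class = c("interval_split", "error", "condition"),
                 list(message = "interval split", call = NULL, rho = rho)))
}
.reject <- function(reason) {
  stop(structure(class = c("interval_reject", "error", "condition"),
                 list(message = reason, call = NULL, reason = reason)))
}

#' Solve a parametric breakpoint
#'
#' The root position where two linear forms d1 + c1 rho and d2 + c2 rho
#' coincide, if it lies strictly inside the open interval.
#' @param d1,c1,d2,c2 rationals with \code{c1 != c2}.
#' @param lo,hi rational interval bounds.
#' @return the breakpoint rational, or NULL when the crossing is outside.
#' @export
solve_breakpoint <- function(d1, c1, d2, c2, lo, hi) {
  if (rat_eq(c1, c2)) stop("solve_breakpoint needs distinct slopes")
  rho <- rat_div(rat_sub(d1, d2), rat_sub(c2, c1))
  if (rat_cmp(rho, lo) > 0 && rat_cmp(rho, hi) < 0) rho else NULL
}

## sign of a linear form over the open interval (lo, hi); raises a split
## when the sign changes inside
lf_sign <- function(a, lo, hi) {
  if (rat_sign(a$c) == 0) return(rat_sign(a$d))
  rho0 <- rat_div(rat_neg(a$d), a$c)
  if (rat_cmp(rho0, lo) > 0 && rat_cmp(rho0, hi) < 0) .split(rho0)
  mid <- rat_half(rat_add(lo, hi))
  rat_sign(lf_eval(a, mid))
}

## compare two linear forms over (lo, hi): -1, 0 (identical), 1
lf_cmp <- function(a, b, lo, hi) {
  d <- lf_sub(a, b)
  if (rat_sign(d$c) == 0 && rat_sign(d$d) == 0) return(0L)
  s <- lf_sign(d, lo, hi)
  if (s == 0L) .split(rat_div(rat_neg(d$d), d$c))  # touches at one point
  s
}

## ---- parametric points ----
## fixed: list(k="f", side=1|2, pt=<tree point in the side index>)
## param: list(k="p", lf=<height above the root r>)
pp_fixed <- function(side, pt) list(k = "f", side = side, pt = pt)
pp_param <- function(l) list(k = "p", lf = l)

pp_eq <- function(p, q) {
  if (p$k != q$k) return(FALSE)
  if (p$k == "p") return(lf_identical(p$lf, q$lf))
  p$side == q$side && tp_eq(p$pt, q$pt)
}

## depth below the root r as a linear form (negative above the root)
pp_depth <- function(ctx, p) {
  if (p$k == "p") return(lf_neg(p$lf))
  side <- if (p$side == 1L) ctx$A else ctx$B
  g <- tp_depth(side$idx, p$pt)   # depth from x_a / x_b (negative on edge)
  if (p$side == 1L) lf(g, RAT1)               # rho + g
  else lf(rat_add(ctx$L, g), rat(-1))         # (L - rho) + g
}

## ancestor test over (lo, hi); may split
pp_is_anc <- function(ctx, p, q, lo, hi) {
  if (p$k == "f" && q$k == "f") {
    if (p$side != q$side) return(FALSE)
    side <- if (p$side == 1L) ctx$A else ctx$B
    return(idx_is_anc(side$idx, p$pt, q$pt))
  }
  if (p$k == "p" && q$k == "f") return(TRUE)   # param points sit at/above r
  if (p$k == "f" && q$k == "p") return(FALSE)
  ## both parametric: ancestor iff height >= height
  lf_cmp(p$lf, q$lf, lo, hi) >= 0L
}

## lowest common ancestor; may split
pp_lca <- function(ctx, p, q, lo, hi) {
  if (p$k == "f" && q$k == "f") {
    if (p$side != q$side) return(pp_param(lf_const(RAT0)))  # the root r
    side <- if (p$side == 1L) ctx$A else ctx$B
    return(pp_fixed(p$side, idx_lca(side$idx, p$pt, q$pt)))
  }
  if (p$k == "p" && q$k == "f") return(p)
  if (p$k == "f" && q$k == "p") return(q)
  if (lf_cmp(p$lf, q$lf, lo, hi) >= 0L) p else q
}

## distance from ancestor point p to descendant q as a linear form
pp_dist <- function(ctx, p, q) lf_sub(pp_depth(ctx, q), pp_depth(ctx, p))

## classify a side-index point that may lie on the host edge: fixed within
## the interval, parametric, or split. `t` is the height above x_a (side 1)
## or x_b (side 2).
.classify_sidepoint <- function(ctx, side, q, lo, hi) {
  sideidx <- if (side == 1L) ctx$A$idx else ctx$B$idx
  aroot <- sideidx$rf$root
  if (!(q$node == aroot && rat_sign(q$h) > 0))
    return(pp_fixed(side, q))
  t <- q$h
  if (side == 1L) {
    if (rat_cmp(t, lo) <= 0) return(pp_fixed(side, q))
    if (rat_cmp(t, hi) >= 0) return(pp_param(lf(t, rat(-1))))
    .split(t)
  } else {
    tt <- rat_sub(ctx$L, t)   # distance from x_a
    if (rat_cmp(tt, hi) >= 0) return(pp_fixed(side, q))
    if (rat_cmp(tt, lo) <= 0) return(pp_param(lf(rat_sub(t, ctx$L), RAT1)))
    .split(tt)
  }
}

#' Parametric level ancestor from a species leaf
#'
#' Computes \code{anc(leaf, d)} when the species tree is rooted at an
#' unknown point of the host edge with offset in the open interval
#' (lo, hi): the result is a fixed point when it stays below every root
#' position in the interval, a parametric point \code{pt(r, d + c rho)}
#' when it lies above every root position, and otherwise the interval is
#' split at the offset where the result crosses the root.
#'
#' @param ctx edge context (internal).
#' @param leaf_global species leaf id in the unrooted tree.
#' @param d rational distance.
#' @param lo,hi current interval.
#' @return a parametric point; may raise an interval split condition.
#' @export
param_anc <- function(ctx, leaf_global, d, lo, hi) {
  side <- ctx$side_of[leaf_global]
  s <- if (side == 1L) ctx$A else ctx$B
  q <- idx_anc(s$idx, tp(s$g2l[leaf_global]), d)
  .classify_sidepoint(ctx, side, q, lo, hi)
}

## anc from an arbitrary parametric point by a *constant* rational distance
pp_anc <- function(ctx, p, d, lo, hi) {
  if (p$k == "p") return(pp_param(lf_add(p$lf, lf_const(d))))
  side <- if (p$side == 1L) ctx$A else ctx$B
  q <- idx_anc(side$idx, p$pt, d)
  .classify_sidepoint(ctx, p$side, q, lo, hi)
}

## ---- edge context ----
## Rooted side views of the unrooted species tree relative to edge ei:
## component of x_a rooted at x_a, component of x_b rooted at x_b, with
## local/global id maps.
.make_edge_ctx <- function(S, ei) {
  xa <- S$edge[ei, 1]; xb <- S$edge[ei, 2]
  L <- S$elen[[ei]]
  n <- tree_n(S)
  adj <- tree_adj(S)
  side_of <- integer(n)
  comp <- function(start, avoid_edge) {
    seen <- logical(n); seen[start] <- TRUE
    queue <- start; qi <- 1L
    while (qi <= length(queue)) {
      x <- queue[qi]; qi <- qi + 1L
      for (j in seq_along(adj$nb[[x]])) {
        if (adj$ei[[x]][j] == avoid_edge) next
        w <- adj$nb[[x]][j]
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    queue
  }
  mk_side <- function(nodes, root_global) {
    g2l <- integer(n); g2l[nodes] <- seq_along(nodes)
    edges <- NULL; lens <- list()
    for (k in seq_len(nrow(S$edge))) {
      if (k == ei) next
      a <- S$edge[k, 1]; b <- S$edge[k, 2]
      if (g2l[a] > 0L && g2l[b] > 0L) {
        edges <- rbind(edges, c(g2l[a], g2l[b]))
        lens[[length(lens) + 1L]] <- S$elen[[k]]
      }
    }
    if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
    t <- itree(S$labels[nodes], edges, lens, rooted = TRUE,
               root = g2l[root_global])
    list(tree = t, idx = build_index(t), g2l = g2l, l2g = nodes)
  }
  nodesA <- comp(xa, ei); nodesB <- comp(xb, ei)
  side_of[nodesA] <- 1L; side_of[nodesB] <- 2L
  list(S = S, ei = ei, xa = xa, xb = xb, L = L, side_of = side_of,
       A = mk_side(nodesA, xa), B = mk_side(nodesB, xb))
}
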