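## Preprocessed query structure over a rooted tree: O(1) lca after linear
## preprocessing (Euler tour + sparse table), exact depths, and a weighted
## level-ancestor built on the heavy path decomposition (binary search over
## the node-weight array of each heavy path, O(log n) light edges on any
## root path).
##
## Tree points are kept in a canonical form relative to the rooted tree:
## list(node = v, h = rational height above v toward its parent), with
## 0 <= h < length(edge to parent), or v == root and h >= 0, which denotes a
## point on the implicit infinite edge above the root. Two equal points
## always have identical canonical forms.

#' Tree point constructor
#'
#' \code{tp(v, h)} is the point at height \code{h} above node \code{v}
#' toward the root (above the root itself when \code{v} is the root).
#' @param node integer node id.
#' @param h rational height above the node (default 0, i.e. the node).
#' @return a tree point.
#' @export
tp <- function(node, h = RAT0) list(node = as.integer(node), h = h)

#' @rdname tp
#' @param p,q tree points.
#' @export
tp_eq <- function(p, q) p$node == q$node && rat_eq(p$h, q$h)

#' Convert an edge point pt(u, v, d) to canonical form
#'
#' The point at distance \code{d} from \code{u} on edge \code{(u, v)} of the
#' indexed tree; \code{pt(u, v, d)} and \code{pt(v, u, len - d)} denote the
#' same point and canonicalize identically.
#' @param idx a tree index.
#' @param u,v adjacent node ids.
#' @param d rational distance from \code{u}, with \code{0 <= d <= d(u,v)}.
#' @return a canonical tree point.
#' @export
edge_point <- function(idx, u, v, d) {
  if (idx$rf$parent[v] == u) { child <- v; up <- u }
  else if (idx$rf$parent[u] == v) { child <- u; up <- v; d <- rat_sub(idx$rf$plen[[child]], d) }
  else stop("edge_point: nodes are not adjacent")
  len <- idx$rf$plen[[child]]
  if (rat_sign(d) < 0 || rat_cmp(d, len) > 0) stop("edge_point: d out of range")
  h <- rat_sub(len, d)
  if (rat_eq(h, len)) return(tp(up))
  tp(child, h)
}

#' Build the query index for a rooted tree
#'
#' @param S a rooted \code{itree} with positive branch lengths.
#' @return an object of class \code{itree_index} supporting [idx_lca()],
#'   [idx_anc()], [idx_is_anc()], [idx_dist()] and [triangulate()].
#' @export
build_index <- function(S) {
  if (!S$rooted) stop("build_index requires a rooted tree")
  n <- tree_n(S)
  rf <- rooted_form(S)
  ## exact depths and integer (edge-count) depths
  w <- vector("list", n); idepth <- integer(n)
  w[[rf$root]] <- RAT0
  for (v in rf$order) if (v != rf$root) {
    w[[v]] <- rat_add(w[[rf$parent[v]]], rf$plen[[v]])
    idepth[v] <- idepth[rf$parent[v]] + 1L
  }
  ## Euler tour for lca
  first <- integer(n)
  tour <- integer(0)
  if (n == 1) { tour <- 1L; first[1] <- 1L } else {
    ## iterative Euler tour
    stack <- list(list(v = rf$root, ci = 0L))
    while (length(stack) > 0) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      tour <- c(tour, v)
      if (first[v] == 0L) first[v] <- length(tour)
      kids <- rf$children[[v]]
      if (fr$ci < length(kids)) {
        stack[[length(stack)]]$ci <- fr$ci + 1L
        stack[[length(stack) + 1L]] <- list(v = kids[fr$ci + 1L], ci = 0L)
      } else stack[[length(stack)]] <- NULL
    }
  }
  m <- length(tour)
  K <- max(1L, floor(log2(m)) + 1L)
  sp <- matrix(0L, nrow = K, ncol = m)
  sp[1, ] <- tour
  if (K > 1) for (k in 2:K) {
    half <- 2L^(k - 2L)
    for (i in seq_len(m - 2L * half + 1L)) {
      a <- sp[k - 1L, i]; b <- sp[k - 1L, i + half]
      sp[k, i] <- if (idepth[a] <= idepth[b]) a else b
    }
  }
  ## subtree sizes and heavy paths; an edge (p, v) is heavy iff
  ## size(v) >= size(p) / 2
  size <- integer(n)
  for (v in rev(rf$order)) {
    size[v] <- 1L
    for (k in rf$children[[v]]) size[v] <- size[v] + size[k]
  }
  heavy <- integer(n)  # heavy child of each node, 0 if none
  for (v in seq_len(n)) {
    for (k in rf$children[[v]]) {
      if (2L * size[k] >= size[v]) { heavy[v] <- k; break }
    }
  }
  path_id <- integer(n); pos <- integer(n)
  paths <- list(); path_wn <- list(); path_wd <- list()
  for (v in rf$order) {
    if (v == rf$root || heavy[rf$parent[v]] != v) {
      ## v heads a new heavy path
      p <- v; nodes <- integer(0)
      while (p != 0L) { nodes <- c(nodes, p); p <- heavy[p] }
      pid <- length(paths) + 1L
      paths[[pid]] <- nodes
      path_id[nodes] <- pid
      pos[nodes] <- seq_along(nodes)
      path_wn[[pid]] <- vapply(nodes, function(x) w[[x]][1], 0)
      path_wd[[pid]] <- vapply(nodes, function(x) w[[x]][2], 0)
    }
  }
  idx <- list(tree = S, rf = rf, n = n, w = w, idepth = idepth,
              first = first, sp = sp, size = size,
              path_id = path_id, pos = pos, paths = paths,
              path_wn = path_wn, path_wd = path_wd)
  class(idx) <- "itree_index"
  idx
}

## lca of two *nodes* in O(1)
.lca_node <- function(idx, u, v) {
  if (u == v) return(u)
  i <- idx$first[u]; j <- idx$first[v]
  if (i > j) { t <- i; i <- j; j <- t }
  len <- j - i + 1L
  k <- floor(log2(len))
  a <- idx$sp[k + 1L, i]
  b <- idx$sp[k + 1L, j - 2L^k + 1L]
  if (idx$idepth[a] <= idx$idepth[b]) a else b
}

#' Exact depth of a tree point (distance from the root; negative above it)
#' @param idx a tree index.
#' @param p a tree point.
#' @return a rational.
#' @export
tp_depth <- function(idx, p) rat_sub(idx$w[[p$node]], p$h)

## deepest ancestor node of u with depth <= t (0 <= t <= w(u)); returns the
## point at depth exactly t on the root path of u as a canonical tree point
.point_at_depth <- function(idx, u, t) {
  rf <- idx$rf
  cur <- u
  repeat {
    pid <- idx$path_id[cur]
    head <- idx$paths[[pid]][1]
    cmp_head <- .rat_cmp2(idx$path_wn[[pid]][1], idx$path_wd[[pid]][1], t)
    if (cmp_head <= 0L) {
      ## answer within this path, among positions 1..pos(cur): binary search
      ## for the deepest v with w(v) <= t
      lo <- 1L; hi <- idx$pos[cur]
      wn <- idx$path_wn[[pid]]; wd <- idx$path_wd[[pid]]
      while (lo < hi) {
        mid <- (lo + hi + 1L) %/% 2L
        if (.rat_cmp2(wn[mid], wd[mid], t) <= 0L) lo <- mid else hi <- mid - 1L
      }
      v <- idx$paths[[pid]][lo]
      if (.rat_cmp2(wn[lo], wd[lo], t) == 0L) return(tp(v))
      child <- idx$paths[[pid]][lo + 1L]
      return(tp(child, rat_sub(idx$w[[child]], t)))
    }
    p <- rf$parent[head]
    cmp_p <- rat_cmp(idx$w[[p]], t)
    if (cmp_p == 0L) return(tp(p))
    if (cmp_p < 0L) return(tp(head, rat_sub(idx$w[[head]], t)))
    cur <- p
  }
}

## compare rational (n/d) to rational t
.rat_cmp2 <- function(n, d, t) rat_cmp(c(n, d), t)

#' Weighted level ancestor of a tree point
#'
#' The point at distance exactly \code{d} from \code{p} toward the root;
#' beyond the root it lies on the implicit infinite edge above it
#' (\code{anc(pt(u, d1), d2) = anc(u, d1 + d2)}).
#' @param idx a tree index.
#' @param p a tree point.
#' @param d nonnegative rational distance.
#' @return a canonical tree point.
#' @export
idx_anc <- function(idx, p, d) {
  if (rat_sign(d) < 0) stop("anc: negative distance")
  t <- rat_sub(tp_depth(idx, p), d)
  if (rat_sign(t) < 0) return(tp(idx$rf$root, rat_neg(t)))
  if (rat_sign(t) == 0) return(tp(idx$rf$root))
  .point_at_depth(idx, p$node, t)
}

#' Lowest common ancestor of two tree points
#' @param idx a tree index.
#' @param p,q tree points.
#' @return a canonical tree point.
#' @export
idx_lca <- function(idx, p, q) {
  A <- .lca_node(idx, p$node, q$node)
  wA <- idx$w[[A]]
  dp <- tp_depth(idx, p)
  dq <- tp_depth(idx, q)
  m <- rat_min(wA, rat_min(dp, dq))
  if (rat_eq(m, dp)) return(p)
  if (rat_eq(m, dq)) return(q)
  tp(A)
}

#' Ancestor test for tree points
#' @param idx a tree index.
#' @param p,q tree points.
#' @return TRUE iff \code{p} lies on the path from \code{q} to the root
#'   (inclusive).
#' @export
idx_is_anc <- function(idx, p, q) tp_eq(idx_lca(idx, p, q), p)

#' Distance from an ancestor point to a descendant point
#' @param idx a tree index.
#' @param p ancestor point.
#' @param q descendant point.
#' @return nonnegative rational.
#' @export
idx_dist <- function(idx, p, q) {
  if (!idx_is_anc(idx, p, q)) stop("idx_dist: p is not an ancestor of q")
  rat_sub(tp_depth(idx, q), tp_depth(idx, p))
}

#' Triangulation of a gene node from two mapped relatives
#'
#' Given a gene node x on the path between gene nodes u and v, with known
#' images of u and v in the species tree and known gene-tree distances
#' d(u,x) and d(v,x), the candidate images are \code{x_u = anc(u_img, d_ux)}
#' and \code{x_v = anc(v_img, d_vx)}. If one candidate is an ancestor of the
#' other, the descendant is the image of x in any true history; otherwise no
#' isometric placement exists and the triangulation is undefined.
#'
#' @param idx index of the rooted species tree.
#' @param d_ux,d_vx rational distances from u and v to x in the gene tree.
#' @param u_img,v_img tree points, the images of u and v.
#' @return list with \code{status} ("resolved" or "undefined"), the
#'   \code{point} when resolved, and the two candidates \code{x_u},
#'   \code{x_v}.
#' @export
triangulate <- function(idx, d_ux, d_vx, u_img, v_img) {
  x_u <- idx_anc(idx, u_img, d_ux)
  x_v <- idx_anc(idx, v_img, d_vx)
  if (idx_is_anc(idx, x_u, x_v))
    return(list(status = "resolved", point = x_v, x_u = x_u, x_v = x_v))
  if (idx_is_anc(idx, x_v, x_u))
    return(list(status = "resolved", point = x_u, x_u = x_u, x_v = x_v))
  list(status = "undefined", point = NULL, x_u = x_u, x_v = x_v)
}
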