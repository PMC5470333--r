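## Reconciliation of an unrooted gene tree with a rooted species tree.
## Two equivalent routes are provided: the stage-based algorithm
## (map internal nodes by triangulation from mapped neighbors, then decide
## per edge whether the root lies inside it) and a per-edge variant that
## maps both endpoints of every gene edge independently from a fixed leaf
## pair; the latter is the basis of the parametric algorithm for unrooted
## species trees.

#' Map internal nodes of an unrooted gene tree by triangulation
#'
#' Repeatedly takes an unmapped internal node with at least two mapped
#' neighbors and maps it by [triangulate()] from those neighbors. The result
#' is independent of the processing order and of which mapped neighbor pair
#' is used; the \code{pop_policy} argument exists so tests can demonstrate
#' this.
#'
#' @param G unrooted gene tree.
#' @param idx index of the rooted species tree.
#' @param leaf_images list over gene nodes: tree point for each leaf, NULL
#'   for internal nodes.
#' @param pop_policy "lifo" (deterministic) or "random" (randomized node and
#'   neighbor-pair selection, driven by the current RNG state).
#' @return list over gene nodes of tree points, or NULL when some
#'   triangulation is undefined (the input is irreconcilable).
#' @export
map_internal_nodes <- function(G, idx, leaf_images,
                               pop_policy = c("lifo", "random")) {
  pop_policy <- match.arg(pop_policy)
  n <- tree_n(G)
  adj <- tree_adj(G)
  images <- leaf_images
  mapped <- !vapply(images, is.null, TRUE)
  cnt <- integer(n)
  for (v in seq_len(n)) cnt[v] <- sum(mapped[adj$nb[[v]]])
  stack <- which(!mapped & cnt >= 2L)
  while (length(stack) > 0) {
    if (pop_policy == "random" && length(stack) > 1) {
      i <- sample.int(length(stack), 1L)
    } else i <- length(stack)
    x <- stack[i]; stack <- stack[-i]
    if (mapped[x]) next
    nbs <- adj$nb[[x]]; eis <- adj$ei[[x]]
    mi <- which(mapped[nbs])
    if (pop_policy == "random" && length(mi) > 2) mi <- sample(mi, 2L)
    u <- nbs[mi[1]]; v <- nbs[mi[2]]
    tr <- triangulate(idx, G$elen[[eis[mi[1]]]], G$elen[[eis[mi[2]]]],
                      images[[u]], images[[v]])
    if (tr$status != "resolved") return(NULL)
    images[[x]] <- tr$point
    mapped[x] <- TRUE
    for (w in nbs) {
      cnt[w] <- cnt[w] + 1L
      if (!mapped[w] && cnt[w] >= 2L) stack <- c(stack, w)
    }
  }
  if (!all(mapped)) stop("internal error: gene tree not fully mapped")
  images
}

#' Decide whether a gene edge hosts the root
#'
#' For gene edge (u, v) with images already known, computes the lowest
#' common ancestor lambda of the two images and
#' \code{eps = (d(u,v) - d(img_u, lambda) - d(img_v, lambda)) / 2}. A
#' potential root subdividing the edge exists iff \code{eps > 0} or lambda
#' differs from both images; it sits at offset \code{d(img_u, lambda) + eps}
#' from u and maps to \code{anc(lambda, eps)}. A negative eps with lambda
#' equal to neither image admits no isometric placement and rejects the
#' edge.
#'
#' @param idx species tree index.
#' @param len rational length of the gene edge.
#' @param img_u,img_v tree points, images of the edge endpoints.
#' @return list with \code{kind} ("candidate", "none" or "reject") and for a
#'   candidate the \code{offset} from u, the image \code{q_img}, plus
#'   \code{lambda} and \code{eps}.
#' @export
place_root_on_edge <- function(idx, len, img_u, img_v) {
  lambda <- idx_lca(idx, img_u, img_v)
  dU <- rat_sub(tp_depth(idx, img_u), tp_depth(idx, lambda))
  dV <- rat_sub(tp_depth(idx, img_v), tp_depth(idx, lambda))
  eps <- rat_half(rat_sub(rat_sub(len, dU), dV))
  in_set <- tp_eq(lambda, img_u) || tp_eq(lambda, img_v)
  s <- rat_sign(eps)
  if (s > 0 || !in_set) {
    if (s < 0)
      return(list(kind = "reject", lambda = lambda, eps = eps))
    return(list(kind = "candidate", offset = rat_add(dU, eps),
                q_img = idx_anc(idx, lambda, eps),
                lambda = lambda, eps = eps))
  }
  list(kind = "none", lambda = lambda, eps = eps)
}

## Subdivide gene edge `ei` of unrooted G at `offset` from edge endpoint
## `from`, label the new node, and return the rooted tree plus new node id.
.root_inside_edge <- function(G, ei, from, offset, label = "Q") {
  a <- G$edge[ei, 1]; b <- G$edge[ei, 2]
  if (from == b) { t <- a; a <- b; b <- t }
  len <- G$elen[[ei]]
  if (rat_sign(offset) <= 0 || rat_cmp(offset, len) >= 0)
    stop("root offset outside edge")
  qlab <- if (label %in% G$labels) .fresh_labels(1L, G$labels, base = label) else label
  labels <- c(G$labels, qlab)
  q <- length(labels)
  keep <- setdiff(seq_len(nrow(G$edge)), ei)
  edges <- rbind(G$edge[keep, , drop = FALSE], c(q, a), c(q, b))
  elens <- c(G$elen[keep], list(offset), list(rat_sub(len, offset)))
  list(G = itree(labels, edges, elens, rooted = TRUE, root = q), q = q)
}

## Shared Stages 4-6: root the gene tree, materialize S, verify.
## cand: NULL or list(ei, from, offset, q_img)
.finish_unrooted <- function(G_I, S_I, images, cand) {
  nG <- tree_n(G_I)
  if (!is.null(cand)) {
    rooted <- .root_inside_edge(G_I, cand$ei, cand$from, cand$offset)
    G <- rooted$G
    images[[rooted$q]] <- cand$q_img
    rootnode <- rooted$q
  } else {
    ## Stage 5: topmost image must be the image of the root; find a maximal
    ## image point and root at its first internal preimage
    idxS <- attr(images, "idx")
    top <- images[[1]]
    for (v in seq_len(nG)) {
      if (idx_is_anc(idxS, images[[v]], top)) top <- images[[v]]
    }
    for (v in seq_len(nG)) {
      if (!idx_is_anc(idxS, top, images[[v]]))
        return(.result("irreconcilable",
                       reason = "no single topmost image exists"))
    }
    deg <- tree_degree(G_I)
    pre <- which(vapply(seq_len(nG), function(v)
      tp_eq(images[[v]], top) && (deg[v] >= 3L || nG == 1L), TRUE))
    if (length(pre) == 0)
      return(.result("irreconcilable",
                     reason = "root position is not an internal gene node and no edge hosts it"))
    rootnode <- pre[1]
    G <- G_I; G$rooted <- TRUE; G$root <- as.integer(rootnode)
    attr(images, "idx") <- NULL
  }
  mat <- materialize_species_tree(S_I, images)
  h <- history(G, mat$S, mat$ids)
  chk <- verify_isometric(h)
  if (!chk$ok)
    return(.result("irreconcilable",
                   reason = sprintf("isometry violated on gene edge (%s,%s)",
                                    chk$edge[1], chk$edge[2]),
                   edge = chk$edge))
  .result("reconciled", h)
}

#' Isometric reconciliation of an unrooted gene tree with a rooted species
#' tree
#'
#' Maps leaves by the input leaf map, maps internal nodes by triangulation,
#' decides for every gene edge whether the root lies inside it (at most one
#' edge may host the root in a reconcilable input), materializes the species
#' tree, roots the gene tree and verifies the mapping. When a reconciliation
#' exists it is unique and this function finds it.
#'
#' @param iph input partial history, gene tree unrooted, species tree
#'   rooted.
#' @param pop_policy passed to [map_internal_nodes()] (tests only).
#' @return an \code{iso_result}.
#' @export
reconcile_unrooted_gene <- function(iph, pop_policy = "lifo") {
  if (iph$G$rooted || !iph$S$rooted)
    stop("reconcile_unrooted_gene requires an unrooted gene tree and a rooted species tree")
  bad <- validate_input(iph)
  if (length(bad) > 0) stop("invalid input: ", paste(bad, collapse = "; "))
  G <- iph$G; S_I <- iph$S; mu <- iph$mu
  nG <- tree_n(G)
  if (nG == 1) {
    G1 <- G; G1$rooted <- TRUE; G1$root <- 1L
    return(.result("reconciled",
                   history(G1, S_I, node_by_label(S_I, mu[[G$labels[1]]]))))
  }
  idx <- build_index(S_I)
  leaves <- tree_leaves(G)
  images <- vector("list", nG)
  for (l in leaves) images[[l]] <- tp(node_by_label(S_I, mu[[G$labels[l]]]))
  images <- map_internal_nodes(G, idx, images, pop_policy)
  if (is.null(images))
    return(.result("irreconcilable", reason = "triangulation undefined"))
  ## Stage 3: scan all edges for a potential root
  cand <- NULL
  for (ei in seq_len(nrow(G$edge))) {
    a <- G$edge[ei, 1]; b <- G$edge[ei, 2]
    pr <- place_root_on_edge(idx, G$elen[[ei]], images[[a]], images[[b]])
    if (pr$kind == "reject")
      return(.result("irreconcilable",
                     reason = "no isometric root placement on a gene edge"))
    if (pr$kind == "candidate") {
      if (!is.null(cand))
        return(.result("irreconcilable",
                       reason = "more than one gene edge hosts a potential root"))
      cand <- list(ei = ei, from = a, offset = pr$offset, q_img = pr$q_img)
    }
  }
  attr(images, "idx") <- idx
  .finish_unrooted(G, S_I, images, cand)
}

## deterministic leaf pair for every internal node of an unrooted tree:
## the lexicographically smallest leaves reachable through two distinct
## neighbors, so the node lies on the path connecting them
.leaf_pairs <- function(G) {
  n <- tree_n(G)
  adj <- tree_adj(G)
  deg <- tree_degree(G)
  leaves <- which(deg == 1L)
  is_leaf <- logical(n); is_leaf[leaves] <- TRUE
  out <- vector("list", n)
  for (x in seq_len(n)) {
    if (is_leaf[x]) next
    mins <- character(0)
    for (nb in adj$nb[[x]]) {
      ## min leaf label in the component of G - x containing nb
      seen <- logical(n); seen[x] <- TRUE; seen[nb] <- TRUE
      queue <- nb; qi <- 1L; best <- NA_character_
      while (qi <= length(queue)) {
        y <- queue[qi]; qi <- qi + 1L
        if (is_leaf[y] && (is.na(best) || G$labels[y] < best)) best <- G$labels[y]
        for (w in adj$nb[[y]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
      mins <- c(mins, best)
    }
    o <- order(mins)
    out[[x]] <- sort(c(mins[o[1]], mins[o[2]]))
  }
  out
}

#' Per-edge reconciliation of an unrooted gene tree
#'
#' Processes each gene edge independently: maps both endpoints by
#' triangulating from a fixed leaf pair (Step A), decides root placement on
#' the edge (Step B) and checks the edge's distances (Step C), then
#' materializes, roots and verifies as usual. Produces exactly the same
#' result as [reconcile_unrooted_gene()] on every input; this formulation is
#' the one simulated parametrically when the species tree is unrooted.
#'
#' @param iph input partial history, gene tree unrooted, species tree
#'   rooted.
#' @return an \code{iso_result}.
#' @export
reconcile_per_edge <- function(iph) {
  if (iph$G$rooted || !iph$S$rooted)
    stop("reconcile_per_edge requires an unrooted gene tree and a rooted species tree")
  bad <- validate_input(iph)
  if (length(bad) > 0) stop("invalid input: ", paste(bad, collapse = "; "))
  G <- iph$G; S_I <- iph$S; mu <- iph$mu
  nG <- tree_n(G)
  if (nG == 1) {
    G1 <- G; G1$rooted <- TRUE; G1$root <- 1L
    return(.result("reconciled",
                   history(G1, S_I, node_by_label(S_I, mu[[G$labels[1]]]))))
  }
  idx <- build_index(S_I)
  pairs <- .leaf_pairs(G)
  adjd <- tree_adj(G)
  leaves <- tree_leaves(G)
  is_leaf <- logical(nG); is_leaf[leaves] <- TRUE
  dists <- vector("list", nG)  # lazy per-node distance vectors
  node_dist <- function(x, lab) {
    if (is.null(dists[[x]])) dists[[x]] <<- tree_dist_all(G, x, adjd)
    dists[[x]][[node_by_label(G, lab)]]
  }
  map_endpoint <- function(x) {
    if (is_leaf[x]) return(tp(node_by_label(S_I, mu[[G$labels[x]]])))
    pr <- pairs[[x]]
    tr <- triangulate(idx, node_dist(x, pr[1]), node_dist(x, pr[2]),
                      tp(node_by_label(S_I, mu[[pr[1]]])),
                      tp(node_by_label(S_I, mu[[pr[2]]])))
    if (tr$status != "resolved") return(NULL)
    tr$point
  }
  images <- vector("list", nG)
  cand <- NULL
  for (ei in seq_len(nrow(G$edge))) {
    a <- G$edge[ei, 1]; b <- G$edge[ei, 2]
    pa <- map_endpoint(a); pb <- map_endpoint(b)
    if (is.null(pa) || is.null(pb))
      return(.result("irreconcilable", reason = "triangulation undefined"))
    images[[a]] <- pa; images[[b]] <- pb
    len <- G$elen[[ei]]
    pr <- place_root_on_edge(idx, len, pa, pb)
    if (pr$kind == "reject")
      return(.result("irreconcilable",
                     reason = "no isometric root placement on a gene edge"))
    if (pr$kind == "candidate") {
      if (!is.null(cand))
        return(.result("irreconcilable",
                       reason = "more than one gene edge hosts a potential root"))
      cand <- list(ei = ei, from = a, offset = pr$offset, q_img = pr$q_img)
      ## Step C with subdivision: both half edges must measure correctly
      okA <- idx_is_anc(idx, pr$q_img, pa) &&
        rat_eq(idx_dist(idx, pr$q_img, pa), pr$offset)
      okB <- idx_is_anc(idx, pr$q_img, pb) &&
        rat_eq(idx_dist(idx, pr$q_img, pb), rat_sub(len, pr$offset))
      if (!okA || !okB)
        return(.result("irreconcilable",
                       reason = "edge length check failed at the root candidate"))
    } else {
      ## Step C without subdivision
      ok <- (idx_is_anc(idx, pa, pb) && rat_eq(idx_dist(idx, pa, pb), len)) ||
        (idx_is_anc(idx, pb, pa) && rat_eq(idx_dist(idx, pb, pa), len))
      if (!ok)
        return(.result("irreconcilable",
                       reason = sprintf("edge (%s,%s) fails the distance check", a, b)))
    }
  }
  attr(images, "idx") <- idx
  .finish_unrooted(G, S_I, images, cand)
}
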