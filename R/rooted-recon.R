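## Rooted/rooted reconciliation, shared species-tree materialization and
## isometry verification, and the branch-length scaling variant.

#' Construct a history (gene tree, species tree, mapping)
#' @param G rooted gene tree.
#' @param S rooted species tree.
#' @param phi integer vector: for each node of G, the node of S it maps to.
#' @return object of class \code{iso_history}.
#' @export
history <- function(G, S, phi) {
  h <- list(G = G, S = S, phi = as.integer(phi))
  class(h) <- "iso_history"
  h
}

.result <- function(status, history = NULL, reason = NULL, ...) {
  r <- list(status = status, history = history, reason = reason, ...)
  class(r) <- "iso_result"
  r
}

#' @export
print.iso_result <- function(x, ...) {
  cat("isometric reconciliation:", x$status, "\n")
  if (!is.null(x$reason)) cat("  ", x$reason, "\n")
  if (!is.null(x$history)) {
    cat("  G:", write_newick(x$history$G), "\n")
    cat("  S:", write_newick(x$history$S), "\n")
  }
  invisible(x)
}

## Fresh labels D1, D2, ... skipping any that already exist in the tree.
.fresh_labels <- function(k, existing, base = "D") {
  out <- character(0); i <- 1L
  while (length(out) < k) {
    cand <- paste0(base, i)
    if (!(cand %in% existing)) out <- c(out, cand)
    i <- i + 1L
  }
  out
}

#' Materialize implicit species-tree points as explicit nodes
#'
#' Given images of gene nodes as (possibly implicit) points of the rooted
#' species tree, subdivides the corresponding edges so that every image is a
#' node: for each node u the points above it are sorted by height, exact
#' duplicates merged, and the edge to the parent replaced by a path; points
#' above the root become a chain of new ancestors of the old root. Added
#' nodes are labeled D1, D2, ... in preorder of the host nodes. Leaf-to-leaf
#' distances are unchanged.
#'
#' @param S_I rooted species tree.
#' @param images list of tree points (as from [tp()]).
#' @return list with the new tree \code{S} and \code{ids}, an integer vector
#'   giving for each input image its node id in \code{S} (old node ids are
#'   preserved).
#' @export
materialize_species_tree <- function(S_I, images) {
  n <- tree_n(S_I)
  rf <- rooted_form(S_I)
  ## group unique positive heights per base node
  hts <- vector("list", n)
  for (p in images) {
    if (rat_sign(p$h) == 0) next
    if (p$node != rf$root) {
      if (rat_cmp(p$h, rf$plen[[p$node]]) >= 0)
        stop("materialize: image outside its host edge")
    }
    cur <- hts[[p$node]]
    dup <- FALSE
    for (q in cur) if (rat_eq(q, p$h)) { dup <- TRUE; break }
    if (!dup) hts[[p$node]] <- c(cur, list(p$h))
  }
  for (u in seq_len(n)) if (length(hts[[u]]) > 1) {
    ## exact insertion sort (lists are short)
    hs <- hts[[u]]
    for (i in 2:length(hs)) {
      x <- hs[[i]]; j <- i - 1L
      while (j >= 1L && rat_cmp(hs[[j]], x) > 0) { hs[[j + 1L]] <- hs[[j]]; j <- j - 1L }
      hs[[j + 1L]] <- x
    }
    hts[[u]] <- hs
  }
  k_new <- sum(vapply(hts, length, 0L))
  labels <- c(S_I$labels, .fresh_labels(k_new, S_I$labels))
  new_id <- n
  id_of <- new.env(parent = emptyenv())
  edges <- NULL; elens <- list()
  add_edge <- function(a, b, l) {
    edges <<- rbind(edges, c(a, b))
    elens[[length(elens) + 1L]] <<- l
  }
  newroot <- rf$root
  for (u in rf$order) {
    hs <- hts[[u]]
    if (u == rf$root) {
      prev <- u; prevh <- RAT0
      for (h in hs) {
        new_id <- new_id + 1L
        assign(paste0(u, "_", h[1], "_", h[2]), new_id, envir = id_of)
        add_edge(new_id, prev, rat_sub(h, prevh))
        prev <- new_id; prevh <- h
      }
      newroot <- prev
    } else {
      plen <- rf$plen[[u]]
      prev <- u; prevh <- RAT0
      for (h in hs) {
        new_id <- new_id + 1L
        assign(paste0(u, "_", h[1], "_", h[2]), new_id, envir = id_of)
        add_edge(new_id, prev, rat_sub(h, prevh))
        prev <- new_id; prevh <- h
      }
      add_edge(rf$parent[u], prev, rat_sub(plen, prevh))
    }
  }
  S <- itree(labels, edges, elens, rooted = TRUE, root = newroot)
  ids <- vapply(images, function(p) {
    if (rat_sign(p$h) == 0) p$node
    else get(paste0(p$node, "_", p$h[1], "_", p$h[2]), envir = id_of)
  }, 0L)
  list(S = S, ids = ids)
}

#' Check that the mapping of a history is isometric
#'
#' Verifies on every gene edge (u parent of v) that the image of u is a
#' proper ancestor of the image of v at exactly the edge's distance. This is
#' the distance/ancestor form of the condition, valid also for histories
#' with zero-length edges.
#'
#' @param h an \code{iso_history}.
#' @return list with \code{ok}, and when not ok the violating \code{edge}
#'   (parent, child gene node ids).
#' @export
verify_isometric <- function(h) {
  rfg <- rooted_form(h$G)
  rfs <- rooted_form(h$S)
  ns <- tree_n(h$S)
  depthS <- vector("list", ns)
  depthS[[rfs$root]] <- RAT0
  for (v in rfs$order) if (v != rfs$root)
    depthS[[v]] <- rat_add(depthS[[rfs$parent[v]]], rfs$plen[[v]])
  idepthS <- integer(ns)
  for (v in rfs$order) if (v != rfs$root)
    idepthS[v] <- idepthS[rfs$parent[v]] + 1L
  is_proper_anc <- function(a, b) {
    ## a proper ancestor of b: walk b upward (integer depths bound the walk)
    while (idepthS[b] > idepthS[a]) b <- rfs$parent[b]
    a == b
  }
  for (v in seq_len(tree_n(h$G))) {
    if (v == rfg$root) next
    u <- rfg$parent[v]
    pu <- h$phi[u]; pv <- h$phi[v]
    ok <- pu != pv && is_proper_anc(pu, pv) &&
      rat_eq(rat_sub(depthS[[pv]], depthS[[pu]]), rfg$plen[[v]])
    if (!ok) return(list(ok = FALSE, edge = c(u, v)))
  }
  list(ok = TRUE)
}

## descendant-leaf choice for every node of a rooted gene tree:
## the lexicographically smallest (policy "min") or largest ("max") leaf
## label below each node
.choose_leaves <- function(G, rf, policy = "min") {
  n <- tree_n(G)
  pick <- rep(NA_character_, n)
  for (v in rev(rf$order)) {
    kids <- rf$children[[v]]
    if (length(kids) == 0) pick[v] <- G$labels[v]
    else {
      cand <- pick[kids]
      pick[v] <- if (policy == "min") sort(cand)[1] else sort(cand, decreasing = TRUE)[1]
    }
  }
  pick
}

#' Isometric reconciliation of two rooted trees
#'
#' Maps each internal gene node v to \code{anc(mu(u), d(u, v))} for a
#' deterministically chosen descendant leaf u, materializes the implied new
#' species-tree nodes, and verifies that the resulting mapping is isometric.
#' The output is independent of the leaf choice: when the input is
#' reconcilable the reconciliation is unique, and otherwise the final
#' verification rejects it.
#'
#' @param iph input partial history with both trees rooted.
#' @param leaf_choice "min" or "max": which descendant leaf (by label order)
#'   anchors the mapping of each internal node. Both give the same result;
#'   the option exists so that tests can demonstrate order independence.
#' @return an \code{iso_result} with status "reconciled" (and a
#'   \code{history}) or "irreconcilable".
#' @export
reconcile_rooted <- function(iph, leaf_choice = c("min", "max")) {
  leaf_choice <- match.arg(leaf_choice)
  if (!iph$G$rooted || !iph$S$rooted)
    stop("reconcile_rooted requires rooted trees")
  bad <- validate_input(iph)
  if (length(bad) > 0) stop("invalid input: ", paste(bad, collapse = "; "))
  G <- iph$G; S_I <- iph$S; mu <- iph$mu
  nG <- tree_n(G)
  sleaf_id <- function(lab) node_by_label(S_I, lab)
  if (nG == 1) {
    phi <- sleaf_id(mu[[G$labels[1]]])
    return(.result("reconciled", history(G, S_I, phi)))
  }
  idx <- build_index(S_I)
  rfg <- rooted_form(G)
  depthG <- vector("list", nG)
  depthG[[rfg$root]] <- RAT0
  for (v in rfg$order) if (v != rfg$root)
    depthG[[v]] <- rat_add(depthG[[rfg$parent[v]]], rfg$plen[[v]])
  pick <- .choose_leaves(G, rfg, leaf_choice)
  leaves <- tree_leaves(G)
  images <- vector("list", nG)
  for (v in seq_len(nG)) {
    if (v %in% leaves) {
      images[[v]] <- tp(sleaf_id(mu[[G$labels[v]]]))
    } else {
      u <- node_by_label(G, pick[v])
      d <- rat_sub(depthG[[u]], depthG[[v]])
      images[[v]] <- idx_anc(idx, tp(sleaf_id(mu[[G$labels[u]]])), d)
    }
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

#' Is a rooted tree ultrametric?
#'
#' TRUE iff all leaves are at exactly the same distance from the root
#' (molecular clock).
#' @param t rooted \code{itree}.
#' @param leaf_ids optionally restrict to a subset of leaves.
#' @return logical.
#' @export
is_ultrametric <- function(t, leaf_ids = tree_leaves(t)) {
  if (!t$rooted) stop("is_ultrametric requires a rooted tree")
  if (tree_n(t) == 1 || length(leaf_ids) <= 1) return(TRUE)
  rf <- rooted_form(t)
  depth <- vector("list", tree_n(t))
  depth[[rf$root]] <- RAT0
  for (v in rf$order) if (v != rf$root)
    depth[[v]] <- rat_add(depth[[rf$parent[v]]], rf$plen[[v]])
  d0 <- depth[[leaf_ids[1]]]
  for (l in leaf_ids[-1]) if (!rat_eq(depth[[l]], d0)) return(FALSE)
  TRUE
}

#' Reconciliation of rooted trees with an unknown gene-tree scaling factor
#'
#' Finds the positive factors alpha for which the gene tree with all branch
#' lengths multiplied by alpha reconciles with the species tree. Subtrees of
#' the species tree carrying no mapped gene leaf are ignored when deciding
#' ultrametricity and heights (the reconciliation itself is computed against
#' the full species tree). Three regimes arise:
#' \itemize{
#' \item neither tree ultrametric: at most one alpha can work; it is pinned
#'   by any leaf pair at unequal depths (certificate case "unique-alpha");
#' \item both trees ultrametric: all alpha at or above a threshold
#'   \code{alpha* = max_v h_S(x_v) / h_G(v)} work, where x_v is the lca of
#'   the images of v's leaf descendants (case "threshold");
#' \item exactly one tree ultrametric: no alpha works (case "none").
#' }
#'
#' @param iph input partial history, both trees rooted.
#' @return an \code{iso_result}; when reconcilable it carries the
#'   \code{history} at the certified alpha and a \code{certificate} list
#'   (case, alpha or alpha_star, witnesses).
#' @export
reconcile_scaled <- function(iph) {
  if (!iph$G$rooted || !iph$S$rooted)
    stop("reconcile_scaled requires rooted trees")
  bad <- validate_input(iph)
  if (length(bad) > 0) stop("invalid input: ", paste(bad, collapse = "; "))
  G <- iph$G; S <- iph$S; mu <- iph$mu
  gl <- tree_leaves(G)
  mapped_sleaves <- unique(vapply(G$labels[gl], function(x) node_by_label(S, mu[[x]]), 0L))
  ultraG <- is_ultrametric(G)
  ultraS <- is_ultrametric(S, mapped_sleaves)
  rfg <- rooted_form(G); rfs <- rooted_form(S)
  nG <- tree_n(G); nS <- tree_n(S)
  depth_of <- function(rf, n) {
    d <- vector("list", n); d[[rf$root]] <- RAT0
    for (v in rf$order) if (v != rf$root)
      d[[v]] <- rat_add(d[[rf$parent[v]]], rf$plen[[v]])
    d
  }
  depthG <- depth_of(rfg, nG); depthS <- depth_of(rfs, nS)
  if (ultraG != ultraS)
    return(.result("irreconcilable",
                   reason = "exactly one tree is ultrametric; no scaling factor exists",
                   certificate = list(case = "none")))
  if (!ultraG) {
    ## unique-alpha case: first leaf pair (by label order) at unequal depths
    labs <- sort(G$labels[gl])
    pair <- NULL
    for (i in seq_along(labs)) {
      for (j in seq_along(labs)) {
        if (i == j) next
        a <- node_by_label(G, labs[i]); b <- node_by_label(G, labs[j])
        dG <- rat_sub(depthG[[a]], depthG[[b]])
        if (rat_sign(dG) > 0) { pair <- c(a, b); break }
      }
      if (!is.null(pair)) break
    }
    a <- pair[1]; b <- pair[2]
    dG <- rat_sub(depthG[[a]], depthG[[b]])
    dS <- rat_sub(depthS[[node_by_label(S, mu[[G$labels[a]]])]],
                  depthS[[node_by_label(S, mu[[G$labels[b]]])]])
    cert <- list(case = "unique-alpha",
                 witness = c(a = G$labels[a], b = G$labels[b]),
                 delta_G = dG, delta_S = dS)
    if (rat_sign(dS) <= 0)
      return(.result("irreconcilable",
                     reason = "leaf depth differences have incompatible signs; no positive scaling factor exists",
                     certificate = cert))
    alpha <- rat_div(dS, dG)
    cert$alpha <- alpha
    res <- reconcile_rooted(input_history(tree_scale(G, alpha), S, mu))
    res$certificate <- cert
    if (res$status != "reconciled")
      res$reason <- paste0("the only admissible scaling factor ",
                           rat_format(alpha), " fails: ", res$reason)
    return(res)
  }
  ## both ultrametric: threshold case
  idx <- build_index(S)
  DS <- depthS[[mapped_sleaves[1]]]
  DG <- depthG[[gl[1]]]
  ## per gene node, lca of species images of its descendant leaves
  xv <- integer(nG)
  for (v in rev(rfg$order)) {
    kids <- rfg$children[[v]]
    if (length(kids) == 0) xv[v] <- node_by_label(S, mu[[G$labels[v]]])
    else {
      acc <- xv[kids[1]]
      for (k in kids[-1]) acc <- .lca_node(idx, acc, xv[k])
      xv[v] <- acc
    }
  }
  internal <- setdiff(seq_len(nG), gl)
  astar <- RAT0
  wit <- NULL
  for (v in internal) {
    hG <- rat_sub(DG, depthG[[v]])
    hS <- rat_sub(DS, depthS[[xv[v]]])
    r <- rat_div(hS, hG)
    if (rat_cmp(r, astar) > 0) { astar <- r; wit <- list(v = v, h_G = hG, h_S = hS) }
    else if (is.null(wit)) wit <- list(v = v, h_G = hG, h_S = hS)
  }
  cert <- list(case = "threshold", alpha_star = astar, witness = wit)
  alpha_run <- if (rat_sign(astar) > 0) astar else RAT1
  res <- reconcile_rooted(input_history(tree_scale(G, alpha_run), S, mu))
  res$certificate <- cert
  res
}
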