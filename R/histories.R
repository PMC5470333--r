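## Simple and inferable histories, the gene-family evolution simulator, and
## derivation of reconciliation inputs from histories.
##
## A simple history is one in which every species-tree node is exactly one
## event: a sample (leaf), a speciation, a duplication or a loss; the
## species tree carries a dedicated one-child node for every duplication
## and loss. An inferable history is what reconciliation can recover: only
## observable gene nodes, strictly positive branch lengths, and one-child
## species nodes only where some gene node maps. The simulator produces
## simple histories with strictly positive branch lengths and known ground
## truth, which the test suite reconciles back.

## ------------------------------------------------------- array form -----

## mutable array form of a history, convenient for surgery
.hist_arrays <- function(h) {
  rfg <- rooted_form(h$G); rfs <- rooted_form(h$S)
  nG <- tree_n(h$G); nS <- tree_n(h$S)
  glen <- vector("list", nG); slen <- vector("list", nS)
  for (v in seq_len(nG)) if (v != rfg$root) glen[[v]] <- rfg$plen[[v]]
  for (v in seq_len(nS)) if (v != rfs$root) slen[[v]] <- rfs$plen[[v]]
  list(gp = rfg$parent, glen = glen, glab = h$G$labels, groot = rfg$root,
       sp = rfs$parent, slen = slen, slab = h$S$labels, sroot = rfs$root,
       phi = h$phi,
       galive = rep(TRUE, nG), salive = rep(TRUE, nS))
}

.arrays_hist <- function(a, allow_zero = TRUE) {
  gids <- which(a$galive); sids <- which(a$salive)
  gmap <- integer(length(a$galive)); gmap[gids] <- seq_along(gids)
  smap <- integer(length(a$salive)); smap[sids] <- seq_along(sids)
  mk <- function(ids, map, parent, plen, labels, root) {
    edges <- NULL; lens <- list()
    for (v in ids) if (v != root) {
      edges <- rbind(edges, c(map[parent[v]], map[v]))
      lens[[length(lens) + 1L]] <- plen[[v]]
    }
    if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
    itree(labels[ids], edges, lens, rooted = TRUE, root = map[root],
          allow_zero = allow_zero)
  }
  G <- mk(gids, gmap, a$gp, a$glen, a$glab, a$groot)
  S <- mk(sids, smap, a$sp, a$slen, a$slab, a$sroot)
  history(G, S, smap[a$phi[gids]])
}

.children_of <- function(parent, alive, v)
  which(alive & parent == v & seq_along(parent) != v)

## ------------------------------------------------ event classification --

#' Extended inverse mapping of a species node
#'
#' The gene nodes mapping to \code{v} together with, for every gene edge
#' spanning \code{v} (child image strictly below, parent image strictly
#' above), the implicit point on that gene edge level with \code{v}.
#'
#' @param h an \code{iso_history}.
#' @param v a species node id.
#' @return list of gene tree points \code{list(node, h)}; \code{h = 0}
#'   entries are the members of the plain inverse mapping.
#' @export
extended_inverse <- function(h, v) {
  rfs <- rooted_form(h$S)
  rfg <- rooted_form(h$G)
  nS <- tree_n(h$S)
  depthS <- vector("list", nS); depthS[[rfs$root]] <- RAT0
  idep <- integer(nS)
  for (x in rfs$order) if (x != rfs$root) {
    depthS[[x]] <- rat_add(depthS[[rfs$parent[x]]], rfs$plen[[x]])
    idep[x] <- idep[rfs$parent[x]] + 1L
  }
  proper_anc <- function(a, b) {  # a proper ancestor of b (topological)
    if (a == b) return(FALSE)
    while (idep[b] > idep[a]) b <- rfs$parent[b]
    a == b
  }
  out <- list()
  for (g in seq_len(tree_n(h$G))) {
    if (h$phi[g] == v) { out[[length(out) + 1L]] <- tp(g); next }
    if (g == rfg$root) next
    p <- rfg$parent[g]
    if (proper_anc(v, h$phi[g]) && proper_anc(h$phi[p], v)) {
      d <- rat_sub(depthS[[h$phi[g]]], depthS[[v]])
      out[[length(out) + 1L]] <- tp(g, d)
    }
  }
  out
}

#' Classify a species node as an evolutionary event
#'
#' Returns the event class of node \code{v} in a history: "sample" (leaf),
#' "duplication" (one child, nonempty preimage, every preimage with two
#' children), "loss" (one child, nonempty preimage, every preimage a gene
#' leaf), "speciation" / "generalized_speciation" (two children, every
#' preimage splitting one child into each side; a strict speciation
#' additionally has no gene edge bypassing the node), or "other". A
#' "speciation" is also a generalized speciation.
#'
#' @param h an \code{iso_history}.
#' @param v species node id.
#' @return a character scalar.
#' @export
classify_species_node <- function(h, v) {
  rfs <- rooted_form(h$S)
  rfg <- rooted_form(h$G)
  kids <- rfs$children[[v]]
  pre <- which(h$phi == v)
  if (length(kids) == 0) return("sample")
  idep <- integer(tree_n(h$S))
  for (x in rfs$order) if (x != rfs$root) idep[x] <- idep[rfs$parent[x]] + 1L
  anc_or_self <- function(a, b) {
    while (idep[b] > idep[a]) b <- rfs$parent[b]
    a == b
  }
  if (length(kids) == 1) {
    if (length(pre) == 0) return("other")
    nk <- vapply(pre, function(u) length(rfg$children[[u]]), 0L)
    if (all(nk == 2L)) return("duplication")
    if (all(nk == 0L)) return("loss")
    return("other")
  }
  if (length(kids) == 2) {
    for (u in pre) {
      uk <- rfg$children[[u]]
      if (length(uk) != 2L) return("other")
      a1 <- anc_or_self(kids[1], h$phi[uk[1]]) && anc_or_self(kids[2], h$phi[uk[2]])
      a2 <- anc_or_self(kids[1], h$phi[uk[2]]) && anc_or_self(kids[2], h$phi[uk[1]])
      if (!a1 && !a2) return("other")
    }
    ext <- extended_inverse(h, v)
    strict <- length(ext) == length(pre)
    return(if (strict) "speciation" else "generalized_speciation")
  }
  "other"
}

## ----------------------------------------------------------- predicates --

.extant_leaves <- function(h) {
  rfg <- rooted_form(h$G); rfs <- rooted_form(h$S)
  gl <- which(vapply(seq_len(tree_n(h$G)),
                     function(v) length(rfg$children[[v]]) == 0L, TRUE))
  gl[vapply(gl, function(v) length(rfs$children[[h$phi[v]]]) == 0L, TRUE)]
}

#' Is a history inferable?
#'
#' An inferable history has strictly positive branch lengths, only
#' observable gene nodes (extant leaves, or nodes with at least two
#' children carrying extant descendants) and a nonempty preimage at every
#' one-child species node.
#' @param h an \code{iso_history}.
#' @return logical.
#' @export
is_inferable <- function(h) {
  for (l in c(h$G$elen, h$S$elen)) if (rat_sign(l) <= 0) return(FALSE)
  rfg <- rooted_form(h$G); rfs <- rooted_form(h$S)
  nG <- tree_n(h$G)
  extant <- logical(nG)
  ext_leaves <- .extant_leaves(h)
  extant[ext_leaves] <- TRUE
  ## observable: extant leaf, or >= 2 children with extant descendants
  has_ext <- logical(nG)
  for (v in rev(rfg$order)) {
    if (extant[v]) has_ext[v] <- TRUE
    for (k in rfg$children[[v]]) if (has_ext[k]) has_ext[v] <- TRUE
  }
  for (v in seq_len(nG)) {
    kids <- rfg$children[[v]]
    if (length(kids) == 0) { if (!extant[v]) return(FALSE) }
    else if (sum(vapply(kids, function(k) has_ext[k], TRUE)) < 2L) return(FALSE)
  }
  for (v in seq_len(tree_n(h$S))) {
    if (length(rfs$children[[v]]) == 1L && !any(h$phi == v)) return(FALSE)
  }
  TRUE
}

#' Does an inferable history admit a positive simple history?
#'
#' TRUE iff every species node classifies as a sample, a duplication or a
#' (generalized) speciation; exactly these inferable histories are the
#' inferable versions of simple histories with strictly positive branch
#' lengths.
#' @param h an inferable \code{iso_history}.
#' @return logical.
#' @export
admits_positive_simple <- function(h) {
  for (v in seq_len(tree_n(h$S))) {
    cl <- classify_species_node(h, v)
    if (!(cl %in% c("sample", "duplication", "speciation",
                    "generalized_speciation")))
      return(FALSE)
  }
  TRUE
}

## ------------------------------------------------- inferable version ----

#' Inferable version of a simple history
#'
#' Applies, in order: deletion of gene nodes with no extant descendant,
#' bypassing of one-child gene nodes, bypassing of one-child species nodes
#' with empty preimage, contraction of zero-length edges, and removal of
#' redundant one-child roots. This is the portion of a history that
#' reconciliation can recover from extant data.
#'
#' @param h an \code{iso_history} whose leaf edges have positive length.
#' @return an \code{iso_history} satisfying [is_inferable()].
#' @export
inferable_version <- function(h) {
  a <- .hist_arrays(h)
  nG <- length(a$gp); nS <- length(a$sp)
  rfs <- rooted_form(h$S)
  sleaf <- vapply(seq_len(nS), function(v) length(rfs$children[[v]]) == 0L, TRUE)
  ## 1: delete gene nodes with no extant leaf below
  rfg <- rooted_form(h$G)
  has_ext <- logical(nG)
  for (v in rev(rfg$order)) {
    if (length(rfg$children[[v]]) == 0L && sleaf[a$phi[v]]) has_ext[v] <- TRUE
    for (k in rfg$children[[v]]) if (has_ext[k]) has_ext[v] <- TRUE
  }
  a$galive <- has_ext
  ## 2: bypass one-child gene nodes (children among alive nodes)
  repeat {
    changed <- FALSE
    for (v in which(a$galive)) {
      kids <- .children_of(a$gp, a$galive, v)
      if (length(kids) == 1L && v != a$groot) {
        k <- kids
        a$glen[[k]] <- rat_add(a$glen[[k]], a$glen[[v]])
        a$gp[k] <- a$gp[v]
        a$galive[v] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ## 3: bypass one-child species nodes with empty preimage
  pre_nonempty <- function(v) any(a$phi[a$galive] == v)
  repeat {
    changed <- FALSE
    for (v in which(a$salive)) {
      kids <- .children_of(a$sp, a$salive, v)
      if (length(kids) == 1L && v != a$sroot && !pre_nonempty(v)) {
        k <- kids
        a$slen[[k]] <- rat_add(a$slen[[k]], a$slen[[v]])
        a$sp[k] <- a$sp[v]
        a$salive[v] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ## 4: contract zero-length edges (merge child into parent)
  repeat {
    changed <- FALSE
    for (v in which(a$salive)) {
      if (v == a$sroot || rat_sign(a$slen[[v]]) != 0) next
      p <- a$sp[v]
      for (k in .children_of(a$sp, a$salive, v)) a$sp[k] <- p
      a$phi[a$phi == v] <- p
      a$salive[v] <- FALSE
      changed <- TRUE
    }
    for (v in which(a$galive)) {
      if (v == a$groot || rat_sign(a$glen[[v]]) != 0) next
      p <- a$gp[v]
      for (k in .children_of(a$gp, a$galive, v)) a$gp[k] <- p
      a$galive[v] <- FALSE
      changed <- TRUE
    }
    if (!changed) break
  }
  ## 5: drop one-child gene roots
  repeat {
    kids <- .children_of(a$gp, a$galive, a$groot)
    if (a$galive[a$groot] && length(kids) == 1L) {
      a$galive[a$groot] <- FALSE
      a$groot <- kids
    } else break
  }
  ## 6: drop one-child, empty-preimage species roots
  repeat {
    kids <- .children_of(a$sp, a$salive, a$sroot)
    if (a$salive[a$sroot] && length(kids) == 1L && !pre_nonempty(a$sroot)) {
      a$salive[a$sroot] <- FALSE
      a$sroot <- kids
    } else break
  }
  .arrays_hist(a, allow_zero = FALSE)
}

## ------------------------------------------------------- derive input ---

## unroot a rooted tree: bypass a two-child root (merging its edges); a
## root with three or more children becomes an ordinary internal node
.unroot_tree <- function(t) {
  if (!t$rooted) return(t)
  rf <- rooted_form(t)
  kids <- rf$children[[rf$root]]
  if (length(kids) <= 1 && tree_n(t) > 1)
    stop("cannot unroot: root has a single child")
  if (length(kids) == 2) {
    a <- kids[1]; b <- kids[2]
    newlen <- rat_add(rf$plen[[a]], rf$plen[[b]])
    keep <- which(!(t$edge[, 1] == rf$root | t$edge[, 2] == rf$root))
    edges <- rbind(t$edge[keep, , drop = FALSE], c(a, b))
    lens <- c(t$elen[keep], list(newlen))
    labels <- t$labels[-rf$root]
    remap <- integer(tree_n(t)); remap[-rf$root] <- seq_len(tree_n(t) - 1L)
    edges <- matrix(remap[edges], ncol = 2)
    return(itree(labels, edges, lens, rooted = FALSE))
  }
  t$rooted <- FALSE; t$root <- NA_integer_
  t
}

#' Derive a reconciliation input from a history
#'
#' Produces the input partial history that, fed back to the matching
#' reconciliation algorithm, recovers the history: the species tree with
#' all one-child nodes bypassed (and any one-child root chain removed), the
#' gene tree (optionally unrooted), and the leaf map read off the mapping.
#'
#' @param h an inferable \code{iso_history}.
#' @param unroot_gene,unroot_species unroot the respective tree?
#' @return an \code{iph}.
#' @export
derive_input <- function(h, unroot_gene = FALSE, unroot_species = FALSE) {
  a <- .hist_arrays(h)
  ## bypass all one-child species nodes; drop one-child root chain
  repeat {
    kids <- .children_of(a$sp, a$salive, a$sroot)
    if (length(kids) == 1L) { a$salive[a$sroot] <- FALSE; a$sroot <- kids }
    else break
  }
  repeat {
    changed <- FALSE
    for (v in which(a$salive)) {
      kids <- .children_of(a$sp, a$salive, v)
      if (length(kids) == 1L && v != a$sroot) {
        k <- kids
        a$slen[[k]] <- rat_add(a$slen[[k]], a$slen[[v]])
        a$sp[k] <- a$sp[v]
        a$salive[v] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  hh <- .arrays_hist(a, allow_zero = FALSE)
  S_I <- hh$S; G_I <- hh$G
  gl <- tree_leaves(G_I)
  mu <- stats::setNames(S_I$labels[hh$phi[gl]], G_I$labels[gl])
  class(mu) <- "leafmap"
  if (unroot_gene && tree_n(G_I) > 1) G_I <- .unroot_tree(G_I)
  if (unroot_species && tree_n(S_I) > 1) S_I <- .unroot_tree(S_I)
  input_history(G_I, S_I, mu)
}

## ------------------------------------------------------------ equality --

## canonical key of every node: sorted descendant leaf labels plus exact
## depth (unique in trees without one-child chains at equal depth)
.node_keys <- function(t) {
  rf <- rooted_form(t)
  n <- tree_n(t)
  depth <- vector("list", n); depth[[rf$root]] <- RAT0
  for (v in rf$order) if (v != rf$root)
    depth[[v]] <- rat_add(depth[[rf$parent[v]]], rf$plen[[v]])
  ls <- vector("list", n)
  for (v in rev(rf$order)) {
    kids <- rf$children[[v]]
    if (length(kids) == 0) ls[[v]] <- t$labels[v]
    else ls[[v]] <- sort(unique(unlist(ls[kids])))
  }
  vapply(seq_len(n), function(v)
    paste0(paste(ls[[v]], collapse = ","), "|", rat_format(depth[[v]])), "")
}

#' Structural equality of two histories
#'
#' Compares gene trees and species trees node-for-node (topology and exact
#' branch lengths, ignoring generated internal labels) and the mappings
#' through canonical node identities (descendant leaf set plus exact
#' depth).
#' @param h1,h2 histories.
#' @return logical.
#' @export
history_equal <- function(h1, h2) {
  if (!tree_equal(h1$G, h2$G) || !tree_equal(h1$S, h2$S)) return(FALSE)
  gk1 <- .node_keys(h1$G); gk2 <- .node_keys(h2$G)
  sk1 <- .node_keys(h1$S); sk2 <- .node_keys(h2$S)
  m1 <- sort(paste0(gk1, " -> ", sk1[h1$phi]))
  m2 <- sort(paste0(gk2, " -> ", sk2[h2$phi]))
  identical(m1, m2)
}

## ------------------------------------------------------------ simulator --

#' Simulation parameters
#'
#' @param n_species number of extant species (>= 1).
#' @param dup_rate,loss_rate duplication and loss rates per gene lineage
#'   per unit branch length (Poisson events).
#' @param seed integer seed fixing all randomness.
#' @param min_genes minimum number of surviving extant gene copies; the
#'   simulator resamples (bounded retries) until satisfied.
#' @param max_genes optional cap on extant gene copies (resample guard).
#' @param mode "ultrametric" for clock-like species trees (all leaves at the
#'   same depth) or "jitter" for unequal leaf depths.
#' @param stem length of the stem branch above the first speciation, on
#'   which pre-speciation duplications and losses may occur.
#' @param retries resampling budget.
#' @return a \code{sim_params} list.
#' @export
sim_params <- function(n_species = 5, dup_rate = 0.3, loss_rate = 0.3,
                       seed = 1L, min_genes = 3L, max_genes = Inf,
                       mode = c("ultrametric", "jitter"),
                       stem = rat(1, 2), retries = 200L) {
  mode <- match.arg(mode)
  if (dup_rate < 0 || loss_rate < 0) stop("rates must be nonnegative")
  if (n_species < 1) stop("need at least one species")
  p <- list(n_species = as.integer(n_species), dup_rate = dup_rate,
            loss_rate = loss_rate, seed = as.integer(seed),
            min_genes = as.integer(min_genes), max_genes = max_genes,
            mode = mode, stem = stem, retries = as.integer(retries))
  class(p) <- "sim_params"
  p
}

## event time grid: all times are rationals with denominator dividing 64
.GRID <- 64

#' Simulate a simple history of gene family evolution
#'
#' Generates a species tree by a random birth process with dyadic-rational
#' split times, then evolves gene lineages from a single ancestral copy
#' down the species tree: at every speciation each lineage splits into both
#' daughter species; along every branch each lineage independently
#' experiences Poisson duplication and loss events at dyadic times. Every
#' duplication and loss inserts a dedicated one-child node into the species
#' tree at its exact time, so each species-tree node is a single event and
#' the resulting history is simple with strictly positive branch lengths.
#' The full mapping is recorded exactly; the output is deterministic under
#' the seed.
#'
#' @param p a [sim_params()] object.
#' @return an \code{iso_history} (simple, positive lengths). Species leaves
#'   are labeled a, b, ...; extant genes a1, a2, ...; loss leaves loss1,
#'   ...; duplication/loss species nodes e1, ....
#' @export
simulate_simple_history <- function(p) {
  set.seed(p$seed)
  for (attempt in seq_len(p$retries)) {
    h <- .sim_once(p)
    ng <- length(.extant_leaves(h))
    if (ng >= p$min_genes && ng <= p$max_genes) return(h)
  }
  stop("simulation retry budget exhausted (guards too strict?)")
}

.sim_once <- function(p) {
  n <- p$n_species
  sp_lab <- if (n <= 26) letters[seq_len(n)] else paste0("s", seq_len(n))
  if (n == 1) {
    G <- itree(paste0(sp_lab, 1), matrix(integer(0), ncol = 2), list(),
               rooted = TRUE, root = 1L)
    S <- itree(sp_lab, matrix(integer(0), ncol = 2), list(),
               rooted = TRUE, root = 1L)
    return(history(G, S, 1L))
  }
  ## ---- species base tree (random birth process, dyadic times)
  bt_parent <- integer(0); bt_time <- list(); bt_leaf <- logical(0)
  newb <- function(parent, time, leaf) {
    bt_parent[length(bt_parent) + 1L] <<- parent
    bt_time[[length(bt_time) + 1L]] <<- time
    bt_leaf[length(bt_leaf) + 1L] <<- leaf
    length(bt_parent)
  }
  root <- newb(0L, RAT0, FALSE)
  lineages <- c(root, root)  # open branches, identified by their top node
  t_cur <- RAT0
  while (length(lineages) < n) {
    t_cur <- rat_add(t_cur, rat(sample.int(8L, 1L), 8))
    i <- sample.int(length(lineages), 1L)
    v <- newb(lineages[i], t_cur, FALSE)
    lineages <- c(lineages[-i], v, v)
  }
  T_end <- rat_add(t_cur, rat(sample.int(8L, 1L), 8))
  leaf_ids <- integer(n)
  repeat {
    times <- vector("list", n)
    for (i in seq_len(n)) {
      times[[i]] <- if (p$mode == "ultrametric") T_end
      else rat_add(T_end, rat(sample.int(8L, 1L) - 1L, 8))
    }
    if (p$mode == "ultrametric") break
    ## non-ultrametric mode must have at least two unequal leaf depths
    if (any(!vapply(times, function(x) rat_eq(x, times[[1]]), TRUE))) break
  }
  for (i in seq_len(n)) leaf_ids[i] <- newb(lineages[i], times[[i]], TRUE)
  B <- length(bt_parent)
  bchildren <- vector("list", B)
  for (v in seq_len(B)) if (bt_parent[v] > 0)
    bchildren[[bt_parent[v]]] <- c(bchildren[[bt_parent[v]]], v)
  ## ---- gene evolution
  rate <- p$dup_rate + p$loss_rate
  pdup <- if (rate > 0) p$dup_rate / rate else 0
  used <- vector("list", B)       # used event grid positions per branch
  events <- vector("list", B)     # per branch: matrix rows (grid, type)
  gp <- integer(0); gtime <- list(); gkey <- list(); gleaf <- logical(0)
  newg <- function(parent, time, key, leaf = FALSE) {
    gp[length(gp) + 1L] <<- parent
    gtime[[length(gtime) + 1L]] <<- time
    gkey[[length(gkey) + 1L]] <<- key
    gleaf[length(gleaf) + 1L] <<- leaf
    length(gp)
  }
  evolve <- function(gparent, t_start, cbase) {
    t1 <- bt_time[[cbase]]
    g_lo <- t_start[1] * (.GRID / t_start[2])      # exact: dyadic grid
    g_hi <- t1[1] * (.GRID / t1[2])
    g <- g_lo + 1
    if (rate > 0) {
      w <- stats::rexp(1L, rate)
      g <- max(g, floor((rat_to_double(t_start) + w) * .GRID) + 1)
    } else g <- g_hi  # no events
    while (g < g_hi && g %in% used[[cbase]]) g <- g + 1
    if (rate > 0 && g < g_hi) {
      ## event strictly inside the branch
      used[[cbase]] <<- c(used[[cbase]], g)
      type <- if (stats::runif(1L) < pdup) "dup" else "loss"
      te <- rat(g, .GRID)
      ge <- newg(gparent, te, list(kind = "event", branch = cbase, grid = g),
                 leaf = (type == "loss"))
      events[[cbase]] <<- rbind(events[[cbase]], c(g, if (type == "dup") 1 else 0))
      if (type == "dup") {
        evolve(ge, te, cbase)
        evolve(ge, te, cbase)
      }
      return(invisible(NULL))
    }
    ## reached the base node at the bottom of the branch
    gv <- newg(gparent, t1, list(kind = "base", node = cbase),
               leaf = bt_leaf[cbase])
    if (!bt_leaf[cbase])
      for (cb in bchildren[[cbase]]) evolve(gv, t1, cb)
    invisible(NULL)
  }
  evolve(0L, rat_neg(p$stem), root)
  ## ---- assemble the species tree with event nodes
  slab <- character(0); sparent <- integer(0); stime <- list()
  news <- function(parent, time, lab) {
    sparent[length(sparent) + 1L] <<- parent
    stime[[length(stime) + 1L]] <<- time
    slab[length(slab) + 1L] <<- lab
    length(sparent)
  }
  base_sid <- integer(B)
  nint <- 0L; nev <- 0L; nleaf <- 0L
  ev_sid <- new.env(parent = emptyenv())
  for (v in seq_len(B)) {   # creation order is deterministic
    lab <- if (bt_leaf[v]) { nleaf <- nleaf + 1L; sp_lab[nleaf] }
    else { nint <- nint + 1L; paste0("n", nint) }
    base_sid[v] <- news(0L, bt_time[[v]], lab)
  }
  sroot <- base_sid[root]
  for (v in seq_len(B)) {
    evs <- events[[v]]
    prev <- if (v == root) 0L else base_sid[bt_parent[v]]
    first_ev <- 0L
    if (!is.null(evs)) {
      o <- order(evs[, 1])
      for (gidx in evs[o, 1]) {
        nev <- nev + 1L
        sid <- news(prev, rat(gidx, .GRID), paste0("e", nev))
        assign(paste0(v, "_", gidx), sid, envir = ev_sid)
        if (first_ev == 0L) first_ev <- sid
        prev <- sid
      }
    }
    sparent[base_sid[v]] <- prev
    ## stem events become a chain of ancestors of the first speciation; the
    ## earliest event is the new species root
    if (v == root && first_ev != 0L) sroot <- first_ev
  }
  nS <- length(sparent)
  ## ---- gene tree arrays -> itree
  nG <- length(gp)
  phi <- integer(nG)
  gcount <- integer(B)
  glabels <- rep(NA_character_, nG)
  nloss <- 0L
  for (v in seq_len(nG)) {
    k <- gkey[[v]]
    if (k$kind == "base") phi[v] <- base_sid[k$node]
    else phi[v] <- get(paste0(k$branch, "_", k$grid), envir = ev_sid)
    if (gleaf[v]) {
      if (k$kind == "base") {
        gcount[k$node] <- gcount[k$node] + 1L
        glabels[v] <- paste0(slab[base_sid[k$node]], gcount[k$node])
      } else { nloss <- nloss + 1L; glabels[v] <- paste0("loss", nloss) }
    }
  }
  gedges <- NULL; glens <- list()
  for (v in seq_len(nG)) if (gp[v] != 0L) {
    gedges <- rbind(gedges, c(gp[v], v))
    glens[[length(glens) + 1L]] <- rat_sub(gtime[[v]], gtime[[gp[v]]])
  }
  if (is.null(gedges)) gedges <- matrix(integer(0), ncol = 2)
  groot <- which(gp == 0L)
  G <- itree(glabels, gedges, glens, rooted = TRUE, root = groot)
  sedges <- NULL; slens <- list()
  for (v in seq_len(nS)) if (sparent[v] != 0L) {
    sedges <- rbind(sedges, c(sparent[v], v))
    slens[[length(slens) + 1L]] <- rat_sub(stime[[v]], stime[[sparent[v]]])
  }
  S <- itree(slab, sedges, slens, rooted = TRUE, root = sroot)
  history(G, S, phi)
}

## ------------------------------------------------- expand to simple -----

## minimum leaf label below each node of an array-form tree (NA-free for
## trees whose leaves are all labeled)
.arr_min_leaf <- function(parent, alive, labels, v) {
  kids <- .children_of(parent, alive, v)
  if (length(kids) == 0) return(labels[v])
  min(vapply(kids, function(k) .arr_min_leaf(parent, alive, labels, k), ""))
}

#' Expand an inferable history into a simple history
#'
#' Converts every species node that aggregates several simultaneous events
#' into a chain of single events: a one-child node whose preimages have up
#' to k children becomes a chain of k - 1 duplications connected by
#' zero-length edges; a node with g >= 2 children becomes g - 1 chained
#' speciations, with loss leaves added for gene lineages missing on a side,
#' duplication chains for lineages with several children on one side, and
#' explicit nodes inserted on gene edges that bypass the node. The result
#' is a simple history (possibly with zero-length edges) whose
#' [inferable_version()] is the input.
#'
#' @param h an inferable \code{iso_history}.
#' @return an \code{iso_history} in which every species node classifies as
#'   a sample, speciation, duplication or loss.
#' @export
expand_to_simple <- function(h) {
  a <- .hist_arrays(h)
  orig_order <- rooted_form(h$S)$order
  addg <- function(parent, len, lab, phiv) {
    a$gp[length(a$gp) + 1L] <<- parent
    a$glen[[length(a$glen) + 1L]] <<- len
    a$glab[length(a$glab) + 1L] <<- lab
    a$phi[length(a$phi) + 1L] <<- phiv
    a$galive[length(a$galive) + 1L] <<- TRUE
    length(a$gp)
  }
  adds <- function(parent, len, lab) {
    a$sp[length(a$sp) + 1L] <<- parent
    a$slen[[length(a$slen) + 1L]] <<- len
    a$slab[length(a$slab) + 1L] <<- lab
    a$salive[length(a$salive) + 1L] <<- TRUE
    length(a$sp)
  }
  nloss <- 0L; nE <- 0L
  fresh_loss <- function() { nloss <<- nloss + 1L; paste0("xloss", nloss) }
  fresh_E <- function() { nE <<- nE + 1L; paste0("E", nE) }
  s_anc_or_self <- function(x, y) {  # x ancestor-or-self of y (current)
    while (y != 0L) { if (y == x) return(TRUE); y <- a$sp[y] }
    FALSE
  }
  s_dist <- function(anc, desc) {    # exact distance along current S
    d <- RAT0; y <- desc
    while (y != anc) { d <- rat_add(d, a$slen[[y]]); y <- a$sp[y] }
    d
  }
  gkids_sorted <- function(u) {
    kids <- .children_of(a$gp, a$galive, u)
    if (length(kids) <= 1) return(kids)
    kids[order(vapply(kids, function(k)
      .arr_min_leaf(a$gp, a$galive, a$glab, k), ""))]
  }
  for (v in orig_order) {
    kids <- .children_of(a$sp, a$salive, v)
    g <- length(kids)
    if (g == 0) next
    U <- which(a$galive & a$phi == v)
    if (g == 1) {
      ells <- vapply(U, function(u) length(.children_of(a$gp, a$galive, u)), 0L)
      k <- max(ells)
      if (all(ells == 2L)) next
      vch <- v
      for (t in seq_len(k - 2L)) vch <- c(vch, adds(vch[length(vch)], RAT0, fresh_E()))
      if (k > 2L) a$sp[kids] <- vch[k - 1L]
      for (ui in seq_along(U)) {
        u <- U[ui]; l <- ells[ui]
        if (l == 2L) next
        uch <- u
        for (t in 2:(l - 1L)) uch <- c(uch, addg(uch[t - 1L], RAT0, NA_character_, vch[t]))
        cs <- gkids_sorted(u)
        for (t in seq_len(l - 1L)) a$gp[cs[t]] <- uch[t]
        a$gp[cs[l]] <- uch[l - 1L]
      }
      next
    }
    ## g >= 2: order sides by the smallest species leaf below
    kids <- kids[order(vapply(kids, function(k)
      .arr_min_leaf(a$sp, a$salive, a$slab, k), ""))]
    side_of <- function(x) {
      for (j in seq_len(g)) if (s_anc_or_self(kids[j], x)) return(j)
      stop("internal: image not below any child")
    }
    grp <- lapply(U, function(u) {
      gs <- lapply(seq_len(g), function(j) integer(0))
      for (gc in .children_of(a$gp, a$galive, u)) {
        j <- side_of(a$phi[gc])
        gs[[j]] <- c(gs[[j]], gc)
      }
      gs
    })
    X <- integer(0)
    for (x in which(a$galive)) {
      if (a$phi[x] == v || a$gp[x] == 0L) next
      px <- a$gp[x]
      if (s_anc_or_self(v, a$phi[x]) && a$phi[x] != v &&
          s_anc_or_self(a$phi[px], v) && a$phi[px] != v)
        X <- c(X, x)
    }
    proper <- all(vapply(seq_along(U), function(ui)
      all(vapply(grp[[ui]], length, 0L) == 1L), TRUE))
    if (g == 2 && length(X) == 0 && proper) next
    ## species chain of g-1 speciation nodes
    vch <- v
    for (t in seq_len(g - 2L)) vch <- c(vch, adds(vch[length(vch)], RAT0, fresh_E()))
    for (i in seq_len(g)) a$sp[kids[i]] <- vch[min(i, g - 1L)]
    edge_len0 <- lapply(seq_len(g), function(j) a$slen[[kids[j]]])
    half <- lapply(edge_len0, rat_half)
    lossnode <- integer(g)          # shared loss node per side
    dupchain <- vector("list", g)   # shared duplication chain per side
    zbc <- kids                     # insertion anchor for chain extension
    insert_above <- function(x, hh) {
      nd <- adds(a$sp[x], rat_sub(a$slen[[x]], hh), fresh_E())
      a$sp[x] <<- nd
      a$slen[[x]] <<- hh
      nd
    }
    get_loss_node <- function(j) {
      if (lossnode[j] == 0L) {
        lossnode[j] <<- insert_above(kids[j], half[[j]])
        zbc[j] <<- lossnode[j]
      }
      lossnode[j]
    }
    ensure_chain <- function(j, m) {
      while (length(dupchain[[j]]) < m) {
        nd <- insert_above(zbc[j], a$slen[[zbc[j]]])
        dupchain[[j]] <<- c(dupchain[[j]], nd)
      }
    }
    expand_u <- function(u, groups) {
      uch <- u
      for (t in seq_len(g - 2L))
        uch <- c(uch, addg(uch[length(uch)], RAT0, NA_character_, vch[t + 1L]))
      for (j in seq_len(g)) {
        host <- uch[min(j, g - 1L)]
        cs <- groups[[j]]
        l <- length(cs)
        if (l == 1L) a$gp[cs] <- host
        else if (l == 0L) {
          ln <- get_loss_node(j)
          addg(host, half[[j]], fresh_loss(), ln)
        } else {
          ensure_chain(j, l - 1L)
          wprev <- host
          wch <- integer(0)
          for (t in seq_len(l - 1L)) {
            wprev <- addg(wprev, RAT0, NA_character_, dupchain[[j]][t])
            wch <- c(wch, wprev)
          }
          cs <- cs[order(vapply(cs, function(k)
            .arr_min_leaf(a$gp, a$galive, a$glab, k), ""))]
          for (t in seq_len(l - 1L)) a$gp[cs[t]] <- wch[t]
          a$gp[cs[l]] <- wch[l - 1L]
        }
      }
    }
    for (ui in seq_along(U)) expand_u(U[ui], grp[[ui]])
    for (x in X) {
      hx <- s_dist(v, a$phi[x])
      j <- side_of(a$phi[x])
      P <- a$gp[x]; L <- a$glen[[x]]
      u1 <- addg(P, rat_sub(L, hx), NA_character_, v)
      groups <- lapply(seq_len(g), function(jj) integer(0))
      a$gp[x] <- u1      # provisionally; expand-style chain below
      a$glen[[x]] <- hx
      groups[[j]] <- x
      ## reuse the u-expansion with u1 as the chain head
      expand_u(u1, groups)
    }
  }
  .arrays_hist(a, allow_zero = TRUE)
}
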