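## Assembly of the full solution set for doubly-unrooted inputs:
## fixed-root runs at internal species nodes and at discovered interval
## boundaries, parametric histories on the open intervals, instantiation of
## parametric histories at concrete root offsets, and merging of adjacent
## agreeing solutions into maximal root-position sets.

#' Rooted version of an unrooted species tree
#'
#' Roots the tree either at an internal node or at offset \code{rho}
#' inside edge \code{ei} (measured from \code{edge[ei, 1]}), subdividing
#' the edge by a new root node.
#' @param S unrooted \code{itree}.
#' @param ei species edge index (edge rooting).
#' @param rho rational offset strictly inside the edge.
#' @param node internal node id (node rooting).
#' @param label label for the new root node.
#' @return a rooted \code{itree}.
#' @export
root_species_at <- function(S, ei = NULL, rho = NULL, node = NULL,
                             label = "R") {
  if (!is.null(node)) {
    S$rooted <- TRUE; S$root <- as.integer(node)
    return(S)
  }
  a <- S$edge[ei, 1]; b <- S$edge[ei, 2]
  len <- S$elen[[ei]]
  if (rat_sign(rho) <= 0 || rat_cmp(rho, len) >= 0)
    stop("root offset outside the edge")
  lab <- if (label %in% S$labels) .fresh_labels(1L, S$labels, base = label) else label
  labels <- c(S$labels, lab)
  r <- length(labels)
  keep <- setdiff(seq_len(nrow(S$edge)), ei)
  edges <- rbind(S$edge[keep, , drop = FALSE], c(r, a), c(r, b))
  lens <- c(S$elen[keep], list(rho), list(rat_sub(len, rho)))
  itree(labels, edges, lens, rooted = TRUE, root = r)
}

## canonicalize a tree point against a rooted form (climb when h reaches
## the parent edge length; used by boundary-limit instantiation)
.tp_canon <- function(rf, p) {
  while (p$node != rf$root && rat_cmp(p$h, rf$plen[[p$node]]) >= 0) {
    if (rat_cmp(p$h, rf$plen[[p$node]]) > 0) stop("point beyond its edge")
    p <- tp(rf$parent[p$node])
  }
  p
}

#' Instantiate a parametric history at a concrete root offset
#'
#' Substitutes the root position \code{rho} (strictly inside the
#' parametric history's interval), roots the species tree there,
#' materializes the implied nodes and returns a concrete verified history.
#'
#' @param ph a \code{param_history} from [simulate_interval()].
#' @param rho rational offset of the root from the edge's first endpoint.
#' @param boundary allow \code{rho} on the interval boundary and normalize
#'   degenerate (coincident) points; used to compute one-sided limits.
#' @return an \code{iso_history}.
#' @export
evaluate_at <- function(ph, rho, boundary = FALSE) {
  ctx <- ph$ctx; gp <- ph$gp
  inside <- rat_cmp(rho, ph$lo) > 0 && rat_cmp(rho, ph$hi) < 0
  at_bound <- rat_eq(rho, ph$lo) || rat_eq(rho, ph$hi)
  if (!inside && !(boundary && at_bound))
    stop("rho outside the parametric history's interval")
  if (rat_sign(rho) <= 0 || rat_cmp(rho, ctx$L) >= 0)
    stop("rho must be strictly inside the species edge")
  Srho <- root_species_at(ctx$S, ei = ctx$ei, rho = rho)
  R <- tree_n(Srho)
  rfS <- rooted_form(Srho)
  conv <- function(pp) {
    if (pp$k == "p") {
      e <- lf_eval(pp$lf, rho)
      if (rat_sign(e) < 0) stop("negative parametric height at rho")
      return(tp(R, e))
    }
    side <- if (pp$side == 1L) ctx$A else ctx$B
    pt <- pp$pt
    if (pt$node == side$idx$rf$root && rat_sign(pt$h) > 0) {
      base <- if (pp$side == 1L) ctx$xa else ctx$xb
      lim <- if (pp$side == 1L) rho else rat_sub(ctx$L, rho)
      if (rat_cmp(pt$h, lim) > 0) stop("fixed point above the root at rho")
      return(.tp_canon(rfS, tp(base, pt$h)))
    }
    tp(side$l2g[pt$node], pt$h)
  }
  images <- lapply(ph$images, conv)
  if (ph$root$type == "edge") {
    off <- lf_eval(ph$root$cand$offset, rho)
    ei <- ph$root$ei
    a <- gp$G$edge[ei, 1]; b <- gp$G$edge[ei, 2]
    len <- gp$G$elen[[ei]]
    if (rat_sign(off) == 0 || rat_eq(off, len)) {
      if (!boundary) stop("degenerate root offset inside the interval")
      rootnode <- if (rat_sign(off) == 0) a else b
      G <- gp$G; G$rooted <- TRUE; G$root <- as.integer(rootnode)
    } else {
      rooted <- .root_inside_edge(gp$G, ei, a, off)
      G <- rooted$G
      images[[rooted$q]] <- conv(ph$root$cand$q)
    }
  } else {
    G <- gp$G; G$rooted <- TRUE; G$root <- as.integer(ph$root$node)
  }
  mat <- materialize_species_tree(Srho, images)
  h <- history(G, mat$S, mat$ids)
  if (!boundary) {
    chk <- verify_isometric(h)
    if (!chk$ok) stop("internal: instantiated parametric history not isometric")
  }
  h
}

## one-sided limit of a parametric history at an interval boundary,
## normalized (zero-length edges contracted); NULL when degenerate beyond
## repair
.limit_history <- function(ph, rho) {
  h <- tryCatch(evaluate_at(ph, rho, boundary = TRUE), error = function(e) NULL)
  if (is.null(h)) return(NULL)
  a <- .hist_arrays(h)
  ## contract zero-length edges (coincident points in the limit)
  repeat {
    changed <- FALSE
    for (v in which(a$salive)) {
      if (v == a$sroot || rat_sign(a$slen[[v]]) != 0) next
      p <- a$sp[v]
      for (k in .children_of(a$sp, a$salive, v)) a$sp[k] <- p
      a$phi[a$phi == v] <- p
      a$salive[v] <- FALSE; changed <- TRUE
    }
    for (v in which(a$galive)) {
      if (v == a$groot || rat_sign(a$glen[[v]]) != 0) next
      p <- a$gp[v]
      for (k in .children_of(a$gp, a$galive, v)) a$gp[k] <- p
      a$galive[v] <- FALSE; changed <- TRUE
    }
    if (!changed) break
  }
  ## drop a redundant species root chain introduced by rooting exactly at
  ## the topmost image boundary
  repeat {
    kids <- .children_of(a$sp, a$salive, a$sroot)
    if (length(kids) == 1L && !any(a$phi[a$galive] == a$sroot)) {
      a$salive[a$sroot] <- FALSE; a$sroot <- kids
    } else break
  }
  tryCatch(.arrays_hist(a, allow_zero = FALSE), error = function(e) NULL)
}

#' Reconciliation when both the gene tree and the species tree are unrooted
#'
#' Enumerates all root positions of the species tree: every internal node
#' (exact fixed-root run), every discovered interval boundary inside an
#' edge (exact fixed-root run after subdividing), and every open interval
#' between boundaries (parametric run). Adjacent accepted intervals and
#' boundary points whose reconciliations agree in the limit are merged
#' into maximal root-position sets, so answers like "any root in [1, 4)"
#' are reported as one set.
#'
#' @param iph input partial history, both trees unrooted.
#' @param instrument optional environment for split-count instrumentation
#'   (see [simulate_interval()]).
#' @return an object of class \code{solution_set} with components
#'   \code{nodes} (per internal species node) and \code{edges} (per
#'   species edge: pieces, boundaries, merged accepted sets).
#' @export
reconcile_both_unrooted <- function(iph, instrument = NULL) {
  if (iph$G$rooted || iph$S$rooted)
    stop("reconcile_both_unrooted requires both trees unrooted")
  bad <- validate_input(iph)
  if (length(bad) > 0) stop("invalid input: ", paste(bad, collapse = "; "))
  G <- iph$G; S <- iph$S; mu <- iph$mu
  out <- list(nodes = list(), edges = list())
  class(out) <- "solution_set"
  if (tree_n(S) == 1) {
    Sx <- S; Sx$rooted <- TRUE; Sx$root <- 1L
    res <- .run_fixed(G, Sx, mu)
    out$nodes[[1]] <- list(node = 1L, label = S$labels[1], result = res)
    return(out)
  }
  deg <- tree_degree(S)
  for (v in which(deg >= 3L)) {
    Sx <- root_species_at(S, node = v)
    res <- .run_fixed(G, Sx, mu)
    out$nodes[[length(out$nodes) + 1L]] <-
      list(node = v, label = S$labels[v], result = res)
  }
  gp <- .gene_prep(G, S, mu)
  for (ei in seq_len(nrow(S$edge))) {
    ctx <- .make_edge_ctx(S, ei)
    sim <- .simulate_edge(ctx, gp, RAT0, ctx$L, instrument)
    boundaries <- list()
    for (rho in sim$endpoints) {
      Sx <- root_species_at(S, ei = ei, rho = rho)
      res <- .run_fixed(G, Sx, mu)
      boundaries[[length(boundaries) + 1L]] <- list(rho = rho, result = res)
    }
    merged <- .merge_edge_solutions(sim$pieces, boundaries)
    out$edges[[ei]] <- list(ei = ei,
                            ends = c(S$labels[S$edge[ei, 1]],
                                     S$labels[S$edge[ei, 2]]),
                            L = ctx$L, pieces = sim$pieces,
                            boundaries = boundaries, merged = merged)
  }
  out
}

## fixed-root run of the unrooted-gene algorithm against a rooted species
## tree, without re-validating the (already validated) input
.run_fixed <- function(G, Sx, mu) {
  reconcile_unrooted_gene(input_history(G, Sx, mu))
}

## merge adjacent accepted pieces and interior boundary points whose
## histories agree in the limit
.merge_edge_solutions <- function(pieces, boundaries) {
  bmap <- list()
  for (b in boundaries) bmap[[paste0(b$rho[1], "/", b$rho[2])]] <- b
  runs <- list()
  cur <- NULL
  close_run <- function() {
    if (!is.null(cur)) runs[[length(runs) + 1L]] <<- cur
    cur <<- NULL
  }
  matches_boundary <- function(piece, rho) {
    key <- paste0(rho[1], "/", rho[2])
    b <- bmap[[key]]
    if (is.null(b) || b$result$status != "reconciled") return(FALSE)
    lim <- .limit_history(piece$ph, rho)
    !is.null(lim) && history_equal(lim, b$result$history)
  }
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    if (!is.null(p$reject)) { close_run(); next }
    lo_closed <- matches_boundary(p, p$lo)
    if (is.null(cur)) {
      cur <- list(lo = p$lo, lo_closed = lo_closed, hi = p$hi,
                  hi_closed = FALSE)
    } else {
      if (lo_closed) { cur$hi <- p$hi } else {
        close_run()
        cur <- list(lo = p$lo, lo_closed = FALSE, hi = p$hi,
                    hi_closed = FALSE)
      }
    }
    hi_closed <- matches_boundary(p, p$hi)
    cur$hi_closed <- hi_closed
    if (!hi_closed) close_run()
  }
  close_run()
  ## lone accepted boundary points not attached to any run
  attached <- function(rho) {
    for (r in runs) {
      if ((r$lo_closed && rat_eq(r$lo, rho)) ||
          (r$hi_closed && rat_eq(r$hi, rho))) return(TRUE)
      if (rat_cmp(r$lo, rho) < 0 && rat_cmp(rho, r$hi) < 0) return(TRUE)
    }
    FALSE
  }
  for (b in boundaries) {
    if (b$result$status == "reconciled" && !attached(b$rho))
      runs[[length(runs) + 1L]] <- list(lo = b$rho, lo_closed = TRUE,
                                        hi = b$rho, hi_closed = TRUE)
  }
  runs
}

#' Does the solution set accept a given root position?
#'
#' @param ss a \code{solution_set}.
#' @param edge species edge index (or NULL when querying a node rooting).
#' @param rho rational offset from the edge's first endpoint; 0 and the
#'   edge length refer to the endpoint nodes.
#' @param node species node id for node rootings.
#' @return logical.
#' @export
solution_accepts <- function(ss, edge = NULL, rho = NULL, node = NULL) {
  if (!is.null(node)) {
    for (nd in ss$nodes)
      if (nd$node == node) return(nd$result$status == "reconciled")
    return(FALSE)
  }
  e <- ss$edges[[edge]]
  if (rat_sign(rho) == 0 || rat_eq(rho, e$L))
    stop("endpoint rootings are node rootings; query with node =")
  for (b in e$boundaries)
    if (rat_eq(b$rho, rho)) return(b$result$status == "reconciled")
  for (p in e$pieces) {
    if (rat_cmp(p$lo, rho) < 0 && rat_cmp(rho, p$hi) < 0)
      return(is.null(p$reject))
  }
  FALSE
}

#' @export
print.solution_set <- function(x, ...) {
  cat("solution set for doubly-unrooted isometric reconciliation\n")
  for (nd in x$nodes)
    cat(sprintf("  root at node %s: %s\n",
                ifelse(is.na(nd$label), nd$node, nd$label), nd$result$status))
  for (e in x$edges) {
    cat(sprintf("  edge (%s,%s) length %s:\n", e$ends[1], e$ends[2],
                rat_format(e$L)))
    for (p in e$pieces) {
      st <- if (is.null(p$reject)) "parametric reconciliation" else
        paste("rejected:", p$reject)
      cat(sprintf("    (%s,%s): %s\n", rat_format(p$lo), rat_format(p$hi), st))
    }
    for (b in e$boundaries)
      cat(sprintf("    rho = %s: %s\n", rat_format(b$rho), b$result$status))
    for (r in e$merged)
      cat(sprintf("    accepted set %s%s,%s%s\n",
                  if (r$lo_closed) "[" else "(", rat_format(r$lo),
                  rat_format(r$hi), if (r$hi_closed) "]" else ")"))
  }
  invisible(x)
}
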