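## Core tree model. A phylogenetic tree is stored as an edge list with exact
## rational branch lengths. The same structure serves rooted and unrooted
## trees; rootedness is a flag plus a designated root node, never a property
## of the serialized text.

#' Construct a phylogenetic tree
#'
#' @param labels character vector of node labels (NA for unlabeled internal
#'   nodes); leaf labels must be unique.
#' @param edge integer matrix with two columns, one row per edge.
#' @param elen list of rationals (see [rat()]), one per edge; all positive
#'   unless \code{allow_zero}.
#' @param rooted logical flag.
#' @param root integer id of the root (rooted trees only).
#' @param allow_zero permit zero-length edges (used internally by the simple
#'   history expansion, where chains of simultaneous events have zero-length
#'   connecting edges; parsed user input is always strictly positive).
#' @return an object of class \code{itree}.
#' @export
itree <- function(labels, edge, elen, rooted, root = NA_integer_,
                  allow_zero = FALSE) {
  n <- length(labels)
  edge <- matrix(as.integer(edge), ncol = 2)
  if (nrow(edge) != length(elen)) stop("edge/elen length mismatch")
  if (n > 1 && nrow(edge) != n - 1) stop("tree must have n-1 edges")
  for (l in elen) {
    s <- rat_sign(l)
    if (s < 0 || (!allow_zero && s == 0)) stop("non-positive branch length")
  }
  if (rooted && (is.na(root) || root < 1 || root > n)) stop("invalid root")
  t <- list(labels = labels, edge = edge, elen = elen,
            rooted = isTRUE(rooted),
            root = if (rooted) as.integer(root) else NA_integer_)
  class(t) <- "itree"
  t
}

#' Number of nodes in a tree
#' @param t an \code{itree}.
#' @return integer.
#' @export
tree_n <- function(t) length(t$labels)

## adjacency list: per node, a list with integer vectors $nb (neighbors) and
## $ei (edge indices)
tree_adj <- function(t) {
  n <- tree_n(t)
  nb <- vector("list", n)
  ei <- vector("list", n)
  for (k in seq_len(nrow(t$edge))) {
    a <- t$edge[k, 1]; b <- t$edge[k, 2]
    nb[[a]] <- c(nb[[a]], b); ei[[a]] <- c(ei[[a]], k)
    nb[[b]] <- c(nb[[b]], a); ei[[b]] <- c(ei[[b]], k)
  }
  list(nb = nb, ei = ei)
}

tree_degree <- function(t) {
  n <- tree_n(t)
  deg <- integer(n)
  for (k in seq_len(nrow(t$edge))) {
    deg[t$edge[k, 1]] <- deg[t$edge[k, 1]] + 1L
    deg[t$edge[k, 2]] <- deg[t$edge[k, 2]] + 1L
  }
  deg
}

#' Leaf ids of a tree
#'
#' For a rooted tree, leaves are the childless nodes; for an unrooted tree,
#' the degree-one nodes. A single-node tree consists of one leaf.
#' @param t an \code{itree}.
#' @return integer vector of node ids.
#' @export
tree_leaves <- function(t) {
  n <- tree_n(t)
  if (n == 1) return(1L)
  deg <- tree_degree(t)
  if (t$rooted) {
    ## root with degree 1 is not a leaf (it has one child)
    out <- which(deg == 1L)
    setdiff(out, t$root)
  } else which(deg == 1L)
}

## Rooted form: parent/child arrays plus preorder, computed by BFS from root.
## plen[[v]] is the length of the edge from v to its parent.
rooted_form <- function(t, root = t$root) {
  n <- tree_n(t)
  adj <- tree_adj(t)
  parent <- integer(n)
  pedge <- integer(n)
  order <- integer(n)
  seen <- logical(n)
  queue <- root; seen[root] <- TRUE; qi <- 1L; cnt <- 0L
  while (qi <= length(queue)) {
    v <- queue[qi]; qi <- qi + 1L
    cnt <- cnt + 1L; order[cnt] <- v
    for (j in seq_along(adj$nb[[v]])) {
      w <- adj$nb[[v]][j]
      if (!seen[w]) {
        seen[w] <- TRUE
        parent[w] <- v
        pedge[w] <- adj$ei[[v]][j]
        queue <- c(queue, w)
      }
    }
  }
  if (cnt != n) stop("tree is not connected")
  children <- vector("list", n)
  for (v in seq_len(n)) if (v != root) {
    children[[parent[v]]] <- c(children[[parent[v]]], v)
  }
  plen <- vector("list", n)
  for (v in seq_len(n)) if (v != root) plen[[v]] <- t$elen[[pedge[v]]]
  list(root = root, parent = parent, children = children, plen = plen,
       order = order)
}

## distance between two nodes along the tree path
tree_dist_nodes <- function(t, u, v) {
  if (u == v) return(RAT0)
  adj <- tree_adj(t)
  n <- tree_n(t)
  prev <- integer(n); prevedge <- integer(n); seen <- logical(n)
  queue <- u; seen[u] <- TRUE; qi <- 1L
  while (qi <= length(queue)) {
    x <- queue[qi]; qi <- qi + 1L
    if (x == v) break
    for (j in seq_along(adj$nb[[x]])) {
      w <- adj$nb[[x]][j]
      if (!seen[w]) {
        seen[w] <- TRUE; prev[w] <- x; prevedge[w] <- adj$ei[[x]][j]
        queue <- c(queue, w)
      }
    }
  }
  d <- RAT0; x <- v
  while (x != u) { d <- rat_add(d, t$elen[[prevedge[x]]]); x <- prev[x] }
  d
}

## distances from node u to all nodes (list of rats)
tree_dist_all <- function(t, u, adj = tree_adj(t)) {
  n <- tree_n(t)
  d <- vector("list", n)
  d[[u]] <- RAT0
  seen <- logical(n); seen[u] <- TRUE
  queue <- u; qi <- 1L
  while (qi <= length(queue)) {
    x <- queue[qi]; qi <- qi + 1L
    for (j in seq_along(adj$nb[[x]])) {
      w <- adj$nb[[x]][j]
      if (!seen[w]) {
        seen[w] <- TRUE
        d[[w]] <- rat_add(d[[x]], t$elen[[adj$ei[[x]][j]]])
        queue <- c(queue, w)
      }
    }
  }
  d
}

node_by_label <- function(t, lab) {
  i <- match(lab, t$labels)
  if (is.na(i)) stop("no node labeled '", lab, "'")
  i
}

#' Scale all branch lengths by a rational factor
#' @param t an \code{itree}.
#' @param alpha a positive rational.
#' @return the scaled tree.
#' @export
tree_scale <- function(t, alpha) {
  if (rat_sign(alpha) <= 0) stop("scaling factor must be positive")
  t$elen <- lapply(t$elen, function(l) rat_mul(l, alpha))
  t
}

## ---------------------------------------------------------------- Newick --

.nwk_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  toks <- list(); buf <- character(0)
  flush <- function() {
    if (length(buf) > 0) {
      toks[[length(toks) + 1L]] <<- paste(buf, collapse = "")
      buf <<- character(0)
    }
  }
  for (ch in chars) {
    if (ch %in% c("(", ")", ",", ":", ";")) {
      flush(); toks[[length(toks) + 1L]] <- ch
    } else if (grepl("^\\s$", ch)) flush()
    else buf <- c(buf, ch)
  }
  flush()
  unlist(toks)
}

#' Parse a Newick string into a tree
#'
#' Branch lengths are mandatory on every edge except the top-level virtual
#' edge and are parsed exactly: decimal literals become exact rationals and
#' \code{"a/b"} fractions are read directly. Whether the tree is rooted is
#' decided by the \code{rooted} flag, not by the text; an unrooted tree is
#' stored with an arbitrary internal anchor node and no root. A top-level
#' bifurcation in an unrooted parse is interpreted as a phantom anchor and
#' its two edges are merged into one.
#'
#' @param text Newick string (single tree, terminated by \code{";"}).
#' @param rooted logical: interpret the tree as rooted?
#' @param allow_zero permit zero branch lengths (internal use).
#' @return an \code{itree}.
#' @examples
#' s <- parse_newick("((B:2,C:2)x:1,A:3)r;", rooted = TRUE)
#' write_newick(s)
#' @export
parse_newick <- function(text, rooted, allow_zero = FALSE) {
  toks <- .nwk_tokenize(text)
  if (length(toks) == 0) stop("empty Newick input")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else ""
  take <- function() { tk <- peek(); pos <<- pos + 1L; tk }
  labels <- character(0)
  edges <- NULL
  elens <- list()
  new_node <- function(lab) {
    labels[length(labels) + 1L] <<- lab
    length(labels)
  }
  ## returns node id; appends child edges
  parse_node <- function() {
    kids <- integer(0); klen <- list()
    if (peek() == "(") {
      take()
      repeat {
        kid <- parse_node()
        if (peek() != ":")
          stop("missing branch length near token '", peek(), "'")
        take()
        l <- rat_parse(take())
        s <- rat_sign(l)
        if (s < 0 || (!allow_zero && s == 0))
          stop("non-positive branch length on edge to '",
               labels[kid], "'")
        kids <- c(kids, kid); klen[[length(klen) + 1L]] <- l
        if (peek() == ",") { take(); next }
        if (peek() == ")") { take(); break }
        stop("malformed Newick near token '", peek(), "'")
      }
    }
    lab <- NA_character_
    if (!(peek() %in% c("(", ")", ",", ":", ";", ""))) lab <- take()
    id <- new_node(lab)
    for (j in seq_along(kids)) {
      edges <<- rbind(edges, c(id, kids[j]))
      elens[[length(elens) + 1L]] <<- klen[[j]]
    }
    id
  }
  top <- parse_node()
  if (peek() != ";") stop("expected ';' near token '", peek(), "'")
  ## duplicate labels among named nodes are ambiguous
  named <- labels[!is.na(labels)]
  if (anyDuplicated(named)) stop("duplicate node label: ",
                                 named[duplicated(named)][1])
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
  if (rooted)
    return(itree(labels, edges, elens, rooted = TRUE, root = top,
                 allow_zero = allow_zero))
  ## unrooted: a top-level node with exactly two children is a phantom
  ## anchor; merge its two incident edges
  topdeg <- sum(edges == top)
  if (topdeg == 2L) {
    ki <- which(edges[, 1] == top)
    a <- edges[ki[1], 2]; b <- edges[ki[2], 2]
    la <- elens[[ki[1]]]; lb <- elens[[ki[2]]]
    keep <- setdiff(seq_len(nrow(edges)), ki)
    edges <- rbind(edges[keep, , drop = FALSE], c(a, b))
    elens <- c(elens[keep], list(rat_add(la, lb)))
    ## drop the phantom node (it is the last id only if it had no parent)
    labels2 <- labels[-top]
    remap <- integer(length(labels))
    remap[-top] <- seq_len(length(labels) - 1L)
    edges <- matrix(remap[edges], ncol = 2)
    return(itree(labels2, edges, elens, rooted = FALSE,
                 allow_zero = allow_zero))
  }
  itree(labels, edges, elens, rooted = FALSE, allow_zero = allow_zero)
}

## smallest leaf label in the subtree below each node (rooted form helper)
.min_leaf_below <- function(t, rf) {
  n <- tree_n(t)
  ml <- rep(NA_character_, n)
  for (v in rev(rf$order)) {
    if (length(rf$children[[v]]) == 0) ml[v] <- t$labels[v]
    else {
      kids <- rf$children[[v]]
      ml[v] <- sort(ml[kids])[1]
    }
  }
  ml
}

#' Serialize a tree to Newick
#'
#' Children are emitted in a canonical order (by the lexicographically
#' smallest leaf label of each subtree) so that output is deterministic and
#' the parse/write cycle is the identity on canonical text. Unrooted trees
#' are emitted as a top-level multifurcation anchored at the internal node
#' adjacent to the smallest leaf; a two-leaf unrooted tree is written with a
#' phantom anchor splitting its single edge in half.
#'
#' @param t an \code{itree}.
#' @return a Newick character scalar.
#' @export
write_newick <- function(t) {
  n <- tree_n(t)
  if (n == 1) return(paste0(t$labels[1], ";"))
  if (!t$rooted) {
    leaves <- tree_leaves(t)
    if (n == 2) {
      labs <- t$labels[order(t$labels)]
      half <- rat_half(t$elen[[1]])
      return(paste0("(", labs[1], ":", rat_format(half), ",",
                    labs[2], ":", rat_format(half), ");"))
    }
    ## anchor at an internal node near the smallest leaf; prefer degree >= 3
    ## so the top level is a multifurcation (a bifurcation would read back
    ## as a phantom anchor)
    minleaf <- leaves[order(t$labels[leaves])][1]
    anchor <- tree_adj(t)$nb[[minleaf]][1]
    if (tree_degree(t)[anchor] < 3L) {
      deg3 <- which(tree_degree(t) >= 3L)
      if (length(deg3) > 0) anchor <- deg3[1]
    }
    rf <- rooted_form(t, root = anchor)
  } else rf <- rooted_form(t)
  ml <- .min_leaf_below(t, rf)
  emit <- function(v) {
    kids <- rf$children[[v]]
    lab <- if (is.na(t$labels[v])) "" else t$labels[v]
    if (length(kids) == 0) return(lab)
    kids <- kids[order(ml[kids])]
    parts <- vapply(kids, function(k)
      paste0(emit(k), ":", rat_format(rf$plen[[k]])), "")
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  paste0(emit(rf$root), ";")
}

#' Structural equality of two trees
#'
#' Compares topology, branch lengths (exactly) and leaf labels via the
#' canonical serialization; internal labels are compared only when both are
#' present in corresponding positions if \code{strict_labels} is TRUE.
#' @param t1,t2 trees.
#' @param strict_labels compare internal node labels too?
#' @return logical.
#' @export
tree_equal <- function(t1, t2, strict_labels = FALSE) {
  s1 <- t1; s2 <- t2
  if (!strict_labels) {
    lv1 <- tree_leaves(s1); lv2 <- tree_leaves(s2)
    s1$labels[setdiff(seq_len(tree_n(s1)), lv1)] <- NA
    s2$labels[setdiff(seq_len(tree_n(s2)), lv2)] <- NA
  }
  identical(write_newick(s1), write_newick(s2))
}

## -------------------------------------------------------------- leaf map --

#' Parse a gene-to-species leaf map
#'
#' The map assigns each gene-tree leaf to the species-tree leaf in which the
#' gene copy resides. Input is a two-column table (gene, species), either a
#' TSV file with header \code{gene<TAB>species} or a data.frame.
#'
#' @param x file path or data.frame with columns gene, species.
#' @param G gene tree.
#' @param S species tree.
#' @return named character vector mapping gene leaf label to species leaf
#'   label, of class \code{leafmap}.
#' @export
parse_leaf_map <- function(x, G, S) {
  if (is.character(x) && length(x) == 1) {
    df <- utils::read.table(x, header = TRUE, sep = "\t",
                            colClasses = "character")
  } else df <- as.data.frame(x, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("leaf map needs two columns (gene, species)")
  gl <- as.character(df[[1]]); sl <- as.character(df[[2]])
  errs <- character(0)
  gleaf <- G$labels[tree_leaves(G)]
  sleaf <- S$labels[tree_leaves(S)]
  dup <- gl[duplicated(gl)]
  for (d in unique(dup)) errs <- c(errs, paste0("duplicate row for gene leaf ", d))
  for (i in seq_along(gl)) {
    if (!(gl[i] %in% gleaf))
      errs <- c(errs, paste0("unknown gene leaf ", gl[i]))
    if (!(sl[i] %in% sleaf))
      errs <- c(errs, paste0("gene ", gl[i], " maps to non-leaf or unknown label ",
                             sl[i]))
  }
  for (g in setdiff(gleaf, gl))
    errs <- c(errs, paste0("unmapped gene leaf ", g))
  if (length(errs) > 0)
    stop("invalid leaf map:\n  ", paste(errs, collapse = "\n  "))
  mu <- stats::setNames(sl, gl)
  class(mu) <- "leafmap"
  mu
}

#' Bundle an input partial history
#'
#' @param G gene tree (rooted or unrooted).
#' @param S species tree (rooted or unrooted).
#' @param mu leaf map (named character vector gene label -> species label).
#' @return an object of class \code{iph}.
#' @export
input_history <- function(G, S, mu) {
  h <- list(G = G, S = S, mu = mu)
  class(h) <- "iph"
  h
}

#' Validate an input partial history
#'
#' Checks the structural requirements on reconciliation inputs: strictly
#' positive branch lengths, internal nodes with at least two children
#' (rooted) or three neighbors (unrooted), and a total leaf map onto species
#' leaves.
#'
#' @param iph an \code{iph} object.
#' @return character vector of violations; empty when the input is valid.
#' @export
validate_input <- function(iph) {
  v <- character(0)
  check_tree <- function(t, name) {
    out <- character(0)
    for (l in t$elen)
      if (rat_sign(l) <= 0) {
        out <- c(out, paste0(name, ": non-positive branch length"))
        break
      }
    n <- tree_n(t)
    if (n == 1) return(out)
    deg <- tree_degree(t)
    if (t$rooted) {
      rf <- rooted_form(t)
      for (u in seq_len(n)) {
        nk <- length(rf$children[[u]])
        if (nk == 1)
          out <- c(out, paste0(name, ": node ",
                               if (is.na(t$labels[u])) u else t$labels[u],
                               " has only one child"))
      }
    } else {
      for (u in seq_len(n)) {
        if (deg[u] == 2)
          out <- c(out, paste0(name, ": internal node ",
                               if (is.na(t$labels[u])) u else t$labels[u],
                               " has fewer than three neighbors"))
      }
    }
    out
  }
  v <- c(v, check_tree(iph$G, "gene tree"), check_tree(iph$S, "species tree"))
  gleaf <- iph$G$labels[tree_leaves(iph$G)]
  sleaf <- iph$S$labels[tree_leaves(iph$S)]
  mu <- iph$mu
  for (g in gleaf) {
    if (!(g %in% names(mu))) v <- c(v, paste0("unmapped gene leaf ", g))
    else if (!(mu[[g]] %in% sleaf))
      v <- c(v, paste0("gene leaf ", g, " maps to non-leaf ", mu[[g]]))
  }
  v
}
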