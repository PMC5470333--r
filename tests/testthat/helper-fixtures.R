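## shared fixtures and independent oracles

fix_S <- function() parse_newick("((B:2,C:2)x:1,A:3)r;", rooted = TRUE)
fix_G <- function() parse_newick("((b1:2,c1:2)y:1,a1:3)q;", rooted = TRUE)
fix_mu <- function() leafmap(b1 = "B", c1 = "C", a1 = "A")

leafmap <- function(...) {
  mu <- c(...)
  class(mu) <- "leafmap"
  mu
}

r <- function(n, d = 1) rat(n, d)

## aliases for internal exact-arithmetic helpers used across tests
rat_half <- isorec:::rat_half
rat_sign <- isorec:::rat_sign
rat_eq <- isorec:::rat_eq
rat_add <- isorec:::rat_add
rat_sub <- isorec:::rat_sub

## locate the simulated root position inside the unrooted species tree:
## either an internal node or (edge index, offset) of the bypassed root
find_true_root <- function(hi, iph_unrooted) {
  Sr <- derive_input(hi)$S
  Su <- iph_unrooted$S
  rf <- isorec:::rooted_form(Sr)
  kids <- rf$children[[rf$root]]
  if (length(kids) >= 3) return(list(type = "node"))
  l1 <- rf$plen[[kids[1]]]
  leafset <- function(t, rfx, v) {
    ls <- vector("list", tree_n(t))
    for (x in rev(rfx$order)) {
      ks <- rfx$children[[x]]
      ls[[x]] <- if (length(ks) == 0) t$labels[x] else sort(unlist(ls[ks]))
    }
    ls[[v]]
  }
  ls1 <- paste(leafset(Sr, rf, kids[1]), collapse = ",")
  adj <- isorec:::tree_adj(Su)
  deg <- isorec:::tree_degree(Su)
  for (ei in seq_len(nrow(Su$edge))) {
    for (dir in 1:2) {
      a <- Su$edge[ei, dir]
      n <- tree_n(Su); seen <- logical(n); seen[a] <- TRUE
      queue <- a; qi <- 1L
      while (qi <= length(queue)) {
        x <- queue[qi]; qi <- qi + 1L
        for (j in seq_along(adj$nb[[x]])) {
          if (adj$ei[[x]][j] == ei) next
          w <- adj$nb[[x]][j]
          if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
        }
      }
      leaves <- intersect(which(deg == 1L), which(seen))
      if (paste(sort(Su$labels[leaves]), collapse = ",") == ls1)
        return(list(type = "edge", ei = ei,
                    rho = if (dir == 1) l1 else rat_sub(Su$elen[[ei]], l1)))
    }
  }
  stop("true root edge not found")
}


## naive edge-by-edge walk: point at distance d above node u in a rooted
## tree; independent of the heavy-path level-ancestor structure
naive_anc <- function(S, u, d) {
  rf <- isorec:::rooted_form(S)
  node <- u; rem <- d
  while (node != rf$root && rat_cmp(rem, rf$plen[[node]]) >= 0) {
    rem <- rat_sub(rem, rf$plen[[node]])
    node <- rf$parent[node]
  }
  tp(node, rem)   # above-root when node == root
}

## naive path length between two nodes
naive_dist <- function(S, u, v) isorec:::tree_dist_nodes(S, u, v)

## simulated inferable history for a seed (shared defaults)
sim_inferable <- function(seed, n_species = 4, dup = 0.3, loss = 0.3,
                          min_genes = 3, max_genes = Inf,
                          mode = "ultrametric") {
  p <- sim_params(n_species = n_species, dup_rate = dup, loss_rate = loss,
                  seed = seed, min_genes = min_genes, max_genes = max_genes,
                  mode = mode)
  inferable_version(simulate_simple_history(p))
}

## history fixture with gene edges bypassing a species node: a duplication
## above a speciation x whose two copies both continue into daughter
## species C, so x is crossed by two gene edges and its extended inverse
## consists of the two implicit points pt(c1, 2) and pt(c2, 2)
bypass_history <- function() {
  S <- parse_newick("(A:3,((B:2,C:2)x:0.5)e:0.5)r;", rooted = TRUE)
  G <- parse_newick("(a1:3,(c1:2.5,c2:2.5)y:0.5)q;", rooted = TRUE)
  phi <- integer(tree_n(G))
  lbl <- function(t, l) isorec:::node_by_label(t, l)
  phi[lbl(G, "a1")] <- lbl(S, "A")
  phi[lbl(G, "c1")] <- lbl(S, "C")
  phi[lbl(G, "c2")] <- lbl(S, "C")
  phi[lbl(G, "y")] <- lbl(S, "e")
  phi[lbl(G, "q")] <- lbl(S, "r")
  history(G, S, phi)
}
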