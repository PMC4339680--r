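# Independent brute-force oracles. These work directly on plain edge
# lists / annotation lists with their own traversal code (matrix closure,
# explicit path enumeration, literal formula transcription), so they share
# no code path with the package internals they check.

# Reflexive-transitive ancestor closure by repeated squaring of the
# reachability matrix.
oracle_closure <- function(edges, terms, from, up = TRUE) {
  n <- length(terms)
  A <- matrix(FALSE, n, n, dimnames = list(terms, terms))
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      if (up) A[edges$child[i], edges$parent[i]] <- TRUE
      else A[edges$parent[i], edges$child[i]] <- TRUE
    }
  }
  diag(A) <- TRUE
  R <- A
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  sort(terms[R[from, ]])
}

oracle_ancestors <- function(edges, terms, t) oracle_closure(edges, terms, t, up = TRUE)
oracle_descendants <- function(edges, terms, t) oracle_closure(edges, terms, t, up = FALSE)

# All terms on any simple upward path from `from` to `to`, by explicit
# depth-first path enumeration.
oracle_path_nodes <- function(edges, from, to) {
  parents_of <- function(t) edges$parent[edges$child == t]
  nodes <- character(0)
  walk <- function(t, path) {
    path <- c(path, t)
    if (t == to) {
      nodes <<- union(nodes, path)
      return()
    }
    for (p in parents_of(t)) walk(p, path)
  }
  walk(from, character(0))
  nodes
}

oracle_path_terms <- function(edges, terms, t_a, t_b, p) {
  sort(unique(c(oracle_path_nodes(edges, t_a, p),
                oracle_path_nodes(edges, t_b, p),
                oracle_descendants(edges, terms, t_a),
                oracle_descendants(edges, terms, t_b))))
}

# Propagated gene set of a term from a direct-annotation list.
oracle_propagated <- function(edges, terms, direct, t) {
  ds <- oracle_descendants(edges, terms, t)
  as.character(sort(unique(unlist(direct[names(direct) %in% ds],
                                  use.names = FALSE))))
}

# Network distances straight off the edge data.frame.
oracle_pair_distance <- function(net_edges, gi, gj) {
  if (gi == gj) return(0)
  hit <- (net_edges$gene1 == gi & net_edges$gene2 == gj) |
         (net_edges$gene1 == gj & net_edges$gene2 == gi)
  if (!any(hit)) 1 else 1 - max(net_edges$conf[hit])
}

# Literal transcription of the product-form gene-set distance.
oracle_D <- function(net_edges, ga, gb) {
  proddist <- function(g, S) {
    d <- 1
    for (s in S) d <- d * oracle_pair_distance(net_edges, g, s)
    d
  }
  s1 <- 0; for (g in ga) s1 <- s1 + proddist(g, gb)
  s2 <- 0; for (g in gb) s2 <- s2 + proddist(g, ga)
  (s1 + s2) / (2 * length(union(ga, gb)) - s1 - s2)
}

oracle_D_v1 <- function(net_edges, ga, gb) {
  tot <- 0
  for (gi in ga) for (gj in gb) tot <- tot + oracle_pair_distance(net_edges, gi, gj)
  tot / (length(ga) * length(gb))
}

oracle_U <- function(edges, terms, direct, t_a, t_b, p) {
  pt <- oracle_path_terms(edges, terms, t_a, t_b, p)
  sort(unique(c(oracle_propagated(edges, terms, direct, t_a),
                oracle_propagated(edges, terms, direct, t_b),
                unlist(direct[names(direct) %in% pt], use.names = FALSE))))
}

# Full network-aware similarity at a fixed ancestor, from scratch.
oracle_netsim_S <- function(edges, terms, direct, net_edges, t_a, t_b, p) {
  ga <- oracle_propagated(edges, terms, direct, t_a)
  gb <- oracle_propagated(edges, terms, direct, t_b)
  gp <- oracle_propagated(edges, terms, direct, p)
  root <- setdiff(terms, edges$child)
  G <- oracle_propagated(edges, terms, direct, root)
  D <- oracle_D(net_edges, ga, gb)
  U <- if (is.null(net_edges) || nrow(net_edges) == 0)
    gp else oracle_U(edges, terms, direct, t_a, t_b, p)
  f <- D^2 * length(U) + (1 - D^2) * sqrt(length(ga) * length(gb))
  h <- D^2 * length(G) + (1 - D^2) * max(length(ga), length(gb))
  den <- 2 * log(length(G)) - (log(length(ga)) + log(length(gb)))
  first <- if (den <= 0) 0 else (2 * log(length(G)) - 2 * log(f)) / den
  first * (1 - (h / length(G)) * (length(gp) / length(G)))
}

oracle_term_sim_max <- function(edges, terms, direct, net_edges, t_a, t_b) {
  ps <- intersect(oracle_ancestors(edges, terms, t_a),
                  oracle_ancestors(edges, terms, t_b))
  ps <- ps[vapply(ps, function(p)
    length(oracle_propagated(edges, terms, direct, p)) > 0, logical(1))]
  max(vapply(ps, function(p)
    oracle_netsim_S(edges, terms, direct, net_edges, t_a, t_b, p), numeric(1)))
}

# Best-match-average gene similarity with leave-one-out, as an explicit
# double loop over term pairs.
oracle_GS <- function(edges, terms, direct, net_edges, g_i, g_j) {
  T_i <- sort(names(direct)[vapply(direct, function(g) g_i %in% g, logical(1))])
  T_j <- sort(names(direct)[vapply(direct, function(g) g_j %in% g, logical(1))])
  red <- lapply(direct, setdiff, y = c(g_i, g_j))
  red <- red[lengths(red) > 0]
  best <- function(t, T_other) {
    if (!length(oracle_propagated(edges, terms, red, t))) return(0)
    b <- 0
    for (ty in T_other) {
      if (!length(oracle_propagated(edges, terms, red, ty))) next
      b <- max(b, oracle_term_sim_max(edges, terms, red, net_edges, t, ty))
    }
    b
  }
  si <- vapply(T_i, best, numeric(1), T_other = T_j)
  sj <- vapply(T_j, best, numeric(1), T_other = T_i)
  (sum(si[si > 0]) + sum(sj[sj > 0])) / (length(T_i) + length(T_j))
}

# Wang similarity by explicit enumeration of all upward paths: the
# semantic contribution of ancestor p to term t is the best product of
# edge weights over paths t -> p.
oracle_wang <- function(edges, terms, t_a, t_b, w = c(is_a = 0.8, part_of = 0.6)) {
  contrib <- function(t) {
    anc <- oracle_ancestors(edges, terms, t)
    s <- setNames(rep(0, length(anc)), anc)
    walk <- function(node, value) {
      s[node] <<- max(s[node], value)
      idx <- which(edges$child == node)
      for (i in idx) walk(edges$parent[i], value * w[[edges$relation[i]]])
    }
    walk(t, 1)
    s
  }
  sa <- contrib(t_a)
  sb <- contrib(t_b)
  shared <- intersect(names(sa), names(sb))
  (sum(sa[shared]) + sum(sb[shared])) / (sum(sa) + sum(sb))
}

# lfc from its definition, with explicit ambiguity filtering.
oracle_lfc_gene <- function(g, r, gs, genes_of, adjacency, all_reactions, c = 0.001) {
  adj_r <- adjacency[[r]]
  non_r <- setdiff(all_reactions, c(r, adj_r))
  g_adj <- unique(unlist(genes_of[adj_r]))
  g_non <- unique(unlist(genes_of[non_r]))
  amb <- intersect(g_adj, g_non)
  g_adj <- setdiff(setdiff(g_adj, amb), genes_of[[r]])
  g_non <- setdiff(setdiff(g_non, amb), genes_of[[r]])
  if (!length(g_adj) || !length(g_non)) return(NA_real_)
  inter <- mean(1 - gs[g, g_non] + c)
  intra <- mean(1 - gs[g, g_adj] + c)
  log(inter / intra)
}

# Benjamini-Hochberg step-up, written out.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Schlicker at a fixed ancestor, from raw counts.
oracle_schlicker_at <- function(edges, terms, direct, t_a, t_b, p) {
  root <- setdiff(terms, edges$child)
  nG <- length(oracle_propagated(edges, terms, direct, root))
  na <- length(oracle_propagated(edges, terms, direct, t_a))
  nb <- length(oracle_propagated(edges, terms, direct, t_b))
  np <- length(oracle_propagated(edges, terms, direct, p))
  ic <- function(n) -log(n / nG)
  if (ic(na) + ic(nb) == 0) return(0)
  (2 * ic(np) / (ic(na) + ic(nb))) * (1 - np / nG)
}
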