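# Term-to-term similarity: the network-aware measure, its reductions, the
# ablation variants and the baselines.

test_that("gene_set_distance handles identity, disjoint no-network, and a 2x2 oracle", {
  empty <- cofunction_network()
  expect_equal(gene_set_distance(empty, c("a", "b"), c("a", "b")), 0) # G_a = G_b
  expect_equal(gene_set_distance(empty, c("a", "b"), c("c", "d")), 1) # disjoint, no net

  net <- cofunction_network(data.frame(gene1 = "a", gene2 = "c", conf = 0.5))
  ga <- c("a", "b"); gb <- c("c", "d")
  expect_equal(gene_set_distance(net, ga, gb), oracle_D(net$edges, ga, gb),
               tolerance = 1e-14)
  # by hand: d(a,{c,d}) = 0.5*1, d(b,.) = 1, d(c,{a,b}) = 0.5, d(d,.) = 1
  expect_equal(gene_set_distance(net, ga, gb), 3 / (8 - 3), tolerance = 1e-14)
  expect_error(gene_set_distance(net, character(0), gb), "nonempty")
})

test_that("mean-pairwise variant matches enumeration", {
  expect_equal(gene_set_distance_v1(NULL, c("a", "b"), c("c", "d")), 1)
  expect_equal(gene_set_distance_v1(NULL, "g", "g"), 0)
  net <- cofunction_network(data.frame(gene1 = c("a", "b"), gene2 = c("c", "c"),
                                       conf = c(0.25, 0.75)))
  ga <- c("a", "b"); gb <- c("c", "d")
  expect_equal(gene_set_distance_v1(net, ga, gb),
               oracle_D_v1(net$edges, ga, gb), tolerance = 1e-14)
  expect_equal(gene_set_distance_v1(net, ga, gb), (0.75 + 1 + 0.25 + 1) / 4)
})

test_that("path-constrained annotation excludes off-path genes", {
  fx <- figure1_fixture()
  u <- path_constrained_annotation(fx$dag, fx$annots, "t_a", "t_b", "t_j")
  expect_setequal(u, c("g1", "g2", "g3", "g5", "g6", "g7", "g10", "g11"))
  # no gene annotated to the off-path terms t_d (g4) or t_g (g9)
  expect_false(any(c("g4", "g9") %in% u))
  # degenerate: the whole propagated set of the term itself
  expect_identical(path_constrained_annotation(fx$dag, fx$annots, "t_a", "t_a", "t_a"),
                   fx$annots$propagated$t_a)
})

test_that("path constraint is bounded by the propagated sets and never changes D", {
  set.seed(20260920)
  for (seed in 1:4) {
    fx <- random_fixture(n_terms = 12L, n_genes = 12L, net_density = 0.2,
                         seed = seed)
    ts <- names(fx$annots$propagated)[lengths(fx$annots$propagated) > 0L]
    pick <- sample(ts, 2L)
    for (p in common_ancestors(fx$dag, pick[1L], pick[2L])) {
      if (!length(fx$annots$propagated[[p]])) next
      u <- path_constrained_annotation(fx$dag, fx$annots, pick[1L], pick[2L], p)
      expect_true(all(u %in% unique(c(fx$annots$propagated[[p]],
                                      fx$annots$propagated[[pick[1L]]],
                                      fx$annots$propagated[[pick[2L]]]))))
      expect_true(all(c(fx$annots$propagated[[pick[1L]]],
                        fx$annots$propagated[[pick[2L]]]) %in% u))
      # v2 (no path constraint) changes only f through |U|, never D
      full <- term_similarity(fx$dag, fx$annots, fx$net, pick[1L], pick[2L], p)
      v2 <- term_similarity(fx$dag, fx$annots, fx$net, pick[1L], pick[2L], p,
                            measure_config("netsim_v2"))
      expect_identical(v2$D, full$D)
      expect_identical(v2$U, fx$annots$propagated[[p]])
    }
  }
})

test_that("term_similarity matches an independent transcription on the toy world", {
  fx <- figure1_fixture()
  for (p in c("t_i", "t_j", "root")) {
    got <- term_similarity(fx$dag, fx$annots, fx$net, "t_a", "t_b", p)
    want <- oracle_netsim_S(fx$dag$edges, fx$dag$terms, fx$annots$direct,
                            fx$net$edges, "t_a", "t_b", p)
    expect_equal(got$S, want, tolerance = 1e-12, label = sprintf("S at %s", p))
  }
})

test_that("weights f and h stay within their bounds and S in [0, 1]", {
  set.seed(20260920)
  for (seed in 1:4) {
    fx <- random_fixture(n_terms = 12L, n_genes = 15L, net_density = 0.25,
                         seed = seed)
    ts <- names(fx$annots$propagated)[lengths(fx$annots$propagated) > 0L]
    for (rep in 1:5) {
      pick <- sample(ts, 2L)
      for (p in common_ancestors(fx$dag, pick[1L], pick[2L])) {
        if (!length(fx$annots$propagated[[p]])) next
        r <- term_similarity(fx$dag, fx$annots, fx$net, pick[1L], pick[2L], p)
        na <- length(fx$annots$propagated[[pick[1L]]])
        nb <- length(fx$annots$propagated[[pick[2L]]])
        nG <- length(fx$annots$universe)
        expect_gte(r$D, 0); expect_lte(r$D, 1)
        expect_gte(r$f, sqrt(na * nb) - 1e-12); expect_lte(r$f, nG + 1e-12)
        expect_gte(r$h, max(na, nb) - 1e-12); expect_lte(r$h, nG + 1e-12)
        expect_gte(r$S, 0); expect_lte(r$S, 1)
        expect_true(all(c(fx$annots$propagated[[pick[1L]]],
                          fx$annots$propagated[[pick[2L]]]) %in% r$U))
      }
    }
  }
})

test_that("with vanishing confidences D tends to the set-overlap distance", {
  set.seed(20260920)
  fx <- random_fixture(n_terms = 10L, n_genes = 12L, net_density = 0.4, seed = 6L)
  tiny <- fx$net$edges
  tiny$conf <- tiny$conf * 1e-9
  net0 <- cofunction_network(tiny)
  ts <- names(fx$annots$propagated)[lengths(fx$annots$propagated) > 0L]
  for (rep in 1:6) {
    pick <- sample(ts, 2L)
    ga <- fx$annots$propagated[[pick[1L]]]
    gb <- fx$annots$propagated[[pick[2L]]]
    cd <- (length(union(ga, gb)) - length(intersect(ga, gb))) /
          (length(union(ga, gb)) + length(intersect(ga, gb)))
    expect_equal(gene_set_distance(net0, ga, gb), cd, tolerance = 1e-6)
  }
})

test_that("term_similarity_max maximizes over ancestors and reports the best one", {
  fx <- figure1_fixture()
  vals <- vapply(c("root", "t_i", "t_j"), function(p)
    term_similarity(fx$dag, fx$annots, fx$net, "t_a", "t_b", p)$S, numeric(1))
  got <- term_similarity_max(fx$dag, fx$annots, fx$net, "t_a", "t_b")
  expect_equal(as.numeric(got), max(vals), tolerance = 1e-14)
  expect_identical(attr(got, "ancestor"), names(vals)[which.max(vals)])

  # self-similarity: the term itself beats all higher ancestors
  self <- term_similarity_max(fx$dag, fx$annots, fx$net, "t_e", "t_e")
  expect_identical(attr(self, "ancestor"), "t_e")

  # leaves whose only informative shared ancestor is the root: |G_p| = |G|
  # forces the second factor towards zero
  root_only <- term_similarity(fx$dag, fx$annots, fx$net, "t_d", "t_g", "root")
  expect_lt(root_only$S, 0.25)
})

test_that("resnik reduces to IC and picks the most informative ancestor", {
  fx <- figure1_fixture()
  an <- fx$annots
  expect_equal(as.numeric(resnik(fx$dag, an, "t_e", "root")), 0) # IC(root) = 0
  expect_equal(as.numeric(resnik(fx$dag, an, "t_e", "t_e")),
               term_ic(an, "t_e"), tolerance = 1e-14) # self LCA
  r <- resnik(fx$dag, an, "t_a", "t_b")
  expect_identical(attr(r, "ancestor"), "t_i") # the designated LCA
  expect_equal(as.numeric(r), -log(length(an$propagated$t_i) / 13),
               tolerance = 1e-14)
})

test_that("schlicker matches substitution and its boundary cases", {
  fx <- figure1_fixture()
  an <- fx$annots
  expect_equal(as.numeric(schlicker(fx$dag, an, "t_e", "root")), 0) # IC(LCA) = 0
  nt <- length(an$propagated$t_e)
  expect_equal(as.numeric(schlicker(fx$dag, an, "t_e", "t_e")),
               1 - nt / 13, tolerance = 1e-14)
  expect_equal(as.numeric(schlicker(fx$dag, an, "t_a", "t_b")),
               oracle_schlicker_at(fx$dag$edges, fx$dag$terms, an$direct,
                                   "t_a", "t_b", "t_i"),
               tolerance = 1e-12)
  expect_equal(as.numeric(schlicker(fx$dag, an, "root", "root")), 0) # 0/0 case
})

test_that("wang matches the chain closed form and brute-force path enumeration", {
  set.seed(20260920)
  chain <- ontology_dag(data.frame(child = "a", parent = "b", relation = "is_a"))
  w <- 0.8
  expect_equal(wang(chain, "a", "b"), (w + 1) / ((1 + w) + 1), tolerance = 1e-14)
  expect_equal(wang(chain, "a", "a"), 1)

  fx <- figure1_fixture()
  pairs <- list(c("t_a", "t_b"), c("t_c", "t_d"), c("t_e", "t_f"), c("t_g", "t_h"))
  for (pr in pairs) {
    expect_equal(wang(fx$dag, pr[1L], pr[2L]),
                 oracle_wang(fx$dag$edges, fx$dag$terms, pr[1L], pr[2L]),
                 tolerance = 1e-12)
  }
  for (seed in 1:3) {
    rfx <- random_fixture(n_terms = 12L, n_genes = 5L, seed = seed)
    pick <- sample(rfx$dag$terms, 2L)
    expect_equal(wang(rfx$dag, pick[1L], pick[2L]),
                 oracle_wang(rfx$dag$edges, rfx$dag$terms, pick[1L], pick[2L]),
                 tolerance = 1e-12)
  }
})

test_that("every measure is symmetric in its term arguments", {
  set.seed(20260920)
  fx <- random_fixture(n_terms = 12L, n_genes = 12L, net_density = 0.2, seed = 8L)
  ts <- names(fx$annots$propagated)[lengths(fx$annots$propagated) > 0L]
  for (m in c("netsim", "netsim_v1", "netsim_v2", "netsim_v3",
              "resnik", "schlicker", "wang")) {
    cfg <- measure_config(m)
    for (rep in 1:4) {
      pick <- sample(ts, 2L)
      expect_equal(as.numeric(term_similarity_max(fx$dag, fx$annots, fx$net,
                                                  pick[1L], pick[2L], cfg)),
                   as.numeric(term_similarity_max(fx$dag, fx$annots, fx$net,
                                                  pick[2L], pick[1L], cfg)),
                   tolerance = 1e-12, label = m)
    }
  }
})

test_that("term_similarity_matrix is symmetric, permutes consistently, and skips empty terms", {
  fx <- figure1_fixture()
  terms <- c("t_a", "t_b", "t_e", "t_f")
  m <- term_similarity_matrix(fx$dag, fx$annots, fx$net, terms)
  expect_identical(m, t(m))
  # element-wise recomputation (cache consistency)
  for (i in seq_along(terms)) {
    for (j in seq_along(terms)) {
      expect_equal(m[i, j],
                   as.numeric(term_similarity_max(fx$dag, fx$annots, fx$net,
                                                  terms[i], terms[j])),
                   tolerance = 1e-14)
    }
  }
  perm <- c(3L, 1L, 4L, 2L)
  m2 <- term_similarity_matrix(fx$dag, fx$annots, fx$net, terms[perm])
  expect_equal(m2, m[perm, perm])

  one <- term_similarity_matrix(fx$dag, fx$annots, fx$net, "t_a")
  expect_equal(dim(one), c(1L, 1L))

  empty_term_an <- remove_genes(fx$annots, "g4") # empties t_d
  expect_warning(m3 <- term_similarity_matrix(fx$dag, empty_term_an, fx$net,
                                              c("t_a", "t_d")),
                 "skipping")
  expect_equal(dim(m3), c(1L, 1L))
})
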