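toy_map <- function() {
  build_reaction_map(data.frame(
    reaction = c("R1", "R2", "R3", "R4", "R5"),
    genes = c("a1,a2", "b1,b2", "c1,c2", "d1,d2", "e1,e2"),
    substrates = c("s0", "s1,ATP", "s2", "s3", "s4"),
    products = c("s1", "s2", "s3", "s4", "s5"),
    stringsAsFactors = FALSE))
}

test_that("reaction adjacency follows shared non-currency compounds", {
  map <- build_reaction_map(data.frame(
    reaction = c("Ra", "Rb", "Rc"),
    genes = c("x1,x2", "y1,y2", "z1,z2"),
    substrates = c("pyruvate", "pyruvate,ATP", "ATP"),
    products = c("x", "y", "z"), stringsAsFactors = FALSE))
  expect_identical(map$adjacency$Ra, "Rb")     # shared pyruvate
  expect_identical(map$adjacency$Rc, character(0)) # only ATP shared: blacklisted
  expect_length(map$small, 0L)
  expect_length(currency_compounds(), 24L)
})

test_that("reaction distances on a chain match breadth-first hop counts", {
  map <- toy_map()
  d <- reaction_distances(map)
  expect_equal(unname(d["R1", c("R1", "R2", "R3", "R4", "R5")]), 0:4)
  expect_identical(d, t(d))
  # adjacency is symmetric and irreflexive
  for (r in map$reactions) {
    expect_false(r %in% map$adjacency[[r]])
    for (r2 in map$adjacency[[r]]) expect_true(r %in% map$adjacency[[r2]])
  }
})

test_that("small reactions are flagged and isolated reactions warned about", {
  expect_warning(map <- build_reaction_map(data.frame(
    reaction = c("R1", "R2"), genes = c("a", "b1,b2"),
    compounds = c("x", ""), stringsAsFactors = FALSE)), "no compounds")
  expect_identical(map$small, "R1")
})

test_that("lfc_gene matches its closed forms", {
  map <- toy_map()
  genes <- unlist(map$genes_of)
  n <- length(genes)
  cfg <- lfc_config(c = 0.001)

  flat <- matrix(0.4, n, n, dimnames = list(genes, genes)); diag(flat) <- 1
  expect_equal(lfc_gene("c1", "R3", flat, map, cfg), 0) # all GS equal -> ln(1)

  perfect <- matrix(0, n, n, dimnames = list(genes, genes)); diag(perfect) <- 1
  sets <- netsim:::lfc_sets_(map, "R3", cfg)
  perfect["c1", sets$adj] <- 1
  perfect[sets$adj, "c1"] <- 1
  expect_equal(lfc_gene("c1", "R3", perfect, map, cfg),
               log((1 + cfg$c) / cfg$c), tolerance = 1e-12)
  expect_error(lfc_gene("zz", "R3", flat, map, cfg), "not in reaction")
})

test_that("lfc matches the spreadsheet-style oracle on a toy map with hand-set GS", {
  map <- toy_map()
  genes <- sort(unlist(map$genes_of))
  n <- length(genes)
  set.seed(99)
  gs <- matrix(runif(n * n), n, n, dimnames = list(genes, genes))
  gs[lower.tri(gs)] <- t(gs)[lower.tri(gs)]
  diag(gs) <- 1
  cfg <- lfc_config(c = 0.01)
  for (r in map$reactions) {
    for (g in map$genes_of[[r]]) {
      expect_equal(lfc_gene(g, r, gs, map, cfg),
                   oracle_lfc_gene(g, r, gs, map$genes_of, map$adjacency,
                                   map$reactions, c = 0.01),
                   tolerance = 1e-12, label = sprintf("lfc(%s, %s)", g, r))
    }
    want_r <- mean(vapply(map$genes_of[[r]], function(g)
      oracle_lfc_gene(g, r, gs, map$genes_of, map$adjacency, map$reactions,
                      c = 0.01), numeric(1)))
    expect_equal(lfc_reaction(r, gs, map, cfg), want_r, tolerance = 1e-12)
  }
})

test_that("lfc is antitone in adjacent GS and monotone in non-adjacent GS", {
  map <- toy_map()
  genes <- sort(unlist(map$genes_of))
  n <- length(genes)
  gs <- matrix(0.5, n, n, dimnames = list(genes, genes)); diag(gs) <- 1
  base <- lfc_gene("c1", "R3", gs, map)
  sets <- netsim:::lfc_sets_(map, "R3")
  up_adj <- gs; up_adj["c1", sets$adj[1L]] <- up_adj[sets$adj[1L], "c1"] <- 0.9
  expect_gt(lfc_gene("c1", "R3", up_adj, map), base)
  up_non <- gs; up_non["c1", sets$non[1L]] <- up_non[sets$non[1L], "c1"] <- 0.9
  expect_lt(lfc_gene("c1", "R3", up_non, map), base)
})

test_that("lfc_benchmark counts winners and summarizes quartiles", {
  map <- toy_map()
  genes <- sort(unlist(map$genes_of))
  n <- length(genes)
  lo <- matrix(0.2, n, n, dimnames = list(genes, genes)); diag(lo) <- 1
  hi <- lo
  # 'good' gets a strict adjacency signal everywhere
  for (r in map$reactions) {
    sets <- netsim:::lfc_sets_(map, r)
    for (g in map$genes_of[[r]]) {
      hi[g, sets$adj] <- 0.95; hi[sets$adj, g] <- 0.95
    }
  }
  b <- lfc_benchmark(map, list(good = hi, flat = lo))
  expect_equal(unname(b$winners["good"]), length(map$reactions))
  expect_equal(unname(b$winners["flat"]), 0L)
  expect_gt(b$summary$median[b$summary$measure == "good"],
            b$summary$median[b$summary$measure == "flat"])
  # identical matrices give identical columns
  b2 <- lfc_benchmark(map, list(m1 = lo, m2 = lo))
  expect_equal(b2$per_reaction$m1, b2$per_reaction$m2)
  expect_equal(b2$summary$median[1L], b2$summary$median[2L])
})

test_that("genome specificity sums organism-pair gaps and degenerates to zero", {
  expect_warning(g1 <- genome_specificity(c(a = 0.5), c(a = 0.2)), "fewer than 2")
  expect_equal(g1$diff, 0)

  same <- genome_specificity(c(a = 0.5, b = 0.7), c(a = 0.5, b = 0.7))
  expect_equal(same$diff, 0) # S_net = S_nonet cancels exactly

  s_net <- c(y = 0.9, a = 0.2, h = 0.5)
  s_non <- c(y = 0.6, a = 0.4, h = 0.5)
  g3 <- genome_specificity(s_net, s_non, "t1", "t2")
  # ordered sums count each unordered pair twice
  dn <- abs(c(0.9 - 0.2, 0.9 - 0.5, 0.2 - 0.5))
  dm <- abs(c(0.6 - 0.4, 0.6 - 0.5, 0.4 - 0.5))
  expect_equal(g3$diff_net, 2 * sum(dn), tolerance = 1e-12)
  expect_equal(g3$diff_nonet, 2 * sum(dm), tolerance = 1e-12)
  expect_equal(g3$diff, g3$diff_net - g3$diff_nonet, tolerance = 1e-12)
  expect_length(g3$components, 3L)
})

test_that("genome_specific_pairs flags constructed outliers and matches a BH oracle", {
  # baseline pairs: network changes nothing, all components exactly 0
  orgs <- letters[1:8]
  base <- lapply(1:30, function(i) {
    v <- setNames(rep(0.5, 8), orgs)
    genome_specificity(v, v, term_a = paste0("t", i), term_b = "tx")
  })
  # outlier: the network spreads the per-organism scores far apart
  outlier <- genome_specificity(setNames(seq(0, 1, length.out = 8), orgs),
                                setNames(rep(0.5, 8), orgs),
                                term_a = "t_out", term_b = "tx")
  res <- genome_specific_pairs(c(base, list(outlier)), alpha = 0.01)
  expect_true(res$significant[res$term_a == "t_out"])
  expect_false(any(res$significant[res$term_a != "t_out"]))
  expect_equal(res$fdr, oracle_bh(res$p_value), tolerance = 1e-12)

  # all-identical records: zero variance is not significant
  flat <- lapply(1:5, function(i)
    genome_specificity(setNames(rep(0.5, 3), letters[1:3]),
                       setNames(rep(0.3, 3), letters[1:3]),
                       term_a = paste0("f", i), term_b = "tx"))
  res2 <- genome_specific_pairs(flat)
  expect_false(any(res2$significant))
})
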