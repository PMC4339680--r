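# Benchmark machinery: metabolic reaction maps, the logged fold-change
# (LFC) statistic comparing within- vs between-pathway gene similarities,
# and the genome-specificity score.

#' Default currency-compound blacklist
#'
#' Ubiquitous metabolites excluded when linking reactions, because they
#' interconnect most of the map and create biologically unrealistic
#' shortcuts. Twenty-four entries; any real reproduction should supply
#' the compound list matching its pathway database's nomenclature.
#'
#' @return character vector of 24 compound names.
#' @export
currency_compounds <- function() {
  c("H2O", "H+", "ATP", "ADP", "AMP", "Pi", "PPi",
    "NAD+", "NADH", "NADP+", "NADPH", "FAD", "FADH2",
    "CO2", "O2", "NH3", "CoA", "acetyl-CoA",
    "UDP", "UTP", "GDP", "GTP",
    "S-adenosyl-L-methionine", "L-glutamate")
}

split_field_ <- function(x, sep = ",") {
  lapply(strsplit(as.character(x), sep, fixed = TRUE),
         function(v) sort(unique(trimws(v[nzchar(trimws(v))]))))
}

#' Build a metabolic reaction map
#'
#' Reactions become nodes; two reactions are adjacent when they share at
#' least one non-currency compound. Reactions with fewer than
#' \code{min_genes} genes are kept in the map but flagged (the benchmark
#' skips them, mirroring the removal of single-gene reactions).
#'
#' @param x a data.frame or TSV path with columns \code{reaction},
#'   \code{genes}, and either \code{substrates} and \code{products} or a
#'   single \code{compounds} column; list fields are comma-separated.
#' @param currency compound blacklist (default
#'   \code{\link{currency_compounds}}).
#' @param min_genes minimum genes per reaction for benchmarking
#'   (default 2).
#' @return a \code{ReactionMap}: list with \code{reactions},
#'   \code{genes_of}, \code{compounds_of}, \code{adjacency} (named list),
#'   \code{currency}, \code{small} (flagged reaction ids).
#' @export
build_reaction_map <- function(x, currency = currency_compounds(),
                               min_genes = 2L) {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.delim(x, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x), all(c("reaction", "genes") %in% names(x)))
  reactions <- as.character(x$reaction)
  if (anyDuplicated(reactions)) stop("duplicate reaction identifiers")
  genes_of <- stats::setNames(split_field_(x$genes), reactions)
  compounds <- if ("compounds" %in% names(x)) split_field_(x$compounds)
               else if (all(c("substrates", "products") %in% names(x))) {
                 mapply(function(s, p) sort(unique(c(s, p))),
                        split_field_(x$substrates), split_field_(x$products),
                        SIMPLIFY = FALSE)
               } else stop("need a 'compounds' column or 'substrates'/'products' columns")
  compounds_of <- stats::setNames(compounds, reactions)

  empty <- reactions[lengths(compounds_of) == 0L]
  if (length(empty)) {
    warning(sprintf("%d reaction(s) with no compounds are isolated: %s",
                    length(empty), paste(empty, collapse = ", ")))
  }

  adjacency <- stats::setNames(rep(list(character(0)), length(reactions)), reactions)
  cpd_to_rxn <- list()
  for (r in reactions) {
    for (cpd in setdiff(compounds_of[[r]], currency)) {
      cpd_to_rxn[[cpd]] <- c(cpd_to_rxn[[cpd]], r)
    }
  }
  for (rs in cpd_to_rxn) {
    if (length(rs) < 2L) next
    for (r in rs) adjacency[[r]] <- c(adjacency[[r]], setdiff(rs, r))
  }
  adjacency <- lapply(adjacency, function(v) sort(unique(v)))

  small <- reactions[lengths(genes_of) < min_genes]

  structure(list(reactions = reactions, genes_of = genes_of,
                 compounds_of = compounds_of, adjacency = adjacency,
                 currency = currency, min_genes = min_genes, small = small),
            class = "ReactionMap")
}

#' @export
print.ReactionMap <- function(x, ...) {
  cat(sprintf("ReactionMap: %d reactions (%d flagged as < %d genes), %d adjacency links\n",
              length(x$reactions), length(x$small), x$min_genes,
              sum(lengths(x$adjacency)) / 2))
  invisible(x)
}

#' Shortest-path distances between reactions
#'
#' Breadth-first distances over the adjacency graph; \code{Inf} for
#' unreachable pairs. Supports stratifying the benchmark by reaction
#' path length.
#'
#' @param map a \code{ReactionMap}.
#' @return symmetric numeric matrix of hop counts.
#' @export
reaction_distances <- function(map) {
  stopifnot(inherits(map, "ReactionMap"))
  rs <- map$reactions
  n <- length(rs)
  d <- matrix(Inf, n, n, dimnames = list(rs, rs))
  for (r in rs) {
    d[r, r] <- 0
    frontier <- r
    lvl <- 0
    while (length(frontier)) {
      lvl <- lvl + 1
      nxt <- setdiff(unique(unlist(map$adjacency[frontier], use.names = FALSE)),
                     rs[is.finite(d[r, ])])
      d[r, nxt] <- lvl
      frontier <- nxt
    }
  }
  d
}

#' LFC benchmark configuration
#'
#' @param c small positive smoothing constant added to every distance
#'   (default 0.001).
#' @param min_genes_per_reaction reactions with fewer genes are skipped
#'   (default 2).
#' @param max_path_length optional: restrict non-adjacent reactions to
#'   those within this many hops.
#' @return an \code{LfcConfig}.
#' @export
lfc_config <- function(c = 0.001, min_genes_per_reaction = 2L,
                       max_path_length = NULL) {
  stopifnot(c > 0)
  structure(list(c = c, min_genes_per_reaction = min_genes_per_reaction,
                 max_path_length = max_path_length),
            class = "LfcConfig")
}

# Adjacent / non-adjacent gene sets for a reaction, after ambiguity
# filtering: genes in both sets are dropped from both, and members of the
# reaction's own gene set are dropped from each.
lfc_sets_ <- function(map, r, cfg = lfc_config()) {
  adj_r <- map$adjacency[[r]]
  non_r <- setdiff(map$reactions, c(r, adj_r))
  if (!is.null(cfg$max_path_length)) {
    d <- reaction_distances(map)[r, non_r]
    non_r <- non_r[is.finite(d) & d <= cfg$max_path_length]
  }
  g_adj <- unique(unlist(map$genes_of[adj_r], use.names = FALSE))
  g_non <- unique(unlist(map$genes_of[non_r], use.names = FALSE))
  amb <- intersect(g_adj, g_non)
  g_adj <- setdiff(g_adj, amb)
  g_non <- setdiff(g_non, amb)
  g_r <- map$genes_of[[r]]
  list(adj = setdiff(g_adj, g_r), non = setdiff(g_non, g_r))
}

#' Logged fold change for one gene in one reaction
#'
#' The log ratio of the gene's mean distance (1 - GS + c) to genes of
#' non-adjacent reactions over its mean distance to genes of adjacent
#' reactions. Positive values mean the gene looks functionally closer to
#' its metabolic neighbourhood than to the rest of the map.
#'
#' @param g a gene in \code{G(r)}.
#' @param r a reaction identifier.
#' @param gs symmetric gene-similarity matrix with named dimensions.
#' @param map a \code{ReactionMap}.
#' @param cfg an \code{LfcConfig}.
#' @return the lfc value, or \code{NA} when either comparison set is
#'   empty after filtering (the reaction is skipped, with a log message).
#' @export
lfc_gene <- function(g, r, gs, map, cfg = lfc_config()) {
  stopifnot(inherits(map, "ReactionMap"))
  if (!g %in% map$genes_of[[r]]) {
    stop(sprintf("gene %s is not in reaction %s", g, r))
  }
  sets <- lfc_sets_(map, r, cfg)
  adj <- intersect(sets$adj, colnames(gs))
  non <- intersect(sets$non, colnames(gs))
  if (!g %in% rownames(gs) || !length(adj) || !length(non)) {
    message(sprintf("lfc(%s, %s): empty comparison set after filtering; skipped", g, r))
    return(NA_real_)
  }
  log(mean(1 - gs[g, non] + cfg$c) / mean(1 - gs[g, adj] + cfg$c))
}

#' Logged fold change for a reaction
#'
#' Mean of \code{\link{lfc_gene}} over the reaction's genes present in
#' the similarity matrix.
#'
#' @inheritParams lfc_gene
#' @return the reaction LFC, or \code{NA} if every gene was skipped.
#' @export
lfc_reaction <- function(r, gs, map, cfg = lfc_config()) {
  genes <- intersect(map$genes_of[[r]], rownames(gs))
  if (!length(genes)) return(NA_real_)
  vals <- vapply(genes, function(g) lfc_gene(g, r, gs, map, cfg), numeric(1))
  vals <- vals[is.finite(vals)]
  if (!length(vals)) NA_real_ else mean(vals)
}

#' LFC benchmark over several measures
#'
#' Computes the per-reaction LFC for each supplied gene-similarity
#' matrix, the per-measure winner counts (argmax per reaction, ties going
#' to the lexicographically first measure), and median/quartile
#' summaries. Reactions flagged as too small are skipped.
#'
#' @param map a \code{ReactionMap}.
#' @param gs_list named list of gene-similarity matrices, one per
#'   measure.
#' @param cfg an \code{LfcConfig}.
#' @return an \code{LfcBenchmark}: list with \code{per_reaction}
#'   (data.frame), \code{winners} (named integer vector) and
#'   \code{summary} (median, 25th, 75th percentile per measure).
#' @export
lfc_benchmark <- function(map, gs_list, cfg = lfc_config()) {
  stopifnot(inherits(map, "ReactionMap"), is.list(gs_list),
            !is.null(names(gs_list)), all(nzchar(names(gs_list))))
  rs <- setdiff(map$reactions,
                map$reactions[lengths(map$genes_of) < cfg$min_genes_per_reaction])
  tab <- vapply(gs_list, function(gs) {
    vapply(rs, function(r) lfc_reaction(r, gs, map, cfg), numeric(1))
  }, numeric(length(rs)))
  tab <- matrix(tab, nrow = length(rs),
                dimnames = list(rs, names(gs_list)))

  winners <- stats::setNames(integer(length(gs_list)), sort(names(gs_list)))
  for (r in rs) {
    row <- tab[r, ]
    if (all(is.na(row))) next
    best <- sort(names(row)[which(row == max(row, na.rm = TRUE))])[1L]
    winners[best] <- winners[best] + 1L
  }

  summ <- do.call(rbind, lapply(names(gs_list), function(m) {
    v <- tab[, m]
    data.frame(measure = m,
               median = stats::median(v, na.rm = TRUE),
               q25 = unname(stats::quantile(v, 0.25, na.rm = TRUE)),
               q75 = unname(stats::quantile(v, 0.75, na.rm = TRUE)),
               n = sum(is.finite(v)),
               stringsAsFactors = FALSE)
  }))

  structure(list(per_reaction = data.frame(reaction = rs, tab,
                                           check.names = FALSE,
                                           stringsAsFactors = FALSE),
                 winners = winners, summary = summ),
            class = "LfcBenchmark")
}

#' @export
print.LfcBenchmark <- function(x, ...) {
  cat("LFC benchmark\n")
  print(x$summary, row.names = FALSE)
  cat("winner counts:\n")
  print(x$winners)
  invisible(x)
}

#' Genome-specificity of a term pair
#'
#' How much more the similarity of a term pair disagrees between
#' organisms when the co-function network is used than when it is not:
#' \code{Diff = Diff_net - Diff_nonet}, each an ordered sum over organism
#' pairs of absolute similarity differences. The per-organism-pair
#' components (unordered) feed the significance test.
#'
#' @param s_net named numeric vector: per-organism similarity with the
#'   network.
#' @param s_nonet named numeric vector: per-organism similarity without
#'   the network.
#' @param term_a,term_b optional term identifiers for bookkeeping.
#' @return a \code{GenomeSpecificity}: list with \code{diff_net},
#'   \code{diff_nonet}, \code{diff} and \code{components}. Fewer than two
#'   shared organisms gives Diff = 0 with a warning.
#' @export
genome_specificity <- function(s_net, s_nonet, term_a = NA_character_,
                               term_b = NA_character_) {
  orgs <- intersect(names(s_net), names(s_nonet))
  k <- length(orgs)
  if (k < 2L) {
    warning("fewer than 2 organisms; genome specificity is 0")
    comp <- numeric(0)
    dnet <- dnonet <- 0
  } else {
    pairs <- utils::combn(orgs, 2L)
    dn <- abs(s_net[pairs[1L, ]] - s_net[pairs[2L, ]])
    dm <- abs(s_nonet[pairs[1L, ]] - s_nonet[pairs[2L, ]])
    comp <- unname(dn - dm)
    dnet <- 2 * sum(dn)     # ordered sum counts each unordered pair twice
    dnonet <- 2 * sum(dm)
  }
  structure(list(term_a = term_a, term_b = term_b,
                 s_net = s_net[orgs], s_nonet = s_nonet[orgs],
                 diff_net = dnet, diff_nonet = dnonet,
                 diff = dnet - dnonet, components = comp),
            class = "GenomeSpecificity")
}

#' Flag genome-specific term pairs
#'
#' Tests, per term pair, whether its organism-pair difference components
#' depart from the pooled mean component over all pairs (one-sample
#' t-test), with Benjamini-Hochberg correction. Pairs with fewer than two
#' components are excluded; zero-variance pairs are treated as not
#' significant.
#'
#' @param records list of \code{GenomeSpecificity} objects.
#' @param alpha FDR threshold (default 0.01).
#' @return data.frame with columns \code{term_a}, \code{term_b},
#'   \code{diff}, \code{n_components}, \code{p_value}, \code{fdr},
#'   \code{significant}.
#' @export
genome_specific_pairs <- function(records, alpha = 0.01) {
  stopifnot(is.list(records),
            all(vapply(records, inherits, logical(1), "GenomeSpecificity")))
  comps <- lapply(records, `[[`, "components")
  usable <- lengths(comps) >= 2L
  if (any(!usable)) {
    message(sprintf("excluding %d pair(s) with fewer than 2 components", sum(!usable)))
  }
  records <- records[usable]
  comps <- comps[usable]
  if (!length(records)) {
    return(data.frame(term_a = character(), term_b = character(),
                      diff = numeric(), n_components = integer(),
                      p_value = numeric(), fdr = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  mu <- mean(unlist(comps))
  p <- vapply(comps, function(x) {
    if (stats::sd(x) == 0) return(1) # no within-pair variance: untestable
    stats::t.test(x, mu = mu)$p.value
  }, numeric(1))
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(term_a = vapply(records, `[[`, character(1), "term_a"),
             term_b = vapply(records, `[[`, character(1), "term_b"),
             diff = vapply(records, `[[`, numeric(1), "diff"),
             n_components = lengths(comps),
             p_value = p, fdr = fdr,
             significant = fdr < alpha,
             stringsAsFactors = FALSE)
}
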