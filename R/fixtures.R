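# Fixture generators: the worked-example toy world, seeded random
# ontology/annotation/network bundles, and the constructed-signal
# benchmark world. Everything regenerates bit-identically from its seed
# and manifest.

new_fixture_ <- function(dag, annots, net, reactions, seed, manifest) {
  structure(list(dag = dag, annots = annots, net = net,
                 reactions = reactions, seed = seed, manifest = manifest),
            class = "FixtureBundle")
}

#' @export
print.FixtureBundle <- function(x, ...) {
  cat(sprintf("FixtureBundle (%s): %d terms, %d genes, %d network edges%s\n",
              x$manifest$type %||% "?", length(x$dag$terms),
              length(x$annots$universe), nrow(x$net$edges),
              if (is.null(x$reactions)) ""
              else sprintf(", %d reactions", length(x$reactions$reactions))))
  invisible(x)
}

#' The worked-example toy world
#'
#' A fixed eleven-term ontology (root plus t_a..t_j) annotated with genes
#' g1..g13 and a small co-function network, arranged so that all the
#' worked examples hold: t_i and t_j are common ancestors of t_a and t_b,
#' the path term sets to t_i and t_j are \{t_a,t_b,t_c,t_e,t_h,t_i\} and
#' \{t_a,t_b,t_c,t_f,t_j\}, the path-constrained set U(t_a,t_b,t_j) is
#' \{g1,g2,g3,g5,g6,g7,g10,g11\} (excluding every gene annotated to the
#' off-path terms t_d and t_g), removing \{g6,g7\} leaves the propagated
#' sets of t_b, t_e, t_f as \{g1,g5\}, \{g1,g5,g8\}, \{g1,g2,g3,g4\}, and
#' the network holds a three-gene set (in the manifest as \code{gb})
#' containing g1 at distance 0.99 from its other two members while g2 has
#' no edge into it. A three-reaction toy map (with an ATP-only link that
#' the currency filter must ignore) is attached.
#'
#' @return a \code{FixtureBundle}.
#' @export
figure1_fixture <- function() {
  edges <- data.frame(
    child    = c("t_c", "t_a", "t_a", "t_e", "t_h", "t_b", "t_b", "t_f",
                 "t_d", "t_g", "t_i", "t_j"),
    parent   = c("t_a", "t_e", "t_f", "t_h", "t_i", "t_i", "t_j", "t_j",
                 "t_f", "t_j", "root", "root"),
    relation = c("is_a", "is_a", "is_a", "is_a", "is_a", "is_a", "part_of",
                 "is_a", "part_of", "is_a", "is_a", "is_a"),
    stringsAsFactors = FALSE)
  dag <- ontology_dag(edges)

  direct <- list(
    t_a = c("g6", "g7"),
    t_b = c("g1", "g5", "g6", "g7"),
    t_c = "g1",
    t_d = "g4",
    t_e = c("g5", "g8"),
    t_f = c("g2", "g3"),
    t_g = "g9",
    t_h = "g12",
    t_i = "g13",
    t_j = c("g10", "g11"))
  annots <- propagate(annotation_set(direct, namespace = "biological_process"), dag)

  net <- cofunction_network(data.frame(
    gene1 = c("g1", "g1", "g2", "g3", "g6", "g10"),
    gene2 = c("g5", "g8", "g3", "g4", "g7", "g11"),
    conf  = c(0.01, 0.01, 0.80, 0.60, 0.93, 0.70),
    stringsAsFactors = FALSE))

  reactions <- build_reaction_map(data.frame(
    reaction   = c("R1", "R2", "R3"),
    genes      = c("g1,g5", "g6,g7", "g2,g3"),
    substrates = c("glucose", "pyruvate,ATP", "ATP,NAD+"),
    products   = c("pyruvate", "acetaldehyde,CO2", "oxaloacetate"),
    stringsAsFactors = FALSE))

  new_fixture_(dag, annots, net, reactions, NA_integer_,
               list(type = "figure1", gb = c("g1", "g5", "g8")))
}

#' Seeded random fixture
#'
#' Generates a layered random DAG (every non-root term draws 1-3 parents
#' among earlier terms, so acyclicity holds by construction), direct
#' annotations with at least one term per gene, and a random network with
#' uniform confidences. Deterministic per seed.
#'
#' @param n_terms number of terms including the root.
#' @param n_genes number of genes.
#' @param annot_density probability of each extra (gene, term) annotation,
#'   in [0, 1]; every gene always keeps at least one.
#' @param net_density probability of each gene-pair edge, in [0, 1]; 0
#'   yields an empty network.
#' @param seed integer seed.
#' @param part_of_prob probability that an edge is part_of rather than
#'   is_a.
#' @return a \code{FixtureBundle} (no reaction map).
#' @export
random_fixture <- function(n_terms = 20L, n_genes = 30L,
                           annot_density = 0.1, net_density = 0.1,
                           seed = 1L, part_of_prob = 0.2) {
  stopifnot(n_terms >= 2L, n_genes >= 1L,
            annot_density >= 0, annot_density <= 1,
            net_density >= 0, net_density <= 1)
  with_seed_(seed, {
    terms <- c("root", sprintf("t%02d", seq_len(n_terms - 1L)))
    ch <- character(0); pa <- character(0)
    for (i in 2L:n_terms) {
      k <- sample.int(min(3L, i - 1L), 1L)
      parents <- if (i == 2L) "root" else sample(terms[seq_len(i - 1L)], k)
      ch <- c(ch, rep(terms[i], length(parents)))
      pa <- c(pa, parents)
    }
    rel <- ifelse(stats::runif(length(ch)) < part_of_prob, "part_of", "is_a")
    dag <- ontology_dag(data.frame(child = ch, parent = pa, relation = rel,
                                   stringsAsFactors = FALSE), terms = terms)

    genes <- sprintf("g%02d", seq_len(n_genes))
    annotatable <- terms[-1L]
    g_col <- character(0); t_col <- character(0)
    for (g in genes) {
      base <- sample(annotatable, 1L)
      extra <- annotatable[stats::runif(length(annotatable)) < annot_density]
      ts <- unique(c(base, extra))
      g_col <- c(g_col, rep(g, length(ts)))
      t_col <- c(t_col, ts)
    }
    direct <- lapply(split(g_col, t_col), unique)
    annots <- propagate(annotation_set(direct, namespace = "biological_process"), dag)

    if (n_genes >= 2L) {
      pairs <- utils::combn(genes, 2L)
      sel <- stats::runif(ncol(pairs)) < net_density
      net <- cofunction_network(data.frame(gene1 = pairs[1L, sel],
                                           gene2 = pairs[2L, sel],
                                           conf = stats::runif(sum(sel)),
                                           stringsAsFactors = FALSE),
                                nodes = genes)
    } else {
      net <- cofunction_network(nodes = genes)
    }

    new_fixture_(dag, annots, net, NULL, as.integer(seed),
                 list(type = "random", n_terms = n_terms, n_genes = n_genes,
                      annot_density = annot_density, net_density = net_density,
                      part_of_prob = part_of_prob, seed = as.integer(seed)))
  })
}

#' Randomly thin direct annotations, keeping one per gene
#'
#' Deletes a seeded random subset of the direct (gene, term) annotations
#' down to the requested coverage, always retaining at least one
#' annotation per gene so the same gene set remains comparable across
#' coverage levels.
#'
#' @param annots an \code{AnnotationSet} (propagation is discarded;
#'   re-propagate afterwards).
#' @param coverage target fraction of annotations to keep, in (0, 1].
#' @param seed optional integer seed.
#' @return a direct-only \code{AnnotationSet}.
#' @export
delete_annotations <- function(annots, coverage, seed = NULL) {
  stopifnot(inherits(annots, "AnnotationSet"), coverage > 0, coverage <= 1)
  genes <- unlist(annots$direct, use.names = FALSE)
  terms <- rep(names(annots$direct), lengths(annots$direct))
  n <- length(genes)
  with_seed_(seed, {
    ord <- sample.int(n) # random priority per annotation
    forced <- vapply(split(ord, genes), min, numeric(1)) # best-priority row per gene
    keep_n <- max(length(forced), round(coverage * n))
    keep_priorities <- sort(unique(c(forced,
                                     setdiff(sort(ord), forced)[seq_len(max(0L, keep_n - length(forced)))])))
    keep <- ord %in% keep_priorities
    annotation_set(lapply(split(genes[keep], terms[keep]), unique),
                   namespace = annots$namespace)
  })
}

#' Constructed-signal benchmark world
#'
#' A synthetic world where metabolic adjacency is encoded in the
#' co-function network but not in the ontology: reactions form a chain
#' (consecutive reactions share a pathway intermediate; every reaction
#' also touches ATP, which the currency filter must ignore), each
#' reaction's genes are annotated to a reaction-specific process term,
#' those terms hang off randomly chosen mid-level terms, and network
#' edges (confidence \code{conf}) connect genes within a reaction and
#' across adjacent reactions only. Annotation placement is random, so an
#' annotation-only measure sees no adjacency signal; the network is the
#' only carrier of it.
#'
#' @param n_reactions number of reactions in the chain.
#' @param genes_per_reaction genes catalyzing each reaction.
#' @param n_mid_terms mid-level ontology terms between root and the
#'   reaction terms.
#' @param conf confidence of the signal edges.
#' @param seed integer seed.
#' @return a \code{FixtureBundle} with a reaction map.
#' @export
signal_fixture <- function(n_reactions = 12L, genes_per_reaction = 3L,
                           n_mid_terms = 4L, conf = 0.9, seed = 1L) {
  stopifnot(n_reactions >= 3L, genes_per_reaction >= 2L, n_mid_terms >= 2L,
            conf > 0, conf <= 1)
  with_seed_(seed, {
    rxn <- sprintf("R%02d", seq_len(n_reactions))
    mids <- sprintf("m%02d", seq_len(n_mid_terms))
    rterms <- sprintf("t%s", rxn)
    edges <- rbind(
      data.frame(child = mids, parent = "root", relation = "is_a",
                 stringsAsFactors = FALSE),
      data.frame(child = rterms, parent = sample(mids, n_reactions, replace = TRUE),
                 relation = "is_a", stringsAsFactors = FALSE))
    dag <- ontology_dag(edges, terms = c("root", mids, rterms))

    genes_of <- lapply(seq_len(n_reactions), function(i) {
      sprintf("g%s_%d", rxn[i], seq_len(genes_per_reaction))
    })
    names(genes_of) <- rxn
    direct <- stats::setNames(genes_of, rterms)
    annots <- propagate(annotation_set(direct, namespace = "biological_process"), dag)

    g1 <- character(0); g2 <- character(0)
    for (i in seq_len(n_reactions)) {
      within <- utils::combn(genes_of[[i]], 2L)
      g1 <- c(g1, within[1L, ]); g2 <- c(g2, within[2L, ])
      if (i < n_reactions) {
        cross <- expand.grid(a = genes_of[[i]], b = genes_of[[i + 1L]],
                             stringsAsFactors = FALSE)
        g1 <- c(g1, cross$a); g2 <- c(g2, cross$b)
      }
    }
    net <- cofunction_network(data.frame(gene1 = g1, gene2 = g2, conf = conf,
                                         stringsAsFactors = FALSE))

    intermediates <- sprintf("cpd%02d", seq_len(n_reactions + 1L))
    rtab <- data.frame(
      reaction = rxn,
      genes = vapply(genes_of, paste, character(1), collapse = ","),
      substrates = paste(intermediates[seq_len(n_reactions)], "ATP", sep = ","),
      products = intermediates[-1L],
      stringsAsFactors = FALSE)
    rmap <- build_reaction_map(rtab)

    new_fixture_(dag, annots, net, rmap, as.integer(seed),
                 list(type = "signal", n_reactions = n_reactions,
                      genes_per_reaction = genes_per_reaction,
                      n_mid_terms = n_mid_terms, conf = conf,
                      seed = as.integer(seed)))
  })
}

#' Write a fixture bundle to files
#'
#' Emits OBO, GAF, a network edge list, an optional reaction table and a
#' JSON manifest, so end-to-end command-line runs have real files.
#'
#' @param bundle a \code{FixtureBundle}.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "FixtureBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(obo = file.path(dir, "fixture.obo"),
             gaf = file.path(dir, "fixture.gaf"),
             network = file.path(dir, "network.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write_obo(bundle$dag, paths[["obo"]])
  write_gaf(bundle$annots, paths[["gaf"]])
  write_network(bundle$net, paths[["network"]])
  if (!is.null(bundle$reactions)) {
    paths["reactions"] <- file.path(dir, "reactions.tsv")
    rm_ <- bundle$reactions
    df <- data.frame(reaction = rm_$reactions,
                     genes = vapply(rm_$genes_of, paste, character(1), collapse = ","),
                     compounds = vapply(rm_$compounds_of, paste, character(1), collapse = ","),
                     stringsAsFactors = FALSE)
    utils::write.table(df, paths[["reactions"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest, paths[["manifest"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}
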