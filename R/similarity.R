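# Term-to-term similarity: the network-aware NETSIM measure, its ablation
# variants, and the Resnik, Schlicker and Wang baselines.
#
# Notation (per pair of terms t_a, t_b with common ancestor p):
#   G_a, G_b, G_p  propagated gene sets; G the annotation universe
#   D              gene-set distance on the co-function network
#   U              path-constrained annotation set
#   f, h           annotation-importance and ancestor-specificity weights
#   S              the similarity in [0, 1]
# Natural logarithms throughout; the leading factor of S is a ratio of
# logs, so the base cancels, but fixing it keeps results bit-reproducible.

#' Measure configuration
#'
#' @param measure one of \code{netsim} (full measure), \code{netsim_v1}
#'   (mean pairwise distance instead of the product-form gene-set
#'   distance), \code{netsim_v2} (no path constraint: U is the ancestor's
#'   full propagated set), \code{netsim_v3} (Schlicker-style specificity
#'   weight), \code{resnik}, \code{schlicker}, \code{wang}.
#' @param wang_weights semantic-contribution factors per edge relation for
#'   the Wang measure; the original defaults are 0.8 (is_a) and 0.6
#'   (part_of). Must lie in (0, 1).
#' @return a \code{MeasureConfig}.
#' @export
measure_config <- function(measure = c("netsim", "netsim_v1", "netsim_v2",
                                       "netsim_v3", "resnik", "schlicker",
                                       "wang"),
                           wang_weights = c(is_a = 0.8, part_of = 0.6)) {
  measure <- match.arg(measure)
  if (any(wang_weights <= 0 | wang_weights >= 1)) {
    stop("wang_weights must lie in (0, 1)")
  }
  structure(list(measure = measure, wang_weights = wang_weights),
            class = "MeasureConfig")
}

netsim_measures_ <- c("netsim", "netsim_v1", "netsim_v2", "netsim_v3")

check_propagated_ <- function(annots) {
  if (is.null(annots$propagated)) {
    stop("annotations are not propagated; call propagate() first")
  }
  invisible(annots)
}

prop_set_ <- function(annots, t) {
  s <- annots$propagated[[t]]
  if (is.null(s) || !length(s)) {
    stop(sprintf("term %s has an empty propagated annotation set", t))
  }
  s
}

#' Gene-set distance between two terms' annotation sets
#'
#' A modified Czekanovski-Dice distance: each gene's distance to the
#' opposite set is the product of its pairwise network distances, so one
#' strong link (or shared gene) is enough to pull a gene close to a set.
#' With no network and disjoint sets the distance is exactly 1; as all
#' confidences vanish it tends to the plain Czekanovski-Dice set-overlap
#' distance.
#'
#' @param net a \code{CoFunctionNetwork} or NULL.
#' @param G_a,G_b nonempty character vectors of genes.
#' @return distance D in [0, 1].
#' @export
gene_set_distance <- function(net, G_a, G_b) {
  if (!length(G_a) || !length(G_b)) stop("gene sets must be nonempty")
  s1 <- sum(vapply(G_a, function(g) gene_to_set_distance(net, g, G_b), numeric(1)))
  s2 <- sum(vapply(G_b, function(g) gene_to_set_distance(net, g, G_a), numeric(1)))
  u <- length(unique(c(G_a, G_b)))
  (s1 + s2) / (2 * u - s1 - s2)
}

#' Mean-pairwise gene-set distance (ablation variant v1)
#'
#' The average of all pairwise distances between the two sets, i.e. the
#' normalized summed edge weights, replacing the product form.
#'
#' @inheritParams gene_set_distance
#' @return distance in [0, 1].
#' @export
gene_set_distance_v1 <- function(net, G_a, G_b) {
  if (!length(G_a) || !length(G_b)) stop("gene sets must be nonempty")
  tot <- 0
  for (gi in G_a) {
    tot <- tot + sum(vapply(G_b, function(gj) pair_distance(net, gi, gj), numeric(1)))
  }
  tot / (length(G_a) * length(G_b))
}

#' Path-constrained annotation set U
#'
#' The union of the propagated sets of the two compared terms with the
#' direct annotations of every term lying on the upward paths from either
#' term to the common ancestor \code{p}. Interior path terms contribute
#' their direct annotations only: propagating them would re-admit exactly
#' the off-path descendant genes the constraint exists to exclude.
#'
#' @param dag an \code{OntologyDAG}.
#' @param annots a propagated \code{AnnotationSet}.
#' @param t_a,t_b the compared terms.
#' @param p a common ancestor.
#' @return sorted character vector of genes.
#' @export
path_constrained_annotation <- function(dag, annots, t_a, t_b, p) {
  check_propagated_(annots)
  pt <- path_terms(dag, t_a, t_b, p)
  sort(unique(c(annots$propagated[[t_a]],
                annots$propagated[[t_b]],
                unlist(annots$direct[intersect(pt, names(annots$direct))],
                       use.names = FALSE))))
}

#' Network-aware term similarity at a fixed common ancestor
#'
#' Computes, for terms \code{t_a}, \code{t_b} and common ancestor
#' \code{p}:
#' \deqn{f = D^2 |U| + (1 - D^2) \sqrt{|G_a||G_b|}}
#' \deqn{h = D^2 |G| + (1 - D^2) \max(|G_a|, |G_b|)}
#' \deqn{S = \frac{2\ln|G| - 2\ln f}{2\ln|G| - (\ln|G_a| + \ln|G_b|)}
#'        \left(1 - \frac{h}{|G|}\frac{|G_p|}{|G|}\right)}
#' Variants: \code{netsim_v1} replaces D by the mean pairwise distance;
#' \code{netsim_v2} uses \code{U = G_p}; \code{netsim_v3} replaces the
#' second factor by \code{1 - |G_p|/|G|}. When the network is absent or
#' empty, \code{U = G_p}, under which the measure reduces exactly to
#' Schlicker's for disjoint gene sets (D = 1) and to
#' \code{1 - (|G_t|/|G|)^2} for self-similarity (D = 0). When both terms
#' are annotated to the whole universe the leading log-ratio is 0/0 and S
#' is defined as 0: such terms carry no information.
#'
#' @param dag an \code{OntologyDAG}.
#' @param annots a propagated \code{AnnotationSet}.
#' @param net a \code{CoFunctionNetwork} or NULL.
#' @param t_a,t_b the compared terms (nonempty propagated sets).
#' @param p a common ancestor with a nonempty propagated set.
#' @param cfg a \code{MeasureConfig} with a netsim-family measure.
#' @return a \code{SimilarityResult}: list with \code{term_a},
#'   \code{term_b}, \code{ancestor}, \code{D}, \code{U}, \code{f},
#'   \code{h}, \code{S}, \code{measure}.
#' @export
term_similarity <- function(dag, annots, net, t_a, t_b, p,
                            cfg = measure_config()) {
  stopifnot(inherits(cfg, "MeasureConfig"))
  if (!cfg$measure %in% netsim_measures_) {
    stop("term_similarity() is defined for the netsim family; use ",
         "resnik(), schlicker() or wang() directly")
  }
  check_propagated_(annots)
  if (!p %in% common_ancestors(dag, t_a, t_b)) {
    stop(sprintf("%s is not a common ancestor of %s and %s", p, t_a, t_b))
  }
  Ga <- prop_set_(annots, t_a)
  Gb <- prop_set_(annots, t_b)
  Gp <- prop_set_(annots, p)
  G <- annots$universe
  if (!length(G)) stop("empty annotation universe")
  nG <- length(G)

  D <- if (cfg$measure == "netsim_v1") gene_set_distance_v1(net, Ga, Gb)
       else gene_set_distance(net, Ga, Gb)

  net_empty <- is.null(net) || nrow(net$edges) == 0L
  U <- if (net_empty || cfg$measure == "netsim_v2") Gp
       else path_constrained_annotation(dag, annots, t_a, t_b, p)

  D2 <- D^2
  f <- D2 * length(U) + (1 - D2) * sqrt(length(Ga) * length(Gb))
  h <- D2 * nG + (1 - D2) * max(length(Ga), length(Gb))

  den <- 2 * log(nG) - (log(length(Ga)) + log(length(Gb)))
  first <- if (den <= 0) 0 else (2 * log(nG) - 2 * log(f)) / den
  second <- if (cfg$measure == "netsim_v3") 1 - length(Gp) / nG
            else 1 - (h / nG) * (length(Gp) / nG)
  # provably in [0, 1]; clamp the ~1e-16 float noise at the boundaries
  # (f -> |G| makes the leading log difference round below zero)
  S <- min(1, max(0, first * second))
  structure(list(term_a = t_a, term_b = t_b, ancestor = p,
                 D = D, U = U, f = f, h = h, S = S,
                 measure = cfg$measure),
            class = "SimilarityResult")
}

#' @export
print.SimilarityResult <- function(x, ...) {
  cat(sprintf("%s(%s, %s | p = %s): S = %.6g (D = %.6g, |U| = %d, f = %.6g, h = %.6g)\n",
              x$measure, x$term_a, x$term_b, x$ancestor, x$S, x$D,
              length(x$U), x$f, x$h))
  invisible(x)
}

#' Term similarity maximized over common ancestors
#'
#' For the netsim family, evaluates \code{\link{term_similarity}} at
#' every common ancestor with a nonempty propagated set and returns the
#' maximum; ties report the lexicographically smallest maximizer. For
#' \code{resnik}, \code{schlicker} and \code{wang} the corresponding
#' baseline is returned.
#'
#' @inheritParams term_similarity
#' @return a numeric scalar S with attributes \code{ancestor} (the best
#'   ancestor, or the LCA for the IC baselines; NA for Wang) and
#'   \code{D} (netsim family only).
#' @export
term_similarity_max <- function(dag, annots, net, t_a, t_b,
                                cfg = measure_config()) {
  stopifnot(inherits(cfg, "MeasureConfig"))
  if (cfg$measure == "resnik") return(resnik(dag, annots, t_a, t_b))
  if (cfg$measure == "schlicker") return(schlicker(dag, annots, t_a, t_b))
  if (cfg$measure == "wang") {
    out <- wang(dag, t_a, t_b, cfg)
    attr(out, "ancestor") <- NA_character_
    return(out)
  }
  check_propagated_(annots)
  ps <- sort(common_ancestors(dag, t_a, t_b))
  ps <- ps[vapply(ps, function(p) length(annots$propagated[[p]]) > 0L, logical(1))]
  if (!length(ps)) stop("no common ancestor with a nonempty propagated set")
  best <- NULL
  for (p in ps) { # sorted: first maximizer is the lexicographically smallest
    res <- term_similarity(dag, annots, net, t_a, t_b, p, cfg)
    if (is.null(best) || res$S > best$S) best <- res
  }
  structure(best$S, ancestor = best$ancestor, D = best$D)
}

#' Information content of a term
#'
#' Minus the natural log of the fraction of the annotation universe
#' covered by the term's propagated gene set.
#'
#' @param annots a propagated \code{AnnotationSet}.
#' @param t a term identifier.
#' @return IC in [0, Inf).
#' @export
term_ic <- function(annots, t) {
  check_propagated_(annots)
  -log(length(prop_set_(annots, t)) / length(annots$universe))
}

# Common ancestor with maximal information content (ties resolved to the
# lexicographically smallest term).
lca_ <- function(dag, annots, t_a, t_b) {
  ps <- sort(common_ancestors(dag, t_a, t_b))
  ps <- ps[vapply(ps, function(p) length(annots$propagated[[p]]) > 0L, logical(1))]
  if (!length(ps)) stop("no common ancestor with a nonempty propagated set")
  ics <- vapply(ps, function(p) term_ic(annots, p), numeric(1))
  list(lca = ps[which.max(ics)], ic = max(ics))
}

#' Resnik similarity
#'
#' The information content of the most informative common ancestor.
#'
#' @param dag an \code{OntologyDAG}.
#' @param annots a propagated \code{AnnotationSet}.
#' @param t_a,t_b terms with nonempty propagated sets.
#' @return IC(LCA) with attribute \code{ancestor} (the LCA).
#' @export
resnik <- function(dag, annots, t_a, t_b) {
  check_propagated_(annots)
  prop_set_(annots, t_a); prop_set_(annots, t_b)
  l <- lca_(dag, annots, t_a, t_b)
  structure(l$ic, ancestor = l$lca)
}

#' Schlicker similarity
#'
#' Resnik normalized by the terms' own information contents and damped
#' by the LCA's annotation frequency. Defined as 0 when both terms have
#' zero information content (both are roots).
#'
#' @inheritParams resnik
#' @return similarity in [0, 1] with attribute \code{ancestor} (the LCA).
#' @export
schlicker <- function(dag, annots, t_a, t_b) {
  check_propagated_(annots)
  ica <- term_ic(annots, t_a)
  icb <- term_ic(annots, t_b)
  l <- lca_(dag, annots, t_a, t_b)
  s <- if (ica + icb == 0) 0
       else (2 * l$ic / (ica + icb)) *
            (1 - length(annots$propagated[[l$lca]]) / length(annots$universe))
  structure(s, ancestor = l$lca)
}

#' Wang graph-based similarity
#'
#' Purely topological: each ancestor p of a term t receives a semantic
#' contribution S_{t,p}, the maximum over paths from t to p of the
#' product of per-edge weights, with S_{t,t} = 1. The similarity is the
#' summed contribution over shared ancestors divided by the total
#' contribution over each term's own ancestors.
#'
#' @param dag an \code{OntologyDAG}.
#' @param t_a,t_b terms in the same namespace.
#' @param cfg a \code{MeasureConfig} carrying \code{wang_weights}.
#' @return similarity in (0, 1].
#' @export
wang <- function(dag, t_a, t_b, cfg = measure_config("wang")) {
  check_term_(dag, t_a); check_term_(dag, t_b)
  if (dag$namespace[[t_a]] != dag$namespace[[t_b]]) {
    stop("terms are in different namespaces")
  }
  w <- cfg$wang_weights
  svalues <- function(t) {
    anc <- ancestors(dag, t)
    s <- stats::setNames(numeric(length(anc)), anc)
    s[t] <- 1
    for (p in dag$topo[dag$topo %in% anc]) { # children before parents
      if (p == t) next
      kids <- intersect(dag$children[[p]], anc)
      contrib <- vapply(kids, function(ch) {
        rel <- edge_relation_(dag, ch, p)
        if (is.na(w[rel])) stop(sprintf("no Wang weight for relation '%s'", rel))
        w[[rel]] * s[[ch]]
      }, numeric(1))
      s[p] <- max(contrib)
    }
    s
  }
  sa <- svalues(t_a)
  sb <- svalues(t_b)
  shared <- intersect(names(sa), names(sb))
  (sum(sa[shared]) + sum(sb[shared])) / (sum(sa) + sum(sb))
}

#' Pairwise term-similarity matrix
#'
#' @param dag an \code{OntologyDAG}.
#' @param annots a propagated \code{AnnotationSet}.
#' @param net a \code{CoFunctionNetwork} or NULL.
#' @param terms character vector of terms in one namespace; terms with an
#'   empty propagated set are skipped with a warning.
#' @param cfg a \code{MeasureConfig}.
#' @return symmetric numeric matrix of maximized similarities, with
#'   self-similarities on the diagonal.
#' @export
term_similarity_matrix <- function(dag, annots, net, terms,
                                   cfg = measure_config()) {
  check_propagated_(annots)
  ok <- vapply(terms, function(t) length(annots$propagated[[t]]) > 0L, logical(1))
  if (any(!ok)) {
    warning(sprintf("skipping %d term(s) with empty propagated sets: %s",
                    sum(!ok), paste(terms[!ok], collapse = ", ")))
  }
  keep <- terms[ok]
  n <- length(keep)
  m <- matrix(NA_real_, n, n, dimnames = list(keep, keep))
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- as.numeric(term_similarity_max(dag, annots, net, keep[i], keep[j], cfg))
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}
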