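# Gene-to-gene functional similarity: best-match aggregation of term
# similarities with leave-one-out removal of the evaluated pair.

#' Gene-to-gene functional similarity (leave-one-out)
#'
#' Aggregates term similarities into a gene similarity. To avoid circular
#' use of data, the two genes are first removed from every term's gene
#' sets and from the annotation universe; their own direct term sets
#' T_i, T_j are taken from the original annotation. Each term's best
#' match against the other gene's term set is computed under the reduced
#' annotation, and
#' \deqn{GS = \frac{\sum_{t \in T_i} Sim(t, T_j) + \sum_{t \in T_j} Sim(t, T_i)}{|T_i| + |T_j|}}
#' where only non-zero best matches contribute to the numerator. A term
#' whose propagated set empties after removal contributes 0. The
#' alternative reading of "only non-zero values are counted" (shrinking
#' the denominator too) is available via \code{nonzero_denominator}.
#'
#' @param dag an \code{OntologyDAG}.
#' @param annots a propagated \code{AnnotationSet}.
#' @param net a \code{CoFunctionNetwork} or NULL.
#' @param g_i,g_j gene identifiers with at least one annotation each.
#' @param cfg a \code{MeasureConfig}.
#' @param nonzero_denominator if TRUE, the denominator counts only terms
#'   with a non-zero best match (default FALSE, the printed formula).
#' @return a \code{GenePairScore}: list with \code{gene_i}, \code{gene_j},
#'   \code{GS}, \code{T_i}, \code{T_j} and \code{best_matches} (per-term
#'   best partner and similarity).
#' @export
gene_similarity <- function(dag, annots, net, g_i, g_j,
                            cfg = measure_config(),
                            nonzero_denominator = FALSE) {
  check_propagated_(annots)
  T_i <- annots$gene_terms[[g_i]]
  T_j <- annots$gene_terms[[g_j]]
  if (is.null(T_i) || !length(T_i)) stop(sprintf("gene %s has no annotations", g_i))
  if (is.null(T_j) || !length(T_j)) stop(sprintf("gene %s has no annotations", g_j))

  if (g_i == g_j) {
    # Self-similarity is a boundary convention, not a measurement:
    # leave-one-out would delete the gene's own annotations.
    return(structure(list(gene_i = g_i, gene_j = g_j, GS = 1,
                          T_i = T_i, T_j = T_j,
                          best_matches = NULL),
                     class = "GenePairScore"))
  }

  red <- remove_genes(annots, c(g_i, g_j))

  best_match <- function(t, T_other) {
    if (!length(red$propagated[[t]] %||% character(0))) {
      return(list(partner = NA_character_, sim = 0))
    }
    best <- 0
    partner <- NA_character_
    for (ty in T_other) {
      if (!length(red$propagated[[ty]] %||% character(0))) next
      v <- as.numeric(term_similarity_max(dag, red, net, t, ty, cfg))
      if (v > best) {
        best <- v
        partner <- ty
      }
    }
    list(partner = partner, sim = best)
  }

  mi <- lapply(T_i, best_match, T_other = T_j)
  mj <- lapply(T_j, best_match, T_other = T_i)
  sim_i <- vapply(mi, `[[`, numeric(1), "sim")
  sim_j <- vapply(mj, `[[`, numeric(1), "sim")

  num <- sum(sim_i[sim_i > 0]) + sum(sim_j[sim_j > 0])
  den <- if (nonzero_denominator) sum(sim_i > 0) + sum(sim_j > 0)
         else length(T_i) + length(T_j)
  gs <- if (den == 0) 0 else num / den

  bm <- data.frame(term = c(T_i, T_j),
                   side = rep(c(g_i, g_j), c(length(T_i), length(T_j))),
                   partner = c(vapply(mi, `[[`, character(1), "partner"),
                               vapply(mj, `[[`, character(1), "partner")),
                   sim = c(sim_i, sim_j),
                   stringsAsFactors = FALSE)

  structure(list(gene_i = g_i, gene_j = g_j, GS = gs,
                 T_i = T_i, T_j = T_j, best_matches = bm),
            class = "GenePairScore")
}

#' @export
print.GenePairScore <- function(x, ...) {
  cat(sprintf("GS(%s, %s) = %.6g  (|T_i| = %d, |T_j| = %d)\n",
              x$gene_i, x$gene_j, x$GS, length(x$T_i), length(x$T_j)))
  invisible(x)
}

#' Pairwise gene-similarity matrix
#'
#' @inheritParams gene_similarity
#' @param genes character vector of genes; unannotated genes are excluded
#'   with a warning.
#' @param ... passed on to \code{\link{gene_similarity}}.
#' @return symmetric numeric matrix of GS values with unit diagonal.
#' @export
gene_similarity_matrix <- function(dag, annots, net, genes,
                                   cfg = measure_config(), ...) {
  check_propagated_(annots)
  ok <- vapply(genes, function(g) !is.null(annots$gene_terms[[g]]), logical(1))
  if (any(!ok)) {
    warning(sprintf("excluding %d unannotated gene(s): %s",
                    sum(!ok), paste(genes[!ok], collapse = ", ")))
  }
  keep <- genes[ok]
  n <- length(keep)
  m <- matrix(NA_real_, n, n, dimnames = list(keep, keep))
  diag(m) <- 1
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        v <- gene_similarity(dag, annots, net, keep[i], keep[j], cfg, ...)$GS
        m[i, j] <- v
        m[j, i] <- v
      }
    }
  }
  m
}
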