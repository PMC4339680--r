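# Weighted gene co-function networks: parsing, gene-pair and gene-to-set
# distances, and the degree-preserving rewiring used for network-quality
# experiments.

#' Construct a co-function network
#'
#' An undirected gene graph whose edge confidences estimate the
#' probability that two genes are functionally linked. Confidences must
#' lie in [0, 1]; self-loops are dropped (the self distance is 0 by
#' definition, not by edge); duplicate edges keep the maximum confidence.
#'
#' @param edges data.frame with columns \code{gene1}, \code{gene2},
#'   \code{conf} (or any three columns in that order).
#' @param nodes optional additional isolated genes.
#' @param raw_score_range optional (min, max) of the input scores before
#'   normalization, kept for provenance.
#' @return an object of class \code{CoFunctionNetwork}.
#' @export
cofunction_network <- function(edges = NULL, nodes = NULL, raw_score_range = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(gene1 = character(), gene2 = character(),
                        conf = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges), ncol(edges) >= 3L)
  edges <- data.frame(gene1 = as.character(edges[[1L]]),
                      gene2 = as.character(edges[[2L]]),
                      conf = as.numeric(edges[[3L]]),
                      stringsAsFactors = FALSE)
  loops <- edges$gene1 == edges$gene2
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop edge(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (anyNA(edges$conf)) stop("non-numeric or missing confidence score")
  if (any(edges$conf < 0 | edges$conf > 1)) {
    stop("edge confidences must lie in [0, 1]; use parse_network(normalize = 'minmax')")
  }
  swap <- edges$gene1 > edges$gene2
  tmp <- edges$gene1[swap]
  edges$gene1[swap] <- edges$gene2[swap]
  edges$gene2[swap] <- tmp
  if (nrow(edges)) {
    key <- paste(edges$gene1, edges$gene2, sep = "\t")
    conf <- tapply(edges$conf, key, max)
    first <- !duplicated(key)
    edges <- edges[first, , drop = FALSE]
    edges$conf <- as.numeric(conf[paste(edges$gene1, edges$gene2, sep = "\t")])
    edges <- edges[order(edges$gene1, edges$gene2), , drop = FALSE]
    rownames(edges) <- NULL
  }
  index <- new.env(parent = emptyenv(), size = max(29L, nrow(edges)))
  for (i in seq_len(nrow(edges))) {
    assign(paste(edges$gene1[i], edges$gene2[i], sep = "\t"), edges$conf[i],
           envir = index)
  }
  structure(list(edges = edges,
                 nodes = sort(unique(c(nodes, edges$gene1, edges$gene2))),
                 index = index,
                 raw_score_range = raw_score_range),
            class = "CoFunctionNetwork")
}

#' @export
print.CoFunctionNetwork <- function(x, ...) {
  cat(sprintf("CoFunctionNetwork: %d genes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Parse a weighted edge list
#'
#' Reads a 3-column TSV (gene1, gene2, score), the format of published
#' functional networks (YeastNet/AraNet/HumanNet style). Published scores
#' are often log-likelihood values, so the default maps them affinely
#' onto [0, 1] using the observed min/max; with \code{normalize = "none"}
#' scores outside [0, 1] are an error.
#'
#' @param path path to the edge list.
#' @param normalize \code{"minmax"} (default) or \code{"none"}.
#' @param header does the file have a header line? (default FALSE).
#' @return a \code{CoFunctionNetwork}.
#' @export
parse_network <- function(path, normalize = c("minmax", "none"), header = FALSE) {
  normalize <- match.arg(normalize)
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) != 3L) stop(sprintf("expected 3 columns, found %d", ncol(df)))
  score <- df[[3L]]
  if (!is.numeric(score)) {
    suppressWarnings(sc <- as.numeric(score))
    if (anyNA(sc)) {
      stop(sprintf("non-numeric score at data row %d: '%s'",
                   which(is.na(sc))[1L], score[which(is.na(sc))[1L]]))
    }
    score <- sc
  }
  raw_range <- if (length(score)) range(score) else NULL
  if (normalize == "minmax" && length(score)) {
    if (diff(raw_range) == 0) {
      warning("constant score column; all confidences set to 1")
      score[] <- 1
    } else {
      score <- (score - raw_range[1L]) / diff(raw_range)
    }
  }
  cofunction_network(data.frame(gene1 = as.character(df[[1L]]),
                                gene2 = as.character(df[[2L]]),
                                conf = score, stringsAsFactors = FALSE),
                     raw_score_range = raw_range)
}

#' Functional distance between two genes
#'
#' 0 for a gene and itself; 1 for a pair with no network edge; otherwise
#' 1 minus the edge confidence. Genes absent from the network behave
#' exactly like unconnected nodes, so the measures degrade gracefully
#' when network coverage is partial. \code{net = NULL} means no network:
#' every non-identical pair is at distance 1.
#'
#' @param net a \code{CoFunctionNetwork} or NULL.
#' @param g_i,g_j gene identifiers.
#' @return distance in [0, 1].
#' @export
pair_distance <- function(net, g_i, g_j) {
  if (g_i == g_j) return(0)
  if (is.null(net)) return(1)
  v <- net$index[[pair_key_(g_i, g_j)]]
  if (is.null(v)) 1 else 1 - v
}

#' Product-form distance between a gene and a gene set
#'
#' The product over members of \code{S} of the pairwise distance from
#' \code{g}. Membership of \code{g} in \code{S} annihilates the product
#' (self distance 0); a gene with no edges into \code{S} scores 1.
#'
#' @param net a \code{CoFunctionNetwork} or NULL.
#' @param g a gene identifier.
#' @param S nonempty character vector of genes.
#' @return distance in [0, 1].
#' @export
gene_to_set_distance <- function(net, g, S) {
  if (!length(S)) stop("gene set S must be nonempty")
  if (g %in% S) return(0)
  if (is.null(net)) return(1)
  prod(vapply(S, function(s) pair_distance(net, g, s), numeric(1)))
}

#' Degree-preserving edge rewiring
#'
#' Randomizes a fraction of the network by seeded double-edge swaps
#' (a-b, c-d) -> (a-d, c-b), which preserve the degree multiset. With
#' \code{fraction = 1} swapping continues until no original edge remains
#' or the attempt budget is exhausted, producing a fully randomized
#' network; on dense graphs a chance-level residue of original edges is
#' unavoidable (a random graph with the same degrees already shares edges
#' with the original). \code{fraction = 0.5} yields the "low quality"
#' variant.
#'
#' @param net a \code{CoFunctionNetwork}.
#' @param fraction fraction of edges to randomize, in [0, 1].
#' @param seed optional integer seed.
#' @param max_tries attempt budget (default 500 per edge).
#' @return a rewired \code{CoFunctionNetwork}.
#' @export
rewire_network <- function(net, fraction, seed = NULL, max_tries = NULL) {
  stopifnot(inherits(net, "CoFunctionNetwork"),
            fraction >= 0, fraction <= 1)
  ed <- net$edges
  E <- nrow(ed)
  if (fraction == 0 || E < 2L) return(net)
  max_tries <- max_tries %||% (500L * E)
  with_seed_(seed, {
    g1 <- ed$gene1; g2 <- ed$gene2
    orig <- paste(g1, g2, sep = "\t")
    have <- new.env(parent = emptyenv(), size = E)
    for (k in orig) assign(k, TRUE, envir = have)
    key_of <- function(a, b) if (a <= b) paste(a, b, sep = "\t") else paste(b, a, sep = "\t")
    need_swaps <- ceiling(fraction * E / 2)
    swaps <- 0L
    tries <- 0L
    repeat {
      cur <- paste(pmin(g1, g2), pmax(g1, g2), sep = "\t")
      more <- swaps < need_swaps ||
        (fraction >= 1 && any(cur %in% orig))
      if (!more || tries >= max_tries) break
      tries <- tries + 1L
      ij <- sample.int(E, 2L)
      a <- g1[ij[1L]]; b <- g2[ij[1L]]
      c_ <- g1[ij[2L]]; d <- g2[ij[2L]]
      if (length(unique(c(a, b, c_, d))) < 4L) next
      k1 <- key_of(a, d); k2 <- key_of(c_, b)
      if (!is.null(have[[k1]]) || !is.null(have[[k2]])) next
      rm(list = c(key_of(a, b), key_of(c_, d)), envir = have)
      assign(k1, TRUE, envir = have)
      assign(k2, TRUE, envir = have)
      g2[ij[1L]] <- d
      g2[ij[2L]] <- b
      swaps <- swaps + 1L
    }
    cofunction_network(data.frame(gene1 = g1, gene2 = g2, conf = ed$conf,
                                  stringsAsFactors = FALSE),
                       nodes = net$nodes,
                       raw_score_range = net$raw_score_range)
  })
}

#' Randomly thin a network
#'
#' Keeps a seeded random fraction of the edges; used for the
#' network-density experiments.
#'
#' @param net a \code{CoFunctionNetwork}.
#' @param keep_fraction fraction of edges to keep, in [0, 1].
#' @param seed optional integer seed.
#' @return a thinned \code{CoFunctionNetwork} (nodes are retained).
#' @export
subsample_edges <- function(net, keep_fraction, seed = NULL) {
  stopifnot(inherits(net, "CoFunctionNetwork"),
            keep_fraction >= 0, keep_fraction <= 1)
  E <- nrow(net$edges)
  n_keep <- round(keep_fraction * E)
  with_seed_(seed, {
    keep <- sort(sample.int(E, n_keep))
    cofunction_network(net$edges[keep, , drop = FALSE], nodes = net$nodes,
                       raw_score_range = net$raw_score_range)
  })
}

#' Write a network as a 3-column TSV edge list
#'
#' @param net a \code{CoFunctionNetwork}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "CoFunctionNetwork"))
  df <- net$edges
  df$conf <- fmt_num_(df$conf)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
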