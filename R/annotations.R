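# Gene -> GO annotations: GAF parsing, evidence filtering, true-path
# propagation and leave-one-out removal.

#' Construct an annotation set
#'
#' @param direct named list mapping term identifiers to character vectors
#'   of gene identifiers (direct annotations only).
#' @param namespace optional namespace label the annotations belong to.
#' @return an object of class \code{AnnotationSet} with elements
#'   \code{direct}, \code{propagated} (filled by \code{\link{propagate}}),
#'   \code{gene_terms} (gene -> directly annotated terms) and
#'   \code{universe} (all annotated genes, the G of the similarity
#'   formulas).
#' @export
annotation_set <- function(direct, namespace = NULL) {
  stopifnot(is.list(direct))
  direct <- lapply(direct, function(g) sort(unique(as.character(g))))
  direct <- direct[lengths(direct) > 0L]
  direct <- direct[order(names(direct))]
  structure(list(direct = direct,
                 propagated = NULL,
                 gene_terms = invert_direct_(direct),
                 universe = NULL,
                 namespace = namespace),
            class = "AnnotationSet")
}

invert_direct_ <- function(direct) {
  if (!length(direct)) return(list())
  genes <- unlist(direct, use.names = FALSE)
  terms <- rep(names(direct), lengths(direct))
  gt <- split(terms, genes)
  gt <- lapply(gt, function(t) sort(unique(t)))
  gt[order(names(gt))]
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d terms with direct annotations, %d genes%s\n",
              length(x$direct), length(x$gene_terms),
              if (is.null(x$propagated)) " (not propagated)"
              else sprintf(", universe %d genes", length(x$universe))))
  invisible(x)
}

GAF_ASPECT <- c(biological_process = "P", molecular_function = "F",
                cellular_component = "C")

#' Parse a GAF annotation file
#'
#' Reads GAF 2.x (17 tab-separated columns, \code{!} comment lines).
#' Rows with an excluded evidence code or a NOT qualifier are dropped;
#' duplicate (gene, term) rows collapse to one annotation. IEA
#' (electronically inferred) annotations are excluded by default; pass
#' \code{exclude_evidence = character(0)} to keep them.
#'
#' @param path path to a GAF file.
#' @param exclude_evidence evidence codes to drop (default \code{"IEA"}).
#' @param namespace optional: keep only rows of this GO namespace
#'   (aspect column).
#' @param exclude_not drop NOT-qualified rows (default TRUE).
#' @return an \code{AnnotationSet} with direct annotations only.
#' @export
parse_gaf <- function(path, exclude_evidence = "IEA", namespace = NULL,
                      exclude_not = TRUE) {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "!") & nzchar(lines)
  # sentinel keeps trailing empty fields that strsplit would drop
  rows <- strsplit(paste0(lines[keep], "\t\x01"), "\t", fixed = TRUE)
  rows <- lapply(rows, function(r) r[-length(r)])
  rownums <- which(keep)
  nc <- lengths(rows)
  if (any(nc != 17L)) {
    bad <- which(nc != 17L)[1L]
    stop(sprintf("GAF format error at line %d: %d columns, expected 17",
                 rownums[bad], nc[bad]))
  }
  gene <- vapply(rows, `[[`, character(1), 2L)
  qualifier <- vapply(rows, `[[`, character(1), 4L)
  term <- vapply(rows, `[[`, character(1), 5L)
  evidence <- vapply(rows, `[[`, character(1), 7L)
  aspect <- vapply(rows, `[[`, character(1), 9L)

  ok <- !(evidence %in% exclude_evidence)
  if (exclude_not) ok <- ok & !grepl("(^|\\|)NOT($|\\|)", qualifier)
  if (!is.null(namespace)) {
    letter <- GAF_ASPECT[[namespace]] %||% namespace
    ok <- ok & aspect == letter
  }
  direct <- if (any(ok)) lapply(split(gene[ok], term[ok]), unique) else list()
  annotation_set(direct, namespace = namespace)
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Fills \code{propagated}: for every term in the chosen namespace,
#' the union of direct annotations over the term's reflexive descendants.
#' The annotation universe G is the propagated set of the namespace root.
#' Annotations to terms absent from the DAG (e.g. obsolete accessions)
#' are skipped with a warning, or raise an error.
#'
#' @param annots an \code{AnnotationSet}.
#' @param dag an \code{OntologyDAG}.
#' @param namespace namespace to propagate within; required when the DAG
#'   holds several namespaces.
#' @param unknown what to do with annotations to unknown terms:
#'   \code{"warn"} (skip with a warning) or \code{"error"}.
#' @return the \code{AnnotationSet} with \code{propagated},
#'   \code{universe} and \code{gene_terms} filled, restricted to the
#'   namespace.
#' @export
propagate <- function(annots, dag, namespace = NULL,
                      unknown = c("warn", "error")) {
  stopifnot(inherits(annots, "AnnotationSet"), inherits(dag, "OntologyDAG"))
  unknown <- match.arg(unknown)
  nss <- names(dag$roots)
  if (is.null(namespace)) {
    namespace <- annots$namespace
    if (is.null(namespace)) {
      if (length(nss) > 1L) stop("DAG has several namespaces; specify one")
      namespace <- nss
    }
  }
  if (!namespace %in% nss) stop(sprintf("namespace '%s' not in ontology", namespace))

  direct <- annots$direct
  bad <- setdiff(names(direct), dag$terms)
  if (length(bad)) {
    msg <- sprintf("%d annotated term(s) absent from the ontology: %s",
                   length(bad), paste(utils::head(bad, 5L), collapse = ", "))
    if (unknown == "error") stop(msg)
    warning("skipping ", msg)
    direct <- direct[!names(direct) %in% bad]
  }
  ns_terms <- dag$terms[dag$namespace == namespace]
  direct <- direct[names(direct) %in% ns_terms]

  prop <- stats::setNames(vector("list", length(ns_terms)), ns_terms)
  for (t in dag$topo) { # children precede parents
    if (!t %in% ns_terms) next
    prop[[t]] <- as.character(sort(unique(c(direct[[t]],
                                            unlist(prop[dag$children[[t]]],
                                                   use.names = FALSE)))))
  }
  universe <- prop[[dag$roots[[namespace]]]] %||% character(0)

  structure(list(direct = direct,
                 propagated = prop,
                 gene_terms = invert_direct_(direct),
                 universe = universe,
                 namespace = namespace),
            class = "AnnotationSet")
}

#' Remove genes from an annotation set
#'
#' Returns a copy with the genes removed from the direct sets, every
#' propagated set, the gene index, and the annotation universe. Used for
#' leave-one-out gene similarity: the evaluated pair is fully excluded
#' from the model, including from the universe |G| that information
#' content depends on. Removing absent genes is a no-op.
#'
#' @param annots an \code{AnnotationSet}.
#' @param genes character vector of gene identifiers.
#' @return a new \code{AnnotationSet}; the input is unchanged.
#' @export
remove_genes <- function(annots, genes) {
  stopifnot(inherits(annots, "AnnotationSet"))
  genes <- as.character(genes)
  direct <- lapply(annots$direct, setdiff, y = genes)
  direct <- direct[lengths(direct) > 0L]
  propagated <- if (is.null(annots$propagated)) NULL
                else lapply(annots$propagated, setdiff, y = genes)
  structure(list(direct = direct,
                 propagated = propagated,
                 gene_terms = invert_direct_(direct),
                 universe = if (is.null(annots$universe)) NULL
                            else setdiff(annots$universe, genes),
                 namespace = annots$namespace),
            class = "AnnotationSet")
}

#' Write annotations as a GAF 2.1 file
#'
#' Fixture serializer: emits one 17-column row per direct (gene, term)
#' annotation with evidence code IDA.
#'
#' @param annots an \code{AnnotationSet}.
#' @param path output path.
#' @param aspect GAF aspect letter (default from the set's namespace, or P).
#' @return the path, invisibly.
#' @export
write_gaf <- function(annots, path, aspect = NULL) {
  stopifnot(inherits(annots, "AnnotationSet"))
  if (is.null(aspect)) {
    aspect <- if (!is.null(annots$namespace)) GAF_ASPECT[[annots$namespace]] %||% "P" else "P"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.1", con)
  for (t in names(annots$direct)) {
    for (g in annots$direct[[t]]) {
      row <- c("NETSIM", g, g, "", t, "REF:0000001", "IDA", "", aspect,
               "", "", "protein", "taxon:0000", "20110601", "NETSIM", "", "")
      writeLines(paste(row, collapse = "\t"), con)
    }
  }
  invisible(path)
}
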