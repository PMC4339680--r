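# Gene Ontology DAG container and graph queries.
#
# Terms are connected by typed child -> parent edges (is_a, part_of). All
# set-valued queries are reflexive: a term is its own ancestor and its own
# descendant, so self-similarity is well defined for every measure.

#' Construct an ontology DAG
#'
#' Builds the directed acyclic graph of ontology terms used by all
#' similarity measures. Edges point from child to parent and carry a
#' relation type (typically \code{is_a} or \code{part_of}).
#'
#' @param edges data.frame with character columns \code{child},
#'   \code{parent}, \code{relation}.
#' @param terms optional character vector of term identifiers; terms
#'   appearing only here (isolated terms) are kept.
#' @param namespace named character vector mapping each term to its
#'   namespace (e.g. \code{"biological_process"}). Defaults to a single
#'   shared namespace. Edges crossing namespaces are an error.
#' @return an object of class \code{OntologyDAG} with elements
#'   \code{terms}, \code{edges}, \code{parents}, \code{children},
#'   \code{namespace}, \code{roots} (one root per namespace) and a
#'   memoisation cache for ancestor/descendant queries.
#' @export
ontology_dag <- function(edges = NULL, terms = NULL, namespace = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges),
            all(c("child", "parent", "relation") %in% names(edges)))
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      relation = as.character(edges$relation),
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  all_terms <- sort(unique(c(terms, edges$child, edges$parent)))
  if (length(all_terms) == 0L) stop("ontology must contain at least one term")
  if (is.null(namespace)) {
    namespace <- stats::setNames(rep("biological_process", length(all_terms)), all_terms)
  }
  namespace <- namespace[all_terms]
  if (anyNA(namespace)) {
    stop("namespace missing for term(s): ",
         paste(all_terms[is.na(namespace)], collapse = ", "))
  }
  names(namespace) <- all_terms
  if (any(edges$child == edges$parent)) stop("self-loop edge in ontology")
  cross <- namespace[edges$child] != namespace[edges$parent]
  if (any(cross)) {
    stop("cross-namespace edge(s): ",
         paste(edges$child[cross], "->", edges$parent[cross], collapse = "; "))
  }

  parents <- stats::setNames(vector("list", length(all_terms)), all_terms)
  children <- parents
  if (nrow(edges)) {
    sp <- split(edges$parent, edges$child)
    parents[names(sp)] <- lapply(sp, unique)
    sc <- split(edges$child, edges$parent)
    children[names(sc)] <- lapply(sc, unique)
  }

  topo <- topo_sort_(all_terms, parents, children)

  relation <- new.env(parent = emptyenv(), size = max(29L, nrow(edges)))
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      assign(paste(edges$child[i], edges$parent[i], sep = "\t"),
             edges$relation[i], envir = relation)
    }
  }

  parentless <- all_terms[lengths(parents) == 0L]
  roots <- character(0)
  for (ns in unique(namespace)) {
    r <- parentless[namespace[parentless] == ns]
    if (length(r) != 1L) {
      stop(sprintf("namespace '%s' has %d parentless terms; expected exactly one root",
                   ns, length(r)))
    }
    roots[ns] <- r
  }

  structure(list(terms = all_terms, edges = edges, parents = parents,
                 children = children, relation = relation,
                 namespace = namespace, roots = roots, topo = topo,
                 cache = new.env(parent = emptyenv())),
            class = "OntologyDAG")
}

# Kahn topological sort over child -> parent edges; returned order places
# every child before all of its parents. Raises an error listing one cycle
# if the graph is cyclic.
topo_sort_ <- function(terms, parents, children) {
  nkids <- stats::setNames(lengths(children)[terms], terms)
  queue <- terms[nkids == 0L]
  order <- character(0)
  nk <- nkids
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]
    order <- c(order, t)
    for (p in parents[[t]]) {
      nk[p] <- nk[p] - 1L
      if (nk[p] == 0L) queue <- c(queue, p)
    }
  }
  if (length(order) != length(terms)) {
    cyc <- find_cycle_(setdiff(terms, order), parents)
    stop("ontology graph contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  order
}

find_cycle_ <- function(terms, parents) {
  state <- stats::setNames(rep(0L, length(terms)), terms) # 0 new, 1 open, 2 done
  stack <- character(0)
  cycle <- NULL
  visit <- function(t) {
    if (!is.null(cycle)) return()
    state[t] <<- 1L
    stack <<- c(stack, t)
    for (p in intersect(parents[[t]], terms)) {
      if (state[p] == 1L) {
        i <- match(p, stack)
        cycle <<- c(stack[i:length(stack)], p)
        return()
      }
      if (state[p] == 0L) visit(p)
      if (!is.null(cycle)) return()
    }
    state[t] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (t in terms) {
    if (state[t] == 0L) visit(t)
    if (!is.null(cycle)) break
  }
  cycle %||% terms[1L]
}

check_term_ <- function(dag, t) {
  if (length(t) != 1L || !t %in% dag$terms) {
    stop(sprintf("unknown term: %s", paste(t, collapse = ", ")))
  }
  invisible(t)
}

closure_ <- function(dag, term, map, tag) {
  key <- paste0(tag, term)
  hit <- dag$cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- term
  frontier <- term
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(map[frontier], use.names = FALSE)), out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out <- sort(out)
  assign(key, out, envir = dag$cache)
  out
}

#' Ancestors of a term
#'
#' Reflexive-transitive closure over child-to-parent edges: the result
#' always contains \code{t} itself.
#'
#' @param dag an \code{OntologyDAG}.
#' @param t a term identifier.
#' @return sorted character vector of ancestor terms.
#' @export
ancestors <- function(dag, t) {
  stopifnot(inherits(dag, "OntologyDAG"))
  check_term_(dag, t)
  closure_(dag, t, dag$parents, "anc\t")
}

#' Descendants of a term (reflexive)
#'
#' @inheritParams ancestors
#' @return sorted character vector of descendant terms, including \code{t}.
#' @export
descendants <- function(dag, t) {
  stopifnot(inherits(dag, "OntologyDAG"))
  check_term_(dag, t)
  closure_(dag, t, dag$children, "des\t")
}

#' Common ancestors of two terms
#'
#' @param dag an \code{OntologyDAG}.
#' @param t_a,t_b term identifiers in the same namespace.
#' @return sorted character vector; never empty (contains the namespace
#'   root). Cross-namespace pairs are an error, not zero: similarity is
#'   defined within one GO category.
#' @export
common_ancestors <- function(dag, t_a, t_b) {
  check_term_(dag, t_a); check_term_(dag, t_b)
  if (dag$namespace[[t_a]] != dag$namespace[[t_b]]) {
    stop(sprintf("terms %s (%s) and %s (%s) are in different namespaces",
                 t_a, dag$namespace[[t_a]], t_b, dag$namespace[[t_b]]))
  }
  intersect(ancestors(dag, t_a), ancestors(dag, t_b))
}

#' Terms on the paths to a common ancestor
#'
#' The union of all terms lying on any directed path from \code{t_a} to
#' \code{p} or from \code{t_b} to \code{p}, plus all (reflexive)
#' descendants of \code{t_a} and \code{t_b}. This is the term set whose
#' direct annotations feed the path-constrained annotation.
#'
#' @param dag an \code{OntologyDAG}.
#' @param t_a,t_b the compared terms.
#' @param p a common ancestor of \code{t_a} and \code{t_b}.
#' @return sorted character vector containing \code{t_a}, \code{t_b} and
#'   \code{p}.
#' @export
path_terms <- function(dag, t_a, t_b, p) {
  ca <- common_ancestors(dag, t_a, t_b)
  if (!p %in% ca) {
    stop(sprintf("%s is not a common ancestor of %s and %s", p, t_a, t_b))
  }
  dp <- descendants(dag, p)
  sort(unique(c(intersect(ancestors(dag, t_a), dp),
                intersect(ancestors(dag, t_b), dp),
                descendants(dag, t_a),
                descendants(dag, t_b))))
}

edge_relation_ <- function(dag, child, parent) {
  rel <- dag$relation[[paste(child, parent, sep = "\t")]]
  if (is.null(rel)) stop(sprintf("no edge %s -> %s", child, parent))
  rel
}

#' @export
print.OntologyDAG <- function(x, ...) {
  cat(sprintf("OntologyDAG: %d terms, %d edges, %d namespace(s)\n",
              length(x$terms), nrow(x$edges), length(x$roots)))
  for (ns in names(x$roots)) {
    cat(sprintf("  %s (root %s): %d terms\n", ns, x$roots[[ns]],
                sum(x$namespace == ns)))
  }
  invisible(x)
}

#' Parse an OBO ontology file
#'
#' Reads OBO 1.2/1.4, keeping non-obsolete terms and the requested
#' relation types. \code{is_a} tags and \code{relationship} tags are both
#' honoured; \code{regulates}-type edges are excluded by default because
#' only \code{is_a} and \code{part_of} are used by the measures.
#' \code{alt_id} aliases are resolved to the primary accession.
#' Cross-namespace edges and edges to terms absent from the file are
#' dropped.
#'
#' @param path path to an OBO file.
#' @param relations character vector of relation types to keep.
#' @return an \code{OntologyDAG}.
#' @export
parse_obo <- function(path, relations = c("is_a", "part_of")) {
  lines <- readLines(path, warn = FALSE)
  stanzas <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) stanzas[[length(stanzas) + 1L]] <<- cur
  }
  for (i in seq_along(lines)) {
    ln <- sub("\\s+$", "", lines[i])
    if (grepl("^\\[", ln)) {
      if (!grepl("^\\[[A-Za-z_-]+\\]$", ln)) {
        stop(sprintf("malformed stanza header at line %d: %s", i, ln))
      }
      flush()
      in_term <- identical(ln, "[Term]")
      cur <- if (in_term) list(parents = list(), alt_id = character(0)) else NULL
      next
    }
    if (ln == "" || startsWith(ln, "!")) next
    if (!in_term) next
    if (!grepl("^[A-Za-z_]+:", ln)) {
      stop(sprintf("malformed tag line at line %d: %s", i, ln))
    }
    key <- sub(":.*$", "", ln)
    val <- trimws(sub("^[A-Za-z_]+:", "", ln))
    val_nc <- trimws(sub("\\s*!.*$", "", val)) # strip trailing OBO comment
    if (key == "id") cur$id <- val_nc
    else if (key == "namespace") cur$namespace <- val_nc
    else if (key == "alt_id") cur$alt_id <- c(cur$alt_id, val_nc)
    else if (key == "is_obsolete") cur$obsolete <- identical(tolower(val_nc), "true")
    else if (key == "is_a") {
      cur$parents[[length(cur$parents) + 1L]] <- c(rel = "is_a", parent = val_nc)
    } else if (key == "relationship") {
      parts <- strsplit(val_nc, "\\s+")[[1L]]
      if (length(parts) < 2L) {
        stop(sprintf("malformed relationship at line %d: %s", i, ln))
      }
      cur$parents[[length(cur$parents) + 1L]] <- c(rel = parts[1L], parent = parts[2L])
    }
  }
  flush()
  if (!length(stanzas)) stop("no [Term] stanzas found in ", path)

  obsolete <- vapply(stanzas, function(s) isTRUE(s$obsolete), logical(1))
  ids <- vapply(stanzas, `[[`, character(1), "id")
  keep <- stanzas[!obsolete]
  keep_ids <- ids[!obsolete]

  alt <- character(0)
  for (s in keep) {
    if (length(s$alt_id)) alt[s$alt_id] <- s$id
  }
  resolve <- function(x) ifelse(x %in% names(alt), alt[x], x)

  ns <- vapply(keep, function(s) s$namespace %||% "biological_process", character(1))
  names(ns) <- keep_ids

  ch <- character(0); pa <- character(0); rel <- character(0)
  for (s in keep) {
    for (e in s$parents) {
      if (!e[["rel"]] %in% relations) next
      ch <- c(ch, s$id); pa <- c(pa, e[["parent"]]); rel <- c(rel, e[["rel"]])
    }
  }
  pa <- unname(resolve(pa))
  ok <- pa %in% keep_ids
  if (any(!ok)) {
    warning(sprintf("dropping %d edge(s) to unknown or obsolete terms", sum(!ok)))
    ch <- ch[ok]; pa <- pa[ok]; rel <- rel[ok]
  }
  same_ns <- ns[ch] == ns[pa]
  ch <- ch[same_ns]; pa <- pa[same_ns]; rel <- rel[same_ns]

  ontology_dag(data.frame(child = ch, parent = pa, relation = rel,
                          stringsAsFactors = FALSE),
               terms = keep_ids, namespace = ns)
}

#' Serialize an ontology DAG to OBO
#'
#' Minimal OBO 1.2 writer used for fixtures and round-trip tests.
#'
#' @param dag an \code{OntologyDAG}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "OntologyDAG"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in dag$terms) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", t), con)
    writeLines(paste0("name: ", t), con)
    writeLines(paste0("namespace: ", dag$namespace[[t]]), con)
    for (p in dag$parents[[t]]) {
      rel <- edge_relation_(dag, t, p)
      if (rel == "is_a") writeLines(paste0("is_a: ", p), con)
      else writeLines(paste0("relationship: ", rel, " ", p), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
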