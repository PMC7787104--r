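# Hypothesis DAG.
#
# Nodes are typed hypotheses about the crystal (its cell, corrections,
# pathologies, symmetry); directed edges add information, so there are no
# directed cycles and a node may have several parents. Node ids are
# content-derived — kind + hash of the defining payload entries and parent
# ids — which makes re-running a stage idempotent and resume trivial.

dag_kinds <- c("crystal", "data", "anisotropy", "tncs_order", "tncs_correction",
               "twinning", "spacegroup", "spacegroup_expansion")

# stage partial order: permissible parent kinds per kind
dag_parent_rules <- list(
  crystal = character(0),
  data = c("crystal", "data"),
  anisotropy = c("data"),
  tncs_order = c("anisotropy", "data"),
  tncs_correction = c("tncs_order"),
  twinning = c("tncs_correction", "tncs_order"),
  spacegroup = c("twinning", "spacegroup"),
  spacegroup_expansion = c("twinning", "spacegroup")
)

#' Create an empty hypothesis DAG
#'
#' @return object of class `hypothesis_dag` (an environment: nodes are added
#'   in place).
#' @export
dag_new <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- list()
  e$children <- list()
  class(e) <- "hypothesis_dag"
  e
}

# id = kind + short hash of (defining payload, parent ids)
dag_node_id <- function(kind, payload, parents, defining = NULL) {
  def <- if (is.null(defining)) payload else payload[intersect(defining, names(payload))]
  paste0(kind, "-", fnv1a_hex(canonical_json(list(k = kind, d = def, p = sort(parents)))))
}

#' Add a hypothesis node
#'
#' Insertion is atomic: an unknown parent, a kind violating the stage order,
#' or an edge that would create a directed cycle leaves the DAG unchanged.
#'
#' @param dag a [dag_new()] object.
#' @param kind one of crystal, data, anisotropy, tncs_order, tncs_correction,
#'   twinning, spacegroup, spacegroup_expansion.
#' @param payload named list of typed entries (statistics, models, dataset
#'   file references); extensible.
#' @param parents character vector of existing node ids (possibly several).
#' @param rank numeric hypothesis score (higher = more believed).
#' @param defining names of the payload entries that define the node identity
#'   (default: all); results computed later should not be defining, so that
#'   resume can recognise the node before recomputing it.
#' @return the node id (invisibly returns the same id if the identical node
#'   already exists).
#' @export
dag_add_node <- function(dag, kind, payload = list(), parents = character(0),
                         rank = 0, defining = NULL) {
  stopifnot(inherits(dag, "hypothesis_dag"))
  kind <- match.arg(kind, dag_kinds)
  missing <- setdiff(parents, names(dag$nodes))
  if (length(missing)) stop("unknown parent node(s): ", paste(missing, collapse = ", "))
  for (p in parents) {
    pk <- dag$nodes[[p]]$kind
    if (!(pk %in% dag_parent_rules[[kind]])) {
      stop("stage order violated: ", kind, " node cannot have a ", pk, " parent")
    }
  }
  id <- dag_node_id(kind, payload, parents, defining)
  if (!is.null(dag$nodes[[id]])) return(invisible(id))
  dag$nodes[[id]] <- list(id = id, kind = kind, payload = payload,
                          parents = sort(unique(parents)), rank = rank)
  dag$children[[id]] <- character(0)
  for (p in parents) dag$children[[p]] <- sort(unique(c(dag$children[[p]], id)))
  id
}

#' Add an edge between existing nodes
#'
#' Rejected atomically if it would create a directed cycle.
#'
#' @param dag a `hypothesis_dag`.
#' @param from,to existing node ids (edge direction: increasing information).
#' @return invisibly TRUE.
#' @export
dag_add_edge <- function(dag, from, to) {
  stopifnot(inherits(dag, "hypothesis_dag"))
  if (is.null(dag$nodes[[from]]) || is.null(dag$nodes[[to]])) stop("unknown node id")
  if (from == to || dag_reachable(dag, to, from)) {
    stop("edge ", from, " -> ", to, " would create a directed cycle")
  }
  dag$nodes[[to]]$parents <- sort(unique(c(dag$nodes[[to]]$parents, from)))
  dag$children[[from]] <- sort(unique(c(dag$children[[from]], to)))
  invisible(TRUE)
}

# is b reachable from a by directed edges?
dag_reachable <- function(dag, a, b) {
  frontier <- a
  seen <- character(0)
  while (length(frontier)) {
    if (b %in% frontier) return(TRUE)
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$children[frontier])), seen)
  }
  FALSE
}

#' Topological order of the DAG
#'
#' Kahn's algorithm; ties broken by id, so the order is deterministic.
#'
#' @param dag a `hypothesis_dag`.
#' @return character vector of node ids, every parent before its children.
#' @export
dag_topological_sort <- function(dag) {
  indeg <- vapply(dag$nodes, function(nd) length(nd$parents), integer(1))
  out <- character(0)
  ready <- sort(names(indeg)[indeg == 0])
  while (length(ready)) {
    v <- ready[1]; ready <- ready[-1]
    out <- c(out, v)
    for (ch in dag$children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- sort(c(ready, ch))
    }
  }
  if (length(out) != length(dag$nodes)) stop("cycle detected (invariant violated)")
  out
}

#' Shortest directed path between two nodes
#'
#' Breadth-first search on edge count; among equal-length paths the
#' lexicographically smallest (by id sequence) is returned.
#'
#' @param dag a `hypothesis_dag`.
#' @param a,b node ids.
#' @return character vector of node ids from `a` to `b`, or `NULL` when `b`
#'   is unreachable from `a`.
#' @export
dag_shortest_path <- function(dag, a, b) {
  if (is.null(dag$nodes[[a]]) || is.null(dag$nodes[[b]])) stop("unknown node id")
  if (a == b) return(a)
  prev <- list()
  frontier <- a
  seen <- a
  while (length(frontier)) {
    nxt <- character(0)
    for (v in sort(frontier)) {
      for (ch in dag$children[[v]]) {
        if (ch %in% seen) next
        # first (lexicographically smallest) predecessor wins
        if (is.null(prev[[ch]])) prev[[ch]] <- v
        nxt <- c(nxt, ch)
      }
    }
    nxt <- unique(nxt)
    seen <- c(seen, nxt)
    if (b %in% nxt) {
      path <- b
      while (path[1] != a) path <- c(prev[[path[1]]], path)
      return(path)
    }
    frontier <- nxt
  }
  NULL
}

#' Leaf hypotheses
#'
#' @param dag a `hypothesis_dag`.
#' @return list of nodes with no children, sorted by rank descending then id.
#' @export
dag_leaves <- function(dag) {
  ids <- names(dag$nodes)
  leaf_ids <- ids[vapply(ids, function(i) length(dag$children[[i]]) == 0, logical(1))]
  nodes <- dag$nodes[leaf_ids]
  ord <- order(-vapply(nodes, function(nd) nd$rank, numeric(1)),
               vapply(nodes, function(nd) nd$id, character(1)))
  unname(nodes[ord])
}

# --- serialization ----------------------------------------------------------

# type-tag a payload entry so scalars round-trip through JSON
tag_value <- function(v) {
  if (is.null(v)) list(type = "null", value = NULL)
  else if (inherits(v, "tncs_model")) list(type = "tncs_model", value = unclass(v)[c("m", "t", "r_eff", "sigma_rmsd", "f0", "beta", "rot")])
  else if (is.matrix(v)) list(type = "matrix", value = as.numeric(v), dim = dim(v))
  else if (is.numeric(v)) list(type = "numeric", value = v)
  else if (is.logical(v)) list(type = "logical", value = v)
  else if (is.character(v)) list(type = "character", value = v)
  else if (is.list(v)) list(type = "list", value = lapply(v, tag_value))
  else stop("unsupported payload type: ", class(v)[1])
}

untag_value <- function(tv) {
  switch(tv$type,
         "null" = NULL,
         "tncs_model" = do.call(tncs_model, lapply(tv$value, unlist)),
         "matrix" = {
           dm <- as.integer(unlist(tv$dim))
           matrix(as.numeric(unlist(tv$value)), nrow = dm[1], ncol = dm[2])
         },
         "numeric" = as.numeric(unlist(tv$value)),
         "logical" = as.logical(unlist(tv$value)),
         "character" = as.character(unlist(tv$value)),
         "list" = lapply(tv$value, untag_value),
         stop("unknown payload type tag: ", tv$type))
}

#' Serialize a DAG to JSON text
#'
#' @param dag a `hypothesis_dag`.
#' @return single JSON string; payload entries carry type tags so
#'   [dag_deserialize()] restores scalars, vectors, matrices and TNCS models
#'   exactly.
#' @export
dag_serialize <- function(dag) {
  nodes <- lapply(dag$nodes[dag_topological_sort(dag)], function(nd) {
    list(id = nd$id, kind = nd$kind, parents = as.list(nd$parents),
         rank = nd$rank, payload = lapply(nd$payload, tag_value))
  })
  as.character(jsonlite::toJSON(list(format = "refltriage-dag", version = 1L,
                                     nodes = unname(nodes)),
                                auto_unbox = TRUE, digits = NA, null = "null",
                                na = "null"))
}

#' Deserialize a DAG from JSON text
#'
#' @param text JSON produced by [dag_serialize()].
#' @return a `hypothesis_dag`.
#' @export
dag_deserialize <- function(text) {
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) stop("DAG parse error: ", conditionMessage(e)))
  if (!identical(doc$format, "refltriage-dag")) stop("not a refltriage DAG document")
  dag <- dag_new()
  for (nd in doc$nodes) {
    payload <- lapply(nd$payload, untag_value)
    parents <- as.character(unlist(nd$parents))
    id <- nd$id
    dag$nodes[[id]] <- list(id = id, kind = nd$kind, payload = payload,
                            parents = sort(parents), rank = as.numeric(nd$rank))
    if (is.null(dag$children[[id]])) dag$children[[id]] <- character(0)
    for (p in parents) dag$children[[p]] <- sort(unique(c(dag$children[[p]], id)))
  }
  invisible(dag_topological_sort(dag))   # validates acyclicity + parent refs
  dag
}

#' Graphviz DOT export
#'
#' @param dag a `hypothesis_dag`.
#' @return single DOT-language string listing every node and edge once.
#' @export
dag_to_dot <- function(dag) {
  ids <- dag_topological_sort(dag)
  lines <- c("digraph hypotheses {", "  rankdir=TB;")
  for (i in ids) {
    nd <- dag$nodes[[i]]
    lines <- c(lines, sprintf("  \"%s\" [label=\"%s\\n%s\"];", i, nd$kind, i))
  }
  for (i in ids) {
    for (ch in dag$children[[i]]) {
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\";", i, ch))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' @export
print.hypothesis_dag <- function(x, ...) {
  cat(sprintf("hypothesis DAG: %d nodes, %d leaves\n",
              length(x$nodes), length(dag_leaves(x))))
  invisible(x)
}
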