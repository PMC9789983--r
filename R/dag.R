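#' Construct a directed acyclic graph over named variables
#'
#' @param nodes Character vector of node names. Order is retained and used
#'   canonically for all deterministic tie-breaking.
#' @param edges Two-column character matrix (or data.frame) of directed
#'   edges, one row per \code{parent -> child} pair. May have zero rows.
#' @param check_acyclic If \code{TRUE} (default), reject cyclic inputs.
#' @return An object of class \code{symptom_dag} with elements \code{nodes}
#'   and \code{edges} (a character matrix with columns \code{from},
#'   \code{to}).
#' @examples
#' g <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' topological_order(g)
#' @export
dag <- function(nodes, edges = NULL, check_acyclic = TRUE) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns (from, to)")
    storage.mode(edges) <- "character"
  }
  colnames(edges) <- c("from", "to")
  bad <- setdiff(unique(c(edges)), nodes)
  if (length(bad) > 0L) {
    stop("edge endpoint(s) not declared as nodes: ",
         paste(bad, collapse = ", "))
  }
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  if (anyDuplicated(paste(edges[, 1L], edges[, 2L]))) {
    stop("duplicate edges are not allowed")
  }
  g <- structure(list(nodes = nodes, edges = edges), class = "symptom_dag")
  if (check_acyclic && !is_acyclic(nodes, edges)) {
    stop("graph is cyclic: ", format_cycle(find_cycle(nodes, edges)))
  }
  g
}

#' Test whether a directed graph is acyclic
#'
#' Kahn's algorithm: repeatedly remove nodes without unremoved parents; the
#' graph is acyclic iff every node can be removed.
#'
#' @param nodes Character vector of node names.
#' @param edges Two-column matrix of directed edges (\code{from}, \code{to}).
#' @return \code{TRUE} iff no directed cycle exists.
#' @export
is_acyclic <- function(nodes, edges) {
  if (inherits(nodes, "symptom_dag")) {
    edges <- nodes$edges
    nodes <- nodes$nodes
  }
  if (NROW(edges) == 0L) return(TRUE)
  edges <- as.matrix(edges)
  bad <- setdiff(unique(c(edges)), nodes)
  if (length(bad) > 0L) {
    stop("edge endpoint(s) not declared as nodes: ",
         paste(bad, collapse = ", "))
  }
  indeg <- table(factor(edges[, 2L], levels = nodes))
  remaining <- rep(TRUE, length(nodes))
  names(remaining) <- nodes
  indeg <- as.integer(indeg)
  names(indeg) <- nodes
  repeat {
    free <- names(which(remaining & indeg == 0L))
    if (length(free) == 0L) break
    remaining[free] <- FALSE
    out <- edges[edges[, 1L] %in% free & remaining[edges[, 2L]], 2L]
    if (length(out) > 0L) {
      dec <- table(out)
      indeg[names(dec)] <- indeg[names(dec)] - as.integer(dec)
    }
  }
  !any(remaining)
}

# Locate one directed cycle (for error messages); assumes one exists.
find_cycle <- function(nodes, edges) {
  adj <- split(edges[, 2L], factor(edges[, 1L], levels = nodes))
  state <- setNames(integer(length(nodes)), nodes)  # 0 new, 1 open, 2 done
  stack <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    state[v] <<- 1L
    stack <<- c(stack, v)
    for (w in adj[[v]]) {
      if (!is.null(found)) return()
      if (state[w] == 1L) {
        i <- match(w, stack)
        found <<- c(stack[i:length(stack)], w)
        return()
      }
      if (state[w] == 0L) visit(w)
    }
    state[v] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (v in nodes) {
    if (state[v] == 0L) visit(v)
    if (!is.null(found)) break
  }
  found
}

format_cycle <- function(cyc) paste(cyc, collapse = " -> ")

#' Topological order of a DAG
#'
#' Deterministic: among nodes that are simultaneously available (all parents
#' already placed), the one earliest in the DAG's canonical node order is
#' placed first. Re-running on the same DAG is therefore bit-identical.
#'
#' @param g A \code{symptom_dag}.
#' @return Character vector: a permutation of \code{g$nodes} in which every
#'   parent precedes every child.
#' @export
topological_order <- function(g) {
  stopifnot(inherits(g, "symptom_dag"))
  nodes <- g$nodes
  edges <- g$edges
  indeg <- setNames(as.integer(table(factor(edges[, 2L], levels = nodes))),
                    nodes)
  placed <- character(0)
  remaining <- nodes
  while (length(remaining) > 0L) {
    free <- remaining[indeg[remaining] == 0L]
    if (length(free) == 0L) {
      stop("graph is cyclic: ", format_cycle(find_cycle(nodes, edges)))
    }
    v <- free[1L]  # remaining is kept in canonical order
    placed <- c(placed, v)
    remaining <- setdiff(remaining, v)
    kids <- edges[edges[, 1L] == v, 2L]
    if (length(kids) > 0L) indeg[kids] <- indeg[kids] - 1L
  }
  placed
}

#' Parents of a node in a DAG
#'
#' @param g A \code{symptom_dag}.
#' @param node Node name.
#' @return Character vector of parent names, in canonical node order.
#' @export
dag_parents <- function(g, node) {
  stopifnot(inherits(g, "symptom_dag"), node %in% g$nodes)
  pa <- g$edges[g$edges[, 2L] == node, 1L]
  g$nodes[g$nodes %in% pa]
}

#' Children of a node in a DAG
#'
#' @param g A \code{symptom_dag}.
#' @param node Node name.
#' @return Character vector of child names, in canonical node order.
#' @export
dag_children <- function(g, node) {
  stopifnot(inherits(g, "symptom_dag"), node %in% g$nodes)
  ch <- g$edges[g$edges[, 1L] == node, 2L]
  g$nodes[g$nodes %in% ch]
}

#' Undirected skeleton of a DAG
#'
#' @param g A \code{symptom_dag}.
#' @return Character vector of undirected adjacencies, each encoded as
#'   \code{"a--b"} with \code{a} before \code{b} in canonical node order.
#' @export
dag_skeleton <- function(g) {
  stopifnot(inherits(g, "symptom_dag"))
  if (nrow(g$edges) == 0L) return(character(0))
  a <- g$edges[, 1L]; b <- g$edges[, 2L]
  i <- match(a, g$nodes); j <- match(b, g$nodes)
  key <- ifelse(i < j, paste0(a, "--", b), paste0(b, "--", a))
  sort(unique(key))
}

#' V-structures (colliders) of a DAG
#'
#' A v-structure is a pattern \code{a -> c <- b} with \code{a} and \code{b}
#' non-adjacent; together with the skeleton it identifies the DAG's Markov
#' equivalence class.
#'
#' @param g A \code{symptom_dag}.
#' @return Character vector of v-structures encoded \code{"a->c<-b"} with
#'   \code{a} before \code{b} in canonical node order.
#' @export
dag_vstructures <- function(g) {
  stopifnot(inherits(g, "symptom_dag"))
  skel <- dag_skeleton(g)
  out <- character(0)
  for (c_node in g$nodes) {
    pa <- dag_parents(g, c_node)
    if (length(pa) < 2L) next
    for (i in seq_len(length(pa) - 1L)) {
      for (j in seq(i + 1L, length(pa))) {
        a <- pa[i]; b <- pa[j]
        ia <- match(a, g$nodes); ib <- match(b, g$nodes)
        adj_key <- if (ia < ib) paste0(a, "--", b) else paste0(b, "--", a)
        if (!(adj_key %in% skel)) {
          out <- c(out, paste0(a, "->", c_node, "<-", b))
        }
      }
    }
  }
  sort(out)
}

#' Export a DAG to Graphviz DOT format
#'
#' @param g A \code{symptom_dag}.
#' @param file Optional path; if given the DOT text is written there.
#' @return The DOT source as a character scalar (invisibly when written to
#'   a file).
#' @export
dag_to_dot <- function(g, file = NULL) {
  stopifnot(inherits(g, "symptom_dag"))
  lines <- c("digraph symptom_network {",
             paste0("  \"", g$nodes, "\";"),
             if (nrow(g$edges) > 0L) {
               paste0("  \"", g$edges[, 1L], "\" -> \"", g$edges[, 2L],
                      "\";")
             },
             "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Export a DAG to GraphML
#'
#' @param g A \code{symptom_dag}.
#' @param file Optional path to write to.
#' @return GraphML XML as a character scalar (invisibly when written).
#' @export
dag_to_graphml <- function(g, file = NULL) {
  stopifnot(inherits(g, "symptom_dag"))
  header <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <graph id=\"G\" edgedefault=\"directed\">")
  nodes <- paste0("    <node id=\"", g$nodes, "\"/>")
  edges <- if (nrow(g$edges) > 0L) {
    paste0("    <edge source=\"", g$edges[, 1L], "\" target=\"",
           g$edges[, 2L], "\"/>")
  } else character(0)
  txt <- paste(c(header, nodes, edges, "  </graph>", "</graphml>"),
               collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @export
print.symptom_dag <- function(x, ...) {
  cat("Directed acyclic graph over", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges) > 0L) {
    cat(paste0("  ", x$edges[, 1L], " -> ", x$edges[, 2L]), sep = "\n")
  }
  invisible(x)
}
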