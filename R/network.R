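#' Construct an undirected gene interaction network
#'
#' Edges are unordered symbol pairs; duplicates (including reversed pairs)
#' are collapsed and self-loops are dropped with a warning. The graph is
#' stored as a simplified undirected \pkg{igraph} object.
#'
#' @param edges Two-column character matrix or data frame of symbol pairs
#'   (may be `NULL` for an edgeless network).
#' @param nodes Optional character vector of additional (possibly isolated)
#'   node symbols.
#' @return An object of class `interaction_network`.
#' @export
interaction_network <- function(edges = NULL, nodes = NULL) {
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    if (length(edges) == 0) {
      edges <- NULL
    } else {
      if (ncol(edges) != 2) {
        stop("`edges` must have exactly two columns", call. = FALSE)
      }
      edges <- matrix(trimws(as.character(edges)), ncol = 2)
      if (any(!nzchar(edges)) || anyNA(edges)) {
        stop("blank node name in edge list", call. = FALSE)
      }
      loops <- edges[, 1] == edges[, 2]
      if (any(loops)) {
        # a self-loop still declares its node
        nodes <- c(nodes, edges[loops, 1])
        warning(sprintf("dropped %d self-loop(s): %s", sum(loops),
                        paste(unique(edges[loops, 1]), collapse = ", ")),
                call. = FALSE)
        edges <- edges[!loops, , drop = FALSE]
      }
    }
  }
  nodes <- unique(trimws(as.character(nodes %||% character(0))))
  if (any(!nzchar(nodes))) {
    stop("blank node name", call. = FALSE)
  }
  all_nodes <- unique(c(if (!is.null(edges)) as.vector(t(edges)), nodes))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(all_nodes), name = all_nodes)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  structure(list(graph = g), class = "interaction_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d node(s), %d edge(s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Node symbols of a network
#' @param network An `interaction_network`.
#' @return Character vector.
#' @export
network_nodes <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  igraph::V(network$graph)$name
}

#' Canonical edge list of a network
#'
#' @param network An `interaction_network`.
#' @return Two-column character matrix, each unordered pair once, the pair
#'   sorted lexicographically within a row and rows sorted; independent of
#'   input file order.
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  e <- igraph::as_edgelist(network$graph)
  if (nrow(e) == 0) {
    return(matrix(character(0), 0, 2))
  }
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' Read an interaction network from SIF or a two-column edge list
#'
#' SIF lines are whitespace-delimited `source relation target1 [target2 ...]`;
#' a line with a single token declares an isolated node. Two-column
#' tab-delimited files are read as plain edge lists. The result is undirected
#' and deduplicated; shuffled input files yield identical networks.
#'
#' @param path File path.
#' @param format `"auto"` (default: `.sif` extension or any line with three
#'   or more fields selects SIF), `"sif"`, or `"tsv"`.
#' @return An `interaction_network`.
#' @export
read_network <- function(path, format = c("auto", "sif", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  tokens <- lapply(lines, function(l) {
    f <- strsplit(trimws(l), "[ \t]+")[[1]]
    f[nzchar(f)]
  })
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE) ||
                  any(lengths(tokens) >= 3)) "sif" else "tsv"
  }
  edges <- list()
  isolated <- character(0)
  for (i in seq_along(tokens)) {
    f <- tokens[[i]]
    if (format == "sif") {
      if (length(f) == 1) {
        isolated <- c(isolated, f)
      } else if (length(f) == 2) {
        stop(sprintf("SIF line %d has a relation but no target", i),
             call. = FALSE)
      } else {
        edges[[length(edges) + 1]] <- cbind(f[1], f[3:length(f)])
      }
    } else {
      raw <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
      if (length(raw) != 2 || any(!nzchar(raw))) {
        stop(sprintf("edge-list line %d must have two non-blank node names", i),
             call. = FALSE)
      }
      edges[[length(edges) + 1]] <- matrix(raw, 1, 2)
    }
  }
  interaction_network(
    edges = if (length(edges) > 0) do.call(rbind, edges) else NULL,
    nodes = isolated
  )
}

#' Write an interaction network
#'
#' @param network An `interaction_network`.
#' @param path Output path.
#' @param format `"tsv"` (two-column edge list; isolated nodes are appended
#'   as degenerate rows is not possible, so `"sif"` is required to round-trip
#'   isolated nodes) or `"sif"` (relation `pp`, isolated nodes as single-token
#'   lines).
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path, format = c("sif", "tsv")) {
  format <- match.arg(format)
  e <- network_edges(network)
  deg <- igraph::degree(network$graph)
  iso <- names(deg)[deg == 0]
  if (format == "sif") {
    lines <- c(
      if (nrow(e) > 0) paste(e[, 1], "pp", e[, 2]),
      iso
    )
  } else {
    if (length(iso) > 0) {
      warning("isolated node(s) cannot be represented in a two-column edge list; use format = \"sif\"",
              call. = FALSE)
    }
    lines <- if (nrow(e) > 0) paste(e[, 1], e[, 2], sep = "\t") else character(0)
  }
  writeLines(lines, path)
  invisible(path)
}
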