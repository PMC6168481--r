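# Background gene-interaction network and tuple connectivity.

.canon_edges <- function(from, to, confidence) {
  a <- pmin(from, to)
  b <- pmax(from, to)
  tibble(from = a, to = b, confidence = confidence)
}

#' Construct an interaction network
#'
#' An undirected gene graph with optional per-edge confidence in `[0,1]`.
#' Self-loops are not stored by edge-list input; they are introduced
#' explicitly by [add_self_loops()] and act only as the marker that permits
#' compound-heterozygous (same-gene) variant combinations.
#'
#' @param edges Data frame with columns `from`, `to` and optionally
#'   `confidence` (`NA` allowed). Edges are undirected; duplicates are
#'   collapsed keeping the maximum confidence; self-pairs are dropped.
#' @param nodes Optional character vector of node ids; defaults to the genes
#'   appearing in `edges`. Extra isolated nodes may be listed.
#' @return An object of class `interaction_network` with elements `nodes`,
#'   `edges` (canonicalised: `from <= to`) and `self_loops` (logical).
#' @export
interaction_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || !nrow(as.data.frame(edges))) {
    e <- tibble(from = character(), to = character(),
                confidence = numeric())
  } else {
    e <- as_tibble(edges)
    if (!"confidence" %in% names(e)) e$confidence <- rep(NA_real_, nrow(e))
    e <- .canon_edges(as.character(e$from), as.character(e$to),
                      as.numeric(e$confidence))
    e <- e[e$from != e$to, , drop = FALSE]
    if (nrow(e)) {
      key <- paste(e$from, e$to, sep = "\r")
      # collapse duplicates keeping the maximum confidence
      keep <- vapply(split(seq_len(nrow(e)), key), function(ix) {
        if (all(is.na(e$confidence[ix]))) ix[[1]]
        else ix[[which.max(replace(e$confidence[ix],
                                   is.na(e$confidence[ix]), -Inf))]]
      }, integer(1))
      e <- e[sort(unname(keep)), , drop = FALSE]
      e <- e[order(e$from, e$to, method = "radix"), ]
    }
    bad <- !is.na(e$confidence) & (e$confidence < 0 | e$confidence > 1)
    if (any(bad)) stop("edge confidence outside [0,1]", call. = FALSE)
  }
  nodes <- .rsort(unique(c(as.character(nodes %||% character()),
                           e$from, e$to)))
  structure(list(nodes = nodes, edges = e, self_loops = FALSE),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d genes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if (x$self_loops) ", self-loops enabled" else ""))
  invisible(x)
}

#' Load a STRING-style edge list
#'
#' Reads a whitespace/tab-separated edge list: two gene ids per line plus an
#' optional integer combined score in 0--1000 (STRING dialect). Scores are
#' rescaled to `[0,1]`; edges below `min_confidence` are dropped; duplicate
#' edges are collapsed keeping the maximum confidence; self-pairs in the
#' input are ignored. An optional two-column mapping file translates the
#' edge-list identifiers (e.g. protein ids) to gene ids before the network
#' is built.
#'
#' @param path Path to the edge-list file. Lines starting with `#` and the
#'   conventional `protein1 protein2 combined_score` header are skipped.
#' @param min_confidence Minimum confidence in `[0,1]`; edges with a score
#'   below it are discarded (edges without a score are kept). Default 0: no
#'   cutoff is applied unless requested.
#' @param id_map Optional path to a two-column TSV mapping input ids to gene
#'   ids; unmapped ids are kept as-is.
#' @return An `interaction_network`.
#' @export
load_network <- function(path, min_confidence = 0, id_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  .assert_scalar_number(min_confidence, "min_confidence", 0, 1)
  lines <- readLines(path, warn = FALSE)
  map <- NULL
  if (!is.null(id_map)) {
    m <- read.table(id_map, stringsAsFactors = FALSE,
                    colClasses = "character")
    map <- setNames(m[[2]], m[[1]])
  }
  from <- character(0); to <- character(0); conf <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (i == 1L && identical(tolower(f[1:2]), c("protein1", "protein2"))) next
    if (length(f) < 2 || length(f) > 3) {
      stop(sprintf("malformed edge list line %d in '%s'", i, path),
           call. = FALSE)
    }
    s <- NA_real_
    if (length(f) == 3) {
      if (!grepl("^[0-9]+$", f[[3]]) || as.numeric(f[[3]]) > 1000) {
        stop(sprintf("malformed combined score at line %d in '%s'", i, path),
             call. = FALSE)
      }
      s <- as.numeric(f[[3]]) / 1000
    }
    from <- c(from, f[[1]]); to <- c(to, f[[2]]); conf <- c(conf, s)
  }
  if (!is.null(map)) {
    from <- ifelse(from %in% names(map), unname(map[from]), from)
    to <- ifelse(to %in% names(map), unname(map[to]), to)
  }
  keep <- is.na(conf) | conf >= min_confidence
  interaction_network(tibble(from = from[keep], to = to[keep],
                             confidence = conf[keep]))
}

#' Enable compound-heterozygote combinations via self-loops
#'
#' Adds a self-edge to every node. With self-loops present, a tuple may
#' contain two different variant alleles of the same gene (compound
#' heterozygosity): the repeated gene then counts as "interacting with
#' itself" for the connectivity test. Idempotent.
#'
#' @param net An `interaction_network`.
#' @return The network with `self_loops = TRUE` and one self-edge per node.
#' @export
add_self_loops <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  e <- net$edges[net$edges$from != net$edges$to, , drop = FALSE]
  loops <- tibble(from = net$nodes, to = net$nodes,
                  confidence = rep(1, length(net$nodes)))
  e <- rbind(e, loops)
  net$edges <- e[order(e$from, e$to, method = "radix"), ]
  net$self_loops <- TRUE
  net
}

# Precomputed lookup structures for fast repeated connectivity checks.
.net_index <- function(net) {
  e <- net$edges
  plain <- e[e$from != e$to, , drop = FALSE]
  adj <- lapply(split(c(plain$to, plain$from), c(plain$from, plain$to)),
                unique)
  list(
    nodes = net$nodes,
    edge_keys = paste(plain$from, plain$to, sep = "\r"),
    adj = adj,
    self = unique(e$from[e$from == e$to])
  )
}

# Connectivity of the subgraph induced on a set of distinct genes, all of
# which are known to be nodes. Plain breadth-first search over the
# precomputed adjacency lists restricted to the set.
.induced_connected <- function(genes, idx) {
  k <- length(genes)
  if (k <= 1L) return(TRUE)
  if (k == 2L) {
    return(paste(min(genes), max(genes), sep = "\r") %in% idx$edge_keys)
  }
  seen <- genes[[1]]
  frontier <- genes[[1]]
  while (length(frontier)) {
    nxt <- character(0)
    for (g in frontier) {
      nb <- intersect(idx$adj[[g]] %||% character(0), genes)
      nxt <- c(nxt, setdiff(nb, seen))
    }
    nxt <- unique(nxt)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == k
}

.tuple_connected_idx <- function(gene_multiset, idx) {
  if (anyNA(gene_multiset)) return(FALSE)
  distinct <- unique(gene_multiset)
  if (!all(distinct %in% idx$nodes)) return(FALSE)
  dup <- unique(gene_multiset[duplicated(gene_multiset)])
  if (length(dup) && !all(dup %in% idx$self)) return(FALSE)
  .induced_connected(distinct, idx)
}

#' Test whether a gene multiset forms a connected module
#'
#' Returns `TRUE` iff (a) every distinct gene is a node of the network,
#' (b) the subgraph induced on the distinct genes is connected, and (c) any
#' gene appearing more than once in the multiset (compound heterozygosity)
#' carries a self-loop. A single distinct gene is trivially connected.
#'
#' With `via_bridges = TRUE` the induced-subgraph requirement (b) is relaxed:
#' the distinct genes only need to lie in one connected component of the
#' full network, so genes outside the tuple may act as bridges. The default
#' is the stricter reading, under which every reported combination has
#' direct interaction evidence among its own genes.
#'
#' @param genes Character vector (multiset) of gene ids; must be nonempty.
#' @param net An `interaction_network`.
#' @param via_bridges Logical; relax connectivity to whole-network
#'   components (default `FALSE`).
#' @return Logical scalar.
#' @export
is_connected_tuple <- function(genes, net, via_bridges = FALSE) {
  stopifnot(inherits(net, "interaction_network"))
  genes <- as.character(genes)
  if (!length(genes)) stop("empty gene multiset", call. = FALSE)
  if (anyNA(genes)) return(FALSE)
  idx <- .net_index(net)
  if (!via_bridges) return(.tuple_connected_idx(genes, idx))
  distinct <- unique(genes)
  if (!all(distinct %in% idx$nodes)) return(FALSE)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) && !all(dup %in% idx$self)) return(FALSE)
  if (length(distinct) == 1L) return(TRUE)
  g <- .as_igraph(net)
  comp <- igraph::components(g)$membership
  length(unique(comp[distinct])) == 1L
}

# igraph view of the network (self-loops dropped; they are a marker, not a
# topological feature).
.as_igraph <- function(net) {
  e <- net$edges[net$edges$from != net$edges$to, , drop = FALSE]
  igraph::graph_from_data_frame(
    e[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = net$nodes)
  )
}
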