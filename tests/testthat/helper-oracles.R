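# Independent oracles, deliberately implemented by different routes than
# the package internals.

# Connectivity oracle: induced subgraph via igraph + explicit self-loop
# rule for repeated genes.
oracle_connected <- function(gene_multiset, net) {
  if (anyNA(gene_multiset)) return(FALSE)
  distinct <- unique(gene_multiset)
  if (!all(distinct %in% net$nodes)) return(FALSE)
  dup <- unique(gene_multiset[duplicated(gene_multiset)])
  loops <- net$edges$from[net$edges$from == net$edges$to]
  if (length(dup) && !all(dup %in% loops)) return(FALSE)
  e <- net$edges[net$edges$from != net$edges$to, , drop = FALSE]
  g <- igraph::graph_from_data_frame(e[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  sub <- igraph::induced_subgraph(g, distinct)
  igraph::is_connected(sub)
}

# Brute-force tuple ranking by plain loops over combn output, scored with
# the igraph oracle.
oracle_rank_tuples <- function(svs, net, k, allow_compound_het = FALSE) {
  n <- nrow(svs)
  if (n < k) {
    return(data.frame(tuple_id = character(), score = numeric()))
  }
  combs <- combn(n, k)
  rows <- list()
  for (j in seq_len(ncol(combs))) {
    ix <- combs[, j]
    genes <- svs$gene[ix]
    if (!allow_compound_het && anyDuplicated(genes[!is.na(genes)])) next
    conn <- oracle_connected(genes, net)
    if (!conn) next
    rows[[length(rows) + 1L]] <- data.frame(
      tuple_id = paste(sort(svs$id[ix], method = "radix"), collapse = ","),
      score = sum(svs$score[ix]))
  }
  if (!length(rows)) {
    return(data.frame(tuple_id = character(), score = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$score, out$tuple_id,
            decreasing = c(TRUE, FALSE), method = "radix"), ]
}

# Pairwise-count Mann-Whitney U for group a (wins + half ties).
oracle_mwu_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) {
    u <- u + (x > y) + 0.5 * (x == y)
  }
  u
}

# Exact two-sided permutation p-value by enumerating group assignments,
# with U recomputed by pairwise counting.
oracle_mwu_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  obs <- abs(oracle_mwu_u(a, b) - n1 * length(b) / 2)
  subsets <- combn(length(pooled), n1)
  hits <- 0
  for (j in seq_len(ncol(subsets))) {
    ga <- pooled[subsets[, j]]
    gb <- pooled[-subsets[, j]]
    dev <- abs(oracle_mwu_u(ga, gb) - n1 * length(gb) / 2)
    if (dev >= obs - 1e-9) hits <- hits + 1
  }
  hits / ncol(subsets)
}
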