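# Spike-in benchmark: synthetic cases with known causative combinations
# and Top-k recovery evaluation, split into "all" and "interacting only".

.default_case_params <- function() {
  list(n_background = 100L, n_genes = 20L, edge_prob = 0.2,
       truth_size = 2L, truth_score_quantile = 1.0, truth_connected = TRUE)
}

#' Generate a synthetic benchmark case
#'
#' Emulates the spike-in protocol: a background of scored variants stands
#' in for a sequenced genome, and a known causative combination of 2 or 3
#' variants in distinct genes is inserted as ground truth. Background
#' scores are drawn from Beta(2, 5) (right-skewed: most variants look
#' benign); genes are assigned to variants uniformly; the gene network is
#' Erdős–Rényi with probability `edge_prob`. Truth variants receive the
#' `truth_score_quantile` quantile of Beta(2, 5) as their score. When
#' `truth_connected`, a path is added among the truth genes so their
#' induced subgraph is connected; otherwise any edges among truth genes are
#' removed, so the causative combination has no interaction evidence. Fully
#' reproducible from `seed`.
#'
#' @param params List with `n_background`, `n_genes`, `edge_prob`,
#'   `truth_size` (2 or 3), `truth_score_quantile` in (0, 1],
#'   `truth_connected`; omitted entries take the defaults above
#'   (100 background variants, 20 genes, edge probability 0.2, truth pair
#'   at the top quantile, connected).
#' @param seed Integer seed.
#' @return An object of class `benchmark_case`: `variants` (scored-variant
#'   tibble), `network`, `truth` (ids), `truth_genes`, `truth_connected`,
#'   `seed`.
#' @export
generate_case <- function(params = list(), seed) {
  p <- utils::modifyList(.default_case_params(), params)
  bad <- setdiff(names(params), names(.default_case_params()))
  if (length(bad)) {
    stop("unknown case parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!p$truth_size %in% c(2L, 3L)) {
    stop("truth_size must be 2 or 3", call. = FALSE)
  }
  .assert_scalar_number(p$edge_prob, "edge_prob", 0, 1)
  if (p$truth_score_quantile <= 0 || p$truth_score_quantile > 1) {
    stop("truth_score_quantile must lie in (0, 1]", call. = FALSE)
  }
  if (p$n_genes < p$truth_size) {
    stop("n_genes must be >= truth_size", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  genes <- sprintf("G%03d", seq_len(p$n_genes))
  bases <- c("A", "C", "G", "T")
  n_bg <- as.integer(p$n_background)

  pos_bg <- sort(sample.int(900000L, n_bg))
  ref_bg <- sample(bases, n_bg, replace = TRUE)
  alt_bg <- vapply(ref_bg, function(r) sample(setdiff(bases, r), 1),
                   character(1))
  bg <- variant_set(tibble(
    chrom = "1", pos = pos_bg, ref = ref_bg, alt = alt_bg,
    genotype = "het", gene = sample(genes, n_bg, replace = TRUE)
  ))

  truth_genes <- sample(genes, p$truth_size)
  pos_tr <- 900000L + 10L * seq_len(p$truth_size)
  ref_tr <- sample(bases, p$truth_size, replace = TRUE)
  alt_tr <- vapply(ref_tr, function(r) sample(setdiff(bases, r), 1),
                   character(1))
  causative <- tibble(chrom = "1", pos = pos_tr, ref = ref_tr,
                      alt = alt_tr, genotype = "het", gene = truth_genes)
  vs <- spike_variants(bg, causative)

  g <- igraph::sample_gnp(p$n_genes, p$edge_prob, directed = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- tibble(from = genes[as.integer(el[, 1])],
                  to = genes[as.integer(el[, 2])],
                  confidence = NA_real_)
  if (isTRUE(p$truth_connected)) {
    chain <- tibble(from = truth_genes[-length(truth_genes)],
                    to = truth_genes[-1], confidence = NA_real_)
    edges <- rbind(edges, chain)
  } else {
    both <- edges$from %in% truth_genes & edges$to %in% truth_genes
    edges <- edges[!both, , drop = FALSE]
  }
  net <- interaction_network(edges, nodes = genes)

  score_of <- setNames(rbeta(n_bg, 2, 5), bg$variants$id)
  score_of[vs$truth] <- qbeta(p$truth_score_quantile, 2, 5)
  v <- vs$variants
  v$score <- unname(score_of[v$id])

  structure(list(variants = v, network = net, truth = vs$truth,
                 truth_genes = .rsort(truth_genes),
                 truth_connected = isTRUE(p$truth_connected),
                 seed = as.integer(seed), params = p),
            class = "benchmark_case")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.benchmark_case <- function(x, ...) {
  cat(sprintf("<benchmark_case> seed %d: %d variants, truth {%s} (%s)\n",
              x$seed, nrow(x$variants), paste(x$truth, collapse = ", "),
              if (x$truth_connected) "connected" else "disconnected"))
  invisible(x)
}

#' Evaluate recovery of the truth set in a single-variant ranking
#'
#' `top_set` is `TRUE` iff all truth variants occupy ranks
#' `1..|truth|` (for a triallelic truth: all three within the first three
#' ranks); `topn_set` iff all truth variants rank at or above `top_n`.
#'
#' @param ranked Output of [rank_variants()].
#' @param truth Character vector of truth variant ids (all must appear in
#'   the ranking).
#' @param top_n Rank window for `topn_set` (default 10).
#' @return List with logicals `top_set` and `topn_set`.
#' @export
evaluate_single_ranking <- function(ranked, truth, top_n = 10) {
  r <- ranked$rank[match(truth, ranked$id)]
  if (anyNA(r)) {
    stop("truth variant(s) absent from the ranking: ",
         paste(truth[is.na(r)], collapse = ", "), call. = FALSE)
  }
  list(top_set = all(r <= length(truth)), topn_set = all(r <= top_n))
}

#' Evaluate recovery of the truth tuple in a tuple ranking
#'
#' Tuple-level criterion (default): `top_set` iff the rank-1 tuple's
#' member ids equal the truth set; `topn_set` iff a tuple whose members
#' equal the truth set appears within the first `top_n` ranks. A truth
#' tuple absent from the ranking (e.g. its genes are disconnected, so its
#' tuple score is 0) yields `FALSE` for both. The alternative `"flattened"`
#' criterion instead flattens the ranked tuples into a deduplicated variant
#' list in rank order and applies the single-ranking windows to it.
#'
#' @param ranked Output of [rank_tuples_exhaustive()] or
#'   [rank_tuples_beam()].
#' @param truth Character vector of truth variant ids.
#' @param top_n Rank window for `topn_set` (default 10).
#' @param criterion `"tuple"` (default) or `"flattened"`.
#' @return List with logicals `top_set` and `topn_set`.
#' @export
evaluate_tuple_ranking <- function(ranked, truth, top_n = 10,
                                   criterion = c("tuple", "flattened")) {
  criterion <- match.arg(criterion)
  truth_id <- paste(.rsort(truth), collapse = ",")
  if (criterion == "tuple") {
    if (!nrow(ranked)) return(list(top_set = FALSE, topn_set = FALSE))
    hit <- match(truth_id, ranked$tuple_id)
    list(top_set = identical(ranked$tuple_id[[1]], truth_id),
         topn_set = !is.na(hit) && hit <= top_n)
  } else {
    flat <- unique(unlist(ranked$variant_ids))
    r <- match(truth, flat)
    list(top_set = !anyNA(r) && all(r <= length(truth)),
         topn_set = !anyNA(r) && all(r <= top_n))
  }
}

#' Run the spike-in benchmark
#'
#' Generates `n_cases` seeded cases, ranks each by the requested methods
#' and reports Top-set / Top-N recovery counts for two splits: `all`
#' (every case) and `interacting_only` (cases whose truth genes form a
#' connected induced subgraph of that case's network, i.e. combinations
#' with background interaction knowledge).
#'
#' @param params Case parameters, as in [generate_case()].
#' @param n_cases Number of cases (>= 1).
#' @param methods Subset of `c("single_ranking", "tuple_ranking")`.
#' @param seed Master seed; case `i` uses `seed + i`.
#' @param top_n Rank window for the Top-N criterion (default 10).
#' @param cfg Ranking configuration for the tuple method; its `k` is
#'   overridden by the truth size. Beam search is used.
#' @return List of class `benchmark_result`: `metrics` (tibble: method,
#'   split, n_cases, top_set, topn_set, top_set_pct, topn_set_pct),
#'   `cases` (per-case tibble), `seed`.
#' @export
run_benchmark <- function(params = list(), n_cases, methods =
                            c("single_ranking", "tuple_ranking"),
                          seed, top_n = 10, cfg = ranking_config()) {
  n_cases <- as.integer(n_cases)
  if (is.na(n_cases) || n_cases < 1L) {
    stop("n_cases must be >= 1", call. = FALSE)
  }
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    case <- generate_case(params, seed = as.integer(seed) + i)
    interacting <- is_connected_tuple(case$truth_genes, case$network)
    res <- list(seed = case$seed, interacting = interacting)
    if ("single_ranking" %in% methods) {
      ev <- evaluate_single_ranking(rank_variants(case$variants),
                                    case$truth, top_n = top_n)
      res$single_top <- ev$top_set; res$single_topn <- ev$topn_set
    }
    if ("tuple_ranking" %in% methods) {
      cfg$k <- length(case$truth)
      ranked <- rank_tuples_beam(case$variants, case$network, cfg)
      ev <- evaluate_tuple_ranking(ranked, case$truth, top_n = top_n)
      res$tuple_top <- ev$top_set; res$tuple_topn <- ev$topn_set
    }
    rows[[i]] <- as_tibble(res)
  }
  cases <- do.call(rbind, rows)
  splits <- list(all = rep(TRUE, n_cases), interacting_only = cases$interacting)
  out <- list()
  for (m in methods) {
    pre <- if (m == "single_ranking") "single" else "tuple"
    for (s in names(splits)) {
      sel <- splits[[s]]
      n <- sum(sel)
      top <- sum(cases[[paste0(pre, "_top")]][sel])
      topn <- sum(cases[[paste0(pre, "_topn")]][sel])
      out[[length(out) + 1L]] <- tibble(
        method = m, split = s, n_cases = n, top_set = top,
        topn_set = topn,
        top_set_pct = if (n) 100 * top / n else NA_real_,
        topn_set_pct = if (n) 100 * topn / n else NA_real_
      )
    }
  }
  structure(list(metrics = do.call(rbind, out), cases = cases,
                 seed = as.integer(seed)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  m <- x$metrics
  m$top_set_pct <- sprintf("%.1f", m$top_set_pct)
  m$topn_set_pct <- sprintf("%.1f", m$topn_set_pct)
  print(as.data.frame(m), row.names = FALSE)
  invisible(x)
}
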