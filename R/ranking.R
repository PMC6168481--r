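# Core ranking: single variants and n-tuples under the network
# connectivity constraint. A tuple scores the sum of its members' scores
# when the genes carrying the variants form a connected subgraph of the
# background network, and zero otherwise; enumeration is exhaustive (the
# oracle) or by beam search.

#' Ranking configuration
#'
#' @param k Tuple cardinality (module size), integer >= 1.
#' @param beam_width Beam width for [rank_tuples_beam()]; partial tuples
#'   kept per level. Default 1000.
#' @param allow_compound_het Allow two variant alleles of the same gene in
#'   one tuple. Such tuples additionally require the gene to carry a
#'   self-loop (see [add_self_loops()]).
#' @param include_disconnected Keep zero-score tuples in the output
#'   (default `FALSE`: a zero tuple score carries no ranking information).
#' @param max_candidates Guard for exhaustive enumeration: refuse when
#'   `choose(n, k)` exceeds this (default 2e6).
#' @return A list of class `ranking_config`.
#' @export
ranking_config <- function(k = 2, beam_width = 1000,
                           allow_compound_het = FALSE,
                           include_disconnected = FALSE,
                           max_candidates = 2e6) {
  k <- as.integer(k)
  beam_width <- as.integer(beam_width)
  if (is.na(k) || k < 1L) stop("k must be >= 1", call. = FALSE)
  if (is.na(beam_width) || beam_width < 1L) {
    stop("beam_width must be >= 1", call. = FALSE)
  }
  structure(list(k = k, beam_width = beam_width,
                 allow_compound_het = isTRUE(allow_compound_het),
                 include_disconnected = isTRUE(include_disconnected),
                 max_candidates = max_candidates),
            class = "ranking_config")
}

# Validate/normalise a scored-variant table.
.as_scored <- function(svs) {
  svs <- as_tibble(svs)
  req <- c("id", "gene", "score")
  miss <- setdiff(req, names(svs))
  if (length(miss)) {
    stop("scored-variant table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(svs$id)) stop("duplicate variant ids", call. = FALSE)
  if (any(svs$score < 0 | svs$score > 1)) {
    stop("variant scores must lie in [0,1]", call. = FALSE)
  }
  svs
}

# Canonical per-tuple quantities from member row indices (ascending).
# Scores are always recomputed here, summing in ascending-index order, so
# that exhaustive and beam enumeration produce bit-identical values.
.finish_tuples <- function(members, svs, idx, cfg) {
  if (!length(members)) {
    return(tibble(rank = integer(), score = numeric(),
                  connected = logical(), tuple_id = character(),
                  variant_ids = list(), genes = list()))
  }
  ids_sorted <- lapply(members, function(ix) .rsort(svs$id[ix]))
  tuple_id <- vapply(ids_sorted, paste, character(1), collapse = ",")
  genes <- lapply(members, function(ix) svs$gene[ix])
  k <- length(members[[1]])
  if (all(lengths(members) == k)) {
    gmat <- matrix(unlist(genes), nrow = k)
    connected <- .tuples_connected_mat(gmat, idx)
  } else {
    connected <- vapply(genes, .tuple_connected_idx, logical(1), idx = idx)
  }
  raw <- vapply(members, function(ix) sum(svs$score[ix]), numeric(1))
  score <- ifelse(connected, raw, 0)
  keep <- if (cfg$include_disconnected) rep(TRUE, length(score)) else score > 0
  ord <- .order_score_key(score[keep], tuple_id[keep])
  sel <- which(keep)[ord]
  tibble(
    rank = seq_along(sel),
    score = score[sel],
    connected = connected[sel],
    tuple_id = tuple_id[sel],
    variant_ids = ids_sorted[sel],
    genes = lapply(genes[sel], function(g) .rsort(g))
  )
}

#' Score one tuple of variants
#'
#' Applies the tuple score: the sum of the members' scores if the gene
#' multiset satisfies [is_connected_tuple()] (every gene in the network,
#' induced subgraph connected, repeated genes self-looped), else 0.
#' Members lacking an assigned gene make the tuple disconnected.
#'
#' @param t Scored-variant table (rows are the tuple members; must be
#'   nonempty and have distinct ids).
#' @param net An `interaction_network`.
#' @return A one-row tibble: `score`, `connected`, `tuple_id`,
#'   `variant_ids`, `genes`.
#' @export
score_tuple <- function(t, net) {
  t <- .as_scored(t)
  if (!nrow(t)) stop("empty tuple", call. = FALSE)
  idx <- .net_index(net)
  cfg <- ranking_config(k = nrow(t), include_disconnected = TRUE)
  out <- .finish_tuples(list(seq_len(nrow(t))), t, idx, cfg)
  out$rank <- NULL
  out
}

#' Rank single variants by score
#'
#' Descending score; ties broken by ascending (chrom, pos, ref, alt);
#' ranks are 1-based ordinal positions after tie-break.
#'
#' @param svs Scored-variant table.
#' @return The table sorted, with a `rank` column prepended.
#' @export
rank_variants <- function(svs) {
  svs <- .as_scored(svs)
  if (!nrow(svs)) return(cbind(tibble(rank = integer()), svs))
  has_pos <- all(c("chrom", "pos", "ref", "alt") %in% names(svs))
  ord <- if (has_pos) {
    order(svs$score, svs$chrom, svs$pos, svs$ref, svs$alt,
          decreasing = c(TRUE, FALSE, FALSE, FALSE, FALSE),
          method = "radix")
  } else {
    .order_score_key(svs$score, svs$id)
  }
  out <- svs[ord, ]
  out <- cbind(tibble(rank = seq_len(nrow(out))), out)
  as_tibble(out)
}

# Vectorised connectivity over a k x m gene matrix (used by the exhaustive
# path). Dispatches to closed forms for k = 2, 3 with all-distinct genes;
# anything else goes through the per-tuple BFS.
.tuples_connected_mat <- function(gmat, idx) {
  k <- nrow(gmat); m <- ncol(gmat)
  if (!m) return(logical(0))
  in_net <- matrix(!is.na(gmat) & gmat %in% idx$nodes, nrow = k)
  all_in <- colSums(in_net) == k
  res <- logical(m)
  if (k == 1L) return(all_in)
  pair_conn <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "\r") %in% idx$edge_keys
  }
  if (k == 2L) {
    same <- !is.na(gmat[1, ]) & gmat[1, ] == gmat[2, ]
    res <- all_in & ifelse(same,
                           gmat[1, ] %in% idx$self,
                           pair_conn(gmat[1, ], gmat[2, ]))
    return(res)
  }
  if (k == 3L) {
    distinct3 <- gmat[1, ] != gmat[2, ] & gmat[1, ] != gmat[3, ] &
      gmat[2, ] != gmat[3, ]
    distinct3[is.na(distinct3)] <- FALSE
    i3 <- which(all_in & distinct3)
    if (length(i3)) {
      p12 <- pair_conn(gmat[1, i3], gmat[2, i3])
      p13 <- pair_conn(gmat[1, i3], gmat[3, i3])
      p23 <- pair_conn(gmat[2, i3], gmat[3, i3])
      # three nodes: any two edges (or all three) connect them
      res[i3] <- (p12 + p13 + p23) >= 2
    }
    rest <- which(all_in & !distinct3)
    for (j in rest) res[j] <- .tuple_connected_idx(gmat[, j], idx)
    return(res)
  }
  for (j in which(all_in)) res[j] <- .tuple_connected_idx(gmat[, j], idx)
  res
}

#' Rank all k-tuples exhaustively (brute-force oracle)
#'
#' Enumerates every k-subset of distinct variants, scores each with the
#' tuple score and returns the connected tuples in descending score order
#' (ties: lexicographically over the sorted member variant ids). Tuples
#' whose gene multiset repeats a gene are generated only when
#' `cfg$allow_compound_het`. Worst-case work is `O(n^k)`; enumeration above
#' `cfg$max_candidates` candidate subsets is refused.
#'
#' @param svs Scored-variant table.
#' @param net An `interaction_network`.
#' @param cfg A [ranking_config()].
#' @return Tibble of ranked tuples: `rank`, `score`, `connected`,
#'   `tuple_id`, `variant_ids` (list), `genes` (list).
#' @export
rank_tuples_exhaustive <- function(svs, net, cfg = ranking_config()) {
  svs <- .as_scored(svs)
  stopifnot(inherits(cfg, "ranking_config"))
  idx <- .net_index(net)
  n <- nrow(svs); k <- cfg$k
  if (n < k) return(.finish_tuples(list(), svs, idx, cfg))
  if (choose(n, k) > cfg$max_candidates) {
    stop(sprintf(paste0("exhaustive enumeration of choose(%d, %d) tuples ",
                        "exceeds max_candidates = %g; use rank_tuples_beam()"),
                 n, k, cfg$max_candidates), call. = FALSE)
  }
  combs <- if (k == 1L) matrix(seq_len(n), nrow = 1) else combn(n, k)
  gmat <- matrix(svs$gene[combs], nrow = k)
  if (!cfg$allow_compound_het && k > 1L) {
    rep_gene <- apply(gmat, 2, function(g) {
      g <- g[!is.na(g)]; anyDuplicated(g) > 0L
    })
    combs <- combs[, !rep_gene, drop = FALSE]
  }
  members <- lapply(seq_len(ncol(combs)), function(j) combs[, j])
  .finish_tuples(members, svs, idx, cfg)
}

#' Rank k-tuples by beam search
#'
#' Memory-bounded tuple construction. Level 1 seeds the beam with the
#' `beam_width` highest-scoring variants whose gene is in the network.
#' Each subsequent level extends every partial tuple by the variants whose
#' gene is adjacent to at least one gene already in the tuple (a self-loop
#' permits same-gene extension when `cfg$allow_compound_het`), removes
#' duplicate member sets, and keeps the `beam_width` partial tuples with
#' the highest score sums (ties broken lexicographically over member ids).
#' Completed tuples are re-scored with the strict tuple score and returned
#' in the same order as [rank_tuples_exhaustive()]; with a saturating beam
#' width the two outputs are identical. Small beams can legitimately lose
#' tuples (including all of them, when every seed is a dead end).
#'
#' @inheritParams rank_tuples_exhaustive
#' @return Tibble of ranked tuples, as for [rank_tuples_exhaustive()].
#' @export
rank_tuples_beam <- function(svs, net, cfg = ranking_config()) {
  svs <- .as_scored(svs)
  stopifnot(inherits(cfg, "ranking_config"))
  idx <- .net_index(net)
  n <- nrow(svs); k <- cfg$k
  elig <- which(!is.na(svs$gene) & svs$gene %in% idx$nodes)
  if (!length(elig) || n < 1L) return(.finish_tuples(list(), svs, idx, cfg))

  variants_of_gene <- split(seq_len(n)[elig], svs$gene[elig])
  truncate <- function(members, sums) {
    key <- vapply(members, function(ix) {
      paste(.rsort(svs$id[ix]), collapse = ",")
    }, character(1))
    dup <- duplicated(key)
    members <- members[!dup]; sums <- sums[!dup]; key <- key[!dup]
    ord <- .order_score_key(sums, key)
    keep <- ord[seq_len(min(cfg$beam_width, length(ord)))]
    list(members = members[keep], sums = sums[keep])
  }

  beam <- truncate(as.list(elig), svs$score[elig])
  lvl <- 1L
  while (lvl < k && length(beam$members)) {
    new_members <- list(); new_sums <- numeric(0)
    for (b in seq_along(beam$members)) {
      ix <- beam$members[[b]]
      tg <- unique(svs$gene[ix])
      cand_genes <- unique(unlist(idx$adj[tg], use.names = FALSE))
      cand_genes <- setdiff(cand_genes, tg)
      if (cfg$allow_compound_het) {
        cand_genes <- c(cand_genes, intersect(tg, idx$self))
      }
      cand <- setdiff(unlist(variants_of_gene[cand_genes],
                             use.names = FALSE), ix)
      if (!length(cand)) next
      new_members <- c(new_members,
                       lapply(cand, function(cix) sort(c(ix, cix))))
      new_sums <- c(new_sums, beam$sums[[b]] + svs$score[cand])
    }
    beam <- truncate(new_members, new_sums)
    lvl <- lvl + 1L
  }
  if (lvl < k) return(.finish_tuples(list(), svs, idx, cfg))
  .finish_tuples(beam$members, svs, idx, cfg)
}

#' Write ranked tuples as TSV
#'
#' One line per tuple: rank, score, connected flag, and per member the
#' variant id, gene and score (members sorted by variant id, separated by
#' `;`).
#'
#' @param ranked Output of [rank_tuples_exhaustive()] or
#'   [rank_tuples_beam()].
#' @param path Output path.
#' @param svs Optional scored-variant table used to annotate member
#'   scores.
#' @param header_lines Optional character vector of `#` comment lines to
#'   prepend.
#' @return Invisibly, `path`.
#' @export
write_ranked_tuples <- function(ranked, path, svs = NULL,
                                header_lines = character()) {
  score_of <- if (!is.null(svs)) setNames(svs$score, svs$id) else NULL
  gene_of <- if (!is.null(svs)) setNames(svs$gene, svs$id) else NULL
  rows <- vapply(seq_len(nrow(ranked)), function(i) {
    ids <- ranked$variant_ids[[i]]
    mem <- vapply(ids, function(v) {
      g <- if (!is.null(gene_of)) gene_of[[v]] else NA
      s <- if (!is.null(score_of)) format(score_of[[v]], digits = 12) else NA
      paste(v, g, s, sep = "|")
    }, character(1))
    paste(ranked$rank[[i]], format(ranked$score[[i]], digits = 12),
          tolower(ranked$connected[[i]]), paste(mem, collapse = ";"),
          sep = "\t")
  }, character(1))
  writeLines(c(header_lines,
               paste("rank", "score", "connected", "members", sep = "\t"),
               rows), path)
  invisible(path)
}
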