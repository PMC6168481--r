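# Per-variant scoring: pathogenicity combined with phenotype semantic
# similarity, or scores supplied by an external predictor.

#' Construct a patient phenotype profile
#'
#' @param terms Character vector of ontology term ids describing the
#'   patient's phenotypes.
#' @return Character vector of unique term ids, classed
#'   `phenotype_profile`.
#' @export
phenotype_profile <- function(terms) {
  terms <- .rsort(unique(as.character(terms)))
  structure(terms, class = c("phenotype_profile", "character"))
}

# IC of the most informative common ancestor of two terms; 0 when the only
# common ancestors carry no information (or none has a defined IC).
.mica_ic <- function(t1, t2, ont, ic) {
  common <- intersect(ont$ancestors[[t1]], ont$ancestors[[t2]])
  common <- common[common %in% names(ic)]
  if (!length(common)) return(0)
  max(ic[common])
}

#' Phenotype semantic similarity between a profile and a gene
#'
#' Resnik best-match-average similarity. For each profile term, the best
#' match is the maximum, over the gene's asserted terms, of the information
#' content of their most informative common ancestor; these best matches
#' are averaged over profile terms, the computation is repeated with the
#' profile and gene roles swapped, and the two directional averages are
#' averaged. The result is normalised by the corpus-wide maximum IC so it
#' lies in `[0,1]`. The average runs over asserted (direct) term sets; the
#' ancestor closure enters through the IC corpus and the common-ancestor
#' search. A gene with no annotations scores 0.
#'
#' @param profile A [phenotype_profile()] (nonempty; terms must exist in
#'   `ont`).
#' @param gene Gene id.
#' @param ont An [ontology()].
#' @param ann A propagated [annotation_set()].
#' @param ic Optional precomputed [information_content()] table (computed
#'   from `ont` and `ann` when omitted).
#' @return Similarity in `[0,1]`.
#' @export
semantic_similarity <- function(profile, gene, ont, ann, ic = NULL) {
  stopifnot(inherits(ont, "ontology"), inherits(ann, "annotation_set"))
  profile <- unique(as.character(profile))
  if (!length(profile)) stop("empty phenotype profile", call. = FALSE)
  unknown <- setdiff(profile, ont$terms)
  if (length(unknown)) {
    stop("profile term(s) not in ontology: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  gts <- ann$direct[[gene]]
  if (is.null(gts) || !length(gts)) return(0)
  if (is.null(ic)) ic <- information_content(ont, ann)
  max_ic <- max(ic)
  if (max_ic <= 0) return(0)
  best <- function(from, against) {
    vapply(from, function(p) {
      max(vapply(against, function(g) .mica_ic(p, g, ont, ic), numeric(1)))
    }, numeric(1))
  }
  d1 <- mean(best(profile, gts))
  d2 <- mean(best(gts, profile))
  min(1, max(0, mean(c(d1, d2)) / max_ic))
}

#' Score one variant
#'
#' The built-in scorer is a transparent stand-in for a trained
#' phenotype-aware pathogenicity predictor: it combines a supplied
#' pathogenicity score with the phenotype similarity of the variant's gene
#' to the patient profile as `w * pathogenicity + (1 - w) * similarity`.
#' Any external predictor producing a `[0,1]` score per variant can be
#' used instead via [load_scores()]; downstream tuple ranking only consumes
#' the scores.
#'
#' @param v Variant id (or a one-row data frame with an `id` column).
#' @param gene Gene id or `NA` (no gene: the similarity component is 0).
#' @param pathogenicity Pathogenicity score in `[0,1]`.
#' @param profile A [phenotype_profile()].
#' @param ont An [ontology()].
#' @param ann A propagated [annotation_set()].
#' @param w Weight of the pathogenicity component, in `[0,1]`; default 0.5.
#' @param ic Optional precomputed IC table.
#' @return A list with `id`, `gene`, `pathogenicity`, `similarity`,
#'   `score`.
#' @export
score_variant <- function(v, gene, pathogenicity, profile, ont, ann,
                          w = 0.5, ic = NULL) {
  .assert_scalar_number(w, "w", 0, 1)
  .assert_scalar_number(pathogenicity, "pathogenicity", 0, 1)
  id <- if (is.data.frame(v)) v$id[[1]] else as.character(v)
  sim <- if (is.na(gene) || is.null(gene)) 0 else {
    semantic_similarity(profile, gene, ont, ann, ic = ic)
  }
  list(id = id, gene = if (is.null(gene)) NA_character_ else gene,
       pathogenicity = pathogenicity, similarity = sim,
       score = w * pathogenicity + (1 - w) * sim)
}

#' Score every variant of a set
#'
#' Vectorised wrapper around [score_variant()] producing the scored-variant
#' table consumed by the ranking functions.
#'
#' @param vs A [variant_set()] with genes assigned.
#' @param pathogenicity Named numeric vector (by variant id) of
#'   pathogenicity scores in `[0,1]`; variants missing from it get 0.5
#'   (uninformative).
#' @param profile,ont,ann,w As in [score_variant()].
#' @return A tibble of scored variants: `id`, `chrom`, `pos`, `ref`,
#'   `alt`, `genotype`, `gene`, `pathogenicity`, `similarity`, `score`.
#' @export
score_variants <- function(vs, pathogenicity, profile, ont, ann, w = 0.5) {
  stopifnot(inherits(vs, "variant_set"))
  .assert_scalar_number(w, "w", 0, 1)
  v <- vs$variants
  p <- rep(0.5, nrow(v))
  if (!is.null(names(pathogenicity))) {
    hit <- match(v$id, names(pathogenicity))
    p[!is.na(hit)] <- unname(pathogenicity[hit[!is.na(hit)]])
  } else if (length(pathogenicity) %in% c(1L, nrow(v))) {
    p <- rep(as.numeric(pathogenicity), length.out = nrow(v))
  }
  if (any(p < 0 | p > 1)) stop("pathogenicity outside [0,1]", call. = FALSE)
  ic <- information_content(ont, ann)
  sim_cache <- new.env(parent = emptyenv())
  sim_of <- function(g) {
    if (is.na(g)) return(0)
    if (is.null(sim_cache[[g]])) {
      sim_cache[[g]] <- semantic_similarity(profile, g, ont, ann, ic = ic)
    }
    sim_cache[[g]]
  }
  sim <- vapply(v$gene, sim_of, numeric(1), USE.NAMES = FALSE)
  out <- v
  out$pathogenicity <- p
  out$similarity <- sim
  out$score <- w * p + (1 - w) * sim
  out
}

#' Load precomputed per-variant scores
#'
#' Attaches scores from an external predictor (TSV: variant id, score in
#' `[0,1]`; `#` comments and an optional header line allowed). Variants of
#' the set absent from the table are scored 0 with a warning; table entries
#' for unknown variants are ignored.
#'
#' @param path Path to the score TSV.
#' @param vs A [variant_set()].
#' @return A scored-variant tibble (`id`, `chrom`, `pos`, `ref`, `alt`,
#'   `genotype`, `gene`, `score`).
#' @export
load_scores <- function(path, vs) {
  stopifnot(inherits(vs, "variant_set"))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.table(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = "character",
                    col.names = c("variant_id", "score"))
  if (nrow(raw) && identical(tolower(raw$variant_id[[1]]), "variant_id")) {
    raw <- raw[-1, , drop = FALSE]
  }
  sc <- suppressWarnings(as.numeric(raw$score))
  if (anyNA(sc)) stop("non-numeric score in ", path, call. = FALSE)
  if (any(sc < 0 | sc > 1)) {
    stop("score outside [0,1] in ", path, call. = FALSE)
  }
  v <- vs$variants
  hit <- match(v$id, raw$variant_id)
  if (anyNA(hit)) {
    warning(sprintf("%d variant(s) missing from score table; scored 0 (e.g. %s)",
                    sum(is.na(hit)), v$id[which(is.na(hit))[1]]),
            call. = FALSE)
  }
  v$score <- ifelse(is.na(hit), 0, sc[hit])
  v
}
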