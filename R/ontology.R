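# Minimal phenotype-ontology support: a DAG of terms with is-a parents,
# annotation propagation, and Resnik information content.

#' Construct an ontology
#'
#' A phenotype ontology is represented as a directed acyclic graph of term
#' ids with is-a parent links. Ancestor closures (reflexive) are precomputed
#' at construction; cycles and dangling parent references are rejected.
#'
#' @param parents Named list: term id -> character vector of parent term
#'   ids (empty for roots).
#' @return An object of class `ontology` with elements `terms`, `parents`,
#'   `roots` and `ancestors` (named list of reflexive ancestor closures).
#' @export
ontology <- function(parents) {
  stopifnot(is.list(parents), !is.null(names(parents)))
  terms <- names(parents)
  if (anyDuplicated(terms)) stop("duplicated term ids", call. = FALSE)
  parents <- lapply(parents, as.character)
  unknown <- setdiff(unique(unlist(parents)), terms)
  if (length(unknown)) {
    stop("parent term(s) not defined: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  roots <- terms[vapply(parents, length, integer(1)) == 0L]
  if (!length(roots) && length(terms)) {
    stop("ontology has no root term (cycle at the top)", call. = FALSE)
  }
  # reflexive-transitive closure with cycle detection (DFS, 3-colour)
  anc <- vector("list", length(terms))
  names(anc) <- terms
  state <- setNames(rep(0L, length(terms)), terms)  # 0 new, 1 open, 2 done
  visit <- function(t) {
    if (state[[t]] == 1L) stop("cycle detected at term ", t, call. = FALSE)
    if (state[[t]] == 2L) return(anc[[t]])
    state[[t]] <<- 1L
    up <- unique(unlist(lapply(parents[[t]], visit)))
    anc[[t]] <<- .rsort(unique(c(t, up)))
    state[[t]] <<- 2L
    anc[[t]]
  }
  for (t in terms) visit(t)
  structure(list(terms = terms, parents = parents, roots = .rsort(roots),
                 ancestors = anc),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms, %d root(s)\n",
              length(x$terms), length(x$roots)))
  invisible(x)
}

#' Read an OBO-format ontology
#'
#' Parses the `[Term]` stanzas of an OBO file, keeping only `id:` and
#' `is_a:` tags (trailing `! comment` text is stripped). Obsolete terms are
#' skipped. This covers the subset of OBO used by HPO/MP-style phenotype
#' ontologies for is-a reasoning.
#'
#' @param path Path to an OBO file.
#' @return An [ontology()].
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  parents <- list()
  cur <- NULL; cur_isa <- character(0); obsolete <- FALSE; in_term <- FALSE
  flush <- function() {
    if (in_term && !is.null(cur) && !obsolete) parents[[cur]] <<- cur_isa
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush(); in_term <- TRUE; cur <- NULL
      cur_isa <- character(0); obsolete <- FALSE
    } else if (startsWith(ln, "[")) {
      flush(); in_term <- FALSE
    } else if (in_term && startsWith(ln, "id:")) {
      cur <- trimws(sub("^id:", "", ln))
    } else if (in_term && startsWith(ln, "is_a:")) {
      v <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur_isa <- c(cur_isa, v)
    } else if (in_term && startsWith(ln, "is_obsolete:") &&
               grepl("true", ln)) {
      obsolete <- TRUE
    }
  }
  flush()
  if (!length(parents)) stop("no [Term] stanzas found in ", path,
                             call. = FALSE)
  # drop is_a links to terms that were filtered out (e.g. obsolete)
  parents <- lapply(parents, function(p) p[p %in% names(parents)])
  ontology(parents)
}

#' Construct a gene-to-phenotype annotation set
#'
#' @param gene_terms Named list: gene id -> character vector of ontology
#'   term ids the gene is asserted to cause/associate with.
#' @return An object of class `annotation_set` with elements `gene_terms`
#'   (the current sets), `direct` (the asserted sets, preserved across
#'   propagation) and `propagated` (logical).
#' @export
annotation_set <- function(gene_terms) {
  stopifnot(is.list(gene_terms))
  gene_terms <- lapply(gene_terms, function(x) .rsort(unique(as.character(x))))
  structure(list(gene_terms = gene_terms, direct = gene_terms,
                 propagated = FALSE),
            class = "annotation_set")
}

#' Read a gene-to-term annotation table
#'
#' Two-column TSV (`gene_id`, `term_id`), `#` comments allowed.
#'
#' @param path Path to the TSV file.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.table(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = "character",
                    col.names = c("gene_id", "term_id"))
  annotation_set(split(raw$term_id, raw$gene_id))
}

#' Propagate annotations up the ontology (true-path closure)
#'
#' Replaces every gene's term set by its reflexive ancestor closure, so
#' that a gene annotated to a specific phenotype is also counted for every
#' more general phenotype. The asserted (direct) sets are preserved in the
#' result for use by the similarity measure.
#'
#' @param ann An [annotation_set()].
#' @param ont An [ontology()].
#' @return The propagated `annotation_set`.
#' @export
propagate_annotations <- function(ann, ont) {
  stopifnot(inherits(ann, "annotation_set"), inherits(ont, "ontology"))
  unknown <- setdiff(unique(unlist(ann$direct)), ont$terms)
  if (length(unknown)) {
    stop("annotation term(s) not in ontology: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ann$gene_terms <- lapply(ann$direct, function(ts) {
    .rsort(unique(unlist(ont$ancestors[ts])))
  })
  ann$propagated <- TRUE
  ann
}

#' Resnik information content of ontology terms
#'
#' `IC(t) = -log(n_t / N)` (natural log), where `n_t` is the number of
#' genes annotated to `t` after propagation and `N` the number of annotated
#' genes. Terms annotating every gene (the root, after propagation) get IC
#' 0; terms annotating no gene are undefined and omitted from the result,
#' which excludes them from similarity maxima.
#'
#' @param ont An [ontology()].
#' @param ann A propagated [annotation_set()].
#' @return Named numeric vector of IC values for terms with at least one
#'   annotated gene.
#' @export
information_content <- function(ont, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  if (!isTRUE(ann$propagated)) {
    stop("annotations must be propagated first (see propagate_annotations)",
         call. = FALSE)
  }
  sets <- Filter(length, ann$gene_terms)
  n_genes <- length(sets)
  if (!n_genes) stop("no annotated genes", call. = FALSE)
  counts <- table(unlist(sets))
  ic <- -log(as.numeric(counts) / n_genes)
  setNames(ic, names(counts))
}
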