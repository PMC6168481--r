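# Variant model: reading VCF, gene assignment, spike-in construction.

.GENOTYPES <- c("het", "hom", "missing")

.variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Construct a variant set
#'
#' A variant set is an ordered table of single-ALT variants. Each variant is
#' keyed by `chrom:pos:ref:alt`; keys must be unique. An optional `truth`
#' vector records the identifiers of causative variants that were spiked
#' into the set (see [spike_variants()]).
#'
#' @param variants Data frame with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`, and optionally `genotype` (`"het"`, `"hom"` or
#'   `"missing"`; defaults to `"het"`) and `gene` (defaults to `NA` until
#'   [assign_genes()] is run).
#' @param truth Character vector of causative variant identifiers
#'   (must be a subset of the set's identifiers).
#' @return An object of class `variant_set` with elements `variants`
#'   (a tibble, including a derived `id` column) and `truth`.
#' @export
variant_set <- function(variants, truth = character()) {
  v <- as_tibble(variants)
  req <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(v))
  if (length(miss)) {
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  v$chrom <- as.character(v$chrom)
  v$pos <- as.integer(v$pos)
  v$ref <- as.character(v$ref)
  v$alt <- as.character(v$alt)
  if (!"genotype" %in% names(v)) v$genotype <- rep("het", nrow(v))
  if (!"gene" %in% names(v)) v$gene <- rep(NA_character_, nrow(v))
  if (nrow(v)) {
    if (any(is.na(v$pos)) || any(v$pos < 1L)) {
      stop("variant positions must be integers >= 1", call. = FALSE)
    }
    if (any(v$ref == v$alt)) {
      stop("ref and alt alleles must differ", call. = FALSE)
    }
    bad_gt <- setdiff(unique(v$genotype), .GENOTYPES)
    if (length(bad_gt)) {
      stop("unknown genotype value(s): ", paste(bad_gt, collapse = ", "),
           call. = FALSE)
    }
  }
  v$id <- .variant_id(v$chrom, v$pos, v$ref, v$alt)
  dup <- v$id[duplicated(v$id)]
  if (length(dup)) {
    stop("duplicate variant id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  truth <- as.character(truth)
  if (length(setdiff(truth, v$id))) {
    stop("truth ids not present in the variant set", call. = FALSE)
  }
  cols <- c("id", "chrom", "pos", "ref", "alt", "genotype", "gene")
  structure(list(variants = v[, cols], truth = truth),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %d variants, %d truth id(s)\n",
              nrow(x$variants), length(x$truth)))
  print(x$variants, n = 6)
  invisible(x)
}

# Structural validation of raw VCF lines so parse errors can name the
# offending line; field extraction itself is delegated to vcfR.
.validate_vcf_lines <- function(lines, path) {
  if (!length(lines) || !grepl("^##fileformat=VCF", lines[[1]])) {
    stop(sprintf("malformed VCF header in '%s' (line 1): missing ##fileformat",
                 path), call. = FALSE)
  }
  header_at <- grep("^#CHROM\t", lines)
  if (!length(header_at)) {
    stop(sprintf("malformed VCF header in '%s': no #CHROM line", path),
         call. = FALSE)
  }
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (!length(body)) {
    stop(sprintf("VCF file '%s' contains no variant records", path),
         call. = FALSE)
  }
  for (i in body) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    ok <- length(f) >= 8 &&
      nzchar(f[[1]]) &&
      grepl("^[0-9]+$", f[[2]]) &&
      grepl("^[ACGTNacgtn]+$", f[[4]]) &&
      grepl("^[ACGTNacgtn*.,<>0-9_]+$", f[[5]])
    if (!ok) {
      stop(sprintf("malformed VCF record in '%s' at line %d", path, i),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Genotype of one ALT allele (1-based allele index) from a GT string.
.parse_gt <- function(gt, allele_index) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (all(alleles == ".")) return("missing")
  n <- sum(alleles == as.character(allele_index))
  if (n >= 2) "hom" else "het"
}

#' Read variants from a VCF file
#'
#' Reads a VCF 4.x file (plain text or gzipped, single sample or no sample
#' column) into a [variant_set()]. Multi-allelic records are split into one
#' variant per ALT allele. Genotypes are taken from the GT field of the
#' first sample when present, otherwise every variant is recorded as
#' heterozygous. No record is discarded: non-PASS FILTER values, any allele
#' frequency and any quality are all retained, so that candidate interacting
#' variants of low apparent pathogenicity or medium population frequency are
#' not lost before ranking.
#'
#' @param path Path to a VCF file.
#' @return A [variant_set()] with variants in file order (ALT alleles of a
#'   record in ALT-column order).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  .validate_vcf_lines(lines, path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  has_gt <- ncol(v@gt) >= 2 && "FORMAT" %in% colnames(v@gt)
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    gt <- NA_character_
    if (has_gt) {
      fmt <- strsplit(v@gt[i, "FORMAT"], ":", fixed = TRUE)[[1]]
      gti <- match("GT", fmt)
      if (!is.na(gti)) {
        smp <- strsplit(v@gt[i, 2], ":", fixed = TRUE)[[1]]
        gt <- smp[gti]
      }
    }
    out[[i]] <- tibble(
      chrom = fix[i, "CHROM"],
      pos = as.integer(fix[i, "POS"]),
      ref = fix[i, "REF"],
      alt = alts,
      genotype = vapply(seq_along(alts), function(a) {
        if (is.na(gt)) "het" else .parse_gt(gt, a)
      }, character(1))
    )
  }
  variant_set(do.call(rbind, out))
}

#' Write a variant set as a minimal VCF file
#'
#' Emits a VCF 4.2 file with one record per variant (no re-merging of split
#' multi-allelic alleles) and a single-sample GT column reflecting the
#' stored genotypes.
#'
#' @param vs A [variant_set()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(vs, path) {
  stopifnot(inherits(vs, "variant_set"))
  v <- vs$variants
  gt <- c(het = "0/1", hom = "1/1", missing = "./.")[v$genotype]
  lines <- c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "SAMPLE"), collapse = "\t"),
    paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT", gt,
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene model table
#'
#' The gene model is a tab-separated table with columns
#' `gene_id, chrom, start, end`; coordinates are 1-based inclusive. Lines
#' starting with `#` are comments; an optional header line naming the
#' columns is recognised and skipped.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   ordered by `gene_id` (C locale).
#' @export
read_gene_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.table(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE,
                    col.names = c("gene_id", "chrom", "start", "end"),
                    colClasses = c("character", "character", "character",
                                   "character"))
  if (nrow(raw) && identical(tolower(raw$gene_id[[1]]), "gene_id")) {
    raw <- raw[-1, , drop = FALSE]
  }
  gm <- tibble(
    gene_id = raw$gene_id,
    chrom = raw$chrom,
    start = as.integer(raw$start),
    end = as.integer(raw$end)
  )
  if (any(is.na(gm$start)) || any(is.na(gm$end))) {
    stop("gene model has non-integer coordinates", call. = FALSE)
  }
  if (any(gm$start > gm$end)) {
    stop("gene model interval(s) with start > end", call. = FALSE)
  }
  if (anyDuplicated(gm$gene_id)) {
    stop("gene model has duplicated gene ids", call. = FALSE)
  }
  gm[order(gm$gene_id, method = "radix"), ]
}

#' Assign each variant its nearest gene
#'
#' A variant inside a gene interval is assigned that gene (distance 0).
#' A variant outside every interval on its chromosome is assigned the gene
#' whose nearest interval boundary is closest (distance in bases to the
#' closer of start/end). A variant on a chromosome with no genes keeps
#' `NA`. Ties are broken toward the lexicographically smallest gene id so
#' that assignment is deterministic.
#'
#' @param vs A [variant_set()].
#' @param gm A gene model from [read_gene_model()] (or an equivalent data
#'   frame).
#' @return `vs` with its `gene` column filled in.
#' @export
assign_genes <- function(vs, gm) {
  stopifnot(inherits(vs, "variant_set"))
  gm <- as_tibble(gm)
  if (!nrow(gm)) stop("gene model is empty", call. = FALSE)
  gm <- gm[order(gm$gene_id, method = "radix"), ]
  v <- vs$variants
  gene <- rep(NA_character_, nrow(v))
  for (chr in unique(v$chrom)) {
    g <- gm[gm$chrom == chr, ]
    if (!nrow(g)) next
    vi <- which(v$chrom == chr)
    for (i in vi) {
      p <- v$pos[[i]]
      d <- pmax(g$start - p, p - g$end, 0L)
      gene[[i]] <- g$gene_id[[which.min(d)]]  # first minimum = smallest id
    }
  }
  v$gene <- gene
  vs$variants <- v
  vs
}

#' Spike causative variants into a background variant set
#'
#' Emulates the construction of a synthetic genome for benchmarking: a known
#' causative combination of variants is inserted into a background set of
#' variants, and the inserted identifiers are recorded as ground truth. The
#' combined set is re-sorted by (chrom, pos).
#'
#' @param background A [variant_set()].
#' @param causative Data frame of variants to insert (columns as for
#'   [variant_set()]).
#' @param genotype Genotype given to inserted variants that carry no
#'   `genotype` column of their own (default `"het"`).
#' @return A [variant_set()] containing all background plus all causative
#'   variants, with `truth` set to the causative ids.
#' @export
spike_variants <- function(background, causative, genotype = "het") {
  stopifnot(inherits(background, "variant_set"))
  cz <- as_tibble(causative)
  if (!"genotype" %in% names(cz)) cz$genotype <- rep(genotype, nrow(cz))
  if (!"gene" %in% names(cz)) cz$gene <- rep(NA_character_, nrow(cz))
  cid <- .variant_id(as.character(cz$chrom), as.integer(cz$pos),
                     as.character(cz$ref), as.character(cz$alt))
  clash <- intersect(cid, background$variants$id)
  if (length(clash)) {
    stop("causative variant(s) already present in background: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  cols <- c("chrom", "pos", "ref", "alt", "genotype", "gene")
  all <- rbind(background$variants[, cols], cz[, cols])
  all <- all[order(all$chrom, all$pos, all$ref, all$alt, method = "radix"), ]
  variant_set(all, truth = c(background$truth, cid))
}
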