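# Fixtures are built in code at test time.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal single-sample VCF; records is a data.frame with chrom, pos, ref,
# alt (possibly comma-separated), gt (or NA for no sample column).
fixture_vcf <- function(records) {
  has_gt <- !is.null(records$gt)
  hdr <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", if (has_gt) c("FORMAT", "S1")), collapse = "\t"))
  body <- vapply(seq_len(nrow(records)), function(i) {
    paste(c(records$chrom[i], records$pos[i], ".", records$ref[i],
            records$alt[i], ".", "PASS", ".",
            if (has_gt) c("GT", records$gt[i])), collapse = "\t")
  }, character(1))
  write_lines_tmp(c(hdr, body), ".vcf")
}

fixture_gene_model <- function(df = NULL) {
  if (is.null(df)) {
    df <- data.frame(gene_id = c("GA", "GB"), chrom = c("1", "1"),
                     start = c(100L, 300L), end = c(200L, 400L))
  }
  write_lines_tmp(c("# gene_id\tchrom\tstart\tend (1-based inclusive)",
                    sprintf("%s\t%s\t%d\t%d", df$gene_id, df$chrom,
                            df$start, df$end)), ".tsv")
}

# Two-level toy ontology: root r; A, B under r; A1, A2 under A; B1, B2
# under B. Three genes annotated g1={A1}, g2={A2,B1}, g3={B2}.
toy_ontology <- function() {
  ontology(list(r = character(), A = "r", B = "r",
                A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
}

toy_annotations <- function() {
  annotation_set(list(g1 = "A1", g2 = c("A2", "B1"), g3 = "B2"))
}

# Small scored-variant table + network used across ranking tests.
six_variant_fixture <- function() {
  list(
    svs = tibble::tibble(
      id = sprintf("v%d", 1:6),
      chrom = "1", pos = 1:6 * 10L, ref = "A", alt = "T",
      gene = c("A", "B", "C", "A", "D", "E"),
      score = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
    ),
    net = interaction_network(data.frame(from = c("A", "B", "C"),
                                         to = c("B", "C", "D")))
  )
}

# Random ranking instance: n variants over g genes, Erdos-Renyi edges,
# uniform scores; optionally with self-loops enabled.
random_instance <- function(seed, n_max = 30, g_max = 15,
                            self_loops = FALSE) {
  set.seed(seed)
  n <- sample(4:n_max, 1)
  g <- sample(3:g_max, 1)
  genes <- sprintf("g%02d", seq_len(g))
  p <- runif(1, 0.15, 0.5)
  pairs <- t(combn(g, 2))
  on <- runif(nrow(pairs)) < p
  net <- interaction_network(
    data.frame(from = genes[pairs[on, 1]], to = genes[pairs[on, 2]]),
    nodes = genes)
  if (self_loops) net <- add_self_loops(net)
  svs <- tibble::tibble(
    id = sprintf("s%03d", seq_len(n)),
    gene = sample(genes, n, replace = TRUE),
    score = round(runif(n), 6)
  )
  list(svs = svs, net = net, n = n, g = g)
}
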