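test_that("ontology construction validates the DAG", {
  expect_error(ontology(list(a = "b")), "not defined")
  expect_error(ontology(list(a = "b", b = "a")), "cycle|root")
  ont <- toy_ontology()
  expect_setequal(ont$roots, "r")
  expect_setequal(ont$ancestors[["A1"]], c("A1", "A", "r"))
})

test_that("read_obo parses id/is_a stanzas and skips obsolete terms", {
  obo <- write_lines_tmp(c(
    "format-version: 1.2", "",
    "[Term]", "id: HP:1", "name: root", "",
    "[Term]", "id: HP:2", "name: child", "is_a: HP:1 ! root", "",
    "[Term]", "id: HP:3", "is_a: HP:2", "is_obsolete: true", "",
    "[Typedef]", "id: part_of"), ".obo")
  ont <- read_obo(obo)
  expect_setequal(ont$terms, c("HP:1", "HP:2"))
  expect_equal(ont$parents[["HP:2"]], "HP:1")
  expect_error(read_obo(write_lines_tmp("no stanzas", ".obo")), "Term")
})

test_that("propagate_annotations closes term sets under ancestors", {
  ont <- toy_ontology()
  ann <- propagate_annotations(toy_annotations(), ont)
  expect_setequal(ann$gene_terms$g1, c("A1", "A", "r"))       # leaf closure
  expect_setequal(ann$gene_terms$g2, c("A2", "A", "B1", "B", "r"))
  root_only <- propagate_annotations(annotation_set(list(g = "r")), ont)
  expect_equal(root_only$gene_terms$g, "r")                   # fixpoint
  empty <- propagate_annotations(annotation_set(list()), ont)
  expect_length(empty$gene_terms, 0)
  expect_error(propagate_annotations(annotation_set(list(g = "nope")), ont),
               "nope")
})

test_that("information content matches hand-computed closed forms", {
  ont <- toy_ontology()
  ann <- propagate_annotations(toy_annotations(), ont)
  ic <- information_content(ont, ann)
  # 3 annotated genes: root covers all (IC 0), A and B cover 2/3,
  # each leaf covers 1/3
  expect_equal(unname(ic["r"]), 0)
  expect_equal(unname(ic["A"]), log(3 / 2))
  expect_equal(unname(ic["B"]), log(3 / 2))
  for (leaf in c("A1", "A2", "B1", "B2")) {
    expect_equal(unname(ic[leaf]), log(3))
  }
  # 1-in-4 term: -log(0.25)
  ont2 <- ontology(list(r = character(), t = "r"))
  ann4 <- propagate_annotations(
    annotation_set(list(g1 = "t", g2 = "r", g3 = "r", g4 = "r")), ont2)
  expect_equal(unname(information_content(ont2, ann4)["t"]), -log(0.25))
  expect_error(information_content(ont, toy_annotations()), "propagated")
  expect_error(information_content(
    ont, propagate_annotations(annotation_set(list()), ont)), "no annotated")
})

test_that("semantic similarity matches an independent best-match-average oracle", {
  ont <- toy_ontology()
  ann <- propagate_annotations(toy_annotations(), ont)
  ic <- information_content(ont, ann)

  # independent BMA: loops over all common-ancestor pairs
  oracle_sim <- function(set1, set2) {
    mica <- function(x, y) {
      common <- intersect(ont$ancestors[[x]], ont$ancestors[[y]])
      common <- common[common %in% names(ic)]
      if (!length(common)) 0 else max(ic[common])
    }
    d1 <- mean(sapply(set1, function(p) max(sapply(set2, mica, x = p))))
    d2 <- mean(sapply(set2, function(g) max(sapply(set1, mica, x = g))))
    mean(c(d1, d2)) / max(ic)
  }

  profiles <- list("A1", c("A1", "B2"), c("A2", "B1"), "r")
  for (p in profiles) {
    for (g in c("g1", "g2", "g3")) {
      expect_equal(semantic_similarity(phenotype_profile(p), g, ont, ann),
                   oracle_sim(p, ann$direct[[g]]),
                   info = paste(paste(p, collapse = "+"), g))
    }
  }
  # frozen derived value for one representative pair
  expect_equal(semantic_similarity(phenotype_profile("A1"), "g2", ont, ann),
               mean(c(log(3 / 2), log(3 / 2) / 2)) / log(3))
})

test_that("semantic similarity is symmetric, bounded, and maximal on self", {
  ont <- toy_ontology()
  ann <- propagate_annotations(toy_annotations(), ont)
  # self-similarity at the normalizing maximum
  expect_equal(semantic_similarity(phenotype_profile("A1"), "g1", ont, ann), 1)
  # only the root in common -> 0
  expect_equal(semantic_similarity(phenotype_profile("A1"), "g3", ont, ann), 0)
  # symmetry: swap the profile and the gene's asserted set while holding
  # the annotation corpus (and so the IC table) fixed
  aug <- propagate_annotations(
    annotation_set(list(g1 = "A1", g2 = c("A2", "B1"), g3 = "B2",
                        gx = "A1")), ont)
  s1 <- semantic_similarity(phenotype_profile("A1"), "g2", ont, aug)
  s2 <- semantic_similarity(phenotype_profile(c("A2", "B1")), "gx", ont, aug)
  expect_equal(s1, s2)
  expect_gt(s1, 0)
  # range and unannotated gene
  for (p in list("A1", c("A2", "B2"), "r")) {
    s <- semantic_similarity(phenotype_profile(p), "g2", ont, ann)
    expect_gte(s, 0); expect_lte(s, 1)
  }
  expect_equal(semantic_similarity(phenotype_profile("A1"), "unknown_gene",
                                   ont, ann), 0)
  expect_error(semantic_similarity(phenotype_profile(character()), "g1",
                                   ont, ann), "empty")
})

test_that("score_variant combines pathogenicity and similarity convexly", {
  ont <- toy_ontology()
  ann <- propagate_annotations(toy_annotations(), ont)
  prof <- phenotype_profile("A1")
  # similarity 1 for g1: any weight keeps a perfect score at 1
  for (w in c(0, 0.3, 1)) {
    expect_equal(score_variant("v", "g1", 1.0, prof, ont, ann, w = w)$score, 1)
  }
  # arithmetic: 0.5 * 0.8 + 0.5 * sim; force sim by using g1 (sim 1)
  expect_equal(score_variant("v", "g1", 0.8, prof, ont, ann, w = 0.5)$score,
               0.9)
  # degenerate weight ignores similarity
  expect_equal(score_variant("v", "g2", 0.37, prof, ont, ann, w = 1)$score,
               0.37)
  # no gene -> similarity component 0
  expect_equal(score_variant("v", NA, 0.6, prof, ont, ann, w = 0.5)$score, 0.3)
  expect_error(score_variant("v", "g1", 0.5, prof, ont, ann, w = 1.5), "w")
  # monotone in both inputs
  s_low <- score_variant("v", "g3", 0.2, prof, ont, ann)$score
  s_high <- score_variant("v", "g3", 0.9, prof, ont, ann)$score
  expect_gte(s_high, s_low)
})

test_that("load_scores applies the table, defaults absences to 0, checks range", {
  vs <- variant_set(data.frame(chrom = "1", pos = c(10L, 20L, 30L),
                               ref = "A", alt = "T"))
  ids <- vs$variants$id
  full <- write_lines_tmp(sprintf("%s\t%s", ids, c("0.9", "0.2", "0.5")))
  sc <- load_scores(full, vs)
  expect_equal(sc$score, c(0.9, 0.2, 0.5))

  partial <- write_lines_tmp(sprintf("%s\t%s", ids[1:2], c("0.9", "0.2")))
  expect_warning(sc2 <- load_scores(partial, vs), "missing")
  expect_equal(sc2$score, c(0.9, 0.2, 0))

  bad <- write_lines_tmp(sprintf("%s\t%s", ids, c("0.9", "1.3", "0.5")))
  expect_error(load_scores(bad, vs), "\\[0,1\\]")
})
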