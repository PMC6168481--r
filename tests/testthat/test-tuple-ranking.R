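test_that("score_tuple sums member scores only when the genes interact", {
  net <- interaction_network(data.frame(from = "A", to = "B"),
                             nodes = c("A", "B", "C"))
  two <- tibble::tibble(id = c("v1", "v2"), gene = c("A", "B"),
                        score = c(0.9, 0.8))
  st <- score_tuple(two, net)
  expect_equal(st$score, 1.7)
  expect_true(st$connected)

  apart <- tibble::tibble(id = c("v1", "v2"), gene = c("A", "C"),
                          score = c(0.9, 0.8))
  expect_equal(score_tuple(apart, net)$score, 0)

  off_net <- tibble::tibble(id = c("v1", "v2"), gene = c("A", "Z"),
                            score = c(0.9, 0.8))
  expect_equal(score_tuple(off_net, net)$score, 0)

  no_gene <- tibble::tibble(id = c("v1", "v2"), gene = c("A", NA),
                            score = c(0.9, 0.8))
  expect_equal(score_tuple(no_gene, net)$score, 0)

  expect_error(score_tuple(two[0, ], net), "empty")
})

test_that("rank_variants sorts by score with positional tie-break", {
  svs <- tibble::tibble(id = c("a", "b", "c"), chrom = "1",
                        pos = c(10L, 20L, 30L), ref = "A", alt = "T",
                        gene = NA_character_, score = c(0.9, 0.5, 0.7))
  r <- rank_variants(svs)
  expect_equal(r$id, c("a", "c", "b"))
  expect_equal(r$rank, 1:3)

  tied <- tibble::tibble(id = c("x", "y"), chrom = c("2", "1"),
                         pos = c(5L, 9L), ref = "A", alt = "T",
                         gene = NA_character_, score = c(0.5, 0.5))
  expect_equal(rank_variants(tied)$id, c("y", "x"))
  expect_equal(nrow(rank_variants(svs[0, ])), 0)
})

test_that("exhaustive ranking enumerates connected k-subsets in score order", {
  svs <- tibble::tibble(id = sprintf("v%d", 1:4),
                        gene = c("A", "B", "C", "D"),
                        score = c(0.9, 0.8, 0.7, 0.6))
  complete <- interaction_network(
    data.frame(from = c("A", "A", "A", "B", "B", "C"),
               to = c("B", "C", "D", "C", "D", "D")))
  r <- rank_tuples_exhaustive(svs, complete, ranking_config(k = 2))
  expect_equal(nrow(r), 6)                      # C(4,2)
  expect_equal(r$tuple_id[1], "v1,v2")          # two highest sigma
  expect_equal(r$score[1], 1.7)

  edgeless <- interaction_network(nodes = c("A", "B", "C", "D"))
  expect_equal(nrow(rank_tuples_exhaustive(svs, edgeless,
                                           ranking_config(k = 2))), 0)

  tiny_cap <- ranking_config(k = 2, max_candidates = 3)
  expect_error(rank_tuples_exhaustive(svs, complete, tiny_cap),
               "rank_tuples_beam")
})

test_that("exhaustive triple ranking matches an independent brute force", {
  fx <- six_variant_fixture()
  got <- rank_tuples_exhaustive(fx$svs, fx$net, ranking_config(k = 3))
  want <- oracle_rank_tuples(fx$svs, fx$net, k = 3)
  expect_equal(got$tuple_id, want$tuple_id)
  expect_equal(got$score, want$score)
})

test_that("saturating beam equals the exhaustive oracle on the 6-variant fixture", {
  fx <- six_variant_fixture()
  for (k in 1:3) {
    cfg_b <- ranking_config(k = k, beam_width = 6^3)
    cfg_e <- ranking_config(k = k)
    b <- rank_tuples_beam(fx$svs, fx$net, cfg_b)
    e <- rank_tuples_exhaustive(fx$svs, fx$net, cfg_e)
    expect_identical(b$tuple_id, e$tuple_id, info = paste("k =", k))
    expect_identical(b$score, e$score, info = paste("k =", k))
  }
})

test_that("beam width 1 dies on a greedy dead end", {
  # highest-scoring variant sits in an isolated gene
  svs <- tibble::tibble(id = c("top", "v2", "v3"),
                        gene = c("ISO", "A", "B"),
                        score = c(0.99, 0.5, 0.4))
  net <- interaction_network(data.frame(from = "A", to = "B"),
                             nodes = c("A", "B", "ISO"))
  narrow <- rank_tuples_beam(svs, net, ranking_config(k = 2, beam_width = 1))
  expect_equal(nrow(narrow), 0)
  wide <- rank_tuples_beam(svs, net, ranking_config(k = 2, beam_width = 10))
  expect_equal(wide$tuple_id, "v2,v3")
})

test_that("k = 1 beam reduces to single-variant ranking on in-network genes", {
  fx <- six_variant_fixture()
  b <- rank_tuples_beam(fx$svs, fx$net, ranking_config(k = 1))
  in_net <- fx$svs[fx$svs$gene %in% fx$net$nodes & fx$svs$score > 0, ]
  r <- rank_variants(in_net)
  expect_equal(unlist(b$variant_ids), r$id)
  expect_equal(b$score, r$score)
})

test_that("compound-heterozygote tuples require both the flag and self-loops", {
  svs <- tibble::tibble(id = c("a1", "a2", "b"),
                        gene = c("A", "A", "B"),
                        score = c(0.9, 0.8, 0.7))
  net <- interaction_network(data.frame(from = "A", to = "B"))
  cfg_ch <- ranking_config(k = 3, allow_compound_het = TRUE)

  # flag without self-loops: the triple stays disconnected (score 0)
  expect_equal(nrow(rank_tuples_exhaustive(svs, net, cfg_ch)), 0)
  expect_equal(nrow(rank_tuples_beam(svs, net, cfg_ch)), 0)

  looped <- add_self_loops(net)
  e <- rank_tuples_exhaustive(svs, looped, cfg_ch)
  b <- rank_tuples_beam(svs, looped, cfg_ch)
  expect_equal(e$tuple_id, "a1,a2,b")
  expect_equal(e$score, 2.4)
  expect_identical(b$tuple_id, e$tuple_id)

  # self-loops without the flag: same-gene tuples are not generated
  cfg_plain <- ranking_config(k = 3, allow_compound_het = FALSE)
  expect_equal(nrow(rank_tuples_exhaustive(svs, looped, cfg_plain)), 0)
  expect_equal(nrow(rank_tuples_beam(svs, looped, cfg_plain)), 0)
})

test_that("beam and exhaustive agree on random instances with saturating width", {
  for (seed in 1:40) {
    inst <- random_instance(seed, self_loops = seed %% 3 == 0)
    k <- 2 + seed %% 2
    cfg <- ranking_config(k = k, beam_width = choose(inst$n, k) + 1,
                          allow_compound_het = inst$net$self_loops)
    e <- rank_tuples_exhaustive(inst$svs, inst$net, cfg)
    b <- rank_tuples_beam(inst$svs, inst$net, cfg)
    expect_identical(b$tuple_id, e$tuple_id, info = paste("seed", seed))
    expect_identical(b$score, e$score, info = paste("seed", seed))
    # additivity and connectivity of everything returned
    if (nrow(e)) {
      sums <- vapply(e$variant_ids, function(ids) {
        sum(inst$svs$score[match(ids, inst$svs$id)])
      }, numeric(1))
      expect_true(all(abs(e$score - sums) <= 1e-12))
      expect_true(all(vapply(e$genes, oracle_connected, logical(1),
                             net = inst$net)))
    }
  }
})

test_that("ranking is deterministic across repeated runs", {
  inst <- random_instance(99)
  cfg <- ranking_config(k = 2, beam_width = 50)
  a <- rank_tuples_beam(inst$svs, inst$net, cfg)
  b <- rank_tuples_beam(inst$svs, inst$net, cfg)
  expect_identical(a, b)
})
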