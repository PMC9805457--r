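test_that("the same seed reproduces a world exactly, including serialized form", {
  s <- small_world_spec(seed = 99)
  w1 <- make_world(s)
  w2 <- make_world(s)
  expect_equal(w1, w2)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_world(w1, d1)
  p2 <- write_world(w2, d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]), info = nm)
  }
})

test_that("worlds survive a round trip through their own file formats", {
  w <- make_world(small_world_spec(seed = 15))
  dir <- withr::local_tempdir()
  paths <- write_world(w, dir)
  expect_equal(read_gmt(paths[["gmt_bp"]], category = "BP"), w$collections$BP)
  expect_equal(read_differential_table(paths[["mrna_table"]]), w$mrna_table,
               tolerance = 1e-9)
  expect_equal(read_target_map(paths[["target_map"]]), w$target_map)
  expect_equal(read_edge_list(paths[["edges"]])$edges, w$network$edges)
  expect_equal(read_expression_matrix(paths[["expr"]]), round(w$expr, 10),
               tolerance = 1e-9)
})

test_that("deg_fraction = 1 makes every gene differential", {
  w <- make_world(small_world_spec(seed = 2, deg_fraction = 1))
  expect_equal(screen_degs(w$mrna_table)$genes, sort(w$genes))
})

test_that("planted genes really pass and background genes really fail the screen", {
  w <- make_world(small_world_spec(seed = 6))
  degs <- screen_degs(w$mrna_table)
  expect_setequal(degs$genes, w$deg_ids)
})

test_that("infeasible specs are rejected up front", {
  expect_error(world_spec(n_genes = 10, pathway_size_range = c(2, 5),
                          signal_block_size = 5, target_set_size = 50),
               "target_set_size")
  expect_error(world_spec(n_genes = 10, pathway_size_range = c(5, 50)),
               "pathway sizes")
  expect_error(world_spec(n_ncrnas = 2, n_planted = 5), "planted")
  expect_error(world_spec(seed = 2^31), "seed")
})

test_that("planted enrichment is recovered and the planted ncRNA dominates", {
  w <- make_world(world_spec(seed = 77))
  fit <- suppressWarnings(score_world(w))
  e <- attr(fit, "enrichments")
  for (cat in names(e)) {
    expect_true(all(w$enriched_pathway_ids[[cat]] %in%
                      e[[cat]]$pathways$pathway_id), info = cat)
  }
  expect_equal(fit$report$ncrna_id[1], w$planted_ncrnas[1])
})

test_that("a zero-coverage planted ncRNA is indistinguishable from decoys", {
  # with planted_coverage = 0 the planted draw is uniform like every decoy
  ranks <- vapply(1:30, function(s) {
    w <- make_world(small_world_spec(seed = 500 + s, planted_coverage = 0))
    fit <- suppressWarnings(score_world(w))
    which(rank_by(w$ncrna_table, fit, "c_value")$ids == w$planted_ncrnas[1])
  }, integer(1))
  # ranks should spread over 1..10 rather than concentrate at 1
  expect_gt(mean(ranks), 2.5)
  expect_gt(length(unique(ranks)), 3)
})

test_that("the expression matrix embeds near-0.98 lnc-target correlations", {
  w <- make_world(small_world_spec(seed = 12))
  id <- w$planted_ncrnas[1]
  rs <- vapply(w$target_map[[id]], function(g) {
    cor(w$expr[id, ], w$expr[g, ])
  }, numeric(1))
  expect_gt(median(rs), 0.9)
})

test_that("the PPI network covers the differential genes with a hub structure", {
  w <- make_world(small_world_spec(seed = 18))
  expect_setequal(w$network$nodes, w$deg_ids)
  part <- degree_partition(w$network)
  deg <- part$degree
  # preferential attachment yields a heavy upper tail
  expect_gt(max(deg), 3 * stats::median(deg))
})

test_that("key lists return planted ids, padded by best-covered decoys", {
  w <- make_world(small_world_spec(seed = 9, n_planted = 2))
  expect_equal(make_key_list(w, 2), w$planted_ncrnas)
  expect_equal(make_key_list(w, 1), w$planted_ncrnas[1])
  k4 <- make_key_list(w, 4)
  expect_equal(k4[1:2], w$planted_ncrnas)
  expect_equal(length(k4), 4L)
  expect_true(all(k4[3:4] %in% setdiff(w$ncrna_ids, w$planted_ncrnas)))
  expect_error(make_key_list(w, 0), "k must be")
  expect_error(make_key_list(w, 99), "exceeds")
})

test_that("enrichment recovery and false-admission behave across replicates", {
  # reduced-replicate sanity check of the planted-enrichment design
  reps <- 30
  recovered <- 0; trials <- 0; false_pos <- 0
  for (s in seq_len(reps)) {
    w <- make_world(world_spec(seed = 60000 + s))
    degs <- screen_degs(w$mrna_table)
    for (cat in c("BP", "KEGG")) {
      e <- suppressWarnings(enrich(degs, w$collections[[cat]]))
      trials <- trials + 1
      recovered <- recovered +
        all(w$enriched_pathway_ids[[cat]] %in% e$pathways$pathway_id)
      false_pos <- false_pos +
        sum(!e$pathways$pathway_id %in% w$enriched_pathway_ids[[cat]])
    }
  }
  expect_gte(recovered / trials, 0.9)
  expect_lte(false_pos / trials, 0.05 * 20)
})
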