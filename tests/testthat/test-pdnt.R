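test_that("pathway proportions are the triple-intersection ratio", {
  fx <- tiny_enrichment()
  pw <- fx$enrichment$pathways[1, ]
  # pathway G01..G05, all differential; targets hit 2 of them
  expect_equal(pathway_proportion(c("G01", "G02", "G18"), fx$degs, pw), 2 / 5)
  expect_equal(pathway_proportion(c("G18", "G19"), fx$degs, pw), 0)
  expect_equal(pathway_proportion(sprintf("G%02d", 1:5), fx$degs, pw), 1.0)
  expect_equal(pathway_proportion(sprintf("G%02d", 1:5), fx$degs, pw,
                                  denominator_mode = "deg_overlap"), 1.0)
})

# hand-buildable enrichment result with chosen p-values
fake_enrichment <- function(ids, gene_sets, p, overlap_sets, category = "BP") {
  pw <- data.frame(pathway_id = ids, category = rep(category, length(ids)),
                   n_universe = lengths(gene_sets),
                   overlap = lengths(overlap_sets), p_value = p,
                   adj_p_value = pmin(1, p * length(p)),
                   stringsAsFactors = FALSE)
  pw$genes <- gene_sets
  pw$overlap_genes <- overlap_sets
  structure(list(category = category, universe = unique(unlist(gene_sets)),
                 alpha = 0.05, n_tested = length(ids), pathways = pw),
            class = "enrichment_result")
}

test_that("category C values follow the proportion-weighted -log10 sum", {
  degs <- structure(list(genes = c("G1", "G2", "G3", "G4"), p_threshold = 0.05,
                         lfc_threshold = 1), class = "deg_set")
  # one pathway, p = 0.01, proportion 0.5 -> 0.5 * 2 = 1.0
  e1 <- fake_enrichment("PW1", list(c("G1", "G9")), 0.01, list("G1"))
  expect_equal(category_c_value("G1", degs, e1)$value, 1.0)

  # (prop 0.3, p 0.1) + (prop 0.5, p 0.01) -> 0.3*1 + 0.5*2 = 1.3
  e2 <- fake_enrichment(
    c("PA", "PB"),
    list(sprintf("G%d", 1:10), c("G1", "G2", "G5", "G9")),
    c(0.1, 0.01),
    list(sprintf("G%d", 1:4), c("G1", "G2")))
  v <- category_c_value(c("G1", "G2", "G3"), degs, e2)
  expect_equal(v$value, 0.3 * 1 + 0.5 * 2, tolerance = 1e-12)
  expect_equal(v$terms$contribution, v$terms$proportion * v$terms$weight)

  # no targets among DEGs -> 0
  expect_equal(category_c_value("G9", degs, e2)$value, 0)
  # empty enrichment -> 0
  e0 <- fake_enrichment(character(), list(), numeric(), list())
  expect_equal(category_c_value("G1", degs, e0)$value, 0)
})

test_that("adjusted-p weighting and the deg_overlap denominator are honoured", {
  degs <- structure(list(genes = c("G1", "G2"), p_threshold = 0.05,
                         lfc_threshold = 1), class = "deg_set")
  e <- fake_enrichment("PW", list(c("G1", "G2", "G3", "G4")), 0.001,
                       list(c("G1", "G2")))
  raw <- category_c_value("G1", degs, e)$value
  expect_equal(raw, (1 / 4) * 3)
  adj <- category_c_value("G1", degs, e, weight_p = "adjusted")$value
  expect_equal(adj, (1 / 4) * -log10(0.001 * 1))
  ov <- category_c_value("G1", degs, e,
                         denominator_mode = "deg_overlap")$value
  expect_equal(ov, (1 / 2) * 3)
})

test_that("category values equal a brute-force recomputation on random small worlds", {
  set.seed(31)
  for (i in 1:30) {
    n_genes <- sample(10:30, 1)
    genes <- sprintf("G%02d", seq_len(n_genes))
    n_pw <- sample(1:5, 1)
    sets <- lapply(seq_len(n_pw), function(j) sample(genes, sample(3:8, 1)))
    ids <- sprintf("PW%d", seq_len(n_pw))
    p <- runif(n_pw, 1e-6, 0.05)
    deg_genes <- sample(genes, sample(3:n_genes, 1))
    ov <- lapply(sets, intersect, deg_genes)
    degs <- structure(list(genes = deg_genes, p_threshold = 0.05,
                           lfc_threshold = 1), class = "deg_set")
    e <- fake_enrichment(ids, sets, p, ov)
    targets <- sample(genes, sample(1:n_genes, 1))
    expect_equal(category_c_value(targets, degs, e)$value,
                 oracle_category_value(targets, deg_genes, sets, p),
                 tolerance = 1e-12)
    expect_equal(category_c_value(targets, degs, e,
                                  denominator_mode = "deg_overlap")$value,
                 oracle_category_value(targets, deg_genes, sets, p,
                                       denominator = "deg_overlap",
                                       overlap_sets = ov),
                 tolerance = 1e-12)
  }
})

test_that("the fit sums the four category values and orders by total", {
  w <- make_world(small_world_spec(seed = 21, n_planted = 2))
  fit <- suppressWarnings(score_world(w))
  r <- fit$report
  expect_equal(nrow(r), nrow(w$ncrna_table))
  expect_equal(r$c_value, r$kegg_value + r$bp_value + r$cc_value + r$mf_value)
  expect_true(all(diff(r$c_value) <= 0))
  expect_equal(sort(r$ncrna_id), sort(w$ncrna_table$feature_id))
  # category value bounded by the total available -log10 weight
  e <- attr(fit, "enrichments")
  expect_true(all(r$bp_value <=
                    sum(-log10(pmax(e$BP$pathways$p_value, 1e-300))) + 1e-9))
})

test_that("ncRNAs with no or useless targets score exactly zero", {
  fx <- tiny_enrichment()
  tm <- target_map(data.frame(ncrna_id = c("M1", "M2"),
                              gene_id = c("G18", "G01")),
                   ncrna_ids = c("M1", "M2", "M3"))
  nc <- diff_table(c("M1", "M2", "M3", "M4"), c(2, 2, 2, 2),
                   c(0.01, 0.01, 0.01, 0.01))
  warnings_seen <- character()
  fit <- withCallingHandlers(
    pdnt(tm, fx$degs, list(KEGG = fx$enrichment), nc),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_match(warnings_seen, "absent from the target map", all = FALSE)
  expect_match(warnings_seen, "missing enrichment categor", all = FALSE)
  r <- fit$report
  expect_equal(r$c_value[r$ncrna_id == "M1"], 0)   # target outside pathway
  expect_equal(r$c_value[r$ncrna_id == "M3"], 0)   # empty target set
  expect_equal(r$c_value[r$ncrna_id == "M4"], 0)   # absent from map
  expect_gt(r$c_value[r$ncrna_id == "M2"], 0)
})

test_that("growing a target set never decreases any component", {
  w <- make_world(small_world_spec(seed = 8))
  fit <- suppressWarnings(score_world(w))
  degs <- attr(fit, "degs")
  enr <- attr(fit, "enrichments")
  id <- w$ncrna_ids[2]
  base_targets <- w$target_map[[id]]
  extra <- setdiff(w$genes, base_targets)
  for (i in 1:5) {
    grown <- c(base_targets, sample(extra, i * 10))
    for (cat in names(enr)) {
      expect_gte(category_c_value(grown, degs, enr[[cat]])$value,
                 category_c_value(base_targets, degs, enr[[cat]])$value)
    }
  }
})

test_that("top_n applies the descending-total, ascending-id order", {
  rep <- data.frame(ncrna_id = c("b", "a", "c"), c_value = c(5, 5, 1))
  rep <- rep[order(-rep$c_value, rep$ncrna_id), ]
  fit <- structure(list(report = rep), class = "pdnt")
  expect_equal(top_n(fit, 1), "a")       # tie broken lexicographically
  expect_equal(top_n(fit, 2), c("a", "b"))
  expect_equal(top_n(fit, 10), c("a", "b", "c"))
  expect_error(top_n(fit, 0))
})

test_that("pdnt methods print, summarise, extract and plot", {
  w <- make_world(small_world_spec(seed = 4))
  fit <- suppressWarnings(score_world(w))
  expect_output(print(fit), "Participation-degree")
  expect_output(print(summary(fit)), "C values for")
  cv <- coef(fit)
  expect_named(cv)
  expect_equal(unname(cv), fit$report$c_value)
  pdf(NULL)
  expect_silent(plot(fit, n = 5))
  dev.off()
})

test_that("the C-value table writes 4-decimal rows in table column order", {
  w <- make_world(small_world_spec(seed = 4))
  fit <- suppressWarnings(score_world(w))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_c_value_table(fit, path)
  lines <- readLines(path)
  expect_equal(lines[1],
               "ncrna_id\tkegg_value\tbp_value\tcc_value\tmf_value\tc_value")
  expect_match(lines[2], "^NCR\\d+\t(\\d+\\.\\d{4}\t){4}\\d+\\.\\d{4}$")
})
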