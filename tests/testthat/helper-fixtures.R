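# Shared fixtures and independent oracles.

# Exhaustive hypergeometric upper tail: direct summation of the pmf written
# as binomial-coefficient ratios, independent of stats::phyper.
oracle_upper_tail <- function(N, K, n, k) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Brute-force C value for one category: element-by-element recomputation of
# every triple intersection, avoiding the package's set helpers.
oracle_category_value <- function(targets, deg_genes, pathway_sets, p_values,
                                  denominator = "pathway_universe",
                                  overlap_sets = NULL) {
  total <- 0
  for (k in seq_along(pathway_sets)) {
    genes <- pathway_sets[[k]]
    hits <- 0
    for (g in genes) {
      in_t <- any(targets == g)
      in_d <- any(deg_genes == g)
      if (in_t && in_d) hits <- hits + 1
    }
    den <- if (denominator == "pathway_universe") {
      length(genes)
    } else {
      length(overlap_sets[[k]])
    }
    total <- total + (hits / den) * (-log10(max(p_values[k], 1e-300)))
  }
  total
}

# Tiny deterministic enrichment scenario: 20-gene universe, one 5-gene
# pathway entirely differential among 10 DEGs.
tiny_enrichment <- function() {
  genes <- sprintf("G%02d", 1:20)
  coll <- gene_set_collection(list(PW1 = genes[1:5]), category = "KEGG")
  dt <- diff_table(genes, rep(2, 20), c(rep(0.01, 10), rep(0.5, 10)))
  degs <- screen_degs(dt)
  enr <- suppressWarnings(enrich(degs, coll, universe = genes))
  list(genes = genes, collection = coll, table = dt, degs = degs,
       enrichment = enr)
}

# Printed report tables used as reference values.
# Top-row C-value components (KEGG, BP, CC, MF -> total):
published_c_rows <- data.frame(
  id = c("mmu-miR-1943-5p", "mmu-miR-497a-5p", "mmu-miR-340-5p", "CYTOR"),
  kegg = c(33.2298, 30.7342, 43.5208, 0.5408),
  bp = c(816.2096, 748.7866, 1010.0391, 27.4816),
  cc = c(57.7971, 69.7075, 99.4072, 1.6461),
  mf = c(86.4830, 79.4659, 95.1248, 3.5501),
  total = c(993.7195, 928.6942, 1248.0919, 33.2186),
  stringsAsFactors = FALSE)

# Core/sub-core/noncore region ratios per dataset and ranking group, and the
# published 2-dp core-region increase rates they imply.
published_region_ratios <- data.frame(
  dataset = c("skeletal_muscle_denervation_mirna", "prostate_cancer",
              "alzheimers_disease", "gastric_cancer",
              "skeletal_muscle_denervation_lncrna",
              "adipocyte_differentiation"),
  fc_core = c(0.1752, 0.6607, 0.2274, 0.2166, 0.0990, 0.2727),
  p_core = c(0.1805, 0.5152, 0.2225, 0.2125, 0.0946, 0.3000),
  c_core = c(0.2020, 0.7045, 0.2460, 0.2391, 0.1915, 0.4800),
  rate_vs_fc = c(0.15, 0.07, 0.08, 0.10, 0.93, 0.76),
  rate_vs_p = c(0.12, 0.37, 0.11, 0.13, 1.02, 0.60),
  stringsAsFactors = FALSE)

# Per-dataset pathway-efficiency increase rates and their printed averages.
published_efficiency <- list(
  mirna_vs_fc = list(rates = c(0.29, 0.40, 0.53, 1.20), average = 0.61),
  mirna_vs_p = list(rates = c(0.30, 0.50, 1.91, 3.09), average = 1.45),
  lncrna_vs_fc = list(rates = c(0.07, 0.71), average = 0.39))

# Published PPI core-ratio increase-rate averages.
published_ppi_averages <- list(
  mirna_vs_fc = list(rates = c(0.15, 0.07, 0.08, 0.10), average = 0.10),
  mirna_vs_p = list(rates = c(0.12, 0.37, 0.11, 0.13), average = 0.18),
  lncrna_vs_fc = list(rates = c(0.93, 0.76), average = 0.85),
  lncrna_vs_p = list(rates = c(1.02, 0.60), average = 0.81))

# Small synthetic world reused across tests (kept light for speed).
small_world_spec <- function(seed = 7, n_samples = 6, ...) {
  world_spec(n_genes = 200, n_pathways = 6, pathway_size_range = c(15, 25),
             signal_block_size = 40, n_ncrnas = 10, target_set_size = 20,
             n_samples = n_samples, seed = seed, ...)
}
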