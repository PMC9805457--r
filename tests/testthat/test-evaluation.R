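test_that("rankings sort by the chosen index with lexicographic tie-breaks", {
  nc <- diff_table(c("a", "b", "c"), c(-3, 2, 2), c(0.01, 0.001, 0.05))
  rk_p <- rank_by(nc, index = "p_value")
  expect_equal(rk_p$ids, c("B", "A", "C"))
  rk_fc <- rank_by(nc, index = "abs_log2fc")
  expect_equal(rk_fc$ids, c("A", "B", "C"))   # |-3| first, tie B/C by id
  rep <- data.frame(ncrna_id = c("A", "B", "C"), c_value = c(1, 1, 5))
  rk_c <- rank_by(nc, rep, index = "c_value")
  expect_equal(rk_c$ids, c("C", "A", "B"))
  expect_equal(unname(rk_c$rank[c("C", "A", "B")]), 1:3)
})

test_that("rank sums add 1-based positions and skip absent keys with a warning", {
  nc <- diff_table(sprintf("N%d", 1:5), 5:1, seq(0.01, 0.05, by = 0.01))
  rk <- rank_by(nc, index = "abs_log2fc")   # N1 best ... N5 worst
  expect_equal(rank_sum(rk, c("N1", "N3")), 4)
  expect_equal(rank_sum(rk, sprintf("N%d", 1:5)), 5 * 6 / 2)
  # the all-keys sum is index-invariant
  expect_equal(rank_sum(rank_by(nc, index = "p_value"), sprintf("N%d", 1:5)),
               5 * 6 / 2)
  expect_warning(s <- rank_sum(rk, c("N1", "NX")), "absent")
  expect_equal(s, 1)
  expect_error(rank_sum(rk, character()), "empty key set")
})

test_that("rank shifts count keys moving up, down or staying", {
  nc <- diff_table(sprintf("N%d", 1:8), 8:1, rep(0.01, 8))
  ref <- rank_by(nc, index = "abs_log2fc")
  expect_equal(unname(rank_shift_counts(ref, ref, c("N1", "N5"))), c(0, 0, 2))
  cmp <- rank_by(nc, index = "p_value")     # all ties -> id order = N1..N8
  # N1: rank 1 in both; N8: rank 8 both; reversed lfc makes e.g. N2 rank 2 both
  expect_equal(unname(rank_shift_counts(ref, cmp, c("N1", "N2"))), c(0, 0, 2))
  rep <- data.frame(ncrna_id = sprintf("N%d", 1:8),
                    c_value = c(0, 8, 7, 6, 5, 4, 3, 2))
  ref2 <- rank_by(nc, rep, index = "c_value")  # N1 drops to last
  sh <- rank_shift_counts(ref2, cmp, c("N1", "N2"))
  expect_equal(unname(sh), c(1, 1, 0))         # N2 up, N1 down
})

test_that("degree partition reproduces hand-computed star and cycle cases", {
  # 10-node star: center degree 9, leaves degree 1
  center <- "C0"
  leaves <- sprintf("L%d", 1:9)
  star <- ppi_network(rep(center, 9), leaves)
  part <- degree_partition(star)
  expect_equal(unname(part$boundaries), c(2, 5))
  core <- names(part$region_of)[part$region_of == "core"]
  expect_equal(sort(core), c("C0", "L1"))   # tie among leaves -> lowest id
  expect_equal(sum(part$region_of == "sub_core"), 3L)
  expect_equal(sum(part$region_of == "noncore"), 5L)

  # 5-node cycle, all degree 2: ceil(0.2*5) = 1 core, lowest id
  cyc <- ppi_network(sprintf("V%d", 1:5), sprintf("V%d", c(2:5, 1)))
  p5 <- degree_partition(cyc)
  expect_equal(names(p5$region_of)[p5$region_of == "core"], "V1")

  # single isolated node is the core
  one <- ppi_network(character(), character(), nodes = "A")
  expect_equal(unname(degree_partition(one)$region_of["A"]), "core")

  expect_error(degree_partition(ppi_network(character(), character())),
               "empty network")
  expect_error(degree_partition(one, core_fraction = 0.6,
                                subcore_fraction = 0.5), "core_fraction")
})

test_that("partition sizes equal ceil(0.2N) and ceil(0.5N) for N up to 1000", {
  sizes_ok <- TRUE
  for (N in 1:1000) {
    ids <- sprintf("N%04d", seq_len(N))
    net <- if (N > 1) {
      ppi_network(ids[-N], ids[-1], nodes = ids)   # path graph
    } else {
      ppi_network(character(), character(), nodes = ids)
    }
    part <- degree_partition(net)
    n_core <- sum(part$region_of == "core")
    n_sub <- sum(part$region_of == "sub_core")
    if (n_core != ceiling(0.2 * N) || n_core + n_sub != ceiling(0.5 * N)) {
      sizes_ok <- FALSE
      break
    }
  }
  expect_true(sizes_ok)
})

test_that("region ratios normalize to 1 and handle edge groups", {
  ids <- sprintf("N%02d", 1:10)
  net <- ppi_network(ids[-10], ids[-1], nodes = ids)
  part <- degree_partition(net)
  core_ids <- names(part$region_of)[part$region_of == "core"]
  expect_equal(unname(group_region_ratios(core_ids, part)), c(1, 0, 0))
  set.seed(5)
  for (i in 1:10) {
    g <- sample(ids, sample(1:10, 1))
    expect_equal(sum(group_region_ratios(g, part)), 1)
  }
  expect_warning(r <- group_region_ratios(c(core_ids, "ZZ"), part), "dropped")
  expect_equal(unname(r), c(1, 0, 0))
  expect_error(suppressWarnings(group_region_ratios("ZZ", part)), "undefined")
})

test_that("increase rates reproduce every published region-ratio cell at 2 dp", {
  tab <- published_region_ratios
  for (i in seq_len(nrow(tab))) {
    expect_equal(round_half_away(increase_rate(tab$c_core[i], tab$fc_core[i])),
                 tab$rate_vs_fc[i], info = tab$dataset[i])
    expect_equal(round_half_away(increase_rate(tab$c_core[i], tab$p_core[i])),
                 tab$rate_vs_p[i], info = tab$dataset[i])
  }
  expect_equal(increase_rate(0.4, 0.4), 0)
  expect_error(increase_rate(0.2, 0), "undefined")
})

test_that("mean increase rates reproduce the published averages at 2 dp", {
  for (nm in names(published_efficiency)) {
    e <- published_efficiency[[nm]]
    expect_equal(round_half_away(mean_increase_rate(e$rates)), e$average,
                 info = nm)
  }
  for (nm in names(published_ppi_averages)) {
    e <- published_ppi_averages[[nm]]
    expect_equal(round_half_away(mean_increase_rate(e$rates)), e$average,
                 info = nm)
  }
  expect_equal(mean_increase_rate(0.37), 0.37)
  expect_error(mean_increase_rate(numeric()), "empty")
})

test_that("decimal presentation rounding is half away from zero", {
  expect_equal(round_half_away(0.605), 0.61)
  expect_equal(round_half_away(0.845), 0.85)
  expect_equal(round_half_away(-0.605), -0.61)
  expect_equal(round_half_away(0.604999), 0.60)
  expect_equal(round_half_away(1.005), 1.01)
  expect_equal(round_half_away(0.12345, digits = 4), 0.1235)
})

test_that("group pathway proportions pool targets as a set union", {
  degs <- structure(list(genes = sprintf("G%d", 1:6), p_threshold = 0.05,
                         lfc_threshold = 1), class = "deg_set")
  tm <- target_map(data.frame(
    ncrna_id = c("M1", "M1", "M2", "M2"),
    gene_id = c("G1", "G2", "G2", "G9")))
  pw <- list(PWA = sprintf("G%d", 1:10))
  # union {G1,G2,G9}; intersect DEGs {G1..G6} and pathway -> {G1,G2} of 10
  expect_equal(unname(group_pathway_proportions(c("M1", "M2"), tm, degs, pw)),
               0.2)
  expect_equal(unname(group_pathway_proportions("M2", tm, degs,
                                                list(P = c("G7", "G8")))), 0)
  full <- group_pathway_proportions(c("M1", "M2"), tm, degs,
                                    list(P = c("G1", "G2")))
  expect_equal(unname(full), 1.0)
})

test_that("aggregate efficiency rates use the ratio of summed proportions", {
  pc <- c(0.4, 0.2); po <- c(0.2, 0.1)
  expect_equal(proportion_increase_rate(pc, po), (0.6 - 0.3) / 0.3)
  expect_equal(proportion_increase_rate(pc, po, aggregate = "mean"),
               (0.3 - 0.15) / 0.15)
})
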