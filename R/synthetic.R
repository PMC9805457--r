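#' Specification of a synthetic study world
#'
#' Describes a self-contained synthetic data set with the structure the
#' pipeline consumes: a gene universe, four overlapping pathway collections
#' (BP, CC, MF, KEGG), a differential-expression table with planted
#' significant genes concentrated in a signal block, ncRNAs whose target sets
#' cover the signal to a controllable degree, a co-expression matrix with
#' embedded lncRNA-target correlations, and a scale-free-like PPI network
#' over the differential genes.
#'
#' Differential status is a two-component mixture: genes of the planted
#' (enriched) pathways' signal block are differential with
#' \code{de_prob_fold} times the base \code{deg_fraction} probability
#' (capped at 1), so those pathways are genuinely over-represented.
#'
#' @param n_genes Gene-universe size (default 600).
#' @param n_pathways Pathways per category (default 20).
#' @param pathway_size_range Inclusive (min, max) pathway sizes (default
#'   c(35, 60)).
#' @param deg_fraction Base probability that a background gene is
#'   differential (default 0.1).
#' @param n_ncrnas Number of ncRNAs, planted plus decoys (default 21).
#' @param target_set_size Targets per ncRNA (default 40).
#' @param n_planted Number of planted high-participation ncRNAs (default 1);
#'   alternatively give \code{planted_ids} explicitly.
#' @param planted_ids Optional explicit planted ncRNA ids (overrides
#'   \code{n_planted}).
#' @param planted_coverage Fraction of a planted ncRNA's targets drawn from
#'   differential signal-block genes (default 0.6); decoys draw uniformly.
#' @param n_samples Expression-matrix samples (default 10).
#' @param ppi_edges_per_node Preferential-attachment edges added per node
#'   (default 2).
#' @param n_enriched_pathways Planted over-represented pathways per category
#'   (default 3).
#' @param de_prob_fold Differential-probability fold for signal genes
#'   (default 5).
#' @param signal_block_size Genes in the shared signal block the planted
#'   pathways concentrate on (default 80); planted pathways are drawn as
#'   heavily overlapping subsets of it, like nested ontology terms.
#' @param signal_purity Fraction of a planted pathway's members drawn from
#'   the signal block (default 1).
#' @param seed Integer root seed; all sub-generators derive from it by fixed
#'   offsets, so adding an output does not perturb existing ones.
#' @return Object of class \code{"world_spec"} (a validated list).
#' @export
world_spec <- function(n_genes = 600, n_pathways = 20,
                       pathway_size_range = c(35, 60), deg_fraction = 0.1,
                       n_ncrnas = 21, target_set_size = 40, n_planted = 1,
                       planted_ids = NULL, planted_coverage = 0.6,
                       n_samples = 10, ppi_edges_per_node = 2,
                       n_enriched_pathways = 3, de_prob_fold = 5,
                       signal_block_size = 80, signal_purity = 1,
                       seed = 1) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed) ||
      seed < 0 || seed > .Machine$integer.max - 100) {
    stop("seed must be a non-negative integer below 2^31 - 100", call. = FALSE)
  }
  spec <- list(n_genes = as.integer(n_genes), n_pathways = as.integer(n_pathways),
               pathway_size_range = as.integer(pathway_size_range),
               deg_fraction = deg_fraction, n_ncrnas = as.integer(n_ncrnas),
               target_set_size = as.integer(target_set_size),
               n_planted = as.integer(n_planted), planted_ids = planted_ids,
               planted_coverage = planted_coverage,
               n_samples = as.integer(n_samples),
               ppi_edges_per_node = as.integer(ppi_edges_per_node),
               n_enriched_pathways = as.integer(n_enriched_pathways),
               de_prob_fold = de_prob_fold,
               signal_block_size = as.integer(signal_block_size),
               signal_purity = signal_purity, seed = as.integer(seed))
  with(spec, {
    stopifnot(n_genes > 0, n_pathways > 0, n_ncrnas > 0, target_set_size > 0,
              n_samples >= 3, ppi_edges_per_node > 0,
              length(pathway_size_range) == 2,
              pathway_size_range[1] >= 1,
              pathway_size_range[1] <= pathway_size_range[2],
              deg_fraction > 0, deg_fraction <= 1,
              planted_coverage >= 0, planted_coverage <= 1,
              n_enriched_pathways >= 0, n_enriched_pathways <= n_pathways,
              de_prob_fold >= 1, signal_purity >= 0, signal_purity <= 1)
    if (pathway_size_range[2] > n_genes) {
      stop("infeasible spec: pathway sizes exceed the gene universe",
           call. = FALSE)
    }
    if (target_set_size > n_genes) {
      stop("infeasible spec: target_set_size exceeds the gene universe",
           call. = FALSE)
    }
    if (signal_block_size > n_genes) {
      stop("infeasible spec: signal block exceeds the gene universe",
           call. = FALSE)
    }
    if (seed < 0 || seed > .Machine$integer.max - 100L) {
      stop("seed must be a non-negative integer below 2^31 - 100",
           call. = FALSE)
    }
  })
  if (!is.null(spec$planted_ids)) {
    spec$planted_ids <- normalize_ids(spec$planted_ids, "ncRNA id")
    spec$n_planted <- length(spec$planted_ids)
  }
  if (spec$n_planted > spec$n_ncrnas) {
    stop("infeasible spec: more planted ncRNAs than ncRNAs", call. = FALSE)
  }
  class(spec) <- "world_spec"
  spec
}

# fixed seed offsets per sub-generator
.SEED_OFFSETS <- c(pathways = 1L, degs = 2L, mrna = 3L, ncrna = 4L,
                   targets = 5L, expr = 6L, ppi = 7L)

with_subseed <- function(spec, component, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(spec$seed + .SEED_OFFSETS[[component]])
  expr
}

#' Generate a full synthetic study world
#'
#' All outputs are a pure function of the spec (including its seed): the same
#' spec yields identical objects, and serialized artifacts are
#' byte-identical across runs.
#'
#' @param spec A \code{world_spec}.
#' @return Object of class \code{"pdnt_world"}: list with \code{spec},
#'   \code{collections} (named list of \code{gene_set_collection}s for BP,
#'   CC, MF, KEGG), \code{mrna_table} and \code{ncrna_table}
#'   (\code{diff_table}s), \code{target_map}, \code{expr} (matrix with ncRNA
#'   and gene rows), \code{network} (\code{ppi_network} over the differential
#'   genes), \code{genes}, \code{ncrna_ids}, \code{planted_ncrnas},
#'   \code{signal_genes}, \code{deg_ids} (the genes planted as differential)
#'   and \code{enriched_pathway_ids} (per category).
#' @export
make_world <- function(spec) {
  stopifnot(inherits(spec, "world_spec"))
  width_g <- max(4L, nchar(as.character(spec$n_genes)))
  genes <- sprintf("G%0*d", width_g, seq_len(spec$n_genes))
  signal <- genes[seq_len(spec$signal_block_size)]
  categories <- c("BP", "CC", "MF", "KEGG")

  # pathway collections: planted pathways concentrate on the signal block
  pw <- with_subseed(spec, "pathways", {
    out <- list()
    for (cat in categories) {
      sets <- list()
      for (j in seq_len(spec$n_pathways)) {
        size <- sample(spec$pathway_size_range[1]:spec$pathway_size_range[2], 1)
        planted <- j <= spec$n_enriched_pathways
        if (planted) {
          n_sig <- min(round(spec$signal_purity * size), length(signal))
          members <- c(sample(signal, n_sig),
                       sample(setdiff(genes, signal), size - n_sig))
        } else {
          members <- sample(genes, size)
        }
        sets[[sprintf("PW_%s_%02d", cat, j)]] <- members
      }
      out[[cat]] <- gene_set_collection(sets, category = cat)
    }
    out
  })
  enriched_ids <- lapply(categories, function(cat) {
    sprintf("PW_%s_%02d", cat, seq_len(spec$n_enriched_pathways))
  })
  names(enriched_ids) <- categories

  # two-component differential mixture over the universe
  p_sig <- min(1, spec$de_prob_fold * spec$deg_fraction)
  deg_ids <- with_subseed(spec, "degs", {
    prob <- ifelse(genes %in% signal, p_sig, spec$deg_fraction)
    genes[stats::runif(spec$n_genes) < prob]
  })

  # DE table: differential genes satisfy both screening criteria,
  # background genes always fail the p criterion
  mrna_table <- with_subseed(spec, "mrna", {
    is_deg <- genes %in% deg_ids
    p <- ifelse(is_deg, stats::runif(spec$n_genes, 1e-6, 0.05 - 1e-6),
                stats::runif(spec$n_genes, 0.05, 1))
    lfc <- ifelse(is_deg,
                  sample(c(-1, 1), spec$n_genes, replace = TRUE) *
                    stats::runif(spec$n_genes, 1, 4),
                  stats::runif(spec$n_genes, -3, 3))
    diff_table(genes, lfc, p)
  })

  width_n <- max(3L, nchar(as.character(spec$n_ncrnas)))
  ncrna_ids <- sprintf("NCR%0*d", width_n, seq_len(spec$n_ncrnas))
  planted <- if (!is.null(spec$planted_ids)) {
    spec$planted_ids
  } else {
    ncrna_ids[seq_len(spec$n_planted)]
  }
  if (!all(planted %in% ncrna_ids)) {
    stop("planted_ids must be among the generated ncRNA ids (",
         paste(utils::head(ncrna_ids, 2), collapse = ", "), ", ...)",
         call. = FALSE)
  }

  ncrna_table <- with_subseed(spec, "ncrna", {
    diff_table(ncrna_ids,
               sample(c(-1, 1), spec$n_ncrnas, replace = TRUE) *
                 stats::runif(spec$n_ncrnas, 1, 4),
               stats::runif(spec$n_ncrnas, 1e-4, 0.05 - 1e-4))
  })

  # planted ncRNAs draw planted_coverage of their targets from the
  # differential signal pool; decoys draw uniformly from the universe
  tmap <- with_subseed(spec, "targets", {
    pool <- intersect(deg_ids, signal)
    pairs <- do.call(rbind, lapply(ncrna_ids, function(id) {
      if (id %in% planted && length(pool)) {
        k <- min(round(spec$planted_coverage * spec$target_set_size),
                 length(pool))
        tg <- c(sample(pool, k),
                sample(setdiff(genes, pool), spec$target_set_size - k))
      } else {
        tg <- sample(genes, spec$target_set_size)
      }
      data.frame(ncrna_id = id, gene_id = tg, stringsAsFactors = FALSE)
    }))
    target_map(pairs, ncrna_ids = ncrna_ids)
  })

  # expression: iid standard normal profiles; planted ncRNAs' targets track
  # the ncRNA profile with noise sized for r ~ 0.98
  expr <- with_subseed(spec, "expr", {
    feats <- c(ncrna_ids, genes)
    m <- matrix(stats::rnorm(length(feats) * spec$n_samples),
                nrow = length(feats),
                dimnames = list(feats, sprintf("S%02d", seq_len(spec$n_samples))))
    noise_sd <- sqrt(1 / 0.98^2 - 1)
    for (id in planted) {
      for (tg in tmap[[id]]) {
        m[tg, ] <- m[id, ] + stats::rnorm(spec$n_samples, sd = noise_sd)
      }
    }
    m
  })

  # scale-free-like PPI over the differential genes
  network <- with_subseed(spec, "ppi", {
    n_deg <- length(deg_ids)
    if (n_deg >= 2) {
      g <- igraph::sample_pa(n_deg, m = min(spec$ppi_edges_per_node, n_deg - 1),
                             directed = FALSE)
      el <- igraph::as_edgelist(g, names = FALSE)
      perm <- sample(deg_ids)
      ppi_network(perm[el[, 1]], perm[el[, 2]])
    } else {
      ppi_network(character(), character())
    }
  })

  structure(list(spec = spec, collections = pw, mrna_table = mrna_table,
                 ncrna_table = ncrna_table, target_map = tmap, expr = expr,
                 network = network, genes = genes, ncrna_ids = ncrna_ids,
                 planted_ncrnas = planted, signal_genes = signal,
                 deg_ids = sort(deg_ids), enriched_pathway_ids = enriched_ids),
            class = "pdnt_world")
}

#' @export
print.pdnt_world <- function(x, ...) {
  cat(sprintf("Synthetic world (seed %d): %d genes (%d differential), %d ncRNAs (%d planted), 4 collections x %d pathways\n",
              x$spec$seed, length(x$genes), length(x$deg_ids),
              length(x$ncrna_ids), length(x$planted_ncrnas),
              x$spec$n_pathways))
  invisible(x)
}

#' Key-ncRNA list of a synthetic world
#'
#' Returns the planted ncRNA ids for rank-sum testing, truncated to \code{k}
#' or padded with the decoys whose target sets happen to cover the most
#' differential signal genes.
#'
#' @param world A \code{pdnt_world}.
#' @param k Number of key ids (1 <= k <= number of ncRNAs).
#' @return Character vector of ncRNA ids.
#' @export
make_key_list <- function(world, k) {
  stopifnot(inherits(world, "pdnt_world"))
  if (k < 1) stop("k must be >= 1: an empty key set is invalid downstream",
                  call. = FALSE)
  if (k > length(world$ncrna_ids)) {
    stop("k exceeds the number of ncRNAs", call. = FALSE)
  }
  planted <- world$planted_ncrnas
  if (k <= length(planted)) return(planted[seq_len(k)])
  decoys <- setdiff(world$ncrna_ids, planted)
  pool <- intersect(world$deg_ids, world$signal_genes)
  cov <- vapply(decoys, function(id) {
    length(intersect(world$target_map[[id]], pool))
  }, integer(1))
  pad <- decoys[order(-cov, decoys)][seq_len(k - length(planted))]
  c(planted, pad)
}

#' Write every artifact of a synthetic world to a directory
#'
#' Serializes the world in the plain-text formats the readers consume (GMT
#' collections, tab-separated DE tables, target pair list, expression matrix,
#' edge list), so generated fixtures double as format-conformance tests.
#'
#' @param world A \code{pdnt_world}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "pdnt_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (cat in names(world$collections)) {
    p <- file.path(dir, sprintf("pathways_%s.gmt", tolower(cat)))
    write_gmt(world$collections[[cat]], p)
    paths[sprintf("gmt_%s", tolower(cat))] <- p
  }
  write_diff <- function(tab, path) {
    lines <- c("id\tlog2fc\tp_value",
               sprintf("%s\t%.10g\t%.10g", tab$feature_id, tab$log2fc,
                       tab$p_value))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writLines_lf(lines, con)
  }
  paths["mrna_table"] <- file.path(dir, "mrna_de.tsv")
  write_diff(world$mrna_table, paths[["mrna_table"]])
  paths["ncrna_table"] <- file.path(dir, "ncrna_de.tsv")
  write_diff(world$ncrna_table, paths[["ncrna_table"]])
  paths["target_map"] <- file.path(dir, "targets.tsv")
  write_target_map(world$target_map, paths[["target_map"]])
  paths["expr"] <- file.path(dir, "expression.tsv")
  write_expression_matrix(round(world$expr, 10), paths[["expr"]])
  paths["edges"] <- file.path(dir, "ppi_edges.tsv")
  write_edge_list(world$network, paths[["edges"]])
  invisible(paths)
}
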