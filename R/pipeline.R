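config_error <- function(...) {
  stop(structure(class = c("pdnt_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Assemble a pipeline configuration
#'
#' Collects every tunable of the scoring and evaluation pipeline with the
#' conventional defaults: DEG screen p < 0.05 and |log2FC| >= 1, enrichment
#' significance at corrected p < 0.05, lncRNA co-expression targets at
#' |r| >= 0.90 with p < 0.01 and FDR < 0.01, PPI core region = top 20\% of
#' nodes by degree and sub-core up to the top 50\%.
#'
#' @param gmt Named list/vector of GMT paths; names are the category labels
#'   (conventionally BP, CC, MF, KEGG).
#' @param mrna_table,ncrna_table Paths to the mRNA / ncRNA DE tables.
#' @param target_map Path to an ncRNA-target pair list, or \code{NULL} to
#'   infer lncRNA targets from \code{expression}.
#' @param expression Optional path to an expression matrix (needed only for
#'   co-expression target inference).
#' @param edges Optional path to a PPI edge list.
#' @param id_col,lfc_col,p_col DE-table column names.
#' @param deg_p_threshold,deg_lfc_threshold DEG screen thresholds.
#' @param alpha Enrichment adjusted-p cutoff.
#' @param universe \code{"annotated"} (default: genes annotated to >= 1
#'   pathway of the collection) or \code{"measured"} (the DE table's genes,
#'   intersected with the annotation).
#' @param min_overlap Minimum DEG overlap for a pathway to be tested.
#' @param correct_length_bias Reserved; must remain \code{FALSE} (no defined
#'   procedure exists for an over-representation test of a DEG list).
#' @param denominator_mode,weight_p C-value modes, see \code{\link{pdnt}}.
#' @param r_threshold,p_threshold,fdr_threshold Co-expression screen.
#' @param mirna_min_score Optional miRNA target-score filter.
#' @param ppi_score_threshold Optional edge-score filter.
#' @param core_fraction,subcore_fraction Degree-partition boundaries.
#' @param top_n Size of the top lists compared in evaluation.
#' @param out_dir Output directory.
#' @param seed Seed for any randomized stage.
#' @return Object of class \code{"pipeline_config"} (a list).
#' @export
pipeline_config <- function(gmt = NULL, mrna_table = NULL, ncrna_table = NULL,
                            target_map = NULL, expression = NULL, edges = NULL,
                            id_col = "id", lfc_col = "log2fc", p_col = "p_value",
                            deg_p_threshold = 0.05, deg_lfc_threshold = 1.0,
                            alpha = 0.05, universe = c("annotated", "measured"),
                            min_overlap = 1L, correct_length_bias = FALSE,
                            denominator_mode = c("pathway_universe", "deg_overlap"),
                            weight_p = c("raw", "adjusted"),
                            r_threshold = 0.90, p_threshold = 0.01,
                            fdr_threshold = 0.01, mirna_min_score = NULL,
                            ppi_score_threshold = NULL, core_fraction = 0.20,
                            subcore_fraction = 0.50, top_n = 10L,
                            out_dir = "pdnt_out", seed = 1L) {
  universe <- match.arg(universe)
  denominator_mode <- match.arg(denominator_mode)
  weight_p <- match.arg(weight_p)
  if (isTRUE(correct_length_bias)) {
    config_error("correct_length_bias is reserved: no defined procedure ",
                 "exists for correcting gene-length bias in an ",
                 "over-representation test of a DEG list; leave it FALSE")
  }
  structure(list(gmt = as.list(gmt), mrna_table = mrna_table,
                 ncrna_table = ncrna_table, target_map = target_map,
                 expression = expression, edges = edges, id_col = id_col,
                 lfc_col = lfc_col, p_col = p_col,
                 deg_p_threshold = deg_p_threshold,
                 deg_lfc_threshold = deg_lfc_threshold, alpha = alpha,
                 universe = universe, min_overlap = as.integer(min_overlap),
                 correct_length_bias = FALSE,
                 denominator_mode = denominator_mode, weight_p = weight_p,
                 r_threshold = r_threshold, p_threshold = p_threshold,
                 fdr_threshold = fdr_threshold,
                 mirna_min_score = mirna_min_score,
                 ppi_score_threshold = ppi_score_threshold,
                 core_fraction = core_fraction,
                 subcore_fraction = subcore_fraction,
                 top_n = as.integer(top_n), out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file path.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    config_error("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' Write the resolved configuration snapshot
#' @param config A \code{pipeline_config}.
#' @param path Output YAML path.
#' @return Invisibly, \code{path}.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

check_readable <- function(path, what) {
  if (is.null(path)) config_error("missing required input: ", what)
  if (!file.exists(path)) {
    config_error(what, " file not found: ", path)
  }
  path
}

#' Run the scoring pipeline: screen, enrich, score
#'
#' Reads all configured inputs, screens the DEGs, runs over-representation
#' analysis per pathway collection, fits the C-value model and writes the
#' C-value table, per-term detail, per-category enrichment reports and a
#' resolved configuration snapshot into \code{config$out_dir}. Counts are
#' logged at every stage.
#'
#' @param config A \code{pipeline_config}.
#' @return The \code{pdnt} fit, invisibly; the enrichments and DEG set are
#'   attached as attributes \code{"enrichments"} and \code{"degs"}.
#' @export
run_score <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(config$gmt) == 0) config_error("no GMT collection configured")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  collections <- lapply(names(config$gmt), function(cat) {
    read_gmt(check_readable(config$gmt[[cat]], paste0("GMT (", cat, ")")),
             category = cat)
  })
  names(collections) <- names(config$gmt)
  for (cat in names(collections)) {
    stage_log("read", "collection %s: %d pathways", cat,
              length(collections[[cat]]$pathways))
  }

  mrna <- read_differential_table(check_readable(config$mrna_table, "mRNA DE table"),
                                  config$id_col, config$lfc_col, config$p_col)
  ncrna <- read_differential_table(check_readable(config$ncrna_table, "ncRNA DE table"),
                                   config$id_col, config$lfc_col, config$p_col)
  stage_log("read", "%d mRNAs, %d ncRNAs", nrow(mrna), nrow(ncrna))

  if (!is.null(config$target_map)) {
    tmap <- read_target_map(check_readable(config$target_map, "target map"))
    if (!is.null(config$mirna_min_score)) {
      tmap <- filter_mirna_targets(tmap, config$mirna_min_score)
    }
  } else if (!is.null(config$expression)) {
    expr <- read_expression_matrix(check_readable(config$expression,
                                                  "expression matrix"))
    lnc <- intersect(ncrna$feature_id, rownames(expr))
    mr <- intersect(setdiff(rownames(expr), lnc), mrna$feature_id)
    stage_log("targets", "inferring targets for %d lncRNAs against %d mRNAs",
              length(lnc), length(mr))
    tmap <- infer_lnc_targets(expr, lnc, mr, config$r_threshold,
                              config$p_threshold, config$fdr_threshold)
  } else {
    config_error("either a target map or an expression matrix is required")
  }
  stage_log("targets", "%d ncRNAs with %d target pairs", length(tmap),
            sum(lengths(unclass(tmap))))

  degs <- screen_degs(mrna, config$deg_p_threshold, config$deg_lfc_threshold)
  stage_log("screen", "%d DEGs of %d mRNAs", length(degs$genes), nrow(mrna))

  universe_genes <- if (config$universe == "measured") mrna$feature_id else NULL
  enrichments <- lapply(collections, function(coll) {
    enrich(degs, coll, universe = universe_genes, alpha = config$alpha,
           min_overlap = config$min_overlap)
  })
  for (cat in names(enrichments)) {
    e <- enrichments[[cat]]
    stage_log("enrich", "%s: %d/%d pathways retained at adjusted p < %g", cat,
              nrow(e$pathways), e$n_tested, e$alpha)
    write_enrichment_report(e, file.path(config$out_dir,
                                         sprintf("enrichment_%s.tsv",
                                                 tolower(cat))))
  }

  fit <- pdnt(tmap, degs, enrichments, ncrna, weight_p = config$weight_p,
              denominator_mode = config$denominator_mode)
  stage_log("score", "%d ncRNAs scored (%d with C value 0)", nrow(fit$report),
            sum(fit$report$c_value == 0))
  write_c_value_table(fit, file.path(config$out_dir, "c_values.tsv"),
                      detail_path = file.path(config$out_dir,
                                              "c_value_terms.tsv"))
  write_pipeline_config(config, file.path(config$out_dir,
                                          "resolved_config.yaml"))
  attr(fit, "enrichments") <- enrichments
  attr(fit, "degs") <- degs
  attr(fit, "target_map") <- tmap
  invisible(fit)
}

#' Run the evaluation suite
#'
#' Compares the C-value index against the two expression-based indexes
#' (absolute log2FC and p-value): top-N lists, pooled-target pathway
#' proportions over the enriched pathways, PPI degree partition and
#' per-group region ratios with core-region increase rates, and — when key
#' ids are supplied — rank sums and rank-shift counts. Reports are written
#' as tab-separated files in \code{config$out_dir}. Without a PPI edge list
#' the network sections are skipped with a logged notice.
#'
#' @param config A \code{pipeline_config}.
#' @param fit Optional \code{pdnt} fit from \code{\link{run_score}}; when
#'   absent \code{run_score(config)} is invoked first.
#' @param key_ids Optional character vector (or path to a one-id-per-line
#'   file) of key ncRNAs for the rank-sum comparison.
#' @return Invisibly, a list with the computed rankings, top lists,
#'   proportions, partition, region ratios, increase rates and (when keys
#'   are given) rank sums and shift counts.
#' @export
run_evaluate <- function(config, fit = NULL, key_ids = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(fit)) fit <- run_score(config)
  enrichments <- attr(fit, "enrichments")
  degs <- attr(fit, "degs")
  tmap <- attr(fit, "target_map")
  ncrna <- fit$de_ncrnas
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  n <- config$top_n
  if (n > nrow(ncrna)) {
    warning(sprintf("top_n (%d) exceeds the %d DE ncRNAs; using all", n,
                    nrow(ncrna)), call. = FALSE)
    n <- nrow(ncrna)
  }
  rankings <- list(c_value = rank_by(ncrna, fit, "c_value"),
                   abs_log2fc = rank_by(ncrna, fit, "abs_log2fc"),
                   p_value = rank_by(ncrna, fit, "p_value"))
  tops <- lapply(rankings, function(r) utils::head(r$ids, n))
  top_lines <- c("index\trank\tncrna_id",
                 unlist(lapply(names(tops), function(ix) {
                   sprintf("%s\t%d\t%s", ix, seq_along(tops[[ix]]), tops[[ix]])
                 })))
  con <- file(file.path(config$out_dir, "top_lists.tsv"), "wb")
  writLines_lf(top_lines, con); close(con)
  stage_log("evaluate", "top-%d lists written for 3 indexes", n)

  # pooled-target proportions over this run's enriched pathways
  pathway_sets <- list()
  for (e in enrichments) {
    sets <- e$pathways$genes
    names(sets) <- e$pathways$pathway_id
    pathway_sets <- c(pathway_sets, sets)
  }
  props <- NULL
  if (length(pathway_sets)) {
    props <- sapply(tops, function(ids) {
      group_pathway_proportions(ids, tmap, degs, pathway_sets)
    })
    prop_lines <- c(paste(c("pathway_id", colnames(props)), collapse = "\t"),
                    vapply(seq_len(nrow(props)), function(i) {
                      paste(c(rownames(props)[i], sprintf("%.6g", props[i, ])),
                            collapse = "\t")
                    }, character(1)))
    con <- file(file.path(config$out_dir, "group_pathway_proportions.tsv"), "wb")
    writLines_lf(prop_lines, con); close(con)
  }

  out <- list(rankings = rankings, top_lists = tops, proportions = props)

  if (!is.null(config$edges)) {
    network <- read_edge_list(check_readable(config$edges, "PPI edge list"),
                              score_threshold = config$ppi_score_threshold)
    partition <- degree_partition(network, config$core_fraction,
                                  config$subcore_fraction)
    group_genes <- lapply(tops, function(ids) {
      unique(unlist(unclass(tmap)[intersect(ids, names(tmap))],
                    use.names = FALSE))
    })
    ratios <- lapply(group_genes, function(g) {
      suppressWarnings(group_region_ratios(g, partition))
    })
    rates <- c(vs_abs_log2fc = increase_rate(ratios$c_value[["core"]],
                                             ratios$abs_log2fc[["core"]]),
               vs_p_value = increase_rate(ratios$c_value[["core"]],
                                          ratios$p_value[["core"]]))
    lines <- c("group\tcore\tsub_core\tnoncore",
               vapply(names(ratios), function(g) {
                 sprintf("%s\t%.4f\t%.4f\t%.4f", g, ratios[[g]][["core"]],
                         ratios[[g]][["sub_core"]], ratios[[g]][["noncore"]])
               }, character(1)),
               "",
               "comparison\tcore_increase_rate",
               sprintf("c_value_vs_abs_log2fc\t%.2f",
                       round_half_away(rates[["vs_abs_log2fc"]])),
               sprintf("c_value_vs_p_value\t%.2f",
                       round_half_away(rates[["vs_p_value"]])))
    con <- file(file.path(config$out_dir, "ppi_region_report.tsv"), "wb")
    writLines_lf(lines, con); close(con)
    stage_log("evaluate", "PPI partition: %d nodes; core increase rates %.2f / %.2f",
              length(network$nodes), rates[["vs_abs_log2fc"]],
              rates[["vs_p_value"]])
    out$partition <- partition
    out$region_ratios <- ratios
    out$core_increase_rates <- rates
  } else {
    stage_log("evaluate", "no PPI edge list configured; network sections skipped")
  }

  if (!is.null(key_ids)) {
    if (length(key_ids) == 1 && file.exists(key_ids)) {
      key_ids <- readLines(key_ids, warn = FALSE)
      key_ids <- key_ids[nzchar(key_ids)]
    }
    key_ids <- normalize_ids(key_ids, "key id")
    if (!any(key_ids %in% ncrna$feature_id)) {
      config_error("no key id is present in the DE ncRNA table")
    }
    sums <- vapply(rankings, rank_sum, numeric(1), key_ids = key_ids)
    shifts_fc <- rank_shift_counts(rankings$c_value, rankings$abs_log2fc,
                                   key_ids)
    shifts_p <- rank_shift_counts(rankings$c_value, rankings$p_value, key_ids)
    lines <- c("index\trank_sum",
               sprintf("%s\t%d", names(sums), as.integer(sums)),
               "",
               "comparison\tup\tdown\tunchanged",
               sprintf("c_value_vs_abs_log2fc\t%d\t%d\t%d", shifts_fc[["up"]],
                       shifts_fc[["down"]], shifts_fc[["unchanged"]]),
               sprintf("c_value_vs_p_value\t%d\t%d\t%d", shifts_p[["up"]],
                       shifts_p[["down"]], shifts_p[["unchanged"]]))
    con <- file(file.path(config$out_dir, "key_rank_report.tsv"), "wb")
    writLines_lf(lines, con); close(con)
    stage_log("evaluate", "key rank sums: %s",
              paste(sprintf("%s=%d", names(sums), as.integer(sums)),
                    collapse = ", "))
    out$rank_sums <- sums
    out$shifts <- list(vs_abs_log2fc = shifts_fc, vs_p_value = shifts_p)
  }
  invisible(out)
}
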