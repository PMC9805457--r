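#' Rank ncRNAs by one of three indexes
#'
#' \code{"c_value"} sorts by descending total C value, \code{"abs_log2fc"} by
#' descending absolute log2 fold change, \code{"p_value"} by ascending
#' p-value; all ties break by ascending id.
#'
#' @param de_ncrnas A \code{diff_table} of the DE ncRNAs.
#' @param fit A \code{pdnt} fit for the same ncRNAs (may be \code{NULL} for
#'   the two expression-based indexes).
#' @param index One of \code{"c_value"}, \code{"abs_log2fc"}, \code{"p_value"}.
#' @return Object of class \code{"ncrna_ranking"}: list with \code{index},
#'   \code{ids} (ordered best first) and \code{rank} (named integer vector of
#'   1-based positions).
#' @export
rank_by <- function(de_ncrnas, fit = NULL,
                    index = c("c_value", "abs_log2fc", "p_value")) {
  index <- match.arg(index)
  stopifnot(inherits(de_ncrnas, "diff_table"))
  ids <- de_ncrnas$feature_id
  ord <- switch(index,
    c_value = {
      if (is.null(fit)) stop("a pdnt fit is required for the c_value index",
                             call. = FALSE)
      report <- if (inherits(fit, "pdnt")) fit$report else fit
      cv <- stats::setNames(report$c_value, report$ncrna_id)
      if (!all(ids %in% names(cv))) {
        stop("C-value report does not cover every DE ncRNA", call. = FALSE)
      }
      order(-cv[ids], ids)
    },
    abs_log2fc = order(-abs(de_ncrnas$log2fc), ids),
    p_value = order(de_ncrnas$p_value, ids))
  ordered <- ids[ord]
  structure(list(index = index, ids = ordered,
                 rank = stats::setNames(seq_along(ordered), ordered)),
            class = "ncrna_ranking")
}

#' @export
print.ncrna_ranking <- function(x, ...) {
  cat(sprintf("Ranking by %s: %d ncRNAs (best: %s)\n", x$index,
              length(x$ids), if (length(x$ids)) x$ids[1] else "-"))
  invisible(x)
}

#' Sum of key-ncRNA ranks under a ranking
#'
#' Smaller sums mean the key (e.g. literature-curated disease) ncRNAs sit
#' nearer the top. Keys absent from the ranking are skipped with a warning.
#'
#' @param ranking An \code{ncrna_ranking}.
#' @param key_ids Non-empty character vector of key ncRNA ids.
#' @return Integer rank sum.
#' @export
rank_sum <- function(ranking, key_ids) {
  stopifnot(inherits(ranking, "ncrna_ranking"))
  key_ids <- unique(normalize_ids(key_ids, "key id"))
  if (length(key_ids) == 0) stop("empty key set", call. = FALSE)
  missing <- setdiff(key_ids, names(ranking$rank))
  if (length(missing)) {
    warning("key id(s) absent from the ranking skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
    key_ids <- setdiff(key_ids, missing)
    if (length(key_ids) == 0) stop("no key id present in the ranking",
                                   call. = FALSE)
  }
  sum(ranking$rank[key_ids])
}

#' Count key ncRNAs ranking up, down or unchanged between two indexes
#'
#' A key counts as "up" when its rank under \code{reference} is better
#' (numerically smaller) than under \code{comparator}.
#'
#' @param reference,comparator \code{ncrna_ranking}s over the same ids.
#' @param key_ids Character vector of key ids (present in both rankings).
#' @return Named integer vector \code{c(up, down, unchanged)}.
#' @export
rank_shift_counts <- function(reference, comparator, key_ids) {
  stopifnot(inherits(reference, "ncrna_ranking"),
            inherits(comparator, "ncrna_ranking"))
  key_ids <- unique(normalize_ids(key_ids, "key id"))
  key_ids <- intersect(key_ids, intersect(names(reference$rank),
                                          names(comparator$rank)))
  r <- reference$rank[key_ids]
  s <- comparator$rank[key_ids]
  c(up = sum(r < s), down = sum(r > s), unchanged = sum(r == s))
}

#' Partition PPI nodes into core, sub-core and noncore regions by degree
#'
#' Nodes are sorted by descending degree (distinct-neighbor count; edge
#' scores are ignored), ties broken by ascending id. The first
#' \code{ceiling(core_fraction * N)} nodes form the core region, the next up
#' to \code{ceiling(subcore_fraction * N)} the sub-core, the rest noncore —
#' the usual 20\% / 20-50\% / bottom-50\% hub partition.
#'
#' @param network A \code{ppi_network} with at least one node.
#' @param core_fraction Top fraction forming the core (default 0.20).
#' @param subcore_fraction Cumulative fraction forming core + sub-core
#'   (default 0.50).
#' @return Object of class \code{"ppi_partition"}: list with \code{region_of}
#'   (named character vector with values \code{"core"}, \code{"sub_core"},
#'   \code{"noncore"}), \code{degree} (named integer vector) and
#'   \code{boundaries} (\code{core_cut}, \code{subcore_cut}).
#' @export
degree_partition <- function(network, core_fraction = 0.20,
                             subcore_fraction = 0.50) {
  stopifnot(inherits(network, "ppi_network"))
  n <- length(network$nodes)
  if (n == 0) stop("empty network", call. = FALSE)
  if (!(core_fraction > 0 && core_fraction < subcore_fraction &&
        subcore_fraction <= 1)) {
    stop("need 0 < core_fraction < subcore_fraction <= 1", call. = FALSE)
  }
  deg <- stats::setNames(integer(n), network$nodes)
  if (nrow(network$edges)) {
    tab <- table(c(network$edges$a, network$edges$b))
    deg[names(tab)] <- as.integer(tab)
  }
  ord <- order(-deg, names(deg))
  sorted <- names(deg)[ord]
  core_cut <- ceiling(core_fraction * n)
  subcore_cut <- ceiling(subcore_fraction * n)
  region <- rep("noncore", n)
  region[seq_len(core_cut)] <- "core"
  if (subcore_cut > core_cut) {
    region[(core_cut + 1):subcore_cut] <- "sub_core"
  }
  structure(list(region_of = stats::setNames(region, sorted),
                 degree = deg,
                 boundaries = c(core_cut = core_cut, subcore_cut = subcore_cut)),
            class = "ppi_partition")
}

#' @export
print.ppi_partition <- function(x, ...) {
  tab <- table(factor(x$region_of, levels = c("core", "sub_core", "noncore")))
  cat(sprintf("PPI degree partition: %d core / %d sub-core / %d noncore nodes\n",
              tab[["core"]], tab[["sub_core"]], tab[["noncore"]]))
  invisible(x)
}

#' Region ratios of a gene group within a PPI partition
#'
#' Fraction of the group's in-network genes falling in each region; genes
#' outside the partitioned network are dropped with a warning reporting the
#' count. The three ratios sum to 1.
#'
#' @param genes Character vector of gene ids (e.g. the pooled targets of a
#'   top-10 ncRNA group).
#' @param partition A \code{ppi_partition}.
#' @return Named numeric vector \code{c(core, sub_core, noncore)}.
#' @export
group_region_ratios <- function(genes, partition) {
  stopifnot(inherits(partition, "ppi_partition"))
  genes <- unique(normalize_ids(genes))
  in_net <- intersect(genes, names(partition$region_of))
  dropped <- length(genes) - length(in_net)
  if (dropped > 0) {
    warning(sprintf("%d gene(s) outside the partitioned network dropped",
                    dropped), call. = FALSE)
  }
  if (length(in_net) == 0) {
    stop("no group gene present in the network: ratios undefined",
         call. = FALSE)
  }
  tab <- table(factor(partition$region_of[in_net],
                      levels = c("core", "sub_core", "noncore")))
  ratios <- as.numeric(tab) / length(in_net)
  stats::setNames(ratios, c("core", "sub_core", "noncore"))
}

#' Relative increase of one ratio over another
#'
#' \code{(ratio_c - ratio_other) / ratio_other}: the relative improvement of
#' the C-value group's statistic over a comparator group's.
#'
#' @param ratio_c,ratio_other Numeric; \code{ratio_other} must be positive.
#' @return Numeric increase rate (vectorised).
#' @export
increase_rate <- function(ratio_c, ratio_other) {
  if (any(ratio_other <= 0)) {
    stop("undefined increase rate: comparator ratio must be > 0",
         call. = FALSE)
  }
  (ratio_c - ratio_other) / ratio_other
}

#' Arithmetic mean of increase rates
#'
#' @param rates Non-empty numeric vector.
#' @return The mean (full precision; use \code{\link{round_half_away}} for
#'   2-dp table presentation).
#' @export
mean_increase_rate <- function(rates) {
  if (length(rates) == 0) stop("empty rate list", call. = FALSE)
  mean(as.numeric(rates))
}

#' Decimal rounding, half away from zero
#'
#' Presentation rounding for report tables: 0.605 rounds to 0.61 and -0.605
#' to -0.61. Values are snapped to a 1e-9 grid before rounding so that
#' numbers that are exact decimals (like means of 2-dp table entries) are not
#' mis-rounded by their binary floating-point representation; base
#' \code{round}'s round-half-even (and its binary artefacts, e.g. 0.845 ->
#' 0.84) is avoided.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Pooled-target proportions of a group of ncRNAs in given pathways
#'
#' For each pathway, the union (not multiset) of the group's target genes is
#' intersected with the differential genes and the pathway, and divided by
#' the pathway's size. The pathways may be an externally curated collection
#' (playing the role of IPA canonical pathways) or this package's own
#' enriched pathways.
#'
#' @param group_ids Character vector of ncRNA ids (e.g. a top-10 list).
#' @param target_map A \code{target_map}.
#' @param degs A \code{deg_set}.
#' @param pathways Named list of pathway gene sets (all non-empty), or a
#'   \code{gene_set_collection}.
#' @return Named numeric vector, one proportion in [0, 1] per pathway.
#' @export
group_pathway_proportions <- function(group_ids, target_map, degs, pathways) {
  stopifnot(inherits(target_map, "target_map"), inherits(degs, "deg_set"))
  if (inherits(pathways, "gene_set_collection")) pathways <- pathways$pathways
  stopifnot(length(pathways) > 0, all(lengths(pathways) > 0))
  group_ids <- unique(normalize_ids(group_ids, "ncRNA id"))
  pooled <- unique(unlist(unclass(target_map)[intersect(group_ids,
                                                        names(target_map))],
                          use.names = FALSE))
  pooled_deg <- intersect(pooled, degs$genes)
  vapply(pathways, function(g) {
    g <- unique(normalize_ids(g))
    length(intersect(pooled_deg, g)) / length(g)
  }, numeric(1))
}

#' Aggregate pathway-proportion efficiency increase of one group over another
#'
#' Summarises per-pathway proportions into one per-dataset rate:
#' \code{(sum_k prop_c_k - sum_k prop_other_k) / sum_k prop_other_k}. Being a
#' ratio of totals it is scale-free in the number of pathways; a
#' \code{"mean"} aggregation is equivalent for equal-length inputs and kept
#' for symmetry.
#'
#' @param prop_c,prop_other Numeric vectors of per-pathway proportions (same
#'   pathways, same order).
#' @param aggregate \code{"sum"} (default) or \code{"mean"}.
#' @return Single numeric increase rate.
#' @export
proportion_increase_rate <- function(prop_c, prop_other,
                                     aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(prop_c) == length(prop_other), length(prop_c) > 0)
  agg <- if (aggregate == "sum") sum else mean
  increase_rate(agg(prop_c), agg(prop_other))
}
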