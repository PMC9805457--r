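#' Screen differentially expressed genes
#'
#' Applies the conventional dual threshold: a gene is differential iff its
#' p-value is strictly below \code{p_threshold} and its absolute log2 fold
#' change is at least \code{lfc_threshold} (strict \code{<} on p, inclusive
#' \code{>=} on |log2FC|).
#'
#' @param table A \code{diff_table}.
#' @param p_threshold P-value cutoff (default 0.05).
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 1).
#' @return Object of class \code{"deg_set"}: list with \code{genes} (sorted
#'   character vector), \code{p_threshold}, \code{lfc_threshold}.
#' @examples
#' dt <- diff_table(c("g1", "g2"), c(1.5, 0.2), c(0.01, 0.2))
#' screen_degs(dt)$genes
#' @export
screen_degs <- function(table, p_threshold = 0.05, lfc_threshold = 1.0) {
  stopifnot(inherits(table, "diff_table"), p_threshold > 0, lfc_threshold > 0)
  keep <- table$p_value < p_threshold & abs(table$log2fc) >= lfc_threshold
  structure(list(genes = sort(table$feature_id[keep]),
                 p_threshold = p_threshold, lfc_threshold = lfc_threshold),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf("DEG set: %d genes (p < %g, |log2FC| >= %g)\n",
              length(x$genes), x$p_threshold, x$lfc_threshold))
  invisible(x)
}

#' Hypergeometric upper-tail probability for over-representation
#'
#' Returns P(X >= overlap) where X is the number of differential genes one
#' would draw into a pathway of \code{pathway_size} genes when
#' \code{deg_count} genes are drawn from a universe of \code{universe_size}
#' without replacement. This one-sided tail equals the one-sided Fisher exact
#' test used for over-representation analysis.
#'
#' @param universe_size,pathway_size,deg_count,overlap Non-negative counts;
#'   \code{overlap <= min(pathway_size, deg_count)} and both margins at most
#'   \code{universe_size}. All arguments recycle to a common length.
#' @return Numeric vector of tail probabilities in (0, 1].
#' @export
hypergeometric_upper_tail <- function(universe_size, pathway_size, deg_count,
                                      overlap) {
  n <- max(length(universe_size), length(pathway_size), length(deg_count),
           length(overlap))
  universe_size <- rep_len(as.numeric(universe_size), n)
  pathway_size <- rep_len(as.numeric(pathway_size), n)
  deg_count <- rep_len(as.numeric(deg_count), n)
  overlap <- rep_len(as.numeric(overlap), n)
  bad <- overlap < 0 | overlap > pmin(pathway_size, deg_count) |
    pathway_size > universe_size | deg_count > universe_size |
    universe_size < 0
  if (any(bad)) {
    stop("inconsistent hypergeometric counts (need 0 <= overlap <= min(pathway, DEG) and margins <= universe)",
         call. = FALSE)
  }
  stats::phyper(overlap - 1, pathway_size, universe_size - pathway_size,
                deg_count, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order. Adjusted
#' values are never below the raw p and are monotone in p-rank.
#'
#' @param p_values Numeric vector with all elements in (0, 1].
#' @return Numeric vector of the same length.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  p_values <- as.numeric(p_values)
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a DEG set against a gene-set collection
#'
#' For each pathway the overlap with the differential genes is tested with
#' the hypergeometric upper tail; Benjamini-Hochberg correction is applied
#' across all tested pathways of the collection, and pathways with adjusted
#' p below \code{alpha} are retained, sorted by ascending raw p (ties by
#' pathway id). The number of retained pathways per category is the \code{n}
#' of the C-value sum.
#'
#' Differential genes outside the universe are dropped with a warning
#' reporting the count; pathway sizes and overlaps are counted within the
#' universe.
#'
#' @param degs A \code{deg_set}.
#' @param collection A \code{gene_set_collection}.
#' @param universe Optional character vector of measured genes, used as
#'   given; default is the collection's annotation universe (every gene
#'   appearing in at least one pathway).
#' @param alpha Adjusted-p significance cutoff (default 0.05).
#' @param min_overlap Pathways overlapping fewer than this many differential
#'   genes are excluded before testing (default 1).
#' @param min_size,max_size Optional pathway-size filters (within the
#'   universe), both inclusive; unset by default.
#' @return Object of class \code{"enrichment_result"}: list with
#'   \code{category}, \code{universe}, \code{alpha}, \code{n_tested}, and
#'   \code{pathways}, a data.frame with columns \code{pathway_id},
#'   \code{category}, \code{n_universe}, \code{overlap}, \code{p_value},
#'   \code{adj_p_value} and list columns \code{genes} (pathway genes in the
#'   universe) and \code{overlap_genes}.
#' @export
enrich <- function(degs, collection, universe = NULL, alpha = 0.05,
                   min_overlap = 1L, min_size = NULL, max_size = NULL) {
  stopifnot(inherits(degs, "deg_set"), inherits(collection, "gene_set_collection"))
  if (is.null(universe)) {
    universe <- annotated_genes(collection)
  } else {
    universe <- sort(unique(normalize_ids(universe)))
  }
  if (length(universe) == 0) {
    stop("empty enrichment universe", call. = FALSE)
  }
  deg_in <- intersect(degs$genes, universe)
  n_out <- length(degs$genes) - length(deg_in)
  if (n_out > 0) {
    warning(sprintf("%d differential gene(s) outside the enrichment universe dropped",
                    n_out), call. = FALSE)
  }
  N <- length(universe)
  n_deg <- length(deg_in)
  sets <- lapply(collection$pathways, intersect, y = universe)
  sizes <- lengths(sets)
  ov_sets <- lapply(sets, intersect, y = deg_in)
  ov <- lengths(ov_sets)
  keep <- ov >= min_overlap & sizes > 0
  if (!is.null(min_size)) keep <- keep & sizes >= min_size
  if (!is.null(max_size)) keep <- keep & sizes <= max_size
  ids <- names(sets)[keep]
  empty <- data.frame(pathway_id = character(), category = character(),
                      n_universe = integer(), overlap = integer(),
                      p_value = numeric(), adj_p_value = numeric(),
                      stringsAsFactors = FALSE)
  empty$genes <- list(); empty$overlap_genes <- list()
  if (length(ids) == 0) {
    res <- empty
  } else {
    p <- hypergeometric_upper_tail(N, sizes[keep], n_deg, ov[keep])
    adj <- benjamini_hochberg(p)
    sig <- adj < alpha
    ord <- order(p[sig], ids[sig])
    res <- data.frame(pathway_id = ids[sig][ord],
                      category = rep(collection$category, sum(sig)),
                      n_universe = as.integer(sizes[keep][sig][ord]),
                      overlap = as.integer(ov[keep][sig][ord]),
                      p_value = p[sig][ord],
                      adj_p_value = adj[sig][ord],
                      stringsAsFactors = FALSE, row.names = NULL)
    res$genes <- unname(sets[keep][sig][ord])
    res$overlap_genes <- unname(ov_sets[keep][sig][ord])
  }
  structure(list(category = collection$category, universe = universe,
                 alpha = alpha, n_tested = sum(keep), pathways = res),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment [%s]: %d/%d pathways significant at adjusted p < %g (universe %d genes)\n",
              x$category, nrow(x$pathways), x$n_tested, x$alpha,
              length(x$universe)))
  invisible(x)
}

#' Write an enrichment report
#'
#' Tab-separated columns: pathway_id, category, size_in_universe, overlap, p,
#' adj_p, overlap gene list (pipe-separated).
#'
#' @param result An \code{enrichment_result}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_enrichment_report <- function(result, path) {
  stopifnot(inherits(result, "enrichment_result"))
  pw <- result$pathways
  lines <- c("pathway_id\tcategory\tsize_in_universe\toverlap\tp\tadj_p\toverlap_genes",
             vapply(seq_len(nrow(pw)), function(i) {
               sprintf("%s\t%s\t%d\t%d\t%.6g\t%.6g\t%s",
                       pw$pathway_id[i], pw$category[i], pw$n_universe[i],
                       pw$overlap[i], pw$p_value[i], pw$adj_p_value[i],
                       paste(pw$overlap_genes[[i]], collapse = "|"))
             }, character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writLines_lf(lines, con)
  invisible(path)
}
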