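#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson coefficient with the usual t-test on n - 2 degrees of
#' freedom. A perfect correlation (|r| = 1) has a degenerate test statistic;
#' its p is reported as the smallest representable positive double rather
#' than 0 so that downstream -log10 weighting stays finite.
#'
#' @param x,y Numeric vectors of equal length n >= 3 with nonzero variance.
#' @return Named list with \code{r} and \code{p}.
#' @export
pearson_with_p <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "pearson"))
  r <- unname(ct$estimate)
  p <- ct$p.value
  if (!is.finite(p) || p <= 0) p <- .Machine$double.xmin
  list(r = r, p = p)
}

# vectorised two-sided p for a matrix of correlations at n - 2 df
cor_p_matrix <- function(r, n) {
  df <- n - 2
  r2 <- pmin(abs(r), 1)
  p <- matrix(.Machine$double.xmin, nrow(r), ncol(r),
              dimnames = dimnames(r))
  ok <- r2 < 1
  tstat <- r2[ok] * sqrt(df / (1 - r2[ok]^2))
  p[ok] <- 2 * stats::pt(tstat, df, lower.tail = FALSE)
  p[p <= 0] <- .Machine$double.xmin
  p
}

#' Infer lncRNA target genes by co-expression
#'
#' Screens every lncRNA x mRNA pair by Pearson correlation across samples and
#' keeps a pair iff |r| >= \code{r_threshold}, the two-sided p-value is below
#' \code{p_threshold}, and its Benjamini-Hochberg FDR — computed over the
#' full family of tested pairs in this call — is below \code{fdr_threshold}.
#' The defaults (|r| >= 0.90, p < 0.01, FDR < 0.01) are the conventional
#' stringent co-expression screen for lncRNA target assignment.
#'
#' @param expr Numeric expression matrix (features x samples, >= 3 samples)
#'   with feature ids as row names.
#' @param lnc_ids,mrna_ids Disjoint character vectors of feature ids present
#'   in \code{expr}.
#' @param r_threshold Minimum |r| (default 0.90).
#' @param p_threshold Maximum raw p (exclusive, default 0.01).
#' @param fdr_threshold Maximum BH FDR (exclusive, default 0.01).
#' @param details Also return the per-pair correlation records.
#' @return A \code{target_map} (every lncRNA present, possibly with an empty
#'   set). With \code{details = TRUE}, a list with \code{map} and
#'   \code{records} (data.frame ncrna_id, gene_id, r, p, fdr of kept pairs).
#' @export
infer_lnc_targets <- function(expr, lnc_ids, mrna_ids, r_threshold = 0.90,
                              p_threshold = 0.01, fdr_threshold = 0.01,
                              details = FALSE) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3)
  lnc_ids <- sort(unique(normalize_ids(lnc_ids, "lncRNA id")))
  mrna_ids <- sort(unique(normalize_ids(mrna_ids, "mRNA id")))
  if (length(intersect(lnc_ids, mrna_ids))) {
    stop("lnc_ids and mrna_ids must be disjoint", call. = FALSE)
  }
  absent <- setdiff(c(lnc_ids, mrna_ids), rownames(expr))
  if (length(absent)) {
    stop("feature id(s) absent from the expression matrix: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  }
  v <- apply(expr[c(lnc_ids, mrna_ids), , drop = FALSE], 1, stats::sd)
  if (any(v == 0)) {
    stop("undefined correlation: zero variance for ",
         paste(utils::head(names(v)[v == 0], 5), collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(t(expr[lnc_ids, , drop = FALSE]),
                  t(expr[mrna_ids, , drop = FALSE]))
  p <- cor_p_matrix(r, ncol(expr))
  fdr <- matrix(benjamini_hochberg(as.vector(p)), nrow(p), ncol(p),
                dimnames = dimnames(p))
  keep <- abs(r) >= r_threshold & p < p_threshold & fdr < fdr_threshold
  idx <- which(keep, arr.ind = TRUE)
  records <- data.frame(ncrna_id = lnc_ids[idx[, 1]],
                        gene_id = mrna_ids[idx[, 2]],
                        r = r[keep], p = p[keep], fdr = fdr[keep],
                        stringsAsFactors = FALSE)
  records <- records[order(records$ncrna_id, records$gene_id), , drop = FALSE]
  row.names(records) <- NULL
  map <- target_map(if (nrow(records)) records[c("ncrna_id", "gene_id")] else NULL,
                    ncrna_ids = lnc_ids)
  if (details) list(map = map, records = records) else map
}

#' Filter miRNA target predictions by score
#'
#' Removes pairs whose prediction score (e.g. a miRanda alignment score)
#' falls below \code{min_score}; ncRNAs whose whole target set is removed are
#' retained with an empty set, so they later score a C value of 0.
#'
#' @param map A \code{target_map}.
#' @param min_score Numeric cutoff, or \code{NULL} for no filtering.
#' @return A \code{target_map}.
#' @export
filter_mirna_targets <- function(map, min_score = NULL) {
  stopifnot(inherits(map, "target_map"))
  if (is.null(min_score)) return(map)
  scores <- attr(map, "scores")
  if (is.null(scores)) {
    stop("min_score given but the target map carries no scores", call. = FALSE)
  }
  ids <- names(map)
  pairs <- do.call(rbind, lapply(ids, function(id) {
    s <- scores[[id]]
    s <- s[s >= min_score]
    if (!length(s)) return(NULL)
    data.frame(ncrna_id = id, gene_id = names(s), score = unname(s),
               stringsAsFactors = FALSE)
  }))
  target_map(pairs, ncrna_ids = ids)
}
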