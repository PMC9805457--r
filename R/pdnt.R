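#' Proportion of an enriched pathway covered by an ncRNA's differential targets
#'
#' The numerator is the triple intersection of the ncRNA's target genes, the
#' differential genes and the pathway's genes within the enrichment universe.
#' The default denominator is the pathway's size within the universe (the
#' "ratio of target genes to the total genes in the pathway"); the alternate
#' mode divides by the pathway's DEG overlap instead.
#'
#' @param targets Character vector of target gene ids.
#' @param degs A \code{deg_set}.
#' @param pathway One-row slice of an \code{enrichment_result}'s
#'   \code{pathways} data.frame.
#' @param denominator_mode \code{"pathway_universe"} (default) or
#'   \code{"deg_overlap"}.
#' @return Proportion in [0, 1].
#' @export
pathway_proportion <- function(targets, degs, pathway,
                               denominator_mode = c("pathway_universe",
                                                    "deg_overlap")) {
  denominator_mode <- match.arg(denominator_mode)
  targets <- if (length(targets)) unique(normalize_ids(targets)) else character()
  num <- length(intersect(intersect(targets, degs$genes), pathway$genes[[1]]))
  den <- switch(denominator_mode,
                pathway_universe = length(pathway$genes[[1]]),
                deg_overlap = length(pathway$overlap_genes[[1]]))
  if (den == 0) stop("empty proportion denominator", call. = FALSE)
  num / den
}

# p-value floor before -log10, so weights stay finite
.P_FLOOR <- 1e-300

#' Per-category C value of one ncRNA
#'
#' Computes \code{sum_k proportion_k * (-log10 p_k)} over the \code{n}
#' pathways retained by the enrichment of one category, where
#' \code{proportion_k} is \code{\link{pathway_proportion}} and \code{p_k} is
#' the pathway's raw enrichment p-value (or the BH-adjusted one under
#' \code{weight_p = "adjusted"}). P-values are floored at 1e-300 before the
#' log. An empty enrichment contributes 0.
#'
#' @param targets Character vector of target gene ids.
#' @param degs A \code{deg_set}.
#' @param enrichment An \code{enrichment_result} for one category.
#' @param weight_p \code{"raw"} (default) or \code{"adjusted"}.
#' @param denominator_mode Passed to \code{\link{pathway_proportion}}.
#' @return List with \code{value} and \code{terms}, a data.frame with columns
#'   \code{category}, \code{pathway_id}, \code{proportion}, \code{weight},
#'   \code{contribution}.
#' @export
category_c_value <- function(targets, degs, enrichment,
                             weight_p = c("raw", "adjusted"),
                             denominator_mode = c("pathway_universe",
                                                  "deg_overlap")) {
  weight_p <- match.arg(weight_p)
  denominator_mode <- match.arg(denominator_mode)
  stopifnot(inherits(enrichment, "enrichment_result"))
  pw <- enrichment$pathways
  if (nrow(pw) == 0) {
    return(list(value = 0,
                terms = data.frame(category = character(),
                                   pathway_id = character(),
                                   proportion = numeric(), weight = numeric(),
                                   contribution = numeric(),
                                   stringsAsFactors = FALSE)))
  }
  targets <- if (length(targets)) unique(normalize_ids(targets)) else character()
  td <- intersect(targets, degs$genes)
  prop <- vapply(seq_len(nrow(pw)), function(k) {
    num <- length(intersect(td, pw$genes[[k]]))
    den <- if (denominator_mode == "pathway_universe") {
      length(pw$genes[[k]])
    } else {
      length(pw$overlap_genes[[k]])
    }
    num / den
  }, numeric(1))
  p <- if (weight_p == "raw") pw$p_value else pw$adj_p_value
  weight <- -log10(pmax(p, .P_FLOOR))
  terms <- data.frame(category = pw$category, pathway_id = pw$pathway_id,
                      proportion = prop, weight = weight,
                      contribution = prop * weight, stringsAsFactors = FALSE)
  list(value = sum(terms$contribution), terms = terms)
}

#' Fit the participation-degree (C value) model for a set of ncRNAs
#'
#' The Contribution value of an ncRNA is the sum, over the pathways enriched
#' in differential genes, of the proportion of each pathway covered by the
#' ncRNA's differential target genes, weighted by -log10 of the pathway's
#' enrichment p-value. Category values (BP, CC, MF, KEGG) are computed from
#' the corresponding enrichment results and the total C value is their sum.
#'
#' @param target_map A \code{target_map} (ncRNA id -> target genes). DE
#'   ncRNAs absent from it score 0 (a warning reports how many).
#' @param degs A \code{deg_set} of differential mRNAs.
#' @param enrichments Named list of \code{enrichment_result}s; names are
#'   category labels, conventionally \code{BP}, \code{CC}, \code{MF},
#'   \code{KEGG}. A missing conventional category contributes 0 with a
#'   warning.
#' @param de_ncrnas A \code{diff_table} of differentially expressed ncRNAs;
#'   one report row is produced per ncRNA in it.
#' @param weight_p \code{"raw"} (default) or \code{"adjusted"}: which pathway
#'   p-value enters the -log10 weight.
#' @param denominator_mode \code{"pathway_universe"} (default) or
#'   \code{"deg_overlap"}: the proportion's denominator.
#' @return Object of class \code{"pdnt"}: list with
#'   \describe{
#'     \item{report}{data.frame (one row per ncRNA, sorted by descending
#'       total, ties by id) with columns \code{ncrna_id}, \code{kegg_value},
#'       \code{bp_value}, \code{cc_value}, \code{mf_value}, \code{c_value}.}
#'     \item{terms}{per-pathway detail: \code{ncrna_id}, \code{category},
#'       \code{pathway_id}, \code{proportion}, \code{weight},
#'       \code{contribution}.}
#'     \item{de_ncrnas, weight_p, denominator_mode, call}{inputs and modes.}
#'   }
#' @examples
#' gsc <- gene_set_collection(list(PW1 = sprintf("G%02d", 1:10)), "KEGG")
#' dt <- diff_table(sprintf("G%02d", 1:20), rep(2, 20),
#'                  c(rep(0.01, 10), rep(0.5, 10)))
#' degs <- screen_degs(dt)
#' enr <- enrich(degs, gsc, universe = dt$feature_id)
#' tm <- target_map(data.frame(ncrna_id = "MIR-1", gene_id = c("G01", "G02")))
#' nc <- diff_table("MIR-1", 1.2, 0.04)
#' fit <- pdnt(tm, degs, list(KEGG = enr), nc)
#' coef(fit)
#' @export
pdnt <- function(target_map, degs, enrichments, de_ncrnas,
                 weight_p = c("raw", "adjusted"),
                 denominator_mode = c("pathway_universe", "deg_overlap")) {
  weight_p <- match.arg(weight_p)
  denominator_mode <- match.arg(denominator_mode)
  stopifnot(inherits(target_map, "target_map"), inherits(degs, "deg_set"),
            inherits(de_ncrnas, "diff_table"))
  ids <- de_ncrnas$feature_id
  missing_tm <- setdiff(ids, names(target_map))
  if (length(missing_tm)) {
    warning(sprintf("%d DE ncRNA(s) absent from the target map score 0",
                    length(missing_tm)), call. = FALSE)
  }
  conventional <- c("BP", "CC", "MF", "KEGG")
  absent_cat <- setdiff(conventional, names(enrichments))
  if (length(absent_cat)) {
    warning("missing enrichment categor(ies) contribute 0: ",
            paste(absent_cat, collapse = ", "), call. = FALSE)
  }
  cats <- names(enrichments)
  rows <- vector("list", length(ids))
  term_list <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    targets <- if (id %in% names(target_map)) target_map[[id]] else character()
    vals <- stats::setNames(numeric(length(cats)), cats)
    for (cat in cats) {
      cc <- category_c_value(targets, degs, enrichments[[cat]],
                             weight_p = weight_p,
                             denominator_mode = denominator_mode)
      vals[cat] <- cc$value
      if (nrow(cc$terms)) {
        cc$terms <- cbind(ncrna_id = id, cc$terms, stringsAsFactors = FALSE)
        term_list[[length(term_list) + 1L]] <- cc$terms
      }
    }
    cat_val <- function(cat) if (cat %in% cats) vals[[cat]] else 0
    rows[[i]] <- data.frame(ncrna_id = id,
                            kegg_value = cat_val("KEGG"),
                            bp_value = cat_val("BP"),
                            cc_value = cat_val("CC"),
                            mf_value = cat_val("MF"),
                            stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  if (is.null(report)) {
    report <- data.frame(ncrna_id = character(), kegg_value = numeric(),
                         bp_value = numeric(), cc_value = numeric(),
                         mf_value = numeric(), stringsAsFactors = FALSE)
  }
  report$c_value <- total_c_value(report$kegg_value, report$bp_value,
                                  report$cc_value, report$mf_value)
  report <- report[order(-report$c_value, report$ncrna_id), , drop = FALSE]
  row.names(report) <- NULL
  terms <- if (length(term_list)) {
    do.call(rbind, term_list)
  } else {
    data.frame(ncrna_id = character(), category = character(),
               pathway_id = character(), proportion = numeric(),
               weight = numeric(), contribution = numeric(),
               stringsAsFactors = FALSE)
  }
  row.names(terms) <- NULL
  structure(list(report = report, terms = terms, de_ncrnas = de_ncrnas,
                 weight_p = weight_p, denominator_mode = denominator_mode,
                 call = match.call()),
            class = "pdnt")
}

#' @export
print.pdnt <- function(x, n = 10L, ...) {
  cat(sprintf("Participation-degree (C value) fit: %d ncRNAs, weight_p = %s, denominator = %s\n",
              nrow(x$report), x$weight_p, x$denominator_mode))
  top <- utils::head(x$report, n)
  num <- c("kegg_value", "bp_value", "cc_value", "mf_value", "c_value")
  top[num] <- lapply(top[num], round, digits = 4)
  print(top, row.names = FALSE)
  if (nrow(x$report) > n) cat(sprintf("... and %d more\n", nrow(x$report) - n))
  invisible(x)
}

#' @export
summary.pdnt <- function(object, ...) {
  r <- object$report
  s <- list(n_ncrna = nrow(r),
            n_zero = sum(r$c_value == 0),
            c_value_summary = summary(r$c_value),
            category_totals = colSums(r[c("kegg_value", "bp_value",
                                          "cc_value", "mf_value")]),
            n_terms = nrow(object$terms))
  class(s) <- "summary.pdnt"
  s
}

#' @export
print.summary.pdnt <- function(x, ...) {
  cat(sprintf("C values for %d ncRNAs (%d scoring 0), built from %d pathway terms\n",
              x$n_ncrna, x$n_zero, x$n_terms))
  cat("Total C value distribution:\n")
  print(x$c_value_summary)
  cat("Summed category values across ncRNAs:\n")
  print(round(x$category_totals, 4))
  invisible(x)
}

#' @export
coef.pdnt <- function(object, ...) {
  stats::setNames(object$report$c_value, object$report$ncrna_id)
}

#' @export
plot.pdnt <- function(x, n = 10L, ...) {
  top <- utils::head(x$report, n)
  m <- t(as.matrix(top[c("kegg_value", "bp_value", "cc_value", "mf_value")]))
  colnames(m) <- top$ncrna_id
  op <- graphics::par(mar = c(9, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(m, las = 2, col = c("#777777", "#1b9e77", "#d95f02", "#7570b3"),
                    ylab = "C value",
                    legend.text = c("KEGG", "BP", "CC", "MF"),
                    args.legend = list(x = "topright", bty = "n"), ...)
  invisible(x)
}

#' Total C value from its four category components
#'
#' The total Contribution value of an ncRNA is the plain sum of its BP, CC,
#' MF and KEGG category values (vectorised over rows).
#'
#' @param kegg_value,bp_value,cc_value,mf_value Numeric category values.
#' @return Numeric total C value.
#' @export
total_c_value <- function(kegg_value, bp_value, cc_value, mf_value) {
  kegg_value + bp_value + cc_value + mf_value
}

#' Top-n ncRNAs by C value
#'
#' @param fit A \code{pdnt} fit (or its report data.frame).
#' @param n Number of ids wanted; ties in the total break by ascending id;
#'   fewer than \code{n} rows returns all of them.
#' @return Character vector of ncRNA ids.
#' @export
top_n <- function(fit, n) {
  stopifnot(n >= 1)
  report <- if (inherits(fit, "pdnt")) fit$report else fit
  utils::head(report$ncrna_id, n)
}

#' Write the C-value table
#'
#' Tab-separated columns ncrna_id, kegg_value, bp_value, cc_value, mf_value,
#' c_value; values printed with 4 decimals (internal arithmetic is full
#' precision).
#'
#' @param fit A \code{pdnt} fit.
#' @param path Output path.
#' @param detail_path Optional path for the per-term detail table.
#' @return Invisibly, \code{path}.
#' @export
write_c_value_table <- function(fit, path, detail_path = NULL) {
  stopifnot(inherits(fit, "pdnt"))
  r <- fit$report
  lines <- c("ncrna_id\tkegg_value\tbp_value\tcc_value\tmf_value\tc_value",
             sprintf("%s\t%.4f\t%.4f\t%.4f\t%.4f\t%.4f", r$ncrna_id,
                     r$kegg_value, r$bp_value, r$cc_value, r$mf_value,
                     r$c_value))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writLines_lf(lines, con)
  if (!is.null(detail_path)) {
    t <- fit$terms
    dl <- c("ncrna_id\tcategory\tpathway_id\tproportion\tweight\tcontribution",
            sprintf("%s\t%s\t%s\t%.6g\t%.6g\t%.6g", t$ncrna_id, t$category,
                    t$pathway_id, t$proportion, t$weight, t$contribution))
    con2 <- file(detail_path, open = "wb")
    on.exit(close(con2), add = TRUE)
    writLines_lf(dl, con2)
  }
  invisible(path)
}
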