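# Identifier normalization: matching across files is exact string equality
# after upper-casing and whitespace stripping; no alias resolution.
normalize_ids <- function(x, what = "gene id") {
  x <- toupper(trimws(as.character(x)))
  if (any(!nzchar(x))) {
    stop(sprintf("empty %s encountered", what), call. = FALSE)
  }
  if (any(grepl("[[:space:]]", x))) {
    stop(sprintf("%s with internal whitespace: %s", what,
                 paste(utils::head(x[grepl("[[:space:]]", x)], 3), collapse = ", ")),
         call. = FALSE)
  }
  x
}

#' Construct a gene-set collection
#'
#' A gene-set collection holds pathways of one category (typically one of the
#' three Gene Ontology branches \code{"BP"}, \code{"CC"}, \code{"MF"}, the
#' KEGG pathway database \code{"KEGG"}, or any custom label). Gene symbols are
#' upper-cased and de-duplicated; pathways and their member genes are stored
#' in sorted order so that two collections built from row-permuted inputs are
#' identical objects.
#'
#' @param pathways Named list; each element a character vector of member genes,
#'   names are pathway ids.
#' @param category Single category label, e.g. \code{"BP"}.
#' @param descriptions Optional named character vector of display names; the
#'   pathway id is used where missing.
#' @return An object of class \code{"gene_set_collection"}.
#' @examples
#' gsc <- gene_set_collection(list(PW1 = c("g1", "g2")), category = "KEGG")
#' @export
gene_set_collection <- function(pathways, category = "custom", descriptions = NULL) {
  if (length(pathways) == 0) {
    pathways <- stats::setNames(list(), character())
  }
  ids <- normalize_ids(names(pathways), "pathway id")
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(pathways, function(g) sort(unique(normalize_ids(g))))
  if (any(lengths(sets) == 0) && length(sets)) {
    stop("every pathway must contain at least one gene", call. = FALSE)
  }
  names(sets) <- ids
  desc <- stats::setNames(ids, ids)
  if (!is.null(descriptions)) {
    dn <- normalize_ids(names(descriptions), "pathway id")
    desc[dn[dn %in% ids]] <- as.character(descriptions)[dn %in% ids]
  }
  ord <- order(ids)
  structure(list(category = as.character(category)[1],
                 pathways = sets[ord],
                 descriptions = desc[ord]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection [%s]: %d pathways, %d distinct genes\n",
              x$category, length(x$pathways),
              length(unique(unlist(x$pathways, use.names = FALSE)))))
  invisible(x)
}

#' Genes annotated to at least one pathway of a collection
#' @param collection A \code{gene_set_collection}.
#' @return Sorted character vector of gene ids.
#' @export
annotated_genes <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  sort(unique(unlist(collection$pathways, use.names = FALSE)))
}

#' Read a GMT gene-set file
#'
#' GMT is the standard tab-separated carrier for GO/KEGG gene sets: one
#' pathway per line with fields set-id, description, then member genes.
#'
#' @param path File path.
#' @param category Category label attached to the collection.
#' @return A \code{gene_set_collection}.
#' @export
read_gmt <- function(path, category = "custom") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(gene_set_collection(list(), category = category))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("GMT format error: line %d has fewer than 3 tab-separated fields",
                 short[1]), call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(toupper(trimws(ids)))) {
    stop("GMT format error: duplicate set id(s): ",
         paste(unique(ids[duplicated(toupper(trimws(ids)))]), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- ids
  desc <- stats::setNames(vapply(fields, `[[`, character(1), 2L), ids)
  gene_set_collection(sets, category = category, descriptions = desc)
}

#' Write a gene-set collection to GMT
#'
#' Output is stable: pathways in sorted id order and genes in sorted order, so
#' two writes of the same collection are byte-identical.
#'
#' @param collection A \code{gene_set_collection}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  ids <- names(collection$pathways)
  lines <- vapply(ids, function(id) {
    paste(c(id, collection$descriptions[[id]], collection$pathways[[id]]),
          collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writLines_lf(lines, con)
  invisible(path)
}

# writeLines with fixed "\n" separator regardless of platform
writLines_lf <- function(lines, con) {
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

#' Read a differential-expression table
#'
#' Reads a tab-separated table with a header row and extracts feature id,
#' log2 fold change and p-value columns. Rows whose log2FC or p cell is
#' missing or unparseable are dropped with a warning reporting the count;
#' p-values outside (0, 1] are an error, never clamped.
#'
#' @param path File path.
#' @param id_col,lfc_col,p_col Column names for feature id, log2 fold change
#'   and p-value.
#' @return A \code{data.frame} of class \code{"diff_table"} with columns
#'   \code{feature_id}, \code{log2fc}, \code{p_value}, sorted by feature id.
#' @export
read_differential_table <- function(path, id_col = "id", lfc_col = "log2fc",
                                    p_col = "p_value") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing_cols <- setdiff(c(id_col, lfc_col, p_col), names(df))
  if (length(missing_cols)) {
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  diff_table(df[[id_col]],
             suppressWarnings(as.numeric(df[[lfc_col]])),
             suppressWarnings(as.numeric(df[[p_col]])),
             drop_incomplete = TRUE)
}

#' Construct a differential-expression table
#'
#' @param feature_id Character vector of feature ids (genes or ncRNAs).
#' @param log2fc Numeric log2 fold changes (finite).
#' @param p_value Numeric p-values in (0, 1].
#' @param drop_incomplete Drop rows with NA log2fc/p (with a warning) instead
#'   of erroring.
#' @return A \code{data.frame} of class \code{"diff_table"}.
#' @export
diff_table <- function(feature_id, log2fc, p_value, drop_incomplete = FALSE) {
  log2fc <- as.numeric(log2fc)
  p_value <- as.numeric(p_value)
  keep <- rep(TRUE, length(feature_id))
  bad <- is.na(log2fc) | is.na(p_value) | is.infinite(log2fc)
  if (any(bad)) {
    if (!drop_incomplete) stop("non-finite log2fc or missing p-value", call. = FALSE)
    warning(sprintf("dropped %d row(s) with missing/unparseable log2fc or p-value",
                    sum(bad)), call. = FALSE)
    keep <- !bad
  }
  ids <- normalize_ids(feature_id[keep], "feature id")
  log2fc <- log2fc[keep]
  p_value <- p_value[keep]
  if (any(p_value <= 0 | p_value > 1)) {
    stop("p-value(s) outside (0, 1] for: ",
         paste(utils::head(ids[p_value <= 0 | p_value > 1], 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  ord <- order(ids)
  structure(data.frame(feature_id = ids[ord], log2fc = log2fc[ord],
                       p_value = p_value[ord], stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("diff_table", "data.frame"))
}

#' Construct an ncRNA-to-target map
#'
#' @param pairs A \code{data.frame} (or list) with columns/elements
#'   \code{ncrna_id}, \code{gene_id} and optional \code{score}. Duplicate
#'   (ncRNA, gene) pairs collapse to one, keeping the maximum score.
#' @param ncrna_ids Optional character vector of ncRNA ids that must appear in
#'   the map even with empty target sets.
#' @return An object of class \code{"target_map"}: a named list of sorted gene
#'   vectors with, when scores are given, a \code{"scores"} attribute (named
#'   list of per-gene scores).
#' @export
target_map <- function(pairs, ncrna_ids = NULL) {
  sc <- NULL
  if (is.null(pairs) || NROW(pairs) == 0) {
    tm <- stats::setNames(list(), character())
  } else {
    nc <- normalize_ids(pairs$ncrna_id, "ncRNA id")
    g <- normalize_ids(pairs$gene_id, "gene id")
    has_score <- !is.null(pairs$score)
    if (has_score) {
      score <- as.numeric(pairs$score)
      # multiple predicted sites for one pair: keep the best score
      agg <- stats::aggregate(score, list(ncrna = nc, gene = g), max)
      nc <- agg$ncrna; g <- agg$gene; score <- agg$x
    } else {
      keep <- !duplicated(paste0(nc, "\r", g))
      nc <- nc[keep]; g <- g[keep]
    }
    ord <- order(nc, g)
    nc <- nc[ord]; g <- g[ord]
    tm <- split(g, factor(nc, levels = unique(nc)))
    tm <- lapply(tm, as.character)
    if (has_score) {
      score <- score[ord]
      sc <- split(score, factor(nc, levels = unique(nc)))
      sc <- Map(function(s, gg) stats::setNames(s, gg), sc, tm)
    }
  }
  if (!is.null(ncrna_ids)) {
    ncrna_ids <- normalize_ids(ncrna_ids, "ncRNA id")
    missing <- setdiff(ncrna_ids, names(tm))
    for (id in missing) {
      tm[[id]] <- character()
      if (!is.null(sc)) sc[[id]] <- stats::setNames(numeric(), character())
    }
  }
  tm <- tm[order(names(tm))]
  if (!is.null(sc)) attr(tm, "scores") <- sc[names(tm)]
  class(tm) <- "target_map"
  tm
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("Target map: %d ncRNAs, %d pairs\n", length(x),
              sum(lengths(unclass(x)))))
  invisible(x)
}

#' Read an ncRNA-to-target pair list
#'
#' Tab-separated rows \code{ncRNA-id <TAB> gene-id [<TAB> score]}, e.g. parsed
#' miRanda output. Duplicate pairs collapse (keeping the best score).
#'
#' @param path File path. A header row is detected when the third field of the
#'   first line is non-numeric while later ones are numeric; plain two-column
#'   files never have a header stripped unless it equals
#'   \code{ncrna_id<TAB>gene_id}.
#' @return A \code{target_map}.
#' @export
read_target_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(target_map(NULL))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop(sprintf("target-map format error: line %d has fewer than 2 fields",
                 which(lengths(fields) < 2L)[1]), call. = FALSE)
  }
  first <- fields[[1]]
  is_header <- identical(toupper(first[1:2]), c("NCRNA_ID", "GENE_ID"))
  if (is_header) fields <- fields[-1]
  if (length(fields) == 0) return(target_map(NULL))
  nc <- vapply(fields, `[[`, character(1), 1L)
  g <- vapply(fields, `[[`, character(1), 2L)
  has_score <- all(lengths(fields) >= 3L)
  if (has_score) {
    sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    if (anyNA(sc)) has_score <- FALSE
  }
  if (has_score) {
    target_map(data.frame(ncrna_id = nc, gene_id = g, score = sc,
                          stringsAsFactors = FALSE))
  } else {
    target_map(data.frame(ncrna_id = nc, gene_id = g, stringsAsFactors = FALSE))
  }
}

#' Write a target map as a tab-separated pair list
#' @param map A \code{target_map}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_target_map <- function(map, path) {
  stopifnot(inherits(map, "target_map"))
  scores <- attr(map, "scores")
  lines <- character()
  for (id in names(map)) {
    genes <- map[[id]]
    if (!length(genes)) next
    if (!is.null(scores)) {
      lines <- c(lines, sprintf("%s\t%s\t%g", id, genes, scores[[id]][genes]))
    } else {
      lines <- c(lines, sprintf("%s\t%s", id, genes))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writLines_lf(lines, con)
  invisible(path)
}

#' Construct an undirected protein-protein interaction network
#'
#' Self-loops are dropped, edges are de-duplicated after canonicalizing each
#' pair into lexicographic order, so \{a,b\} and \{b,a\} are one edge.
#'
#' @param from,to Character vectors of endpoint ids.
#' @param score Optional numeric confidence score per edge (max kept on
#'   duplicates).
#' @param nodes Optional additional node ids (isolated nodes allowed); the
#'   node set is always the union with the edge endpoints.
#' @return Object of class \code{"ppi_network"}: list with \code{nodes}
#'   (sorted) and \code{edges} (data.frame \code{a}, \code{b}, optional
#'   \code{score}, sorted).
#' @export
ppi_network <- function(from, to, score = NULL, nodes = NULL) {
  from <- normalize_ids(from, "protein id")
  to <- normalize_ids(to, "protein id")
  if (!is.null(nodes)) nodes <- normalize_ids(nodes, "protein id")
  stopifnot(length(from) == length(to))
  keep <- from != to
  from2 <- pmin(from[keep], to[keep])
  to2 <- pmax(from[keep], to[keep])
  if (!is.null(score)) {
    score <- as.numeric(score)[keep]
    if (length(from2)) {
      agg <- stats::aggregate(score, list(a = from2, b = to2), max)
      edges <- data.frame(a = agg$a, b = agg$b, score = agg$x,
                          stringsAsFactors = FALSE)
    } else {
      edges <- data.frame(a = character(), b = character(), score = numeric(),
                          stringsAsFactors = FALSE)
    }
  } else {
    dup <- duplicated(paste0(from2, "\r", to2))
    edges <- data.frame(a = from2[!dup], b = to2[!dup], stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  row.names(edges) <- NULL
  structure(list(nodes = sort(unique(c(from, to, nodes))), edges = edges),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a STRING-style edge list
#'
#' Tab-separated rows \code{protein-a <TAB> protein-b [<TAB> combined-score]}.
#'
#' @param path File path.
#' @param score_threshold When given, edges with score below it are dropped
#'   (STRING combined scores are conventionally 0-1000).
#' @return A \code{ppi_network}.
#' @export
read_edge_list <- function(path, score_threshold = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(ppi_network(character(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop(sprintf("edge-list format error: line %d has fewer than 2 fields",
                 which(lengths(fields) < 2L)[1]), call. = FALSE)
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  sc <- NULL
  if (all(lengths(fields) >= 3L)) {
    sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    if (anyNA(sc)) sc <- NULL
  }
  if (!is.null(score_threshold)) {
    if (is.null(sc)) {
      stop("score_threshold given but the edge list has no score column",
           call. = FALSE)
    }
    keep <- sc >= score_threshold
    a <- a[keep]; b <- b[keep]; sc <- sc[keep]
  }
  ppi_network(a, b, sc)
}

#' Write a PPI network as an edge list
#' @param network A \code{ppi_network}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "ppi_network"))
  e <- network$edges
  lines <- if ("score" %in% names(e)) {
    sprintf("%s\t%s\t%g", e$a, e$b, e$score)
  } else {
    sprintf("%s\t%s", e$a, e$b)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writLines_lf(lines, con)
  invisible(path)
}

#' Read an expression matrix
#'
#' Tab-separated features x samples table: header row of sample ids, first
#' column feature ids.
#'
#' @param path File path.
#' @return Numeric matrix with feature ids as row names (upper-cased) and
#'   sample ids as column names.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  rownames(m) <- normalize_ids(rownames(m), "feature id")
  if (anyDuplicated(rownames(m))) stop("duplicate feature ids", call. = FALSE)
  m
}

#' Write an expression matrix
#' @param m Numeric matrix (features x samples) with dimnames.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_expression_matrix <- function(m, path) {
  lines <- c(paste(c("feature_id", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], format(m[i, ], digits = 15, trim = TRUE,
                                              scientific = FALSE)),
                     collapse = "\t")
             }, character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writLines_lf(lines, con)
  invisible(path)
}
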