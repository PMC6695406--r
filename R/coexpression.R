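# Tissue averaging, cross-tissue Pearson correlation, edge selection and
# focal-class subsetting.

#' Average expression by grouped tissue
#'
#' @param expr Expression matrix (genes x samples).
#' @param design Sample design with a \code{group} column of grouped tissue
#'   labels covering every sample.
#' @return Tissue profile matrix (genes x grouped tissues, tissues in
#'   lexicographic order), entries are arithmetic means over the tissue's
#'   samples.
#' @export
average_by_tissue <- function(expr, design) {
  validate_expression(expr)
  validate_design(design, expr)
  if (is.null(design$group)) design$group <- design$tissue
  groups <- design$group[match(colnames(expr), design$sample)]
  tissues <- sort(unique(groups), method = "radix")
  prof <- vapply(tissues, function(t)
    rowMeans(expr[, groups == t, drop = FALSE]), numeric(nrow(expr)))
  dimnames(prof) <- list(rownames(expr), tissues)
  prof
}

#' Cross-tissue Pearson correlation
#'
#' Correlates genes over the tissue dimension, so r measures the tendency of
#' two genes to be expressed in similar sets of tissues. Zero-variance genes
#' yield undefined correlations (NA), are reported via a message and are
#' excluded from edge selection downstream.
#'
#' @param profile Tissue profile matrix (genes x tissues); a sample-level
#'   expression matrix may be passed to correlate over samples instead.
#' @param genes Optional gene subset; an absent gene is an error.
#' @param log_transform Apply log2(x + 1) before correlating?
#' @return Symmetric correlation matrix with unit diagonal where defined.
#' @export
cross_tissue_correlation <- function(profile, genes = NULL,
                                     log_transform = FALSE) {
  if (ncol(profile) < 3L)
    stop("need at least 3 tissues to correlate across tissues")
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(profile))
    if (length(missing))
      stop("gene(s) absent from profile: ", paste(missing, collapse = ", "))
    profile <- profile[genes, , drop = FALSE]
  }
  x <- t(profile)
  if (isTRUE(log_transform)) x <- log2(x + 1)
  sds <- apply(x, 2L, stats::sd)
  zero_var <- sds == 0 | !is.finite(sds)
  if (any(zero_var))
    message(sum(zero_var), " zero-variance gene(s) have undefined correlation")
  r <- suppressWarnings(stats::cor(x))
  r[zero_var, ] <- NA_real_
  r[, zero_var] <- NA_real_
  diag(r)[!zero_var] <- 1
  r
}

#' Select network edges from a correlation matrix
#'
#' In \code{top_k} mode the k highest defined off-diagonal pairs are kept,
#' ordered by descending r with ties broken by lexicographic gene pair; if
#' ties straddle the cut-off, all pairs tied with the k-th are included and
#' the realized edge count is reported via a message. In \code{threshold}
#' mode all pairs with r strictly above the cutoff are kept.
#'
#' @param corr Correlation matrix.
#' @param mode \code{"top_k"} or \code{"threshold"}.
#' @param value Edge count k (positive) or correlation cutoff in (-1, 1).
#' @return Data frame (gene1, gene2, r), gene1 < gene2 within each row,
#'   sorted by descending r then lexicographic pair.
#' @export
select_edges <- function(corr, mode = c("top_k", "threshold"), value) {
  mode <- match.arg(mode)
  if (mode == "top_k" && value < 1) stop("k must be a positive integer")
  if (mode == "threshold" && (value <= -1 || value >= 1))
    stop("threshold must lie in (-1, 1)")
  genes <- rownames(corr)
  ut <- upper.tri(corr)
  idx <- which(ut & !is.na(corr), arr.ind = TRUE)
  pc <- pair_canonical(genes[idx[, 1L]], genes[idx[, 2L]])
  ed <- data.frame(gene1 = pc$lo, gene2 = pc$hi, r = corr[idx],
                   stringsAsFactors = FALSE)
  ed <- ed[order(-ed$r, ed$gene1, ed$gene2, method = "radix"), , drop = FALSE]
  if (mode == "threshold") {
    ed <- ed[ed$r > value, , drop = FALSE]
  } else if (nrow(ed) > value) {
    rk <- ed$r[value]
    keep <- ed$r > rk | ed$r == rk
    ed <- ed[keep, , drop = FALSE]
    if (nrow(ed) != value)
      message("ties at the top-k boundary: realized k = ", nrow(ed))
  }
  rownames(ed) <- NULL
  ed
}

#' Restrict a correlation matrix to genes of given classes
#'
#' @param corr Correlation matrix.
#' @param catalog Gene-set catalog.
#' @param classes Character vector of classes to retain.
#' @return Correlation sub-matrix over the retained genes (intersection of
#'   class members and matrix genes); empty result is an error.
#' @export
subset_correlation <- function(corr, catalog, classes = FOCAL_CLASSES) {
  keep <- catalog$gene[catalog$class %in% classes]
  genes <- intersect(rownames(corr), keep)
  if (!length(genes))
    stop("no genes of class ", paste(classes, collapse = "/"),
         " present in the correlation matrix")
  message(length(genes), " gene(s) retained after class subsetting")
  corr[genes, genes, drop = FALSE]
}

#' Build a co-expression network from selected edges
#'
#' Nodes are the union of edge endpoints (catalog genes without any edge are
#' not added); node attributes class, family and adme_status come from the
#' catalog (genes absent from the catalog get class "other", family "none",
#' status "none"); the edge attribute \code{correlation} carries r.
#'
#' @param edges Edge data frame from [select_edges()].
#' @param catalog Gene-set catalog.
#' @return Undirected igraph object.
#' @export
build_network <- function(edges, catalog = NULL) {
  if (nrow(edges) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(g)
  }
  ed <- data.frame(from = edges$gene1, to = edges$gene2,
                   correlation = edges$r, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  nodes <- igraph::V(g)$name
  if (!is.null(catalog)) {
    m <- match(nodes, catalog$gene)
    igraph::V(g)$class <- ifelse(is.na(m), "other", catalog$class[m])
    igraph::V(g)$family <- ifelse(is.na(m), "none", catalog$family[m])
    igraph::V(g)$adme_status <- ifelse(is.na(m), "none",
                                       catalog$adme_status[m])
  }
  g
}
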