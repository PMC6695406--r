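# Tissue assignment of genes and edges, cluster proximity matrix with
# hierarchical ordering, and the gut-liver-kidney edge-fraction statistic
# with control sampling.

#' Assign each gene its tissue of highest mean expression
#'
#' Ties are broken by lexicographic tissue label. All-zero genes get the
#' label \code{"undetermined"} with a warning; they are excluded from
#' proximity counts downstream.
#'
#' @param profile Tissue profile matrix (genes x grouped tissues).
#' @param genes Optional subset of genes (default: all).
#' @return Named character vector gene -> tissue label.
#' @export
assign_gene_tissue <- function(profile, genes = NULL) {
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(profile))
    if (length(missing))
      stop("gene(s) absent from profile: ", paste(missing, collapse = ", "))
    profile <- profile[genes, , drop = FALSE]
  }
  ts <- sort(colnames(profile), method = "radix")
  m <- profile[, ts, drop = FALSE]
  lab <- ts[max.col(m, ties.method = "first")]
  allzero <- rowSums(m != 0) == 0
  if (any(allzero)) {
    warning(sum(allzero), " all-zero gene(s) assigned 'undetermined'")
    lab[allzero] <- "undetermined"
  }
  stats::setNames(lab, rownames(profile))
}

#' Assign edges the tissue of highest average endpoint expression
#'
#' For each edge the assigned tissue is the argmax over tissues of the
#' unweighted mean of the two endpoints' tissue means (ties lexicographic).
#' If the argmax tissue is outside \code{focus_tissues} the label is
#' \code{"other"}; the true argmax is always returned alongside so focus
#' lists can change without recomputation.
#'
#' @param profile Tissue profile matrix.
#' @param gene1,gene2 Endpoint vectors (recycled together).
#' @param focus_tissues Grouped tissue labels of interest, or NULL to keep
#'   the raw argmax as the label.
#' @return Data frame with columns \code{tissue} (focus label or "other")
#'   and \code{tissue_raw} (the argmax).
#' @export
assign_edge_tissue <- function(profile, gene1, gene2,
                               focus_tissues = c("gut", "liver", "kidney")) {
  missing <- setdiff(unique(c(gene1, gene2)), rownames(profile))
  if (length(missing))
    stop("gene(s) absent from profile: ", paste(missing, collapse = ", "))
  ts <- sort(colnames(profile), method = "radix")
  m <- profile[, ts, drop = FALSE]
  pair_mean <- (m[gene1, , drop = FALSE] + m[gene2, , drop = FALSE]) / 2
  raw <- ts[max.col(pair_mean, ties.method = "first")]
  allzero <- rowSums(pair_mean != 0) == 0
  if (any(allzero)) {
    warning(sum(allzero), " all-zero edge pair(s) assigned 'undetermined'")
    raw[allzero] <- "undetermined"
  }
  lab <- raw
  if (!is.null(focus_tissues)) lab[!(lab %in% focus_tissues)] <- "other"
  data.frame(tissue = lab, tissue_raw = raw, stringsAsFactors = FALSE)
}

#' Label a network's edges and nodes with tissue assignments
#'
#' Sets the vertex attribute \code{tissue} (gene argmax tissue) and edge
#' attributes \code{tissue} / \code{tissue_raw} (pair-mean argmax, bucketed
#' to "other" outside the focus list).
#'
#' @param net igraph network.
#' @param profile Tissue profile matrix covering all network genes.
#' @param focus_tissues Focus tissue labels (NULL keeps raw labels).
#' @return The annotated igraph object.
#' @export
annotate_tissues <- function(net, profile,
                             focus_tissues = c("gut", "liver", "kidney")) {
  nodes <- igraph::V(net)$name
  igraph::V(net)$tissue <- unname(assign_gene_tissue(profile, nodes))
  if (igraph::ecount(net) > 0) {
    el <- igraph::as_edgelist(net)
    lab <- assign_edge_tissue(profile, el[, 1L], el[, 2L], focus_tissues)
    igraph::E(net)$tissue <- lab$tissue
    igraph::E(net)$tissue_raw <- lab$tissue_raw
  }
  net
}

#' Cluster proximity matrix
#'
#' Counts network edges by the tissue assignment of their endpoints: entry
#' (t1, t2) is the number of edges with endpoint tissues \{t1, t2\}, each
#' edge counted once; the diagonal holds within-tissue edges. Genes labeled
#' \code{"undetermined"} are excluded.
#'
#' @param net igraph network.
#' @param assignment Named gene -> tissue vector covering network genes
#'   (defaults to the \code{tissue} vertex attribute).
#' @return Symmetric integer matrix, tissues in lexicographic order. The
#'   upper triangle plus diagonal sums to the number of counted edges.
#' @export
cluster_proximity <- function(net, assignment = NULL) {
  if (is.null(assignment))
    assignment <- stats::setNames(igraph::V(net)$tissue, igraph::V(net)$name)
  nodes <- igraph::V(net)$name
  missing <- setdiff(nodes, names(assignment))
  if (length(missing))
    stop("no tissue assignment for gene(s): ", paste(missing, collapse = ", "))
  tissues <- sort(setdiff(unique(assignment[nodes]), "undetermined"),
                  method = "radix")
  prox <- matrix(0L, length(tissues), length(tissues),
                 dimnames = list(tissues, tissues))
  if (igraph::ecount(net) == 0) return(prox)
  el <- igraph::as_edgelist(net)
  t1 <- assignment[el[, 1L]]
  t2 <- assignment[el[, 2L]]
  ok <- t1 != "undetermined" & t2 != "undetermined"
  lo <- pmin(t1[ok], t2[ok])
  hi <- pmax(t1[ok], t2[ok])
  for (i in seq_along(lo)) {
    prox[lo[i], hi[i]] <- prox[lo[i], hi[i]] + 1L
    if (lo[i] != hi[i]) prox[hi[i], lo[i]] <- prox[hi[i], lo[i]] + 1L
  }
  prox
}

#' Hierarchically order tissues by proximity-profile similarity
#'
#' Agglomerative clustering with average linkage on the distance
#' 1 - Pearson correlation between tissue rows of the proximity matrix.
#' A constant (zero-variance) row has undefined correlation; its distance to
#' every other tissue is set to the maximum 2.0, with a message.
#'
#' @param prox Proximity matrix from [cluster_proximity()] (>= 2 tissues).
#' @return List with \code{order} (tissue labels in dendrogram leaf order)
#'   and \code{tree} (the \code{hclust} object).
#' @export
hierarchical_order <- function(prox) {
  n <- nrow(prox)
  if (n < 2L) stop("need at least 2 tissues to order")
  sds <- apply(prox, 1L, stats::sd)
  const <- sds == 0
  if (any(const))
    message(sum(const), " constant proximity row(s); distance set to 2.0")
  r <- suppressWarnings(stats::cor(t(prox)))
  d <- 1 - r
  d[const, ] <- 2
  d[, const] <- 2
  diag(d) <- 0
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  list(order = rownames(prox)[tree$order], tree = tree)
}

#' Fraction of top co-expression edges assigned to target tissues
#'
#' Takes the top-k edges among pairs of the focal gene set (from the full
#' correlation matrix) and measures what fraction have their pair-mean
#' argmax tissue in \code{target_tissues}.
#'
#' @param corr_full Correlation matrix over the full gene universe.
#' @param focal Focal gene set (must be present in \code{corr_full}).
#' @param k Number of top edges to take.
#' @param profile Tissue profile matrix.
#' @param target_tissues Tissues counted as hits (default gut/liver/kidney).
#' @return List with \code{fraction} and \code{n_edges} (realized count).
#' @export
focal_edge_fraction <- function(corr_full, focal, k, profile,
                                target_tissues = c("gut", "liver", "kidney")) {
  missing <- setdiff(focal, rownames(corr_full))
  if (length(missing))
    stop("focal gene(s) absent from correlation matrix: ",
         paste(missing, collapse = ", "))
  if (k < 1) stop("k must be >= 1")
  sub <- corr_full[focal, focal, drop = FALSE]
  if (all(is.na(sub[upper.tri(sub)])))
    stop("no defined focal gene pair")
  ed <- suppressMessages(select_edges(sub, "top_k", k))
  lab <- assign_edge_tissue(profile, ed$gene1, ed$gene2,
                            focus_tissues = NULL)
  list(fraction = mean(lab$tissue_raw %in% target_tissues),
       n_edges = nrow(ed))
}

#' Edge fractions of size-matched random control gene sets
#'
#' Draws \code{reps} uniform without-replacement samples of \code{size}
#' genes from \code{pool}, computes [focal_edge_fraction()] for each, and
#' returns the mean and population standard deviation, as used for control
#' error bars over a fixed small number of replicates.
#'
#' @param corr_full Correlation matrix over the full gene universe.
#' @param pool Gene pool to sample from (e.g. all non-focal genes, or a
#'   GPCR-like control class).
#' @param size Sample size (must not exceed the pool size).
#' @param k Number of top edges per sample.
#' @param reps Number of replicates (default 10).
#' @param seed Integer seed.
#' @param profile Tissue profile matrix.
#' @param target_tissues Tissues counted as hits.
#' @return List with \code{mean}, \code{sd} (population), \code{samples}
#'   (per-replicate fractions), \code{reps}, \code{seed}.
#' @export
control_fractions <- function(corr_full, pool, size, k, reps = 10L, seed = 1L,
                              profile,
                              target_tissues = c("gut", "liver", "kidney")) {
  if (size > length(pool))
    stop("sample size ", size, " exceeds pool size ", length(pool))
  set.seed(seed)
  fr <- vapply(seq_len(reps), function(i) {
    g <- sample(pool, size)
    focal_edge_fraction(corr_full, g, k, profile, target_tissues)$fraction
  }, numeric(1))
  m <- mean(fr)
  list(mean = m, sd = sqrt(mean((fr - m)^2)), samples = fr,
       reps = as.integer(reps), seed = as.integer(seed))
}
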