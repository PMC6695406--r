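# Betweenness centrality and degree tables, and the family-level network
# with hypergeometric edge-enrichment scores.

#' Betweenness centrality table
#'
#' Unweighted shortest-path betweenness, normalized per node by
#' (n-1)(n-2)/2 (the undirected convention), so values lie in [0, 1].
#' Isolated nodes score 0; graphs with fewer than 3 nodes are all zero.
#'
#' @param net Undirected igraph network.
#' @return Data frame (gene, betweenness, degree), descending betweenness,
#'   ties by gene id.
#' @export
betweenness_table <- function(net) {
  n <- igraph::vcount(net)
  genes <- igraph::V(net)$name
  if (n < 3L) {
    bt <- rep(0, n)
  } else {
    bt <- igraph::betweenness(net, directed = FALSE, normalized = TRUE)
  }
  deg <- igraph::degree(net)
  out <- data.frame(gene = genes, betweenness = unname(bt),
                    degree = as.integer(unname(deg)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$betweenness, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Degree table with high-degree report
#'
#' @param net igraph network.
#' @param threshold Degree cutoff for the high-degree report (default 30;
#'   genes with degree strictly greater are reported).
#' @return List with \code{table} (gene, degree; descending) and
#'   \code{high_degree} (the subset with degree > threshold).
#' @export
degree_table <- function(net, threshold = 30L) {
  deg <- igraph::degree(net)
  out <- data.frame(gene = igraph::V(net)$name,
                    degree = as.integer(unname(deg)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  list(table = out, high_degree = out[out$degree > threshold, , drop = FALSE])
}

#' Family/group label per gene
#'
#' SLC and ABC genes are grouped by their family; Phase 1 and Phase 2 DMEs
#' are pooled into the groups \code{"DME_phase1"} / \code{"DME_phase2"}.
#'
#' @param catalog Gene-set catalog.
#' @return Named character vector gene -> group.
#' @export
family_grouping <- function(catalog) {
  grp <- ifelse(catalog$class %in% c("DME_phase1", "DME_phase2"),
                catalog$class, catalog$family)
  stats::setNames(grp, catalog$gene)
}

#' Count network edges between gene families/groups
#'
#' @param net igraph network whose genes are all covered by the grouping.
#' @param grouping Named gene -> group vector from [family_grouping()].
#' @return Symmetric integer matrix of edge counts; the diagonal holds
#'   within-group counts. Upper triangle plus diagonal sums to the edge
#'   count of the gene network.
#' @export
family_edge_counts <- function(net, grouping) {
  nodes <- igraph::V(net)$name
  missing <- setdiff(nodes, names(grouping))
  if (length(missing))
    stop("gene(s) with no family/group: ", paste(missing, collapse = ", "))
  groups <- sort(unique(grouping[nodes]), method = "radix")
  counts <- matrix(0L, length(groups), length(groups),
                   dimnames = list(groups, groups))
  if (igraph::ecount(net) == 0) return(counts)
  el <- igraph::as_edgelist(net)
  f1 <- grouping[el[, 1L]]
  f2 <- grouping[el[, 2L]]
  lo <- pmin(f1, f2)
  hi <- pmax(f1, f2)
  for (i in seq_along(lo)) {
    counts[lo[i], hi[i]] <- counts[lo[i], hi[i]] + 1L
    if (lo[i] != hi[i]) counts[hi[i], lo[i]] <- counts[hi[i], lo[i]] + 1L
  }
  counts
}

#' Hypergeometric edge-enrichment score between two families
#'
#' Conditioned on the realized network (E edges among N possible gene
#' pairs), the number of edges X falling between family A and family B is
#' hypergeometric with population N, K "success" pairs (sizeA * sizeB
#' across families, or choose(sizeA, 2) within one family), and E draws.
#' The score is -log10 P(X >= x), computed through the survival function in
#' log space for numerical stability; a score of 2 corresponds to p < 0.01.
#'
#' @param x Observed edge count between the families.
#' @param sizeA,sizeB Family sizes (node counts in the network).
#' @param E Total edges in the gene network.
#' @param N Total possible gene pairs, choose(n_nodes, 2).
#' @param within Is this a within-family count? (uses K = choose(sizeA, 2)).
#' @return Non-negative score; 0 when x = 0.
#' @export
family_hyper_score <- function(x, sizeA, sizeB = sizeA, E, N,
                               within = FALSE) {
  K <- if (within) choose(sizeA, 2L) else sizeA * sizeB
  if (E > N) stop("edge count E exceeds the number of possible pairs N")
  if (x > K) stop("observed count x exceeds the number of eligible pairs K")
  if (x > E) stop("observed count x exceeds the total edge count E")
  if (x <= 0) return(0)
  lp <- stats::phyper(x - 1, K, N - K, E, lower.tail = FALSE, log.p = TRUE)
  -lp / log(10)
}

#' Build the family-level network
#'
#' Computes hypergeometric scores for every family pair from the count
#' matrix and retains an edge iff its score exceeds the threshold. Node
#' attribute \code{sig_degree} counts retained incident edges; betweenness
#' over the family network is also computed. Within-family counts are
#' scored but excluded from the displayed network by default.
#'
#' @param counts Count matrix from [family_edge_counts()].
#' @param family_sizes Named vector group -> number of network genes.
#' @param E Total edges in the gene network.
#' @param N Total possible gene pairs in the gene network.
#' @param score_threshold Display cutoff (default 2.0, i.e. p < 0.01).
#' @param include_within Also admit within-family edges (self-loops are
#'   never drawn; the within scores stay in the table either way)?
#' @return List: \code{graph} (igraph over families), \code{table} (all
#'   pairs with count, score, within flag, retained flag) and
#'   \code{betweenness} (family betweenness table).
#' @export
build_family_network <- function(counts, family_sizes, E, N,
                                 score_threshold = 2.0,
                                 include_within = FALSE) {
  groups <- rownames(counts)
  missing <- setdiff(groups, names(family_sizes))
  if (length(missing))
    stop("no size for group(s): ", paste(missing, collapse = ", "))
  pairs <- which(upper.tri(counts, diag = TRUE), arr.ind = TRUE)
  tab <- data.frame(
    family1 = groups[pairs[, 1L]],
    family2 = groups[pairs[, 2L]],
    count = counts[pairs],
    within = pairs[, 1L] == pairs[, 2L],
    stringsAsFactors = FALSE)
  tab$score <- vapply(seq_len(nrow(tab)), function(i)
    family_hyper_score(tab$count[i],
                       family_sizes[[tab$family1[i]]],
                       family_sizes[[tab$family2[i]]],
                       E, N, within = tab$within[i]), numeric(1))
  tab$retained <- tab$score > score_threshold &
    (!tab$within | include_within)
  keep <- tab[tab$retained & !tab$within, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = keep$family1, to = keep$family2,
               edge_count = keep$count, hyper_score = keep$score,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = groups, size = unname(family_sizes[groups]),
                          stringsAsFactors = FALSE))
  igraph::V(g)$sig_degree <- igraph::degree(g)
  list(graph = g, table = tab, betweenness = betweenness_table(g))
}
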