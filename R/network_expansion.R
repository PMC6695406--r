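# Ranking non-focal genes by single- and paired-tissue connectivity,
# network expansion, and protein-protein interaction filtering.

#' Per-tissue connection counts of candidate genes
#'
#' For every candidate gene, counts how many focal genes assigned to each
#' focus tissue it is connected to under the adjacency rule (correlation
#' strictly above the threshold). Candidates must be disjoint from the
#' focal genes.
#'
#' @param corr_full Correlation matrix over the full gene universe.
#' @param glk_genes_by_tissue Named list tissue -> character vector of focal
#'   genes assigned to that tissue.
#' @param candidates Candidate gene vector.
#' @param threshold Correlation cutoff defining adjacency (default 0.59,
#'   the same regime as the main network).
#' @return Integer matrix, candidates x tissues.
#' @export
tissue_connection_counts <- function(corr_full, glk_genes_by_tissue,
                                     candidates, threshold = 0.59) {
  overlap <- intersect(candidates, unlist(glk_genes_by_tissue))
  if (length(overlap))
    stop("candidates must be disjoint from focal genes: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  tissues <- names(glk_genes_by_tissue)
  counts <- vapply(tissues, function(t) {
    genes <- intersect(glk_genes_by_tissue[[t]], colnames(corr_full))
    if (!length(genes)) return(integer(length(candidates)))
    sub <- corr_full[candidates, genes, drop = FALSE]
    as.integer(rowSums(sub > threshold, na.rm = TRUE))
  }, integer(length(candidates)))
  if (length(candidates) == 1L) counts <- matrix(counts, nrow = 1L)
  dimnames(counts) <- list(candidates, tissues)
  counts
}

#' Rank candidates by single-tissue connectivity
#'
#' @param counts Count matrix from [tissue_connection_counts()].
#' @param tissue Tissue to rank by.
#' @param top_n Number of genes to return.
#' @return Data frame (gene, count), descending count, ties by gene id.
#' @export
rank_single_tissue <- function(counts, tissue, top_n = nrow(counts)) {
  if (!tissue %in% colnames(counts))
    stop("tissue '", tissue, "' not in the count table")
  genes <- rownames(counts)
  cnt <- counts[, tissue]
  ord <- order(-cnt, genes, method = "radix")
  out <- data.frame(gene = genes[ord], count = as.integer(cnt[ord]),
                    stringsAsFactors = FALSE)
  utils::head(out, top_n)
}

#' Rank candidates by paired-tissue connectivity
#'
#' The score of a gene for a tissue pair is the minimum of its two
#' per-tissue connection counts, recovering genes with many connections to
#' both tissues rather than just one. Ties are broken by total count over
#' the pair, then by gene id.
#'
#' @param counts Count matrix from [tissue_connection_counts()].
#' @param pair Character vector of two tissues.
#' @param top_n Number of genes to return (default 20).
#' @return Data frame (gene, score, count_1, count_2), descending score.
#' @export
rank_paired_tissue <- function(counts, pair, top_n = 20L) {
  if (length(pair) != 2L || !all(pair %in% colnames(counts)))
    stop("pair must name two tissues present in the count table")
  genes <- rownames(counts)
  c1 <- counts[, pair[1L]]
  c2 <- counts[, pair[2L]]
  score <- pmin(c1, c2)
  ord <- order(-score, -(c1 + c2), genes, method = "radix")
  out <- data.frame(gene = genes[ord], score = as.integer(score[ord]),
                    count_1 = as.integer(c1[ord]),
                    count_2 = as.integer(c2[ord]),
                    stringsAsFactors = FALSE)
  names(out)[3:4] <- paste0("count_", pair)
  utils::head(out, top_n)
}

#' Expand a network with highly connected outside genes
#'
#' Adds the expansion genes as nodes and every qualifying expansion-to-core
#' and expansion-to-expansion edge (correlation above the threshold). New
#' edges are labeled by [assign_edge_tissue()]; the vertex attribute
#' \code{origin} distinguishes original (\code{"glk"}) from
#' \code{"expansion"} nodes, and the edge attribute \code{origin}
#' distinguishes original from expansion edges.
#'
#' @param glk_net Core igraph network (edges carry \code{correlation}).
#' @param expansion_genes Genes to add (must be in \code{corr_full}).
#' @param corr_full Correlation matrix over the full gene universe.
#' @param threshold Adjacency cutoff for new edges (default 0.59).
#' @param profile Tissue profile matrix for edge labeling.
#' @param catalog Optional catalog for new-node attributes.
#' @param focus_tissues Focus tissues for edge labels.
#' @return Expanded igraph network.
#' @export
expand_network <- function(glk_net, expansion_genes, corr_full,
                           threshold = 0.59, profile, catalog = NULL,
                           focus_tissues = c("gut", "liver", "kidney")) {
  expansion_genes <- setdiff(expansion_genes, igraph::V(glk_net)$name)
  if (!length(expansion_genes)) {
    if (!"origin" %in% igraph::vertex_attr_names(glk_net))
      igraph::V(glk_net)$origin <- "glk"
    return(glk_net)
  }
  missing <- setdiff(expansion_genes, rownames(corr_full))
  if (length(missing))
    stop("expansion gene(s) absent from correlation matrix: ",
         paste(missing, collapse = ", "))
  core <- igraph::V(glk_net)$name
  ed_old <- igraph::as_data_frame(glk_net, what = "edges")
  nd_old <- igraph::as_data_frame(glk_net, what = "vertices")
  if (!"origin" %in% names(nd_old)) nd_old$origin <- "glk"
  if (nrow(ed_old) && !"origin" %in% names(ed_old)) ed_old$origin <- "glk"

  all_new <- c(core, expansion_genes)
  sub <- corr_full[expansion_genes, all_new, drop = FALSE]
  idx <- which(sub > threshold, arr.ind = TRUE)
  g1 <- expansion_genes[idx[, 1L]]
  g2 <- all_new[idx[, 2L]]
  pc <- pair_canonical(g1, g2)
  # expansion x expansion pairs appear twice; keep the canonical orientation
  keep <- g1 != g2 & (g2 %in% core | g1 == pc$lo)
  ed_new <- data.frame(from = pc$lo[keep], to = pc$hi[keep],
                       correlation = sub[idx][keep], origin = "expansion",
                       stringsAsFactors = FALSE)
  ed_new <- unique(ed_new)
  if (nrow(ed_new)) {
    lab <- assign_edge_tissue(profile, ed_new$from, ed_new$to, focus_tissues)
    ed_new$tissue <- lab$tissue
    ed_new$tissue_raw <- lab$tissue_raw
  }
  nd_new <- data.frame(name = expansion_genes, stringsAsFactors = FALSE)
  if (!is.null(catalog)) {
    m <- match(expansion_genes, catalog$gene)
    nd_new$class <- ifelse(is.na(m), "other", catalog$class[m])
    nd_new$family <- ifelse(is.na(m), "none", catalog$family[m])
    nd_new$adme_status <- ifelse(is.na(m), "none", catalog$adme_status[m])
  }
  nd_new$tissue <- unname(assign_gene_tissue(profile, expansion_genes))
  nd_new$origin <- "expansion"
  for (col in setdiff(names(nd_old), names(nd_new))) nd_new[[col]] <- NA
  for (col in setdiff(names(nd_new), names(nd_old))) nd_old[[col]] <- NA
  for (col in setdiff(names(ed_old), names(ed_new)))
    if (nrow(ed_new)) ed_new[[col]] <- NA else ed_new[[col]] <- ed_old[[col]][0]
  for (col in setdiff(names(ed_new), names(ed_old)))
    if (nrow(ed_old)) ed_old[[col]] <- NA else ed_old[[col]] <- ed_new[[col]][0]
  nodes <- rbind(nd_old[names(nd_old)], nd_new[names(nd_old)])
  edges <- rbind(ed_old[names(ed_old)], ed_new[names(ed_old)])
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Filter network edges by protein-protein interactions
#'
#' Keeps only edges that are also present (in either endpoint order) in the
#' PPI network. All nodes are retained; nodes left without any edge are
#' flagged via the vertex attribute \code{isolated_after_ppi}. Edge
#' attributes are preserved. The operation is idempotent.
#'
#' @param net igraph network.
#' @param ppi PPI edge data frame from [read_ppi()] / [ppi_network()].
#' @return Filtered igraph network.
#' @export
ppi_filter <- function(net, ppi) {
  n_before <- igraph::ecount(net)
  if (n_before > 0) {
    el <- igraph::as_edgelist(net)
    keep <- edge_keys(el[, 1L], el[, 2L]) %in% edge_keys(ppi$a, ppi$b)
    net <- igraph::delete_edges(net, igraph::E(net)[!keep])
  }
  igraph::V(net)$isolated_after_ppi <- igraph::degree(net) == 0
  message("PPI filter: ", n_before, " -> ", igraph::ecount(net), " edges")
  net
}
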