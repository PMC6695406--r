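# ADME-status integration, remote sensing and signaling (RSS) network
# assembly, the validation percent-overlap statistic, and end-to-end
# pipeline orchestration.

#' Annotate network genes with ADME status
#'
#' Sets the vertex attribute \code{adme_status} from the catalog (genes not
#' in the catalog get \code{"none"}) and reports the per-status counts.
#'
#' @param net igraph network.
#' @param catalog Gene-set catalog carrying adme_status.
#' @return Annotated igraph object.
#' @export
annotate_adme <- function(net, catalog) {
  nodes <- igraph::V(net)$name
  m <- match(nodes, catalog$gene)
  status <- ifelse(is.na(m), "none", catalog$adme_status[m])
  igraph::V(net)$adme_status <- status
  cnt <- table(factor(status, levels = ADME_STATUSES))
  message("ADME status counts: ",
          paste(names(cnt), cnt, sep = "=", collapse = ", "))
  net
}

#' Transcriptome-wide search for genes most connected to the network
#'
#' Unions the top-m genes of every single-tissue ranking and every
#' paired-tissue ranking over all candidates outside the core network, and
#' records which ranking(s) brought each gene in.
#'
#' @param counts Count matrix from [tissue_connection_counts()] over all
#'   candidate genes.
#' @param focus_tissues Focus tissue labels.
#' @param top_m Genes kept per ranking (default 100).
#' @return Data frame (gene, sources) where sources is a comma-separated
#'   provenance string; empty data frame when there are no candidates.
#' @export
top_connected_transcriptome <- function(counts,
                                        focus_tissues = c("gut", "liver",
                                                          "kidney"),
                                        top_m = 100L) {
  src <- list()
  if (nrow(counts)) {
    for (t in focus_tissues) {
      top <- rank_single_tissue(counts, t, top_m)
      src[[paste0("single:", t)]] <- top$gene[top$count > 0]
    }
    prs <- utils::combn(sort(focus_tissues, method = "radix"), 2L,
                        simplify = FALSE)
    for (p in prs) {
      top <- rank_paired_tissue(counts, p, top_m)
      src[[paste0("pair:", p[1L], "-", p[2L])]] <- top$gene[top$score > 0]
    }
  }
  genes <- unique(unlist(src))
  genes <- if (length(genes)) sort(genes, method = "radix") else character(0)
  sources <- vapply(genes, function(g)
    paste(names(src)[vapply(src, function(s) g %in% s, logical(1))],
          collapse = ","), character(1))
  data.frame(gene = genes, sources = unname(sources),
             stringsAsFactors = FALSE)
}

#' Build the remote sensing and signaling network
#'
#' PPI-filters the annotated network, seeds on every ADME gene (status
#' core, extended or related), and takes the seeds plus their first
#' neighbors in the PPI-filtered network. Edges are the PPI-filtered edges
#' among that node set, i.e. every edge is both co-expressed and present in
#' the PPI database. Isolated ADME seeds are retained. The vertex attribute
#' \code{shape} encodes status (core/extended = "triangle", related =
#' "square", neighbors = "circle"); betweenness and degree are recomputed
#' on this network and stored as vertex attributes.
#'
#' @param net Annotated igraph network (adme_status set).
#' @param ppi PPI edge data frame.
#' @return RSS igraph network.
#' @export
build_rss_network <- function(net, ppi) {
  status <- igraph::V(net)$adme_status
  if (is.null(status)) stop("network lacks adme_status; run annotate_adme()")
  seeds <- igraph::V(net)$name[status %in% c("core", "extended", "related")]
  if (!length(seeds)) stop("no ADME genes present in the network")
  filt <- ppi_filter(net, ppi)
  nbr <- unique(unlist(lapply(igraph::adjacent_vertices(filt, seeds, "all"),
                              function(v) igraph::V(filt)$name[v])))
  keep <- union(seeds, nbr)
  rss <- igraph::induced_subgraph(filt, igraph::V(filt)$name %in% keep)
  st <- igraph::V(rss)$adme_status
  igraph::V(rss)$shape <- ifelse(st %in% c("core", "extended"), "triangle",
                                 ifelse(st == "related", "square", "circle"))
  bt <- betweenness_table(rss)
  m <- match(igraph::V(rss)$name, bt$gene)
  igraph::V(rss)$betweenness <- bt$betweenness[m]
  igraph::V(rss)$degree <- bt$degree[m]
  rss
}

#' Percent overlap between associated and experimentally supported genes
#'
#' The statistic used to validate network-predicted transcription-factor
#' targets against knockout and ChIP-seq evidence: the percentage of
#' network-associated genes that carry wet-lab support, rounded to one
#' decimal.
#'
#' @param associated Gene set (character) or count of associated genes.
#' @param supported Gene set (must be a subset of \code{associated}) or
#'   count (must not exceed it). When component counts are supplied (e.g.
#'   down-regulated in a knockout plus ChIP-only), de-duplicate before
#'   summing.
#' @return List with \code{n_associated}, \code{n_supported},
#'   \code{percent}.
#' @export
validation_overlap <- function(associated, supported) {
  if (is.character(associated)) {
    if (!is.character(supported))
      stop("give both arguments as sets or both as counts")
    extra <- setdiff(supported, associated)
    if (length(extra))
      stop("supported gene(s) not among associated: ",
           paste(extra, collapse = ", "))
    n_a <- length(unique(associated))
    n_s <- length(unique(supported))
  } else {
    n_a <- sum(associated)
    n_s <- sum(supported)
    if (n_s > n_a) stop("supported count exceeds associated count")
  }
  if (n_a == 0) stop("associated set is empty")
  list(n_associated = n_a, n_supported = n_s,
       percent = round(100 * n_s / n_a, 1))
}

#' Run the full cross-tissue co-expression pipeline
#'
#' Executes every stage end to end: tissue averaging, cross-tissue
#' correlation, focal-class subsetting and edge selection, tissue
#' annotation, proximity matrix and dendrogram ordering, gut-liver-kidney
#' edge fractions with random and control-class replicates, single- and
#' paired-tissue connectivity rankings, network expansion, PPI filtering,
#' betweenness/degree tables, the family network, ADME annotation and the
#' RSS network. All tables, networks and a JSON run manifest are written to
#' \code{out_dir} when given.
#'
#' @param expr Expression matrix.
#' @param design Sample design (sample, tissue, group).
#' @param catalog Gene-set catalog.
#' @param ppi PPI edge data frame.
#' @param config [pipeline_config()] list.
#' @param out_dir Optional output directory.
#' @return List with every intermediate and final result plus the manifest.
#' @export
run_pipeline <- function(expr, design, catalog, ppi,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "glknet_config"))
  focus <- config$focus_tissues
  log <- list(seed = config$seed)

  # 1-2: tissue means and full cross-tissue correlation
  profile <- average_by_tissue(expr, design)
  corr_source <- if (config$correlation_scope == "tissue_means") profile
                 else expr
  corr_full <- cross_tissue_correlation(corr_source,
                                        log_transform = config$log_transform)

  # 3-4: subset to focal classes, then select the top edges among them
  corr_focal <- subset_correlation(corr_full, catalog, FOCAL_CLASSES)
  log$focal_gene_count <- nrow(corr_focal)
  edges <- select_edges(corr_focal, config$edge_mode, config$edge_value)
  log$focal_edge_count <- nrow(edges)
  net <- build_network(edges, catalog)
  net <- annotate_tissues(net, profile, focus)
  log$focal_network_gene_count <- igraph::vcount(net)

  # 5: tissue annotation products
  assignment <- stats::setNames(igraph::V(net)$tissue, igraph::V(net)$name)
  prox <- cluster_proximity(net, assignment)
  ord <- hierarchical_order(prox)

  # GLK core subnetwork: focal genes whose tissue of highest expression is
  # a focus tissue, with the edges among them
  glk_genes <- names(assignment)[assignment %in% focus]
  glk_net <- igraph::induced_subgraph(net,
                                      igraph::V(net)$name %in% glk_genes)
  log$glk_gene_count <- igraph::vcount(glk_net)
  log$glk_edge_count <- igraph::ecount(glk_net)
  glk_by_tissue <- lapply(stats::setNames(nm = sort(focus, method = "radix")),
                          function(t)
    glk_genes[assignment[glk_genes] == t])

  # Edge-fraction statistic with controls
  focal_all <- intersect(catalog$gene[catalog$class %in% FOCAL_CLASSES],
                         rownames(corr_full))
  k_frac <- if (config$edge_mode == "top_k") config$edge_value
            else max(1L, nrow(edges))
  frac <- focal_edge_fraction(corr_full, focal_all, k_frac, profile, focus)
  universe <- rownames(corr_full)
  rand_pool <- setdiff(universe, focal_all)
  ctrl_pool <- intersect(catalog$gene[catalog$class == "control"], universe)
  rand_ctrl <- control_fractions(corr_full, rand_pool,
                                 min(length(focal_all), length(rand_pool)),
                                 k_frac, config$control_reps, config$seed,
                                 profile, focus)
  class_ctrl <- if (length(ctrl_pool) >= length(focal_all))
    control_fractions(corr_full, ctrl_pool, length(focal_all), k_frac,
                      config$control_reps, config$seed + 1L, profile, focus)
  else NULL
  fractions <- list(focal = frac, random = rand_ctrl, control = class_ctrl)

  # Adjacency threshold reused genome-wide for expansion: in threshold
  # mode the configured cutoff, otherwise the configured expansion
  # threshold (top-k ranks depend on the candidate universe, so a fixed
  # cutoff is the only criterion that extends beyond the focal set)
  thr <- if (config$edge_mode == "threshold") config$edge_value
         else config$expansion_threshold
  log$adjacency_threshold <- thr

  # Expansion rankings over all candidates outside the focal set
  candidates <- setdiff(universe, focal_all)
  counts <- tissue_connection_counts(corr_full, glk_by_tissue, candidates,
                                     thr)
  pair_list <- utils::combn(sort(focus, method = "radix"), 2L,
                            simplify = FALSE)
  single_rank <- lapply(stats::setNames(nm = sort(focus, method = "radix")),
                        function(t)
    rank_single_tissue(counts, t, config$expansion_top_n))
  pair_rank <- lapply(pair_list, function(p)
    rank_paired_tissue(counts, p, config$expansion_top_n))
  names(pair_rank) <- vapply(pair_list, paste, character(1), collapse = "-")
  expansion_genes <- unique(unlist(lapply(pair_rank, function(x)
    x$gene[x$score > 0])))
  log$expansion_gene_count <- length(expansion_genes)

  # Expanded network and PPI filtering
  expanded <- expand_network(glk_net, expansion_genes, corr_full, thr,
                             profile, catalog, focus)
  log$expanded_gene_count <- igraph::vcount(expanded)
  log$expanded_edge_count <- igraph::ecount(expanded)
  expanded_ppi <- ppi_filter(expanded, ppi)
  log$expanded_edge_count_after_ppi <- igraph::ecount(expanded_ppi)
  central <- betweenness_table(expanded_ppi)

  # Family network over the focal network
  grouping <- family_grouping(catalog)
  fam_counts <- family_edge_counts(net, grouping)
  fam_sizes <- table(grouping[igraph::V(net)$name])
  fam <- build_family_network(fam_counts,
                              stats::setNames(as.integer(fam_sizes),
                                              names(fam_sizes)),
                              E = igraph::ecount(net),
                              N = choose(igraph::vcount(net), 2L),
                              score_threshold = config$family_score_threshold)

  # ADME integration and RSS network
  top_tw <- top_connected_transcriptome(counts, focus,
                                        config$transcriptome_top_m)
  adme_added <- top_tw$gene[top_tw$gene %in%
    catalog$gene[catalog$adme_status %in% c("core", "extended", "related")]]
  expanded_all <- expand_network(expanded, adme_added, corr_full, thr,
                                 profile, catalog, focus)
  expanded_all <- annotate_adme(expanded_all, catalog)
  st <- igraph::V(expanded_all)$adme_status
  log$adme_core_count <- sum(st == "core")
  log$adme_extended_count <- sum(st == "extended")
  log$adme_related_count <- sum(st == "related")
  rss <- build_rss_network(expanded_all, ppi)
  log$rss_gene_count <- igraph::vcount(rss)
  log$rss_edge_count <- igraph::ecount(rss)
  rss_central <- betweenness_table(rss)
  rss_degree <- degree_table(rss, config$degree_threshold)

  manifest <- c(log, list(
    config = unclass(config)[setdiff(names(config), "tissue_group_map")],
    focal_fraction = frac$fraction,
    random_control = rand_ctrl[c("mean", "sd")],
    class_control = if (!is.null(class_ctrl)) class_ctrl[c("mean", "sd")]))

  res <- list(profile = profile, corr_full = corr_full, edges = edges,
              network = net, proximity = prox, ordering = ord,
              glk_network = glk_net, fractions = fractions,
              connection_counts = counts, single_rank = single_rank,
              pair_rank = pair_rank, expanded = expanded,
              expanded_ppi = expanded_ppi, centrality = central,
              family = fam, top_transcriptome = top_tw,
              expanded_annotated = expanded_all, rss = rss,
              rss_centrality = rss_central, rss_degree = rss_degree,
              manifest = manifest, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Write all pipeline outputs to a run directory
#'
#' @param res Result list from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_network(res$network, file.path(out_dir, "focal_network"))
  write_network(res$expanded_ppi, file.path(out_dir, "expanded_ppi_network"))
  write_network(res$rss, file.path(out_dir, "rss_network"))
  utils::write.csv(res$proximity, file.path(out_dir, "proximity_matrix.csv"))
  jsonlite::write_json(list(order = res$ordering$order),
                       file.path(out_dir, "tissue_ordering.json"),
                       auto_unbox = TRUE)
  wt(res$centrality, "betweenness_expanded.tsv")
  wt(res$rss_centrality, "betweenness_rss.tsv")
  wt(res$rss_degree$table, "degree_rss.tsv")
  wt(res$rss_degree$high_degree, "degree_rss_high.tsv")
  wt(res$family$table, "family_edges.tsv")
  wt(res$family$betweenness, "betweenness_family.tsv")
  for (nm in names(res$pair_rank))
    wt(res$pair_rank[[nm]], paste0("pair_rank_", nm, ".tsv"))
  for (nm in names(res$single_rank))
    wt(res$single_rank[[nm]], paste0("single_rank_", nm, ".tsv"))
  fr <- res$fractions
  frac_tab <- data.frame(
    set = c("focal", "random", if (!is.null(fr$control)) "control"),
    mean = c(fr$focal$fraction, fr$random$mean,
             if (!is.null(fr$control)) fr$control$mean),
    sd = c(0, fr$random$sd, if (!is.null(fr$control)) fr$control$sd))
  wt(frac_tab, "glk_edge_fractions.tsv")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
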