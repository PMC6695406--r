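# Synthetic tissue-stratified expression with planted co-expression modules.
#
# The generative model is log-normal: gene g in sample s has expression
#   exp(mu + beta * 1[tissue(s) elevated for module(g)] + eps),  eps ~ N(0, sigma^2)
# Background genes carry no beta term. Raw-scale Pearson correlation across
# tissue means then recovers the planted modules, because exp(mu + beta * I)
# is an affine function of the 0/1 elevation indicator.

#' Specify one planted co-expression module
#'
#' @param id Short module identifier (used to derive gene ids).
#' @param n_genes Number of member genes (>= 2).
#' @param tissues Elevated tissue set (1 or 2 grouped tissue labels).
#' @param class Gene class label for the catalog.
#' @param family Gene family label for the catalog.
#' @param adme_status Intended ADME status for all members, or
#'   \code{"none"} to leave members to the random status draw.
#' @return Module spec list.
#' @export
module_spec <- function(id, n_genes, tissues, class, family,
                        adme_status = "none") {
  stopifnot(n_genes >= 2, length(tissues) %in% 1:2,
            class %in% GENE_CLASSES, adme_status %in% ADME_STATUSES)
  list(id = id, n_genes = as.integer(n_genes), tissues = tissues,
       class = class, family = family, adme_status = adme_status)
}

#' Simulation parameters
#'
#' @param tissues Grouped tissue labels; must contain gut, liver and kidney.
#' @param samples_per_tissue Samples drawn per tissue.
#' @param modules List of [module_spec()] entries.
#' @param n_background Number of diffusely expressed background genes.
#' @param mu Baseline log-mean of expression.
#' @param beta Log-scale elevation in a module's tissues (> 0).
#' @param sigma Log-scale noise standard deviation (>= 0).
#' @param ppi_true_fraction Probability a within-module pair is a PPI edge.
#' @param ppi_noise_fraction Probability any other pair is a PPI edge.
#' @param adme_fractions Named vector of probabilities: \code{core} and
#'   \code{extended} are drawn over focal-class genes, \code{related} over
#'   class-"other" genes; module-spec statuses take precedence.
#' @param seed Integer seed; all outputs are pure functions of
#'   (params, seed).
#' @return Parameter list of class \code{glknet_sim_params}.
#' @export
simulation_params <- function(tissues = c("gut", "liver", "kidney", "brain",
                                          "testis", "lung", "heart", "muscle",
                                          "pancreas", "placenta", "skin",
                                          "spleen"),
                              samples_per_tissue = 4L,
                              modules = list(),
                              n_background = 500L,
                              mu = 2, beta = 2, sigma = 0.5,
                              ppi_true_fraction = 0.5,
                              ppi_noise_fraction = 0.015,
                              adme_fractions = c(core = 0.02, extended = 0.09,
                                                 related = 0.01),
                              seed = 1L) {
  if (!all(c("gut", "liver", "kidney") %in% tissues))
    stop("tissues must include gut, liver and kidney")
  if (anyDuplicated(tissues)) stop("duplicate tissue labels")
  if (beta <= 0) stop("beta must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  probs <- c(ppi_true_fraction, ppi_noise_fraction, adme_fractions)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  mod_tissues <- unlist(lapply(modules, `[[`, "tissues"))
  if (!all(mod_tissues %in% tissues))
    stop("module elevated tissues must be simulated tissues")
  ids <- vapply(modules, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate module ids")
  structure(list(tissues = tissues,
                 samples_per_tissue = as.integer(samples_per_tissue),
                 modules = modules, n_background = as.integer(n_background),
                 mu = mu, beta = beta, sigma = sigma,
                 ppi_true_fraction = ppi_true_fraction,
                 ppi_noise_fraction = ppi_noise_fraction,
                 adme_fractions = adme_fractions, seed = as.integer(seed)),
            class = "glknet_sim_params")
}

#' Default gut-liver-kidney simulation scenario
#'
#' A ~1,200-gene, 12-tissue, 48-sample scenario with: focal transporter/DME
#' modules elevated in gut, liver and kidney (including dual-tissue modules
#' that create the cross-tissue edges characteristic of the gut-liver-kidney
#' axis), a small regulator module elevated in both liver and kidney that
#' plays the role of cross-tissue hub transcription factors (ADME
#' "related"), two focal modules elevated outside the axis (brain, testis),
#' a large GPCR-like control module, and diffuse background genes.
#'
#' @param seed Integer seed.
#' @return \code{glknet_sim_params} list.
#' @export
glk_default_params <- function(seed = 1L) {
  simulation_params(
    modules = list(
      module_spec("gut_slc5",       40, "gut",                  "SLC", "SLC5"),
      module_spec("liver_abcc",     40, "liver",                "ABC", "ABCC"),
      module_spec("kidney_slc22",   40, "kidney",               "SLC", "SLC22"),
      module_spec("liver_cyp",      30, "liver",                "DME_phase1", "CYP"),
      module_spec("kidney_ugt",     30, "kidney",               "DME_phase2", "UGT"),
      module_spec("gutliver_abcg",  25, c("gut", "liver"),      "ABC", "ABCG"),
      module_spec("liverkidney_slco", 25, c("liver", "kidney"), "SLC", "SLCO"),
      module_spec("gutkidney_slc7", 25, c("gut", "kidney"),     "SLC", "SLC7"),
      module_spec("nr_hub",          8, c("liver", "kidney"),   "other", "NR",
                  adme_status = "related"),
      module_spec("brain_slc6",     40, "brain",                "SLC", "SLC6"),
      module_spec("testis_slc25",   40, "testis",               "SLC", "SLC25"),
      module_spec("gpcr_control",  350, "brain",                "control", "GPR")
    ),
    n_background = 507L,
    seed = seed
  )
}

sim_gene_ids <- function(params) {
  mod_ids <- unlist(lapply(params$modules, function(m)
    sprintf("%s_%03d", toupper(m$id), seq_len(m$n_genes))))
  bg_ids <- if (params$n_background > 0)
    sprintf("BG_%04d", seq_len(params$n_background)) else character(0)
  ids <- c(mod_ids, bg_ids)
  if (anyDuplicated(ids)) stop("gene ids not unique across modules")
  ids
}

sim_truth <- function(params) {
  gene_module <- unlist(lapply(params$modules, function(m)
    stats::setNames(rep(m$id, m$n_genes),
                    sprintf("%s_%03d", toupper(m$id), seq_len(m$n_genes)))))
  module_tissues <- stats::setNames(lapply(params$modules, `[[`, "tissues"),
                                    vapply(params$modules, `[[`,
                                           character(1), "id"))
  list(gene_module = gene_module, module_tissues = module_tissues,
       modules = params$modules)
}

#' Simulate a tissue-stratified expression matrix
#'
#' See the package vignette for the generative model. The same params and
#' seed always yield identical output.
#'
#' @param params [simulation_params()] list.
#' @return List with \code{expr} (matrix), \code{design} (data frame) and
#'   \code{truth} (gene-to-module map and module tissue sets).
#' @export
simulate_expression <- function(params) {
  stopifnot(inherits(params, "glknet_sim_params"))
  set.seed(params$seed)
  genes <- sim_gene_ids(params)
  truth <- sim_truth(params)
  samples <- unlist(lapply(params$tissues, function(t)
    sprintf("%s_s%d", gsub("[^A-Za-z0-9]", "", t),
            seq_len(params$samples_per_tissue))))
  sample_tissue <- rep(params$tissues, each = params$samples_per_tissue)

  elev <- matrix(0, nrow = length(genes), ncol = length(params$tissues),
                 dimnames = list(genes, params$tissues))
  for (m in params$modules) {
    mg <- names(truth$gene_module)[truth$gene_module == m$id]
    elev[mg, m$tissues] <- 1
  }
  logmean <- params$mu + params$beta * elev[, sample_tissue, drop = FALSE]
  noise <- matrix(stats::rnorm(length(genes) * length(samples),
                               sd = params$sigma),
                  nrow = length(genes))
  expr <- exp(logmean + noise)
  dimnames(expr) <- list(genes, samples)
  design <- data.frame(sample = samples, tissue = sample_tissue,
                       group = sample_tissue, stringsAsFactors = FALSE)
  validate_expression(expr)
  list(expr = expr, design = design, truth = truth)
}

#' Simulate the gene-set catalog matching a simulation
#'
#' Module genes carry their module's class and family; background genes are
#' class \code{"other"} (family \code{"none"}). ADME statuses fixed by a
#' module spec are applied as-is; remaining statuses are drawn from
#' \code{params$adme_fractions} (core/extended over focal-class genes,
#' related over class-"other" genes) using a seed derived from
#' \code{params$seed}, so the draw is reproducible and independent of
#' whether the expression matrix was generated first.
#'
#' @param params [simulation_params()] list.
#' @return Catalog data frame (gene, family, class, adme_status).
#' @export
simulate_catalog <- function(params) {
  stopifnot(inherits(params, "glknet_sim_params"))
  set.seed(params$seed %% 1000000L + 1L)
  truth <- sim_truth(params)
  genes <- sim_gene_ids(params)
  class <- rep("other", length(genes))
  family <- rep("none", length(genes))
  status <- rep("none", length(genes))
  names(class) <- names(family) <- names(status) <- genes
  for (m in params$modules) {
    mg <- names(truth$gene_module)[truth$gene_module == m$id]
    class[mg] <- m$class
    family[mg] <- m$family
    status[mg] <- m$adme_status
  }
  fr <- params$adme_fractions
  free <- status == "none"
  focal <- free & class %in% FOCAL_CLASSES
  u <- stats::runif(length(genes))
  p_core <- if ("core" %in% names(fr)) fr[["core"]] else 0
  p_ext <- if ("extended" %in% names(fr)) fr[["extended"]] else 0
  p_rel <- if ("related" %in% names(fr)) fr[["related"]] else 0
  status[focal & u < p_core] <- "core"
  status[focal & u >= p_core & u < p_core + p_ext] <- "extended"
  other <- free & class == "other"
  status[other & u < p_rel] <- "related"
  validate_catalog(data.frame(gene = genes, family = unname(family),
                              class = unname(class),
                              adme_status = unname(status),
                              stringsAsFactors = FALSE))
}

#' Simulate a PPI network partially concordant with planted modules
#'
#' Within-module gene pairs become PPI edges with probability
#' \code{ppi_true_fraction}; every other pair with probability
#' \code{ppi_noise_fraction}.
#'
#' @param truth Ground truth as returned by [simulate_expression()].
#' @param params [simulation_params()] list.
#' @return List with \code{ppi} (canonical edge data frame) and
#'   \code{true_edges} (the within-module edges that were included).
#' @export
simulate_ppi <- function(truth, params) {
  stopifnot(inherits(params, "glknet_sim_params"))
  set.seed(params$seed %% 1000000L + 2L)
  genes <- sim_gene_ids(params)
  gm <- truth$gene_module[genes]
  gm[is.na(gm)] <- ""
  idx <- utils::combn(length(genes), 2L)
  within <- gm[idx[1L, ]] != "" & gm[idx[1L, ]] == gm[idx[2L, ]]
  p <- ifelse(within, params$ppi_true_fraction, params$ppi_noise_fraction)
  keep <- stats::runif(ncol(idx)) < p
  ppi <- ppi_network(genes[idx[1L, keep]], genes[idx[2L, keep]])
  true_edges <- ppi_network(genes[idx[1L, keep & within]],
                            genes[idx[2L, keep & within]])
  list(ppi = ppi, true_edges = true_edges)
}

#' Simulate the full default scenario
#'
#' Convenience wrapper generating expression, design, catalog, PPI and
#' ground truth for [glk_default_params()].
#'
#' @param seed Integer seed.
#' @param params Optional params list overriding the default scenario.
#' @return List with expr, design, catalog, ppi, truth, params.
#' @export
simulate_glk_default <- function(seed = 1L, params = glk_default_params(seed)) {
  sim <- simulate_expression(params)
  catalog <- simulate_catalog(params)
  ppi <- simulate_ppi(sim$truth, params)
  list(expr = sim$expr, design = sim$design, catalog = catalog,
       ppi = ppi$ppi, truth = c(sim$truth, list(ppi_true = ppi$true_edges)),
       params = params)
}

#' Write a simulated scenario to a directory
#'
#' Emits expression TSV, design TSV, catalog TSV, PPI TSV and a truth JSON.
#'
#' @param sim Output of [simulate_glk_default()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the output file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, c("expression.tsv", "design.tsv", "catalog.tsv",
                        "ppi.tsv", "truth.json"))
  write_expression(sim$expr, sim$design, p[1], p[2])
  utils::write.table(sim$catalog, p[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$ppi, p[4], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(gene_module = as.list(sim$truth$gene_module),
                            module_tissues = sim$truth$module_tissues,
                            seed = sim$params$seed),
                       p[5], auto_unbox = TRUE, pretty = TRUE)
  invisible(p)
}
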