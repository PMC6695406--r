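# Domain constants ----------------------------------------------------------

#' Gene classes recognised by the pipeline
#'
#' Focal classes are the transporter/DME superfamilies the network is built
#' from; \code{"control"} marks GPCR-like control genes and \code{"other"}
#' everything else in the transcriptome.
#'
#' @format Character vectors.
#' @name gene-classes
NULL

#' @rdname gene-classes
#' @export
FOCAL_CLASSES <- c("SLC", "ABC", "DME_phase1", "DME_phase2")

#' @rdname gene-classes
#' @export
GENE_CLASSES <- c(FOCAL_CLASSES, "control", "other")

#' @rdname gene-classes
#' @export
ADME_STATUSES <- c("core", "extended", "related", "none")

# Validators -----------------------------------------------------------------

#' Validate an expression matrix
#'
#' An expression matrix is a numeric matrix of nonnegative, finite normalized
#' counts with unique gene row names and unique sample column names, and at
#' least 2 genes and 2 samples.
#'
#' @param expr Numeric matrix, genes in rows, samples in columns.
#' @return The matrix, invisibly, after validation.
#' @export
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix must have gene row names and sample column names")
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(expr)[duplicated(rownames(expr))]), collapse = ", "))
  if (anyDuplicated(colnames(expr)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(expr)[duplicated(colnames(expr))]), collapse = ", "))
  if (nrow(expr) < 2L || ncol(expr) < 2L)
    stop("expression matrix needs at least 2 genes and 2 samples")
  if (any(!is.finite(expr)))
    stop("expression matrix contains non-finite values")
  if (any(expr < 0))
    stop("expression matrix contains negative values")
  invisible(expr)
}

#' Validate a sample design table
#'
#' @param design Data frame with columns \code{sample}, \code{tissue} and
#'   (after grouping) \code{group}.
#' @param expr Optional expression matrix whose samples must all be covered.
#' @return The design, invisibly.
#' @export
validate_design <- function(design, expr = NULL) {
  if (!is.data.frame(design) || !all(c("sample", "tissue") %in% names(design)))
    stop("design must be a data frame with columns 'sample' and 'tissue'")
  if (anyDuplicated(design$sample))
    stop("duplicate sample identifiers in design")
  if (!is.null(expr)) {
    missing <- setdiff(colnames(expr), design$sample)
    if (length(missing))
      stop("no design entry for sample(s): ", paste(missing, collapse = ", "))
  }
  invisible(design)
}

# Tissue grouping ------------------------------------------------------------

#' Default raw-tissue to grouped-tissue map
#'
#' Small intestine and duodenum are pooled into a single \code{"gut"} label;
#' every other tissue maps to itself. Whether colon belongs in "gut" is
#' dataset-dependent, so it is not pooled by default; pass an extended map to
#' change this.
#'
#' @return Named character vector (raw name -> group label).
#' @export
default_tissue_group_map <- function() {
  c("small intestine" = "gut", "duodenum" = "gut")
}

#' Apply a tissue group map
#'
#' @param tissues Character vector of raw tissue labels.
#' @param map Named character vector; unlisted tissues map to themselves.
#' @return Character vector of grouped labels.
#' @export
group_tissues <- function(tissues, map = default_tissue_group_map()) {
  out <- as.character(tissues)
  hit <- out %in% names(map)
  out[hit] <- unname(map[out[hit]])
  out
}

# Readers / writers ----------------------------------------------------------

#' Read an expression matrix and its sample design
#'
#' The expression TSV has a first column of gene identifiers (header
#' \code{gene}) and one column per sample; the design TSV has columns
#' \code{sample_id} and \code{tissue}. Tissue grouping is applied at read
#' time, so all downstream stages see grouped labels in \code{design$group}.
#'
#' @param path Path to the expression TSV.
#' @param design_path Path to the design TSV.
#' @param tissue_group_map Raw-to-grouped tissue map.
#' @return List with elements \code{expr} (matrix, genes x samples) and
#'   \code{design} (data frame: sample, tissue, group).
#' @export
read_expression <- function(path, design_path,
                            tissue_group_map = default_tissue_group_map()) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L)
    stop("expression TSV needs a gene column plus at least 2 sample columns")
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1L]
      stop(sprintf("non-numeric expression value at row %d, column '%s'",
                   bad, names(vals)[j]))
    }
  }
  expr <- as.matrix(vals)
  rownames(expr) <- genes
  validate_expression(expr)

  des <- utils::read.delim(design_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  names(des)[names(des) == "sample_id"] <- "sample"
  validate_design(des, expr)
  des$group <- group_tissues(des$tissue, tissue_group_map)
  des <- des[match(colnames(expr), des$sample), c("sample", "tissue", "group")]
  rownames(des) <- NULL
  list(expr = expr, design = des)
}

#' Write an expression matrix and design to TSV
#'
#' @param expr Expression matrix.
#' @param design Sample design data frame.
#' @param path,design_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(expr, design, path, design_path) {
  tab <- data.frame(gene = rownames(expr), expr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  des <- data.frame(sample_id = design$sample, tissue = design$tissue,
                    stringsAsFactors = FALSE)
  utils::write.table(des, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, design_path))
}

#' Read a gene-set catalog
#'
#' Expects TSV columns \code{gene}, \code{family}, \code{class} and
#' optionally \code{adme_status} (defaulting to \code{"none"}). Each gene
#' must map to exactly one family and class; exact duplicate rows are
#' collapsed, conflicting duplicates are an error.
#'
#' @param path Path to the catalog TSV.
#' @return Data frame with columns gene, family, class, adme_status.
#' @export
read_catalog <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene", "family", "class")
  if (!all(need %in% names(tab)))
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  if (!"adme_status" %in% names(tab)) tab$adme_status <- "none"
  tab <- tab[, c("gene", "family", "class", "adme_status")]
  tab <- unique(tab)
  dup <- tab$gene[duplicated(tab$gene)]
  if (length(dup))
    stop("gene(s) with conflicting catalog entries: ",
         paste(unique(dup), collapse = ", "))
  validate_catalog(tab)
}

#' Validate a gene-set catalog
#'
#' @param catalog Data frame with gene, family, class, adme_status.
#' @return The catalog (row names dropped) after validation.
#' @export
validate_catalog <- function(catalog) {
  bad_class <- setdiff(unique(catalog$class), GENE_CLASSES)
  if (length(bad_class))
    stop("unknown gene class(es): ", paste(bad_class, collapse = ", "),
         " (expected one of ", paste(GENE_CLASSES, collapse = ", "), ")")
  bad_status <- setdiff(unique(catalog$adme_status), ADME_STATUSES)
  if (length(bad_status))
    stop("unknown adme_status value(s): ", paste(bad_status, collapse = ", "))
  if (anyDuplicated(catalog$gene))
    stop("duplicate genes in catalog")
  rownames(catalog) <- NULL
  catalog
}

#' Read a protein-protein interaction edge list
#'
#' Accepts a two-column TSV edge list or a three-column SIF file
#' (\code{source interaction target}). Reversed duplicates are collapsed to
#' a single undirected edge and self-loops are dropped with a message.
#'
#' @param path Path to the PPI file.
#' @return Data frame with columns \code{a}, \code{b} (lexicographically
#'   ordered within each row), one row per undirected edge.
#' @export
read_ppi <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  nfield <- lengths(parts)
  bad <- which(!(nfield %in% c(2L, 3L)))
  if (length(bad))
    stop(sprintf("malformed PPI line %d: '%s'", bad[1L], lines[bad[1L]]))
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, function(p) p[[length(p)]], character(1))
  ppi_network(a, b)
}

#' Canonically order the endpoints of undirected pairs
#'
#' Orders each (a, b) pair so that \code{lo <= hi} under locale-independent
#' (C/byte) collation, so pair canonicalisation does not depend on the
#' session locale.
#'
#' @param a,b Character endpoint vectors (recycled together).
#' @return List with components \code{lo} and \code{hi}.
#' @export
pair_canonical <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (!length(a) && !length(b))
    return(list(lo = character(0), hi = character(0)))
  lv <- sort(unique(c(a, b)), method = "radix")
  swap <- match(a, lv) > match(b, lv)
  list(lo = ifelse(swap, b, a), hi = ifelse(swap, a, b))
}

#' Build a PPI network from endpoint vectors
#'
#' @param a,b Character vectors of endpoints.
#' @return Canonical undirected edge data frame (columns a, b).
#' @export
ppi_network <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  self <- a == b
  if (any(self))
    message(sum(self), " self-loop(s) dropped from PPI input")
  pc <- pair_canonical(a[!self], b[!self])
  out <- unique(data.frame(a = pc$lo, b = pc$hi, stringsAsFactors = FALSE))
  out <- out[order(out$a, out$b, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Canonical string keys for undirected gene pairs
#'
#' @param a,b Endpoint vectors.
#' @return Character vector, one key per pair, symmetric in endpoint order.
#' @export
edge_keys <- function(a, b) {
  pc <- pair_canonical(a, b)
  paste(pc$lo, pc$hi, sep = "\r")
}

#' Write a co-expression network to disk
#'
#' Emits an edge-list TSV (source, target, correlation, tissue), a node
#' table TSV, and a GraphML mirror carrying all node and edge attributes.
#' The edge-list TSV is the canonical on-disk form.
#'
#' @param net igraph network as built by [build_network()].
#' @param prefix Output path prefix; files are written as
#'   \code{<prefix>_edges.tsv}, \code{<prefix>_nodes.tsv},
#'   \code{<prefix>.graphml}.
#' @return Invisibly, the three file paths.
#' @export
write_network <- function(net, prefix) {
  ed <- igraph::as_data_frame(net, what = "edges")
  names(ed)[1:2] <- c("source", "target")
  if (!"correlation" %in% names(ed) && nrow(ed) == 0) ed$correlation <- numeric(0)
  if (!"tissue" %in% names(ed) && nrow(ed) == 0) ed$tissue <- character(0)
  nd <- igraph::as_data_frame(net, what = "vertices")
  if (!"name" %in% names(nd)) nd$name <- character(0)
  names(nd)[names(nd) == "name"] <- "gene"
  paths <- c(edges = paste0(prefix, "_edges.tsv"),
             nodes = paste0(prefix, "_nodes.tsv"),
             graphml = paste0(prefix, ".graphml"))
  utils::write.table(ed, paths[["edges"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(nd, paths[["nodes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  igraph::write_graph(net, paths[["graphml"]], format = "graphml")
  invisible(paths)
}

#' Read a network back from its GraphML mirror
#'
#' @param path GraphML file written by [write_network()].
#' @return igraph object.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if ("id" %in% igraph::vertex_attr_names(g) &&
      !"name" %in% igraph::vertex_attr_names(g))
    igraph::V(g)$name <- igraph::V(g)$id
  g
}

# Configuration --------------------------------------------------------------

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults follow
#' the reference analysis: edges are the top 10,000 correlation pairs
#' (equivalently r > 0.59 on the original data), correlations are taken over
#' per-tissue mean profiles without log transform, the focus tissues are
#' gut, liver and kidney, paired-tissue expansion keeps the top 20 genes per
#' tissue pair, transcriptome-wide ADME search keeps the top 100, control
#' fractions use 10 random replicates, family edges are displayed above a
#' hypergeometric score of 2 (p < 0.01), and the degree report threshold
#' is 30.
#'
#' @param edge_mode \code{"top_k"} or \code{"threshold"}.
#' @param edge_value Number of edges (top_k) or correlation cutoff
#'   (threshold, in (0,1)).
#' @param correlation_scope \code{"tissue_means"} or \code{"samples"}.
#' @param log_transform Apply log2(x+1) before correlating?
#' @param focus_tissues Grouped tissue labels of interest.
#' @param tissue_group_map Raw-to-grouped tissue map.
#' @param expansion_threshold Correlation cutoff defining adjacency for
#'   connection counts and expansion edges genome-wide (default 0.59, the
#'   cutoff equivalent to the top-10,000 rule on the reference data). In
#'   \code{"threshold"} edge mode, \code{edge_value} is used instead.
#' @param expansion_top_n Genes kept per tissue pair when expanding.
#' @param transcriptome_top_m Genes kept per ranking in the
#'   transcriptome-wide ADME search.
#' @param control_reps Random control replicates for edge fractions.
#' @param family_score_threshold Hypergeometric score display cutoff.
#' @param degree_threshold Degree report cutoff.
#' @param seed Integer seed recorded in all outputs.
#' @return List of class \code{glknet_config}.
#' @export
pipeline_config <- function(edge_mode = c("top_k", "threshold"),
                            edge_value = 10000,
                            correlation_scope = c("tissue_means", "samples"),
                            log_transform = FALSE,
                            focus_tissues = c("gut", "liver", "kidney"),
                            tissue_group_map = default_tissue_group_map(),
                            expansion_threshold = 0.59,
                            expansion_top_n = 20L,
                            transcriptome_top_m = 100L,
                            control_reps = 10L,
                            family_score_threshold = 2.0,
                            degree_threshold = 30L,
                            seed = 1L) {
  edge_mode <- match.arg(edge_mode)
  correlation_scope <- match.arg(correlation_scope)
  if (edge_mode == "top_k") {
    if (edge_value < 1) stop("top_k edge_value must be a positive integer")
  } else if (edge_value <= -1 || edge_value >= 1) {
    stop("threshold edge_value must lie in (-1, 1)")
  }
  for (nm in c("expansion_top_n", "transcriptome_top_m", "control_reps")) {
    v <- get(nm)
    if (length(v) != 1L || v < 1) stop(nm, " must be a positive integer")
  }
  structure(list(
    edge_mode = edge_mode,
    edge_value = edge_value,
    correlation_scope = correlation_scope,
    log_transform = isTRUE(log_transform),
    focus_tissues = focus_tissues,
    tissue_group_map = tissue_group_map,
    expansion_threshold = expansion_threshold,
    expansion_top_n = as.integer(expansion_top_n),
    transcriptome_top_m = as.integer(transcriptome_top_m),
    control_reps = as.integer(control_reps),
    family_score_threshold = family_score_threshold,
    degree_threshold = as.integer(degree_threshold),
    seed = as.integer(seed)
  ), class = "glknet_config")
}

#' Read a pipeline configuration from a YAML key/value file
#'
#' Keys not present fall back to [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return \code{glknet_config} list.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configuration requires the 'yaml' package")
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(vals$tissue_group_map))
    vals$tissue_group_map <- unlist(vals$tissue_group_map)
  do.call(pipeline_config, vals)
}
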