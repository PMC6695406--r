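test_that("percent overlap reproduces the published validation figures", {
  # HNF4alpha: 85 of 108 associated genes supported by knockout/ChIP data
  o1 <- validation_overlap(108, 85)
  expect_equal(o1$percent, 78.7)
  # HNF1alpha: 62 of 101
  expect_equal(validation_overlap(101, 62)$percent, 61.4)
  # PXR: 70 of 118
  expect_equal(validation_overlap(118, 70)$percent, 59.3)
})

test_that("percent overlap handles sets, monotonicity and edge cases", {
  a <- sprintf("g%02d", 1:40)
  expect_equal(validation_overlap(a, a)$percent, 100.0)
  expect_equal(validation_overlap(a, a[1:10])$percent, 25.0)
  # monotone in the supported count
  prev <- -1
  for (s in c(0, 10, 20, 40)) {
    p <- validation_overlap(40, s)$percent
    expect_gt(p, prev)
    prev <- p
  }
  # duplicated set members are de-duplicated before counting
  expect_equal(validation_overlap(c(a, a), a)$percent, 100.0)
  expect_error(validation_overlap(a, c(a[1], "zz")), "zz")
  expect_error(validation_overlap(10, 11), "exceeds")
  expect_error(validation_overlap(character(0), character(0)), "empty")
})

test_that("ADME annotation counts statuses via set intersection", {
  ed <- data.frame(gene1 = c("A", "B", "C"), gene2 = c("B", "C", "D"), r = 1)
  cat <- data.frame(gene = c("A", "B", "C", "D", "E"),
                    family = "SLC22", class = "SLC",
                    adme_status = c("core", "extended", "none", "core",
                                    "related"))
  net <- build_network(ed, cat)
  net <- suppressMessages(annotate_adme(net, cat))
  st <- stats::setNames(igraph::V(net)$adme_status, igraph::V(net)$name)
  # oracle: intersect network genes with the catalog status sets
  for (s in c("core", "extended", "related")) {
    expect_setequal(names(st)[st == s],
                    intersect(igraph::V(net)$name,
                              cat$gene[cat$adme_status == s]))
  }
  expect_equal(sum(st == "core"), 2L)

  # all-none catalog yields zero ADME flags and no RSS network
  cat0 <- cat; cat0$adme_status <- "none"
  net0 <- suppressMessages(annotate_adme(build_network(ed, cat0), cat0))
  expect_error(build_rss_network(net0, ppi_network("A", "B")),
               "no ADME genes")
})

test_that("RSS network is the PPI-supported depth-1 ADME closure", {
  # chain A - B - C - D - E with a spur C - F; ADME seed is C
  ed <- data.frame(gene1 = c("A", "B", "C", "D", "C"),
                   gene2 = c("B", "C", "D", "E", "F"), r = 0.9)
  cat <- data.frame(gene = LETTERS[1:6], family = "SLC22", class = "SLC",
                    adme_status = c("none", "none", "core", "none", "none",
                                    "none"))
  net <- suppressMessages(annotate_adme(build_network(ed, cat), cat))
  # PPI supports B-C and C-D but not C-F
  ppi <- ppi_network(c("B", "C", "A"), c("C", "D", "B"))
  rss <- suppressMessages(build_rss_network(net, ppi))
  # nodes: seed C plus its PPI-filtered first neighbors B and D
  expect_setequal(igraph::V(rss)$name, c("B", "C", "D"))
  expect_equal(igraph::ecount(rss), 2L)
  shapes <- stats::setNames(igraph::V(rss)$shape, igraph::V(rss)$name)
  expect_equal(unname(shapes["C"]), "triangle")
  expect_equal(unname(shapes[c("B", "D")]), c("circle", "circle"))

  # an ADME gene whose edges all fail the PPI filter stays, isolated
  ppi2 <- ppi_network("A", "B")
  rss2 <- suppressMessages(build_rss_network(net, ppi2))
  expect_true("C" %in% igraph::V(rss2)$name)
  expect_equal(igraph::degree(rss2, "C"), c(C = 0))

  # node set equals a BFS depth-1 oracle on a random instance
  g <- random_graph(40, 0.12, seed = 22)
  igraph::V(g)$adme_status <- "none"
  set.seed(22)
  seeds <- sample(igraph::V(g)$name, 5)
  igraph::V(g)$adme_status[igraph::V(g)$name %in% seeds] <- "extended"
  el <- igraph::as_edgelist(g)
  keep <- sample(nrow(el), floor(nrow(el) * 0.6))
  rppi <- ppi_network(el[keep, 1], el[keep, 2])
  rss3 <- suppressMessages(build_rss_network(g, rppi))
  kept_keys <- edge_keys(el[keep, 1], el[keep, 2])
  nbrs <- unique(unlist(lapply(seeds, function(s) {
    hit <- (el[, 1] == s | el[, 2] == s) &
      edge_keys(el[, 1], el[, 2]) %in% kept_keys
    setdiff(c(el[hit, 1], el[hit, 2]), s)
  })))
  expect_setequal(igraph::V(rss3)$name, union(seeds, nbrs))
})

test_that("transcriptome-wide search unions rankings with provenance", {
  counts <- matrix(c(9, 9, 9,
                     8, 0, 0,
                     0, 8, 0,
                     1, 1, 0,
                     0, 0, 0), byrow = TRUE, nrow = 5,
                   dimnames = list(c("hub", "g_gut", "g_liv", "weak", "zero"),
                                   c("gut", "liver", "kidney")))
  top <- top_connected_transcriptome(counts, c("gut", "liver", "kidney"),
                                     top_m = 2)
  # a gene connected to all tissues appears in every ranking
  hub_src <- top$sources[top$gene == "hub"]
  expect_true(grepl("single:gut", hub_src) && grepl("single:liver", hub_src)
              && grepl("pair:gut-liver", hub_src))
  # zero-count genes never enter
  expect_false("zero" %in% top$gene)
  # empty candidate table gives an empty result
  expect_equal(nrow(top_connected_transcriptome(counts[0, , drop = FALSE])),
               0L)
})

test_that("pipeline reruns with a fixed seed are identical end to end", {
  sim <- simulate_glk_default(seed = 42, params = tiny_sim_params(42))
  cfg <- pipeline_config(edge_mode = "top_k", edge_value = 150, seed = 42,
                         control_reps = 3L)
  r1 <- suppressWarnings(suppressMessages(run_pipeline(
    sim$expr, sim$design, sim$catalog, sim$ppi, cfg)))
  r2 <- suppressWarnings(suppressMessages(run_pipeline(
    sim$expr, sim$design, sim$catalog, sim$ppi, cfg)))
  expect_identical(r1$manifest, r2$manifest)
  expect_identical(r1$edges, r2$edges)
  expect_identical(r1$rss_centrality, r2$rss_centrality)

  # manifest counts agree with the emitted files
  d1 <- tempfile(); d2 <- tempfile()
  write_pipeline_outputs(r1, d1)
  write_pipeline_outputs(r2, d2)
  etab <- utils::read.delim(file.path(d1, "focal_network_edges.tsv"))
  expect_equal(nrow(etab), r1$manifest$focal_edge_count)
  for (f in setdiff(list.files(d1), list.files(d1, pattern = "graphml"))) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
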