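test_that("gene tissue assignment is an argmax with lexicographic ties", {
  prof <- rbind(g1 = c(liver = 10, kidney = 0, gut = 1),
                g2 = c(liver = 5, kidney = 5, gut = 0),
                g3 = c(liver = 0, kidney = 0, gut = 0))
  expect_warning(a <- assign_gene_tissue(prof), "undetermined")
  expect_equal(unname(a["g1"]), "liver")
  expect_equal(unname(a["g2"]), "kidney")    # kidney < liver
  expect_equal(unname(a["g3"]), "undetermined")

  # random profile equals a linear-scan argmax oracle
  set.seed(13)
  rp <- matrix(rexp(60), nrow = 12,
               dimnames = list(sprintf("G%02d", 1:12),
                               c("t3", "t1", "t5", "t2", "t4")))
  a2 <- assign_gene_tissue(rp)
  for (g in rownames(rp)) {
    ts <- sort(colnames(rp))
    expect_equal(unname(a2[g]), ts[which.max(rp[g, ts])])
  }
})

test_that("edge tissue is the argmax of the unweighted pair mean", {
  prof <- rbind(s = c(liver = 10, kidney = 0),
                t = c(liver = 4, kidney = 5),
                u = c(liver = 0, kidney = 8))
  colnames(prof) <- c("liver", "kidney")
  prof <- cbind(prof, gut = c(0, 0, 0))
  lab <- assign_edge_tissue(prof, "s", "t")
  expect_equal(lab$tissue, "liver")          # pair means (7, 2.5, 0)
  lab2 <- assign_edge_tissue(prof, c("s", "t"), c("t", "u"))
  expect_equal(lab2$tissue_raw, c("liver", "kidney"))
  # symmetric in endpoint order
  expect_equal(assign_edge_tissue(prof, "t", "s")$tissue, "liver")
  # outside the focus list the label buckets to "other"
  lab3 <- assign_edge_tissue(prof, "s", "t", focus_tissues = "gut")
  expect_equal(lab3$tissue, "other")
  expect_equal(lab3$tissue_raw, "liver")

  # random pairs match a pairwise-mean argmax oracle
  set.seed(17)
  rp <- matrix(rexp(50), nrow = 10,
               dimnames = list(sprintf("G%02d", 1:10), paste0("T", 1:5)))
  g1 <- sprintf("G%02d", sample(10, 20, TRUE))
  g2 <- sprintf("G%02d", sample(10, 20, TRUE))
  lab4 <- assign_edge_tissue(rp, g1, g2, focus_tissues = NULL)
  for (i in seq_along(g1)) {
    pm <- (rp[g1[i], ] + rp[g2[i], ]) / 2
    ts <- sort(names(pm))
    expect_equal(lab4$tissue[i], ts[which.max(pm[ts])])
  }
})

test_that("proximity matrix counts each edge once and conserves |E|", {
  ed <- data.frame(gene1 = c("a", "a", "c"), gene2 = c("b", "c", "d"),
                   r = 1)
  net <- build_network(ed)
  assign <- c(a = "L", b = "L", c = "K", d = "G")
  prox <- cluster_proximity(net, assign)
  expect_equal(prox["L", "L"], 1L)
  expect_equal(prox["K", "L"], 1L)
  expect_equal(prox["G", "K"], 1L)
  expect_true(isSymmetric(prox))
  expect_equal(sum(prox[upper.tri(prox, diag = TRUE)]), igraph::ecount(net))

  # all genes in one tissue: single diagonal cell equal to |E|
  p1 <- cluster_proximity(net, c(a = "L", b = "L", c = "L", d = "L"))
  expect_equal(unname(p1["L", "L"]), 3L)

  # conservation holds on a random network with random assignments
  g <- random_graph(30, 0.2, seed = 2)
  set.seed(2)
  ra <- stats::setNames(sample(c("t1", "t2", "t3", "t4"), 30, TRUE),
                        igraph::V(g)$name)
  pr <- cluster_proximity(g, ra)
  expect_equal(sum(pr[upper.tri(pr, diag = TRUE)]), igraph::ecount(g))
})

test_that("hierarchical ordering matches a naive average-linkage oracle", {
  # identical rows merge first at height 0
  prox <- rbind(gut = c(5, 9, 1), liver = c(5, 9, 1), brain = c(1, 1, 20))
  colnames(prox) <- rownames(prox)
  ho <- hierarchical_order(prox)
  # first merge joins the two identical rows at height 0
  expect_equal(sort(-ho$tree$merge[1, ]),
               which(rownames(prox) %in% c("gut", "liver")))
  expect_equal(ho$tree$height[1], 0)
  # and they sit adjacent in the leaf order
  expect_equal(abs(diff(match(c("gut", "liver"), ho$order))), 1)

  # 5-tissue random matrix: merge heights equal the O(n^3) oracle
  set.seed(31)
  m <- matrix(rpois(25, 20), 5)
  m <- m + t(m)
  dimnames(m) <- list(paste0("T", 1:5), paste0("T", 1:5))
  h1 <- hierarchical_order(m)
  d <- 1 - suppressWarnings(stats::cor(t(m)))
  diag(d) <- 0
  expect_equal(sort(h1$tree$height), sort(naive_average_linkage(d)),
               tolerance = 1e-10)

  # constant rows get maximal distance 2.0 with a message
  mc <- m; mc[1, ] <- 7; mc[, 1] <- 7; mc[1, 1] <- 7
  expect_message(h2 <- hierarchical_order(mc), "2.0")
  expect_equal(max(h2$tree$height), 2)
  expect_error(hierarchical_order(m[1, 1, drop = FALSE]), "at least 2")
})

test_that("focal edge fraction hits the documented extremes", {
  # profile in which every focal gene peaks in liver
  prof <- rbind(f1 = c(liver = 9, gut = 1, brain = 0),
                f2 = c(liver = 8, gut = 2, brain = 0),
                f3 = c(liver = 7, gut = 1, brain = 1),
                b1 = c(liver = 0, gut = 0, brain = 9),
                b2 = c(liver = 0, gut = 1, brain = 8))
  corr <- cross_tissue_correlation(prof)
  r1 <- focal_edge_fraction(corr, c("f1", "f2", "f3"), 3, prof, "liver")
  expect_equal(r1$fraction, 1.0)
  expect_equal(r1$n_edges, 3L)
  r0 <- focal_edge_fraction(corr, c("b1", "b2"), 1, prof,
                            c("gut", "liver", "kidney"))
  expect_equal(r0$fraction, 0.0)
  expect_error(focal_edge_fraction(corr, c("f1", "zz"), 3, prof, "liver"),
               "zz")
})

test_that("control sampling is seeded, degenerate cases behave", {
  set.seed(1)
  prof <- matrix(rexp(100), nrow = 20,
                 dimnames = list(sprintf("G%02d", 1:20), paste0("T", 1:5)))
  corr <- cross_tissue_correlation(prof)
  pool <- rownames(prof)

  # reps = 1 has sd 0
  c1 <- control_fractions(corr, pool, 10, 5, reps = 1, seed = 2,
                          profile = prof, target_tissues = "T1")
  expect_equal(c1$sd, 0)

  # pool = focal set and size = |focal|: every draw identical to the focal
  foc <- pool[1:8]
  cf <- control_fractions(corr, foc, 8, 5, reps = 4, seed = 3,
                          profile = prof, target_tissues = "T1")
  ff <- focal_edge_fraction(corr, foc, 5, prof, "T1")
  expect_equal(cf$mean, ff$fraction)
  expect_equal(cf$sd, 0)

  # fixed seed reproduces the sample fractions exactly
  c2 <- control_fractions(corr, pool, 10, 5, reps = 6, seed = 9,
                          profile = prof, target_tissues = "T1")
  c3 <- control_fractions(corr, pool, 10, 5, reps = 6, seed = 9,
                          profile = prof, target_tissues = "T1")
  expect_identical(c2$samples, c3$samples)
  expect_error(control_fractions(corr, pool, 21, 5, profile = prof,
                                 target_tissues = "T1"),
               "exceeds pool size")
})
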