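test_that("covering prefix retains the shortest score-descending cover", {
  # d = 3: top-2 edges already cover all taxa
  sc <- scores_fixture(c("B/A" = 3, "C/A" = 2, "C/B" = 1))
  net <- covering_prefix_network(sc)
  expect_equal(net$q, 2L)
  expect_setequal(net$edges$ratio, c("B/A", "C/A"))

  # d = 4 with top-3 edges all among {A,B,C}: prefix extends until D appears
  sc4 <- scores_fixture(c("B/A" = 9, "C/A" = 8, "C/B" = 7, "D/A" = 2,
                          "D/B" = 1, "D/C" = 0.5))
  net4 <- covering_prefix_network(sc4)
  expect_equal(net4$q, 4L)
  expect_true("D/A" %in% net4$edges$ratio)

  # random scores on d = 8 vs an independent linear-scan oracle
  withr::with_seed(13, {
    taxa <- LETTERS[1:8]
    sc8 <- all_pairs_scores(taxa, rnorm(choose(8, 2)))
    net8 <- covering_prefix_network(sc8)
    ord <- order(-sc8$scores, names(sc8$scores))
    rt <- sc8$ratios[ord, ]
    q <- 0
    repeat {
      q <- q + 1
      sub <- rt[1:q, ]
      covered <- length(unique(c(sub$num, sub$den))) == 8
      g <- igraph::graph_from_data_frame(sub, directed = FALSE,
                                         vertices = data.frame(name = taxa))
      if (covered && igraph::is_connected(g)) break
    }
    expect_equal(net8$q, q)
    expect_identical(net8$edges$ratio, names(sc8$scores)[ord][1:q])
  })
})

test_that("maximum spanning tree is optimal, deterministic, and stable", {
  withr::with_seed(7, {
    taxa <- LETTERS[1:5]
    w <- rnorm(choose(5, 2))
    sc <- all_pairs_scores(taxa, w)
    net <- covering_prefix_network(sc)
    # build the full graph as a network for MST purposes
    full <- selenergy:::new_logratio_network(
      data.frame(num = sc$ratios$num, den = sc$ratios$den,
                 weight = unname(sc$scores), ratio = names(sc$scores)),
      taxa)
    tree <- maximum_spanning_tree(full)
    expect_equal(nrow(tree$edges), 4L)
    expect_setequal(unique(c(tree$edges$num, tree$edges$den)), taxa)

    # Cayley enumeration oracle: 5^3 = 125 labeled trees
    wt <- function(a, b) {
      key <- paste0(pmax(a, b), "/", pmin(a, b))
      unname(sc$scores[key])
    }
    expect_equal(tree$total_weight, prufer_max_weight(taxa, wt), tolerance = 1e-12)

    # igraph cross-check (negated weights -> minimum spanning tree)
    g <- igraph::graph_from_data_frame(full$edges, directed = FALSE)
    mst <- igraph::mst(g, weights = -full$edges$weight)
    expect_equal(tree$total_weight, sum(igraph::E(mst)$weight), tolerance = 1e-12)

    # repeated runs return the identical edge set; input order irrelevant
    tree2 <- maximum_spanning_tree(full)
    expect_identical(tree$edges, tree2$edges)
    shuffled <- full
    shuffled$edges <- full$edges[sample(nrow(full$edges)), ]
    expect_identical(maximum_spanning_tree(shuffled)$edges, tree$edges)

    # a tree passed in comes back unchanged
    asnet <- selenergy:::new_logratio_network(tree$edges, taxa)
    expect_setequal(maximum_spanning_tree(asnet)$edges$ratio, tree$edges$ratio)
  })
})

test_that("clustering coefficient matches hand-computed graphs", {
  tri <- data.frame(num = c("B", "C", "C"), den = c("A", "A", "B"),
                    weight = 1, ratio = c("B/A", "C/A", "C/B"))
  expect_equal(global_clustering_coefficient(tri), 1)

  path <- data.frame(num = c("B", "C", "D"), den = c("A", "B", "C"),
                     weight = 1, ratio = c("B/A", "C/B", "D/C"))
  expect_equal(global_clustering_coefficient(path), 0)

  # square A-B-C-D-A plus diagonal A-C: 2 triangles, 8 triples -> 0.75
  sq <- data.frame(num = c("B", "C", "D", "D", "C"),
                   den = c("A", "B", "C", "A", "A"), weight = 1,
                   ratio = c("B/A", "C/B", "D/C", "D/A", "C/A"))
  expect_equal(global_clustering_coefficient(sq), 0.75)

  # cross-check against igraph on a random graph
  withr::with_seed(3, {
    taxa <- LETTERS[1:7]
    pairs <- t(combn(taxa, 2))
    keep <- runif(nrow(pairs)) < 0.5
    ed <- data.frame(num = pairs[keep, 2], den = pairs[keep, 1], weight = 1,
                     ratio = paste0(pairs[keep, 2], "/", pairs[keep, 1]))
    g <- igraph::graph_from_data_frame(ed, directed = FALSE)
    ig <- igraph::transitivity(g, type = "global")
    if (is.nan(ig)) ig <- 0
    expect_equal(global_clustering_coefficient(ed), ig, tolerance = 1e-12)
  })
})

test_that("spanning-tree subframes recompute exactly and have full rank", {
  comp <- random_composition(25, 10, seed = 17)
  Z <- pairwise_logratios(comp)
  y <- two_class_labels(12, 13)
  sc <- dcv_scores(Z, y)
  tree <- maximum_spanning_tree(covering_prefix_network(sc))
  Zp <- plr_subset(Z, tree$edges)
  expect_equal(ncol(Zp), 9L)
  for (j in seq_len(ncol(Zp))) {
    expect_equal(Zp[, j], log(comp[, tree$edges$num[j]] / comp[, tree$edges$den[j]]),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  # the d-1 tree logratios span the full logratio space
  expect_equal(qr(unclass(Zp))$rank, 9L)
  expect_equal(qr(unclass(Z))$rank, 9L)
  expect_equal(global_clustering_coefficient(tree), 0)
})

test_that("network writers round-trip the edge list", {
  sc <- scores_fixture(c("B/A" = 3, "C/A" = 2, "C/B" = 1))
  net <- covering_prefix_network(sc)
  tsv <- tempfile(fileext = ".tsv")
  write_edge_list(net, tsv)
  back <- read.delim(tsv)
  expect_equal(back$num, net$edges$num)
  expect_equal(back$weight, net$edges$weight)
  gml <- tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), net$q)
})
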