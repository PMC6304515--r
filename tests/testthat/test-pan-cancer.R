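# three-cancer toy status/pair lists used across the aggregation tests
toy_status <- function() {
  list(CA = data.frame(feature_id = c("gA", "gB", "m1"),
                       final_direction = c("up", "down", "up")),
       CB = data.frame(feature_id = c("gA", "m1"),
                       final_direction = c("up", "up")),
       CC = data.frame(feature_id = c("gA", "gB"),
                       final_direction = c("down", "down")))
}

toy_pairs <- function() {
  list(CA = data.frame(mirna_id = c("m1", "m2"), gene_id = c("gA", "gB"),
                       delta_r = c(0.2, 0.5)),
       CB = data.frame(mirna_id = "m1", gene_id = "gA", delta_r = 0.3),
       CC = data.frame(mirna_id = "m1", gene_id = "gA", delta_r = 0.1))
}

test_that("status aggregation counts non-absent tokens and sorts by frequency", {
  agg <- aggregate_status(toy_status())
  expect_identical(agg$item_id, c("gA", "gB", "m1"))
  expect_identical(agg$frequency, c(3L, 2L, 2L))
  # discordant directions are retained as mixed tokens, not collapsed
  gA <- agg[agg$item_id == "gA", ]
  expect_identical(unlist(gA[, c("CA", "CB", "CC")], use.names = FALSE),
                   c("up", "up", "down"))
  # independent recount oracle over the raw lists
  recount <- vapply(agg$item_id, function(id)
    sum(vapply(toy_status(), function(st) id %in% st$feature_id, logical(1))),
    integer(1))
  expect_identical(agg$frequency, unname(recount))
})

test_that("pair aggregation keys mirna/gene and stores per-cancer delta_r", {
  agg <- aggregate_pairs(toy_pairs())
  expect_identical(agg$item_id, c("m1/gA", "m2/gB"))
  expect_identical(agg$frequency, c(3L, 1L))
  expect_equal(agg[1, c("CA", "CB", "CC")],
               data.frame(CA = 0.2, CB = 0.3, CC = 0.1), ignore_attr = TRUE)
  expect_true(is.na(agg$CB[agg$item_id == "m2/gB"]))
  empty <- aggregate_pairs(list(CA = toy_pairs()$CA[0, ]))
  expect_identical(nrow(empty), 0L)
})

test_that("published frequency tables recount through the aggregation code", {
  tab <- read_frequency_table(
    system.file("extdata", "pan_de_frequency_table.tsv", package = "mirrewire"),
    kind = "status")
  agg <- aggregate_status(tab$per_cancer)
  m <- match(tab$printed$item_id, agg$item_id)
  expect_identical(agg$frequency[m], tab$printed$frequency)
  # spot-check the published discordant case: down in THCA, up elsewhere
  mybl2 <- agg[agg$item_id == "MYBL2", ]
  expect_identical(mybl2$THCA, "down")
  expect_true(all(unlist(mybl2[, c("BLCA", "BRCA", "HNSC")]) == "up"))
})

test_that("network keeps pairs at min frequency with inherited regulation", {
  cfg <- threshold_config(min_pair_frequency = 3)
  agg <- aggregate_pairs(toy_pairs())
  net <- build_network(agg, dems = toy_status(), degs = toy_status(), cfg)
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$mirna_id, "m1")
  expect_identical(net$edges$frequency, 3L)
  expect_identical(net$edges$cancers, "CA;CB;CC")
  # nodes are exactly the endpoints of retained edges
  expect_setequal(net$nodes$id, c("m1", "gA"))
  # gA is up in two cancers and down in one: mixed
  expect_identical(net$nodes$regulation[net$nodes$id == "gA"], "mixed")
  expect_identical(net$nodes$regulation[net$nodes$id == "m1"], "up")

  # raising the cutoff never adds edges
  for (cut in 1:4) {
    n_cut <- nrow(build_network(agg, toy_status(), toy_status(),
                                threshold_config(min_pair_frequency = cut))$edges)
    if (cut > 1) expect_lte(n_cut, n_prev)
    n_prev <- n_cut
  }
  none <- build_network(agg, toy_status(), toy_status(),
                        threshold_config(min_pair_frequency = 4))
  expect_identical(nrow(none$edges), 0L)
  expect_identical(nrow(none$nodes), 0L)
})

test_that("network exports to SIF/GraphML and round-trips via the edge list", {
  cfg <- threshold_config(min_pair_frequency = 2)
  net <- build_network(aggregate_pairs(toy_pairs()), toy_status(),
                       toy_status(), cfg)
  d <- withr::local_tempdir()
  sif <- file.path(d, "net.sif")
  export_network(net, "sif", sif)
  expect_identical(readLines(sif), "m1\ttargets\tgA")
  gml <- file.path(d, "net.graphml")
  export_network(net, "graphml", gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(as.integer(igraph::vcount(g)), 2L)
  expect_setequal(igraph::V(g)$regulation, c("up", "mixed"))
  tsv <- file.path(d, "net.tsv")
  export_network(net, "tsv", tsv)
  back <- read_network_edgelist(tsv)
  expect_identical(back$edges, net$edges)
  expect_identical(back$nodes, net$nodes)
  expect_error(export_network(net, "gexf", file.path(d, "x")))
  # an empty network still writes a valid (empty) file
  empty <- build_network(aggregate_pairs(toy_pairs()), toy_status(),
                         toy_status(), threshold_config(min_pair_frequency = 5))
  export_network(empty, "sif", sif)
  expect_identical(length(readLines(sif)), 0L)
})

test_that("bipartiteness is asserted structurally", {
  bad <- structure(list(
    nodes = data.frame(id = c("x", "y"), node_type = c("miRNA", "miRNA"),
                       regulation = c("up", "up")),
    edges = data.frame(mirna_id = "x", gene_id = "y", frequency = 3L,
                       cancers = "CA")), class = "bipartite_network")
  expect_error(mirrewire:::as_igraph_network(bad), "bipartite")
})

test_that("pan aggregation over pipeline results builds tables and network", {
  # three pseudo-cancers from different seeds of the same generator
  results <- lapply(c(301L, 302L, 303L), function(s) {
    coh <- generate_cohort(small_config(seed = s))
    run_single_cancer(coh$mrna, coh$mirna, coh$samples, coh$db)
  })
  names(results) <- c("CA", "CB", "CC")
  pan <- run_pan(results, threshold_config())
  # frequency equals an independent recount from the raw per-cancer lists
  for (i in sample(nrow(pan$pairs), min(10, nrow(pan$pairs)))) {
    key <- pan$pairs$item_id[i]
    recount <- sum(vapply(results, function(r)
      key %in% pair_key(r$paired_pairs), logical(1)))
    expect_identical(pan$pairs$frequency[i], as.integer(recount))
  }
  expect_true(all(pan$network$edges$frequency >= 3))
  d <- withr::local_tempdir()
  write_pan(pan, d)
  expect_true(all(file.exists(file.path(d, c("pan_features.tsv",
                                             "pan_pairs.tsv", "network.sif",
                                             "network.graphml",
                                             "network_edges.tsv")))))
  # "/" renders absent entries in the written tables
  feat <- readLines(file.path(d, "pan_features.tsv"))
  expect_true(any(grepl("\t/\t", feat)) || all(pan$features$frequency == 3))
})
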