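mk_pairs <- function(mirna, mdir, transcript, kind, tdir, n_sites = 1L) {
  data.frame(mirna = mirna, mirna_direction = mdir, transcript = transcript,
             kind = kind, transcript_direction = tdir,
             n_sites = as.integer(n_sites), stringsAsFactors = FALSE)
}

test_that("directionality filter keeps only opposite-direction sited pairs", {
  de_mir <- data.frame(feature = c("m1", "m2"), direction = c("up", "up"))
  de_tx <- data.frame(feature = c("g1", "g2", "l1"),
                      kind = c("mRNA", "mRNA", "lncRNA"),
                      direction = c("down", "up", "down"))
  sites <- data.frame(mirna = c("m1", "m1", "m1", "m2"),
                      transcript = c("g1", "g2", "l1", "g3"),
                      n_sites = c(2L, 1L, 1L, 5L))
  out <- filter_directional_pairs(de_mir, de_tx, sites)
  # m1-g1 kept (up/down, 2 sites); m1-g2 dropped (up/up);
  # m1-l1 kept; m2-g3 dropped (g3 not DE)
  expect_equal(out$transcript, c("g1", "l1"))
  expect_equal(out$n_sites, c(2L, 1L))
  expect_true(all(out$mirna_direction != out$transcript_direction))
  expect_error(
    filter_directional_pairs(data.frame(feature = "m", direction = "none"),
                             de_tx, sites), "up")
})

test_that("triplet assembly is the per-miRNA cartesian product", {
  lnc <- mk_pairs("m", "up", "l1", "lncRNA", "down")
  mrna <- mk_pairs("m", "up", "g1", "mRNA", "down")
  expect_equal(nrow(assemble_triplets(lnc, mrna)), 1L)

  lnc3 <- mk_pairs(rep("m", 3), "up", paste0("l", 1:3), "lncRNA", "down")
  mrna4 <- mk_pairs(rep("m", 4), "up", paste0("g", 1:4), "mRNA", "down")
  got <- assemble_triplets(lnc3, mrna4)
  expect_equal(nrow(got), 12L)
  expect_equal(nrow(unique(got[, c("lncrna", "mrna")])), 12L)

  expect_equal(nrow(assemble_triplets(lnc3, mk_pairs("other", "up", "g9",
                                                     "mRNA", "down"))), 0L)
})

test_that("triplet counts equal the combinatorial oracle on random input", {
  set.seed(31)
  for (rep in 1:20) {
    mirs <- sprintf("m%d", 1:6)
    lnc <- mk_pairs(sample(mirs, 15, TRUE), "up",
                    sprintf("l%d", sample(1:8, 15, TRUE)), "lncRNA", "down")
    lnc <- lnc[!duplicated(lnc[, c("mirna", "transcript")]), ]
    mrna <- mk_pairs(sample(mirs, 20, TRUE), "up",
                     sprintf("g%d", sample(1:10, 20, TRUE)), "mRNA", "down")
    mrna <- mrna[!duplicated(mrna[, c("mirna", "transcript")]), ]
    got <- assemble_triplets(lnc, mrna)
    want <- sum(vapply(mirs, function(m)
      sum(lnc$mirna == m) * sum(mrna$mirna == m), numeric(1)))
    expect_equal(nrow(got), want)
  }
})

test_that("one triplet yields a 3-node path with degrees 1,2,1", {
  trip <- data.frame(lncrna = "l1", mirna = "m1", mrna = "g1",
                     lnc_sites = 1L, mrna_sites = 1L)
  net <- build_network(trip)
  expect_equal(igraph::vcount(net$graph), 3L)
  expect_equal(igraph::ecount(net$graph), 2L)
  deg <- setNames(net$degree$degree, net$degree$node)
  expect_equal(deg[["m1"]], 2L)
  expect_equal(deg[["l1"]], 1L)
  expect_equal(deg[["g1"]], 1L)
})

test_that("shared arms are not duplicated as edges", {
  trip <- data.frame(lncrna = c("l1", "l1"), mirna = c("m1", "m1"),
                     mrna = c("g1", "g2"), lnc_sites = 1L, mrna_sites = 1L)
  net <- build_network(trip)
  expect_equal(igraph::ecount(net$graph), 3L)  # l1-m1 shared, two mRNA arms
  expect_equal(sum(net$degree$degree), 2L * igraph::ecount(net$graph))
})

test_that("network is layered bipartite: no lncRNA-mRNA or same-kind edges", {
  set.seed(32)
  trip <- data.frame(
    lncrna = sprintf("l%d", sample(1:10, 40, TRUE)),
    mirna = sprintf("m%d", sample(1:8, 40, TRUE)),
    mrna = sprintf("g%d", sample(1:15, 40, TRUE)),
    lnc_sites = 1L, mrna_sites = 1L)
  trip <- unique(trip)
  net <- build_network(trip)
  e <- igraph::as_data_frame(net$graph, what = "edges")
  v <- igraph::as_data_frame(net$graph, what = "vertices")
  kind <- setNames(v$kind, v$name)
  expect_true(all(kind[e$from] == "miRNA" | kind[e$to] == "miRNA"))
  expect_false(any(kind[e$from] == kind[e$to]))

  # degree table equals exhaustive incidence counting
  inc <- table(c(e$from, e$to))
  for (i in seq_len(nrow(net$degree)))
    expect_equal(net$degree$degree[i],
                 as.integer(inc[[net$degree$node[i]]]))
})

test_that("regulation conflicts across inputs are rejected", {
  trip <- data.frame(lncrna = "l1", mirna = "m1", mrna = "g1",
                     lnc_sites = 1L, mrna_sites = 1L)
  reg <- data.frame(feature = c("m1", "m1"), direction = c("up", "down"))
  expect_error(build_network(trip, reg), "conflicting")
  net <- build_network(trip, data.frame(feature = "m1", direction = "up"))
  expect_equal(net$degree$regulation[net$degree$node == "m1"], "up")
})

test_that("hub ranking sorts by degree with lexicographic tie-break", {
  trip <- data.frame(
    lncrna = rep("lc", 5), mirna = sprintf("m%d", 1:5),
    mrna = sprintf("g%d", 1:5), lnc_sites = 1L, mrna_sites = 1L)
  net <- build_network(trip)  # lc is degree 5, each miRNA 2, each gene 1
  expect_equal(rank_hubs(net, 1)$node, "lc")
  # within the tied degree-2 miRNAs, lexicographic order decides
  top4 <- rank_hubs(net, 4)$node
  expect_equal(top4, c("lc", "m1", "m2", "m3"))
  expect_equal(nrow(rank_hubs(net, 100)), igraph::vcount(net$graph))

  set.seed(33)
  trip2 <- unique(data.frame(
    lncrna = sprintf("l%d", sample(1:12, 60, TRUE)),
    mirna = sprintf("m%d", sample(1:9, 60, TRUE)),
    mrna = sprintf("g%d", sample(1:20, 60, TRUE)),
    lnc_sites = 1L, mrna_sites = 1L))
  net2 <- build_network(trip2)
  full_sort <- net2$degree[order(-net2$degree$degree, net2$degree$node), ]
  expect_equal(rank_hubs(net2, 10), head(full_sort, 10),
               ignore_attr = TRUE)
})

test_that("subnet extraction equals a breadth-first search oracle", {
  set.seed(34)
  trip <- unique(data.frame(
    lncrna = sprintf("l%d", sample(1:10, 50, TRUE)),
    mirna = sprintf("m%d", sample(1:8, 50, TRUE)),
    mrna = sprintf("g%d", sample(1:15, 50, TRUE)),
    lnc_sites = 1L, mrna_sites = 1L))
  net <- build_network(trip)
  e <- igraph::as_data_frame(net$graph, what = "edges")
  adj <- split(c(e$to, e$from), c(e$from, e$to))

  bfs_oracle <- function(seeds, radius) {
    level <- seeds
    seen <- seeds
    for (r in seq_len(radius)) {
      level <- setdiff(unique(unlist(adj[level])), seen)
      seen <- c(seen, level)
    }
    sort(seen)
  }
  seed <- "m1"
  sub1 <- extract_subnet(net, seed, radius = 1)
  expect_equal(sort(igraph::V(sub1$graph)$name), bfs_oracle(seed, 1))
  # radius 1 around a miRNA is the miRNA plus all partners
  expect_setequal(igraph::V(sub1$graph)$name,
                  c(seed, unlist(adj[[seed]])))
  sub0 <- extract_subnet(net, c("m1", "m2"), radius = 0)
  expect_setequal(igraph::V(sub0$graph)$name, c("m1", "m2"))
  sub2 <- extract_subnet(net, seed, radius = 2)
  expect_equal(sort(igraph::V(sub2$graph)$name), bfs_oracle(seed, 2))
  expect_error(extract_subnet(net, "nope"), "unknown seed")
})

test_that("network export writes deterministic files", {
  trip <- data.frame(lncrna = c("l1", "l2"), mirna = "m1",
                     mrna = c("g1", "g2"), lnc_sites = 1L, mrna_sites = 1L)
  net <- build_network(trip)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f1)
  write_network(net, f2)
  expect_identical(readLines(f1), readLines(f2))
  g <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, g, format = "graphml")
  expect_true(any(grepl("graphml", readLines(g))))
})
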