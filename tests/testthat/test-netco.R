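test_that("taxon filtering applies the abundance and prevalence rules exactly", {
  # 6-genus fixture with hand-computed cumulative shares over 10 samples
  mat <- rbind(
    high2   = c(0.5, 0.5, rep(0, 8)),        # big but in only 2 samples
    rare10  = rep(0.004, 10),                 # 10 samples, share 0.4%
    ok      = rep(0.05, 10),
    ok2     = rep(0.03, 10),
    border  = rep(0.0005 * 10.04 / 10 * 1.0001, 10),
    big     = c(rep(0, 7), 0.3, 0.3, 0.3)
  )
  colnames(mat) <- paste0("s", 1:10)
  mat <- rbind(mat, filler = pmax(1 - colSums(mat), 0))
  tab <- structure(list(mat = mat,
                        taxonomy = parse_taxonomy(NULL, rownames(mat)),
                        mode = "relative"),
                   class = "abundance_table")
  suppressMessages(kept <- filter_taxa(tab))
  expect_false("high2" %in% rownames(kept$mat))   # prevalence rule
  expect_false("rare10" %in% rownames(kept$mat))  # abundance rule
  expect_true(all(c("ok", "ok2", "big", "filler") %in% rownames(kept$mat)))
  expect_gte(attr(kept, "removed_abundance"), 1)
  expect_gte(attr(kept, "removed_prevalence"), 1)
  # counts-mode input is rejected
  expect_error(filter_taxa(toy_table()), "relative")
  # over-aggressive thresholds give an informative error
  expect_error(suppressMessages(filter_taxa(tab, min_cum_abundance = 0.99)),
               "threshold")
})

test_that("network edges reproduce the exhaustive all-pairs oracle", {
  tab <- blocky_relative_table(n_samples = 12, blocks = list(1:3, 4:5),
                               n_taxa = 8, seed = 23)
  net <- build_network(tab)
  orc <- oracle_edges(tab$mat)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_setequal(key(net$edges$source, net$edges$target),
                  key(orc$source, orc$target))
  m <- merge(net$edges, orc, by = c("source", "target"))
  expect_equal(m$r.x, m$r.y, tolerance = 1e-12)
  # the planted blocks are fully connected and perfectly concordant pairs hit r = 1
  expect_true(all(key("t1", c("t2", "t3")) %in%
                  key(net$edges$source, net$edges$target)))
  expect_true(all(net$edges$sign[net$edges$r > 0] == "positive"))
})

test_that("identical rank profiles give a perfect positive edge; constants are excluded", {
  # ranks are what matters; no column normalization so `flat` stays constant
  mat <- rbind(a = 1:10, b = (1:10)^2, flat = rep(1, 10),
               noise = c(3, 1, 4, 1, 5, 9, 2, 6, 8, 7))
  colnames(mat) <- paste0("s", 1:10)
  tab <- structure(list(mat = mat,
                        taxonomy = parse_taxonomy(NULL, rownames(mat)),
                        mode = "relative"),
                   class = "abundance_table")
  expect_warning(net <- build_network(tab), "flat")
  ab <- net$edges[net$edges$source == "a" & net$edges$target == "b", ]
  expect_equal(ab$r, 1)
  expect_equal(ab$sign, "positive")
})

test_that("independent genera stay below 5% edge density", {
  set.seed(24)
  dens <- vapply(1:20, function(i) {
    mat <- matrix(rexp(30 * 30), 30, 30)
    mat <- sweep(mat, 2, colSums(mat), "/")
    rownames(mat) <- paste0("g", 1:30)
    colnames(mat) <- paste0("s", 1:30)
    tab <- structure(list(mat = mat,
                          taxonomy = parse_taxonomy(NULL, rownames(mat)),
                          mode = "relative"),
                     class = "abundance_table")
    nrow(build_network(tab)$edges) / choose(30, 2)
  }, numeric(1))
  expect_lt(mean(dens), 0.05)
})

test_that("topology metrics match closed forms on canonical graphs", {
  tri <- igraph::make_ring(3)
  t_tri <- network_topology(tri, detect = FALSE)
  expect_equal(t_tri$average_degree, 2)
  expect_equal(t_tri$clustering_coefficient, 1)
  expect_equal(t_tri$average_path_length, 1)
  path <- igraph::make_graph(~ a - b, b - c)
  t_path <- network_topology(path, detect = FALSE)
  expect_equal(t_path$clustering_coefficient, 0)
  expect_equal(t_path$average_path_length, 4 / 3)
  expect_equal(t_path$average_degree, 4 / 3)
  # edgeless graph: clustering and path length are undefined markers
  lone <- igraph::make_empty_graph(3, directed = FALSE)
  t_lone <- network_topology(lone, detect = FALSE)
  expect_true(is.na(t_lone$clustering_coefficient))
  expect_true(is.na(t_lone$average_path_length))
})

test_that("positive-edge fraction reflects the built edge signs", {
  # construct a network with a planted positive/negative split (58 / 45)
  set.seed(25)
  n_pos <- 58; n_neg <- 45
  shared <- rnorm(20)
  mat <- rbind(
    t(sapply(seq_len(n_pos), function(i) shared + rnorm(20, 0, 0.05))),
    t(sapply(seq_len(n_neg), function(i) -shared + rnorm(20, 0, 0.05))))
  # keep only hub-spoke pairs: hub row correlates +1 with first block, -1 with second
  hub <- shared
  mat <- rbind(hub, mat)
  rownames(mat) <- c("hub", paste0("p", seq_len(n_pos)), paste0("n", seq_len(n_neg)))
  colnames(mat) <- paste0("s", 1:20)
  mat <- exp(mat); mat <- sweep(mat, 2, colSums(mat), "/")
  tab <- structure(list(mat = mat,
                        taxonomy = parse_taxonomy(NULL, rownames(mat)),
                        mode = "relative"),
                   class = "abundance_table")
  net <- build_network(tab)
  topo <- network_topology(net, detect = FALSE)
  expect_equal(topo$positive_edge_fraction,
               100 * mean(net$edges$sign == "positive"))
  expect_gt(topo$positive_edge_fraction, 50)
  expect_lt(topo$positive_edge_fraction, 65)
})

test_that("Louvain recovers the two-clique partition with the hand-derived modularity", {
  g <- two_clique_graph()
  mods <- detect_modules(g, seed = 2)
  expect_equal(mods$n_modules, 2)
  expect_equal(sort(as.integer(table(mods$membership))), c(4L, 4L))
  # hand evaluation: m = 13, within = 12/13, degree halves -> Q = 12/13 - 1/2
  expect_equal(mods$modularity, 12 / 13 - 1 / 2, tolerance = 1e-12)
  # oracle from the definition on the found membership
  el <- igraph::as_edgelist(g)
  expect_equal(oracle_modularity(el, mods$membership), mods$modularity,
               tolerance = 1e-12)
  # a random partition never beats the Louvain one
  set.seed(26)
  for (i in 1:10) {
    rand <- sample(1:2, 8, replace = TRUE)
    expect_lte(oracle_modularity(el, rand), mods$modularity + 1e-12)
  }
  # complete graph has no structure
  mods_k <- detect_modules(igraph::make_full_graph(8), seed = 1)
  expect_lt(mods_k$modularity, 0.1)
  expect_true(mods_k$modularity >= -0.5 && mods_k$modularity <= 1)
})

test_that("Louvain recovers planted three-block structure", {
  recovered <- vapply(1:10, function(s) {
    set.seed(s + 400)
    g <- igraph::sample_sbm(90, pref.matrix = diag(0.49, 3) + 0.01,
                            block.sizes = rep(30, 3))
    mods <- detect_modules(g, seed = s)
    mods$n_major_modules == 3 && mods$modularity > 0.4
  }, logical(1))
  expect_true(all(recovered))
})

test_that("G(n,m) replicates have exactly the requested size and no defects", {
  ens <- er_null_ensemble(30, 60, n_replicates = 20, seed = 5,
                          detect_modules = FALSE)
  expect_equal(nrow(ens$replicates), 20)
  expect_true(all(ens$replicates$average_degree == 2 * 60 / 30))
  # directly inspect replicates for simplicity and exact edge count
  with_seed_graphs <- with(list(), {
    set.seed(pahnet:::child_seed(5, "null"))
    lapply(1:5, function(i) igraph::sample_gnm(30, 60))
  })
  for (g in with_seed_graphs) {
    expect_equal(igraph::ecount(g), 60)
    expect_false(any(igraph::which_loop(g)))
    expect_false(any(igraph::which_multiple(g)))
  }
  # saturated case: complete graph, zero variance across replicates
  sat <- er_null_ensemble(6, 15, n_replicates = 5, seed = 1,
                          detect_modules = FALSE)
  expect_equal(unique(sat$replicates$clustering_coefficient), 1)
  expect_equal(sat$summary$sd[sat$summary$metric == "clustering_coefficient"], 0)
  expect_error(er_null_ensemble(5, 11), "infeasible")
})

test_that("small-world assessment flags structured graphs and not null draws", {
  g <- two_clique_graph()
  topo <- network_topology(g, seed = 1)
  null <- er_null_ensemble(topo$n_nodes, topo$n_edges, n_replicates = 60,
                           seed = 9)
  sw <- small_world_assessment(topo, null)
  mt <- sw$metrics
  expect_true(mt$exceeds_null[mt$metric == "clustering_coefficient"])
  expect_true(mt$exceeds_null[mt$metric == "modularity"])
  expect_true(sw$verdict)
  expect_match(sw$note, "identical by construction")
  # a draw from its own null shows no systematic excess
  set.seed(27)
  zs <- vapply(1:15, function(i) {
    gg <- igraph::sample_gnm(24, 40)
    tt <- network_topology(gg, seed = i)
    nn <- er_null_ensemble(24, 40, n_replicates = 40, seed = i + 100)
    ss <- small_world_assessment(tt, nn)
    max(abs(ss$metrics$z), na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(zs < 3), 0.9)
  # mismatched null is rejected
  bad_null <- er_null_ensemble(10, 12, n_replicates = 5, seed = 1,
                               detect_modules = FALSE)
  expect_error(small_world_assessment(topo, bad_null), "generated at")
})

test_that("keystone ranking equals brute-force betweenness enumeration", {
  # star: hub maximal, leaves zero
  star_tab <- blocky_relative_table(n_samples = 10, blocks = list(),
                                    n_taxa = 5, seed = 28)
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("t", 1:6)
  fake_net <- structure(list(
    graph = star,
    edges = igraph::as_data_frame(star),
    nodes = data.frame(taxon_id = paste0("t", 1:6),
                       genus = c("Halomonas", "Pseudomonas", "", "g4", "g5", "g6"),
                       phylum = "Proteobacteria", stringsAsFactors = FALSE)
  ), class = "cooccurrence_network")
  ks <- keystone_taxa(fake_net, top_k = 6)
  expect_equal(ks$taxon_id[1], "t1")
  expect_true(all(ks$betweenness[-1] == 0))
  # unresolved genera can be excluded from the ranking
  ks2 <- keystone_taxa(fake_net, top_k = 5, exclude_unclassified = TRUE)
  expect_false("t3" %in% ks2$taxon_id)
  expect_warning(keystone_taxa(fake_net, top_k = 99), "exceeds")

  # 8-node fixture vs exhaustive shortest-path enumeration oracle
  set.seed(29)
  repeat {
    adj <- matrix(0, 8, 8, dimnames = list(paste0("v", 1:8), paste0("v", 1:8)))
    idx <- which(upper.tri(adj))
    on <- sample(idx, 12)
    adj[on] <- 1; adj <- adj + t(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::components(g)$no == 1) break
  }
  igraph::V(g)$name <- rownames(adj)
  net8 <- structure(list(
    graph = g, edges = igraph::as_data_frame(g),
    nodes = data.frame(taxon_id = rownames(adj), genus = rownames(adj),
                       phylum = "p", stringsAsFactors = FALSE)
  ), class = "cooccurrence_network")
  ks8 <- keystone_taxa(net8, top_k = 8)
  orc <- oracle_betweenness(adj)
  expect_equal(setNames(ks8$betweenness, ks8$taxon_id)[names(orc)], orc,
               tolerance = 1e-10)
})

test_that("network exports round-trip through GraphML and stay Gephi-consistent", {
  tab <- blocky_relative_table(n_samples = 12, blocks = list(1:4),
                               n_taxa = 6, seed = 30)
  net <- build_network(tab)
  mods <- detect_modules(net, seed = 1)
  dir <- withr::local_tempdir()
  paths <- export_network(net,
                          graphml = file.path(dir, "net.graphml"),
                          gexf = file.path(dir, "net.gexf"),
                          edge_csv = file.path(dir, "edges.csv"),
                          topology_json = file.path(dir, "topo.json"),
                          modules = mods)
  expect_true(all(file.exists(paths)))
  back <- igraph::read_graph(file.path(dir, "net.graphml"), format = "graphml")
  expect_equal(igraph::vcount(back), nrow(net$nodes))
  expect_equal(igraph::ecount(back), nrow(net$edges))
  expect_equal(sort(igraph::V(back)$name), sort(net$nodes$taxon_id))
  edges_back <- read.csv(file.path(dir, "edges.csv"))
  expect_equal(nrow(edges_back), nrow(net$edges))
  topo <- jsonlite::read_json(file.path(dir, "topo.json"))
  expect_equal(topo$n_edges, nrow(net$edges))
  # GEXF is well-formed XML with every node and edge
  gexf <- xml2::read_xml(file.path(dir, "net.gexf"))
  expect_equal(length(xml2::xml_find_all(gexf, ".//*[local-name()='node']")),
               nrow(net$nodes))
  expect_equal(length(xml2::xml_find_all(gexf, ".//*[local-name()='edge']")),
               nrow(net$edges))
})
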