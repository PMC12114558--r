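# Shared fixture builders; all data is generated in code.

# tiny counts table: 5 genera in 2 phyla across 3 samples
toy_table <- function() {
  mat <- matrix(c(10, 5, 0,
                  20, 0, 1,
                  0, 8, 4,
                  3, 3, 3,
                  7, 0, 2), nrow = 5, byrow = TRUE,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  lin <- c(
    "k__Bacteria;p__Proteobacteria;c__A;o__A;f__A;g__Halomonas",
    "k__Bacteria;p__Proteobacteria;c__A;o__A;f__A;g__Pseudomonas",
    "k__Bacteria;p__Proteobacteria;c__B;o__B;f__B;g__Marinobacter",
    "k__Bacteria;p__Firmicutes;c__C;o__C;f__C;g__Bacillus",
    "k__Bacteria;p__Firmicutes;c__C;o__C;f__C;g__"
  )
  abundance_table(mat, taxonomy = lin, mode = "counts")
}

# igraph: two K4 cliques joined by a single bridge edge (8 nodes, 13 edges)
two_clique_graph <- function() {
  edges <- rbind(t(utils::combn(1:4, 2)), t(utils::combn(5:8, 2)), c(4, 5))
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

# relative-mode table whose rows are built to a target correlation pattern:
# genera within `blocks` share a latent profile, others are independent
blocky_relative_table <- function(n_samples = 12, blocks = list(1:3, 4:5),
                                  n_taxa = 7, noise = 0.05, seed = 42) {
  set.seed(seed)
  base <- matrix(rnorm(n_taxa * n_samples, 0, 1), n_taxa, n_samples)
  for (b in blocks) {
    shared <- rnorm(n_samples)
    for (i in b) base[i, ] <- shared + rnorm(n_samples, 0, noise)
  }
  mat <- exp(base)
  mat <- sweep(mat, 2, colSums(mat), "/")
  rownames(mat) <- paste0("t", seq_len(n_taxa))
  colnames(mat) <- paste0("s", seq_len(n_samples))
  abundance_table(mat, mode = "relative")
}

# small study config keeping unit tests fast; callers may override any field
small_config <- function(...) {
  args <- utils::modifyList(
    list(samples_per_cell = 5L, n_genera = 60L, depth = 20000L),
    list(...))
  do.call(study_config, args)
}
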