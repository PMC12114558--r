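# Co-occurrence network construction, topology, Louvain modules,
# Erdos-Renyi null ensembles, small-world assessment and keystone ranking.

#' Filter genera before network construction
#'
#' Retains genera whose cumulative relative abundance across all samples is
#' at least `min_cum_abundance` (default 0.5%) of the table total AND that
#' are detected (nonzero) in at least `min_prevalence` samples (default 3).
#' Counts removed by each rule are reported as attributes and a message.
#'
#' @param tab A relative-mode [abundance_table()] at genus level (convert
#'   counts with [to_relative()] first).
#' @param min_cum_abundance Cumulative-abundance threshold as a fraction of
#'   the table total (default 0.005).
#' @param min_prevalence Minimum number of samples with nonzero abundance
#'   (default 3).
#' @param top_n Optional pre-selection: keep only the `top_n` genera by mean
#'   relative abundance before applying the two rules (disabled by default).
#' @return The filtered `abundance_table` with attributes
#'   `removed_abundance`, `removed_prevalence`.
#' @export
filter_taxa <- function(tab, min_cum_abundance = 0.005, min_prevalence = 3L,
                        top_n = NULL) {
  stopifnot(inherits(tab, "abundance_table"))
  if (tab$mode != "relative")
    stop("filter_taxa expects a relative-mode table; use to_relative() first")
  mat <- tab$mat
  if (!is.null(top_n)) {
    keep_top <- rank(-rowMeans(mat), ties.method = "first") <= top_n
    mat <- mat[keep_top, , drop = FALSE]
  }
  cum_share <- rowSums(mat) / sum(tab$mat)
  prevalence <- rowSums(mat > 0)
  pass_ab <- cum_share >= min_cum_abundance
  pass_prev <- prevalence >= min_prevalence
  keep <- pass_ab & pass_prev
  if (!any(keep))
    stop("no genera survive filtering; review the abundance (",
         min_cum_abundance, ") and prevalence (", min_prevalence,
         ") thresholds")
  # a filtered relative table is a sub-composition: columns sum to < 1 by
  # design, so bypass the full-composition column-sum check
  out <- structure(list(mat = mat[keep, , drop = FALSE],
                        taxonomy = tab$taxonomy[rownames(mat)[keep], ],
                        mode = "relative"),
                   class = "abundance_table")
  attr(out, "removed_abundance") <- sum(!pass_ab)
  attr(out, "removed_prevalence") <- sum(!pass_prev)
  message(sum(!keep), " of ", nrow(mat), " genera removed (",
          sum(!pass_ab), " below cumulative abundance, ",
          sum(!pass_prev), " below prevalence)")
  out
}

#' Build a co-occurrence network
#'
#' Computes all pairwise Spearman correlations between genera across samples
#' and adds an undirected edge wherever `|r| > r_threshold` and
#' `p < p_threshold` (defaults 0.6 and 0.01; p from the t approximation on
#' n - 2 df). The threshold is applied to the magnitude of r; the sign is
#' kept as an edge attribute (negative associations are real edges).
#' Constant genera are excluded from pairing with a warning. By default the
#' network's nodes are the genera incident to at least one edge.
#'
#' @param tab A filtered relative-mode [abundance_table()] with >= 4 samples
#'   and >= 2 genera.
#' @param r_threshold Correlation-magnitude threshold (default 0.6).
#' @param p_threshold p-value threshold (default 0.01).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param adjust_bh Apply Benjamini-Hochberg correction to edge p-values
#'   before thresholding? (off by default; raw p is conventional).
#' @param keep_isolates Keep genera without any edge as isolated nodes?
#' @return Object of class `cooccurrence_network`: `graph` (igraph),
#'   `edges` (data.frame `source, target, r, p, sign`), `nodes` (data.frame
#'   `taxon_id, lineage, genus, phylum, mean_abundance`), `provenance`.
#' @export
build_network <- function(tab, r_threshold = 0.6, p_threshold = 0.01,
                          method = c("spearman", "pearson"),
                          adjust_bh = FALSE, keep_isolates = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(tab, "abundance_table"))
  mat <- tab$mat
  if (ncol(mat) < 4L) stop("need at least 4 samples")
  if (nrow(mat) < 2L) stop("need at least 2 genera")
  constant <- apply(mat, 1L, function(x) var(x) == 0)
  if (any(constant)) {
    warning("constant genus row(s) excluded from pairing: ",
            paste(rownames(mat)[constant], collapse = ", "))
    mat <- mat[!constant, , drop = FALSE]
  }
  res <- cor_with_p(t(mat), method = method)
  r <- res$r; p <- res$p
  idx <- which(upper.tri(r), arr.ind = TRUE)
  pvec <- p[idx]
  if (adjust_bh) pvec <- stats::p.adjust(pvec, method = "BH")
  hit <- abs(r[idx]) > r_threshold & pvec < p_threshold
  edges <- data.frame(
    source = rownames(mat)[idx[hit, 1L]],
    target = rownames(mat)[idx[hit, 2L]],
    r = r[idx][hit],
    p = pvec[hit],
    stringsAsFactors = FALSE
  )
  edges$sign <- ifelse(edges$r > 0, "positive", "negative")
  node_ids <- if (keep_isolates) rownames(mat)
              else sort(unique(c(edges$source, edges$target)))
  lineages <- lineage_strings(tab)[node_ids]
  nodes <- data.frame(
    taxon_id = node_ids,
    lineage = unname(lineages),
    genus = tab$taxonomy[node_ids, "genus"],
    phylum = tab$taxonomy[node_ids, "phylum"],
    mean_abundance = rowMeans(tab$mat)[node_ids],
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(
    graph = g, edges = edges, nodes = nodes,
    provenance = list(r_threshold = r_threshold, p_threshold = p_threshold,
                      method = method, adjust_bh = adjust_bh,
                      n_samples = ncol(mat), n_input_taxa = nrow(mat),
                      samples = colnames(mat))
  ), class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf(
    "cooccurrence_network: %d nodes, %d edges (|r| > %.2f, p < %.3g, %s)\n",
    nrow(x$nodes), nrow(x$edges), x$provenance$r_threshold,
    x$provenance$p_threshold, x$provenance$method))
  invisible(x)
}

as_unweighted_graph <- function(net) {
  if (inherits(net, "cooccurrence_network")) net$graph
  else if (inherits(net, "igraph")) net
  else stop("expected a cooccurrence_network or igraph object")
}

#' Network topology metrics
#'
#' Node and edge counts, positive-edge percentage, average degree
#' (`2m / n`), mean local clustering coefficient (nodes of degree < 2
#' contribute 0), average shortest path length over the largest connected
#' component, and Louvain modularity with module counts. Path length and
#' clustering are `NA` for edgeless graphs.
#'
#' @param net A `cooccurrence_network` or igraph graph.
#' @param seed Seed for the Louvain restarts.
#' @param detect Run module detection? (set `FALSE` to skip the most
#'   expensive metric, e.g. inside large null ensembles).
#' @return List of class `network_topology` with fields `n_nodes`,
#'   `n_edges`, `positive_edge_fraction` (%, `NA` for unsigned graphs),
#'   `average_degree`, `clustering_coefficient`, `average_path_length`,
#'   `modularity`, `n_modules`, `n_major_modules`.
#' @export
network_topology <- function(net, seed = 1L, detect = TRUE) {
  g <- as_unweighted_graph(net)
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  pos_frac <- if (inherits(net, "cooccurrence_network") && nrow(net$edges))
    100 * mean(net$edges$sign == "positive") else NA_real_
  if (m == 0L) {
    clus <- NA_real_; apl <- NA_real_
  } else {
    lc <- igraph::transitivity(g, type = "local", isolates = "zero")
    lc[is.na(lc)] <- 0
    clus <- mean(lc)
    comp <- igraph::components(g)
    big <- igraph::induced_subgraph(g, which(comp$membership ==
                                               which.max(comp$csize)))
    apl <- igraph::mean_distance(big, directed = FALSE)
  }
  mods <- if (detect && m > 0L) detect_modules(g, seed = seed) else NULL
  structure(list(
    n_nodes = n, n_edges = m,
    positive_edge_fraction = pos_frac,
    average_degree = if (n > 0L) 2 * m / n else NA_real_,
    clustering_coefficient = clus,
    average_path_length = apl,
    modularity = if (is.null(mods)) NA_real_ else mods$modularity,
    n_modules = if (is.null(mods)) NA_integer_ else mods$n_modules,
    n_major_modules = if (is.null(mods)) NA_integer_ else mods$n_major_modules
  ), class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf(paste0(
    "network_topology: %d nodes, %d edges, <k> = %.2f\n",
    "  clustering %.3f | path length %.3f | modularity %.3f ",
    "(%s modules, %s major)\n"),
    x$n_nodes, x$n_edges, x$average_degree, x$clustering_coefficient,
    x$average_path_length, x$modularity, x$n_modules, x$n_major_modules))
  invisible(x)
}

#' Louvain module detection
#'
#' Greedy modularity optimization (Louvain) on the unsigned, unweighted
#' graph, best of `n_restarts` seeded runs. Modularity is
#' \eqn{Q = \sum_i (e_{ii}/m - (d_i/2m)^2)}. "Major" modules contain at
#' least `major_fraction` of the nodes.
#'
#' @param net A `cooccurrence_network` or igraph graph with >= 1 edge.
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed Seed for the restart stream.
#' @param n_restarts Number of Louvain runs (default 10).
#' @param major_fraction Node fraction defining a major module
#'   (default 0.05).
#' @return List: `membership` (named integer vector), `modularity`,
#'   `n_modules`, `n_major_modules`, `sizes`.
#' @export
detect_modules <- function(net, resolution = 1, seed = 1L, n_restarts = 10L,
                           major_fraction = 0.05) {
  g <- as_unweighted_graph(net)
  if (igraph::ecount(g) == 0L) stop("module detection needs at least 1 edge")
  if ("weight" %in% igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, "weight")   # unweighted by design
  best <- NULL
  with_stage_seed(seed, "modules", {
    for (i in seq_len(n_restarts)) {
      cl <- igraph::cluster_louvain(g, resolution = resolution)
      q <- igraph::modularity(g, igraph::membership(cl))
      if (is.null(best) || q > best$q) best <- list(cl = cl, q = q)
    }
  })
  memb <- igraph::membership(best$cl)
  sizes <- table(memb)
  structure(list(
    membership = setNames(as.integer(memb), names(memb)),
    modularity = best$q,
    n_modules = length(sizes),
    n_major_modules = sum(sizes >= major_fraction * igraph::vcount(g)),
    sizes = as.integer(sizes)
  ), class = "module_partition")
}

#' Erdos-Renyi G(n, m) null ensemble
#'
#' Generates `n_replicates` uniform random simple graphs with exactly the
#' real network's node and edge counts, computes the topology of each, and
#' summarizes the ensemble (mean and SD per metric). Average degree is
#' identical to the real network by construction.
#'
#' @param n_nodes,n_edges Node and edge counts to match.
#' @param n_replicates Ensemble size (default 100).
#' @param seed Seed for the replicate stream.
#' @param detect_modules Compute Louvain modularity per replicate? (default
#'   TRUE; the dominant cost for large graphs).
#' @return List of class `null_ensemble`: `replicates` (data.frame of
#'   per-replicate metrics), `summary` (mean and sd per metric),
#'   `n_replicates`, `seed`.
#' @export
er_null_ensemble <- function(n_nodes, n_edges, n_replicates = 100L,
                             seed = 1L, detect_modules = TRUE) {
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_edges)
    stop("infeasible edge count: ", n_edges, " > n(n-1)/2 = ", max_edges)
  reps <- with_stage_seed(seed, "null", {
    do.call(rbind, lapply(seq_len(n_replicates), function(i) {
      g <- igraph::sample_gnm(n_nodes, n_edges)
      topo <- network_topology(g, seed = seed + i, detect = detect_modules)
      data.frame(replicate = i,
                 clustering_coefficient = topo$clustering_coefficient,
                 average_path_length = topo$average_path_length,
                 modularity = topo$modularity,
                 average_degree = topo$average_degree)
    }))
  })
  metrics <- c("clustering_coefficient", "average_path_length", "modularity",
               "average_degree")
  summ <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(reps[[m]], na.rm = TRUE),
                  numeric(1L)),
    sd = vapply(metrics, function(m) sd(reps[[m]], na.rm = TRUE),
                numeric(1L)),
    stringsAsFactors = FALSE
  )
  rownames(summ) <- NULL
  structure(list(replicates = reps, summary = summ, n_nodes = n_nodes,
                 n_edges = n_edges, n_replicates = n_replicates, seed = seed),
            class = "null_ensemble")
}

#' Small-world and modular-structure assessment
#'
#' Compares a real network's topology with its equal-(n, m) Erdos-Renyi
#' ensemble: per metric (modularity, clustering coefficient, average path
#' length) the z-score against the ensemble and whether the real value
#' exceeds the ensemble mean. The overall verdict is "small-world and
#' modular" when clustering and modularity both exceed the null and
#' modularity > `q_threshold` (default 0.4). Average degree is reported as
#' identical by construction (2m/n is fixed by the null's definition), hence
#' non-informative.
#'
#' @param real A `network_topology` of the real network.
#' @param null A matching `null_ensemble` (same n and m).
#' @param q_threshold Modularity level indicating modular structure.
#' @return List of class `small_world_assessment`: `metrics` (data.frame
#'   `metric, real, null_mean, null_sd, z, exceeds_null`), `verdict`
#'   (logical), `note` on average degree.
#' @export
small_world_assessment <- function(real, null, q_threshold = 0.4) {
  stopifnot(inherits(real, "network_topology"),
            inherits(null, "null_ensemble"))
  if (real$n_nodes != null$n_nodes || real$n_edges != null$n_edges)
    stop("null ensemble was generated at (n = ", null$n_nodes, ", m = ",
         null$n_edges, ") but the real network has (n = ", real$n_nodes,
         ", m = ", real$n_edges, ")")
  metrics <- c("modularity", "clustering_coefficient", "average_path_length")
  rows <- lapply(metrics, function(m) {
    s <- null$summary[null$summary$metric == m, ]
    z <- if (is.finite(s$sd) && s$sd > 0) (real[[m]] - s$mean) / s$sd
         else NA_real_
    data.frame(metric = m, real = real[[m]], null_mean = s$mean,
               null_sd = s$sd, z = z,
               exceeds_null = isTRUE(real[[m]] > s$mean),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  verdict <- tab$exceeds_null[tab$metric == "clustering_coefficient"] &&
    tab$exceeds_null[tab$metric == "modularity"] &&
    isTRUE(real$modularity > q_threshold)
  structure(list(
    metrics = tab, verdict = verdict, q_threshold = q_threshold,
    note = paste("average degree is identical by construction (2m/n fixed)",
                 "and therefore non-informative for this comparison")
  ), class = "small_world_assessment")
}

#' @export
print.small_world_assessment <- function(x, ...) {
  print(x$metrics)
  cat(if (x$verdict) "verdict: small-world and modular\n"
      else "verdict: not distinguishable from the random ensemble\n")
  invisible(x)
}

#' Keystone taxa by betweenness centrality
#'
#' Ranks nodes by exact unweighted shortest-path betweenness centrality,
#' descending. Taxa unresolved at genus rank ("unclassified", "uncultured",
#' "unidentified" or empty) can be excluded from the ranking, mirroring the
#' common practice of reporting keystones among identifiable genera only.
#'
#' @param net A `cooccurrence_network` whose largest connected component has
#'   >= 3 nodes.
#' @param top_k Number of taxa to return (default 10; truncated with a
#'   warning if larger than the node count).
#' @param exclude_unclassified Drop genus-unresolved taxa from the ranking?
#' @return data.frame `taxon_id, genus, phylum, betweenness, degree`, ranked.
#' @export
keystone_taxa <- function(net, top_k = 10L, exclude_unclassified = FALSE) {
  stopifnot(inherits(net, "cooccurrence_network"))
  g <- net$graph
  comp <- igraph::components(g)
  if (max(comp$csize) < 3L)
    stop("no connected component with >= 3 nodes")
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  deg <- igraph::degree(g)
  out <- data.frame(taxon_id = names(btw),
                    genus = net$nodes$genus[match(names(btw),
                                                  net$nodes$taxon_id)],
                    phylum = net$nodes$phylum[match(names(btw),
                                                    net$nodes$taxon_id)],
                    betweenness = as.numeric(btw),
                    degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  if (exclude_unclassified) {
    bad <- is.na(out$genus) | out$genus == "" |
      grepl("^(unclassified|uncultured|unidentified)", out$genus,
            ignore.case = TRUE)
    out <- out[!bad, , drop = FALSE]
  }
  out <- out[order(-out$betweenness, out$taxon_id), ]
  rownames(out) <- NULL
  if (top_k > nrow(out)) {
    warning("top_k (", top_k, ") exceeds the number of rankable taxa (",
            nrow(out), "); returning all")
    top_k <- nrow(out)
  }
  head(out, top_k)
}

#' Export a network for Gephi and downstream tools
#'
#' Writes GraphML (via igraph) and/or GEXF and/or an edge-list CSV, with
#' node attributes (lineage, mean abundance, module, betweenness) and edge
#' attributes (r, p, sign).
#'
#' @param net A `cooccurrence_network`.
#' @param graphml,gexf,edge_csv,topology_json Output paths; `NULL` skips.
#' @param modules Optional result of [detect_modules()] to attach as a node
#'   attribute.
#' @param seed Seed used for any topology computation.
#' @return Invisibly, the vector of paths written.
#' @export
export_network <- function(net, graphml = NULL, gexf = NULL, edge_csv = NULL,
                           topology_json = NULL, modules = NULL, seed = 1L) {
  stopifnot(inherits(net, "cooccurrence_network"))
  g <- net$graph
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  igraph::V(g)$betweenness <- as.numeric(btw)
  igraph::V(g)$mean_abundance <- net$nodes$mean_abundance
  igraph::V(g)$lineage <- net$nodes$lineage
  if (!is.null(modules))
    igraph::V(g)$module <- unname(modules$membership[net$nodes$taxon_id])
  written <- character(0L)
  if (!is.null(graphml)) {
    igraph::write_graph(g, graphml, format = "graphml")
    written <- c(written, graphml)
  }
  if (!is.null(gexf)) {
    write_gexf(g, gexf)
    written <- c(written, gexf)
  }
  if (!is.null(edge_csv)) {
    write.csv(net$edges, edge_csv, row.names = FALSE)
    written <- c(written, edge_csv)
  }
  if (!is.null(topology_json)) {
    topo <- network_topology(net, seed = seed)
    jsonlite::write_json(unclass(topo), topology_json, auto_unbox = TRUE,
                         digits = NA, na = "null")
    written <- c(written, topology_json)
  }
  invisible(written)
}

# Minimal GEXF 1.2 writer (igraph has no GEXF backend). Covers what Gephi
# needs: ids, labels, declared node/edge attributes.
write_gexf <- function(g, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", gsub(">", "&gt;", x, fixed = TRUE), fixed = TRUE)
  }
  vattrs <- setdiff(igraph::vertex_attr_names(g), "name")
  eattrs <- setdiff(igraph::edge_attr_names(g), "weight")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">')
  w('  <graph mode="static" defaultedgetype="undirected">')
  gexf_type <- function(v) if (is.numeric(v)) "double" else "string"
  w('    <attributes class="node">')
  for (i in seq_along(vattrs))
    w('      <attribute id="%d" title="%s" type="%s"/>', i - 1L,
      esc(vattrs[i]), gexf_type(igraph::vertex_attr(g, vattrs[i])))
  w('    </attributes>')
  w('    <attributes class="edge">')
  for (i in seq_along(eattrs))
    w('      <attribute id="%d" title="%s" type="%s"/>', i - 1L,
      esc(eattrs[i]), gexf_type(igraph::edge_attr(g, eattrs[i])))
  w('    </attributes>')
  w('    <nodes>')
  ids <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  for (i in seq_len(igraph::vcount(g))) {
    w('      <node id="%s" label="%s">', esc(ids[i]), esc(ids[i]))
    if (length(vattrs)) {
      w('        <attvalues>')
      for (j in seq_along(vattrs))
        w('          <attvalue for="%d" value="%s"/>', j - 1L,
          esc(as.character(igraph::vertex_attr(g, vattrs[j])[i])))
      w('        </attvalues>')
    }
    w('      </node>')
  }
  w('    </nodes>')
  w('    <edges>')
  el <- igraph::as_edgelist(g, names = TRUE)
  for (i in seq_len(nrow(el))) {
    w('      <edge id="%d" source="%s" target="%s">', i - 1L,
      esc(el[i, 1L]), esc(el[i, 2L]))
    if (length(eattrs)) {
      w('        <attvalues>')
      for (j in seq_along(eattrs))
        w('          <attvalue for="%d" value="%s"/>', j - 1L,
          esc(as.character(igraph::edge_attr(g, eattrs[j])[i])))
      w('        </attvalues>')
    }
    w('      </edge>')
  }
  w('    </edges>')
  w('  </graph>')
  w('</gexf>')
  invisible(path)
}
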