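# Genus/OTU abundance container, taxonomic aggregation, alpha diversity,
# Bray-Curtis dissimilarity and NMDS ordination.

TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Construct an abundance table
#'
#' The central container for community data: a taxa x samples matrix of
#' counts or relative abundances plus a 6-rank taxonomy
#' (kingdom, phylum, class, order, family, genus) per taxon.
#'
#' @param mat Numeric matrix, taxa in rows, samples in columns; rownames are
#'   taxon ids, colnames sample ids. No negative entries.
#' @param taxonomy Either a character vector of
#'   `k__...;p__...;c__...;o__...;f__...;g__...` lineage strings (one per
#'   taxon) or a data.frame with the 6 rank columns. May be `NULL`.
#' @param mode `"counts"` or `"relative"`. In relative mode every sample
#'   column must sum to 1 (within 1e-9) or be all zero.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(mat, taxonomy = NULL,
                            mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("taxon_", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("sample_", seq_len(ncol(mat)))
  if (anyDuplicated(rownames(mat)))
    stop("duplicate taxon id(s): ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  if (any(!is.finite(mat)) || any(mat < 0))
    stop("abundance matrix must be finite and non-negative")
  if (mode == "relative") {
    cs <- colSums(mat)
    bad <- colnames(mat)[cs > 0 & abs(cs - 1) > 1e-9]
    if (length(bad))
      stop("relative-mode columns must sum to 1: ", paste(bad, collapse = ", "))
  }
  tax <- parse_taxonomy(taxonomy, rownames(mat))
  structure(list(mat = mat, taxonomy = tax, mode = mode),
            class = "abundance_table")
}

parse_taxonomy <- function(taxonomy, taxon_ids) {
  n <- length(taxon_ids)
  if (is.null(taxonomy)) {
    tax <- as.data.frame(matrix(NA_character_, n, length(TAXONOMIC_RANKS)),
                         stringsAsFactors = FALSE)
    names(tax) <- TAXONOMIC_RANKS
    rownames(tax) <- taxon_ids
    return(tax)
  }
  if (is.character(taxonomy)) {
    if (length(taxonomy) != n)
      stop("need one lineage string per taxon (", n, "), got ", length(taxonomy))
    prefixes <- c(kingdom = "k__", phylum = "p__", class = "c__",
                  order = "o__", family = "f__", genus = "g__")
    parts <- strsplit(taxonomy, ";", fixed = TRUE)
    tax <- as.data.frame(t(vapply(seq_along(parts), function(i) {
      p <- trimws(parts[[i]])
      out <- setNames(rep(NA_character_, 6L), names(prefixes))
      for (j in seq_along(prefixes)) {
        hit <- p[startsWith(p, prefixes[[j]])]
        if (length(hit) > 1L)
          stop("malformed lineage for taxon '", taxon_ids[i],
               "': repeated rank prefix ", prefixes[[j]])
        if (length(hit) == 1L) {
          val <- sub(prefixes[[j]], "", hit, fixed = TRUE)
          out[j] <- if (nzchar(val)) val else NA_character_
        }
      }
      if (all(is.na(out)) && any(nzchar(p)))
        stop("malformed lineage for taxon '", taxon_ids[i], "': ", taxonomy[i])
      out
    }, character(6L))), stringsAsFactors = FALSE)
  } else if (is.data.frame(taxonomy)) {
    missing <- setdiff(TAXONOMIC_RANKS, names(taxonomy))
    if (length(missing))
      stop("taxonomy data.frame missing rank column(s): ",
           paste(missing, collapse = ", "))
    if (nrow(taxonomy) != n) stop("taxonomy must have one row per taxon")
    tax <- taxonomy[, TAXONOMIC_RANKS]
  } else stop("taxonomy must be NULL, a character vector or a data.frame")
  rownames(tax) <- taxon_ids
  tax
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples (%s mode)\n",
              nrow(x$mat), ncol(x$mat), x$mode))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$mat)

lineage_strings <- function(tab) {
  tax <- tab$taxonomy
  pre <- c("k__", "p__", "c__", "o__", "f__", "g__")
  apply(tax, 1L, function(r) {
    paste0(pre, ifelse(is.na(r), "", r), collapse = ";")
  })
}

#' Aggregate an abundance table at a taxonomic rank
#'
#' Sums rows sharing the same label at the requested rank; taxa with no
#' assignment at that rank are pooled under `"unclassified"`. Column totals
#' (library sizes) are preserved and the counts/relative mode is unchanged.
#'
#' @param tab An [abundance_table()].
#' @param rank One of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return An `abundance_table` whose rows are the rank labels.
#' @export
aggregate_taxa <- function(tab, rank) {
  stopifnot(inherits(tab, "abundance_table"))
  if (!rank %in% TAXONOMIC_RANKS)
    stop("unknown rank '", rank, "'; valid ranks: ",
         paste(TAXONOMIC_RANKS, collapse = ", "))
  labels <- tab$taxonomy[[rank]]
  labels[is.na(labels) | labels == ""] <- "unclassified"
  agg <- rowsum(tab$mat, group = labels)
  # carry taxonomy up to (and including) the aggregation rank
  keep <- TAXONOMIC_RANKS[seq_len(match(rank, TAXONOMIC_RANKS))]
  tax <- as.data.frame(matrix(NA_character_, nrow(agg), 6L),
                       stringsAsFactors = FALSE)
  names(tax) <- TAXONOMIC_RANKS
  first <- match(rownames(agg), labels)
  for (r in keep) tax[[r]] <- tab$taxonomy[[r]][first]
  tax[[rank]] <- rownames(agg)
  tax[[rank]][rownames(agg) == "unclassified"] <- "unclassified"
  abundance_table(agg, taxonomy = tax, mode = tab$mode)
}

#' Convert counts to relative abundances
#'
#' Divides every sample column by its total. Idempotent on tables already in
#' relative mode.
#'
#' @param tab An [abundance_table()].
#' @return The table in relative mode.
#' @export
to_relative <- function(tab) {
  stopifnot(inherits(tab, "abundance_table"))
  if (tab$mode == "relative") return(tab)
  cs <- colSums(tab$mat)
  zero <- colnames(tab$mat)[cs == 0]
  if (length(zero))
    stop("cannot normalize all-zero sample(s): ", paste(zero, collapse = ", "))
  abundance_table(sweep(tab$mat, 2L, cs, "/"), taxonomy = tab$taxonomy,
                  mode = "relative")
}

#' Bias-corrected Chao1 richness estimator
#'
#' \eqn{S_{chao1} = S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} where
#' \eqn{F_1, F_2} are the singleton and doubleton counts. The bias-corrected
#' form is defined even when no doubletons are observed, and collapses to the
#' observed richness whenever \eqn{F_1 \le 1}.
#'
#' @param counts Integer vector of per-taxon counts for one sample. Chao1 is
#'   undefined on relative abundances; non-integer input is an error.
#' @return The richness estimate (numeric scalar).
#' @export
#' @examples
#' chao1(c(1, 1, 2, 5)) # S_obs = 4, F1 = 2, F2 = 1 -> 4.5
chao1 <- function(counts) {
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("Chao1 requires integer counts (it is undefined on relative abundances)")
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \log p_i} over the positive proportions, natural log
#' by default.
#'
#' @param abundances Non-negative vector (counts or proportions) with at
#'   least one positive entry; normalized internally.
#' @param base Logarithm base (default `exp(1)`, i.e. nats).
#' @return Shannon index (numeric scalar).
#' @export
shannon <- function(abundances, base = exp(1)) {
  if (any(!is.finite(abundances)) || any(abundances < 0))
    stop("abundances must be finite and non-negative")
  tot <- sum(abundances)
  if (tot <= 0) stop("at least one positive abundance is required")
  p <- abundances[abundances > 0] / tot
  -sum(p * log(p)) / log(base)
}

#' Per-sample alpha diversity
#'
#' Observed richness, bias-corrected Chao1 and Shannon (nats) for every
#' sample of a counts-mode table. Optional rarefaction to an even depth
#' before estimation (off by default).
#'
#' @param tab A counts-mode [abundance_table()].
#' @param rarefy_depth Optional even depth to subsample each column to before
#'   computing the metrics (sampling without replacement); `NULL` disables.
#' @param seed Seed used only when rarefying.
#' @return data.frame: `sample_id`, `observed_richness`, `chao1`, `shannon`.
#' @export
alpha_diversity <- function(tab, rarefy_depth = NULL, seed = 1L) {
  stopifnot(inherits(tab, "abundance_table"))
  if (tab$mode != "counts")
    stop("alpha_diversity needs a counts-mode table (Chao1 is undefined otherwise)")
  mat <- tab$mat
  if (!is.null(rarefy_depth)) {
    if (any(colSums(mat) < rarefy_depth))
      stop("rarefy_depth exceeds the depth of at least one sample")
    mat <- with_stage_seed(seed, "abundance",
                           round(t(vegan::rrarefy(t(mat), rarefy_depth))))
  }
  data.frame(
    sample_id = colnames(mat),
    observed_richness = colSums(mat > 0),
    chao1 = apply(mat, 2L, chao1),
    shannon = apply(mat, 2L, shannon),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}; symmetric, zero
#' diagonal, bounded in \[0, 1\]. A pair of all-zero samples is assigned
#' distance 0 with a warning.
#'
#' @param tab An [abundance_table()] (counts or relative) with >= 2 samples.
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(tab) {
  stopifnot(inherits(tab, "abundance_table"))
  if (ncol(tab$mat) < 2L) stop("need at least 2 samples")
  d <- vegan::vegdist(t(tab$mat), method = "bray")
  if (anyNA(d)) {
    warning("all-zero sample pair(s): Bray-Curtis undefined, set to 0")
    d[is.na(d)] <- 0
  }
  d
}

#' Non-metric multidimensional scaling (NMDS)
#'
#' Kruskal stress-1 minimization (global monotone model, primary tie
#' treatment) via [vegan::monoMDS()], restarted from `n_restarts` random
#' configurations; the lowest-stress solution is returned with coordinates
#' centered at the origin.
#'
#' @param distances A `dist` object or symmetric distance matrix.
#' @param k Number of ordination dimensions (default 2); must be smaller
#'   than the number of samples.
#' @param n_restarts Random restarts (default 20).
#' @param max_iter Maximum iterations per restart (default 500).
#' @param seed Seed for the restart stream.
#' @return List with `points` (samples x k, centered), `stress` (Kruskal
#'   stress-1), `n_restarts`, `converged`.
#' @export
nmds_ordination <- function(distances, k = 2L, n_restarts = 20L,
                            max_iter = 500L, seed = 1L) {
  d <- as.dist(distances)
  n <- attr(d, "Size")
  if (k < 1L) stop("k must be >= 1")
  if (k >= n) stop("k must be smaller than the number of samples (", n, ")")
  best <- NULL
  with_stage_seed(seed, "nmds", {
    for (r in seq_len(n_restarts)) {
      init <- matrix(rnorm(n * k), n, k)
      fit <- vegan::monoMDS(d, y = init, k = k, model = "global",
                            maxit = max_iter)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
  })
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  dimnames(pts) <- list(attr(d, "Labels"), paste0("NMDS", seq_len(k)))
  list(points = pts, stress = best$stress, n_restarts = n_restarts,
       converged = isTRUE(best$icause == 3L) || best$stress < 1e-6)
}

#' Recompute Kruskal stress-1 for a configuration
#'
#' Independent evaluation of stress-1 for an existing configuration:
#' isotonic regression (ties averaged) of configuration distances on the
#' dissimilarity order, then
#' \eqn{\sqrt{\sum (d - \hat d)^2 / \sum d^2}}.
#'
#' @param distances Original dissimilarities (`dist` or matrix).
#' @param points Configuration matrix (samples x k).
#' @return Stress-1 (numeric scalar in \[0, 1\]).
#' @export
kruskal_stress1 <- function(distances, points) {
  dd <- as.vector(as.dist(distances))
  dc <- as.vector(dist(points))
  ord <- order(dd)
  iso <- stats::isoreg(x = seq_along(ord), y = dc[ord])
  dhat <- iso$yf
  sqrt(sum((dc[ord] - dhat)^2) / sum(dc[ord]^2))
}
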