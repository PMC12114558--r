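# File readers/writers and the end-to-end pipeline.

#' Read an abundance table from TSV
#'
#' Expects a tab-separated file whose first column is the taxon id, with a
#' `taxonomy` column of `k__;p__;c__;o__;f__;g__` lineage strings, and
#' numeric sample columns. Duplicate taxon ids and negative values are
#' rejected.
#'
#' @param path Path to the TSV file.
#' @param mode `"counts"` (default) or `"relative"`.
#' @return An [abundance_table()].
#' @export
read_abundance <- function(path, mode = "counts") {
  x <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 3L)
    stop("abundance TSV needs a taxon id column, a 'taxonomy' column and ",
         "at least one sample column")
  if (!"taxonomy" %in% names(x))
    stop("abundance TSV is missing the 'taxonomy' column")
  ids <- as.character(x[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated taxon id(s): ", paste(dup, collapse = ", "))
  taxonomy <- x$taxonomy
  num <- x[, setdiff(names(x)[-1L], "taxonomy"), drop = FALSE]
  bad <- which(!vapply(num, is.numeric, logical(1L)))
  if (length(bad))
    stop("non-numeric sample column(s): ", paste(names(num)[bad], collapse = ", "))
  mat <- as.matrix(num)
  if (any(mat < 0)) {
    ij <- which(mat < 0, arr.ind = TRUE)[1L, ]
    stop("negative abundance at taxon '", ids[ij[1L]], "', sample '",
         colnames(mat)[ij[2L]], "' (line ", ij[1L] + 1L, ")")
  }
  rownames(mat) <- ids
  abundance_table(mat, taxonomy = taxonomy, mode = mode)
}

#' Write an abundance table to TSV
#'
#' Inverse of [read_abundance()]: taxon id column, `taxonomy` lineage
#' column, one numeric column per sample.
#'
#' @param tab An [abundance_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_abundance <- function(tab, path) {
  stopifnot(inherits(tab, "abundance_table"))
  out <- data.frame(taxon_id = rownames(tab$mat),
                    taxonomy = lineage_strings(tab),
                    tab$mat, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from CSV
#'
#' Requires `sample_id`, `region` and `cover` columns; `cover` must be
#' `vegetated` or `bare`. Numeric physicochemistry columns (pH, EC, OM,
#' CAT, AN, AP, TPH, in Table-style units) are passed through; missing cells
#' are allowed and propagate as `NA`.
#'
#' @param path Path to the CSV file.
#' @return data.frame with `cover` as a 2-level factor.
#' @export
read_metadata <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "region", "cover")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("metadata CSV is missing column(s): ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(x$cover), c("vegetated", "bare"))
  if (length(bad))
    stop("unknown cover label(s): ", paste(bad, collapse = ", "),
         " (expected 'vegetated' or 'bare')")
  x$cover <- factor(x$cover, levels = c("vegetated", "bare"))
  x
}

#' Check that two tables describe the same samples
#'
#' @param abundance_samples,metadata_samples Character vectors of ids.
#' @return Invisibly TRUE; mismatches raise an error listing them.
#' @export
reconcile_samples <- function(abundance_samples, metadata_samples) {
  only_meta <- setdiff(metadata_samples, abundance_samples)
  only_ab <- setdiff(abundance_samples, metadata_samples)
  if (length(only_meta) || length(only_ab))
    stop("sample sets do not match; only in metadata: ",
         paste(only_meta, collapse = ", "), "; only in abundance: ",
         paste(only_ab, collapse = ", "))
  invisible(TRUE)
}

#' Group summary of numeric metadata columns
#'
#' Mean and SD of each numeric column per group label (e.g. region x cover
#' cell), the shape in which soil surveys report their Table-1-style
#' summaries.
#'
#' @param metadata data.frame with a grouping column.
#' @param group Name of the grouping column, or a vector of columns pasted
#'   together (default `c("region", "cover")`).
#' @return data.frame: `group`, then `<var>_mean` and `<var>_sd` columns.
#' @export
group_summary <- function(metadata, group = c("region", "cover")) {
  g <- if (length(group) > 1L)
    do.call(paste0, c(metadata[group[1L]],
                      list(toupper(substr(metadata[[group[2L]]], 1L, 1L)))))
  else metadata[[group]]
  num <- metadata[vapply(metadata, is.numeric, logical(1L))]
  out <- data.frame(group = sort(unique(g)), stringsAsFactors = FALSE)
  for (v in names(num)) {
    out[[paste0(v, "_mean")]] <-
      as.numeric(tapply(num[[v]], g, mean, na.rm = TRUE)[out$group])
    out[[paste0(v, "_sd")]] <-
      as.numeric(tapply(num[[v]], g, sd, na.rm = TRUE)[out$group])
  }
  out
}

#' Read a PAH concentration table from CSV
#'
#' One row per sample: `sample_id` plus 16 congener columns (mg kg^-1).
#'
#' @param path Path to the CSV file.
#' @return data.frame.
#' @export
read_pah_csv <- function(path) {
  x <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(x)) stop("PAH CSV needs a 'sample_id' column")
  codes <- intersect(pah_congeners()$code, names(x))
  if (!length(codes)) stop("PAH CSV contains no recognized congener columns")
  x
}

#' Read qPCR sample and standard-curve CSVs
#'
#' @param samples_path CSV `sample_id,gene,ct`.
#' @param standards_path CSV `gene,log10_copies,ct`.
#' @return List with `samples` and `standards` data.frames.
#' @export
read_qpcr_csv <- function(samples_path, standards_path) {
  samples <- read.csv(samples_path, stringsAsFactors = FALSE)
  standards <- read.csv(standards_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "gene", "ct") %in% names(samples)))
    stop("qPCR sample CSV needs columns sample_id, gene, ct")
  if (!all(c("gene", "log10_copies", "ct") %in% names(standards)))
    stop("standard-curve CSV needs columns gene, log10_copies, ct")
  list(samples = samples, standards = standards)
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on either a simulated study (`config$simulate`,
#' a [study_config()]) or files on disk (`config$inputs`, a named list of
#' paths): PAH summaries, TEQ and contamination classes; alpha diversity and
#' NMDS on Bray-Curtis distances; qPCR quantification; environment
#' correlations, Mantel test, RDA and per-cell ANOVA letters; and per-cover
#' (vegetated vs bare) co-occurrence networks with Erdos-Renyi null
#' ensembles, small-world verdicts and keystone rankings. All outputs plus a
#' machine-readable run manifest (seeds, thresholds, stage status) are
#' written under `out_dir`. A stage failure is recorded in the manifest and
#' later stages that do not depend on it still run.
#'
#' @param config List with elements `simulate` (a `study_config`) or
#'   `inputs` (paths: `abundance`, `metadata`, `pah`, `qpcr_samples`,
#'   `qpcr_standards`, optional `tef`), plus optional `r_threshold` (0.6),
#'   `p_threshold` (0.01), `alpha` (0.05), `scheme`, `null_reps` (100),
#'   `stratify_by` ("cover"), `seed`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  r_thr <- config$r_threshold %||% 0.6
  p_thr <- config$p_threshold %||% 0.01
  alpha <- config$alpha %||% 0.05
  scheme <- config$scheme %||% "four_tier"
  null_reps <- config$null_reps %||% 100L
  strat_col <- config$stratify_by %||% "cover"
  manifest <- list(seed = seed,
                   child_seeds = as.list(vapply(names(pahnet_seed_offsets),
                     function(s) child_seed(seed, s), integer(1L))),
                   thresholds = list(r_threshold = r_thr,
                                     p_threshold = p_thr, alpha = alpha,
                                     scheme = scheme, null_reps = null_reps),
                   package_version = as.character(utils::packageVersion("pahnet")),
                   stages = list())
  results <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      warning("stage '", name, "' failed: ", conditionMessage(e))
      structure(list(message = conditionMessage(e)), class = "stage_failure")
    })
    manifest$stages[[name]] <<- if (inherits(res, "stage_failure"))
      list(status = "failed", message = res$message) else list(status = "ok")
    res
  }

  # --- load or simulate -----------------------------------------------------
  data <- stage("data", {
    if (!is.null(config$simulate)) {
      cfg <- config$simulate
      if (!inherits(cfg, "study_config")) cfg <- do.call(study_config, cfg)
      cfg$seed <- seed
      study <- generate_study(cfg, seed = seed)
      write_study_bundle(study, file.path(out_dir, "bundle"))
      study
    } else if (!is.null(config$inputs)) {
      inp <- config$inputs
      metadata <- read_metadata(inp$metadata)
      abundance <- read_abundance(inp$abundance)
      reconcile_samples(colnames(abundance$mat), metadata$sample_id)
      pah <- if (!is.null(inp$pah)) read_pah_csv(inp$pah) else NULL
      genes <- if (!is.null(inp$qpcr_samples)) {
        q <- read_qpcr_csv(inp$qpcr_samples, inp$qpcr_standards)
        qt <- quantify_gene_table(q$samples, q$standards,
                                  extraction_factor = inp$extraction_factor %||% 1)
        qt
      } else NULL
      list(metadata = metadata, pah = pah, abundance = abundance,
           genes = genes)
    } else stop("config must contain either 'simulate' or 'inputs'")
  })
  if (inherits(data, "stage_failure")) {
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
    stop("pipeline aborted: data stage failed")
  }
  metadata <- data$metadata

  # --- PAH toxicity ---------------------------------------------------------
  tef <- if (!is.null(config$inputs$tef)) read_tef_csv(config$inputs$tef)
         else default_tef()
  results$pah <- stage("pah", {
    if (is.null(data$pah)) NULL else {
      s <- summarize_pah_table(data$pah, tef = tef, scheme = scheme)
      write.csv(s, file.path(out_dir, "pah_summary.csv"), row.names = FALSE)
      s
    }
  })

  # --- diversity and ordination --------------------------------------------
  results$diversity <- stage("diversity", {
    div <- alpha_diversity(data$abundance)
    write.csv(div, file.path(out_dir, "alpha_diversity.csv"),
              row.names = FALSE)
    div
  })
  results$ordination <- stage("ordination", {
    d <- bray_curtis(to_relative(data$abundance))
    ord <- nmds_ordination(d, k = 2L, seed = seed)
    write.csv(data.frame(sample_id = rownames(ord$points), ord$points,
                         stringsAsFactors = FALSE),
              file.path(out_dir, "nmds_points.csv"), row.names = FALSE)
    dmat <- as.matrix(d)
    write.csv(dmat, file.path(out_dir, "bray_curtis.csv"))
    ord
  })

  # --- qPCR -----------------------------------------------------------------
  results$genes <- stage("qpcr", {
    if (is.null(data$genes)) NULL else {
      g <- data$genes
      if (inherits(data, "study_dataset")) {
        # round-trip the emitted Ct values through the standard curves
        q <- quantify_gene_table(g[, c("sample_id", "gene", "ct")],
                                 attr(g, "standards"),
                                 extraction_factor = 1)
        g$copies_requant <- q$copies_per_g[match(
          paste(g$sample_id, g$gene), paste(q$sample_id, q$gene))]
      }
      write.csv(g, file.path(out_dir, "gene_quant.csv"), row.names = FALSE)
      g
    }
  })

  # --- association statistics ----------------------------------------------
  results$assoc <- stage("assoc", {
    env_cols <- intersect(c("ph", "ec", "om", "cat", "an", "ap", "tph"),
                          names(metadata))
    div <- results$diversity
    env <- metadata[match(div$sample_id, metadata$sample_id), env_cols]
    X <- cbind(env, div[c("chao1", "shannon")])
    corr <- correlation_matrix(X, method = "spearman")
    write.csv(corr, file.path(out_dir, "correlations.csv"),
              row.names = FALSE)
    d_comm <- bray_curtis(to_relative(data$abundance))
    env_m <- scale(as.matrix(env))
    rownames(env_m) <- div$sample_id
    d_env <- dist(env_m)
    mant <- mantel_test(d_comm, d_env, method = "spearman",
                        n_perm = 999L, seed = seed)
    rda <- rda_explained(div[c("observed_richness", "chao1", "shannon")],
                         env)
    write.csv(rda$table, file.path(out_dir, "rda_explained.csv"),
              row.names = FALSE)
    cell <- paste0(metadata$region,
                   toupper(substr(as.character(metadata$cover), 1L, 1L)))
    letters_ec <- anova_tukey_letters(metadata$ec, cell, alpha = alpha)
    write.csv(letters_ec, file.path(out_dir, "ec_group_letters.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(mantel = list(r = mant$r, p = mant$p, n_perm = mant$n_perm),
           rda = rda$table, anova_ec = letters_ec),
      file.path(out_dir, "assoc.json"), auto_unbox = TRUE, digits = NA)
    list(correlations = corr, mantel = mant, rda = rda,
         ec_letters = letters_ec)
  })

  # --- per-stratum networks -------------------------------------------------
  results$networks <- stage("networks", {
    strata <- unique(as.character(metadata[[strat_col]]))
    nets <- lapply(setNames(strata, strata), function(s) {
      ids <- metadata$sample_id[metadata[[strat_col]] == s]
      sub <- abundance_table(
        data$abundance$mat[, ids, drop = FALSE],
        taxonomy = data$abundance$taxonomy, mode = data$abundance$mode)
      rel <- filter_taxa(to_relative(sub))
      net <- build_network(rel, r_threshold = r_thr, p_threshold = p_thr)
      mods <- detect_modules(net, seed = seed)
      topo <- network_topology(net, seed = seed)
      null <- er_null_ensemble(topo$n_nodes, topo$n_edges,
                               n_replicates = null_reps, seed = seed)
      sw <- small_world_assessment(topo, null)
      keys <- keystone_taxa(net, top_k = min(10L, nrow(net$nodes)))
      export_network(net,
                     graphml = file.path(out_dir, paste0("network_", s, ".graphml")),
                     gexf = file.path(out_dir, paste0("network_", s, ".gexf")),
                     edge_csv = file.path(out_dir, paste0("edges_", s, ".csv")),
                     modules = mods, seed = seed)
      list(network = net, topology = topo, modules = mods, null = null,
           small_world = sw, keystones = keys)
    })
    jsonlite::write_json(
      lapply(nets, function(x) list(
        n_nodes = x$topology$n_nodes, n_edges = x$topology$n_edges,
        positive_edge_fraction = x$topology$positive_edge_fraction,
        modularity = x$topology$modularity,
        n_major_modules = x$topology$n_major_modules,
        small_world_verdict = x$small_world$verdict,
        keystones = x$keystones$taxon_id)),
      file.path(out_dir, "networks.json"), auto_unbox = TRUE, digits = NA)
    nets
  })

  if (!is.null(results$networks) &&
      !inherits(results$networks, "stage_failure")) {
    manifest$network_edges <- lapply(results$networks,
                                     function(x) x$topology$n_edges)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
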