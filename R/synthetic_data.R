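# Synthetic study generator: emulates a 3-region salinity gradient with
# paired vegetated/bare plots, 16-congener PAH profiles, genus abundance
# tables with niche responses and correlated guilds, and qPCR gene counts.

#' Configure a synthetic soil study
#'
#' Defines the study design and effect sizes used by [generate_study()].
#' Defaults emulate an aged PAH-contaminated coastal oilfield survey: three
#' regions (GA, GB, GC) with an increasing electrical-conductivity (EC,
#' i.e. salinity) gradient toward the coast, paired vegetated and bare plots
#' per region, vegetated soils with lower EC and PAH burdens and higher
#' catalase activity, genus abundances with negative salinity niche
#' responses plus correlated guild blocks, and functional-gene copy numbers
#' declining with salinity and elevated under vegetation.
#'
#' `noise_sd_log = 0` switches the generator into a deterministic mean-only
#' mode in which every stochastic draw (environmental scatter, PAH and gene
#' noise, abundance noise) is silenced.
#'
#' @param n_regions Number of regions (default 3, labelled GA, GB, GC, ...).
#' @param samples_per_cell Samples per region x cover cell (default 10).
#' @param ec_region_means Bare-soil EC mean per region, mS cm^-1.
#' @param ec_region_sds EC standard deviation per region, mS cm^-1.
#' @param vegetation_ec_multiplier Scalar or per-region multiplier (< or = 1)
#'   applied to vegetated-plot EC means.
#' @param pah_region_means Bare-soil TPAH mean per region, mg kg^-1.
#' @param pah_cv Lognormal coefficient of variation of per-sample TPAH.
#' @param vegetation_pah_multiplier Scalar or per-region multiplier applied
#'   to vegetated-plot TPAH means.
#' @param lmw_fraction Scalar or per-region fraction of TPAH in the 2-3-ring
#'   (LMW) congeners.
#' @param n_genera Number of genera (default 120).
#' @param n_guilds Number of correlated guild blocks (default 12).
#' @param guild_loading Latent-factor strength in \[0, 1): scalar or named
#'   per-cover vector `c(vegetated=, bare=)`. Default `c(0.9, 0.4)` makes
#'   vegetated communities more tightly co-structured than bare ones, so
#'   vegetated co-occurrence networks are denser.
#' @param niche_ec_slopes Per-genus response of log-abundance to centered EC;
#'   `NULL` (default) draws most genera from
#'   `Normal(niche_slope_mean, niche_slope_sd)` and designates a small
#'   halotolerant fraction with strong positive slopes (below).
#' @param niche_slope_mean,niche_slope_sd Distribution of drawn niche slopes
#'   (defaults -0.10 and 0.08 per mS cm^-1): mostly negative, mildly
#'   heterogeneous.
#' @param halophile_fraction,halophile_slope Fraction of genera (default
#'   0.07) given a strong positive EC slope (default 0.6 per mS cm^-1) and a
#'   moderately low baseline: they surge to dominance in high-salinity
#'   samples, which is what drives evenness (Shannon) down along the EC
#'   gradient.
#' @param baseline_sd SD of genus baseline log-abundances (default 0.8).
#' @param noise_sd_log Residual lognormal noise scale on genus log
#'   abundances (default 0.5); 0 = deterministic mode (see above).
#' @param depth Fixed sequencing depth per sample (default 60000 reads).
#' @param gene_mean_16s,gene_mean_rhd,gene_mean_c12o Cohort-mean gene copy
#'   numbers per gram dry soil (defaults 4.02e8, 1.37e6, 2.26e5).
#' @param gene_ec_slope log10 copies per mS cm^-1 of centered EC
#'   (default -0.08, negative: salinity suppresses abundance).
#' @param gene_vegetation_offset log10 copies added under vegetation
#'   (default 0.15).
#' @param gene_noise_sd_log10 Residual gene noise, log10 scale (default 0.25).
#' @param curve_slope,curve_intercept_16s,curve_intercept_rhd,curve_intercept_c12o
#'   Standard-curve parameters used to emit synthetic Ct values.
#' @param seed Integer study seed; expanded into per-stage child seeds.
#' @return An object of class `study_config` (validated list).
#' @export
study_config <- function(n_regions = 3L,
                         samples_per_cell = 10L,
                         ec_region_means = c(1.25, 2.06, 7.23),
                         ec_region_sds = c(0.70, 0.37, 2.32),
                         vegetation_ec_multiplier = c(0.99, 0.96, 0.41),
                         pah_region_means = c(2.30, 2.04, 1.77),
                         pah_cv = 0.28,
                         vegetation_pah_multiplier = c(0.49, 0.44, 0.45),
                         lmw_fraction = c(0.20, 0.31, 0.35),
                         n_genera = 120L,
                         n_guilds = 12L,
                         guild_loading = c(vegetated = 0.9, bare = 0.4),
                         niche_ec_slopes = NULL,
                         niche_slope_mean = -0.10,
                         niche_slope_sd = 0.08,
                         halophile_fraction = 0.07,
                         halophile_slope = 0.6,
                         baseline_sd = 0.8,
                         noise_sd_log = 0.5,
                         depth = 60000L,
                         gene_mean_16s = 4.02e8,
                         gene_mean_rhd = 1.37e6,
                         gene_mean_c12o = 2.26e5,
                         gene_ec_slope = -0.08,
                         gene_vegetation_offset = 0.15,
                         gene_noise_sd_log10 = 0.25,
                         curve_slope = -3.3219,
                         curve_intercept_16s = 38,
                         curve_intercept_rhd = 38,
                         curve_intercept_c12o = 38,
                         seed = 1L) {
  cfg <- list(
    n_regions = as.integer(n_regions),
    samples_per_cell = as.integer(samples_per_cell),
    ec_region_means = ec_region_means,
    ec_region_sds = ec_region_sds,
    vegetation_ec_multiplier = vegetation_ec_multiplier,
    pah_region_means = pah_region_means,
    pah_cv = pah_cv,
    vegetation_pah_multiplier = vegetation_pah_multiplier,
    lmw_fraction = lmw_fraction,
    n_genera = as.integer(n_genera),
    n_guilds = as.integer(n_guilds),
    guild_loading = guild_loading,
    niche_ec_slopes = niche_ec_slopes,
    niche_slope_mean = niche_slope_mean,
    niche_slope_sd = niche_slope_sd,
    halophile_fraction = halophile_fraction,
    halophile_slope = halophile_slope,
    baseline_sd = baseline_sd,
    noise_sd_log = noise_sd_log,
    depth = as.integer(depth),
    gene_mean_16s = gene_mean_16s,
    gene_mean_rhd = gene_mean_rhd,
    gene_mean_c12o = gene_mean_c12o,
    gene_ec_slope = gene_ec_slope,
    gene_vegetation_offset = gene_vegetation_offset,
    gene_noise_sd_log10 = gene_noise_sd_log10,
    curve_slope = curve_slope,
    curve_intercept_16s = curve_intercept_16s,
    curve_intercept_rhd = curve_intercept_rhd,
    curve_intercept_c12o = curve_intercept_c12o,
    seed = as.integer(seed)
  )
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  if (cfg$n_regions < 1L || cfg$samples_per_cell < 1L ||
      cfg$n_genera < 1L || cfg$n_guilds < 1L || cfg$depth < 1L)
    stop("all design counts (regions, samples, genera, guilds, depth) must be >= 1")
  if (cfg$n_genera < cfg$n_guilds)
    stop("n_genera must be >= n_guilds")
  for (nm in c("vegetation_ec_multiplier", "vegetation_pah_multiplier")) {
    m <- cfg[[nm]]
    if (any(!is.finite(m)) || any(m <= 0) || any(m > 1))
      stop("'", nm, "' must lie in (0, 1]")
  }
  gl <- cfg$guild_loading
  if (any(!is.finite(gl)) || any(gl < 0) || any(gl >= 1))
    stop("guild_loading must lie in [0, 1)")
  if (cfg$halophile_fraction < 0 || cfg$halophile_fraction >= 1)
    stop("halophile_fraction must lie in [0, 1)")
  if (cfg$baseline_sd < 0) stop("baseline_sd must be >= 0")
  for (nm in c("gene_mean_16s", "gene_mean_rhd", "gene_mean_c12o"))
    if (cfg[[nm]] <= 0) stop("'", nm, "' must be > 0")
  if (cfg$noise_sd_log < 0) stop("noise_sd_log must be >= 0")
  if (!is.null(cfg$niche_ec_slopes) &&
      length(cfg$niche_ec_slopes) != cfg$n_genera)
    stop("niche_ec_slopes must have one entry per genus")
  invisible(cfg)
}

region_labels <- function(n) paste0("G", LETTERS[seq_len(n)])

# deterministic mean-only mode?
noise_off <- function(cfg) cfg$noise_sd_log == 0

#' Generate sample metadata for a synthetic study
#'
#' Lays out `2 * n_regions * samples_per_cell` samples (vegetated and bare
#' per region) and draws EC, pH, organic matter (OM), catalase activity
#' (CAT), available nitrogen (AN), available phosphorus (AP) and total
#' petroleum hydrocarbons (TPH) around region x cover means. EC is drawn
#' from the per-region normal (vegetated means scaled by
#' `vegetation_ec_multiplier`) and truncated at zero; vegetated CAT is
#' elevated and vegetated TPH reduced.
#'
#' @param config A [study_config()].
#' @param seed Study seed (default `config$seed`).
#' @return data.frame: `sample_id`, `region`, `cover`, `ec`, `ph`, `om`,
#'   `cat`, `an`, `ap`, `tph`.
#' @export
generate_metadata <- function(config, seed = config$seed) {
  validate_study_config(config)
  nr <- config$n_regions
  regions <- region_labels(nr)
  covers <- c("vegetated", "bare")
  ec_mu <- recycle_to(config$ec_region_means, nr, what = "ec_region_means")
  ec_sd <- recycle_to(config$ec_region_sds, nr, what = "ec_region_sds")
  ec_vm <- recycle_to(config$vegetation_ec_multiplier, nr,
                      what = "vegetation_ec_multiplier")
  # auxiliary physicochemistry: per-region bare means patterned on a coastal
  # oilfield survey; vegetated CAT elevated, vegetated TPH reduced
  ph_mu  <- rep(7.8, nr)[seq_len(nr)]
  om_mu  <- rep(c(132, 169, 20), length.out = nr)
  cat_mu <- rep(c(4.07, 3.52, 2.39), length.out = nr)
  an_mu  <- rep(c(50.4, 47.5, 41.3), length.out = nr)
  ap_mu  <- rep(c(7.2, 7.8, 4.1), length.out = nr)
  tph_mu <- rep(c(5.7, 5.9, 1.7), length.out = nr)
  off <- noise_off(config)
  grid <- expand.grid(rep = seq_len(config$samples_per_cell),
                      cover = covers, region = regions,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  with_stage_seed(seed, "metadata", {
    ri <- match(grid$region, regions)
    veg <- grid$cover == "vegetated"
    mu <- ec_mu[ri] * ifelse(veg, ec_vm[ri], 1)
    ec <- if (off) mu else pmax(rnorm(n, mu, ec_sd[ri]), 1e-3)
    draw <- function(mu_i, sd_i) if (off) mu_i else pmax(rnorm(n, mu_i, sd_i), 1e-3)
    meta <- data.frame(
      sample_id = sprintf("%s%s%02d", grid$region,
                          ifelse(veg, "V", "B"), grid$rep),
      region = grid$region,
      cover = grid$cover,
      ec = ec,
      ph = draw(ph_mu[ri], 0.15),
      om = draw(om_mu[ri], 0.25 * om_mu[ri]),
      cat = draw(cat_mu[ri] * ifelse(veg, 1.15, 1), 0.15 * cat_mu[ri]),
      an = draw(an_mu[ri], 0.15 * an_mu[ri]),
      ap = draw(ap_mu[ri], 0.20 * ap_mu[ri]),
      tph = draw(tph_mu[ri] * ifelse(veg, 0.45, 1), 0.30 * tph_mu[ri]),
      stringsAsFactors = FALSE
    )
    meta
  })
}

#' Generate per-sample 16-congener PAH profiles
#'
#' Draws per-sample TPAH lognormally around the region mean (vegetated means
#' scaled by `vegetation_pah_multiplier`; the lognormal multiplier has unit
#' arithmetic mean, so region means are matched in expectation), then
#' partitions TPAH across the 16 congeners: the region's `lmw_fraction` goes
#' to the six 2-3-ring congeners and the remainder to the ten 4-6-ring
#' congeners, with per-sample jitter of the congener weights. Concentrations
#' sum to TPAH exactly.
#'
#' @param metadata Output of [generate_metadata()].
#' @param config The [study_config()].
#' @param seed Study seed (default `config$seed`).
#' @return data.frame: `sample_id`, the 16 congener columns (mg kg^-1) and
#'   a `tpah` column equal to their row sum.
#' @export
generate_pah_profiles <- function(metadata, config, seed = config$seed) {
  validate_study_config(config)
  if (nrow(metadata) == 0L) stop("metadata is empty")
  regions <- region_labels(config$n_regions)
  unknown <- !metadata$region %in% regions
  if (any(unknown))
    stop("unknown region label for sample(s): ",
         paste(metadata$sample_id[unknown], collapse = ", "))
  nr <- config$n_regions
  pah_mu <- recycle_to(config$pah_region_means, nr, what = "pah_region_means")
  pah_vm <- recycle_to(config$vegetation_pah_multiplier, nr,
                       what = "vegetation_pah_multiplier")
  lmw_fr <- recycle_to(config$lmw_fraction, nr, what = "lmw_fraction")
  # base congener weights within each molecular-weight class
  w_lmw <- c(NAP = 0.05, ACY = 0.05, ACE = 0.05, FLU = 0.15, PHE = 0.55,
             ANT = 0.15)
  w_hmw <- c(FLA = 0.14, PYR = 0.13, BaA = 0.10, CHR = 0.12, BbF = 0.11,
             BkF = 0.08, BaP = 0.09, IndP = 0.08, DahA = 0.05, BghiP = 0.10)
  off <- noise_off(config)
  sdlog <- sqrt(log(1 + config$pah_cv^2))
  n <- nrow(metadata)
  with_stage_seed(seed, "pah", {
    ri <- match(metadata$region, regions)
    veg <- metadata$cover == "vegetated"
    mu <- pah_mu[ri] * ifelse(veg, pah_vm[ri], 1)
    tpah <- if (off) mu else mu * exp(rnorm(n, -sdlog^2 / 2, sdlog))
    conc <- t(vapply(seq_len(n), function(i) {
      jl <- if (off) w_lmw else w_lmw * exp(rnorm(6L, 0, 0.3))
      jh <- if (off) w_hmw else w_hmw * exp(rnorm(10L, 0, 0.3))
      c(tpah[i] * lmw_fr[ri[i]] * jl / sum(jl),
        tpah[i] * (1 - lmw_fr[ri[i]]) * jh / sum(jh))
    }, numeric(16L)))
    colnames(conc) <- c(names(w_lmw), names(w_hmw))
    out <- data.frame(sample_id = metadata$sample_id, conc,
                      stringsAsFactors = FALSE, check.names = FALSE)
    out$tpah <- rowSums(conc)
    out
  })
}

# fabricated but field-plausible lineage pool for synthetic genera
synthetic_lineages <- function(n_genera) {
  phyla <- c("Proteobacteria", "Actinobacteria", "Firmicutes", "Chloroflexi",
             "Gemmatimonadetes", "Bacteroidetes", "Planctomycetes",
             "Acidobacteria")
  named <- c("Halomonas", "Pseudomonas", "Marinobacter", "Geodermatophilus",
             "Klebsiella", "Methylobacterium", "Bacillus", "Aquabacterium")
  genus <- c(named, paste0("Genus_", sprintf("%03d", seq_len(max(0, n_genera - length(named))))))
  genus <- genus[seq_len(n_genera)]
  # a small tail of genera unresolved at genus rank
  if (n_genera >= 20L)
    genus[seq(n_genera - floor(n_genera * 0.05) + 1L, n_genera)] <- ""
  ph <- phyla[(seq_len(n_genera) - 1L) %% length(phyla) + 1L]
  sprintf("k__Bacteria;p__%s;c__%s_cl;o__%s_or;f__%s_fa;g__%s",
          ph, ph, ph, ph, genus)
}

#' Generate a genus-level count table
#'
#' Per-genus log-abundance is `baseline + niche_slope * centered EC +
#' guild_loading(cover) * guild factor + noise`; guild factors are standard
#' normal latents shared by all genera of a guild within a sample, so guild
#' members are correlated above the co-occurrence threshold by construction.
#' Log-abundances are softmax-transformed into sample composition and
#' converted to integer counts by a multinomial draw at fixed depth.
#'
#' @param metadata Output of [generate_metadata()].
#' @param config The [study_config()].
#' @param seed Study seed (default `config$seed`).
#' @return A counts-mode [abundance_table()] with fabricated 6-rank lineages;
#'   attribute `truth` records baselines, slopes and guild assignment.
#' @export
generate_abundance_table <- function(metadata, config, seed = config$seed) {
  validate_study_config(config)
  ng <- config$n_genera
  if (config$depth < ng)
    warning("sequencing depth (", config$depth,
            ") is below the number of genera (", ng, ")")
  gl <- config$guild_loading
  load_veg <- if (length(gl) > 1L || !is.null(names(gl)))
    recycle_to(gl, 2L, nm = c("vegetated", "bare"), what = "guild_loading")[1L]
  else gl
  load_bare <- if (length(gl) > 1L || !is.null(names(gl)))
    recycle_to(gl, 2L, nm = c("vegetated", "bare"), what = "guild_loading")[2L]
  else gl
  off <- noise_off(config)
  n <- nrow(metadata)
  with_stage_seed(seed, "abundance", {
    baseline <- rnorm(ng, 0, config$baseline_sd)
    slopes <- config$niche_ec_slopes %||% {
      s <- rnorm(ng, config$niche_slope_mean, config$niche_slope_sd)
      # a small halotolerant set with strongly positive salinity response
      # drives dominance (and hence the Shannon decline) at high EC; their
      # baselines start moderately low so the high-salinity surge is
      # consistent across realizations rather than baseline-lottery driven
      nh <- round(config$halophile_fraction * ng)
      if (nh > 0L) {
        s[seq_len(nh)] <- rnorm(nh, config$halophile_slope, 0.05)
        baseline[seq_len(nh)] <- rnorm(nh, -0.5, 0.2)
      }
      s
    }
    guild <- sort(rep_len(seq_len(config$n_guilds), ng))
    ecc <- metadata$ec - mean(metadata$ec)
    fac <- matrix(rnorm(config$n_guilds * n), config$n_guilds, n)
    loading <- ifelse(metadata$cover == "vegetated", load_veg, load_bare)
    eta <- outer(baseline, rep(1, n)) + outer(slopes, ecc)
    eta <- eta + fac[guild, , drop = FALSE] *
      matrix(loading, ng, n, byrow = TRUE)
    if (!off) eta <- eta + matrix(rnorm(ng * n, 0, config$noise_sd_log), ng, n)
    prob <- apply(eta, 2L, function(e) { e <- exp(e - max(e)); e / sum(e) })
    counts <- vapply(seq_len(n), function(j) {
      rmultinom(1L, size = config$depth, prob = prob[, j])[, 1L]
    }, integer(ng))
    rownames(counts) <- paste0("g", sprintf("%04d", seq_len(ng)))
    colnames(counts) <- metadata$sample_id
    tab <- abundance_table(counts, taxonomy = synthetic_lineages(ng),
                           mode = "counts")
    attr(tab, "truth") <- list(baseline = baseline, niche_ec_slopes = slopes,
                               guild = guild,
                               guild_loading = c(vegetated = load_veg,
                                                 bare = load_bare))
    tab
  })
}

#' Generate qPCR gene quantities and synthetic Ct values
#'
#' Per gene (16S rRNA, PAH-RHD-alpha, C12O), log10 copies per gram follow
#' `log10(gene mean) + gene_ec_slope * centered EC + vegetation offset +
#' noise`; the multiplicative effect is normalized to unit arithmetic mean
#' across the cohort so the configured gene mean is the cohort mean exactly.
#' Ct values consistent with the configured standard curves are emitted,
#' along with the dilution series that defines each curve, enabling
#' round-trip testing of [quantify_gene_table()].
#'
#' @param metadata Output of [generate_metadata()].
#' @param config The [study_config()].
#' @param seed Study seed (default `config$seed`).
#' @return data.frame `sample_id, gene, copies_per_g, ct` with attribute
#'   `standards` (data.frame `gene, log10_copies, ct`) and attribute
#'   `curves` (configured slope/intercept per gene).
#' @export
generate_gene_quant <- function(metadata, config, seed = config$seed) {
  validate_study_config(config)
  if (nrow(metadata) == 0L) stop("metadata is empty")
  genes <- c(`16S` = config$gene_mean_16s,
             `PAH-RHDa` = config$gene_mean_rhd,
             C12O = config$gene_mean_c12o)
  intercepts <- c(`16S` = config$curve_intercept_16s,
                  `PAH-RHDa` = config$curve_intercept_rhd,
                  C12O = config$curve_intercept_c12o)
  off <- noise_off(config)
  n <- nrow(metadata)
  ecc <- metadata$ec - mean(metadata$ec)
  veg <- as.numeric(metadata$cover == "vegetated")
  with_stage_seed(seed, "genes", {
    out <- do.call(rbind, lapply(names(genes), function(g) {
      lmult <- config$gene_ec_slope * ecc + config$gene_vegetation_offset * veg
      if (!off) lmult <- lmult + rnorm(n, 0, config$gene_noise_sd_log10)
      mult <- 10^lmult
      mult <- mult / mean(mult)   # unit-mean: cohort mean == configured mean
      copies <- genes[[g]] * mult
      data.frame(sample_id = metadata$sample_id, gene = g,
                 copies_per_g = copies,
                 ct = config$curve_slope * log10(copies) + intercepts[[g]],
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    standards <- do.call(rbind, lapply(names(genes), function(g) {
      # 7-point dilution series spanning the gene's expected copy range
      lg <- seq(floor(log10(genes[[g]])) - 4, length.out = 7L)
      data.frame(gene = g, log10_copies = lg,
                 ct = config$curve_slope * lg + intercepts[[g]],
                 stringsAsFactors = FALSE)
    }))
    attr(out, "standards") <- standards
    attr(out, "curves") <- data.frame(gene = names(genes),
                                      slope = config$curve_slope,
                                      intercept = unname(intercepts),
                                      stringsAsFactors = FALSE)
    out
  })
}

#' Generate a complete synthetic study
#'
#' Runs all four generator stages under the child-seed scheme and bundles
#' the results with a truth record (the configuration actually used plus the
#' realized genus-level parameters).
#'
#' @param config A [study_config()].
#' @param seed Study seed (default `config$seed`).
#' @return Object of class `study_dataset`: `metadata`, `pah`, `abundance`,
#'   `genes`, `truth`.
#' @export
generate_study <- function(config = study_config(), seed = config$seed) {
  validate_study_config(config)
  metadata <- generate_metadata(config, seed)
  pah <- generate_pah_profiles(metadata, config, seed)
  abundance <- generate_abundance_table(metadata, config, seed)
  genes <- generate_gene_quant(metadata, config, seed)
  truth <- c(unclass(config),
             list(seed_used = as.integer(seed),
                  realized = attr(abundance, "truth")))
  structure(list(metadata = metadata, pah = pah, abundance = abundance,
                 genes = genes, truth = truth),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("study_dataset: %d samples, %d genera, seed %d\n",
              nrow(x$metadata), nrow(x$abundance$mat), x$truth$seed_used))
  invisible(x)
}

#' Write a study bundle to disk
#'
#' Writes the standard file bundle: abundance TSV (taxon id + `taxonomy`
#' lineage column + sample columns), metadata CSV, PAH CSV, gene CSV,
#' standard-curve CSV and a truth YAML recording the generating
#' configuration.
#'
#' @param study A `study_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_study_bundle <- function(study, dir) {
  stopifnot(inherits(study, "study_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(abundance = file.path(dir, "abundance.tsv"),
             metadata = file.path(dir, "metadata.csv"),
             pah = file.path(dir, "pah.csv"),
             genes = file.path(dir, "genes.csv"),
             standards = file.path(dir, "standards.csv"),
             truth = file.path(dir, "truth.yaml"))
  write_abundance(study$abundance, paths["abundance"])
  write.csv(study$metadata, paths["metadata"], row.names = FALSE)
  write.csv(study$pah, paths["pah"], row.names = FALSE)
  write.csv(study$genes, paths["genes"], row.names = FALSE)
  write.csv(attr(study$genes, "standards"), paths["standards"],
            row.names = FALSE)
  truth <- study$truth
  truth <- truth[!vapply(truth, is.null, logical(1L))]
  yaml::write_yaml(lapply(truth, function(v)
    if (is.numeric(v)) as.numeric(v) else v), paths["truth"])
  invisible(paths)
}
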