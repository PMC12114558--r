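# qPCR standard-curve fitting and absolute gene quantification.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of cycle threshold on log10 template copies over a
#' dilution series: \eqn{Ct = slope \cdot \log_{10}(copies) + intercept}.
#' Amplification efficiency is \eqn{10^{-1/slope} - 1} (1.0 = perfect
#' doubling per cycle, slope -3.3219).
#'
#' @param log10_copies Numeric vector of log10 template copies (>= 3 distinct
#'   dilution points).
#' @param ct Matching cycle-threshold values.
#' @return Object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `ct_range` (range of fitted Ct values,
#'   used to flag extrapolation), `n_points`.
#' @export
#' @examples
#' fit_standard_curve(3:8, -3.3219 * (3:8) + 38)
fit_standard_curve <- function(log10_copies, ct) {
  if (length(log10_copies) != length(ct))
    stop("log10_copies and ct must have equal length")
  ok <- is.finite(log10_copies) & is.finite(ct)
  x <- log10_copies[ok]; y <- ct[ok]
  if (length(x) < 3L) stop("need at least 3 dilution points")
  if (var(x) == 0) stop("dilution points must span distinct log10 copies")
  if (var(y) == 0) stop("constant Ct across dilutions: no usable signal")
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2L])
  r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(
    slope = slope,
    intercept = unname(coef(fit)[1L]),
    r_squared = r2,
    efficiency = 10^(-1 / slope) - 1,
    ct_range = range(fitted(fit)),
    n_points = length(x)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve: Ct = %.4f * log10(copies) + %.4f  (R2 = %.4f, E = %.1f%%)\n",
    x$slope, x$intercept, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Absolute quantification from Ct values
#'
#' Inverts a standard curve:
#' \eqn{copies = 10^{(Ct - intercept)/slope} \times extraction\_factor}.
#' The extraction factor collapses soil mass, elution volume and template
#' dilution into one copies-in-reaction to copies-per-gram multiplier; with
#' the default of 1 the result is copies per reaction, and a reminder is
#' messaged once per call.
#'
#' @param ct Cycle-threshold value(s).
#' @param curve A `standard_curve` (slope < 0).
#' @param extraction_factor Multiplier to copies per gram dry soil
#'   (default 1).
#' @return Numeric vector of copy numbers with a logical attribute
#'   `extrapolated` marking Ct values outside the fitted dilution range.
#' @export
quantify_copies <- function(ct, curve, extraction_factor = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope >= 0) stop("standard curve slope must be negative")
  if (missing(extraction_factor))
    message("extraction_factor = 1: results are copies per reaction, ",
            "not per gram, unless a factor is supplied")
  copies <- 10^((ct - curve$intercept) / curve$slope) * extraction_factor
  tol <- 1e-9 * max(1, abs(curve$ct_range))
  extra <- ct < min(curve$ct_range) - tol | ct > max(curve$ct_range) + tol
  if (any(extra, na.rm = TRUE))
    warning(sum(extra, na.rm = TRUE),
            " Ct value(s) outside the fitted dilution range; flagged extrapolated")
  attr(copies, "extrapolated") <- extra
  copies
}

#' Quantify a table of qPCR measurements
#'
#' Fits one standard curve per gene from a dilution-series table and applies
#' it to every sample Ct.
#'
#' @param samples data.frame `sample_id, gene, ct` (optionally a logical
#'   `qc_pass` column; failed rows are dropped with a warning).
#' @param standards data.frame `gene, log10_copies, ct`.
#' @param extraction_factor Copies-in-reaction to copies-per-gram multiplier.
#' @return data.frame `sample_id, gene, ct, copies_per_g, extrapolated`, with
#'   the fitted curves attached as attribute `curves`.
#' @export
quantify_gene_table <- function(samples, standards, extraction_factor = 1) {
  stopifnot(all(c("sample_id", "gene", "ct") %in% names(samples)),
            all(c("gene", "log10_copies", "ct") %in% names(standards)))
  if ("qc_pass" %in% names(samples) && any(!samples$qc_pass)) {
    warning(sum(!samples$qc_pass), " row(s) failed qPCR QC and were dropped")
    samples <- samples[samples$qc_pass, , drop = FALSE]
  }
  genes <- unique(samples$gene)
  missing <- setdiff(genes, unique(standards$gene))
  if (length(missing))
    stop("no standard curve for gene(s): ", paste(missing, collapse = ", "))
  curves <- lapply(setNames(genes, genes), function(g) {
    s <- standards[standards$gene == g, ]
    fit_standard_curve(s$log10_copies, s$ct)
  })
  out <- do.call(rbind, lapply(genes, function(g) {
    rows <- samples[samples$gene == g, , drop = FALSE]
    cp <- quantify_copies(rows$ct, curves[[g]],
                          extraction_factor = extraction_factor)
    data.frame(sample_id = rows$sample_id, gene = g, ct = rows$ct,
               copies_per_g = as.numeric(cp),
               extrapolated = attr(cp, "extrapolated"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  out
}
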