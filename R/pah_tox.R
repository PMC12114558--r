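# PAH congener bookkeeping, molecular-weight fractions, BaP toxic equivalents
# and contamination classification.

#' The 16 priority PAH congeners
#'
#' Reference table of the 16 US-EPA priority polycyclic aromatic hydrocarbons
#' tracked throughout the package: congener code, full name, number of
#' aromatic rings and molecular-weight class. Low-molecular-weight (LMW)
#' congeners are the 2-3-ring compounds; the remaining ten 4-6-ring compounds
#' are high-molecular-weight (HMW).
#'
#' @return A data.frame with columns `code`, `name`, `rings`, `class`
#'   (`"LMW"` or `"HMW"`).
#' @export
#' @examples
#' pah_congeners()
pah_congeners <- function() {
  data.frame(
    code = c("NAP", "ACY", "ACE", "FLU", "PHE", "ANT",
             "FLA", "PYR", "BaA", "CHR", "BbF", "BkF",
             "BaP", "IndP", "DahA", "BghiP"),
    name = c("naphthalene", "acenaphthylene", "acenaphthene", "fluorene",
             "phenanthrene", "anthracene", "fluoranthene", "pyrene",
             "benzo[a]anthracene", "chrysene", "benzo[b]fluoranthene",
             "benzo[k]fluoranthene", "benzo[a]pyrene",
             "indeno[1,2,3-cd]pyrene", "dibenz[a,h]anthracene",
             "benzo[g,h,i]perylene"),
    rings = c(2L, 3L, 3L, 3L, 3L, 3L, 4L, 4L, 4L, 4L, 5L, 5L, 5L, 6L, 5L, 6L),
    class = c(rep("LMW", 6L), rep("HMW", 10L)),
    stringsAsFactors = FALSE
  )
}

lmw_codes <- function() pah_congeners()$code[pah_congeners()$class == "LMW"]
hmw_codes <- function() pah_congeners()$code[pah_congeners()$class == "HMW"]

#' Default toxic equivalency factors (Nisbet & LaGoy convention)
#'
#' Congener potencies relative to benzo\[a\]pyrene: BaP and DahA 1; BaA, BbF,
#' BkF and IndP 0.1; ANT, CHR and BghiP 0.01; all others 0.001. Any published
#' TEF set can be substituted via [read_tef_csv()].
#'
#' @return Named numeric vector of 16 TEFs, names are congener codes.
#' @export
default_tef <- function() {
  tef <- setNames(rep(0.001, 16L), pah_congeners()$code)
  tef[c("BaP", "DahA")] <- 1
  tef[c("BaA", "BbF", "BkF", "IndP")] <- 0.1
  tef[c("ANT", "CHR", "BghiP")] <- 0.01
  tef
}

#' Read a TEF table from CSV
#'
#' Expects columns `congener,tef`. TEF(BaP) must be 1 and all TEFs positive.
#'
#' @param path Path to a CSV file.
#' @return Named numeric vector of TEFs.
#' @export
read_tef_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("congener", "tef") %in% names(x)))
    stop("TEF CSV must have columns 'congener' and 'tef'")
  tef <- setNames(as.numeric(x$tef), x$congener)
  validate_tef(tef)
  tef
}

validate_tef <- function(tef) {
  if (any(!is.finite(tef)) || any(tef <= 0))
    stop("all TEFs must be positive and finite")
  if (!"BaP" %in% names(tef) || abs(tef[["BaP"]] - 1) > 1e-12)
    stop("TEF table must assign TEF(BaP) = 1")
  invisible(tef)
}

# coerce a profile (named vector or one-row data.frame of congener columns)
# into a full named 16-vector; missing congeners become 0 with a warning
as_pah_profile <- function(x) {
  codes <- pah_congeners()$code
  if (is.data.frame(x)) x <- unlist(x[intersect(names(x), codes)])
  if (is.null(names(x))) {
    if (length(x) != 16L)
      stop("unnamed PAH profile must have exactly 16 concentrations")
    names(x) <- codes
  }
  unknown <- setdiff(names(x), codes)
  if (length(unknown))
    stop("unrecognized congener code(s): ", paste(unknown, collapse = ", "))
  neg <- names(x)[!is.na(x) & x < 0]
  if (length(neg))
    stop("negative concentration for congener(s): ", paste(neg, collapse = ", "))
  missing <- setdiff(codes, names(x))
  if (length(missing)) {
    warning("congener(s) absent from profile, treated as 0: ",
            paste(missing, collapse = ", "))
  }
  out <- setNames(numeric(16L), codes)
  out[names(x)] <- as.numeric(x)
  out
}

#' Summarize a 16-congener PAH profile
#'
#' Partitions the profile into low-molecular-weight (2-3 ring) and
#' high-molecular-weight (4-6 ring) totals; TPAH is their sum. If a TEF table
#' is supplied, the BaP toxic equivalent (TEQ) and, if a scheme is given, the
#' contamination class are appended.
#'
#' @param profile Named numeric vector of congener concentrations
#'   (mg kg^-1 dry soil); names are congener codes. Missing congeners are
#'   treated as 0 with a warning.
#' @param tef Optional named TEF vector (see [default_tef()]).
#' @param scheme Optional classification scheme passed to
#'   [classify_contamination()]; used only when `tef` is supplied.
#' @return A list with `lmw`, `hmw`, `tpah` (all mg kg^-1), and when requested
#'   `teq_bap` and `contamination_class`.
#' @export
#' @examples
#' summarize_pah_profile(c(PHE = 0.46, BaP = 0.39), tef = default_tef())
summarize_pah_profile <- function(profile, tef = NULL, scheme = NULL) {
  conc <- as_pah_profile(profile)
  lmw <- sum(conc[lmw_codes()])
  hmw <- sum(conc[hmw_codes()])
  out <- list(lmw = lmw, hmw = hmw, tpah = lmw + hmw)
  if (!is.null(tef)) {
    out$teq_bap <- teq_bap(conc, tef)
    if (!is.null(scheme))
      out$contamination_class <- classify_contamination(out$tpah, scheme)
  }
  out
}

#' BaP-based total toxic equivalent (TEQ)
#'
#' Computes the TEF-weighted sum of congener concentrations,
#' \eqn{TEQ_{BaP} = \sum_i c_i \cdot TEF_i}, expressing total PAH toxicity as
#' an equivalent benzo\[a\]pyrene concentration.
#'
#' @param profile Named congener concentration vector (mg kg^-1).
#' @param tef Named TEF vector; must cover every congener with a nonzero
#'   concentration (no silent zero-weighting).
#' @return TEQ in mg kg^-1.
#' @export
teq_bap <- function(profile, tef = default_tef()) {
  conc <- as_pah_profile(profile)
  validate_tef(tef)
  nonzero <- names(conc)[conc > 0]
  uncovered <- setdiff(nonzero, names(tef))
  if (length(uncovered))
    stop("TEF table missing congener(s) with nonzero concentration: ",
         paste(uncovered, collapse = ", "))
  sum(conc[nonzero] * tef[nonzero])
}

#' Classify soil PAH contamination from TPAH
#'
#' Four-tier agronomic scheme with boundaries at 0.2, 0.6 and 1.0 mg kg^-1:
#' unpolluted (<= 0.2), weakly polluted (<= 0.6), contaminated (<= 1.0) and
#' heavily polluted (strictly > 1.0). `scheme = "two_tier"` collapses the
#' lower three tiers into "slightly polluted", keeping the same strict
#' > 1.0 mg kg^-1 rule for "heavily polluted".
#'
#' @param tpah Total PAH concentration(s), mg kg^-1 (vectorized).
#' @param scheme `"four_tier"` (default) or `"two_tier"`.
#' @return Character vector of class labels.
#' @export
#' @examples
#' classify_contamination(c(0.1, 0.5, 0.9, 2.3))
#' classify_contamination(0.79, scheme = "two_tier")
classify_contamination <- function(tpah, scheme = c("four_tier", "two_tier")) {
  scheme <- match.arg(scheme)
  if (any(!is.finite(tpah)) || any(tpah < 0))
    stop("tpah must be finite and >= 0")
  four <- ifelse(tpah > 1.0, "heavily polluted",
          ifelse(tpah > 0.6, "contaminated",
          ifelse(tpah > 0.2, "weakly polluted", "unpolluted")))
  if (scheme == "four_tier") return(four)
  ifelse(tpah > 1.0, "heavily polluted", "slightly polluted")
}

#' Summarize a table of PAH profiles
#'
#' Applies [summarize_pah_profile()] to every row of a per-sample congener
#' table and checks internal consistency of any pre-computed totals.
#'
#' @param pah A data.frame with a `sample_id` column and 16 congener columns.
#' @param tef Named TEF vector, default [default_tef()].
#' @param scheme Classification scheme (see [classify_contamination()]).
#' @return A data.frame: `sample_id`, `lmw`, `hmw`, `tpah`, `teq_bap`,
#'   `contamination_class`.
#' @export
summarize_pah_table <- function(pah, tef = default_tef(),
                                scheme = c("four_tier", "two_tier")) {
  scheme <- match.arg(scheme)
  if (!"sample_id" %in% names(pah)) stop("pah table needs a 'sample_id' column")
  codes <- intersect(pah_congeners()$code, names(pah))
  rows <- lapply(seq_len(nrow(pah)), function(i) {
    s <- summarize_pah_profile(unlist(pah[i, codes, drop = FALSE]),
                               tef = tef, scheme = scheme)
    data.frame(sample_id = pah$sample_id[i], lmw = s$lmw, hmw = s$hmw,
               tpah = s$tpah, teq_bap = s$teq_bap,
               contamination_class = s$contamination_class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Check additivity of an ingested PAH summary table
#'
#' For tables of pre-computed group or sample summaries, flags rows where
#' the reported LMW + HMW totals disagree with the reported TPAH by more than
#' `tol` (default 0.01 mg kg^-1, i.e. printed rounding). Inconsistency is a
#' data warning, not an error: published summary tables occasionally carry
#' internally inconsistent rows.
#'
#' @param summary_df data.frame with columns `tpah`, `lmw`, `hmw`.
#' @param tol Tolerance in mg kg^-1.
#' @return Logical vector, TRUE where consistent; inconsistent rows warn.
#' @export
check_pah_additivity <- function(summary_df, tol = 0.01) {
  stopifnot(all(c("tpah", "lmw", "hmw") %in% names(summary_df)))
  delta <- abs(summary_df$lmw + summary_df$hmw - summary_df$tpah)
  ok <- delta <= tol
  if (any(!ok)) {
    lab <- if ("group" %in% names(summary_df)) summary_df$group
           else if ("sample_id" %in% names(summary_df)) summary_df$sample_id
           else seq_len(nrow(summary_df))
    warning("LMW + HMW differs from TPAH by > ", tol, " mg/kg for: ",
            paste(lab[!ok], collapse = ", "))
  }
  ok
}
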