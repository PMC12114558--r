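# Environment-community association statistics: correlation matrices,
# Mantel tests, redundancy analysis, and ANOVA with compact letter display.

# Spearman r for a matrix (variables in columns) with p from the t
# approximation on n - 2 df; mid-ranks for ties, then Pearson on ranks.
cor_with_p <- function(X, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  n <- nrow(X)
  R <- if (method == "spearman") apply(X, 2L, rank) else X
  r <- cor(R)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1 - 1e-15] <- 0
  diag(p) <- 0
  list(r = r, p = p, n = n)
}

#' Pairwise correlation matrix with p-values
#'
#' All pairwise correlations between variables. Spearman (default) uses
#' mid-ranks for ties followed by Pearson on the ranks; two-sided p-values
#' come from the t approximation with n - 2 degrees of freedom. Pairs are
#' computed on pairwise-complete observations; constant variables yield
#' missing coefficients with a warning. Optional Benjamini-Hochberg
#' adjustment (off by default: raw per-pair significance is conventional for
#' environment-community correlation grids).
#'
#' @param X Numeric matrix or data.frame, variables in columns, samples in
#'   rows (>= 4 complete samples per pair).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param adjust_bh Apply Benjamini-Hochberg correction to the p-values?
#' @return data.frame `var1, var2, r, p, n, method` (one row per unordered
#'   pair) with the full `r` and `p` matrices attached as attributes
#'   `r_matrix`, `p_matrix`.
#' @export
correlation_matrix <- function(X, method = c("spearman", "pearson"),
                               adjust_bh = FALSE) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  vars <- colnames(X)
  nv <- length(vars)
  constant <- apply(X, 2L, function(v) var(v[is.finite(v)]) == 0)
  if (any(constant))
    warning("constant variable(s), correlations reported as NA: ",
            paste(vars[constant], collapse = ", "))
  r <- matrix(NA_real_, nv, nv, dimnames = list(vars, vars))
  p <- r
  nmat <- matrix(NA_integer_, nv, nv, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0; diag(nmat) <- colSums(is.finite(X))
  for (i in seq_len(nv - 1L)) for (j in (i + 1L):nv) {
    if (constant[i] || constant[j]) next
    ok <- is.finite(X[, i]) & is.finite(X[, j])
    if (sum(ok) < 4L)
      stop("fewer than 4 complete samples for pair ", vars[i], " / ", vars[j])
    res <- cor_with_p(X[ok, c(i, j), drop = FALSE], method = method)
    r[i, j] <- r[j, i] <- res$r[1L, 2L]
    p[i, j] <- p[j, i] <- res$p[1L, 2L]
    nmat[i, j] <- nmat[j, i] <- res$n
  }
  idx <- which(upper.tri(r), arr.ind = TRUE)
  out <- data.frame(var1 = vars[idx[, 1L]], var2 = vars[idx[, 2L]],
                    r = r[idx], p = p[idx], n = nmat[idx], method = method,
                    stringsAsFactors = FALSE)
  if (adjust_bh) {
    out$p <- stats::p.adjust(out$p, method = "BH")
    p[idx] <- out$p
    p[cbind(idx[, 2L], idx[, 1L])] <- out$p
  }
  attr(out, "r_matrix") <- r
  attr(out, "p_matrix") <- p
  out
}

dist_upper <- function(d) as.vector(as.dist(d))

#' Mantel test between two distance matrices
#'
#' Correlates the upper off-diagonal vectors of two distance matrices
#' (Spearman by default) and assesses significance by jointly permuting the
#' rows and columns of the second matrix. The one-sided (positive
#' association) permutation p-value is
#' `(1 + #\{permuted r >= observed r\}) / (1 + n_perm)`. With
#' `exhaustive = TRUE` all `n! - 1` nontrivial permutations are enumerated
#' instead (feasible for small n), making the p-value exact.
#'
#' @param d1,d2 `dist` objects or symmetric matrices over the same samples
#'   (matching labels if labelled).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Seed for the permutation stream.
#' @param exhaustive Enumerate all permutations instead of sampling.
#' @return List of class `mantel_result`: `r`, `p`, `n_perm`, `method`,
#'   `seed`.
#' @export
mantel_test <- function(d1, d2, method = c("spearman", "pearson"),
                        n_perm = 999L, seed = 1L, exhaustive = FALSE) {
  method <- match.arg(method)
  d1 <- as.dist(d1); d2 <- as.dist(d2)
  n <- attr(d1, "Size")
  if (attr(d2, "Size") != n)
    stop("distance matrices differ in size: ", n, " vs ", attr(d2, "Size"))
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2)) {
    if (setequal(l1, l2)) {
      d2 <- as.dist(as.matrix(d2)[l1, l1])
    } else {
      stop("sample sets differ; only in d1: ",
           paste(setdiff(l1, l2), collapse = ", "), "; only in d2: ",
           paste(setdiff(l2, l1), collapse = ", "))
    }
  }
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  ut <- upper.tri(m2)   # one index set keeps every pair aligned
  v1 <- m1[ut]
  corfun <- function(a, b) cor(a, b, method = method)
  r_obs <- corfun(v1, m2[ut])
  perm_r <- function(ord) {
    mp <- m2[ord, ord]
    corfun(v1, mp[ut])
  }
  if (exhaustive) {
    perms <- all_permutations(n)
    rs <- vapply(perms, perm_r, numeric(1L))
    # drop the identity; count it through the +1 convention
    rs <- rs[-1L]
    n_used <- length(rs)
  } else {
    rs <- with_stage_seed(seed, "mantel",
      vapply(seq_len(n_perm), function(i) {
        ord <- sample.int(n)
        # the identity is already counted by the +1 convention
        while (all(ord == seq_len(n))) ord <- sample.int(n)
        perm_r(ord)
      }, numeric(1L)))
    n_used <- n_perm
  }
  p <- (1 + sum(rs >= r_obs - 1e-12)) / (1 + n_used)
  structure(list(r = r_obs, p = p, n_perm = n_used, method = method,
                 seed = seed, exhaustive = exhaustive),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel (%s): r = %.4f, p = %.4g (%d permutations%s)\n",
              x$method, x$r, x$p, x$n_perm,
              if (x$exhaustive) ", exhaustive" else ""))
  invisible(x)
}

# all permutations of 1..n in lexicographic order, identity first
all_permutations <- function(n) {
  if (n > 8L) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", factorial(n))
  k <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (s in sub) {
      k <- k + 1L
      out[[k]] <- c(first, rest[s])
    }
  }
  out
}

#' Marginal redundancy analysis (RDA) explained fractions
#'
#' For each explanatory variable fitted alone, the fraction of total
#' variance in the (centered, optionally standardized) response matrix
#' captured by the constrained ordination: `trace(Y_hat_v) / trace(Y) * 100`,
#' ranked descending. Collinear explanatory variables (beyond `tol` in a QR
#' decomposition of the full model matrix) are dropped with a warning.
#'
#' @param Y Response matrix, samples x features (community or diversity
#'   metrics).
#' @param X Explanatory data.frame or matrix, samples x variables.
#' @param standardize Standardize the response columns to unit variance
#'   before analysis? (default TRUE, appropriate for mixed-unit responses).
#' @param tol QR tolerance for collinearity detection.
#' @return List of class `rda_result`: `table` (data.frame `variable`,
#'   `explained_pct`, ranked), `total_constrained_pct` (full model),
#'   `scores` (sample scores on the full-model constrained axes),
#'   `dropped` (collinear variables removed).
#' @export
rda_explained <- function(Y, X, standardize = TRUE, tol = 1e-7) {
  Y <- as.matrix(Y)
  X <- as.data.frame(X)
  if (nrow(Y) != nrow(X)) stop("Y and X must have the same number of samples")
  if (nrow(Y) < ncol(X) + 2L)
    stop("need at least ", ncol(X) + 2L, " samples for ", ncol(X),
         " explanatory variables")
  if (standardize) {
    sds <- apply(Y, 2L, sd)
    if (any(sds == 0)) {
      warning("constant response column(s) dropped: ",
              paste(colnames(Y)[sds == 0], collapse = ", "))
      Y <- Y[, sds > 0, drop = FALSE]
      if (ncol(Y) == 0L) stop("no non-constant response columns left")
    }
    Y <- scale(Y)
  } else {
    Y <- scale(Y, center = TRUE, scale = FALSE)
  }
  # drop collinear explanatory variables
  Xm <- scale(as.matrix(X))
  qrx <- qr(cbind(1, Xm), tol = tol)
  keep_idx <- qrx$pivot[seq_len(qrx$rank)]
  keep_idx <- setdiff(keep_idx, 1L) - 1L
  dropped <- setdiff(names(X), names(X)[keep_idx])
  if (length(dropped))
    warning("collinear explanatory variable(s) dropped: ",
            paste(dropped, collapse = ", "))
  X <- X[, names(X)[keep_idx], drop = FALSE]
  marg <- vapply(names(X), function(v) {
    fit <- vegan::rda(Y ~ x, data = data.frame(x = X[[v]]))
    100 * fit$CCA$tot.chi / fit$tot.chi
  }, numeric(1L))
  full <- vegan::rda(Y ~ ., data = X)
  tab <- data.frame(variable = names(marg), explained_pct = unname(marg),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$explained_pct), ]
  rownames(tab) <- NULL
  structure(list(
    table = tab,
    total_constrained_pct = 100 * full$CCA$tot.chi / full$tot.chi,
    scores = vegan::scores(full, display = "sites",
                           choices = seq_len(full$CCA$rank)),
    dropped = dropped
  ), class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("RDA: full model explains %.1f%% of variance\n",
              x$total_constrained_pct))
  print(x$table)
  invisible(x)
}

#' One-way ANOVA with Tukey HSD compact letter display
#'
#' Fits a one-way ANOVA, runs Tukey's honest significant difference test on
#' the studentized-range distribution, and assigns letters by the
#' insert-and-absorb algorithm: groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param values Numeric measurements.
#' @param groups Group labels (coerced to factor); >= 2 groups with >= 2
#'   replicates each.
#' @param alpha Familywise significance level (default 0.05).
#' @return data.frame `group, n, mean, sd, letters` (groups ordered by
#'   decreasing mean) with attributes `anova_p` and `tukey` (the pairwise
#'   table).
#' @export
anova_tukey_letters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L))
    stop("every group needs >= 2 replicates; offending group(s): ",
         paste(names(table(groups))[table(groups) < 2L], collapse = ", "))
  fit <- aov(values ~ groups)
  anova_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  tuk <- TukeyHSD(fit, conf.level = 1 - alpha)$groups
  pairs <- do.call(rbind, strsplit(rownames(tuk), "-", fixed = TRUE))
  sig <- tuk[, "p adj"] < alpha
  letters_df <- cld_insert_absorb(levels(groups),
                                  pairs[sig, , drop = FALSE])
  means <- tapply(values, groups, mean)
  sds <- tapply(values, groups, sd)
  ns <- tapply(values, groups, length)
  out <- data.frame(group = names(means), n = as.integer(ns),
                    mean = as.numeric(means), sd = as.numeric(sds),
                    letters = letters_df[names(means)],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean), ]
  rownames(out) <- NULL
  attr(out, "anova_p") <- anova_p
  attr(out, "tukey") <- tuk
  out
}

# Insert-and-absorb compact letter display (Piepho-style). `sig_pairs` is a
# 2-column matrix of significantly different group pairs. Returns a named
# character vector of letter strings.
cld_insert_absorb <- function(groups, sig_pairs) {
  cols <- list(groups)   # each column: set of groups sharing a letter
  if (nrow(sig_pairs)) {
    for (k in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs[k, 1L]; b <- sig_pairs[k, 2L]
      new_cols <- list()
      for (col in cols) {
        if (a %in% col && b %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(new_cols))
      for (i in seq_along(new_cols)) for (j in seq_along(new_cols)) {
        if (i != j && keep[i] && keep[j] &&
            all(new_cols[[i]] %in% new_cols[[j]]) &&
            (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j))
          keep[i] <- FALSE
      }
      cols <- new_cols[keep]
    }
  }
  # order columns by the first (alphabetical) member for stable lettering
  cols <- cols[order(vapply(cols, function(c) min(match(c, groups)), numeric(1L)))]
  out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(cols)) {
    lab <- letters[(i - 1L) %% 26L + 1L]
    for (g in cols[[i]]) out[g] <- paste0(out[g], lab)
  }
  if (any(out == "")) stop("internal error: group left without a letter")
  out
}
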