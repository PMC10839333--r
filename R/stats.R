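# Group-comparison statistics: normality-gated two-group tests, fold
# changes, gated correlations and Pareto-scaled PCA of lipid profiles.

#' Normality gate for small samples
#'
#' Tests whether a sample is compatible with a Gaussian at `alpha`. The gate
#' uses the Lilliefors-corrected Kolmogorov-Smirnov test (parameters are
#' estimated from the data, so the plain KS null distribution would be
#' anti-conservative); samples of 3-4 values fall back to Shapiro-Wilk
#' (the Lilliefors implementation needs n >= 5), and samples with fewer than
#' 3 values or zero variance fail the gate.
#'
#' @param x Numeric vector.
#' @param alpha Gate level (default 0.05).
#' @return Logical scalar with attributes `method` and `p_value`.
#' @export
passes_normality <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0) {
    return(structure(FALSE, method = "degenerate", p_value = NA_real_))
  }
  if (n >= 5L) {
    ht <- nortest::lillie.test(x)
    method <- "lilliefors"
  } else {
    ht <- stats::shapiro.test(x)
    method <- "shapiro"
  }
  structure(ht$p.value >= alpha, method = method, p_value = ht$p.value)
}

#' Fold change of two group means
#'
#' @param mean_a,mean_b Group means (numerator, denominator).
#' @param digits Optional rounding for table display (round-half-even, the
#'   default R rounding); `NULL` returns the raw ratio only.
#' @return The ratio `mean_a / mean_b`; if `digits` is given, the rounded
#'   value with the raw ratio in attribute `"raw"`. `NA` when `mean_b` is 0.
#' @export
#' @examples
#' fold_change(0.082, 0.041, digits = 2)  # 2
fold_change <- function(mean_a, mean_b, digits = NULL) {
  if (!is.finite(mean_b) || mean_b == 0) return(NA_real_)
  fc <- mean_a / mean_b
  if (is.null(digits)) return(fc)
  structure(round(fc, digits), raw = fc)
}

#' Compare two groups with a normality-gated test
#'
#' Applies [passes_normality()] to both groups; if both pass, an unpaired
#' two-tailed t test is used (Welch by default), otherwise a two-tailed
#' Mann-Whitney test (exact p when both groups have n <= 8 and there are no
#' ties, normal approximation with continuity correction otherwise). The
#' gate decision is always recorded: data that fail it are never silently
#' routed to the t test.
#'
#' @param a,b Numeric vectors (n >= 2 each, finite values).
#' @param alpha Significance level (two-tailed, default 0.05).
#' @param measurand Optional name carried into the result.
#' @param labels Group labels, default `c("group1", "group2")`.
#' @param var_equal Use the pooled-variance t test instead of Welch?
#' @return An object of class `group_comparison`: a list with `measurand`,
#'   `labels`, `n`, `means`, `sds`, `sems`, `fold_change` (group1/group2),
#'   `test_used` (`"student_t"` or `"mann_whitney"`), `p_value`,
#'   `significant`, `normal` (logical per group), `gate` (gate methods).
#' @export
#' @examples
#' set.seed(1)
#' compare_groups(rnorm(5, 10), rnorm(5, 0))
compare_groups <- function(a, b, alpha = 0.05, measurand = "",
                           labels = c("group1", "group2"),
                           var_equal = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("insufficient data: each group needs n >= 2 finite values",
         call. = FALSE)
  }
  ga <- passes_normality(a, alpha)
  gb <- passes_normality(b, alpha)
  pooled <- c(a, b)
  if (stats::sd(pooled) == 0) {
    # all observations identical: no evidence of any difference
    test_used <- "mann_whitney"
    p <- 1
  } else if (isTRUE(as.logical(ga)) && isTRUE(as.logical(gb))) {
    test_used <- "student_t"
    p <- stats::t.test(a, b, var.equal = var_equal)$p.value
  } else {
    test_used <- "mann_whitney"
    exact <- length(a) <= 8L && length(b) <= 8L &&
      !anyDuplicated(pooled)
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  }
  means <- c(mean(a), mean(b))
  sds <- c(stats::sd(a), stats::sd(b))
  ns <- c(length(a), length(b))
  structure(list(measurand = measurand,
                 labels = labels,
                 n = ns,
                 means = means,
                 sds = sds,
                 sems = sds / sqrt(ns),
                 fold_change = fold_change(means[1L], means[2L]),
                 test_used = test_used,
                 p_value = p,
                 significant = is.finite(p) && p < alpha,
                 normal = c(isTRUE(as.logical(ga)), isTRUE(as.logical(gb))),
                 gate = c(attr(ga, "method"), attr(gb, "method"))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison>%s %s (n=%d) vs %s (n=%d)\n",
              if (nzchar(x$measurand)) paste0(" ", x$measurand, ":") else "",
              x$labels[1L], x$n[1L], x$labels[2L], x$n[2L]))
  cat(sprintf("  means %.4g / %.4g, FC %.4g, %s p = %.4g%s\n",
              x$means[1L], x$means[2L], x$fold_change, x$test_used,
              x$p_value, if (x$significant) " *" else " (NS)"))
  invisible(x)
}

#' Normality-gated correlation
#'
#' Pearson when both variables pass the normality gate, Spearman otherwise;
#' two-tailed p value; the method used is recorded.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param alpha Gate level.
#' @return List with `method` (`"pearson"`/`"spearman"`), `estimate`, and
#'   `p_value`.
#' @export
correlate <- function(x, y, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 paired finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  method <- if (isTRUE(as.logical(passes_normality(x, alpha))) &&
                isTRUE(as.logical(passes_normality(y, alpha)))) {
    "pearson"
  } else {
    "spearman"
  }
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = method, alternative = "two.sided",
                    exact = FALSE))
  list(method = method, estimate = unname(ht$estimate),
       p_value = ht$p.value)
}

#' Pareto-scaled PCA of lipid profiles
#'
#' Standard metabolomics preprocessing followed by PCA: each sample (row) is
#' divided by its total area, each variable (column) is mean-centered and
#' divided by the square root of its standard deviation (Pareto scaling),
#' and the result is decomposed by [stats::prcomp()]. Columns that are
#' constant after normalization are dropped with a warning. Component signs
#' are fixed so that the largest-magnitude loading of each component is
#' positive.
#'
#' @param areas Numeric matrix or data.frame, samples x peaks, no missing
#'   cells, >= 3 samples and >= 2 peaks.
#' @return An object of class `pca_result`: list with `scores`, `loadings`,
#'   `explained_variance` (fractions, non-increasing), `dropped` (names of
#'   dropped constant columns), `preprocessing`.
#' @export
#' @examples
#' x <- matrix(rexp(60), nrow = 6)
#' pca_lipid_profiles(x)$explained_variance
pca_lipid_profiles <- function(areas) {
  x <- as.matrix(areas)
  if (nrow(x) < 3L || ncol(x) < 2L) {
    stop("need >= 3 samples and >= 2 peaks", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("missing cells are not allowed", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("peak", seq_len(ncol(x)))
  if (is.null(rownames(x))) rownames(x) <- paste0("sample", seq_len(nrow(x)))
  rs <- rowSums(x)
  if (any(rs == 0)) stop("sample with zero total area", call. = FALSE)
  xn <- x / rs
  sds <- apply(xn, 2L, stats::sd)
  dropped <- colnames(xn)[sds == 0]
  keep <- sds > 0
  if (length(dropped)) {
    warning("dropping constant column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (sum(keep) < 2L) {
    # degenerate profile set: no variation to decompose
    ncomp <- min(nrow(x) - 1L, sum(keep))
    ncomp <- max(ncomp, 1L)
    scores <- matrix(0, nrow(x), ncomp,
                     dimnames = list(rownames(x),
                                     paste0("PC", seq_len(ncomp))))
    loadings <- matrix(0, sum(keep), ncomp,
                       dimnames = list(colnames(xn)[keep],
                                       paste0("PC", seq_len(ncomp))))
    return(structure(list(scores = scores, loadings = loadings,
                          explained_variance = rep(0, ncomp),
                          dropped = dropped,
                          preprocessing = c("total-area normalization",
                                            "pareto scaling")),
                     class = "pca_result"))
  }
  xp <- sweep(xn[, keep, drop = FALSE], 2L, sds[keep]^0.5, `/`)
  pc <- stats::prcomp(xp, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  ev <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  # sign convention: the largest-magnitude loading of each PC is positive
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explained_variance = ev, dropped = dropped,
                 preprocessing = c("total-area normalization",
                                   "pareto scaling")),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d samples x %d peaks, EV: %s\n",
              nrow(x$scores), nrow(x$loadings),
              paste(sprintf("%.1f%%", 100 * utils::head(x$explained_variance,
                                                        3L)),
                    collapse = ", ")))
  invisible(x)
}

#' Build a publication-style group summary table
#'
#' For each measurand and each requested pair of groups: group means and SDs,
#' the fold change of the pair, and the normality-gated test with `"NS"`
#' emitted for p >= `alpha`. Missing measurand values (e.g. undefined
#' indices) are excluded pairwise, with the per-cell n reported.
#'
#' @param cohort Data.frame with a `group` column and one numeric column per
#'   measurand (as returned by [simulate_cohort()]).
#' @param measurands Character vector of measurand column names.
#' @param group_pairs List of 2-vectors of group labels, each
#'   `c(numerator, denominator)`.
#' @param alpha Significance level.
#' @param digits Rounding applied to the reported fold change
#'   (round-half-even); `NULL` leaves it raw.
#' @return A `data.frame` with one row per measurand x pair.
#' @export
build_summary_table <- function(cohort, measurands, group_pairs,
                                alpha = 0.05, digits = NULL) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  bad <- setdiff(measurands, names(cohort))
  if (length(bad)) {
    stop("configuration error: unknown measurand(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (m in measurands) {
    for (pair in group_pairs) {
      va <- cohort[[m]][cohort$group == pair[1L]]
      vb <- cohort[[m]][cohort$group == pair[2L]]
      va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
      cmp <- compare_groups(va, vb, alpha = alpha, measurand = m,
                            labels = pair)
      fc <- cmp$fold_change
      if (!is.null(digits) && is.finite(fc)) fc <- round(fc, digits)
      rows[[length(rows) + 1L]] <- data.frame(
        measurand = m, group1 = pair[1L], group2 = pair[2L],
        n1 = cmp$n[1L], n2 = cmp$n[2L],
        mean1 = cmp$means[1L], sd1 = cmp$sds[1L],
        mean2 = cmp$means[2L], sd2 = cmp$sds[2L],
        fold_change = fc, test_used = cmp$test_used,
        p_value = cmp$p_value,
        p_label = if (cmp$p_value < alpha) {
          formatC(cmp$p_value, format = "g", digits = 3)
        } else "NS",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Load a packaged group-mean fixture table
#'
#' The published group means/SDs of the study tables are shipped as TSV
#' fixtures: `"table1"` (adipose-tissue lipid classes, 10 months),
#' `"table2"` (liver MRS measurands at 6 and 10 months) and `"table3"`
#' (liver lipid classes, 10 months).
#'
#' @param name `"table1"`, `"table2"` or `"table3"`.
#' @return The fixture as a `data.frame`.
#' @export
#' @examples
#' head(group_table_fixture("table3"))
group_table_fixture <- function(name = c("table1", "table2", "table3")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, "_means.tsv"),
                      package = "lipospec", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
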