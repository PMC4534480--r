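# Nonparametric cohort comparisons: omnibus Kruskal-Wallis, pairwise
# Mann-Whitney against the reference group with Bonferroni correction, and
# Spearman rank correlation of defect extent with vector magnitude.

#' Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U test. The exact null distribution is used when the
#' pooled sample has at most 12 observations and no ties; otherwise the
#' normal approximation with tie correction and continuity correction is used.
#' The branch that ran is reported.
#'
#' @param a,b Numeric samples, both non-empty.
#' @return List of class `mw_test`: `U` (statistic for `a`), `p_value`,
#'   `method` (`"exact"` or `"normal_approx"`), `n_a`, `n_b`.
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L || anyNA(a) || anyNA(b)) {
    abort("both samples must be non-empty and free of missing values",
          "perfvec_insufficient_data")
  }
  pooled <- c(a, b)
  ties <- anyDuplicated(pooled) > 0L
  exact <- (length(pooled) <= 12L) && !ties
  if (length(unique(pooled)) == 1L) {
    # All observations identical: no rank information, U at its null mean.
    return(structure(list(U = length(a) * length(b) / 2, p_value = 1,
                          method = "normal_approx",
                          n_a = length(a), n_b = length(b)),
                     class = "mw_test"))
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  p <- ht$p.value
  if (!is.finite(p)) p <- 1
  structure(list(U = unname(ht$statistic), p_value = min(1, p),
                 method = if (exact) "exact" else "normal_approx",
                 n_a = length(a), n_b = length(b)),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney (%s): U = %g, p = %.4g (n = %d, %d)\n",
              x$method, x$U, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based one-way comparison of two or more groups, with tie correction;
#' p from the chi-square approximation on `k - 1` degrees of freedom.
#'
#' @param groups List of two or more non-empty numeric samples.
#' @return List of class `kw_test`: `H`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    abort("need at least two groups", "perfvec_insufficient_data")
  }
  if (any(vapply(groups, length, 1L) == 0L)) {
    abort("every group must be non-empty", "perfvec_insufficient_data")
  }
  x <- unlist(groups, use.names = FALSE)
  if (anyNA(x)) {
    abort("groups must be free of missing values", "perfvec_insufficient_data")
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (length(unique(x)) == 1L) {
    return(structure(list(H = 0, p_value = 1, df = length(groups) - 1L),
                     class = "kw_test"))
  }
  ht <- stats::kruskal.test(x, g)
  structure(list(H = unname(ht$statistic), p_value = ht$p.value,
                 df = unname(ht$parameter)),
            class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n",
              x$H, x$df, x$p_value))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. The p value comes from the
#' exact permutation distribution for `n <= 7` without ties, otherwise from
#' the t approximation.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return List of class `spearman_test`: `rho`, `p_value`, `n`, `method`.
#' @export
spearman_correlation <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length", "perfvec_insufficient_data")
  }
  if (length(x) < 3L || anyNA(x) || anyNA(y)) {
    abort("need at least 3 complete pairs", "perfvec_insufficient_data")
  }
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  exact <- length(x) <= 7L && !ties
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = exact))
  p <- ht$p.value
  if (!is.finite(p)) p <- 1
  structure(list(rho = unname(ht$estimate), p_value = min(1, p),
                 n = length(x),
                 method = if (exact) "exact" else "t_approx"),
            class = "spearman_test")
}

#' @export
print.spearman_test <- function(x, ...) {
  cat(sprintf("Spearman (%s): rho = %.4g, p = %.4g (n = %d)\n",
              x$method, x$rho, x$p_value, x$n))
  invisible(x)
}

#' Compare abnormal groups against a reference group
#'
#' Runs the omnibus Kruskal-Wallis test over all groups on one metric; when
#' the omnibus is significant at `omnibus_alpha`, each non-reference group is
#' compared to the reference with a two-sided Mann-Whitney test. The pairwise
#' significance threshold is Bonferroni-corrected: `0.05 / k` for `k` pairwise
#' tests (0.0125 for four comparison groups, 0.025 for two).
#'
#' @param cohort A `cohort_table` or data frame.
#' @param metric Name of the numeric column to compare.
#' @param reference Reference group label (default `"normal"`).
#' @param group_col Column holding group labels (default `"group"`; use
#'   `"condition"` for the normal/ischemia/infarction split).
#' @param omnibus_alpha Gate for running the pairwise tests (default 0.05).
#' @return List of class `group_comparison`: `metric`, `reference`,
#'   `kruskal` (a `kw_test`), `n_comparisons`, `bonferroni_threshold`,
#'   `omnibus_significant`, and `pairwise` (data frame with columns `group`,
#'   `U`, `p_value`, `method`, `significant`; zero rows when the omnibus gate
#'   fails).
#' @export
compare_groups <- function(cohort, metric, reference = "normal",
                           group_col = "group", omnibus_alpha = 0.05) {
  df <- as.data.frame(cohort)
  if (!metric %in% names(df)) {
    abort(sprintf("unknown metric column: %s", metric), "perfvec_schema_error")
  }
  if (!group_col %in% names(df)) {
    abort(sprintf("unknown group column: %s", group_col),
          "perfvec_schema_error")
  }
  labels <- sort(unique(as.character(df[[group_col]])))
  if (!reference %in% labels) {
    abort(sprintf("reference group '%s' not present", reference),
          "perfvec_schema_error")
  }
  others <- setdiff(labels, reference)
  if (length(others) == 0L) {
    abort("no non-reference groups to compare", "perfvec_insufficient_data")
  }
  samples <- lapply(c(reference, others),
                    function(g) df[[metric]][df[[group_col]] == g])
  names(samples) <- c(reference, others)
  kw <- kruskal_wallis(samples)
  k <- length(others)
  threshold <- 0.05 / k
  gate <- kw$p_value < omnibus_alpha
  pairwise <- data.frame(group = character(0), U = numeric(0),
                         p_value = numeric(0), method = character(0),
                         significant = logical(0), stringsAsFactors = FALSE)
  if (gate) {
    pairwise <- do.call(rbind, lapply(others, function(g) {
      mw <- mann_whitney(samples[[g]], samples[[reference]])
      data.frame(group = g, U = mw$U, p_value = mw$p_value,
                 method = mw$method, significant = mw$p_value < threshold,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(metric = metric, reference = reference, kruskal = kw,
                 n_comparisons = k, bonferroni_threshold = threshold,
                 omnibus_significant = gate, pairwise = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> metric '%s' vs reference '%s'\n",
              x$metric, x$reference))
  cat(sprintf("  omnibus H = %.4g, p = %.4g (%s)\n", x$kruskal$H,
              x$kruskal$p_value,
              if (x$omnibus_significant) "significant" else "not significant"))
  cat(sprintf("  Bonferroni threshold %.4g for %d comparisons\n",
              x$bonferroni_threshold, x$n_comparisons))
  if (nrow(x$pairwise)) {
    print(x$pairwise, row.names = FALSE)
  } else {
    cat("  (no pairwise tests run)\n")
  }
  invisible(x)
}
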