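# Cohort-level statistics: rank correlations, group tests, phylum
# summaries, and the principal component regression decomposition.

#' Spearman rank correlation with asymptotic p-value
#'
#' Rho is computed on average ranks (midranks for ties); the two-sided
#' p-value uses the asymptotic approximation t = rho * sqrt((n-2)/(1-rho^2))
#' on n-2 degrees of freedom, appropriate for the cohort sizes this package
#' targets. For tiny samples an exact permutation p-value is available.
#'
#' @param x,y Numeric vectors; pairs with a missing value in either are
#'   dropped.
#' @param p_method `"asymptotic"` (default) or `"exact"` (full permutation
#'   enumeration, only for n <= 10).
#' @return One-row tibble: `rho`, `p_value`, `n_pairs`. If either vector is
#'   constant after pair removal, `rho` and `p_value` are `NA` with a
#'   warning.
#' @examples
#' spearman_test(1:4, c(10, 20, 30, 40))
#' @export
spearman_test <- function(x, y, p_method = c("asymptotic", "exact")) {
  p_method <- match.arg(p_method)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    abort_bias("Spearman correlation needs at least 3 complete pairs",
               "strandbias_error_undefined")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in one of the vectors: Spearman undefined")
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n_pairs = n))
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (p_method == "exact") {
    if (n > 10L) abort_bias("exact permutation p-value limited to n <= 10",
                            "strandbias_error_undefined")
    rx <- rank(x); perms <- permutations_of(n)
    ry <- rank(y)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (abs(rho) >= 1) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(rho = rho, p_value = p, n_pairs = n)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Two-sample comparison of score means
#'
#' Compares the mean composition-bias score between two genome groups
#' (e.g. obligate-intracellular vs free-living), Welch's unequal-variance
#' t-test by default.
#'
#' @param scores_group1,scores_group2 Numeric score vectors (each n >= 2).
#' @param var_equal If `TRUE`, the pooled-variance Student t-test.
#' @return One-row tibble: `mean_group1`, `mean_group2`, `t_statistic`,
#'   `p_value`, `n1`, `n2`.
#' @export
group_t_test <- function(scores_group1, scores_group2, var_equal = FALSE) {
  scores_group1 <- scores_group1[!is.na(scores_group1)]
  scores_group2 <- scores_group2[!is.na(scores_group2)]
  if (length(scores_group1) < 2L || length(scores_group2) < 2L) {
    abort_bias("t-test needs at least two scores per group",
               "strandbias_error_undefined")
  }
  tt <- stats::t.test(scores_group1, scores_group2, var.equal = var_equal)
  tibble::tibble(mean_group1 = mean(scores_group1),
                 mean_group2 = mean(scores_group2),
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 n1 = length(scores_group1), n2 = length(scores_group2))
}

#' Per-phylum summaries of the bias score and companion features
#'
#' Mean, standard deviation and variance of the composition-bias score per
#' phylum, plus phylum means of genome size, GC content, leading-strand
#' gene density and the gcRF/taRF indices. Single-member phyla report
#' `NA` dispersion. Output is ordered alphabetically by phylum.
#'
#' @param features Feature table with at least `phylum` and `score`;
#'   companion columns are summarised when present.
#' @return Tibble, one row per phylum.
#' @export
phylum_summaries <- function(features) {
  features <- tibble::as_tibble(features)
  stopifnot(all(c("phylum", "score") %in% names(features)))
  companions <- intersect(c("genome_size", "gc_content",
                            "gene_density_leading", "gcRF", "taRF"),
                          names(features))
  out <- dplyr::summarise(
    dplyr::group_by(features, .data$phylum),
    n = dplyr::n(),
    mean_score = mean(.data$score, na.rm = TRUE),
    sd_score = stats::sd(.data$score),
    var_score = stats::var(.data$score),
    dplyr::across(dplyr::all_of(companions), ~ mean(.x, na.rm = TRUE),
                  .names = "mean_{.col}"),
    .groups = "drop")
  dplyr::arrange(out, .data$phylum)
}

#' Principal component regression with per-feature R-squared attribution
#'
#' Z-standardises the feature matrix, extracts principal components with
#' unit-norm loadings, and regresses the response on all retained
#' components. Because components are orthogonal, the squared correlation
#' between each component and the response sums to the full regression
#' R-squared; the contribution of an original feature is the
#' loading-squared-weighted sum of the component R-squared values, which
#' again sums exactly to the total. Zero-variance components (rank
#' deficiency) are dropped with a message.
#'
#' @param features Data frame or matrix of numeric features (n rows, k >= 2
#'   columns); rows with any missing value are dropped (listwise) with a
#'   message.
#' @param y Numeric response (the composition-bias score).
#' @return Object of class `pcr_decomp` with fields `contributions` (named
#'   per-feature R-squared shares), `total_r2`, `component_r2`, `loadings`,
#'   `n`, `dropped_rows`. Use [tidy()] / [glance()] for tibble views.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(100), 25, 4, dimnames = list(NULL, paste0("f", 1:4)))
#' fit <- pcr_decomposition(X, X[, 1] + rnorm(25, sd = 0.1))
#' glance(fit)
#' @export
pcr_decomposition <- function(features, y) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("feature_", seq_len(ncol(X)))
  if (ncol(X) < 2L) {
    abort_bias("principal component regression needs at least two features",
               "strandbias_error_invalid")
  }
  keep <- stats::complete.cases(X, y)
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf("pcr_decomposition: dropping %d row(s) with missing values",
                    dropped))
  }
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (nrow(X) <= ncol(X)) {
    abort_bias("principal component regression needs more rows than features",
               "strandbias_error_invalid")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ok <- pc$sdev > 1e-10
  if (any(!ok)) {
    message(sprintf("pcr_decomposition: dropping %d zero-variance component(s)",
                    sum(!ok)))
  }
  scores <- pc$x[, ok, drop = FALSE]
  loadings <- pc$rotation[, ok, drop = FALSE]
  r2 <- as.numeric(stats::cor(scores, y))^2
  contributions <- as.numeric(loadings^2 %*% r2)
  names(contributions) <- colnames(X)
  structure(
    list(contributions = contributions, total_r2 = sum(r2),
         component_r2 = r2, loadings = loadings,
         n = nrow(X), dropped_rows = dropped),
    class = "pcr_decomp"
  )
}

#' @export
print.pcr_decomp <- function(x, ...) {
  cat(sprintf("<pcr_decomp> n=%d, %d components, total R2 = %.4f\n",
              x$n, length(x$component_r2), x$total_r2))
  print(round(x$contributions, 4))
  invisible(x)
}

#' Tidy a principal component regression decomposition
#'
#' @param x A [pcr_decomposition()] fit.
#' @param ... Unused.
#' @return Tibble with one row per feature: `feature`, `r_squared`.
#' @method tidy pcr_decomp
#' @export
tidy.pcr_decomp <- function(x, ...) {
  tibble::tibble(feature = names(x$contributions),
                 r_squared = unname(x$contributions))
}

#' One-row summary of a principal component regression decomposition
#'
#' @inheritParams tidy.pcr_decomp
#' @return Tibble with `total_r2`, `n`, `n_components`, `dropped_rows`.
#' @method glance pcr_decomp
#' @export
glance.pcr_decomp <- function(x, ...) {
  tibble::tibble(total_r2 = x$total_r2, n = x$n,
                 n_components = length(x$component_r2),
                 dropped_rows = x$dropped_rows)
}

#' Spearman battery of every feature against the bias score
#'
#' Correlates the composition-bias score with every numeric feature column
#' of the feature table (pairwise-complete) and annotates two significance
#' conventions: the overall p < 0.05 rule and the stricter cutoff used for
#' COG subcategory percentages (p < 1e-8 by default).
#'
#' @param features Feature table with a `score` column.
#' @param cutoff,strict_cutoff Significance conventions annotated in the
#'   output (defaults 0.05 and 1e-8).
#' @return Tibble of class `cohort_battery`: `feature`, `rho`, `p_value`,
#'   `n_pairs`, `significant`, `significant_strict`. Constant features give
#'   `NA` rows with a warning.
#' @export
correlation_battery <- function(features, cutoff = 0.05,
                                strict_cutoff = 1e-8) {
  features <- tibble::as_tibble(features)
  stopifnot("score" %in% names(features))
  numeric_cols <- names(features)[vapply(features, is.numeric, logical(1))]
  numeric_cols <- setdiff(numeric_cols, "score")
  rows <- purrr::map_dfr(numeric_cols, function(col) {
    res <- spearman_test(features$score, features[[col]])
    dplyr::mutate(res, feature = col, .before = 1)
  })
  rows <- dplyr::mutate(rows,
                        significant = !is.na(.data$p_value) & .data$p_value < cutoff,
                        significant_strict = !is.na(.data$p_value) &
                          .data$p_value < strict_cutoff)
  class(rows) <- c("cohort_battery", class(rows))
  rows
}
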