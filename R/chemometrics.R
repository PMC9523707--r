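#' Percent relative standard deviation
#'
#' `100 * sample SD / mean`; the repeatability indicator used for retention
#' times and responses. Scale-invariant. Undefined (NA with a warning) when
#' the mean is zero.
#'
#' @param values Numeric vector (>= 2 values).
#' @return %RSD.
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop("need at least two values")
  m <- mean(values)
  if (m == 0) {
    warning("zero mean: %RSD undefined")
    return(NA_real_)
  }
  100 * sd(values) / m
}

#' Fisher ratio of one feature across sample classes
#'
#' One-way ANOVA F statistic: between-class mean square over within-class
#' mean square. Invariant under affine transforms of the responses. `Inf`
#' when class means differ but within-class variance is zero; `NA` when all
#' responses are equal.
#'
#' @param responses Per-sample values.
#' @param classes Per-sample class labels.
#' @return F value.
#' @export
fisher_ratio <- function(responses, classes) {
  classes <- as.factor(classes)
  if (nlevels(classes) < 2L) stop("need at least two classes")
  n <- length(responses)
  stopifnot(length(classes) == n)
  counts <- tabulate(classes)
  if (all(counts < 2L)) stop("need replication in at least one class")
  grand <- mean(responses)
  means <- tapply(responses, classes, mean)
  ss_between <- sum(counts * (means - grand)^2)
  ss_within <- sum((responses - means[classes])^2)
  df1 <- nlevels(classes) - 1L
  df2 <- n - nlevels(classes)
  if (ss_within == 0) {
    if (ss_between == 0) return(NA_real_)
    return(Inf)
  }
  (ss_between / df1) / (ss_within / df2)
}

#' Fisher ratios for every row of a response matrix
#'
#' @param responses Features x samples matrix.
#' @param classes Per-sample class labels.
#' @return Numeric vector of F values, one per feature.
#' @export
fisher_ratios <- function(responses, classes) {
  apply(responses, 1, fisher_ratio, classes = classes)
}

#' Upper-tail critical value of the F distribution
#'
#' @param df1,df2 Degrees of freedom (>= 1).
#' @param alpha Upper-tail probability in (0, 1).
#' @return Critical value; e.g. `f_critical(4, 8, 0.05)` is 3.84.
#' @export
f_critical <- function(df1, df2, alpha = 0.05) {
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  qf(1 - alpha, df1, df2)
}

#' Sieve a feature table by Fisher ratio
#'
#' Retains the features whose between-class variability is statistically
#' relevant: `F_calc > threshold` (default 3.84, the F(4, 8) critical value
#' at the 5% level used by the method; the neighbouring convention of 4 is
#' a parameter away). QC samples are excluded from the class structure by
#' default. Raising the threshold never enlarges the result.
#'
#' @param ft A `gc2d_feature_table` (or plain matrix with `classes` given).
#' @param threshold F threshold.
#' @param classes Per-sample labels; default from the table metadata.
#' @param exclude_classes Labels excluded from the F computation (default
#'   `"qc"`).
#' @return The input table subset to the sieved features, with the F values
#'   in `$features$f_calc` (matrix input: subset matrix with attribute
#'   `f_calc`).
#' @export
sieve <- function(ft, threshold = 3.84, classes = NULL,
                  exclude_classes = "qc") {
  if (inherits(ft, "gc2d_feature_table")) {
    classes <- classes %||% ft$meta$class_label
    use <- !(classes %in% exclude_classes)
    f <- fisher_ratios(ft$responses[, use, drop = FALSE], classes[use])
    keep <- !is.na(f) & f > threshold
    out <- ft
    out$features <- cbind(ft$features, f_calc = f)[keep, , drop = FALSE]
    out$responses <- ft$responses[keep, , drop = FALSE]
    out$normalized <- ft$normalized[keep, , drop = FALSE]
    out$missing <- ft$missing[keep, , drop = FALSE]
    out
  } else {
    stopifnot(!is.null(classes))
    use <- !(classes %in% exclude_classes)
    f <- fisher_ratios(ft[, use, drop = FALSE], classes[use])
    keep <- !is.na(f) & f > threshold
    out <- ft[keep, , drop = FALSE]
    attr(out, "f_calc") <- f[keep]
    out
  }
}

#' Principal component analysis of a feature table
#'
#' Mean centering and normalization (per-feature unit-variance
#' autoscaling, configurable) before singular decomposition on the samples.
#' Constant features are dropped with a warning. Explained-variance
#' fractions sum to 1 over all components.
#'
#' @param responses Features x samples matrix (or `gc2d_feature_table`).
#' @param center,scale. Passed to the autoscaling step.
#' @return List with `scores` (samples x components), `loadings`,
#'   `explained` (fractions).
#' @export
pca_features <- function(responses, center = TRUE, scale. = TRUE) {
  if (inherits(responses, "gc2d_feature_table"))
    responses <- responses$responses
  x <- t(responses)  # samples x features
  v <- apply(x, 2, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " constant feature(s) dropped before PCA")
    x <- x[, v > 0, drop = FALSE]
  }
  p <- prcomp(x, center = center, scale. = scale.)
  list(scores = p$x, loadings = p$rotation,
       explained = p$sdev^2 / sum(p$sdev^2))
}

#' Pearson correlation matrix with hierarchical clustering and Z-scores
#'
#' Feature-feature Pearson correlations across samples; hierarchical
#' clustering (average linkage on the distance `1 - r`, i.e. Pearson
#' similarity); per-feature Z-scored responses (subtract mean, divide by
#' SD); and the strongly correlated pairs at `r >= r_min` with a two-sided
#' significance test at level `alpha`. Zero-variance features are excluded
#' with a warning. Set `plot = TRUE` to draw the clustered heatmap (uses
#' the pheatmap package if installed).
#'
#' @param responses Features x samples matrix (or `gc2d_feature_table`).
#' @param r_min Correlation threshold for flagged pairs (default 0.900).
#' @param alpha Significance level for the correlation test.
#' @param plot Draw a heatmap of the Z-scored matrix.
#' @return List with `r` (correlation matrix), `p` (two-sided P values),
#'   `z` (Z-scored matrix), `dendrogram` (hclust), `flagged` (data frame of
#'   feature pairs with `r >= r_min` and `p < alpha`).
#' @export
correlation_clustered_heatmap <- function(responses, r_min = 0.900,
                                          alpha = 0.05, plot = FALSE) {
  if (inherits(responses, "gc2d_feature_table"))
    responses <- responses$responses
  if (ncol(responses) < 3L) stop("need at least three samples")
  v <- apply(responses, 1, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance feature(s) excluded")
    responses <- responses[v > 0, , drop = FALSE]
  }
  n <- ncol(responses)
  r <- cor(t(responses))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- NA
  z <- t(scale(t(responses)))
  hc <- hclust(as.dist(1 - r), method = "average")
  ut <- upper.tri(r)
  sel <- which(ut & r >= r_min & p < alpha, arr.ind = TRUE)
  flagged <- data.frame(feature_a = rownames(r)[sel[, 1]],
                        feature_b = rownames(r)[sel[, 2]],
                        r = r[sel], p = p[sel])
  flagged <- flagged[order(-flagged$r), , drop = FALSE]
  rownames(flagged) <- NULL
  if (plot) {
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      pheatmap::pheatmap(z, clustering_distance_rows = as.dist(1 - r),
                         clustering_distance_cols = "euclidean",
                         clustering_method = "average")
    } else {
      stats::heatmap(z, Rowv = stats::as.dendrogram(hc), scale = "none")
    }
  }
  list(r = r, p = p, z = z, dendrogram = hc, flagged = flagged)
}

#' Per-feature response ratio between two classes
#'
#' Mean response of `class_a` over mean response of `class_b` (the ratio of
#' absolute 2D peak volumes used to rank up-regulated analytes). `Inf` when
#' only the denominator is zero; `NaN` when both are.
#'
#' @param ft A `gc2d_feature_table` (or features x samples matrix with
#'   `classes`).
#' @param class_a,class_b Class labels.
#' @param classes Per-sample labels (matrix input).
#' @return Named numeric vector of fold-changes.
#' @export
response_ratio <- function(ft, class_a, class_b, classes = NULL) {
  if (inherits(ft, "gc2d_feature_table")) {
    classes <- classes %||% ft$meta$class_label
    responses <- ft$responses
  } else responses <- ft
  stopifnot(!is.null(classes))
  if (!class_a %in% classes) stop("unknown class: ", class_a)
  if (!class_b %in% classes) stop("unknown class: ", class_b)
  a <- rowMeans(responses[, classes == class_a, drop = FALSE])
  b <- rowMeans(responses[, classes == class_b, drop = FALSE])
  ifelse(b == 0 & a == 0, NaN, a / b)
}

#' Two-way analysis of variance with Bonferroni post hoc
#'
#' Completely randomized two-factor model
#' `Y_ijk = mu + alpha_i + beta_j + (alpha beta)_ij + e_ijk` with dry-matter
#' level and inoculum as fixed effects. On balanced data the sums of
#' squares decompose exactly (`SS_D + SS_L + SS_DxL + SS_error = SS_total`).
#' Pairwise inoculum comparisons use pooled-variance t statistics on the
#' residual mean square with Bonferroni-adjusted P values, summarised as
#' compact letter groups (means sharing a letter do not differ at the
#' adjusted 5% level).
#'
#' @param y Response values.
#' @param dm_level Factor: dry-matter level (e.g. LOW / HIGH).
#' @param inoculum Factor: inoculum (e.g. CON / Lbuc / Lpar).
#' @param alpha Significance level for the letter groups.
#' @return Object of class `gc2d_anova`: list with `table` (SS, df, F, P
#'   per term), `means` (inoculum marginal means), `letters`, `posthoc`
#'   (pairwise comparisons).
#' @export
two_way_anova <- function(y, dm_level, inoculum, alpha = 0.05) {
  dm_level <- as.factor(dm_level)
  inoculum <- as.factor(inoculum)
  if (any(table(dm_level, inoculum) == 0L))
    stop("empty dm x inoculum cell")
  fit <- aov(y ~ dm_level * inoculum)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  mse <- tab["Residuals", "Mean Sq"]
  dfe <- tab["Residuals", "Df"]

  means <- tapply(y, inoculum, mean)
  counts <- tapply(y, inoculum, length)
  lv <- levels(inoculum)
  pairs <- utils::combn(lv, 2)
  n_comp <- ncol(pairs)
  ph <- data.frame(a = pairs[1, ], b = pairs[2, ], t = NA_real_,
                   p_adj = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(n_comp)) {
    se <- sqrt(mse * (1 / counts[ph$a[k]] + 1 / counts[ph$b[k]]))
    if (se == 0) { ph$t[k] <- NA; ph$p_adj[k] <- 1; next }
    tval <- (means[ph$a[k]] - means[ph$b[k]]) / se
    ph$t[k] <- tval
    ph$p_adj[k] <- min(1, 2 * pt(-abs(tval), dfe) * n_comp)
  }
  letters <- letter_groups(means, ph, alpha)
  structure(list(table = tab, means = means, letters = letters,
                 posthoc = ph, mse = mse, df_error = dfe),
            class = "gc2d_anova")
}

# Compact letter display from pairwise adjusted P values: insert-and-absorb
# over means sorted in descending order.
letter_groups <- function(means, posthoc, alpha) {
  lv <- names(sort(means, decreasing = TRUE))
  differs <- function(a, b) {
    row <- posthoc[(posthoc$a == a & posthoc$b == b) |
                     (posthoc$a == b & posthoc$b == a), ]
    nrow(row) > 0 && !is.na(row$p_adj[1]) && row$p_adj[1] < alpha
  }
  groups <- list()
  for (g in lv) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (!any(vapply(groups[[gi]], differs, logical(1), b = g))) {
        groups[[gi]] <- c(groups[[gi]], g)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- g
  }
  out <- vapply(names(means), function(m) {
    paste0(letters[which(vapply(groups, function(g) m %in% g, logical(1)))],
           collapse = "")
  }, character(1))
  out
}

#' @export
print.gc2d_anova <- function(x, ...) {
  print(x$table)
  cat("\nInoculum means (Bonferroni letters):\n")
  print(data.frame(mean = round(x$means, 4), group = x$letters))
  invisible(x)
}

#' Unpaired two-sided t test (pooled variance)
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @return List with `statistic`, `p_value`, `df`. `NA` statistic with
#'   P = 1 flagged when the pooled variance is zero.
#' @export
t_test_unpaired <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) {
    return(list(statistic = NA_real_,
                p_value = if (mean(a) == mean(b)) 1 else 0,
                df = length(a) + length(b) - 2, undefined = TRUE))
  }
  ht <- t.test(a, b, var.equal = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}
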