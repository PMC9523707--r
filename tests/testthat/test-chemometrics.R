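test_that("%RSD matches the direct formula and is scale invariant", {
  expect_identical(rsd(c(10, 10, 10)), 0)
  expect_equal(rsd(c(9, 11)), 14.14, tolerance = 1e-3)
  set.seed(61)
  x <- runif(20, 5, 50)
  expect_equal(rsd(x), rsd(x * 137.5))
  expect_warning(out <- rsd(c(-1, 1)), "zero mean")
  expect_true(is.na(out))
  expect_error(rsd(5), "at least two")
})

test_that("Fisher ratio reproduces one-way ANOVA arithmetic", {
  expect_equal(fisher_ratio(c(1, 2, 3, 4, 5, 6),
                            rep(c("a", "b"), each = 3)), 13.5)
  # equal means, symmetric deviations: F = 0
  expect_equal(fisher_ratio(c(1, 3, 1, 3), c("a", "a", "b", "b")), 0)
  # affine invariance
  set.seed(62)
  y <- rnorm(18); cl <- rep(c("a", "b", "c"), each = 6)
  expect_equal(fisher_ratio(y, cl), fisher_ratio(3.7 * y - 11, cl))
  # cross-check against the standard ANOVA fit
  f_aov <- summary(aov(y ~ cl))[[1]]["cl", "F value"]
  expect_equal(fisher_ratio(y, cl), f_aov)
  # degenerate cases
  expect_true(is.infinite(fisher_ratio(c(1, 1, 2, 2),
                                       c("a", "a", "b", "b"))))
  expect_true(is.na(fisher_ratio(c(2, 2, 2, 2), c("a", "a", "b", "b"))))
})

test_that("F critical values: printed value, z^2 limit, quadrature oracle", {
  expect_equal(round(f_critical(4, 8, 0.05), 2), 3.84)
  expect_equal(f_critical(1, 1e7, 0.05), qnorm(0.975)^2, tolerance = 1e-3)
  # independent quadrature of the F density up to the reported quantile
  for (al in c(0.5, 0.05)) {
    q <- f_critical(4, 8, al)
    mass <- integrate(function(x) df(x, 4, 8), 0, q)$value
    expect_equal(mass, 1 - al, tolerance = 1e-6)
  }
  expect_error(f_critical(0, 8), "degrees of freedom")
  expect_error(f_critical(4, 8, 1.5), "alpha")
})

test_that("sieve keeps discriminant features and is monotone in threshold", {
  eff <- matrix(1, 5, 100, dimnames = list(
    c("herbage_low", "herbage_high", "con", "lbuc", "lpar"), NULL))
  eff["lpar", 1:10] <- 8   # 10 planted discriminant features
  rt <- simulate_response_table(n_features = 100, effect = eff, seed = 63)
  s0 <- sieve(rt$responses, threshold = 0, classes = rt$classes)
  expect_identical(nrow(s0), 100L)
  s <- sieve(rt$responses, threshold = 3.84, classes = rt$classes)
  kept <- as.integer(sub("feature_", "", rownames(s)))
  expect_gte(sum(kept <= 10), 9)
  expect_lte(sum(kept > 10), 10)
  s_inf <- sieve(rt$responses, threshold = Inf, classes = rt$classes)
  expect_identical(nrow(s_inf), 0L)
  # monotone: larger threshold -> subset
  s2 <- sieve(rt$responses, threshold = 10, classes = rt$classes)
  expect_true(all(rownames(s2) %in% rownames(s)))
})

test_that("PCA autoscaling, variance fractions and class separation", {
  eff <- matrix(1, 5, 50, dimnames = list(
    c("herbage_low", "herbage_high", "con", "lbuc", "lpar"), NULL))
  eff["lpar", 1:20] <- 6
  rt <- simulate_response_table(n_features = 50,
                                classes = c(con = 10, lpar = 10),
                                effect = eff, seed = 64)
  pc <- pca_features(rt$responses)
  expect_equal(sum(pc$explained), 1)
  expect_true(all(abs(colMeans(scale(t(rt$responses)))) < 1e-9))
  skip_if_not_installed("cluster")
  sil <- cluster::silhouette(as.integer(factor(rt$classes)),
                             dist(pc$scores[, 1:2]))
  expect_gt(mean(sil[, 3]), 0.5)
})

test_that("constant features are dropped from PCA with a warning", {
  m <- rbind(matrix(rnorm(40), 4, 10), rep(7, 10))
  expect_warning(pc <- pca_features(m), "constant feature")
  expect_identical(ncol(pc$loadings), 4L)
})

test_that("correlation matrix, significance flags and clustering", {
  set.seed(65)
  x <- rnorm(35, 100, 10)
  m <- rbind(x, 2 * x, -x + 300, matrix(rnorm(35 * 3, 50, 5), 3))
  rownames(m) <- paste0("f", 1:6)
  co <- correlation_clustered_heatmap(m)
  expect_equal(co$r["f1", "f2"], 1)
  expect_equal(co$r["f1", "f3"], -1)
  expect_true(any(co$flagged$feature_a == "f1" & co$flagged$feature_b == "f2"))
  # Z-scored rows have mean 0, SD 1
  expect_true(all(abs(rowMeans(co$z)) < 1e-12))
  expect_true(all(abs(apply(co$z, 1, sd) - 1) < 1e-12))
  expect_s3_class(co$dendrogram, "hclust")
  expect_error(correlation_clustered_heatmap(m[, 1:2]), "three samples")
  mm <- m; mm[4, ] <- 5
  expect_warning(correlation_clustered_heatmap(mm), "zero-variance")
})

test_that("a planted shared-factor acid/ester pair correlates above 0.9", {
  # latent run-level factor shared by two features, mirroring the common
  # biosynthetic origin of an alcohol and its acid
  set.seed(66)
  n <- 35
  eta <- rnorm(n, 0, 0.15)
  base <- c(2e6, 5e6)
  resp <- rbind(base[1] * exp(eta + rnorm(n, 0, 0.05)),
                base[2] * exp(eta + rnorm(n, 0, 0.05)))
  rownames(resp) <- c("alcohol", "acid")
  co <- correlation_clustered_heatmap(resp)
  expect_gte(co$r["alcohol", "acid"], 0.9)
})

test_that("response ratios: identity, planted effect, degenerate flags", {
  m <- matrix(c(10, 10, 20, 20), 1)
  expect_equal(unname(response_ratio(m, "a", "b",
                                     classes = c("a", "a", "b", "b"))), 0.5)
  expect_equal(unname(response_ratio(m, "a", "a",
                                     classes = c("a", "a", "b", "b"))), 1)
  m2 <- rbind(c(5, 5, 0, 0), c(0, 0, 0, 0))
  rr <- response_ratio(m2, "a", "b", classes = c("a", "a", "b", "b"))
  expect_true(is.infinite(rr[1]))
  expect_true(is.nan(rr[2]))
  expect_error(response_ratio(m, "a", "nope", classes = c("a", "a", "b", "b")),
               "unknown class")
})

test_that("a planted 46-fold effect is recovered at n = 6 within the
          log-normal tolerance band", {
  eff <- matrix(1, 5, 1, dimnames = list(
    c("herbage_low", "herbage_high", "con", "lbuc", "lpar"), NULL))
  eff["lpar", 1] <- 46
  est <- vapply(1:40, function(s) {
    rt <- simulate_response_table(n_features = 1,
                                  classes = c(herbage_low = 6, lpar = 6),
                                  effect = eff, seed = 700 + s)
    unname(response_ratio(rt$responses, "lpar", "herbage_low",
                          classes = rt$classes))
  }, numeric(1))
  expect_gt(mean(est >= 39 & est <= 53), 0.9)
  expect_equal(median(est), 46, tolerance = 0.08)
})

test_that("two-way ANOVA: exact decomposition, additivity, letters", {
  # balanced 2x3 with 2 replicates per cell and known values
  dm <- rep(rep(c("LOW", "HIGH"), each = 6), 1)
  inoc <- rep(rep(c("CON", "Lbuc", "Lpar"), each = 2), 2)
  y <- c(10, 12, 11, 13, 30, 32,   # LOW
         20, 22, 21, 23, 40, 42)   # HIGH
  res <- two_way_anova(y, dm, inoc)
  tab <- res$table
  ss <- tab[, "Sum Sq"]
  expect_equal(sum(ss), sum((y - mean(y))^2))
  # hand decomposition: dm adds +10 to every cell -> SS_D = 12 * 5^2
  expect_equal(unname(ss[1]), 300)
  # inoculum means 16, 17, 36 about grand 23 -> 4 * (49 + 36 + 169)
  expect_equal(unname(ss[2]), 1016)
  # additive construction: interaction SS = 0
  expect_equal(unname(ss[3]), 0, tolerance = 1e-9)
  # Lpar clearly separated from CON and Lbuc at adjusted 5%
  expect_identical(res$letters[["Lpar"]], "a")
  expect_identical(res$letters[["CON"]], res$letters[["Lbuc"]])
  expect_false(res$letters[["CON"]] == res$letters[["Lpar"]])
  expect_error(two_way_anova(y[1:10], dm[1:10], inoc[1:10]), "empty")
})

test_that("all-equal responses give a single letter group", {
  dm <- rep(c("L", "H"), each = 6)
  inoc <- rep(rep(c("a", "b", "c"), 2), 2)
  res <- two_way_anova(rep(5, 12), dm, inoc)
  expect_identical(unname(res$letters), rep("a", 3))
})

test_that("unpaired t test matches the pooled-variance formula", {
  out <- t_test_unpaired(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$statistic, -3.674, tolerance = 1e-3)
  expect_identical(out$df, 4)
  # identical groups: P = 1
  expect_equal(t_test_unpaired(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # swapping groups flips the sign
  expect_equal(t_test_unpaired(c(4, 5, 6), c(1, 2, 3))$statistic, 3.674,
               tolerance = 1e-3)
  # zero pooled variance flag
  z <- t_test_unpaired(c(2, 2), c(2, 2))
  expect_true(z$undefined && is.na(z$statistic))
  expect_error(t_test_unpaired(1, c(1, 2)), ">= 2 values")
})
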