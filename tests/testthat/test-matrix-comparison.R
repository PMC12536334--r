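test_that("occurrence sets respect censor flags and the detected/quantified nesting", {
  m <- make_measurements(
    compound_id = c("a", "b", "c", "c"),
    matrix = c("water", "water", "psd_hlb", "biota"),
    value = c(5, NA, 0.3, NA),
    censor = c("quantified", "detected_below_loq", "quantified",
               "not_detected")
  )
  os <- occurrence_sets(m)
  expect_equal(os$water$detected, c("a", "b"))
  expect_equal(os$water$quantified, "a")
  expect_equal(os$psd_any$detected, "c")
  expect_equal(os$biota$detected, character(0)) # not_detected contributes nothing
  for (nm in names(os)) {
    expect_true(all(os[[nm]]$quantified %in% os[[nm]]$detected))
  }
  empty <- occurrence_sets(m[0, ])
  expect_true(all(vapply(empty, function(s) length(s$detected) == 0,
                         logical(1))))
})

test_that("venn counts agree with brute-force region enumeration", {
  count_oracle <- function(sets) {
    elems <- unique(unlist(sets))
    pat <- vapply(elems, function(e) {
      paste0(as.integer(vapply(sets, function(s) e %in% s, logical(1))),
             collapse = "")
    }, character(1))
    table(factor(pat, levels = c("100", "010", "001", "110", "101", "011",
                                 "111")))
  }
  set.seed(7)
  for (i in 1:20) {
    sets <- list(A = sample(letters, sample(0:15, 1)),
                 B = sample(letters, sample(0:15, 1)),
                 C = sample(letters, sample(0:15, 1)))
    got <- venn_counts(sets)
    expect_equal(unname(got$count), as.numeric(count_oracle(sets)))
    expect_equal(sum(got$count), length(unique(unlist(sets))))
  }
  got <- venn_counts(list(A = c("1", "2"), B = c("2", "3"), C = "2"))
  expect_equal(got$count[got$region == "A:B:C"], 1)
  expect_equal(got$count[got$region == "A_only"], 1)
  expect_equal(got$count[got$region == "C_only"], 0)
  expect_equal(sum(got$count), 3)
  # identical sets: only the triple region
  same <- venn_counts(list(A = "x", B = "x", C = "x"))
  expect_equal(sum(same$count), 1)
  expect_equal(same$count[same$region == "A:B:C"], 1)
  # disjoint sets: only the "only" regions
  dis <- venn_counts(list(A = "a", B = "b", C = "c"))
  expect_equal(sum(dis$count[grepl("_only", dis$region)]), 3)
})

test_that("per-replicate min-max scaling spans [0,1] and is idempotent", {
  expect_equal(.scale_row(c(2, 4, 6)), c(0, 0.5, 1))
  mat <- rbind(c(2, 4, 6), c(5, 5, 5), c(1, NA, 3))
  sc <- minmax_scale(mat)
  expect_equal(sc[1, ], c(0, 0.5, 1))
  expect_equal(sc[2, ], c(0, 0, 0)) # constant row
  expect_equal(sc[3, ], c(1 / 3, 0, 1)) # NA zero-filled before scaling
  set.seed(3)
  rand <- matrix(stats::rnorm(60), nrow = 6)
  scr <- minmax_scale(rand)
  expect_true(all(apply(scr, 1, min) == 0))
  expect_true(all(apply(scr, 1, max) == 1))
  expect_equal(minmax_scale(scr), scr) # idempotent
  expect_error(minmax_scale(matrix(numeric(0), 0, 0)), "empty")
})

test_that("profile matrix pivots measurements wide and scales per replicate", {
  m <- make_measurements(
    compound_id = c("a", "b", "a", "b"),
    matrix = c("water", "water", "biota", "biota"),
    value = c(10, 30, 2, NA),
    censor = c("quantified", "quantified", "quantified", "not_detected")
  )
  prof <- profile_matrix(m)
  expect_equal(nrow(prof), 2)
  expect_true(all(c("matrix", "month", "replicate", "a", "b") %in% names(prof)))
  sc <- minmax_scale(prof)
  water_row <- sc[sc$matrix == "water", c("a", "b")]
  expect_equal(unlist(water_row, use.names = FALSE), c(0, 1))
})

test_that("profile PCA matches an eigendecomposition oracle on a 5x4 fixture", {
  set.seed(42)
  X <- matrix(stats::runif(20), nrow = 5, ncol = 4,
              dimnames = list(NULL, paste0("cmp", 1:4)))
  pca <- pca_profiles(X, n_components = 4)

  # oracle: eigendecomposition of the covariance of the centred data
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(Xc))
  expect_equal(pca$explained_var_pct,
               100 * eig$values / sum(eig$values), tolerance = 1e-8)
  scores <- as.matrix(pca$scores[, paste0("PC", 1:4)])
  oracle_scores <- Xc %*% eig$vectors
  for (j in 1:4) {
    expect_equal(abs(scores[, j]), abs(oracle_scores[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }

  # deterministic sign: the largest-magnitude loading of each PC is positive
  for (j in 1:4) {
    v <- pca$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }

  # variance accounting and diagonal score covariance
  expect_equal(sum(pca$explained_var_pct), 100)
  expect_false(is.unsorted(rev(pca$explained_var_pct)))
  cv <- stats::cov(scores)
  expect_equal(cv[lower.tri(cv)], rep(0, 6), tolerance = 1e-10)
})

test_that("perfectly correlated columns load on a single component", {
  x <- stats::rnorm(10)
  X <- cbind(a = x, b = 2 * x)
  pca <- pca_profiles(X)
  expect_equal(pca$explained_var_pct[1], 100)
  expect_equal(pca$explained_var_pct[2], 0, tolerance = 1e-10)
  expect_error(pca_profiles(X[1, , drop = FALSE]), "at least 2")
})

test_that("top loadings pick the strongest compounds", {
  set.seed(9)
  X <- matrix(stats::rnorm(40, sd = 0.05), nrow = 10, ncol = 4,
              dimnames = list(NULL, c("weak1", "strong", "weak2", "weak3")))
  X[, "strong"] <- X[, "strong"] + c(rep(0, 5), rep(5, 5))
  pca <- pca_profiles(X, top_k = 2)
  expect_equal(pca$top_loadings[1], "strong")
})

test_that("hierarchical clustering separates groups and is permutation-invariant", {
  set.seed(5)
  g1 <- matrix(stats::rnorm(12, mean = 0, sd = 0.05), nrow = 3)
  g2 <- matrix(stats::rnorm(12, mean = 10, sd = 0.05), nrow = 3)
  X <- rbind(g1, g2)
  hca <- hca_profiles(X, k = 2)
  expect_equal(length(unique(hca$labels[1:3])), 1)
  expect_equal(length(unique(hca$labels[4:6])), 1)
  expect_false(hca$labels[1] == hca$labels[4])
  expect_true(same_cluster(hca, 1, 2))
  expect_false(same_cluster(hca, 1, 5))

  # merge heights non-decreasing (ultrametric tree)
  expect_false(is.unsorted(hca$tree$height))

  # permutation invariance via cophenetic distances
  perm <- sample(nrow(X))
  hca_p <- hca_profiles(X[perm, ], k = 2)
  d0 <- as.matrix(stats::cophenetic(hca$tree))
  dp <- as.matrix(stats::cophenetic(hca_p$tree))
  expect_equal(dp, d0[perm, perm], ignore_attr = TRUE, tolerance = 1e-10)

  # two-row input: trivial single merge
  tiny <- hca_profiles(X[c(1, 4), ], k = 2)
  expect_equal(length(tiny$tree$height), 1)
  expect_error(hca_profiles(X[1, , drop = FALSE]), "at least 2")
})

test_that("paired linear correlation matches lm and the Pearson identity", {
  x <- 1:10
  expect_equal(linear_matrix_correlation(x, 2 * x)$slope, 2)
  expect_equal(linear_matrix_correlation(x, 2 * x)$r_squared, 1)

  set.seed(31)
  xr <- stats::rnorm(50)
  yr <- stats::rnorm(50) # independent: no relationship
  fit <- linear_matrix_correlation(xr, yr)
  expect_lt(fit$r_squared, 0.2)
  expect_gt(fit$p_value, 0.05)
  expect_equal(fit$r_squared, stats::cor(xr, yr)^2, tolerance = 1e-12)
  expect_error(linear_matrix_correlation(1:2, 1:2), "3 pairs")
})

test_that("pairing two matrices joins compound-month means", {
  m <- make_measurements(
    compound_id = c("a", "a", "a", "b"),
    matrix = c("biota", "biota", "psd_hlb", "biota"),
    value = c(4, 6, 0.3, 2),
    replicate = c(1L, 2L, 1L, 1L)
  )
  pairs <- pair_matrix_values(m, "biota", "psd_hlb")
  expect_equal(nrow(pairs), 1) # only compound a present in both
  expect_equal(pairs$x, 5) # replicate mean
  expect_equal(pairs$y, 0.3)
})
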