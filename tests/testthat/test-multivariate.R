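test_that("row z-scoring matches the direct formula and flags constant rows", {
  expect_equal(unname(zscore_rows(rbind(a = 1:3))[1, ]), c(-1, 0, 1))
  z <- zscore_rows(rbind(a = c(5, 5, 5), b = c(1, 2, 4)))
  expect_equal(unname(z["a", ]), c(0, 0, 0))
  expect_identical(attr(z, "constant_rows"), "a")

  set.seed(4)
  m <- matrix(rnorm(30), 10, 3)
  rownames(m) <- paste0("r", 1:10)
  z2 <- zscore_rows(m)
  expect_equal(unname(rowMeans(z2)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(z2, 1, sd)), rep(1, 10), tolerance = 1e-12)
  expect_equal(z2, (m - rowMeans(m)) / apply(m, 1, sd),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("PCA satisfies the closed form for a two-variable correlation design", {
  rho <- 0.6
  u <- c(1, -1, 1, -1) / 2
  v <- c(1, 1, -1, -1) / 2
  x <- cbind(a = u, b = rho * u + sqrt(1 - rho^2) * v)
  p <- run_pca(x, preprocessing = "zscore")
  expect_equal(unname(p$explained_variance_ratio),
               c((1 + rho) / 2, (1 - rho) / 2), tolerance = 1e-12)
})

test_that("PCA loadings are orthonormal, variance is conserved, input reconstructs", {
  set.seed(20)
  x <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, paste0("v", 1:4)))
  p <- run_pca(x, preprocessing = "center")
  expect_equal(crossprod(p$loadings), diag(4), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
  expect_equal(sum(p$explained_variance_ratio), 1, tolerance = 1e-12)
  expect_equal(sum(p$eigenvalues), sum(diag(cov(x))), tolerance = 1e-9)
  # full reconstruction of the centered data
  xc <- scale(x, center = TRUE, scale = FALSE)
  expect_equal(p$scores %*% t(p$loadings), xc, ignore_attr = TRUE,
               tolerance = 1e-9)
  # sign convention: largest-magnitude element of each column positive
  for (j in 1:4) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
})

test_that("collinear data loads entirely on the first component", {
  x <- cbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4))
  p <- run_pca(x, preprocessing = "center")
  expect_equal(unname(p$explained_variance_ratio[1]), 1, tolerance = 1e-12)
})

test_that("joint PCA concatenates blocks, z-scores them, and tracks labels", {
  set.seed(30)
  s <- matrix(runif(9, 2, 8), 3, 3,
              dimnames = list(c("A", "B", "C"), paste0("attr", 1:3)))
  cmpd <- matrix(runif(6, 0.1, 20), 3, 2,
                 dimnames = list(c("B", "C", "A"), paste0("cmp", 1:2)))
  jp <- joint_pca(s, cmpd)
  expect_identical(unname(jp$blocks),
                   c(rep("attribute", 3), rep("compound", 2)))
  # a compound duplicated as a fake attribute has identical loadings
  s2 <- cbind(s, fake = cmpd[rownames(s), "cmp1"])
  jp2 <- joint_pca(s2, cmpd)
  cl <- colocalize(jp2, pairs = data.frame(compound = "cmp1",
                                           attribute = "fake"))
  expect_equal(cl$theta, 0, tolerance = 1e-6)
  expect_equal(cl$r, 1, tolerance = 1e-12)

  rownames(cmpd) <- c("B", "C", "D")
  expect_error(joint_pca(s, cmpd), "sample sets")
})

test_that("co-localization angles match a direct arccos oracle", {
  set.seed(40)
  x <- matrix(rnorm(40), 5, 8,
              dimnames = list(paste0("s", 1:5),
                              c(paste0("attr", 1:4), paste0("cmp", 1:4))))
  jp <- joint_pca(x[, 1:4], x[, 5:8])
  cl <- colocalize(jp)
  expect_identical(nrow(cl), 16L)
  L <- jp$loadings[, 1:2]
  for (i in seq_len(nrow(cl))) {
    v1 <- L[cl$compound[i], ]; v2 <- L[cl$attribute[i], ]
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    expect_equal(cl$theta[i], ang, tolerance = 1e-9)
    expect_equal(cl$r[i], cor(x[, cl$compound[i]], x[, cl$attribute[i]]),
                 tolerance = 1e-12)
  }
  # orthogonal / identical loading vectors
  jp$loadings[c("cmp1", "attr1"), 1:2] <- rbind(c(1, 0), c(0, 1))
  cl2 <- colocalize(jp, pairs = data.frame(compound = "cmp1",
                                           attribute = "attr1"))
  expect_equal(cl2$theta, 90, tolerance = 1e-12)
})

test_that("theta and r are invariant under sample reordering", {
  set.seed(50)
  x <- matrix(rnorm(30), 5, 6,
              dimnames = list(paste0("s", 1:5),
                              c(paste0("attr", 1:3), paste0("cmp", 1:3))))
  jp1 <- joint_pca(x[, 1:3], x[, 4:6])
  perm <- c(3, 1, 5, 2, 4)
  jp2 <- joint_pca(x[perm, 1:3], x[perm, 4:6])
  cl1 <- colocalize(jp1)
  cl2 <- colocalize(jp2)
  expect_equal(cl1$theta, cl2$theta, tolerance = 1e-9)
  expect_equal(cl1$r, cl2$r, tolerance = 1e-12)
})

test_that("with 3 samples, exactly correlated variables are collinear in loading space", {
  set.seed(60)
  base <- c(A = 1, B = 7, C = 3)
  s <- cbind(attr1 = base, attr2 = c(5, 2, 8))
  cmpd <- cbind(cmp1 = 2.5 * base + 1, cmp2 = c(4, 4.5, 1))
  jp <- joint_pca(s, cmpd)
  cl <- colocalize(jp, pairs = data.frame(compound = "cmp1",
                                          attribute = "attr1"))
  expect_true(cl$theta < 1e-6 || abs(cl$theta - 180) < 1e-6)
  expect_equal(abs(cl$r), 1, tolerance = 1e-12)
  expect_true(cl$small_n)
})

test_that("hierarchical clustering matches an exhaustive agglomeration oracle", {
  set.seed(70)
  for (linkage in c("average", "single", "complete")) {
    x <- matrix(rnorm(16), 8, 2)
    rownames(x) <- paste0("i", 1:8)
    hc <- hcluster(x, linkage = linkage)
    oracle <- oracle_agglomerate(x, linkage = linkage)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-9)
    for (step in seq_along(oracle$partitions)) {
      k <- 8 - step
      if (k < 1) break
      got <- partition_signature(cutree(hc$hclust, k = k))
      want <- partition_signature(oracle$partitions[[step]])
      expect_identical(got, want)
    }
  }
})

test_that("clustering degenerate geometries behaves as forced", {
  # pairwise distances 1, 1, 10-ish: the close pair merges first
  x <- rbind(p1 = c(0, 0), p2 = c(1, 0), p3 = c(10, 0))
  hc <- hcluster(x)
  expect_identical(sort(hc$merge[1, ]), c(-2L, -1L))
  # duplicate rows merge at height zero
  y <- rbind(a = c(1, 1), b = c(1, 1), c = c(5, 5))
  expect_equal(hcluster(y)$height[1], 0)
  # merge heights never decrease
  set.seed(71)
  z <- matrix(rnorm(20), 10, 2)
  expect_true(all(diff(hcluster(z)$height) >= -1e-12))
})

test_that("cluster heatmap standardizes rows and returns permutations", {
  sim <- simulate_dataset(sim_config(seed = 13))
  rt <- roav_table(sim$voc, sim$thresholds)
  key <- rownames(rt$tier)[rowSums(rt$tier == "key") > 0]
  hm <- cluster_heatmap(sim$voc$mean[key, ])
  expect_setequal(hm$row_order, seq_len(nrow(hm$zmatrix)))
  expect_setequal(hm$col_order, seq_len(ncol(hm$zmatrix)))
  ok <- setdiff(rownames(hm$zmatrix), hm$constant_rows)
  expect_equal(unname(rowMeans(hm$zmatrix[ok, ])), rep(0, length(ok)),
               tolerance = 1e-9)
})

test_that("planted proportional pairs are recovered monotonically as noise shrinks", {
  set.seed(80)
  attrs <- c(A = 2.9, B = 8.2, C = 3.0)
  other <- cbind(attr2 = c(A = 7, B = 3, C = 4))
  thetas <- numeric(0)
  rs <- numeric(0)
  for (sigma in c(1.0, 0.3, 0.02)) {
    comp <- cbind(cmp1 = 0.5 * attrs + rnorm(3, 0, sigma))
    jp <- joint_pca(cbind(attr1 = attrs, other), comp)
    cl <- colocalize(jp, pairs = data.frame(compound = "cmp1",
                                            attribute = "attr1"))
    thetas <- c(thetas, cl$theta)
    rs <- c(rs, cl$r)
  }
  expect_true(all(diff(thetas) < 0))
  expect_true(all(diff(rs) > 0))
  expect_lt(thetas[3], 10)
  expect_gt(rs[3], 0.9)
})
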