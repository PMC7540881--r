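test_that("PCA of the standardised environment matches a direct eigen-solve", {
  set.seed(30)
  nr <- 20; nc <- 20
  a <- matrix(rnorm(nr * nc), nr, nc)
  b <- 0.6 * a + matrix(rnorm(nr * nc, sd = 0.8), nr, nc)
  c_ <- matrix(rnorm(nr * nc), nr, nc)
  stack <- eln_stack(list(a = a, b = b, c = c_))
  pca <- fit_env_pca(stack)

  X <- cbind(as.vector(a), as.vector(b), as.vector(c_))
  ref <- eigen(cor(X), symmetric = TRUE)$values
  expect_equal(unname(pca$eigenvalues), ref, tolerance = 1e-10)
  expect_equal(sum(pca$explained), 1)

  # loadings orthonormal
  gram <- t(pca$loadings) %*% pca$loadings
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)
  # sign convention: dominant loading of each component is positive
  for (j in seq_len(ncol(pca$loadings)))
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
})

test_that("perfectly correlated variables load on one component", {
  v <- matrix(rnorm(400), 20, 20)
  pca <- fit_env_pca(eln_stack(list(a = v, b = 3 * v + 2)))
  expect_equal(pca$explained[1], 1, tolerance = 1e-12)
})

test_that("independent equal-variance variables split evenly", {
  set.seed(33)
  pca <- fit_env_pca(eln_stack(list(a = matrix(rnorm(1e4), 100, 100),
                                    b = matrix(rnorm(1e4), 100, 100))))
  expect_equal(pca$explained[1], 0.5, tolerance = 0.05)
})

test_that("niche clouds hold exactly the cells above the threshold", {
  set.seed(34)
  stack <- make_test_stack(10, 10, vars = c("a", "b"), seed = 34)
  pca <- fit_env_pca(stack)
  vals <- matrix(runif(100), 10, 10)
  map <- as_suit_map(vals)

  cloud_all <- project_eln(pca, map, stack, threshold = 0)
  expect_equal(nrow(cloud_all$scores), sum(vals > 0))

  n_hi <- sum(vals > 0.9)
  cloud_hi <- project_eln(pca, map, stack, threshold = 0.9)
  expect_equal(nrow(cloud_hi$scores), n_hi)
  expect_false(cloud_hi$empty)

  none <- project_eln(pca, as_suit_map(matrix(0.5, 10, 10)), stack,
                      threshold = 0.9)
  expect_true(none$empty)
})

test_that("inertia ellipses cover the requested fraction of Gaussian clouds", {
  set.seed(35)
  pts <- cbind(rnorm(1e5), rnorm(1e5))
  ell <- inertia_ellipse(pts, coverage = 0.61)
  expect_equal(mean(ellipse_contains(ell, pts)), 0.61, tolerance = 0.01)

  # isotropic cloud: axes equal within sampling error
  ev <- eigen(ell$covariance, only.values = TRUE)$values
  expect_equal(ev[1] / ev[2], 1, tolerance = 0.05)

  # coverage 0 degenerates to the mean point
  ell0 <- inertia_ellipse(pts[1:100, ], coverage = 0)
  expect_equal(ell0$radius2, 0)
  expect_equal(sum(ellipse_contains(ell0, pts[1:100, ])), 0)
})

test_that("overlap scores match hand values and literal-formula oracles", {
  p1 <- matrix(c(0.5, 0.5, 0), 1)
  p2 <- matrix(c(0, 0.5, 0.5), 1)
  expect_equal(schoener_d(p1, p2), 0.5)
  expect_equal(hellinger_i(p1, p2), 0.5)

  m <- matrix(runif(25), 5, 5)
  expect_equal(schoener_d(m, m), 1)
  expect_equal(hellinger_i(m, m), 1)

  a <- matrix(c(1, 1, 0, 0), 2, 2)
  b <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(schoener_d(a, b), 0)
  expect_equal(hellinger_i(a, b), 0)

  set.seed(36)
  for (rep in 1:25) {
    v1 <- matrix(runif(64), 8, 8); v2 <- matrix(runif(64), 8, 8)
    expect_equal(schoener_d(v1, v2), schoener_oracle(v1, v2),
                 tolerance = 1e-12)
    expect_equal(hellinger_i(v1, v2), hellinger_oracle(v1, v2),
                 tolerance = 1e-12)
    # invariance to positive rescaling of either map
    expect_equal(schoener_d(3.7 * v1, v2), schoener_d(v1, v2),
                 tolerance = 1e-12)
    expect_equal(hellinger_i(v1, 0.2 * v2), hellinger_i(v1, v2),
                 tolerance = 1e-12)
  }
  expect_error(schoener_d(matrix(0, 2, 2), matrix(1, 2, 2)), "all-zero")
})

test_that("overlap matrices are symmetric with unit diagonal", {
  set.seed(37)
  elns <- lapply(1:3, function(i) as_suit_map(matrix(runif(36), 6, 6), paste0("g", i)))
  names(elns) <- paste0("g", 1:3)
  ov <- overlap_matrix(elns)
  expect_equal(ov$d, t(ov$d), tolerance = 1e-12)
  expect_equal(unname(diag(ov$d_dissim)), rep(0, 3))
  expect_equal(ov$d["g1", "g3"],
               schoener_d(elns[[1]], elns[[3]]))
  expect_equal(ov$i["g2", "g3"], hellinger_i(elns[[2]], elns[[3]]))
})

test_that("complete-linkage clustering matches a brute-force agglomeration", {
  set.seed(38)
  # 4-niche dissimilarity profile matrix
  dis <- matrix(runif(16, 0.2, 0.9), 4, 4)
  dis <- (dis + t(dis)) / 2; diag(dis) <- 0
  rownames(dis) <- colnames(dis) <- paste0("g", 1:4)
  hc <- cluster_niches(dis)
  oracle <- complete_linkage_heights_oracle(dist(dis))
  expect_equal(hc$height, oracle, tolerance = 1e-12)
  expect_true(all(diff(hc$height) >= 0))     # monotone merge heights

  # identical niches merge first at height zero
  dup <- dis; dup[2, ] <- dup[1, ]; dup[, 2] <- dup[, 1]
  dup[1, 2] <- dup[2, 1] <- 0; diag(dup) <- 0
  hc2 <- cluster_niches(dup)
  expect_equal(hc2$height[1], 0)
  expect_equal(sort(-hc2$merge[1, ]), c(1, 2))
})
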