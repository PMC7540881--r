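train_mat <- function(x, vars = c("v1")) {
  m <- as.matrix(x)
  colnames(m) <- vars[seq_len(ncol(m))]
  m
}

test_that("training statistics follow their definitions", {
  same <- train_mat(rbind(c(1, 2, 3), c(1, 2, 3)), c("a", "b", "c"))
  fit <- fit_niche_model(algorithm_config("bioclim"), same)
  expect_equal(unname(fit$stats$sd), c(0, 0, 0))
  expect_equal(fit$stats$min, fit$stats$max)

  set.seed(31)
  x <- train_mat(matrix(rnorm(100), 20, 5), paste0("v", 1:5))
  fit2 <- fit_niche_model(
    algorithm_config("env_distance", metric = "mahalanobis"), x)
  # brute-force sample covariance
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(fit2$covariance, t(xc) %*% xc / (nrow(x) - 1),
               tolerance = 1e-12)

  expect_error(fit_niche_model(algorithm_config(), x[1, , drop = FALSE]),
               "at least 2")
  x_na <- x; x_na[3, 2] <- NA
  expect_error(fit_niche_model(algorithm_config(), x_na), "missing")
})

test_that("singular covariance is ridge-regularised with a warning", {
  x <- train_mat(cbind(1:10, 2 * (1:10)), c("a", "b"))  # perfectly collinear
  expect_warning(
    fit <- fit_niche_model(algorithm_config("env_distance",
                                            metric = "mahalanobis"), x),
    "ridge")
  ev <- eigen(fit$covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("bioclim scores 1 / 0.5 / 0 by core and min-max envelopes", {
  x <- train_mat(c(10, 12, 14))   # mean 12, sd 2
  fit <- fit_niche_model(algorithm_config("bioclim", sd_cutoff = 0.674), x)
  stack <- eln_stack(list(v1 = matrix(c(12, 10, 20, 13), 2, 2)))
  map <- predict(fit, stack)
  expect_equal(map$values[1, 1], 1)     # inside mean +/- 0.674 sd
  expect_equal(map$values[2, 1], 0.5)   # inside [min, max] only
  expect_equal(map$values[1, 2], 0)     # outside the envelope
  expect_equal(map$values[2, 2], 1)
})

test_that("envelope_score is the fraction of in-range variables", {
  x <- train_mat(rbind(c(0, 0, 0, 0), c(1, 1, 1, 1)), paste0("v", 1:4))
  fit <- fit_niche_model(algorithm_config("envelope_score"), x)
  stack <- eln_stack(list(v1 = matrix(0.5), v2 = matrix(0.5),
                          v3 = matrix(2), v4 = matrix(-1)))
  expect_equal(predict(fit, stack)$values[1, 1], 0.5)  # 2 of 4 in range
})

test_that("a cell identical to the training environment scores 1 everywhere", {
  x <- train_mat(rbind(c(3, 7), c(3, 7)), c("a", "b"))
  stack <- eln_stack(list(a = matrix(c(3, 0), 1, 2),
                          b = matrix(c(7, 0), 1, 2)))
  for (alg in c("bioclim", "envelope_score", "env_distance")) {
    fit <- fit_niche_model(algorithm_config(alg), x)
    expect_equal(predict(fit, stack)$values[1, 1], 1,
                 label = paste(alg, "at training cell"))
  }
})

test_that("predictions stay in [0,1] and ignore training order", {
  set.seed(8)
  stack <- make_test_stack(12, 12, vars = paste0("v", 1:4), seed = 8)
  x <- train_mat(matrix(runif(40), 10, 4), paste0("v", 1:4))
  for (alg in list(algorithm_config("bioclim"),
                   algorithm_config("envelope_score"),
                   algorithm_config("env_distance", metric = "euclidean"),
                   algorithm_config("env_distance", metric = "gower"),
                   algorithm_config("env_distance", metric = "chebyshev"),
                   algorithm_config("env_distance", metric = "mahalanobis"))) {
    m1 <- predict(fit_niche_model(alg, x), stack)
    expect_true(all(m1$values >= 0 & m1$values <= 1), label = alg$model_id)
    perm <- x[sample(nrow(x)), , drop = FALSE]
    m2 <- predict(fit_niche_model(alg, perm), stack)
    expect_equal(m1$values, m2$values, label = alg$model_id)
  }
})

test_that("env_distance suitability rises toward the training centroid", {
  set.seed(9)
  x <- train_mat(matrix(runif(20, 2, 4), 10, 2), c("a", "b"))
  centroid <- colMeans(x)
  # cells interpolating from a far corner toward the centroid
  alpha <- seq(0, 1, length.out = 11)
  far <- c(0, 0)
  pts <- t(sapply(alpha, function(al) (1 - al) * far + al * centroid))
  stack <- eln_stack(list(a = matrix(pts[, 1], 1), b = matrix(pts[, 2], 1)))
  cfg <- algorithm_config("env_distance", metric = "euclidean",
                          n_nearest_points = nrow(x))
  suit <- predict(fit_niche_model(cfg, x), stack)$values[1, ]
  expect_true(all(diff(suit) >= -1e-12))
})

test_that("the 0.5-level set of bioclim recovers a planted envelope exactly", {
  set.seed(12)
  nr <- 25; nc <- 25
  stack <- eln_stack(list(p = matrix(runif(nr * nc), nr, nc),
                          q = matrix(runif(nr * nc), nr, nc)))
  # plant a rectangular envelope niche and train on its corners
  x <- train_mat(rbind(c(0.3, 0.2), c(0.7, 0.6), c(0.5, 0.4)), c("p", "q"))
  fit <- fit_niche_model(algorithm_config("bioclim"), x)
  map <- predict(fit, stack)
  inside <- stack$layers$p >= 0.3 & stack$layers$p <= 0.7 &
    stack$layers$q >= 0.2 & stack$layers$q <= 0.6
  expect_equal(map$values >= 0.5, inside)
})

test_that("a variable missing from the stack is a named error", {
  x <- train_mat(cbind(1:3, 4:6), c("a", "zz"))
  stack <- eln_stack(list(a = matrix(1, 2, 2)))
  fit <- fit_niche_model(algorithm_config("envelope_score"), x)
  expect_error(predict(fit, stack), "zz")
})
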