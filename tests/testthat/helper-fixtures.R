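# Shared fixtures and independent oracles, built in code at test time.

# small stack of named random layers on a unit grid
make_test_stack <- function(nr = 10, nc = 10, vars = c("a", "b", "c"),
                            seed = 42) {
  set.seed(seed)
  layers <- lapply(vars, function(v) matrix(runif(nr * nc), nr, nc))
  names(layers) <- vars
  eln_stack(layers)
}

# constant monthly climate (matrices of one value each month)
constant_monthly <- function(value, nr = 3, nc = 3) {
  lapply(1:12, function(m) matrix(value, nr, nc))
}

# random monthly climate lists with tmin <= tmax, prec >= 0
random_monthly <- function(nr = 5, nc = 5, seed = 1) {
  set.seed(seed)
  tmin <- lapply(1:12, function(m) matrix(rnorm(nr * nc, 15, 5), nr, nc))
  tmax <- lapply(seq_along(tmin), function(m)
    tmin[[m]] + matrix(runif(nr * nc, 0.5, 12), nr, nc))
  prec <- lapply(1:12, function(m) matrix(rexp(nr * nc, 1 / 100), nr, nc))
  list(tmin = tmin, tmax = tmax, prec = prec)
}

# literal-definition bioclim oracle for a single cell: enumerates all 12
# wrapping quarters explicitly, independent of the array implementation
bioclim_cell_oracle <- function(tn, tx, pr) {
  tm <- (tn + tx) / 2
  out <- list()
  out$bio1 <- mean(tm)
  out$bio2 <- mean(tx - tn)
  out$bio4 <- 100 * sd(tm)
  out$bio5 <- max(tx)
  out$bio6 <- min(tn)
  out$bio7 <- out$bio5 - out$bio6
  out$bio3 <- if (out$bio7 == 0) 0 else 100 * out$bio2 / out$bio7
  out$bio12 <- sum(pr)
  out$bio13 <- max(pr)
  out$bio14 <- min(pr)
  out$bio15 <- if (mean(pr) == 0) 0 else 100 * sd(pr) / mean(pr)
  qt <- qp <- numeric(12)
  for (q in 1:12) {
    idx <- ((q - 1):(q + 1)) %% 12 + 1
    qt[q] <- mean(tm[idx])
    qp[q] <- sum(pr[idx])
  }
  out$bio8 <- qt[which.max(qp)]
  out$bio9 <- qt[which.min(qp)]
  out$bio10 <- max(qt)
  out$bio11 <- min(qt)
  out$bio16 <- max(qp)
  out$bio17 <- min(qp)
  out$bio18 <- qp[which.max(qt)]
  out$bio19 <- qp[which.min(qt)]
  out[paste0("bio", 1:19)]
}

# exhaustive pairwise AUC oracle (ties count one half)
auc_pairwise_oracle <- function(pres, bg) {
  tot <- 0
  for (p in pres) for (b in bg)
    tot <- tot + (p > b) + 0.5 * (p == b)
  tot / (length(pres) * length(bg))
}

# literal-formula overlap oracles on two raw value vectors
schoener_oracle <- function(v1, v2) {
  p1 <- v1 / sum(v1); p2 <- v2 / sum(v2)
  1 - 0.5 * sum(abs(p1 - p2))
}
hellinger_oracle <- function(v1, v2) {
  p1 <- v1 / sum(v1); p2 <- v2 / sum(v2)
  1 - 0.5 * sum((sqrt(p1) - sqrt(p2))^2)
}

# O(n^3) complete-linkage agglomeration oracle over a distance matrix;
# returns merge heights in order
complete_linkage_heights_oracle <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- 0
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) if (j > i) {
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# small synthetic world shared by pipeline-level tests (cheap: 60 x 60)
small_world <- local({
  cache <- NULL
  function(seed = 11) {
    if (is.null(cache))
      cache <<- generate_synthetic_world(
        synthetic_world_config(n_rows = 60, n_cols = 60, seed = seed))
    cache
  }
})

# a suitability_map wrapper around a plain matrix
as_suit_map <- function(values, group_id = "g") {
  structure(list(group_id = group_id, values = values,
                 grid = eln_grid(nrow(values), ncol(values), 0, nrow(values), 1),
                 provenance = list(list(model_id = "test", weight = 1)),
                 omission_threshold = NA_real_),
            class = "suitability_map")
}
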