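blob_grid <- function(nr = 12, nc = 12, blobs) {
  m <- matrix(FALSE, nr, nc)
  for (b in blobs) m[b$rows, b$cols] <- TRUE
  m
}

test_that("accessibility keeps only components reachable from the territory", {
  grid <- eln_grid(12, 12, 0, 12, 1)
  # two 8-connected presence blobs; polygon covers the first
  range <- blob_grid(blobs = list(list(rows = 2:5, cols = 2:5),
                                  list(rows = 8:11, cols = 8:11)))
  poly <- eln_polygon(rbind(c(1, 6), c(6, 6), c(6, 11), c(1, 11)))

  kept <- accessibility_filter(range, poly, grid, maritime = FALSE)
  expect_true(all(kept[2:5, 2:5]))
  expect_false(any(kept[8:11, 8:11]))

  # a single component containing the polygon is unchanged
  one <- blob_grid(blobs = list(list(rows = 2:6, cols = 2:6)))
  expect_identical(accessibility_filter(one, poly, grid), one)
})

test_that("maritime groups keep disconnected components that touch the sea", {
  grid <- eln_grid(12, 12, 0, 12, 1)
  range <- blob_grid(blobs = list(list(rows = 8:11, cols = 2:5),
                                  list(rows = 2:3, cols = 9:11)))
  sea <- matrix(FALSE, 12, 12); sea[1, ] <- TRUE      # northern sea edge
  poly <- eln_polygon(rbind(c(1, 1), c(6, 1), c(6, 5), c(1, 5)))

  landlocked <- accessibility_filter(range, poly, grid,
                                     maritime = FALSE, sea = sea)
  expect_false(any(landlocked[2:3, 9:11]))            # island patch dropped

  seafaring <- accessibility_filter(range, poly, grid,
                                    maritime = TRUE, sea = sea)
  expect_true(all(seafaring[2:3, 9:11]))              # island patch kept
  expect_true(all(seafaring[8:11, 2:5]))
  expect_error(accessibility_filter(range, poly, grid, maritime = TRUE),
               "sea mask")
})

test_that("geographic overlap is the Jaccard index of presence cells", {
  a <- blob_grid(blobs = list(list(rows = 1:2, cols = 1:5)))   # 10 cells
  b <- blob_grid(blobs = list(list(rows = 2:3, cols = 1:5)))   # 10, share 5
  expect_equal(geographic_overlap(a, a), 1)
  expect_equal(geographic_overlap(a, b), 5 / 15)
  c_ <- blob_grid(blobs = list(list(rows = 10:11, cols = 1:5)))
  expect_equal(geographic_overlap(a, c_), 0)
})

test_that("patterns are connected components of the double-threshold graph", {
  ids <- c("A", "B", "C", "D")
  lowgeo <- matrix(0.1, 4, 4, dimnames = list(ids, ids)); diag(lowgeo) <- 1
  lowd <- matrix(0.2, 4, 4, dimnames = list(ids, ids)); diag(lowd) <- 1

  # everything below threshold: four singletons
  singl <- identify_elps(ids, lowgeo, lowd)
  expect_equal(length(singl), 4)
  expect_true(all(vapply(singl, function(e) e$n_groups, integer(1)) == 1))

  # chain A-B and B-C above both thresholds, A-C below: one transitive ELP
  geo <- lowgeo; d <- lowd
  geo["A", "B"] <- geo["B", "A"] <- 0.8; d["A", "B"] <- d["B", "A"] <- 0.9
  geo["B", "C"] <- geo["C", "B"] <- 0.7; d["B", "C"] <- d["C", "B"] <- 0.8
  elps <- identify_elps(ids, geo, d, g_min = 0.4, d_min = 0.6)
  expect_equal(elps[[1]]$member_ids, c("A", "B", "C"))
  expect_equal(elps[[1]]$n_groups, 3)
  expect_equal(elps[[2]]$member_ids, "D")

  # a high geographic overlap alone (env overlap low) does not link
  geo2 <- lowgeo; geo2["A", "D"] <- geo2["D", "A"] <- 0.9
  expect_equal(length(identify_elps(ids, geo2, lowd)), 4)
})

test_that("every group lands in exactly one pattern", {
  set.seed(40)
  ids <- sprintf("%02d", 0:9)
  geo <- matrix(runif(100), 10, 10); geo <- (geo + t(geo)) / 2; diag(geo) <- 1
  d <- matrix(runif(100), 10, 10); d <- (d + t(d)) / 2; diag(d) <- 1
  elps <- identify_elps(ids, geo, d, g_min = 0.5, d_min = 0.5)
  all_members <- unlist(lapply(elps, `[[`, "member_ids"))
  expect_setequal(all_members, ids)
  expect_equal(anyDuplicated(all_members), 0)
})

test_that("raising thresholds only refines the partition", {
  set.seed(41)
  ids <- letters[1:8]
  geo <- matrix(runif(64), 8, 8); geo <- (geo + t(geo)) / 2; diag(geo) <- 1
  d <- matrix(runif(64), 8, 8); d <- (d + t(d)) / 2; diag(d) <- 1
  part <- function(elps) {
    lab <- rep(NA_character_, 8); names(lab) <- ids
    for (e in elps) lab[e$member_ids] <- e$elp_label
    lab
  }
  loose <- part(identify_elps(ids, geo, d, g_min = 0.3, d_min = 0.3))
  for (thr in list(c(0.5, 0.3), c(0.3, 0.5), c(0.7, 0.7))) {
    tight <- part(identify_elps(ids, geo, d, g_min = thr[1], d_min = thr[2]))
    # refinement: groups together under tight must be together under loose
    for (lbl in unique(tight)) {
      members <- names(tight)[tight == lbl]
      expect_equal(length(unique(loose[members])), 1)
    }
  }
})

test_that("diversity summaries count members and sum language counts", {
  meta <- data.frame(group_id = c("a", "b", "c"),
                     family = c("TNG", "TNG", "Austronesian"),
                     n_languages = c(4L, 6L, 1L))
  elps <- list(list(elp_label = "ELP 1", member_ids = c("a", "b")),
               list(elp_label = "ELP 2", member_ids = "c"))
  tab <- diversity_summary(elps, meta)
  expect_equal(tab$n_groups, c(2L, 1L))
  expect_equal(tab$n_languages, c(10L, 1L))     # brute-force sum oracle
  expect_equal(tab$families, c("TNG", "Austronesian"))

  expect_equal(nrow(diversity_summary(list(), meta)), 0)

  # unknown member counts propagate NA rather than a misleading total
  meta$n_languages[2] <- NA
  expect_true(is.na(diversity_summary(elps, meta)$n_languages[1]))
})
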