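# Axis profiles, kymographs, demographs, profile matrices, clustering.

test_that("axis_profile averages per bin and interpolates empty bins", {
  px <- tibble::tibble(l_rel = stats::runif(500, -0.5, 0.5), intensity = 3)
  prof <- axis_profile(px)
  expect_true(all(prof$value == 3))

  # linear gradient: bin mean equals the mean l of member pixels
  set.seed(401)
  px2 <- tibble::tibble(l_rel = stats::runif(2000, -0.5, 0.5))
  px2$intensity <- px2$l_rel
  prof2 <- axis_profile(px2, n_bins = 20)
  edges <- seq(-0.5, 0.5, length.out = 21)
  for (b in 1:20) {
    sel <- px2$l_rel >= edges[b] & (px2$l_rel < edges[b + 1] | b == 20)
    if (any(sel)) expect_equal(prof2$value[b], mean(px2$l_rel[sel]), tolerance = 1e-9)
  }

  # single-pixel cell: one populated bin, the rest interpolated + flagged
  p1 <- axis_profile(tibble::tibble(l_rel = 0.01, intensity = 9), n_bins = 25)
  expect_equal(sum(!p1$interpolated), 1)
  expect_true(all(p1$value == 9))       # constant extension from one point
  expect_error(axis_profile(tibble::tibble(l_rel = numeric(), intensity = numeric())),
               class = "cellmapr_empty_cell")
})

test_that("kymographs of uniform movies are constant with the right shape", {
  v <- make_mesh("rod", 24, 8, center = c(20, 16), angle = 0)
  frames <- lapply(1:30, function(i) matrix(5, 32, 40))
  tm <- tibble::tibble(frame_id = 0:29, mesh = rep(list(v), 30))
  ky <- kymograph(tm, frames, n_bins = 25)
  expect_equal(dim(ky$matrix), c(30, 25))
  expect_true(all(ky$matrix == 5))
  expect_error(kymograph(tibble::tibble(frame_id = 99L, mesh = list(v)), frames),
               class = "cellmapr_missing_frame")
})

test_that("kymograph argmax follows a planted sweeping band within one bin", {
  n_frames <- 30
  v <- make_mesh("rod", 40, 10, center = c(32, 32), angle = 0)
  fit <- min_bounding_box(v)
  centers <- numeric(n_frames)
  frames <- lapply(seq_len(n_frames), function(i) {
    s <- (i - 1) / (n_frames - 1)
    sp <- plant_spots(fit, "sweep", s = s)
    centers[i] <<- sp$l_rel[1]
    render_image(dim = c(64, 64), spots = sp, psf_sigma = 2, background = 1)
  })
  tm <- tibble::tibble(frame_id = seq_len(n_frames) - 1L,
                       mesh = rep(list(v), n_frames))
  ky <- kymograph(tm, frames, n_bins = 25)
  edges <- seq(-0.5, 0.5, length.out = 26)
  for (i in seq_len(n_frames)) {
    got_bin <- which.max(ky$matrix[i, ])
    true_bin <- findInterval(centers[i], edges, rightmost.closed = TRUE)
    expect_lte(abs(got_bin - true_bin), 1)
  }
})

test_that("demographs order rows by cell length and normalize per cell", {
  profiles <- tibble::tibble(cell_id = c("a", "b"),
                             profile = list(c(1, 2, 4), c(8, 2, 2)))
  cl <- tibble::tibble(cell_id = c("a", "b"), length = c(4, 2))
  m <- demograph(profiles, cl)
  expect_equal(rownames(m), c("b", "a"))
  expect_equal(m["a", ], c(1, 2, 4))
  mn <- demograph(profiles, cl, normalize = TRUE)
  expect_equal(unname(apply(mn, 1, max)), c(1, 1))

  # order invariance
  perm <- demograph(profiles[2:1, ], cl[2:1, ])
  expect_identical(m, perm)
})

test_that("profile_matrix interpolates linearly onto the percentage grid", {
  tr <- tibble::tibble(track_id = "t", frame_id = 0:4,
                       time = (0:4) * 60, length = 2 * 2^((0:4) / 4),
                       width = 1, fluor = c(0, 2.5, 5, 7.5, 10),
                       percent = c(0, 25, 50, 75, 100),
                       cycle = 1L, complete = TRUE)
  pm <- profile_matrix(tr)
  expect_equal(dim(pm), c(1, 101))
  expect_equal(as.vector(pm), 0:100 / 10, tolerance = 1e-9)

  const <- dplyr::mutate(tr, fluor = 5)
  pmc <- profile_matrix(const)
  expect_true(all(pmc == 5))

  # piecewise-linear oracle on random knots
  set.seed(411)
  for (rep in 1:5) {
    p <- sort(c(0, stats::runif(6, 1, 99), 100))
    f <- stats::rnorm(8)
    tr2 <- tibble::tibble(track_id = "r", frame_id = seq_along(p) - 1L,
                          time = p * 6, length = 2 + p / 100, width = 1,
                          fluor = f, percent = p, cycle = 1L, complete = TRUE)
    pm2 <- profile_matrix(tr2)
    oracle <- sapply(0:100, function(g) {
      i <- max(which(p <= g))
      if (p[i] == g) f[i] else f[i] + (f[i + 1] - f[i]) * (g - p[i]) / (p[i + 1] - p[i])
    })
    expect_equal(as.vector(pm2), oracle, tolerance = 1e-9)
  }
})

test_that("dissimilarity matrices are symmetric, zero-diagonal and match definitions", {
  pm <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1))
  d <- dissimilarity_matrix(pm)
  expect_equal(d["a", "b"], 0)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_equal(d["a", "c"], sqrt(8))

  dc <- dissimilarity_matrix(pm[c("a", "c"), ], method = "correlation")
  expect_equal(dc["a", "c"], 2)        # r = -1 -> 1 - (-1)

  flat <- rbind(x = c(1, 1, 1), y = c(1, 2, 3))
  expect_error(dissimilarity_matrix(flat, method = "correlation"),
               class = "cellmapr_dissimilarity_error")
  expect_error(dissimilarity_matrix(pm[1, , drop = FALSE]),
               class = "cellmapr_dissimilarity_error")
})

test_that("cluster_profiles with k = 1 puts everything in one cluster", {
  pm <- matrix(stats::rnorm(50), 10, 5,
               dimnames = list(sprintf("c%d", 1:10), NULL))
  res <- cluster_profiles(dissimilarity_matrix(pm), 1, pm = pm)
  expect_equal(unname(unique(res$labels)), 1L)
  expect_equal(res$fractions, 1)
  expect_error(cluster_profiles(dissimilarity_matrix(pm), 11),
               class = "cellmapr_cluster_error")
})

test_that("two planted archetypes are recovered with ARI >= 0.9", {
  skip_if_not_installed("mclust")
  set.seed(421)
  grid <- 0:100
  step_down <- ifelse(grid < 50, 1, 0.2)
  flat <- rep(0.6, 101)
  truth <- rep(1:2, each = 50)
  sep <- max(abs(step_down - flat))                    # archetype separation
  rows <- t(sapply(truth, function(g) {
    base <- if (g == 1) step_down else flat
    base + stats::rnorm(101, 0, 0.1 * sep)
  }))
  rownames(rows) <- sprintf("c%03d", 1:100)
  res <- cluster_profiles(dissimilarity_matrix(rows), 2, pm = rows)
  expect_gte(adjusted_rand(res$labels, truth), 0.9)
  # labels are dense 1..k and fractions sum to 1
  expect_setequal(unique(res$labels), 1:2)
  expect_equal(sum(res$fractions), 1)
})

test_that("constant-intensity input stays constant end-to-end", {
  v <- make_mesh("ovococcus", 20, 10, center = c(16, 16))
  img <- matrix(4, 32, 32)
  prof <- axis_profile(pixels_in_mesh(v, img))
  expect_true(all(prof$value == 4))
  pm <- rbind(a = rep(4, 101), b = rep(4, 101))
  expect_true(all(dissimilarity_matrix(pm) == 0))
})
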