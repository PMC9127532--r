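test_that("pixel-pixel entanglement needs both gray and distance conditions", {
  img <- gray_image(matrix(100L, 8, 8))
  cp <- cluster_params(th_f = 10, th_o = 5)
  expect_true(pixels_entangled(c(2, 2), c(2, 2), img, cp))
  img2 <- gray_image(matrix(c(rep(100L, 32), rep(150L, 32)), 8, 8))
  expect_false(pixels_entangled(c(0, 0), c(0, 7), img2, cluster_params(10, 100)))
  # 3-4-5 triangle, boundary inclusive
  expect_true(pixels_entangled(c(0, 0), c(3, 4), img, cp))
  expect_false(pixels_entangled(c(0, 0), c(3, 5), img, cp))
  expect_error(pixels_entangled(c(-1, 0), c(0, 0), img, cp), "bounds")
})

test_that("pixel-seed absorption tests the running mean and nearest member", {
  img <- gray_image(matrix(100L, 8, 8))
  cp <- cluster_params(th_f = 10, th_o = 5)
  cl <- mk_cluster(img, rbind(c(0, 0), c(0, 1)))
  expect_true(pixel_absorbed_by_seed(c(0, 2), cl, img, cp))
  # boundary-inclusive gray test: |gray - mean| exactly th_f
  vals <- matrix(100L, 8, 8); vals[1, 3] <- 110L
  img3 <- gray_image(vals)
  cl3 <- mk_cluster(img3, rbind(c(0, 0), c(0, 1)))
  expect_true(pixel_absorbed_by_seed(c(0, 2), cl3, img3, cp))
  # distance to the nearest member governs, not the intensity alone
  single <- mk_cluster(img, rbind(c(0, 0)))
  expect_false(pixel_absorbed_by_seed(c(0, 6), single, img, cp))
})

test_that("wormhole existence follows the three definitions", {
  img <- gray_image(matrix(100L, 64, 64))
  cp <- cluster_params(th_f = 10, th_o = 3)
  wp <- wormhole_params(connect_prob_min = 1e-12)
  # (1) at least two members each
  a1 <- mk_cluster(img, rbind(c(10, 10)), id = 1L)
  b1 <- mk_cluster(img, rbind(c(10, 50)), id = 2L)
  expect_false(wormhole_exists(a1, b1, img, cp, wp))
  # (2) not in the neighborhood: adjacent centroids fail
  a2 <- mk_cluster(img, rbind(c(10, 10), c(10, 11)), id = 1L)
  b2 <- mk_cluster(img, rbind(c(10, 12), c(10, 13)), id = 2L)
  expect_false(wormhole_exists(a2, b2, img, cp, wp))
  # all three satisfied: 3-pixel clusters, equal means, 40 px apart
  a3 <- mk_cluster(img, rbind(c(12, 10), c(12, 11), c(12, 12)), id = 1L)
  b3 <- mk_cluster(img, rbind(c(52, 10), c(52, 11), c(52, 12)), id = 2L)
  expect_true(wormhole_exists(a3, b3, img, cp, wp))
  # dissimilar means fail regardless of geometry
  vals <- matrix(100L, 64, 64); vals[53, 11:13] <- 180L
  img4 <- gray_image(vals)
  b4 <- mk_cluster(img4, rbind(c(52, 10), c(52, 11), c(52, 12)), id = 2L)
  expect_false(wormhole_exists(a3, b4, img4, cp, wp))
})

test_that("merging through a wormhole pools members and weights the mean", {
  vals <- matrix(50L, 16, 16)
  vals[1, 1:2] <- 100L; vals[9, 1:2] <- 110L
  img <- gray_image(vals)
  a <- mk_cluster(img, rbind(c(0, 0), c(0, 1)), id = 1L)
  b <- mk_cluster(img, rbind(c(8, 0), c(8, 1)), id = 2L)
  m <- merge_via_wormhole(a, b)
  expect_equal(m$mean_gray, 105)
  expect_equal(nrow(m$members), 4L)
  expect_identical(m$id, 1L)
  expect_identical(m$kind, "seed")
  # equal means leave the pooled mean unchanged
  b2 <- mk_cluster(img, rbind(c(1, 0), c(1, 1)), id = 3L)  # gray 50
  a2 <- mk_cluster(img, rbind(c(2, 0), c(2, 1)), id = 4L)  # gray 50
  expect_equal(merge_via_wormhole(a2, b2)$mean_gray, 50)
})

test_that("a constant image yields a single cluster and empty foreground", {
  res <- qwpso_segment(flat_image(24), qwpso_config(seed = 3))
  expect_length(res$clusters, 1L)
  expect_false(any(res$foreground))
  expect_true(is.na(res$threshold))
})

test_that("a noiseless dual-tail phantom is recovered with its tail tips", {
  ph <- make_phantom(phantom_spec("dualtail", 64, tail_length = 20, seed = 4))
  res <- qwpso_segment(ph$image, qwpso_config(seed = 6))
  expect_equal(f_measure(res$foreground, ph$mask), 1.0)
  tail_cols <- range(which(colSums(ph$mask) > 0))
  expect_true(any(res$foreground[, tail_cols[1]]))
  expect_true(any(res$foreground[, tail_cols[2]]))
})

test_that("gap-separated lobes are joined into one cluster only via wormholes", {
  ph <- make_phantom(phantom_spec("bottleneck", 64, neck_width = 3,
                                  neck_gap = 3, seed = 5))
  m <- ph$mask
  top <- m & row(m) <= 32; bot <- m & row(m) > 32
  spans <- function(res) any(vapply(res$clusters, function(cl) {
    idx <- cbind(cl$members[, 1] + 1L, cl$members[, 2] + 1L)
    any(top[idx]) && any(bot[idx])
  }, logical(1)))
  for (s in 1:3) {
    with_worm <- qwpso_segment(ph$image, qwpso_config(seed = s))
    without <- qwpso_segment(ph$image, qwpso_config(seed = s,
                                                    wormhole_enabled = FALSE))
    expect_true(spans(with_worm), label = sprintf("wormhole spans (seed %d)", s))
    expect_false(spans(without), label = sprintf("disabled spans (seed %d)", s))
  }
})

test_that("every in-loop admission replays against its entanglement rule", {
  ph <- make_phantom(phantom_spec("disc", 32, noise_sd = 10, seed = 8))
  cfg <- qwpso_config(seed = 9)
  res <- qwpso_segment(ph$image, cfg)
  img <- unclass(ph$image)
  cp <- cfg$cluster
  members <- list()  # per cluster id: accumulated (row, col) and grays
  for (i in seq_len(nrow(res$log))) {
    ev <- res$log[i, ]
    k <- as.character(ev$cluster)
    if (ev$event == "entangle") {
      g1 <- img[ev$row + 1L, ev$col + 1L]
      g2 <- img[ev$row2 + 1L, ev$col2 + 1L]
      expect_lte(abs(g1 - g2), cp$th_f)
      expect_lte((ev$row - ev$row2)^2 + (ev$col - ev$col2)^2, cp$th_o^2)
      pts <- unique(rbind(c(ev$row, ev$col), c(ev$row2, ev$col2)))
      members[[k]] <- pts
    } else if (ev$event == "absorb") {
      mem <- members[[k]]
      grays <- img[cbind(mem[, 1] + 1L, mem[, 2] + 1L)]
      expect_equal(mean(grays), ev$mean_before, tolerance = 1e-9)
      expect_lte(abs(ev$gray - ev$mean_before), cp$th_f)
      d2 <- (mem[, 1] - ev$row)^2 + (mem[, 2] - ev$col)^2
      expect_lte(min(d2), cp$th_o^2)
      members[[k]] <- rbind(mem, c(ev$row, ev$col))
    } else if (ev$event %in% c("merge", "consolidate")) {
      src <- as.character(ev$partner)
      members[[k]] <- rbind(members[[k]], members[[src]])
      members[[src]] <- NULL
    }
  }
})

test_that("stored cluster means and foreground agree with the label map", {
  ph <- make_phantom(phantom_spec("bottleneck", 48, noise_sd = 10, seed = 3))
  res <- qwpso_segment(ph$image, qwpso_config(seed = 2))
  img <- unclass(ph$image)
  fg_ids <- integer(0)
  for (cl in res$clusters) {
    from_labels <- which(res$labels == cl$id)
    expect_equal(length(from_labels), nrow(cl$members))
    expect_equal(mean(img[res$labels == cl$id]), cl$mean_gray, tolerance = 1e-9)
    if (isTRUE(cl$object)) fg_ids <- c(fg_ids, cl$id)
  }
  expect_identical(res$foreground,
                   matrix(res$labels %in% fg_ids, nrow(res$labels),
                          ncol(res$labels)))
  expect_true(all(res$labels >= 1L))  # every pixel carries exactly one label
})

test_that("wormhole angular separations stay in the admissible range", {
  ph <- make_phantom(phantom_spec("bottleneck", 48, noise_sd = 10, seed = 6))
  res <- qwpso_segment(ph$image, qwpso_config(seed = 4))
  expect_gt(length(res$delta_theta_log), 0)
  expect_true(all(res$delta_theta_log > 0))
  expect_true(all(res$delta_theta_log <= 57.32))
})

test_that("qwpso with the wormhole disabled reduces exactly to qpso", {
  ph <- make_phantom(phantom_spec("dualtail", 48, noise_sd = 10, seed = 2))
  a <- qwpso_segment(ph$image, qwpso_config(seed = 11, wormhole_enabled = FALSE))
  b <- qpso_segment(ph$image, seed = 11)
  expect_identical(a$labels, b$labels)
  expect_identical(a$foreground, b$foreground)
  expect_identical(a$log, b$log)
  expect_length(a$delta_theta_log, 0)
})
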