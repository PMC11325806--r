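test_that("thinning matches the reference Zhang-Suen implementation exactly", {
  # single pixel is a fixpoint
  single <- matrix(0L, 3, 3); single[2, 2] <- 1L
  expect_equal(thin_mask(single)$grid, single)

  # filled 3x9 bar reduces to its middle row (up to end erosion), exactly as
  # the reference implementation says
  bar <- matrix(1L, 3, 9)
  expect_equal(thin_mask(bar)$grid, ref_zhang_suen(bar))

  # 1-px ring is already thin; the loop must be preserved
  ring <- matrix(0L, 7, 7)
  ring[2, 2:6] <- 1L; ring[6, 2:6] <- 1L; ring[2:6, 2] <- 1L; ring[2:6, 6] <- 1L
  expect_equal(thin_mask(ring)$grid, ring)
  expect_equal(ref_zhang_suen(ring), ring)

  # random blobs: exact pixel-set equality with the oracle, skeleton is a
  # subset of the input, connectivity preserved
  for (s in 1:6) {
    g <- random_blob(24, 24, 140, seed = s)
    sk <- thin_mask(g)
    expect_equal(sk$grid, ref_zhang_suen(g), info = paste("blob", s))
    expect_true(all(g[sk$grid == 1L] == 1L))
    if (flood_connected(g)) expect_true(flood_connected(sk$grid))
  }
})

test_that("longest skeleton path is exact on trees and matches all-pairs BFS", {
  # straight row: all pixels, in order
  row <- matrix(0L, 3, 12); row[2, 2:11] <- 1L
  p <- longest_skeleton_path(thin_mask(row))
  expect_equal(nrow(p), 10L)
  expect_equal(p[, 1], rep(2L, 10))
  expect_equal(p[, 2], 2:11)

  # T-shape: path runs along the 9-px crossbar, not into the stem
  tgrid <- matrix(0L, 9, 11)
  tgrid[2, 2:10] <- 1L        # crossbar, 9 px
  tgrid[3:6, 6] <- 1L         # stem, 4 more px
  sk <- woodmorph:::skeleton_from_grid(tgrid)
  path <- longest_skeleton_path(sk)
  expect_equal(nrow(path), 9L)
  expect_true(all(path[, 1] == 2L))
  expect_equal(nrow(longest_skeleton_path(sk, exact = TRUE)), 9L)

  # single pixel
  single <- matrix(0L, 3, 3); single[2, 2] <- 1L
  expect_equal(nrow(longest_skeleton_path(thin_mask(single))), 1L)

  # consecutive path pixels are 8-adjacent, and double BFS agrees with both
  # the exhaustive mode and an igraph all-pairs oracle on random skeletons
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    g <- ref_zhang_suen(random_blob(20, 20, 90, seed = 100 + s))
    sk <- woodmorph:::skeleton_from_grid(g)
    p1 <- longest_skeleton_path(sk)
    expect_true(all(apply(abs(diff(p1)), 1, max) == 1))
    p2 <- longest_skeleton_path(sk, exact = TRUE)
    expect_equal(nrow(p1), nrow(p2), info = paste("skeleton", s))
    expect_equal(nrow(p2), ref_longest_path_length(sk),
                 info = paste("skeleton", s))
  }
})

test_that("skeleton length modes give pixel counts and weighted step sums", {
  row <- matrix(0L, 1, 100); row[1, ] <- 1L
  sk <- woodmorph:::skeleton_from_grid(row)
  expect_equal(skeleton_length_px(sk, "pixel_count"), 100)

  diag10 <- matrix(0L, 10, 10); diag(diag10) <- 1L
  skd <- woodmorph:::skeleton_from_grid(diag10)
  expect_equal(skeleton_length_px(skd, "pixel_count"), 10)
  expect_equal(skeleton_length_px(skd, "weighted_path"), 9 * sqrt(2))

  # L-path: 5 px down then 5 px right sharing the corner. Under
  # 8-connectivity the path cuts the corner diagonally, so the longest path
  # holds 8 pixels over 7 steps (6 axial + 1 diagonal) -- confirmed by the
  # exhaustive all-pairs oracle.
  L <- matrix(0L, 6, 6)
  L[1:5, 1] <- 1L; L[5, 1:5] <- 1L
  skl <- woodmorph:::skeleton_from_grid(L)
  expect_equal(nrow(longest_skeleton_path(skl, exact = TRUE)), 8L)
  expect_equal(skeleton_length_px(skl, "pixel_count"), 8)
  expect_equal(skeleton_length_px(skl, "weighted_path"), 6 + sqrt(2))
  expect_equal(skeleton_length_px(skl, "all_pixels"), 9)

  expect_error(skeleton_length_px(skl, "geodesic"))
})

test_that("distance transform equals the brute-force oracle exactly", {
  single <- matrix(0L, 1, 1); single[1, 1] <- 1L
  expect_equal(distance_transform(single), matrix(1, 1, 1))

  sq7 <- matrix(1L, 7, 7)
  dt <- distance_transform(sq7)
  expect_equal(max(dt), 4)
  expect_equal(dt[4, 4], 4)
  expect_equal(dt, ref_distance_transform(sq7))

  for (s in 1:5) {
    set.seed(s)
    g <- matrix(rbinom(48 * 64, 1, 0.55), 48, 64)
    if (sum(g) == 0) next
    expect_equal(distance_transform(g), ref_distance_transform(g),
                 info = paste("random mask", s))
  }
})

test_that("width is twice the max distance transform, with optional bias fix", {
  band <- instance_mask(matrix(1L, 7, 40))
  expect_equal(width_px(band), 8)                      # overestimates 7 by 1
  expect_equal(width_px(band, bias_correction = TRUE), 7)

  line <- instance_mask(matrix(1L, 1, 30))
  expect_equal(width_px(line), 2)

  # rasterized disk of radius 10: width close to the 20-px diameter
  disk <- render_instance(cbind(30, 30), 20, "vessel")$mask
  expect_gte(width_px(disk), 20)
  expect_lte(width_px(disk), 22)
})

test_that("width never decreases under 1-px dilation", {
  for (s in 1:4) {
    g <- random_blob(20, 20, 60, seed = 300 + s)
    w0 <- width_px(instance_mask(g))
    pad <- matrix(0L, 22, 22)
    pad[2:21, 2:21] <- g
    dil <- matrix(0L, 22, 22)
    for (dr in -1:1) for (dc in -1:1)
      dil[(2:21) + dr, (2:21) + dc] <- pmax(dil[(2:21) + dr, (2:21) + dc], g)
    expect_gte(width_px(instance_mask(dil)), w0)
  }
})

test_that("border touch honours the margin against the full frame", {
  poly <- polygon_annotation("fiber", rbind(c(0, 5), c(8, 5), c(4, 9)))
  expect_true(touches_border(poly, 100L, 100L))

  inner <- square_mask(5L, c(10L, 10L))
  expect_false(touches_border(inner, 100L, 100L, margin = 0L))

  near <- square_mask(5L, c(2L, 10L))   # 2 px from the top edge
  expect_false(touches_border(near, 100L, 100L, margin = 0L))
  expect_true(touches_border(near, 100L, 100L, margin = 2L))
})

test_that("calibration arithmetic is exact in the measurement records", {
  line <- instance_mask(matrix(1L, 1, 100))
  rec <- measure_instance(line, calibration(0.65), 200L, 50L)
  expect_equal(rec$length_px, 100)
  expect_equal(rec$length_um, 65)
  expect_equal(rec$length_um / rec$length_px, 0.65)

  sq <- polygon_annotation("fiber",
                           rbind(c(0, 0), c(40, 0), c(40, 25), c(0, 25)))
  expect_equal(polygon_area_px2(sq) * 0.65^2, 1000 * 0.4225)
})

test_that("a straight synthetic fiber is measured near its ground truth", {
  ri <- render_instance(cbind(c(10, 210), c(50, 50)), 9, "fiber")
  rec <- measure_instance(ri$mask, calibration(0.65), 400L, 100L)
  expect_gte(rec$length_px, 180)
  expect_lte(rec$length_px, 205)
  expect_gte(rec$width_px, 8)
  expect_lte(rec$width_px, 11)
  expect_false(rec$touches_border)
})

test_that("stadium shapes obey the length/width error envelopes", {
  for (L in c(120, 200)) for (w in c(9, 15)) {
    ri <- render_instance(cbind(c(20, 20 + L), c(40, 40)), w, "fiber")
    rec <- measure_instance(ri$mask, calibration(), 320L, 90L)
    expect_lte(abs(rec$width_px - w), 2)
    expect_gte(rec$length_px, L - 1.5 * w)
    expect_lte(rec$length_px, L + 2)
  }
})

test_that("measurements are invariant under lattice rotations and flips", {
  g <- render_instance(cbind(c(8, 60), c(14, 30)), 7, "fiber")$mask$grid
  base <- c(skeleton_length_px(thin_mask(g)), width_px(instance_mask(g)),
            sum(g))
  variants <- list(g[nrow(g):1, ], g[, ncol(g):1], t(g),
                   t(g)[ncol(g):1, ], g[nrow(g):1, ncol(g):1])
  for (v in variants) {
    got <- c(skeleton_length_px(thin_mask(v)), width_px(instance_mask(v)),
             sum(v))
    expect_equal(got, base)
  }
})

test_that("border exclusion filters summaries but keeps all records", {
  interior <- lapply(1:3, function(i) square_mask(5L, c(10L + i, 20L), "fiber"))
  border <- list(square_mask(5L, c(0L, 30L), "fiber"),
                 square_mask(5L, c(40L, 95L), "fiber"))
  recs <- measure_collection(c(interior, border), calibration(),
                             image_width = 100L, image_height = 100L,
                             image_id = "im")
  expect_equal(nrow(recs), 5L)
  expect_equal(sum(recs$excluded), 2L)
  expect_equal(summarize_records(recs, "length_um")$n, 3L)

  recs_all <- measure_collection(c(interior, border), calibration(),
                                 image_width = 100L, image_height = 100L,
                                 exclude_border = FALSE, image_id = "im")
  expect_equal(sum(recs_all$excluded), 0L)
  expect_equal(summarize_records(recs_all, "length_um")$n, 5L)

  # overlapping instances are measured independently (full-mask semantics)
  a <- square_mask(9L, c(10L, 10L), instance_id = "a")
  b <- square_mask(9L, c(14L, 14L), instance_id = "b")
  r2 <- measure_collection(list(a, b), calibration(), 50L, 50L)
  expect_equal(r2$area_px2, c(81, 81))
})

test_that("empty inputs produce an empty record table", {
  expect_equal(nrow(measure_collection(list(), calibration(), 10L, 10L)), 0L)
  expect_error(thin_mask(matrix(0L, 3, 3)), "empty")
})
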