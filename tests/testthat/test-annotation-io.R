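test_that("VGG reader parses polygon regions and image entries", {
  path <- tempfile(fileext = ".json")
  writeLines('{
    "img1.png-1": {"filename": "img1.png",
      "file_attributes": {"width": 100, "height": 80},
      "regions": [
        {"shape_attributes": {"name": "polygon",
           "all_points_x": [0, 10, 10, 0], "all_points_y": [0, 0, 10, 10]},
         "region_attributes": {"type": "fiber"}}]},
    "img2.png-1": {"filename": "img2.png",
      "file_attributes": {"width": 50, "height": 50}, "regions": []}
  }', path)
  sets <- read_vgg_json(path)
  expect_length(sets, 2L)
  expect_equal(sets[[1]]$image_id, "img1.png")
  expect_length(sets[[1]]$annotations, 1L)
  a <- sets[[1]]$annotations[[1]]
  expect_equal(a$class_label, "fiber")
  expect_equal(nrow(a$vertices), 4L)
  expect_length(sets[[2]]$annotations, 0L)
})

test_that("VGG reader drops short polygons with a warning and collects region errors", {
  path <- tempfile(fileext = ".json")
  writeLines('{"im-1": {"filename": "im",
    "file_attributes": {"width": 20, "height": 20},
    "regions": [
      {"shape_attributes": {"name": "polygon",
         "all_points_x": [1, 5], "all_points_y": [1, 5]},
       "region_attributes": {"label": "fiber"}},
      {"shape_attributes": {"name": "rect", "x": 1},
       "region_attributes": {"label": "fiber"}}]}}', path)
  expect_warning(expect_warning(sets <- read_vgg_json(path),
                                "dropped"), "skipped")
  expect_length(sets[[1]]$annotations, 0L)
  expect_length(attr(sets, "errors"), 1L)
})

test_that("VGG reader handles the project-export dialect and odd labels", {
  path <- tempfile(fileext = ".json")
  writeLines('{"_via_img_metadata": {"x-1": {"filename": "x",
    "file_attributes": {"width": 30, "height": 30},
    "regions": [
      {"shape_attributes": {"name": "polygon",
         "all_points_x": [0, 9, 9], "all_points_y": [0, 0, 9]},
       "region_attributes": {"cell": "Vessel"}},
      {"shape_attributes": {"name": "polygon",
         "all_points_x": [1, 8, 8], "all_points_y": [1, 1, 8]},
       "region_attributes": {"label": "ray"}}]}}}', path)
  expect_warning(sets <- read_vgg_json(path), "unknown class")
  labs <- vapply(sets[[1]]$annotations, `[[`, "", "class_label")
  expect_equal(labs, c("Vessel", "ray"))
})

test_that("malformed JSON fails with a parse error naming the file", {
  path <- tempfile(fileext = ".json")
  writeLines('{"img": {', path)
  expect_error(read_vgg_json(path), "malformed VGG JSON")
})

test_that("VGG write/read round-trips vertex coordinates", {
  set.seed(42)
  anns <- lapply(1:5, function(i) {
    n <- sample(3:12, 1)
    polygon_annotation(sample(c("fiber", "vessel"), 1),
                       cbind(runif(n, 0, 600), runif(n, 0, 400)))
  })
  s <- annotation_set("round.png", 600L, 400L, anns)
  path <- tempfile(fileext = ".json")
  write_vgg_json(s, path)
  back <- read_vgg_json(path)[[1]]
  expect_equal(back$width_px, 600L)
  for (i in seq_along(anns))
    expect_lt(max(abs(back$annotations[[i]]$vertices - anns[[i]]$vertices)),
              1e-5 * 600)
})

test_that("YOLO writer emits normalized 6-decimal lines with class indices", {
  sq <- polygon_annotation("fiber",
                           rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  vs <- polygon_annotation("vessel", rbind(c(5, 5), c(20, 5), c(20, 30)))
  s <- annotation_set("im", 100L, 100L, list(sq, vs))
  lines <- write_yolo_seg_labels(s, c("fiber", "vessel"))
  expect_equal(lines[1],
    "0 0.000000 0.000000 0.100000 0.000000 0.100000 0.100000 0.000000 0.100000")
  expect_match(lines[2], "^1 ")
  expect_error(write_yolo_seg_labels(s, c("vessel")), "fiber")
})

test_that("YOLO write/read round-trips within 1e-5 of an image dimension", {
  set.seed(7)
  anns <- lapply(1:6, function(i) {
    n <- sample(3:9, 1)
    polygon_annotation(sample(c("fiber", "vessel"), 1),
                       cbind(runif(n, 0, 1920), runif(n, 0, 1440)))
  })
  s <- annotation_set("rt", 1920L, 1440L, anns)
  lines <- write_yolo_seg_labels(s)
  back <- read_yolo_seg_labels(lines, "rt", 1920L, 1440L)
  for (i in seq_along(anns)) {
    expect_equal(back$annotations[[i]]$class_label, anns[[i]]$class_label)
    expect_lt(max(abs(back$annotations[[i]]$vertices - anns[[i]]$vertices)),
              1e-5 * 1920)
  }
})

test_that("rasterization matches the brute-force even-odd oracle", {
  sq <- polygon_annotation("fiber",
                           rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  m <- rasterize_polygon(sq, 20L, 20L)
  expect_equal(sum(m$grid), 121L)  # 11 x 11 boundary-inclusive
  expect_equal(dim(m$grid), c(11L, 11L))

  tri <- polygon_annotation("fiber", rbind(c(0, 0), c(4, 0), c(0, 3)))
  mt <- rasterize_polygon(tri, 10L, 10L)
  expect_equal(sum(mt$grid), ref_rasterize_count(c(0, 4, 0), c(0, 0, 3), 10L, 10L))

  set.seed(11)
  for (k in 1:8) {
    n <- sample(3:8, 1)
    v <- cbind(runif(n, 0, 18), runif(n, 0, 14))
    poly <- polygon_annotation("fiber", v)
    if (polygon_area_px2(poly) < 1) next
    m <- rasterize_polygon(poly, 16L, 20L)
    expect_equal(sum(m$grid),
                 ref_rasterize_count(v[, 1], v[, 2], 16L, 20L),
                 info = paste("random polygon", k))
  }
})

test_that("degenerate polygons are rejected by the rasterizer", {
  coll <- polygon_annotation("fiber", rbind(c(0, 0), c(2, 2), c(4, 4)))
  expect_error(rasterize_polygon(coll, 10L, 10L), "degenerate")
})

test_that("shoelace area is exact and orientation-independent", {
  sq <- polygon_annotation("fiber",
                           rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  expect_equal(polygon_area_px2(sq), 100)
  tri <- rbind(c(0, 0), c(4, 0), c(0, 3))
  expect_equal(polygon_area_px2(polygon_annotation("v", tri)), 6)
  expect_equal(polygon_area_px2(polygon_annotation("v", tri[3:1, ])), 6)
})

test_that("tiling covers every pixel with inward-shifted last windows", {
  w <- tile_image(2048L, 2048L, 1024L, 0)
  expect_equal(nrow(w), 4L)
  expect_equal(w$row0, c(0L, 0L, 1024L, 1024L))
  expect_equal(w$col0, c(0L, 1024L, 0L, 1024L))

  w1 <- tile_image(1000L, 1000L, 1024L, 0)
  expect_equal(w1, data.frame(row0 = 0L, col0 = 0L, rows = 1000L,
                              cols = 1000L))

  w2 <- tile_image(3000L, 2000L, 1024L, 0.1)
  expect_true(all(w2$row0 + w2$rows <= 2000L))
  expect_true(all(w2$col0 + w2$cols <= 3000L))
  cover <- matrix(0L, 2000L, 3000L)
  for (i in seq_len(nrow(w2)))
    cover[w2$row0[i] + seq_len(w2$rows[i]),
          w2$col0[i] + seq_len(w2$cols[i])] <- 1L
  expect_equal(sum(cover), 2000L * 3000L)
})

test_that("augmentation ops are exact, composable and invertible", {
  v <- rbind(c(3, 4), c(60, 10), c(40, 70))
  s <- annotation_set("a", 100L, 80L, list(polygon_annotation("fiber", v)))

  fh <- augment(s, "fliph")
  expect_equal(fh$annotations[[1]]$vertices[, 1], 100 - v[, 1])
  expect_equal(fh$annotations[[1]]$vertices[, 2], v[, 2])

  r9twice <- augment(augment(s, "rot90"), "rot90")
  r180 <- augment(s, "rot180")
  expect_equal(r9twice$annotations[[1]]$vertices,
               r180$annotations[[1]]$vertices)

  sc <- augment(s, "scale", scale = 0.5)
  expect_equal(polygon_area_px2(sc$annotations[[1]]),
               0.25 * polygon_area_px2(s$annotations[[1]]))

  inverses <- list(c("fliph", "fliph"), c("flipv", "flipv"),
                   c("rot90", "rot270"), c("rot180", "rot180"))
  for (pair in inverses) {
    back <- augment(augment(s, pair[1]), pair[2])
    expect_lt(max(abs(back$annotations[[1]]$vertices - v)), 1e-9)
  }
  back <- augment(augment(s, "scale", scale = 2), "scale", scale = 0.5)
  expect_lt(max(abs(back$annotations[[1]]$vertices - v)), 1e-9)

  expect_error(augment(s, "shear"), "unknown")
})

test_that("train/val split is deterministic, disjoint and correctly sized", {
  ids <- sprintf("img%03d", 1:100)
  sp <- split_manifest(ids, 0.85, seed = 3L)
  expect_length(sp$train, 85L)
  expect_length(sp$val, 15L)
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_setequal(c(sp$train, sp$val), ids)
  expect_identical(sp, split_manifest(ids, 0.85, seed = 3L))
  sp20 <- split_manifest(ids[1:20], 0.85, seed = 1L)
  expect_length(sp20$train, 17L)
  expect_length(sp20$val, 3L)
  expect_error(split_manifest("one", 0.85, 1L), "at least 2")
})

test_that("instance mask PNGs round-trip with sidecar metadata", {
  dir <- tempfile()
  masks <- list(square_mask(5L, c(2L, 3L), "fiber", 0.8, "a"),
                square_mask(7L, c(10L, 10L), "vessel", 0.6, "b"))
  write_instance_masks(masks, dir, "im1", 32L, 24L)
  back <- read_instance_masks(dir, "im1")
  expect_length(back, 2L)
  expect_equal(attr(back, "image_dim"), c(24L, 32L))
  expect_equal(back[[1]]$offset, c(2L, 3L))
  expect_equal(back[[1]]$class_label, "fiber")
  expect_equal(back[[1]]$confidence, 0.8)
  expect_equal(sum(back[[2]]$grid), 49L)
})
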