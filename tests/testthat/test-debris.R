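test_that("connected nucleus components become objects with calibrated geometry", {
  lab <- matrix(3L, 40, 40)
  lab[5:14, 5:14] <- 1L            # 10x10 square nucleus
  lab[25:30, 25:30] <- 1L          # second disjoint nucleus
  objs <- label_objects(label_map(lab))
  expect_length(objs, 2)
  sq <- objs[[which.max(vapply(objs, function(o) o$area, numeric(1)))]]
  expect_equal(sq$area, 100)
  expect_gte(sq$perimeter, 36)
  expect_lte(sq$perimeter, 40)
  # area factor scales area linearly and perimeter by its square root
  objs16 <- label_objects(label_map(lab), area_factor = 16)
  expect_equal(objs16[[1]]$area, objs[[1]]$area * 16)
  expect_equal(objs16[[1]]$perimeter, objs[[1]]$perimeter * 4)
  expect_length(label_objects(label_map(matrix(3L, 10, 10))), 0)
})

test_that("diagonally touching nucleus pixels join one object (8-connectivity)", {
  lab <- matrix(3L, 12, 12)
  lab[3:5, 3:5] <- 1L
  lab[6:8, 6:8] <- 1L   # touches only at the (5,5)-(6,6) diagonal
  objs <- label_objects(label_map(lab), close_radius = 0)
  expect_length(objs, 1)
})

test_that("the size gate applies the inclusive area band at its printed bounds", {
  mk <- function(area) structure(list(area = area, rejection_stage = "NONE"),
                                 class = "cell_object")
  cfg <- debris_config()
  expect_equal(size_gate(mk(624), cfg)$rejection_stage, "SIZE")
  expect_equal(size_gate(mk(625), cfg)$rejection_stage, "NONE")
  expect_equal(size_gate(mk(85267), cfg)$rejection_stage, "NONE")
  expect_equal(size_gate(mk(85268), cfg)$rejection_stage, "SIZE")
})

test_that("circularity is 1 for a circle, pi/4 for a square, and scale-stable on disks", {
  expect_equal(circularity(pi * 5^2, 2 * pi * 5), 1)
  s <- 3.7
  expect_equal(circularity(s^2, 4 * s), pi / 4)
  # discrete disks: value drifts < 2% when the radius doubles from 20
  c20 <- compactness(disk_object(20)$obj)
  c40 <- compactness(disk_object(40)$obj)
  expect_lt(abs(c40 - c20) / c20, 0.02)
})

test_that("a thin line falls below the elongation side of the shape band", {
  lab <- matrix(3L, 10, 40)
  lab[5, 6:30] <- 1L  # 1 x 25 line
  obj <- label_objects(label_map(lab), close_radius = 0)[[1]]
  expect_lt(compactness(obj), 0.15)
  expect_equal(shape_gate(obj)$rejection_stage, "SHAPE")
})

test_that("the shape gate rejects at both circularity extremes", {
  mk <- function(cval) structure(list(compactness = cval, perimeter = 10,
                                      rejection_stage = "NONE"),
                                 class = "cell_object")
  expect_equal(shape_gate(mk(0.98))$rejection_stage, "SHAPE")
  expect_equal(shape_gate(mk(0.5))$rejection_stage, "NONE")
  expect_equal(shape_gate(mk(0.14))$rejection_stage, "SHAPE")
  deg <- structure(list(compactness = NA_real_, perimeter = 0,
                        rejection_stage = "NONE"), class = "cell_object")
  expect_error(compactness(deg), "degenerate")
})

test_that("single-pixel objects are degenerate for the shape descriptor", {
  lab <- matrix(3L, 9, 9); lab[5, 5] <- 1L
  obj <- label_objects(label_map(lab), close_radius = 0)[[1]]
  expect_error(compactness(obj), "degenerate")
})

test_that("the texture gate respects fixed thresholds and degenerate input", {
  mk <- function(s) structure(list(texture_score = s, rejection_stage = "NONE"),
                              class = "cell_object")
  objs <- lapply(c(1, 5, 100), mk)
  out <- texture_gate(objs, debris_config(texture_threshold = Inf))
  expect_true(all(vapply(out, function(o) o$rejection_stage, character(1)) == "NONE"))
  out2 <- texture_gate(objs, debris_config(texture_threshold = 50))
  expect_equal(vapply(out2, function(o) o$rejection_stage, character(1)),
               c("NONE", "NONE", "TEXTURE"))
  expect_identical(texture_gate(list(), debris_config()), list())
  expect_warning(texture_gate(objs[1], debris_config(texture_threshold = "AUTO")),
                 "at least 2")
})

test_that("AUTO texture thresholding rejects outlying scores but not a homogeneous batch", {
  mk <- function(s) structure(list(texture_score = s, rejection_stage = "NONE"),
                              class = "cell_object")
  homog <- lapply(c(100, 104, 98, 109, 95, 101, 103), mk)
  out <- texture_gate(homog, debris_config())
  expect_true(all(vapply(out, function(o) o$rejection_stage, character(1)) == "NONE"))
  spiked <- lapply(c(100, 104, 98, 109, 95, 101, 103, 480, 510), mk)
  out2 <- texture_gate(spiked, debris_config())
  stages <- vapply(out2, function(o) o$rejection_stage, character(1))
  expect_equal(stages, c(rep("NONE", 7), "TEXTURE", "TEXTURE"))
})

test_that("three-phase rejection trips each gate once on the staged scene", {
  sc <- small_scene()
  cfg <- debris_config(area_factor = sc$area_factor)
  dr <- reject_debris(sc$enh, sc$truth, cfg,
                      candidate_classes = c("NUCLEUS", "DEBRIS"))
  expect_equal(dr$report$rejected[dr$report$stage == "SIZE"], 2L)
  expect_equal(dr$report$rejected[dr$report$stage == "SHAPE"], 1L)
  expect_equal(dr$report$rejected[dr$report$stage == "TEXTURE"], 1L)
  expect_equal(length(dr$retained), sum(sc$manifest$is_cell))
  # retained + rejected partition the candidates
  expect_equal(length(dr$retained) + length(dr$rejected), nrow(dr$objects))
  # sequentiality: no SHAPE/TEXTURE-rejected object violates the size band
  later <- dr$objects[dr$objects$rejection_stage %in% c("SHAPE", "TEXTURE"), ]
  expect_true(all(later$area >= cfg$area_min & later$area <= cfg$area_max))
})

test_that("an all-cell scene and an empty map produce no rejections", {
  counts <- c(SUPERFICIAL = 0, INTERMEDIATE = 1, COLUMNAR = 1, MILD = 1,
              MODERATE = 1, SEVERE = 1, CARCINOMA_IN_SITU = 1)
  sc <- render_scene(scene_recipe(cells_per_class = counts, seed = 77))
  dr <- reject_debris(enhance(sc$gray), sc$truth,
                      debris_config(area_factor = sc$area_factor),
                      candidate_classes = c("NUCLEUS", "DEBRIS"))
  expect_equal(sum(dr$report$rejected), 0L)
  expect_equal(length(dr$retained), 6L)
  empty <- label_map(matrix(3L, 30, 30))
  dr0 <- reject_debris(matrix(200, 30, 30), empty, debris_config())
  expect_length(dr0$retained, 0)
  expect_equal(sum(dr0$report$rejected), 0L)
})
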