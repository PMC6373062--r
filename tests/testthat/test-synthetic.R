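test_that("generated tables match the class statistics and are reproducible", {
  tbl <- gen_feature_table(1000, seed = 3)
  sup <- dplyr::filter(tbl, label == "SUPERFICIAL")
  # sample mean within 3 standard errors of the class mean
  expect_lt(abs(mean(sup$nucleus_area) - 631), 3 * 206 / sqrt(1000))
  expect_identical(gen_feature_table(50, seed = 9), gen_feature_table(50, seed = 9))
  expect_false(identical(gen_feature_table(50, seed = 9),
                         gen_feature_table(50, seed = 10)))
  expect_true(all(tbl$nc_ratio >= 0 & tbl$nc_ratio <= 1))
  expect_true(all(tbl$nucleus_area > 0))
  expect_true(all(tbl$nucleus_gray_level >= 0 & tbl$nucleus_gray_level <= 255))
  expect_error(gen_feature_table(0), "n_per_class")
})

test_that("per-feature draws agree with the stated truncated Gaussians (KS)", {
  tbl <- gen_feature_table(500, seed = 13)
  stats <- class_stats()
  ptrunc <- function(x, mean, sd, lower, upper) {
    (pnorm(x, mean, sd) - pnorm(lower, mean, sd)) /
      (pnorm(upper, mean, sd) - pnorm(lower, mean, sd))
  }
  cases <- list(
    c("SUPERFICIAL", "nucleus_area"), c("COLUMNAR", "nc_ratio"),
    c("MODERATE", "cyto_area"), c("SEVERE", "nucleus_gray_level")
  )
  cols <- c(nucleus_area = "nucleus_area", nc_ratio = "nc_ratio",
            cyto_area = "cyto_area", nucleus_gray_level = "nucleus_brightness")
  for (cs in cases) {
    cl <- cs[1]; col <- cs[2]
    stat_feat <- cols[[col]]
    row <- dplyr::filter(stats, class == cl, feature == stat_feat)
    b <- papscreen:::physical_bounds(stat_feat)
    x <- tbl[[col]][tbl$label == cl]
    ks <- suppressWarnings(stats::ks.test(
      x, function(q) ptrunc(q, row$mean, row$sd, b[1], b[2])))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("the shipped statistics carry the flagged inconsistent entry", {
  s <- class_stats()
  flagged <- dplyr::filter(s, flagged)
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$class, "CARCINOMA_IN_SITU")
  expect_equal(flagged$feature, "cyto_perimeter")
  expect_equal(flagged$mean, 28)
  sup <- dplyr::filter(s, class == "SUPERFICIAL", feature == "nucleus_area")
  expect_equal(c(sup$mean, sup$sd), c(631, 206))
})

test_that("scenes are bit-identical under a seed and honour their manifest", {
  r <- scene_recipe(cells_per_class = c(SUPERFICIAL = 0, INTERMEDIATE = 0,
                                        COLUMNAR = 1, MILD = 1, MODERATE = 1,
                                        SEVERE = 0, CARCINOMA_IN_SITU = 1),
                    n_speck = 2, seed = 31)
  a <- render_scene(r)
  b <- render_scene(r)
  expect_identical(a$image, b$image)
  expect_identical(a$manifest, b$manifest)
  # specks sit below the lower area bound by construction
  specks <- dplyr::filter(a$manifest, kind == "speck")
  expect_true(all(specks$area_units < 625))
  # object map covers exactly the non-background ground truth
  expect_equal(a$object_map > 0,
               matrix(a$truth$labels != match("BACKGROUND", scene_classes),
                      nrow(a$object_map)))
  # manifest cell areas are consistent with the ground-truth label map
  cells <- dplyr::filter(a$manifest, is_cell)
  for (i in seq_len(nrow(cells))) {
    own <- a$object_map == cells$id[i]
    nuc <- own & a$truth$labels == match("NUCLEUS", scene_classes)
    expect_equal(sum(nuc) * a$area_factor, cells$nucleus_area[i])
  }
})

test_that("a debris-free recipe yields no rejections end to end", {
  sc <- render_scene(scene_recipe(cells_per_class = c(
    SUPERFICIAL = 0, INTERMEDIATE = 1, COLUMNAR = 1, MILD = 1,
    MODERATE = 1, SEVERE = 1, CARCINOMA_IN_SITU = 1), seed = 63))
  dr <- reject_debris(enhance(sc$gray), sc$truth,
                      debris_config(area_factor = sc$area_factor),
                      candidate_classes = c("NUCLEUS", "DEBRIS"))
  expect_equal(sum(dr$report$rejected), 0L)
})

test_that("manifest matching is one-to-one and distance-bounded", {
  sc <- small_scene()
  objs <- label_objects(sc$truth, area_factor = sc$area_factor)
  mi <- match_manifest(objs, sc$manifest)
  matched <- mi[!is.na(mi)]
  expect_equal(length(matched), length(unique(matched)))
  expect_equal(sort(matched), sort(sc$manifest$id[sc$manifest$is_cell]))
  expect_identical(match_manifest(list(), sc$manifest), integer(0))
})
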