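test_that("an analytic circle-in-disk cell yields the expected morphometry", {
  # nucleus: radius-10 disk at intensity 60 inside a radius-50 cytoplasm disk
  dim <- 120
  ctr <- c(60, 60)
  cyto_all <- papscreen:::ellipse_mask_idx(dim, dim, ctr, 50, 50, 0)
  nuc <- papscreen:::ellipse_mask_idx(dim, dim, ctr, 10, 10, 0)
  lab <- matrix(3L, dim, dim)
  lab[cyto_all] <- 2L
  lab[nuc] <- 1L
  img <- matrix(200, dim, dim)
  img[cyto_all] <- 130
  img[nuc] <- 60
  obj <- label_objects(label_map(lab))[[1]]
  f <- extract_features(img, obj)
  expect_equal(f$nucleus_area, 314, tolerance = 4 / 314)
  expect_lte(f$nucleus_eccentricity, 0.1)
  expect_gte(f$nucleus_elongation, 0.95)
  expect_equal(f$nucleus_mean, 60)
  expect_equal(f$nucleus_gray_level, 60)
  expect_equal(f$nucleus_variance, 0)
  expect_equal(f$nucleus_sd, 0)
  expect_equal(f$nucleus_entropy, 0)
  expect_equal(f$nucleus_energy, 1)
  expect_equal(f$nucleus_smoothness, 0)
  # nucleus centered in the cytoplasm: relative position ~ 0
  expect_lt(f$nucleus_relative_position, 0.02)
  expect_equal(f$nc_ratio, f$nucleus_area / (f$nucleus_area + f$cyto_area))
  expect_lte(f$nucleus_shortest_diameter, f$nucleus_longest_diameter)
  expect_lte(f$nucleus_roundness, 1)
  expect_lte(f$cyto_roundness, 1)
  expect_identical(names(f), feature_names)
})

test_that("a superficial-like rendered cell lands in the expected N/C band", {
  dim <- 360
  ctr <- c(180, 180)
  # nucleus area 631 px, whole cell 631 + 61487 px (class-typical values)
  rn <- sqrt(631 / pi)
  rc <- sqrt((631 + 61487) / pi)
  cell <- papscreen:::ellipse_mask_idx(dim, dim, ctr, rc, rc * 0.995, 0)
  nuc <- papscreen:::ellipse_mask_idx(dim, dim, ctr, rn, rn * 0.95, 0.3)
  lab <- matrix(3L, dim, dim)
  lab[cell] <- 2L
  lab[nuc] <- 1L
  img <- matrix(200, dim, dim); img[cell] <- 134; img[nuc] <- 66
  obj <- label_objects(label_map(lab))[[1]]
  f <- extract_features(img, obj)
  expect_lt(abs(f$nc_ratio - 0.01), 0.01)   # band 0.01 +- 0.01
})

test_that("histogram features depend only on the intensity multiset", {
  set.seed(11)
  d <- disk_object(12, dim = 40)
  vals <- runif(length(d$obj$nucleus_idx), 0, 255)
  img_a <- d$img
  img_a[d$obj$nucleus_idx] <- vals
  img_b <- d$img
  img_b[d$obj$nucleus_idx] <- sample(vals)
  fa <- extract_features(img_a, d$obj)
  fb <- extract_features(img_b, d$obj)
  for (col in c("nucleus_mean", "nucleus_sd", "nucleus_variance",
                "nucleus_entropy", "nucleus_energy", "nucleus_smoothness")) {
    expect_equal(fa[[col]], fb[[col]])
  }
})

test_that("a nucleus without cytoplasm gets sentinel features and N/C ratio 1", {
  d <- disk_object(8, dim = 30)
  f <- extract_features(d$img, d$obj)
  expect_equal(f$nc_ratio, 1)
  expect_true(is.na(f$cyto_area))
  expect_true(is.na(f$cyto_perimeter))
  bad <- d$obj
  bad$nucleus_idx <- integer(0)
  expect_error(extract_features(d$img, bad), "empty nucleus")
})

test_that("nucleus compactness agrees with the debris-gate descriptor", {
  d <- disk_object(15, dim = 50, ratio = 0.7)
  f <- extract_features(d$img, d$obj)
  expect_equal(f$nucleus_compactness, d$obj$compactness, tolerance = 1e-9)
})

test_that("extracted N/C ratios reproduce the class ordering on rendered cells", {
  counts <- c(SUPERFICIAL = 6, INTERMEDIATE = 6, COLUMNAR = 6, MILD = 0,
              MODERATE = 0, SEVERE = 0, CARCINOMA_IN_SITU = 6)
  sc <- render_scene(scene_recipe(cells_per_class = counts, seed = 55))
  objs <- label_objects(sc$truth, area_factor = sc$area_factor)
  ft <- extract_features_all(sc$gray, objs, sc$area_factor)
  mi <- match_manifest(objs, sc$manifest)
  kinds <- sc$manifest$kind[match(mi, sc$manifest$id)]
  m <- tapply(ft$nc_ratio, kinds, mean)
  expect_lt(m[["SUPERFICIAL"]], m[["INTERMEDIATE"]])
  expect_lt(m[["INTERMEDIATE"]], m[["COLUMNAR"]])
  expect_lt(m[["COLUMNAR"]], m[["CARCINOMA_IN_SITU"]])
})

test_that("the binary diagnosis maps all seven classes onto normal/abnormal", {
  expect_equal(as.character(binary_label("SUPERFICIAL")), "NORMAL")
  expect_equal(as.character(binary_label("INTERMEDIATE")), "NORMAL")
  expect_equal(as.character(binary_label("COLUMNAR")), "NORMAL")
  expect_equal(as.character(binary_label(cell_classes[4:7])),
               rep("ABNORMAL", 4))
  expect_error(binary_label("BASAL"), "unknown")
})

test_that("feature tables round-trip through CSV with exact header validation", {
  tbl <- gen_feature_table(3, seed = 2)
  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tbl, p)
  back <- read_feature_table(p)
  expect_equal(as.data.frame(back[feature_names]), as.data.frame(tbl[feature_names]),
               tolerance = 1e-12)
  expect_identical(as.character(back$label), as.character(tbl$label))
  bad <- dplyr::rename(tbl, area = nucleus_area)
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, p2, row.names = FALSE)
  expect_error(read_feature_table(p2), "header")
})
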