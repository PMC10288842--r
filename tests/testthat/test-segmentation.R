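make_vol <- function(arr, spacing = c(2, 2, 2)) pet_volume(arr, spacing)

test_that("segmentation threshold is 1.5 * liver mean + 2 * liver SD", {
  expect_equal(segmentation_threshold(4.41, 1.14), 8.895)
  expect_equal(segmentation_threshold(0, 0), 0)
  expect_equal(segmentation_threshold(2, 0), 3.0)
  ref <- tibble::tibble(label = "liver", suv_mean = 4.41, suv_max = 6,
    suv_sd = 1.14, n_voxels = 600, sd_type = "sample")
  expect_equal(segmentation_threshold(ref), 8.895)
  expect_error(segmentation_threshold(-1, 1), class = "mtvsurv_invalid_argument")
})

test_that("a volume entirely below threshold yields an empty segmentation", {
  vol <- make_vol(array(4, dim = c(10, 10, 10)))
  seg <- segment_mtv(vol, 8.895)
  expect_equal(total_mtv(seg), 0)
  expect_equal(nrow(seg$lesions), 0)
  expect_error(largest_lesion_metrics(seg),
    class = "mtvsurv_empty_segmentation")
})

test_that("voxels at exactly the threshold stay background", {
  vol <- make_vol(array(8.895, dim = c(5, 5, 5)))
  expect_equal(total_mtv(segment_mtv(vol, 8.895)), 0)
  vol2 <- make_vol(array(8.896, dim = c(5, 5, 5)))
  expect_gt(total_mtv(segment_mtv(vol2, 8.895)), 0)
})

test_that("a digital 25 mm sphere is recovered within the surface-shell bound", {
  ph <- generate_phantom(single_lesion_config(seed = 2))
  seg <- segment_mtv(ph$volume, 8.895, exclusion_mask = ph$exclusion_mask,
    min_lesion_ml = 0.5)
  expect_equal(nrow(seg$lesions), 1)
  true_vol <- 4 / 3 * pi * 2.5^3 # 65.45 ml
  expect_lt(abs(total_mtv(seg) - true_vol) / true_vol, 0.10)
  lm <- largest_lesion_metrics(seg)
  expect_equal(lm$suv_max, 12)
  expect_equal(lm$suv_mean, 12)
})

test_that("a hot sphere inside the exclusion mask is dropped and counted", {
  cfg <- phantom_config(
    lesions = data.frame(x = 90, y = 64, z = 64, radius_mm = 25, suv = 12),
    physiological = data.frame(x = 30, y = 30, z = 30, radius_mm = 10, suv = 20),
    seed = 2)
  ph <- generate_phantom(cfg)
  with_excl <- segment_mtv(ph$volume, 8.895, exclusion_mask = ph$exclusion_mask,
    min_lesion_ml = 0.5)
  expect_equal(with_excl$excluded_component_count, 1)
  without <- segment_mtv(ph$volume, 8.895, min_lesion_ml = 0.5)
  expect_equal(nrow(without$lesions), 2)
  # the retained tumor volume is unchanged by the exclusion
  expect_equal(total_mtv(with_excl), max(without$lesions$volume_ml))
})

test_that("an exclusion mask disjoint from all hot voxels changes nothing", {
  ph <- generate_phantom(single_lesion_config(seed = 3))
  excl <- array(FALSE, dim = dim(ph$volume))
  excl[1:5, 1:5, 1:5] <- TRUE
  a <- segment_mtv(ph$volume, 8.895)
  b <- segment_mtv(ph$volume, 8.895, exclusion_mask = excl)
  expect_equal(a$lesions, b$lesions)
  expect_equal(b$excluded_component_count, 0)
})

test_that("raising the threshold never increases the total MTV", {
  ph <- generate_phantom(single_lesion_config(seed = 4, noise_sd = 0.5))
  thresholds <- c(6, 8, 8.895, 10, 11.5, 12.5)
  mtvs <- vapply(thresholds, function(th) total_mtv(segment_mtv(ph$volume, th)),
    numeric(1))
  expect_true(all(diff(mtvs) <= 0))
})

test_that("MTV is additive over disjoint lesions", {
  one <- phantom_config(lesions = data.frame(x = 40, y = 64, z = 64,
    radius_mm = 12, suv = 12), seed = 5)
  other <- phantom_config(lesions = data.frame(x = 95, y = 64, z = 64,
    radius_mm = 18, suv = 14), seed = 5)
  both <- phantom_config(lesions = data.frame(
    x = c(40, 95), y = c(64, 64), z = c(64, 64),
    radius_mm = c(12, 18), suv = c(12, 14)), seed = 5)
  m1 <- total_mtv(segment_mtv(generate_phantom(one)$volume, 8.895,
    min_lesion_ml = 0.5))
  m2 <- total_mtv(segment_mtv(generate_phantom(other)$volume, 8.895,
    min_lesion_ml = 0.5))
  m12 <- total_mtv(segment_mtv(generate_phantom(both)$volume, 8.895,
    min_lesion_ml = 0.5))
  expect_equal(m12, m1 + m2)
})

test_that("component labeling agrees with a brute-force flood fill", {
  set.seed(42)
  for (rep in 1:5) {
    dims <- c(sample(6:12, 1), sample(6:12, 1), sample(6:12, 1))
    arr <- array(ifelse(runif(prod(dims)) < 0.2, 10, 1), dim = dims)
    vol <- make_vol(arr)
    for (conn in c(26, 6)) {
      seg <- segment_mtv(vol, 5, connectivity = conn)
      oracle <- flood_fill_components(arr > 5, connectivity = conn)
      expect_equal(nrow(seg$lesions), max(oracle))
      # identical partitions up to relabeling: the label pairing over
      # foreground voxels must be one-to-one
      fg <- which(arr > 5)
      lab_pkg <- seg$labels[fg]
      lab_orc <- oracle[fg]
      expect_equal(length(unique(paste(lab_pkg, lab_orc))), max(oracle))
      expect_setequal(
        sort(as.vector(table(lab_pkg))), sort(as.vector(table(lab_orc))))
    }
  }
})

test_that("largest lesion is selected by volume with a documented tie-break", {
  vol <- make_vol(array(1, dim = c(20, 20, 20)))
  vol[2:3, 2:3, 2:3] <- 20          # 8 voxels, SUVmax 20
  vol[10:13, 10:13, 10:13] <- 15    # 64 voxels, SUVmax 15
  seg <- segment_mtv(vol, 8.895)
  lm <- largest_lesion_metrics(seg)
  expect_equal(lm$suv_max, 15)
  expect_equal(lm$volume_ml, 64 * voxel_volume_ml(vol))

  # equal volumes: higher SUVmax wins
  vol2 <- make_vol(array(1, dim = c(20, 20, 20)))
  vol2[2:3, 2:3, 2:3] <- 18
  vol2[10:11, 10:11, 10:11] <- 25
  lm2 <- largest_lesion_metrics(segment_mtv(vol2, 8.895))
  expect_equal(lm2$suv_max, 25)
})

test_that("min_lesion_ml filters small components", {
  vol <- make_vol(array(1, dim = c(20, 20, 20)))
  vol[2, 2, 2] <- 20                 # 0.008 ml speck
  vol[10:13, 10:13, 10:13] <- 15
  seg <- segment_mtv(vol, 8.895, min_lesion_ml = 0.1)
  expect_equal(nrow(seg$lesions), 1)
  expect_equal(seg$lesions$suv_max, 15)
})

test_that("grid mismatch between volume and exclusion mask is a shape error", {
  vol <- make_vol(array(1, dim = c(5, 5, 5)))
  expect_error(segment_mtv(vol, 3, exclusion_mask = array(TRUE, dim = c(4, 5, 5))),
    class = "mtvsurv_shape_error")
})

test_that("tidy and glance expose the lesion table and summary", {
  ph <- generate_phantom(single_lesion_config(seed = 6))
  seg <- segment_mtv(ph$volume, 8.895)
  expect_named(tidy(seg),
    c("lesion_id", "n_voxels", "volume_ml", "suv_max", "suv_mean"))
  g <- glance(seg)
  expect_equal(g$total_mtv_ml, total_mtv(seg))
  expect_equal(g$threshold, 8.895)
})
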