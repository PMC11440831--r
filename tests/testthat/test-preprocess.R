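test_that("body mask rejects an all-air volume and covers the trunk", {
  air <- ct_volume(array(-1000, c(10, 10, 10)), c(4, 4, 4))
  expect_error(body_mask(air), "degenerate")

  ph <- generate_phantom(flat_spec(seed = 3L), return_construction = TRUE)
  mask <- body_mask(ph$volume, preprocess_preset("desk"))
  # every constructed trunk voxel (soft tissue + bone, lungs excluded)
  # must be inside the mask
  expect_true(all(mask[ph$construction$body]))
})

test_that("a detached high-HU artifact is excluded by the largest-component rule", {
  ph <- generate_phantom(small_spec(seed = 4L))
  v <- ph$volume$voxels
  v[1:3, 1:2, 1:2] <- 500  # scanner-table-like block in a far corner
  vol <- ct_volume(v, ph$volume$spacing_mm)
  mask <- body_mask(vol, preprocess_preset("desk"))
  expect_false(any(mask[1:2, 1, 1]))
})

test_that("coronal max projection equals a naive triple-loop recomputation", {
  set.seed(10)
  v <- array(sample(-1000:1000, 12 * 9 * 7, TRUE), c(12, 9, 7))
  vol <- ct_volume(v, c(2, 1, 1))
  mask <- array(runif(length(v)) > 0.3, dim(v))
  proj <- coronal_max_projection(vol, mask)
  naive <- matrix(NA_real_, 12, 7)
  for (z in 1:12) for (x in 1:7) {
    best <- -1000  # background value stands in for fully masked rays
    for (y in 1:9) if (mask[z, y, x] && v[z, y, x] > best) best <- v[z, y, x]
    naive[z, x] <- best
  }
  expect_equal(proj$image, naive, ignore_attr = TRUE)
})

test_that("single bright voxel and fully masked volumes project as defined", {
  v <- array(-1000, c(6, 5, 4))
  v[3, 2, 4] <- 1000
  vol <- ct_volume(v, c(1, 1, 1))
  proj <- coronal_max_projection(vol)
  expect_equal(proj$image[3, 4], 1000)
  expect_equal(sum(proj$image != -1000), 1)

  masked <- coronal_max_projection(vol, array(FALSE, dim(v)))
  expect_true(all(masked$image == -1000))
})

test_that("pre-crop only fires beyond the 20 cm centroid rule", {
  cfg <- preprocess_preset("desk")
  # centroids < 20 cm apart: volume must come back untouched
  near <- generate_phantom(short_spec(seed = 5L))
  res <- precrop(near$volume, cfg)
  expect_false(res$cropped)
  expect_identical(res$volume$voxels, near$volume$voxels)
  expect_equal(res$crop_offset_mm, 0)
  expect_lte(abs(res$lung_z_mm - res$pelvis_z_mm), 200)

  # centroids ~ 29 cm apart: cropped, with the caudal cut as the offset
  far <- generate_phantom(phantom_spec(seed = 5L))
  res2 <- precrop(far$volume, cfg)
  expect_true(res2$cropped)
  expect_lt(dim(res2$volume$voxels)[1], dim(far$volume$voxels)[1])
  expect_gt(res2$crop_offset_mm, 0)
  expect_equal(res2$crop_offset_mm %% far$volume$spacing_mm[1], 0)
  # the L3 slice must survive the crop
  kept <- res2$crop_offset_mm / far$volume$spacing_mm[1] +
    seq_len(dim(res2$volume$voxels)[1]) - 1
  expect_true(far$truth$l3_slice_index %in% kept)
})

test_that("estimated centroids sit within 10 mm of the construction", {
  for (seed in c(6L, 7L)) {
    ph <- generate_phantom(phantom_spec(seed = seed))
    res <- precrop(ph$volume, preprocess_preset("desk"))
    expect_lt(abs(res$lung_z_mm - ph$truth$lung_z_mm), 10)
    expect_lt(abs(res$pelvis_z_mm - ph$truth$pelvis_z_mm), 10)
  }
})

test_that("precrop falls back with a warning when lungs are missing", {
  ph <- generate_phantom(small_spec(seed = 8L), return_construction = TRUE)
  v <- ph$volume$voxels
  v[ph$construction$tissue == 1L] <- 40  # fill the lungs with soft tissue
  vol <- ct_volume(v, ph$volume$spacing_mm)
  expect_warning(res <- precrop(vol, preprocess_preset("desk")),
                 "not found")
  expect_false(res$cropped)
})

test_that("standardization rescales rows to 1 mm and pads to 1064 x 512", {
  set.seed(11)
  raw <- list(image = matrix(runif(200 * 300, -500, 500), 200, 300),
              spacing_z_mm = 2, spacing_x_mm = 1, crop_offset_mm = 0,
              original_n_slices = 200L)
  cfg <- preprocess_config()  # full-scale profile
  proj <- standardize(raw, cfg)
  expect_equal(dim(proj$image), c(1064, 512))
  expect_equal(proj$provenance$n_rows_scaled, 400)  # 200 rows at 2 mm
  expect_equal(proj$provenance$row_scale, 2)
  # padded regions are exactly the background value
  expect_true(all(proj$image[1:proj$provenance$pad_top_rows, ] == -1000))
  expect_true(all(proj$image[, 1:proj$provenance$pad_left_cols] == -1000))

  # an image already at 1064 x 512 and 1 mm passes through unchanged,
  # apart from the 1088-row network pad
  raw2 <- list(image = matrix(runif(1064 * 512), 1064, 512),
               spacing_z_mm = 1, spacing_x_mm = 1, crop_offset_mm = 0,
               original_n_slices = 1064L)
  proj2 <- standardize(raw2, cfg)
  expect_identical(proj2$image, raw2$image)
  expect_equal(proj2$provenance$pad_top_rows, 0)
  net <- pad_for_network(proj2, cfg)
  expect_equal(dim(net$image), c(1088, 512))
  expect_equal(net$provenance$pad_top_rows, 12)
  expect_true(all(net$image[1:12, ] == -1000))
})

test_that("standardization preserves marked z positions to half a row", {
  for (sz in c(1, 2.5, 5)) {
    n <- round(400 / sz)
    img <- matrix(-1000, n, 40)
    k <- round(n * 0.6)
    img[k, ] <- 1000  # marked slice (0-based index k - 1)
    raw <- list(image = img, spacing_z_mm = sz, spacing_x_mm = 6,
                crop_offset_mm = 0, original_n_slices = n)
    cfg <- preprocess_config(row_mm = 1, target_rows = 512,
                             target_cols = 64, net_rows = 512)
    proj <- standardize(raw, cfg)
    r_star <- which.max(proj$image[, 30]) - 1
    z_star <- row_to_z_mm(r_star, proj$provenance)
    expect_lte(abs(z_star - (k - 1) * sz), 0.5 + 1e-9)
  }
})

test_that("row/slice mapping is the identity across spacing, pad and crop", {
  for (sz in c(1, 2.5, 5)) {
    for (pad in c(0L, 12L)) {
      for (off in c(0, 15 * sz)) {
        prov <- list(row_mm = 1, row_scale = sz, spacing_z_mm = sz,
                     crop_offset_mm = off, pad_top_rows = pad,
                     pad_left_cols = 0, original_n_slices = 200L)
        idx <- 0:80
        back <- row_to_slice_index(slice_index_to_row(idx, prov), prov)
        expect_identical(back, as.integer(idx))
      }
    }
  }
})

test_that("the L3 target band is 10 rows wide, full width, clipped at borders", {
  prov <- list(row_mm = 1, row_scale = 1, spacing_z_mm = 1,
               crop_offset_mm = 0, pad_top_rows = 0, pad_left_cols = 0,
               original_n_slices = 1064L)
  m <- make_l3_target(500, prov, c(1064, 512))
  expect_equal(sum(m), 10 * 512)
  on_rows <- which(rowSums(m) > 0) - 1
  expect_equal(on_rows, 496:505)  # rows r-4 .. r+5 around the annotation
  expect_true(all(m[on_rows + 1, ] == 1))

  expect_warning(clipped <- make_l3_target(2, prov, c(1064, 512)),
                 "clipped")
  expect_equal(sort(unique(which(rowSums(clipped) > 0) - 1)), 0:7)

  # at 2 mm rows the 1 cm band is 5 rows
  prov2 <- list(row_mm = 2, row_scale = 2, spacing_z_mm = 4,
                crop_offset_mm = 0, pad_top_rows = 0, pad_left_cols = 0,
                original_n_slices = 100L)
  m2 <- make_l3_target(200, prov2, c(208, 32))
  expect_equal(sum(m2), 5 * 32)
})

test_that("identity augmentation returns the batch unchanged", {
  set.seed(12)
  imgs <- list(matrix(runif(40 * 30, -500, 500), 40, 30))
  tgts <- list(matrix(sample(0:4, 40 * 30, TRUE), 40, 30))
  cfg <- augment_config(rotate_deg = c(0, 0), scale = c(1, 1),
                        translate_px = c(0, 0), elastic_alpha = 0,
                        arm_prob = 0)
  out <- augment_batch(imgs, tgts, cfg, seed = 1L)
  expect_identical(out$images[[1]], imgs[[1]])
  expect_identical(out$targets[[1]], tgts[[1]])
})

test_that("augmentation is deterministic and transforms pairs jointly", {
  ph <- generate_l3_sample(small_spec(seed = 13L))
  imgs <- list(ph$hu * 1.0)
  tgts <- list(ph$labels$labels * 1.0)
  cfg <- augment_config(rotate_deg = c(-10, 10), scale = c(0.9, 1.1),
                        translate_px = c(-5, 5), elastic_alpha = 2)
  a <- augment_batch(imgs, tgts, cfg, seed = 7L)
  b <- augment_batch(imgs, tgts, cfg, seed = 7L)
  expect_identical(a, b)
  c <- augment_batch(imgs, tgts, cfg, seed = 8L)
  expect_false(identical(a$images[[1]], c$images[[1]]))
  # a pure integer translation moves image and target identically
  cfg_t <- augment_config(rotate_deg = c(0, 0), scale = c(1, 1),
                          translate_px = c(3, 3), elastic_alpha = 0)
  d <- augment_batch(imgs, tgts, cfg_t, seed = 1L)
  nr <- nrow(imgs[[1]]); nc <- ncol(imgs[[1]])
  expect_equal(d$images[[1]][4:nr, 4:nc],
               imgs[[1]][1:(nr - 3), 1:(nc - 3)] * 1.0, ignore_attr = TRUE)
  expect_equal(d$targets[[1]][4:nr, 4:nc],
               tgts[[1]][1:(nr - 3), 1:(nc - 3)] * 1.0, ignore_attr = TRUE)
})

test_that("inserted arm pixels lie outside the body and in soft-tissue HU", {
  ph <- generate_l3_sample(phantom_spec(seed = 14L))
  img <- ph$hu * 1.0
  cfg <- augment_config(rotate_deg = c(0, 0), scale = c(1, 1),
                        translate_px = c(0, 0), elastic_alpha = 0,
                        arm_prob = 1)
  out <- augment_batch(list(img), list(img * 0), cfg, seed = 3L)
  aug <- out$images[[1]]
  changed <- which(aug != img)
  expect_gt(length(changed), 0)
  body <- bodycomp:::largest_component(img > -200)
  # pixel-by-pixel: no painted pixel inside the pre-insertion body mask,
  # every painted value inside the muscle soft-tissue window
  expect_true(all(!body[changed]))
  expect_true(all(aug[changed] >= -29 & aug[changed] <= 150))
})

test_that("degenerate augmentation ranges are rejected", {
  expect_error(augment_config(scale = c(0, 1)), "scale")
  expect_error(augment_config(arm_prob = 2), "arm_prob")
})
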