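test_that("dice coefficient matches its closed forms and conventions", {
  a <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 2)
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, 1 - a), 0)
  b <- matrix(c(1, 1, 0, 0, 1, 1, 0, 0), 2)  # |A|=|B|=4, overlap 2
  expect_equal(dice_coefficient(a, b), 0.5)
  z <- matrix(0, 2, 4)
  expect_equal(dice_coefficient(z, z), 1)  # empty-vs-empty convention
  expect_error(dice_coefficient(a, matrix(0, 3, 3)), "shape")
})

test_that("dice coefficient is symmetric and complements the dice loss", {
  set.seed(30)
  for (i in 1:5) {
    a <- matrix(runif(36) > 0.5, 6) * 1
    b <- matrix(runif(36) > 0.5, 6) * 1
    expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
    expect_equal(dice_loss(a, b, smooth = 0), 1 - dice_coefficient(a, b))
  }
})

test_that("agreement statistics match independent arithmetic", {
  t <- 1:10
  expect_equal(agreement_stats(t, t), c(mae = 0, mape = 0, r2 = 1))
  expect_equal(agreement_stats(t + 1, t)[["mae"]], 1)
  set.seed(31)
  p <- runif(20, 10, 50); tr <- runif(20, 10, 50)
  got <- agreement_stats(p, tr)
  # brute-force oracle, written out elementwise
  abs_err <- 0; pct <- 0; ssr <- 0; sst <- 0; mu <- sum(tr) / 20
  for (i in 1:20) {
    abs_err <- abs_err + abs(p[i] - tr[i]) / 20
    pct <- pct + 100 * abs(p[i] - tr[i]) / tr[i] / 20
    ssr <- ssr + (p[i] - tr[i])^2
    sst <- sst + (tr[i] - mu)^2
  }
  expect_equal(unname(got), c(abs_err, pct, 1 - ssr / sst),
               tolerance = 1e-12)
  expect_error(agreement_stats(1:3, c(1, 0, 2)), "MAPE")
  expect_error(agreement_stats(1:3, c(2, 2, 2)), "variance")
  expect_error(agreement_stats(1, 1), "at least 2")
})

test_that("areas scale with pixel size", {
  lab <- matrix(0L, 20, 20); lab[1:10, 1:10] <- 2L
  lm1 <- tissue_label_map(lab, c(1, 1))
  expect_equal(area_cm2(lm1, "SM"), 1)          # 100 px at 1 mm^2
  lm2 <- tissue_label_map(lab, c(2, 2))
  expect_equal(area_cm2(lm2, "SM"), 4)
  expect_equal(area_cm2(lm2, "VAT"), 0)
  expect_error(area_cm2(lm2, "bone"), "unknown")
})

test_that("SMD averages HU inside the muscle window only", {
  hu <- matrix(c(0, 50, 100, 200), 2)
  mask <- matrix(1, 2, 2)
  expect_equal(smd(hu, mask), 50)  # 200 excluded by the window
  hu2 <- matrix(c(0, 50, 100, -10), 2)
  expect_equal(smd(hu2, mask), 35)
  expect_error(smd(matrix(-30, 2, 2), mask), "undefined")
})

test_that("SMI, SMG and LBM are the exact closed forms", {
  expect_equal(smi(120, 1.0), 120)
  expect_equal(smi(120, 2.0), 30)
  expect_error(smi(120, 0), "height")
  expect_equal(smg(40, 35), 1400)
  expect_equal(smg(40, 0), 0)
  expect_equal(lbm(0), 6.06)
  expect_equal(lbm(100), 36.06)
  expect_error(lbm(-1), "negative")
  areas <- seq(0, 300, by = 50)
  expect_true(all(diff(lbm(areas)) > 0))  # strictly increasing
})

test_that("correct-slice rate counts the tolerance window", {
  expect_equal(correct_slice_rate(c(1, 2, 3, 4), c(3, 4, 1, 2), 20), 1)
  expect_equal(correct_slice_rate(c(0, 0, 0, 30), c(0, 5, 10, 0), 20),
               0.75)
  expect_equal(correct_slice_rate(c(10, 12), c(10, 13), 0), 0.5)
  expect_error(correct_slice_rate(1:3, 1:2), "unmatched")
})

test_that("sarcopenia reports assemble all quantities with units", {
  s <- generate_l3_sample(small_spec(seed = 50L))
  rep <- build_report(s$hu, s$labels, height_m = 1.6)
  px_cm2 <- prod(s$labels$spacing_mm) / 100
  expect_equal(rep$area_sm_cm2,
               sum(s$labels$labels == 2L) * px_cm2)
  expect_equal(rep$lbm_kg, 0.3 * rep$area_sm_cm2 + 6.06)
  expect_equal(rep$smi_cm2_m2, rep$area_sm_cm2 / 1.6^2)
  expect_equal(rep$smg_hu_cm2_m2, rep$smi_cm2_m2 * rep$smd_hu)
  # area mode multiplies the raw area instead of the index
  rep2 <- build_report(s$hu, s$labels, height_m = 1.6, smg_mode = "area")
  expect_equal(rep2$smg_hu_cm2_m2, rep2$area_sm_cm2 * rep2$smd_hu)
  # no height: SMI/SMG undefined, the rest intact
  rep3 <- build_report(s$hu, s$labels)
  expect_true(is.na(rep3$smi_cm2_m2))
  expect_equal(rep3$area_sm_cm2, rep$area_sm_cm2)
})

make_items <- function(seeds, perturb = 0L) {
  # body-size jitter so the derived quantities vary across the cohort
  specs <- cohort_specs(length(seeds), small_spec(),
                        variability = list(body_scale = c(0.85, 1.1)),
                        seed = seeds[1])
  lapply(specs, function(sp) {
    s <- generate_l3_sample(sp)
    pred <- s$labels
    if (perturb > 0) {
      lab <- pred$labels
      idx <- which(lab == 2L)[seq_len(perturb)]
      lab[idx] <- 3L
      pred <- tissue_label_map(lab, pred$spacing_mm)
    }
    list(pred_z_mm = s$l3_z_mm + perturb, true_z_mm = s$l3_z_mm,
         pred_labels = pred, true_labels = s$labels, slice_hu = s$hu,
         height_m = s$height_m)
  })
}

test_that("perfect predictions evaluate to DICE 1, MAE 0, R^2 1", {
  summ <- evaluate_cohort(make_items(60:64))
  expect_equal(summ$l3$mae_mm, 0)
  expect_equal(summ$l3$correct_rate, 1)
  expect_true(all(summ$dice$median == 1))
  expect_true(all(summ$agreement$mae == 0))
  expect_true(all(summ$agreement$r2[!is.na(summ$agreement$r2)] == 1))
})

test_that("cohort evaluation is permutation invariant", {
  items <- make_items(60:64, perturb = 10L)
  a <- evaluate_cohort(items)
  b <- evaluate_cohort(rev(items))
  expect_equal(a$l3, b$l3)
  expect_equal(a$dice, b$dice)
  expect_equal(a$agreement, b$agreement)
})

test_that("a single-item cohort reports R^2 as undefined", {
  summ <- evaluate_cohort(make_items(70L))
  expect_true(all(is.na(summ$agreement$r2)))
  expect_false(any(is.na(summ$agreement$mae)))
})

test_that("cohort summaries match a hand recomputation on a 5-item fixture", {
  items <- make_items(60:64, perturb = 25L)
  summ <- evaluate_cohort(items)
  # recompute SM-area agreement with plain arithmetic
  px_cm2 <- prod(items[[1]]$true_labels$spacing_mm) / 100
  p <- sapply(items, function(it) sum(it$pred_labels$labels == 2) * px_cm2)
  t <- sapply(items, function(it) sum(it$true_labels$labels == 2) * px_cm2)
  row <- summ$agreement[summ$agreement$quantity == "SM area (cm^2)", ]
  expect_equal(row$mae, mean(abs(p - t)))
  expect_equal(row$mape, 100 * mean(abs(p - t) / t))
  expect_equal(row$r2, 1 - sum((p - t)^2) / sum((t - mean(t))^2))
  # L3 block: every prediction is off by exactly 25 mm
  expect_equal(summ$l3$mae_mm, 25)
  expect_equal(summ$l3$correct_rate, 0)
  # SM dice by hand on item 1
  it <- items[[1]]
  inter <- sum(it$pred_labels$labels == 2 & it$true_labels$labels == 2)
  d1 <- 2 * inter / (sum(it$pred_labels$labels == 2) +
                       sum(it$true_labels$labels == 2))
  d_all <- sapply(items, function(i2)
    dice_coefficient(i2$pred_labels$labels == 2,
                     i2$true_labels$labels == 2))
  expect_equal(d_all[1], d1)
  expect_equal(summ$dice$median[summ$dice$class == "SM"], median(d_all))
})
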