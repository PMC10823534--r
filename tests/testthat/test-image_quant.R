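test_that("bimodal images threshold between the modes", {
  set.seed(1)
  ch <- matrix(0.1, 40, 50)
  ch[sample(2000, 200)] <- 0.9          # 10% bright
  seg <- multi_threshold(ch, 2)
  expect_gt(seg$thresholds[1], 0.1)
  expect_lt(seg$thresholds[1], 0.9)
  expect_equal(mean(seg$mask), 0.1)
})

test_that("a constant channel yields an empty mask with a warning", {
  expect_warning(seg <- multi_threshold(matrix(0.4, 10, 10), 2),
                 "constant")
  expect_false(any(seg$mask))
  expect_equal(vessel_density(seg), 0)
})

test_that("multi-Otsu equals the exhaustive-search oracle", {
  set.seed(47)
  for (nc in 2:3) {
    for (rep in 1:3) {
      # mixture of 2-3 intensity populations + noise
      ch <- matrix(sample(c(rnorm(400, 0.2, 0.05), rnorm(300, 0.5, 0.05),
                            rnorm(300, 0.8, 0.05))), 25, 40)
      ch <- pmin(pmax(ch, 0), 1)
      seg <- multi_threshold(ch, nc)
      orc <- oracle_multiotsu(ch, nc)
      got_cuts <- round(seg$thresholds * 256) - 1
      expect_equal(orc$score(got_cuts), orc$best, tolerance = 1e-12,
                   label = sprintf("nc=%d rep=%d", nc, rep))
    }
  }
})

test_that("2-class Otsu agrees with an established implementation", {
  skip_if_not_installed("EBImage")
  set.seed(13)
  ch <- matrix(pmin(pmax(c(rnorm(700, 0.25, 0.08),
                           rnorm(300, 0.75, 0.08)), 0), 1), 25, 40)
  seg <- multi_threshold(ch, 2)
  ref <- EBImage::otsu(EBImage::Image(ch), range = c(0, 1), levels = 256)
  # equivalent thresholds can sit anywhere on an empty-bin plateau, so
  # compare the induced masks rather than the cut values
  expect_identical(seg$mask, ch > ref)
})

test_that("vessel density is the foreground percentage", {
  expect_equal(vessel_density(matrix(TRUE, 5, 5)), 100)
  expect_equal(vessel_density(matrix(FALSE, 5, 5)), 0)
  m <- matrix(FALSE, 10, 10); m[1:25] <- TRUE
  expect_equal(vessel_density(m), 25)
})

test_that("components are 8-connected and filtered by area", {
  m <- matrix(FALSE, 10, 10)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE       # touch diagonally: one block
  lab <- label_components(m)
  expect_equal(max(lab), 1)
  m[9:10, 9:10] <- TRUE                  # separate 4-pixel block
  expect_equal(max(label_components(m)), 2)

  b <- matrix(FALSE, 10, 10); b[1, 1] <- TRUE
  expect_equal(count_overlap_blocks(m, b, min_block_px = 1), 1)
  # the overlapping diagonal pair has only 2 px: filtered at min 3
  expect_equal(count_overlap_blocks(m, b, min_block_px = 3), 0)
  none <- matrix(FALSE, 10, 10); none[5, 5] <- TRUE
  expect_equal(count_overlap_blocks(m, none, min_block_px = 1), 0)
})

test_that("planted nucleus/vessel overlap counts are exact at zero noise", {
  syn <- synthesize_fluor_image(width = 320, height = 240, n_vessels = 3,
                                n_nuclei = 25, frac_ec = 0.6,
                                noise_sd = 0, seed = 47)
  g <- multi_threshold(syn$image$green, 2)
  b <- multi_threshold(syn$image$blue, 2)
  expect_equal(count_overlap_blocks(b, g), syn$truth$n_ec_nuclei)
  expect_equal(vessel_density(g), syn$truth$vessel_density_pct)
})

test_that("Ki67 fractions are recovered exactly on clean scenes", {
  syn <- synthesize_fluor_image(width = 320, height = 240, n_vessels = 3,
                                n_nuclei = 24, frac_ec = 0.5,
                                frac_positive = 0.25, noise_sd = 0,
                                seed = 53)
  met <- image_metrics(syn$image)
  expect_equal(met$n_ec_nuclei, syn$truth$n_ec_nuclei)
  expect_equal(met$n_ki67_pos_ec, syn$truth$n_positive)
  expect_equal(met$ki67_pct,
               100 * syn$truth$n_positive / syn$truth$n_ec_nuclei)

  # no red signal: 0 positives (constant channel warns)
  syn0 <- synthesize_fluor_image(width = 320, height = 240,
                                 n_vessels = 3, n_nuclei = 20,
                                 frac_ec = 0.5, frac_positive = 0,
                                 noise_sd = 0, seed = 54)
  met0 <- suppressWarnings(image_metrics(syn0$image))
  expect_equal(met0$ki67_pct, 0)

  # all EC nuclei positive: 100%
  syn1 <- synthesize_fluor_image(width = 320, height = 240,
                                 n_vessels = 3, n_nuclei = 20,
                                 frac_ec = 0.5, frac_positive = 1,
                                 noise_sd = 0, seed = 55)
  met1 <- image_metrics(syn1$image)
  expect_equal(met1$ki67_pct, 100)
})

test_that("mean intensity over a mask matches a loop oracle", {
  mask <- matrix(FALSE, 8, 8); mask[3:5, 2:6] <- TRUE
  expect_equal(mean_intensity_over_mask(matrix(0.4, 8, 8), mask), 0.4)
  expect_equal(mean_intensity_over_mask(matrix(0, 8, 8), mask), 0)
  set.seed(59)
  ch <- matrix(runif(64), 8, 8)
  acc <- 0; n <- 0
  for (i in 1:8) for (j in 1:8) if (mask[i, j]) {
    acc <- acc + ch[i, j]; n <- n + 1
  }
  expect_equal(mean_intensity_over_mask(ch, mask), acc / n,
               tolerance = 1e-12)
  expect_warning(out <- mean_intensity_over_mask(ch, matrix(FALSE, 8, 8)),
                 "empty")
  expect_true(is.na(out))
})

test_that("the PLVAP composite amplifies and gates red by green", {
  set.seed(61)
  green <- matrix(0.05, 30, 30); green[10:20, ] <- 0.6
  red <- matrix(runif(900) * 0.4, 30, 30)
  blue <- matrix(0.1, 30, 30)
  img <- fluor_image(red, green, blue, red_role = "PLVAP")
  comp <- plvap_composite(img, amplification = 2)
  g_mask <- multi_threshold(green, 2)$mask
  want_red <- pmin(red * 2, 1) * g_mask
  expect_equal(comp$red, want_red, tolerance = 1e-12)
  expect_equal(comp$green, pmin(green * 2, 1))
  expect_identical(comp$blue, blue)
  expect_true(all(comp$red[!g_mask] == 0))
  # amplification 1 with red inside green: red unchanged there
  comp1 <- plvap_composite(img, amplification = 1)
  expect_equal(comp1$red[g_mask], red[g_mask])
})

test_that("metrics are invariant under a toroidal shift of a scene", {
  # content placed away from borders so the shift never wraps content
  g <- matrix(0.05, 60, 60); g[20:30, 10:50] <- 0.8
  b <- matrix(0.05, 60, 60); b[22:26, 15:19] <- 0.85
  r <- matrix(0.02, 60, 60); r[23:25, 16:18] <- 0.9
  img <- fluor_image(r, g, b)
  met <- image_metrics(img, min_block_px = 5, n_classes_nuclei = 2)
  shift <- function(m, dr, dc) {
    m[c((61 - dr):60, 1:(60 - dr)), c((61 - dc):60, 1:(60 - dc))]
  }
  img_s <- fluor_image(shift(r, 7, 4), shift(g, 7, 4), shift(b, 7, 4))
  met_s <- image_metrics(img_s, min_block_px = 5, n_classes_nuclei = 2)
  expect_equal(met_s, met)
})

test_that("image synthesis is deterministic and truth-consistent", {
  a <- synthesize_fluor_image(width = 200, height = 150, n_vessels = 2,
                              n_nuclei = 12, noise_sd = 0.03, seed = 9)
  b <- synthesize_fluor_image(width = 200, height = 150, n_vessels = 2,
                              n_nuclei = 12, noise_sd = 0.03, seed = 9)
  expect_identical(a$image$green, b$image$green)
  expect_identical(a$truth$centers, b$truth$centers)
  expect_equal(a$truth$n_ec_nuclei, sum(a$truth$on_vessel))
  expect_error(synthesize_fluor_image(width = 60, height = 60,
                                      n_vessels = 1, n_nuclei = 200,
                                      seed = 1, max_tries = 50),
               "place")
})

test_that("PDGFRA mean-intensity readout matches the planted field", {
  syn <- synthesize_fluor_image(width = 320, height = 240, n_vessels = 3,
                                n_nuclei = 15, scenario = "pdgfra",
                                noise_sd = 0, seed = 59)
  met <- image_metrics(syn$image)
  expect_equal(met$mean_red_over_green, syn$truth$mean_red_over_vessel,
               tolerance = 1e-12)
})
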