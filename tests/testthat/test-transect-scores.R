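# Transect sampling, element means, contrast and crypsis scores.

test_that("a uniform image samples to its own colour everywhere", {
  img <- array(0, c(30, 60, 3))
  img[, , 1] <- 0.5; img[, , 2] <- 0.325; img[, , 3] <- 0.2
  lm <- rbind(c(15, 5), c(15, 20), c(15, 30), c(15, 45), c(15, 55))
  prof <- sample_transect(img, lm)
  expect_true(all(abs(prof$R - 0.5) < 1e-12))
  expect_true(all(abs(prof$G - 0.325) < 1e-12))
  expect_true(all(abs(prof$B - 0.2) < 1e-12))
})

test_that("rasterization counts pixels as expected and dedupes landmarks", {
  # one horizontal 10-px leg: cols 5..14 on one row
  lm <- rbind(c(3, 5), c(3, 8), c(3, 10), c(3, 12), c(3, 14))
  tr <- rasterize_transect(lm)
  expect_equal(nrow(tr), 10L)
  expect_equal(tr[, "col"], 5:14)
  expect_true(!any(duplicated(tr)))
  # a diagonal leg is 8-connected: max(|dr|, |dc|) + 1 pixels
  lm2 <- rbind(c(2, 2), c(6, 10), c(10, 12), c(12, 20), c(14, 30))
  tr2 <- rasterize_transect(lm2)
  steps <- abs(diff(tr2[, 1])) <= 1 & abs(diff(tr2[, 2])) <= 1
  expect_true(all(steps))
})

test_that("transects too close to the border are rejected", {
  img <- array(0.5, c(20, 20, 3))
  lm <- rbind(c(0, 2), c(0, 5), c(0, 8), c(0, 12), c(0, 15))
  expect_error(sample_transect(img, lm), "border")
  expect_error(landmark_set(rbind(c(1, 1), c(1, 1), c(2, 2), c(3, 3), c(4, 4))),
               "distinct")
  expect_error(landmark_set(rbind(c(1, 1), c(2, 2))), "five")
})

test_that("zero-noise wing samples equal generator colours inside elements", {
  w <- make_test_wings(noise_sd = 0)$td27
  prof <- sample_transect(w$image, w$annotation$landmarks)
  b <- w$annotation$boundaries$eyespot_focus
  idx <- (b[1, 1] + 1L):b[1, 2]
  focus_col <- w$annotation$element_colors$eyespot_focus
  expect_gt(length(idx), 0)
  expect_true(all(abs(prof$R[idx] - focus_col[1]) < 1e-12))
  expect_true(all(abs(prof$G[idx] - focus_col[2]) < 1e-12))
  expect_true(all(abs(prof$B[idx] - focus_col[3]) < 1e-12))
})

test_that("element_mean_colors averages RGB first, then converts", {
  img <- array(0, c(10, 40, 3))
  c1 <- c(0.8, 0.2, 0.1); c2 <- c(0.2, 0.6, 0.7)
  img[, 1:20, 1] <- c1[1]; img[, 1:20, 2] <- c1[2]; img[, 1:20, 3] <- c1[3]
  img[, 21:40, 1] <- c2[1]; img[, 21:40, 2] <- c2[2]; img[, 21:40, 3] <- c2[3]
  lm <- rbind(c(5, 3), c(5, 8), c(5, 12), c(5, 14), c(5, 16))
  prof <- sample_transect(img, lm) # 14 samples, all in the c1 half
  means <- element_mean_colors(prof, list(wing_background = c(0, 14)))
  expect_equal(means$x, rgb_to_xyY(c1)$x, tolerance = 1e-12)
  # two equal-length intervals average the two colours in RGB space
  means2 <- element_mean_colors(
    rbind(prof[1:4, ], transform(prof[1:4, ], R = c2[1], G = c2[2], B = c2[3])),
    list(wing_background = rbind(c(0, 4), c(4, 8)))
  )
  expect_equal(means2$x, rgb_to_xyY((c1 + c2) / 2)$x, tolerance = 1e-12)
  # single-sample interval is that sample's chromaticity
  means3 <- element_mean_colors(prof, list(wing_background = c(0, 1)))
  expect_equal(means3$y, rgb_to_xyY(c1)$y, tolerance = 1e-12)
  expect_error(element_mean_colors(prof, list(wing_background = c(3, 3))),
               "outside|empty")
})

test_that("internal contrast is zero for self, ordered by construction", {
  wings <- make_test_wings(noise_sd = 0)
  for (w in wings[c("td19", "td27")]) {
    prof <- sample_transect(w$image, w$annotation$landmarks)
    ic <- internal_contrast(prof, w$annotation$boundaries)
    expect_true(all(ic$distance >= 0))
    # closed-form distances from generator targets
    cols <- w$annotation$element_colors
    bgxy <- rgb_to_xyY(cols$wing_background)
    for (i in seq_len(nrow(ic))) {
      target <- chromatic_distance(bgxy, rgb_to_xyY(cols[[ic$element[i]]]))
      expect_equal(ic$distance[i], target, tolerance = 1e-12)
    }
  }
  # Td19 defaults are nearer their background than Td27: every score smaller
  p19 <- sample_transect(wings$td19$image, wings$td19$annotation$landmarks)
  p27 <- sample_transect(wings$td27$image, wings$td27$annotation$landmarks)
  ic19 <- internal_contrast(p19, wings$td19$annotation$boundaries)
  ic27 <- internal_contrast(p27, wings$td27$annotation$boundaries)
  expect_true(all(ic19$distance < ic27$distance))
  expect_error(internal_contrast(p19, wings$td19$annotation$boundaries[
    setdiff(names(wings$td19$annotation$boundaries), "wing_background")]),
    "wing_background")
})

test_that("contrast scores are invariant to uniform intensity scaling", {
  w <- make_test_wings(noise_sd = 0)$td27
  prof <- sample_transect(w$image, w$annotation$landmarks)
  prof2 <- prof
  prof2[, c("R", "G", "B")] <- prof[, c("R", "G", "B")] * 0.5
  ic1 <- internal_contrast(prof, w$annotation$boundaries)
  ic2 <- internal_contrast(prof2, w$annotation$boundaries)
  expect_equal(ic1$distance, ic2$distance, tolerance = 1e-12)
})

test_that("crypsis score reduces to chromatic_distance on uniform profiles", {
  img <- array(0, c(20, 40, 3))
  img[, , 1] <- 1; img[, , 2] <- 1; img[, , 3] <- 1 # white
  lm <- rbind(c(10, 3), c(10, 10), c(10, 20), c(10, 30), c(10, 36))
  prof <- sample_transect(img, lm)
  red <- rgb_to_xyY(c(1, 0, 0))
  cs <- crypsis_score(prof, red)
  expect_equal(cs$score, 0.3273, tolerance = 1e-3)
  white <- rgb_to_xyY(c(1, 1, 1))
  expect_equal(crypsis_score(prof, white)$score, 0, tolerance = 1e-9)
  # appending reference-coloured samples strictly lowers a positive score
  more <- prof[rep(1, 20), ]
  more$R <- 1; more$G <- 0; more$B <- 0
  cs2 <- crypsis_score(rbind(prof, more), red)
  expect_lt(cs2$score, cs$score)
})

test_that("degenerate black samples are excluded from the crypsis mean", {
  img <- array(0, c(20, 40, 3))
  img[, 1:20, ] <- 0 # black half
  img[, 21:40, 1] <- 1; img[, 21:40, 2] <- 1; img[, 21:40, 3] <- 1
  lm <- rbind(c(10, 25), c(10, 28), c(10, 31), c(10, 34), c(10, 37))
  prof <- sample_transect(img, lm) # fully in the white half
  allb <- prof; allb$R <- 0; allb$G <- 0; allb$B <- 0
  expect_error(crypsis_score(allb, rgb_to_xyY(c(1, 0, 0))), "degenerate")
  mixed <- rbind(prof, allb[1:3, ])
  cs <- crypsis_score(mixed, rgb_to_xyY(c(1, 0, 0)))
  expect_equal(cs$n_degenerate, 3L)
  expect_equal(cs$score, 0.3273, tolerance = 1e-3) # black rows ignored
})
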