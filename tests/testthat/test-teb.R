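test_that("ratio images respect the threshold and flag invalid pixels", {
  a <- te_chan(matrix(c(2, 0.5), 1), 126)
  b <- te_chan(matrix(c(4, 4), 1), 128)
  r <- ratio_image(a, b, threshold = 1, sigma = 0)
  expect_identical(r$valid, matrix(c(TRUE, FALSE), 1))
  expect_equal(r$values[1, 1], 0.5)
  expect_true(is.na(r$values[1, 2]))

  same <- ratio_image(te_chan(matrix(1:6 + 0.5, 2), 126),
                      te_chan(matrix(1:6 + 0.5, 2), 128), sigma = 0)
  expect_true(all(same$values[same$valid] == 1))

  expect_error(ratio_image(a, te_chan(matrix(1, 2, 2), 128), sigma = 0),
               "shape")
  expect_error(ratio_image(a, b, threshold = 0), "> 0")
})

test_that("an unbiased Poisson phantom has the theoretical median ratio", {
  dex <- std_dexenon()
  r <- ratio_image(stack_channel(dex, 126), stack_channel(dex, 128))
  med <- median(r$values[r$valid])
  expect_equal(med, theoretical_ratio("Te", 126, 128), tolerance = 0.02)
})

test_that("TEB is exactly 1 for a noiseless natural-abundance pair", {
  b <- te_chan(matrix(runif(64, 2, 40), 8), 128)
  a <- te_chan(theoretical_ratio("Te", 126, 128) * ch_pixels(b), 126)
  res <- compute_teb(a, b, sigma = 0)
  expect_equal(res$teb, 1, tolerance = 1e-12)
  expect_identical(res$n_valid, 64L)
  expect_equal(res$teb, res$median_ratio / res$theoretical_ratio)
})

test_that("injected detection bias is recovered and symmetric", {
  dex <- std_dexenon()
  biased <- inject_teb(dex, list("126" = 1.2))
  ab <- compute_teb(stack_channel(biased, 126), stack_channel(biased, 128))
  expect_gt(ab$teb, 1.14)
  expect_lt(ab$teb, 1.26)
  ba <- compute_teb(stack_channel(biased, 128), stack_channel(biased, 126))
  expect_equal(ab$teb * ba$teb, 1, tolerance = 0.05)
})

test_that("a mass-increasing bias profile over-detects heavier isotopes", {
  ph <- generate_phantom(phantom_spec(bias = list("124" = 0.9, "126" = 1.0,
                                                  "128" = 1.1, "130" = 1.2),
                                      background_rate = 2, seed = 3))
  dex <- dexenon_stack(ph$stack)
  for (pair in list(c(128, 126), c(130, 126), c(130, 128))) {
    res <- compute_teb(stack_channel(dex, pair[1]), stack_channel(dex, pair[2]))
    expect_gt(res$teb, 1)
  }
})

test_that("TEB is invariant to a global intensity rescaling", {
  dex <- std_dexenon()
  a <- stack_channel(dex, 126); b <- stack_channel(dex, 128)
  base <- compute_teb(a, b, threshold = 1)
  c0 <- 3.7
  scaled <- compute_teb(te_chan(c0 * ch_pixels(a), 126),
                        te_chan(c0 * ch_pixels(b), 128), threshold = c0)
  expect_equal(scaled$teb, base$teb, tolerance = 1e-10)
  expect_identical(scaled$n_valid, base$n_valid)
})

test_that("dividing by the computed TEB restores an unbiased pair", {
  b <- te_chan(matrix(runif(100, 5, 50), 10), 128)
  a <- te_chan(1.3 * theoretical_ratio("Te", 126, 128) * ch_pixels(b), 126)
  res <- compute_teb(a, b, sigma = 0)
  corrected <- apply_teb(a, res)
  res2 <- compute_teb(corrected, b, sigma = 0)
  expect_equal(res2$teb, 1, tolerance = 1e-6)
})

test_that("apply_teb validates its divisor and isotope pairing", {
  a <- te_chan(matrix(10, 2, 2), 126)
  expect_identical(ch_pixels(apply_teb(a, 1)), ch_pixels(a))
  expect_equal(apply_teb(a, 2)[1, 1], 5)
  expect_error(apply_teb(a, 0), "positive")
  res <- compute_teb(te_chan(matrix(4, 2, 2), 128), te_chan(matrix(2, 2, 2), 130),
                     sigma = 0)
  expect_error(apply_teb(a, res), "isotope 128")
})

test_that("SLIP differences classify late-versus-early signal three ways", {
  early <- te_chan(matrix(c(1, 5, 3), 1), 125)
  late <- te_chan(matrix(c(4, 2, 3), 1), 122)
  sd <- slip_difference(early, late)
  expect_identical(sd$classification, matrix(c(1, -1, 0), 1))
  expect_equal(sd$difference, matrix(c(3, -3, 0), 1))

  tie <- slip_difference(early, early)
  expect_true(all(tie$classification == 0))

  res <- compute_teb(te_chan(matrix(2, 2, 2), 128), te_chan(matrix(2, 2, 2), 130),
                     sigma = 0)
  expect_error(slip_difference(early, late, res), "does not match")
})

test_that("TEB correction flips exactly the pixels straddling the factor", {
  teb <- 1.5
  early <- te_chan(matrix(1, 10, 10), 125)
  ratios <- matrix(2, 10, 10)        # well above teb: stays +1
  flip <- cbind(sample(10, 6, replace = TRUE), 1:6)
  ratios[flip] <- 1.2                # in (1, teb): +1 flips to -1
  late <- te_chan(ratios, 122)
  before <- slip_difference(early, late)$classification
  after <- slip_difference(early, late, teb)$classification
  changed <- before != after
  expect_identical(which(changed), which(ratios == 1.2))
  expect_true(all(after[changed] == -1))
})

test_that("the flipped fraction counts classified pixels only", {
  early <- te_chan(matrix(1, 10, 10), 125)
  ratios <- matrix(3, 10, 10)
  ratios[1, 1:7] <- 1.1              # exactly 7 pixels inside (1, teb)
  late <- te_chan(ratios, 122)
  expect_identical(fraction_sign_changed(early, late, teb = 1), 0)
  expect_equal(fraction_sign_changed(early, late, teb = 1.5), 0.07)
})
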