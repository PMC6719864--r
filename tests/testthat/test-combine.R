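three_stack <- function(v1, v2, v3) {
  image_stack(list(te_chan(v1, 126), te_chan(v2, 128), te_chan(v3, 130)))
}

test_that("arithmetic combination is the pixelwise sum", {
  st <- three_stack(matrix(1, 2, 2), matrix(2, 2, 2), matrix(3, 2, 2))
  out <- arithmetic_combine(st, c(126, 128, 130))
  expect_true(all(out == 6))
  expect_identical(attr(out, "combination")$mode, "arithmetic")

  single <- arithmetic_combine(st, 128)
  expect_identical(ch_pixels(single), ch_pixels(stack_channel(st, 128)))
  zeros <- three_stack(matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2))
  expect_true(all(arithmetic_combine(zeros, c(126, 128, 130)) == 0))
  expect_error(arithmetic_combine(st, c(126, 125)), "no channel")
})

test_that("geometric combination is the n-th root of the product with zero propagation", {
  st <- three_stack(matrix(4, 1, 1), matrix(9, 1, 1), matrix(1, 1, 1))
  expect_equal(geometric_combine(st, c(126, 128))[1, 1], 6)

  zp <- three_stack(matrix(0, 1, 1), matrix(100, 1, 1), matrix(100, 1, 1))
  expect_identical(geometric_combine(zp, c(126, 128, 130))[1, 1], 0)

  for (c0 in c(0, 0.5, 17)) {
    idem <- three_stack(matrix(c0, 2, 2), matrix(c0, 2, 2), matrix(c0, 2, 2))
    expect_equal(ch_pixels(geometric_combine(idem, c(126, 128, 130))),
                 matrix(c0, 2, 2), tolerance = 1e-12)
  }

  neg <- image_stack(list(
    channel_image(matrix(-1, 1, 1), "Te", 126, allow_negative = TRUE),
    channel_image(matrix(2, 1, 1), "Te", 128)))
  expect_error(geometric_combine(neg, c(126, 128)), "non-negative")
})

test_that("geometric never exceeds arithmetic mean (AM-GM), on random stacks", {
  set.seed(5)
  for (i in 1:5) {
    st <- three_stack(matrix(rexp(36), 6), matrix(rpois(36, 3), 6),
                      matrix(runif(36, 0, 10), 6))
    g <- ch_pixels(geometric_combine(st, c(126, 128, 130)))
    am <- ch_pixels(arithmetic_combine(st, c(126, 128, 130))) / 3
    expect_true(all(g <= am + 1e-12))
  }
})

test_that("geometric combination ignores channel order; the 3-D blur does not", {
  set.seed(6)
  st <- three_stack(matrix(rexp(36) + 0.1, 6), matrix(rexp(36) + 0.1, 6),
                    matrix(rexp(36) + 5, 6))
  g1 <- geometric_combine(st, c(126, 128, 130))
  g2 <- geometric_combine(st, c(130, 126, 128))
  expect_equal(ch_pixels(g1), ch_pixels(g2), tolerance = 1e-12)

  # note: reversing the list is a symmetry of the reflective kernel, so use a
  # permutation that moves a channel from the edge to the middle
  b1 <- blur_stack_3d(st, c(126, 128, 130), sigma = 1)
  b2 <- blur_stack_3d(st, c(128, 126, 130), sigma = 1)
  expect_gt(max(abs(ch_pixels(stack_channel(b1, 126)) -
                      ch_pixels(stack_channel(b2, 126)))), 1e-6)
})

test_that("3-D blurring preserves constants and composes with the collapses", {
  st <- three_stack(matrix(2.5, 5, 5), matrix(2.5, 5, 5), matrix(2.5, 5, 5))
  bl <- blur_stack_3d(st, c(126, 128, 130), sigma = 1)
  for (ch in bl$channels) expect_equal(ch_pixels(ch), matrix(2.5, 5, 5),
                                       tolerance = 1e-12)
  expect_identical(
    ch_pixels(blur_stack_3d(st, c(126, 128), sigma = 0)$channels[[1]]),
    ch_pixels(stack_channel(st, 126)))

  set.seed(8)
  rnd <- three_stack(matrix(rexp(25), 5), matrix(rexp(25), 5),
                     matrix(rexp(25), 5))
  expect_identical(ch_pixels(combine(rnd, c(126, 128, 130), "arithmetic")),
                   ch_pixels(arithmetic_combine(rnd, c(126, 128, 130))))
  expect_identical(ch_pixels(combine(rnd, c(126, 128, 130), "geometric")),
                   ch_pixels(geometric_combine(rnd, c(126, 128, 130))))
})

test_that("arithmetic background accrues with channel count; geometric does not", {
  set.seed(9)
  noise_stack <- image_stack(lapply(c(120, 122, 123, 125, 126, 128), function(m) {
    channel_image(matrix(rpois(2500, 1), 50), "Te", m)
  }))
  masses <- c(120, 122, 123, 125, 126, 128)
  arith2 <- mean(arithmetic_combine(noise_stack, masses[1:2]))
  arith6 <- mean(arithmetic_combine(noise_stack, masses))
  expect_gt(arith6, 2.5 * arith2)  # grows roughly linearly in channel count
  geo2 <- mean(geometric_combine(noise_stack, masses[1:2]))
  geo6 <- mean(geometric_combine(noise_stack, masses))
  expect_lte(geo6, geo2 + 0.05)
})

test_that("SNR is signal mean over population noise standard deviation", {
  img <- matrix(10, 4, 4)
  img[3:4, ] <- rep(c(0, 4), 4)  # noise rows alternate 0/4: sd 2, mean 2
  sig <- matrix(FALSE, 4, 4); sig[1:2, ] <- TRUE
  noi <- matrix(FALSE, 4, 4); noi[3:4, ] <- TRUE
  res <- snr(img, sig, noi)
  expect_equal(res$snr, 5)
  expect_equal(res$signal_mean, 10)
  expect_equal(res$noise_std, 2)

  expect_error(snr(img, sig, sig), "disjoint")
  flat <- matrix(1, 4, 4)
  expect_error(snr(flat, sig, noi), "degenerate")
  expect_error(snr(img, matrix(FALSE, 4, 4), noi), "at least 2")
})
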