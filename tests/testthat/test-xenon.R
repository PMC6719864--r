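xe_ref <- function(values, nrow = 1) {
  channel_image(if (is.matrix(values)) values else matrix(values, nrow),
                "Xe", 134)
}

test_that("the xenon component is the 134 channel scaled by the abundance ratio", {
  y <- estimate_xenon_component(xe_ref(10), 128)
  expect_equal(round(y[1, 1], 3), 1.830)
  expect_identical(ch_element(y), "Xe")
  expect_identical(ch_mass(y), 128L)

  zeros <- estimate_xenon_component(xe_ref(matrix(0, 3, 3)), 126)
  expect_true(all(zeros == 0))

  ident <- estimate_xenon_component(xe_ref(matrix(c(1, 2, 3, 4), 2)), 134)
  expect_equal(ch_pixels(ident), matrix(c(1, 2, 3, 4), 2))

  expect_error(estimate_xenon_component(xe_ref(10), 125), "no xenon isobar")
  # an explicit ratio bypasses the table
  y2 <- estimate_xenon_component(xe_ref(10), 128, ratio_override = 0.5)
  expect_equal(y2[1, 1], 5)
})

test_that("subtraction recovers tellurium and clips on request", {
  obs <- te_chan(5, 128)
  t_img <- subtract_xenon(obs, xe_ref(10), clip = FALSE)
  expect_equal(round(t_img[1, 1], 3), 3.170)
  expect_identical(ch_element(t_img), "Te")

  clipped <- subtract_xenon(te_chan(1, 128), xe_ref(10))
  expect_identical(clipped[1, 1], 0)
  expect_identical(attr(clipped, "n_clipped"), 1L)

  # no contamination: output equals input exactly
  same <- subtract_xenon(te_chan(matrix(c(1, 2.5, 0, 7), 2), 128),
                         xe_ref(matrix(0, 2, 2)))
  expect_identical(ch_pixels(same), matrix(c(1, 2.5, 0, 7), 2))

  expect_error(subtract_xenon(te_chan(5, 128), xe_ref(matrix(1, 2, 2))),
               "shape")
})

test_that("subtraction is affine in the observed image (clip off)", {
  set.seed(7)
  X <- xe_ref(matrix(rpois(48, 5), 6))
  I1 <- te_chan(matrix(rpois(48, 9), 6), 128)
  I2 <- te_chan(matrix(rpois(48, 4), 6), 128)
  r <- theoretical_ratio("Xe", 128, 134)
  for (ab in list(c(2, 3), c(0.5, 0.5), c(1, 0))) {
    a <- ab[1]; b <- ab[2]
    lhs <- subtract_xenon(te_chan(a * ch_pixels(I1) + b * ch_pixels(I2), 128),
                          X, clip = FALSE)
    rhs <- a * ch_pixels(subtract_xenon(I1, X, clip = FALSE)) +
      b * ch_pixels(subtract_xenon(I2, X, clip = FALSE)) +
      (a + b - 1) * r * ch_pixels(X)
    expect_equal(ch_pixels(lhs), rhs, tolerance = 1e-12)
  }
})

test_that("the empirical spillover ratio is a masked median of pixel ratios", {
  set.seed(1)
  xe <- xe_ref(matrix(rpois(400, 50) + 1, 20))
  obs <- te_chan(0.5 * ch_pixels(xe), 128)
  mask <- matrix(TRUE, 20, 20)
  expect_identical(empirical_spillover_ratio(obs, xe, mask), 0.5)

  small <- matrix(FALSE, 20, 20); small[1:5, 1:5] <- TRUE
  expect_error(empirical_spillover_ratio(obs, xe, small), "25 valid")
})

test_that("a pure-xenon phantom reproduces the theoretical spillover ratio", {
  ph <- generate_phantom(phantom_spec(height = 128, width = 128,
                                      tissue_fraction = 0,
                                      xenon_baseline = 200, streak_rows = 0,
                                      seed = 11))
  r <- empirical_spillover_ratio(stack_channel(ph$stack, 128, "Te"),
                                 stack_channel(ph$stack, 134, "Xe"),
                                 matrix(TRUE, 128, 128))
  expect_equal(r, theoretical_ratio("Xe", 128, 134), tolerance = 0.02)
})

test_that("dexenon corrects only channels with a xenon isobar", {
  ph <- std_phantom()
  dex <- std_dexenon()
  # 125 and 122 pass through untouched; 134 is retained
  for (m in c(122, 125)) {
    expect_identical(ch_pixels(stack_channel(dex, m)),
                     ch_pixels(stack_channel(ph$stack, m, "Te")))
  }
  expect_true(stack_has_channel(dex, 134, "Xe"))
  expect_named(dex$provenance$dexenon_ratios, c("124", "126", "128", "130"))
  # clip on: never negative
  for (ch in dex$channels) expect_true(min(ch) >= 0)
})

test_that("dexenon is exact on a noiseless phantom and inert without xenon", {
  nl <- generate_phantom(phantom_spec(noise = "none", background_rate = 2))
  dn <- dexenon_stack(nl$stack, clip = FALSE)
  for (key in names(nl$truth$true_te)) {
    expect_equal(ch_pixels(stack_channel(dn, as.integer(key))),
                 nl$truth$true_te[[key]], tolerance = 1e-12)
  }

  # an empty 134 channel: every channel passes through exactly
  st <- image_stack(list(te_chan(matrix(c(1, 2, 3, 4.5), 2), 128),
                         channel_image(matrix(0, 2, 2), "Xe", 134)))
  dex0 <- dexenon_stack(st)
  expect_identical(ch_pixels(stack_channel(dex0, 128)),
                   matrix(c(1, 2, 3, 4.5), 2))

  expect_error(dexenon_stack(image_stack(list(te_chan(1, 128)))), "134")
})

test_that("per-mass ratio overrides and empirical masks drive the correction", {
  st <- image_stack(list(te_chan(matrix(10, 4, 4), 128),
                         channel_image(matrix(4, 4, 4), "Xe", 134)))
  dex <- dexenon_stack(st, ratios = list("128" = 0.5))
  expect_equal(ch_pixels(stack_channel(dex, 128)), matrix(8, 4, 4))
  expect_equal(dex$provenance$dexenon_ratios[["128"]], 0.5)
})
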