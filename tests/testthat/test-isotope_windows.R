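test_that("isotope table matches the reference decay data", {
  lu <- get_isotope("Lu177")
  expect_equal(lu$lines$energy, c(113, 208))
  expect_equal(lu$lines$intensity, c(0.062, 0.104))
  expect_equal(lu$half_life, 6.65 * 86400)

  re <- get_isotope("Re188")
  expect_equal(re$lines$energy, c(155, 478, 633))
  expect_equal(re$lines$intensity, c(0.156, 0.011, 0.014))
  expect_equal(re$half_life, 17 * 3600)

  expect_error(get_isotope("Tc99m"), "unsupported isotope")
})

test_that("window settings match the reference acquisition protocol", {
  w <- get_windows("I131")
  expect_equal(c(w$pw$lo, w$pw$hi), c(328, 400))
  expect_equal(c(w$lsw$lo, w$lsw$hi), c(306, 328))
  expect_equal(c(w$usw$lo, w$usw$hi), c(400, 422))

  q <- get_windows("Lu177", dialect = "quebec")
  expect_equal(c(q$lsw$lo, q$lsw$hi), c(166, 187))
  expect_equal(c(q$usw$lo, q$usw$hi), c(229, 250))

  # widths are derived from bounds, never stored separately
  re <- get_windows("Re188")
  expect_equal(window_width(re$pw), 31)
  expect_equal(window_width(re$lsw), 8)
  expect_equal(window_width(re$usw), 7)

  expect_error(get_windows("Re188", dialect = "quebec"), "Lu177 only")
})

test_that("window triplets are abutting, non-overlapping and contain the photopeak", {
  peaks <- c(I131 = 364, Lu177 = 208, Re188 = 155)
  cases <- list(c("I131", "default"), c("Lu177", "default"),
                c("Lu177", "quebec"), c("Re188", "default"))
  for (cs in cases) {
    w <- get_windows(cs[1], cs[2])
    expect_lte(w$lsw$hi, w$pw$lo)
    expect_lte(w$pw$hi, w$usw$lo)
    if (cs[2] == "default") {
      expect_equal(w$lsw$hi, w$pw$lo)  # abutting
      expect_equal(w$pw$hi, w$usw$lo)
    }
    pk <- peaks[[cs[1]]]
    expect_true(w$pw$lo <= pk && pk <= w$pw$hi)
    expect_equal(photopeak_energy(cs[1]), pk)
  }
})

test_that("all stored lines satisfy the >1% intensity cutoff", {
  for (iso in supported_isotopes()) {
    sp <- get_isotope(iso)
    expect_true(all(sp$lines$intensity > 0.01 & sp$lines$intensity <= 1))
    expect_true(all(sp$lines$energy > 0))
    expect_gt(nrow(sp$lines), 0)
  }
})
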