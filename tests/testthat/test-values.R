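test_that("sample extraction preserves order and drops missing values", {
  ds <- make_ds(matrix(c(1, NA, 3, 4, 5, 6), 3, 2))
  v <- extract_sample(ds, "S1")
  expect_equal(v$entity_ids, c("g1", "g3"))
  expect_equal(v$v, c(1, 3))
  expect_error(extract_sample(ds, "S9"), "S1, S2")
  all_na <- make_ds(matrix(c(NA, NA, 1, 2), 2, 2))
  expect_warning(extract_sample(all_na, "S1"), "no present values")

  set.seed(2)
  big <- make_ds(matrix(rnorm(300), 100, 3))
  v2 <- extract_sample(big, "S2")
  expect_equal(v2$v, unname(big$values[, 2]))
})

test_that("two-sample comparison statistics match their definitions", {
  ds <- make_ds(matrix(c(5, 6, 5, 2), 2, 2))
  expect_equal(compare_samples(ds, "S1", "S2", "difference")$v, c(0, 4))
  expect_equal(compare_samples(ds, "S1", "S2", "fold")$v, c(1, 3))
  expect_equal(compare_samples(ds, "S1", "S2", "difference_fold")$v, c(0, 2))
  expect_error(compare_samples(ds, "S1", "S1"), "must differ")

  # random vectors with zeros in the denominator sample
  set.seed(3)
  va <- rnorm(200); vb <- rnorm(200)
  vb[sample(200, 17)] <- 0
  ds2 <- make_ds(cbind(va, vb))
  fold <- suppressMessages(compare_samples(ds2, "S1", "S2", "fold"))
  dfold <- suppressMessages(compare_samples(ds2, "S1", "S2", "difference_fold"))
  expect_equal(fold$n_excluded, 17L)
  expect_equal(dfold$n_excluded, 17L)
  keep <- vb != 0
  expect_equal(fold$v, (va / vb)[keep])
  expect_equal(dfold$v, ((va - vb) / vb)[keep])
  # algebraic identity: difference_fold = fold - 1 wherever both defined
  expect_equal(dfold$v, fold$v - 1, tolerance = 1e-12)
})

test_that("min-value filter is strict, idempotent, and matches a row scan", {
  ds <- make_ds(matrix(c(50, 60, 50, 10), 2, 2))
  out <- filter_min_value(ds, 50)
  expect_equal(out$entity_ids, "g2")   # (50, 50) is not over 50

  set.seed(4)
  big <- make_ds(matrix(rlnorm(800, 3, 1), 200, 4))
  thr <- median(big$values)
  f1 <- filter_min_value(big, thr)
  oracle <- sum(apply(big$values, 1, function(r) max(r) > thr))
  expect_equal(length(f1$entity_ids), oracle)
  f2 <- filter_min_value(f1, thr)
  expect_identical(f2$entity_ids, f1$entity_ids)
  # a threshold below every value is the identity
  expect_identical(filter_min_value(big, -Inf)$entity_ids, big$entity_ids)
})

test_that("keep-over / keep-under displayed-value filters", {
  v <- value_vector(c("a", "b", "c"), c(1, 5, 9))
  expect_equal(filter_value_range(v, keep_over = 2)$entity_ids, c("b", "c"))
  expect_equal(filter_value_range(v, keep_under = 5)$entity_ids, "a")
  expect_equal(filter_value_range(v, 2, 9)$entity_ids, "b")
})

test_that("auto scale spans the value range; constant vectors hit mid-bin", {
  v <- value_vector(c("a", "b"), c(1, 9))
  sc <- auto_scale(v)
  expect_equal(c(sc$vmin, sc$vmax), c(1, 9))
  expect_error(auto_scale(value_vector(character(0), numeric(0))), "empty")

  const <- auto_scale(value_vector(letters[1:3], c(4, 4, 4)), n_bins = 9)
  expect_equal(bin_index(const, c(4, 4, 4)), rep(4L, 3))
  const6 <- auto_scale(value_vector(letters[1:3], c(4, 4, 4)), n_bins = 6)
  expect_equal(unique(bin_index(const6, c(-1, 4, 100))), 3L)
})

test_that("bin_index follows the half-open formula, clamps, and is monotone", {
  sc <- color_scale(0, 10, n_bins = 5)
  expect_equal(bin_index(sc, 0), 0L)
  expect_equal(bin_index(sc, 10), 4L)
  expect_equal(bin_index(sc, 99), 4L)     # saturation above user vmax
  expect_equal(bin_index(sc, -5), 0L)
  expect_equal(bin_index(sc, 2), 1L)      # [2,4) is bin 1

  set.seed(5)
  v <- sort(runif(1000, -3, 13))
  idx <- bin_index(sc, v)
  formula <- pmin(pmax(floor((v - 0) / 10 * 5), 0), 4)
  expect_equal(idx, as.integer(formula))
  expect_true(all(diff(idx) >= 0))
})

test_that("YlOrRd palette anchors, reversal symmetry, and interpolation", {
  sc <- color_scale(0, 1, n_bins = 9)
  expect_equal(palette_color(sc, 0), "#FFFFCC")
  expect_equal(palette_color(sc, 8), "#800026")
  expect_error(palette_color(sc, 9), "out of range")

  rev_sc <- color_scale(0, 1, n_bins = 9, reversed = TRUE)
  for (i in 0:8)
    expect_equal(palette_color(rev_sc, i), palette_color(sc, 8L - i))

  # interpolation oracle over the 9 anchors, per RGB channel
  anchors <- t(sapply(c("#FFFFCC", "#FFEDA0", "#FED976", "#FEB24C", "#FD8D3C",
                        "#FC4E2A", "#E31A1C", "#BD0026", "#800026"),
                      function(h) strtoi(substring(h, c(2, 4, 6), c(3, 5, 7)),
                                         16L)))
  for (n in c(2, 5, 7, 9, 13)) {
    sc_n <- color_scale(0, 1, n_bins = n)
    got <- sapply(0:(n - 1), function(i) palette_color(sc_n, i))
    want <- sapply(seq(0, 1, length.out = n), function(t) {
      ch <- round(apply(anchors, 2, function(col)
        approx(seq(0, 1, length.out = 9), col, xout = t)$y))
      sprintf("#%02X%02X%02X", ch[1], ch[2], ch[3])
    })
    expect_equal(got, want, info = paste("n_bins =", n))
  }
})
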