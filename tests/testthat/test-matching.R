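# sliding Pearson matching over position x orientation x stretch

test_that("lambda-DNA calibration converts pixels to bp per pixel", {
  expect_equal(calibrate_bp_per_pixel(100), 485.02)
  expect_equal(calibrate_bp_per_pixel(48502), 1)
  expect_equal(calibrate_bp_per_pixel(61), 795.11, tolerance = 0.01 / 795)
  expect_error(calibrate_bp_per_pixel(0), class = "cbmapr_bad_input")
  expect_error(calibrate_bp_per_pixel(-3), class = "cbmapr_bad_input")
})

test_that("stretch grid is symmetric and contains 1", {
  g <- stretch_grid(0.05, 0.01)
  expect_equal(g, seq(0.95, 1.05, by = 0.01))
  expect_true(1 %in% g)
  expect_equal(g, rev(2 - g))
})

test_that("resampling is identity at stretch 1 and invertible on smooth input", {
  b0 <- cut_barcode(th_small[[1]], 0, 100)
  expect_equal(as.numeric(resample_barcode(b0, 1)), as.numeric(b0))

  # band-limited (smooth at the pixel scale) barcode for round trips
  x <- seq(0, 6 * pi, length.out = 100)
  b <- barcode(sin(x) + 0.4 * cos(2.3 * x), 800)
  for (s in c(0.95, 1.03, 1.2)) {
    rt <- resample_barcode(resample_barcode(b, s), 1 / s)
    expect_equal(length(rt), length(b))
    expect_lt(max(abs(as.numeric(rt) - as.numeric(b))), 0.05)
  }

  # linear ramps are preserved exactly (up to re-normalization)
  ramp <- barcode(seq_len(50), 800)
  rr <- resample_barcode(ramp, 1.37)
  expect_equal(as.numeric(rr),
               as.numeric(barcode(seq_len(length(rr)), 800)),
               tolerance = 1e-12)
  expect_error(resample_barcode(b, 0.4))
})

test_that("pearson scan equals the naive two-pass formula", {
  withr::with_seed(31, {
    for (i in 1:30) {
      n <- sample(5:12, 1); m <- sample(15:40, 1)
      q <- barcode(rnorm(n), 800)
      r <- barcode(rnorm(m), 800)
      sc <- pearson_scan(q, r)
      expect_equal(nrow(sc), m - n + 1)
      expect_lt(max(abs(sc$forward - naive_pearson_scan(as.numeric(q),
                                                        as.numeric(r)))),
                1e-12)
      expect_lt(max(abs(sc$flipped - naive_pearson_scan(rev(as.numeric(q)),
                                                        as.numeric(r)))),
                1e-12)
      expect_true(all(sc$forward >= -1 & sc$forward <= 1))
    }
  })
})

test_that("scan scores are invariant under affine transforms of the query", {
  withr::with_seed(32, {
    q <- rnorm(20); r <- rnorm(60)
    s0 <- pearson_scan(barcode(q, 800, normalize = FALSE),
                       barcode(r, 800, normalize = FALSE))
    s1 <- pearson_scan(barcode(3.7 * q + 11, 800, normalize = FALSE),
                       barcode(r, 800, normalize = FALSE))
    expect_lt(max(abs(s0$forward - s1$forward)), 1e-12)
    expect_lt(max(abs(s0$flipped - s1$flipped)), 1e-12)
  })
})

test_that("exact and reversed windows score 1.0 in the right orientation", {
  r <- th_small[[1]]
  q <- cut_barcode(r, 30, 75)
  sc <- pearson_scan(q, r)
  expect_equal(sc$forward[31], 1, tolerance = 1e-9)
  scf <- pearson_scan(flip_barcode(q), r)
  expect_equal(scf$flipped[31], 1, tolerance = 1e-9)
  # query longer than reference: empty scan, unmappable via best_match
  long_q <- barcode(rnorm(200), 800)
  expect_equal(nrow(pearson_scan(long_q, cut_barcode(r, 0, 50))), 0)
})

test_that("zero-variance windows are excluded with a sentinel", {
  r <- barcode(c(rep(0, 30), rnorm(40)), 800, normalize = FALSE)
  q <- barcode(rnorm(10), 800)
  sc <- pearson_scan(q, r)
  expect_true(all(sc$forward[1:21] == -Inf))
  expect_true(all(is.finite(sc$forward[32:61])))
})

test_that("best match recovers planted windows with deterministic tie-breaks", {
  q <- cut_barcode(th_1mb[[1]], 400, 600)
  m <- best_match(q, th_1mb)
  expect_equal(m$chrom, "chr1")
  expect_equal(m$start_px, 400)
  expect_equal(m$cmax, 1, tolerance = 1e-9)
  expect_equal(m$orientation, "forward")
  expect_equal(m$stretch, 1)
  expect_equal(m$bp_start, 400 * 800)

  # resampled at 1.03: recovered within 20 px, stretch near the truth
  q3 <- resample_barcode(q, 1.03)
  m3 <- best_match(q3, th_1mb)
  expect_lte(abs(m3$start_px - 400), 20)
  expect_true(m3$stretch %in% c(0.96, 0.97, 0.98))

  expect_error(best_match(barcode(rnorm(5000), 800), th_1mb),
               class = "cbmapr_unmappable")
})

test_that("flip involution returns the same interval with orientation toggled", {
  withr::with_seed(33, {
    q <- barcode(as.numeric(cut_barcode(th_1mb[[1]], 777, 927)) +
                   rnorm(150, 0, 0.4), 800)
    m1 <- best_match(q, th_1mb)
    m2 <- best_match(flip_barcode(q), th_1mb)
    expect_equal(m1$start_px, m2$start_px)
    expect_equal(m1$cmax, m2$cmax, tolerance = 1e-12)
    expect_true(m1$orientation != m2$orientation)
  })
})

test_that("random queries absent from the genome score low", {
  gsmall <- theory_genome(random_genome(5e5, seed = 103))
  low <- 0
  for (i in 1:100) {
    nb <- sample_null_cmax(200, gsmall, R = 1, seed = 4000 + i)
    low <- low + (nb$cmax < 0.5)
  }
  expect_gte(low / 100, 0.99)
})

test_that("placement correctness uses the 20-pixel window", {
  truth <- tibble::tibble(chrom = "chr1", start_px = 500)
  m <- tibble::tibble(chrom = "chr1", start_px = 500)
  expect_true(is_correct_placement(m, truth))
  expect_true(is_correct_placement(dplyr::mutate(m, start_px = 520), truth))
  expect_false(is_correct_placement(dplyr::mutate(m, start_px = 521), truth))
  expect_false(is_correct_placement(dplyr::mutate(m, chrom = "chr2"), truth))

  # flipped placements land on the same leftmost-window coordinate
  q <- cut_barcode(th_1mb[[1]], 650, 800)
  mf <- best_match(flip_barcode(q), th_1mb)
  expect_equal(mf$orientation, "flipped")
  expect_true(is_correct_placement(mf, tibble::tibble(chrom = "chr1",
                                                      start_px = 650)))
})
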