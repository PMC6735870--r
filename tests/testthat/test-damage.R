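# second-channel damage traces: averaging, ROI, background, peaks, projection

test_that("stack averaging is exact and denoises at the expected rate", {
  one <- matrix(rnorm(60), 6, 10)
  expect_equal(average_stack(array(one, c(6, 10, 1))), one)
  expect_equal(average_stack(list(one, -one)), matrix(0, 6, 10))
  expect_error(average_stack(list(one, matrix(0, 3, 3))),
               class = "cbmapr_bad_input")

  withr::with_seed(61, {
    truth <- matrix(runif(40 * 5), 5, 40)
    frames <- lapply(1:20, function(i) truth + matrix(rnorm(200, 0, 1), 5))
    avg <- average_stack(frames)
    expect_equal(sd(avg - truth), 1 / sqrt(20), tolerance = 0.2)
  })
})

test_that("ROI traces average the transverse band", {
  img <- matrix(3.5, 9, 30)
  expect_equal(roi_trace(img, 5, 5), rep(3.5, 30))

  img2 <- matrix(0, 9, 30); img2[4, ] <- 10
  expect_equal(roi_trace(img2, 5, 5), rep(2, 30))  # single row / width
  expect_error(roi_trace(img2, 1, 5), class = "cbmapr_bad_input")

  # Gaussian spot: transverse sum over a wide band approaches the closed
  # form amplitude * sigma * sqrt(2*pi) / width
  rows <- matrix(rep(1:31, 41), 31, 41)
  cols <- matrix(rep(1:41, each = 31), 31, 41)
  spot <- 2 * exp(-((rows - 16)^2 + (cols - 21)^2) / (2 * 1.5^2))
  tr <- roi_trace(spot, 16, 15)
  expect_equal(max(tr), 2 * 1.5 * sqrt(2 * pi) / 15, tolerance = 1e-5)
})

test_that("background correction flags empty traces and normalizes peaks", {
  tr <- rnorm(80, 5, 0.001)
  out <- background_correct(tr, tr, sigma = 8)
  expect_true(attr(out, "all_background"))
  expect_equal(nrow(call_peaks(out)), 0)

  imp <- rep(0, 101); imp[51] <- 1
  out2 <- background_correct(imp, rep(0, 101), sigma = 8)
  expect_false(attr(out2, "all_background"))
  expect_equal(max(out2), 1)
  expect_equal(which.max(as.numeric(out2)), 51)

  # two spots with 3:1 amplitude keep their ratio after correction
  x <- seq_len(200)
  trace <- 0.5 + 3 * exp(-(x - 60)^2 / 8) + 1 * exp(-(x - 140)^2 / 8)
  out3 <- background_correct(trace, rep(0.5, 200), sigma = 2)
  pk <- call_peaks(out3, min_height = 0.1)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$height[pk$peak_px == 59] /
                 pk$height[pk$peak_px == 139], 3, tolerance = 0.05)
  expect_error(background_correct(rnorm(10), rnorm(9)),
               class = "cbmapr_bad_input")
})

test_that("peak calling finds separated bumps and respects thinning", {
  expect_equal(nrow(call_peaks(rep(1, 50))), 0)

  x <- seq_len(120)
  tr <- exp(-(x - 30)^2 / 6) + 0.8 * exp(-(x - 90)^2 / 6)
  pk <- call_peaks(tr)
  expect_equal(pk$peak_px, c(29L, 89L))

  # two candidates closer than min_separation: only the higher survives
  tr2 <- exp(-(x - 50)^2 / 2) + 0.9 * exp(-(x - 53)^2 / 2)
  pk2 <- call_peaks(tr2, min_separation = 6)
  expect_equal(nrow(pk2), 1)
})

test_that("planted spots are recalled with high precision at SNR 10", {
  withr::with_seed(62, {
    n <- 500
    sites <- sort(sample(20:480, 8))
    noise_sd <- 0.05
    x <- seq_len(n)
    tr <- rnorm(n, 0, noise_sd)
    for (s in sites) tr <- tr + 10 * noise_sd * exp(-(x - s)^2 / (2 * 4))
    out <- background_correct(tr, rep(0, n), sigma = 2)
    pk <- call_peaks(out)
    hits <- vapply(pk$peak_px, function(p) min(abs(p + 1 - sites)) <= 3,
                   logical(1))
    recall <- sum(vapply(sites, function(s)
      any(abs(pk$peak_px + 1 - s) <= 3), logical(1))) / length(sites)
    expect_gte(recall, 0.9)
    expect_gte(mean(hits), 0.9)
  })
})

test_that("peaks project onto the genome in both orientations", {
  q <- cut_barcode(th_1mb[[1]], 300, 400)
  m_f <- best_match(q, th_1mb)
  m_r <- best_match(flip_barcode(q), th_1mb)
  pk <- tibble::tibble(peak_px = c(0L, 50L, 99L), height = 1)

  pf <- peaks_to_genome(pk, m_f)
  expect_equal(pf$bp_start[1], m_f$bp_start)
  expect_equal(pf$strand, rep("+", 3))
  pr <- peaks_to_genome(pk, m_r)
  expect_equal(pr$bp_start[1], m_r$bp_end - m_r$bp_per_pixel)
  expect_false(any(pf$out_of_bounds))
  expect_false(any(pr$out_of_bounds))

  # round trip: a site at genome bp g maps to molecule pixel and back
  for (m in list(m_f, m_r)) {
    for (px in c(0, 31, 99)) {
      g_bp <- peaks_to_genome(tibble::tibble(peak_px = px, height = 1),
                              m)$bp_start
      expect_lte(abs(g_bp / 800 -
                       (if (m$orientation == "forward") m$start_px + px
                        else m$start_px + m$query_stretched_px - 1 - px)),
                 1)
    }
  }

  oob <- peaks_to_genome(tibble::tibble(peak_px = 150L, height = 1), m_f)
  expect_true(oob$out_of_bounds)
})

test_that("the barcode channel is unaffected by damage processing", {
  frag <- cut_barcode(th_1mb[[1]], 500, 650)
  s0 <- simulate_kymograph(frag, frames = 6, drift_sd = 1, noise_sd = 0.5,
                           seed = 63, damage_rate = 0)
  s1 <- simulate_kymograph(frag, frames = 6, drift_sd = 1, noise_sd = 0.5,
                           seed = 63, damage_rate = 0.03)
  expect_identical(unclass(s0$kymo), unclass(s1$kymo))
  expect_null(s0$damage)
  expect_false(is.null(s1$damage))
  b0 <- collapse_kymograph(align_kymograph(s0$kymo), 6)
  b1 <- collapse_kymograph(align_kymograph(s1$kymo), 6)
  expect_identical(best_match(b0, th_1mb), best_match(b1, th_1mb))
})

test_that("treated and untreated cohorts separate by called peak counts", {
  count_peaks <- function(rate, seed) {
    frag <- cut_barcode(th_1mb[[1]], 100, 300)
    s <- simulate_kymograph(frag, frames = 8, drift_sd = 0, noise_sd = 0.2,
                            seed = seed, damage_rate = rate, snr = 10)
    if (is.null(s$damage)) return(0L)
    mg <- s$truth$margin
    tr <- colMeans(s$damage)[(mg + 1):(mg + length(frag))]
    out <- background_correct(tr, rep(0, length(frag)), sigma = 2)
    if (isTRUE(attr(out, "all_background"))) return(0L)
    nrow(call_peaks(out))
  }
  treated <- vapply(1:10, function(i) count_peaks(0.02, 700 + i), integer(1))
  untreated <- vapply(1:10, function(i) count_peaks(0, 800 + i), integer(1))
  expect_gt(mean(treated), mean(untreated))
})
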