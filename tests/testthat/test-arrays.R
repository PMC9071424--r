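# Array screen: GPR I/O, S/N, control normalisation, duplicate averaging,
# loess M-values and hit calling.

test_that("read_gpr parses a small fixture and enforces mandatory columns", {
  path <- write_tiny_gpr(withr::local_tempfile(fileext = ".gpr"))
  scan <- read_gpr(path, "bound")
  expect_s3_class(scan, "array_scan")
  expect_equal(nrow(scan$spots), 4L)
  expect_equal(length(unique(scan$spots$feature_id)), 2L)
  expect_equal(scan$spots$fg_median, c(900, 910, 300, 310))
  expect_equal(scan$header, "Type=test")

  bad <- write_tiny_gpr(withr::local_tempfile(fileext = ".gpr"),
                        drop_col = "B median")
  expect_error(read_gpr(bad, "bound"), "B median")

  empty <- withr::local_tempfile(fileext = ".gpr")
  writeLines(c("ATF\t1.0", "0\t11"), empty)
  expect_error(read_gpr(empty, "bound"), "empty")
})

test_that("write_gpr/read_gpr round-trips a generated scan exactly", {
  sim <- gen_array(seed = 1, n_features = 60, n_blocks = 2, n_controls = 4)
  path <- withr::local_tempfile(fileext = ".gpr")
  write_gpr(sim$bound, path)
  back <- read_gpr(path, "bound")
  expect_equal(back$spots, sim$bound$spots)
  expect_equal(back$header, sim$bound$header)
})

test_that("snr follows the (fg - bg) / bg_sd convention", {
  expect_equal(snr(1000, 100, 10), 90)
  expect_equal(snr(100, 100, 10), 0)
  expect_equal(snr(50, 100, 25), -2)
  # zero bg_sd falls back to the scan-median bg_sd, with a warning
  expect_warning(v <- snr(c(200, 200), c(100, 100), c(0, 20)), "median")
  expect_equal(v, c(5, 5))
  expect_error(snr(200, 100, 0), class = "sumoscreen_degenerate")
})

test_that("normalize_to_controls divides by the non-flagged control median", {
  # control S/N {4, 6} -> median 5; feature S/N 10 -> 2.0
  spots <- make_spots(c("C1", "C2", "F1"), fg = c(140, 160, 200),
                      is_control = c(TRUE, TRUE, FALSE))
  scan <- array_scan(spots, "bound")
  tab <- normalize_to_controls(scan)
  expect_equal(attr(tab, "control_median"), 5)
  expect_equal(tab$norm_value[3], 2)

  # flagged control excluded: controls {4, 6, 40}, flag the 40 -> median 5
  spots3 <- make_spots(c("C1", "C2", "C3", "F1"), fg = c(140, 160, 500, 200),
                       is_control = c(TRUE, TRUE, TRUE, FALSE),
                       flag = c(0L, 0L, -100L, 0L))
  expect_equal(attr(normalize_to_controls(array_scan(spots3, "bound")),
                    "control_median"), 5)

  # all features at control median -> all 1.0
  spots2 <- make_spots(c("C1", "F1", "F2"), fg = 150,
                       is_control = c(TRUE, FALSE, FALSE))
  expect_equal(normalize_to_controls(array_scan(spots2, "bound"))$norm_value,
               c(1, 1, 1))

  # no usable controls -> instructive error, override accepted
  spots4 <- make_spots("F1", fg = 200)
  expect_error(normalize_to_controls(array_scan(spots4, "bound")), "override")
  expect_equal(normalize_to_controls(array_scan(spots4, "bound"),
                                     control_median = 5)$norm_value, 2)
})

test_that("summarize_duplicates averages non-flagged spots and reports drops", {
  spots <- make_spots(c("A", "A", "B", "B", "C", "C"),
                      fg = c(120, 140, 170, 200, 150, 150),
                      flag = c(0L, 0L, -50L, 0L, -50L, -75L))
  tab <- normalize_to_controls(array_scan(spots, "bound"), control_median = 1)
  out <- summarize_duplicates(tab)
  expect_equal(out$value[out$feature_id == "A"], 3)   # mean(2, 4)
  expect_equal(out$value[out$feature_id == "B"], 10)  # single survivor
  expect_false("C" %in% out$feature_id)               # all flagged
  expect_equal(attr(out, "dropped"), "C")
})

test_that("identical bound and mock scans give all-zero M-values", {
  sim <- gen_array(seed = 7, n_features = 300, n_blocks = 4)
  mt <- compute_m_values(sim$bound, sim$bound)
  expect_lt(max(abs(mt$m_value)), 1e-9)
})

test_that("loess stages absorb planted constant and linear technical trends", {
  # constant offset on features only (controls normalise it away otherwise):
  # D is constant c, the fitted trend equals c, residual M ~ 0
  set.seed(11)
  n <- 200
  fg_mock <- 100 + 10 * exp(rnorm(n, 3, 0.5))
  spots_m <- make_spots(sprintf("F%03d", 1:n), fg = fg_mock)
  spots_b <- spots_m
  ctrl <- make_spots("CTRL", fg = 150, is_control = TRUE)
  ctrl$row <- 21L
  cc <- 0.8   # log2 offset
  spots_b$fg_median <- 100 + (spots_b$fg_median - 100) * 2^cc
  bound <- array_scan(rbind(spots_b, ctrl), "bound")
  mock <- array_scan(rbind(spots_m, ctrl), "mock")
  mt <- compute_m_values(bound, mock)
  feat <- !mt$is_control
  expect_lt(max(abs(mt$m_value[feat])), 1e-6)
  expect_equal(mean(mt$d_raw[feat]), cc, tolerance = 1e-9)

  # planted linear spatial gradient, no true binders: local linear
  # regression removes a globally linear trend essentially exactly,
  # and never increases the spread of M
  sim <- gen_array(seed = 12, n_features = 800, noise_sd = 0.05,
                   spatial_grad = c(1.2, 0.8))
  mt2 <- compute_m_values(sim$bound, sim$mock)
  expect_lt(stats::sd(mt2$m_value), stats::sd(mt2$d_raw))
})

test_that("hit calls are invariant under common intensity scaling", {
  sim <- gen_array(seed = 21, n_features = 400, n_spikes = 8)
  scale_scan <- function(scan, f) {
    scan$spots$fg_median <- scan$spots$fg_median * f
    scan$spots$bg_median <- scan$spots$bg_median * f
    scan$spots$bg_sd <- scan$spots$bg_sd * f
    scan
  }
  h1 <- call_hits(compute_m_values(sim$bound, sim$mock))
  h2 <- call_hits(compute_m_values(scale_scan(sim$bound, 7.5),
                                   scale_scan(sim$mock, 7.5)))
  expect_equal(h2$table$m_value, h1$table$m_value, tolerance = 1e-9)
  expect_identical(h2$hits$feature_id, h1$hits$feature_id)
})

test_that("call_hits thresholds at mean + k * sample SD over non-controls", {
  mt <- data.frame(feature_id = paste0("F", 1:4),
                   protein_id = paste0("P", 1:4),
                   is_control = FALSE, block_id = 1L, x = 1:4, y = 1,
                   a_value = 0, d_raw = 0, m_value = c(0, 0, 0, 10))
  res <- call_hits(mt, k = 1)
  expect_equal(res$threshold, 7.5)         # mean 2.5 + 1 * sample SD 5
  expect_equal(res$hits$feature_id, "F4")
  # boundary: {0,0,0,10} at k = 1.5 puts the threshold exactly at 10,
  # and >= counts as a hit
  mt$m_value <- c(0, 0, 0, 10)
  res15 <- call_hits(mt, k = 1.5)
  expect_equal(res15$threshold, 10)
  expect_equal(res15$hits$feature_id, "F4")
  # degenerate: all equal -> no hits, warning
  mt$m_value <- rep(1, 4)
  expect_warning(res0 <- call_hits(mt), "variance")
  expect_equal(nrow(res0$hits), 0L)
})

test_that("isoform collapsing yields unique candidate ids", {
  mt <- data.frame(feature_id = paste0("F", 1:5),
                   protein_id = c("GENE1-1", "GENE1-2", "GENE2", "GENE3.b", "GENE4"),
                   is_control = FALSE, block_id = 1L, x = 1:5, y = 1,
                   a_value = 0, d_raw = 0, m_value = c(10, 9, 8, 7, -20))
  res <- call_hits(mt, k = 0)
  expect_equal(res$unique_candidates, c("GENE1", "GENE2", "GENE3"))
})
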