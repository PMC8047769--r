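test_that("TopN selects the most intense non-excluded peaks", {
  scan <- ms1_scan(100, mz = c(150, 300, 450), intensity = c(1e5, 5e5, 2e5))

  sel <- topn_select(scan, N = 2, min_intensity = 1e4)
  expect_equal(sel$requests$precursor_mz, c(300, 450))  # two most intense
  expect_equal(sel$requests$intensity, c(5e5, 2e5))
  expect_equal(sel$dew$mz, c(300, 450))
  expect_equal(sel$dew$t_f, c(100, 100))

  # most intense peak fragmented 5 s ago with t0 = 15: skipped
  dew <- data.frame(mz = 300, t_f = 95)
  sel2 <- topn_select(scan, N = 1, min_intensity = 1e4, dew = dew, t0 = 15)
  expect_equal(sel2$requests$precursor_mz, 450)

  # exactly at the window edge the peak is still excluded
  dew3 <- data.frame(mz = 300, t_f = 85)
  sel3 <- topn_select(scan, N = 1, min_intensity = 1e4, dew = dew3, t0 = 15)
  expect_equal(sel3$requests$precursor_mz, 450)

  # nothing above the floor: MS1-only duty cycle
  sel4 <- topn_select(scan, N = 2, min_intensity = 1e6)
  expect_equal(nrow(sel4$requests), 0)

  # re-fragmentation overwrites the existing exclusion record
  sel5 <- topn_select(ms1_scan(130, c(300), c(5e5)), N = 1,
                      min_intensity = 1e4, dew = sel$dew, t0 = 15)
  expect_equal(nrow(sel5$dew), 2)
  expect_equal(sel5$dew$t_f[sel5$dew$mz == 300], 130)
})

test_that("the WeightedDEW weight function has the documented shape", {
  # standard exclusion until t0, then linear to 1 at t1
  expect_equal(weighted_dew_weight(50, 30, t0 = 20, t1 = 100), 0)
  expect_equal(weighted_dew_weight(130, 30, t0 = 20, t1 = 100), 1)
  expect_equal(weighted_dew_weight(90, 30, t0 = 20, t1 = 100), 0.5)
  expect_equal(weighted_dew_weight(35, 30, t0 = 20, t1 = 100), 0)  # inside t0

  # nondecreasing and continuous on a fine grid, range exactly [0, 1]
  t <- seq(30, 200, by = 0.01)
  w <- weighted_dew_weight(t, 30, t0 = 20, t1 = 100)
  expect_true(all(diff(w) >= 0))
  expect_lt(max(abs(diff(w))), 2e-4)   # no jumps
  expect_equal(range(w), c(0, 1))

  # t1 = t0 recovers the binary window
  expect_equal(weighted_dew_weight(45, 30, 15, 15), 0)
  expect_equal(weighted_dew_weight(45.001, 30, 15, 15), 1)

  expect_error(weighted_dew_weight(10, 30, 20, 100), "future")
  expect_error(weighted_dew_weight(50, 30, 100, 20))  # t1 < t0
})

test_that("WeightedDEW ranks peaks by intensity times weight", {
  scan <- ms1_scan(100, mz = c(150, 300, 450), intensity = c(1e5, 5e5, 2e5))

  # with no history the selection equals TopN
  a <- topn_select(scan, N = 2, min_intensity = 1e4)
  b <- weighted_dew_select(scan, N = 2, min_intensity = 1e4)
  expect_equal(a$requests, b$requests)
  expect_equal(a$dew, b$dew)

  # peak A at 1e6 down-weighted to w = 0.1 loses to an unfragmented peak
  # B at 2e5 (priority 1e5 < 2e5)
  scan2 <- ms1_scan(t = 47.5, mz = c(100, 200), intensity = c(1e6, 2e5))
  dew <- data.frame(mz = 100, t_f = 25)  # dt = 22.5, t0=15, t1=90 -> w = 0.1
  expect_equal(weighted_dew_weight(47.5, 25, 15, 90), 0.1)
  sel <- weighted_dew_select(scan2, N = 1, min_intensity = 1e4, dew = dew,
                             t0 = 15, t1 = 90)
  expect_equal(sel$requests$precursor_mz, 200)

  # every candidate fully excluded: empty request list
  dew_all <- data.frame(mz = c(150, 300, 450), t_f = c(95, 95, 95))
  sel0 <- weighted_dew_select(scan, N = 3, min_intensity = 1e4,
                              dew = dew_all, t0 = 15, t1 = 120)
  expect_equal(nrow(sel0$requests), 0)
})

test_that("SmartROI requests available ROIs by descending intensity", {
  store <- roi_store(min_roi_intensity = 1e3)
  store <- update_rois(store, ms1_scan(0, c(100, 200, 300), c(2e4, 8e4, 4e4)))

  sel <- smartroi_select(store, N = 10, min_intensity = 1e3, scan_time = 0)
  expect_equal(sel$requests$precursor_mz, c(200, 300, 100))
  expect_equal(sel$requests$intensity, c(8e4, 4e4, 2e4))

  # an ROI made unavailable by rules 3a/3b is skipped even if most intense
  store2 <- sel$store
  store2 <- update_rois(store2, ms1_scan(1, c(100, 200, 300),
                                         c(2e4, 9e4, 4e4)))
  sel2 <- smartroi_select(store2, N = 10, min_intensity = 1e3,
                          alpha = 1000, beta = 0.1, scan_time = 1)
  expect_equal(nrow(sel2$requests), 0)  # none rose by alpha or fell to beta

  # zero active ROIs: empty request list
  empty <- roi_store()
  sel3 <- smartroi_select(empty, N = 5, min_intensity = 1e3, scan_time = 0)
  expect_equal(nrow(sel3$requests), 0)
})

test_that("WeightedDEW with t1 = t0 reproduces TopN scan for scan", {
  timing <- scan_timing_model(0.56, 0.2)
  for (seed in c(31, 32)) {
    mix <- generate_mixture(60, rt_range = c(0, 150), run_length = 150,
                            seed = seed)
    a <- run_acquisition(topn_controller(N = 5, dew = 15), mix,
                         timing = timing)
    b <- run_acquisition(weighted_dew_controller(N = 5, t0 = 15, t1 = 15),
                         mix, timing = timing)
    expect_identical(a$scans, b$scans)
  }
})

test_that("no controller exceeds N requests per cycle or the intensity floor", {
  mix <- generate_mixture(120, rt_range = c(0, 200), run_length = 200,
                          seed = 33)
  N <- 4
  for (ctl in list(topn_controller(N = N),
                   weighted_dew_controller(N = N),
                   smartroi_controller(N = N))) {
    run <- run_acquisition(ctl, mix, timing = scan_timing_model(0.6, 0.2))
    ms2 <- run$scans[run$scans$level == 2L, ]
    expect_true(all(table(ms2$source_ms1_index) <= N))
    expect_true(all(ms2$precursor_intensity >= 5e3))
  }
})

test_that("TopN never re-requests an m/z inside the exclusion window", {
  mix <- generate_mixture(80, rt_range = c(0, 300), run_length = 300,
                          seed = 34)
  run <- run_acquisition(topn_controller(N = 5, dew = 15), mix,
                         timing = scan_timing_model(0.56, 0.2))
  ev <- fragmentation_events(run)
  # synthetic peaks sit at their exact m/z, so repeats are exact repeats
  by_mz <- split(ev$source_ms1_time, ev$precursor_mz)
  gaps <- unlist(lapply(by_mz, function(x) diff(sort(x))))
  if (length(gaps) > 0) expect_true(all(gaps > 15))
})

test_that("SmartROI with alpha = Inf, beta = 0 fragments each ROI at most once", {
  for (seed in c(35, 36)) {
    mix <- generate_mixture(100, rt_range = c(0, 200), run_length = 200,
                            seed = seed)
    run <- run_acquisition(
      smartroi_controller(N = 10, alpha = Inf, beta = 0), mix,
      timing = scan_timing_model(0.68, 0.2))
    store <- run$controller_state$store
    nfrag <- vapply(c(store$active, store$discarded),
                    function(r) r$n_fragmentations, integer(1))
    expect_true(all(nfrag <= 1L))
    expect_gt(sum(nfrag), 0)  # the run did fragment something
  }
})
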