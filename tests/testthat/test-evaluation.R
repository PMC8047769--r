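test_that("events are assigned to boxes with inclusive bounds", {
  boxes <- data.frame(id = c("a", "b"),
                      mz_min = c(99.99, 199.99), mz_max = c(100.01, 200.01),
                      rt_min = c(10, 15), rt_max = c(20, 25))
  ev <- data.frame(time = c(15, 30, 20, 15),
                   precursor_mz = c(100, 100, 100.01, 150))
  hits <- assign_events(ev, boxes)
  expect_equal(hits[[1]], "a")          # inside one box
  expect_equal(hits[[2]], character(0)) # outside all boxes in RT
  expect_equal(hits[[3]], "a")          # exactly at the m/z and RT corner
  expect_equal(hits[[4]], character(0)) # between the boxes in m/z

  # overlapping boxes: one event can hit several
  overlap <- data.frame(id = c("x", "y"),
                        mz_min = c(99.9, 99.9), mz_max = c(100.1, 100.1),
                        rt_min = c(0, 0), rt_max = c(50, 50))
  h2 <- assign_events(data.frame(time = 10, precursor_mz = 100), overlap)
  expect_equal(h2[[1]], c("x", "y"))
})

test_that("coverage counts distinct fragmented boxes", {
  boxes <- data.frame(id = c("a", "b"),
                      mz_min = c(99.99, 199.99), mz_max = c(100.01, 200.01),
                      rt_min = c(10, 15), rt_max = c(20, 25))
  two_in_one <- data.frame(time = c(12, 18), precursor_mz = c(100, 100))
  expect_equal(coverage(two_in_one, boxes), 1)
  none <- data.frame(time = numeric(0), precursor_mz = numeric(0))
  expect_equal(coverage(none, boxes), 0)

  # randomized instances equal a brute-force double loop
  set.seed(61)
  for (i in 1:5) {
    n_b <- 15; n_e <- 40
    centers_mz <- runif(n_b, 100, 110)
    centers_rt <- runif(n_b, 0, 100)
    b <- data.frame(id = sprintf("b%02d", 1:n_b),
                    mz_min = centers_mz - 0.5, mz_max = centers_mz + 0.5,
                    rt_min = centers_rt - 10, rt_max = centers_rt + 10)
    e <- data.frame(time = runif(n_e, 0, 100),
                    precursor_mz = runif(n_e, 100, 110))
    oracle <- 0L
    for (j in seq_len(n_b)) {
      hit <- FALSE
      for (k in seq_len(n_e)) {
        if (b$mz_min[j] <= e$precursor_mz[k] &&
            e$precursor_mz[k] <= b$mz_max[j] &&
            b$rt_min[j] <= e$time[k] && e$time[k] <= b$rt_max[j]) hit <- TRUE
      }
      oracle <- oracle + hit
    }
    expect_equal(coverage(e, b), oracle)
    # invariant to event and box order
    expect_equal(coverage(e[rev(seq_len(n_e)), ], b[sample(n_b), ]), oracle)
  }
})

test_that("single-credit mode assigns each event to at most one box", {
  overlap <- data.frame(id = c("x", "y"),
                        mz_min = c(99.9, 99.9), mz_max = c(100.1, 100.1),
                        rt_min = c(0, 0), rt_max = c(50, 50))
  one_event <- data.frame(time = 10, precursor_mz = 100)
  expect_equal(coverage(one_event, overlap), 2)
  expect_equal(coverage(one_event, overlap, unique_assignment = TRUE), 1)
})

test_that("efficiency is coverage over MS2 scans, exactly", {
  boxes <- data.frame(id = "a", mz_min = 99.99, mz_max = 100.01,
                      rt_min = 0, rt_max = 100)
  ev <- data.frame(time = c(10, 20), precursor_mz = c(100, 100))
  expect_equal(efficiency(ev, boxes, n_ms2 = 4), 0.25)
  expect_error(efficiency(ev, boxes, n_ms2 = 0), "undefined")

  # identity: efficiency * n_ms2 == coverage before any rounding
  mix <- generate_mixture(70, rt_range = c(0, 150), run_length = 150,
                          seed = 62)
  run <- run_acquisition(topn_controller(N = 4), mix,
                         timing = scan_timing_model(0.56, 0.2))
  rep <- evaluate_run(run, ground_truth_boxes(mix))
  expect_equal(rep$efficiency * rep$n_ms2, rep$coverage)
  expect_equal(rep$n_scans, rep$n_ms1 + rep$n_ms2)
  expect_equal(sum(rep$box_hits > 0), rep$coverage)
  expect_lte(rep$coverage, rep$n_boxes)
})

test_that("grid search scores every point and returns the argmax", {
  mix <- generate_mixture(40, rt_range = c(0, 120), run_length = 120,
                          seed = 63)
  timing <- scan_timing_model(0.56, 0.2)

  # single-point grid returns that point
  g1 <- grid_search("topn", data.frame(dew = 15), mix, timing = timing,
                    fixed = list(N = 3))
  expect_equal(nrow(g1$table), 1)
  expect_equal(g1$best$params$dew, 15)
  expect_equal(g1$best$score, g1$table$coverage[1])

  # a t1 = t0 WeightedDEW point scores identically to the matching TopN
  gw <- grid_search("weighteddew",
                    expand.grid(t0 = 15, t1 = c(15, 120)), mix,
                    timing = timing, fixed = list(N = 3))
  expect_equal(nrow(gw$table), 2)
  expect_equal(gw$table$coverage[1], g1$table$coverage[1])
  expect_equal(gw$table$n_ms2[1], g1$table$n_ms2[1])

  # ties break toward earlier grid order
  gtie <- grid_search("topn", data.frame(dew = c(15, 15)), mix,
                      timing = timing, fixed = list(N = 3))
  expect_equal(gtie$best$row, 1L)

  expect_error(grid_search("topn", data.frame(), mix), "grid")
  expect_error(grid_search("nope", data.frame(dew = 1), mix), "unknown")
})

test_that("runs, reports and configs round-trip through files", {
  mix <- generate_mixture(30, rt_range = c(0, 100), run_length = 100,
                          seed = 64)
  run <- run_acquisition(topn_controller(N = 3), mix,
                         timing = scan_timing_model(0.56, 0.2))
  p <- withr::local_tempfile(fileext = ".csv")
  write_acquisition_csv(run, p)
  back <- read_acquisition_csv(p)
  expect_equal(back, run$scans, tolerance = 1e-12)

  rep <- evaluate_run(run, ground_truth_boxes(mix))
  pj <- withr::local_tempfile(fileext = ".json")
  write_evaluation_json(rep, pj)
  parsed <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_equal(parsed$coverage, rep$coverage)
  expect_equal(parsed$efficiency, rep$efficiency)

  cfg <- list(controller = "smartroi",
              params = list(N = 10, alpha = 1000, beta = 0.1),
              timing = list(ms1 = 0.68, ms2 = 0.2),
              run_length = 1560, seed = 1)
  py <- withr::local_tempfile(fileext = ".yml")
  write_config(cfg, py)
  expect_equal(read_config(py), cfg)
})

test_that("mean scan durations are recovered from a log", {
  mix <- generate_mixture(50, rt_range = c(0, 150), run_length = 150,
                          seed = 65)
  run <- run_acquisition(topn_controller(N = 5), mix,
                         timing = scan_timing_model(0.61, 0.23))
  mst <- mean_scan_times(run)
  expect_equal(mst$mean_ms1, 0.61, tolerance = 1e-9)
  expect_equal(mst$mean_ms2, 0.23, tolerance = 1e-9)
})
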