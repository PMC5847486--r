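test_that("synthetic scenes are reproducible and respect the requested SNR", {
  s1 <- bench_scene(51, n_filaments = 4, snr = 0.2, image_A = 2500)
  s2 <- bench_scene(51, n_filaments = 4, snr = 0.2, image_A = 2500)
  expect_identical(s1$micrograph$pixels, s2$micrograph$pixels)
  expect_identical(s1$truth_traces, s2$truth_traces)
  expect_false(identical(
    s1$micrograph$pixels,
    bench_scene(52, n_filaments = 4, snr = 0.2, image_A = 2500)$micrograph$pixels))
  # variance ratio of the rendered signal to the added noise
  noise <- s1$micrograph$pixels - s1$signal
  expect_equal(var(as.numeric(s1$signal)) / var(as.numeric(noise)), 0.2,
               tolerance = 0.05)
  # truth paths stay inside the frame with the width buffer
  for (tr in s1$truth_traces) {
    expect_true(all(tr >= 100))
    expect_true(all(tr <= 2400))
  }
  expect_error(bench_scene(1, image_A = 800, length_range_A = c(900, 1000)),
               "fit")
})

test_that("a noise-free straight filament correlates almost perfectly with
           the matched reference", {
  path <- cbind(x = rep(1250, 2), y = c(300, 2200))
  img <- helixtracer:::render_path(matrix(0, 250, 250), path, 100, 50, 10)
  m <- micrograph(img, 10, "clean")
  p <- bench_params()
  work <- normalize_and_bin(m, 1)  # no high-pass: keep the pure signal
  g <- make_tile_grid(dim(work$pixels), p, 10)
  prep <- prepare_reference(bench_ref(g$tile_size_px), g, 10)
  # tile centered on the filament
  org <- g$origins[which.min(abs(g$origins[, "col"] + 25 - 125) +
                               abs(g$origins[, "row"] + 25 - 125)), ]
  tile <- extract_tile(work, org, g)
  tm <- translational_match(tile, 0, prep$image)
  expect_gt(tm$cc_score, 0.95)
  expect_lte(abs(tm$delta_px - (125 - (org[2] + 25))), 1)
})

test_that("box files roundtrip helix coordinates in the corner convention", {
  tr1 <- structure(list(coords_A = cbind(x = c(1000, 1500, 2000),
                                         y = c(2000, 2100, 2200))),
                   class = "helix_trace")
  ts <- structure(list(traces = list(tr1)), class = "trace_set")
  f <- withr::local_tempfile(fileext = ".box")
  write_box(ts, f, pixel_size_A = 1, box_size_px = 100)
  lines <- readLines(f)
  body <- lines[!grepl("^#", lines)]
  expect_equal(body[1], "950\t1950\t100\t100\t-1")  # corner = center - box/2
  expect_equal(body[2], "1950\t2150\t100\t100\t-2")
  back <- read_box(f, pixel_size_A = 1)
  expect_length(back, 1)
  expect_equal(back[[1]], cbind(x = c(1000, 2000), y = c(2000, 2200)))
  # segments variant keeps every coordinate
  write_box(ts, f, pixel_size_A = 1, box_size_px = 100, segments = TRUE)
  back2 <- read_box(f, pixel_size_A = 1)
  expect_equal(back2[[1]], unname(tr1$coords_A), ignore_attr = TRUE)
  # empty trace set: header-only file
  write_box(structure(list(traces = list()), class = "trace_set"), f, 1)
  expect_length(read_box(f, 1), 0)
  expect_match(readLines(f)[1], "^#")
})

test_that("angstrom/pixel coordinate conversions compose to identity", {
  ps_raw <- 1.07; bin <- 4
  x_A <- c(1177, 2043.5, 3899.12)
  binned_px <- x_A / (ps_raw * bin)
  unbinned_px <- binned_px * bin
  expect_equal(unbinned_px * ps_raw, x_A, tolerance = 1e-9)
  # rounding to whole unbinned pixels stays within half a pixel
  expect_lt(max(abs(round(unbinned_px) - unbinned_px)), 0.5 + 1e-12)
})

test_that("config files map Table-style keys onto tracing parameters", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# ParM-like settings",
               "tile_size_A = 500",
               "overlap-pct = 80",
               "Binning Factor = 4",
               "helix_width_A = 80",
               "min_helix_len_A = 594",
               "max_helix_len_A = 1500",
               "alpha = 0.000859"), f)
  p <- read_config(f)
  expect_s3_class(p, "tracing_params")
  expect_equal(p$tile_size_A, 500)
  expect_equal(p$binning_factor, 4L)
  expect_equal(p$helix_width_A, 80)
  expect_equal(p$alpha, 0.000859)
  expect_equal(p$min_helix_len_A, 594)
})

test_that("the full pipeline is deterministic and finds clean filaments", {
  scene <- bench_scene(53, n_filaments = 5, snr = 0.3, image_A = 3000,
                       length_range_A = c(800, 1300))
  ref <- bench_ref()
  ts1 <- trace_micrograph(scene$micrograph, ref, bench_params(), prune = FALSE)
  ts2 <- trace_micrograph(scene$micrograph, ref, bench_params(), prune = FALSE)
  expect_identical(lapply(ts1$traces, `[[`, "coords_A"),
                   lapply(ts2$traces, `[[`, "coords_A"))
  expect_gte(length(ts1$traces), 3)
})

test_that("straight filaments at high SNR are each traced within one helix
           width of their axis", {
  # five perfectly straight filaments in parallel lanes (no crossings)
  set.seed(55)
  sig <- matrix(0, 300, 300)
  truth <- list()
  for (k in 1:5) {
    y <- 250 + 500 * k
    x0 <- runif(1, 400, 800); len <- runif(1, 1000, 1300)
    ang <- runif(1, -0.15, 0.15)
    truth[[k]] <- cbind(x = c(x0, x0 + len * cos(ang)),
                        y = c(y, y + len * sin(ang)))
    sig <- helixtracer:::render_path(sig, truth[[k]], 100, 50, 10)
  }
  noise <- matrix(rnorm(300^2, 0, sd(sig)), 300)  # SNR 1
  m <- micrograph(sig + noise, 10, "lanes")
  # max length above filament length + end overshoot so nothing is split
  ts <- trace_micrograph(m, bench_ref(),
                         bench_params(max_helix_len_A = 2000), prune = FALSE)
  expect_length(ts$traces, 5)
  # lateral deviation from the generating axis (trace ends may overshoot
  # along the axis by up to half a tile; that ambiguity is axial, not
  # lateral, and is excluded by the end discs in formal evaluation)
  line_dist <- function(q, p0, p1) {
    v <- p1 - p0
    abs((q[1] - p0[1]) * v[2] - (q[2] - p0[2]) * v[1]) / sqrt(sum(v^2))
  }
  for (tr in ts$traces) {
    d <- apply(tr$coords_A, 1, function(q)
      min(vapply(truth, function(p) line_dist(q, p[1, ], p[2, ]),
                 numeric(1))))
    expect_gte(mean(d <= 100), 0.9)
    expect_lt(median(d), 30)  # the axis itself is recovered tightly
  }
})

test_that("cli rejects bad invocations and runs the synthetic chain", {
  expect_equal(suppressMessages(hx_cli(character(0))), 2L)
  expect_equal(suppressMessages(hx_cli(c("trace", "--input"))), 2L)
  expect_equal(suppressMessages(hx_cli(c("nonsense", "--a", "1"))), 2L)
  expect_equal(suppressMessages(hx_cli(c("trace", "--input", "x.mrc"))), 2L)
  dir <- withr::local_tempdir()
  mrc <- file.path(dir, "scene.mrc")
  truth <- file.path(dir, "truth.box")
  out <- file.path(dir, "trace.box")
  refp <- file.path(dir, "ref.mrc")
  st <- suppressMessages(hx_cli(c(
    "synthesize", "--output", mrc, "--truth-out", truth,
    "--filaments", "4", "--snr", "0.5", "--image-size", "2500",
    "--pixel-size", "10", "--seed", "54")))
  expect_equal(st, 0L)
  expect_true(file.exists(mrc) && file.exists(truth))
  ref <- bench_ref()
  write_mrc(ref$pixels, refp, pixel_size_A = 10)
  st <- suppressMessages(hx_cli(c(
    "trace", "--input", mrc, "--reference", refp, "--output", out,
    "--pixel-size", "10", "--binning", "1", "--min-length", "500",
    "--max-length", "1500", "--alpha", "0.001")))
  expect_equal(st, 0L)
  expect_true(file.exists(out))
  ev_out <- capture.output(st <- suppressMessages(hx_cli(c(
    "evaluate", "--result", out, "--truth", truth, "--pixel-size", "10",
    "--extent", "2500", "--helix-width", "100"))))
  expect_equal(st, 0L)
  expect_match(ev_out[3], "^F1\t")
  f1 <- as.numeric(sub("^F1\t", "", ev_out[3]))
  expect_gte(f1, 0)
  st <- suppressMessages(hx_cli(c("simulate", "--persistence", "33.9",
                                  "--chains", "50", "--seed", "3")))
  expect_equal(st, 0L)
})
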