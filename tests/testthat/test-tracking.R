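test_that("stationary detections link to their own heads at zero cost", {
  heads <- tibble::tibble(row = c(10, 40), col = c(10, 40))
  det <- tibble::tibble(row = c(40, 10), col = c(40, 10))
  lk <- link_frame(heads, det, gate_px = 15)
  expect_equal(lk$assignment, c(2L, 1L))
  expect_equal(lk$total_distance, 0)
  expect_length(lk$unmatched_detections, 0)
})

test_that("crossing configurations match the brute-force optimum", {
  heads <- tibble::tibble(row = c(10, 12), col = c(10, 12))
  det <- tibble::tibble(row = c(11.5, 10.2), col = c(11.5, 10.2))
  lk <- link_frame(heads, det, gate_px = 15)
  D <- sqrt(outer(heads$row, det$row, "-")^2 + outer(heads$col, det$col, "-")^2)
  orc <- oracle_assignment(D, 15)
  expect_equal(lk$total_distance, orc$cost, tolerance = 1e-9)
  expect_equal(sum(!is.na(lk$assignment)), orc$count)
})

test_that("detections beyond the gate leave heads gapped", {
  heads <- tibble::tibble(row = 10, col = 10)
  det <- tibble::tibble(row = 60, col = 60)
  lk <- link_frame(heads, det, gate_px = 15)
  expect_true(is.na(lk$assignment[1]))
  expect_equal(lk$unmatched_detections, 1L)
  expect_error(link_frame(heads, det, gate_px = 0),
               class = "wormtrace_invalid_parameter")
})

test_that("gated assignment equals full enumeration on random instances", {
  set.seed(10)
  for (i in 1:200) {
    nh <- sample(1:4, 1); nd <- sample(1:4, 1)
    heads <- tibble::tibble(row = runif(nh, 0, 100), col = runif(nh, 0, 100))
    det <- tibble::tibble(row = runif(nd, 0, 100), col = runif(nd, 0, 100))
    gate <- runif(1, 10, 80)
    lk <- link_frame(heads, det, gate)
    D <- sqrt(outer(heads$row, det$row, "-")^2 +
              outer(heads$col, det$col, "-")^2)
    orc <- oracle_assignment(D, gate)
    expect_equal(sum(!is.na(lk$assignment)), orc$count)
    expect_equal(lk$total_distance, orc$cost, tolerance = 1e-9)
  }
})

test_that("a drift-free noiseless pair yields two gap-free tracks on ground truth", {
  sim <- simulate_movie(static_scene(seed = 1, n_frames = 30,
                                     shot_noise = FALSE, read_noise_sd = 0))
  st <- segment_and_track(sim, label_seed = 3)
  expect_false(st$track_set$failed)
  expect_length(st$track_set$tracks, 2)
  H <- 64
  for (tr in st$track_set$tracks) {
    expect_false(any(tr$data$gap))
    # nearest ground-truth neuron is within 1 px on every frame
    for (t in c(1, 15, 30)) {
      d <- vapply(sim$truth$masks, function(m) {
        lin <- m[[t]]
        sqrt((mean((lin - 1) %% H) - tr$data$row[t])^2 +
             (mean((lin - 1) %/% H) - tr$data$col[t])^2)
      }, 0)
      expect_lt(min(d), 1)
    }
  }
})

test_that("a missing detection produces a gap and the identity survives coasting", {
  segs <- lapply(1:12, function(t) {
    comps <- tibble::tibble(label = 1:2, area = c(40L, 38L),
                            centroid_row = c(10, 40) + 0.2 * t,
                            centroid_col = c(10, 40),
                            mean_intensity = c(200, 180))
    if (t == 6) comps <- comps[1, ]    # second neuron vanishes at frame 6
    structure(list(frame = t - 1L, components = comps,
                   pixels = rep(list(1L), nrow(comps))),
              class = "frame_segmentation")
  })
  ts <- track_movie(segs, expected_count = 2, gate_px = 10, max_gap = 3)
  expect_false(ts$failed)
  cov <- vapply(ts$tracks, function(tr) sum(!tr$data$gap), 0L)
  expect_setequal(cov, c(12L, 11L))
  tr2 <- ts$tracks[[which.min(cov)]]
  expect_true(tr2$data$gap[6])
  expect_false(tr2$data$gap[7])
  expect_equal(tr2$data$row[7], 40 + 0.2 * 7)
})

test_that("tracks that exceed the gap limit are terminated and flagged", {
  segs <- lapply(1:20, function(t) {
    comps <- tibble::tibble(label = 1L, area = 40L,
                            centroid_row = 10, centroid_col = 10,
                            mean_intensity = 200)
    if (t >= 5) comps <- comps[0, ]
    structure(list(frame = t - 1L, components = comps,
                   pixels = rep(list(1L), nrow(comps))),
              class = "frame_segmentation")
  })
  ts <- track_movie(segs, expected_count = 1, gate_px = 10, max_gap = 5)
  expect_true(ts$tracks[[1]]$terminated)
  expect_true(ts$failed)
})

test_that("a movie with no usable initialization frame is flagged failed", {
  segs <- lapply(1:15, function(t)
    structure(list(frame = t - 1L,
                   components = tibble::tibble(label = integer(),
                                               area = integer(),
                                               centroid_row = numeric(),
                                               centroid_col = numeric(),
                                               mean_intensity = numeric()),
                   pixels = list()), class = "frame_segmentation"))
  ts <- track_movie(segs, expected_count = 2)
  expect_true(ts$failed)
  expect_length(ts$tracks, 0)
})

test_that("pair identity is positional, order-invariant, and tie-flagged", {
  mk_ts <- function(cols1, cols2, rows1 = 10, rows2 = 40) {
    mk <- function(id, cols, rows) list(
      track_id = id, identity = NA_character_, terminated = FALSE,
      gap_run_max = 0L,
      data = tibble::tibble(frame = seq_along(cols) - 1, row = rows,
                            col = cols, area = 40L, label = 1L, gap = FALSE))
    structure(list(tracks = list(mk(1, cols1, rows1), mk(2, cols2, rows2)),
                   failed = FALSE, n_frames = length(cols1)),
              class = "track_set")
  }
  a <- assign_pair_identity(mk_ts(c(40, 41, 40), c(90, 91, 90)))
  expect_equal(vapply(a$tracks, `[[`, "", "identity"), c("left", "right"))
  b <- assign_pair_identity(mk_ts(c(90, 91, 90), c(40, 41, 40)))
  expect_equal(vapply(b$tracks, `[[`, "", "identity"), c("right", "left"))
  expect_false(a$tie_flag)

  tie <- assign_pair_identity(mk_ts(c(50, 50, 50), c(50, 50, 50),
                                    rows1 = 30, rows2 = 10))
  expect_true(tie$tie_flag)
  expect_equal(vapply(tie$tracks, `[[`, "", "identity"), c("right", "left"))
})

test_that("no detection is shared between tracks and identities match construction", {
  sim <- simulate_movie(tiny_scene(seed = 13, n_frames = 50))
  st <- segment_and_track(sim, label_seed = 4)
  expect_false(st$track_set$failed)
  ts <- assign_pair_identity(st$track_set)
  for (t in 1:50) {
    labs <- vapply(ts$tracks, function(tr) tr$data$label[t], 1L)
    labs <- labs[!is.na(labs)]
    expect_equal(anyDuplicated(labs), 0L)
  }
  expect_equal(count_identity_switches(ts, sim$truth), 0L)
  # N1 sits at column 20, N2 at 46: left must follow N1
  left <- ts$tracks[[which(vapply(ts$tracks, `[[`, "", "identity") == "left")]]
  expect_lt(median(left$data$col, na.rm = TRUE), 33)
})
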