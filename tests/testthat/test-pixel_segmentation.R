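test_that("feature planes are the advertised transforms", {
  set.seed(1)
  img <- matrix(runif(32 * 32, 0, 200), 32, 32)

  fc <- feature_bank_config(c("identity", "range"), c(NA, 3))
  X <- compute_feature_bank(img, fc)
  expect_identical(X[, "identity"], as.numeric(img))

  const <- matrix(7, 32, 32)
  Xc <- compute_feature_bank(const, feature_bank_config("range", 3))
  expect_true(all(Xc == 0))

  # range filter equals brute-force local max - min with replicated borders
  rng <- matrix(compute_feature_bank(img, feature_bank_config("range", 5)),
                32, 32)
  for (p in list(c(1, 1), c(5, 9), c(32, 32), c(16, 2))) {
    rs <- pmin(pmax(p[1] + (-2:2), 1), 32)
    cs <- pmin(pmax(p[2] + (-2:2), 1), 32)
    expect_equal(rng[p[1], p[2]], max(img[rs, cs]) - min(img[rs, cs]))
  }

  # median against the brute-force sliding window, including borders
  out <- matrix(compute_feature_bank(img, feature_bank_config("median", 3)),
                32, 32)
  expect_equal(out, oracle_median_filter(img, 3), tolerance = 1e-12)
  img2 <- matrix(100, 9, 9); img2[5, 5] <- 10000   # single outlier
  out2 <- matrix(compute_feature_bank(img2, feature_bank_config("median", 3)),
                 9, 9)
  expect_equal(out2[5, 5], 100)

  expect_error(feature_bank_config("laplacian", 3),
               class = "wormtrace_invalid_parameter")
  expect_error(feature_bank_config(character(), numeric()),
               class = "wormtrace_invalid_parameter")
})

test_that("reordering the feature config reorders planes identically", {
  set.seed(2)
  img <- matrix(runif(32 * 32, 0, 200), 32, 32)
  fc <- feature_bank_config(c("identity", "gaussian", "median", "range"),
                            c(NA, 2, 3, 3))
  X <- compute_feature_bank(img, fc)
  perm <- c(3, 1, 4, 2)
  Xp <- compute_feature_bank(img, fc[perm, ])
  expect_identical(unname(Xp), unname(X[, perm]))
})

test_that("the fast tree applier reproduces predict.rpart exactly", {
  set.seed(3)
  n <- 5000
  X <- matrix(runif(n * 4), n, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- factor(as.integer(X[, 1] + 0.5 * X[, 3] + rnorm(n, 0, 0.1) > 0.8))
  df <- data.frame(X, .class = y)
  fit <- rpart::rpart(.class ~ ., df, method = "class",
                      control = rpart::rpart.control(maxdepth = 8,
                                                     minbucket = 20, cp = 1e-4,
                                                     xval = 0, maxcompete = 0,
                                                     maxsurrogate = 0,
                                                     usesurrogate = 0))
  expect_identical(wormtrace:::rpart_apply(fit, X),
                   unname(predict(fit, data.frame(X), type = "class")))
})

test_that("separable labels train to perfect accuracy; single-class input errors", {
  set.seed(4)
  img <- matrix(runif(40 * 40, 0, 64), 40, 40)
  img[10:20, 10:20] <- runif(121, 128, 255)
  lab <- matrix(255L, 40, 40)
  lab[img > 128] <- 1L
  lab[img < 64] <- 0L
  clf <- train_pixel_classifier(list(img), list(lab),
                                feature_bank_config("identity", NA),
                                min_leaf = 5)
  expect_equal(clf$train_accuracy, 1)

  lab0 <- matrix(0L, 40, 40)
  expect_error(train_pixel_classifier(list(img), list(lab0)),
               class = "wormtrace_invalid_training")
})

test_that("classifier application is deterministic and respects training accuracy", {
  sim <- simulate_movie(tiny_scene(seed = 5, n_frames = 40))
  proj <- max_project(sim$movie)
  labels <- training_labels_from_truth(sim$truth, frames = c(0:4, 17:21),
                                       seed = 1)
  frames <- lapply(c(1:5, 18:22), function(t) proj$data[, , t])
  fc <- feature_bank_config(c("identity", "gaussian", "median", "range"),
                            c(NA, 2, 3, 3))
  clf <- train_pixel_classifier(frames, labels, fc, seed = 1)
  clf2 <- train_pixel_classifier(frames, labels, fc, seed = 1)
  m1 <- apply_classifier(frames[[1]], clf)
  expect_identical(m1, apply_classifier(frames[[1]], clf2))

  # reproduces >= training accuracy on its own labelled pixels
  lab <- labels[[1]]
  sel <- lab %in% c(0L, 1L)
  acc <- mean((m1[sel] * 1L) == lab[sel])
  expect_gte(acc, clf$train_accuracy - 0.02)

  # a neuron-free, stimulus-free frame yields a near-empty mask
  flat <- simulate_movie(tiny_scene(amplitude = c(0, 0), seed = 6,
                                    n_frames = 10))
  bgonly <- max_project(flat$movie)$data[, , 1]
  bgonly[] <- pmin(bgonly, 130)   # clamp away the somata
  expect_lt(mean(apply_classifier(bgonly, clf)), 0.02)
})

test_that("8-connected labelling merges diagonal touches and filtering keeps the largest", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE     # diagonal pair
  seg <- postprocess_masks(m, min_area = 1, expected_count = 5)
  expect_equal(nrow(seg$components), 1)
  expect_equal(seg$components$area, 2)

  # areas {50, 4, 60}, min_area 10, expected 2 -> keep {60, 50}
  m2 <- matrix(FALSE, 40, 40)
  m2[2:11, 2:6] <- TRUE            # 50 px
  m2[20:21, 20:21] <- TRUE         # 4 px
  m2[25:34, 25:30] <- TRUE         # 60 px
  seg2 <- postprocess_masks(m2, min_area = 10, expected_count = 2)
  expect_equal(seg2$components$area, c(60, 50))

  empty <- postprocess_masks(matrix(FALSE, 10, 10), 5, 2)
  expect_equal(nrow(empty$components), 0)
  expect_error(postprocess_masks(m, min_area = 1, expected_count = 0),
               class = "wormtrace_invalid_parameter")
})

test_that("component centroids sit within 1 px of simulator ground truth", {
  sim <- simulate_movie(static_scene(seed = 7, n_frames = 20,
                                     shot_noise = FALSE, read_noise_sd = 0))
  proj <- max_project(sim$movie)
  st <- segment_and_track(sim, label_seed = 2)
  H <- 64
  for (t in c(1, 10, 20)) {
    comp <- st$segs[[t]]$components
    for (nm in names(sim$truth$masks)) {
      lin <- sim$truth$masks[[nm]][[t]]
      gt <- c(mean((lin - 1) %% H), mean((lin - 1) %/% H))
      d <- sqrt((comp$centroid_row - gt[1])^2 + (comp$centroid_col - gt[2])^2)
      expect_lt(min(d), 1)
    }
  }
})

test_that("fixed and Otsu thresholding behave as specified", {
  img <- matrix(runif(100, 10, 250), 10, 10)
  expect_true(all(threshold_baseline(img, "fixed", 0)))

  set.seed(8)
  bim <- matrix(c(rnorm(200, 50, 5), rnorm(200, 200, 5)), 20, 20)
  th_mask <- threshold_baseline(bim, "global_otsu")
  oth <- oracle_otsu(bim)      # exhaustive intra-class variance minimizer
  expect_identical(th_mask, bim >= oth)
  expect_equal(sum(th_mask), 200)   # separates the modes
  expect_error(threshold_baseline(img, "fixed"),
               class = "wormtrace_invalid_parameter")
})
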