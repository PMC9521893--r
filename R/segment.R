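# Trainable pixel segmentation: a decision tree over a filter-bank feature
# stack (gaussian / median / range transforms of the frame), trained on a
# few sparsely labelled frames and applied to the whole movie, then reduced
# to 8-connected components. A global-threshold baseline (Otsu) is kept for
# comparison.

#' Define a filter-bank feature configuration
#'
#' @param transform Character vector in `{identity, gaussian, median,
#'   range}`.
#' @param scale Numeric vector: sigma (px) for gaussian, odd window width
#'   (px) for median/range, `NA` for identity.
#' @return Tibble with columns `transform`, `scale`, `name`.
#' @export
feature_bank_config <- function(transform = c("identity", "gaussian",
                                              "gaussian", "gaussian",
                                              "median", "median",
                                              "range", "range"),
                                scale = c(NA, 1, 2, 4, 3, 5, 3, 5)) {
  if (length(transform) < 1 || length(transform) != length(scale))
    abort("feature_bank_config: transform and scale must match and be non-empty.",
          class = "wormtrace_invalid_parameter")
  bad <- setdiff(transform, c("identity", "gaussian", "median", "range"))
  if (length(bad))
    abort(paste0("feature_bank_config: unknown transform(s): ",
                 paste(bad, collapse = ", ")),
          class = "wormtrace_invalid_parameter")
  if (any(!is.na(scale) & scale <= 0))
    abort("feature_bank_config: scales must be positive.",
          class = "wormtrace_invalid_parameter")
  tibble(transform = transform, scale = scale,
         name = ifelse(transform == "identity", "identity",
                       paste0(transform, "_", scale)))
}

.gauss_cache <- new.env(parent = emptyenv())

# dense 1-D Gaussian convolution operator with replicated borders, cached
# per (n, sigma); blur = K_H %*% img %*% t(K_W) (BLAS, faster per frame than
# FFT filtering at these sizes)
gauss_operator <- function(n, sigma) {
  key <- paste(n, sigma)
  if (!is.null(.gauss_cache[[key]])) return(.gauss_cache[[key]])
  r <- ceiling(3 * sigma)
  g <- exp(-(-r:r)^2 / (2 * sigma^2))
  g <- g / sum(g)
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (o in -r:r) {
    j <- pmin(pmax(idx + o, 1L), n)
    K[cbind(idx, j)] <- K[cbind(idx, j)] + g[o + r + 1]
  }
  .gauss_cache[[key]] <- K
  K
}

gaussian_filter <- function(image, sigma) {
  gauss_operator(nrow(image), sigma) %*% image %*%
    t(gauss_operator(ncol(image), sigma))
}

apply_transform <- function(image, transform, scale) {
  switch(transform,
    identity = image,
    gaussian = gaussian_filter(image, scale),
    median = {
      if (scale == 3) median3_filter(image)
      else {
        mx <- max(image, 1)
        EBImage::medianFilter(image / mx, size = as.integer((scale - 1) / 2)) * mx
      }
    },
    range = range_filter(image, as.integer(scale)),
    abort(paste0("compute_feature_bank: unknown transform '", transform, "'."),
          class = "wormtrace_invalid_parameter"))
}

# local max - min over a w x w window with replicated borders, computed
# separably (EBImage grayscale morphology clamps intensities to [0, 1], so
# it cannot be used on count-scale images)
range_filter <- function(image, w) {
  h <- (w - 1L) %/% 2L
  H <- nrow(image); W <- ncol(image)
  amin <- function(a, b) { s <- a + b; (s - abs(a - b)) / 2 }
  amax <- function(a, b) { s <- a + b; (s + abs(a - b)) / 2 }
  mx <- image; mn <- image
  for (o in setdiff(-h:h, 0L)) {
    idx <- pmin(pmax(seq_len(H) + o, 1L), H)
    mx <- amax(mx, image[idx, , drop = FALSE])
    mn <- amin(mn, image[idx, , drop = FALSE])
  }
  mx2 <- mx; mn2 <- mn
  for (o in setdiff(-h:h, 0L)) {
    idx <- pmin(pmax(seq_len(W) + o, 1L), W)
    mx2 <- amax(mx2, mx[, idx, drop = FALSE])
    mn2 <- amin(mn2, mn[, idx, drop = FALSE])
  }
  mx2 - mn2
}

# exact 3x3 median with replicated borders via a 9-input min/max median
# network (EBImage::medianFilter is slow at radius 1 and quantizes)
median3_filter <- function(image) {
  H <- nrow(image); W <- ncol(image)
  P <- matrix(0, H + 2L, W + 2L)
  P[2:(H + 1), 2:(W + 1)] <- image
  P[1, ] <- P[2, ]; P[H + 2L, ] <- P[H + 1L, ]
  P[, 1] <- P[, 2]; P[, W + 2L] <- P[, W + 1L]
  base <- rep((2:(W + 1)) - 1L, each = H) * (H + 2L) + rep(2:(H + 1), W)
  x <- vector("list", 9)
  k <- 1L
  for (dx in -1:1) for (dy in -1:1) {
    x[[k]] <- P[base + dy + dx * (H + 2L)]
    k <- k + 1L
  }
  sw <- function(i, j) {
    a <- x[[i]]; b <- x[[j]]
    s <- a + b; d <- abs(a - b)      # exact min/max for values << 2^52
    x[[i]] <<- (s - d) / 2; x[[j]] <<- (s + d) / 2
  }
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6)
  sw(5, 8); sw(5, 3); sw(7, 5)
  sw(5, 3)
  matrix(x[[5]], H, W)
}

#' Compute the filter-bank feature stack of an image
#'
#' @param image 2-D matrix.
#' @param config A [feature_bank_config()].
#' @return Numeric matrix with one column per transform (pixels in
#'   column-major order) and column names from the config.
#' @export
compute_feature_bank <- function(image, config = feature_bank_config()) {
  X <- matrix(0, length(image), nrow(config))
  for (k in seq_len(nrow(config)))
    X[, k] <- as.numeric(apply_transform(image, config$transform[k],
                                         config$scale[k]))
  colnames(X) <- config$name
  X
}

# vectorized descent over a fitted rpart classification tree; requires the
# tree to have been grown with maxcompete = 0, maxsurrogate = 0 so that
# splits rows map 1:1 onto internal nodes in frame order
rpart_apply <- function(fit, X) {
  lev <- attr(fit, "ylevels")
  frame <- fit$frame
  if (all(frame$var == "<leaf>"))
    return(factor(rep(lev[frame$yval[1]], nrow(X)), levels = lev))
  nodes <- as.integer(rownames(frame))
  leaf <- frame$var == "<leaf>"
  internal <- which(!leaf)
  sp <- fit$splits
  svar <- rownames(sp)
  scol <- match(svar, colnames(X))
  pos <- integer(max(nodes)); pos[nodes] <- seq_along(nodes)
  cur <- rep(1L, nrow(X))
  repeat {
    p <- pos[cur]
    act <- which(!leaf[p])
    if (!length(act)) break
    srow <- match(p[act], internal)
    v <- X[cbind(act, scol[srow])]
    goleft <- ifelse(sp[srow, "ncat"] < 0, v < sp[srow, "index"],
                     v >= sp[srow, "index"])
    cur[act] <- 2L * cur[act] + ifelse(goleft, 0L, 1L)
  }
  factor(lev[frame$yval[pos[cur]]], levels = lev)
}

#' Train the pixel classifier
#'
#' Fits a decision tree (neuron vs background) on the filter-bank features
#' of sparsely labelled frames. Label images use 0 = background,
#' 1 = neuron, 255 = unlabelled (ignored).
#'
#' @param frames List of 2-D matrices.
#' @param labels List of same-shape label matrices.
#' @param feature_config A [feature_bank_config()].
#' @param max_depth,min_leaf Tree size controls.
#' @param seed Seed fixed before fitting (tie-breaks).
#' @param frame_ids Optional identifiers recorded on the classifier.
#' @return A `pixel_classifier` with the fitted tree, the feature config
#'   and the training accuracy.
#' @export
train_pixel_classifier <- function(frames, labels,
                                   feature_config = feature_bank_config(),
                                   max_depth = 8, min_leaf = 20, seed = 0L,
                                   frame_ids = seq_along(frames)) {
  stopifnot(length(frames) == length(labels))
  Xs <- list(); ys <- list()
  for (i in seq_along(frames)) {
    lab <- as.integer(labels[[i]])
    keep <- lab %in% c(0L, 1L)
    if (!any(keep)) next
    X <- compute_feature_bank(frames[[i]], feature_config)
    Xs[[length(Xs) + 1L]] <- X[keep, , drop = FALSE]
    ys[[length(ys) + 1L]] <- lab[keep]
  }
  y <- unlist(ys)
  if (length(unique(y)) < 2L)
    abort("train_pixel_classifier: both classes (0 background, 1 neuron) must be present.",
          class = "wormtrace_invalid_training")
  X <- do.call(rbind, Xs)
  df <- as.data.frame(X)
  df$.class <- factor(y, levels = c(0L, 1L))
  set.seed(as.integer(seed))
  fit <- rpart::rpart(.class ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        maxdepth = max_depth, minbucket = min_leaf,
                        cp = 1e-4, xval = 0, maxcompete = 0,
                        maxsurrogate = 0, usesurrogate = 0))
  pred <- rpart_apply(fit, X)
  acc <- mean(as.integer(as.character(pred)) == y)
  structure(list(tree = fit, feature_config = feature_config,
                 max_depth = max_depth, min_leaf = min_leaf, seed = seed,
                 training_frame_ids = frame_ids, train_accuracy = acc),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier: %d features, depth <= %d, training accuracy %.3f>\n",
              nrow(x$feature_config), x$max_depth, x$train_accuracy))
  invisible(x)
}

#' Apply a pixel classifier to a frame or a whole movie
#'
#' @param x 2-D matrix or `projected_movie`.
#' @param clf A [train_pixel_classifier()] result.
#' @return Logical mask matrix (for a frame) or Y by X by T logical array
#'   (for a movie); `TRUE` = neuron.
#' @export
apply_classifier <- function(x, clf) {
  if (inherits(x, "projected_movie")) {
    d <- dim(x$data)
    out <- array(FALSE, d)
    for (t in seq_len(d[3]))
      out[, , t] <- apply_classifier(x$data[, , t], clf)
    return(out)
  }
  X <- compute_feature_bank(x, clf$feature_config)
  pred <- rpart_apply(clf$tree, X)
  matrix(pred == "1", nrow(x), ncol(x))
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally via union-find over the label graph
label_components8 <- function(mask) {
  L <- EBImage::bwlabel(mask * 1)
  nl <- max(L)
  if (nl <= 1L) return(L)
  H <- nrow(L); W <- ncol(L)
  a <- c(L[-H, -W], L[-1, -W])   # upper-left vs lower-right, lower-left vs upper-right
  b <- c(L[-1, -1], L[-H, -1])
  sel <- a > 0 & b > 0 & a != b
  if (!any(sel)) return(L)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in which(sel)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(nl), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  L[L > 0] <- relab[L[L > 0]]
  L
}

#' Reduce a binary mask to discrete neuron components
#'
#' 8-connected components; components below `min_area` are dropped and the
#' `expected_count` largest are kept, sorted by area descending. An empty
#' result is returned as an empty segmentation (a downstream gap), not an
#' error.
#'
#' @param mask Logical/0-1 matrix.
#' @param min_area Minimum component area in pixels.
#' @param expected_count Number of components to keep.
#' @param image Optional intensity image for per-component mean intensity.
#' @param frame Frame index recorded on the result (0-based).
#' @return A `frame_segmentation`: list with `frame`, `components` (tibble:
#'   label, area, centroid_row, centroid_col, mean_intensity) and `pixels`
#'   (list of linear index vectors). Centroids are 0-based.
#' @export
postprocess_masks <- function(mask, min_area = 5, expected_count = 2,
                              image = NULL, frame = NA_integer_) {
  if (expected_count < 1)
    abort("postprocess_masks: expected_count must be >= 1.",
          class = "wormtrace_invalid_parameter")
  L <- label_components8(mask)
  H <- nrow(L)
  empty <- structure(list(frame = frame,
                          components = tibble(label = integer(),
                                              area = integer(),
                                              centroid_row = numeric(),
                                              centroid_col = numeric(),
                                              mean_intensity = numeric()),
                          pixels = list()), class = "frame_segmentation")
  nl <- max(L)
  if (nl == 0L) return(empty)
  areas <- tabulate(L[L > 0], nbins = nl)
  keep <- which(areas >= min_area)
  if (!length(keep)) return(empty)
  keep <- keep[order(areas[keep], decreasing = TRUE)]
  keep <- head(keep, expected_count)
  idx <- which(L > 0)
  labv <- L[idx]
  nk <- length(keep)
  area <- integer(nk); crow <- numeric(nk); ccol <- numeric(nk)
  mint <- rep(NA_real_, nk); pix <- vector("list", nk)
  for (j in seq_len(nk)) {
    lin <- idx[labv == keep[j]]
    area[j] <- length(lin)
    crow[j] <- mean((lin - 1L) %% H)    # 0-based
    ccol[j] <- mean((lin - 1L) %/% H)
    if (!is.null(image)) mint[j] <- mean(image[lin])
    pix[[j]] <- lin
  }
  comps <- tibble::new_tibble(list(label = seq_len(nk), area = area,
                                   centroid_row = crow, centroid_col = ccol,
                                   mean_intensity = mint), nrow = nk)
  structure(list(frame = frame, components = comps, pixels = pix),
            class = "frame_segmentation")
}

#' Global-threshold baseline segmentation
#'
#' @param image 2-D matrix.
#' @param method `"global_otsu"` or `"fixed"`.
#' @param value Threshold for `method = "fixed"`.
#' @return Logical mask (`TRUE` where `image >= threshold`).
#' @export
threshold_baseline <- function(image, method = c("global_otsu", "fixed"),
                               value = NULL) {
  method <- match.arg(method)
  th <- switch(method,
    global_otsu = {
      mx <- max(image, 1)
      EBImage::otsu(image / mx, range = c(0, 1), levels = 65536L) * mx
    },
    fixed = {
      if (is.null(value))
        abort("threshold_baseline: `value` required for fixed threshold.",
              class = "wormtrace_invalid_parameter")
      value
    })
  image >= th
}

#' Segment every frame of a registered movie
#'
#' @param movie A `projected_movie` (typically registered).
#' @param clf A `pixel_classifier`.
#' @param min_area,expected_count Passed to [postprocess_masks()].
#' @return List of `frame_segmentation`, one per frame.
#' @export
segment_movie <- function(movie, clf, min_area = 5, expected_count = 2) {
  d <- dim(movie$data)
  lapply(seq_len(d[3]), function(t) {
    img <- movie$data[, , t]
    postprocess_masks(apply_classifier(img, clf), min_area, expected_count,
                      image = img, frame = t - 1L)
  })
}

#' Sparse training labels from simulator ground truth
#'
#' Emulates operator scribbles the way trainable-segmentation annotation is
#' done in practice: ground-truth neuron pixels are labelled 1, a ring of
#' background immediately around each neuron plus a random sample of far
#' background are labelled 0, everything else 255 (ignored). Labelling the
#' periphery is what teaches the tree where the soma boundary sits at each
#' brightness level.
#'
#' @param truth A `ground_truth` from [simulate_movie()].
#' @param frames 0-based frame indices to label; spreading them across
#'   baseline and response frames exposes the classifier to the full
#'   brightness range.
#' @param n_background Far-background pixels sampled per frame.
#' @param ring_px Width of the labelled background ring around each neuron.
#' @param seed Sampling seed.
#' @return List of label matrices aligned with `frames`.
#' @export
training_labels_from_truth <- function(truth, frames = 0:9,
                                       n_background = 500, ring_px = 4,
                                       seed = 0L) {
  cfg <- truth$config
  H <- cfg$height_px; W <- cfg$width_px
  set.seed(as.integer(seed))
  brush <- EBImage::makeBrush(2L * ring_px + 1L, "disc")
  lapply(frames, function(f) {
    lab <- matrix(255L, H, W)
    fgm <- matrix(FALSE, H, W)
    for (m in truth$masks) fgm[m[[f + 1L]]] <- TRUE
    ring <- (EBImage::dilate(fgm * 1, brush) > 0) & !fgm
    far <- which(!fgm & !ring)
    lab[sample(far, min(n_background, length(far)))] <- 0L
    lab[ring] <- 0L
    lab[fgm] <- 1L
    lab
  })
}
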