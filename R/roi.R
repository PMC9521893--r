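# Static-image ROI quantification: background-subtracted mean intensity
# inside a manually drawn polygon (int1, EPC) or a threshold superlevel set
# (I2 neurons), on a maximum-intensity projection.

#' Rasterize a polygon onto a pixel grid
#'
#' A pixel belongs to the polygon iff its center lies inside under the
#' even-odd rule; vertices are 0-based `(row, col)`.
#'
#' @param vertices Numeric matrix, one vertex per row.
#' @param dimhw `c(height, width)` of the target grid.
#' @return Logical matrix.
#' @export
rasterize_polygon <- function(vertices, dimhw) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3)
    abort("rasterize_polygon: a polygon needs at least 3 vertices.",
          class = "wormtrace_invalid_parameter")
  H <- dimhw[1]; W <- dimhw[2]
  vr <- vertices[, 1]; vc <- vertices[, 2]
  pr <- rep(0:(H - 1), W)
  pc <- rep(0:(W - 1), each = H)
  inside <- rep(FALSE, H * W)
  n <- length(vr)
  j <- n
  for (i in seq_len(n)) {
    cond <- (vr[i] > pr) != (vr[j] > pr)
    xint <- (vc[j] - vc[i]) * (pr - vr[i]) / (vr[j] - vr[i]) + vc[i]
    inside <- xor(inside, cond & (pc < xint))
    j <- i
  }
  matrix(inside, H, W)
}

#' Define a polygon or threshold ROI
#'
#' @param vertices Polygon vertex matrix (0-based `(row, col)`).
#' @param background_roi Optional polygon used to estimate background; if
#'   absent, the background is the median outside the 3 px dilated mask.
#' @return An `roi` object.
#' @export
roi_polygon <- function(vertices, background_roi = NULL) {
  structure(list(kind = "polygon", vertices = as.matrix(vertices),
                 background_roi = background_roi), class = "roi")
}

#' @rdname roi_polygon
#' @param method `"fixed"` or `"global_otsu"`.
#' @param value Threshold for `method = "fixed"`.
#' @export
roi_threshold <- function(method = c("fixed", "global_otsu"), value = NULL,
                          background_roi = NULL) {
  method <- match.arg(method)
  structure(list(kind = "threshold", method = method, value = value,
                 background_roi = background_roi), class = "roi")
}

#' Background-subtracted mean intensity in an ROI
#'
#' The mask is the polygon rasterization (pixel center-in-polygon,
#' even-odd) or the threshold superlevel set; the background is the mean
#' over the background ROI when given, else the median of pixels outside
#' the mask dilated by 3 px. The result is `mean(in-mask) - background`.
#'
#' @param image 2-D matrix, or Y by X by Z array (max-projected first).
#' @param roi An [roi_polygon()] / [roi_threshold()].
#' @return One-row tibble: `mean_intensity, area, background, roi_kind`.
#' @export
quantify_roi <- function(image, roi) {
  if (length(dim(image)) == 3L) {
    proj <- image[, , 1]
    if (dim(image)[3] > 1)
      for (z in 2:dim(image)[3]) proj <- pmax(proj, image[, , z])
    image <- proj
  }
  mask <- if (roi$kind == "polygon") {
    rasterize_polygon(roi$vertices, dim(image))
  } else {
    m <- threshold_baseline(image, method = roi$method, value = roi$value)
    if (roi$method == "global_otsu") m else image >= roi$value
  }
  if (!any(mask))
    abort("quantify_roi: empty mask.", class = "wormtrace_empty_roi")
  bg <- if (!is.null(roi$background_roi)) {
    bmask <- rasterize_polygon(roi$background_roi, dim(image))
    mean(image[bmask])
  } else {
    dil <- EBImage::dilate(mask * 1, EBImage::makeBrush(7L, "disc")) > 0
    outside <- image[!dil]
    if (!length(outside))
      abort("quantify_roi: no background pixels outside the dilated mask.",
            class = "wormtrace_empty_roi")
    median(outside)
  }
  tibble(mean_intensity = mean(image[mask]) - bg,
         area = sum(mask), background = bg, roi_kind = roi$kind)
}

#' Quantify a batch of images into a long table
#'
#' @param images List of images (matrices or Z-stacks).
#' @param rois List of [roi_polygon()] / [roi_threshold()] (one per image;
#'   `NULL` entries produce a flagged row, not a silent drop).
#' @param conditions Condition label per image.
#' @param cells Optional cell label per image.
#' @param image_ids Optional identifiers (default `names(images)` or an
#'   index).
#' @return Tibble `(image_id, condition, cell, mean, area, background,
#'   flagged)` ready for the group-comparison statistics.
#' @export
batch_quantify <- function(images, rois, conditions, cells = NA_character_,
                           image_ids = NULL) {
  n <- length(images)
  stopifnot(length(rois) == n, length(conditions) == n)
  cells <- rep_len(cells, n)
  if (is.null(image_ids))
    image_ids <- if (!is.null(names(images))) names(images)
                 else paste0("img", seq_len(n))
  bind_rows(lapply(seq_len(n), function(i) {
    if (is.null(rois[[i]]))
      return(tibble(image_id = image_ids[i], condition = conditions[i],
                    cell = cells[i], mean = NA_real_, area = NA_integer_,
                    background = NA_real_, flagged = TRUE))
    q <- quantify_roi(images[[i]], rois[[i]])
    tibble(image_id = image_ids[i], condition = conditions[i],
           cell = cells[i], mean = q$mean_intensity, area = q$area,
           background = q$background, flagged = FALSE)
  }))
}
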