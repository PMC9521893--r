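# Whole-field registration against the first frame, by integer-shift
# zero-normalized cross-correlation. Both images are mean-subtracted over
# the full frame and the correlation is normalized by the product of their
# L2 norms, so the score lies in [-1, 1] and the argmax over the shift gate
# equals the exhaustive-search optimum; the search itself is done exactly
# with a zero-padded FFT (padding >= gate on every side, so no wrap-around
# contaminates gated lags).

#' Translate an image by an integer pixel offset
#'
#' Content moves by `(dy, dx)` (down/right positive); vacated pixels are
#' filled with `fill`.
#'
#' @param img 2-D matrix.
#' @param dy,dx Integer offsets (rows, cols).
#' @param fill Fill value for vacated pixels.
#' @return Matrix of the same shape.
#' @export
translate_image <- function(img, dy, dx, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(fill, H, W)
  y0 <- max(1L, 1L + dy); y1 <- min(H, H + dy)
  x0 <- max(1L, 1L + dx); x1 <- min(W, W + dx)
  if (y0 <= y1 && x0 <= x1)
    out[y0:y1, x0:x1] <- img[(y0:y1) - dy, (x0:x1) - dx]
  out
}

zncc_map <- function(reference, moving, max_shift) {
  H <- nrow(reference); W <- ncol(reference)
  g <- as.integer(max_shift)
  a <- reference - mean(reference)
  b <- moving - mean(moving)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NULL)
  P1 <- H + 2L * g; P2 <- W + 2L * g
  A <- matrix(0, P1, P2); B <- matrix(0, P1, P2)
  A[(g + 1):(g + H), (g + 1):(g + W)] <- a
  B[(g + 1):(g + H), (g + 1):(g + W)] <- b
  cc <- Re(fft(Conj(fft(A)) * fft(B), inverse = TRUE)) / (P1 * P2)
  lags <- -g:g
  idx1 <- (lags %% P1) + 1L
  idx2 <- (lags %% P2) + 1L
  S <- cc[idx1, idx2, drop = FALSE] / (na * nb)
  dimnames(S) <- list(dy = lags, dx = lags)
  S
}

#' Estimate the integer shift between two frames
#'
#' Returns the shift `(dy, dx)` within `[-max_shift, max_shift]` that
#' maximizes the zero-normalized cross-correlation of `moving` against
#' `reference`; ties are broken by smallest `|dy| + |dx|`, then smallest
#' `dy`, then `dx`. A constant (zero-variance) image yields shift `(0, 0)`
#' with a degenerate flag; a best score below `score_floor` sets the
#' low-confidence flag.
#'
#' @param reference,moving 2-D matrices of identical shape.
#' @param max_shift Shift gate in pixels.
#' @param score_floor Normalized-correlation floor for the
#'   low-confidence flag.
#' @return List with `dy`, `dx`, `score`, `degenerate`, `low_confidence`.
#' @export
estimate_shift <- function(reference, moving, max_shift = 20,
                           score_floor = 0.3) {
  if (!identical(dim(reference), dim(moving)))
    abort("estimate_shift: images must have the same shape.",
          class = "wormtrace_invalid_parameter")
  if (max_shift < 0)
    abort("estimate_shift: max_shift must be >= 0.",
          class = "wormtrace_invalid_parameter")
  S <- zncc_map(reference, moving, max_shift)
  if (is.null(S))
    return(list(dy = 0L, dx = 0L, score = 0, degenerate = TRUE,
                low_confidence = TRUE))
  lags <- -as.integer(max_shift):as.integer(max_shift)
  best <- max(S)
  cand <- which(S >= best - 1e-12, arr.ind = TRUE)
  dy <- lags[cand[, 1]]; dx <- lags[cand[, 2]]
  ord <- order(abs(dy) + abs(dx), dy, dx)
  pick <- ord[1]
  score <- min(S[cand[pick, 1], cand[pick, 2]], 1)
  list(dy = dy[pick], dx = dx[pick], score = score, degenerate = FALSE,
       low_confidence = score < score_floor)
}

#' Register a projected movie to its first frame
#'
#' Estimates the per-frame shift against frame 0 and translates each frame
#' back by the negated shift with zero fill. Padding introduced by the
#' translation is tracked through the shift table so downstream background
#' estimation can exclude it.
#'
#' @param movie A `projected_movie`.
#' @param max_shift Shift gate in pixels.
#' @param score_floor Low-confidence score floor.
#' @return List with `movie` (registered `projected_movie`) and `shifts`,
#'   a tibble `(frame, dy, dx, score, degenerate, low_confidence)` with the
#'   reference frame at shift `(0, 0)`, score 1.
#' @export
register_movie <- function(movie, max_shift = 20, score_floor = 0.3) {
  if (!inherits(movie, "projected_movie"))
    abort("register_movie: input must be a projected_movie.",
          class = "wormtrace_invalid_parameter")
  d <- dim(movie$data)
  Tn <- d[3]
  ref <- movie$data[, , 1]
  reg <- movie$data
  out <- vector("list", Tn)
  out[[1]] <- list(dy = 0L, dx = 0L, score = 1,
                   degenerate = sd(ref) == 0, low_confidence = FALSE)
  if (Tn > 1) for (t in 2:Tn) {
    s <- estimate_shift(ref, movie$data[, , t], max_shift, score_floor)
    out[[t]] <- s
    if (s$dy != 0L || s$dx != 0L)
      reg[, , t] <- translate_image(movie$data[, , t], -s$dy, -s$dx)
  }
  shifts <- tibble(frame = 0:(Tn - 1),
                   dy = map_int(out, function(s) as.integer(s$dy)),
                   dx = map_int(out, function(s) as.integer(s$dx)),
                   score = map_dbl(out, "score"),
                   degenerate = map_lgl(out, "degenerate"),
                   low_confidence = map_lgl(out, "low_confidence"))
  rmov <- projected_movie(reg, movie)
  list(movie = rmov, shifts = shifts)
}

# logical mask of pixels untouched by the zero-fill of register_movie
registration_validity <- function(dimhw, dy, dx) {
  H <- dimhw[1]; W <- dimhw[2]
  v <- matrix(FALSE, H, W)
  y0 <- max(1L, 1L - dy); y1 <- min(H, H - dy)
  x0 <- max(1L, 1L - dx); x1 <- min(W, W - dx)
  if (y0 <= y1 && x0 <= x1) v[y0:y1, x0:x1] <- TRUE
  v
}
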