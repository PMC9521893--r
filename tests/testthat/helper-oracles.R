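# Independent oracles: brute-force / closed-form implementations kept
# deliberately separate from the package's code paths.

# exhaustive zero-normalized cross-correlation search over gated integer
# shifts; overlap sums written directly from index arithmetic
oracle_zncc_search <- function(ref, mov, gate) {
  H <- nrow(ref); W <- ncol(ref)
  a <- ref - mean(ref); b <- mov - mean(mov)
  den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  best <- list(score = -Inf, dy = 0L, dx = 0L)
  for (dy in -gate:gate) for (dx in -gate:gate) {
    # moving ~ reference translated by (dy, dx): correlate ref(y, x) with
    # mov(y + dy, x + dx) over their overlap
    r0 <- max(1, 1 - dy); r1 <- min(H, H - dy)
    c0 <- max(1, 1 - dx); c1 <- min(W, W - dx)
    if (r0 > r1 || c0 > c1) next
    s <- sum(a[r0:r1, c0:c1] * b[(r0:r1) + dy, (c0:c1) + dx]) / den
    better <- s > best$score + 1e-12
    tie <- abs(s - best$score) <= 1e-12
    if (better ||
        (tie && (abs(dy) + abs(dx) < abs(best$dy) + abs(best$dx) ||
                 (abs(dy) + abs(dx) == abs(best$dy) + abs(best$dx) &&
                  (dy < best$dy || (dy == best$dy && dx < best$dx)))))) {
      best <- list(score = s, dy = dy, dx = dx)
    }
  }
  best
}

# brute-force gated assignment: enumerate every injective mapping of a
# subset of heads into detections (via combn + full permutation recursion)
oracle_assignment <- function(D, gate) {
  nh <- nrow(D); nd <- ncol(D)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- list(count = 0L, cost = 0)
  for (k in seq_len(min(nh, nd))) {
    hs <- utils::combn(nh, k, simplify = FALSE)
    ds <- utils::combn(nd, k, simplify = FALSE)
    for (h in hs) for (d in ds) for (p in perms(d)) {
      dd <- D[cbind(h, p)]
      if (any(dd > gate)) next
      cost <- sum(dd)
      if (k > best$count || (k == best$count && cost < best$cost - 1e-12))
        best <- list(count = k, cost = cost)
    }
  }
  best
}

# brute-force sliding-window median with replicated (clamped) borders
oracle_median_filter <- function(img, w) {
  H <- nrow(img); W <- ncol(img); out <- img
  h <- (w - 1) / 2
  for (r in seq_len(H)) for (c in seq_len(W)) {
    rs <- pmin(pmax(r + (-h:h), 1), H)
    cs <- pmin(pmax(c + (-h:h), 1), W)
    out[r, c] <- median(img[rs, cs])
  }
  out
}

# exhaustive Otsu: threshold over observed values minimizing within-class
# variance
oracle_otsu <- function(img) {
  v <- sort(unique(as.numeric(img)))
  best <- list(th = v[1], wcv = Inf)
  for (th in v[-1]) {
    lo <- img[img < th]; hi <- img[img >= th]
    if (!length(lo) || !length(hi)) next
    wcv <- length(lo) * var_n(lo) + length(hi) * var_n(hi)
    if (wcv < best$wcv) best <- list(th = th, wcv = wcv)
  }
  best$th
}
var_n <- function(x) if (length(x) < 2) 0 else var(x) * (length(x) - 1) / length(x)

# tie-corrected Kruskal-Wallis H from first principles
oracle_kruskal_H <- function(samples) {
  values <- unlist(samples)
  N <- length(values)
  r <- rank(values)
  groups <- rep(seq_along(samples), lengths(samples))
  H <- 12 / (N * (N + 1)) *
    sum(vapply(seq_along(samples), function(g)
      sum(r[groups == g])^2 / sum(groups == g), 0)) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Dunn pairwise z from first principles (pooled ranks, tie-corrected SE)
oracle_dunn_z <- function(samples, i, j) {
  values <- unlist(samples)
  N <- length(values)
  r <- rank(values)
  groups <- rep(seq_along(samples), lengths(samples))
  ties <- table(values)
  A <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  ni <- sum(groups == i); nj <- sum(groups == j)
  (mean(r[groups == i]) - mean(r[groups == j])) /
    sqrt(A * (1 / ni + 1 / nj))
}

# two-sided Monte-Carlo permutation p for the rank-sum statistic
oracle_mw_permutation <- function(a, b, n_perm = 1e5, seed = 1) {
  set.seed(seed)
  pooled <- c(a, b)
  n1 <- length(a)
  robs <- sum(rank(pooled)[seq_len(n1)])
  mu <- n1 * (length(pooled) + 1) / 2
  hits <- 0L
  for (i in seq_len(n_perm)) {
    rp <- sum(rank(pooled)[sample.int(length(pooled), n1)])
    if (abs(rp - mu) >= abs(robs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / n_perm
}

# identity switches of a 2-track set against simulator neuron positions
count_identity_switches <- function(track_set, truth) {
  H <- truth$config$height_px
  gt_pos <- lapply(truth$masks, function(m) {
    t(vapply(m, function(lin)
      c(mean((lin - 1L) %% H), mean((lin - 1L) %/% H)), c(0, 0)))
  })
  switches <- 0L
  for (tr in track_set$tracks) {
    prev <- NA_integer_
    for (t in seq_len(nrow(tr$data))) {
      if (tr$data$gap[t]) next
      ## track rows/cols are in registered coordinates: move ground truth
      ## back by the frame shift before comparing
      ds <- vapply(seq_along(gt_pos), function(i) {
        P <- gt_pos[[i]]
        sqrt((P[t, 1] - truth$shifts$dy[t] - tr$data$row[t])^2 +
             (P[t, 2] - truth$shifts$dx[t] - tr$data$col[t])^2)
      }, 0)
      cur <- which.min(ds)
      if (!is.na(prev) && cur != prev) switches <- switches + 1L
      prev <- cur
    }
  }
  switches
}

# pooled per-pixel F1 of predicted masks vs ground-truth masks
pixel_f1 <- function(pred_list, truth, frames) {
  tp <- fp <- fn <- 0
  H <- truth$config$height_px; W <- truth$config$width_px
  for (t in frames) {
    tm <- matrix(FALSE, H, W)
    for (m in truth$masks) tm[m[[t]]] <- TRUE
    pm <- pred_list[[t]]
    tp <- tp + sum(pm & tm)
    fp <- fp + sum(pm & !tm)
    fn <- fn + sum(!pm & tm)
  }
  2 * tp / (2 * tp + fp + fn)
}
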