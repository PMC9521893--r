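# The statistical decision tree used for group comparisons: samples are
# deemed normal when both Anderson-Darling and Shapiro-Wilk fail to reject
# at alpha = 0.05, or by the N > 30 shortcut. Two groups: Student t, with
# the Welch correction when an F-ratio test rejects variance homogeneity;
# otherwise Mann-Whitney. Three or more: one-way ANOVA with Bonferroni
# pairwise t tests, or Kruskal-Wallis followed by tie-corrected Dunn tests
# with Bonferroni adjustment. Stars: ns > 0.05 >= * > 0.01 >= ** ... ****
# at <= 0.0001.

#' Star label for a p value
#'
#' `p > 0.05` is `"ns"`, then `"*"` (<= 0.05), `"**"` (<= 0.01), `"***"`
#' (<= 0.001), `"****"` (<= 0.0001); the most extreme applicable label is
#' returned. Vectorized.
#'
#' @param p Numeric p value(s) in `[0, 1]`.
#' @return Character vector.
#' @export
star_label <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    abort("star_label: p must lie in [0, 1].",
          class = "wormtrace_invalid_parameter")
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] > 0.05, "ns",
             ifelse(p[ok] > 0.01, "*",
             ifelse(p[ok] > 0.001, "**",
             ifelse(p[ok] > 0.0001, "***", "****"))))
  out
}

#' Normality gate
#'
#' A sample passes (is treated as normal) iff `n > 30`, or both the
#' Shapiro-Wilk and Anderson-Darling tests fail to reject at
#' `alpha`. Constant samples are non-normal with a degenerate flag. The
#' Anderson-Darling test needs `n >= 8`; below that only Shapiro-Wilk
#' gates.
#'
#' @param x Numeric sample, `n >= 3`.
#' @param alpha Rejection level for both tests.
#' @return List: `normal`, `shapiro_p`, `ad_p`, `shortcut` (N > 30 used),
#'   `degenerate`, `n`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3)
    abort("normality_gate: need at least 3 observations.",
          class = "wormtrace_invalid_parameter")
  if (sd(x) == 0)
    return(list(normal = FALSE, shapiro_p = NA_real_, ad_p = NA_real_,
                shortcut = FALSE, degenerate = TRUE, n = n))
  sp <- tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
  ad <- if (n >= 8) nortest::ad.test(x)$p.value else NA_real_
  if (n > 30)
    return(list(normal = TRUE, shapiro_p = sp, ad_p = ad, shortcut = TRUE,
                degenerate = FALSE, n = n))
  tests <- c(sp, ad)
  tests <- tests[!is.na(tests)]
  list(normal = length(tests) > 0 && all(tests > alpha), shapiro_p = sp,
       ad_p = ad, shortcut = FALSE, degenerate = FALSE, n = n)
}

#' Compare two groups through the decision tree
#'
#' Both samples normal (per [normality_gate()]): unpaired two-tailed t
#' test, Welch variant iff a two-sided F-ratio test rejects variance
#' homogeneity at `alpha`. Otherwise: two-sided Mann-Whitney (exact when
#' sample sizes permit and there are no ties, tie-corrected normal
#' approximation otherwise). The decision path is recorded on the result.
#'
#' @param a,b Numeric samples, each `n >= 3`.
#' @param alpha Level used inside the gates (not for the final star).
#' @return One-row tibble of class `wt_test`: test name, statistic,
#'   p_value, star, sample sizes and the gate booleans.
#' @export
compare_two <- function(a, b, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3)
    abort("compare_two: both groups need n >= 3.",
          class = "wormtrace_invalid_parameter")
  ga <- normality_gate(a, alpha); gb <- normality_gate(b, alpha)
  if (ga$normal && gb$normal) {
    fp <- var.test(a, b)$p.value
    welch <- fp <= alpha
    tt <- t.test(a, b, var.equal = !welch)
    res <- tibble(test = if (welch) "Welch t" else "Student t",
                  statistic = unname(tt$statistic),
                  p_value = tt$p.value,
                  variance_homogeneous = !welch)
  } else {
    wt <- suppressWarnings(wilcox.test(a, b))
    res <- tibble(test = "Mann-Whitney", statistic = unname(wt$statistic),
                  p_value = wt$p.value, variance_homogeneous = NA)
  }
  res <- mutate(res, star = star_label(.data$p_value),
                n_a = length(a), n_b = length(b),
                normal_a = ga$normal, normal_b = gb$normal,
                shortcut_a = ga$shortcut, shortcut_b = gb$shortcut)
  class(res) <- c("wt_test", class(res))
  res
}

# tie-corrected Dunn post-hoc z tests on pooled ranks, Bonferroni-adjusted
dunn_pairwise <- function(values, groups) {
  groups <- as.character(groups)
  N <- length(values)
  r <- rank(values)
  tie_sizes <- table(values)
  Tcorr <- sum(tie_sizes^3 - tie_sizes)
  gl <- unique(groups)
  rbar <- vapply(gl, function(g) mean(r[groups == g]), 0)
  ns <- vapply(gl, function(g) sum(groups == g), 0)
  m <- length(gl) * (length(gl) - 1) / 2
  out <- list()
  for (i in seq_along(gl)[-length(gl)]) for (j in (i + 1):length(gl)) {
    se <- sqrt((N * (N + 1) / 12 - Tcorr / (12 * (N - 1))) *
               (1 / unname(ns[i]) + 1 / unname(ns[j])))
    z <- unname(rbar[i] - rbar[j]) / se
    p <- 2 * pnorm(-abs(z))
    out[[length(out) + 1L]] <- tibble(group1 = gl[i], group2 = gl[j],
                                      statistic = z, p_value = p,
                                      p_adjusted = min(1, p * m))
  }
  bind_rows(out)
}

#' Compare three or more groups through the decision tree
#'
#' All groups normal: one-way ANOVA, then pairwise t tests (pooled SD)
#' with Bonferroni adjustment. Otherwise: Kruskal-Wallis, then Dunn's
#' tie-corrected z tests on pooled ranks, Bonferroni-adjusted.
#'
#' @param samples Named list of numeric vectors (>= 3 groups), or a data
#'   frame with `value` and `group` columns.
#' @param alpha Gate level.
#' @return List of class `wt_omnibus`: `omnibus` (one-row tibble),
#'   `pairwise` (tibble with adjusted p and stars), `parametric`
#'   (branch taken), `gates`.
#' @export
compare_many <- function(samples, alpha = 0.05) {
  if (is.data.frame(samples))
    samples <- split(samples$value, samples$group)
  if (length(samples) < 3)
    abort("compare_many: need at least 3 groups.",
          class = "wormtrace_invalid_parameter")
  if (is.null(names(samples)) || any(names(samples) == ""))
    names(samples) <- paste0("group_", seq_along(samples))
  gates <- lapply(samples, normality_gate, alpha = alpha)
  parametric <- all(vapply(gates, `[[`, logical(1), "normal"))
  values <- unlist(samples, use.names = FALSE)
  groups <- factor(rep(names(samples), lengths(samples)),
                   levels = names(samples))
  if (parametric) {
    fit <- aov(values ~ groups)
    sm <- summary(fit)[[1]]
    omni <- tibble(test = "one-way ANOVA", statistic = sm[["F value"]][1],
                   p_value = sm[["Pr(>F)"]][1])
    pw <- stats::pairwise.t.test(values, groups, pool.sd = TRUE,
                                 p.adjust.method = "bonferroni")$p.value
    pairs <- list()
    for (i in rownames(pw)) for (j in colnames(pw))
      if (!is.na(pw[i, j]))
        pairs[[length(pairs) + 1L]] <- tibble(group1 = j, group2 = i,
                                              statistic = NA_real_,
                                              p_value = NA_real_,
                                              p_adjusted = pw[i, j])
    pairwise <- bind_rows(pairs)
  } else {
    kw <- kruskal.test(values, groups)
    omni <- tibble(test = "Kruskal-Wallis", statistic = unname(kw$statistic),
                   p_value = kw$p.value)
    pairwise <- dunn_pairwise(values, groups)
  }
  omni$star <- star_label(omni$p_value)
  pairwise$star <- star_label(pairwise$p_adjusted)
  structure(list(omnibus = omni, pairwise = pairwise,
                 parametric = parametric, gates = gates),
            class = "wt_omnibus")
}

#' @export
print.wt_omnibus <- function(x, ...) {
  cat(sprintf("<%s: %s = %.4g, p = %.4g %s>\n",
              if (x$parametric) "parametric branch" else "rank branch",
              x$omnibus$test, x$omnibus$statistic, x$omnibus$p_value,
              x$omnibus$star))
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.wt_test <- function(x, ...) {
  as_tibble(x)[, c("test", "statistic", "p_value", "star", "n_a", "n_b")]
}

#' @export
glance.wt_test <- function(x, ...) {
  as_tibble(x)[, c("test", "p_value", "star", "normal_a", "normal_b",
                   "variance_homogeneous")]
}

#' @export
tidy.wt_omnibus <- function(x, ...) x$pairwise

#' @export
glance.wt_omnibus <- function(x, ...)
  mutate(x$omnibus, parametric = x$parametric)
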