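# Frequency-area fits, growth-cone moments, and the normality-gated
# statistical testing cascade.

#' Zero-intercept fit of track frequency against mask area
#'
#' Least-squares line through the origin, `slope = sum(x * y) / sum(x^2)`,
#' relating tracks/min to the neuronal mask area (excluding the cell body);
#' per-video normalised counts `y / x` are returned alongside.
#'
#' @param area_um2 Mask areas, um^2 (one per video, > 0).
#' @param tracks_per_min Track counts per minute (same length).
#' @return List: `slope`, `normalized` (tracks/min/um^2 per video).
#' @export
frequency_area_fit <- function(area_um2, tracks_per_min) {
  stopifnot(length(area_um2) == length(tracks_per_min), length(area_um2) >= 1)
  if (all(area_um2 == 0)) stop("all areas are zero")
  stopifnot(all(area_um2 > 0))
  list(slope = sum(area_um2 * tracks_per_min) / sum(area_um2^2),
       normalized = tracks_per_min / area_um2)
}

#' Growth-cone orientation, width and area from a boundary mask
#'
#' The major axis comes from the second central moments of the mask; the
#' orientation is its axial alignment angle with the ridge (`[0, 90]`), the
#' width is the pixel extent along the minor axis, and the class follows the
#' parallel (0-15 degrees) / perpendicular (75-90 degrees) bands.
#' Near-isotropic masks (eigenvalue ratio below `anisotropy_min`) get an NA
#' orientation.
#'
#' @param mask Logical matrix with a single connected region of >= 5 px.
#' @param ridge_angle Axial ridge angle, degrees.
#' @param anisotropy_min Minimum major/minor eigenvalue ratio for a defined
#'   orientation.
#' @return An `aw_growth_cone` list: `orientation` (degrees in `[0, 90]` or
#'   NA), `major_axis_angle` (axial, `[0, 180)`), `width` (px), `area` (px^2),
#'   `class` (`"parallel"`, `"perpendicular"`, `"intermediate"`, or
#'   `"undefined"`).
#' @export
growth_cone_orientation <- function(mask, ridge_angle, anisotropy_min = 1.1) {
  stopifnot(is.matrix(mask))
  px <- which(mask > 0, arr.ind = TRUE)
  if (nrow(px) < 5) stop("growth-cone region smaller than 5 px: moments unstable")
  x <- px[, 2]; y <- px[, 1]
  mxx <- mean((x - mean(x))^2); myy <- mean((y - mean(y))^2)
  mxy <- mean((x - mean(x)) * (y - mean(y)))
  tr <- mxx + myy
  disc <- sqrt((mxx - myy)^2 + 4 * mxy^2)
  l1 <- (tr + disc) / 2; l2 <- (tr - disc) / 2
  area <- nrow(px)
  if (l2 <= 0 || l1 / l2 >= anisotropy_min) {
    major <- (atan2(2 * mxy, mxx - myy) / 2 * 180 / pi) %% 180
    th <- major * pi / 180
    minor_u <- c(-sin(th), cos(th))
    proj <- (x - mean(x)) * minor_u[1] + (y - mean(y)) * minor_u[2]
    width <- diff(range(proj)) + 1
    ori <- axial_angle(major, ridge_angle)
    cls <- if (ori <= 15) "parallel" else if (ori >= 75) "perpendicular"
           else "intermediate"
  } else {
    major <- NA_real_; width <- sqrt(area / pi) * 2; ori <- NA_real_
    cls <- "undefined"
  }
  structure(list(orientation = ori, major_axis_angle = major, width = width,
                 area = area, class = cls),
            class = "aw_growth_cone")
}

shapiro_p <- function(x) {
  if (length(unique(x)) < 2) return(0)           # constant: clearly non-normal
  stats::shapiro.test(x)$p.value
}

#' Dunn's post hoc test for pairwise comparisons after Kruskal-Wallis
#'
#' Rank-sum z statistics with tie correction; two-sided p-values, adjusted
#' for multiple comparisons.
#'
#' @param values Numeric vector of all observations.
#' @param groups Group labels (same length).
#' @param p_adjust Adjustment method passed to [stats::p.adjust()].
#' @return data.frame with `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) >= 2)
  N <- length(values)
  r <- rank(values)
  rb <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  combs <- utils::combn(levels(groups), 2)
  z <- p <- numeric(ncol(combs))
  for (i in seq_len(ncol(combs))) {
    a <- combs[1, i]; b <- combs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
    z[i] <- (rb[[a]] - rb[[b]]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  data.frame(group1 = combs[1, ], group2 = combs[2, ], z = z, p = p,
             p_adj = stats::p.adjust(p, method = p_adjust))
}

#' Normality-gated group comparison cascade
#'
#' Shapiro-Wilk is run on every group at `alpha`; if all groups pass, the
#' parametric branch is taken (Welch's t-test for two groups, one-way ANOVA
#' with Tukey's HSD for three or more), otherwise the nonparametric branch
#' (Mann-Whitney U for two groups, Kruskal-Wallis with Dunn's post hoc for
#' more). The full decision trail is returned.
#'
#' @param groups Named (or unnamed) list of numeric samples, each with >= 3
#'   observations.
#' @param alpha Normality-gate significance level.
#' @param p_adjust Adjustment for Dunn's post hoc.
#' @return An `aw_stattest` list: `gate` (per-group Shapiro p and pass),
#'   `normal` (all passed), `chosen_test`, `statistic`, `p_value`, `posthoc`
#'   (pairwise data.frame or NULL), `stars`.
#' @export
compare_groups <- function(groups, alpha = 0.05, p_adjust = "bonferroni") {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 3))
    stop("every group needs at least 3 observations")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  ps <- vapply(groups, shapiro_p, numeric(1))
  gate <- data.frame(group = names(groups), shapiro_p = ps, pass = ps > alpha)
  normal <- all(gate$pass)
  k <- length(groups)
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                   levels = names(groups))
  posthoc <- NULL
  if (normal && k == 2) {
    tst <- stats::t.test(groups[[1]], groups[[2]])
    chosen <- "t-test"; statistic <- unname(tst$statistic); pv <- tst$p.value
  } else if (normal) {
    fit <- stats::aov(values ~ labels)
    an <- summary(fit)[[1]]
    chosen <- "one-way ANOVA + Tukey HSD"
    statistic <- an[["F value"]][1]; pv <- an[["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)[[1]]
    posthoc <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL)
  } else if (k == 2) {
    tst <- stats::wilcox.test(groups[[1]], groups[[2]], exact = FALSE)
    chosen <- "Mann-Whitney U"
    statistic <- unname(tst$statistic); pv <- tst$p.value
  } else {
    tst <- stats::kruskal.test(values, labels)
    chosen <- "Kruskal-Wallis + Dunn"
    statistic <- unname(tst$statistic); pv <- tst$p.value
    posthoc <- dunn_test(values, labels, p_adjust = p_adjust)
  }
  structure(list(gate = gate, normal = normal, chosen_test = chosen,
                 statistic = statistic, p_value = pv, posthoc = posthoc,
                 alpha = alpha, stars = significance_stars(pv)),
            class = "aw_stattest")
}

#' @export
print.aw_stattest <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g %s (normality gate %s)\n",
              x$chosen_test, x$statistic, x$p_value, x$stars,
              if (x$normal) "passed" else "failed"))
  invisible(x)
}

#' Significance annotation bands
#'
#' `****` for p <= 1e-4, `***` for p <= 1e-3, `**` for p <= 0.01, `*` for
#' p <= 0.05; the p-value itself for 0.05 < p < 0.1; `"ns"` otherwise.
#'
#' @param p A p-value in `[0, 1]` (vectorised).
#' @return Character vector of annotations.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) NA_character_
    else if (pi <= 1e-4) "****"
    else if (pi <= 1e-3) "***"
    else if (pi <= 0.01) "**"
    else if (pi <= 0.05) "*"
    else if (pi < 0.1) sprintf("p=%.3g", pi)
    else "ns"
  }, character(1))
}
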