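# -- movie synchronisation, binning and genotype comparison -------------------

#' Synchronise movies to the onset of germband extension
#'
#' Two stages. Stage 1: each movie is offset so that the time its
#' AP-projected tissue strain rate first reaches `threshold` (0.01 pp/min),
#' sustained for at least `sustain_min` minutes, becomes a provisional zero;
#' the nonzero threshold guards against minor fluctuations around the onset.
#' Stage 2: the average strain-rate curve of each genotype is computed on
#' the provisionally aligned grid and all movies of the genotype are shifted
#' together so that this average crosses 0 pp/min at exactly t = 0. Movies
#' whose series never reaches the threshold are flagged unsynchronisable.
#'
#' @param series long tibble with columns `movie`, `time_min`, `value`
#'   (per-frame mean AP-projected tissue strain rate), and optionally
#'   `genotype`.
#' @param threshold onset threshold, pp/min.
#' @param sustain_min minimum duration the series must stay at or above the
#'   threshold for a crossing to count.
#' @param grid_step_min grid spacing for the genotype average (default 0.5,
#'   i.e. the 30-s frame interval).
#' @return Tibble with `movie`, `genotype`, `offset_min` (subtract from raw
#'   times to get synchronised time), `stage1_min`, `unsynchronisable`.
#' @export
synchronise <- function(series, threshold = 0.01, sustain_min = 2,
                        grid_step_min = 0.5) {
  if (!"genotype" %in% names(series)) series$genotype <- "all"
  by_movie <- split(series, series$movie)

  stage1 <- lapply(by_movie, function(g) {
    g <- g[order(g$time_min), ]
    v <- g$value; t <- g$time_min
    cross <- NA_real_
    for (i in seq_along(v)) {
      if (is.na(v[i]) || v[i] < threshold) next
      win <- which(t >= t[i] & t <= t[i] + sustain_min)
      if (all(v[win] >= threshold, na.rm = TRUE) &&
          !all(is.na(v[win]))) {
        if (i > 1 && !is.na(v[i - 1]) && v[i - 1] < threshold) {
          cross <- t[i - 1] + (threshold - v[i - 1]) *
            (t[i] - t[i - 1]) / (v[i] - v[i - 1])
        } else cross <- t[i]
        break
      }
    }
    list(genotype = g$genotype[1], stage1 = cross)
  })

  out <- tibble::tibble(
    movie = names(by_movie),
    genotype = unname(vapply(stage1, `[[`, character(1), "genotype")),
    stage1_min = unname(vapply(stage1, `[[`, numeric(1), "stage1")))
  out$unsynchronisable <- is.na(out$stage1_min)
  out$offset_min <- out$stage1_min

  for (gt in unique(out$genotype)) {
    mv <- out$movie[out$genotype == gt & !out$unsynchronisable]
    if (!length(mv)) next
    shifted <- lapply(mv, function(m) {
      g <- by_movie[[m]]
      tibble::tibble(time = g$time_min - out$stage1_min[out$movie == m],
                     value = g$value)
    })
    lo <- max(vapply(shifted, function(s) min(s$time), numeric(1)))
    hi <- min(vapply(shifted, function(s) max(s$time), numeric(1)))
    grid <- seq(ceiling(lo / grid_step_min) * grid_step_min, hi,
                by = grid_step_min)
    if (length(grid) < 2) next
    avg <- rowMeans(vapply(shifted, function(s)
      stats::approx(s$time, s$value, xout = grid)$y, numeric(length(grid))),
      na.rm = TRUE)
    # anchor on the main rise: from the first sustained threshold crossing of
    # the average, walk back to the last point at or below zero (ignores
    # isolated zero-crossings of pre-onset fluctuations)
    i_thr <- NA_integer_
    for (i in seq_along(avg)) {
      if (is.na(avg[i]) || avg[i] < threshold) next
      win <- which(grid >= grid[i] & grid <= grid[i] + sustain_min)
      if (all(avg[win] >= threshold, na.rm = TRUE)) { i_thr <- i; break }
    }
    if (is.na(i_thr)) next
    below <- which(avg[seq_len(i_thr)] <= 0)
    if (!length(below)) next
    k <- max(below)
    t0 <- if (k == length(grid) || avg[k + 1] == avg[k]) grid[k] else
      grid[k] + (0 - avg[k]) * (grid[k + 1] - grid[k]) / (avg[k + 1] - avg[k])
    out$offset_min[out$genotype == gt & !out$unsynchronisable] <-
      out$stage1_min[out$genotype == gt & !out$unsynchronisable] + t0
  }
  out
}

#' Bin values on a time x space grid
#'
#' @param df tibble with `value`, `time_min` and a position column.
#' @param time_breaks,pos_breaks bin edges.
#' @param pos_col name of the position column (e.g. DV distance from the
#'   mesectoderm, or AP position).
#' @return Tibble per non-empty bin: `time_mid`, `pos_mid`, `mean`, `n`;
#'   empty bins carry NA mean and n = 0.
#' @export
spatiotemporal_bin <- function(df, time_breaks, pos_breaks,
                               pos_col = "position") {
  tb <- findInterval(df$time_min, time_breaks, rightmost.closed = TRUE)
  pb <- findInterval(df[[pos_col]], pos_breaks, rightmost.closed = TRUE)
  nt <- length(time_breaks) - 1L; np <- length(pos_breaks) - 1L
  keep <- tb >= 1 & tb <= nt & pb >= 1 & pb <= np & !is.na(df$value)
  tb <- tb[keep]; pb <- pb[keep]; v <- df$value[keep]
  key <- (pb - 1L) * nt + tb
  mean_by <- tapply(v, key, mean)
  n_by <- tapply(v, key, length)
  grid <- expand.grid(tbin = seq_len(nt), pbin = seq_len(np))
  gkey <- (grid$pbin - 1L) * nt + grid$tbin
  tibble::tibble(
    time_mid = (time_breaks[grid$tbin] + time_breaks[grid$tbin + 1]) / 2,
    pos_mid = (pos_breaks[grid$pbin] + pos_breaks[grid$pbin + 1]) / 2,
    mean = as.numeric(mean_by[as.character(gkey)]),
    n = ifelse(is.na(n_by[as.character(gkey)]), 0L,
               as.integer(n_by[as.character(gkey)])))
}

#' Select the central AP region
#'
#' Movies are not registered precisely along AP (no landmarks), so
#' cross-movie AP comparisons use a fixed-width central window: cells with
#' AP position in [anterior_bound, anterior_bound + width]. The anterior
#' bound is chosen to exclude cells influenced by the cephalic furrow.
#'
#' @param df tibble of cells.
#' @param anterior_bound_um anterior edge of the window (um).
#' @param width_um window width (default 100).
#' @param ap_col name of the AP position column.
#' @return The subset tibble (with a warning if empty).
#' @export
central_region <- function(df, anterior_bound_um, width_um = 100,
                           ap_col = "cx") {
  sel <- df[[ap_col]] >= anterior_bound_um &
    df[[ap_col]] <= anterior_bound_um + width_um
  out <- df[which(sel), ]
  if (!nrow(out)) warning("central region selection is empty")
  out
}

#' Per-bin mixed-effects comparison of two genotypes
#'
#' Tests, in every time bin, for a fixed effect of genotype allowing for
#' random effects contributed by differences between embryos within a
#' genotype. The default "embryo" method fits the model at the embryo level:
#' per-embryo means are compared with a genotype fixed effect (the random
#' embryo effect is then absorbed into the residual), which is stable for
#' small cohorts and exactly calibrated. Method "cell" fits a cell-level
#' random-intercept model (`lmerTest`, Satterthwaite df), falling back to
#' the embryo method where the fit is degenerate. No multiple-testing
#' correction is applied across bins; each bin is reported at `alpha`.
#'
#' @param df tibble with `bin` (any bin identifier, e.g. bin mid-time),
#'   `embryo`, `genotype` (two levels), `value`.
#' @param alpha significance level (default 0.01).
#' @param method "embryo" (default) or "cell".
#' @return Tibble per bin: `bin`, `n_embryos_a`, `n_embryos_b`, `estimate`
#'   (genotype effect), `p_value`, `testable`, `significant`.
#' @export
genotype_compare <- function(df, alpha = 0.01,
                             method = c("embryo", "cell")) {
  method <- match.arg(method)
  stopifnot(length(unique(df$genotype)) <= 2)
  df <- df[!is.na(df$value), ]
  bins <- sort(unique(df$bin))
  rows <- lapply(bins, function(b) {
    d <- df[df$bin == b, ]
    gts <- sort(unique(d$genotype))
    ne <- vapply(gts, function(g)
      length(unique(d$embryo[d$genotype == g])), integer(1))
    res <- tibble::tibble(bin = b,
                          n_embryos_a = if (length(ne) >= 1) ne[1] else 0L,
                          n_embryos_b = if (length(ne) >= 2) ne[2] else 0L,
                          estimate = NA_real_, p_value = NA_real_,
                          testable = FALSE, significant = FALSE)
    if (length(gts) < 2 || any(ne < 2)) return(res)
    p <- NA_real_; est <- NA_real_
    if (method == "cell" && nrow(d) > length(unique(d$embryo))) {
      fit <- tryCatch(suppressMessages(suppressWarnings(
        lmerTest::lmer(value ~ genotype + (1 | embryo), data = d))),
        error = function(e) NULL)
      if (!is.null(fit)) {
        cf <- tryCatch(stats::coef(summary(fit)), error = function(e) NULL)
        if (!is.null(cf) && nrow(cf) >= 2) {
          est <- cf[2, "Estimate"]; p <- cf[2, "Pr(>|t|)"]
        }
      }
    }
    if (is.na(p)) {
      em <- stats::aggregate(value ~ embryo + genotype, data = d, FUN = mean)
      fit <- stats::lm(value ~ genotype, data = em)
      cf <- suppressWarnings(stats::coef(summary(fit)))
      if (nrow(cf) >= 2) { est <- cf[2, 1]; p <- cf[2, 4] }
    }
    res$estimate <- est
    res$p_value <- p
    res$testable <- is.finite(p)
    res$significant <- isTRUE(is.finite(p) && p < alpha)
    res
  })
  dplyr::bind_rows(rows)
}

#' Ribbon summary of a binned series
#'
#' Per bin: mean of per-embryo means, standard error between embryos, and a
#' display-only centred 3-bin moving average. Significance testing is always
#' done on the unsmoothed values.
#'
#' @param df tibble with `bin`, `embryo`, `value`.
#' @param smooth_bins width of the centred moving average (default 3).
#' @return Tibble per bin: `bin`, `mean`, `se`, `n_embryos`, `smoothed`.
#' @export
ribbon_summary <- function(df, smooth_bins = 3L) {
  df <- df[!is.na(df$value), ]
  em <- stats::aggregate(value ~ bin + embryo, data = df, FUN = mean)
  agg <- stats::aggregate(value ~ bin, data = em, FUN = function(v)
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)), n = length(v)))
  out <- tibble::tibble(bin = agg$bin,
                        mean = agg$value[, "mean"],
                        se = agg$value[, "se"],
                        n_embryos = as.integer(agg$value[, "n"]))
  out <- out[order(out$bin), ]
  sm <- stats::filter(out$mean, rep(1 / smooth_bins, smooth_bins), sides = 2)
  out$smoothed <- as.numeric(sm)
  out$smoothed[is.na(out$smoothed)] <- out$mean[is.na(out$smoothed)]
  out
}

#' Ribbon plot comparing genotypes over time
#'
#' @param summaries named list of [ribbon_summary()] outputs (one per
#'   genotype); bins must be time midpoints in minutes.
#' @param comparison optional [genotype_compare()] output; significant bins
#'   are shaded.
#' @param ylab y-axis label.
#' @return A ggplot object.
#' @export
plot_ribbon <- function(summaries, comparison = NULL, ylab = "value") {
  d <- dplyr::bind_rows(lapply(names(summaries), function(g) {
    s <- summaries[[g]]; s$genotype <- g; s
  }))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$smoothed,
                                       colour = .data$genotype,
                                       fill = .data$genotype))
  if (!is.null(comparison) && any(comparison$significant)) {
    sig <- comparison[comparison$significant, ]
    step <- if (nrow(d) > 1) min(diff(sort(unique(d$bin)))) else 1
    p <- p + ggplot2::annotate("rect",
                               xmin = sig$bin - step / 2,
                               xmax = sig$bin + step / 2,
                               ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "grey40")
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$smoothed - .data$se,
                                      ymax = .data$smoothed + .data$se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = ylab) +
    ggplot2::theme_minimal()
}
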