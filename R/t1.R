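# -- T1 neighbour-exchange detection and productivity -------------------------

#' Continuous productivity of a T1 neighbour exchange
#'
#' Scores how much a neighbour exchange contributes to axis extension from
#' the angle of the gaining pair's centroid-centroid line: +1 when aligned
#' with DV (the new junction extends the tissue along AP), 0 at 45 degrees,
#' -1 when aligned with AP. The default smooth form -cos(2 theta) equals the
#' strain projection factor, making productive exchange rates directly
#' comparable to intercalation strain rates; a linear-in-angle alternative
#' through the same anchor values is provided.
#'
#' @param centroid_angle_deg angle of the gaining pair's centroid line from
#'   the AP axis, in [0, 90] degrees.
#' @param method "cos" (default) or "linear".
#' @return Productivity in [-1, 1].
#' @examples
#' t1_productivity(c(0, 45, 90))  # -1, 0, 1
#' @export
t1_productivity <- function(centroid_angle_deg, method = c("cos", "linear")) {
  method <- match.arg(method)
  stopifnot(all(centroid_angle_deg >= 0 & centroid_angle_deg <= 90, na.rm = TRUE))
  switch(method,
         cos = -cos(2 * centroid_angle_deg * pi / 180),
         linear = (centroid_angle_deg - 45) / 45)
}

# collapse presence runs shorter than `persist` frames into the previous state
deflicker <- function(x, persist = 2L) {
  if (persist <= 1L || length(x) < 2L) return(x)
  r <- rle(x)
  while (length(r$lengths) > 2L) {
    short <- which(r$lengths < persist)
    short <- short[short > 1L & short < length(r$lengths)]
    if (!length(short)) break
    i <- short[1]
    r$values[i] <- r$values[i - 1]
    r <- rle(inverse.rle(r))
  }
  inverse.rle(r)
}

#' Detect T1 neighbour-exchange events in a tracked movie
#'
#' An event is recorded when a cell pair gains contact and, within the same
#' four-cell quartet, the opposite pair lost contact in a nearby earlier
#' frame. Contact changes must persist at least `persist_frames` frames to
#' count (transient flickers at near-4-way vertices are suppressed). The
#' swap time is the midpoint between the last frame of old contact and the
#' first frame of new contact. Events whose quartet cannot be completed
#' (e.g. at the field edge) are discarded.
#'
#' @param movie an `epi_movie`.
#' @param persist_frames minimum persistence of a contact change, in frames.
#' @param match_window_frames maximum frames between the loss and the gain.
#' @return Tibble with one row per event: `t_swap_min`, `frame_lose`,
#'   `frame_gain`, losing pair, gaining pair, `centroid_angle_deg` of the
#'   gaining pair at first contact, and `productivity`.
#' @export
detect_t1 <- function(movie, persist_frames = 2L, match_window_frames = 6L) {
  intf <- interfaces_table(movie)
  nF <- length(movie$meshes)
  if (!nrow(intf)) return(empty_t1_table())
  intf$key <- pair_key(intf$cell_a, intf$cell_b)
  keys <- unique(intf$key)
  P <- matrix(FALSE, length(keys), nF, dimnames = list(keys, NULL))
  P[cbind(match(intf$key, keys), intf$frame)] <- TRUE
  P <- t(apply(P, 1, deflicker, persist = persist_frames))

  # adjacency sets per frame from the deflickered presence
  split_keys <- strsplit(keys, "|", fixed = TRUE)
  ka <- vapply(split_keys, `[`, character(1), 1L)
  kb <- vapply(split_keys, `[`, character(1), 2L)
  neighbours_at <- function(f) {
    on <- P[, f]
    split(c(kb[on], ka[on]), c(ka[on], kb[on]))
  }

  cent <- lapply(movie$meshes, function(m) {
    d <- mesh_cells(m)
    mm <- cbind(d$cx, d$cy); rownames(mm) <- d$cell_id; mm
  })

  rows <- list()
  for (r in seq_along(keys)) {
    pr <- P[r, ]
    gains <- which(!c(TRUE, pr[-nF]) & pr)  # FALSE -> TRUE transitions
    for (fg in gains) {
      c1 <- ka[r]; c2 <- kb[r]
      nb <- neighbours_at(fg)
      common <- intersect(nb[[c1]], nb[[c2]])
      common <- setdiff(common, c(c1, c2))
      if (length(common) < 2L) next
      best <- NULL
      for (a in common) for (b in common) {
        if (a >= b) next
        kk <- pair_key(a, b)
        if (!kk %in% keys) next
        pp <- P[kk, ]
        if (pp[fg]) next                       # still in contact: not a swap
        prior <- which(pp[seq_len(fg - 1L)])
        if (!length(prior)) next
        fl <- max(prior)
        if (fg - fl > match_window_frames) next
        if (is.null(best) || fl > best$fl) best <- list(a = a, b = b, fl = fl)
      }
      if (is.null(best)) next
      ga <- cent[[fg]][c1, ]; gb <- cent[[fg]][c2, ]
      ang <- acute_angle_from_ap(gb[1] - ga[1], gb[2] - ga[2])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        t_swap_min = (movie$times_min[best$fl] + movie$times_min[fg]) / 2,
        frame_lose = best$fl, frame_gain = fg,
        lose_a = best$a, lose_b = best$b,
        gain_a = c1, gain_b = c2,
        centroid_angle_deg = ang,
        productivity = t1_productivity(ang))
    }
  }
  if (!length(rows)) return(empty_t1_table())
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$t_swap_min), ]
  out$event <- seq_len(nrow(out))
  out[, c("event", names(out)[names(out) != "event"])]
}

empty_t1_table <- function() {
  tibble::tibble(event = integer(), t_swap_min = numeric(),
                 frame_lose = integer(), frame_gain = integer(),
                 lose_a = character(), lose_b = character(),
                 gain_a = character(), gain_b = character(),
                 centroid_angle_deg = numeric(), productivity = numeric())
}

#' Neighbour-exchange rates per time bin
#'
#' Expresses swaps as a proportion of the total number of DV-oriented
#' interfaces (oriented more than `dv_threshold_deg` from the AP axis) and as
#' a rate per minute, so the measures are directly comparable to
#' intercalation strain rates (pp/min). The productive rate replaces the
#' event count by the sum of continuous productivities.
#'
#' @param events tibble from [detect_t1()].
#' @param movie the `epi_movie` the events came from (supplies the
#'   per-frame DV-oriented interface counts).
#' @param breaks_min time bin edges in minutes.
#' @param dv_threshold_deg orientation threshold; ties at exactly 45 degrees
#'   count as AP-oriented (the DV class is strictly greater).
#' @return Tibble per bin: `t_mid_min`, `n_swaps`, `sum_productivity`,
#'   `n_dv_interfaces` (bin-average), `swap_rate`, `productive_rate`
#'   (pp/min; NA where the bin has no DV-oriented interfaces).
#' @export
exchange_rates <- function(events, movie, breaks_min,
                           dv_threshold_deg = 45) {
  intf <- interfaces_table(movie)
  bin_of <- function(t) findInterval(t, breaks_min, rightmost.closed = TRUE)
  nb <- length(breaks_min) - 1L
  dv <- intf[intf$orientation_deg > dv_threshold_deg, ]
  dv_per_frame <- table(factor(bin_of(dv$time_min), levels = seq_len(nb))) /
    pmax(table(factor(bin_of(movie$times_min), levels = seq_len(nb))), 1)
  minutes <- diff(breaks_min)
  ev_bin <- factor(bin_of(events$t_swap_min), levels = seq_len(nb))
  n_swaps <- as.numeric(table(ev_bin))
  sum_prod <- as.numeric(tapply(events$productivity, ev_bin, sum,
                                default = 0))
  n_dv <- as.numeric(dv_per_frame)
  tibble::tibble(
    t_mid_min = (breaks_min[-1] + breaks_min[-length(breaks_min)]) / 2,
    n_swaps = n_swaps, sum_productivity = sum_prod,
    n_dv_interfaces = n_dv,
    swap_rate = ifelse(n_dv > 0, n_swaps / n_dv / minutes, NA_real_),
    productive_rate = ifelse(n_dv > 0, sum_prod / n_dv / minutes, NA_real_))
}

#' Interface trajectories aligned to the time of T1 swap
#'
#' For each event, the losing interface is traced backward (negative
#' time-to-swap) and the gaining interface forward (positive), giving length,
#' absolute and proportional length-change rates, and optionally the Myosin
#' density on the interface. Shrinking trajectories with fewer than 2
#' pre-swap frames are excluded.
#'
#' @param events tibble from [detect_t1()].
#' @param movie the `epi_movie`.
#' @param myosin optional per-interface Myosin table with columns `frame`,
#'   `cell_a`, `cell_b`, `density`.
#' @param rate_window half-window (frames) for the rates of change.
#' @return Long tibble: `event`, `phase` ("shrinking"/"growing"),
#'   `time_to_swap_min`, `length_um`, `abs_rate_um_min`, `prop_rate_pp_min`,
#'   `myosin_density`, `t_swap_min`.
#' @export
align_to_swap <- function(events, movie, myosin = NULL, rate_window = 2L) {
  intf <- interfaces_table(movie)
  intf$key <- pair_key(intf$cell_a, intf$cell_b)
  if (!is.null(myosin)) {
    myosin$key <- pair_key(myosin$cell_a, myosin$cell_b)
    intf <- dplyr::left_join(
      intf, myosin[, c("frame", "key", "density")], by = c("frame", "key"))
  } else intf$density <- NA_real_
  out <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    shrink <- intf[intf$key == pair_key(ev$lose_a, ev$lose_b) &
                     intf$frame <= ev$frame_lose, ]
    if (nrow(shrink) >= 2) {
      shrink <- shrink[order(shrink$frame), ]
      out[[length(out) + 1L]] <- tibble::tibble(
        event = ev$event, phase = "shrinking",
        time_to_swap_min = shrink$time_min - ev$t_swap_min,
        length_um = shrink$length_um,
        abs_rate_um_min = rate_of_change(shrink$length_um, shrink$time_min,
                                         rate_window),
        prop_rate_pp_min = rate_of_change(shrink$length_um, shrink$time_min,
                                          rate_window, transform = log),
        myosin_density = shrink$density,
        t_swap_min = ev$t_swap_min)
    }
    grow <- intf[intf$key == pair_key(ev$gain_a, ev$gain_b) &
                   intf$frame >= ev$frame_gain, ]
    if (nrow(grow)) {
      grow <- grow[order(grow$frame), ]
      out[[length(out) + 1L]] <- tibble::tibble(
        event = ev$event, phase = "growing",
        time_to_swap_min = grow$time_min - ev$t_swap_min,
        length_um = grow$length_um,
        abs_rate_um_min = rate_of_change(grow$length_um, grow$time_min,
                                         rate_window),
        prop_rate_pp_min = rate_of_change(grow$length_um, grow$time_min,
                                          rate_window, transform = log),
        myosin_density = grow$density,
        t_swap_min = ev$t_swap_min)
    }
  }
  if (!length(out)) return(tibble::tibble())
  dplyr::bind_rows(out)
}

#' Ensemble mean of swap-aligned trajectories
#'
#' @param aligned output of [align_to_swap()].
#' @param lag_breaks_min bin edges for time-to-swap.
#' @param value column to summarise.
#' @param swap_window_min optional length-2 window: only events whose swap
#'   time falls inside are pooled (e.g. c(0, 30) for shrinkage, c(0, 20) for
#'   growth).
#' @return Tibble per lag bin: `lag_mid_min`, `mean`, `se`, `n`.
#' @export
aligned_ensemble <- function(aligned, lag_breaks_min,
                             value = "prop_rate_pp_min",
                             swap_window_min = NULL) {
  d <- aligned
  if (!is.null(swap_window_min))
    d <- d[d$t_swap_min >= swap_window_min[1] &
             d$t_swap_min <= swap_window_min[2], ]
  d <- d[!is.na(d[[value]]), ]
  b <- findInterval(d$time_to_swap_min, lag_breaks_min,
                    rightmost.closed = TRUE)
  keep <- b >= 1 & b <= length(lag_breaks_min) - 1
  d <- d[keep, ]; b <- b[keep]
  v <- d[[value]]
  agg <- tapply(v, b, function(z)
    c(mean(z), stats::sd(z) / sqrt(length(z)), length(z)))
  bins <- as.integer(names(agg))
  m <- do.call(rbind, agg)
  tibble::tibble(
    lag_mid_min = (lag_breaks_min[bins] + lag_breaks_min[bins + 1]) / 2,
    mean = m[, 1], se = m[, 2], n = as.integer(m[, 3]))
}

#' Orientation of new-neighbour centroid lines after a swap
#'
#' @param events tibble from [detect_t1()].
#' @param movie the `epi_movie`.
#' @param max_lag_min maximum time after the swap to follow the pair.
#' @return Tibble: `event`, `time_from_swap_min`, `angle_deg` (acute, from
#'   AP); series truncate where either track is lost.
#' @export
new_neighbour_angle <- function(events, movie, max_lag_min = 10) {
  cent <- lapply(movie$meshes, function(m) {
    d <- mesh_cells(m)
    mm <- cbind(d$cx, d$cy); rownames(mm) <- d$cell_id; mm
  })
  out <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    for (f in seq.int(ev$frame_gain, length(movie$meshes))) {
      lag <- movie$times_min[f] - ev$t_swap_min
      if (lag > max_lag_min) break
      if (!(ev$gain_a %in% rownames(cent[[f]])) ||
          !(ev$gain_b %in% rownames(cent[[f]]))) break
      ga <- cent[[f]][ev$gain_a, ]; gb <- cent[[f]][ev$gain_b, ]
      out[[length(out) + 1L]] <- tibble::tibble(
        event = ev$event, time_from_swap_min = lag,
        angle_deg = acute_angle_from_ap(gb[1] - ga[1], gb[2] - ga[2]))
    }
  }
  dplyr::bind_rows(out)
}
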