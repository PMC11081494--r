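# -- synthetic movies: flows + scripted T1 neighbour exchanges ----------------

unit2 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) c(1, 0) else v / n
}

# cells of a mesh that use a given vertex id
cells_using_vertex <- function(cells, v) {
  names(cells)[vapply(cells, function(cyc) v %in% cyc, logical(1))]
}

has_edge <- function(cyc, a, b) {
  nxt <- c(cyc[-1], cyc[1])
  any((cyc == a & nxt == b) | (cyc == b & nxt == a))
}

#' Schedule T1 neighbour exchanges on a tessellation
#'
#' Selects interior interfaces whose quartets (the two cells losing contact
#' and the two gaining it) are pairwise disjoint across events and assigns
#' each a swap time. By default DV-oriented interfaces (> 45 degrees from AP)
#' are preferred, mimicking polarised intercalation; the gaining pair of such
#' an event lies roughly along DV, so its scripted productivity is close
#' to +1.
#'
#' @param mesh an `epi_mesh` (the movie's starting tessellation).
#' @param n number of events to schedule.
#' @param t_range length-2 numeric, swap times drawn uniformly in this window
#'   (minutes).
#' @param min_orientation_deg minimum interface orientation from AP for a
#'   candidate losing interface; set to 0 to allow any orientation.
#' @param shrink_min,grow_min durations of scripted shrinkage and regrowth.
#' @param new_length_um length the new junction reaches after `grow_min`.
#' @param seed optional integer seed.
#' @return A `swap_schedule` tibble: one row per event with the losing pair,
#'   gaining pair, losing vertex ids and swap time.
#' @export
schedule_swaps <- function(mesh, n, t_range = c(2, 20),
                           min_orientation_deg = 45,
                           shrink_min = 5, grow_min = 5,
                           new_length_um = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  intf <- mesh_interfaces(mesh)
  boundary <- mesh_boundary_cells(mesh)
  vuse <- table(unlist(mesh$cells, use.names = FALSE))
  ok <- !(intf$cell_a %in% boundary) & !(intf$cell_b %in% boundary) &
    vuse[as.character(intf$v1)] == 3 & vuse[as.character(intf$v2)] == 3 &
    intf$orientation_deg >= min_orientation_deg
  cand <- intf[which(ok), ]
  cand <- cand[sample.int(nrow(cand)), ]
  used <- character(0)
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, ]
    cp <- setdiff(cells_using_vertex(mesh$cells, r$v1), c(r$cell_a, r$cell_b))
    cq <- setdiff(cells_using_vertex(mesh$cells, r$v2), c(r$cell_a, r$cell_b))
    if (length(cp) != 1L || length(cq) != 1L || cp == cq) next
    quartet <- c(r$cell_a, r$cell_b, cp, cq)
    if (any(quartet %in% used)) next
    if (cp %in% boundary || cq %in% boundary) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      event = length(rows) + 1L,
      lose_a = r$cell_a, lose_b = r$cell_b,
      gain_a = cp, gain_b = cq, v_p = r$v1, v_q = r$v2,
      t_swap_min = NA_real_,
      shrink_min = shrink_min, grow_min = grow_min,
      new_length_um = new_length_um)
    used <- c(used, quartet)
    if (length(rows) == n) break
  }
  if (length(rows) < n)
    warning(sprintf("only %d of %d requested swaps could be scheduled",
                    length(rows), n))
  sched <- dplyr::bind_rows(rows)
  if (nrow(sched))
    sched$t_swap_min <- sort(stats::runif(nrow(sched), t_range[1], t_range[2]))
  class(sched) <- c("swap_schedule", class(sched))
  sched
}

#' Simulate a tracked synthetic movie
#'
#' Advects a tessellation through a prescribed flow, executes scheduled T1
#' neighbour exchanges (linear shrinkage of the losing junction to a 4-way
#' vertex at the scripted time, then growth of the new junction
#' perpendicular to it), and records ground truth: per-cell true strain
#' tensors, realised swap events and per-cell bipolarity parameters used by
#' the renderer.
#'
#' @param mesh an `epi_mesh` starting tessellation.
#' @param times_min frame times in minutes (30-s spacing in the emulated
#'   movies).
#' @param flow a `flow_spec`.
#' @param swaps a `swap_schedule` from [schedule_swaps()], or NULL.
#' @param id,genotype movie labels.
#' @param pixel_size_um micrometres per pixel for rendering.
#' @param track_noise_um SD of the sub-pixel tracking/segmentation jitter
#'   added to the stored vertex positions of every frame (the underlying
#'   dynamics stay exact; ground-truth tensors are computed from the clean
#'   state). 0.1 um is about 0.2 px at the default pixel size, typical of
#'   manually corrected segmentations. Set to 0 for exactness checks.
#' @param bipolarity_base,bipolarity_amp_range,bipolarity_phase_mean,bipolarity_phase_sd,seed
#'   per-cell myosin intensity model: base junctional density (f.i.),
#'   uniform range for the period-2 amplitude, and the Gaussian law for the
#'   enrichment direction (degrees from AP; 90 = DV-oriented junctions).
#' @return An `epi_movie` with a `ground_truth` list: `strain` (per frame and
#'   cell), `swaps` (realised events), `bipolarity` (per cell).
#' @export
simulate_movie <- function(mesh, times_min, flow = flow_none(), swaps = NULL,
                           id = "synthetic", genotype = "unknown",
                           pixel_size_um = 0.5, track_noise_um = 0.1,
                           bipolarity_base = 100,
                           bipolarity_amp_range = c(20, 60),
                           bipolarity_phase_mean = 90,
                           bipolarity_phase_sd = 15,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nF <- length(times_min)
  events <- if (is.null(swaps) || !nrow(swaps)) list() else
    lapply(seq_len(nrow(swaps)), function(i) {
      e <- as.list(swaps[i, ])
      e$state <- "pending"; e$h0 <- NA_real_
      e$u <- NA_integer_; e$w <- NA_integer_
      e
    })

  vmat <- mesh$vertices
  cells <- mesh$cells
  meshes <- vector("list", nF)
  truth_strain <- vector("list", nF)
  swap_rows <- list()

  enforce_events <- function(t) {
    for (k in seq_along(events)) {
      e <- events[[k]]
      if (e$state == "pending" && t >= e$t_swap_min - e$shrink_min &&
          t < e$t_swap_min) {
        events[[k]]$state <<- "shrinking"
        events[[k]]$h0 <<- sqrt(sum((vmat[e$v_p, ] - vmat[e$v_q, ])^2))
        e <- events[[k]]
      }
      if (e$state == "shrinking" || (e$state == "pending" && t >= e$t_swap_min)) {
        if (t < e$t_swap_min) {
          h <- max(e$h0 * (e$t_swap_min - t) / e$shrink_min, 0.05)
          m <- (vmat[e$v_p, ] + vmat[e$v_q, ]) / 2
          dir <- unit2(vmat[e$v_p, ] - vmat[e$v_q, ])
          vmat[e$v_p, ] <<- m + dir * h / 2
          vmat[e$v_q, ] <<- m - dir * h / 2
        } else {
          # execute the swap: collapse p,q and regrow perpendicular
          m <- (vmat[e$v_p, ] + vmat[e$v_q, ]) / 2
          dir <- unit2(vmat[e$v_p, ] - vmat[e$v_q, ])
          perp <- c(-dir[2], dir[1])
          centA <- poly_centroid(vmat[cells[[e$lose_a]], , drop = FALSE])
          if (sum((centA - m) * perp) < 0) perp <- -perp
          h <- max(e$new_length_um *
                     min((t - e$t_swap_min) / e$grow_min, 1), 0.05)
          u <- nrow(vmat) + 1L; w <- nrow(vmat) + 2L
          vmat <<- rbind(vmat, m + perp * h / 2, m - perp * h / 2)
          cycA <- cells[[e$lose_a]]; cycB <- cells[[e$lose_b]]
          replace_pair <- function(cyc, a, b, nw) {
            nxt <- c(cyc[-1], cyc[1])
            i <- which((cyc == a & nxt == b) | (cyc == b & nxt == a))[1]
            if (is.na(i)) stop("losing edge not found during T1 edit")
            j <- i %% length(cyc) + 1L
            out <- cyc[-c(i, j)]
            append(out, nw, after = if (j < i) 0L else i - 1L)
          }
          # the gaining cell's boundary runs ..., a_prev, <kept by the losing
          # cell sharing edge (a_prev, r)>, <other new vertex>, ...
          insert_pair <- function(cyc, r) {
            i <- which(cyc == r)
            a_prev <- cyc[(i - 2L) %% length(cyc) + 1L]
            first <- if (has_edge(cycA, a_prev, r)) u else w
            second <- if (first == u) w else u
            out <- cyc[-i]
            append(out, c(first, second), after = i - 1L)
          }
          cells[[e$lose_a]] <<- replace_pair(cells[[e$lose_a]], e$v_p, e$v_q, u)
          cells[[e$lose_b]] <<- replace_pair(cells[[e$lose_b]], e$v_p, e$v_q, w)
          cells[[e$gain_a]] <<- insert_pair(cells[[e$gain_a]], e$v_p)
          cells[[e$gain_b]] <<- insert_pair(cells[[e$gain_b]], e$v_q)
          events[[k]]$state <<- "growing"
          events[[k]]$u <<- u; events[[k]]$w <<- w
          ga <- poly_centroid(vmat[cells[[e$gain_a]], , drop = FALSE])
          gb <- poly_centroid(vmat[cells[[e$gain_b]], , drop = FALSE])
          ang <- acute_angle_from_ap(gb[1] - ga[1], gb[2] - ga[2])
          swap_rows[[length(swap_rows) + 1L]] <<- tibble::tibble(
            event = e$event, t_swap_min = e$t_swap_min,
            lose_a = e$lose_a, lose_b = e$lose_b,
            gain_a = e$gain_a, gain_b = e$gain_b,
            gain_angle_deg = ang,
            productivity = t1_productivity(ang))
        }
      } else if (e$state == "growing" && t <= e$t_swap_min + e$grow_min) {
        m <- (vmat[e$u, ] + vmat[e$w, ]) / 2
        dir <- unit2(vmat[e$u, ] - vmat[e$w, ])
        h <- max(e$new_length_um * min((t - e$t_swap_min) / e$grow_min, 1), 0.05)
        vmat[e$u, ] <<- m + dir * h / 2
        vmat[e$w, ] <<- m - dir * h / 2
      }
    }
  }

  for (f in seq_len(nF)) {
    t <- times_min[f]
    if (f > 1L)
      vmat <- advect_points(vmat, flow, times_min[f - 1], t - times_min[f - 1])
    enforce_events(t)
    vobs <- vmat
    if (track_noise_um > 0)
      vobs <- vobs + stats::rnorm(length(vobs), 0, track_noise_um)
    meshes[[f]] <- epi_mesh(vobs, cells)
    cen <- vapply(cells, function(cyc)
      poly_centroid(vmat[cyc, , drop = FALSE]), numeric(2))
    cen <- t(cen)
    ts <- flow_true_strain(flow, cen, t)
    ts$frame <- f; ts$time_min <- t
    ts$cell_id <- names(cells)
    truth_strain[[f]] <- ts
  }

  amp <- stats::runif(length(cells), bipolarity_amp_range[1],
                      bipolarity_amp_range[2])
  phase <- (stats::rnorm(length(cells), bipolarity_phase_mean,
                         bipolarity_phase_sd)) %% 180
  bip <- tibble::tibble(cell_id = names(cells), base = bipolarity_base,
                        amplitude = amp, phase_deg = phase)
  # effective per-cell polarity of the painted field: shared junctions carry
  # the mean of the two adjacent cells' laws, so the field each cell actually
  # displays differs from its sampling parameters; this is the recoverable
  # ground truth (computed analytically on the first frame, before noise)
  eff <- bipolarity(meshes[[1]], painted_densities(meshes[[1]], bip))
  bip$true_amplitude <- eff$amplitude[match(bip$cell_id, eff$cell_id)]
  bip$true_phase_deg <- eff$phase_deg[match(bip$cell_id, eff$cell_id)]
  bip$true_ap_projected <- eff$ap_projected[match(bip$cell_id, eff$cell_id)]

  epi_movie(meshes, times_min, id = id, genotype = genotype,
            pixel_size_um = pixel_size_um,
            ground_truth = list(
              strain = dplyr::bind_rows(truth_strain),
              swaps = dplyr::bind_rows(swap_rows),
              bipolarity = bip))
}
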