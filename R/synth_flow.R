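# -- prescribed tissue flows --------------------------------------------------
#
# A flow_spec describes a time-varying velocity field v(x, t) (um/min) with an
# analytic velocity gradient L(x, t) (per min). Meshes are advected through
# the field and the symmetric part of L at each cell centroid is recorded as
# the ground-truth local strain-rate tensor.

ramp_window <- function(t, t_on, t_off, ramp_min) {
  if (ramp_min <= 0) return(as.numeric(t >= t_on & t < t_off))
  up <- pmin(pmax((t - t_on) / ramp_min, 0), 1)
  down <- pmin(pmax((t_off - t) / ramp_min, 0), 1)
  pmin(up, down)
}

#' Flow specifications for synthetic embryos
#'
#' `flow_affine` is a spatially uniform velocity gradient. `flow_dv_pull`
#' emulates the ventral pull of mesoderm invagination: DV stretch strongest at
#' the midline and decaying exponentially with distance from it.
#' `flow_ap_pull` emulates the posterior pull of endoderm invagination: AP
#' stretch increasing toward the posterior with an exponential profile.
#' `flow_sum` superimposes component flows. All components are gated by a
#' time window `[t_on, t_off]` with a linear ramp of `ramp_min` minutes.
#'
#' @param L 2x2 velocity-gradient matrix (per min) for `flow_affine`.
#' @param rate peak local strain rate (pp/min).
#' @param decay_um decay length of the spatial profile (micrometres).
#' @param x_ref AP position where the AP-pull rate equals `rate`
#'   (posterior edge of the field).
#' @param t_on,t_off activity window (minutes).
#' @param ramp_min ramp duration at the window edges (minutes).
#' @param origin flow origin for `flow_affine` (point with zero velocity).
#' @param ... component `flow_spec`s for `flow_sum`.
#' @return A `flow_spec`: list of functions `velocity(xy, t)` and
#'   `gradient(xy, t)`.
#' @name flow_spec
NULL

new_flow_spec <- function(velocity, gradient) {
  structure(list(velocity = velocity, gradient = gradient),
            class = "flow_spec")
}

#' @rdname flow_spec
#' @export
flow_affine <- function(L, t_on = -Inf, t_off = Inf, ramp_min = 0,
                        origin = c(0, 0)) {
  L <- matrix(as.numeric(L), 2, 2)
  new_flow_spec(
    velocity = function(xy, t) {
      g <- ramp_window(t, t_on, t_off, ramp_min)
      g * (sweep(xy, 2, origin) %*% t(L))
    },
    gradient = function(xy, t) {
      g <- ramp_window(t, t_on, t_off, ramp_min)
      lapply(seq_len(nrow(xy)), function(i) g * L)
    }
  )
}

#' @rdname flow_spec
#' @export
flow_dv_pull <- function(rate = 0.02, decay_um = 50, t_on = -13, t_off = 7,
                         ramp_min = 2) {
  new_flow_spec(
    velocity = function(xy, t) {
      g <- ramp_window(t, t_on, t_off, ramp_min)
      y <- pmax(xy[, 2], 0)
      # d v_y / d y = rate * exp(-y/decay): DV stretch strongest at the
      # midline, 1/e of the peak at one decay length from it
      vy <- rate * decay_um * (1 - exp(-y / decay_um))
      cbind(0, g * vy)
    },
    gradient = function(xy, t) {
      g <- ramp_window(t, t_on, t_off, ramp_min)
      y <- pmax(xy[, 2], 0)
      lyy <- g * rate * exp(-y / decay_um)
      lapply(seq_along(lyy), function(i) matrix(c(0, 0, 0, lyy[i]), 2, 2))
    }
  )
}

#' @rdname flow_spec
#' @export
flow_ap_pull <- function(rate = 0.02, decay_um = 120, x_ref = 180,
                         t_on = 0, t_off = 20, ramp_min = 1) {
  new_flow_spec(
    velocity = function(xy, t) {
      g <- ramp_window(t, t_on, t_off, ramp_min)
      vx <- rate * decay_um * exp((xy[, 1] - x_ref) / decay_um)
      cbind(g * vx, 0)
    },
    gradient = function(xy, t) {
      g <- ramp_window(t, t_on, t_off, ramp_min)
      lxx <- g * rate * exp((xy[, 1] - x_ref) / decay_um)
      lapply(seq_along(lxx), function(i) matrix(c(lxx[i], 0, 0, 0), 2, 2))
    }
  )
}

#' @rdname flow_spec
#' @export
flow_sum <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "flow_spec")))
  new_flow_spec(
    velocity = function(xy, t) {
      Reduce(`+`, lapply(parts, function(p) p$velocity(xy, t)))
    },
    gradient = function(xy, t) {
      gl <- lapply(parts, function(p) p$gradient(xy, t))
      lapply(seq_len(nrow(xy)), function(i)
        Reduce(`+`, lapply(gl, `[[`, i)))
    }
  )
}

#' Zero flow
#' @return A `flow_spec` with zero velocity everywhere.
#' @export
flow_none <- function() flow_affine(matrix(0, 2, 2))

#' Ground-truth strain tensor of a flow at given points
#'
#' @param flow a `flow_spec`.
#' @param xy n x 2 matrix of positions.
#' @param t time (minutes).
#' @return Tibble with `exx`, `exy`, `eyy`: symmetric part of the velocity
#'   gradient (pp/min).
#' @export
flow_true_strain <- function(flow, xy, t) {
  Ls <- flow$gradient(xy, t)
  tibble::tibble(
    exx = vapply(Ls, function(L) L[1, 1], numeric(1)),
    exy = vapply(Ls, function(L) (L[1, 2] + L[2, 1]) / 2, numeric(1)),
    eyy = vapply(Ls, function(L) L[2, 2], numeric(1))
  )
}

# advect a set of points through the flow from t to t + dt (Euler substeps)
advect_points <- function(xy, flow, t, dt_min, n_sub = 5L) {
  h <- dt_min / n_sub
  for (s in seq_len(n_sub)) {
    tt <- t + (s - 1) * h
    xy <- xy + h * flow$velocity(xy, tt)
  }
  xy
}
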