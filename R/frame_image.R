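# -- building frames from label images ---------------------------------------
#
# Image convention: a label image is an integer matrix with background 0 and
# one positive label per cell. Rows index the DV axis (y), columns the AP
# axis (x); the centre of pixel [r, c] sits at ((c - 0.5), (r - 0.5)) *
# pixel_size micrometres, giving a right-handed (AP, DV) frame.

px_centre <- function(r, c, pixel_size) {
  cbind((c - 0.5) * pixel_size, (r - 0.5) * pixel_size)
}

# corners between 2x2 pixel blocks where >= min_labels distinct regions
# (background counts as a region) meet; returns corner coordinates in px
# units together with the participating labels
junction_corners <- function(label) {
  M <- rbind(0L, cbind(0L, label, 0L), 0L)
  a <- M[-nrow(M), -ncol(M)]
  b <- M[-nrow(M), -1]
  c_ <- M[-1, -ncol(M)]
  d <- M[-1, -1]
  n_distinct <- 1L +
    (b != a) +
    ((c_ != a) & (c_ != b)) +
    ((d != a) & (d != b) & (d != c_))
  idx <- which(n_distinct >= 3L, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(list(row_px = numeric(0), col_px = numeric(0),
                labels = list()))
  }
  labs <- lapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    unique(c(M[i, j], M[i, j + 1], M[i + 1, j], M[i + 1, j + 1]))
  })
  # corner between padded rows (i, i+1) = original rows (i-1, i): at y = (i-1) px
  list(row_px = as.numeric(idx[, 1] - 1L), col_px = as.numeric(idx[, 2] - 1L),
       labels = labs)
}

# 4-adjacency contacts between distinct positive labels
label_adjacency <- function(label) {
  h_a <- label[, -ncol(label)]; h_b <- label[, -1]
  v_a <- label[-nrow(label), ]; v_b <- label[-1, ]
  aa <- c(h_a, v_a); bb <- c(h_b, v_b)
  keep <- aa > 0 & bb > 0 & aa != bb
  if (!any(keep)) return(tibble::tibble(a = integer(), b = integer(),
                                        n_adjacent = integer()))
  a <- pmin(aa[keep], bb[keep]); b <- pmax(aa[keep], bb[keep])
  tab <- table(paste(a, b))
  ab <- do.call(rbind, strsplit(names(tab), " "))
  tibble::tibble(a = as.integer(ab[, 1]), b = as.integer(ab[, 2]),
                 n_adjacent = as.integer(tab))
}

# Moore boundary tracing of one label's mask; returns polygon of boundary
# pixel centres (px units)
trace_boundary <- function(label, lab) {
  pix <- which(label == lab, arr.ind = TRUE)
  if (nrow(pix) < 3L) stop(sprintf("degenerate cell: label %d has < 3 pixels", lab))
  inside <- function(r, c) r >= 1 && r <= nrow(label) && c >= 1 &&
    c <= ncol(label) && label[r, c] == lab
  start <- pix[order(pix[, 1], pix[, 2]), , drop = FALSE][1, ]
  # Moore-neighbour tracing, clockwise offsets starting from west
  offs <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
                 ncol = 2, byrow = TRUE)
  path <- list(start)
  cur <- start; backtrack <- 1L  # came from west
  repeat {
    found <- FALSE
    for (s in 0:7) {
      k <- (backtrack + s) %% 8L + 1L
      nr <- cur[1] + offs[k, 1]; nc <- cur[2] + offs[k, 2]
      if (inside(nr, nc)) {
        # resume the scan from the direction pointing back at the previous cell
        prev_off <- c(cur[1] - nr, cur[2] - nc)
        backtrack <- which(offs[, 1] == prev_off[1] & offs[, 2] == prev_off[2])
        cur <- c(nr, nc)
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel cluster
    if (all(cur == start) && length(path) > 1L) break
    path[[length(path) + 1L]] <- cur
    if (length(path) > 4L * nrow(pix) + 8L) break  # safety
  }
  do.call(rbind, path)
}

#' Build a frame of cell geometry from a label image
#'
#' Reconstructs per-cell geometry from a segmented label image: one cell per
#' positive label, interfaces where two labels touch (4-adjacency), and
#' vertices at corners where three or more regions meet. Interface lengths
#' are straight vertex-to-vertex distances and orientations acute angles
#' from the AP axis; interfaces whose two endpoint vertices cannot be found
#' (field edge) carry NA geometry.
#'
#' @param label integer matrix, background 0, one positive label per cell.
#' @param pixel_size micrometres per pixel.
#' @param trace_polygons if TRUE, also trace each cell's boundary polygon
#'   (Moore tracing); slower, off by default.
#' @return An object of class `epi_frame`: list with `cells` (tibble:
#'   `cell_id`, `label`, `cx`, `cy`, `area_um2`, shape tensor columns
#'   `sxx`, `sxy`, `syy`), `interfaces` (tibble: `cell_a`, `cell_b`,
#'   endpoints, `length_um`, `orientation_deg`, `n_adjacent`), `vertices`
#'   (matrix, um, corners where >= 3 cells meet), `pixel_size_um`, `label`
#'   (the input image), and optionally `polygons`.
#' @export
build_frame <- function(label, pixel_size = 0.5, trace_polygons = FALSE) {
  if (!is.matrix(label)) stop("label must be a matrix")
  if (is.double(label)) {
    if (max(abs(label - round(label))) > 0) stop("label image must be integer")
    storage.mode(label) <- "integer"
  }
  if (pixel_size <= 0) stop("pixel_size must be positive")
  labs <- sort(unique(as.vector(label)))
  labs <- labs[labs > 0]
  if (!length(labs)) stop("label image contains no cells")

  pix_idx <- which(label > 0)
  rr <- ((pix_idx - 1L) %% nrow(label)) + 1L
  cc <- ((pix_idx - 1L) %/% nrow(label)) + 1L
  ll <- label[pix_idx]
  xy <- px_centre(rr, cc, pixel_size)
  cells <- dplyr::bind_rows(lapply(labs, function(lb) {
    sel <- ll == lb
    n <- sum(sel)
    if (n < 3L) stop(sprintf("degenerate cell: label %d has < 3 pixels", lb))
    x <- xy[sel, 1]; y <- xy[sel, 2]
    cx <- mean(x); cy <- mean(y)
    # pixel covariance + the pixel's own square contributes ps^2/12
    sxx <- mean((x - cx)^2) + pixel_size^2 / 12
    syy <- mean((y - cy)^2) + pixel_size^2 / 12
    sxy <- mean((x - cx) * (y - cy))
    tibble::tibble(cell_id = sprintf("L%d", lb), label = lb, cx = cx, cy = cy,
                   area_um2 = n * pixel_size^2,
                   sxx = sxx, sxy = sxy, syy = syy)
  }))

  jc <- junction_corners(label)
  adj <- label_adjacency(label)
  n_int <- nrow(adj)
  x1 <- y1 <- x2 <- y2 <- len <- ori <- rep(NA_real_, n_int)
  if (n_int && length(jc$row_px)) {
    for (i in seq_len(n_int)) {
      hit <- which(vapply(jc$labels, function(L)
        adj$a[i] %in% L && adj$b[i] %in% L, logical(1)))
      if (length(hit) >= 2L) {
        px <- cbind(jc$col_px[hit], jc$row_px[hit]) * pixel_size
        if (length(hit) > 2L) {
          dm <- as.matrix(stats::dist(px))
          far <- which(dm == max(dm), arr.ind = TRUE)[1, ]
          px <- px[far, , drop = FALSE]
        }
        x1[i] <- px[1, 1]; y1[i] <- px[1, 2]
        x2[i] <- px[2, 1]; y2[i] <- px[2, 2]
        len[i] <- sqrt((x2[i] - x1[i])^2 + (y2[i] - y1[i])^2)
        ori[i] <- acute_angle_from_ap(x2[i] - x1[i], y2[i] - y1[i])
      }
    }
  }
  interfaces <- tibble::tibble(
    cell_a = sprintf("L%d", adj$a), cell_b = sprintf("L%d", adj$b),
    label_a = adj$a, label_b = adj$b,
    x1 = x1, y1 = y1, x2 = x2, y2 = y2,
    length_um = len, orientation_deg = ori, n_adjacent = adj$n_adjacent)

  cell_only <- lengths(jc$labels) > 0 &
    vapply(jc$labels, function(L) sum(L > 0) >= 3L, logical(1))
  vertices <- cbind(jc$col_px[cell_only], jc$row_px[cell_only]) * pixel_size

  polys <- NULL
  if (trace_polygons) {
    polys <- lapply(stats::setNames(labs, sprintf("L%d", labs)), function(lb) {
      b <- trace_boundary(label, lb)
      px_centre(b[, 1], b[, 2], pixel_size)
    })
  }
  structure(list(cells = cells, interfaces = interfaces, vertices = vertices,
                 pixel_size_um = pixel_size, label = label, polygons = polys),
            class = "epi_frame")
}

#' @export
print.epi_frame <- function(x, ...) {
  cat(sprintf("<epi_frame> %d cells, %d interfaces, %d vertices (%.3g um/px)\n",
              nrow(x$cells), nrow(x$interfaces), nrow(x$vertices),
              x$pixel_size_um))
  invisible(x)
}

#' Link cell labels between two consecutive label images
#'
#' Matches each cell of the later frame to the earlier cell with maximal
#' pixel overlap; ties are broken by the smaller centroid displacement.
#' Later cells with no overlap become new tracks (NA in `from`).
#'
#' @param label_t,label_t1 integer label matrices of the same size.
#' @return Tibble with `to` (label in `label_t1`), `from` (matched label in
#'   `label_t` or NA), `overlap_px`.
#' @export
link_frames <- function(label_t, label_t1) {
  stopifnot(all(dim(label_t) == dim(label_t1)))
  keep <- label_t1 > 0
  if (!any(keep)) return(tibble::tibble(to = integer(), from = integer(),
                                        overlap_px = integer()))
  ov <- table(to = label_t1[keep], from = label_t[keep])
  cen <- function(lbl) {
    idx <- which(lbl > 0)
    r <- ((idx - 1L) %% nrow(lbl)) + 1L
    c_ <- ((idx - 1L) %/% nrow(lbl)) + 1L
    do.call(rbind, lapply(split(seq_along(idx), lbl[idx]), function(s)
      c(mean(r[s]), mean(c_[s]))))
  }
  c0 <- cen(label_t); c1 <- cen(label_t1)
  out <- lapply(rownames(ov), function(to_lab) {
    counts <- ov[to_lab, ]
    counts <- counts[names(counts) != "0"]
    if (!length(counts) || max(counts) == 0)
      return(tibble::tibble(to = as.integer(to_lab), from = NA_integer_,
                            overlap_px = 0L))
    best <- names(counts)[counts == max(counts)]
    if (length(best) > 1L) {
      disp <- vapply(best, function(fr)
        sum((c1[to_lab, ] - c0[fr, ])^2), numeric(1))
      best <- best[which.min(disp)]
    }
    tibble::tibble(to = as.integer(to_lab), from = as.integer(best),
                   overlap_px = as.integer(max(counts)))
  })
  dplyr::bind_rows(out)
}
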