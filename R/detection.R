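# Per-slice blob detection and the axial-oversampling correction: repeated
# per-plane detections of the same soma are grouped by 3D proximity and
# collapsed to one cell.

# 8-connected component labelling of a logical mask (two-pass union-find).
label_components <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(labels)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pos <- matrix(0L, nr, nc)
  pos[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  for (t in seq_along(idx)) {
    r <- rows[t]; cl <- cols[t]
    # neighbours already visited in column-major order
    for (d in list(c(-1L, 0L), c(-1L, -1L), c(0L, -1L), c(1L, -1L))) {
      rr <- r + d[1]; cc <- cl + d[2]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && pos[rr, cc] > 0L) {
        a <- find(t); b <- find(pos[rr, cc])
        if (a != b) parent[a] <- b
      }
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  labels[idx] <- match(roots, unique(roots))
  labels
}

#' Detect blobs in a 2D intensity image
#'
#' Thresholds the image, labels 8-connected super-threshold components,
#' discards components smaller than `min_area_px`, and returns the
#' intensity-weighted centroid of each remaining component in micrometres
#' (pixel i centre at `(i - 0.5) * pixel_um`, matching
#' [render_synthetic_slice()]). Two blobs merged by a low threshold yield a
#' single centroid; that is documented behaviour, not an error.
#'
#' @param image numeric matrix; rows index y, columns x.
#' @param threshold intensity threshold (> 0); pixels with value strictly
#'   above it form the mask.
#' @param min_area_px minimum component area in pixels.
#' @param pixel_um micrometres per pixel.
#' @return `data.frame` with `x_um`, `y_um`, `area_px`, `total_intensity`;
#'   zero rows when nothing is detected.
#' @export
detect_blobs <- function(image, threshold, min_area_px = 1L, pixel_um = 1) {
  stopifnot(is.matrix(image))
  check_number(threshold, "threshold", 0, strict_lower = TRUE)
  check_number(min_area_px, "min_area_px", 1)
  check_number(pixel_um, "pixel_um", 0, strict_lower = TRUE)
  labels <- label_components(image > threshold)
  k <- max(labels)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      area_px = integer(0), total_intensity = numeric(0))
  if (k == 0L) return(empty)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  w <- image[idx]
  rows <- ((idx - 1L) %% nrow(image)) + 1L
  cols <- ((idx - 1L) %/% nrow(image)) + 1L
  area <- tabulate(lab, k)
  wsum <- as.numeric(rowsum(w, lab))
  cx <- as.numeric(rowsum(w * (cols - 0.5), lab)) / wsum
  cy <- as.numeric(rowsum(w * (rows - 0.5), lab)) / wsum
  keep <- area >= min_area_px
  out <- data.frame(x_um = cx[keep] * pixel_um, y_um = cy[keep] * pixel_um,
                    area_px = area[keep], total_intensity = wsum[keep])
  out[order(out$y_um, out$x_um), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

# Single-linkage grouping: union events whose 3D distance is <= radius;
# groups are the transitive closure, hence independent of input order.
link_events <- function(pts, radius) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  r2 <- radius^2
  ord <- order(pts[, 3], pts[, 1], pts[, 2])
  zs <- pts[ord, 3]
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    # only events within radius in z can be linked
    b_max <- a
    while (b_max < n && zs[b_max + 1L] - zs[a] <= radius) b_max <- b_max + 1L
    if (b_max == a) next
    js <- ord[(a + 1L):b_max]
    d2 <- (pts[js, 1] - pts[i, 1])^2 + (pts[js, 2] - pts[i, 2])^2 +
      (pts[js, 3] - pts[i, 3])^2
    for (j in js[d2 <= r2]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots[order(pts[, 3], pts[, 1], pts[, 2])]))
}

#' Correct axial oversampling of per-slice detection events
#'
#' Events are grouped by the transitive closure of "3D Euclidean distance
#' <= radius" (single linkage) and each group is collapsed to one cell:
#'
#' * `mode = "median"` (default): the member whose z is the median of the
#'   group's z values is kept. With an even group there is no member at the
#'   median; the member closest to it is taken, ties resolved towards lower
#'   z and then lexicographically by (x, y) — a canonical rule, never input
#'   order.
#' * `mode = "mean"`: the group's positions are averaged. This is the
#'   variant that recovers the true z to within half the plane spacing for
#'   even two-plane groups.
#'
#' Output is invariant to the order of the input events, and increasing the
#' radius can only merge groups, never split them.
#'
#' @param events `data.frame` with `x_um`, `y_um`, `z_um` (one row per
#'   per-slice detection).
#' @param radius grouping radius in micrometres (> 0); default 10.
#' @param mode `"median"` or `"mean"`.
#' @return `data.frame` of corrected cells: `x_um`, `y_um`, `z_um`,
#'   `n_events` (group size). Empty input gives an empty frame.
#' @export
correct_axial_oversampling <- function(events, radius = 10,
                                       mode = c("median", "mean")) {
  mode <- match.arg(mode)
  check_number(radius, "radius", 0, strict_lower = TRUE)
  if (inherits(events, "brain_dataset")) events <- events$cells
  if (!nrow(events)) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      n_events = integer(0)))
  }
  pts <- as_coord_matrix(events)
  grp <- link_events(pts, radius)
  k <- max(grp)
  out <- matrix(0, nrow = k, ncol = 3)
  nev <- tabulate(grp, k)
  for (g in seq_len(k)) {
    members <- pts[grp == g, , drop = FALSE]
    if (mode == "mean") {
      out[g, ] <- colMeans(members)
    } else {
      m <- stats::median(members[, 3])
      d <- abs(members[, 3] - m)
      cand <- which(d == min(d))
      # canonical tie-break: lowest z, then lexicographic (x, y)
      cand <- cand[order(members[cand, 3], members[cand, 1],
                         members[cand, 2])]
      out[g, ] <- members[cand[1L], ]
    }
  }
  data.frame(x_um = out[, 1], y_um = out[, 2], z_um = out[, 3],
             n_events = nev)
}

#' Count corrected cells in one atlas region
#'
#' @param cells corrected-cell `data.frame` or [brain_dataset()].
#' @param atlas a [region_atlas()].
#' @param region_id id of a region present in the atlas.
#' @return integer count of cells assigned to `region_id`.
#' @export
count_region <- function(cells, atlas, region_id) {
  stopifnot(inherits(atlas, "region_atlas"))
  if (!region_id %in% atlas$ids) {
    stop("unknown region_id '", region_id, "'", call. = FALSE)
  }
  if (inherits(cells, "brain_dataset")) cells <- cells$cells
  if (!nrow(cells)) return(0L)
  sum(locate_points(cells, atlas) == region_id)
}

#' Read / write per-slice detection-event tables
#'
#' CSV columns: `brain_id`, `slice_index`, `x_um`, `y_um`, `z_um`.
#'
#' @param path CSV path.
#' @return [load_events()] returns a `data.frame`.
#' @export
load_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_um", "y_um", "z_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("event table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname load_events
#' @param events event `data.frame`.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
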