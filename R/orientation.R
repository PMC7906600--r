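# Leading-process orientation analysis. Each migrating cell is reduced to
# the vector from its soma to the tip of its leading process, expressed in
# the brain's axes (+x lateral, +y dorsal, +z rostral) and in spherical
# coordinates with the rostro-caudal axis as zenith: theta = arccos(v_z /
# |v|) in [0, pi] (0 = pure rostral), phi = atan2(v_y, v_x) in [-pi, pi)
# (0 = pure lateral).

AXIS_DIRECTION_NAMES <- list(
  x = c(positive = "medio-lateral", negative = "latero-medial"),
  y = c(positive = "ventro-dorsal", negative = "dorso-ventral"),
  z = c(positive = "caudo-rostral", negative = "rostro-caudal")
)

#' Soma-to-tip vectors with spherical coordinates
#'
#' @param records `data.frame` with `soma_x_um`, `soma_y_um`, `soma_z_um`,
#'   `tip_x_um`, `tip_y_um`, `tip_z_um` (other columns pass through).
#' @return the input plus `vx`, `vy`, `vz`, `length_um`, `theta`, `phi`
#'   (radians). Zero-length processes are an error naming the row.
#' @export
process_vectors <- function(records) {
  need <- c("soma_x_um", "soma_y_um", "soma_z_um",
            "tip_x_um", "tip_y_um", "tip_z_um")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  vx <- records$tip_x_um - records$soma_x_um
  vy <- records$tip_y_um - records$soma_y_um
  vz <- records$tip_z_um - records$soma_z_um
  len <- sqrt(vx^2 + vy^2 + vz^2)
  if (any(len == 0)) {
    stop("zero-length leading process at row ", which(len == 0)[1],
         " (tip coincides with soma)", call. = FALSE)
  }
  records$vx <- vx; records$vy <- vy; records$vz <- vz
  records$length_um <- len
  records$theta <- acos(pmin(pmax(vz / len, -1), 1))
  records$phi <- atan2(vy, vx)
  # atan2 returns pi for (-1, 0); map to -pi so phi lies in [-pi, pi)
  records$phi[records$phi >= pi] <- -pi
  records
}

# Extract an n x 3 vector matrix from records (runs process_vectors if
# needed).
vector_matrix <- function(records) {
  if (is.matrix(records)) {
    stopifnot(ncol(records) == 3L)
    return(records)
  }
  if (!all(c("vx", "vy", "vz") %in% names(records))) {
    records <- process_vectors(records)
  }
  cbind(records$vx, records$vy, records$vz)
}

#' 2D angular histogram of process orientations
#'
#' Equal-width bins over theta in [0, pi] and phi in [-pi, pi); right-open
#' intervals with the last bin closed. Frequencies sum to 1.
#'
#' @param records process records (see [process_vectors()]).
#' @param n_theta_bins,n_phi_bins bin counts (>= 2 each; defaults 18 x 36,
#'   i.e. 10 degree resolution).
#' @return an `angular_histogram` list: `counts` and `freq`
#'   (theta-bin x phi-bin matrices), `theta_breaks`, `phi_breaks`.
#' @export
angular_histogram <- function(records, n_theta_bins = 18L, n_phi_bins = 36L) {
  check_number(n_theta_bins, "n_theta_bins", 2)
  check_number(n_phi_bins, "n_phi_bins", 2)
  if (!NROW(records)) stop("no records", call. = FALSE)
  v <- vector_matrix(records)
  len <- sqrt(rowSums(v^2))
  theta <- acos(pmin(pmax(v[, 3] / len, -1), 1))
  phi <- atan2(v[, 2], v[, 1]); phi[phi >= pi] <- -pi
  tb <- seq(0, pi, length.out = n_theta_bins + 1L)
  pb <- seq(-pi, pi, length.out = n_phi_bins + 1L)
  ti <- pmin(findInterval(theta, tb, rightmost.closed = TRUE), n_theta_bins)
  pi_ <- pmin(findInterval(phi, pb, rightmost.closed = TRUE), n_phi_bins)
  counts <- matrix(0L, n_theta_bins, n_phi_bins,
                   dimnames = list(theta_bin = NULL, phi_bin = NULL))
  for (i in seq_along(ti)) counts[ti[i], pi_[i]] <- counts[ti[i], pi_[i]] + 1L
  structure(list(counts = counts, freq = counts / length(ti),
                 theta_breaks = tb, phi_breaks = pb, n = length(ti)),
            class = "angular_histogram")
}

#' Dominant-orientation fractions along each anatomical axis
#'
#' For each axis, the fraction of processes whose vector component is
#' positive, negative, or exactly zero, labelled with anatomical direction
#' names (+z = caudo-rostral, -y = dorso-ventral, ...). Depends only on
#' component signs, so it is invariant to vector magnitude. Equivalent to
#' integrating the angular histogram over the corresponding hemisphere when
#' bin edges align with the hemisphere boundaries.
#'
#' @param records process records.
#' @return `data.frame` with one row per axis: `axis`, `positive_name`,
#'   `negative_name`, `frac_positive`, `frac_negative`, `frac_zero`.
#' @export
dominant_axis_fractions <- function(records) {
  if (!NROW(records)) stop("no records", call. = FALSE)
  v <- vector_matrix(records)
  n <- nrow(v)
  out <- lapply(1:3, function(a) {
    ax <- c("x", "y", "z")[a]
    data.frame(axis = ax,
               positive_name = AXIS_DIRECTION_NAMES[[ax]][["positive"]],
               negative_name = AXIS_DIRECTION_NAMES[[ax]][["negative"]],
               frac_positive = sum(v[, a] > 0) / n,
               frac_negative = sum(v[, a] < 0) / n,
               frac_zero = sum(v[, a] == 0) / n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Polar histogram of orientations projected onto an anatomical plane
#'
#' Projects each vector onto the stated plane and bins the in-plane angle
#' over [-pi, pi) (equal-width, right-open bins). Angles: `"xy"` from +x
#' towards +y (latero-medial x dorso-ventral view), `"yz"` from +y towards
#' +z, `"xz"` from +x towards +z. Vectors nearly orthogonal to the plane
#' (projection norm < 1e-6 of the vector norm) are excluded and counted.
#'
#' @param records process records.
#' @param plane `"xy"`, `"yz"` or `"xz"`.
#' @param n_bins number of angular bins.
#' @return a `polar_histogram` list: `counts`, `freq`, `breaks`,
#'   `n_excluded`.
#' @export
polar_histogram <- function(records, plane = c("xy", "yz", "xz"),
                            n_bins = 36L) {
  plane <- match.arg(plane)
  check_number(n_bins, "n_bins", 2)
  if (!NROW(records)) stop("no records", call. = FALSE)
  v <- vector_matrix(records)
  ax <- switch(plane, xy = c(1L, 2L), yz = c(2L, 3L), xz = c(1L, 3L))
  u <- v[, ax, drop = FALSE]
  pnorm_ <- sqrt(rowSums(u^2))
  vnorm <- sqrt(rowSums(v^2))
  keep <- pnorm_ >= 1e-6 * vnorm
  n_excluded <- sum(!keep)
  if (!any(keep)) {
    stop("no records left after projection filtering", call. = FALSE)
  }
  ang <- atan2(u[keep, 2], u[keep, 1])
  ang[ang >= pi] <- -pi
  br <- seq(-pi, pi, length.out = n_bins + 1L)
  bi <- pmin(findInterval(ang, br, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(bi, n_bins)
  structure(list(counts = counts, freq = counts / sum(counts),
                 breaks = br, plane = plane, n_excluded = n_excluded),
            class = "polar_histogram")
}

#' Per-stage fraction of cells with an identifiable leading process
#'
#' @param records `data.frame` with `stage` and logical `traceable` columns,
#'   one row per cell.
#' @return `data.frame` with `stage`, `n`, `n_traceable`, `fraction`.
#' @export
traceable_fraction <- function(records) {
  stopifnot(all(c("stage", "traceable") %in% names(records)))
  if (!nrow(records)) stop("no records", call. = FALSE)
  stages <- unique(records$stage)
  out <- lapply(stages, function(s) {
    sub <- records[records$stage == s, ]
    data.frame(stage = s, n = nrow(sub),
               n_traceable = sum(sub$traceable),
               fraction = sum(sub$traceable) / nrow(sub),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mean resultant direction of a set of process vectors
#'
#' Normalises each vector to unit length, averages, and reports the mean
#' direction and the mean resultant length R-bar (1 = perfectly aligned,
#' near 0 = uniform).
#'
#' @param records process records or n x 3 matrix.
#' @return list with `direction` (unit 3-vector) and `R_bar`.
#' @export
mean_direction <- function(records) {
  v <- vector_matrix(records)
  u <- v / sqrt(rowSums(v^2))
  m <- colMeans(u)
  r <- sqrt(sum(m^2))
  list(direction = if (r > 0) m / r else c(NA_real_, NA_real_, NA_real_),
       R_bar = r)
}

#' Read a leading-process table from CSV
#'
#' Columns: `brain_id`, `stage`, `region_id`, `soma_x_um` ... `tip_z_um`,
#' `traceable`.
#'
#' @param path CSV path.
#' @return `data.frame`.
#' @export
load_processes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("soma_x_um", "soma_y_um", "soma_z_um",
            "tip_x_um", "tip_y_um", "tip_z_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("process table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if ("traceable" %in% names(df)) df$traceable <- as.logical(df$traceable)
  df
}
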