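# Seeded synthetic-data generators with planted ground truth. These state the
# world the analyses are tested against: two interneuron classes with distinct
# 3D enrichment (class A caudal, class B rostro-medial), serial optical
# sectioning at 10 um spacing that detects each soma on several neighbouring
# planes, migrating cells whose leading processes concentrate around a planted
# mean direction, and fluorescence-like 2D blob images for the detection
# front end. Every generator is a pure function of (config, seed).

#' Gaussian-mixture spatial model for one cell class
#'
#' @param means k x 3 matrix of component means (um).
#' @param sds length-k vector (isotropic SD per component) or k x 3 matrix
#'   (per-axis SDs); all > 0.
#' @param weights mixture weights, summing to 1.
#' @param n_cells cells drawn per brain.
#' @return a `class_model` list.
#' @export
class_model <- function(means, sds, weights = NULL, n_cells = 1000L) {
  means <- matrix(as.numeric(means), ncol = 3)
  k <- nrow(means)
  if (is.matrix(sds)) {
    sds <- matrix(as.numeric(sds), ncol = 3)
  } else {
    sds <- matrix(rep(as.numeric(sds), 3), ncol = 3)
  }
  if (nrow(sds) != k) stop("sds must match number of components", call. = FALSE)
  if (any(sds <= 0)) stop("all SDs must be > 0", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k || abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  check_number(n_cells, "n_cells", lower = 0)
  structure(list(means = means, sds = sds, weights = weights,
                 n_cells = as.integer(n_cells)),
            class = "class_model")
}

#' Configuration for the two-class synthetic brain generator
#'
#' Defaults plant the spatial structure the downstream analyses assume:
#' `classA` caudal (two components in the LGd/VP territory of [demo_atlas()])
#' and `classB` rostro-medial (MD/LD territory), 1000 cells per class per
#' brain, within-class SD 200 um — well below the ~1400 um separation of the
#' class centroids.
#'
#' @param seed base seed; brains derive sub-seeds from it.
#' @param n_brains number of brains to simulate.
#' @param class_models named list of [class_model()]s, one per class label.
#' @param atlas [region_atlas()] used to imprint region labels.
#' @param genotype genotype recorded on each brain.
#' @return a `synthetic_brain_config`.
#' @export
synthetic_brain_config <- function(seed = 1L, n_brains = 3L,
                                   class_models = NULL,
                                   atlas = demo_atlas(),
                                   genotype = "het") {
  if (is.null(class_models)) {
    class_models <- list(
      classA = class_model(
        means = rbind(c(1500, 1100, 550), c(1400, 400, 650)),
        sds = c(200, 200), weights = c(0.6, 0.4), n_cells = 1000L),
      classB = class_model(
        means = rbind(c(500, 800, 1900)),
        sds = 200, n_cells = 1000L)
    )
  }
  stopifnot(length(class_models) >= 1L, !is.null(names(class_models)))
  check_number(n_brains, "n_brains", lower = 1)
  structure(list(seed = as.integer(seed), n_brains = as.integer(n_brains),
                 class_models = class_models, atlas = atlas,
                 genotype = genotype),
            class = "synthetic_brain_config")
}

# Draw n points from a 3D Gaussian mixture (uses the current RNG stream).
draw_mixture <- function(model, n) {
  comp <- sample.int(nrow(model$means), n, replace = TRUE,
                     prob = model$weights)
  pts <- model$means[comp, , drop = FALSE] +
    matrix(stats::rnorm(3 * n), ncol = 3) * model$sds[comp, , drop = FALSE]
  pts
}

#' Simulate one two-class brain with planted ground truth
#'
#' Positions are drawn from each class's Gaussian mixture; every cell carries
#' its true class label and its atlas region. Deterministic given
#' `(config$seed, brain_index)`.
#'
#' @param config a [synthetic_brain_config()].
#' @param brain_index 1-based brain number (also names the brain).
#' @return a [brain_dataset()]; cells carry `cell_id`, true `class_label`
#'   and `region_id`.
#' @export
simulate_two_class_brain <- function(config, brain_index = 1L) {
  stopifnot(inherits(config, "synthetic_brain_config"))
  check_number(brain_index, "brain_index", lower = 1)
  total <- sum(vapply(config$class_models, `[[`, integer(1), "n_cells"))
  if (total == 0L) stop("config yields zero cells", call. = FALSE)
  cells <- with_seed(mix_seed(config$seed, brain_index), {
    parts <- lapply(names(config$class_models), function(lbl) {
      m <- config$class_models[[lbl]]
      if (m$n_cells == 0L) return(NULL)
      pts <- draw_mixture(m, m$n_cells)
      data.frame(x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
                 class_label = lbl, stringsAsFactors = FALSE)
    })
    do.call(rbind, parts)
  })
  cells$cell_id <- seq_len(nrow(cells))
  cells$genotype <- config$genotype
  cells <- assign_regions(cells, config$atlas)
  brain_dataset(sprintf("synthetic_%02d", as.integer(brain_index)), cells,
                genotype = config$genotype)
}

#' Simulate a series of brains from one config
#'
#' @inheritParams simulate_two_class_brain
#' @return list of [brain_dataset()]s of length `config$n_brains`, each with
#'   a distinct `brain_id`.
#' @export
simulate_brain_series <- function(config) {
  lapply(seq_len(config$n_brains),
         function(i) simulate_two_class_brain(config, i))
}

#' Serial-imaging configuration
#'
#' Defaults mirror serial two-photon acquisition: optical planes every 10 um
#' (grid anchored at z = 0) and a soma radius of 10 um, so one cell is
#' detected on every plane within its radius.
#'
#' @param optical_spacing_um plane spacing (> 0).
#' @param cell_radius_um soma radius; a cell appears on planes with
#'   `|plane - z| <= cell_radius_um`.
#' @param xy_jitter_sd_um per-event centroid jitter in x and y.
#' @param detection_prob per-plane detection probability in (0, 1].
#' @return a `serial_imaging_config`.
#' @export
serial_imaging_config <- function(optical_spacing_um = 10,
                                  cell_radius_um = 10,
                                  xy_jitter_sd_um = 0,
                                  detection_prob = 1) {
  check_number(optical_spacing_um, "optical_spacing_um", 0, strict_lower = TRUE)
  check_number(cell_radius_um, "cell_radius_um", 0, strict_lower = TRUE)
  check_number(xy_jitter_sd_um, "xy_jitter_sd_um", 0)
  check_number(detection_prob, "detection_prob", 0, 1, strict_lower = TRUE)
  structure(list(optical_spacing_um = optical_spacing_um,
                 cell_radius_um = cell_radius_um,
                 xy_jitter_sd_um = xy_jitter_sd_um,
                 detection_prob = detection_prob),
            class = "serial_imaging_config")
}

#' Simulate per-slice detection events from true cells
#'
#' The inverse model of the axial-oversampling correction: every cell yields
#' one detection event per optical plane within `cell_radius_um` of its z
#' (each retained with `detection_prob`), with the event z set to the plane z
#' (what per-slice segmentation actually yields) and optional xy jitter.
#' Events record their source cell as hidden truth.
#'
#' @param cells cell `data.frame` or [brain_dataset()].
#' @param cfg a [serial_imaging_config()].
#' @param seed RNG seed (jitter and detection draws).
#' @return `data.frame` with `x_um`, `y_um`, `z_um` (plane z), `slice_index`,
#'   `source_cell_id`.
#' @export
simulate_serial_detections <- function(cells, cfg = serial_imaging_config(),
                                       seed = 1L) {
  stopifnot(inherits(cfg, "serial_imaging_config"))
  if (inherits(cells, "brain_dataset")) cells <- cells$cells
  pts <- as_coord_matrix(cells)
  ids <- if ("cell_id" %in% names(as.data.frame(cells))) {
    as.data.frame(cells)$cell_id
  } else {
    seq_len(nrow(pts))
  }
  dz <- cfg$optical_spacing_um
  r <- cfg$cell_radius_um
  with_seed(seed, {
    out <- vector("list", nrow(pts))
    for (i in seq_len(nrow(pts))) {
      z <- pts[i, 3]
      k <- seq(ceiling((z - r) / dz), floor((z + r) / dz))
      if (!length(k)) next
      keep <- stats::runif(length(k)) <= cfg$detection_prob
      k <- k[keep]
      if (!length(k)) next
      n <- length(k)
      out[[i]] <- data.frame(
        x_um = pts[i, 1] + stats::rnorm(n, 0, cfg$xy_jitter_sd_um),
        y_um = pts[i, 2] + stats::rnorm(n, 0, cfg$xy_jitter_sd_um),
        z_um = k * dz,
        slice_index = as.integer(k),
        source_cell_id = ids[i])
    }
    ev <- do.call(rbind, out)
    if (is.null(ev)) {
      ev <- data.frame(x_um = numeric(0), y_um = numeric(0),
                       z_um = numeric(0), slice_index = integer(0),
                       source_cell_id = integer(0))
    }
    rownames(ev) <- NULL
    ev
  })
}

#' Sample directions from a von Mises-Fisher distribution on the sphere
#'
#' Wood's (1994) rejection sampler. `kappa = 0` gives the uniform
#' distribution on the sphere. Uses the current RNG stream; wrap in a seeded
#' context (as [simulate_migration()] does) for reproducibility.
#'
#' @param n number of unit vectors.
#' @param mu mean direction (any non-zero 3-vector; normalised internally).
#' @param kappa concentration (>= 0).
#' @return n x 3 matrix of unit vectors.
#' @export
sample_vmf <- function(n, mu, kappa) {
  check_number(kappa, "kappa", lower = 0)
  mu <- as.numeric(mu)
  nrm <- sqrt(sum(mu^2))
  if (length(mu) != 3L || nrm == 0) {
    stop("mu must be a non-zero 3-vector", call. = FALSE)
  }
  mu <- mu / nrm
  if (kappa == 0) {
    v <- matrix(stats::rnorm(3 * n), ncol = 3)
    return(v / sqrt(rowSums(v^2)))
  }
  # Sample the cosine w of the angle to the mean (d = 3).
  b <- -kappa + sqrt(kappa^2 + 1)
  x0 <- (1 - b) / (1 + b)
  c0 <- kappa * x0 + 2 * log(1 - x0^2)
  w <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    z <- stats::runif(m)   # Beta(1, 1)
    u <- stats::runif(m)
    wi <- (1 - (1 + b) * z) / (1 - (1 - b) * z)
    ok <- kappa * wi + 2 * log(1 - x0 * wi) - c0 >= log(u)
    nok <- sum(ok)
    if (nok) {
      w[(got + 1L):(got + nok)] <- wi[ok]
      got <- got + nok
    }
  }
  # Uniform direction in the tangent plane, then rotate the pole to mu.
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  samp <- cbind(s * cos(phi), s * sin(phi), w)
  pole <- c(0, 0, 1)
  if (sum((mu - pole)^2) < 1e-24) return(samp)
  # Householder reflection mapping pole -> mu.
  v <- pole - mu
  v <- v / sqrt(sum(v^2))
  samp - 2 * (samp %*% v) %*% t(v)
}

#' Migration-simulation configuration
#'
#' One planted von Mises-Fisher mean direction and concentration per region.
#' Process lengths are Gaussian (truncated at a small positive floor).
#' Default direction `(0, -1, 1)/sqrt(2)` points ventrally and rostrally —
#' the dominant orientation reported for cells entering the dorsal lateral
#' geniculate — with kappa 20 and 100 cells per region.
#'
#' @param regions named list; each element a list with `mean_dir` (3-vector),
#'   `kappa` (>= 0) and `n` (cells).
#' @param length_mean_um,length_sd_um leading-process length distribution.
#' @param stage developmental stage label recorded on each record.
#' @param atlas [region_atlas()] used to place somas inside their region box.
#' @return a `migration_config`.
#' @export
migration_config <- function(regions = list(
                               LGd = list(mean_dir = c(0, -1, 1),
                                          kappa = 20, n = 100L)),
                             length_mean_um = 30, length_sd_um = 8,
                             stage = "E17.5", atlas = demo_atlas()) {
  stopifnot(length(regions) >= 1L, !is.null(names(regions)))
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (!nm %in% atlas$ids) stop("unknown region '", nm, "'", call. = FALSE)
    check_number(r$kappa, "kappa", lower = 0)
    check_number(r$n, "n", lower = 1)
  }
  check_number(length_mean_um, "length_mean_um", 0, strict_lower = TRUE)
  check_number(length_sd_um, "length_sd_um", 0)
  structure(list(regions = regions, length_mean_um = length_mean_um,
                 length_sd_um = length_sd_um, stage = stage, atlas = atlas),
            class = "migration_config")
}

#' Simulate leading-process records of migrating cells
#'
#' Somas are uniform inside their region's box; leading-process directions
#' are von Mises-Fisher around the planted per-region mean; lengths are
#' Gaussian truncated below at 1 um. Deterministic given `seed`.
#'
#' @param cfg a [migration_config()].
#' @param seed RNG seed.
#' @param brain_id identifier recorded on each record.
#' @return `data.frame` with soma and tip coordinates, `region_id`, `stage`,
#'   `brain_id` and a `traceable` flag (all `TRUE` here).
#' @export
simulate_migration <- function(cfg, seed = 1L, brain_id = "synthetic_01") {
  stopifnot(inherits(cfg, "migration_config"))
  with_seed(seed, {
    parts <- lapply(names(cfg$regions), function(nm) {
      r <- cfg$regions[[nm]]
      box <- cfg$atlas$boxes[[match(nm, cfg$atlas$ids)]]
      n <- as.integer(r$n)
      soma <- sapply(1:3, function(a) {
        stats::runif(n, box$min[a], box$max[a])
      })
      dirs <- sample_vmf(n, r$mean_dir, r$kappa)
      len <- pmax(1, stats::rnorm(n, cfg$length_mean_um, cfg$length_sd_um))
      tip <- soma + dirs * len
      data.frame(brain_id = brain_id, stage = cfg$stage, region_id = nm,
                 soma_x_um = soma[, 1], soma_y_um = soma[, 2],
                 soma_z_um = soma[, 3],
                 tip_x_um = tip[, 1], tip_y_um = tip[, 2],
                 tip_z_um = tip[, 3],
                 traceable = TRUE, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  })
}

#' Render a synthetic fluorescence-like slice image
#'
#' Sum of isotropic Gaussian blobs on a constant background, optionally
#' Poisson-sampled — a stand-in for soma-localised fluorescence feeding the
#' detection front end.
#'
#' @param centers_xy_um n x 2 matrix of blob centres in micrometres.
#' @param amplitudes peak intensity per blob (recycled).
#' @param size_px image side length in pixels (square image).
#' @param pixel_um micrometres per pixel; pixel i covers
#'   `[(i-1), i) * pixel_um`, centre `(i - 0.5) * pixel_um`.
#' @param psf_sd_px blob Gaussian SD in pixels.
#' @param background constant background level.
#' @param poisson_noise draw each pixel from Poisson(mean)?
#' @param seed RNG seed (used only when `poisson_noise`).
#' @return `size_px` x `size_px` numeric matrix; rows index y, columns x.
#' @export
render_synthetic_slice <- function(centers_xy_um, amplitudes = 100,
                                   size_px = 128L, pixel_um = 2,
                                   psf_sd_px = 2, background = 10,
                                   poisson_noise = FALSE, seed = 1L) {
  check_number(size_px, "size_px", 1)
  check_number(pixel_um, "pixel_um", 0, strict_lower = TRUE)
  check_number(psf_sd_px, "psf_sd_px", 0, strict_lower = TRUE)
  size_px <- as.integer(size_px)
  img <- matrix(background, nrow = size_px, ncol = size_px)
  if (!is.null(centers_xy_um) && NROW(centers_xy_um) > 0) {
    centers_xy_um <- matrix(as.numeric(centers_xy_um), ncol = 2)
    amplitudes <- rep_len(amplitudes, nrow(centers_xy_um))
    fov <- size_px * pixel_um
    if (any(centers_xy_um < 0) || any(centers_xy_um >= fov)) {
      stop("all blob centres must lie inside the field of view", call. = FALSE)
    }
    px_centers <- (seq_len(size_px) - 0.5) * pixel_um
    for (i in seq_len(nrow(centers_xy_um))) {
      gx <- exp(-(px_centers - centers_xy_um[i, 1])^2 /
                  (2 * (psf_sd_px * pixel_um)^2))
      gy <- exp(-(px_centers - centers_xy_um[i, 2])^2 /
                  (2 * (psf_sd_px * pixel_um)^2))
      img <- img + amplitudes[i] * outer(gy, gx)
    }
  }
  if (poisson_noise) {
    img <- with_seed(seed, {
      matrix(stats::rpois(length(img), lambda = img), nrow = size_px)
    })
  }
  img
}
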