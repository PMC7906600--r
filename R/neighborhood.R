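# Nearest-neighbour-distance (NND) statistics: within-class and between-class
# distances, per-set max-normalisation, across-brain cumulative-distribution
# pooling, and the two-sample Kolmogorov-Smirnov contrast.

#' Within-set nearest-neighbour distances
#'
#' One distance per point: 3D Euclidean distance to the nearest *other*
#' point of the same set. Duplicate points yield 0.
#'
#' @param points n x 3 coordinate matrix (um) or cell `data.frame`.
#' @return numeric vector of length n.
#' @export
nnd_within <- function(points) {
  pts <- as_coord_matrix(points)
  n <- nrow(pts)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  unname(apply(d, 1L, min))
}

#' Between-set nearest-neighbour distances
#'
#' Bidirectional and pooled: for every point of A the distance to its nearest
#' point in B, and for every point of B the distance to its nearest point in
#' A, concatenated (length |A| + |B|). Symmetric in its arguments up to
#' ordering, so the pooled distribution is label-order invariant.
#'
#' @param points_a,points_b coordinate matrices or cell `data.frame`s.
#' @return numeric vector of length `nrow(a) + nrow(b)`.
#' @export
nnd_between <- function(points_a, points_b) {
  a <- as_coord_matrix(points_a)
  b <- as_coord_matrix(points_b)
  if (!nrow(a) || !nrow(b)) stop("both sets must be non-empty", call. = FALSE)
  na <- nrow(a)
  d <- as.matrix(stats::dist(rbind(a, b)))
  cross <- d[seq_len(na), na + seq_len(nrow(b)), drop = FALSE]
  unname(c(apply(cross, 1L, min), apply(cross, 2L, min)))
}

#' Bundle distances as a normalised NND set
#'
#' Normalises to the largest distance within the set (per set, per brain), so
#' the maximum of the normalised values is 1 and cumulative distributions
#' from different brains share a [0, 1] axis.
#'
#' @param distances numeric vector of NNDs (um).
#' @param label set label, e.g. `"within-A"`, `"within-B"`, `"between"`.
#' @param brain_id brain the set came from.
#' @return an `nnd_set` list with `distances` and `normalized`.
#' @export
nnd_set <- function(distances, label = "within", brain_id = NA_character_) {
  distances <- as.numeric(distances)
  if (!length(distances)) stop("empty distance set", call. = FALSE)
  if (any(!is.finite(distances)) || any(distances < 0)) {
    stop("distances must be finite and non-negative", call. = FALSE)
  }
  mx <- max(distances)
  normalized <- if (mx > 0) distances / mx else rep(0, length(distances))
  structure(list(label = label, brain_id = brain_id,
                 distances = distances, normalized = normalized),
            class = "nnd_set")
}

#' Pool per-brain normalised NND distributions onto a common grid
#'
#' Evaluates each brain's empirical CDF of normalised distances on a uniform
#' grid over [0, 1] and averages across brains (mean and SEM per grid
#' point). With one brain the SEM is 0 and `n_brains = 1` flags it.
#'
#' @param sets list of [nnd_set()]s, one per brain, same label.
#' @param grid_size number of grid points (>= 2).
#' @return `data.frame` with `grid`, `mean_cdf`, `sem_cdf`; attribute
#'   `n_brains`.
#' @export
pooled_cdf <- function(sets, grid_size = 256L) {
  check_number(grid_size, "grid_size", 2)
  if (!length(sets)) stop("no sets supplied", call. = FALSE)
  if (inherits(sets, "nnd_set")) sets <- list(sets)
  stopifnot(all(vapply(sets, inherits, logical(1), "nnd_set")))
  grid <- seq(0, 1, length.out = as.integer(grid_size))
  cdfs <- vapply(sets, function(s) {
    v <- sort(s$normalized)
    vapply(grid, function(g) mean(v <= g), numeric(1))
  }, numeric(length(grid)))
  cdfs <- matrix(cdfs, nrow = length(grid))
  out <- data.frame(grid = grid,
                    mean_cdf = rowMeans(cdfs),
                    sem_cdf = apply(cdfs, 1L, sem))
  attr(out, "n_brains") <- length(sets)
  out
}

# Survival function of the Kolmogorov distribution, Q(lambda) =
# 2 * sum_{k>=1} (-1)^{k-1} exp(-2 k^2 lambda^2).
kolmogorov_sf <- function(lambda) {
  if (lambda < 0.05) return(1)
  k <- 1:100
  q <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(q, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Statistic `D = sup_x |F_a(x) - F_b(x)|` over the two empirical CDFs; the
#' p-value uses the asymptotic Kolmogorov distribution evaluated at
#' `sqrt(n_e) * D` with effective size `n_e = n_a n_b / (n_a + n_b)` (no
#' exact small-sample enumeration).
#'
#' @param sample_a,sample_b numeric vectors (>= 1 value each).
#' @return a `thalamap_test` with `statistic` (D), `p_value`, `n_effective`.
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty",
                                     call. = FALSE)
  if (any(!is.finite(c(a, b)))) stop("samples must be finite", call. = FALSE)
  na <- length(a); nb <- length(b)
  z <- c(a, b)
  o <- order(z)
  step <- c(rep(1 / na, na), rep(-1 / nb, nb))[o]
  cum <- cumsum(step)
  zs <- z[o]
  # evaluate only where the next value differs (handles ties)
  keep <- c(diff(zs) != 0, TRUE)
  D <- max(abs(cum[keep]))
  ne <- na * nb / (na + nb)
  test_result(statistic = D, p_value = kolmogorov_sf(sqrt(ne) * D),
              method = "Two-sample Kolmogorov-Smirnov test (asymptotic)",
              n_effective = ne)
}

#' Full NND contrast for one multi-brain two-class dataset
#'
#' Convenience wrapper implementing the standard workflow: per brain, compute
#' within-class and between-class NNDs, normalise each set to its own
#' maximum, pool CDFs across brains, and run the KS test of within vs between
#' on the normalised values pooled over brains (per-brain tests are also
#' returned).
#'
#' @param brains list of [brain_dataset()]s (or cell `data.frame`s) with a
#'   `class_label` column carrying exactly the two `classes`.
#' @param classes length-2 character: the two class labels to contrast.
#' @param grid_size CDF grid resolution.
#' @return list with `cdf` (named list of [pooled_cdf()] tables for
#'   `within_A`, `within_B`, `between`), `ks` (named list of pooled KS tests
#'   A-vs-between and B-vs-between), `ks_per_brain`, and the `sets`.
#' @export
nnd_analysis <- function(brains, classes = c("classA", "classB"),
                         grid_size = 256L) {
  stopifnot(length(classes) == 2L)
  if (inherits(brains, "brain_dataset") || is.data.frame(brains)) {
    brains <- list(brains)
  }
  sets <- list(within_A = list(), within_B = list(), between = list())
  for (i in seq_along(brains)) {
    cells <- if (inherits(brains[[i]], "brain_dataset")) {
      brains[[i]]$cells
    } else {
      brains[[i]]
    }
    bid <- if (nrow(cells)) cells$brain_id[1] else as.character(i)
    pa <- cells[cells$class_label == classes[1], , drop = FALSE]
    pb <- cells[cells$class_label == classes[2], , drop = FALSE]
    if (nrow(pa) < 2L || nrow(pb) < 2L) {
      stop("brain '", bid, "' needs >= 2 cells of each class", call. = FALSE)
    }
    sets$within_A[[i]] <- nnd_set(nnd_within(pa), "within-A", bid)
    sets$within_B[[i]] <- nnd_set(nnd_within(pb), "within-B", bid)
    sets$between[[i]] <- nnd_set(nnd_between(pa, pb), "between", bid)
  }
  pooled_norm <- lapply(sets, function(s) unlist(lapply(s, `[[`, "normalized")))
  ks_per_brain <- lapply(seq_along(brains), function(i) {
    list(A_vs_between = ks_two_sample(sets$within_A[[i]]$normalized,
                                      sets$between[[i]]$normalized),
         B_vs_between = ks_two_sample(sets$within_B[[i]]$normalized,
                                      sets$between[[i]]$normalized))
  })
  list(
    cdf = lapply(sets, pooled_cdf, grid_size = grid_size),
    ks = list(A_vs_between = ks_two_sample(pooled_norm$within_A,
                                           pooled_norm$between),
              B_vs_between = ks_two_sample(pooled_norm$within_B,
                                           pooled_norm$between)),
    ks_per_brain = ks_per_brain,
    sets = sets
  )
}
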