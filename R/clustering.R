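# Spatial clustering: seeded k-means (k-means++ initialisation, Lloyd
# iterations, best of n_init restarts), Rousseeuw silhouette scoring,
# silhouette-based selection of k, and per-cluster class composition.
# Distances are Euclidean on raw micrometre coordinates: all axes share
# physical units, so no standardisation is applied.

# Squared distances from every point to every centroid (n x k).
dist2_to_centroids <- function(pts, centroids) {
  outer(rowSums(pts^2), rep(1, nrow(centroids))) +
    outer(rep(1, nrow(pts)), rowSums(centroids^2)) -
    2 * pts %*% t(centroids)
}

# k-means++ seeding (uses current RNG stream).
kmeanspp_init <- function(pts, k) {
  n <- nrow(pts)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((pts - matrix(pts[centers[1L], ], n, ncol(pts),
                              byrow = TRUE))^2)
  if (k > 1L) {
    for (j in 2:k) {
      if (all(d2 <= 0)) {
        centers[j] <- sample.int(n, 1L)
      } else {
        centers[j] <- sample.int(n, 1L, prob = d2 / sum(d2))
      }
      nd2 <- rowSums((pts - matrix(pts[centers[j], ], n, ncol(pts),
                                   byrow = TRUE))^2)
      d2 <- pmin(d2, nd2)
    }
  }
  pts[centers, , drop = FALSE]
}

lloyd_once <- function(pts, k, max_iter) {
  centroids <- kmeanspp_init(pts, k)
  n <- nrow(pts)
  labels <- integer(n)
  inertia <- Inf
  for (iter in seq_len(max_iter)) {
    d2 <- dist2_to_centroids(pts, centroids)
    new_labels <- max.col(-d2, ties.method = "first")
    # re-seed any emptied cluster with the point farthest from its centroid
    for (j in which(tabulate(new_labels, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(n), new_labels)])
      new_labels[far] <- j
      d2[far, ] <- Inf; d2[far, j] <- 0
    }
    new_inertia <- sum(d2[cbind(seq_len(n), new_labels)])
    stopifnot(new_inertia <= inertia + 1e-6 * (1 + abs(inertia)))
    if (identical(new_labels, labels)) {
      inertia <- new_inertia
      break
    }
    labels <- new_labels
    inertia <- new_inertia
    centroids <- rowsum(pts, labels) / tabulate(labels, k)
  }
  # final inertia against final centroids
  centroids <- rowsum(pts, labels) / tabulate(labels, k)
  dimnames(centroids) <- list(NULL, colnames(pts))
  d2 <- dist2_to_centroids(pts, centroids)
  inertia <- sum(pmax(d2[cbind(seq_len(n), labels)], 0))
  list(labels = labels, centroids = centroids, inertia = inertia,
       iter = iter)
}

#' Fit k-means to 3D cell coordinates
#'
#' k-means++ initial centroids, Lloyd iterations until the assignment is
#' stable (or `max_iter`), best of `n_init` restarts by inertia.
#' Deterministic given `seed`. Within-iteration inertia is asserted
#' non-increasing.
#'
#' @param points n x 3 coordinate matrix (um) or cell `data.frame`.
#' @param k number of clusters (>= 1, <= number of distinct points).
#' @param seed RNG seed.
#' @param n_init number of restarts.
#' @param max_iter Lloyd iteration cap.
#' @return a `kmeans_fit` list: `k`, `labels` (1..k), `centroids` (k x 3),
#'   `inertia` (um^2), `seed`, `n_init`.
#' @export
kmeans_fit <- function(points, k, seed = 1L, n_init = 10L, max_iter = 300L) {
  pts <- as_coord_matrix(points)
  check_number(k, "k", 1)
  check_number(n_init, "n_init", 1)
  k <- as.integer(k)
  n_distinct <- nrow(unique(pts))
  if (k > n_distinct) {
    stop("k (", k, ") exceeds the number of distinct points (", n_distinct,
         ")", call. = FALSE)
  }
  best <- NULL
  with_seed(seed, {
    for (i in seq_len(as.integer(n_init))) {
      fit <- lloyd_once(pts, k, as.integer(max_iter))
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  structure(list(k = k, labels = best$labels, centroids = best$centroids,
                 inertia = best$inertia, seed = seed,
                 n_init = as.integer(n_init)),
            class = "kmeans_fit")
}

#' @export
print.kmeans_fit <- function(x, ...) {
  cat(sprintf("kmeans_fit: k = %d, n = %d, inertia = %.4g um^2\n",
              x$k, length(x$labels), x$inertia))
  invisible(x)
}

#' Mean silhouette coefficient of a labelled point set
#'
#' Standard per-sample silhouette: `a(i)` is the mean distance to the other
#' members of i's cluster, `b(i)` the smallest mean distance to any other
#' cluster, and `s(i) = (b - a) / max(a, b)`; members of singleton clusters
#' contribute 0. Returns the mean over samples, in [-1, 1].
#'
#' @param points coordinate matrix or cell `data.frame`.
#' @param labels integer cluster labels, >= 2 non-empty clusters.
#' @param dist_matrix optional precomputed full n x n distance matrix
#'   (lets callers scoring many partitions of the same points pay for the
#'   distances once).
#' @return mean silhouette (single number).
#' @export
silhouette_score <- function(points, labels, dist_matrix = NULL) {
  labels <- as.integer(factor(labels))
  if (is.null(dist_matrix)) {
    pts <- as_coord_matrix(points)
    dist_matrix <- as.matrix(stats::dist(pts))
  }
  D <- dist_matrix
  n <- nrow(D)
  stopifnot(length(labels) == n)
  k <- max(labels)
  if (k < 2L) stop("silhouette needs >= 2 clusters", call. = FALSE)
  sizes <- tabulate(labels, k)
  # sums[c, j] = total distance from cluster c to point j
  sums <- rowsum(D, labels)
  a <- sums[cbind(labels, seq_len(n))] / pmax(sizes[labels] - 1L, 1L)
  meand <- sums / sizes
  meand[cbind(labels, seq_len(n))] <- Inf
  b <- if (k == 2L) meand[cbind(3L - labels, seq_len(n))] else {
    do.call(pmin, lapply(seq_len(k), function(j) meand[j, ]))
  }
  s <- (b - a) / pmax(a, b)
  s[sizes[labels] == 1L] <- 0
  s[!is.finite(s)] <- 0
  mean(s)
}

#' Select the number of spatial clusters by silhouette
#'
#' Fits k-means for every k in `k_range`, scores each partition with the
#' mean silhouette, and picks the k with the highest score (ties towards
#' smaller k).
#'
#' @inheritParams kmeans_fit
#' @param k_range integer vector of candidate k, all in
#'   `[2, n_points - 1]`.
#' @return a `k_selection` list: `k_values`, `silhouette`, `chosen_k`,
#'   `fits` (one `kmeans_fit` per k).
#' @export
select_k <- function(points, k_range = 2:10, seed = 1L, n_init = 10L) {
  pts <- as_coord_matrix(points)
  k_range <- as.integer(k_range)
  if (!length(k_range)) stop("k_range must be non-empty", call. = FALSE)
  if (any(k_range < 2L) || any(k_range > nrow(pts) - 1L)) {
    stop("k_range must lie within [2, n_points - 1]", call. = FALSE)
  }
  fits <- lapply(seq_along(k_range), function(i) {
    kmeans_fit(pts, k_range[i], seed = mix_seed(seed, k_range[i]),
               n_init = n_init)
  })
  D <- as.matrix(stats::dist(pts))
  sil <- vapply(fits, function(f) {
    silhouette_score(pts, f$labels, dist_matrix = D)
  }, numeric(1))
  chosen <- k_range[which.max(sil)]  # which.max takes the first max: smaller k
  structure(list(k_values = k_range, silhouette = sil, chosen_k = chosen,
                 fits = stats::setNames(fits, paste0("k", k_range))),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("silhouette by k:\n")
  print(stats::setNames(round(x$silhouette, 4), paste0("k=", x$k_values)))
  cat("chosen_k =", x$chosen_k, "\n")
  invisible(x)
}

#' Silhouette-selected k across several brains
#'
#' Clusters each brain separately, averages the silhouette across brains per
#' k (mean and SD/SEM), and chooses the k maximising the mean.
#'
#' @param point_sets list of per-brain coordinate matrices or cell
#'   `data.frame`s.
#' @inheritParams select_k
#' @return list: `k_values`, `silhouette_mean`, `silhouette_sd`,
#'   `silhouette_sem`, `chosen_k`, `per_brain` (one [select_k()] result per
#'   brain).
#' @export
select_k_brains <- function(point_sets, k_range = 2:10, seed = 1L,
                            n_init = 10L) {
  stopifnot(length(point_sets) >= 1L)
  per_brain <- lapply(seq_along(point_sets), function(i) {
    select_k(point_sets[[i]], k_range, seed = mix_seed(seed, i),
             n_init = n_init)
  })
  sil <- do.call(rbind, lapply(per_brain, `[[`, "silhouette"))
  mean_sil <- colMeans(sil)
  chosen <- as.integer(k_range)[which.max(mean_sil)]
  list(k_values = as.integer(k_range), silhouette_mean = mean_sil,
       silhouette_sd = apply(sil, 2L, stats::sd),
       silhouette_sem = apply(sil, 2L, sem),
       chosen_k = chosen, per_brain = per_brain)
}

#' Class composition of spatial clusters
#'
#' Cross-tabulates cluster labels against true class labels; reports the
#' fraction of each class in every cluster and, per class, the fraction
#' captured by its best (majority) cluster.
#'
#' @param labels cluster labels (from [kmeans_fit()]).
#' @param classes class labels, same length.
#' @return a `cluster_composition` list: `table` (cluster x class counts),
#'   `cluster_fractions` (rows sum to 1), `capture` (named per-class
#'   fraction in its majority cluster).
#' @export
cluster_composition <- function(labels, classes) {
  if (length(labels) != length(classes)) {
    stop("labels and classes must have the same length", call. = FALSE)
  }
  tab <- table(cluster = labels, class = classes)
  frac <- prop.table(tab, margin = 1L)
  class_tot <- colSums(tab)
  capture <- apply(tab, 2L, max) / class_tot
  structure(list(table = tab, cluster_fractions = frac,
                 capture = capture),
            class = "cluster_composition")
}

#' Across-brain summary of per-class capture
#'
#' @param compositions list of [cluster_composition()]s (one per brain).
#' @return `data.frame` with `class`, `mean_capture`, `sd_capture`,
#'   `sem_capture`, `n_brains`.
#' @export
capture_summary <- function(compositions) {
  stopifnot(length(compositions) >= 1L)
  caps <- do.call(rbind, lapply(compositions, `[[`, "capture"))
  data.frame(class = colnames(caps),
             mean_capture = colMeans(caps),
             sd_capture = apply(caps, 2L, stats::sd),
             sem_capture = apply(caps, 2L, sem),
             n_brains = nrow(caps), row.names = NULL)
}
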