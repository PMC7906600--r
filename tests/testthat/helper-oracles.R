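# Independent brute-force oracles and fixture builders. Every oracle here is
# a direct transcription of the defining formula, kept deliberately separate
# from the package's implementations.

# -- nearest-neighbour distances (all-pairs loops) --------------------------
bf_nnd_within <- function(pts) {
  n <- nrow(pts)
  vapply(seq_len(n), function(i) {
    d <- sqrt(rowSums((pts[-i, , drop = FALSE] -
                         matrix(pts[i, ], n - 1L, 3, byrow = TRUE))^2))
    min(d)
  }, numeric(1))
}

bf_nnd_between <- function(a, b) {
  one_way <- function(p, q) {
    vapply(seq_len(nrow(p)), function(i) {
      min(sqrt(rowSums((q - matrix(p[i, ], nrow(q), 3, byrow = TRUE))^2)))
    }, numeric(1))
  }
  c(one_way(a, b), one_way(b, a))
}

# -- silhouette (per-sample definition, explicit loops) ---------------------
bf_silhouette <- function(pts, labels) {
  n <- nrow(pts)
  labels <- as.integer(factor(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    if (sum(labels == labels[i]) == 1L) { s[i] <- 0; next }
    d <- sqrt(rowSums((pts - matrix(pts[i, ], n, ncol(pts), byrow = TRUE))^2))
    a <- mean(d[labels == labels[i] & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# -- exhaustive 1D k-means (contiguous partitions of the sorted values) -----
bf_kmeans_1d <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1L, k - 1L)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    edges <- c(0L, cuts[, j], n)
    tot <- 0
    for (g in seq_len(k)) {
      tot <- tot + sse(x[(edges[g] + 1L):edges[g + 1L]])
    }
    best <- min(best, tot)
  }
  best
}

# -- first-matching-box containment (per-point scan) ------------------------
bf_locate <- function(pts, atlas) {
  apply(pts, 1L, function(p) {
    for (b in atlas$boxes) {
      if (all(p >= b$min) && all(p < b$max)) return(b$id)
    }
    "unassigned"
  })
}

# -- fixture builders -------------------------------------------------------

# Random cells pairwise farther apart than min_sep, via a jittered 3D grid.
make_separated_cells <- function(n, min_sep = 20, seed = 1) {
  spacing <- min_sep + 5
  jit <- 2  # spacing - 2*jit > min_sep
  set.seed(seed)
  side <- ceiling(n^(1 / 3)) + 1L
  grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                z = seq_len(side))) * spacing
  pick <- grid[sample.int(nrow(grid), n), , drop = FALSE]
  pts <- pick + matrix(runif(3 * n, -jit, jit), ncol = 3)
  data.frame(x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
             class_label = "classA", cell_id = seq_len(n))
}

# Two well-separated single-Gaussian classes (separation / SD configurable).
make_two_class_config <- function(seed, n_per_class = 500L, sd_um = 200,
                                  n_brains = 3L) {
  cm <- list(
    classA = class_model(rbind(c(1500, 1100, 550)), sd_um,
                         n_cells = n_per_class),
    classB = class_model(rbind(c(500, 800, 1900)), sd_um,
                         n_cells = n_per_class)
  )
  synthetic_brain_config(seed = seed, n_brains = n_brains, class_models = cm)
}

random_points <- function(n, scale = 100) {
  matrix(runif(3 * n, 0, scale), ncol = 3,
         dimnames = list(NULL, c("x_um", "y_um", "z_um")))
}

write_tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
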