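# Shared internal helpers: seeded RNG scoping, SEM, argument checks.

#' Standard error of the mean
#'
#' Returns 0 for a single value (the n = 1 convention used by the per-brain
#' summaries; callers flag n alongside).
#'
#' @param x numeric vector.
#' @return SEM as a single number; 0 when `length(x) < 2`.
#' @export
sem <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x) / sqrt(length(x))
}

# Evaluate `code` under a given seed, restoring the caller's RNG state.
# All generators route their randomness through this so no global state leaks.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a sub-seed; keeps results < 2^31 - 1.
mix_seed <- function(seed, salt) {
  as.integer((abs(as.numeric(seed)) * 7919 + abs(as.numeric(salt)) * 104729 + 1) %%
               2147483647)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  }
  invisible(x)
}

# Coerce cells input (brain_dataset or data.frame) to an n x 3 coordinate
# matrix in micrometres.
as_coord_matrix <- function(x) {
  if (inherits(x, "brain_dataset")) x <- x$cells
  if (is.data.frame(x)) {
    need <- c("x_um", "y_um", "z_um")
    miss <- setdiff(need, names(x))
    if (length(miss)) {
      stop("missing coordinate column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    x <- as.matrix(x[, need])
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("coordinates must have 3 columns", call. = FALSE)
  if (!all(is.finite(x))) stop("coordinates must be finite", call. = FALSE)
  storage.mode(x) <- "double"
  colnames(x) <- c("x_um", "y_um", "z_um")
  x
}

# A two-sided test result container shared by the statistics modules.
test_result <- function(statistic, p_value, df = NA_real_, method = "",
                        ...) {
  out <- list(statistic = unname(statistic), df = unname(df),
              p_value = unname(min(max(p_value, 0), 1)), method = method, ...)
  class(out) <- "thalamap_test"
  out
}

#' @export
print.thalamap_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.6g", x$statistic))
  if (is.finite(x$df)) cat(sprintf(", df = %g", x$df))
  cat(sprintf(", p = %.4g\n", x$p_value))
  invisible(x)
}
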