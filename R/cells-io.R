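# Cell tables and per-brain datasets: CSV I/O, per-nucleus counting, and
# across-brain proportion summaries.

CELL_COLUMNS <- c("brain_id", "genotype", "x_um", "y_um", "z_um", "class_label")

#' Construct a per-brain dataset of classed cells
#'
#' @param brain_id identifier shared by all cells.
#' @param cells `data.frame` with columns `x_um`, `y_um`, `z_um`,
#'   `class_label` and optionally `region_id`; coordinates in micrometres
#'   (+x lateral, +y dorsal, +z rostral).
#' @param genotype e.g. `"het"`, `"ko"`, `"wt"`.
#' @param section_thickness_um physical/optical section thickness.
#' @param section_sampling_interval every n-th section analysed (>= 1), e.g.
#'   10 for "every tenth coronal section".
#' @return a `brain_dataset`.
#' @export
brain_dataset <- function(brain_id, cells, genotype = "het",
                          section_thickness_um = 10,
                          section_sampling_interval = 1L) {
  stopifnot(is.data.frame(cells))
  check_number(section_sampling_interval, "section_sampling_interval", lower = 1)
  if (nrow(cells)) {
    as_coord_matrix(cells)  # validates finite 3D coordinates
    if (!"class_label" %in% names(cells)) {
      stop("cells must carry a class_label column", call. = FALSE)
    }
    if ("brain_id" %in% names(cells) &&
        !all(cells$brain_id == brain_id)) {
      stop("all cells must share brain_id '", brain_id, "'", call. = FALSE)
    }
  }
  cells$brain_id <- if (nrow(cells)) brain_id else character(0)
  if (!"region_id" %in% names(cells)) {
    cells$region_id <- rep("unassigned", nrow(cells))
  }
  structure(list(brain_id = brain_id, genotype = genotype, cells = cells,
                 sampling = list(section_thickness_um = section_thickness_um,
                                 section_sampling_interval =
                                   as.integer(section_sampling_interval))),
            class = "brain_dataset")
}

#' @export
print.brain_dataset <- function(x, ...) {
  cat(sprintf("brain_dataset '%s' (%s): %d cells", x$brain_id, x$genotype,
              nrow(x$cells)))
  if (nrow(x$cells)) {
    tab <- table(x$cells$class_label)
    cat(" [", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "]")
  }
  cat("\n")
  invisible(x)
}

#' Read a validated cell table from CSV
#'
#' Required header columns: `brain_id`, `genotype`, `x_um`, `y_um`, `z_um`,
#' `class_label`; `region_id` optional. Malformed rows are an error naming
#' the offending row, never skipped silently.
#'
#' @param path CSV path (UTF-8, `.` decimal separator).
#' @return a `data.frame`, one row per cell.
#' @export
load_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(CELL_COLUMNS, names(df))
  if (length(miss)) {
    stop("cell table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c("x_um", "y_um", "z_um")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' at data row %d", col,
                   bad[1]), call. = FALSE)
    }
    df[[col]] <- v
  }
  if (!"region_id" %in% names(df)) {
    df$region_id <- rep("unassigned", nrow(df))
  }
  df
}

#' Load cells for one brain
#'
#' Reads and validates the CSV (see [load_cell_table()]) and wraps it as a
#' [brain_dataset()]. The file must contain a single brain unless `brain_id`
#' selects one.
#'
#' @inheritParams load_cell_table
#' @param brain_id optional: select this brain from a multi-brain file.
#' @inheritParams brain_dataset
#' @return a `brain_dataset`.
#' @export
load_cells <- function(path, brain_id = NULL, section_thickness_um = 10,
                       section_sampling_interval = 1L) {
  df <- load_cell_table(path)
  if (!is.null(brain_id)) {
    df <- df[df$brain_id == brain_id, , drop = FALSE]
  } else if (nrow(df)) {
    ids <- unique(df$brain_id)
    if (length(ids) > 1L) {
      stop("file contains several brains (", paste(ids, collapse = ", "),
           "); pass brain_id= or use load_cell_table()", call. = FALSE)
    }
    brain_id <- ids
  } else {
    brain_id <- "unknown"
  }
  genotype <- if (nrow(df)) df$genotype[1] else "het"
  brain_dataset(brain_id, df, genotype = genotype,
                section_thickness_um = section_thickness_um,
                section_sampling_interval = section_sampling_interval)
}

#' Write a cell table to CSV
#'
#' @param cells cell `data.frame` or [brain_dataset()].
#' @param path output path.
#' @export
write_cells <- function(cells, path) {
  if (inherits(cells, "brain_dataset")) cells <- cells$cells
  keep <- intersect(c(CELL_COLUMNS, "region_id", "cell_id"), names(cells))
  utils::write.csv(cells[, keep, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Count cells per (region, class)
#'
#' The sum over the whole table always equals the number of cells:
#' unassigned cells appear as their own row.
#'
#' @param cells cell `data.frame` (with `region_id` set) or [brain_dataset()].
#' @param atlas optional [region_atlas()]; when given, all atlas regions
#'   appear as rows even at zero count.
#' @return a contingency `table`, regions x classes.
#' @export
counts_by_region <- function(cells, atlas = NULL) {
  if (inherits(cells, "brain_dataset")) cells <- cells$cells
  region_levels <- if (is.null(atlas)) {
    sort(unique(cells$region_id))
  } else {
    unique(c(atlas$ids, "unassigned"))
  }
  table(region_id = factor(cells$region_id, levels = region_levels),
        class_label = factor(cells$class_label))
}

#' Across-brain summary of per-region proportions for one class
#'
#' For each brain the region count is divided by that brain's class total, so
#' proportions sum to 1 per brain; mean and SEM are then taken across brains
#' region by region. With a single brain the SEM is reported as 0 and
#' `n_brains = 1` flags it.
#'
#' @param counts `data.frame` with columns `brain_id`, `region_id`, `count`:
#'   per-brain counts of one cell class across regions.
#' @return `data.frame` with `region_id`, `mean_prop`, `sem_prop`, plus
#'   attribute `n_brains`.
#' @export
distribution_proportions <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("brain_id", "region_id", "count") %in% names(counts)))
  if (!nrow(counts)) stop("no counts supplied", call. = FALSE)
  brains <- unique(counts$brain_id)
  regions <- unique(counts$region_id)
  prop <- matrix(0, nrow = length(brains), ncol = length(regions),
                 dimnames = list(brains, regions))
  for (b in brains) {
    sub <- counts[counts$brain_id == b, ]
    tot <- sum(sub$count)
    if (tot <= 0) {
      stop("brain '", b, "' has zero cells of this class", call. = FALSE)
    }
    prop[b, sub$region_id] <- sub$count / tot
  }
  out <- data.frame(
    region_id = regions,
    mean_prop = colMeans(prop),
    sem_prop = apply(prop, 2, sem),
    row.names = NULL
  )
  attr(out, "n_brains") <- length(brains)
  out
}
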