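# Box atlas: named axis-aligned boxes standing in for anatomical nuclei.
# Containment is half-open [min, max) on every axis so that boxes sharing a
# face never double-count a cell; overlap between listed boxes is resolved by
# list order (first match wins), which is deterministic and mirrors
# "first recognisable structure" manual annotation.

#' Create one atlas region box
#'
#' @param id unique region identifier (e.g. `"LGd"`).
#' @param min,max numeric length-3 vectors, lower and upper corners in
#'   micrometres, ordered (x, y, z). `min < max` on every axis.
#' @param name human-readable name; defaults to `id`.
#' @return a `region_box` list.
#' @export
region_box <- function(id, min, max, name = id) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("region id must be a non-empty string", call. = FALSE)
  }
  min <- as.numeric(min); max <- as.numeric(max)
  if (length(min) != 3L || length(max) != 3L ||
      !all(is.finite(min)) || !all(is.finite(max))) {
    stop("box bounds must be finite length-3 numeric vectors", call. = FALSE)
  }
  if (!all(min < max)) {
    stop(sprintf("region '%s': min must be < max on every axis", id),
         call. = FALSE)
  }
  structure(list(id = id, name = name, min = min, max = max),
            class = "region_box")
}

#' Create a region atlas from an ordered list of boxes
#'
#' List order is priority order: a point inside several boxes is assigned to
#' the first one.
#'
#' @param boxes list of [region_box()] objects.
#' @return a `region_atlas`.
#' @export
region_atlas <- function(boxes) {
  if (!length(boxes)) stop("atlas must contain at least one box", call. = FALSE)
  if (!all(vapply(boxes, inherits, logical(1), "region_box"))) {
    stop("all atlas entries must be region_box objects", call. = FALSE)
  }
  ids <- vapply(boxes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate region ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(boxes = boxes, ids = ids), class = "region_atlas")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("region_atlas with", length(x$boxes), "boxes:",
      paste(x$ids, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write an atlas as JSON
#'
#' Format: `{"regions": [{"id", "name", "min": [x,y,z], "max": [x,y,z]}, ...]}`
#' with list order giving assignment priority.
#'
#' @param path file path.
#' @return [read_atlas()] returns a `region_atlas`; [write_atlas()] returns
#'   `path` invisibly.
#' @export
read_atlas <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$regions) || !length(obj$regions)) {
    stop("atlas JSON must contain a non-empty 'regions' array", call. = FALSE)
  }
  boxes <- lapply(obj$regions, function(r) {
    region_box(id = r$id,
               min = unlist(r$min), max = unlist(r$max),
               name = if (is.null(r$name)) r$id else r$name)
  })
  region_atlas(boxes)
}

#' @rdname read_atlas
#' @param atlas a `region_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "region_atlas"))
  obj <- list(regions = lapply(atlas$boxes, function(b) {
    list(id = b$id, name = b$name, min = b$min, max = b$max)
  }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Stylised demonstration atlas of thalamocortical nuclei
#'
#' Seven axis-aligned boxes named after thalamocortical nuclei (LGd, LP, VP,
#' PO, MD, LD and a catch-all `other_TC`) tiling a 2000 x 1500 x 2500 um
#' volume. Caudal sensory nuclei (LGd, VP, LP, PO) sit at low z, rostro-medial
#' associative nuclei (MD, LD) at high z and low x; `other_TC` is listed last
#' and spans the whole volume, so the specific nuclei win by list order. This
#' is an artificial stand-in for a reference taxonomy, intended for synthetic
#' data and examples.
#'
#' @return a `region_atlas`.
#' @export
demo_atlas <- function() {
  region_atlas(list(
    region_box("LGd", min = c(1000,  750,    0), max = c(2000, 1500, 1200)),
    region_box("VP",  min = c(1000,    0,    0), max = c(2000,  750, 1200)),
    region_box("LP",  min = c(   0,  750,    0), max = c(1000, 1500, 1200)),
    region_box("PO",  min = c(   0,    0,    0), max = c(1000,  750, 1200)),
    region_box("MD",  min = c(   0,    0, 1200), max = c(1000, 1500, 2500)),
    region_box("LD",  min = c(1000,    0, 1200), max = c(2000, 1500, 2500)),
    region_box("other_TC", min = c(0, 0, 0),     max = c(2000, 1500, 2500))
  ))
}

# Locate points in the atlas: character vector of region ids, "unassigned"
# for points contained in no box. Half-open [min, max) containment,
# first-matching box wins.
locate_points <- function(points, atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  pts <- as_coord_matrix(points)
  out <- rep("unassigned", nrow(pts))
  todo <- rep(TRUE, nrow(pts))
  for (b in atlas$boxes) {
    if (!any(todo)) break
    inside <- todo &
      pts[, 1] >= b$min[1] & pts[, 1] < b$max[1] &
      pts[, 2] >= b$min[2] & pts[, 2] < b$max[2] &
      pts[, 3] >= b$min[3] & pts[, 3] < b$max[3]
    out[inside] <- b$id
    todo <- todo & !inside
  }
  out
}

#' Assign cells to atlas regions
#'
#' Sets `region_id` for every cell to the first atlas box whose half-open
#' interval `[min, max)` contains it on all three axes; cells contained in no
#' box get `"unassigned"`. Input order is preserved and the operation is
#' idempotent.
#'
#' @param cells a cell table (`data.frame` with `x_um`, `y_um`, `z_um`) or a
#'   [brain_dataset()].
#' @param atlas a [region_atlas()].
#' @return the input with its `region_id` column (re)filled.
#' @export
assign_regions <- function(cells, atlas) {
  if (inherits(cells, "brain_dataset")) {
    cells$cells <- assign_regions(cells$cells, atlas)
    return(cells)
  }
  cells$region_id <- locate_points(cells, atlas)
  cells
}
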