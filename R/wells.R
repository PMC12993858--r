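#' Assign wells to the catchments that contain them
#'
#' Spatial join of well points to catchment polygons on a planar (km)
#' coordinate system, by ray casting. A point lying exactly on a polygon
#' boundary counts as inside. Catchments may nest: a well can be assigned to
#' several catchments. Alternatively a precomputed membership table
#' (`well_id`, `sample_id`) can be passed through unchanged.
#'
#' @param wells well record table with columns `well_id`, `x`, `y`.
#' @param catchments polygon table with columns `sample_id`, `vertex`, `x`,
#'   `y` (vertices in order, one ring per sample), or a membership table with
#'   columns `well_id`, `sample_id`.
#' @return data.frame with columns `well_id`, `sample_id`, one row per
#'   (well, containing catchment) pair.
#' @export
assign_wells <- function(wells, catchments) {
  if (all(c("well_id", "sample_id") %in% names(catchments)) &&
      !"vertex" %in% names(catchments)) {
    return(catchments[, c("well_id", "sample_id")])
  }
  stopifnot(all(c("sample_id", "vertex", "x", "y") %in% names(catchments)))
  out <- list()
  rings <- split(catchments[, c("vertex", "x", "y")], catchments$sample_id)
  for (sid in names(rings)) {
    ring <- rings[[sid]]
    ring <- ring[order(ring$vertex), ]
    if (polygon_self_intersects(ring$x, ring$y)) {
      stop("self-intersecting polygon for catchment ", sid, call. = FALSE)
    }
    # bounding-box prefilter; boundary points stay candidates
    cand <- which(wells$x >= min(ring$x) & wells$x <= max(ring$x) &
                    wells$y >= min(ring$y) & wells$y <= max(ring$y))
    if (!length(cand)) next
    inside <- point_in_polygon(wells$x[cand], wells$y[cand], ring$x, ring$y)
    if (any(inside)) {
      out[[sid]] <- data.frame(well_id = wells$well_id[cand[inside]],
                               sample_id = sid, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(well_id = character(), sample_id = character()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ray-casting point-in-polygon test (boundary inclusive)
#'
#' @param px,py point coordinates (vectors).
#' @param vx,vy polygon vertex coordinates in ring order (not closed).
#' @return logical vector, TRUE when the point is inside or on the boundary.
#' @export
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  stopifnot(n >= 3, length(vy) == n)
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
      if (point_on_segment(x, y, xi, yi, xj, yj)) return(TRUE)
      if ((yi > y) != (yj > y)) {
        xcross <- xi + (y - yi) / (yj - yi) * (xj - xi)
        if (x < xcross) inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}

point_on_segment <- function(x, y, x1, y1, x2, y2, tol = 1e-12) {
  cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
  if (abs(cross) > tol * max(1, abs(x2 - x1), abs(y2 - y1))) return(FALSE)
  dot <- (x - x1) * (x - x2) + (y - y1) * (y - y2)
  dot <= tol
}

# O(n^2) check that no two non-adjacent edges properly intersect
polygon_self_intersects <- function(vx, vy) {
  n <- length(vx)
  seg <- function(i) c(i, if (i == n) 1L else i + 1L)
  for (a in seq_len(n - 2L)) {
    for (b in seq(a + 2L, n)) {
      if (a == 1L && b == n) next  # adjacent through the closing edge
      sa <- seg(a); sb <- seg(b)
      if (segments_cross(vx[sa[1]], vy[sa[1]], vx[sa[2]], vy[sa[2]],
                         vx[sb[1]], vy[sb[1]], vx[sb[2]], vy[sb[2]])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

segments_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  d2 <- sign((bx - ax) * (dy - ay) - (by - ay) * (dx - ax))
  d3 <- sign((dx - cx) * (ay - cy) - (dy - cy) * (ax - cx))
  d4 <- sign((dx - cx) * (by - cy) - (dy - cy) * (bx - cx))
  d1 != d2 && d3 != d4 && d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0
}

#' Well densities and presence flags for one sample catchment
#'
#' Counts only `active` wells spudded strictly before the sample date
#' (well records spudded on or after the sampling day are excluded), split by
#' development type, and divides by the catchment area.
#'
#' @param sample one-row sample data.frame with `sample_id`, `sample_date`,
#'   `catchment_area_km2`.
#' @param wells well records assigned to this sample's catchment (columns
#'   `dev_type`, `status`, `spud_date`).
#' @return one-row data.frame: `sample_id`, `cogd_density`, `uogd_density`,
#'   `cogd_present`, `uogd_present`, `n_cog_wells`, `n_uog_wells`.
#' @export
well_density <- function(sample, wells) {
  area <- sample$catchment_area_km2
  if (!is.finite(area) || area <= 0) {
    stop("catchment area must be positive", call. = FALSE)
  }
  keep <- if (nrow(wells)) {
    wells$status == "active" &
      as.Date(wells$spud_date) < as.Date(sample$sample_date)
  } else logical(0)
  n_c <- sum(keep & wells$dev_type == "conventional")
  n_u <- sum(keep & wells$dev_type == "unconventional")
  data.frame(
    sample_id = sample$sample_id,
    cogd_density = n_c / area, uogd_density = n_u / area,
    cogd_present = n_c >= 1L, uogd_present = n_u >= 1L,
    n_cog_wells = n_c, n_uog_wells = n_u,
    stringsAsFactors = FALSE
  )
}

#' Catchment attribution for a whole sample table
#'
#' Runs [assign_wells()] then [well_density()] per sample and returns the
#' stacked attribution table.
#'
#' @param samples sample covariate table.
#' @param wells well record table.
#' @param catchments polygon or membership table (see [assign_wells()]).
#' @return data.frame, one attribution row per sample.
#' @export
attribute_wells <- function(samples, wells, catchments) {
  assignment <- assign_wells(wells, catchments)
  merged <- merge(assignment, wells, by = "well_id")
  by_sample <- split(merged, merged$sample_id)
  empty <- merged[0, , drop = FALSE]
  out <- lapply(seq_len(nrow(samples)), function(i) {
    s <- samples[i, ]
    w <- by_sample[[s$sample_id]]
    well_density(s, if (is.null(w)) empty else w)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
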