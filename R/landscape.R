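#' Island shape index
#'
#' Dimensionless perimeter-to-area shape complexity,
#' \eqn{SI = P / (2 \sqrt{\pi A})}, equal to 1 for a perfect circle and
#' increasing with shape irregularity. Inputs follow the field convention of
#' hectares for area and kilometers for perimeter; both are converted to
#' meters internally before the ratio is formed, so the index is truly
#' dimensionless.
#'
#' @param area_ha island area in hectares (> 0); vectorized.
#' @param perimeter_km island perimeter in kilometers (> 0); vectorized.
#' @return numeric vector of shape indices (>= 1 for simple closed shapes).
#' @examples
#' r <- 120 # meters
#' shape_index(area_ha = pi * r^2 / 1e4, perimeter_km = 2 * pi * r / 1e3)
#' shape_index(1, 0.4) # 100 m square: 2 / sqrt(pi)
#' @export
shape_index <- function(area_ha, perimeter_km) {
  if (!is.numeric(area_ha) || !is.numeric(perimeter_km)) {
    stop_invalid("area_ha and perimeter_km must be numeric")
  }
  if (any(is.na(area_ha)) || any(is.na(perimeter_km)) ||
      any(area_ha <= 0) || any(perimeter_km <= 0)) {
    stop_invalid("area_ha and perimeter_km must be positive and non-missing")
  }
  area_m2 <- area_ha * 1e4
  perim_m <- perimeter_km * 1e3
  perim_m / (2 * sqrt(pi * area_m2))
}

as_polygon <- function(poly) {
  if (is.data.frame(poly)) poly <- as.matrix(poly[, c("x", "y")])
  if (!is.matrix(poly) || ncol(poly) != 2L || !is.numeric(poly)) {
    stop_geometry("a polygon must be a 2-column numeric matrix (x, y) in projected meters")
  }
  # drop an explicitly repeated closing vertex
  n <- nrow(poly)
  if (n >= 2L && all(poly[1L, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  if (nrow(poly) < 3L) stop_geometry("a polygon needs at least 3 distinct vertices")
  if (any(is.na(poly))) stop_geometry("polygon vertices contain missing values")
  poly
}

polygon_edges <- function(poly) {
  n <- nrow(poly)
  cbind(poly, poly[c(2:n, 1L), , drop = FALSE])
}

# signed orientation of the triangle (p, q, r)
orient <- function(px, py, qx, qy, rx, ry) {
  (qx - px) * (ry - py) - (qy - py) * (rx - px)
}

segments_properly_cross <- function(a, b) {
  d1 <- orient(a[1], a[2], a[3], a[4], b[1], b[2])
  d2 <- orient(a[1], a[2], a[3], a[4], b[3], b[4])
  d3 <- orient(b[1], b[2], b[3], b[4], a[1], a[2])
  d4 <- orient(b[1], b[2], b[3], b[4], a[3], a[4])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

check_simple <- function(poly) {
  e <- polygon_edges(poly)
  n <- nrow(e)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next # adjacent edges share a vertex
      if (segments_properly_cross(e[i, ], e[j, ])) {
        stop_geometry("polygon is self-intersecting (edges ", i, " and ", j, " cross)")
      }
    }
  }
  invisible(poly)
}

#' Polygon area and perimeter
#'
#' Shoelace area and boundary length for a simple polygon in projected planar
#' coordinates (meters). Vertex orientation is irrelevant; a repeated closing
#' vertex is tolerated. Units are converted to the attribute-table
#' conventions: hectares and kilometers.
#'
#' @param poly a 2-column numeric matrix or a data frame with columns `x`,
#'   `y`, vertices in order, in meters.
#' @return a tibble with one row: `area_ha`, `perimeter_km`.
#' @examples
#' polygon_area_perimeter(cbind(c(0, 100, 0), c(0, 0, 100)))
#' @export
polygon_area_perimeter <- function(poly) {
  poly <- check_simple(as_polygon(poly))
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  area_m2 <- abs(sum(poly[, 1] * poly[nxt, 2] - poly[nxt, 1] * poly[, 2])) / 2
  perim_m <- sum(sqrt(rowSums((poly[nxt, , drop = FALSE] - poly)^2)))
  tibble::tibble(area_ha = area_m2 / 1e4, perimeter_km = perim_m / 1e3)
}

point_segment_distance <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  wx <- px - ax; wy <- py - ay
  L2 <- vx^2 + vy^2
  t <- if (L2 == 0) 0 else pmin(1, pmax(0, (wx * vx + wy * vy) / L2))
  sqrt((wx - t * vx)^2 + (wy - t * vy)^2)
}

segment_segment_distance <- function(a, b) {
  if (segments_properly_cross(a, b)) return(0)
  min(point_segment_distance(a[1], a[2], b[1], b[2], b[3], b[4]),
      point_segment_distance(a[3], a[4], b[1], b[2], b[3], b[4]),
      point_segment_distance(b[1], b[2], a[1], a[2], a[3], a[4]),
      point_segment_distance(b[3], b[4], a[1], a[2], a[3], a[4]))
}

point_in_polygon <- function(px, py, poly) {
  # ray casting; boundary points may land on either side, callers handle
  # touching separately via distance 0
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

#' Edge-to-edge isolation distance
#'
#' Shortest boundary-to-boundary distance between two simple polygons in
#' projected meters, returned in kilometers: the isolation of a focal island
#' from the mainland. Touching boundaries give 0; overlapping interiors are
#' rejected.
#'
#' @param island,mainland polygons as in [polygon_area_perimeter()].
#' @return distance in kilometers (scalar).
#' @examples
#' sq <- function(x0) cbind(c(0, 100, 100, 0) + x0, c(0, 0, 100, 100))
#' isolation_km(sq(0), sq(1100)) # facing edges 1000 m apart
#' @export
isolation_km <- function(island, mainland) {
  a <- check_simple(as_polygon(island))
  b <- check_simple(as_polygon(mainland))
  ea <- polygon_edges(a)
  eb <- polygon_edges(b)
  d <- Inf
  for (i in seq_len(nrow(ea))) {
    for (j in seq_len(nrow(eb))) {
      d <- min(d, segment_segment_distance(ea[i, ], eb[j, ]))
      if (d == 0) break
    }
    if (d == 0) break
  }
  if (d > 0) {
    # disjoint boundaries: reject one polygon strictly inside the other
    if (point_in_polygon(a[1, 1], a[1, 2], b) ||
        point_in_polygon(b[1, 1], b[1, 2], a)) {
      stop_geometry("polygons have overlapping interiors; isolation is undefined")
    }
  } else {
    # boundaries meet; proper edge crossings mean interior overlap
    for (i in seq_len(nrow(ea))) {
      for (j in seq_len(nrow(eb))) {
        if (segments_properly_cross(ea[i, ], eb[j, ])) {
          stop_geometry("polygons have overlapping interiors; isolation is undefined")
        }
      }
    }
  }
  d / 1e3
}

#' Compute or validate an island attribute table
#'
#' Takes either a ready attribute table (columns `island_id`, `area_ha`,
#' `perimeter_km`, optional `shape_index` which is recomputed when absent,
#' `isolation_km`, `sampling_area_ha`, optional logical `is_reference`) or a
#' long vertex table (`island_id`, `x`, `y` in meters) plus a mainland
#' polygon, from which area, perimeter, shape index and isolation are
#' computed.
#'
#' @param data a data frame in one of the two layouts above.
#' @param mainland optional mainland polygon (matrix or data frame with
#'   `x`, `y`), required for the vertex layout.
#' @return a tibble with columns `island_id`, `area_ha`, `perimeter_km`,
#'   `shape_index`, `isolation_km`, `sampling_area_ha`, `is_reference`.
#' @export
island_attributes <- function(data, mainland = NULL) {
  data <- tibble::as_tibble(data)
  if (all(c("island_id", "x", "y") %in% names(data))) {
    if (is.null(mainland)) {
      stop_schema("vertex input requires a `mainland` polygon for isolation")
    }
    out <- data |>
      dplyr::group_by(.data$island_id) |>
      dplyr::group_modify(function(d, key) {
        ap <- polygon_area_perimeter(d[, c("x", "y")])
        ap$isolation_km <- isolation_km(d[, c("x", "y")], mainland)
        ap
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(
        shape_index = shape_index(.data$area_ha, .data$perimeter_km),
        sampling_area_ha = sampling_area_rule(.data$area_ha),
        is_reference = FALSE
      )
    return(out[, c("island_id", "area_ha", "perimeter_km", "shape_index",
                   "isolation_km", "sampling_area_ha", "is_reference")])
  }
  need <- c("island_id", "area_ha", "perimeter_km", "isolation_km")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop_schema("attribute table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(data$area_ha <= 0) || any(data$perimeter_km <= 0)) {
    stop_invalid("area_ha and perimeter_km must be positive")
  }
  if (any(data$isolation_km < 0)) stop_invalid("isolation_km must be >= 0")
  if (anyDuplicated(data$island_id)) stop_schema("duplicated island_id in attribute table")
  if (!"shape_index" %in% names(data) || any(is.na(data$shape_index))) {
    data$shape_index <- shape_index(data$area_ha, data$perimeter_km)
  }
  if (any(data$shape_index < 1 - 1e-9)) {
    stop_invalid("shape_index below 1 violates the isoperimetric inequality")
  }
  if (!"sampling_area_ha" %in% names(data)) {
    data$sampling_area_ha <- sampling_area_rule(data$area_ha)
  }
  if (!"is_reference" %in% names(data)) data$is_reference <- FALSE
  data[, c("island_id", "area_ha", "perimeter_km", "shape_index",
           "isolation_km", "sampling_area_ha", "is_reference")]
}

# census protocol: full census below 1 ha, 0.5 ha plots on 1-5 ha islands,
# 1 ha plots above 5 ha
sampling_area_rule <- function(area_ha) {
  dplyr::case_when(
    area_ha < 1 ~ area_ha,
    area_ha <= 5 ~ 0.5,
    TRUE ~ 1
  )
}
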