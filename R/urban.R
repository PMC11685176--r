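# Distance from arrival locations to the nearest urban area, computed as
# geodesic point-to-polygon-boundary distance on WGS84 polygons (GeoJSON in),
# with boundaries densified to <= 1 km vertex spacing. A point inside any
# polygon is at distance zero.

#' Urban area polygon set
#'
#' @param polygons list of polygons; each polygon is a list of rings, each
#'   ring a two-column matrix of lon/lat vertices (first ring outer, rest
#'   holes).
#' @param ids character ids, one per polygon.
#' @return An object of class `urban_areas`.
#' @export
urban_areas <- function(polygons, ids = as.character(seq_along(polygons))) {
  stopifnot(length(polygons) == length(ids))
  if (!length(polygons)) stop("no urban polygons")
  for (p in polygons) {
    for (ring in p) {
      if (!is.matrix(ring) || ncol(ring) != 2 || nrow(ring) < 4)
        stop("each ring must be a lon/lat matrix with >= 4 rows (closed)")
      if (any(ring[1, ] != ring[nrow(ring), ]))
        stop("rings must be closed (first vertex == last vertex)")
      if (any(abs(ring[, 2]) > 90) || any(abs(ring[, 1]) > 180))
        stop("ring coordinates out of range")
    }
  }
  structure(list(polygons = polygons, ids = as.character(ids)),
            class = "urban_areas")
}

#' @export
print.urban_areas <- function(x, ...) {
  cat(sprintf("<urban_areas> %d polygon(s)\n", length(x$polygons)))
  invisible(x)
}

# A ring self-intersects if any two non-adjacent edges cross (planar test in
# lon/lat; urban polygons are small, so this is adequate screening).
ring_self_intersects <- function(ring) {
  seg_cross <- function(p1, p2, p3, p4) {
    d <- function(a, b, c)
      (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  }
  n <- nrow(ring) - 1L
  if (n < 4) return(FALSE)
  for (i in 1:(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through closure
      if (seg_cross(ring[i, ], ring[i + 1, ], ring[j, ], ring[j + 1, ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Load urban polygons from GeoJSON
#'
#' Accepts Polygon and MultiPolygon features (FeatureCollection, single
#' Feature, or bare geometry). Self-intersecting rings are rejected with a
#' warning; an input with no usable polygons is an error.
#'
#' @param path GeoJSON file.
#' @return An [urban_areas()] object.
#' @export
load_urban <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::read_json(path)
  feats <- switch(gj$type %||% "",
                  FeatureCollection = gj$features,
                  Feature = list(gj),
                  Polygon = , MultiPolygon = list(list(geometry = gj)),
                  stop("unsupported GeoJSON type: ", gj$type))
  polys <- list()
  ids <- character()
  k <- 0L
  for (f in feats) {
    geom <- f$geometry
    if (is.null(geom)) next
    id <- as.character(f$properties$id %||% (length(polys) + 1L))
    coord_sets <- switch(geom$type,
                         Polygon = list(geom$coordinates),
                         MultiPolygon = geom$coordinates,
                         NULL)
    if (is.null(coord_sets)) next
    for (cs in coord_sets) {
      k <- k + 1L
      rings <- lapply(cs, function(r)
        do.call(rbind, lapply(r, function(v) c(v[[1]], v[[2]]))))
      if (any(vapply(rings, ring_self_intersects, logical(1)))) {
        warning("rejecting self-intersecting polygon (id ", id, ")")
        next
      }
      polys[[length(polys) + 1L]] <- rings
      ids <- c(ids, id)
    }
  }
  if (!length(polys)) stop("no urban polygons")
  urban_areas(polys, ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Insert vertices along each edge so consecutive vertices are <= max_km
# apart (linear interpolation in lon/lat; edges are short after splitting).
densify_ring <- function(ring, max_km = 1) {
  out <- list()
  n <- nrow(ring)
  for (i in 1:(n - 1)) {
    a <- ring[i, ]; b <- ring[i + 1, ]
    d <- haversine_km(a[1], a[2], b[1], b[2])
    k <- max(1L, ceiling(d / max_km))
    t <- seq(0, 1, length.out = k + 1)[-(k + 1)]
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  rbind(do.call(rbind, out), ring[n, , drop = FALSE])
}

point_in_polygon <- function(lon, lat, polygon) {
  inside_outer <- sp::point.in.polygon(lon, lat, polygon[[1]][, 1],
                                       polygon[[1]][, 2]) > 0
  if (!inside_outer) return(FALSE)
  if (length(polygon) > 1) {
    for (hole in polygon[-1]) {
      if (sp::point.in.polygon(lon, lat, hole[, 1], hole[, 2]) == 1)
        return(FALSE)
    }
  }
  TRUE
}

#' Geodesic distance from a point to the nearest urban area
#'
#' Zero if the point lies inside any polygon; otherwise the minimum
#' great-circle distance from the point to any polygon boundary, with
#' boundaries densified to at most 1-km vertex spacing before point-to-vertex
#' minimisation. Invariant to polygon ordering; adding polygons can only
#' decrease the result.
#'
#' @param lon,lat query point, decimal degrees (scalars).
#' @param urban an [urban_areas()] object.
#' @param densify_km maximum boundary vertex spacing, km.
#' @return distance in km.
#' @export
distance_to_urban <- function(lon, lat, urban, densify_km = 1) {
  stopifnot(inherits(urban, "urban_areas"), length(lon) == 1, length(lat) == 1)
  best <- Inf
  for (poly in urban$polygons) {
    if (point_in_polygon(lon, lat, poly)) return(0)
    for (ring in poly) {
      dr <- densify_ring(ring, densify_km)
      best <- min(best, min(haversine_km(lon, lat, dr[, 1], dr[, 2])))
    }
  }
  best
}

#' Synthetic urban polygon set
#'
#' A small set of square "cities" spanning typical mallard breeding
#' latitudes, used by the demo pipeline and tests in place of a land-cover
#' extract. Synthetic stand-in: locations and sizes are invented.
#'
#' @param centers two-column matrix of lon/lat square centers.
#' @param half_deg half side length, degrees.
#' @return An [urban_areas()] object.
#' @export
synthetic_urban_areas <- function(centers = rbind(c(-93.3, 44.9),
                                                  c(-97.0, 49.9),
                                                  c(-100.8, 46.8),
                                                  c(-89.4, 43.1)),
                                  half_deg = 0.15) {
  polys <- lapply(seq_len(nrow(centers)), function(i) {
    cx <- centers[i, 1]; cy <- centers[i, 2]; h <- half_deg
    list(cbind(c(cx - h, cx + h, cx + h, cx - h, cx - h),
               c(cy - h, cy - h, cy + h, cy + h, cy - h)))
  })
  urban_areas(polys, paste0("city", seq_len(nrow(centers))))
}
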