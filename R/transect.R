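#' Great-circle distance in kilometres
#'
#' Haversine formula on a sphere of radius 6371 km. Vectorised over all
#' arguments.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance(s) in km.
#' @examples
#' haversine_km(0, 0, 0, 1) # one degree of longitude at the equator
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Interpolate the hybrid-index surface over the locality map
#'
#' Linear (barycentric) interpolation of locality hybrid indices on a
#' Delaunay triangulation of the locality coordinates, evaluated on a
#' regular lat/long grid over the locality bounding box. Cells outside the
#' convex hull of the localities are `NA`. Interpolation is node-exact: the
#' surface at a locality equals its hybrid index.
#'
#' @param localities a [locality_frame()] (or any data frame with
#'   `longitude`, `latitude` and the value column).
#' @param resolution grid spacing in degrees (default 0.01, roughly 1 km).
#' @param value column interpolated (default `"hybrid_index"`).
#' @return object of class `hi_surface`: list with `lon`, `lat` (grid
#'   vectors) and `z` (matrix, `length(lon)` x `length(lat)`).
#' @export
interpolate_hi_surface <- function(localities, resolution = 0.01,
                                   value = "hybrid_index") {
  x <- localities$longitude; y <- localities$latitude; z <- localities[[value]]
  keep <- complete.cases(x, y, z)
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  if (length(x) < 3L) stop("need at least 3 localities")
  # collinearity check: rank of centred coordinates
  if (qr(cbind(x - mean(x), y - mean(y)))$rank < 2L)
    stop("all localities are collinear; no surface can be interpolated")
  xo <- seq(min(x), max(x), by = resolution)
  yo <- seq(min(y), max(y), by = resolution)
  surf <- interp::interp(x = x, y = y, z = z, xo = xo, yo = yo,
                         method = "linear", duplicate = "mean")
  tri <- interp::triangles(interp::tri.mesh(x, y))[, 1:3, drop = FALSE]
  structure(list(lon = surf$x, lat = surf$y, z = surf$z,
                 localities = data.frame(longitude = x, latitude = y, value = z),
                 triangles = tri, resolution = resolution),
            class = "hi_surface")
}

#' Surface value at point coordinates (nearest grid cell)
#'
#' @param surface an `hi_surface`.
#' @param latitude,longitude point coordinates.
#' @return numeric vector (`NA` off-grid / outside the hull).
#' @export
surface_value <- function(surface, latitude, longitude) {
  res_x <- if (length(surface$lon) > 1L) surface$lon[2L] - surface$lon[1L] else 1
  res_y <- if (length(surface$lat) > 1L) surface$lat[2L] - surface$lat[1L] else 1
  ci <- as.integer(round((longitude - surface$lon[1L]) / res_x)) + 1L
  ri <- as.integer(round((latitude - surface$lat[1L]) / res_y)) + 1L
  ci[ci < 1L | ci > length(surface$lon)] <- NA_integer_
  ri[ri < 1L | ri > length(surface$lat)] <- NA_integer_
  surface$z[cbind(ci, ri)]
}

#' Extract a level isoline from the hybrid-index surface
#'
#' Computes the exact level set of the piecewise-linear surface: every
#' Delaunay triangle crossed by the level contributes one straight segment
#' (with linearly interpolated endpoints on the crossed edges), and the
#' segments are chained into connected polylines. This is the limit of
#' marching-squares contouring as the grid is refined, but is independent
#' of grid resolution. Of the components found, the longest (by
#' great-circle length) is retained as the zone-center isoline. An optional
#' clipping polygon restricts the isoline to the species' range. For
#' surfaces lacking a triangulation, marching squares on the grid
#' ([grDevices::contourLines()]) is the fallback.
#'
#' @param surface an `hi_surface` from [interpolate_hi_surface()].
#' @param level contour level (default 0.5, the theoretical zone center).
#' @param clip optional polygon (data frame `longitude`, `latitude`);
#'   isoline vertices outside it are dropped.
#' @return data frame of class `isoline` with columns `longitude`,
#'   `latitude` (ordered vertices of a polyline).
#' @export
extract_isoline <- function(surface, level = 0.5, clip = NULL) {
  z <- surface$z
  rng <- range(z, na.rm = TRUE)
  if (rng[1L] >= level || rng[2L] <= level)
    stop("no contact in sampled area: surface never crosses level ", level)
  if (!is.null(surface$triangles)) {
    pts <- surface$localities
    comps <- triangle_level_components(pts$longitude, pts$latitude,
                                       pts$value, surface$triangles, level)
  } else {
    segs <- grDevices::contourLines(surface$lon, surface$lat, z, levels = level)
    comps <- lapply(segs, function(s) data.frame(longitude = s$x, latitude = s$y))
  }
  if (length(comps) == 0L)
    stop("no contact in sampled area: surface never crosses level ", level)
  len <- vapply(comps, function(s) {
    n <- nrow(s)
    if (n < 2L) return(0)
    sum(haversine_km(s$latitude[-n], s$longitude[-n],
                     s$latitude[-1L], s$longitude[-1L]))
  }, numeric(1L))
  iso <- comps[[which.max(len)]]
  if (!is.null(clip)) {
    inside <- point_in_polygon(iso$longitude, iso$latitude,
                               clip$longitude, clip$latitude)
    iso <- iso[inside, , drop = FALSE]
    if (nrow(iso) < 2L) stop("clipping removed the whole isoline")
  }
  class(iso) <- c("isoline", "data.frame")
  iso
}

# Exact level set of a linear interpolant on a triangulation: one straight
# segment per crossed triangle, chained into connected polylines.
triangle_level_components <- function(x, y, z, tri, level) {
  # nudge nodes sitting exactly on the level so every crossing is a proper
  # edge intersection
  z <- ifelse(abs(z - level) < 1e-12, level + 1e-9, z)
  seg_list <- list()
  for (t in seq_len(nrow(tri))) {
    v <- tri[t, ]
    below <- z[v] < level
    if (all(below) || all(!below)) next
    odd <- which(below == (sum(below) == 1L))   # the vertex on its own side
    oth <- setdiff(1:3, odd)
    pt <- function(i, j) {
      a <- v[i]; b <- v[j]
      f <- (level - z[a]) / (z[b] - z[a])
      c(x[a] + f * (x[b] - x[a]), y[a] + f * (y[b] - y[a]))
    }
    seg_list[[length(seg_list) + 1L]] <- c(pt(odd, oth[1L]), pt(odd, oth[2L]))
  }
  if (length(seg_list) == 0L) return(list())
  segs <- do.call(rbind, seg_list)
  key <- function(p) sprintf("%.10f_%.10f", p[, 1L], p[, 2L])
  k1 <- key(segs[, 1:2, drop = FALSE]); k2 <- key(segs[, 3:4, drop = FALSE])
  nodes <- unique(c(k1, k2))
  i1 <- match(k1, nodes); i2 <- match(k2, nodes)
  coords <- rbind(segs[, 1:2, drop = FALSE],
                  segs[, 3:4, drop = FALSE])[match(nodes, c(k1, k2)), , drop = FALSE]
  adj <- vector("list", length(nodes))
  for (s in seq_along(i1)) {
    adj[[i1[s]]] <- c(adj[[i1[s]]], i2[s])
    adj[[i2[s]]] <- c(adj[[i2[s]]], i1[s])
  }
  visited <- logical(length(nodes))
  comps <- list()
  deg <- lengths(adj)
  for (start in order(deg)) {                   # open paths start at degree-1
    if (visited[start]) next
    path <- start; visited[start] <- TRUE
    cur <- start
    repeat {
      nxt <- adj[[cur]][!visited[adj[[cur]]]]
      if (length(nxt) == 0L) break
      cur <- nxt[1L]
      visited[cur] <- TRUE
      path <- c(path, cur)
    }
    if (length(path) >= 2L)
      comps[[length(comps) + 1L]] <-
        data.frame(longitude = coords[path, 1L], latitude = coords[path, 2L])
  }
  comps
}

# Ray-casting point-in-polygon (even-odd rule); vertices px, py.
point_in_polygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- (py[i] > y) != (py[j] > y)
    xs <- (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i]
    inside <- xor(inside, cross & (x < xs))
    j <- i
  }
  inside
}

# Densify a polyline so consecutive vertices are at most step_km apart
# (great-circle); interpolation is linear in lon/lat, adequate at km scale.
densify_polyline <- function(lon, lat, step_km = 0.1) {
  n <- length(lon)
  if (n < 2L) return(cbind(lon = lon, lat = lat))
  out_lon <- list(); out_lat <- list()
  for (i in seq_len(n - 1L)) {
    d <- haversine_km(lat[i], lon[i], lat[i + 1L], lon[i + 1L])
    k <- max(1L, ceiling(d / step_km))
    t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    out_lon[[i]] <- lon[i] + t * (lon[i + 1L] - lon[i])
    out_lat[[i]] <- lat[i] + t * (lat[i + 1L] - lat[i])
  }
  cbind(lon = c(unlist(out_lon), lon[n]), lat = c(unlist(out_lat), lat[n]))
}

#' Signed great-circle distances of localities from the isoline
#'
#' Distance of each locality to the nearest point of the (densified)
#' isoline, signed by which side of the zone the locality falls on:
#' negative on the *nesterovi* side (hybrid index below the level), positive
#' on the *ophryticus* side.
#'
#' @param localities a [locality_frame()].
#' @param isoline an `isoline` from [extract_isoline()].
#' @param surface optional `hi_surface`, used to determine the side when a
#'   locality has no `hybrid_index` value.
#' @param level the isoline level (default 0.5).
#' @param step_km densification step along isoline segments (default 0.1 km).
#' @return data frame of class `isoline_transect`: `code`, `distance_km`,
#'   `side`.
#' @export
signed_distances <- function(localities, isoline, surface = NULL,
                             level = 0.5, step_km = 0.1) {
  if (nrow(isoline) < 1L) stop("empty isoline")
  dense <- densify_polyline(isoline$longitude, isoline$latitude, step_km)
  hi <- localities$hybrid_index
  if (is.null(hi) && is.null(surface))
    stop("need locality hybrid indices or a surface to determine sides")
  d <- mapply(function(la, lo) {
    min(haversine_km(la, lo, dense[, "lat"], dense[, "lon"]))
  }, localities$latitude, localities$longitude)
  side_val <- hi
  if (!is.null(surface)) {
    fill <- is.na(side_val)
    side_val[fill] <- surface_value(surface, localities$latitude[fill],
                                    localities$longitude[fill])
  }
  sgn <- ifelse(side_val < level, -1, 1)
  out <- data.frame(code = localities$code,
                    distance_km = sgn * d,
                    side = ifelse(sgn < 0, "nesterovi", "ophryticus"))
  class(out) <- c("isoline_transect", "data.frame")
  out
}

#' Build the full 1D transect from a locality map
#'
#' Convenience wrapper: interpolates the hybrid-index surface, extracts the
#' level isoline, and computes signed distances.
#'
#' @inheritParams interpolate_hi_surface
#' @inheritParams extract_isoline
#' @return list of class `transect_build` with `surface`, `isoline`,
#'   `distances`.
#' @examples
#' \donttest{
#' tr <- build_transect(ommatotriton_localities(natural_only = TRUE))
#' head(tr$distances)
#' }
#' @export
build_transect <- function(localities, resolution = 0.01, level = 0.5,
                           clip = NULL) {
  surface <- interpolate_hi_surface(localities, resolution)
  isoline <- extract_isoline(surface, level, clip)
  distances <- signed_distances(localities, isoline, surface, level)
  structure(list(surface = surface, isoline = isoline, distances = distances),
            class = "transect_build")
}
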