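#' Aligned stack of gridded environmental layers
#'
#' A lightweight raster container: named layers on a shared regular lat/long
#' grid. Each layer is a numeric matrix with rows indexing latitude
#' (ascending, south to north) and columns indexing longitude (ascending).
#' Cells that are `NA` in any layer are masked in all layers, so the valid
#' mask is identical across the stack.
#'
#' @param layers named list of equally sized numeric matrices.
#' @param xmin,xmax,ymin,ymax extent in decimal degrees (cell edges).
#' @return object of class `raster_stack` with elements `layers`, `extent`,
#'   `lon`, `lat` (cell-center coordinate vectors).
#' @export
raster_stack <- function(layers, xmin, xmax, ymin, ymax) {
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("layers must be named")
  dims <- vapply(layers, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("all layers must share the same grid")
  nr <- dims[1L, 1L]; nc <- dims[2L, 1L]
  # harmonize nodata across layers
  na_mask <- Reduce(`|`, lapply(layers, is.na))
  layers <- lapply(layers, function(m) { m[na_mask] <- NA_real_; m })
  structure(list(layers = layers,
                 extent = c(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
                 lon = xmin + (seq_len(nc) - 0.5) * (xmax - xmin) / nc,
                 lat = ymin + (seq_len(nr) - 0.5) * (ymax - ymin) / nr),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack> %d layers (%s), %d x %d cells, extent [%g, %g] x [%g, %g]\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              nrow(x$layers[[1L]]), ncol(x$layers[[1L]]),
              x$extent["xmin"], x$extent["xmax"],
              x$extent["ymin"], x$extent["ymax"]))
  invisible(x)
}

#' Extract layer values at point coordinates (nearest cell)
#'
#' @param stack a [raster_stack()].
#' @param latitude,longitude point coordinates.
#' @return matrix, points x layers; `NA` for points off the grid or on
#'   masked cells.
#' @export
extract_cells <- function(stack, latitude, longitude) {
  nr <- nrow(stack$layers[[1L]]); nc <- ncol(stack$layers[[1L]])
  ext <- stack$extent
  ri <- floor((latitude - ext["ymin"]) / (ext["ymax"] - ext["ymin"]) * nr) + 1L
  ci <- floor((longitude - ext["xmin"]) / (ext["xmax"] - ext["xmin"]) * nc) + 1L
  ri[ri < 1L | ri > nr] <- NA_integer_
  ci[ci < 1L | ci > nc] <- NA_integer_
  out <- sapply(stack$layers, function(m) m[cbind(ri, ci)])
  if (is.null(dim(out))) out <- matrix(out, nrow = length(latitude),
                                       dimnames = list(NULL, names(stack$layers)))
  out
}

#' Write one layer as an ESRI ASCII grid
#'
#' Plain-text raster interchange (no binary GeoTIFF dependency is available
#' in this toolchain); readable by QGIS/GDAL.
#'
#' @param stack a [raster_stack()].
#' @param layer layer name.
#' @param path output `.asc` path.
#' @param nodata nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(stack, layer, path, nodata = -9999) {
  m <- stack$layers[[layer]]
  if (is.null(m)) stop("no such layer: ", layer)
  ext <- stack$extent
  cell <- (ext["xmax"] - ext["xmin"]) / ncol(m)
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", ext["xmin"]),
           sprintf("yllcorner %.10g", ext["ymin"]),
           sprintf("cellsize %.10g", cell),
           sprintf("NODATA_value %g", nodata))
  m2 <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # ASCII grids run north->south
  m2[is.na(m2)] <- nodata
  body <- apply(m2, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid as a one-layer stack
#'
#' @param path `.asc` path.
#' @param name layer name to assign.
#' @return a [raster_stack()] with a single layer.
#' @export
read_ascii_grid <- function(path, name = "layer") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  vals <- lapply(lines[i:length(lines)],
                 function(l) as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1L]]))
  m <- do.call(rbind, vals)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  raster_stack(setNames(list(m), name),
               xmin = hdr$xllcorner, xmax = hdr$xllcorner + hdr$ncols * hdr$cellsize,
               ymin = hdr$yllcorner, ymax = hdr$yllcorner + hdr$nrows * hdr$cellsize)
}
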