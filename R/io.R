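#' Read and write rasters as ESRI ASCII grids
#'
#' Grids are persisted in the plain-text ESRI ASCII grid format (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value` header
#' followed by rows north to south). Values are written at full double
#' precision so write/read round-trips are bitwise exact. A JSON sidecar
#' (`<path>.aux.json`) records the coordinate-system tag and, for
#' categorical grids, the legend keyed by integer code; `read_grid`
#' restores both when the sidecar is present.
#'
#' @param path file path (conventionally `.asc`).
#' @param band band index; ASCII grids are single-band so any value other
#'   than 1 is a range error.
#' @param grid an `eco_grid` or `eco_catgrid`.
#' @param nodata nodata sentinel written to file for masked cells.
#' @return `read_grid` returns an `eco_grid` (or `eco_catgrid` when the
#'   sidecar carries a legend); `write_grid` invisibly returns `path`.
#' @examples
#' f <- tempfile(fileext = ".asc")
#' write_grid(eco_grid(matrix(1:6 / 2, 2, 3)), f)
#' read_grid(f)
#' @export
read_grid <- function(path, band = 1) {
  if (!file.exists(path)) {
    stop_ecovuln(sprintf("file not found: %s", path), "ecovuln_format_error")
  }
  if (!identical(as.numeric(band), 1)) {
    stop_ecovuln("ASCII grids are single-band; band must be 1",
                 "ecovuln_range_error")
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) {
    stop_ecovuln(sprintf("not an ESRI ASCII grid: %s", path),
                 "ecovuln_format_error")
  }
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop_ecovuln(sprintf("malformed ASCII grid header: %s", path),
                 "ecovuln_format_error")
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(body) != hdr$ncols * hdr$nrows) {
    stop_ecovuln(sprintf("grid body has %d values, expected %d",
                         length(body), hdr$ncols * hdr$nrows),
                 "ecovuln_format_error")
  }
  vals <- matrix(body, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  vals[vals == nodata] <- NA
  origin <- c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize)
  aux_path <- paste0(path, ".aux.json")
  crs <- "unknown"
  legend <- NULL
  if (file.exists(aux_path)) {
    aux <- jsonlite::read_json(aux_path, simplifyVector = TRUE)
    crs <- aux$crs_label %||% crs
    if (!is.null(aux$legend)) legend <- unlist(aux$legend)
  }
  if (!is.null(legend)) {
    eco_catgrid(matrix(as.integer(round(vals)), nrow(vals), ncol(vals)),
                legend = legend, cell_size = hdr$cellsize, origin = origin,
                crs_label = crs)
  } else {
    eco_grid(vals, cell_size = hdr$cellsize, origin = origin, crs_label = crs)
  }
}

#' @rdname read_grid
#' @export
write_grid <- function(grid, path, nodata = -9999) {
  if (!inherits(grid, "eco_grid")) {
    stop_ecovuln("'grid' must be an eco_grid", "ecovuln_usage_error")
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop_ecovuln(sprintf("directory does not exist: %s", dir),
                 "ecovuln_io_error")
  }
  d <- grid_dim(grid)
  vals <- grid$values
  vals[is.na(vals)] <- nodata
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2] - d[1] * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  rows <- apply(vals, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  aux <- list(crs_label = grid$crs_label)
  if (is_catgrid(grid)) aux$legend <- as.list(grid$legend)
  jsonlite::write_json(aux, paste0(path, ".aux.json"), auto_unbox = TRUE)
  invisible(path)
}
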