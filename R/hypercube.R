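#' Hyperspectral image cube
#'
#' A stack of co-registered single-band greyscale images along a wavelength
#' axis, stored as a `rows x cols x bands` array plus its [band_grid()] and
#' free-form metadata.
#'
#' @param values numeric array `rows x cols x bands`, finite and >= 0.
#' @param grid a [band_grid()] with one wavelength per band.
#' @param metadata named list (scene id, render settings, ...).
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(values, grid, metadata = list()) {
  stopifnot(is.array(values), length(dim(values)) == 3,
            inherits(grid, "band_grid"),
            dim(values)[3] == length(grid$wavelengths))
  if (any(!is.finite(values)) || any(values < 0))
    stop("cube values must be finite and nonnegative")
  structure(list(values = values, grid = grid, metadata = metadata),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %d x %d px, %d bands (%s), max %.4g\n",
              d[1], d[2], d[3], format(x$grid), max(x$values)))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$values)

band_index_of <- function(cube, band_nm) {
  wl <- cube$grid$wavelengths
  dif <- abs(wl - band_nm)
  # ties resolve to the lower wavelength for determinism
  which(dif == min(dif))[1]
}

#' Extract one band image by wavelength
#'
#' Picks the band whose centre is nearest to `band_nm`; ties resolve to the
#' lower wavelength.
#'
#' @param cube a [hypercube()].
#' @param band_nm wavelength in nm.
#' @return The band's image matrix.
#' @export
cube_band <- function(cube, band_nm) {
  stopifnot(inherits(cube, "hypercube"))
  cube$values[, , band_index_of(cube, band_nm)]
}

#' Write / read an ENVI-format cube
#'
#' Standard ENVI pair: a flat binary raster (band-sequential interleave,
#' 64-bit IEEE floating point, little endian) and a text header carrying the
#' dimensions and the wavelength array in nm. The round trip is bitwise
#' lossless.
#'
#' @param cube a [hypercube()].
#' @param path base path; `.dat` and `.hdr` extensions are appended.
#' @return `read_envi` returns the restored `hypercube`.
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  path <- sub("\\.(dat|hdr)$", "", path)
  d <- dim(cube$values)
  hdr <- c("ENVI",
           "description = {pbrsim hyperspectral cube}",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           "interleave = bsq",
           "byte order = 0",
           "wavelength units = nm",
           sprintf("wavelength = {%s}",
                   paste(sprintf("%.9g", cube$grid$wavelengths),
                         collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  # BSQ: band by band, row-major within band (line = image row)
  for (b in seq_len(d[3]))
    writeBin(as.numeric(t(cube$values[, , b])), con, size = 8,
             endian = "little")
  invisible(path)
}

#' @rdname write_envi
#' @export
read_envi <- function(path) {
  path <- sub("\\.(dat|hdr)$", "", path)
  hdr_path <- paste0(path, ".hdr")
  dat_path <- paste0(path, ".dat")
  if (!file.exists(hdr_path)) stop("ENVI header not found: ", hdr_path)
  if (!file.exists(dat_path)) stop("ENVI data file not found: ", dat_path)
  hdr <- readLines(hdr_path)
  getv <- function(key) {
    ln <- grep(paste0("^", key, "\\s*="), hdr, value = TRUE)
    if (!length(ln)) stop("ENVI header missing field: ", key)
    trimws(sub(".*=", "", ln[1]))
  }
  samples <- as.integer(getv("samples"))
  lines_ <- as.integer(getv("lines"))
  bands <- as.integer(getv("bands"))
  if (as.integer(getv("data type")) != 5)
    stop("only ENVI data type 5 (double) is supported")
  if (tolower(getv("interleave")) != "bsq")
    stop("only BSQ interleave is supported")
  wl_txt <- paste(hdr[seq(grep("wavelength\\s*=", hdr)[1], length(hdr))],
                  collapse = " ")
  wl <- as.numeric(strsplit(gsub(".*\\{|\\}.*", "", wl_txt), ",")[[1]])
  if (length(wl) != bands) stop("wavelength count does not match band count")
  n_expect <- samples * lines_ * bands
  con <- file(dat_path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, "numeric", n = n_expect, size = 8,
                      endian = "little")
  if (length(raw_vals) != n_expect)
    stop("ENVI data size does not match header dimensions")
  vals <- array(0, dim = c(lines_, samples, bands))
  for (b in seq_len(bands)) {
    off <- (b - 1) * samples * lines_
    vals[, , b] <- matrix(raw_vals[(off + 1):(off + samples * lines_)],
                          nrow = lines_, byrow = TRUE)
  }
  steps <- diff(wl)
  grid <- if (length(wl) > 1 && max(steps) - min(steps) < 1e-6)
    band_grid(wl[1], wl[length(wl)], steps[1])
  else structure(list(wavelengths = wl, step = NA_real_), class = "band_grid")
  hypercube(vals, grid, metadata = list(source = dat_path))
}
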