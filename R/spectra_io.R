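# Peak-table and spectral-grid I/O shared by all downstream stages.
# Intensities are quantified by nine-point averaging (peak centre plus its
# eight neighbours) and uncertainties taken from the standard deviation of a
# signal-free spectral region, mirroring standard HSQC practice.

#' 15N/1H gyromagnetic frequency ratio
#'
#' Ratio of the 15N to the 1H resonance frequency; used to convert ppm to Hz
#' on the indirect dimension of an HSQC.
#' @keywords internal
.N15_FREQ_RATIO <- 0.10132905

#' Construct a 2D spectral intensity grid
#'
#' A minimal container for a processed 2D spectrum: a real intensity matrix
#' with per-axis digital resolution and ppm origins. Axis 1 (rows) is the
#' direct 1H dimension, axis 2 (columns) the indirect 15N dimension. The ppm
#' scale decreases with increasing index, as spectra are conventionally drawn.
#'
#' @param intensities numeric matrix of intensities, at least 3 x 3.
#' @param hz_per_point length-2 numeric, digital resolution (Hz/point) of
#'   axis 1 and axis 2; both must be positive.
#' @param origin_ppm length-2 numeric, ppm value of index (1, 1) on each axis.
#' @param sf_mhz spectrometer 1H resonance frequency in MHz (default 700).
#' @return an object of class \code{spectrum_grid}.
#' @examples
#' g <- spectrum_grid(matrix(0, 64, 64), c(6, 12), c(10.5, 133))
#' @export
spectrum_grid <- function(intensities, hz_per_point, origin_ppm,
                          sf_mhz = 700) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("'intensities' must be a numeric matrix")
  if (nrow(intensities) < 3L || ncol(intensities) < 3L)
    stop("grid must be at least 3 x 3")
  hz_per_point <- rep_len(as.numeric(hz_per_point), 2L)
  if (any(hz_per_point <= 0)) stop("hz_per_point must be positive")
  origin_ppm <- rep_len(as.numeric(origin_ppm), 2L)
  if (!is.numeric(sf_mhz) || length(sf_mhz) != 1L || sf_mhz <= 0)
    stop("sf_mhz must be a single positive number")
  structure(
    list(intensities = intensities, hz_per_point = hz_per_point,
         origin_ppm = origin_ppm, sf_mhz = sf_mhz),
    class = "spectrum_grid")
}

#' @export
print.spectrum_grid <- function(x, ...) {
  cat(sprintf("<spectrum_grid> %d x %d points, %.3f / %.3f Hz per point, %g MHz\n",
              nrow(x$intensities), ncol(x$intensities),
              x$hz_per_point[1], x$hz_per_point[2], x$sf_mhz))
  invisible(x)
}

# axis Larmor frequencies in MHz: axis 1 = 1H, axis 2 = 15N
.axis_freq_mhz <- function(grid) c(grid$sf_mhz, grid$sf_mhz * .N15_FREQ_RATIO)

#' Convert ppm coordinates to Hz offsets on a grid axis
#'
#' @param grid a \code{\link{spectrum_grid}}.
#' @param ppm ppm values.
#' @param axis 1 (1H, rows) or 2 (15N, columns).
#' @return offsets in Hz relative to the axis origin.
#' @export
ppm_to_hz <- function(grid, ppm, axis = 1) {
  axis <- as.integer(axis)
  stopifnot(axis %in% c(1L, 2L))
  (grid$origin_ppm[axis] - ppm) * .axis_freq_mhz(grid)[axis]
}

#' @rdname ppm_to_hz
#' @param hz Hz offsets relative to the axis origin.
#' @export
hz_to_ppm <- function(grid, hz, axis = 1) {
  axis <- as.integer(axis)
  stopifnot(axis %in% c(1L, 2L))
  grid$origin_ppm[axis] - hz / .axis_freq_mhz(grid)[axis]
}

# round half away from zero (so ties never depend on IEEE round-to-even)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Nearest grid index for a ppm coordinate pair
#'
#' The peak centre on the digital grid is the grid point nearest to the given
#' (1H ppm, 15N ppm) position, with half-way ties rounded away from zero.
#'
#' @param grid a \code{\link{spectrum_grid}}.
#' @param h_ppm,n_ppm peak position in ppm.
#' @return integer vector \code{c(row, col)}.
#' @export
nearest_grid_point <- function(grid, h_ppm, n_ppm) {
  f <- .axis_freq_mhz(grid)
  i <- .round_half_away((grid$origin_ppm[1] - h_ppm) * f[1] / grid$hz_per_point[1]) + 1
  j <- .round_half_away((grid$origin_ppm[2] - n_ppm) * f[2] / grid$hz_per_point[2]) + 1
  c(as.integer(i), as.integer(j))
}

#' Nine-point peak intensity
#'
#' Quantifies a peak as the arithmetic mean of the intensities of the peak
#' centre and its eight surrounding grid points (a 3 x 3 block).
#'
#' @param grid a \code{\link{spectrum_grid}}.
#' @param center integer vector \code{c(row, col)}; must lie at least one
#'   point away from every grid edge.
#' @return the mean intensity over the 3 x 3 block.
#' @examples
#' g <- spectrum_grid(matrix(2, 5, 5), c(5, 10), c(10, 130))
#' nine_point_intensity(g, c(3, 3))  # 2
#' @export
nine_point_intensity <- function(grid, center) {
  stopifnot(inherits(grid, "spectrum_grid"))
  center <- as.integer(center)
  if (length(center) != 2L) stop("'center' must be an index pair (row, col)")
  d <- dim(grid$intensities)
  if (center[1] < 2L || center[1] > d[1] - 1L ||
      center[2] < 2L || center[2] > d[2] - 1L)
    stop(sprintf("peak centre (%d, %d) is on or outside the grid edge; nine-point averaging needs a 1-point margin",
                 center[1], center[2]))
  mean(grid$intensities[(center[1] - 1L):(center[1] + 1L),
                        (center[2] - 1L):(center[2] + 1L)])
}

#' Spectral noise from a signal-free region
#'
#' Estimates the intensity noise as the sample standard deviation (n - 1
#' denominator) of a rectangular spectral region containing no peaks.
#'
#' @param grid a \code{\link{spectrum_grid}}.
#' @param region integer vector \code{c(row_min, row_max, col_min, col_max)};
#'   must lie within the grid and contain at least 16 points.
#' @return the noise standard deviation.
#' @export
estimate_noise <- function(grid, region) {
  stopifnot(inherits(grid, "spectrum_grid"))
  region <- as.integer(region)
  if (length(region) != 4L) stop("'region' must be c(row_min, row_max, col_min, col_max)")
  d <- dim(grid$intensities)
  if (region[1] < 1L || region[2] > d[1] || region[3] < 1L || region[4] > d[2] ||
      region[1] > region[2] || region[3] > region[4])
    stop("noise region lies outside the grid")
  n_pts <- (region[2] - region[1] + 1L) * (region[4] - region[3] + 1L)
  if (n_pts < 16L)
    stop(sprintf("noise region has %d points; at least 16 are required", n_pts))
  sd(grid$intensities[region[1]:region[2], region[3]:region[4]])
}

#' Construct a peak table
#'
#' One row per assigned backbone amide: residue number (author numbering),
#' residue name, peak position in ppm, quantified intensity and its
#' uncertainty. A non-empty condition label records what the table belongs to
#' (a ligand concentration, a relaxation delay, a para/dia state, ...).
#'
#' @param residue_id integer residue numbers; must be unique.
#' @param residue_name residue codes (one- or three-letter).
#' @param h_ppm,n_ppm peak positions in ppm.
#' @param intensity peak intensities.
#' @param intensity_sd intensity uncertainties; non-negative. Default 0.
#' @param condition non-empty condition label.
#' @return a \code{data.frame} of class \code{peak_table} with the condition
#'   stored as attribute \code{"condition"}.
#' @export
peak_table <- function(residue_id, residue_name, h_ppm, n_ppm, intensity,
                       intensity_sd = 0, condition) {
  residue_id <- as.integer(residue_id)
  n <- length(residue_id)
  if (anyDuplicated(residue_id)) {
    dup <- residue_id[duplicated(residue_id)][1]
    stop(sprintf("duplicate residue_id %d in peak table", dup))
  }
  if (missing(condition) || !nzchar(condition))
    stop("a non-empty condition label is required")
  intensity_sd <- rep_len(as.numeric(intensity_sd), n)
  if (any(intensity_sd < 0)) stop("intensity_sd must be non-negative")
  tab <- data.frame(residue_id = residue_id,
                    residue_name = as.character(rep_len(residue_name, n)),
                    h_ppm = as.numeric(h_ppm), n_ppm = as.numeric(n_ppm),
                    intensity = as.numeric(intensity),
                    intensity_sd = intensity_sd,
                    stringsAsFactors = FALSE)
  attr(tab, "condition") <- as.character(condition)
  class(tab) <- c("peak_table", "data.frame")
  tab
}

.PEAK_COLS <- c("residue_id", "residue_name", "h_ppm", "n_ppm",
                "intensity", "intensity_sd")

#' Read a peak table from a tab-separated file
#'
#' The dialect is tab-separated with the header
#' \code{residue_id residue_name h_ppm n_ppm intensity intensity_sd};
#' \code{#}-prefixed lines are comments, and a \code{# condition:} comment
#' carries the condition label.
#'
#' @param path file to read.
#' @param condition condition label; if \code{NULL} (default) it is taken
#'   from a \code{# condition:} comment line, falling back to the file name.
#' @return a \code{\link{peak_table}}.
#' @export
read_peak_table <- function(path, condition = NULL) {
  if (!file.exists(path)) stop(sprintf("peak table '%s' does not exist", path))
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  if (is.null(condition)) {
    cond_line <- grep("^\\s*#\\s*condition:", lines, value = TRUE)
    condition <- if (length(cond_line))
      trimws(sub("^\\s*#\\s*condition:", "", cond_line[1])) else basename(path)
  }
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (!length(body_idx)) stop(sprintf("'%s' has no header row", path))
  header <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(trimws(header), .PEAK_COLS))
    stop(sprintf("'%s': header must be '%s'", path,
                 paste(.PEAK_COLS, collapse = "\t")))
  data_idx <- body_idx[-1]
  rows <- lapply(data_idx, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 6L)
      stop(sprintf("'%s' line %d: expected 6 tab-separated fields, got %d",
                   path, i, length(f)))
    num <- suppressWarnings(as.numeric(f[c(1, 3, 4, 5, 6)]))
    if (anyNA(num))
      stop(sprintf("'%s' line %d: malformed numeric field", path, i))
    list(id = num[1], name = f[2], vals = num[-1])
  })
  ids <- vapply(rows, `[[`, numeric(1), "id")
  if (anyDuplicated(ids))
    stop(sprintf("'%s': duplicate residue_id %d", path,
                 as.integer(ids[duplicated(ids)][1])))
  vals <- do.call(rbind, lapply(rows, `[[`, "vals"))
  if (is.null(vals)) vals <- matrix(numeric(0), 0, 4)
  peak_table(residue_id = ids,
             residue_name = vapply(rows, `[[`, character(1), "name"),
             h_ppm = vals[, 1], n_ppm = vals[, 2],
             intensity = vals[, 3], intensity_sd = vals[, 4],
             condition = condition)
}

#' Write a peak table
#'
#' Writes the tab-separated dialect read by \code{\link{read_peak_table}}.
#' Numeric fields are written with 17 significant digits so that finite
#' doubles round-trip exactly.
#'
#' @param table a \code{\link{peak_table}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_peak_table <- function(table, path) {
  stopifnot(inherits(table, "peak_table"))
  fmt <- function(x) sprintf("%.17g", x)
  lines <- c(sprintf("# condition: %s", attr(table, "condition")),
             paste(.PEAK_COLS, collapse = "\t"))
  if (nrow(table))
    lines <- c(lines, paste(table$residue_id, table$residue_name,
                            fmt(table$h_ppm), fmt(table$n_ppm),
                            fmt(table$intensity), fmt(table$intensity_sd),
                            sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a spectral grid as plain text
#'
#' A deliberately minimal text format for processed 2D spectra: header
#' comment lines carrying dimensions, digital resolution, ppm origins and the
#' spectrometer frequency, followed by the intensity matrix, one row per
#' line, whitespace-separated.
#'
#' @param path file to read or write.
#' @return \code{read_spectrum_grid} returns a \code{\link{spectrum_grid}}.
#' @export
read_spectrum_grid <- function(path) {
  if (!file.exists(path)) stop(sprintf("spectrum file '%s' does not exist", path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stop(sprintf("'%s': missing header '%s'", path, key))
    as.numeric(strsplit(trimws(sub(".*:", "", ln[1])), "\\s+")[[1]])
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  mat <- do.call(rbind, lapply(body, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  spectrum_grid(mat, hz_per_point = get("hz_per_point"),
                origin_ppm = get("origin_ppm"), sf_mhz = get("sf_mhz")[1])
}

#' @rdname read_spectrum_grid
#' @param grid a \code{\link{spectrum_grid}} to write.
#' @export
write_spectrum_grid <- function(grid, path) {
  stopifnot(inherits(grid, "spectrum_grid"))
  hdr <- c(sprintf("# dims: %d %d", nrow(grid$intensities), ncol(grid$intensities)),
           sprintf("# hz_per_point: %.17g %.17g", grid$hz_per_point[1], grid$hz_per_point[2]),
           sprintf("# origin_ppm: %.17g %.17g", grid$origin_ppm[1], grid$origin_ppm[2]),
           sprintf("# sf_mhz: %.17g", grid$sf_mhz))
  body <- apply(grid$intensities, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
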