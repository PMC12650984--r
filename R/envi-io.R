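#' Write a cube as ENVI header + band-sequential binary
#'
#' Writes `<prefix>.hdr` (plain-text ENVI header with samples, lines,
#' bands, interleave and the wavelength list) and `<prefix>.dat`
#' (band-sequential little-endian 32-bit floats). ENVI stores `samples` as
#' image columns and `lines` as rows.
#'
#' @param data 3-D numeric array, rows x cols x bands.
#' @param wavelengths Numeric vector of band centres in nm.
#' @param prefix File path prefix (without extension).
#' @return The prefix, invisibly.
#' @export
write_envi <- function(data, wavelengths, prefix) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(wavelengths))
  d <- dim(data)
  hdr <- c(
    "ENVI",
    "description = {hyperbrix export}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {",
           paste(format(wavelengths, trim = TRUE, digits = 10),
                 collapse = ", "), "}")
  )
  writeLines(hdr, paste0(prefix, ".hdr"))
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  # BSQ: band-major; within a band ENVI is row-major (line by line)
  for (b in seq_len(d[3])) {
    writeBin(as.numeric(t(data[, , b])), con, size = 4, endian = "little")
  }
  invisible(prefix)
}

#' Read an ENVI header + band-sequential binary cube
#'
#' Counterpart of [write_envi()]. Supports BSQ interleave with 32-bit
#' float (data type 4) or 64-bit float (data type 5) samples.
#'
#' @param prefix File path prefix (without extension).
#' @return A list with `data` (rows x cols x bands array) and
#'   `wavelengths` (nm vector, or `NULL` if the header has none).
#' @export
read_envi <- function(prefix) {
  hdr_path <- paste0(prefix, ".hdr")
  if (!file.exists(hdr_path)) stop("no header file: ", hdr_path, call. = FALSE)
  hdr <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  field <- function(name) {
    m <- regmatches(hdr, regexec(paste0(name, "\\s*=\\s*([0-9]+)"), hdr))[[1]]
    if (length(m) < 2) stop("ENVI header missing field: ", name, call. = FALSE)
    as.integer(m[2])
  }
  samples <- field("samples"); lines <- field("lines"); bands <- field("bands")
  dtype <- field("data type")
  if (!dtype %in% c(4L, 5L)) {
    stop("unsupported ENVI data type ", dtype, " (need 4 or 5)", call. = FALSE)
  }
  interleave <- regmatches(hdr,
    regexec("interleave\\s*=\\s*(\\w+)", hdr))[[1]][2]
  if (!identical(tolower(interleave), "bsq")) {
    stop("unsupported interleave '", interleave, "' (need bsq)", call. = FALSE)
  }
  wl <- NULL
  wm <- regmatches(hdr, regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", hdr))[[1]]
  if (length(wm) == 2) {
    wl <- as.numeric(strsplit(wm[2], ",")[[1]])
  }
  size <- if (dtype == 4L) 4L else 8L
  con <- file(paste0(prefix, ".dat"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = samples * lines * bands,
                  size = size, endian = "little")
  data <- array(0, dim = c(lines, samples, bands))
  per_band <- samples * lines
  for (b in seq_len(bands)) {
    data[, , b] <- t(matrix(vals[(b - 1) * per_band + seq_len(per_band)],
                            samples, lines))
  }
  list(data = data, wavelengths = wl)
}

#' Write a synthetic dataset to disk
#'
#' Writes each cube's raw, white-reference and black-reference components
#' as ENVI files (`<id>_raw`, `<id>_white`, `<id>_black`) plus
#' `labels.csv` with columns `sample_id`, `ssc_brix`, `split`.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(dataset$cubes)) {
    cube <- dataset$cubes[[id]]
    write_envi(cube$raw, cube$wavelengths, file.path(dir, paste0(id, "_raw")))
    write_envi(cube$white_ref, cube$wavelengths,
               file.path(dir, paste0(id, "_white")))
    write_envi(cube$black_ref, cube$wavelengths,
               file.path(dir, paste0(id, "_black")))
  }
  utils::write.csv(dataset$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  invisible(dir)
}
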