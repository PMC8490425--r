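#' Write a cube in ENVI format
#'
#' Writes `<path>.hdr` (text header: samples/lines/bands, interleave, data
#' type, byte order, wavelength list to 4 decimals) and `<path>.raw` (raw
#' binary). Defaults: BSQ interleave, little-endian, float32 reflectance.
#'
#' @param cube `hs_cube`.
#' @param path base path; `.hdr` and `.raw` extensions are appended.
#' @param interleave `"bsq"`, `"bil"` or `"bip"`.
#' @param data_type ENVI data type code: 4 (float32) or 5 (float64).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       data_type = 4L) {
  interleave <- match.arg(interleave)
  if (!data_type %in% c(4L, 5L)) stop("data type must be 4 or 5")
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    sprintf("description = {hsifuse %s cube}", cube$modality),
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(sprintf("%.4f", cube$wavelengths), collapse = ", "))
  )
  ok <- tryCatch({
    writeLines(hdr, paste0(path, ".hdr"))
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write header at ", path, ".hdr")
  # reorder (row, col, band) into the requested on-disk order
  v <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),  # col, row, band
    bil = as.vector(aperm(cube$data, c(2, 3, 1))),  # col, band, row
    bip = as.vector(aperm(cube$data, c(3, 2, 1))))  # band, col, row
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(v), con, size = if (data_type == 4L) 4L else 8L,
           endian = "little")
  invisible(path)
}

#' Read a cube from ENVI format
#'
#' Parses a `.hdr` text header plus the companion raw binary. Supports BSQ,
#' BIL and BIP interleaves, float32/float64 data, and the brace-delimited
#' wavelength list (which may span lines).
#'
#' @param path base path (as given to [write_envi()]) or the `.hdr` path.
#' @param modality modality tag for the result, or `NULL` to guess from the
#'   header description.
#' @return `hs_cube`.
#' @export
read_envi <- function(path, modality = NULL) {
  base <- sub("\\.hdr$", "", path)
  hdr_path <- paste0(base, ".hdr")
  raw_path <- paste0(base, ".raw")
  if (!file.exists(hdr_path)) stop("header not found: ", hdr_path)
  if (!file.exists(raw_path)) stop("raw file not found: ", raw_path)
  fields <- parse_envi_header(hdr_path)
  for (f in c("samples", "lines", "bands", "data type", "interleave"))
    if (is.null(fields[[f]]))
      stop("ENVI header missing required field: ", f)
  ns <- as.integer(fields$samples); nl <- as.integer(fields$lines)
  nb <- as.integer(fields$bands)
  dt <- as.integer(fields[["data type"]])
  if (!dt %in% c(4L, 5L)) stop("unsupported ENVI data type: ", dt)
  il <- tolower(fields$interleave)
  if (!il %in% c("bsq", "bil", "bip")) stop("unsupported interleave: ", il)
  if (is.null(fields$wavelength))
    stop("ENVI header missing required field: wavelength")
  w <- as.numeric(strsplit(gsub("[{}]", "", fields$wavelength), ",")[[1]])
  if (length(w) != nb)
    stop("header declares ", nb, " bands but lists ", length(w),
         " wavelengths")
  n <- ns * nl * nb
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = n, size = if (dt == 4L) 4L else 8L,
               endian = "little")
  if (length(v) != n)
    stop("raw file holds ", length(v), " values, header implies ", n)
  arr <- switch(il,
    bsq = aperm(array(v, c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(v, c(ns, nb, nl)), c(3, 1, 2)),
    bip = aperm(array(v, c(nb, ns, nl)), c(3, 2, 1)))
  if (is.null(modality)) {
    desc <- fields$description %||% ""
    modality <- if (grepl("NIR cube", desc) && !grepl("VNIR", desc)) "NIR"
                else if (grepl("FUSED", desc)) "FUSED" else "VNIR"
  }
  hs_cube(arr, w, modality, meta = list(source = base, interleave = il))
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  fields <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("=", ln, fixed = TRUE)) {
      key <- tolower(trimws(sub("=.*", "", ln)))
      val <- trimws(sub("^[^=]*=", "", ln))
      # brace-delimited values may continue on following lines
      if (grepl("\\{", val)) {
        while (!grepl("\\}", val) && i < length(lines)) {
          i <- i + 1L
          val <- paste(val, trimws(lines[i]))
        }
      }
      fields[[key]] <- val
    }
    i <- i + 1L
  }
  fields
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a label map as PNG plus JSON sidecar
#'
#' The PNG stores the class index in the 8-bit gray channel (0 =
#' unlabeled); `<path>.json` names the classes.
#'
#' @param lm `label_map`.
#' @param path base path; `.png` and `.json` are appended.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(lm, path) {
  if (max(lm$labels) > 255L) stop("more than 255 classes not supported")
  png::writePNG(lm$labels / 255, paste0(path, ".png"))
  jsonlite::write_json(list(class_names = lm$class_names),
                       paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#' @param path base path.
#' @return `label_map`.
#' @export
read_label_map <- function(path) {
  img <- png::readPNG(paste0(path, ".png"))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  label_map(round(img * 255), side$class_names)
}
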