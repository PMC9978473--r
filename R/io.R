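#' Read a label volume from NIfTI or NRRD
#'
#' Supported formats are NIfTI-1 (`.nii`, `.nii.gz`) and NRRD (`.nrrd`),
#' selected by file extension. The image must be 3D and integer-valued; voxel
#' spacing is taken from the header. When a taxonomy is supplied, every value
#' must be the background value or a declared label value.
#'
#' @param path input file.
#' @param taxonomy optional [level_taxonomy()] used for validation.
#' @param slice_axis,lr_axis axis conventions, see [label_volume()].
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, taxonomy = NULL,
                              slice_axis = 3L, lr_axis = 1L) {
  img <- read_image(path)
  if (length(img$dim) != 3L)
    stop("expected a 3D image, got ", length(img$dim), "D: ", path)
  if (any(img$array != round(img$array)))
    stop("label image contains non-integer values: ", path)
  label_volume(img$array, img$spacing, slice_axis = slice_axis,
               lr_axis = lr_axis, taxonomy = taxonomy)
}

#' Write a label volume to NIfTI or NRRD
#'
#' Round-trips exactly: [read_label_volume()] on the written file recovers the
#' identical array and spacing. Labels are stored as 32-bit integers.
#'
#' @param volume a [label_volume()].
#' @param path output file (`.nii`, `.nii.gz` or `.nrrd`); its parent
#'   directory must exist.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "label_volume"))
  write_image(volume$array, volume$spacing, path, integer = TRUE)
  invisible(path)
}

#' Read an intensity (CT-like) volume
#'
#' @inheritParams read_label_volume
#' @return An [intensity_volume()].
#' @export
read_intensity_volume <- function(path, slice_axis = 3L, lr_axis = 1L) {
  img <- read_image(path)
  if (length(img$dim) != 3L)
    stop("expected a 3D image, got ", length(img$dim), "D: ", path)
  intensity_volume(img$array, img$spacing, slice_axis = slice_axis,
                   lr_axis = lr_axis)
}

#' Write an intensity volume
#'
#' @param volume an [intensity_volume()].
#' @param path output file (`.nii`, `.nii.gz` or `.nrrd`).
#' @return `path`, invisibly.
#' @export
write_intensity_volume <- function(volume, path) {
  stopifnot(inherits(volume, "intensity_volume"))
  write_image(volume$array, volume$spacing, path, integer = FALSE)
  invisible(path)
}

# ---- format dispatch ------------------------------------------------------

image_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  if (grepl("\\.nrrd$", lower)) return("nrrd")
  stop("unsupported image format (use .nii, .nii.gz or .nrrd): ", path)
}

read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  switch(image_format(path),
         nifti = {
           img <- RNifti::readNifti(path)
           d <- dim(img)
           list(array = array(as.numeric(img), dim = d), dim = d,
                spacing = RNifti::pixdim(img)[seq_along(d)])
         },
         nrrd = read_nrrd(path))
}

write_image <- function(arr, spacing, path, integer) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  switch(image_format(path),
         nifti = {
           if (integer) storage.mode(arr) <- "integer"
           img <- RNifti::asNifti(arr)
           RNifti::pixdim(img) <- spacing
           RNifti::writeNifti(img, path,
                              datatype = if (integer) "int32" else "float")
         },
         nrrd = write_nrrd(arr, spacing, path, integer = integer))
  invisible(path)
}

# ---- minimal NRRD0004 support ---------------------------------------------
# Covers the subset this package writes: 3D, little-endian raw or ascii
# encoding, per-axis "spacings". Axis order matches R column-major storage
# (first axis fastest), which is NRRD's convention.

write_nrrd <- function(arr, spacing, path, integer, encoding = "raw") {
  type <- if (integer) "int32" else "double"
  header <- c(
    "NRRD0004",
    "# minimal NRRD written by levelpost",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dim(arr), collapse = " ")),
    paste0("spacings: ", paste(format(spacing, digits = 17), collapse = " ")),
    paste0("encoding: ", encoding),
    if (encoding == "raw") "endian: little"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, ""), con, sep = "\n")
  if (encoding == "raw") {
    if (integer) {
      writeBin(as.integer(arr), con, size = 4L, endian = "little")
    } else {
      writeBin(as.double(arr), con, size = 8L, endian = "little")
    }
  } else {
    writeLines(paste(format(as.vector(arr), digits = 17), collapse = " "), con)
  }
  invisible(path)
}

read_nrrd <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  # header ends at the first blank line
  nl <- which(bytes == as.raw(10L))
  hdr_end <- NA_integer_
  prev <- 0L
  for (i in nl) {
    if (i == prev + 1L) { hdr_end <- i; break }
    prev <- i
  }
  if (is.na(hdr_end)) stop("malformed NRRD (no blank line after header): ", path)
  hdr <- strsplit(rawToChar(bytes[seq_len(hdr_end - 1L)]), "\n")[[1]]
  if (!grepl("^NRRD", hdr[1])) stop("not an NRRD file: ", path)
  hdr <- hdr[-1]
  hdr <- hdr[!grepl("^#", hdr) & nzchar(hdr)]
  fields <- list()
  for (line in hdr) {
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  need <- c("type", "dimension", "sizes", "encoding")
  miss <- setdiff(need, names(fields))
  if (length(miss)) stop("NRRD header missing field(s): ",
                         paste(miss, collapse = ", "))
  if (fields$dimension != "3") stop("only 3D NRRD supported, got dimension ",
                                    fields$dimension)
  sizes <- as.integer(strsplit(fields$sizes, "[ \t]+")[[1]])
  n <- prod(sizes)
  spacing <- if (!is.null(fields$spacings)) {
    as.numeric(strsplit(fields$spacings, "[ \t]+")[[1]])
  } else rep(1, 3)
  type <- fields$type
  enc <- fields$encoding
  data_raw <- bytes[(hdr_end + 1L):length(bytes)]
  vals <- if (enc %in% c("raw")) {
    endian <- if (!is.null(fields$endian)) fields$endian else "little"
    switch(type,
           "int32" = , "int" = readBin(data_raw, "integer", n, size = 4L,
                                       endian = endian),
           "int16" = , "short" = readBin(data_raw, "integer", n, size = 2L,
                                         endian = endian),
           "uint8" = , "uchar" = as.integer(data_raw[seq_len(n)]),
           "double" = readBin(data_raw, "double", n, size = 8L,
                              endian = endian),
           "float" = readBin(data_raw, "double", n, size = 4L,
                             endian = endian),
           stop("unsupported NRRD type: ", type))
  } else if (enc %in% c("ascii", "text", "txt")) {
    as.numeric(strsplit(trimws(rawToChar(data_raw)), "[ \t\n\r]+")[[1]])
  } else {
    stop("unsupported NRRD encoding: ", enc)
  }
  if (length(vals) < n) stop("NRRD data truncated: ", path)
  list(array = array(as.numeric(vals[seq_len(n)]), dim = sizes),
       dim = sizes, spacing = spacing)
}
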