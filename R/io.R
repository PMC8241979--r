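#' Read a density volume from disk
#'
#' Supports MetaImage (`.mhd` + `.raw`), NIfTI (`.nii` / `.nii.gz`) and
#' multi-page TIFF stacks. Voxel size is taken from the file header; TIFF
#' carries no physical spacing, so it is read from a JSON sidecar
#' (`<file>.json` with a `voxel_size_mm` field) or from the `voxel_size`
#' argument. The voxel finite-element mesh requires cubic voxels, so
#' anisotropic spacing is rejected.
#'
#' @param path Path to the image file.
#' @param format One of `"auto"`, `"mhd"`, `"nifti"`, `"tiff"`.
#' @param voxel_size Voxel size in mm; mandatory for TIFF without a sidecar,
#'   ignored (header wins) otherwise.
#' @return A [density_volume()].
#' @export
read_volume <- function(path, format = c("auto", "mhd", "nifti", "tiff"),
                        voxel_size = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    mhd = read_mhd(path),
    nifti = read_nifti(path, voxel_size),
    tiff = read_tiff_stack(path, voxel_size),
    stop("unknown volume format for ", path, call. = FALSE)
  )
}

guess_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.mhd$", lp)) return("mhd")
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.tiff?$", lp)) return("tiff")
  stop("cannot infer volume format from extension of ", path, call. = FALSE)
}

#' Write a density volume to disk
#'
#' Format is chosen from the file extension (see [read_volume()]). MetaImage
#' writes a text `.mhd` header plus a `.raw` little-endian payload; NIfTI
#' stores the voxel size in `pixdim`; TIFF writes a 32-bit float multi-page
#' stack plus a JSON sidecar with the voxel size.
#'
#' @param vol A [density_volume()].
#' @param path Output path.
#' @param format One of `"auto"`, `"mhd"`, `"nifti"`, `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "mhd", "nifti", "tiff")) {
  assert_volume(vol)
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    mhd = write_mhd(vol, path),
    nifti = write_nifti(vol, path),
    tiff = write_tiff_stack(vol, path)
  )
  invisible(path)
}

# --- MetaImage (.mhd/.raw): minimal text header + raw payload ---------------

write_mhd <- function(vol, path) {
  raw_path <- sub("\\.mhd$", ".raw", path)
  if (identical(raw_path, path)) raw_path <- paste0(path, ".raw")
  d <- dim(vol)
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.10g %.10g %.10g",
            vol$voxel_size, vol$voxel_size, vol$voxel_size),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", basename(raw_path))
  )
  writeLines(header, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  writeBin(as.vector(vol$values), con, size = 8L, endian = "little")
  invisible(path)
}

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " = "), "")
  get <- function(k) vals[match(k, keys)]
  if (!identical(get("NDims"), "3")) {
    stop("only 3-D MetaImage volumes are supported", call. = FALSE)
  }
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  sp <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
  if (length(unique(signif(sp, 10))) != 1L) {
    stop("anisotropic voxels are unsupported (the voxel FE needs cubic voxels)",
         call. = FALSE)
  }
  type <- get("ElementType")
  size <- switch(type, MET_DOUBLE = 8L, MET_FLOAT = 4L,
                 stop("unsupported MetaImage ElementType: ", type, call. = FALSE))
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  n <- prod(dims)
  x <- readBin(con, "double", n = n, size = size, endian = "little")
  density_volume(array(x, dims), sp[1],
                 metadata = list(source = path, format = "mhd"))
}

# --- NIfTI via RNifti --------------------------------------------------------

write_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- rep(vol$voxel_size, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti <- function(path, voxel_size = NULL) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  if (max(sp) - min(sp) > 1e-9 * max(sp)) {
    stop("anisotropic voxels are unsupported (the voxel FE needs cubic voxels)",
         call. = FALSE)
  }
  vs <- if (sp[1] > 0) sp[1] else voxel_size
  if (is.null(vs)) stop("NIfTI header has no voxel size; pass `voxel_size`",
                        call. = FALSE)
  density_volume(array(as.numeric(img), dim(img)[1:3]), vs,
                 metadata = list(source = path, format = "nifti"))
}

# --- TIFF stack via the tiff package ----------------------------------------

write_tiff_stack <- function(vol, path) {
  nz <- dim(vol)[3L]
  # tiff wants row-major (y, x) planes in [0, 1]; store density / scale and
  # record the scale in the sidecar so physical units survive the round trip
  scale <- max(vol$values, 1)
  pages <- lapply(seq_len(nz), function(k) t(vol$values[, , k]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(voxel_size_mm = vol$voxel_size,
                            density_scale = scale),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_tiff_stack <- function(path, voxel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  a <- array(0, c(d[2], d[1], length(pages)))
  for (k in seq_along(pages)) a[, , k] <- t(pages[[k]])
  sidecar <- paste0(path, ".json")
  scale <- 1
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (is.null(voxel_size)) voxel_size <- meta$voxel_size_mm
    scale <- meta$density_scale %||% 1
  }
  if (is.null(voxel_size)) {
    stop("TIFF carries no voxel size; pass `voxel_size` or provide a sidecar",
         call. = FALSE)
  }
  density_volume(a * scale, voxel_size,
                 metadata = list(source = path, format = "tiff"))
}
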