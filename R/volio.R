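#' Voxel images and label maps
#'
#' A `voxel_image` is a 3D scalar lattice (Hounsfield units for CT) with an
#' axis-aligned world geometry: voxel `(i, j, k)` (1-based) has its *center*
#' at world position `origin + (c(i, j, k) - 1) * spacing` (mm). An axial
#' slice is a fixed `k`. A `label_map` is the same structure holding small
#' non-negative integers on the grid of a paired image; rotated (oblique)
#' geometries are deliberately unsupported.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, per-axis voxel spacing in mm (all > 0).
#' @param origin numeric length-3, world coordinates (mm) of voxel (1,1,1).
#' @return A `voxel_image` (or `label_map`) object.
#' @export
voxel_image <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L || any(dim(data) < 1L))
    stop_vamorph("data must be a non-empty 3D array", class = "vamorph_format_error")
  spacing <- as.double(spacing); origin <- as.double(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_vamorph("spacing must be 3 positive numbers", class = "vamorph_format_error")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop_vamorph("origin must be 3 finite numbers", class = "vamorph_format_error")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_image")
}

#' @rdname voxel_image
#' @export
label_map <- function(data, spacing, origin = c(0, 0, 0)) {
  img <- voxel_image(data, spacing, origin)
  storage.mode(img$data) <- "integer"
  if (any(img$data < 0L, na.rm = TRUE))
    stop_vamorph("label values must be non-negative", class = "vamorph_format_error")
  class(img) <- c("label_map", "voxel_image")
  img
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin (%s) mm\n",
              class(x)[1L], paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x"),
              paste(format(x$origin, digits = 4), collapse = ", ")))
  invisible(x)
}

#' Convert between voxel indices and world coordinates
#'
#' Indices are 1-based; the world position is the voxel center. Both accept
#' an `n x 3` matrix (or length-3 vector) and return the same shape.
#'
#' @param img a [voxel_image()].
#' @param index,world `n x 3` matrix or length-3 numeric.
#' @return `n x 3` matrix of world mm (`index_to_world`) or continuous
#'   1-based indices (`world_to_index`); `nearest_voxel` rounds and clamps
#'   to the lattice.
#' @export
index_to_world <- function(img, index) {
  index <- rbind3(index)
  sweep(sweep(index - 1, 2L, img$spacing, `*`), 2L, img$origin, `+`)
}

#' @rdname index_to_world
#' @export
world_to_index <- function(img, world) {
  world <- rbind3(world)
  sweep(sweep(world, 2L, img$origin, `-`), 2L, img$spacing, `/`) + 1
}

#' @rdname index_to_world
#' @export
nearest_voxel <- function(img, world) {
  idx <- round(world_to_index(img, world))
  dm <- dim(img$data)
  for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 1), dm[a])
  storage.mode(idx) <- "integer"
  idx
}

rbind3 <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.double(x), nrow = 1L)
  if (ncol(x) != 3L) stop_vamorph("expected 3 columns", class = "vamorph_format_error")
  x
}

in_bounds <- function(img, world) {
  idx <- world_to_index(img, world)
  dm <- dim(img$data)
  all(idx >= 0.5 & sweep(idx, 2L, dm + 0.5, `<`))
}

#' Read and write volumetric images
#'
#' NIfTI-1 (`.nii`, `.nii.gz`) is handled through the RNifti library;
#' MetaImage (`.mha`, uncompressed, local data) through a minimal built-in
#' codec. Values round-trip bit-exactly and geometry to <= 1e-6 mm. A
#' volume whose stored transform contains a rotation (oblique acquisition)
#' raises an unsupported-geometry error: the package's world model is
#' axis-aligned.
#'
#' @param path file path ending in `.nii`, `.nii.gz`, or `.mha`.
#' @param image a [voxel_image()].
#' @return `read_image`: a `voxel_image`. `write_image`: `path`, invisibly.
#' @export
read_image <- function(path) {
  ext <- image_ext(path)
  if (!file.exists(path))
    stop_vamorph("no such file: %s", path, class = "vamorph_format_error")
  if (ext == "mha") return(read_mha(path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_vamorph("malformed NIfTI file %s: %s",
                                                   path, conditionMessage(e),
                                                   class = "vamorph_format_error"))
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-6 || any(diag(rot) <= 0))
    stop_vamorph("rotated/oblique NIfTI geometry is unsupported",
                 class = "vamorph_geometry_error")
  arr <- array(as.double(img), dim = dim(img))
  if (length(dim(arr)) != 3L)
    stop_vamorph("expected a 3D volume in %s", path, class = "vamorph_format_error")
  voxel_image(arr, spacing = diag(rot), origin = xf[1:3, 4])
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "voxel_image"))
  ext <- image_ext(path)
  if (ext == "mha") return(write_mha(image, path))
  arr <- image$data
  storage.mode(arr) <- "double"
  nim <- RNifti::asNifti(arr)
  nim <- RNifti::`pixdim<-`(nim, image$spacing)
  m <- diag(c(image$spacing, 1))
  m[1:3, 4] <- image$origin
  nim <- RNifti::`sform<-`(nim, structure(m, code = 2L))
  nim <- RNifti::`qform<-`(nim, structure(m, code = 2L))
  RNifti::writeNifti(nim, path)
  invisible(path)
}

image_ext <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nii")
  if (grepl("\\.mha$", low)) return("mha")
  stop_vamorph("unknown image extension in '%s' (use .nii, .nii.gz, .mha)",
               path, class = "vamorph_format_error")
}

# --- MetaImage (.mha), the minimal axis-aligned subset -----------------------

write_mha <- function(image, path) {
  dm <- dim(image$data)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %.9g %.9g %.9g", image$origin[1], image$origin[2], image$origin[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g", image$spacing[1], image$spacing[2], image$spacing[3]),
    sprintf("DimSize = %d %d %d", dm[1], dm[2], dm[3]),
    "ElementType = MET_DOUBLE",
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(as.double(image$data), con, size = 8L, endian = "little")
  invisible(path)
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list(); raw_line <- function() {
    out <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0L || b == as.raw(10L)) break
      if (b == as.raw(0L) || length(out) > 4096L)
        stop_vamorph("malformed MetaImage header in %s", path,
                     class = "vamorph_format_error")
      out <- c(out, b)
    }
    rawToChar(out)
  }
  repeat {
    ln <- raw_line()
    if (!grepl("=", ln, fixed = TRUE))
      stop_vamorph("malformed MetaImage header in %s", path, class = "vamorph_format_error")
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L]); val <- trimws(paste(kv[-1L], collapse = "="))
    fields[[key]] <- val
    if (key == "ElementDataFile") break
  }
  need <- c("ObjectType", "DimSize", "ElementSpacing", "ElementType", "ElementDataFile")
  if (!all(need %in% names(fields)) || fields$ObjectType != "Image")
    stop_vamorph("not a MetaImage volume: %s", path, class = "vamorph_format_error")
  if (fields$ElementDataFile != "LOCAL")
    stop_vamorph("only LOCAL MetaImage data supported", class = "vamorph_format_error")
  if (!is.null(fields$CompressedData) && tolower(fields$CompressedData) == "true")
    stop_vamorph("compressed MetaImage unsupported", class = "vamorph_format_error")
  tm <- fields$TransformMatrix
  if (!is.null(tm) &&
      max(abs(as.double(strsplit(tm, "\\s+")[[1L]]) - c(1,0,0,0,1,0,0,0,1))) > 1e-6)
    stop_vamorph("rotated/oblique MetaImage geometry is unsupported",
                 class = "vamorph_geometry_error")
  dm <- as.integer(strsplit(fields$DimSize, "\\s+")[[1L]])
  spacing <- as.double(strsplit(fields$ElementSpacing, "\\s+")[[1L]])
  origin <- if (is.null(fields$Offset)) c(0, 0, 0)
            else as.double(strsplit(fields$Offset, "\\s+")[[1L]])
  type <- fields$ElementType
  sz <- switch(type, MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_SHORT = 2L,
               MET_USHORT = 2L, MET_UCHAR = 1L,
               stop_vamorph("unsupported MetaImage ElementType %s", type,
                            class = "vamorph_format_error"))
  what <- if (type %in% c("MET_DOUBLE", "MET_FLOAT")) "double" else "integer"
  vals <- readBin(con, what, n = prod(dm), size = sz, endian = "little",
                  signed = !(type %in% c("MET_USHORT", "MET_UCHAR")))
  if (length(vals) != prod(dm))
    stop_vamorph("truncated MetaImage payload in %s", path, class = "vamorph_format_error")
  voxel_image(array(as.double(vals), dim = dm), spacing = spacing, origin = origin)
}
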