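#' Write a volume as MetaImage (.mha)
#'
#' Single-file MetaImage: ASCII header followed by little-endian raw voxel
#' data. Spacing is stored in millimetres.
#'
#' @param values 3D numeric (or integer) array.
#' @param path Output file path (conventionally `.mha`).
#' @param voxel_size Voxel edge, micrometres.
#' @param type `"float"`, `"double"` or `"uchar"`.
#' @return `path`, invisibly.
#' @export
write_mha <- function(values, path, voxel_size, type = c("float", "double",
                                                         "uchar")) {
  type <- match.arg(type)
  d <- dim(values)
  stopifnot(length(d) == 3L)
  met <- c(float = "MET_FLOAT", double = "MET_DOUBLE", uchar = "MET_UCHAR")[type]
  sp <- voxel_size / 1000
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1", "Offset = 0 0 0",
           sprintf("ElementSpacing = %.9g %.9g %.9g", sp, sp, sp),
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           sprintf("ElementType = %s", met),
           "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  v <- as.vector(values)
  if (type == "uchar") {
    writeBin(as.integer(v), con, size = 1L, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = if (type == "float") 4L else 8L,
             endian = "little")
  }
  invisible(path)
}

#' Read a MetaImage (.mha) volume
#'
#' Supports uncompressed local-data files as written by [write_mha()].
#'
#' @param path File path.
#' @return List with `values` (3D array) and `voxel_size` (micrometres).
#' @export
read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only single-file (LOCAL) MetaImage volumes are supported")
  if (identical(hdr[["CompressedData"]], "True"))
    stop("compressed MetaImage volumes are not supported")
  d <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])[1]
  n <- prod(d)
  v <- switch(hdr[["ElementType"]],
              MET_FLOAT = readBin(con, numeric(), n, size = 4L,
                                  endian = "little"),
              MET_DOUBLE = readBin(con, numeric(), n, size = 8L,
                                   endian = "little"),
              MET_UCHAR = as.numeric(readBin(con, integer(), n, size = 1L,
                                             signed = FALSE,
                                             endian = "little")),
              stop("unsupported ElementType ", hdr[["ElementType"]]))
  list(values = array(v, d), voxel_size = sp * 1000)
}

#' Write a density image as MetaImage
#'
#' @param image A [density_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_mha <- function(image, path) {
  write_mha(image$values, path, image$voxel_size, "float")
}

#' Read a density image from MetaImage
#'
#' @param path File path.
#' @param frame Frame index to attach.
#' @return A [density_image()].
#' @export
read_density_mha <- function(path, frame = 0L) {
  m <- read_mha(path)
  density_image(m$values, m$voxel_size, frame)
}

#' Serialise a VOI set as a labelled volume plus JSON sidecar
#'
#' Codes: 0 = DC, 1 = DP, 2 = FC, 3 = FP.
#'
#' @param vois A `voi_set`.
#' @param path Output `.mha` path; the sidecar is `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_voi_mha <- function(vois, path) {
  lab <- array(0L, dim(vois$DC))
  lab[vois$DP] <- 1L
  lab[vois$FC] <- 2L
  lab[vois$FP] <- 3L
  write_mha(lab, path, vois$voxel_size, "uchar")
  jsonlite::write_json(list(codes = list(DC = 0, DP = 1, FC = 2, FP = 3),
                            TV_defect = vois$TV_defect,
                            TV_fragment = vois$TV_fragment,
                            voxel_size_um = vois$voxel_size),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
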