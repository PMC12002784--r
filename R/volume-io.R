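# Volumetric image I/O. NIfTI (.nii/.nii.gz) goes through RNifti; MetaImage
# (.mha/.mhd) is a simple keyword header + raw block and is read/written
# directly. Orientation: direction cosines are accepted on read but the
# internal frame is axis-aligned (origin + index * spacing); non-identity
# directions are resampled trilinearly onto an axis-aligned grid.

.fileExt <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii\\.gz$", low)) return("nii.gz")
  sub(".*\\.", "", low)
}

#' Read a 3D volume from NIfTI or MetaImage
#'
#' @param path file path (.nii, .nii.gz, .mha or .mhd).
#' @return A \linkS4class{Volume3D}; grid, spacing and origin are decoded
#'   from the file, intensities preserved. Files carrying non-axis-aligned
#'   direction cosines are resampled (trilinear) onto an axis-aligned grid.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(Volume3D(array(1:8, c(2, 2, 2))), f)
#' v <- readVolume(f)
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- .fileExt(path)
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
    if (length(dim(a)) != 3L) stop("expected a 3D image, got ",
                                   length(dim(a)), " dimensions")
    x <- RNifti::xform(img)
    sp <- sqrt(colSums(x[1:3, 1:3]^2))
    dir <- sweep(x[1:3, 1:3], 2, sp, "/")
    vol <- Volume3D(array(as.numeric(a), dim(a)), spacing = sp,
                    origin = x[1:3, 4])
    if (max(abs(dir - diag(3))) > 1e-6) vol <- .resampleAxisAligned(vol, dir)
    vol
  } else if (ext %in% c("mha", "mhd")) {
    .readMetaImage(path)
  } else {
    stop("unsupported volume format: .", ext)
  }
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' Round-trips losslessly through \code{\link{readVolume}} for double
#' intensities (NIfTI, MetaImage) and exactly for integer-valued data.
#'
#' @param vol a \linkS4class{Volume3D}.
#' @param path output path (.nii, .nii.gz, .mha or .mhd).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "Volume3D"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  if (file.access(dir, 2) != 0) stop("directory not writable: ", dir)
  ext <- .fileExt(path)
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::asNifti(vol@voxels)
    RNifti::pixdim(img) <- vol@spacing
    m <- diag(c(vol@spacing, 1))
    m[1:3, 4] <- vol@origin
    img <- RNifti::`sform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (ext %in% c("mha", "mhd")) {
    .writeMetaImage(vol, path)
  } else {
    stop("unsupported volume format: .", ext)
  }
  invisible(path)
}

#' Read / write a segmentation mask
#'
#' Masks use the same formats as volumes; labels are stored as integers and
#' survive a round-trip exactly.
#'
#' @param path file path.
#' @param labelSet admissible labels (default inferred from the data).
#' @return \code{readMask}: a \linkS4class{SegmentationMask}.
#' @export
readMask <- function(path, labelSet = NULL) {
  v <- readVolume(path)
  lab <- round(v@voxels)
  if (max(abs(lab - v@voxels)) > 1e-6)
    stop("file does not contain integer labels")
  SegmentationMask(lab, spacing = v@spacing, origin = v@origin,
                   labelSet = labelSet)
}

#' @rdname readMask
#' @param mask a \linkS4class{SegmentationMask}.
#' @return \code{writeMask}: \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "SegmentationMask"))
  writeVolume(Volume3D(array(as.numeric(mask@labels), dim(mask@labels)),
                       spacing = mask@spacing, origin = mask@origin), path)
}

# resample a volume carrying direction cosines onto an axis-aligned grid
# with the same spacing; world = origin + D %*% (index * spacing)
.resampleAxisAligned <- function(vol, dir) {
  d <- dim(vol@voxels)
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                   c(0, d[3] - 1)))
  world <- t(dir %*% (t(corners) * vol@spacing) + vol@origin)
  lo <- apply(world, 2, min)
  hi <- apply(world, 2, max)
  nd <- pmax(2L, as.integer(floor((hi - lo) / vol@spacing)) + 1L)
  idx <- as.matrix(expand.grid(seq_len(nd[1]) - 1, seq_len(nd[2]) - 1,
                               seq_len(nd[3]) - 1))
  pts <- sweep(idx, 2, vol@spacing, "*")
  pts <- sweep(pts, 2, lo, "+")
  # map world points into the source index frame: i = D^T (w - o) / spacing
  rel <- t(t(dir) %*% t(sweep(pts, 2, vol@origin, "-")))
  src <- sweep(rel, 2, vol@spacing, "/")
  vals <- cpp_trilinear_sample(vol@voxels, dim(vol@voxels), c(1, 1, 1),
                               c(0, 0, 0), src)
  Volume3D(array(vals, nd), spacing = vol@spacing, origin = lo)
}

# ---- MetaImage ---------------------------------------------------------

.metaTypes <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                MET_SHORT = "integer", MET_USHORT = "integer",
                MET_INT = "integer", MET_UINT = "integer",
                MET_FLOAT = "double", MET_DOUBLE = "double")
.metaBytes <- c(MET_UCHAR = 1, MET_CHAR = 1, MET_SHORT = 2, MET_USHORT = 2,
                MET_INT = 4, MET_UINT = 4, MET_FLOAT = 4, MET_DOUBLE = 8)

.readMetaImage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("truncated MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!is.null(hdr$CompressedData) &&
      tolower(hdr$CompressedData) == "true")
    stop("compressed MetaImage data is not supported")
  nd <- as.integer(hdr$NDims)
  if (is.na(nd) || nd != 3L) stop("expected a 3D MetaImage")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  org <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  type <- hdr$ElementType
  if (!type %in% names(.metaTypes)) stop("unsupported ElementType: ", type)
  n <- prod(dims)
  bigend <- isTRUE(tolower(hdr$BinaryDataByteOrderMSB %||% "false") == "true")
  endian <- if (bigend) "big" else "little"
  if (hdr$ElementDataFile == "LOCAL") {
    raw <- .readMetaBlock(con, type, n, endian)
  } else {
    rawPath <- file.path(dirname(path), hdr$ElementDataFile)
    con2 <- file(rawPath, "rb")
    on.exit(close(con2), add = TRUE)
    raw <- .readMetaBlock(con2, type, n, endian)
  }
  vol <- Volume3D(array(as.numeric(raw), dims), spacing = sp, origin = org)
  tm <- hdr$TransformMatrix
  if (!is.null(tm)) {
    dir <- matrix(as.numeric(strsplit(tm, "\\s+")[[1]]), 3, 3, byrow = TRUE)
    if (max(abs(dir - diag(3))) > 1e-6)
      vol <- .resampleAxisAligned(vol, dir)
  }
  vol
}

.readMetaBlock <- function(con, type, n, endian) {
  what <- .metaTypes[[type]]
  size <- .metaBytes[[type]]
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  readBin(con, what = what, n = n, size = size, signed = signed,
          endian = endian)
}

.writeMetaImage <- function(vol, path) {
  ext <- .fileExt(path)
  vals <- as.vector(vol@voxels)
  isInt <- max(abs(vals - round(vals))) < 1e-9 &&
    all(vals >= -32768 & vals <= 32767)
  type <- if (isInt) "MET_SHORT" else "MET_DOUBLE"
  dataFile <- if (ext == "mha") "LOCAL" else
    paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(format(vol@origin, digits = 17),
                                   collapse = " ")),
           paste("ElementSpacing =", paste(format(vol@spacing, digits = 17),
                                           collapse = " ")),
           paste("DimSize =", paste(dim(vol@voxels), collapse = " ")),
           paste("ElementType =", type),
           paste("ElementDataFile =", dataFile))
  con <- file(path, "wb")
  writeLines(hdr, con)
  if (dataFile == "LOCAL") {
    .writeMetaBlock(con, vals, type)
    close(con)
  } else {
    close(con)
    con2 <- file(file.path(dirname(path), dataFile), "wb")
    .writeMetaBlock(con2, vals, type)
    close(con2)
  }
  invisible(path)
}

.writeMetaBlock <- function(con, vals, type) {
  if (type == "MET_SHORT")
    writeBin(as.integer(round(vals)), con, size = 2, endian = "little")
  else
    writeBin(as.numeric(vals), con, size = 8, endian = "little")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- temporal mean -----------------------------------------------------

#' Collapse a 4D CEUS acquisition to a 3D mean-intensity volume
#'
#' The mean contrast intensity of each voxel over the ~2 minute acquisition
#' summarises perfusion into a single 3D image used for segmentation.
#'
#' @param seq a \linkS4class{Volume4D}.
#' @return A \linkS4class{Volume3D} of per-voxel arithmetic means, inheriting
#'   the grid geometry.
#' @export
temporalMean <- function(seq) {
  stopifnot(is(seq, "Volume4D"))
  d <- dim(seq@frames)
  if (d[4] < 1L) stop("need at least one frame")
  m <- rowMeans(array(seq@frames, c(prod(d[1:3]), d[4])))
  Volume3D(array(m, d[1:3]), spacing = seq@spacing, origin = seq@origin)
}

# ---- mesh export -------------------------------------------------------

#' Export a triangle mesh to STL or PLY
#'
#' ASCII STL and PLY are written; both re-parse with common mesh viewers.
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param path output path (.stl or .ply).
#' @return \code{path}, invisibly.
#' @export
exportMesh <- function(mesh, path) {
  stopifnot(is(mesh, "TriMesh"))
  if (nrow(mesh@faces) == 0L) stop("empty mesh")
  ext <- .fileExt(path)
  v <- mesh@vertices
  f <- mesh@faces
  if (ext == "stl") {
    lines <- character(0)
    p1 <- v[f[, 1], , drop = FALSE]
    p2 <- v[f[, 2], , drop = FALSE]
    p3 <- v[f[, 3], , drop = FALSE]
    u <- p2 - p1
    w <- p3 - p1
    nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                 u[, 3] * w[, 1] - u[, 1] * w[, 3],
                 u[, 1] * w[, 2] - u[, 2] * w[, 1])
    len <- sqrt(rowSums(nrm^2))
    nrm <- nrm / ifelse(len > 0, len, 1)
    fmt <- function(m) apply(m, 1, function(r)
      paste(format(r, digits = 17, scientific = TRUE, trim = TRUE),
            collapse = " "))
    lines <- c("solid trusseg",
               as.vector(rbind(
                 paste("facet normal", fmt(nrm)),
                 "  outer loop",
                 paste("    vertex", fmt(p1)),
                 paste("    vertex", fmt(p2)),
                 paste("    vertex", fmt(p3)),
                 "  endloop",
                 "endfacet")),
               "endsolid trusseg")
    writeLines(lines, path)
  } else if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(v)),
             "property double x", "property double y", "property double z",
             paste("element face", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    vl <- apply(v, 1, function(r)
      paste(format(r, digits = 17, trim = TRUE), collapse = " "))
    fl <- apply(f - 1L, 1, function(r) paste(3, paste(r, collapse = " ")))
    writeLines(c(hdr, vl, fl), path)
  } else {
    stop("unsupported mesh format: .", ext)
  }
  invisible(path)
}

#' Read a triangle mesh written by \code{\link{exportMesh}}
#'
#' STL stores vertices per facet; identical coordinates are merged back into
#' a shared vertex list on read.
#'
#' @param path .stl or .ply file.
#' @return A \linkS4class{TriMesh}.
#' @export
readMesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- .fileExt(path)
  lines <- readLines(path)
  if (ext == "stl") {
    vl <- grep("^\\s*vertex ", lines, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                    function(x) as.numeric(x[2:4])))
    key <- apply(coords, 1, paste, collapse = "|")
    uk <- !duplicated(key)
    vid <- match(key, key[uk])
    verts <- coords[uk, , drop = FALSE]
    faces <- matrix(vid, ncol = 3, byrow = TRUE)
    TriMesh(verts, faces)
  } else if (ext == "ply") {
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", lines, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", lines, value = TRUE)))
    start <- which(lines == "end_header")
    verts <- do.call(rbind, lapply(strsplit(lines[start + seq_len(nv)], " "),
                                   as.numeric))
    faces <- do.call(rbind, lapply(
      strsplit(lines[start + nv + seq_len(nf)], " "),
      function(x) as.integer(x[2:4]) + 1L))
    TriMesh(verts, faces)
  } else {
    stop("unsupported mesh format: .", ext)
  }
}
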