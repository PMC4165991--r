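pose_csv_header <- c("frame_id", "tx", "ty", "tz",
                     "r11", "r12", "r13", "r21", "r22", "r23",
                     "r31", "r32", "r33")

#' Write frame poses to CSV
#'
#' One row per frame with columns `frame_id`, translation `tx, ty, tz`
#' (mm) and the 3x3 rotation row-major as `r11..r33`.
#'
#' @param frames list of [tracked_frame()] objects.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_pose_csv <- function(frames, path) {
  rows <- lapply(frames, function(f) {
    m <- unclass(f$pose)
    data.frame(frame_id = f$frame_id, tx = m[1, 4], ty = m[2, 4],
               tz = m[3, 4],
               r11 = m[1, 1], r12 = m[1, 2], r13 = m[1, 3],
               r21 = m[2, 1], r22 = m[2, 2], r23 = m[2, 3],
               r31 = m[3, 1], r32 = m[3, 2], r33 = m[3, 3])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read frame poses from CSV
#'
#' Strictly checks the header (`frame_id, tx, ty, tz, r11..r33`), parses
#' each row, validates the rotation block to an orthonormality tolerance
#' of `1e-4` and then re-orthonormalises it by polar decomposition.
#'
#' @param path pose CSV path.
#' @return A data frame with `frame_id` and a list column `pose` of
#'   [rigid_transform()] objects, ordered by `frame_id`.
#' @export
read_pose_csv <- function(path) {
  if (!file.exists(path)) stop("pose file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(df), pose_csv_header))
    stop("pose CSV header mismatch: expected ",
         paste(pose_csv_header, collapse = ","), call. = FALSE)
  poses <- vector("list", nrow(df))
  ids <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    num <- suppressWarnings(as.numeric(df[i, ]))
    if (any(is.na(num)))
      stop("pose CSV parse error in row ", i, call. = FALSE)
    ids[i] <- as.integer(num[1L])
    R <- matrix(num[5:13], 3L, 3L, byrow = TRUE)
    if (max(abs(crossprod(R) - diag(3))) > 1e-4 || det(R) < 0)
      stop("non-orthonormal rotation for frame_id ", ids[i], call. = FALSE)
    # polar decomposition: nearest proper rotation
    sv <- svd(R)
    R <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
    poses[[i]] <- make_pose(R, num[2:4])
  }
  ord <- order(ids)
  out <- data.frame(frame_id = ids[ord])
  out$pose <- poses[ord]
  out
}

#' Save a tracked sweep to disk
#'
#' Writes the frame images as one multi-page 8-bit grayscale TIFF (values
#' rounded and clipped to 0-255) and the poses as a CSV (see
#' [write_pose_csv()]). Pages follow ascending `frame_id` order.
#'
#' @param frames list of [tracked_frame()] objects.
#' @param image_path output TIFF path.
#' @param pose_path output CSV path.
#' @return Invisibly, a list with both paths.
#' @export
save_sweep <- function(frames, image_path, pose_path) {
  frames <- frames[order(vapply(frames, `[[`, integer(1), "frame_id"))]
  pages <- lapply(frames, function(f)
    pmin(pmax(round(f$image), 0), 255) / 255)
  tiff::writeTIFF(pages, image_path, bits.per.sample = 8L)
  write_pose_csv(frames, pose_path)
  invisible(list(image_path = image_path, pose_path = pose_path))
}

#' Load a tracked sweep from disk
#'
#' Reads a multi-page TIFF frame stack plus its pose CSV, pairing page k
#' with the k-th pose row in ascending `frame_id` order.
#'
#' @param image_path TIFF frame stack path.
#' @param pose_path pose CSV path (see [read_pose_csv()]).
#' @param spacing pixel size in mm/pixel of the stored frames.
#' @return A list of [tracked_frame()] objects ordered by `frame_id`.
#' @export
load_sweep <- function(image_path, pose_path, spacing = 1.0) {
  if (!file.exists(image_path))
    stop("frame stack not found: ", image_path, call. = FALSE)
  pages <- tiff::readTIFF(image_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  poses <- read_pose_csv(pose_path)
  if (length(pages) != nrow(poses))
    stop("frame/pose count mismatch: ", length(pages), " images vs ",
         nrow(poses), " pose rows", call. = FALSE)
  lapply(seq_along(pages), function(i) {
    img <- pages[[i]]
    if (length(dim(img)) == 3L) img <- img[, , 1L]  # grayscale pages only
    tracked_frame(round(img * 255), poses$pose[[i]], spacing,
                  frame_id = poses$frame_id[i])
  })
}

#' Save a volume in a standard medical format
#'
#' Supported by extension: `.mhd` (MetaImage header + raw, little-endian)
#' and `.nii` / `.nii.gz` (NIfTI-1 via RNifti, with spacing and origin in
#' the qform). `dtype = "double"` round-trips values losslessly;
#' `dtype = "uchar"` quantises to 8 bits.
#'
#' @param grid a [volume_grid()].
#' @param path output path ending in `.mhd`, `.nii` or `.nii.gz`.
#' @param dtype `"double"` or `"uchar"`.
#' @return The path, invisibly.
#' @export
save_volume <- function(grid, path, dtype = c("double", "uchar")) {
  stopifnot(inherits(grid, "volume_grid"))
  dtype <- match.arg(dtype)
  vals <- grid$values
  if (dtype == "uchar") vals <- array(pmin(pmax(round(vals), 0), 255),
                                      dim = grid$dims)
  if (grepl("\\.mhd$", path, ignore.case = TRUE)) {
    raw_path <- sub("\\.mhd$", ".raw", path, ignore.case = TRUE)
    et <- if (dtype == "double") "MET_DOUBLE" else "MET_UCHAR"
    hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
             "BinaryDataByteOrderMSB = False",
             "CompressedData = False",
             "TransformMatrix = 1 0 0 0 1 0 0 0 1",
             paste("Offset =", paste(grid$origin, collapse = " ")),
             "CenterOfRotation = 0 0 0",
             paste("ElementSpacing =", paste(grid$spacing, collapse = " ")),
             paste("DimSize =", paste(grid$dims, collapse = " ")),
             paste("ElementType =", et),
             paste("ElementDataFile =", basename(raw_path)))
    writeLines(hdr, path)
    con <- file(raw_path, "wb")
    on.exit(close(con))
    if (dtype == "double")
      writeBin(as.numeric(vals), con, size = 8L, endian = "little")
    else
      writeBin(as.raw(as.integer(vals)), con)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(vals)
    m <- diag(4)
    diag(m)[1:3] <- grid$spacing
    m[1:3, 4L] <- grid$origin
    img <- RNifti::`qform<-`(img, value = structure(m, code = 2L))
    img <- RNifti::`pixdim<-`(img, value = grid$spacing)
    RNifti::writeNifti(img, path,
                       datatype = if (dtype == "uchar") "uint8" else "double")
  } else {
    stop("unsupported volume extension: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Load a volume saved by [save_volume()]
#'
#' @param path `.mhd`, `.nii` or `.nii.gz` path.
#' @return A [volume_grid()] (filled mask all `TRUE`).
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("volume not found: ", path, call. = FALSE)
  if (grepl("\\.mhd$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    kv <- strsplit(lines, "\\s*=\\s*")
    keys <- vapply(kv, `[`, character(1), 1L)
    vals <- vapply(kv, function(x) paste(x[-1L], collapse = " "), character(1))
    getf <- function(k) as.numeric(strsplit(trimws(vals[keys == k]), "\\s+")[[1L]])
    dims <- as.integer(getf("DimSize"))
    spacing <- getf("ElementSpacing")
    origin <- getf("Offset")
    et <- trimws(vals[keys == "ElementType"])
    raw_path <- file.path(dirname(path),
                          trimws(vals[keys == "ElementDataFile"]))
    n <- prod(dims)
    con <- file(raw_path, "rb")
    on.exit(close(con))
    data <- if (et == "MET_DOUBLE")
      readBin(con, numeric(), n = n, size = 8L, endian = "little")
    else if (et == "MET_UCHAR")
      as.numeric(readBin(con, raw(), n = n))
    else stop("unsupported MetaImage ElementType: ", et, call. = FALSE)
    volume_grid(origin, spacing, dims, values = array(data, dim = dims),
                filled = array(TRUE, dim = dims),
                counts = array(1L, dim = dims))
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    xf <- RNifti::xform(img)
    dims <- dim(img)
    volume_grid(origin = xf[1:3, 4L], spacing = RNifti::pixdim(img)[1:3],
                dims = dims,
                values = array(as.numeric(img), dim = dims),
                filled = array(TRUE, dim = dims),
                counts = array(1L, dim = dims))
  } else {
    stop("unsupported volume extension: ", path, call. = FALSE)
  }
}
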