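# Readers/writers: NIfTI-1 (scalar + 3-component vector) through RNifti,
# a minimal NRRD subset (scalar, raw/gzip, little-endian) written by hand,
# and landmark CSV (label,fx,fy,fz,mx,my,mz in mm).

# Normalise an axis-aligned NIfTI xform (flips/permutations allowed) into the
# internal convention: +x/+y/+z ordered axes, positive spacing, voxel-centre
# origin. Returns list(perm, flip, spacing, origin).
.normalize_xform <- function(m, dims) {
  R <- m[1:3, 1:3]; t <- m[1:3, 4]
  perm <- integer(3); flip <- logical(3); spacing <- numeric(3); origin <- t
  for (w in 1:3) {
    j <- which(abs(R[w, ]) > 1e-6 * max(abs(R)))
    if (length(j) != 1L)
      stop("oblique orientation matrices are not supported (axis-aligned, flips/permutations only)",
           call. = FALSE)
    perm[w] <- j
    spacing[w] <- abs(R[w, j])
    flip[w] <- R[w, j] < 0
    if (flip[w]) origin[w] <- t[w] + R[w, j] * (dims[j] - 1)
  }
  if (length(unique(perm)) != 3L)
    stop("degenerate orientation matrix", call. = FALSE)
  # NIfTI-1 stores geometry in single precision; snap to its 7 significant
  # digits so round trips are exact
  list(perm = perm, flip = flip, spacing = signif(spacing, 7),
       origin = signif(origin, 7))
}

.reorient_array <- function(a, nz, vector = FALSE) {
  # nz: output of .normalize_xform. Flip then permute the spatial axes so that
  # world axis w comes from source axis nz$perm[w].
  idx <- lapply(seq_along(dim(a)), function(i) seq_len(dim(a)[i]))
  for (w in 1:3) if (nz$flip[w]) idx[[nz$perm[w]]] <- rev(idx[[nz$perm[w]]])
  a <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  p <- nz$perm
  if (!identical(p, 1:3)) {
    ord <- if (vector) c(p, 4L) else p
    a <- aperm(a, ord)
  }
  a
}

.read_nifti_any <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  dims <- dim(a)
  m <- RNifti::xform(img)
  # Collapse singleton 4th dim of 5-D vector images (nx,ny,nz,1,3)
  if (length(dims) == 5L && dims[4] == 1L) {
    a <- array(a, dims[c(1:3, 5)]); dims <- dim(a)
  }
  nz <- .normalize_xform(m, dims[1:3])
  vector <- length(dims) == 4L
  a <- .reorient_array(a, nz, vector = vector)
  list(data = a, spacing = nz$spacing, origin = nz$origin, vector = vector)
}

#' Read a volume from NIfTI or NRRD
#'
#' Scalar NIfTI (`.nii`, `.nii.gz`) and scalar NRRD (`.nrrd`) are read as
#' images or masks; 4-D NIfTI with 3 components is read as a displacement
#' field in mm. File orientation is normalised internally (axis flips and
#' permutations; oblique matrices are rejected).
#'
#' @param path file path.
#' @param kind one of `"image"`, `"mask"`, `"dvf"`.
#' @return An [image_volume()], [binary_mask()] or [displacement_field()].
#' @export
read_volume <- function(path, kind = c("image", "mask", "dvf")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  ext_nrrd <- grepl("\\.nrrd$", path, ignore.case = TRUE)
  r <- if (ext_nrrd) .read_nrrd(path) else .read_nifti_any(path)
  if (kind == "dvf") {
    if (!isTRUE(r$vector) || length(dim(r$data)) != 4L || dim(r$data)[4] != 3L)
      stop("a displacement field must have exactly 3 vector components", call. = FALSE)
    if (!all(is.finite(r$data))) stop("non-finite values in displacement field", call. = FALSE)
    return(displacement_field(r$data, r$spacing, r$origin))
  }
  if (isTRUE(r$vector))
    stop("expected a scalar volume, found a vector image", call. = FALSE)
  if (kind == "mask") {
    v <- as.numeric(r$data)
    if (!all(v %in% c(0, 1)))
      stop("mask file contains values other than 0/1", call. = FALSE)
    return(binary_mask(r$data, r$spacing, r$origin))
  }
  image_volume(r$data, r$spacing, r$origin)
}

#' Write a volume to NIfTI or NRRD
#'
#' Displacement fields are written as 4-D NIfTI with 3 components; NRRD output
#' (chosen by a `.nrrd` extension) supports scalars only.
#'
#' @param vol an [image_volume()], [binary_mask()] or [displacement_field()].
#' @param path destination path (`.nii`, `.nii.gz`, `.nrrd`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    if (inherits(vol, "bmdir_dvf"))
      stop("NRRD output supports scalar volumes only", call. = FALSE)
    .write_nrrd(vol, path)
    return(invisible(path))
  }
  a <- if (inherits(vol, "bmdir_dvf")) vol$vectors else vol$voxels
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(vol$spacing, rep(1, length(dim(a)) - 3L))
  m <- diag(4); diag(m)[1:3] <- vol$spacing; m[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- minimal NRRD (scalar, little-endian, raw or gzip, attached data) ------

.read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file", call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header", call. = FALSE)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(": ?", line), invert = TRUE)[[1]]
    if (length(kv) == 2L) fields[[tolower(kv[1])]] <- trimws(kv[2])
  }
  need <- function(k) {
    if (is.null(fields[[k]])) stop("NRRD header missing field: ", k, call. = FALSE)
    fields[[k]]
  }
  dimension <- as.integer(need("dimension"))
  if (dimension != 3L) stop("only 3-D scalar NRRD is supported", call. = FALSE)
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  type <- need("type")
  enc <- tolower(need("encoding"))
  endian <- tolower(fields[["endian"]] %||% "little")
  if (endian != "little") stop("big-endian NRRD not supported", call. = FALSE)
  spacing <- c(1, 1, 1); origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    M <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3)))
    if (any(abs(M[upper.tri(M) | lower.tri(M)]) > 1e-9))
      stop("oblique NRRD space directions not supported", call. = FALSE)
    spacing <- abs(diag(M))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  n <- prod(sizes)
  sz <- switch(type,
               "float" = 4L, "double" = 8L,
               "int" = 4L, "short" = 2L, "uchar" = 1L, "unsigned char" = 1L,
               stop("unsupported NRRD type: ", type, call. = FALSE))
  what <- if (type %in% c("float", "double")) "numeric" else "integer"
  raw_data <- readBin(con, "raw", n = file.info(path)$size)
  if (enc == "gzip") raw_data <- memDecompress(raw_data, type = "gzip")
  if (length(raw_data) < n * sz) stop("truncated NRRD data", call. = FALSE)
  vals <- readBin(raw_data, what, n = n, size = sz, endian = "little",
                  signed = !(type %in% c("uchar", "unsigned char")))
  list(data = array(as.numeric(vals), sizes), spacing = spacing, origin = origin,
       vector = FALSE)
}

.write_nrrd <- function(vol, path, encoding = "gzip") {
  d <- vol_dim(vol)
  hdr <- c("NRRD0004",
           "type: double",
           "dimension: 3",
           "space: right-anterior-superior",
           paste("sizes:", paste(d, collapse = " ")),
           sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   vol$spacing[1], vol$spacing[2], vol$spacing[3]),
           sprintf("space origin: (%.17g,%.17g,%.17g)",
                   vol$origin[1], vol$origin[2], vol$origin[3]),
           "endian: little",
           paste0("encoding: ", encoding),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  payload <- writeBin(as.numeric(vol$voxels), raw(), size = 8L, endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  writeBin(payload, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read paired landmarks from CSV
#'
#' Expects columns `label, fx, fy, fz, mx, my, mz` (physical mm): the fixed
#' point and its corresponding moving point per row.
#'
#' @param path CSV file path.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "fx", "fy", "fz", "mx", "my", "mz")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  landmark_set(as.matrix(df[, c("fx", "fy", "fz")]),
               as.matrix(df[, c("mx", "my", "mz")]),
               labels = df$label)
}

#' Write paired landmarks to CSV
#' @param landmarks a [landmark_set()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  write.csv(as.data.frame(landmarks), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
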