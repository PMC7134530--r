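#' Read a 3D volume from NIfTI or NRRD
#'
#' Spacing is taken from the file header; the function fails on non-3D images
#' rather than guessing an orientation. NIfTI arrays are stored (x, y, z) on
#' disk and are re-ordered to the package's (z, y, x) convention.
#'
#' @param path path to a .nii, .nii.gz or .nrrd file.
#' @return a \code{\linkS4class{Volume}}.
#' @export
loadVolume <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return(.read_nrrd(path))
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L)
        stop("expected a 3D image, got ", length(dim(arr)), "D")
    pd <- RNifti::pixdim(img)[1:3]  # (x, y, z)
    Volume(aperm(arr, c(3, 2, 1)), spacing = rev(pd))
}

#' Write a Volume or LabelVolume to NIfTI or NRRD
#'
#' Masks are written as unsigned 8-bit integers, images as 32-bit float NIfTI
#' (NRRD output is raw little-endian double / uint8).
#'
#' @param x a \code{Volume} or \code{LabelVolume}.
#' @param path output path (.nii, .nii.gz or .nrrd).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(x, path) {
    is_mask <- is(x, "LabelVolume")
    arr <- if (is_mask) x@labels else x@voxels
    sp <- x@spacing
    if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
        .write_nrrd(arr, sp, path, if (is_mask) "uint8" else "double")
        return(invisible(path))
    }
    out <- aperm(arr, c(3, 2, 1))  # to (x, y, z)
    img <- RNifti::asNifti(out)
    RNifti::pixdim(img) <- rev(sp)
    RNifti::writeNifti(img, path, datatype = if (is_mask) "uint8" else "double")
    invisible(path)
}

# Minimal NRRD (raw encoding) support; no R package in the stack reads NRRD.
.read_nrrd <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readLines(con, n = 1L)
    if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
    hdr <- list()
    repeat {
        line <- readLines(con, n = 1L)
        if (!length(line) || line == "") break
        if (grepl("^#", line)) next
        kv <- strsplit(line, ":\\s*", fixed = FALSE)[[1]]
        hdr[[tolower(kv[1])]] <- kv[2]
    }
    if (as.integer(hdr[["dimension"]]) != 3L)
        stop("expected a 3D image, got ", hdr[["dimension"]], "D")
    sizes <- as.integer(strsplit(hdr[["sizes"]], "\\s+")[[1]])  # fastest first = z
    if (!identical(hdr[["encoding"]], "raw")) stop("only raw NRRD encoding supported")
    type <- hdr[["type"]]
    n <- prod(sizes)
    vals <- switch(type,
        "double" = readBin(con, "double", n = n, size = 8, endian = "little"),
        "float" = readBin(con, "double", n = n, size = 4, endian = "little"),
        "uint8" = as.numeric(readBin(con, "integer", n = n, size = 1,
                                     signed = FALSE, endian = "little")),
        stop("unsupported NRRD type: ", type))
    sp <- if (!is.null(hdr[["spacings"]]))
        as.numeric(strsplit(hdr[["spacings"]], "\\s+")[[1]]) else c(1, 1, 1)
    Volume(array(vals, dim = sizes), spacing = sp)
}

.write_nrrd <- function(arr, spacing, path, type = "double") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- c("NRRD0004",
             paste0("type: ", type),
             "dimension: 3",
             paste0("sizes: ", paste(dim(arr), collapse = " ")),
             paste0("spacings: ", paste(spacing, collapse = " ")),
             "endian: little",
             "encoding: raw",
             "")
    writeLines(hdr, con)
    if (type == "uint8") writeBin(as.raw(as.vector(arr)), con)
    else writeBin(as.vector(as.numeric(arr)), con, size = 8, endian = "little")
}

#' Slice-wise mean normalization
#'
#' Each axial slice is independently mapped to
#' \code{(I - mean(I)) / (max(I) - min(I))}, so every output slice has zero mean
#' and the output range is contained in [-1, 1]. A constant slice maps to zeros
#' (the numerator is exactly zero; the unique continuous completion of the
#' degenerate denominator).
#'
#' @param v a \code{Volume}.
#' @return a normalized \code{Volume}.
#' @export
normalizeSlicewise <- function(v) {
    stopifnot(is(v, "Volume"))
    a <- v@voxels
    nz <- dim(a)[1]
    for (k in seq_len(nz)) {
        s <- a[k, , ]
        rng <- max(s) - min(s)
        a[k, , ] <- if (rng > 0) (s - mean(s)) / rng else 0
    }
    Volume(a, spacing = v@spacing, origin = v@origin)
}

#' Resample a volume to an isotropic cube by trilinear interpolation
#'
#' Uses corner-aligned coordinates, so an already-cubic edge^3 input is returned
#' unchanged and a constant volume stays constant. Spacing is rescaled to keep
#' the physical extent (edge-1)*spacing of each axis.
#'
#' @param v a \code{Volume}.
#' @param edge target cube edge (>= 8).
#' @return an edge^3 \code{Volume}.
#' @export
resampleToCube <- function(v, edge) {
    stopifnot(is(v, "Volume"))
    edge <- as.integer(edge)
    if (edge < 8L) stop("edge must be >= 8")
    d <- dim(v@voxels)
    if (all(d == edge)) return(v)
    coords <- lapply(d, function(n)
        if (edge == 1L) 0 else (0:(edge - 1)) * (n - 1) / (edge - 1))
    a <- .trilinear(v@voxels, coords[[1]], coords[[2]], coords[[3]])
    newsp <- v@spacing * (d - 1) / pmax(edge - 1, 1)
    Volume(a, spacing = newsp, origin = v@origin)
}

# Trilinear interpolation of vol at the grid cz x cy x cx (0-based source
# coordinates), fully vectorized via linear indexing of the 8 cell corners.
.trilinear <- function(vol, cz, cy, cx) {
    d <- dim(vol)
    nz <- length(cz); ny <- length(cy); nx <- length(cx)
    f <- function(c0, n) pmin(pmax(floor(c0), 0), n - 2L)
    z0 <- if (d[1] > 1) f(cz, d[1]) else rep(0, nz)
    y0 <- if (d[2] > 1) f(cy, d[2]) else rep(0, ny)
    x0 <- if (d[3] > 1) f(cx, d[3]) else rep(0, nx)
    tz <- if (d[1] > 1) cz - z0 else rep(0, nz)
    ty <- if (d[2] > 1) cy - y0 else rep(0, ny)
    tx <- if (d[3] > 1) cx - x0 else rep(0, nx)
    Z0 <- rep(z0, times = ny * nx); TZ <- rep(tz, times = ny * nx)
    Y0 <- rep(rep(y0, each = nz), times = nx); TY <- rep(rep(ty, each = nz), times = nx)
    X0 <- rep(x0, each = nz * ny); TX <- rep(tx, each = nz * ny)
    idx <- function(dz, dy, dx) {
        zz <- pmin(Z0 + dz, d[1] - 1L); yy <- pmin(Y0 + dy, d[2] - 1L)
        xx <- pmin(X0 + dx, d[3] - 1L)
        1 + zz + d[1] * (yy + d[2] * xx)
    }
    out <- vol[idx(0, 0, 0)] * (1 - TZ) * (1 - TY) * (1 - TX) +
           vol[idx(1, 0, 0)] * TZ * (1 - TY) * (1 - TX) +
           vol[idx(0, 1, 0)] * (1 - TZ) * TY * (1 - TX) +
           vol[idx(1, 1, 0)] * TZ * TY * (1 - TX) +
           vol[idx(0, 0, 1)] * (1 - TZ) * (1 - TY) * TX +
           vol[idx(1, 0, 1)] * TZ * (1 - TY) * TX +
           vol[idx(0, 1, 1)] * (1 - TZ) * TY * TX +
           vol[idx(1, 1, 1)] * TZ * TY * TX
    array(out, dim = c(nz, ny, nx))
}

#' Decompose a cubic volume into ordered axial, sagittal and coronal slice stacks
#'
#' A pure re-indexing: axial planes (y, x) indexed by z, sagittal planes (z, y)
#' indexed by x, coronal planes (z, x) indexed by y.
#'
#' @param v a cubic \code{Volume} or 3D array.
#' @return a \code{\linkS4class{ViewDecomposition}}.
#' @export
decomposeViews <- function(v) {
    a <- if (is(v, "Volume")) v@voxels else v
    d <- dim(a)
    if (length(unique(d)) != 1L)
        stop("decomposeViews requires a cubic volume; got ",
             paste(d, collapse = "x"))
    new("ViewDecomposition",
        axial = aperm(a, c(2, 3, 1)),
        sagittal = a,                 # (z, y) planes indexed by x
        coronal = aperm(a, c(1, 3, 2)),
        sourceDim = as.integer(d))
}

#' Recompose a volume from a view decomposition
#'
#' @param vd a \code{ViewDecomposition}.
#' @param view which stack to rebuild from.
#' @return the source 3D array, voxel-exact.
#' @export
recomposeViews <- function(vd, view = c("axial", "sagittal", "coronal")) {
    view <- match.arg(view)
    switch(view,
           axial = aperm(vd@axial, c(3, 1, 2)),
           sagittal = vd@sagittal,
           coronal = aperm(vd@coronal, c(1, 3, 2)))
}

#' Transpose a sagittal or coronal slice stack to axial ordering
#'
#' The transposition operator of the multiview fusion: a pure axis permutation
#' that maps per-view feature stacks onto the axial stack's layout so they can
#' be summed elementwise. Accepts 3D stacks (H, W, N) from
#' \code{decomposeViews} or 4D feature stacks (H, W, C, N).
#'
#' @param stack a 3D or 4D slice/feature stack built over a cubic grid.
#' @param view "sagittal" or "coronal".
#' @return the stack re-ordered as axial planes (y, x[, C], z).
#' @export
transposeToAxial <- function(stack, view = c("sagittal", "coronal")) {
    view <- match.arg(view)
    d <- dim(stack)
    is3d <- length(d) == 3L
    if (is3d) dim(stack) <- c(d[1], d[2], 1L, d[3])
    dd <- dim(stack)
    if (length(unique(dd[c(1, 2, 4)])) != 1L)
        stop("transposeToAxial requires a stack over a cubic grid")
    out <- if (view == "sagittal") aperm(stack, c(2, 4, 3, 1))
           else aperm(stack, c(4, 2, 3, 1))
    if (is3d) { do <- dim(out); dim(out) <- do[c(1, 2, 4)] }
    out
}
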