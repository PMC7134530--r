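test_that("NIfTI round trip is bit-exact and preserves anisotropic spacing", {
    set.seed(1)
    v <- Volume(array(rnorm(12^3), dim = c(12, 12, 12)),
                spacing = c(2.0, 0.7, 0.7))  # (z, y, x): 0.7 x 0.7 x 2 mm
    path <- tempfile(fileext = ".nii.gz")
    writeVolume(v, path)
    v2 <- loadVolume(path)
    expect_identical(dim(voxels(v2)), dim(voxels(v)))
    expect_equal(voxels(v2), voxels(v), tolerance = 0)
    expect_equal(spacing(v2), c(2.0, 0.7, 0.7), tolerance = 1e-6)
    unlink(path)
})

test_that("masks round-trip through unsigned-integer NIfTI", {
    m <- LabelVolume(array(rbinom(10^3, 1, 0.3), dim = c(10, 10, 10)))
    path <- tempfile(fileext = ".nii.gz")
    writeVolume(m, path)
    v2 <- loadVolume(path)
    expect_equal(voxels(v2), m@labels + 0, tolerance = 0)
    unlink(path)
})

test_that("loading a 4D image is a shape error", {
    path <- tempfile(fileext = ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(array(0, dim = c(4, 4, 4, 2))), path)
    expect_error(loadVolume(path), "3D")
    expect_error(loadVolume(tempfile(fileext = ".nii")), "not found")
    unlink(path)
})

test_that("NRRD round trip preserves voxels and spacing", {
    set.seed(2)
    v <- Volume(array(rnorm(6 * 7 * 8), dim = c(6, 7, 8)), spacing = c(1, 1.5, 2))
    path <- tempfile(fileext = ".nrrd")
    writeVolume(v, path)
    v2 <- loadVolume(path)
    expect_equal(voxels(v2), voxels(v), tolerance = 0)
    expect_equal(spacing(v2), c(1, 1.5, 2))
    unlink(path)
})

test_that("slice-wise normalization maps the stated examples exactly", {
    # slice {0,1} -> {-0.5, +0.5}
    v <- Volume(array(c(0, 1), dim = c(1, 2, 1)))
    expect_equal(as.vector(voxels(normalizeSlicewise(v))), c(-0.5, 0.5))
    # slice {2,4,6} -> {-0.5, 0, +0.5}
    v <- Volume(array(c(2, 4, 6), dim = c(1, 3, 1)))
    expect_equal(as.vector(voxels(normalizeSlicewise(v))), c(-0.5, 0, 0.5))
    # constant slice -> zeros (degenerate denominator)
    v <- Volume(array(7, dim = c(2, 3, 3)))
    expect_equal(as.vector(voxels(normalizeSlicewise(v))), rep(0, 18))
})

test_that("normalized slices have zero mean and range within [-1, 1]", {
    set.seed(3)
    v <- Volume(array(rnorm(10 * 8 * 9, mean = 40, sd = 25), dim = c(10, 8, 9)))
    nv <- voxels(normalizeSlicewise(v))
    for (k in 1:10) expect_lt(abs(mean(nv[k, , ])), 1e-6)
    expect_gte(min(nv), -1)
    expect_lte(max(nv), 1)
})

test_that("resampling preserves constants and is the identity on cubes", {
    v <- Volume(array(3.7, dim = c(20, 24, 28)))
    r <- resampleToCube(v, 16L)
    expect_identical(dim(voxels(r)), c(16L, 16L, 16L))
    expect_equal(as.vector(voxels(r)), rep(3.7, 16^3))
    set.seed(4)
    v <- Volume(array(rnorm(16^3), dim = c(16, 16, 16)))
    expect_identical(voxels(resampleToCube(v, 16L)), voxels(v))
    expect_error(resampleToCube(v, 4L), ">= 8")
})

test_that("resampling a linear ramp matches direct trilinear evaluation", {
    n <- 16L
    vol <- array(rep(0:(n - 1), times = n * n), dim = c(n, n, n))  # ramp along z
    v <- Volume(vol)
    m <- 8L
    r <- voxels(resampleToCube(v, m))
    coords <- (0:(m - 1)) * (n - 1) / (m - 1)
    for (i in seq_len(m)) {
        expected <- trilinear_point(vol, coords[i], coords[1], coords[1])
        expect_equal(r[i, 1, 1], expected, tolerance = 1e-12)
        # ramp: interpolated value equals the source coordinate itself
        expect_equal(r[i, 3, 5], coords[i], tolerance = 1e-12)
    }
})

test_that("view decomposition re-indexes a coordinate-encoded volume", {
    n <- 4L
    v <- array(0, dim = c(n, n, n))
    for (z in 1:n) for (y in 1:n) for (x in 1:n)
        v[z, y, x] <- 100 * (z - 1) + 10 * (y - 1) + (x - 1)
    vd <- decomposeViews(v)
    for (k in 1:n) {
        expect_true(all(vd@axial[, , k] %/% 100 == k - 1))     # hundreds = z
        expect_true(all(vd@sagittal[, , k] %% 10 == k - 1))    # units = x
        expect_true(all(vd@coronal[, , k] %/% 10 %% 10 == k - 1))  # tens = y
    }
    expect_error(decomposeViews(array(0, dim = c(3, 4, 4))), "cubic")
})

test_that("decompose/recompose and plane counts are exact on random volumes", {
    set.seed(5)
    for (i in 1:5) {
        v <- array(rnorm(10^3), dim = c(10, 10, 10))
        vd <- decomposeViews(v)
        expect_identical(dim(vd@axial)[3], 10L)
        expect_identical(dim(vd@sagittal)[3], 10L)
        expect_identical(dim(vd@coronal)[3], 10L)
        for (view in c("axial", "sagittal", "coronal"))
            expect_identical(recomposeViews(vd, view), v)
    }
})

test_that("transposition returns sagittal/coronal stacks to axial order exactly", {
    set.seed(6)
    for (i in 1:5) {
        v <- array(rnorm(8^3), dim = c(8, 8, 8))
        vd <- decomposeViews(v)
        expect_identical(transposeToAxial(vd@sagittal, "sagittal"), vd@axial)
        expect_identical(transposeToAxial(vd@coronal, "coronal"), vd@axial)
    }
    expect_error(transposeToAxial(array(0, dim = c(3, 4, 3)), "sagittal"), "cubic")
})

test_that("the transposition permutations are the unique round-trip pair", {
    # brute force over all 6 axis permutations of a 3x3x3 grid: exactly one
    # permutation maps each non-axial stack onto the axial stack for a generic
    # volume, and it is the one the package applies
    set.seed(7)
    v <- array(rnorm(27), dim = c(3, 3, 3))
    vd <- decomposeViews(v)
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    for (view in c("sagittal", "coronal")) {
        stack <- slot(vd, view)
        hits <- vapply(perms, function(p) identical(aperm(stack, p), vd@axial),
                       logical(1))
        expect_identical(sum(hits), 1L)
        expect_identical(aperm(stack, perms[[which(hits)]]), vd@axial)
        # applying the matching inverse permutation twice round-trips
        p <- perms[[which(hits)]]
        expect_identical(aperm(aperm(stack, p), order(p)), stack)
    }
    # 4D feature stacks: round trip through the channel-aware transposition
    f <- array(rnorm(3 * 3 * 2 * 3), dim = c(3, 3, 2, 3))
    for (view in c("sagittal", "coronal")) {
        t1 <- transposeToAxial(f, view)
        expect_identical(dim(t1), dim(f))
    }
    # zero stack stays zero
    expect_equal(transposeToAxial(array(0, dim = c(3, 3, 3)), "sagittal"),
                 array(0, dim = c(3, 3, 3)))
})
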