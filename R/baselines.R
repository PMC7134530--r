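# Unsupervised scar-segmentation comparators. All three operate on the voxel
# intensities inside the atrial wall shell (derived from the anatomy at a fixed
# wall thickness), which isolates scar detection from anatomy errors.

#' Collect wall-shell intensities for the unsupervised baselines
#'
#' @param image intensity \code{Volume}.
#' @param anatomy anatomy \code{LabelVolume} (blood pool); blood statistics are
#'   estimated from the intensities inside it unless supplied.
#' @param wallMM wall thickness in mm.
#' @param bloodStats optional list(mean, sd) of blood-pool intensity statistics.
#' @return list with intensities, voxelIndices (linear), shell mask, bloodStats,
#'   dim and spacing.
#' @export
wallIntensitySample <- function(image, anatomy, wallMM = 2.25, bloodStats = NULL) {
    stopifnot(is(image, "Volume"), is(anatomy, "LabelVolume"))
    shell <- wallShell(anatomy, image@spacing, wallMM)
    idx <- which(shell@labels > 0)
    if (!length(idx)) stop("wall shell is empty")
    if (is.null(bloodStats)) {
        blood <- image@voxels[anatomy@labels > 0]
        bloodStats <- list(mean = mean(blood), sd = stats::sd(blood))
    }
    if (is.na(bloodStats$sd) || bloodStats$sd < 0) stop("blood sd must be >= 0")
    list(intensities = image@voxels[idx], voxelIndices = idx, shell = shell,
         bloodStats = bloodStats, dim = dim(image@voxels),
         spacing = image@spacing)
}

.mask_from_indices <- function(sample, idx) {
    m <- array(0L, dim = sample$dim)
    m[idx] <- 1L
    LabelVolume(m, spacing = sample$spacing)
}

#' 2-SD thresholding scar baseline
#'
#' Labels a wall voxel as scar iff its intensity exceeds the blood-pool mean
#' plus two blood-pool standard deviations.
#'
#' @param sample from \code{wallIntensitySample}.
#' @return binary scar \code{LabelVolume} over the shell.
#' @export
twoSDThreshold <- function(sample) {
    bs <- sample$bloodStats
    if (bs$sd == 0 && length(unique(sample$intensities)) == 1L)
        warning("degenerate sample: zero blood sd and constant wall intensities")
    thr <- bs$mean + 2 * bs$sd
    .mask_from_indices(sample, sample$voxelIndices[sample$intensities > thr])
}

# k-means++ style seeding for 1-D intensities: first center uniform, the rest
# sampled proportional to squared distance from the nearest chosen center.
.kmeanspp_centers <- function(x, k) {
    centers <- x[sample.int(length(x), 1L)]
    while (length(centers) < k) {
        d2 <- vapply(x, function(v) min((v - centers)^2), numeric(1))
        if (all(d2 == 0)) {
            centers <- c(centers, rep(centers[1], k - length(centers)))
            break
        }
        centers <- c(centers, x[sample.int(length(x), 1L, prob = d2)])
    }
    centers
}

#' k-means scar baseline
#'
#' 1-D k-means (Lloyd's algorithm with k-means++ style seeding, fixed seed) on
#' the wall intensities; the cluster with the highest centroid is scar. If all
#' centroids coincide the scar mask is empty (conservative tie rule).
#'
#' @param sample from \code{wallIntensitySample}.
#' @param k number of clusters.
#' @param seed seed for the seeding step.
#' @return binary scar \code{LabelVolume}.
#' @export
kmeansScar <- function(sample, k = 2L, seed = 1L) {
    x <- sample$intensities
    if (length(x) < k) stop("fewer wall voxels than clusters")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    init <- .kmeanspp_centers(x, k)
    if (length(unique(init)) < k)
        return(.mask_from_indices(sample, integer(0)))
    km <- stats::kmeans(x, centers = matrix(init, ncol = 1),
                        algorithm = "Lloyd", iter.max = 100L)
    hi <- which.max(km$centers)
    if (sum(km$centers == max(km$centers)) > 1L)
        return(.mask_from_indices(sample, integer(0)))
    .mask_from_indices(sample, sample$voxelIndices[km$cluster == hi])
}

#' Fuzzy c-means scar baseline
#'
#' Standard FCM alternating updates (memberships
#' u_ij = 1 / sum_k (d_ij / d_kj)^(2/(m-1)), centroids = weighted means under
#' u^m) until convergence; scar = voxels with majority membership in the
#' highest-centroid cluster.
#'
#' @param sample from \code{wallIntensitySample}.
#' @param c number of clusters.
#' @param m fuzzifier (> 1, default 2).
#' @param tol convergence tolerance on the objective.
#' @param maxIter iteration cap.
#' @param seed seed for initialization.
#' @param centers optional explicit initial centroids (length c); default is
#'   k-means++-style seeding from the data.
#' @return list(membership = n x c matrix, mask = binary \code{LabelVolume},
#'   centers).
#' @export
fuzzyCMeansScar <- function(sample, c = 2L, m = 2.0, tol = 1e-6, maxIter = 300L,
                            seed = 1L, centers = NULL) {
    x <- sample$intensities
    if (length(x) < c) stop("fewer wall voxels than clusters")
    if (m <= 1) stop("fuzzifier m must be > 1")
    if (length(unique(x)) < c) {
        u <- matrix(1 / c, length(x), c)
        return(list(membership = u, mask = .mask_from_indices(sample, integer(0)),
                    centers = rep(x[1], c)))
    }
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    init <- matrix(if (is.null(centers)) .kmeanspp_centers(x, c) else centers,
                   ncol = 1)
    fit <- e1071::cmeans(matrix(x, ncol = 1), centers = init, m = m,
                         iter.max = maxIter, method = "cmeans",
                         control = list(reltol = tol))
    centers <- as.numeric(fit$centers)
    hi <- which.max(centers)
    if (sum(centers == max(centers)) > 1L)
        return(list(membership = fit$membership,
                    mask = .mask_from_indices(sample, integer(0)),
                    centers = centers))
    scar_idx <- sample$voxelIndices[apply(fit$membership, 1, which.max) == hi]
    list(membership = fit$membership,
         mask = .mask_from_indices(sample, scar_idx), centers = centers)
}
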