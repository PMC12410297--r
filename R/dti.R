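#' Fit diffusion tensors by log-linear least squares
#'
#' Ordinary least squares on the log signal with design rows
#' `[1, -b gx^2, -b gy^2, -b gz^2, -2 b gx gy, -2 b gx gz, -2 b gy gz]`,
#' solved with one QR factorization for all voxels. Multiple b = 0 volumes
#' are averaged into one before fitting. Voxels containing a nonpositive
#' signal are marked invalid (NA tensor) rather than aborting the fit;
#' noise-free simulated signals are recovered to linear-solve tolerance.
#'
#' @param signals 4D array `(nx, ny, nz, nvol)` or `n x nvol` matrix, or a
#'   NIfTI file path.
#' @param scheme a [diffusion_scheme()] matching the volumes.
#' @param mask optional binary array restricting the fit; voxels outside are
#'   invalid.
#' @return A `tensor_fit` list: `tensors` (dims x 6, order xx, yy, zz, xy,
#'   xz, yz), `S0`, logical `valid`.
#' @export
fit_tensor <- function(signals, scheme, mask = NULL) {
  stopifnot(inherits(scheme, "diffusion_scheme"))
  if (is.character(signals)) signals <- as_volume(signals, "signals")
  dims <- NULL
  if (is.matrix(signals)) {
    mat <- signals
  } else {
    d <- dim(signals)
    stopifnot(length(d) == 4L)
    dims <- d[1:3]
    mat <- matrix(signals, prod(dims), d[4])
  }
  if (ncol(mat) != length(scheme$bvalues)) {
    stop("number of volumes does not match the scheme")
  }
  if (ncol(mat) < 7L) stop("tensor fit needs at least 7 volumes")

  b0 <- scheme$bvalues == 0
  if (sum(b0) > 1L) {
    mat <- cbind(rowMeans(mat[, b0, drop = FALSE]), mat[, !b0, drop = FALSE])
    b <- c(0, scheme$bvalues[!b0])
    g <- rbind(c(0, 0, 0), scheme$directions[!b0, , drop = FALSE])
  } else {
    b <- scheme$bvalues
    g <- scheme$directions
  }
  X <- cbind(1, -bmatrix_rows(b, g))
  qrx <- qr(X)
  if (qrx$rank < 7L) stop("gradient scheme defect: tensor design is rank-deficient")

  valid <- apply(mat, 1L, function(r) all(is.finite(r)) && all(r > 0))
  if (!is.null(mask)) valid <- valid & (as.integer(as_volume(mask, "mask")) != 0L)
  tensors <- matrix(NA_real_, nrow(mat), 6L)
  s0 <- rep(NA_real_, nrow(mat))
  if (any(valid)) {
    coefs <- qr.coef(qrx, t(log(mat[valid, , drop = FALSE])))  # 7 x nvalid
    s0[valid] <- exp(coefs[1L, ])
    tensors[valid, ] <- t(coefs[2:7, , drop = FALSE])
  }
  if (!is.null(dims)) {
    tensors <- array(tensors, c(dims, 6L))
    s0 <- array(s0, dims)
    valid <- array(valid, dims)
  }
  structure(list(tensors = tensors, S0 = s0, valid = valid),
            class = "tensor_fit")
}

#' Scalar metrics of a diffusion tensor
#'
#' Eigen-decomposes a symmetric tensor and reports the standard scalar maps:
#' fractional anisotropy
#' `FA = sqrt(3/2) sqrt(sum (li - MD)^2) / sqrt(sum li^2)`, mean diffusivity
#' `MD = (l1 + l2 + l3) / 3` (reported unchanged as ADC), axial diffusivity
#' `l1` and radial diffusivity `(l2 + l3) / 2`. Negative eigenvalues are
#' clamped to zero for the metric computation and lower the validity flag;
#' the FA of the zero tensor is defined as 0.
#'
#' @param D symmetric 3x3 matrix or length-6 vector (xx, yy, zz, xy, xz, yz),
#'   mm^2/s.
#' @return List: `eigenvalues` (descending), `FA`, `MD`, `ADC`,
#'   `lambda_parallel`, `lambda_perp`, `valid`.
#' @examples
#' m <- tensor_metrics(c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0))
#' round(m$FA, 3)  # 0.799
#' @export
tensor_metrics <- function(D) {
  if (is.matrix(D)) {
    stopifnot(all(dim(D) == c(3L, 3L)))
    sc <- max(abs(D), 1e-300)
    if (max(abs(D - t(D))) > 1e-8 * sc) stop("tensor is not symmetric")
    m <- (D + t(D)) / 2
  } else {
    stopifnot(length(D) == 6L)
    m <- tensor6_to_mat(D)
  }
  ev <- sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  valid <- all(ev >= -1e-12 * max(abs(ev), 1e-300))
  l <- pmax(ev, 0)
  md <- mean(l)
  ss <- sum(l^2)
  fa <- if (ss == 0) 0 else sqrt(1.5 * sum((l - md)^2) / ss)
  fa <- min(max(fa, 0), 1)
  list(eigenvalues = l, FA = fa, MD = md, ADC = md,
       lambda_parallel = l[1], lambda_perp = (l[2] + l[3]) / 2,
       valid = valid)
}

#' Voxelwise tensor metric maps
#'
#' @param fit a `tensor_fit` from [fit_tensor()], or a tensor field
#'   (dims x 6 array / n x 6 matrix).
#' @return List of arrays (or vectors for matrix input): `FA`, `MD`, `AD`
#'   (axial), `RD` (radial), logical `valid` (invalid fit voxels are NA in
#'   every map).
#' @export
tensor_metric_maps <- function(fit) {
  tensors <- if (inherits(fit, "tensor_fit")) fit$tensors else fit
  tm <- tensors_as_matrix(tensors)
  n <- nrow(tm$mat)
  fa <- md <- ad <- rd <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (i in seq_len(n)) {
    v <- tm$mat[i, ]
    if (any(!is.finite(v))) next
    m <- tensor_metrics(v)
    fa[i] <- m$FA; md[i] <- m$MD
    ad[i] <- m$lambda_parallel; rd[i] <- m$lambda_perp
    valid[i] <- m$valid
  }
  shape <- function(x) if (is.null(tm$dims)) x else array(x, tm$dims)
  list(FA = shape(fa), MD = shape(md), AD = shape(ad), RD = shape(rd),
       valid = shape(valid))
}

#' Mean-FA profile along the cord axis
#'
#' Per slice along the chosen axis, the unweighted mean FA over in-cord
#' voxels; slices with an empty mask are omitted. Positions are slice
#' centers, `(index - 0.5) * voxel_size`.
#'
#' @param fa_map 3D FA volume (array or NIfTI path).
#' @param cord_mask binary 3D mask (array or NIfTI path), nonempty.
#' @param axis `"x"`, `"y"` or `"z"` (array dimension 1, 2 or 3).
#' @param voxel_size slice thickness along the axis (mm).
#' @return An `axial_profile` data frame: `index`, `position_mm`, `mean_fa`.
#' @export
fa_axial_profile <- function(fa_map, cord_mask, axis = c("z", "x", "y"),
                             voxel_size = 1) {
  axis <- match.arg(axis)
  fa_map <- as_volume(fa_map, "fa_map")
  cord_mask <- as_volume(cord_mask, "cord_mask")
  stopifnot(identical(dim(fa_map), dim(cord_mask)))
  if (!any(cord_mask != 0)) stop("cord mask is empty")
  ax <- match(axis, c("x", "y", "z"))
  n <- dim(fa_map)[ax]
  idx <- integer(0)
  mfa <- numeric(0)
  for (i in seq_len(n)) {
    sl_fa <- slice_along(fa_map, ax, i)
    sl_m <- slice_along(cord_mask, ax, i) != 0
    sel <- sl_m & is.finite(sl_fa)
    if (!any(sel)) next
    idx <- c(idx, i)
    mfa <- c(mfa, mean(sl_fa[sel]))
  }
  out <- data.frame(index = idx, position_mm = (idx - 0.5) * voxel_size,
                    mean_fa = mfa)
  class(out) <- c("axial_profile", "data.frame")
  out
}

slice_along <- function(vol, ax, i) {
  switch(ax,
         vol[i, , , drop = TRUE],
         vol[, i, , drop = TRUE],
         vol[, , i, drop = TRUE])
}

#' Localize the injury epicenter at the minimum of the smoothed FA profile
#'
#' Smooths the profile with a moving average (window truncated at the ends)
#' and returns the argmin; a tied minimum run is resolved to its middle
#' element. An all-equal profile returns the midpoint with a warning.
#'
#' @param profile an `axial_profile` from [fa_axial_profile()], or a numeric
#'   vector of per-slice means.
#' @param smoothing_halfwidth moving-average halfwidth in slices (window
#'   `2 h + 1`).
#' @return List: `index` (slice index in the input volume), `position_mm`
#'   (NA for bare numeric input), `smoothed` (the smoothed profile).
#' @export
locate_epicenter <- function(profile, smoothing_halfwidth = 2L) {
  if (is.numeric(profile)) {
    vals <- profile
    idx <- seq_along(vals)
    pos <- rep(NA_real_, length(vals))
  } else {
    stopifnot(is.data.frame(profile), all(c("index", "mean_fa") %in% names(profile)))
    vals <- profile$mean_fa
    idx <- profile$index
    pos <- if ("position_mm" %in% names(profile)) profile$position_mm else rep(NA_real_, length(vals))
  }
  n <- length(vals)
  if (n < 3L) stop("profile needs at least 3 positions")
  h <- as.integer(smoothing_halfwidth)
  sm <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    mean(vals[lo:hi])
  }, numeric(1))
  if (max(sm) - min(sm) <= 1e-12 * max(abs(sm), 1)) {
    warning("degenerate (flat) FA profile; returning the midpoint")
    k <- ceiling(n / 2)
    return(list(index = idx[k], position_mm = pos[k], smoothed = sm))
  }
  tied <- which(sm <= min(sm) + 1e-12 * max(abs(sm), 1))
  # middle of the tied run containing the first minimum
  runs <- split(tied, cumsum(c(1L, diff(tied) != 1L)))
  run <- runs[[1L]]
  k <- run[ceiling(length(run) / 2)]
  list(index = idx[k], position_mm = pos[k], smoothed = sm)
}

#' Write tensor metric maps as NIfTI volumes
#'
#' @param maps output of [tensor_metric_maps()] (array form).
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_metric_maps <- function(maps, dir, prefix = "dti") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("FA", "MD", "AD", "RD")) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    RNifti::writeNifti(RNifti::asNifti(maps[[nm]]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
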