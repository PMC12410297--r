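#' Diffusion acquisition scheme
#'
#' Bundles b-values (s/mm^2) with unit gradient directions, one per volume.
#' At least one b = 0 volume and at least six non-collinear nonzero-b
#' directions are required for the tensor design to be full rank.
#'
#' @param bvalues numeric vector of b-values (s/mm^2), one per volume.
#' @param directions matrix of gradient directions, `n x 3` (or `3 x n`,
#'   FSL bvec layout, auto-transposed). Directions of nonzero-b volumes must
#'   be unit vectors within 1e-6; b = 0 rows may be zero.
#' @return A `diffusion_scheme` list with elements `bvalues`, `directions`.
#' @export
diffusion_scheme <- function(bvalues, directions) {
  directions <- as.matrix(directions)
  if (nrow(directions) == 3L && ncol(directions) != 3L) directions <- t(directions)
  stopifnot(ncol(directions) == 3L, length(bvalues) == nrow(directions))
  if (any(bvalues < 0)) stop("b-values must be nonnegative")
  if (!any(bvalues == 0)) stop("scheme needs at least one b = 0 volume")
  nz <- bvalues > 0
  if (sum(nz) < 6L) stop("scheme needs at least 6 nonzero-b directions")
  nrm <- sqrt(rowSums(directions[nz, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("nonzero-b directions must be unit vectors")
  if (qr(bmatrix_rows(bvalues[nz], directions[nz, , drop = FALSE]))$rank < 6L) {
    stop("gradient directions are collinear: tensor design is rank-deficient")
  }
  structure(list(bvalues = as.numeric(bvalues), directions = directions),
            class = "diffusion_scheme")
}

# Rows [b gx^2, b gy^2, b gz^2, 2 b gx gy, 2 b gx gz, 2 b gy gz]: the
# quadratic form b g' D g as a linear functional of the 6 unique tensor
# elements (order xx, yy, zz, xy, xz, yz).
bmatrix_rows <- function(b, g) {
  cbind(b * g[, 1]^2, b * g[, 2]^2, b * g[, 3]^2,
        2 * b * g[, 1] * g[, 2], 2 * b * g[, 1] * g[, 3], 2 * b * g[, 2] * g[, 3])
}

#' Default 30-direction single-shell scheme
#'
#' One b = 0 volume plus 30 directions at the given b-value; the direction
#' table was produced once by electrostatic-repulsion minimization on the
#' projective sphere and ships with the package as a text fixture.
#'
#' @param b shell b-value (s/mm^2).
#' @return A [diffusion_scheme()].
#' @export
default_diffusion_scheme <- function(b = 1000) {
  path <- system.file("extdata", "dwi_directions_30.txt", package = "cordquant",
                      mustWork = TRUE)
  g <- as.matrix(utils::read.table(path))
  diffusion_scheme(c(0, rep(b, nrow(g))), rbind(c(0, 0, 0), unname(g)))
}

#' Read / write FSL-style gradient tables
#'
#' `bvec` files hold three whitespace-separated rows (x, y, z across
#' volumes); `bval` files hold one row of b-values.
#'
#' @param bval_path,bvec_path file paths.
#' @return `read_fsl_gradients()` returns a [diffusion_scheme()].
#' @export
read_fsl_gradients <- function(bval_path, bvec_path) {
  b <- scan(bval_path, quiet = TRUE)
  g <- as.matrix(utils::read.table(bvec_path))
  diffusion_scheme(b, g)
}

#' @rdname read_fsl_gradients
#' @param scheme a [diffusion_scheme()].
#' @param prefix output path prefix; writes `<prefix>.bval`, `<prefix>.bvec`.
#' @export
write_fsl_gradients <- function(scheme, prefix) {
  stopifnot(inherits(scheme, "diffusion_scheme"))
  writeLines(paste(format(scheme$bvalues, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  tg <- t(scheme$directions)
  writeLines(apply(tg, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                            collapse = " ")),
             paste0(prefix, ".bvec"))
  invisible(c(paste0(prefix, ".bval"), paste0(prefix, ".bvec")))
}

# Tensor <-> 6-vector helpers (order xx, yy, zz, xy, xz, yz).
tensor6_to_mat <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

mat_to_tensor6 <- function(m) c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])

# Coerce a tensor field (4D array dims x 6, or n x 6 matrix) to a matrix,
# remembering spatial dims.
tensors_as_matrix <- function(tensors) {
  if (is.matrix(tensors)) {
    stopifnot(ncol(tensors) == 6L)
    list(mat = tensors, dims = NULL)
  } else {
    d <- dim(tensors)
    stopifnot(length(d) == 4L, d[4] == 6L)
    list(mat = matrix(tensors, prod(d[1:3]), 6L), dims = d[1:3])
  }
}

#' Simulate diffusion-weighted volumes from a tensor field
#'
#' Per voxel and volume, the noise-free signal is
#' `S = S0 exp(-b g' D g)`; Rician noise (the magnitude of a
#' complex-Gaussian-perturbed signal) is applied when `sigma > 0`.
#'
#' @param tensors tensor field: 4D array `(nx, ny, nz, 6)` or `n x 6` matrix,
#'   element order xx, yy, zz, xy, xz, yz (mm^2/s). Tensors must be positive
#'   semi-definite.
#' @param scheme a [diffusion_scheme()].
#' @param S0 noise-free b = 0 signal, `> 0`.
#' @param sigma Rician noise level (same units as `S0`); `0` is deterministic.
#' @param seed optional RNG seed.
#' @return Signal array `(nx, ny, nz, nvol)` (or `n x nvol` matrix for matrix
#'   input), with the scheme attached as the `"scheme"` attribute.
#' @export
simulate_dwi <- function(tensors, scheme, S0 = 1000, sigma = 0, seed = NULL) {
  stopifnot(inherits(scheme, "diffusion_scheme"), S0 > 0, sigma >= 0)
  tm <- tensors_as_matrix(tensors)
  check_psd(tm$mat, tm$dims)
  bm <- bmatrix_rows(scheme$bvalues, scheme$directions)  # nvol x 6
  expo <- tm$mat %*% t(bm)                                # nvox x nvol
  sig <- S0 * exp(-expo)
  if (sigma > 0) {
    sig <- with_seed(seed, {
      n <- length(sig)
      sqrt((sig + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
    })
  }
  out <- if (is.null(tm$dims)) sig else array(sig, c(tm$dims, nrow(bm)))
  attr(out, "scheme") <- scheme
  attr(out, "S0") <- S0
  out
}

check_psd <- function(mat, dims, tol = 1e-10) {
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    if (all(v == 0)) next
    ev <- eigen(tensor6_to_mat(v), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -tol * max(abs(ev), 1e-12)) {
      loc <- if (is.null(dims)) sprintf("row %d", i) else {
        ijk <- arrayInd(i, dims)
        sprintf("(%d, %d, %d)", ijk[1], ijk[2], ijk[3])
      }
      stop(sprintf("tensor at voxel %s is not positive semi-definite", loc))
    }
  }
  invisible(TRUE)
}

#' Spinal cord diffusion phantom with a lesion-site FA dip
#'
#' Builds a straight cord along the slice axis: in-cord voxels carry a
#' prolate tensor (principal axis along the cord); near the lesion slice the
#' tensor is blended toward an isotropic tensor of equal mean diffusivity,
#' producing a Gaussian dip in FA at constant MD. Out-of-cord voxels are
#' isotropic free-water-like.
#'
#' @param n_slices slices along the cord axis (3rd array dimension).
#' @param grid in-plane grid size (`grid x grid`).
#' @param radius in-plane cord radius in voxels.
#' @param dip_slice slice index of the lesion epicenter.
#' @param dip_depth blend weight at the epicenter, in `[0, 1)`; larger means
#'   deeper FA dip.
#' @param dip_sigma Gaussian width of the dip (slices).
#' @param lambdas healthy-cord eigenvalues `(axial, radial, radial)` in
#'   mm^2/s.
#' @return List with `tensors` (`grid x grid x n_slices x 6`), binary `mask`,
#'   and the `dip_slice`.
#' @export
cord_phantom_tensors <- function(n_slices = 80, grid = 7, radius = 2,
                                 dip_slice = 40, dip_depth = 0.6, dip_sigma = 3,
                                 lambdas = c(1.7, 0.3, 0.3) * 1e-3) {
  stopifnot(n_slices >= 3, dip_depth >= 0, dip_depth < 1)
  d_healthy <- diag(c(lambdas[2], lambdas[3], lambdas[1]))  # axis along z
  md <- mean(lambdas)
  d_iso <- diag(rep(md, 3))
  d_free <- diag(rep(2.0e-3, 3))
  ctr <- (grid + 1) / 2
  mask <- array(0L, c(grid, grid, n_slices))
  tensors <- array(0, c(grid, grid, n_slices, 6))
  for (z in seq_len(n_slices)) {
    w <- dip_depth * exp(-(z - dip_slice)^2 / (2 * dip_sigma^2))
    d_cord <- (1 - w) * d_healthy + w * d_iso
    for (x in seq_len(grid)) for (y in seq_len(grid)) {
      inside <- (x - ctr)^2 + (y - ctr)^2 <= radius^2
      mask[x, y, z] <- as.integer(inside)
      tensors[x, y, z, ] <- mat_to_tensor6(if (inside) d_cord else d_free)
    }
  }
  list(tensors = tensors, mask = mask, dip_slice = dip_slice)
}
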