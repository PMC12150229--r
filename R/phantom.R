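# Bi-tensor forward model and synthetic DWI phantoms.
#
# Signal model per voxel and gradient direction g at b-value b:
#   S(g, b) = S0 * [ (1 - f) * exp(-b g' D g) + f * exp(-b * d_w) ]
# with d_w the free-water diffusivity (3.0e-3 mm^2/s at body temperature).

#' Free-water diffusivity constant (mm^2/s)
#' @export
D_WATER <- 3.0e-3

#' Build a diffusion tensor from eigenvalues and a principal axis
#'
#' @param evals length-3 eigenvalues (mm^2/s), sorted or not; `evals[1]` is
#'   paired with the principal axis.
#' @param axis unit 3-vector for the principal eigenvector (default z).
#' @return 3 x 3 symmetric tensor.
#' @export
make_tensor <- function(evals, axis = c(0, 0, 1)) {
  stopifnot(length(evals) == 3L, all(evals > 0))
  v <- axis / sqrt(sum(axis^2))
  # complete an orthonormal frame around v
  h <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- h - sum(h * v) * v
  u <- u / sqrt(sum(u^2))
  w <- c(v[2] * u[3] - v[3] * u[2], v[3] * u[1] - v[1] * u[3],
         v[1] * u[2] - v[2] * u[1])
  evals[1] * tcrossprod(v) + evals[2] * tcrossprod(u) + evals[3] * tcrossprod(w)
}

#' Noiseless bi-tensor signal for one voxel
#'
#' @param f free-water fraction in [0, 1].
#' @param D 3 x 3 tissue tensor (mm^2/s).
#' @param gtab a [gradient_table()].
#' @param s0 non-diffusion-weighted signal.
#' @param d_water isotropic free-water diffusivity.
#' @return numeric vector, one signal per volume.
#' @export
bitensor_signal <- function(f, D, gtab, s0 = 1, d_water = D_WATER) {
  if (f < 0 || f > 1) fw_stop("f must lie in [0, 1]", "fwtrace_domain_error")
  b <- gtab$bvals
  g <- gtab$bvecs
  q <- rowSums((g %*% D) * g)          # g' D g per volume
  s0 * ((1 - f) * exp(-b * q) + f * exp(-b * d_water))
}

#' Generate a synthetic single-shell DWI phantom
#'
#' Simulates voxelwise signals from the two-compartment (tissue + free water)
#' model, optionally corrupted by Rician noise of the magnitude-MR kind, with
#' the generating parameters stored per voxel for recovery tests.
#'
#' @param n_voxels number of voxels.
#' @param f_values per-voxel free-water fractions in [0, 1] (recycled).
#' @param evals tissue-tensor eigenvalues: length 3 or n_voxels x 3 (mm^2/s).
#' @param axes principal-axis unit vectors: length 3 or n_voxels x 3;
#'   default z for every voxel.
#' @param bval diffusion weighting of the non-zero shell (s/mm^2).
#' @param n_directions number of diffusion-weighted directions.
#' @param n_b0 number of b = 0 volumes.
#' @param s0 noise-free b0 intensity.
#' @param snr signal-to-noise ratio defined on the b0 signal, or `NULL`
#'   for noiseless data. Noise is Rician: magnitude of the complex signal
#'   with i.i.d. Gaussian real/imaginary perturbations of SD `s0 / snr`.
#' @param seed RNG seed (used only when `snr` is finite).
#' @return Object of class `dwi_phantom`: list with `signals`
#'   (n_voxels x n_volumes), `gtab`, `truth` (data.frame with `f` and
#'   eigenvalues), `tensors` (list of 3 x 3), and `s0`.
#' @examples
#' ph <- generate_dwi_phantom(4, f_values = c(0, 0.2, 0.5, 1),
#'                            evals = c(1.7e-3, 0.2e-3, 0.2e-3))
#' dim(ph$signals)
#' @export
generate_dwi_phantom <- function(n_voxels, f_values,
                                 evals = c(1.7e-3, 0.2e-3, 0.2e-3),
                                 axes = NULL, bval = 1000, n_directions = 32,
                                 n_b0 = 1, s0 = 1000, snr = NULL, seed = 1L) {
  check_number(n_voxels, "n_voxels", lower = 1)
  check_number(bval, "bval", lower = 1e-6)
  f_values <- rep_len(as.numeric(f_values), n_voxels)
  if (any(f_values < 0 | f_values > 1)) {
    fw_stop("f_values must lie in [0, 1]", "fwtrace_domain_error")
  }
  if (is.null(dim(evals))) evals <- matrix(evals, n_voxels, 3, byrow = TRUE)
  if (any(evals <= 0)) fw_stop("eigenvalues must be positive", "fwtrace_domain_error")
  if (is.null(axes)) axes <- matrix(c(0, 0, 1), n_voxels, 3, byrow = TRUE)
  if (is.null(dim(axes))) axes <- matrix(axes, n_voxels, 3, byrow = TRUE)

  dirs <- sphere_directions(n_directions)
  gtab <- gradient_table(c(rep(0, n_b0), rep(bval, n_directions)),
                         rbind(matrix(0, n_b0, 3), dirs))
  tensors <- lapply(seq_len(n_voxels), function(i) make_tensor(evals[i, ], axes[i, ]))
  signals <- t(vapply(seq_len(n_voxels), function(i) {
    bitensor_signal(f_values[i], tensors[[i]], gtab, s0 = s0)
  }, numeric(length(gtab$bvals))))

  if (!is.null(snr)) {
    check_number(snr, "snr", lower = 1e-6)
    sigma <- s0 / snr
    withr_seed <- function(expr) { set.seed(as.integer(seed)); expr }
    signals <- withr_seed({
      n1 <- matrix(stats::rnorm(length(signals), 0, sigma), nrow(signals))
      n2 <- matrix(stats::rnorm(length(signals), 0, sigma), nrow(signals))
      sqrt((signals + n1)^2 + n2^2)
    })
  }

  structure(list(signals = signals, gtab = gtab,
                 truth = data.frame(f = f_values, lambda1 = evals[, 1],
                                    lambda2 = evals[, 2], lambda3 = evals[, 3]),
                 tensors = tensors, s0 = s0, snr = snr),
            class = "dwi_phantom")
}

#' @export
print.dwi_phantom <- function(x, ...) {
  cat("<dwi_phantom> ", nrow(x$signals), " voxels x ", ncol(x$signals),
      " volumes", if (is.null(x$snr)) ", noiseless" else
        sprintf(", Rician SNR %.3g", x$snr), "\n", sep = "")
  invisible(x)
}

#' Write a phantom as NIfTI + FSL bval/bvec
#'
#' Voxels are laid out along the first image axis of a (n, 1, 1, volumes)
#' 4-D image.
#' @param phantom a `dwi_phantom`.
#' @param prefix output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`.
#' @return Invisibly, the paths written.
#' @export
write_dwi_phantom <- function(phantom, prefix) {
  arr <- array(phantom$signals, dim = c(nrow(phantom$signals), 1, 1,
                                        ncol(phantom$signals)))
  nii <- file.path(paste0(prefix, ".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(arr), nii)
  write_bvalbvec(phantom$gtab, paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  invisible(c(nii, paste0(prefix, ".bval"), paste0(prefix, ".bvec")))
}
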