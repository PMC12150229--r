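#' Construct a diffusion gradient table
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs 3 x n or n x 3 matrix of gradient directions; vectors for
#'   non-zero b-values must be unit norm (tolerance 1e-6).
#' @return An object of class `gradient_table` with elements `bvals` (length n)
#'   and `bvecs` (n x 3).
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L && nrow(bvecs) == 3L) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3L || nrow(bvecs) != length(bvals)) {
    fw_stop("bvecs must be n x 3 (or 3 x n) matching length(bvals)",
            "fwtrace_input_error")
  }
  if (!any(bvals < 50)) {
    fw_stop("gradient table needs at least one b ~ 0 volume", "fwtrace_input_error")
  }
  nz <- bvals >= 50
  if (any(nz)) {
    nrm <- sqrt(rowSums(bvecs[nz, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      fw_stop("non-zero b-vectors must be unit norm (tol 1e-6)", "fwtrace_input_error")
    }
  }
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat("<gradient_table> ", length(x$bvals), " volumes (",
      sum(x$bvals < 50), " b0, shells: ",
      paste(sort(unique(round(x$bvals[x$bvals >= 50]))), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Evenly spread unit directions on the sphere
#'
#' Deterministic golden-angle (Fibonacci) spiral; adequate angular coverage
#' for single-shell tensor estimation at n >= 6.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Read / write FSL-style bval and bvec files
#'
#' FSL convention: one whitespace-separated row of b-values; three rows of
#' x/y/z gradient components.
#' @param path_bval,path_bvec file paths.
#' @return `read_bvalbvec`: a [gradient_table()].
#' @export
read_bvalbvec <- function(path_bval, path_bvec) {
  bvals <- scan(path_bval, quiet = TRUE)
  bv <- as.matrix(utils::read.table(path_bvec))
  gradient_table(bvals, bv)
}

#' @rdname read_bvalbvec
#' @param gtab a `gradient_table`.
#' @export
write_bvalbvec <- function(gtab, path_bval, path_bvec) {
  writeLines(paste(format(gtab$bvals, trim = TRUE, digits = 15),
                   collapse = " "), path_bval)
  m <- t(gtab$bvecs)
  writeLines(apply(m, 1L, function(r) {
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")
  }), path_bvec)
  invisible(c(path_bval, path_bvec))
}
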