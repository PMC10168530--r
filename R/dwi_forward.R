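#' Diffusion acquisition protocol
#'
#' Bundle of b-values and unit gradient directions, one per acquired volume.
#' b=0 volumes carry a zero direction vector.
#'
#' @param bvals Numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs 3 x n numeric matrix of gradient directions; columns at
#'   b > 0 must be unit-norm (tolerance 1e-6).
#' @return Object of class `dwi_protocol`.
#' @export
dwi_protocol <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3 || ncol(bvecs) != length(bvals))
    stop("bvecs must be a 3 x length(bvals) matrix", call. = FALSE)
  if (!any(bvals == 0))
    stop("protocol needs at least one b=0 volume for tensor fitting", call. = FALSE)
  nz <- which(bvals > 0)
  norms <- sqrt(colSums(bvecs[, nz, drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-6))
    stop("gradient directions at b > 0 must be unit-norm (tol 1e-6)", call. = FALSE)
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs), class = "dwi_protocol")
}

#' Default single-shell protocol
#'
#' 30 non-collinear b=800 s/mm^2 directions plus 5 interleaved b=0 volumes.
#' Directions are generated once by electrostatic repulsion on the sphere
#' (antipodally symmetric Coulomb energy) from a fixed seed, since the
#' acquisition's gradient table is not published.
#'
#' @param n_directions Number of diffusion-weighted directions.
#' @param b Shell b-value (s/mm^2).
#' @param n_b0 Number of b=0 volumes, interleaved through the series.
#' @param seed Seed for the repulsion initialization.
#' @return A [dwi_protocol()].
#' @export
default_protocol <- function(n_directions = 30L, b = 800, n_b0 = 5L, seed = 7L) {
  dirs <- repulsion_directions(n_directions, seed = seed)
  n_tot <- n_directions + n_b0
  # interleave b0 volumes evenly through the series
  b0_pos <- unique(round(seq(1, n_tot, length.out = n_b0)))
  bvals <- rep(b, n_tot)
  bvals[b0_pos] <- 0
  bvecs <- matrix(0, 3, n_tot)
  bvecs[, setdiff(seq_len(n_tot), b0_pos)] <- dirs
  dwi_protocol(bvals, bvecs)
}

# Electrostatic repulsion of n antipodally-symmetric unit vectors: Coulomb
# forces between all +/- pairs, capped per-point step, decaying step size.
repulsion_directions <- function(n, seed = 7L, n_iter = 400L, step = 0.05) {
  with_local_seed(seed, {
    x <- matrix(rnorm(3 * n), 3, n)
    x <- sweep(x, 2, sqrt(colSums(x^2)), "/")
    for (it in seq_len(n_iter)) {
      f <- matrix(0, 3, n)
      for (i in seq_len(n)) {
        d1 <- x[, i] - x
        d2 <- x[, i] + x
        r1 <- pmax(colSums(d1^2), 1e-8); r1[i] <- Inf
        r2 <- pmax(colSums(d2^2), 1e-8)
        f[, i] <- rowSums(sweep(d1, 2, r1^1.5, "/")) +
          rowSums(sweep(d2, 2, r2^1.5, "/"))
      }
      fn <- sqrt(colSums(f^2))
      f <- sweep(f, 2, pmax(fn, 1), "/")  # cap each point's move at unit force
      x <- x + step * (0.995^it) * f
      x <- sweep(x, 2, sqrt(colSums(x^2)), "/")
    }
    x
  })
}

tensor_to_matrix <- function(tensor) {
  if (is.matrix(tensor)) {
    stopifnot(all(dim(tensor) == c(3, 3)))
    return((tensor + t(tensor)) / 2)
  }
  stopifnot(length(tensor) == 6)
  t6 <- as.numeric(tensor)
  matrix(c(t6[1], t6[4], t6[5],
           t6[4], t6[2], t6[6],
           t6[5], t6[6], t6[3]), 3, 3)
}

matrix_to_tensor <- function(m) {
  c(Dxx = m[1, 1], Dyy = m[2, 2], Dzz = m[3, 3],
    Dxy = m[1, 2], Dxz = m[1, 3], Dyz = m[2, 3])
}

#' Predict diffusion-weighted signals from a tensor
#'
#' Mono-exponential tensor model `S = S0 * exp(-b * g' D g)`.
#'
#' @param tensor Diffusion tensor: either a symmetric 3x3 matrix or a
#'   6-vector `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)` in mm^2/s.
#' @param s0 Non-diffusion-weighted signal (> 0).
#' @param protocol A [dwi_protocol()].
#' @return Numeric signal vector, one value per protocol volume; equals `s0`
#'   exactly at every b=0 volume.
#' @export
predict_signal <- function(tensor, s0, protocol) {
  stopifnot(inherits(protocol, "dwi_protocol"))
  if (!is.numeric(s0) || length(s0) != 1 || s0 <= 0)
    stop("s0 must be a single positive number", call. = FALSE)
  D <- tensor_to_matrix(tensor)
  g <- protocol$bvecs
  quad <- colSums(g * (D %*% g))
  as.numeric(s0 * exp(-protocol$bvals * quad))
}

# 7-column log-linear design: log S = log S0 - b g' D g
tensor_design <- function(protocol) {
  g <- protocol$bvecs
  b <- protocol$bvals
  cbind(1,
        -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
        -2 * b * g[1, ] * g[2, ],
        -2 * b * g[1, ] * g[3, ],
        -2 * b * g[2, ] * g[3, ])
}

#' Fit a diffusion tensor by ordinary least squares on log-signals
#'
#' The classic first-pass estimator: regress `log(S)` on the 7-parameter
#' design (log S0 and the six unique tensor elements). Noiseless signals
#' from [predict_signal()] are recovered to machine precision.
#'
#' @param signals Positive signal vector, one per protocol volume.
#' @param protocol A [dwi_protocol()] with >= 7 volumes spanning six
#'   independent direction outer products.
#' @return List with `tensor` (named 6-vector), `s0`, `indefinite` (TRUE if
#'   any fitted eigenvalue is negative).
#' @export
fit_tensor_loglinear <- function(signals, protocol) {
  stopifnot(inherits(protocol, "dwi_protocol"))
  if (length(signals) != length(protocol$bvals))
    stop("signals length must match protocol volumes", call. = FALSE)
  bad <- which(!is.finite(signals) | signals <= 0)
  if (length(bad))
    stop(sprintf("non-positive signal at volume %d", bad[1]), call. = FALSE)
  X <- tensor_design(protocol)
  qrX <- qr(X)
  if (qrX$rank < 7)
    stop("rank-deficient design: protocol does not span 6 independent directions",
         call. = FALSE)
  beta <- qr.coef(qrX, log(signals))
  tensor <- c(Dxx = beta[2], Dyy = beta[3], Dzz = beta[4],
              Dxy = beta[5], Dxz = beta[6], Dyz = beta[7])
  names(tensor) <- c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")
  ev <- eigen(tensor_to_matrix(tensor), symmetric = TRUE, only.values = TRUE)$values
  list(tensor = tensor, s0 = exp(beta[[1]]), indefinite = any(ev < 0))
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' `FA = sqrt(3/2) * sqrt(sum((lambda - mean)^2)) / sqrt(sum(lambda^2))`,
#' a scalar in `[0, 1]`: 0 for isotropic diffusion, 1 for a single nonzero
#' eigenvalue. Scale-invariant.
#'
#' @param eigenvalues Numeric length-3, all >= 0 (floor negatives before
#'   calling), not all zero.
#' @return FA scalar.
#' @export
fractional_anisotropy <- function(eigenvalues) {
  ev <- as.numeric(eigenvalues)
  if (length(ev) != 3) stop("need exactly 3 eigenvalues", call. = FALSE)
  if (any(ev < 0))
    stop("eigenvalues must be non-negative (floor them first)", call. = FALSE)
  if (all(ev == 0))
    stop("FA undefined for all-zero eigenvalues", call. = FALSE)
  sqrt(1.5) * sqrt(sum((ev - mean(ev))^2)) / sqrt(sum(ev^2))
}

#' FA of a diffusion tensor, flooring negative eigenvalues
#'
#' @param tensor 6-vector or 3x3 symmetric matrix.
#' @return List with `fa` and `floored` (TRUE if any eigenvalue was negative
#'   and floored at 0 before the FA computation).
#' @export
tensor_fa <- function(tensor) {
  ev <- eigen(tensor_to_matrix(tensor), symmetric = TRUE, only.values = TRUE)$values
  floored <- any(ev < 0)
  ev <- pmax(ev, 0)
  list(fa = fractional_anisotropy(ev), floored = floored)
}

#' Read / write FSL-style bval/bvec text pairs
#'
#' `write_protocol` writes `<prefix>.bval` (one row of b-values) and
#' `<prefix>.bvec` (three rows: x, y, z components). `read_protocol` is the
#' inverse.
#'
#' @param protocol A [dwi_protocol()].
#' @param prefix Path prefix (without extension).
#' @return `read_protocol` returns a [dwi_protocol()];
#'   `write_protocol` returns the prefix invisibly.
#' @export
write_protocol <- function(protocol, prefix) {
  stopifnot(inherits(protocol, "dwi_protocol"))
  writeLines(paste(format(protocol$bvals, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  writeLines(apply(protocol$bvecs, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = " ")),
    paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(prefix) {
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  bv <- scan(paste0(prefix, ".bvec"), quiet = TRUE)
  bvecs <- matrix(bv, nrow = 3, byrow = TRUE)
  dwi_protocol(bvals, bvecs)
}
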