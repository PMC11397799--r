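#' Registration transforms
#'
#' A registration transform describes how the moving channel (typically NIR)
#' is displaced relative to the reference channel.
#'
#' Sign and mapping convention (fixed across the package): the transform
#' maps moving-frame pixel coordinates into reference-frame coordinates.
#' For a pure translation `(dy, dx)` the moving image satisfies
#' `moving(r, c) = reference(r - dy, c - dx)`, i.e. `(dy, dx)` is the
#' displacement of the moving content relative to the reference, and the
#' equivalent 2x3 matrix is `[I | -(dy, dx)]`.  For an affine matrix `M`
#' (row-major 2x3, acting on 0-based (row, col) coordinates),
#' `moving(q) = reference(M %*% c(q, 1))`.  [apply_transform()] inverts this
#' mapping to resample the moving channel into the reference frame.
#'
#' @param dy,dx Subpixel translation components in pixels (row, col).
#' @param matrix Optional 2x3 affine matrix superseding the pure
#'   translation.
#' @param moving_channel Which channel the transform applies to.
#' @param peak_confidence Correlation peak score in [0, 1] (for affine fits,
#'   a proxy derived from the tile-fit residual RMS; see
#'   [estimate_affine()]).
#' @return An object of class `registration_transform`.
#' @export
registration_transform <- function(dy = 0, dx = 0, matrix = NULL,
                                   moving_channel = "nir",
                                   peak_confidence = 1) {
  if (!is.null(matrix)) {
    matrix <- base::matrix(as.numeric(matrix), 2, 3)
    if (any(!is.finite(matrix)))
      stop_canopyspec("affine matrix entries must be finite",
                      "canopyspec_validation_error")
  }
  stopifnot(is.finite(dy), is.finite(dx))
  structure(list(dy = dy, dx = dx, matrix = matrix,
                 moving_channel = moving_channel,
                 peak_confidence = min(max(peak_confidence, 0), 1)),
            class = "registration_transform")
}

#' @export
print.registration_transform <- function(x, ...) {
  if (is.null(x$matrix)) {
    cat(sprintf("<registration_transform> translation (dy, dx) = (%.4g, %.4g), confidence %.3f\n",
                x$dy, x$dx, x$peak_confidence))
  } else {
    cat(sprintf("<registration_transform> affine (confidence %.3f):\n",
                x$peak_confidence))
    print(round(x$matrix, 5))
  }
  invisible(x)
}

is_identity_transform <- function(t, tol = 0) {
  if (is.null(t$matrix)) return(abs(t$dy) <= tol && abs(t$dx) <= tol)
  all(abs(t$matrix - cbind(diag(2), c(0, 0))) <= tol)
}

## transform as 2x3 matrix in the moving -> reference convention
transform_matrix <- function(t) {
  if (!is.null(t$matrix)) t$matrix else cbind(diag(2), -c(t$dy, t$dx))
}

## inverse of a 2x3 affine (also 2x3)
invert_affine <- function(M) {
  A <- M[, 1:2, drop = FALSE]
  Ai <- solve(A)
  cbind(Ai, -Ai %*% M[, 3])
}

## signed DFT sample frequencies (cycles per full extent)
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k
}

#' Translate an image by a (sub)pixel offset
#'
#' Produces `out(r, c) = img(r - dy, c - dx)`: positive `dy`/`dx` move
#' content down/right.  Fractional offsets are bilinearly interpolated;
#' integer offsets are exact.  Out-of-frame pixels take `fill`.
#'
#' @param img Numeric matrix.
#' @param dy,dx Offsets in pixels (row, col).
#' @param fill Value for pixels with no source.
#' @return Matrix of the same dimensions.
#' @export
translate_image <- function(img, dy, dx, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  rr <- matrix(seq_len(nr), nr, nc) - dy
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - dx
  bilinear_sample(img, rr, cc, fill = fill)
}

## bilinear interpolation at 1-based fractional coordinates; returns matrix
## with attribute "oob" marking out-of-frame queries (set to fill)
bilinear_sample <- function(img, rr, cc, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  pick <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- numeric(length(r))
    v[ok] <- img[(c[ok] - 1L) * nr + r[ok]]
    v
  }
  v <- pick(r0, c0) * (1 - fr) * (1 - fc) +
    pick(r0 + 1, c0) * fr * (1 - fc) +
    pick(r0, c0 + 1) * (1 - fr) * fc +
    pick(r0 + 1, c0 + 1) * fr * fc
  oob <- rr < 1 | rr > nr | cc < 1 | cc > nc
  v[oob] <- fill
  out <- matrix(v, nrow(rr), ncol(rr))
  attr(out, "oob") <- matrix(oob, nrow(rr), ncol(rr))
  out
}

## Catmull-Rom bicubic interpolation at 1-based fractional coordinate
## vectors; edge queries (within 1 px of the border) return NA
bicubic_sample_vec <- function(img, rr, cc) {
  nr <- nrow(img); nc <- ncol(img)
  kern <- function(t) {
    at <- abs(t)
    ifelse(at <= 1, 1.5 * at^3 - 2.5 * at^2 + 1,
           ifelse(at < 2, -0.5 * at^3 + 2.5 * at^2 - 4 * at + 2, 0))
  }
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  v <- numeric(length(rr))
  for (i in -1:2) {
    ri <- pmin(pmax(r0 + i, 1L), nr)
    wr <- kern(fr - i)
    acc <- numeric(length(rr))
    for (j in -1:2) {
      cj <- pmin(pmax(c0 + j, 1L), nc)
      acc <- acc + kern(fc - j) * img[(cj - 1L) * nr + ri]
    }
    v <- v + wr * acc
  }
  v[rr < 2 | rr > nr - 1 | cc < 2 | cc > nc - 1] <- NA_real_
  v
}

#' Estimate the translation between two rasters by phase correlation
#'
#' Finds the displacement of `moving` relative to `reference` as the peak
#' of the cross-correlation surface, optionally refined to `1/upsample`
#' pixel by evaluating an upsampled DFT of the cross-power spectrum around
#' the integer peak.  Both the coarse and the fine search weight the
#' cross-power spectrum by its magnitude and a gentle Gaussian low-pass
#' (sigma 0.15 cycles/px) rather than whitening it: sampled imagery is not
#' band-limited and carries an optical PSF, so equal-weight ("phase-only")
#' correlation amplifies noise at frequencies with no signal — measurably
#' biasing subpixel estimates and occasionally displacing the integer peak
#' — while magnitude weighting concentrates on frequencies that carry
#' signal.  `peak_confidence` is still the normalized phase-correlation
#' peak height, which lives on a fixed [0, 1] scale.
#'
#' @param reference,moving Numeric matrices of identical dimensions with
#'   nonzero variance.
#' @param upsample Positive integer subpixel refinement factor; 1 returns
#'   the integer-pixel peak.
#' @return A [registration_transform()] whose `(dy, dx)` satisfies
#'   `moving(r, c) ~= reference(r - dy, c - dx)` and whose
#'   `peak_confidence` is the normalized phase-correlation peak height.
#' @export
estimate_shift <- function(reference, moving, upsample = 1) {
  stopifnot(all(dim(reference) == dim(moving)), upsample >= 1)
  if (sd(reference) < 1e-12 || sd(moving) < 1e-12)
    stop_canopyspec("cannot register a constant (zero-variance) image",
                    "canopyspec_degenerate_image_error")
  nr <- nrow(reference); nc <- ncol(reference)
  a <- reference - mean(reference); b <- moving - mean(moving)
  R <- fft(a) * Conj(fft(b))
  Rn <- R / pmax(Mod(R), 1e-15)
  conf <- max(Re(fft(Rn, inverse = TRUE)) / length(Rn))
  kr <- fft_freqs(nr); kc <- fft_freqs(nc)
  f2 <- outer((kr / nr)^2, rep(1, nc)) + outer(rep(1, nr), (kc / nc)^2)
  W <- R * exp(-f2 / (2 * 0.15^2))
  cc <- Re(fft(W, inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc)) - 1L
  wrap <- function(p, n) if (p > n / 2) p - n else p
  d <- as.numeric(c(-wrap(pk[1], nr), -wrap(pk[2], nc)))
  if (upsample > 1) {
    S <- ceiling(1.5 * upsample)
    sr <- d[1] + (seq_len(2 * S + 1) - S - 1) / upsample
    sc <- d[2] + (seq_len(2 * S + 1) - S - 1) / upsample
    CC <- Re(exp(-2i * pi * outer(sr, kr) / nr) %*% W %*%
               t(exp(-2i * pi * outer(sc, kc) / nc)))
    pk2 <- arrayInd(which.max(CC), dim(CC))
    d <- c(sr[pk2[1]], sc[pk2[2]])
  }
  registration_transform(dy = d[1], dx = d[2], peak_confidence = conf)
}

#' Estimate a mild affine misalignment from tile displacements
#'
#' The image is divided into a `grid x grid` mosaic; each tile's
#' displacement is estimated with [estimate_shift()], and a 2x3 affine
#' matrix (moving-frame to reference-frame convention, see
#' [registration_transform()]) is least-squares fitted to the tile-center
#' displacement field.  When `refine = TRUE` (default) the fit is polished
#' by directly maximizing the normalized cross-correlation between the
#' reference and the warped moving image (Nelder-Mead over the 6 affine
#' parameters, bicubic resampling, both images pre-smoothed with a Gaussian
#' of `smooth_sigma` px to suppress interpolation/aliasing bias).
#' Correlation rather than intensity difference is used because different
#' wavelength channels share geometry but not intensity scale.
#'
#' `peak_confidence` is reported as `1 / (1 + rms)` where `rms` is the
#' root-mean-square residual (px) of the tile displacement field about the
#' fitted affine, so 1 means a perfectly affine field.
#'
#' @param reference,moving Numeric matrices of identical dimensions.
#' @param grid Tiles per side (>= 3).
#' @param upsample Subpixel factor for the per-tile shift estimates.
#' @param refine Polish the tile fit by intensity-based optimization.
#' @param smooth_sigma Pre-smoothing sigma (px) for the refinement stage.
#' @param conf_min Minimum per-tile phase-correlation peak for a tile to
#'   enter the fit.
#' @return A [registration_transform()] with a 2x3 `matrix`; its `(dy, dx)`
#'   is the implied displacement at the image center.
#' @export
estimate_affine <- function(reference, moving, grid = 4, upsample = 20,
                            refine = TRUE, smooth_sigma = 1.5,
                            conf_min = 0.05) {
  stopifnot(all(dim(reference) == dim(moving)))
  if (grid < 3)
    stop_canopyspec("affine estimation needs grid >= 3",
                    "canopyspec_validation_error")
  nr <- nrow(reference); nc <- ncol(reference)
  tr <- floor(nr / grid); tc <- floor(nc / grid)
  if (tr < 8 || tc < 8)
    stop_canopyspec("image too small for the requested tile grid",
                    "canopyspec_validation_error")
  P <- NULL; D <- NULL
  for (i in 0:(grid - 1)) for (j in 0:(grid - 1)) {
    rs <- (i * tr + 1):((i + 1) * tr); cs <- (j * tc + 1):((j + 1) * tc)
    rt <- reference[rs, cs]; mt <- moving[rs, cs]
    if (sd(rt) < 1e-9 || sd(mt) < 1e-9) next
    e <- estimate_shift(rt, mt, upsample = upsample)
    if (e$peak_confidence < conf_min) next
    ## displacement larger than a half tile is a wrapped/unreliable peak
    if (abs(e$dy) > tr / 2 || abs(e$dx) > tc / 2) next
    P <- rbind(P, c(i * tr + (tr - 1) / 2, j * tc + (tc - 1) / 2))
    D <- rbind(D, c(e$dy, e$dx))
  }
  if (is.null(P) || nrow(P) < 3)
    stop_canopyspec("fewer than 3 tiles produced a confident correlation peak",
                    "canopyspec_insufficient_signal_error")
  X <- cbind(P, 1)
  Y <- P - D                       # moving-frame coords of the tile centers
  M <- t(qr.solve(X, Y))
  rms <- sqrt(mean((X %*% t(M) - Y)^2))
  if (refine) M <- refine_affine_ncc(reference, moving, M, smooth_sigma)
  ctr <- c((nr - 1) / 2, (nc - 1) / 2)
  d_ctr <- ctr - (M[, 1:2] %*% ctr + M[, 3])
  registration_transform(dy = d_ctr[1], dx = d_ctr[2], matrix = M,
                         peak_confidence = 1 / (1 + rms))
}

## intensity-based polish of an affine initialization (see estimate_affine).
## The metric is negative Pearson correlation between the reference and the
## warped moving channel (bicubic resampling): different wavelengths share
## geometry but not intensity scale, so plain SSD would be dominated by
## band contrast while NCC is invariant to affine intensity maps.
refine_affine_ncc <- function(reference, moving, M0, smooth_sigma = 1.5,
                              stride = 2L) {
  nr <- nrow(reference); nc <- ncol(reference)
  ref <- EBImage::gblur(reference, smooth_sigma)
  mov <- EBImage::gblur(moving, smooth_sigma)
  border <- max(8L, ceiling(4 * smooth_sigma))
  rows <- seq(border + 1, nr - border, by = stride)
  cols <- seq(border + 1, nc - border, by = stride)
  p_r <- rep(rows - 1, times = length(cols))   # 0-based interior coords
  p_c <- rep(cols - 1, each = length(rows))
  refv <- ref[cbind(rep(rows, times = length(cols)),
                    rep(cols, each = length(rows)))]
  obj <- function(par) {
    Mi <- invert_affine(matrix(par, 2, 3))
    qr_ <- Mi[1, 1] * p_r + Mi[1, 2] * p_c + Mi[1, 3]
    qc_ <- Mi[2, 1] * p_r + Mi[2, 2] * p_c + Mi[2, 3]
    w <- bicubic_sample_vec(mov, qr_ + 1, qc_ + 1)
    ok <- !is.na(w)
    if (sum(ok) < 16 || sd(w[ok]) < 1e-12) return(0)
    -stats::cor(w[ok], refv[ok])
  }
  ps <- c(rep(2 / max(nr, nc), 4), 1, 1)
  o <- optim(as.vector(M0), obj, method = "Nelder-Mead",
             control = list(maxit = 800, parscale = ps, reltol = 1e-13))
  o <- optim(o$par, obj, method = "Nelder-Mead",
             control = list(maxit = 400, parscale = ps * 0.05,
                            reltol = 1e-14))
  matrix(o$par, 2, 3)
}

#' Resample the moving channel into the reference frame
#'
#' Applies the inverse of `transform` to the `moving_channel` raster
#' (bilinear interpolation), leaving every other channel untouched.  Pixels
#' whose source location falls outside the frame are set to 0 and flagged
#' in `stack$oob[[channel]]`, which index computations treat as invalid.
#' Identity transforms return the channel bitwise unchanged.
#'
#' @param stack A [spectral_stack()].
#' @param transform A [registration_transform()] whose `moving_channel` is
#'   present in the stack.
#' @return The stack with the moving channel re-registered.
#' @export
apply_transform <- function(stack, transform) {
  stopifnot(inherits(stack, "spectral_stack"),
            inherits(transform, "registration_transform"))
  ch <- transform$moving_channel
  img <- get_channel(stack, ch, "apply_transform")
  if (is_identity_transform(transform)) return(stack)
  nr <- nrow(img); nc <- ncol(img)
  if (is.null(transform$matrix)) {
    ## corrected(p) = moving(p + d): undo the displacement
    out <- translate_image(img, -transform$dy, -transform$dx, fill = 0)
  } else {
    Mi <- invert_affine(transform$matrix)
    p_r <- matrix(0:(nr - 1), nr, nc)
    p_c <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
    qr_ <- Mi[1, 1] * p_r + Mi[1, 2] * p_c + Mi[1, 3]
    qc_ <- Mi[2, 1] * p_r + Mi[2, 2] * p_c + Mi[2, 3]
    out <- bilinear_sample(img, qr_ + 1, qc_ + 1, fill = 0)
  }
  stack$channels[[ch]] <- pmin(pmax(unclass_matrix(out), 0), 1)
  stack$oob[[ch]] <- attr(out, "oob")
  stack
}

unclass_matrix <- function(x) { attr(x, "oob") <- NULL; x }
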