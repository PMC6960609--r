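# TV-L1 optical flow: R surface over the C++ solver, plus the colour-coded
# flow feature map consumed by the classifier.

#' TV-L1 solver parameters
#'
#' Defaults follow the standard duality-based TV-L1 parameterisation for
#' micro-expression work: `tau` 0.25 (dual step), `lam` 0.05 (data term
#' weight), `theta` 0.3 (coupling), `epsilon` 0.01 (stopping tolerance on
#' the mean absolute flow change), `eta` 0.5 (pyramid downscale), 3 scales
#' and 5 warpings per scale.
#'
#' @param tau dual ascent step size.
#' @param lam weight of the L1 data term; larger values trust the
#'   brightness-constancy residual more and smooth less.
#' @param theta coupling between the flow and its auxiliary field.
#' @param epsilon convergence tolerance for the inner loop.
#' @param eta pyramid downscale factor in (0, 1).
#' @param n_scales pyramid depth; @param n_warpings warps per scale.
#' @param max_inner_iters inner iteration cap per warp.
#' @param median_filter apply a 5-point median to the flow after each warp.
#' @param n_warpings,max_inner_iters,median_filter see above.
#' @return A `tvl1_params` list.
#' @export
tvl1_params <- function(tau = 0.25, lam = 0.05, theta = 0.3, epsilon = 0.01,
                        eta = 0.5, n_scales = 3, n_warpings = 5,
                        max_inner_iters = 300, median_filter = TRUE) {
  if (!(eta > 0 && eta < 1)) abort("`eta` must be in (0, 1)")
  if (any(c(tau, lam, theta, epsilon) <= 0)) abort("all weights must be > 0")
  if (n_scales < 1) abort("`n_scales` must be >= 1")
  structure(list(tau = tau, lam = lam, theta = theta, epsilon = epsilon,
                 eta = eta, n_scales = as.integer(n_scales),
                 n_warpings = as.integer(n_warpings),
                 max_inner_iters = as.integer(max_inner_iters),
                 median_filter = isTRUE(median_filter)),
            class = "tvl1_params")
}

#' Compute TV-L1 optical flow between two frames
#'
#' Coarse-to-fine estimation of the displacement field `U = (u, v)` mapping
#' `I0` coordinates toward `I1`, alternating the pointwise threshold update
#' of the auxiliary field with total-variation denoising of each flow
#' component (Chambolle dual projection). RGB inputs are converted to
#' luminance first.
#'
#' @param I0,I1 frames: `H x W` matrices or `H x W x 3` arrays of identical
#'   shape, intensities in `[0, 1]`.
#' @param params a [tvl1_params()].
#' @return A `flow_field` object: list with `u`, `v` (`H x W` matrices,
#'   displacement in pixels along x and y).
#' @export
compute_tvl1_flow <- function(I0, I1, params = tvl1_params()) {
  I0 <- to_grayscale(I0); I1 <- to_grayscale(I1)
  if (!identical(dim(I0), dim(I1))) abort("frames differ in shape")
  if (!all(is.finite(I0)) || !all(is.finite(I1))) abort("non-finite input")
  # the classical (tau, lam, theta) parameterisation is calibrated for 8-bit
  # intensities; rescale so the data term sees the 0-255 range
  I0 <- I0 * 255; I1 <- I1 * 255
  res <- .tvl1_flow_cpp(I0, I1, params$tau, params$lam, params$theta,
                        params$epsilon, params$eta, params$n_scales,
                        params$n_warpings, params$max_inner_iters,
                        params$median_filter)
  flow_field(res$u, res$v)
}

#' Construct a flow field
#' @param u,v `H x W` numeric matrices: x and y displacement in pixels.
#' @return A `flow_field` object.
#' @export
flow_field <- function(u, v) {
  stopifnot(is.matrix(u), is.matrix(v), all(dim(u) == dim(v)))
  if (!all(is.finite(u)) || !all(is.finite(v))) abort("flow must be finite")
  structure(list(u = u, v = v), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  mag <- sqrt(x$u^2 + x$v^2)
  cat(sprintf("<flow_field> %d x %d px; |U|: median %.3f, max %.3f\n",
              nrow(x$u), ncol(x$u), median(mag), max(mag)))
  invisible(x)
}

#' Pointwise TV-L1 threshold update
#'
#' The closed-form minimiser of the linearised L1 data term plus quadratic
#' coupling, for one pixel: with `g2 = |grad|^2` and residual `rho`,
#' the auxiliary flow is `U + lam*theta*grad` when `rho < -lam*theta*g2`,
#' `U - lam*theta*grad` when `rho > lam*theta*g2`, and `U - rho*grad/g2`
#' in between (`U` unchanged when `g2 = 0`). Total on all finite inputs.
#'
#' @param U numeric length-2 flow vector `(u, v)`.
#' @param rho brightness-constancy residual at the pixel.
#' @param grad length-2 warped spatial gradient of `I1`.
#' @param lam,theta data weight and coupling constant.
#' @return Length-2 numeric vector: the updated auxiliary flow.
#' @export
threshold_update <- function(U, rho, grad, lam = 0.05, theta = 0.3) {
  g2 <- sum(grad^2)
  lt <- lam * theta
  if (g2 == 0) return(U)
  if (rho < -lt * g2) U + lt * grad
  else if (rho > lt * g2) U - lt * grad
  else U - rho * grad / g2
}

#' Surrogate-energy trace of the inner alternation
#'
#' Runs the threshold / TV-denoise alternation at a single scale with the
#' TV proximal step iterated to near-convergence, returning the surrogate
#' energy `TV(U) + (1/2 theta)(U - U')^2 + lam*|rho(U')|` after each outer
#' iteration. Used to verify that the alternation is a descent scheme.
#'
#' @inheritParams compute_tvl1_flow
#' @param n_outer outer alternations to trace.
#' @param n_dual dual iterations per TV proximal solve.
#' @return Numeric vector of energies, length `n_outer`.
#' @export
tvl1_energy_trace <- function(I0, I1, params = tvl1_params(), n_outer = 20,
                              n_dual = 40) {
  .tvl1_energy_trace_cpp(to_grayscale(I0) * 255, to_grayscale(I1) * 255,
                         params$tau, params$lam, params$theta, n_outer, n_dual)
}

# ---- colour-coded feature map ----------------------------------------------

#' Render a flow field as a colour-coded feature map
#'
#' Middlebury-style colour wheel: hue encodes the flow direction
#' (`atan2(v, u)`), saturation the magnitude relative to `max_mag` (clipped
#' at 1), value is 1 everywhere -- so zero flow renders white and opposite
#' directions take opposite hues.
#'
#' @param flow a [flow_field()].
#' @param max_mag magnitude mapped to full saturation; `"auto"` (default)
#'   uses the 95th percentile of `|U|` (or a small floor for all-zero flow).
#' @return `H x W x 3` RGB array in `[0, 1]`.
#' @export
flow_to_feature_map <- function(flow, max_mag = "auto") {
  stopifnot(inherits(flow, "flow_field"))
  mag <- sqrt(flow$u^2 + flow$v^2)
  if (identical(max_mag, "auto")) {
    max_mag <- max(quantile(mag, 0.95), 1e-6)
  }
  if (!is_scalar_number(max_mag) || max_mag <= 0)
    abort("`max_mag` must be a positive number")
  h <- (atan2(flow$v, flow$u) / (2 * pi)) %% 1
  s <- clamp01(mag / max_mag)
  hsv_to_rgb_array(h, s)
}

# Vectorised HSV -> RGB with V = 1.
hsv_to_rgb_array <- function(h, s) {
  d <- dim(h)
  hh <- as.vector(h) * 6
  i <- floor(hh) %% 6
  f <- hh - floor(hh)
  sv <- as.vector(s)
  p <- 1 - sv
  q <- 1 - sv * f
  t <- 1 - sv * (1 - f)
  r <- ifelse(i == 0, 1, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, 1)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, 1, ifelse(i == 2, 1,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, 1, ifelse(i == 4, 1, q)))))
  out <- array(0, c(d, 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}

# ---- Middlebury .flo I/O ----------------------------------------------------

#' Read and write Middlebury .flo flow files
#'
#' Binary interchange format: magic float 202021.25, int32 width and height,
#' then row-major interleaved little-endian float32 `(u, v)` pairs.
#'
#' @param flow a [flow_field()]; @param file path to a `.flo` file.
#' @param file see above.
#' @return `read_flo()` returns a [flow_field()]; `write_flo()` returns
#'   `file` invisibly.
#' @export
write_flo <- function(flow, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(202021.25, con, size = 4, endian = "little")
  writeBin(as.integer(c(ncol(flow$u), nrow(flow$u))), con, size = 4,
           endian = "little")
  inter <- rbind(as.vector(t(flow$u)), as.vector(t(flow$v)))
  writeBin(as.vector(inter), con, size = 4, endian = "little")
  invisible(file)
}

#' @rdname write_flo
#' @export
read_flo <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  magic <- readBin(con, "numeric", 1, size = 4, endian = "little")
  if (abs(magic - 202021.25) > 1e-3) abort("not a .flo file (bad magic)")
  wh <- readBin(con, "integer", 2, size = 4, endian = "little")
  n <- wh[1] * wh[2]
  dat <- readBin(con, "numeric", 2 * n, size = 4, endian = "little")
  uv <- matrix(dat, nrow = 2)
  flow_field(matrix(uv[1, ], nrow = wh[2], byrow = TRUE),
             matrix(uv[2, ], nrow = wh[2], byrow = TRUE))
}
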