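#' Coarse-grained chemical diffusion by composed-kernel convolution
#'
#' Chemical transport follows the diffusion-decay equation
#' `dc/dt = D lap(c) - gamma c`.  An explicit 6-neighbour finite-difference
#' step on the patch lattice is a convolution with a 3x3x3 stencil whose
#' centre weight is `1 - 6*lambda - gamma*dt` and whose six face-neighbour
#' weights are `lambda = D*dt/dx^2`.  Non-negativity of the centre weight
#' gives the stability bound `dt <= dx^2 / (6 D)` (tightened slightly when
#' decay is folded into the step).  Because agents act on a much slower
#' 30-minute tick, the `m` micro-steps per tick are collapsed into a single
#' convolution with the m-fold self-convolved stencil, which is then
#' truncated to a dense central window with a measured, logged mass loss.
#'
#' @name diffusion
NULL

#' Explicit-step stability bound
#'
#' Largest micro time step keeping the 6-neighbour explicit scheme's centre
#' weight non-negative: `dx^2 / (6 D + gamma dx^2)` (the classical
#' `dx^2 / 6D` when `gamma = 0`).
#'
#' @param D Diffusivity, um^2/minute.
#' @param dx Patch width, um.
#' @param gamma Decay constant, 1/minute (default 0).
#' @return Bound in minutes; `Inf` when `D = 0` and `gamma = 0` (no
#'   constraint).
#' @export
#' @examples
#' stability_dt(900, 15) * 60  # 2.5 seconds
stability_dt <- function(D, dx, gamma = 0) {
  if (D < 0 || gamma < 0) stop("D and gamma must be non-negative")
  if (dx <= 0) stop("dx must be positive")
  denom <- 6 * D + gamma * dx^2
  if (denom == 0) return(Inf)
  dx^2 / denom
}

#' Choose the shared micro step and steps-per-tick
#'
#' One micro step `dt` is shared by all chemicals (set by the fastest
#' diffuser) so that a single `m = ceil(tick / dt_max)` applies per tick;
#' `dt` is then `tick / m` exactly, so `m * dt == tick` holds by
#' construction.
#'
#' @param tick Tick length in minutes (> 0).
#' @param specs List of `vf_chemical` objects.
#' @param dx Patch width, um.
#' @return List of class `vf_timescales`: `tick`, `micro_step` (minutes),
#'   `steps_per_tick` (integer m), `dt_max`.
#' @export
#' @examples
#' ts <- choose_timescales(30, default_chemical_specs(), 15)
#' ts$steps_per_tick  # 720
choose_timescales <- function(tick, specs, dx) {
  if (tick <= 0) stop("tick must be positive")
  bounds <- vapply(specs, function(s)
    stability_dt(s$diffusivity, dx, s$decay), numeric(1))
  dt_max <- min(bounds)
  if (!is.finite(dt_max)) {
    m <- 1L
  } else {
    m <- as.integer(ceiling(tick / dt_max - 1e-12))
  }
  structure(list(tick = tick, micro_step = tick / m,
                 steps_per_tick = m, dt_max = dt_max),
            class = "vf_timescales")
}

#' Single-micro-step diffusion stencil
#'
#' The 3x3x3 coefficient kernel of the explicit scheme: centre
#' `1 - 6*lambda - gamma*dt`, six face neighbours `lambda`, zero elsewhere.
#' Total mass is `1 - gamma*dt`.
#'
#' @param spec A `vf_chemical`.
#' @param dx Patch width, um.
#' @param dt Micro step, minutes; must satisfy the stability bound.
#' @return Object of class `vf_stencil` with `lam`, `decay_step` and the
#'   3x3x3 `weights` array.
#' @export
build_step_stencil <- function(spec, dx, dt) {
  lam <- spec$diffusivity * dt / dx^2
  gdt <- spec$decay * dt
  center <- 1 - 6 * lam - gdt
  if (center < -1e-12)
    stop(sprintf(
      "stability violated for %s: 1 - 6*lambda - gamma*dt = %.6g < 0 (dt = %g min)",
      spec$name, center, dt))
  center <- max(center, 0)
  w <- array(0, c(3, 3, 3))
  w[2, 2, 2] <- center
  w[1, 2, 2] <- w[3, 2, 2] <- lam
  w[2, 1, 2] <- w[2, 3, 2] <- lam
  w[2, 2, 1] <- w[2, 2, 3] <- lam
  structure(list(spec = spec, dx = dx, dt = dt, lam = lam,
                 decay_step = gdt, weights = w),
            class = "vf_stencil")
}

## good FFT sizes (factors 2, 3, 5) at or above n
good_fft_size <- function(n) {
  as.integer(stats::nextn(as.integer(n), c(2L, 3L, 5L)))
}

## place a centred kernel (odd width per axis) into an array of size `dims`
## circularly, origin at index [1, 1, 1].  Kernels wider than a dimension
## wrap around; coinciding positions accumulate (fold per axis).
embed_kernel <- function(weights, dims) {
  a <- weights
  for (axis in 1:3) a <- fold_axis(a, axis, dims[axis])
  a
}

fold_axis <- function(a, axis, n) {
  w <- dim(a)[axis]
  h <- (w - 1L) %/% 2L
  pos <- ((-h:h) %% n) + 1L
  dn <- dim(a)
  dn[axis] <- n
  out <- array(0, dn)
  if (!anyDuplicated(pos)) {
    idx <- list(seq_len(dn[1]), seq_len(dn[2]), seq_len(dn[3]))
    idx[[axis]] <- pos
    out[idx[[1]], idx[[2]], idx[[3]]] <- a
    return(out)
  }
  src <- list(seq_len(dim(a)[1]), seq_len(dim(a)[2]), seq_len(dim(a)[3]))
  dst <- list(seq_len(dn[1]), seq_len(dn[2]), seq_len(dn[3]))
  for (j in seq_len(w)) {
    src[[axis]] <- j
    dst[[axis]] <- pos[j]
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      out[dst[[1]], dst[[2]], dst[[3]]] + a[src[[1]], src[[2]], src[[3]]]
  }
  out
}

## extract the centred window of odd width `wd` from a circular array whose
## origin is at [1,1,1]
extract_window <- function(a, wd) {
  d <- dim(a)
  h <- (wd - 1L) %/% 2L
  ix <- ((-h[1]:h[1]) %% d[1]) + 1L
  iy <- ((-h[2]:h[2]) %% d[2]) + 1L
  iz <- ((-h[3]:h[3]) %% d[3]) + 1L
  a[ix, iy, iz]
}

#' Compose the per-tick diffusion kernel
#'
#' Self-convolves the single-step stencil `m` times and restricts the result
#' to a centred cubic window of at most `max_width` patches.  The
#' composition runs in the spectral domain: the stencil is transformed once,
#' raised elementwise to the m-th power by binary exponentiation (the
#' spectral form of repeated convolution-squaring) and transformed back on
#' an enclosing box, so the full `(2m+1)^3` support is never materialised.
#' The retained mass fraction is measured against the analytic untruncated
#' mass `(1 - gamma*dt)^m`.
#'
#' @param stencil A [build_step_stencil()] result.
#' @param m Number of micro steps per tick (>= 1).
#' @param max_width Odd cap on the kernel window width in patches.
#' @return Object of class `vf_kernel`: `weights` (width^3 array), `m`,
#'   `width`, `retained_mass_fraction`, `lam`, `decay_step`.
#' @export
compose_kernel <- function(stencil, m, max_width = 147L) {
  stopifnot(inherits(stencil, "vf_stencil"))
  m <- as.integer(m)
  if (m < 1) stop("m must be >= 1")
  if (max_width %% 2 == 0) stop("max_width must be odd")
  full_width <- 2L * m + 1L
  wd <- min(max_width, full_width)
  ## box large enough for an exact result when the support fits, else a
  ## margin beyond the window so folded tail mass is vanishingly small
  box <- good_fft_size(max(wd, min(full_width, wd + 32L), 3L))
  dims <- rep(box, 3L)
  spec <- .Call(C_rfft3, embed_kernel(stencil$weights, dims))
  spec_m <- .Call(C_cpow_int, spec, m)
  km <- .Call(C_irfft3, spec_m, dims)
  w <- extract_window(km, rep(wd, 3L))
  w[w < 0] <- 0          # spectral round-off
  w <- symmetrize_cubic(w)  # f_m is invariant under the 48 cube symmetries
  new_kernel(w, m, stencil)
}

## make a cubic centred kernel bitwise-invariant under the 48 cube
## symmetries by reading every voxel from the canonical representative of
## its orbit (sorted absolute offsets); removes ~1e-16 FFT asymmetries
symmetrize_cubic <- function(w) {
  wd <- dim(w)[1]
  h <- (wd - 1L) %/% 2L
  o <- abs(seq_len(wd) - (h + 1L))
  X <- array(o, dim(w))
  Y <- array(rep(o, each = wd), dim(w))
  Z <- array(rep(o, each = wd * wd), dim(w))
  lo <- pmin(X, Y, Z)
  hi <- pmax(X, Y, Z)
  mid <- X + Y + Z - lo - hi
  array(w[cbind(lo + h + 1L, mid + h + 1L, hi + h + 1L)], dim(w))
}

new_kernel <- function(weights, m, stencil) {
  mass <- sum(weights)
  target <- (1 - stencil$decay_step)^m
  structure(list(weights = weights, m = m, width = dim(weights)[1],
                 mass = mass, untruncated_mass = target,
                 retained_mass_fraction = min(1, mass / target),
                 lam = stencil$lam, decay_step = stencil$decay_step,
                 spec = stencil$spec),
            class = "vf_kernel")
}

#' Truncate a composed kernel to a narrower centred window
#'
#' Weights are *not* renormalised: the truncation loss is real, tracked in
#' `retained_mass_fraction` and surfaced in run logs.
#'
#' @param kernel A `vf_kernel`.
#' @param width Odd target width, at most the current width.
#' @return The truncated `vf_kernel`.
#' @export
truncate_kernel <- function(kernel, width) {
  stopifnot(inherits(kernel, "vf_kernel"))
  if (width %% 2 == 0) stop("width must be odd")
  if (width > kernel$width) stop("width exceeds current kernel width")
  h <- (kernel$width - 1L) %/% 2L
  hw <- (width - 1L) %/% 2L
  sel <- (h - hw + 1L):(h + hw + 1L)
  w <- kernel$weights[sel, sel, sel, drop = FALSE]
  k <- kernel
  k$weights <- array(w, rep(width, 3L))
  k$width <- as.integer(width)
  k$mass <- sum(w)
  k$retained_mass_fraction <- min(1, k$mass / k$untruncated_mass)
  k
}

#' Mass coverage of centred windows of increasing width
#'
#' @param kernel A `vf_kernel`.
#' @return Data frame with `width` (odd) and `mass_fraction` (relative to the
#'   kernel's own total mass, ending at 1 at full width).
#' @export
kernel_mass_curve <- function(kernel) {
  stopifnot(inherits(kernel, "vf_kernel"))
  W <- kernel$width
  h <- (W - 1L) %/% 2L
  co <- abs(seq_len(W) - (h + 1L))  # per-axis offset magnitude
  ## Chebyshev radius per voxel
  r <- array(0L, dim = dim(kernel$weights))
  for (i in seq_len(W)) r[i, , ] <- pmax(r[i, , ], co[i])
  for (j in seq_len(W)) r[, j, ] <- pmax(r[, j, ], co[j])
  for (k in seq_len(W)) r[, , k] <- pmax(r[, , k], co[k])
  mass_by_r <- vapply(0:h, function(rr) sum(kernel$weights[r == rr]),
                      numeric(1))
  cum <- cumsum(mass_by_r) / kernel$mass
  data.frame(width = 2L * (0:h) + 1L, mass_fraction = cum)
}

#' Width needed to retain a requested mass coverage
#' @param kernel A `vf_kernel`.
#' @param coverage Required fraction of the kernel's mass in (0, 1].
#' @return Smallest odd width whose centred window holds at least `coverage`.
#' @export
kernel_width_for_coverage <- function(kernel, coverage) {
  curve <- kernel_mass_curve(kernel)
  i <- which(curve$mass_fraction >= coverage - 1e-12)
  if (!length(i)) return(kernel$width)
  curve$width[i[1]]
}

#' Monte-Carlo estimate of truncated-kernel mass loss
#'
#' For the pure-diffusion kernel at the stability limit (`lambda = 1/6`,
#' `gamma = 0`) the m-step composed kernel is the distribution of an m-step
#' uniform walk on the face-neighbour lattice.  This routine simulates
#' independent walkers (via per-walker multinomial step counts over the six
#' directions, which is distributionally identical to stepping) and
#' estimates the probability of ending outside the centred cube of
#' half-width `half_width` -- i.e. the mass lost when the kernel is
#' truncated to width `2 * half_width + 1`.
#'
#' @param m Number of micro steps (e.g. 720 for a 30-minute tick at the
#'   stability limit of the fastest diffuser).
#' @param half_width Per-axis offset kept by the window (73 for width 147).
#' @param n_walkers Number of simulated walkers (>= 1).
#' @param lambda Per-direction step probability times 6 must be <= 1;
#'   default 1/6 (no laziness, the stability-limit walk).
#' @return List: `loss` (estimated mass fraction outside the window),
#'   `n_walkers`, `n_outside`, `se` (binomial standard error).
#' @export
kernel_truncation_loss_mc <- function(m, half_width, n_walkers = 1e6,
                                      lambda = 1 / 6) {
  if (lambda < 0 || 6 * lambda > 1 + 1e-12)
    stop("lambda must be in [0, 1/6]")
  n_walkers <- as.integer(n_walkers)
  p <- c(rep(lambda, 6), max(0, 1 - 6 * lambda))
  counts <- stats::rmultinom(n_walkers, size = m, prob = p)
  dx <- counts[1, ] - counts[2, ]
  dy <- counts[3, ] - counts[4, ]
  dz <- counts[5, ] - counts[6, ]
  outside <- abs(dx) > half_width | abs(dy) > half_width |
    abs(dz) > half_width
  n_out <- sum(outside)
  loss <- n_out / n_walkers
  list(loss = loss, n_walkers = n_walkers, n_outside = n_out,
       se = sqrt(loss * (1 - loss) / n_walkers))
}

## --- applying kernels to fields ------------------------------------------

## crop a kernel per axis to the largest width that can influence a grid of
## dims n (offsets beyond n-1 only touch absorbed, out-of-grid mass)
crop_kernel_to_grid <- function(weights, dims) {
  kd <- dim(weights)
  h <- (kd - 1L) %/% 2L
  heff <- pmin(h, dims - 1L)
  if (all(heff == h)) return(weights)
  sel <- function(i) (h[i] - heff[i] + 1L):(h[i] + heff[i] + 1L)
  weights[sel(1), sel(2), sel(3), drop = FALSE]
}

#' Precompute the spectral plan for repeated diffusion on one grid
#'
#' @param kernel A `vf_kernel`.
#' @param grid A `vf_grid` (or dims vector).
#' @param boundary `"absorbing"` (zero-padded linear convolution; chemical
#'   leaving the tissue is lost) or `"periodic"` (used by conservation
#'   tests).
#' @return Opaque plan object for [diffuse()].
#' @export
diffusion_plan <- function(kernel, grid, boundary = c("absorbing", "periodic")) {
  boundary <- match.arg(boundary)
  dims <- if (inherits(grid, "vf_grid")) grid_dims(grid) else as.integer(grid)
  if (any(kernel$weights < 0)) stop("kernel weights must be non-negative")
  if (boundary == "absorbing") {
    w <- crop_kernel_to_grid(kernel$weights, dims)
    h <- (dim(w) - 1L) %/% 2L
    P <- vapply(1:3, function(i) good_fft_size(dims[i] + h[i]), integer(1))
  } else {
    w <- kernel$weights
    P <- dims
  }
  kspec <- .Call(C_rfft3, embed_kernel(w, P))
  structure(list(boundary = boundary, dims = dims, P = P, kspec = kspec),
            class = "vf_diffusion_plan")
}

#' Diffuse a chemical field for one tick
#'
#' Convolves the field with the composed kernel.  With the default absorbing
#' boundary this is a zero-padded linear convolution cropped back to the
#' grid, so mass crossing the tissue boundary is lost; the periodic mode
#' wraps instead and exists for conservation checks.  Negative round-off is
#' clamped to zero.
#'
#' @param field 3D array of concentrations (or a `vf_world` chemical field).
#' @param kernel A `vf_kernel`, or a precomputed [diffusion_plan()].
#' @param boundary Boundary handling; ignored when `kernel` is a plan.
#' @return The diffused field (same dims).
#' @export
diffuse <- function(field, kernel, boundary = c("absorbing", "periodic")) {
  if (inherits(kernel, "vf_diffusion_plan")) {
    plan <- kernel
  } else {
    plan <- diffusion_plan(kernel, dim(field), match.arg(boundary))
  }
  dims <- dim(field)
  if (!identical(as.integer(dims), as.integer(plan$dims)))
    stop("field dims do not match the diffusion plan")
  P <- plan$P
  if (all(P == dims)) {
    padded <- field
  } else {
    padded <- array(0, P)
    padded[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])] <- field
  }
  fspec <- .Call(C_rfft3, padded)
  out <- .Call(C_irfft3, fspec * plan$kspec, P)
  res <- out[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]), drop = FALSE]
  dim(res) <- dims
  res[res < 0] <- 0
  res
}

#' Reference m-step stencil diffusion (naive oracle)
#'
#' Applies the 3x3x3 single-step stencil `m` times by direct neighbour
#' summation.  In absorbing mode the field is first zero-padded by `m`
#' patches per side so the m-fold stencil application equals the m-composed
#' kernel convolution exactly (chemical may wander outside the tissue block
#' and back within one tick; whatever ends outside is lost at the crop).
#' Much slower than the composed-kernel path; kept as the independent
#' reference the FFT path is verified against.
#'
#' @param field 3D concentration array.
#' @param stencil A [build_step_stencil()] result.
#' @param m Number of micro steps.
#' @param boundary `"absorbing"` (zero outside) or `"periodic"`.
#' @return The diffused field.
#' @export
diffuse_naive <- function(field, stencil, m,
                          boundary = c("absorbing", "periodic")) {
  boundary <- match.arg(boundary)
  if (boundary == "absorbing") {
    d0 <- dim(field)
    big <- array(0, d0 + 2L * m)
    big[m + seq_len(d0[1]), m + seq_len(d0[2]), m + seq_len(d0[3])] <- field
    out <- diffuse_naive(big, stencil, m, "periodic")
    return(out[m + seq_len(d0[1]), m + seq_len(d0[2]), m + seq_len(d0[3]),
               drop = FALSE])
  }
  lam <- stencil$lam
  c0 <- stencil$weights[2, 2, 2]
  d <- dim(field)
  shift <- function(a, axis, by) {
    ## shift contents by `by` (+1/-1) along axis, zero or periodic fill
    idx <- lapply(d, seq_len)
    src <- seq_len(d[axis]) - by
    if (boundary == "periodic") {
      src <- ((src - 1L) %% d[axis]) + 1L
      idx[[axis]] <- src
      return(array(a[idx[[1]], idx[[2]], idx[[3]]], d))
    }
    keep <- src >= 1L & src <= d[axis]
    out <- array(0, d)
    dst <- idx
    dst[[axis]] <- which(keep)
    idx[[axis]] <- src[keep]
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[idx[[1]], idx[[2]], idx[[3]]]
    out
  }
  f <- field
  for (step in seq_len(m)) {
    f <- c0 * f +
      lam * (shift(f, 1L, 1L) + shift(f, 1L, -1L) +
             shift(f, 2L, 1L) + shift(f, 2L, -1L) +
             shift(f, 3L, 1L) + shift(f, 3L, -1L))
  }
  f
}

#' Build per-chemical tick kernels for a configuration
#'
#' Chooses the shared micro step, composes each chemical's kernel to the
#' configured truncation policy (fixed `max_width`, or the narrowest window
#' reaching `min_mass_coverage`) and reports the per-tick truncation loss.
#'
#' @param config A [simulation_config()].
#' @param quiet Suppress the per-chemical loss message.
#' @return List of class `vf_kernel_set`: `timescales`, `kernels` (named by
#'   chemical), `max_loss`.
#' @export
build_kernels <- function(config, quiet = TRUE) {
  ts <- choose_timescales(config$tick_minutes, config$chemicals,
                          config$grid$patch_width)
  pol <- config$kernel
  kernels <- lapply(config$chemicals, function(spec) {
    st <- build_step_stencil(spec, config$grid$patch_width, ts$micro_step)
    if (!is.null(pol$max_width)) {
      compose_kernel(st, ts$steps_per_tick, as.integer(pol$max_width))
    } else {
      cov <- pol$min_mass_coverage %||% 0.993
      ## compose on a generous window, then shrink to the coverage target
      k <- compose_kernel(st, ts$steps_per_tick,
                          min(2L * ts$steps_per_tick + 1L, 147L))
      truncate_kernel(k, kernel_width_for_coverage(k, cov))
    }
  })
  names(kernels) <- names(config$chemicals)
  losses <- vapply(kernels, function(k) 1 - k$retained_mass_fraction,
                   numeric(1))
  if (!quiet)
    message(sprintf("kernel truncation loss per tick: max %.3g (%s)",
                    max(losses), names(which.max(losses))))
  if (!is.null(pol$max_width) && !is.null(pol$min_mass_coverage) &&
      max(losses) > 1 - pol$min_mass_coverage)
    warning(sprintf(
      "fixed kernel width %d retains less than the requested %.4g coverage",
      pol$max_width, pol$min_mass_coverage))
  structure(list(timescales = ts, kernels = kernels,
                 max_loss = max(losses)),
            class = "vf_kernel_set")
}

#' @export
print.vf_kernel <- function(x, ...) {
  cat(sprintf(
    "<composed kernel %s: m = %d, width = %d, retained mass = %.6f>\n",
    x$spec$name %||% "?", x$m, x$width, x$retained_mass_fraction))
  invisible(x)
}
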