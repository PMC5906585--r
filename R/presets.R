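#' Shipped configuration presets and synthetic test fields
#'
#' Three presets cover the scales the package is used at:
#' \describe{
#'   \item{human_full}{The physiological human vocal-fold scale: a
#'     1390 x 1006 x 110 lattice of 15-um patches (20.85 x 15.09 x 1.65 mm,
#'     153,817,400 patches) with 1.72 M neutrophils, 0.97 M macrophages and
#'     12.20 M fibroblasts.  Shipped for configuration arithmetic and
#'     documentation; running it needs cluster-class hardware.}
#'   \item{desk}{The same physics at roughly 1/10 per axis
#'     (139 x 101 x 11); patch width and tick are unchanged so the kernel
#'     maths is identical, and cell counts scale with the volume ratio.
#'     Runs a 7-day course on a single CPU.}
#'   \item{micro}{A 25^3 world for oracle-scale tests and smoke runs.}
#' }
#'
#' @param name Preset name.
#' @return A [simulation_config()].
#' @export
#' @examples
#' patch_count(make_preset("desk")$grid)  # 154429
make_preset <- function(name = c("desk", "micro", "human_full")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("preset_", name, ".yaml"),
                      package = "vfheal", mustWork = TRUE)
  read_config(path)
}

#' Synthetic chemical fields for tests and demonstrations
#'
#' @param kind One of `"zero"`, `"uniform"`, `"point"`, `"linear-gradient"`,
#'   `"random"`.
#' @param grid A `vf_grid` (or dims vector).
#' @param value Level: the uniform value, the point total mass, the gradient
#'   maximum, or the upper bound of the uniform random draw.
#' @param axis Gradient axis (1, 2 or 3) for `"linear-gradient"`.
#' @param at 0-based coordinates of the point mass (default: grid centre).
#' @param seed Seed for `"random"` (required there; ignored otherwise).
#' @return 3D array.
#' @export
make_field <- function(kind = c("zero", "uniform", "point",
                                "linear-gradient", "random"),
                       grid, value = 1, axis = 1L, at = NULL, seed = NULL) {
  kind <- match.arg(kind)
  dims <- if (inherits(grid, "vf_grid")) grid_dims(grid) else as.integer(grid)
  switch(kind,
    zero = array(0, dims),
    uniform = array(value, dims),
    point = {
      f <- array(0, dims)
      if (is.null(at)) at <- (dims - 1L) %/% 2L
      f[at[1] + 1L, at[2] + 1L, at[3] + 1L] <- value
      f
    },
    "linear-gradient" = {
      ramp <- seq(0, value, length.out = dims[axis])
      perm <- c(axis, setdiff(1:3, axis))
      aperm(array(ramp, dims[perm]), order(perm))
    },
    random = {
      if (is.null(seed)) stop("random fields require a seed")
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(seed)
      array(stats::runif(prod(dims), 0, value), dims)
    })
}
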