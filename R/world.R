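#' World state: fields, agents and bookkeeping
#'
#' A `vf_world` holds the complete simulation state at one published tick:
#' the eight chemical concentration fields, three ECM protein fields (each
#' split into an intact and a fragment layer), the tissue damage field in
#' \[0, 1\], the mobile agent population and a seedable RNG state.  All
#' per-patch fields are 3D arrays indexed `[x, y, z]` (1-based internally;
#' agent coordinates are stored 0-based to match the external interfaces).
#'
#' @name world
NULL

## --- deterministic RNG threading -----------------------------------------
## The world carries its own RNG state so that any sequence of operations is
## a pure function of (config, seed), independent of the caller's RNG.

rng_restore <- function(world) {
  assign(".Random.seed", world$rng_state, envir = globalenv())
  invisible(NULL)
}

rng_capture <- function(world) {
  world$rng_state <- get(".Random.seed", envir = globalenv())
  world
}

zero_field <- function(grid, fill = 0) {
  array(fill, dim = grid_dims(grid))
}

empty_agents <- function(n = 0L) {
  data.frame(kind = character(n), x = integer(n), y = integer(n),
             z = integer(n), activated = logical(n), age = integer(n),
             stringsAsFactors = FALSE)
}

#' Initialise a world from a configuration
#'
#' Chemical fields start at zero, ECM fields at the configured uninjured
#' baseline, damage at zero.  Initial neutrophils, macrophages and
#' fibroblasts are placed uniformly at random over the grid (wounding later
#' re-seeds platelets on damaged patches).  Two calls with the same
#' configuration (including seed) produce bit-identical worlds.
#'
#' @param config A [simulation_config()].
#' @return An object of class `vf_world` at tick 0.
#' @export
init_world <- function(config) {
  validate_config(config)
  grid <- config$grid
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  chems <- lapply(chemical_names(), function(nm) zero_field(grid))
  names(chems) <- chemical_names()
  ecm <- lapply(ecm_names(), function(nm)
    list(intact = zero_field(grid, config$baseline_ecm),
         fragments = zero_field(grid)))
  names(ecm) <- ecm_names()

  counts <- config$agents
  agents <- empty_agents()
  np <- patch_count(grid)
  for (kind in c("neutrophil", "macrophage", "fibroblast")) {
    n <- as.integer(counts[[kind]] %||% 0)
    if (n > 0) {
      idx <- sample.int(np, n, replace = TRUE)
      xyz <- patch_coords(grid, idx)
      agents <- rbind(agents, data.frame(
        kind = rep(kind, n), x = as.integer(xyz[, "x"]),
        y = as.integer(xyz[, "y"]), z = as.integer(xyz[, "z"]),
        activated = rep(FALSE, n), age = rep(0L, n),
        stringsAsFactors = FALSE))
    }
  }

  world <- structure(list(
    grid = grid, config = config,
    chemicals = chems, ecm = ecm,
    damage = zero_field(grid),
    agents = agents,
    secretion = NULL,
    entry_patches = integer(0),
    tick = 0L,
    log = list()
  ), class = "vf_world")
  world <- rng_capture(world)

  if (!is.null(config$wound)) {
    rules <- rule_table(config$rules)
    world <- apply_wound(world, config$wound$center, config$wound$radii,
                         config$wound$severity, rules)
  }
  world
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inflict an ellipsoidal wound
#'
#' Sets the damage field to `severity` inside the axis-aligned ellipsoid
#' `(dx/rx)^2 + (dy/ry)^2 + (dz/rz)^2 <= 1` around `center`, seeds platelets
#' on every damaged patch (degranulation source), deposits the platelet-
#' derived chemical bolus (TGF-beta1, IL-1beta, MMP8 by default) on damaged
#' patches, and records the surrounding entry region used for later cell
#' recruitment.
#'
#' @param world A `vf_world`.
#' @param center 0-based patch coordinates of the wound centre (length 3).
#' @param radii Per-axis radii in patches (> 0, length 3).
#' @param severity Damage level in \[0, 1\]; 0 leaves the world unwounded.
#' @param rules A [rule_table()]; defaults to the world's configured rules.
#' @return The wounded `vf_world`.
#' @export
apply_wound <- function(world, center, radii, severity,
                        rules = rule_table(world$config$rules)) {
  stopifnot(inherits(world, "vf_world"))
  grid <- world$grid
  if (length(center) != 3L || length(radii) != 3L)
    stop("center and radii must have length 3")
  if (any(radii <= 0)) stop("wound radii must be positive")
  if (!in_grid(grid, center[1], center[2], center[3]))
    stop("wound center lies outside the grid")
  if (severity < 0 || severity > 1) stop("severity must be in [0, 1]")
  if (severity == 0) return(world)

  dims <- grid_dims(grid)
  ax <- lapply(1:3, function(i) (seq_len(dims[i]) - 1 - center[i]) / radii[i])
  ## squared normalised distance, built axis by axis (outer sums)
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  mask <- d2 <= 1
  world$damage[mask] <- severity

  idx <- which(mask)
  dep <- rules$platelet$wound_deposit
  for (nm in names(dep))
    world$chemicals[[nm]][idx] <- world$chemicals[[nm]][idx] + dep[[nm]]

  per <- as.integer(rules$platelet$per_patch)
  if (per > 0) {
    pidx <- rep(idx, per)
    xyz <- patch_coords(grid, pidx)
    platelets <- data.frame(
      kind = rep("platelet", length(pidx)), x = as.integer(xyz[, "x"]),
      y = as.integer(xyz[, "y"]), z = as.integer(xyz[, "z"]),
      activated = rep(TRUE, length(pidx)), age = rep(0L, length(pidx)),
      stringsAsFactors = FALSE)
    world$agents <- rbind(world$agents, platelets)
  }

  world$entry_patches <- wound_entry_region(mask, rules$entry_margin)
  world
}

## undamaged patches within `margin` face-steps of the damaged region,
## found by repeated binary dilation with the 6-neighbour structuring element
wound_entry_region <- function(mask, margin) {
  dil <- mask
  d <- dim(mask)
  shift_or <- function(m) {
    out <- m
    out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
    out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
    if (d[3] > 1) {
      out[, , -1] <- out[, , -1] | m[, , -d[3]]
      out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
    }
    out
  }
  for (i in seq_len(margin)) dil <- shift_or(dil)
  which(dil & !mask)
}

#' Total damage mass and per-field totals
#' @param world A `vf_world`.
#' @return Named list of summary totals used by the time-series observer.
#' @export
world_totals <- function(world) {
  kinds <- agent_kinds()
  pop <- vapply(kinds, function(k) sum(world$agents$kind == k), numeric(1))
  chem <- vapply(world$chemicals, sum, numeric(1))
  intact <- vapply(world$ecm, function(e) sum(e$intact), numeric(1))
  frag <- vapply(world$ecm, function(e) sum(e$fragments), numeric(1))
  list(population = pop, chemicals = chem, ecm_intact = intact,
       ecm_fragments = frag, damage = sum(world$damage))
}

#' Export the agent population as CSV
#'
#' Columns: `kind, x, y, z, activated, age` with 0-based patch coordinates.
#'
#' @param world A `vf_world`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_agents_csv <- function(world, path) {
  utils::write.csv(world$agents, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.vf_world <- function(x, ...) {
  cat(sprintf("<world tick %d: %s patches, %d agents, total damage %.4g>\n",
              x$tick, format(patch_count(x), big.mark = ","),
              nrow(x$agents), sum(x$damage)))
  invisible(x)
}
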