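#' Simulation configuration
#'
#' Bundles everything a run needs: lattice geometry, chemical physics, agent
#' counts, wound geometry, tick length, kernel truncation policy, random seed
#' and rule-table overrides.  Configurations round-trip through YAML
#' ([read_config()] / [write_config()]); the shipped presets are YAML files
#' of this shape.
#'
#' @param grid A [grid_spec()] or list with `nx`, `ny`, `nz`, `patch_width`.
#' @param seed Integer random seed; every stochastic element of a run derives
#'   from it.
#' @param chemicals Named list of `vf_chemical` objects (all eight required);
#'   defaults to [default_chemical_specs()].
#' @param agents Named list/vector of initial cell counts for `neutrophil`,
#'   `macrophage`, `fibroblast` (platelets are created by wounding only).
#' @param wound `NULL` for an uninjured run, else list with `center` (0-based
#'   patch coordinates), `radii` (per-axis patch radii > 0) and `severity`
#'   in \[0, 1\].
#' @param tick_minutes Coarse time step in simulated minutes (default 30).
#' @param kernel Truncation policy: list with either `max_width` (odd patch
#'   count) or `min_mass_coverage` (fraction of composed-kernel mass the
#'   retained window must hold, default 0.993).
#' @param baseline_ecm Uninjured ECM level per patch (au); default 0.
#' @param rules Nested list of [rule_table()] overrides.
#' @param name Optional configuration name.
#' @return An object of class `vf_config`.
#' @export
simulation_config <- function(grid, seed,
                              chemicals = default_chemical_specs(),
                              agents = list(neutrophil = 0, macrophage = 0,
                                            fibroblast = 0),
                              wound = NULL,
                              tick_minutes = 30,
                              kernel = list(max_width = NULL,
                                            min_mass_coverage = 0.993),
                              baseline_ecm = 0,
                              rules = NULL,
                              name = "custom") {
  if (!inherits(grid, "vf_grid"))
    grid <- grid_spec(grid$nx, grid$ny, grid$nz,
                      if (is.null(grid$patch_width)) 15 else grid$patch_width)
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("a random seed must be provided")
  cfg <- structure(list(
    name = name, grid = grid, seed = as.integer(seed),
    chemicals = chemicals, agents = agents, wound = wound,
    tick_minutes = as.numeric(tick_minutes), kernel = kernel,
    baseline_ecm = as.numeric(baseline_ecm), rules = rules
  ), class = "vf_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "vf_config"))
  if (cfg$tick_minutes <= 0) stop("tick_minutes must be positive")
  if (!identical(sort(names(cfg$chemicals)), sort(chemical_names())))
    stop("configuration must specify exactly the eight known chemicals")
  for (ch in cfg$chemicals)
    if (!inherits(ch, "vf_chemical")) stop("invalid chemical spec")
  bad <- setdiff(names(cfg$agents), c("neutrophil", "macrophage", "fibroblast"))
  if (length(bad)) stop("unknown agent kind in initial counts: ", bad[1])
  counts <- unlist(cfg$agents)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("agent counts must be non-negative integers")
  if (sum(counts) > patch_count(cfg$grid))
    stop("initial agent counts exceed the number of patches")
  if (!is.null(cfg$wound)) {
    w <- cfg$wound
    if (length(w$center) != 3L || length(w$radii) != 3L)
      stop("wound center and radii must each have 3 components")
    if (!all(in_grid(cfg$grid, w$center[1], w$center[2], w$center[3])))
      stop("wound center lies outside the grid")
    if (any(w$radii <= 0)) stop("wound radii must be positive")
    if (w$severity < 0 || w$severity > 1)
      stop("wound severity must be in [0, 1]")
  }
  k <- cfg$kernel
  if (!is.null(k$max_width) &&
      (k$max_width < 1 || k$max_width %% 2 == 0))
    stop("kernel max_width must be a positive odd integer")
  if (!is.null(k$min_mass_coverage) &&
      (k$min_mass_coverage <= 0 || k$min_mass_coverage > 1))
    stop("kernel min_mass_coverage must be in (0, 1]")
  if (cfg$baseline_ecm < 0) stop("baseline_ecm must be non-negative")
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#' @param path Path to a YAML file shaped like the shipped presets.
#' @return A `vf_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  chems <- default_chemical_specs()
  if (!is.null(y$chemicals)) {
    for (entry in y$chemicals) {
      chems[[entry$name]] <- chemical_spec(
        entry$name,
        if (is.null(entry$diffusivity)) chems[[entry$name]]$diffusivity
        else entry$diffusivity,
        if (is.null(entry$decay)) 0 else entry$decay)
    }
  }
  wound <- y$wound
  if (!is.null(wound))
    wound <- list(center = as.numeric(wound$center),
                  radii = as.numeric(wound$radii),
                  severity = as.numeric(wound$severity))
  simulation_config(
    grid = grid_spec(y$grid$nx, y$grid$ny, y$grid$nz, y$grid$patch_width),
    seed = if (is.null(y$seed)) 1L else y$seed,
    chemicals = chems,
    agents = if (is.null(y$agents)) list(neutrophil = 0, macrophage = 0,
                                         fibroblast = 0) else y$agents,
    wound = wound,
    tick_minutes = if (is.null(y$tick_minutes)) 30 else y$tick_minutes,
    kernel = if (is.null(y$kernel))
      list(max_width = NULL, min_mass_coverage = 0.993) else y$kernel,
    baseline_ecm = if (is.null(y$baseline_ecm)) 0 else y$baseline_ecm,
    rules = y$rules,
    name = if (is.null(y$name)) "custom" else y$name)
}

#' Write a simulation configuration to YAML
#' @param cfg A `vf_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  y <- list(
    name = cfg$name,
    grid = list(nx = cfg$grid$nx, ny = cfg$grid$ny, nz = cfg$grid$nz,
                patch_width = cfg$grid$patch_width),
    seed = cfg$seed,
    tick_minutes = cfg$tick_minutes,
    chemicals = unname(lapply(cfg$chemicals, function(ch)
      list(name = ch$name, diffusivity = ch$diffusivity, decay = ch$decay))),
    agents = cfg$agents,
    wound = cfg$wound,
    kernel = cfg$kernel,
    baseline_ecm = cfg$baseline_ecm,
    rules = cfg$rules)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @export
print.vf_config <- function(x, ...) {
  cat(sprintf("<simulation config '%s'>\n", x$name))
  print(x$grid)
  cat(sprintf("  tick = %g min, seed = %d\n", x$tick_minutes, x$seed))
  cat(sprintf("  initial cells: %s\n",
              paste(names(x$agents), unlist(x$agents), sep = "=",
                    collapse = " ")))
  if (!is.null(x$wound))
    cat(sprintf("  wound: center (%s), radii (%s), severity %g\n",
                paste(x$wound$center, collapse = ","),
                paste(x$wound$radii, collapse = ","), x$wound$severity))
  invisible(x)
}
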