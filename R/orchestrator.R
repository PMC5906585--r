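#' Tick orchestration: phase plan, barriers and double buffering
#'
#' One tick executes the fixed phase sequence seed cells -> cell function ->
#' ECM function -> ECM fragmentation -> chemical diffusion -> world update.
#' Agent-side phases read the chemical fields published at tick start and
#' write secretions to a separate buffer; diffusion consumes published
#' fields plus the full secretion buffer once all secreting phases have
#' passed (the secretion barrier); the update phase alone publishes new
#' state.  Because of this dataflow the "overlapped" plan -- which computes
#' diffusion while the remaining coarse-grain work (ECM fragmentation,
#' bookkeeping) proceeds -- is guaranteed to produce bit-identical results
#' to the sequential plan, and the test suite verifies it does.
#'
#' @name orchestrator
NULL

#' Phase execution plan
#'
#' @param mode `"sequential"` runs every phase in order with diffusion last
#'   before the update; `"overlapped"` schedules diffusion at the secretion
#'   barrier, alongside the remaining coarse-grain phases.  Results are
#'   identical by construction; the two plans exist to make that claim
#'   testable.
#' @param chemical_state Which chemical state agents read within a tick:
#'   `"pre-diffusion"` (default: the previous tick's published fields;
#'   this tick's secretions diffuse in this tick's diffusion phase) or
#'   `"post-diffusion"` (fields are diffused first, agents read the fresh
#'   state, and this tick's secretions join the fields undiffused, to
#'   diffuse next tick).
#' @param agent_workers,field_workers Informational worker hints carried in
#'   run logs; execution in this implementation is single-threaded.
#' @return An object of class `vf_plan`.
#' @export
phase_plan <- function(mode = c("sequential", "overlapped"),
                       chemical_state = c("pre-diffusion", "post-diffusion"),
                       agent_workers = 1L, field_workers = 1L) {
  structure(list(mode = match.arg(mode),
                 chemical_state = match.arg(chemical_state),
                 agent_workers = as.integer(agent_workers),
                 field_workers = as.integer(field_workers)),
            class = "vf_plan")
}

diffuse_chemicals <- function(world, kernels) {
  plans <- attr(kernels, "plans")
  if (is.null(plans)) {
    plans <- lapply(kernels$kernels, diffusion_plan, grid = world$grid)
  }
  out <- world$chemicals
  for (nm in names(out)) {
    f <- out[[nm]]
    if (!is.null(world$secretion)) f <- f + world$secretion[[nm]]
    out[[nm]] <- diffuse(f, plans[[nm]])
  }
  out
}

#' Attach cached per-grid diffusion plans to a kernel set
#'
#' Precomputes the spectral plans for every chemical on a fixed grid so
#' repeated ticks skip the kernel transforms.
#'
#' @param kernels A [build_kernels()] result.
#' @param grid A `vf_grid`.
#' @return The kernel set with plans attached.
#' @export
prepare_kernels <- function(kernels, grid) {
  attr(kernels, "plans") <- lapply(kernels$kernels, diffusion_plan,
                                   grid = grid)
  kernels
}

#' Execute one simulation tick
#'
#' @param world A published `vf_world`.
#' @param rules A [rule_table()].
#' @param kernels A [build_kernels()] result (ideally passed through
#'   [prepare_kernels()] for the world's grid).
#' @param plan A [phase_plan()].
#' @return The next published world (tick advanced by one).  Any phase
#'   failure aborts the tick; the caller's world remains the last published
#'   state.
#' @export
run_tick <- function(world, rules = rule_table(world$config$rules),
                     kernels, plan = phase_plan()) {
  stopifnot(inherits(world, "vf_world"), inherits(kernels, "vf_kernel_set"))
  if (!identical(sort(names(kernels$kernels)), sort(chemical_names())))
    stop("kernels must be prepared for all eight chemicals")
  w <- world
  w$secretion <- NULL
  w <- ensure_secretion(w)
  w$log <- list()

  if (identical(plan$chemical_state, "post-diffusion")) {
    ## diffuse first; agents read the fresh fields, their secretions join
    ## the published state undiffused and diffuse next tick
    w$chemicals <- diffuse_chemicals(w, kernels)
    w <- seed_cells(w, rules)
    w <- cell_function(w, rules)
    w <- ecm_function(w, rules)
    w <- ecm_fragmentation(w, rules)
    for (nm in names(w$chemicals))
      w$chemicals[[nm]] <- w$chemicals[[nm]] + w$secretion[[nm]]
    w$secretion <- NULL
    w$tick <- w$tick + 1L
    return(w)
  }

  w <- seed_cells(w, rules)
  w <- cell_function(w, rules)
  w <- ecm_function(w, rules)
  ## secretion barrier: all chemical sources for this tick are now buffered
  if (plan$mode == "overlapped") {
    chems_next <- diffuse_chemicals(w, kernels)  # field-phase work
    w <- ecm_fragmentation(w, rules)             # remaining coarse grain
  } else {
    w <- ecm_fragmentation(w, rules)
    chems_next <- diffuse_chemicals(w, kernels)
  }
  ## world update: the only phase that publishes state
  w$chemicals <- chems_next
  w$secretion <- NULL
  w$tick <- w$tick + 1L
  w
}

#' Run a simulation for a number of ticks
#'
#' Applies [run_tick()] repeatedly, collecting a per-tick time series of
#' population counts, chemical totals, ECM totals and total damage, and
#' invoking any observers after each publish.  Observer failures are logged
#' as warnings and do not stop the run.
#'
#' @param world A `vf_world`.
#' @param n_ticks Number of ticks (>= 0); 336 ticks are 7 simulated days at
#'   the default 30-minute tick.
#' @param rules A [rule_table()].
#' @param kernels A [build_kernels()] result; built from the world's
#'   configuration when missing.
#' @param plan A [phase_plan()].
#' @param observers Named list of functions `f(world)` called after each
#'   published tick.
#' @param progress Print a line every `progress` ticks (0 = quiet).
#' @return List of class `vf_run`: `world` (final state) and `timeseries`
#'   (data frame, one row per published tick including tick 0).
#' @export
run <- function(world, n_ticks, rules = rule_table(world$config$rules),
                kernels = NULL, plan = phase_plan(), observers = list(),
                progress = 0) {
  stopifnot(n_ticks >= 0)
  if (is.null(kernels)) kernels <- build_kernels(world$config)
  if (is.null(attr(kernels, "plans")))
    kernels <- prepare_kernels(kernels, world$grid)
  rows <- vector("list", n_ticks + 1L)
  rows[[1L]] <- timeseries_row(world)
  for (i in seq_len(n_ticks)) {
    world <- run_tick(world, rules, kernels, plan)
    rows[[i + 1L]] <- timeseries_row(world)
    for (nm in names(observers)) {
      tryCatch(observers[[nm]](world), error = function(e)
        warning(sprintf("observer '%s' failed at tick %d: %s",
                        nm, world$tick, conditionMessage(e)), call. = FALSE))
    }
    if (progress > 0 && i %% progress == 0)
      message(sprintf("tick %d / %d (%d agents)", i, n_ticks,
                      nrow(world$agents)))
  }
  structure(list(world = world, timeseries = do.call(rbind, rows)),
            class = "vf_run")
}

timeseries_row <- function(world) {
  tt <- world_totals(world)
  row <- data.frame(tick = world$tick,
                    time_min = world$tick * world$config$tick_minutes)
  for (k in names(tt$population)) row[[paste0("n_", k)]] <- tt$population[[k]]
  for (k in names(tt$chemicals)) row[[paste0("chem_", k)]] <- tt$chemicals[[k]]
  for (k in names(tt$ecm_intact))
    row[[paste0("ecm_", k, "_intact")]] <- tt$ecm_intact[[k]]
  for (k in names(tt$ecm_fragments))
    row[[paste0("ecm_", k, "_fragments")]] <- tt$ecm_fragments[[k]]
  row$damage_total <- tt$damage
  row
}

#' @export
print.vf_run <- function(x, ...) {
  cat(sprintf("<simulation run: %d published ticks>\n",
              nrow(x$timeseries) - 1L))
  print(x$world)
  invisible(x)
}
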