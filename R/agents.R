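#' Per-tick agent and ECM behaviour
#'
#' The four phases below implement one tick of cellular activity.  Every
#' phase reads the chemical fields *published at the start of the tick*
#' (post-diffusion state of the previous tick); everything a phase writes --
#' secreted chemicals, ECM changes, agent moves -- is merged before the
#' diffusion barrier, so the tick result does not depend on how phases are
#' interleaved by the orchestrator.
#'
#' @name agent_engine
NULL

## ensure the per-tick secretion buffer exists
ensure_secretion <- function(world) {
  if (is.null(world$secretion)) {
    world$secretion <- lapply(world$chemicals, function(f)
      zero_field(world$grid))
  }
  world
}

agent_patch_index <- function(world, rows = NULL) {
  a <- if (is.null(rows)) world$agents else world$agents[rows, , drop = FALSE]
  patch_index(world$grid, a$x, a$y, a$z)
}

#' Recruit inflammatory cells from the surrounding tissue
#'
#' For each mobile kind the Poisson recruitment mean is
#' `rate * S / scale`, where `S` is the kind's weighted attractant total
#' over the entry region (the undamaged shell around the wound recorded by
#' [apply_wound()]); recruits are placed uniformly over that region,
#' unactivated, age 0.  With no wound (empty entry region) or zero
#' attractant the mean is 0 and nothing is recruited.
#'
#' @param world A `vf_world`.
#' @param rules A [rule_table()].
#' @return The world with recruits appended (and an updated RNG state).
#' @export
seed_cells <- function(world, rules = rule_table(world$config$rules)) {
  world <- ensure_secretion(world)
  entry <- world$entry_patches
  if (!length(entry)) return(world)
  rng_restore(world)
  recruited <- 0L
  for (kind in names(rules$recruitment)) {
    pol <- rules$recruitment[[kind]]
    S <- 0
    for (nm in names(pol$signal))
      S <- S + pol$signal[[nm]] * sum(world$chemicals[[nm]][entry])
    mu <- pol$rate * S / pol$scale
    n <- stats::rpois(1L, mu)
    if (n > 0) {
      idx <- entry[sample.int(length(entry), n, replace = TRUE)]
      xyz <- patch_coords(world$grid, idx)
      world$agents <- rbind(world$agents, data.frame(
        kind = rep(kind, n), x = as.integer(xyz[, "x"]),
        y = as.integer(xyz[, "y"]), z = as.integer(xyz[, "z"]),
        activated = rep(FALSE, n), age = rep(0L, n),
        stringsAsFactors = FALSE))
      recruited <- recruited + n
    }
  }
  world$log$recruited <- recruited
  rng_capture(world)
}

## chemotaxis score field for one kind: weighted sum of attractant fields
chemotaxis_score <- function(world, weights) {
  S <- NULL
  for (nm in names(weights)) {
    term <- weights[[nm]] * world$chemicals[[nm]]
    S <- if (is.null(S)) term else S + term
  }
  S
}

## one biased-walk step for agents at 0-based coords (matrix n x 3):
## with prob p_follow move to the strictly-best of the 6 face neighbours
## (ties: stay if the best does not beat the current patch, else a seeded
## uniform choice among tied neighbours); otherwise step to a uniform
## neighbour, staying put if the drawn neighbour is off-grid.
step_agents <- function(grid, pos, S, p_follow) {
  n <- nrow(pos)
  if (n == 0L) return(pos)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  self <- S[patch_index(grid, pos[, 1], pos[, 2], pos[, 3])]
  sc <- matrix(-Inf, n, 6)
  for (d in 1:6) {
    nx <- pos[, 1] + offs[d, 1]
    ny <- pos[, 2] + offs[d, 2]
    nz <- pos[, 3] + offs[d, 3]
    ok <- in_grid(grid, nx, ny, nz)
    if (any(ok))
      sc[ok, d] <- S[patch_index(grid, nx[ok], ny[ok], nz[ok])]
  }
  ## RNG draws in fixed order: follow coin, tie-break, uniform direction
  follow <- stats::runif(n) < p_follow
  pick <- max.col(sc, ties.method = "random")
  best <- sc[cbind(seq_len(n), pick)]
  rand_dir <- sample.int(6L, n, replace = TRUE)
  move_dir <- integer(n)            # 0 = stay
  take_best <- follow & best > self # strict improvement, ties stay
  move_dir[take_best] <- pick[take_best]
  explore <- !follow
  if (any(explore)) {
    d <- rand_dir[explore]
    tx <- pos[explore, 1] + offs[d, 1]
    ty <- pos[explore, 2] + offs[d, 2]
    tz <- pos[explore, 3] + offs[d, 3]
    ok <- in_grid(grid, tx, ty, tz)
    md <- ifelse(ok, d, 0L)
    move_dir[explore] <- md
  }
  moved <- move_dir > 0L
  if (any(moved)) {
    d <- move_dir[moved]
    pos[moved, 1] <- pos[moved, 1] + offs[d, 1]
    pos[moved, 2] <- pos[moved, 2] + offs[d, 2]
    pos[moved, 3] <- pos[moved, 3] + offs[d, 3]
  }
  pos
}

#' Cell function phase: migration, secretion, ECM work, proliferation, death
#'
#' Agents are processed in a seeded random order.  Each mobile agent takes
#' one chemotaxis step (see [rule_table()] for weights and `p_follow`), then
#' activation is re-evaluated (sticky: any activation chemical above its
#' threshold on the agent's patch).  Activated agents secrete their kind's
#' chemical panel into the tick's secretion buffer (IL-10 damps TNF-alpha
#' and IL-1beta secretion multiplicatively when enabled); macrophages clear
#' fragment debris on their patch; activated fibroblasts deposit collagen,
#' elastin and hyaluronan; fibroblasts proliferate under growth-factor
#' stimulus up to a per-patch contact-inhibition cap; agents age and die
#' (stochastic turnover plus a hard lifespan cap; platelets expire at the
#' end of their degranulation window).
#'
#' All chemical reads use the tick-start fields; secretion goes to the
#' buffer merged at the diffusion barrier.
#'
#' @param world A `vf_world`.
#' @param rules A [rule_table()].
#' @return The updated world.
#' @export
cell_function <- function(world, rules = rule_table(world$config$rules)) {
  world <- ensure_secretion(world)
  n <- nrow(world$agents)
  world$log$born <- 0L
  world$log$died <- 0L
  if (n == 0L) return(world)
  rng_restore(world)
  grid <- world$grid

  ## explicit seeded shuffle: the processing order of the tick
  ord <- sample.int(n)
  ag <- world$agents[ord, , drop = FALSE]
  rownames(ag) <- NULL

  ## (a) movement, kind by kind (platelets are sessile)
  for (kind in names(rules$chemotaxis)) {
    rows <- which(ag$kind == kind)
    if (!length(rows)) next
    S <- chemotaxis_score(world, rules$chemotaxis[[kind]])
    pos <- cbind(ag$x[rows], ag$y[rows], ag$z[rows])
    pos <- step_agents(grid, pos, S, rules$p_follow)
    ag$x[rows] <- pos[, 1]; ag$y[rows] <- pos[, 2]; ag$z[rows] <- pos[, 3]
  }

  idx <- patch_index(grid, ag$x, ag$y, ag$z)
  np <- patch_count(grid)

  ## activation (sticky)
  for (kind in names(rules$activation_thresholds)) {
    rows <- which(ag$kind == kind & !ag$activated)
    if (!length(rows)) next
    th <- rules$activation_thresholds[[kind]]
    hot <- rep(FALSE, length(rows))
    for (nm in names(th))
      hot <- hot | world$chemicals[[nm]][idx[rows]] > th[[nm]]
    ag$activated[rows[hot]] <- TRUE
  }

  ## (b) secretion by activated agents, accumulated per patch
  damp <- NULL
  if (isTRUE(rules$il10_damping$enabled)) {
    damp <- 1 / (1 + world$chemicals[["IL10"]] / rules$il10_damping$halfmax)
  }
  for (kind in names(rules$secretion)) {
    rows <- which(ag$kind == kind & ag$activated)
    if (!length(rows)) next
    cnt <- tabulate(idx[rows], nbins = np)
    touched <- which(cnt > 0L)
    for (nm in names(rules$secretion[[kind]])) {
      rate <- rules$secretion[[kind]][[nm]]
      add <- rate * cnt[touched]
      if (!is.null(damp) && nm %in% c("TNFa", "IL1b"))
        add <- add * damp[touched]
      world$secretion[[nm]][touched] <- world$secretion[[nm]][touched] + add
    }
  }

  ## (c) macrophages clear debris (fragment mass) on their patch
  rows <- which(ag$kind == "macrophage")
  if (length(rows) && rules$macrophage_clear_frac > 0) {
    cnt <- tabulate(idx[rows], nbins = np)
    touched <- which(cnt > 0L)
    keep <- (1 - rules$macrophage_clear_frac)^cnt[touched]
    for (en in ecm_names())
      world$ecm[[en]]$fragments[touched] <-
        world$ecm[[en]]$fragments[touched] * keep
  }

  ## (d) activated fibroblasts deposit ECM proteins; collagen synthesis is
  ## suppressed by local TNF-alpha when that inhibition is enabled
  rows <- which(ag$kind == "fibroblast" & ag$activated)
  if (length(rows)) {
    cnt <- tabulate(idx[rows], nbins = np)
    touched <- which(cnt > 0L)
    cti <- rules$collagen_inhibition
    for (en in names(rules$ecm_deposition)) {
      add <- rules$ecm_deposition[[en]] * cnt[touched]
      if (en == "collagen" && isTRUE(cti$enabled)) {
        for (nm in setdiff(names(cti), "enabled")) {
          K <- cti[[nm]]
          add <- add * K / (K + world$chemicals[[nm]][touched])
        }
      }
      world$ecm[[en]]$intact[touched] <- world$ecm[[en]]$intact[touched] + add
    }
  }

  ## (e) proliferation (stimulus-gated, contact-inhibited), ageing, death
  children <- NULL
  for (kind in names(rules$proliferation)) {
    pr <- rules$proliferation[[kind]]
    rows <- which(ag$kind == kind & ag$activated)
    if (!length(rows)) next
    cnt <- tabulate(idx[rows], nbins = np)
    stim <- world$chemicals[[pr$stimulus]][idx[rows]] > pr$threshold
    roomy <- cnt[idx[rows]] < pr$max_per_patch
    u <- stats::runif(length(rows))
    divide <- stim & roomy & u < pr$prob
    if (any(divide)) {
      kid <- ag[rows[divide], , drop = FALSE]
      kid$age <- 0L
      children <- if (is.null(children)) kid else rbind(children, kid)
    }
  }

  ag$age <- ag$age + 1L
  u <- stats::runif(nrow(ag))
  dp <- unlist(rules$death_prob)[ag$kind]
  ls <- unlist(rules$lifespan)[ag$kind]
  dead <- u < dp | ag$age >= ls
  world$log$born <- if (is.null(children)) 0L else nrow(children)
  world$log$died <- sum(dead)
  ag <- ag[!dead, , drop = FALSE]
  if (!is.null(children)) ag <- rbind(ag, children)
  rownames(ag) <- NULL
  world$agents <- ag
  rng_capture(world)
}

#' ECM function phase: danger signalling and tissue repair
#'
#' Fragmented ECM acts as a danger signal: every unit of fragment mass emits
#' the configured amounts of TNF-alpha and IL-1beta into the tick's
#' secretion buffer.  Intact ECM on damaged patches drives repair: damage is
#' reduced by `repair_rate * intact mass` and clamped at zero.
#'
#' @param world A `vf_world`.
#' @param rules A [rule_table()].
#' @return The updated world.
#' @export
ecm_function <- function(world, rules = rule_table(world$config$rules)) {
  world <- ensure_secretion(world)
  frag_total <- world$ecm[[1]]$fragments
  for (en in ecm_names()[-1]) frag_total <- frag_total + world$ecm[[en]]$fragments
  for (nm in names(rules$danger_emission)) {
    e <- rules$danger_emission[[nm]]
    if (e > 0) world$secretion[[nm]] <- world$secretion[[nm]] + e * frag_total
  }
  if (rules$repair_rate > 0) {
    intact_total <- world$ecm[[1]]$intact
    for (en in ecm_names()[-1]) intact_total <- intact_total + world$ecm[[en]]$intact
    world$damage <- pmax(world$damage - rules$repair_rate * intact_total, 0)
    dim(world$damage) <- grid_dims(world$grid)
  }
  world
}

#' ECM fragmentation phase
#'
#' On every patch where the published TNF-alpha *or* MMP8 concentration
#' exceeds its threshold, a fraction of each intact ECM protein moves to
#' that protein's fragment layer.  The fraction may be a scalar (same for
#' all proteins) or named per protein -- MMP8 is a collagenase, so the
#' shipped presets fragment collagen much faster than hyaluronan.
#' Intact + fragments is conserved per patch.
#'
#' @param world A `vf_world`.
#' @param rules A [rule_table()].
#' @return The updated world.
#' @export
ecm_fragmentation <- function(world, rules = rule_table(world$config$rules)) {
  fr <- rules$fragmentation
  frac <- fragmentation_fractions(fr)
  if (all(frac <= 0)) return(world)
  hot <- world$chemicals[["TNFa"]] > fr$TNFa |
    world$chemicals[["MMP8"]] > fr$MMP8
  idx <- which(hot)
  if (!length(idx)) return(world)
  for (en in ecm_names()) {
    if (frac[[en]] <= 0) next
    moved <- frac[[en]] * world$ecm[[en]]$intact[idx]
    world$ecm[[en]]$intact[idx] <- world$ecm[[en]]$intact[idx] - moved
    world$ecm[[en]]$fragments[idx] <- world$ecm[[en]]$fragments[idx] + moved
  }
  world
}

fragmentation_fractions <- function(fr) {
  f <- fr$fraction
  if (is.list(f) || length(f) > 1L) {
    out <- stats::setNames(numeric(length(ecm_names())), ecm_names())
    out[names(f)] <- unlist(f)
    out
  } else {
    stats::setNames(rep(as.numeric(f), length(ecm_names())), ecm_names())
  }
}
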