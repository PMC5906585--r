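# Shared fixtures: tiny configurations, a brute-force convolution oracle and
# memoised desk-scale kernels (expensive to compose; built once per session).

.vfheal_cache <- new.env(parent = emptyenv())

desk_kernels <- function() {
  if (is.null(.vfheal_cache$desk)) {
    cfg <- make_preset("desk")
    .vfheal_cache$desk <- prepare_kernels(build_kernels(cfg), cfg$grid)
  }
  .vfheal_cache$desk
}

micro_kernels <- function(cfg = make_preset("micro")) {
  if (is.null(.vfheal_cache$micro)) {
    .vfheal_cache$micro <- prepare_kernels(build_kernels(cfg), cfg$grid)
  }
  .vfheal_cache$micro
}

# tick kernels for the default chemicals, no grid plans attached (usable on
# any grid; plans are derived per call)
loose_kernels <- function() {
  if (is.null(.vfheal_cache$loose)) {
    .vfheal_cache$loose <- build_kernels(tiny_config(15, 15, 15))
  }
  .vfheal_cache$loose
}

# minimal config on a small grid, no wound unless requested
tiny_config <- function(nx = 11, ny = 11, nz = 11, seed = 42, wound = NULL,
                        agents = list(neutrophil = 0, macrophage = 0,
                                      fibroblast = 0), ...) {
  simulation_config(grid = grid_spec(nx, ny, nz, 15), seed = seed,
                    agents = agents, wound = wound, ...)
}

# direct nested-loop full 3D convolution (independent oracle)
conv3_bruteforce <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, da + db - 1L)
  for (i in seq_len(da[1])) for (j in seq_len(da[2])) for (k in seq_len(da[3])) {
    if (a[i, j, k] != 0) {
      out[i:(i + db[1] - 1L), j:(j + db[2] - 1L), k:(k + db[3] - 1L)] <-
        out[i:(i + db[1] - 1L), j:(j + db[2] - 1L), k:(k + db[3] - 1L)] +
        a[i, j, k] * b
    }
  }
  out
}

# the 48 symmetries of the cube as coordinate permutations + sign flips
cube_symmetries <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  flips <- expand.grid(c(1, -1), c(1, -1), c(1, -1))
  out <- list()
  for (p in perms) for (i in seq_len(nrow(flips)))
    out[[length(out) + 1L]] <- list(perm = p, flip = as.numeric(flips[i, ]))
  out
}

apply_cube_symmetry <- function(a, sym) {
  b <- aperm(a, sym$perm)
  for (ax in 1:3) {
    if (sym$flip[ax] < 0) {
      idx <- rev(seq_len(dim(b)[ax]))
      b <- switch(ax, b[idx, , , drop = FALSE], b[, idx, , drop = FALSE],
                  b[, , idx, drop = FALSE])
    }
  }
  b
}
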