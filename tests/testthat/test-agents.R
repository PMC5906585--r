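# Agent behaviour: recruitment, chemotaxis, secretion, ECM work.

make_wounded <- function(seed = 7, agents = list(neutrophil = 0,
                                                 macrophage = 0,
                                                 fibroblast = 0)) {
  cfg <- tiny_config(15, 15, 15, seed = seed, agents = agents,
                     wound = list(center = c(7, 7, 7), radii = c(3, 3, 3),
                                  severity = 1))
  init_world(cfg)
}

test_that("recruitment is zero without attractant and reproducible with it", {
  rules <- rule_table()
  w <- make_wounded()
  w0 <- w
  w0$chemicals <- lapply(w0$chemicals, function(f) f * 0)
  expect_equal(nrow(seed_cells(w0, rules)$agents), nrow(w0$agents))
  # attractant present over the entry shell
  w$chemicals$IL1b <- make_field("uniform", c(15, 15, 15), value = 0.5)
  # fixed world state -> identical recruitment draw
  a1 <- seed_cells(w, rules)$agents
  a2 <- seed_cells(w, rules)$agents
  expect_identical(a1, a2)
  # recruits appear in the entry region, unactivated
  new <- a1[-seq_len(nrow(w$agents)), ]
  expect_gt(nrow(new), 0)
  idx <- 1 + new$x + 15 * (new$y + 15 * new$z)
  expect_true(all(idx %in% w$entry_patches))
  expect_true(all(!new$activated))
})

test_that("recruitment mean is linear in the attractant field", {
  rules <- rule_table()
  w <- make_wounded()
  w$chemicals$IL1b <- make_field("uniform", c(15, 15, 15), value = 0.3)
  count_recruits <- function(world, n_draws) {
    base <- nrow(world$agents)
    counts <- numeric(n_draws)
    for (i in seq_len(n_draws)) {
      world2 <- seed_cells(world, rules)
      counts[i] <- nrow(world2$agents) - base
      world$rng_state <- world2$rng_state  # advance the stream
    }
    counts
  }
  n <- 3000
  c1 <- count_recruits(w, n)
  w2 <- w
  w2$chemicals <- lapply(w2$chemicals, function(f) f * 2)
  c2 <- count_recruits(w2, n)
  expect_gt(mean(c1), 0)
  # Poisson: Var(mean(c2) - 2 mean(c1)) = (2 mu + 4 mu) / n
  se <- sqrt(6 * mean(c1) / n)
  expect_lt(abs(mean(c2) - 2 * mean(c1)), 3 * se + 0.05)
})

test_that("agents climb a gradient, verified against exhaustive scoring", {
  cfg <- tiny_config(15, 3, 3, seed = 1)
  w <- init_world(cfg)
  w$chemicals$IL8 <- make_field("linear-gradient", c(15, 3, 3), value = 10,
                                axis = 1)
  w$agents <- data.frame(kind = "neutrophil", x = 2L, y = 1L, z = 1L,
                         activated = FALSE, age = 0L,
                         stringsAsFactors = FALSE)
  rules <- rule_table(list(p_follow = 1,
                           death_prob = list(neutrophil = 0)))
  weights <- rules$chemotaxis$neutrophil
  score <- function(x, y, z) {
    if (x < 0 || x > 14 || y < 0 || y > 2 || z < 0 || z > 2) return(-Inf)
    s <- 0
    for (nm in names(weights))
      s <- s + weights[[nm]] * w$chemicals[[nm]][x + 1, y + 1, z + 1]
    s
  }
  for (step in 1:6) {
    prev <- c(w$agents$x, w$agents$y, w$agents$z)
    # oracle: best of the six face neighbours (must beat the current patch)
    cand <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
    sc <- apply(cand, 1, function(d)
      score(prev[1] + d[1], prev[2] + d[2], prev[3] + d[3]))
    best <- cand[which.max(sc), ]
    w <- cell_function(w, rules)
    if (max(sc) > score(prev[1], prev[2], prev[3])) {
      expect_equal(c(w$agents$x, w$agents$y, w$agents$z), prev + best)
    } else {
      expect_equal(c(w$agents$x, w$agents$y, w$agents$z), prev)
    }
  }
  # monotone chemotaxis: x never decreased along the run
  expect_gte(w$agents$x, 2L + 6L)  # strict gradient: moved every tick
})

test_that("zero gradient with p_follow = 1 means agents stay put", {
  cfg <- tiny_config(9, 9, 9, seed = 3)
  w <- init_world(cfg)
  w$agents <- data.frame(kind = "fibroblast", x = 4L, y = 4L, z = 4L,
                         activated = FALSE, age = 0L,
                         stringsAsFactors = FALSE)
  rules <- rule_table(list(p_follow = 1,
                           death_prob = list(fibroblast = 0)))
  for (i in 1:5) w <- cell_function(w, rules)
  expect_equal(c(w$agents$x, w$agents$y, w$agents$z), c(4L, 4L, 4L))
})

test_that("an empty world passes through cell_function unchanged", {
  w <- init_world(tiny_config())
  w2 <- cell_function(w, rule_table())
  expect_identical(w2$agents, w$agents)
  expect_true(all(vapply(w2$secretion, function(f) all(f == 0), logical(1))))
})

test_that("activated agents secrete their panel onto their patch", {
  cfg <- tiny_config(9, 9, 9, seed = 3)
  w <- init_world(cfg)
  w$agents <- data.frame(kind = c("neutrophil", "neutrophil"),
                         x = c(4L, 4L), y = c(4L, 4L), z = c(4L, 4L),
                         activated = TRUE, age = 0L,
                         stringsAsFactors = FALSE)
  rules <- rule_table(list(p_follow = 1, il10_damping = list(enabled = FALSE),
                           death_prob = list(neutrophil = 0)))
  w <- cell_function(w, rules)
  sec <- rules$secretion$neutrophil
  expect_equal(w$secretion$TNFa[5, 5, 5], 2 * sec$TNFa)
  expect_equal(w$secretion$MMP8[5, 5, 5], 2 * sec$MMP8)
  expect_equal(sum(w$secretion$TGFb1), 0)
  # with IL-10 damping enabled, TNF output is halved at IL10 == halfmax
  w2 <- init_world(cfg)
  w2$agents <- w$agents
  rules2 <- rule_table(list(p_follow = 1,
                            death_prob = list(neutrophil = 0),
                            il10_damping = list(enabled = TRUE, halfmax = 1)))
  w2$chemicals$IL10 <- make_field("uniform", c(9, 9, 9), value = 1)
  w2 <- cell_function(w2, rules2)
  expect_equal(w2$secretion$TNFa[5, 5, 5], 2 * sec$TNFa / 2)
  expect_equal(w2$secretion$MMP8[5, 5, 5], 2 * sec$MMP8)  # undamped
})

test_that("fragmentation obeys OR semantics and conserves per-patch mass", {
  w <- init_world(tiny_config(9, 9, 9, seed = 3))
  w$ecm$collagen$intact <- make_field("uniform", c(9, 9, 9), value = 10)
  rules <- rule_table(list(
    fragmentation = list(TNFa = 1, MMP8 = 1, fraction = 0.2)))
  # both below threshold: no-op
  w1 <- ecm_fragmentation(w, rules)
  expect_identical(w1$ecm, w$ecm)
  # MMP8 alone above threshold suffices (OR), only on that patch
  w$chemicals$MMP8[3, 3, 3] <- 2
  w2 <- ecm_fragmentation(w, rules)
  expect_equal(w2$ecm$collagen$intact[3, 3, 3], 8)
  expect_equal(w2$ecm$collagen$fragments[3, 3, 3], 2)
  expect_equal(w2$ecm$collagen$intact[4, 4, 4], 10)
  # TNFa alone also triggers
  w$chemicals$MMP8[3, 3, 3] <- 0
  w$chemicals$TNFa[2, 2, 2] <- 2
  w3 <- ecm_fragmentation(w, rules)
  expect_equal(w3$ecm$collagen$intact[2, 2, 2], 8)
  # intact + fragments conserved everywhere
  tot <- w3$ecm$collagen$intact + w3$ecm$collagen$fragments
  expect_equal(tot, w$ecm$collagen$intact + w$ecm$collagen$fragments)
  # per-protein fractions apply independently
  rules2 <- rule_table(list(fragmentation = list(
    TNFa = 1, MMP8 = 1,
    fraction = list(collagen = 0.5, elastin = 0.1, hyaluronan = 0))))
  w$ecm$hyaluronan$intact <- make_field("uniform", c(9, 9, 9), value = 4)
  w4 <- ecm_fragmentation(w, rules2)
  expect_equal(w4$ecm$collagen$intact[2, 2, 2], 5)
  expect_equal(w4$ecm$hyaluronan$intact[2, 2, 2], 4)
})

test_that("ECM function emits danger signals and repairs damage with clamp", {
  w <- init_world(tiny_config(9, 9, 9, seed = 3))
  rules <- rule_table(list(danger_emission = list(TNFa = 0.1, IL1b = 0.05),
                           repair_rate = 0.7))
  # no fragments, no damage: no-op
  w0 <- ecm_function(w, rules)
  expect_true(all(w0$secretion$TNFa == 0))
  expect_identical(w0$damage, w$damage)
  # fragments F emit e * F
  w$ecm$elastin$fragments[5, 5, 5] <- 3
  w1 <- ecm_function(w, rules)
  expect_equal(w1$secretion$TNFa[5, 5, 5], 0.1 * 3)
  expect_equal(w1$secretion$IL1b[5, 5, 5], 0.05 * 3)
  # repair clamps at zero: damage 0.5, credit 0.7 * 1 -> 0
  w$damage[5, 5, 5] <- 0.5
  w$ecm$collagen$intact[5, 5, 5] <- 1
  w2 <- ecm_function(w, rules)
  expect_equal(w2$damage[5, 5, 5], 0)
  expect_true(all(w2$damage >= 0))
})

test_that("population bookkeeping matches the per-tick log", {
  cfg <- tiny_config(15, 15, 15, seed = 11,
                     agents = list(neutrophil = 60, macrophage = 20,
                                   fibroblast = 80),
                     wound = list(center = c(7, 7, 7), radii = c(3, 3, 3),
                                  severity = 1))
  w <- init_world(cfg)
  ker <- loose_kernels()
  rules <- rule_table()
  for (i in 1:5) {
    before <- nrow(w$agents)
    w2 <- run_tick(w, rules, ker)
    recruited <- if (is.null(w2$log$recruited)) 0L else w2$log$recruited
    expect_equal(nrow(w2$agents) - before,
                 recruited + w2$log$born - w2$log$died)
    w <- w2
  }
})
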