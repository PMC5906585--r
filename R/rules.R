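#' Behavioural rule table for cell agents and ECM updates
#'
#' The biology of vocal-fold wound healing fixes *who does what*: platelets
#' degranulate and release TGF-beta1, IL-1beta and MMP8; neutrophils secrete
#' TNF-alpha and MMP8; macrophages secrete a broad cytokine panel and clear
#' debris; fibroblasts secrete growth factors and deposit collagen, elastin
#' and hyaluronan.  The *rates*, thresholds, lifespans and probabilities are
#' not quantified there, so every number lives in this table with
#' order-of-magnitude defaults calibrated so that the canonical wound-healing
#' time course (neutrophil peak around day 1, macrophage peak days 2-4,
#' fibroblast proliferation from day 1, collagen accumulation from day 3)
#' emerges at the shipped preset scale.  All concentrations are in arbitrary
#' units (au); times are in 30-minute ticks.  None of these defaults is
#' authoritative biology; override any entry via the `rules` block of the
#' simulation configuration.
#'
#' @param overrides Nested named list merged over the defaults
#'   (via [utils::modifyList()]), e.g.
#'   `list(fragmentation = list(fraction = 0.5))`.
#' @return An object of class `vf_rules`.
#' @export
#' @examples
#' r <- rule_table(list(p_follow = 1))
#' r$p_follow
rule_table <- function(overrides = NULL) {
  rules <- list(
    ## per-tick secretion by activated agents (au added to the agent's patch)
    secretion = list(
      platelet   = list(TGFb1 = 4, IL1b = 4, MMP8 = 3),
      neutrophil = list(TNFa = 1, MMP8 = 1),
      macrophage = list(TNFa = 0.3, TGFb1 = 1, FGF = 0.5, IL1b = 0.2,
                        IL6 = 1, IL8 = 1, IL10 = 2),
      fibroblast = list(TNFa = 0.02, TGFb1 = 0.05, FGF = 0.05,
                        IL6 = 0.2, IL8 = 0.2)
    ),
    ## chemotaxis: attraction weight per (kind, chemical); platelets immobile
    chemotaxis = list(
      neutrophil = list(IL8 = 1, IL1b = 1, TNFa = 0.5),
      macrophage = list(TNFa = 1, IL1b = 0.5, IL8 = 0.5, IL6 = 0.5),
      fibroblast = list(TGFb1 = 1, FGF = 1)
    ),
    ## probability of taking the gradient-following step (else uniform walk)
    p_follow = 0.8,
    ## sticky activation: any listed chemical above threshold on the patch
    activation_thresholds = list(
      neutrophil = list(TNFa = 0.1, IL1b = 0.1, IL8 = 0.1),
      macrophage = list(TNFa = 0.1, IL1b = 0.1),
      fibroblast = list(TGFb1 = 0.1, FGF = 0.1)
    ),
    ## proliferation: per-tick probability, gating stimulus, contact
    ## inhibition cap (max agents of that kind per patch)
    proliferation = list(
      fibroblast = list(prob = 0.05, stimulus = "TGFb1", threshold = 0.15,
                        max_per_patch = 4)
    ),
    ## stochastic turnover (per-tick death probability, geometric lifetime)
    ## and a hard maximum age in ticks
    death_prob = list(platelet = 0, neutrophil = 1 / 96,
                      macrophage = 1 / 288, fibroblast = 1 / 4800),
    lifespan = list(platelet = 24, neutrophil = 480,
                    macrophage = 960, fibroblast = 100000),
    ## recruitment from native tissue surrounding the wound: Poisson mean =
    ## rate * (weighted attractant total over entry region) / scale
    recruitment = list(
      ## the neutrophil influx tracks the platelet-derived IL-1beta pulse,
      ## so it rises within hours and collapses as degranulation ends
      neutrophil = list(rate = 1, signal = list(IL1b = 1), scale = 4),
      ## macrophages follow the neutrophil-derived TNF-alpha wave
      macrophage = list(rate = 1, signal = list(TNFa = 1), scale = 8),
      fibroblast = list(rate = 1, signal = list(TGFb1 = 1, FGF = 1),
                        scale = 2000)
    ),
    entry_margin = 3,  # patches around the damaged region that admit recruits
    ## ECM fragmentation trigger (either chemical above threshold) and the
    ## per-protein fraction of intact mass converted to fragments per
    ## triggering tick (MMP8 is a collagenase: collagen is most susceptible,
    ## hyaluronan barely affected)
    fragmentation = list(TNFa = 0.05, MMP8 = 0.05,
                         fraction = list(collagen = 0.3, elastin = 0.1,
                                         hyaluronan = 0.02)),
    ## fragments act as danger signals: au of chemical emitted per unit
    ## fragment mass per tick
    danger_emission = list(TNFa = 0.005, IL1b = 0.005),
    ## deposition by one activated fibroblast per tick (au)
    ecm_deposition = list(collagen = 0.05, elastin = 0.02, hyaluronan = 0.08),
    ## inflammatory suppression of net collagen synthesis: deposition is
    ## multiplied by prod( halfmax_c / (halfmax_c + conc_c) ) over the listed
    ## chemicals on the depositing patch.  TNF-alpha inhibits type-I collagen
    ## synthesis and MMP8 (collagenase) degrades nascent collagen, so net
    ## collagen accumulates only once the inflammatory pulse resolves
    collagen_inhibition = list(enabled = TRUE, TNFa = 0.008, MMP8 = 0.0015),
    ## damage removed per unit intact ECM on the patch per tick
    repair_rate = 0.002,
    ## fraction of fragment mass removed per macrophage on the patch per tick
    macrophage_clear_frac = 0.3,
    ## anti-inflammatory damping: TNF-alpha and IL-1beta secretion are
    ## multiplied by 1 / (1 + IL10 / halfmax) at the secreting patch
    il10_damping = list(enabled = TRUE, halfmax = 1),
    ## platelets appear only at wounding; initial chemical bolus per damaged
    ## patch and platelets seeded per damaged patch
    platelet = list(per_patch = 1,
                    wound_deposit = list(TGFb1 = 10, IL1b = 10, MMP8 = 10))
  )
  if (!is.null(overrides)) {
    if (!is.list(overrides)) stop("rule overrides must be a named list")
    rules <- utils::modifyList(rules, overrides)
  }
  validate_rules(rules)
  structure(rules, class = "vf_rules")
}

validate_rules <- function(r) {
  nonneg <- function(x, what) {
    v <- unlist(x, use.names = FALSE)
    if (length(v) && (any(!is.finite(v)) | any(v < 0)))
      stop("rule table: ", what, " must be finite and non-negative")
  }
  nonneg(r$secretion, "secretion rates")
  nonneg(r$chemotaxis, "chemotaxis weights")
  nonneg(r$activation_thresholds, "activation thresholds")
  nonneg(r$ecm_deposition, "ECM deposition rates")
  for (p in r$proliferation)
    if (p$prob < 0 || p$prob > 1) stop("proliferation prob must be in [0, 1]")
  for (d in r$death_prob)
    if (d < 0 || d > 1) stop("death probabilities must be in [0, 1]")
  if (r$p_follow < 0 || r$p_follow > 1) stop("p_follow must be in [0, 1]")
  frag <- unlist(r$fragmentation$fraction)
  if (any(frag < 0) || any(frag > 1))
    stop("fragmentation fraction(s) must be in [0, 1]")
  if (length(frag) > 1L && !all(names(frag) %in% ecm_names()))
    stop("per-protein fragmentation fractions must be named by ECM kind")
  if (r$macrophage_clear_frac < 0 || r$macrophage_clear_frac > 1)
    stop("macrophage_clear_frac must be in [0, 1]")
  bad <- setdiff(names(r$secretion),
                 c("platelet", "neutrophil", "macrophage", "fibroblast"))
  if (length(bad)) stop("unknown agent kind in secretion: ", bad[1])
  for (kind in names(r$secretion)) {
    nm <- names(r$secretion[[kind]])
    if (!all(nm %in% chemical_names()))
      stop("unknown chemical in secretion rules for ", kind)
  }
  invisible(r)
}

agent_kinds <- function() c("platelet", "neutrophil", "macrophage", "fibroblast")

#' @export
print.vf_rules <- function(x, ...) {
  cat("<agent rule table>\n")
  cat("  secretion (activated, au/tick):\n")
  for (k in names(x$secretion))
    cat(sprintf("    %-10s %s\n", k,
                paste(names(x$secretion[[k]]), unlist(x$secretion[[k]]),
                      sep = "=", collapse = " ")))
  fr <- fragmentation_fractions(x$fragmentation)
  cat(sprintf("  p_follow = %g; fragmentation (TNFa > %g | MMP8 > %g): %s\n",
              x$p_follow, x$fragmentation$TNFa, x$fragmentation$MMP8,
              paste(names(fr), fr, sep = "=", collapse = " ")))
  invisible(x)
}
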