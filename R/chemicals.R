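#' Signalling chemicals tracked by the simulator
#'
#' The model follows eight diffusing, decaying signalling chemicals:
#' TNF-alpha, TGF-beta1, FGF, MMP8, IL-1beta, IL-6, IL-8 and IL-10.  Each is
#' described by a [chemical_spec()] holding its effective diffusivity in
#' tissue (um^2/minute) and a first-order decay constant (1/minute).
#'
#' @name chemicals
NULL

#' Names of the eight chemical fields
#' @return Character vector of chemical identifiers.
#' @export
chemical_names <- function() {
  c("TNFa", "TGFb1", "FGF", "MMP8", "IL1b", "IL6", "IL8", "IL10")
}

#' Names of the three structural (ECM) protein fields
#' @return Character vector of ECM protein identifiers.
#' @export
ecm_names <- function() {
  c("collagen", "elastin", "hyaluronan")
}

#' Physical description of one diffusing chemical
#'
#' @param name Chemical identifier; one of [chemical_names()].
#' @param diffusivity Effective diffusivity in tissue, um^2/minute (>= 0).
#' @param decay First-order decay constant, 1/minute (>= 0).
#' @return An object of class `vf_chemical`.
#' @export
chemical_spec <- function(name, diffusivity, decay = 0) {
  if (!is.character(name) || length(name) != 1L || !name %in% chemical_names())
    stop("unknown chemical name: ", paste(name, collapse = ", "))
  if (!is.numeric(diffusivity) || length(diffusivity) != 1L || diffusivity < 0)
    stop("diffusivity must be a single non-negative number")
  if (!is.numeric(decay) || length(decay) != 1L || decay < 0)
    stop("decay must be a single non-negative number")
  structure(list(name = name, diffusivity = as.numeric(diffusivity),
                 decay = as.numeric(decay)),
            class = "vf_chemical")
}

#' Default chemical specifications
#'
#' Effective diffusivities (um^2/minute) for the eight chemicals; decay
#' constants default to zero and are normally overridden by the simulation
#' configuration (presets ship calibrated values).
#'
#' @param decay Named numeric vector of decay constants (1/minute) to merge
#'   over the zero default; names must be chemical names.
#' @return Named list of `vf_chemical` objects in [chemical_names()] order.
#' @export
#' @examples
#' default_chemical_specs()[["TNFa"]]$diffusivity  # 900
default_chemical_specs <- function(decay = NULL) {
  D <- c(TNFa = 900, TGFb1 = 780, FGF = 780, MMP8 = 780,
         IL1b = 900, IL6 = 810, IL8 = 900, IL10 = 900)
  g <- stats::setNames(numeric(8L), chemical_names())
  if (!is.null(decay)) {
    if (is.null(names(decay)) || !all(names(decay) %in% chemical_names()))
      stop("decay overrides must be named by chemical")
    g[names(decay)] <- decay
  }
  out <- lapply(chemical_names(), function(nm)
    chemical_spec(nm, D[[nm]], g[[nm]]))
  stats::setNames(out, chemical_names())
}

#' @export
print.vf_chemical <- function(x, ...) {
  cat(sprintf("<chemical %s: D = %g um^2/min, decay = %g /min>\n",
              x$name, x$diffusivity, x$decay))
  invisible(x)
}
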