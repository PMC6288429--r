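#' PKA-phosphorylated fraction of an LTCC subgroup class
#'
#' Channels associated with both beta-2 adrenergic receptors and PDEs
#' (`"with_PDE"`; subgroups A, D) carry the basal fraction at rest and the
#' stimulated fraction under sympathetic stimulation. Channels associated
#' with beta-2 ARs but lacking PDE (`"without_PDE"`; subgroups B, E) are
#' fully phosphorylated under stimulation -- with no phosphodiesterase there
#' is nothing to limit PKA activity -- but, because PDE is itself activated
#' by PKA and is therefore inactive at rest, they carry the same basal
#' fraction as PDE-associated channels when unstimulated. Channels without
#' beta-2 AR association (`"without_B2AR"`; subgroups C, F) are never
#' phosphorylated.
#'
#' @param config a [phospho_config()].
#' @param subgroup_class one of `"with_PDE"`, `"without_PDE"`,
#'   `"without_B2AR"`.
#' @param stimulated logical; sympathetic stimulation applied?
#' @return the PKA-phosphorylated fraction, in `[0, 1]`.
#' @export
pka_fraction <- function(config, subgroup_class, stimulated = FALSE) {
  stopifnot(inherits(config, "phospho_config"))
  switch(subgroup_class,
    with_PDE = if (stimulated) config$stim_pka_fraction
               else config$basal_pka_fraction,
    without_PDE = if (stimulated) 1.0 else config$basal_pka_fraction,
    without_B2AR = 0.0,
    stop("unknown subgroup class: ", subgroup_class, call. = FALSE)
  )
}

subgroup_classes <- c(A = "with_PDE", B = "without_PDE", C = "without_B2AR",
                      D = "with_PDE", E = "without_PDE", F = "without_B2AR")

#' Per-subgroup PKA-phosphorylated fractions
#'
#' @inheritParams pka_fraction
#' @return named vector `pA..pF`.
#' @export
subgroup_pka_fractions <- function(config, stimulated = FALSE) {
  p <- vapply(subgroup_classes, function(cl)
    pka_fraction(config, cl, stimulated), numeric(1))
  names(p) <- paste0("p", names(subgroup_classes))
  p
}

#' Weighted-population current composition
#'
#' Computes the total current density through a target divided into up to
#' four binary-phosphorylation populations (PKA +/- crossed with CaMKII
#' +/-), assuming PKA and CaMKII act independently (their multipliers
#' combine as a product).
#'
#' @param base_current current density through a fully unphosphorylated
#'   population of unit weight.
#' @param pka_weight fraction of the population PKA-phosphorylated.
#' @param camk_weight fraction CaMKII-phosphorylated.
#' @param pka_effect,camk_effect multipliers applied to the respective
#'   phosphorylated populations.
#' @return total current density.
#' @export
population_current <- function(base_current, pka_weight = 0,
                               camk_weight = 0, pka_effect = 1,
                               camk_effect = 1) {
  if (any(c(pka_weight, camk_weight) < 0) ||
      any(c(pka_weight, camk_weight) > 1))
    stop("population weights must lie in [0, 1]", call. = FALSE)
  pka_mult <- (1 - pka_weight) + pka_weight * pka_effect
  camk_mult <- (1 - camk_weight) + camk_weight * camk_effect
  base_current * pka_mult * camk_mult
}

#' Parameter modifications of a phosphorylated target
#'
#' Returns the multiplicative modifications applied to a target's kinetics
#' when its population is PKA-phosphorylated, as tabulated in the
#' constants file shipped with the package (see [phospho_effects()]).
#' The unphosphorylated state is always the identity.
#'
#' @param target one of `RyR`, `PLB`, `IKs`, `INa`, `INaK`, `IKur`, `TnI`,
#'   `LTCC`, `INaL`.
#' @param phosphorylated logical.
#' @param effects optional effect table from [phospho_effects()].
#' @return named list of modifications (`amp`, `km_up_factor`,
#'   `km_trpn_factor` as applicable).
#' @export
target_effects <- function(target, phosphorylated = TRUE, effects = NULL) {
  if (is.null(effects)) effects <- phospho_effects()
  if (!target %in% names(effects))
    stop("unsupported phosphorylation target: ", target, call. = FALSE)
  entry <- effects[[target]]
  identity_mod <- list(amp = 1, km_up_factor = 1, km_trpn_factor = 1)
  if (!phosphorylated) return(identity_mod)
  modifyList(identity_mod,
             entry[intersect(names(entry),
                             c("amp", "km_up_factor", "km_trpn_factor"))])
}
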