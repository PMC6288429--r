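#' LTCC subgroup fractions from remodeling parameters
#'
#' Each LTCC is assigned to one of six subgroups by the product of three
#' independent probabilities: residing in the T-tubular membrane (`f_tt`),
#' being associated with a beta-2 adrenergic receptor (`f_b2ar`), and
#' experiencing PDE activity (`f_pde`). Channels lacking beta-2 AR
#' association are never phosphorylated whether or not a PDE is present, so
#' both PDE states collapse into subgroups C (T-tubular) and F (surface).
#'
#' @param params a [remodeling_params()] object.
#' @return named numeric vector `wA..wF` summing to 1.
#' @export
subgroup_fractions <- function(params) {
  stopifnot(inherits(params, "remodeling_params"))
  ft <- params$f_tt; fb <- params$f_b2ar; fp <- params$f_pde
  w <- c(wA = ft * fb * fp,
         wB = ft * fb * (1 - fp),
         wC = ft * (1 - fb),
         wD = (1 - ft) * fb * fp,
         wE = (1 - ft) * fb * (1 - fp),
         wF = (1 - ft) * (1 - fb))
  # the three factors partition unity; absorb any rounding residue into the
  # largest weight so the sum is exactly 1
  imax <- which.max(w)
  w[imax] <- 1 - sum(w[-imax])
  w
}

case_corners <- list(
  `1` = c(f_tt = 1, f_b2ar = 1, f_pde = 1),  # A: T-tubular, B2AR + PDE
  `2` = c(f_tt = 1, f_b2ar = 1, f_pde = 0),  # B: T-tubular, B2AR only
  `3` = c(f_tt = 1, f_b2ar = 0, f_pde = 1),  # C: T-tubular, no B2AR
  `4` = c(f_tt = 0, f_b2ar = 1, f_pde = 1),  # D: surface, B2AR + PDE
  `5` = c(f_tt = 0, f_b2ar = 1, f_pde = 0),  # E: surface, B2AR only
  `6` = c(f_tt = 0, f_b2ar = 0, f_pde = 1)   # F: surface, no B2AR
)

#' Preset case definitions (1-6)
#'
#' Each case assigns 80% of the LTCCs to one dominant subgroup (case 1 ->
#' A, ..., case 6 -> F) and distributes the remaining 20% uniformly over
#' the other five subgroups. The NCX/RyR remodeling parameters take the
#' case's nominal corner values (e.g. case 4 is fully de-tubulated).
#'
#' @param case_id integer 1-6.
#' @param stimulated logical; sympathetic stimulation applied?
#' @param dominant_weight weight of the dominant subgroup (default 0.8).
#' @return list with elements `case_id`, `remodeling`, and `weights`.
#' @export
case_definition <- function(case_id, stimulated = FALSE,
                            dominant_weight = 0.8) {
  if (!case_id %in% 1:6) stop("case_id must be 1..6", call. = FALSE)
  corner <- case_corners[[as.character(case_id)]]
  rem <- remodeling_params(corner[["f_tt"]], corner[["f_b2ar"]],
                           corner[["f_pde"]], stimulated = stimulated)
  w <- rep((1 - dominant_weight) / 5, 6)
  w[case_id] <- dominant_weight
  names(w) <- c("wA", "wB", "wC", "wD", "wE", "wF")
  list(case_id = as.integer(case_id), remodeling = rem,
       weights = validate_weights(w))
}

#' NCX distribution across membranes
#'
#' In the intact cell a fifth of the Na+/Ca2+ exchangers operate at the
#' surface membrane and the rest in the T-tubular region; T-tubule loss
#' redistributes a proportional fraction of the T-tubular exchangers to the
#' surface, where the redistributed exchangers sense the sub-sarcolemmal
#' Ca2+ concentration.
#'
#' @param f_tt T-tubule integrity fraction in `[0, 1]`.
#' @return named vector `c(t_tubular, surface)` summing to 1.
#' @export
ncx_distribution <- function(f_tt) {
  if (!is.numeric(f_tt) || length(f_tt) != 1L || is.na(f_tt) ||
      f_tt < 0 || f_tt > 1)
    stop("f_tt must be a single number in [0, 1]", call. = FALSE)
  c(t_tubular = 0.8 * f_tt, surface = 0.2 + 0.8 * (1 - f_tt))
}

#' RyR dyadic coupling
#'
#' The fraction of ryanodine receptors still coupled to T-tubular LTCC
#' clusters equals the T-tubule integrity; the rest are orphaned, triggered
#' by the bulk cytosolic Ca2+ signal and releasing into the myoplasm.
#'
#' @inheritParams ncx_distribution
#' @return named vector `c(coupled, orphaned)`.
#' @export
ryr_coupling <- function(f_tt) {
  if (!is.numeric(f_tt) || length(f_tt) != 1L || is.na(f_tt) ||
      f_tt < 0 || f_tt > 1)
    stop("f_tt must be a single number in [0, 1]", call. = FALSE)
  c(coupled = f_tt, orphaned = 1 - f_tt)
}
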