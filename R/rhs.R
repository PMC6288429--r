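#' State variable names of the extended myocyte model
#'
#' The 41 baseline states plus the sub-sarcolemmal Ca concentration
#' (`casl`), its CDI mode fraction (`ncasl`), and the orphaned-RyR release
#' flux state (`jrelorph`).
#'
#' @return character vector of length 44.
#' @export
ord_state_names <- function() {
  c("v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr",
    "m", "hf", "hs", "j", "hsp", "jp", "ml", "hl", "hlp",
    "a", "if", "is", "ap", "ifp", "isp",
    "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
    "xrf", "xrs", "xs1", "xs2", "xk1",
    "jrelnp", "jrelp", "camkt",
    "casl", "ncasl", "jrelorph")
}

ord_gate_names <- function() {
  setdiff(ord_state_names(),
          c("v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr",
            "cajsr", "casl", "jrelnp", "jrelp", "jrelorph"))
}

ord_conc_names <- function() {
  c("nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr", "casl")
}

#' Names of the packed parameter vector (C order)
#' @return character vector of length 55.
#' @export
ord_parameter_names <- function() {
  c("istim", "clamp",
    "wA", "wB", "wC", "wD", "wE", "wF",
    "pA", "pB", "pC", "pD", "pE", "pF",
    "camk_sl", "ttub_camk_dyn",
    "pk_ryr", "pk_plb", "pk_iks", "pk_ina", "pk_inak", "pk_ikb", "pk_tni",
    "eff_ltcc", "eff_ryr", "eff_plb", "eff_iks", "eff_ina", "eff_inak",
    "eff_ikb", "eff_tni",
    "f_tt",
    "orph_amp", "orph_km",
    "vsl_frac", "tau_sl", "sl_cdi_scale",
    "gna", "gnal", "gto", "pca", "gkr", "gks", "gk1", "gncx", "pnak",
    "gkb", "pnab", "pcab", "gpca", "jrel_scale", "jup_scale",
    "nao", "cao", "ko")
}

ord_aux_names <- function() {
  c("ical_tt", "ical_sl", "ical", "icana", "icak", "ina", "inal", "ito",
    "ikr", "iks", "ik1", "inaca", "inaca_sl", "inak", "ikb", "inab",
    "icab", "ipca", "jrel", "jrelorph_flux", "jup", "jdiff", "jdiffsl",
    "camka", "istim_applied", "itot")
}

#' Pack a model configuration into the solver parameter vector
#'
#' Resolves subgroup weights, per-subgroup PKA fractions, the seven-target
#' phosphorylation fractions, and the effect multipliers from the constants
#' table into the flat numeric vector consumed by the compiled
#' right-hand side.
#'
#' @param config a [model_config()].
#' @param istim applied stimulus current (uA/uF) held during the segment.
#' @param clamp logical; hold the membrane potential fixed?
#' @return named numeric vector in canonical order.
#' @export
build_parms <- function(config, istim = 0, clamp = FALSE) {
  stopifnot(inherits(config, "model_config"))
  stim <- config$remodeling$stimulated
  ph <- config$phospho
  eff <- config$effects
  pk7 <- if (stim) ph$stim_pka_fraction else ph$basal_pka_fraction
  psub <- subgroup_pka_fractions(ph, stimulated = stim)
  p <- c(
    istim = istim, clamp = as.numeric(clamp),
    config$weights,
    psub,
    camk_sl = ph$camk_fraction,
    ttub_camk_dyn = as.numeric(config$ttub_camk == "dynamic"),
    pk_ryr = pk7, pk_plb = pk7, pk_iks = pk7, pk_ina = pk7,
    pk_inak = pk7, pk_ikb = pk7, pk_tni = pk7,
    eff_ltcc = ph$ltcc_amp_factor,
    eff_ryr = eff$RyR$amp,
    eff_plb = eff$PLB$km_up_factor,
    eff_iks = eff$IKs$amp,
    eff_ina = eff$INa$amp,
    eff_inak = eff$INaK$amp,
    eff_ikb = eff$IKur$amp,
    eff_tni = eff$TnI$km_trpn_factor,
    f_tt = config$remodeling$f_tt,
    orph_amp = config$orphan$amp, orph_km = config$orphan$km,
    vsl_frac = config$geometry$vsl_frac, tau_sl = config$geometry$tau_sl,
    sl_cdi_scale = config$geometry$sl_cdi_scale,
    unlist(config$conductances),
    unlist(config$extracellular)
  )
  names(p) <- ord_parameter_names()
  p
}

#' Default initial state
#'
#' A paced-steady-state-like starting point for the baseline endocardial
#' cell; protocols condition from here (clamped relaxation or pacing until
#' their steady-state criterion is met), so the exact values only set the
#' starting basin.
#'
#' @param config a [model_config()] (reserved for future use).
#' @return named numeric state vector of length 44.
#' @export
ord_initial_state <- function(config = NULL) {
  y <- c(
    v = -87.5, nai = 7.268, nass = 7.268, ki = 144.65, kss = 144.65,
    cai = 8.6e-5, cass = 8.49e-5, cansr = 1.619, cajsr = 1.571,
    m = 0.0074621, hf = 0.692591, hs = 0.692574, j = 0.692477,
    hsp = 0.448501, jp = 0.692413, ml = 0.000194015, hl = 0.496116,
    hlp = 0.265885, a = 0.00101185, `if` = 0.999542, is = 0.589579,
    ap = 0.000515567, ifp = 0.999542, isp = 0.641861,
    d = 2.43015e-9, ff = 1, fs = 0.910671, fcaf = 1, fcas = 0.99982,
    jca = 0.999977, nca = 0.00267171, ffp = 1, fcafp = 1,
    xrf = 8.26608e-6, xrs = 0.453268, xs1 = 0.270492, xs2 = 0.0001963,
    xk1 = 0.996801, jrelnp = 2.53943e-5, jrelp = 3.17262e-7,
    camkt = 0.0124065,
    casl = 8.6e-5, ncasl = 0.00267171, jrelorph = 0
  )
  names(y) <- ord_state_names()
  y
}

#' Evaluate the model right-hand side
#'
#' Returns the time derivative of every state together with the auxiliary
#' observables (per-component LTCC currents, NCX, SR fluxes, ...). Fails
#' hard, naming the offending field, if any state entry is non-finite.
#'
#' @param state named state vector (see [ord_state_names()]).
#' @param t time (ms); the model is autonomous, so this only matters for
#'   bookkeeping.
#' @param config a [model_config()], or a pre-packed parameter vector from
#'   [build_parms()].
#' @param istim applied stimulus (uA/uF) when `config` is a `model_config`.
#' @param clamp hold membrane potential fixed?
#' @return list with elements `derivatives` and `currents` (named vectors).
#' @export
ord_rhs <- function(state, t = 0, config = model_config(), istim = 0,
                    clamp = FALSE) {
  if (length(state) != 44L)
    stop("state must have 44 entries", call. = FALSE)
  bad <- which(!is.finite(state))
  if (length(bad))
    stop("non-finite state entry: ",
         paste(ord_state_names()[bad], collapse = ", "), call. = FALSE)
  p <- if (inherits(config, "model_config"))
    build_parms(config, istim = istim, clamp = clamp) else config
  out <- .C("c_ord_rhs", t = as.double(t), y = as.double(state),
            p = as.double(p), dy = double(44), aux = double(26),
            PACKAGE = "cardiomd")
  dy <- out$dy; names(dy) <- ord_state_names()
  aux <- out$aux; names(aux) <- ord_aux_names()
  list(derivatives = dy, currents = aux)
}

#' Total cell calcium (free plus buffered, volume-weighted)
#'
#' Sums Ca over all compartments including instantaneously buffered Ca
#' (calmodulin and the two troponin populations in the myoplasm, BSR/BSL in
#' the dyadic and sub-sarcolemmal spaces, calsequestrin in the junctional
#' SR), expressed as total moles per cell volume (mM).
#'
#' @param state named state vector.
#' @param config a [model_config()] (supplies the TnI phosphorylated
#'   fraction and sub-sarcolemmal volume).
#' @return total Ca in mM of cell volume.
#' @export
total_calcium <- function(state, config = model_config()) {
  p <- build_parms(config)
  vfrac <- c(myo = 0.68, nsr = 0.0552, jsr = 0.0048, ss = 0.02,
             sl = unname(p["vsl_frac"]))
  bound <- function(bmax, km, ca) bmax * ca / (km + ca)
  cai <- state[["cai"]]; cass <- state[["cass"]]; casl <- state[["casl"]]
  cajsr <- state[["cajsr"]]; cansr <- state[["cansr"]]
  pT <- unname(p["pk_tni"]); kmtrpn <- 0.0005
  kmtrpn_p <- kmtrpn * unname(p["eff_tni"])
  myo <- cai + bound(0.05, 0.00238, cai) +
    (1 - pT) * bound(0.07, kmtrpn, cai) + pT * bound(0.07, kmtrpn_p, cai)
  ss <- cass + bound(0.047, 0.00087, cass) + bound(1.124, 0.0087, cass)
  sl <- casl + bound(1.65, 0.013, casl) + bound(0.3, 0.0003, casl)
  jsr <- cajsr + bound(10, 0.8, cajsr)
  unname(vfrac["myo"] * myo + vfrac["ss"] * ss + vfrac["sl"] * sl +
         vfrac["jsr"] * jsr + vfrac["nsr"] * cansr)
}
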