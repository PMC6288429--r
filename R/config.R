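#' @useDynLib cardiomd, .registration = TRUE
#' @importFrom stats approx coef predict sd
#' @importFrom utils modifyList write.csv
"_PACKAGE"

.cardiomd_env <- new.env(parent = emptyenv())

#' Remodeling parameters of the heart-failure myocyte family
#'
#' `f_tt` encodes T-tubule integrity (1 = fully tubulated, 0 = fully
#' de-tubulated), `f_b2ar` the fraction of LTCCs associated with beta-2
#' adrenergic receptors, and `f_pde` the fraction of LTCCs experiencing
#' phosphodiesterase activity. `stimulated` switches sympathetic
#' (beta-2 adrenergic) stimulation on.
#'
#' @param f_tt,f_b2ar,f_pde fractions in `[0, 1]`.
#' @param stimulated logical; sympathetic stimulation applied?
#' @return an object of class `remodeling_params`.
#' @export
remodeling_params <- function(f_tt = 1, f_b2ar = 1, f_pde = 1,
                              stimulated = FALSE) {
  for (nm in c("f_tt", "f_b2ar", "f_pde")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(sprintf("%s must be a single number in [0, 1], got %s",
                   nm, format(x)), call. = FALSE)
  }
  stopifnot(is.logical(stimulated), length(stimulated) == 1L)
  structure(list(f_tt = f_tt, f_b2ar = f_b2ar, f_pde = f_pde,
                 stimulated = stimulated),
            class = "remodeling_params")
}

#' Phosphorylation configuration
#'
#' Binary-population phosphorylation constants: the PKA-phosphorylated
#' fraction of each substrate population under basal conditions and under
#' sympathetic stimulation, the LTCC current amplification applied to a
#' PKA-phosphorylated channel, and the (constant) CaMKII-phosphorylated
#' fraction of surface-membrane LTCCs.
#'
#' @param basal_pka_fraction phosphorylated fraction at rest (default 0.25).
#' @param stim_pka_fraction phosphorylated fraction under stimulation
#'   (default 0.75).
#' @param ltcc_amp_factor current amplification of a PKA-phosphorylated
#'   LTCC (default 2.5).
#' @param camk_fraction constant CaMKII-phosphorylated fraction of
#'   surface-membrane LTCCs.
#' @return an object of class `phospho_config`.
#' @export
phospho_config <- function(basal_pka_fraction = 0.25,
                           stim_pka_fraction = 0.75,
                           ltcc_amp_factor = 2.5,
                           camk_fraction = 0.25) {
  for (nm in c("basal_pka_fraction", "stim_pka_fraction", "camk_fraction")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(sprintf("%s must be in [0, 1]", nm), call. = FALSE)
  }
  if (!is.numeric(ltcc_amp_factor) || ltcc_amp_factor < 1)
    stop("ltcc_amp_factor must be >= 1", call. = FALSE)
  structure(list(basal_pka_fraction = basal_pka_fraction,
                 stim_pka_fraction = stim_pka_fraction,
                 ltcc_amp_factor = ltcc_amp_factor,
                 camk_fraction = camk_fraction),
            class = "phospho_config")
}

#' Phosphorylation effect constants
#'
#' Reads the per-target PKA phosphorylation effect table shipped with the
#' package (`inst/extdata/phospho_effects.yaml`): each entry gives the
#' multiplicative modification applied to a phosphorylated target population
#' together with a citation string for its source. The table is data, not
#' code, and can be replaced by the user.
#'
#' @param path optional path to an alternative effects file.
#' @return named list of per-target effect entries.
#' @export
phospho_effects <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.cardiomd_env$phospho_effects))
      return(.cardiomd_env$phospho_effects)
    path <- system.file("extdata", "phospho_effects.yaml",
                        package = "cardiomd", mustWork = TRUE)
  }
  eff <- yaml::read_yaml(path)$targets
  if (is.null(path) || identical(path, system.file(
        "extdata", "phospho_effects.yaml", package = "cardiomd")))
    .cardiomd_env$phospho_effects <- eff
  eff
}

#' Full model configuration
#'
#' Assembles a validated configuration for the extended ventricular myocyte
#' model: remodeling parameters (or a preset case), phosphorylation
#' constants, cell geometry of the new sub-sarcolemmal compartment, channel
#' conductances/permeabilities, orphaned-RyR trigger constants, solver
#' tolerances, and the pacing/stimulus protocol.
#'
#' All constants default to the baseline endocardial formulation; with
#' `remodeling = remodeling_params(1, 1, 1)` and phosphorylation fractions
#' set to zero the model reduces to the unmodified baseline cell.
#'
#' @param remodeling a [remodeling_params()] object.
#' @param phospho a [phospho_config()] object.
#' @param case_id optional preset case (1-6); overrides the LTCC subgroup
#'   weights with the dominant-subgroup (0.8) weighting.
#' @param weights optional explicit subgroup weight vector (named wA..wF);
#'   defaults to the product weights of `remodeling`.
#' @param ttub_camk `"none"` (T-tubular LTCCs carry no CaMKII
#'   phosphorylation; the remodeled-family default) or `"dynamic"`
#'   (the baseline model's dynamic CaMKII mix, used for exact reduction).
#' @param geometry,conductances,extracellular,orphan,solver,protocol named
#'   lists overriding individual defaults.
#' @return an object of class `model_config`.
#' @export
model_config <- function(remodeling = remodeling_params(),
                         phospho = phospho_config(),
                         case_id = NULL,
                         weights = NULL,
                         ttub_camk = c("none", "dynamic"),
                         geometry = list(),
                         conductances = list(),
                         extracellular = list(),
                         orphan = list(),
                         solver = list(),
                         protocol = list()) {
  stopifnot(inherits(remodeling, "remodeling_params"),
            inherits(phospho, "phospho_config"))
  ttub_camk <- match.arg(ttub_camk)
  if (!is.null(case_id)) {
    cd <- case_definition(case_id, stimulated = remodeling$stimulated)
    remodeling <- cd$remodeling
    weights <- cd$weights
  }
  if (is.null(weights)) weights <- subgroup_fractions(remodeling)
  weights <- validate_weights(weights)

  defaults <- list(
    geometry = list(vsl_frac = 0.02, tau_sl = 0.18, sl_cdi_scale = 0.65),
    conductances = list(gna = 75, gnal = 0.0075, gto = 0.02, pca = 1e-4,
                        gkr = 0.046, gks = 0.0034, gk1 = 0.1908,
                        gncx = 0.0008, pnak = 30, gkb = 0.003,
                        pnab = 3.75e-10, pcab = 2.5e-8, gpca = 0.0005,
                        jrel_scale = 1, jup_scale = 1),
    extracellular = list(nao = 140, cao = 1.8, ko = 5.4),
    orphan = list(amp = 2.0, km = 0.002),
    solver = list(rtol = 1e-6, atol = 1e-8, dt_record = 0.1,
                  max_steps = 1e6),
    protocol = list(cl = 1000, stim_amp = -80, stim_dur = 0.5,
                    conditioning_tol = 1e-4, max_conditioning_beats = 1000,
                    ead_prominence = 1, ead_floor = -50, ead_takeoff = 20)
  )
  merge_block <- function(name, user) {
    d <- defaults[[name]]
    unknown <- setdiff(names(user), names(d))
    if (length(unknown))
      stop(sprintf("unknown %s key(s): %s", name,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    modifyList(d, user)
  }
  cfg <- structure(list(
    remodeling = remodeling,
    phospho = phospho,
    case_id = case_id,
    weights = weights,
    ttub_camk = ttub_camk,
    geometry = merge_block("geometry", geometry),
    conductances = merge_block("conductances", conductances),
    extracellular = merge_block("extracellular", extracellular),
    orphan = merge_block("orphan", orphan),
    solver = merge_block("solver", solver),
    protocol = merge_block("protocol", protocol),
    effects = phospho_effects()
  ), class = "model_config")
  if (cfg$protocol$cl <= cfg$protocol$stim_dur)
    stop("cycle length must exceed stimulus duration", call. = FALSE)
  cfg
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  r <- x$remodeling
  cat(sprintf("  remodeling: f_tt=%.2f f_b2ar=%.2f f_pde=%.2f %s\n",
              r$f_tt, r$f_b2ar, r$f_pde,
              if (r$stimulated) "stimulated" else "basal"))
  if (!is.null(x$case_id)) cat(sprintf("  case: %d\n", x$case_id))
  cat(sprintf("  weights: %s\n",
              paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                    collapse = " ")))
  invisible(x)
}

validate_weights <- function(w) {
  nm <- c("wA", "wB", "wC", "wD", "wE", "wF")
  if (is.null(names(w))) names(w) <- nm
  if (!setequal(names(w), nm) || length(w) != 6L)
    stop("weights must be a named vector wA..wF", call. = FALSE)
  w <- w[nm]
  if (any(w < 0)) stop("subgroup weights must be >= 0", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-12)
    stop("subgroup weights must sum to 1", call. = FALSE)
  w
}

#' Load a run configuration from YAML or JSON
#'
#' Reads a (possibly partial) configuration file, validates every block, and
#' returns the fully default-expanded [model_config()]. Unknown keys are
#' rejected with the offending key named. A round trip through
#' [write_config()] and `load_config()` reproduces the configuration.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `model_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- c("remodeling", "phospho", "case_id", "weights", "ttub_camk",
             "geometry", "conductances", "extracellular", "orphan",
             "solver", "protocol")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  rem <- do.call(remodeling_params, modifyList(
    list(f_tt = 1, f_b2ar = 1, f_pde = 1, stimulated = FALSE),
    as.list(raw$remodeling %||% list())))
  ph <- do.call(phospho_config, as.list(raw$phospho %||% list()))
  model_config(remodeling = rem, phospho = ph,
               case_id = raw$case_id,
               weights = if (!is.null(raw$weights)) unlist(raw$weights),
               ttub_camk = raw$ttub_camk %||% "none",
               geometry = as.list(raw$geometry %||% list()),
               conductances = as.list(raw$conductances %||% list()),
               extracellular = as.list(raw$extracellular %||% list()),
               orphan = as.list(raw$orphan %||% list()),
               solver = as.list(raw$solver %||% list()),
               protocol = as.list(raw$protocol %||% list()))
}

#' Write an expanded configuration to YAML
#'
#' @param config a `model_config`.
#' @param path output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  out <- list(
    remodeling = unclass(config$remodeling),
    phospho = unclass(config$phospho),
    case_id = config$case_id,
    weights = as.list(config$weights),
    ttub_camk = config$ttub_camk,
    geometry = config$geometry,
    conductances = config$conductances,
    extracellular = config$extracellular,
    orphan = config$orphan,
    solver = config$solver,
    protocol = config$protocol
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
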