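# Parameter handling: the 19 baseline constants plus per-variant extras.
# The packaged YAML config is the single source of truth for their values.

# canonical order, shared with the compiled right-hand sides
.param_names <- c("U1", "M1", "Ks", "I1", "D1", "O2", "I2", "D2", "C1", "C2",
                  "R1", "S", "r", "O3", "R2", "Met1", "CellVol", "molML",
                  "GCperGen")

.extra_names <- c("U2", "K2", "ROSC", "ROSC2", "kdiff", "C3", "C3a", "C3G",
                  "C3b", "C3c", "Kt", "kAhp", "kmAhp", "kKat", "kmKat")

# variant registry: integer code used by the C derivatives, the extra
# constants each variant is allowed to carry, and any extra state variable
.variant_registry <- list(
  A = list(code = 1L, extra = character(0),               extra_state = character(0)),
  B = list(code = 2L, extra = c("U2", "K2"),              extra_state = character(0)),
  C = list(code = 3L, extra = "ROSC",                     extra_state = character(0)),
  D = list(code = 4L, extra = c("ROSC2", "kdiff"),        extra_state = "ROSexternal"),
  E = list(code = 5L, extra = "C3",                       extra_state = character(0)),
  F = list(code = 6L, extra = "C3a",                      extra_state = character(0)),
  G = list(code = 7L, extra = "C3G",                      extra_state = character(0)),
  H = list(code = 8L, extra = "C3b",                      extra_state = character(0)),
  I = list(code = 9L, extra = "C3c",                      extra_state = character(0)),
  J = list(code = 10L, extra = "Kt",                      extra_state = character(0)),
  K = list(code = 11L, extra = c("kAhp", "kmAhp", "kKat", "kmKat", "kdiff"),
           extra_state = "ROSexternal"),
  D_coculture = list(code = 12L, extra = c("ROSC2", "kdiff"),
                     extra_state = "ROSexternal")
)

.default_config_path <- function() {
  system.file("extdata", "model_parameters.yml", package = "dampsim",
              mustWork = TRUE)
}

#' Recognised model variant identifiers
#'
#' @return Character vector of the valid variant ids: the baseline model
#'   `"A"`, structural variants `"B"` to `"K"`, and the two-population
#'   `"D_coculture"`.
#' @export
variant_ids <- function() names(.variant_registry)

#' Read a parameter configuration file
#'
#' Parses a plain-text YAML key/value document with a `baseline` section
#' (all 19 model constants) and a `variants` section carrying per-variant
#' `overrides` and `extra` constants.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `baseline` (named numeric vector of length
#'   19 in canonical order) and `variants` (list keyed by variant id).
#' @export
read_parameter_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$baseline))
    stop("configuration error: no 'baseline' section in ", path)
  base <- unlist(cfg$baseline)
  missing <- setdiff(.param_names, names(base))
  extra <- setdiff(names(base), .param_names)
  if (length(missing))
    stop("configuration error: missing parameter(s): ",
         paste(missing, collapse = ", "))
  if (length(extra))
    stop("configuration error: unknown parameter(s): ",
         paste(extra, collapse = ", "))
  base <- base[.param_names]
  if (any(!is.finite(base)) || any(base <= 0))
    stop("configuration error: all parameters must be finite and positive")
  variants <- cfg$variants
  if (is.null(variants)) variants <- list()
  list(baseline = base, variants = variants)
}

#' Baseline model parameters
#'
#' Returns the 19 constants of the baseline batch-culture model (model A):
#' glucose uptake `U1` and half-saturation `Ks`, dGTP synthesis `M1`,
#' incorporation and strand-completion rates `I1`/`D1`, nucleotide oxidation
#' `O2`, misincorporation and fixation rates `I2`/`D2`/`R1`/`R2`, repair
#' rates `C1` (MutT), `C2` (MutY), `S` (MutS), peroxide production multiplier
#' `r` and degradation `O3`, glucose-per-dGTP stoichiometry `Met1`, and the
#' conversion constants `CellVol`, `molML`, `GCperGen`.
#'
#' @param config Optional path to a parameter configuration file; defaults
#'   to the configuration packaged with dampsim.
#' @return Named numeric vector of length 19.
#' @examples
#' p <- baseline_parameters()
#' p[["Ks"]]
#' @export
baseline_parameters <- function(config = NULL) {
  if (is.null(config)) config <- .default_config_path()
  read_parameter_config(config)$baseline
}

#' Write a parameter configuration file
#'
#' Inverse of [read_parameter_config()]: serialises a baseline parameter set
#' (and optionally the variant sections) back to a YAML document so that a
#' round trip reproduces the identical set.
#'
#' @param params Named numeric vector of the 19 baseline constants.
#' @param path Output file path.
#' @param variants Optional variants section (as returned by
#'   [read_parameter_config()]).
#' @return `path`, invisibly.
#' @export
write_parameter_config <- function(params, path, variants = NULL) {
  missing <- setdiff(.param_names, names(params))
  if (length(missing))
    stop("configuration error: missing parameter(s): ",
         paste(missing, collapse = ", "))
  out <- list(baseline = as.list(params[.param_names]))
  if (!is.null(variants)) out$variants <- variants
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}

#' Variant specification
#'
#' Builds the specification of a model variant: its baseline parameter
#' overrides (the printed re-fits, e.g. `O2 = 40` for variant D), its extra
#' constants, and any extra state variable (the external peroxide pool for
#' variants D, K and the coculture).
#'
#' @param variant_id One of [variant_ids()].
#' @param config Optional path to a parameter configuration file.
#' @return An object of class `variant_spec` with elements `variant_id`,
#'   `code`, `overrides`, `extra_params` and `extra_state`.
#' @examples
#' variant_spec("D")$extra_params
#' @export
variant_spec <- function(variant_id, config = NULL) {
  if (length(variant_id) != 1L || !variant_id %in% names(.variant_registry))
    stop("unknown variant '", paste(variant_id, collapse = ","),
         "'; valid variants: ", paste(names(.variant_registry), collapse = ", "))
  if (is.null(config)) config <- .default_config_path()
  reg <- .variant_registry[[variant_id]]
  cfg <- read_parameter_config(config)$variants[[variant_id]]
  overrides <- unlist(cfg$overrides)
  if (is.null(overrides)) overrides <- numeric(0)
  extra <- unlist(cfg$extra)
  if (is.null(extra)) extra <- numeric(0)
  bad <- union(setdiff(names(extra), reg$extra), setdiff(reg$extra, names(extra)))
  if (length(bad))
    stop("configuration error: variant ", variant_id,
         " must carry exactly the extra constant(s) ",
         paste(reg$extra, collapse = ", "))
  structure(list(variant_id = variant_id, code = reg$code,
                 overrides = overrides, extra_params = extra,
                 extra_state = reg$extra_state),
            class = "variant_spec")
}

.as_variant <- function(variant) {
  if (inherits(variant, "variant_spec")) variant else variant_spec(variant)
}

#' Effective parameter set for a variant
#'
#' Applies a variant's overrides to a baseline parameter set and appends its
#' extra constants.
#'
#' @param variant A `variant_spec` or a variant id.
#' @param params Baseline parameters (defaults to [baseline_parameters()]).
#' @return Named numeric vector: the 19 baseline slots (with overrides
#'   applied) followed by the variant's extra constants.
#' @export
variant_parameters <- function(variant, params = baseline_parameters()) {
  variant <- .as_variant(variant)
  p <- params[.param_names]
  if (any(is.na(p)))
    stop("params must contain all 19 baseline constants")
  if (length(variant$overrides))
    p[names(variant$overrides)] <- variant$overrides
  c(p, variant$extra_params)
}

# Pack parameters into the fixed-length vector consumed by the C derivatives.
.pack_parms <- function(variant, params = baseline_parameters()) {
  variant <- .as_variant(variant)
  full <- variant_parameters(variant, params)
  pv <- numeric(length(.param_names) + 1L + length(.extra_names))
  names(pv) <- c(.param_names, "variant_code", .extra_names)
  pv[.param_names] <- full[.param_names]
  pv["variant_code"] <- variant$code
  have <- intersect(.extra_names, names(full))
  pv[have] <- full[have]
  pv
}
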