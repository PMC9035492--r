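#' @keywords internal
#' @useDynLib tregsim
#' @importFrom stats setNames
"_PACKAGE"

## Canonical ordering of the 14 state variables. Everything downstream
## (RHS evaluation, the compiled solver core, trajectory matrices, CSV
## output) relies on this order, so it is defined exactly once.
STATE_NAMES <- c(
  "T_H_LN",   # CD4 T helper cells, lymph node (cells)
  "T_E_LN",   # CD8 cytotoxic T cells, lymph node (cells)
  "T_R_LN",   # activated Tregs, lymph node (cells)
  "T_RN_LN",  # naive Tregs, lymph node (cells)
  "A_mat_LN", # mature dendritic cells, lymph node (cells)
  "T_H_G",    # CD4 T cells, graft (cells)
  "T_E_G",    # CD8 T cells, graft (cells)
  "T_R_G",    # activated Tregs, graft (cells)
  "A_imm",    # immature (donor-derived) dendritic cells (cells)
  "A_mat_G",  # mature dendritic cells, graft (cells)
  "A_inf",    # inflammatory macrophages, graft (cells)
  "C_p",      # pro-inflammatory cytokine (normalized units)
  "C_a",      # anti-inflammatory cytokine (normalized units)
  "G"         # surviving graft cells (cells)
)

## Rate/half-saturation constants of the ten equations whose functional
## forms are not part of the printed Treg equations.  Kept in a named
## registry so a different calibration can be dropped in from a config
## file without touching code.
SUPPLEMENTARY_RATE_NAMES <- c(
  "mu_IA",     # immature-DC decay coefficient, scaled by remaining graft mass (1/day)
  "m_A",       # DC maturation rate coefficient (1/day)
  "k_mp",      # cytokine half-saturation of the maturation signal (conc)
  "k_mh",      # graft-CD4 half-saturation of the maturation signal (cells)
  "kappa_RA",  # Treg inhibition constant for DC maturation (cells)
  "e_A",       # mature-DC graft-to-LN trafficking rate (1/day)
  "mu_A",      # mature-DC death rate (1/day)
  "a_H",       # CD4 activation/recruitment coefficient (cells/day)
  "a_E",       # CD8 activation/recruitment coefficient (cells/day)
  "gamma_act", # mature-LN-DC half-saturation for T cell activation (cells)
  "kappa_act", # LN-Treg inhibition constant for activation (cells)
  "r_H",       # CD4 antigen-driven proliferation coefficient (1/day)
  "r_E",       # CD8 antigen-driven proliferation coefficient (1/day)
  "alpha_T",   # effector proliferation half-saturation (cells)
  "mu_TH",     # LN CD4 death rate (1/day)
  "mu_TE",     # LN CD8 death rate (1/day)
  "e_H",       # CD4 LN-to-graft trafficking rate (1/day)
  "e_E",       # CD8 LN-to-graft trafficking rate (1/day)
  "mu_THG",    # graft CD4 death rate (1/day)
  "mu_TEG",    # graft CD8 death rate (1/day)
  "a_M",       # macrophage activation coefficient (cells/day)
  "gamma_M",   # cytokine half-saturation of macrophage activation (conc)
  "kappa_Ma",  # anti-inflammatory inhibition constant for macrophages (conc)
  "mu_M",      # macrophage death rate (1/day)
  "p_p",       # pro-inflammatory cytokine production per cell (conc/day/cell)
  "kappa_pa",  # anti-inflammatory inhibition constant for C_p production (conc)
  "mu_Cp",     # pro-inflammatory cytokine decay rate (1/day)
  "p_a",       # anti-inflammatory cytokine production per graft Treg (conc/day/cell)
  "mu_Ca",     # anti-inflammatory cytokine decay rate (1/day)
  "k_GE",      # CD8 graft-destruction coefficient (1/(cell day))
  "k_GM",      # macrophage graft-destruction coefficient (1/(cell day))
  "kappa_k",   # graft-Treg inhibition constant for effector killing (cells)
  "kappa_ca"   # anti-inflammatory inhibition constant for effector killing (conc)
)

PRINTED_PARAMETER_NAMES <- c(
  "k_eR", "mu_R", "r_RG", "alpha_6", "a_R", "gamma_2",
  "r_R", "alpha_2", "e_R", "mu_RN", "T_0"
)

#' Construct an immune state vector
#'
#' Builds and validates the 14-component state of the two-compartment
#' alloimmune model: lymph-node and graft T cell populations (CD4 helper,
#' CD8 cytotoxic, activated and naive regulatory), dendritic cells,
#' inflammatory macrophages, the two cytokine pools, and surviving graft
#' cells. All populations are absolute cell counts; cytokines are in
#' model-normalized concentration units.
#'
#' @param ... Named state values (any subset of the 14 names); unnamed
#'   fields default to 0.
#' @param values Optionally, a full named numeric vector instead of `...`.
#' @return A named numeric vector of length 14, class `immune_state`.
#' @export
#' @examples
#' immune_state(G = 1e9, T_RN_LN = 1e5, A_imm = 1e5, C_p = 1)
immune_state <- function(..., values = NULL) {
  x <- stats::setNames(numeric(length(STATE_NAMES)), STATE_NAMES)
  supplied <- if (is.null(values)) unlist(list(...)) else values
  if (length(supplied)) {
    if (is.null(names(supplied)) || any(names(supplied) == "")) {
      stop("all state values must be named", call. = FALSE)
    }
    unknown <- setdiff(names(supplied), STATE_NAMES)
    if (length(unknown)) {
      stop("unknown state field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    x[names(supplied)] <- supplied
  }
  validate_immune_state(x)
  structure(x, class = c("immune_state", "numeric"))
}

validate_immune_state <- function(x, context = "immune state") {
  bad <- !is.finite(x)
  if (any(bad)) {
    stop(context, ": non-finite value in field(s) ",
         paste(STATE_NAMES[bad], collapse = ", "), call. = FALSE)
  }
  neg <- x < 0
  if (any(neg)) {
    stop(context, ": negative value in field(s) ",
         paste(STATE_NAMES[neg], collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Construct a model parameter set
#'
#' Bundles the printed Treg-equation constants, the registry of
#' supplementary rate constants for the remaining ten equations, and the
#' initial condition. Rates are per day, half-saturation constants in
#' cells (or normalized concentration units for cytokine constants).
#'
#' @param printed Named list/vector of the eleven Treg-equation constants
#'   (`k_eR`, `mu_R`, `r_RG`, `alpha_6`, `a_R`, `gamma_2`, `r_R`,
#'   `alpha_2`, `e_R`, `mu_RN`, `T_0`).
#' @param supplementary Named list/vector covering every name in
#'   [supplementary_rate_names()].
#' @param initial_state An [immune_state()] used at `t = 0`; must have
#'   `G > 0`.
#' @return An object of class `parameter_set`.
#' @seealso [default_parameters()] for the package's reference calibration.
#' @export
parameter_set <- function(printed, supplementary, initial_state) {
  printed <- as.list(printed)
  supplementary <- as.list(supplementary)
  missing_p <- setdiff(PRINTED_PARAMETER_NAMES, names(printed))
  if (length(missing_p)) {
    stop("missing printed parameter(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(names(supplementary))) {
    stop("duplicate supplementary_rates keys: ",
         paste(unique(names(supplementary)[duplicated(names(supplementary))]),
               collapse = ", "), call. = FALSE)
  }
  vals <- unlist(c(printed[PRINTED_PARAMETER_NAMES], supplementary))
  if (any(!is.finite(vals))) {
    stop("non-finite parameter value(s): ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "), call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("negative parameter value(s): ",
         paste(names(vals)[vals < 0], collapse = ", "), call. = FALSE)
  }
  if (printed$T_0 <= 0) stop("T_0 must be > 0", call. = FALSE)
  if (!inherits(initial_state, "immune_state")) {
    initial_state <- immune_state(values = unlist(initial_state)[STATE_NAMES])
  }
  if (initial_state[["G"]] <= 0) {
    stop("initial_state.G must be > 0", call. = FALSE)
  }
  structure(
    list(printed = printed[PRINTED_PARAMETER_NAMES],
         supplementary_rates = supplementary,
         initial_state = initial_state),
    class = "parameter_set"
  )
}

#' Look up a supplementary rate constant
#'
#' Unknown keys fail loudly rather than returning `NULL`, so a
#' mistranscribed configuration cannot silently zero out a term.
#'
#' @param p A [parameter_set()].
#' @param name Registry key.
#' @return The numeric value.
#' @export
supp_rate <- function(p, name) {
  v <- p$supplementary_rates[[name]]
  if (is.null(v)) {
    stop("unknown supplementary_rates key: '", name, "'", call. = FALSE)
  }
  v
}

#' Names of the supplementary rate registry
#'
#' @return Character vector of registry keys with one entry per rate or
#'   half-saturation constant appearing in the ten non-Treg equations.
#' @export
supplementary_rate_names <- function() SUPPLEMENTARY_RATE_NAMES

#' State variable names in canonical order
#' @return Character vector of the 14 state names.
#' @export
state_names <- function() STATE_NAMES

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat("  printed Treg-equation constants:",
      paste(sprintf("%s=%g", names(x$printed), unlist(x$printed)),
            collapse = ", "), "\n")
  cat("  supplementary rates:", length(x$supplementary_rates), "entries\n")
  cat("  initial graft cells:", format(x$initial_state[["G"]]), "\n")
  invisible(x)
}

#' Reference calibration of the model
#'
#' The package's default parameter set and initial condition for murine
#' heterotopic heart transplantation. These values are a synthetic
#' reference calibration produced with this package (structural constants
#' chosen at immunologically conventional scales, then calibrated so that
#' the untreated model rejects on POD 11 and adoptive-transfer responses
#' fall in the reported therapeutic range); they are not transcribed
#' experimental measurements. Any externally calibrated table can replace
#' them via [read_model_config()].
#'
#' @return A [parameter_set()].
#' @export
default_parameters <- function() {
  printed <- list(
    k_eR    = 0.00359, # LN -> graft Treg trafficking (1/day)
    mu_R    = 0.188,   # activated Treg death (1/day)
    r_RG    = 0.443,   # graft Treg proliferation coefficient (1/day)
    alpha_6 = 1.24e5,  # graft Treg proliferation half-saturation (cells)
    a_R     = 0.05,    # naive Treg activation coefficient (1/day)
    gamma_2 = 2e4,     # DC half-saturation for Treg activation (cells)
    r_R     = 0.05,    # LN Treg proliferation coefficient (1/day)
    alpha_2 = 1e5,     # LN Treg proliferation half-saturation (cells)
    e_R     = 0.385,   # LN Treg egress (1/day)
    mu_RN   = 0.05,    # naive Treg homeostatic turnover (1/day)
    T_0     = 1e5      # naive Treg set point (cells)
  )
  supplementary <- list(
    mu_IA = 0.859, m_A = 1.50, k_mp = 0.5, k_mh = 5e4, kappa_RA = 1.42e5,
    e_A = 0.319, mu_A = 0.0404,
    a_H = 2e3, a_E = 2e3, gamma_act = 2e3, kappa_act = 7.32e4,
    r_H = 4.89, r_E = 3.09, alpha_T = 3.32e4, mu_TH = 0.25, mu_TE = 0.25,
    e_H = 0.6, e_E = 0.6, mu_THG = 0.35, mu_TEG = 0.35,
    a_M = 1.76e4, gamma_M = 1.31, kappa_Ma = 2.85, mu_M = 0.342,
    p_p = 1.02e-4, kappa_pa = 2.0, mu_Cp = 1.69,
    p_a = 1.41e-5, mu_Ca = 1.0,
    k_GE = 3.93e-6, k_GM = 6.6e-7, kappa_k = 9.99e3, kappa_ca = 4.55
  )
  init <- immune_state(T_RN_LN = 1e5, A_imm = 1e5, C_p = 0.167, G = 1e9)
  parameter_set(printed, supplementary, init)
}

#' Read a model configuration file
#'
#' Parses a structured configuration (YAML or JSON, auto-detected from
#' the file extension) with sections `printed_parameters`,
#' `supplementary_rates`, `initial_state`, and optionally `schedule`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `parameters` (a [parameter_set()]) and
#'   `schedule` (a [dosing_schedule()] or `NULL`).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config extension '.", ext, "' (use yaml or json)",
         call. = FALSE)
  )
  for (sec in c("printed_parameters", "supplementary_rates", "initial_state")) {
    if (is.null(cfg[[sec]])) {
      stop("config missing section '", sec, "'", call. = FALSE)
    }
  }
  p <- parameter_set(cfg$printed_parameters, cfg$supplementary_rates,
                     immune_state(values = unlist(cfg$initial_state)[STATE_NAMES]))
  sched <- NULL
  if (!is.null(cfg$schedule)) {
    s <- cfg$schedule
    sched <- dosing_schedule(
      D0 = s$D0, beta = s$beta, dose_days = unlist(s$dose_days),
      f_G = s$f_G, f_LN = s$f_LN, f_N = s$f_N
    )
  }
  list(parameters = p, schedule = sched)
}

#' Write a model configuration file
#'
#' Inverse of [read_model_config()]; format chosen from the extension.
#'
#' @param p A [parameter_set()].
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @param schedule Optional [dosing_schedule()] to embed.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(p, path, schedule = NULL) {
  cfg <- list(
    printed_parameters = p$printed,
    supplementary_rates = p$supplementary_rates,
    initial_state = as.list(unclass(p$initial_state))
  )
  if (!is.null(schedule)) {
    cfg$schedule <- list(
      D0 = schedule$D0, beta = schedule$beta,
      dose_days = schedule$dose_days,
      f_G = schedule$f_G, f_LN = schedule$f_LN, f_N = schedule$f_N
    )
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(cfg, path),
    json = jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop("unsupported config extension '.", ext, "'", call. = FALSE)
  )
  invisible(path)
}
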