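# Registry of drugs, linkers and antibodies, and the mass bookkeeping of
# lysine-directed NHS-ester conjugation.

#' Linker specification
#'
#' Describes a heterobifunctional NHS-ester/maleimide crosslinker. On
#' coupling to a lysine amine the N-hydroxysuccinimide leaving group
#' (115 Da) departs, so the mass added to the antibody per conjugated
#' drug-linker is `drug + linker - leaving_group`.
#'
#' @param name Short identifier, e.g. `"SMCC"`.
#' @param mw_Da Average molecular weight of the intact linker, Da.
#' @param spacer_arm_A Spacer arm length, Angstrom.
#' @param leaving_group_Da Mass lost on antibody coupling, Da (default 115,
#'   the NHS leaving group).
#' @return A `linker_spec` object.
#' @export
#' @examples
#' linker_spec("SMCC", mw_Da = 334.32, spacer_arm_A = 8.3)
linker_spec <- function(name, mw_Da, spacer_arm_A, leaving_group_Da = 115) {
  check_number(mw_Da, "mw_Da", positive = TRUE)
  check_number(spacer_arm_A, "spacer_arm_A", positive = TRUE)
  check_number(leaving_group_Da, "leaving_group_Da", positive = TRUE)
  if (mw_Da <= leaving_group_Da)
    stop_arg("linker mw_Da (%g) must exceed leaving_group_Da (%g)",
             mw_Da, leaving_group_Da)
  structure(list(name = as.character(name), mw_Da = mw_Da,
                 spacer_arm_A = spacer_arm_A,
                 leaving_group_Da = leaving_group_Da),
            class = "linker_spec")
}

#' Drug (payload) specification
#'
#' @param name Short identifier, e.g. `"DM1"`.
#' @param mw_Da Average molecular weight, Da.
#' @param lambda_max_nm Wavelength of maximum absorbance, nm (252 for DM1).
#' @return A `drug_spec` object.
#' @export
drug_spec <- function(name, mw_Da, lambda_max_nm = 252) {
  check_number(mw_Da, "mw_Da", positive = TRUE)
  check_number(lambda_max_nm, "lambda_max_nm")
  if (lambda_max_nm < 200 || lambda_max_nm > 400)
    stop_arg("lambda_max_nm must lie in [200, 400] nm (got %g)", lambda_max_nm)
  structure(list(name = as.character(name), mw_Da = mw_Da,
                 lambda_max_nm = lambda_max_nm),
            class = "drug_spec")
}

#' Antibody specification
#'
#' Holds both the sequence-derived formula mass and (optionally) the
#' observed intact mass. For a glycosylated IgG the measured mass exceeds
#' the formula mass by the glycan load; intact-MS mass shifts are computed
#' against the measured mass when it is available.
#'
#' @param name Identifier, e.g. `"trastuzumab"`.
#' @param mw_formula_Da Sequence-based molecular weight, Da.
#' @param mw_measured_Da Observed intact mass, Da, or `NULL`.
#' @return An `antibody_spec` object.
#' @export
antibody_spec <- function(name, mw_formula_Da, mw_measured_Da = NULL) {
  check_number(mw_formula_Da, "mw_formula_Da", positive = TRUE)
  if (mw_formula_Da <= 1e5)
    stop_arg("mw_formula_Da must exceed 100000 Da for an intact IgG (got %g)",
             mw_formula_Da)
  if (!is.null(mw_measured_Da)) {
    check_number(mw_measured_Da, "mw_measured_Da", positive = TRUE)
    if (mw_measured_Da <= 1e5)
      stop_arg("mw_measured_Da must exceed 100000 Da (got %g)", mw_measured_Da)
  }
  structure(list(name = as.character(name), mw_formula_Da = mw_formula_Da,
                 mw_measured_Da = mw_measured_Da),
            class = "antibody_spec")
}

#' Conjugate design: antibody + drug + linker
#'
#' Bundles the three components of a lysine-linked ADC. If
#' `per_drug_mass_override_Da` is supplied (e.g. a published per-drug-linker
#' mass addition) it takes precedence over the component sum in
#' [per_drug_mass_addition()]; it must agree with the component sum to
#' within 5 Da.
#'
#' @param antibody An [antibody_spec()].
#' @param drug A [drug_spec()].
#' @param linker A [linker_spec()].
#' @param per_drug_mass_override_Da Optional explicit mass addition per
#'   conjugated drug-linker, Da.
#' @return A `conjugate_design` object.
#' @export
conjugate_design <- function(antibody, drug, linker,
                             per_drug_mass_override_Da = NULL) {
  if (!inherits(antibody, "antibody_spec"))
    stop_arg("configuration error: `antibody` must be an antibody_spec")
  if (!inherits(drug, "drug_spec"))
    stop_arg("configuration error: `drug` must be a drug_spec")
  if (!inherits(linker, "linker_spec"))
    stop_arg("configuration error: `linker` must be a linker_spec")
  if (!is.null(per_drug_mass_override_Da)) {
    check_number(per_drug_mass_override_Da, "per_drug_mass_override_Da",
                 positive = TRUE)
    nominal <- drug$mw_Da + linker$mw_Da - linker$leaving_group_Da
    if (abs(per_drug_mass_override_Da - nominal) > 5)
      stop_arg(paste0("per_drug_mass_override_Da (%g) differs from the ",
                      "component sum %g by more than 5 Da"),
               per_drug_mass_override_Da, nominal)
  }
  structure(list(antibody = antibody, drug = drug, linker = linker,
                 per_drug_mass_override_Da = per_drug_mass_override_Da),
            class = "conjugate_design")
}

#' Mass added to the antibody per conjugated drug-linker
#'
#' The denominator of the intact-MS DAR: the drug mass plus the linker mass
#' minus the NHS leaving group lost on lysine coupling. An explicit override
#' stored in the design (e.g. a published per-drug-linker value) wins.
#'
#' @param design A [conjugate_design()].
#' @return Mass in Da.
#' @export
#' @examples
#' d <- conjugate_design(
#'   antibody_spec("trastuzumab", 145423, 147836.9),
#'   drug_spec("DM1", 738.08),
#'   linker_spec("SMCC", 334.32, 8.3))
#' per_drug_mass_addition(d)  # 957.40
per_drug_mass_addition <- function(design) {
  if (!inherits(design, "conjugate_design"))
    stop_arg("configuration error: `design` must be a conjugate_design")
  if (is.null(design$drug)) stop_arg("configuration error: missing drug record")
  if (is.null(design$linker))
    stop_arg("configuration error: missing linker record")
  if (!is.null(design$per_drug_mass_override_Da))
    return(design$per_drug_mass_override_Da)
  design$drug$mw_Da + design$linker$mw_Da - design$linker$leaving_group_Da
}

#' Built-in linker registry
#'
#' The three crosslinkers shipped with the package: SMCC and the hydrophilic
#' PEG linkers SM(PEG)2 and SM(PEG)12.
#'
#' @return Named list of [linker_spec()] objects.
#' @export
default_linkers <- function() {
  cfg <- load_constants()
  lst <- lapply(cfg$linkers, function(l)
    linker_spec(l$name, l$mw_Da, l$spacer_arm_A, l$leaving_group_Da %||% 115))
  setNames(lst, vapply(lst, `[[`, "", "name"))
}

#' Look up a linker by name
#'
#' @param name Linker name, e.g. `"SM(PEG)12"`.
#' @param registry Named list of [linker_spec()]s; defaults to the shipped
#'   registry ([default_linkers()]).
#' @return The matching [linker_spec()].
#' @export
lookup_linker <- function(name, registry = default_linkers()) {
  if (!name %in% names(registry))
    stop_arg("unknown linker \"%s\"; known linkers: %s",
             name, paste(names(registry), collapse = ", "))
  registry[[name]]
}

#' Load the physical-constants configuration
#'
#' Reads the JSON configuration holding the antibody, drug, linker and
#' extinction-coefficient constants. With `path = NULL` the configuration
#' shipped with the package is used; a user file may override any subset of
#' keys (missing keys fall back to the shipped values).
#'
#' @param path Path to a JSON file, or `NULL` for the packaged defaults.
#' @return A nested list with elements `antibody`, `drug`, `linkers`,
#'   `extinctions`, `path_cm`.
#' @export
load_constants <- function(path = NULL) {
  builtin <- system.file("extdata", "constants.json", package = "adcdar",
                         mustWork = TRUE)
  cfg <- jsonlite::read_json(builtin, simplifyVector = FALSE)
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = FALSE)
    cfg <- modifyList(cfg, user)
  }
  cfg
}

#' Default DM1 drug record
#' @param config Constants list from [load_constants()].
#' @return A [drug_spec()].
#' @export
default_drug <- function(config = load_constants()) {
  d <- config$drug
  drug_spec(d$name, d$mw_Da, d$lambda_max_nm %||% 252)
}

#' Default trastuzumab antibody record
#' @param config Constants list from [load_constants()].
#' @return An [antibody_spec()].
#' @export
default_antibody <- function(config = load_constants()) {
  a <- config$antibody
  antibody_spec(a$name, a$mw_formula_Da, a$mw_measured_Da)
}

#' @export
print.linker_spec <- function(x, ...) {
  cat(sprintf("<linker_spec> %s: %.2f Da, arm %.1f A, leaves %.0f Da\n",
              x$name, x$mw_Da, x$spacer_arm_A, x$leaving_group_Da))
  invisible(x)
}

#' @export
print.conjugate_design <- function(x, ...) {
  cat(sprintf("<conjugate_design> %s + %s via %s (per-drug mass %.2f Da%s)\n",
              x$antibody$name, x$drug$name, x$linker$name,
              per_drug_mass_addition(x),
              if (is.null(x$per_drug_mass_override_Da)) "" else ", override"))
  invisible(x)
}
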