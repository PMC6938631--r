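## The four-step decision procedure: disease mechanism, assay-class
## applicability, validation-tier assignment, and the objects they act on.

#' Structured disease-mechanism statement
#'
#' The structured narrative describing the gene-disease mechanism: gene
#' symbol (HGNC style), disease (MONDO identifier), mode of inheritance,
#' molecular mechanism of pathogenesis, and optionally the biological
#' pathways involved (GO identifiers). Identifiers are validated lexically
#' (prefix plus digits) and carried as opaque strings; no ontology lookups
#' are performed.
#'
#' @param geneSymbol HGNC-style gene symbol, e.g. \code{"CFTR"}.
#' @param disease MONDO-style identifier, e.g. \code{"MONDO:0009061"}.
#' @param modeOfInheritance one of \code{autosomal_dominant},
#'   \code{autosomal_recessive}, \code{mitochondrial}, \code{x_linked},
#'   \code{undetermined}.
#' @param molecularMechanism one of \code{loss_of_function},
#'   \code{gain_of_function}, \code{dominant_negative}.
#' @param pathways character vector of GO-style identifiers (may be empty).
#' @return A \code{DiseaseMechanismStatement} object.
#' @examples
#' DiseaseMechanismStatement("CFTR", "MONDO:0009061",
#'                           "autosomal_recessive", "loss_of_function",
#'                           pathways = "GO:0006811")
#' @aliases DiseaseMechanismStatement-class
#' @export
DiseaseMechanismStatement <- function(geneSymbol, disease, modeOfInheritance,
                                      molecularMechanism,
                                      pathways = character()) {
  new("DiseaseMechanismStatement",
      geneSymbol = geneSymbol, disease = disease,
      modeOfInheritance = modeOfInheritance,
      molecularMechanism = molecularMechanism,
      pathways = as.character(pathways))
}

#' General class of functional assay
#'
#' Describes a general class of assay used in the field: the model system,
#' experimental method, functional outcome measured, and which molecular
#' disease mechanisms the readout can probe.
#'
#' @param classId identifier for the class.
#' @param modelSystem one of \code{patient_derived}, \code{model_organism},
#'   \code{cellular}, \code{in_vitro}.
#' @param method free-text description of the experimental method.
#' @param functionalOutcome free-text description of the outcome measured.
#' @param mechanismsProbed non-empty subset of the molecular-mechanism
#'   vocabulary.
#' @param probesFullFunction FALSE when the assay is limited to a specific
#'   domain or single functional readout; normal results from such assays
#'   carry a completeness warning when used for BS3.
#' @return An \code{AssayClass} object.
#' @aliases AssayClass-class
#' @export
AssayClass <- function(classId, modelSystem, method = "", functionalOutcome = "",
                       mechanismsProbed, probesFullFunction = TRUE) {
  new("AssayClass", classId = classId, modelSystem = modelSystem,
      method = method, functionalOutcome = functionalOutcome,
      mechanismsProbed = mechanismsProbed,
      probesFullFunction = probesFullFunction)
}

#' Specific published instance of an assay
#'
#' A specific execution of a general assay class as performed by one group:
#' its provenance, experimental controls, replication, documentation basis,
#' and (optionally) its clinical calibration against classified variant
#' controls with a formally estimated OddsPath.
#'
#' @param instanceId,classId identifiers.
#' @param sourceRef PMID or DOI string for the source publication.
#' @param readoutType \code{"quantitative"} or \code{"qualitative"}.
#' @param hasWildtypeControl,hasNullControl presence of the negative
#'   (wild-type/normal) and positive (null/abnormal) experimental controls.
#' @param hasTechnicalReplicates,hasBiologicalReplicates replication flags.
#' @param basis \code{"documented"} when controls/replicates are documented
#'   for this instance; \code{"historical_or_kit"} for assay classes broadly
#'   accepted historically, previously validated, or provided as kits with
#'   defined performance characteristics.
#' @param calibration optional \code{CalibrationSummary} from
#'   \code{\link{calibrate}}.
#' @param formalOddsPath optional \code{OddsPathResult} from a rigorous
#'   statistical analysis; requires \code{calibration}.
#' @return An \code{AssayInstance} object.
#' @aliases AssayInstance-class
#' @export
AssayInstance <- function(instanceId, classId, sourceRef = "unpublished",
                          readoutType = "quantitative",
                          hasWildtypeControl = TRUE, hasNullControl = TRUE,
                          hasTechnicalReplicates = TRUE,
                          hasBiologicalReplicates = TRUE,
                          basis = "documented",
                          calibration = NULL, formalOddsPath = NULL) {
  new("AssayInstance", instanceId = instanceId, classId = classId,
      sourceRef = sourceRef, readoutType = readoutType,
      hasWildtypeControl = hasWildtypeControl,
      hasNullControl = hasNullControl,
      hasTechnicalReplicates = hasTechnicalReplicates,
      hasBiologicalReplicates = hasBiologicalReplicates,
      basis = basis, calibration = calibration,
      formalOddsPath = formalOddsPath)
}

#' Variant-level functional call
#'
#' The standardized description of a variant's result in an assay:
#' functionally normal, functionally abnormal, or indeterminate, with an
#' optional granular subtype for abnormal results (complete or partial
#' loss-of-function, gain-of-function, dominant-negative) and context flags
#' that drive advisory warnings (\code{patient_derived},
#' \code{model_organism}, \code{cdna_construct}, \code{splicing_assay},
#' \code{ptc_nmd_subject}, ...).
#'
#' @param variantId opaque variant identifier.
#' @param call one of \code{functionally_normal}, \code{functionally_abnormal},
#'   \code{indeterminate}.
#' @param abnormalSubtype optional subtype; only for abnormal calls.
#' @param contextFlags character vector of context flags (may be empty).
#' @return A \code{FunctionalCall} object.
#' @aliases FunctionalCall-class
#' @export
FunctionalCall <- function(variantId, call, abnormalSubtype = NA_character_,
                           contextFlags = character()) {
  new("FunctionalCall", variantId = variantId, call = call,
      abnormalSubtype = abnormalSubtype,
      contextFlags = as.character(contextFlags))
}

#' Applicability of an assay class to a disease mechanism
#'
#' An assay class is applicable when its readout probes the molecular
#' mechanism stated for the gene-disease pair; an assay validated for one
#' disorder does not automatically transfer to a disorder with a different
#' mechanism. Applicability never caps evidence strength -- strength is
#' determined by validation of the specific instance, not by the class.
#'
#' @param assayClass an \code{\link{AssayClass}}.
#' @param mechanism a \code{\link{DiseaseMechanismStatement}}.
#' @return A list with \code{applicable} (logical) and \code{rationale}
#'   (character).
#' @export
assessApplicability <- function(assayClass, mechanism) {
  stopifnot(is(assayClass, "AssayClass"),
            is(mechanism, "DiseaseMechanismStatement"))
  probed <- mechanism@molecularMechanism %in% assayClass@mechanismsProbed
  rationale <- if (probed)
    sprintf("assay class '%s' probes %s, the stated mechanism for %s (%s); strength is set by instance validation, not by assay class",
            assayClass@classId, mechanism@molecularMechanism,
            mechanism@geneSymbol, mechanism@disease)
  else
    sprintf("assay class '%s' probes {%s} but the stated mechanism for %s is %s; an assay validated for a different mechanism is not applicable",
            assayClass@classId,
            paste(assayClass@mechanismsProbed, collapse = ", "),
            mechanism@geneSymbol, mechanism@molecularMechanism)
  list(applicable = probed, rationale = rationale)
}

## Scenario rules used in tier assignment; the strings travel into
## justifications and reports.
.RULES <- c(
  no_experimental_controls =
    "no evidence: assay lacks wild-type/null experimental controls or any replication, and no historical/kit validation applies",
  historical_or_kit =
    "supporting: assay class broadly accepted historically, previously validated, or provided as a kit, without documented controls for this instance",
  controls_le_10 =
    "supporting: experimental controls and replicates present but 10 or fewer validation controls",
  controls_ge_11 =
    "moderate: at least 11 total validation controls including a mix of benign and pathogenic variants, without formal statistical analysis",
  formal_oddspath =
    "formal OddsPath: strength set by the odds of pathogenicity from rigorous statistical analysis (benign direction capped at strong)")

#' Maximum applicable strength tier for an assay instance
#'
#' Implements the instance-validation scenarios. With a documented basis, an
#' instance missing a wild-type or null control, or missing both replicate
#' types, supports no evidence. Otherwise: historical/kit classes without
#' documented controls, or instances with 10 or fewer validation controls,
#' reach supporting; at least 11 validation controls mixing benign and
#' pathogenic classes reach moderate without formal statistics; a formal
#' OddsPath sets the tier directly from the strength-equivalence table, with
#' the benign direction capped at strong. Ceilings are reported separately
#' per direction.
#'
#' @param instance an \code{\link{AssayInstance}}.
#' @return A list with \code{pathogenic} and \code{benign} tier names,
#'   \code{rule} (the scenario that set the ceilings) and \code{nControls}.
#' @examples
#' inst <- AssayInstance("i1", "c1", hasNullControl = FALSE)
#' assignValidationTier(inst)$pathogenic # "none"
#' @export
assignValidationTier <- function(instance) {
  stopifnot(is(instance, "AssayInstance"))
  cal <- instance@calibration
  nControls <- if (is.null(cal)) 0L else sum(controlCounts(cal))
  mixed <- !is.null(cal) &&
    any(.classSide(cal@perVariant$classification) == "benign") &&
    any(.classSide(cal@perVariant$classification) == "pathogenic")

  if (!is.null(instance@formalOddsPath)) {
    op <- instance@formalOddsPath
    pathTier <- mapStrength(oddsPathPathogenic(op), "pathogenic")
    benTier <- mapStrength(oddsPathBenign(op), "benign")
    path <- if (pathTier@code == "PS3") pathTier@tier else "none"
    # mapStrength has no very-strong benign tier, so the strong cap on the
    # benign direction is structural
    ben <- if (benTier@code == "BS3") benTier@tier else "none"
    return(list(pathogenic = path, benign = ben,
                rule = .RULES[["formal_oddspath"]], nControls = nControls))
  }

  if (instance@basis == "documented" &&
      (!instance@hasWildtypeControl || !instance@hasNullControl ||
       (!instance@hasTechnicalReplicates && !instance@hasBiologicalReplicates)))
    return(list(pathogenic = "none", benign = "none",
                rule = .RULES[["no_experimental_controls"]],
                nControls = nControls))

  if (nControls >= 11L && mixed)
    return(list(pathogenic = "moderate", benign = "moderate",
                rule = .RULES[["controls_ge_11"]], nControls = nControls))

  rule <- if (instance@basis == "historical_or_kit")
    .RULES[["historical_or_kit"]] else .RULES[["controls_le_10"]]
  list(pathogenic = "supporting", benign = "supporting", rule = rule,
       nControls = nControls)
}
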