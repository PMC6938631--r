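## Variant-level evidence application, stacking of results from multiple
## assays, context warnings, and the nonsense-mediated-decay boundary rule.

.subtypeCompatible <- function(subtype, mechanism) {
  switch(subtype,
         complete_loss_of_function = mechanism == "loss_of_function",
         partial_loss_of_function  = mechanism == "loss_of_function",
         gain_of_function          = mechanism == "gain_of_function",
         dominant_negative         = mechanism == "dominant_negative",
         FALSE)
}

.downTier <- function(tier) {
  c(none = "none", indeterminate = "none", supporting = "none",
    moderate = "supporting", strong = "moderate",
    very_strong = "strong")[[tier]]
}

.upTier <- function(tier, cap) {
  up <- c(supporting = "moderate", moderate = "strong", strong = "very_strong")
  if (!tier %in% names(up)) return(tier)
  out <- up[[tier]]
  if (tierRank(out) > tierRank(cap)) cap else out
}

.noneApplication <- function(variantId, instanceId, justification,
                             warnings = character()) {
  new("EvidenceApplication", variantId = variantId, code = "none",
      tier = "none", instanceId = instanceId,
      justification = justification, warnings = warnings)
}

#' Apply PS3/BS3 evidence for one variant from one assay instance
#'
#' A functionally abnormal result consistent with the disease mechanism
#' supports PS3 at the instance's pathogenic validation ceiling; a
#' functionally normal result supports BS3 at the benign ceiling; an
#' indeterminate result supports neither code. Partial loss-of-function
#' (hypomorphic) results merit special consideration: by default the applied
#' strength is reduced one tier with a warning. A normal result from an
#' assay limited to a single domain or functional readout carries a
#' completeness warning, since such an assay provides less strong evidence
#' of a benign effect.
#'
#' Evidence from an assay class that does not probe the stated disease
#' mechanism may not be applied (error). Evidence from patient-derived
#' material requires the policy's explicit acknowledgment flag; otherwise an
#' error directs the curator toward PP4.
#'
#' @param call a \code{\link{FunctionalCall}}.
#' @param instance the \code{\link{AssayInstance}} that produced the call.
#' @param mechanism the \code{\link{DiseaseMechanismStatement}}.
#' @param assayClass optional \code{\link{AssayClass}}; when supplied,
#'   applicability to the mechanism is enforced and the completeness warning
#'   can fire.
#' @param policy an \code{\link{evidencePolicy}}.
#' @return An \code{EvidenceApplication}.
#' @examples
#' cal <- calibrate(exampleFixture()$controls)
#' inst <- AssayInstance("i1", "c1", calibration = cal,
#'                       formalOddsPath = oddsPath(cal))
#' mech <- DiseaseMechanismStatement("GENE1", "MONDO:0000001",
#'                                   "autosomal_recessive", "loss_of_function")
#' app <- applyEvidence(FunctionalCall("VUS3", "functionally_abnormal"),
#'                      inst, mech)
#' tierLabel(app) # PS3_moderate
#' @aliases EvidenceApplication-class
#' @export
applyEvidence <- function(call, instance, mechanism, assayClass = NULL,
                          policy = evidencePolicy()) {
  stopifnot(is(call, "FunctionalCall"), is(instance, "AssayInstance"),
            is(mechanism, "DiseaseMechanismStatement"),
            inherits(policy, "evidencePolicy"))
  if (!is.null(assayClass)) {
    appl <- assessApplicability(assayClass, mechanism)
    if (!appl$applicable)
      stop("evidence may not be applied: ", appl$rationale)
  }
  warnings <- contextWarnings(call, instance)
  if ("patient_derived" %in% call@contextFlags &&
      !policy$acknowledgePatientDerived)
    stop("evidence from patient-derived material is better used to satisfy ",
         "PP4; to proceed with PS3/BS3 anyway, set ",
         "evidencePolicy(acknowledgePatientDerived = TRUE)")

  ceilings <- assignValidationTier(instance)

  if (call@call == "indeterminate")
    return(.noneApplication(call@variantId, instance@instanceId,
                            "indeterminate assay readout: neither PS3 nor BS3 can be applied",
                            warnings))

  if (call@call == "functionally_normal") {
    if (!is.null(assayClass) && !assayClass@probesFullFunction)
      warnings <- c(warnings,
                    paste0("assay is limited to a specific domain or functional ",
                           "readout; a normal result provides less strong ",
                           "evidence of a benign effect"))
    tier <- ceilings$benign
    if (tierRank(tier) == 0L)
      return(.noneApplication(call@variantId, instance@instanceId,
                              paste0("functionally normal readout, but instance validation supports no evidence (",
                                     ceilings$rule, ")"), warnings))
    return(new("EvidenceApplication", variantId = call@variantId,
               code = "BS3", tier = tier, instanceId = instance@instanceId,
               justification = paste0("functionally normal readout; ",
                                      ceilings$rule),
               warnings = warnings))
  }

  ## functionally abnormal
  subtype <- call@abnormalSubtype
  if (is.na(subtype)) {
    warnings <- c(warnings,
                  "abnormal subtype not specified; assumed consistent with the disease mechanism")
  } else if (!.subtypeCompatible(subtype, mechanism@molecularMechanism)) {
    return(.noneApplication(call@variantId, instance@instanceId,
                            sprintf("functionally abnormal (%s) readout is not consistent with the %s disease mechanism; PS3 not applied",
                                    subtype, mechanism@molecularMechanism),
                            warnings))
  }
  tier <- ceilings$pathogenic
  if (identical(subtype, "partial_loss_of_function") &&
      policy$hypomorphDowngrade) {
    tier <- .downTier(tier)
    warnings <- c(warnings,
                  paste0("intermediate (hypomorphic/partial loss-of-function) ",
                         "impact merits special consideration; strength ",
                         "reduced one tier"))
  }
  if (tierRank(tier) == 0L)
    return(.noneApplication(call@variantId, instance@instanceId,
                            paste0("functionally abnormal readout, but instance validation supports no evidence (",
                                   ceilings$rule, ")"), warnings))
  new("EvidenceApplication", variantId = call@variantId, code = "PS3",
      tier = tier, instanceId = instance@instanceId,
      justification = paste0("functionally abnormal readout consistent with ",
                             "the ", mechanism@molecularMechanism,
                             " mechanism; ", ceilings$rule),
      warnings = warnings)
}

## lexicographic validation key: (max direction ceiling, validation-control
## count, formal OddsPath present). Higher is better-validated.
.validationKey <- function(app, instances) {
  inst <- if (!is.null(instances)) instances[[app@instanceId]] else NULL
  if (is.null(inst))
    return(c(tierRank(app@tier), 0, 0))
  ceilings <- assignValidationTier(inst)
  c(max(tierRank(ceilings$pathogenic), tierRank(ceilings$benign)),
    ceilings$nControls,
    as.numeric(!is.null(inst@formalOddsPath)))
}

.keyCompare <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(1L)
    if (a[i] < b[i]) return(-1L)
  }
  0L
}

#' Combine evidence applications for one variant across assays
#'
#' When multiple assay results are available for a variant, the evidence
#' from the most well-validated assay is applied. Validation is ranked
#' lexicographically: tier ceiling, then number of validation controls, then
#' presence of a formal OddsPath. Consistent directions yield the
#' best-validated application; conflicting directions with strictly unequal
#' validation yield the better-validated side; conflicting directions at
#' essentially the same level of validation yield no evidence (conflicting
#' functional evidence should not be used). Combining same-direction results
#' from different assay classes into a higher tier is disabled by default
#' (\code{\link{evidencePolicy}}), since independence of the measured
#' functions cannot usually be ascertained.
#'
#' @param applications list of \code{EvidenceApplication}s for one variant.
#' @param instances optional named list of \code{AssayInstance}s keyed by
#'   instance id, used for validation ranking.
#' @param policy an \code{\link{evidencePolicy}}.
#' @return A single \code{EvidenceApplication}. The result is invariant to
#'   the order of \code{applications}.
#' @export
combineEvidence <- function(applications, instances = NULL,
                            policy = evidencePolicy()) {
  stopifnot(is.list(applications), length(applications) >= 1L,
            all(vapply(applications, is, logical(1), "EvidenceApplication")))
  ids <- vapply(applications, function(a) a@variantId, character(1))
  if (length(unique(ids)) > 1L)
    stop("applications refer to different variants: ",
         paste(unique(ids), collapse = ", "))
  if (length(applications) == 1L) return(applications[[1L]])

  ## deterministic order regardless of input order
  ord <- order(vapply(applications, function(a) a@instanceId, character(1)),
               vapply(applications, tierLabel, character(1)))
  applications <- applications[ord]

  active <- Filter(function(a) a@code != "none", applications)
  if (!length(active))
    return(.noneApplication(ids[1L], applications[[1L]]@instanceId,
                            "no assay supported PS3 or BS3 for this variant"))

  keys <- lapply(active, .validationKey, instances = instances)
  bestOf <- function(apps, ks) {
    best <- 1L
    for (i in seq_along(apps)[-1L]) {
      cmp <- .keyCompare(ks[[i]], ks[[best]])
      if (cmp > 0L ||
          (cmp == 0L && tierRank(apps[[i]]@tier) > tierRank(apps[[best]]@tier)))
        best <- i
    }
    apps[[best]]
  }

  codes <- vapply(active, function(a) a@code, character(1))
  if (length(unique(codes)) == 1L) {
    winner <- bestOf(active, keys)
    classes <- vapply(active, function(a) {
      inst <- if (!is.null(instances)) instances[[a@instanceId]] else NULL
      if (is.null(inst)) a@instanceId else inst@classId
    }, character(1))
    if (policy$allowCrossClassStacking && length(unique(classes)) >= 2L) {
      cap <- if (winner@code == "BS3") "strong" else "very_strong"
      stacked <- .upTier(winner@tier, cap)
      if (!identical(stacked, winner@tier)) {
        winner@tier <- stacked
        winner@warnings <- c(winner@warnings,
                             paste0("tier raised by cross-class stacking of ",
                                    "consistent results (policy opt-in); beware ",
                                    "double-counting of non-independent functions"))
      }
    }
    return(winner)
  }

  ## conflicting directions
  ps <- Filter(function(a) a@code == "PS3", active)
  bs <- Filter(function(a) a@code == "BS3", active)
  kps <- lapply(ps, .validationKey, instances = instances)
  kbs <- lapply(bs, .validationKey, instances = instances)
  bestPS <- bestOf(ps, kps); bestBS <- bestOf(bs, kbs)
  cmp <- .keyCompare(.validationKey(bestPS, instances),
                     .validationKey(bestBS, instances))
  if (cmp == 0L)
    return(.noneApplication(ids[1L], bestPS@instanceId,
                            "conflicting functional evidence from assays at the same level of validation; functional evidence not used"))
  winner <- if (cmp > 0L) bestPS else bestBS
  winner@warnings <- c(winner@warnings,
                       "conflicting result from a less-validated assay was overridden")
  winner
}

#' Context warnings for a functional call
#'
#' Advisory warnings driven by the call's context flags. Evidence from
#' patient-derived material is flagged toward PP4 with a prompt for the
#' number of unrelated individuals tested; model-organism data prompt a
#' nuanced evaluation; variants subject to nonsense-mediated decay studied
#' in cDNA constructs are flagged as possibly unrepresentative of the
#' endogenous situation; splicing assays are routed to splice-specific
#' guidance. The performing entity (clinical vs research laboratory) never
#' affects any warning or strength decision.
#'
#' @param call a \code{\link{FunctionalCall}}.
#' @param instance the \code{\link{AssayInstance}} (reserved for
#'   instance-level context; currently the flags live on the call).
#' @return Character vector of warnings (possibly empty).
#' @export
contextWarnings <- function(call, instance = NULL) {
  stopifnot(is(call, "FunctionalCall"))
  flags <- call@contextFlags
  w <- character()
  if ("patient_derived" %in% flags)
    w <- c(w, paste0("patient-derived material best reflects the organismal ",
                     "phenotype; this evidence would be better used to satisfy ",
                     "PP4. If proceeding, record the number of unrelated ",
                     "individuals in whom the variant was tested."))
  if ("model_organism" %in% flags)
    w <- c(w, paste0("model-organism evidence warrants a nuanced evaluation ",
                     "(orthology, genetic background, phenotype ",
                     "recapitulation); adjust strength to the rigor and ",
                     "reproducibility of the data"))
  if ("cdna_construct" %in% flags && "ptc_nmd_subject" %in% flags)
    w <- c(w, paste0("variant is expected to undergo nonsense-mediated decay; ",
                     "studying it in a cDNA construct or another system where ",
                     "NMD is not active may not reflect the endogenous ",
                     "situation"))
  if ("splicing_assay" %in% flags)
    w <- c(w, paste0("splicing readouts do not directly measure protein ",
                     "function; combining PS3 with PVS1 for splice-impact ",
                     "variants requires splice-specific guidance and is out ",
                     "of scope here"))
  w
}

#' Is a premature termination codon subject to nonsense-mediated decay?
#'
#' Applies the 50-nucleotide boundary rule: premature termination codons
#' before the 3'-most 50 nucleotides of the penultimate coding exon are
#' expected to trigger NMD and eliminate the transcript; PTCs at or beyond
#' that boundary (including anywhere in the last exon) are expected to
#' escape. The rule is inapplicable to single-exon transcripts, which return
#' FALSE with a note.
#'
#' @param ptcPosition 1-based coding coordinate of the first base of the
#'   premature termination codon.
#' @param exonLengths ordered coding-exon lengths in nucleotides.
#' @return Logical; for single-exon transcripts, FALSE with
#'   \code{attr(, "note")} explaining inapplicability.
#' @examples
#' nmdSubject(120, c(100, 100, 100)) # TRUE  (boundary at 150)
#' nmdSubject(151, c(100, 100, 100)) # FALSE (escapes NMD)
#' @export
nmdSubject <- function(ptcPosition, exonLengths) {
  if (!is.numeric(exonLengths) || length(exonLengths) < 1L ||
      any(exonLengths <= 0) || any(exonLengths != as.integer(exonLengths)))
    stop("exonLengths must be positive integer exon lengths in order")
  total <- sum(exonLengths)
  if (!.isCount(ptcPosition) || ptcPosition < 1 || ptcPosition > total)
    stop("ptcPosition must be a 1-based coding coordinate within the transcript")
  if (length(exonLengths) == 1L) {
    message("single-exon transcript: the 50-nt NMD boundary rule is inapplicable")
    return(structure(FALSE, note = "single-exon transcript: NMD rule inapplicable"))
  }
  junction <- sum(exonLengths[-length(exonLengths)])  # last exon-exon junction
  ptcPosition <= junction - 50
}

#' Evaluate variants end to end against a calibrated assay
#'
#' Convenience pipeline: calibrates the pooled controls, attaches the
#' calibration (and its OddsPath, when estimable) to the assay instance,
#' classifies each queried variant's readout against the selected
#' thresholds, and applies PS3/BS3 evidence per variant.
#'
#' @param controls controls table (see \code{\link{readControls}}).
#' @param calls data.frame with columns \code{variant_id},
#'   \code{readout_value}, and optionally \code{abnormal_subtype} and
#'   \code{context_flags} (semicolon-joined).
#' @param mechanism a \code{\link{DiseaseMechanismStatement}}.
#' @param instance optional \code{\link{AssayInstance}} skeleton; a fully
#'   documented quantitative instance is assumed when NULL.
#' @param assayClass optional \code{\link{AssayClass}}.
#' @param policy an \code{\link{evidencePolicy}}.
#' @return A list with \code{calibration} (CalibrationSummary),
#'   \code{instance} (the calibrated AssayInstance) and \code{applications}
#'   (named list of EvidenceApplication, one per call row).
#' @export
evaluateVariants <- function(controls, calls, mechanism, instance = NULL,
                             assayClass = NULL, policy = evidencePolicy()) {
  stopifnot(is.data.frame(calls),
            all(c("variant_id", "readout_value") %in% names(calls)))
  cal <- calibrate(controls, gridStep = policy$gridStep,
                   polarity = policy$polarity)
  if (is.null(instance))
    instance <- AssayInstance(instanceId = "pooled",
                              classId = if (is.null(assayClass)) "pooled"
                                        else assayClass@classId)
  instance@calibration <- cal
  instance@formalOddsPath <- oddsPath(cal)
  validObject(instance)

  apps <- lapply(seq_len(nrow(calls)), function(i) {
    subtype <- if ("abnormal_subtype" %in% names(calls))
      calls$abnormal_subtype[i] else NA_character_
    if (!is.na(subtype) && !nzchar(subtype)) subtype <- NA_character_
    flags <- if ("context_flags" %in% names(calls) &&
                 !is.na(calls$context_flags[i]) && nzchar(calls$context_flags[i]))
      trimws(strsplit(calls$context_flags[i], ";")[[1L]]) else character()
    zone <- classifyReadout(calls$readout_value[i], thresholds(cal))
    if (!is.na(subtype) && zone != "functionally_abnormal")
      subtype <- NA_character_
    fc <- FunctionalCall(calls$variant_id[i], zone,
                         abnormalSubtype = subtype, contextFlags = flags)
    applyEvidence(fc, instance, mechanism, assayClass = assayClass,
                  policy = policy)
  })
  names(apps) <- calls$variant_id
  list(calibration = cal, instance = instance, applications = apps)
}
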