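#' @import methods
NULL

## Controlled vocabularies ----------------------------------------------------

.CLASSIFICATIONS <- c("B", "LB", "P", "LP")
.POLARITIES      <- c("higher_is_normal", "lower_is_normal")
.TIER_RANK <- c(none = 0L, indeterminate = 0L, supporting = 1L,
                moderate = 2L, strong = 3L, very_strong = 4L)
.CODES           <- c("PS3", "BS3", "none")
.INHERITANCE     <- c("autosomal_dominant", "autosomal_recessive",
                      "mitochondrial", "x_linked", "undetermined")
.MECHANISMS      <- c("loss_of_function", "gain_of_function", "dominant_negative")
.MODEL_SYSTEMS   <- c("patient_derived", "model_organism", "cellular", "in_vitro")
.BASES           <- c("documented", "historical_or_kit")
.FUNCTION_CALLS  <- c("functionally_normal", "functionally_abnormal", "indeterminate")
.ABNORMAL_SUBTYPES <- c("complete_loss_of_function", "partial_loss_of_function",
                        "gain_of_function", "dominant_negative")

.isProb <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0 && x < 1
.isCount <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == as.integer(x)
.isFlag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
.isString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Rank of an evidence-strength tier
#'
#' Orders the strength vocabulary used throughout the package:
#' none/indeterminate (0) < supporting (1) < moderate (2) < strong (3) <
#' very_strong (4).
#'
#' @param tier character vector of tier names.
#' @return integer vector of ranks.
#' @export
tierRank <- function(tier) {
  bad <- setdiff(tier, names(.TIER_RANK))
  if (length(bad))
    stop("unknown strength tier(s): ", paste(bad, collapse = ", "))
  unname(.TIER_RANK[tier])
}

## AdjustedContingency ---------------------------------------------------------

#' @rdname adjustedContingency
#' @export
setClass("AdjustedContingency",
  representation(
    nBenignConcordant     = "integer",
    nPathogenicConcordant = "integer",
    nIndeterminate        = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nBenignConcordant < 1L)
      msg <- c(msg, "benign-class concordant controls missing (need >= 1)")
    if (object@nPathogenicConcordant < 1L)
      msg <- c(msg, "pathogenic-class concordant controls missing (need >= 1)")
    if (object@nIndeterminate < 0L)
      msg <- c(msg, "nIndeterminate must be >= 0")
    if (length(msg)) msg else TRUE
  })

## OddsPathResult --------------------------------------------------------------

#' @rdname oddsPathFromControls
#' @export
setClass("OddsPathResult",
  representation(
    p1                 = "numeric",
    p2Abnormal         = "numeric",
    p2Normal           = "numeric",
    oddsPathPathogenic = "numeric",
    oddsPathBenign     = "numeric",
    contingency        = "AdjustedContingency"),
  validity = function(object) {
    msg <- character()
    for (nm in c("p1", "p2Abnormal", "p2Normal"))
      if (!.isProb(slot(object, nm)))
        msg <- c(msg, sprintf("%s must be a probability strictly inside (0, 1)", nm))
    if (!is.numeric(object@oddsPathPathogenic) || object@oddsPathPathogenic <= 0)
      msg <- c(msg, "oddsPathPathogenic must be positive")
    if (!is.numeric(object@oddsPathBenign) || object@oddsPathBenign <= 0)
      msg <- c(msg, "oddsPathBenign must be positive")
    if (length(msg)) msg else TRUE
  })

setClassUnion("OddsPathResultOrNULL", c("OddsPathResult", "NULL"))

## StrengthTier ----------------------------------------------------------------

#' @rdname mapStrength
#' @export
setClass("StrengthTier",
  representation(code = "character", tier = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@code %in% .CODES)
      msg <- c(msg, "code must be one of PS3, BS3, none")
    if (!object@tier %in% names(.TIER_RANK))
      msg <- c(msg, "unknown strength tier")
    if (object@code == "BS3" && object@tier == "very_strong")
      msg <- c(msg, "BS3 never exceeds strong")
    if (object@code == "none" && tierRank(object@tier) > 0L)
      msg <- c(msg, "code 'none' implies tier none/indeterminate")
    if (object@code != "none" && tierRank(object@tier) == 0L)
      msg <- c(msg, "an applied code requires a tier above indeterminate")
    if (length(msg)) msg else TRUE
  })

## ReadoutThresholds -----------------------------------------------------------

#' @rdname selectThresholds
#' @export
setClass("ReadoutThresholds",
  representation(
    normalCutoff   = "numeric",
    abnormalCutoff = "numeric",
    polarity       = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@polarity %in% .POLARITIES)
      msg <- c(msg, "polarity must be higher_is_normal or lower_is_normal")
    ok <- if (identical(object@polarity, "lower_is_normal"))
      object@normalCutoff < object@abnormalCutoff
    else
      object@abnormalCutoff < object@normalCutoff
    if (!isTRUE(ok))
      msg <- c(msg, "cutoffs must leave an indeterminate zone between the normal and abnormal zones")
    if (length(msg)) msg else TRUE
  })

## CalibrationSummary ----------------------------------------------------------

#' @rdname calibrate
#' @export
setClass("CalibrationSummary",
  representation(
    perVariant            = "data.frame",
    nBenignConcordant     = "integer",
    nPathogenicConcordant = "integer",
    nIndeterminate        = "integer",
    nDiscordant           = "integer",
    thresholds            = "ReadoutThresholds",
    oddsPath              = "OddsPathResultOrNULL",
    notes                 = "character"),
  validity = function(object) {
    msg <- character()
    total <- object@nBenignConcordant + object@nPathogenicConcordant +
      object@nIndeterminate + object@nDiscordant
    if (total != nrow(object@perVariant))
      msg <- c(msg, "concordant/indeterminate/discordant counts must partition the control set")
    if (length(msg)) msg else TRUE
  })

setClassUnion("CalibrationSummaryOrNULL", c("CalibrationSummary", "NULL"))

## DiseaseMechanismStatement ---------------------------------------------------

#' @rdname DiseaseMechanismStatement
#' @export
setClass("DiseaseMechanismStatement",
  representation(
    geneSymbol         = "character",
    disease            = "character",
    modeOfInheritance  = "character",
    molecularMechanism = "character",
    pathways           = "character"),
  validity = function(object) {
    msg <- character()
    if (!grepl("^[A-Z][A-Z0-9-]*$", object@geneSymbol))
      msg <- c(msg, "geneSymbol must look like an HGNC symbol (capitals, digits, hyphens)")
    if (!grepl("^MONDO:[0-9]+$", object@disease))
      msg <- c(msg, "disease must be a MONDO-style identifier, e.g. MONDO:0011705")
    if (!object@modeOfInheritance %in% .INHERITANCE)
      msg <- c(msg, paste("modeOfInheritance must be one of:",
                          paste(.INHERITANCE, collapse = ", ")))
    if (!object@molecularMechanism %in% .MECHANISMS)
      msg <- c(msg, paste("molecularMechanism must be one of:",
                          paste(.MECHANISMS, collapse = ", ")))
    if (length(object@pathways) && !all(grepl("^GO:[0-9]{7}$", object@pathways)))
      msg <- c(msg, "pathways must be GO-style identifiers, e.g. GO:0006281")
    if (length(msg)) msg else TRUE
  })

## AssayClass ------------------------------------------------------------------

#' @rdname AssayClass
#' @export
setClass("AssayClass",
  representation(
    classId            = "character",
    modelSystem        = "character",
    method             = "character",
    functionalOutcome  = "character",
    mechanismsProbed   = "character",
    probesFullFunction = "logical"),
  validity = function(object) {
    msg <- character()
    if (!object@modelSystem %in% .MODEL_SYSTEMS)
      msg <- c(msg, paste("modelSystem must be one of:",
                          paste(.MODEL_SYSTEMS, collapse = ", ")))
    if (!length(object@mechanismsProbed))
      msg <- c(msg, "mechanismsProbed must be non-empty")
    if (!all(object@mechanismsProbed %in% .MECHANISMS))
      msg <- c(msg, "mechanismsProbed must be drawn from the molecular-mechanism vocabulary")
    if (length(msg)) msg else TRUE
  })

## AssayInstance ---------------------------------------------------------------

#' @rdname AssayInstance
#' @export
setClass("AssayInstance",
  representation(
    instanceId              = "character",
    classId                 = "character",
    sourceRef               = "character",
    readoutType             = "character",
    hasWildtypeControl      = "logical",
    hasNullControl          = "logical",
    hasTechnicalReplicates  = "logical",
    hasBiologicalReplicates = "logical",
    basis                   = "character",
    calibration             = "CalibrationSummaryOrNULL",
    formalOddsPath          = "OddsPathResultOrNULL"),
  validity = function(object) {
    msg <- character()
    if (!object@readoutType %in% c("quantitative", "qualitative"))
      msg <- c(msg, "readoutType must be quantitative or qualitative")
    if (!object@basis %in% .BASES)
      msg <- c(msg, "basis must be documented or historical_or_kit")
    if (!is.null(object@formalOddsPath) && is.null(object@calibration))
      msg <- c(msg, "a formal OddsPath requires the calibration it was derived from")
    if (length(msg)) msg else TRUE
  })

## FunctionalCall --------------------------------------------------------------

#' @rdname FunctionalCall
#' @export
setClass("FunctionalCall",
  representation(
    variantId       = "character",
    call            = "character",
    abnormalSubtype = "character",
    contextFlags    = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@call %in% .FUNCTION_CALLS)
      msg <- c(msg, paste("call must be one of:", paste(.FUNCTION_CALLS, collapse = ", ")))
    hasSubtype <- length(object@abnormalSubtype) == 1L && !is.na(object@abnormalSubtype)
    if (hasSubtype && !object@abnormalSubtype %in% .ABNORMAL_SUBTYPES)
      msg <- c(msg, paste("abnormalSubtype must be one of:",
                          paste(.ABNORMAL_SUBTYPES, collapse = ", ")))
    if (hasSubtype && object@call != "functionally_abnormal")
      msg <- c(msg, "abnormalSubtype only applies to functionally_abnormal calls")
    if (length(msg)) msg else TRUE
  })

## EvidenceApplication ---------------------------------------------------------

#' @rdname applyEvidence
#' @export
setClass("EvidenceApplication",
  representation(
    variantId     = "character",
    code          = "character",
    tier          = "character",
    instanceId    = "character",
    justification = "character",
    warnings      = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@code %in% .CODES)
      msg <- c(msg, "code must be PS3, BS3 or none")
    if (!object@tier %in% names(.TIER_RANK))
      msg <- c(msg, "unknown strength tier")
    if ((object@code == "none") != (tierRank(object@tier) == 0L))
      msg <- c(msg, "code 'none' if and only if tier is none/indeterminate")
    if (object@code == "BS3" && tierRank(object@tier) > tierRank("strong"))
      msg <- c(msg, "BS3 never exceeds strong")
    if (length(msg)) msg else TRUE
  })

## Accessor generics -----------------------------------------------------------

#' @export
setGeneric("oddsPathPathogenic", function(object) standardGeneric("oddsPathPathogenic"))
#' @export
setGeneric("oddsPathBenign", function(object) standardGeneric("oddsPathBenign"))
#' @export
setGeneric("priorP1", function(object) standardGeneric("priorP1"))
#' @export
setGeneric("normalCutoff", function(object) standardGeneric("normalCutoff"))
#' @export
setGeneric("abnormalCutoff", function(object) standardGeneric("abnormalCutoff"))
#' @export
setGeneric("polarity", function(object) standardGeneric("polarity"))
#' @export
setGeneric("thresholds", function(object) standardGeneric("thresholds"))
#' @export
setGeneric("oddsPath", function(object) standardGeneric("oddsPath"))
#' @export
setGeneric("controlCounts", function(object) standardGeneric("controlCounts"))
#' @export
setGeneric("tierLabel", function(object) standardGeneric("tierLabel"))

#' @describeIn oddsPathFromControls OddsPath toward pathogenicity.
#' @export
setMethod("oddsPathPathogenic", "OddsPathResult", function(object) object@oddsPathPathogenic)
#' @describeIn oddsPathFromControls OddsPath toward a benign interpretation.
#' @export
setMethod("oddsPathBenign", "OddsPathResult", function(object) object@oddsPathBenign)
#' @describeIn oddsPathFromControls Prior probability of pathogenicity P1.
#' @export
setMethod("priorP1", "OddsPathResult", function(object) object@p1)

#' @describeIn selectThresholds Cutoff at/beyond which a readout is functionally normal.
#' @export
setMethod("normalCutoff", "ReadoutThresholds", function(object) object@normalCutoff)
#' @describeIn selectThresholds Cutoff at/beyond which a readout is functionally abnormal.
#' @export
setMethod("abnormalCutoff", "ReadoutThresholds", function(object) object@abnormalCutoff)
#' @describeIn selectThresholds Readout polarity.
#' @export
setMethod("polarity", "ReadoutThresholds", function(object) object@polarity)

#' @describeIn calibrate Selected (or supplied) readout thresholds.
#' @export
setMethod("thresholds", "CalibrationSummary", function(object) object@thresholds)
#' @describeIn calibrate OddsPathResult, or NULL when a control class had no
#'   concordant member.
#' @export
setMethod("oddsPath", "CalibrationSummary", function(object) object@oddsPath)
#' @describeIn calibrate Named count vector (benign_concordant,
#'   pathogenic_concordant, indeterminate, discordant).
#' @export
setMethod("controlCounts", "CalibrationSummary", function(object) {
  c(benign_concordant = object@nBenignConcordant,
    pathogenic_concordant = object@nPathogenicConcordant,
    indeterminate = object@nIndeterminate,
    discordant = object@nDiscordant)
})

#' @describeIn mapStrength Serialized ACMG-style label: \code{PS3_supporting},
#'   \code{PS3_moderate}, \code{PS3} (strong), \code{PS3_very_strong},
#'   \code{BS3_supporting}, \code{BS3_moderate}, \code{BS3} (strong), or
#'   \code{none}.
#' @export
setMethod("tierLabel", "StrengthTier", function(object) {
  .tierLabel(object@code, object@tier)
})

#' @describeIn applyEvidence Serialized ACMG-style label of the application.
#' @export
setMethod("tierLabel", "EvidenceApplication", function(object) {
  .tierLabel(object@code, object@tier)
})

.tierLabel <- function(code, tier) {
  if (code == "none" || tierRank(tier) == 0L) return("none")
  if (tier == "strong") code else paste0(code, "_", tier)
}

## show methods ----------------------------------------------------------------

setMethod("show", "AdjustedContingency", function(object) {
  cat("AdjustedContingency\n")
  cat(sprintf("  abnormal-readout set: %d pathogenic + 1 added benign\n",
              object@nPathogenicConcordant))
  cat(sprintf("  normal-readout set:   %d benign + 1 added pathogenic\n",
              object@nBenignConcordant))
  cat(sprintf("  indeterminate (excluded): %d\n", object@nIndeterminate))
})

setMethod("show", "OddsPathResult", function(object) {
  cat("OddsPathResult\n")
  cat(sprintf("  prior P1: %.4g   P2(abnormal): %.4g   P2(normal): %.4g\n",
              object@p1, object@p2Abnormal, object@p2Normal))
  cat(sprintf("  OddsPath toward pathogenic: %.4g  -> %s\n",
              object@oddsPathPathogenic,
              tierLabel(mapStrength(object@oddsPathPathogenic, "pathogenic"))))
  cat(sprintf("  OddsPath toward benign:     %.4g  -> %s\n",
              object@oddsPathBenign,
              tierLabel(mapStrength(object@oddsPathBenign, "benign"))))
})

setMethod("show", "StrengthTier", function(object) {
  cat(sprintf("StrengthTier: %s (code %s, tier %s)\n",
              tierLabel(object), object@code, object@tier))
})

setMethod("show", "ReadoutThresholds", function(object) {
  cat(sprintf("ReadoutThresholds (%s): normal %s %g, abnormal %s %g\n",
              object@polarity,
              if (object@polarity == "higher_is_normal") ">=" else "<=",
              object@normalCutoff,
              if (object@polarity == "higher_is_normal") "<=" else ">=",
              object@abnormalCutoff))
})

setMethod("show", "CalibrationSummary", function(object) {
  cat("CalibrationSummary\n")
  cts <- controlCounts(object)
  cat(sprintf("  controls: %d benign concordant, %d pathogenic concordant, %d indeterminate, %d discordant\n",
              cts[["benign_concordant"]], cts[["pathogenic_concordant"]],
              cts[["indeterminate"]], cts[["discordant"]]))
  show(object@thresholds)
  if (!is.null(object@oddsPath)) show(object@oddsPath)
  else cat("  OddsPath: not estimable (a control class has no concordant member)\n")
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

setMethod("show", "DiseaseMechanismStatement", function(object) {
  cat("DiseaseMechanismStatement\n")
  cat(sprintf("  gene: %s  disease: %s\n", object@geneSymbol, object@disease))
  cat(sprintf("  inheritance: %s  mechanism: %s\n",
              object@modeOfInheritance, object@molecularMechanism))
  if (length(object@pathways))
    cat("  pathways:", paste(object@pathways, collapse = ", "), "\n")
})

setMethod("show", "AssayInstance", function(object) {
  cat(sprintf("AssayInstance %s (class %s, %s)\n",
              object@instanceId, object@classId, object@sourceRef))
  cat(sprintf("  readout: %s  basis: %s\n", object@readoutType, object@basis))
  cat(sprintf("  wild-type control: %s  null control: %s  technical reps: %s  biological reps: %s\n",
              object@hasWildtypeControl, object@hasNullControl,
              object@hasTechnicalReplicates, object@hasBiologicalReplicates))
  cat(sprintf("  clinical validation: %s\n",
              if (is.null(object@calibration)) "none attached"
              else sprintf("%d controls%s", sum(controlCounts(object@calibration)),
                           if (is.null(object@formalOddsPath)) "" else " + formal OddsPath")))
})

setMethod("show", "EvidenceApplication", function(object) {
  cat(sprintf("EvidenceApplication: %s -> %s (instance %s)\n",
              object@variantId, tierLabel(object), object@instanceId))
  cat("  ", object@justification, "\n", sep = "")
  for (w in object@warnings) cat("  warning: ", w, "\n", sep = "")
})
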