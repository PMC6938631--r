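## Pooling classified variant-control readouts across assay instances,
## readout-threshold selection, and clinical calibration of an assay.

.classSide <- function(classification) {
  ifelse(classification %in% c("B", "LB"), "benign",
         ifelse(classification %in% c("P", "LP"), "pathogenic", NA_character_))
}

.CONTROL_COLUMNS <- c("variant_id", "gene", "classification",
                      "classification_basis", "assay_instance_id",
                      "readout_value")

# Validates an in-memory controls table (one row per variant x assay
# instance) and enforces the circularity guard: validation controls must be
# classified without functional evidence.
.validateControls <- function(controls) {
  if (!is.data.frame(controls) || nrow(controls) == 0L)
    stop("controls must be a non-empty data.frame of per-instance readouts")
  missing <- setdiff(.CONTROL_COLUMNS, names(controls))
  if (length(missing))
    stop("controls table is missing column(s): ", paste(missing, collapse = ", "))
  bad <- unique(controls$classification[!controls$classification %in% .CLASSIFICATIONS])
  if (length(bad))
    stop("unknown classification token(s): ", paste(bad, collapse = ", "),
         " (expected B, LB, P or LP)")
  if (!is.numeric(controls$readout_value) || anyNA(controls$readout_value))
    stop("readout_value must be numeric with no missing values")
  circular <- vapply(strsplit(as.character(controls$classification_basis), ";"),
                     function(codes) any(grepl("^(PS3|BS3)", trimws(codes))),
                     logical(1))
  if (any(circular))
    stop("circularity guard: control variant(s) classified using PS3/BS3: ",
         paste(unique(controls$variant_id[circular]), collapse = ", "),
         ". Validation controls must be classified with evidence independent ",
         "of functional data.")
  # a variant must carry a single classification across instances
  byVar <- tapply(controls$classification, controls$variant_id,
                  function(x) length(unique(x)))
  if (any(byVar > 1L))
    stop("inconsistent classification across instances for variant(s): ",
         paste(names(byVar)[byVar > 1L], collapse = ", "))
  invisible(controls)
}

#' Summarize a variant's readouts across assay instances
#'
#' A variant tested in several specific instances of the same general class
#' of assay contributes one summarized readout: the median of the
#' per-instance values (with an even count, the midpoint of the two central
#' values). The median keeps a control concordant when a single instance out
#' of three or more is discordant; with exactly two conflicting instances the
#' midpoint may land in the indeterminate zone, the conservative outcome.
#'
#' @param readouts numeric vector of per-instance readout values (>= 1).
#' @return The summarized readout (a single number).
#' @examples
#' summarizeVariantReadout(c(12, 15, 70)) # 15
#' summarizeVariantReadout(c(40, 60))     # 50
#' @export
summarizeVariantReadout <- function(readouts) {
  if (!is.numeric(readouts) || length(readouts) == 0L || anyNA(readouts))
    stop("readouts must be a non-empty numeric vector")
  stats::median(readouts)
}

# One row per control variant: classification side and summarized readout.
.perVariantReadouts <- function(controls) {
  ids <- unique(controls$variant_id)
  rows <- lapply(ids, function(id) {
    sub <- controls[controls$variant_id == id, , drop = FALSE]
    data.frame(variant_id = id,
               gene = sub$gene[1L],
               classification = sub$classification[1L],
               class_side = .classSide(sub$classification[1L]),
               n_instances = nrow(sub),
               summarized_readout = summarizeVariantReadout(sub$readout_value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select normal/abnormal readout thresholds from classified controls
#'
#' Places the two readout cutoffs that partition the assay scale into
#' functionally normal, indeterminate and functionally abnormal zones, the
#' way a curator would draw them from a pooled control plot:
#' \enumerate{
#'   \item Per-variant readouts are summarized (median across instances) and
#'     oriented so that higher means more function (readouts are negated
#'     under \code{lower_is_normal} polarity).
#'   \item Outlier screen: a control lying on the wrong side of the midpoint
#'     between the benign-class and pathogenic-class medians is demoted to
#'     indeterminate (it is never reassigned to the other class).
#'   \item The normal cutoff is the largest multiple of \code{gridStep} at or
#'     below every remaining benign readout; the abnormal cutoff is the
#'     smallest multiple at or above every remaining pathogenic readout.
#'   \item If the cutoffs fail to separate, or any kept control falls in the
#'     opposite zone, controls are demoted greedily -- fewest first, deepest
#'     offender first, ties demoting benign-class controls first (the
#'     conservative choice for PS3) -- and the cutoffs recomputed.
#' }
#'
#' @param controls controls table (one row per variant x instance; see
#'   \code{\link{readControls}} for the column dialect).
#' @param gridStep grid the cutoffs snap to, in assay readout units
#'   (default 5, reproducing round percent cutoffs such as 60/30).
#' @param polarity \code{"higher_is_normal"}, \code{"lower_is_normal"}, or
#'   NULL to infer from the class means (benign mean above pathogenic mean
#'   implies \code{higher_is_normal}).
#' @return A \code{ReadoutThresholds} object; the variant ids demoted to
#'   indeterminate during selection are attached as \code{attr(x, "demoted")}.
#' @examples
#' fx <- exampleFixture()
#' th <- selectThresholds(fx$controls)
#' normalCutoff(th)   # 60
#' abnormalCutoff(th) # 30
#' @aliases ReadoutThresholds-class
#' @export
selectThresholds <- function(controls, gridStep = 5, polarity = NULL) {
  .validateControls(controls)
  if (!is.numeric(gridStep) || length(gridStep) != 1L || gridStep <= 0)
    stop("gridStep must be a single positive number")
  pv <- .perVariantReadouts(controls)
  ben <- pv$class_side == "benign"
  pat <- pv$class_side == "pathogenic"
  if (!any(ben) || !any(pat))
    stop("threshold selection needs at least one benign-class and one ",
         "pathogenic-class control")
  if (is.null(polarity)) {
    polarity <- if (mean(pv$summarized_readout[ben]) >
                    mean(pv$summarized_readout[pat]))
      "higher_is_normal" else "lower_is_normal"
  }
  polarity <- match.arg(polarity, .POLARITIES)
  s <- if (polarity == "higher_is_normal") 1 else -1
  o <- s * pv$summarized_readout

  mid <- (stats::median(o[ben]) + stats::median(o[pat])) / 2
  keep <- logical(nrow(pv))
  keep[ben] <- o[ben] > mid
  keep[pat] <- o[pat] < mid

  inseparable <- function()
    stop("controls are inseparable: every candidate cutoff pair forces a ",
         "discordant control. Supply thresholds manually (calibrate(..., ",
         "thresholds = )) after reviewing the control readouts.")

  repeat {
    if (!any(keep & ben) || !any(keep & pat)) inseparable()
    normalO   <- gridStep * floor(min(o[keep & ben]) / gridStep)
    abnormalO <- gridStep * ceiling(max(o[keep & pat]) / gridStep)
    depth <- rep(-Inf, nrow(pv))
    depth[keep & ben] <- abnormalO - o[keep & ben]  # >= 0: benign at/below abnormal cutoff
    depth[keep & pat] <- o[keep & pat] - normalO    # >= 0: pathogenic at/above normal cutoff
    offenders <- which(depth >= 0)
    if (abnormalO < normalO && !length(offenders)) break
    if (length(offenders)) {
      worst <- offenders[order(-depth[offenders], !ben[offenders])][1L]
    } else {
      # separated by discordance but cutoffs collide: demote the control
      # nearest the class midpoint, benign first on ties
      cand <- c(which(keep & ben)[which.min(o[keep & ben])],
                which(keep & pat)[which.max(o[keep & pat])])
      dist <- abs(o[cand] - mid)
      worst <- cand[order(dist, !ben[cand])][1L]
    }
    keep[worst] <- FALSE
  }

  thr <- new("ReadoutThresholds",
             normalCutoff = s * normalO, abnormalCutoff = s * abnormalO,
             polarity = polarity)
  attr(thr, "demoted") <- pv$variant_id[!keep]
  thr
}

#' Classify a readout value against calibrated thresholds
#'
#' A readout at or beyond the normal cutoff is functionally normal; at or
#' beyond the abnormal cutoff, functionally abnormal; strictly between the
#' cutoffs, indeterminate. Cutoff values are inclusive toward their own zone.
#'
#' @param value numeric readout value(s), in assay units.
#' @param thresholds a \code{ReadoutThresholds} object.
#' @return Character vector over \code{functionally_normal},
#'   \code{functionally_abnormal}, \code{indeterminate}.
#' @examples
#' thr <- new("ReadoutThresholds", normalCutoff = 60, abnormalCutoff = 30,
#'            polarity = "higher_is_normal")
#' classifyReadout(c(75, 45, 12), thr)
#' @export
classifyReadout <- function(value, thresholds) {
  stopifnot(is(thresholds, "ReadoutThresholds"), is.numeric(value))
  s <- if (polarity(thresholds) == "higher_is_normal") 1 else -1
  o <- s * value
  ifelse(o >= s * normalCutoff(thresholds), "functionally_normal",
         ifelse(o <= s * abnormalCutoff(thresholds), "functionally_abnormal",
                "indeterminate"))
}

#' Calibrate an assay's clinical validation from classified controls
#'
#' Summarizes each control variant's readouts, selects readout thresholds
#' when none are supplied (\code{\link{selectThresholds}}), counts
#' concordant, indeterminate and discordant controls per class, and -- when
#' both classes retain at least one concordant control -- estimates the
#' directional OddsPath via the adjusted contingency
#' (\code{\link{oddsPathFromControls}}).
#'
#' Controls demoted to indeterminate during default threshold selection stay
#' indeterminate (never discordant), so \code{n_discordant} is 0 under
#' default selection; discordant counts can arise only with user-supplied
#' thresholds. Discordant controls are excluded from the contingency.
#'
#' @param controls controls table (see \code{\link{readControls}}).
#' @param thresholds optional \code{ReadoutThresholds}; selected from the
#'   controls when NULL.
#' @param gridStep,polarity passed to \code{\link{selectThresholds}}.
#' @return A \code{CalibrationSummary}; access pieces with
#'   \code{controlCounts()}, \code{thresholds()}, \code{oddsPath()}.
#' @examples
#' cal <- calibrate(exampleFixture()$controls)
#' controlCounts(cal)
#' oddsPathPathogenic(oddsPath(cal)) # 5
#' @aliases CalibrationSummary-class
#' @export
calibrate <- function(controls, thresholds = NULL, gridStep = 5,
                      polarity = NULL) {
  .validateControls(controls)
  demoted <- character()
  if (is.null(thresholds)) {
    thresholds <- selectThresholds(controls, gridStep = gridStep,
                                   polarity = polarity)
    demoted <- attr(thresholds, "demoted")
    attr(thresholds, "demoted") <- NULL
  } else if (!is(thresholds, "ReadoutThresholds")) {
    stop("thresholds must be a ReadoutThresholds object (or NULL)")
  }

  pv <- .perVariantReadouts(controls)
  pv$zone <- classifyReadout(pv$summarized_readout, thresholds)
  concordantZone <- ifelse(pv$class_side == "benign",
                           "functionally_normal", "functionally_abnormal")
  pv$status <- ifelse(pv$variant_id %in% demoted, "indeterminate",
                      ifelse(pv$zone == "indeterminate", "indeterminate",
                             ifelse(pv$zone == concordantZone,
                                    "concordant", "discordant")))

  notes <- character()
  offZone <- pv$variant_id %in% demoted & pv$zone ==
    ifelse(pv$class_side == "benign", "functionally_abnormal", "functionally_normal")
  if (any(offZone))
    notes <- c(notes, paste0("demoted control(s) with readout in the opposite ",
                             "class's zone, review their classification: ",
                             paste(pv$variant_id[offZone], collapse = ", ")))

  nB <- sum(pv$status == "concordant" & pv$class_side == "benign")
  nP <- sum(pv$status == "concordant" & pv$class_side == "pathogenic")
  nI <- sum(pv$status == "indeterminate")
  nD <- sum(pv$status == "discordant")

  odds <- NULL
  if (nB >= 1L && nP >= 1L) {
    odds <- oddsPathFromControls(adjustedContingency(nB, nP, nI))
  } else {
    missingSide <- if (nB < 1L) "benign" else "pathogenic"
    notes <- c(notes, paste0("no concordant ", missingSide,
                             "-class control: OddsPath not estimable"))
    warning("calibration has zero concordant ", missingSide,
            "-class controls; summary returned without an OddsPath")
  }
  if (nD > 0L)
    notes <- c(notes, paste0(nD, " discordant control(s) excluded from the ",
                             "adjusted contingency"))

  new("CalibrationSummary",
      perVariant = pv,
      nBenignConcordant = as.integer(nB),
      nPathogenicConcordant = as.integer(nP),
      nIndeterminate = as.integer(nI),
      nDiscordant = as.integer(nD),
      thresholds = thresholds,
      oddsPath = odds,
      notes = notes)
}
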