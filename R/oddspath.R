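## OddsPath arithmetic and evidence-strength mapping.
##
## The odds of pathogenicity contributed by a functional assay is the Bayesian
## likelihood ratio OddsPath = [P2 * (1 - P1)] / [(1 - P2) * P1], where P1 is
## the proportion of pathogenic variants among the validation controls (prior)
## and P2 the proportion of pathogenic variants among controls sharing the
## readout group of interest (posterior).

#' Odds of pathogenicity from prior and posterior probabilities
#'
#' Computes \code{OddsPath = [p2 * (1 - p1)] / [(1 - p2) * p1]}, the
#' likelihood ratio a functional readout contributes toward a pathogenic
#' (OddsPath > 1) or benign (OddsPath < 1) interpretation.
#'
#' Boundary probabilities (0 or 1) are rejected: posterior probabilities of
#' zero or one arise from perfectly classified control sets and must first be
#' regularized with the one-added-misclassified-variant adjustment; see
#' \code{\link{adjustedContingency}}.
#'
#' @param p1 prior probability of pathogenicity, strictly inside (0, 1).
#' @param p2 posterior probability of pathogenicity, strictly inside (0, 1).
#' @return A positive number; \code{computeOddsPath(p, p)} is exactly 1.
#' @examples
#' computeOddsPath(0.5, 5 / 6) # 5
#' computeOddsPath(0.5, 1 / 6) # 0.2
#' @export
computeOddsPath <- function(p1, p2) {
  if (!is.numeric(p1) || !is.numeric(p2) || length(p1) != 1L || length(p2) != 1L)
    stop("p1 and p2 must be single numeric probabilities")
  if (is.na(p1) || is.na(p2) || p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1)
    stop("p1 and p2 must lie strictly inside (0, 1); boundary posteriors from ",
         "perfectly classified controls require the one-added-misclassified-",
         "variant adjustment (see adjustedContingency())")
  (p2 * (1 - p1)) / ((1 - p2) * p1)
}

#' Adjusted contingency of classified controls
#'
#' Builds the regularized two-set contingency used to estimate an assay's
#' OddsPath from classified variant controls. To avoid posterior probabilities
#' of exactly zero or one -- and to account for the possibility that the next
#' variant tested would be discordant -- exactly one misclassified variant is
#' added to each readout set: the abnormal-readout set holds the
#' pathogenic-concordant controls plus one added benign variant, and the
#' normal-readout set holds the benign-concordant controls plus one added
#' pathogenic variant. Indeterminate controls appear in neither set.
#'
#' @param nBenignConcordant number of benign-class controls with a
#'   functionally normal readout (>= 1).
#' @param nPathogenicConcordant number of pathogenic-class controls with a
#'   functionally abnormal readout (>= 1).
#' @param nIndeterminate number of controls with indeterminate readouts
#'   (excluded from both sets).
#' @return An \code{AdjustedContingency} object.
#' @examples
#' adjustedContingency(5, 5, 1)
#' @aliases AdjustedContingency-class
#' @seealso \code{\link{oddsPathFromControls}}
#' @export
adjustedContingency <- function(nBenignConcordant, nPathogenicConcordant,
                                nIndeterminate = 0L) {
  if (!.isCount(nBenignConcordant) || nBenignConcordant < 1)
    stop("no benign-class concordant controls: at least one benign/likely-benign ",
         "control with a normal readout is required")
  if (!.isCount(nPathogenicConcordant) || nPathogenicConcordant < 1)
    stop("no pathogenic-class concordant controls: at least one pathogenic/",
         "likely-pathogenic control with an abnormal readout is required")
  if (!.isCount(nIndeterminate))
    stop("nIndeterminate must be a non-negative integer")
  new("AdjustedContingency",
      nBenignConcordant     = as.integer(nBenignConcordant),
      nPathogenicConcordant = as.integer(nPathogenicConcordant),
      nIndeterminate        = as.integer(nIndeterminate))
}

#' Estimate OddsPath from an adjusted contingency of controls
#'
#' The prior \code{P1} is the proportion of pathogenic variants among the
#' determinate (concordant) controls only -- the two added misclassified
#' members and any indeterminate controls are excluded. The posteriors are the
#' pathogenic proportions within the adjusted abnormal- and normal-readout
#' sets. Both directional OddsPath values are reported: with B benign and P
#' pathogenic concordant controls the closed forms are
#' \code{oddsPathPathogenic = B} and \code{oddsPathBenign = 1/P}.
#'
#' @param contingency an \code{\link{adjustedContingency}} object.
#' @return An \code{OddsPathResult} with slots \code{p1}, \code{p2Abnormal},
#'   \code{p2Normal}, \code{oddsPathPathogenic}, \code{oddsPathBenign}.
#' @examples
#' res <- oddsPathFromControls(adjustedContingency(5, 5, 1))
#' oddsPathPathogenic(res) # 5
#' oddsPathBenign(res)     # 0.2
#' @aliases OddsPathResult-class
#' @export
oddsPathFromControls <- function(contingency) {
  stopifnot(is(contingency, "AdjustedContingency"))
  B <- contingency@nBenignConcordant
  P <- contingency@nPathogenicConcordant
  p1 <- P / (P + B)
  p2Abnormal <- P / (P + 1)        # abnormal set: P pathogenic + 1 added benign
  p2Normal   <- 1 / (B + 1)        # normal set:   B benign + 1 added pathogenic
  new("OddsPathResult",
      p1 = p1, p2Abnormal = p2Abnormal, p2Normal = p2Normal,
      oddsPathPathogenic = computeOddsPath(p1, p2Abnormal),
      oddsPathBenign     = computeOddsPath(p1, p2Normal),
      contingency = contingency)
}

## Evidence-strength boundaries on the OddsPath scale. Strict inequalities:
## a value exactly on a boundary falls in the weaker tier (equality tested
## with absolute tolerance .BOUNDARY_TOL). Carried as named constants; not
## re-derived from the Bayesian adaptation they originate in.
.PS3_BOUNDS <- c(supporting = 2.1, moderate = 4.3, strong = 18.7, very_strong = 350)
.BS3_BOUNDS <- c(supporting = 0.48, moderate = 0.23, strong = 0.053)
.BOUNDARY_TOL <- 1e-9

#' Map an OddsPath value to an evidence-strength tier
#'
#' Applies the strength-equivalence table: OddsPath > 2.1 supports PS3 at
#' supporting strength, > 4.3 moderate, > 18.7 strong, > 350 very strong;
#' OddsPath < 0.48 supports BS3 at supporting strength, < 0.23 moderate,
#' < 0.053 strong. Values in [0.48, 2.1] are indeterminate (no code). All
#' inequalities are strict; a value within \code{1e-9} of a boundary is
#' treated as equal to it and falls in the weaker tier. There is no
#' very-strong benign tier: BS3 is capped at strong by construction.
#'
#' The reported code follows the value, not the query direction: an OddsPath
#' below 0.48 yields a BS3 tier even if the caller was asking about the
#' pathogenic direction, and vice versa. PS3 is never emitted for OddsPath
#' < 1 nor BS3 for OddsPath > 1.
#'
#' @param oddsPath positive OddsPath value.
#' @param direction the direction being queried (\code{"pathogenic"} or
#'   \code{"benign"}); informational, recorded for provenance only.
#' @return A \code{StrengthTier} object with slots \code{code} and \code{tier}.
#' @examples
#' tierLabel(mapStrength(5.0, "pathogenic"))  # PS3_moderate
#' tierLabel(mapStrength(0.2, "benign"))      # BS3_moderate
#' tierLabel(mapStrength(1.0, "pathogenic"))  # none
#' @aliases StrengthTier-class
#' @export
mapStrength <- function(oddsPath, direction = c("pathogenic", "benign")) {
  direction <- match.arg(direction)
  if (!is.numeric(oddsPath) || length(oddsPath) != 1L || is.na(oddsPath) ||
      oddsPath <= 0)
    stop("oddsPath must be a single positive number")
  above <- function(b) oddsPath > b + .BOUNDARY_TOL
  below <- function(b) oddsPath < b - .BOUNDARY_TOL
  if (above(.PS3_BOUNDS[["supporting"]])) {
    tier <- if (above(.PS3_BOUNDS[["very_strong"]])) "very_strong"
    else if (above(.PS3_BOUNDS[["strong"]])) "strong"
    else if (above(.PS3_BOUNDS[["moderate"]])) "moderate"
    else "supporting"
    return(new("StrengthTier", code = "PS3", tier = tier))
  }
  if (below(.BS3_BOUNDS[["supporting"]])) {
    tier <- if (below(.BS3_BOUNDS[["strong"]])) "strong"
    else if (below(.BS3_BOUNDS[["moderate"]])) "moderate"
    else "supporting"
    return(new("StrengthTier", code = "BS3", tier = tier))
  }
  new("StrengthTier", code = "none", tier = "indeterminate")
}

#' Theoretical OddsPath grid over control counts
#'
#' Regenerates the minimum-validation-controls grids: for every split of
#' benign and pathogenic control counts up to \code{maxTotal}, the OddsPath
#' obtainable by a theoretical assay in which all determinate controls read
#' out concordantly. Under \code{scenario = "perfect"} every control is
#' concordant; under \code{"one_indeterminate"} exactly one control has an
#' indeterminate readout, taken from the majority side (ties broken toward
#' the benign side). Because the convention for which side loses a control is
#' a modeling choice, the worst-case placement per direction is also reported
#' (\code{oddsPathPathogenicWorst}/\code{tierPathogenicWorst} remove a benign
#' control; the benign-direction worst case removes a pathogenic control).
#'
#' @param maxTotal largest total control count to enumerate (>= 2).
#' @param scenario \code{"perfect"} or \code{"one_indeterminate"}.
#' @return A data.frame with one row per (nBenign, nPathogenic) split and
#'   columns for the concordant counts, prior, posteriors, both OddsPath
#'   values and their mapped tier labels (plus worst-case columns under
#'   \code{one_indeterminate}).
#' @seealso \code{\link{minimumControlsForModerate}}
#' @export
minimumControlsGrid <- function(maxTotal,
                                scenario = c("perfect", "one_indeterminate")) {
  scenario <- match.arg(scenario)
  if (!.isCount(maxTotal) || maxTotal < 2)
    stop("maxTotal must be an integer >= 2")
  rows <- list()
  for (nB in seq_len(maxTotal - 1L)) {
    for (nP in seq_len(maxTotal - nB)) {
      if (scenario == "perfect") {
        bConc <- nB; pConc <- nP; nInd <- 0L; side <- NA_character_
      } else {
        side <- if (nB >= nP) "benign" else "pathogenic"
        bConc <- nB - (side == "benign")
        pConc <- nP - (side == "pathogenic")
        nInd <- 1L
        if (bConc < 1L || pConc < 1L) next
      }
      res <- oddsPathFromControls(adjustedContingency(bConc, pConc, nInd))
      row <- data.frame(
        n_benign = nB, n_pathogenic = nP, n_total = nB + nP,
        n_indeterminate = nInd, indeterminate_side = side,
        p1 = res@p1, p2_abnormal = res@p2Abnormal, p2_normal = res@p2Normal,
        oddspath_pathogenic = oddsPathPathogenic(res),
        oddspath_benign = oddsPathBenign(res),
        tier_pathogenic = tierLabel(mapStrength(oddsPathPathogenic(res), "pathogenic")),
        tier_benign = tierLabel(mapStrength(oddsPathBenign(res), "benign")),
        stringsAsFactors = FALSE)
      if (scenario == "one_indeterminate") {
        # worst case per direction: the indeterminate control is taken from
        # the side that weakens that direction most
        if (nB >= 2L) {
          wp <- oddsPathFromControls(adjustedContingency(nB - 1L, nP, 1L))
          row$oddspath_pathogenic_worst <- oddsPathPathogenic(wp)
          row$tier_pathogenic_worst <-
            tierLabel(mapStrength(oddsPathPathogenic(wp), "pathogenic"))
        } else {
          row$oddspath_pathogenic_worst <- NA_real_
          row$tier_pathogenic_worst <- NA_character_
        }
        if (nP >= 2L) {
          wb <- oddsPathFromControls(adjustedContingency(nB, nP - 1L, 1L))
          row$oddspath_benign_worst <- oddsPathBenign(wb)
          row$tier_benign_worst <-
            tierLabel(mapStrength(oddsPathBenign(wb), "benign"))
        } else {
          row$oddspath_benign_worst <- NA_real_
          row$tier_benign_worst <- NA_character_
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Smallest control count reaching moderate evidence in both directions
#'
#' Enumerates total control counts N (splitting with a benign majority for odd
#' N, as in the pooled worked example) and reports the smallest N at which
#' both the pathogenic and benign directions reach at least moderate-level
#' evidence. Under the conservative \code{one_indeterminate} scenario this
#' minimum is 11 (6 benign of which one indeterminate, plus 5 pathogenic).
#'
#' @param maxTotal largest total to consider.
#' @param scenario as in \code{\link{minimumControlsGrid}}.
#' @return A list with \code{minimumTotal} (integer, NA if not reached) and
#'   \code{table}, the per-total enumeration with OddsPath values and tiers.
#' @export
minimumControlsForModerate <- function(maxTotal = 20L,
                                       scenario = c("one_indeterminate", "perfect")) {
  scenario <- match.arg(scenario)
  rows <- list()
  minTotal <- NA_integer_
  lo <- if (scenario == "one_indeterminate") 3L else 2L
  for (N in lo:maxTotal) {
    nB <- as.integer(ceiling(N / 2)); nP <- N - nB
    if (scenario == "one_indeterminate") {
      bConc <- nB - 1L; pConc <- nP; nInd <- 1L   # benign majority loses one
    } else {
      bConc <- nB; pConc <- nP; nInd <- 0L
    }
    if (bConc < 1L || pConc < 1L) next
    res <- oddsPathFromControls(adjustedContingency(bConc, pConc, nInd))
    tp <- mapStrength(oddsPathPathogenic(res), "pathogenic")
    tb <- mapStrength(oddsPathBenign(res), "benign")
    both <- tierRank(tp@tier) >= tierRank("moderate") &&
      tierRank(tb@tier) >= tierRank("moderate")
    rows[[length(rows) + 1L]] <- data.frame(
      n_total = N, n_benign = nB, n_pathogenic = nP, n_indeterminate = nInd,
      oddspath_pathogenic = oddsPathPathogenic(res),
      oddspath_benign = oddsPathBenign(res),
      tier_pathogenic = tierLabel(tp), tier_benign = tierLabel(tb),
      both_at_least_moderate = both, stringsAsFactors = FALSE)
    if (both && is.na(minTotal)) minTotal <- N
  }
  list(minimumTotal = minTotal, table = do.call(rbind, rows))
}
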