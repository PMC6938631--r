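#' Run policy for evidence application
#'
#' Collects the configurable policy switches that govern evidence
#' application and stacking. Defaults are deliberately conservative.
#'
#' @param allowCrossClassStacking combine same-direction results from
#'   different assay classes into a higher tier (default FALSE: expert groups
#'   have not reached consensus that two assays measure independent
#'   functions, so stacking risks double-counting).
#' @param hypomorphDowngrade reduce the applied PS3 strength by one tier for
#'   partial loss-of-function (hypomorphic) results (default TRUE; may be
#'   disabled per gene where intermediate function is the disease mechanism).
#' @param acknowledgePatientDerived explicit acknowledgment that evidence
#'   from patient-derived material is being used for PS3/BS3 rather than
#'   routed to PP4 (default FALSE: applying such evidence without the flag is
#'   an error).
#' @param gridStep,polarity calibration defaults, passed through to
#'   \code{\link{selectThresholds}}.
#' @return A list with class \code{"evidencePolicy"}.
#' @export
evidencePolicy <- function(allowCrossClassStacking = FALSE,
                           hypomorphDowngrade = TRUE,
                           acknowledgePatientDerived = FALSE,
                           gridStep = 5,
                           polarity = NULL) {
  stopifnot(.isFlag(allowCrossClassStacking), .isFlag(hypomorphDowngrade),
            .isFlag(acknowledgePatientDerived))
  structure(list(allowCrossClassStacking = allowCrossClassStacking,
                 hypomorphDowngrade = hypomorphDowngrade,
                 acknowledgePatientDerived = acknowledgePatientDerived,
                 gridStep = gridStep,
                 polarity = polarity),
            class = "evidencePolicy")
}
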