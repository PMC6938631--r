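## Structured evidence reports: assembly, schema validation, JSON round trip.
## Every applied code names its tier-setting rule and instance provenance.

# stable small digest of the run configuration (polynomial rolling hash over
# the serialized policy); detects config drift between runs, not cryptographic
.configDigest <- function(policy) {
  bytes <- utf8ToInt(paste(deparse(unclass(policy)), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.oddsPathToList <- function(op) {
  if (is.null(op)) return(NULL)
  list(p1 = op@p1, p2_abnormal = op@p2Abnormal, p2_normal = op@p2Normal,
       oddspath_pathogenic = oddsPathPathogenic(op),
       oddspath_benign = oddsPathBenign(op))
}

.calibrationToList <- function(cal) {
  cts <- controlCounts(cal)
  list(n_benign_concordant = unname(cts[["benign_concordant"]]),
       n_pathogenic_concordant = unname(cts[["pathogenic_concordant"]]),
       n_indeterminate = unname(cts[["indeterminate"]]),
       n_discordant = unname(cts[["discordant"]]),
       thresholds = list(normal_cutoff = normalCutoff(thresholds(cal)),
                         abnormal_cutoff = abnormalCutoff(thresholds(cal)),
                         polarity = polarity(thresholds(cal))),
       oddspath = .oddsPathToList(oddsPath(cal)),
       notes = as.list(cal@notes))
}

.applicationToList <- function(app, rule = NULL) {
  list(variant_id = app@variantId, code = app@code, tier = app@tier,
       label = tierLabel(app), instance_id = app@instanceId,
       justification = app@justification,
       warnings = as.list(app@warnings))
}

#' Assemble a structured evidence report
#'
#' Bundles per-variant evidence applications with run metadata (tool
#' version, seed, configuration digest) and the calibration summaries they
#' rest on, so that every applied code references the strength of the
#' clinical validation behind it.
#'
#' @param applications list of \code{EvidenceApplication}s.
#' @param calibrations named list of \code{CalibrationSummary}s keyed by
#'   instance id (may be empty).
#' @param policy the \code{\link{evidencePolicy}} used for the run.
#' @param seed integer seed recorded for reproducibility.
#' @param warnings run-level warnings.
#' @return A list with class \code{"evidenceReport"}, schema-validated.
#' @export
evidenceReport <- function(applications, calibrations = list(),
                           policy = evidencePolicy(), seed = NA_integer_,
                           warnings = character()) {
  stopifnot(is.list(applications),
            all(vapply(applications, is, logical(1), "EvidenceApplication")))
  report <- structure(list(
    tool = "funcevkit",
    version = as.character(utils::packageVersion("funcevkit")),
    seed = seed,
    config_digest = .configDigest(policy),
    applications = lapply(applications, .applicationToList),
    calibrations = lapply(calibrations, .calibrationToList),
    warnings = as.list(warnings)), class = "evidenceReport")
  validateEvidenceReport(report)
  report
}

.REPORT_REQUIRED <- c("tool", "version", "seed", "config_digest",
                      "applications", "calibrations", "warnings")
.APPLICATION_REQUIRED <- c("variant_id", "code", "tier", "label",
                           "instance_id", "justification", "warnings")

#' Validate an evidence report against the published schema
#'
#' Checks the required top-level keys and, for every application record, the
#' required provenance fields (variant, code, tier, instance id,
#' justification). Fails with a message naming every violation.
#'
#' @param report a report list (from \code{\link{evidenceReport}} or
#'   \code{\link{readReport}}).
#' @return Invisibly TRUE; errors on violation.
#' @export
validateEvidenceReport <- function(report) {
  msg <- character()
  missing <- setdiff(.REPORT_REQUIRED, names(report))
  if (length(missing))
    msg <- c(msg, paste("missing top-level key(s):",
                        paste(missing, collapse = ", ")))
  if (is.null(missing) || !"applications" %in% missing) {
    for (i in seq_along(report$applications)) {
      rec <- report$applications[[i]]
      m <- setdiff(.APPLICATION_REQUIRED, names(rec))
      if (length(m))
        msg <- c(msg, sprintf("application %d missing field(s): %s", i,
                              paste(m, collapse = ", ")))
      else {
        if (!rec$code %in% .CODES)
          msg <- c(msg, sprintf("application %d has unknown code '%s'", i, rec$code))
        if (!rec$tier %in% names(.TIER_RANK))
          msg <- c(msg, sprintf("application %d has unknown tier '%s'", i, rec$tier))
      }
    }
  }
  if (length(msg))
    stop("evidence report fails schema validation:\n  ",
         paste(msg, collapse = "\n  "))
  invisible(TRUE)
}

#' Write / read an evidence report as JSON
#'
#' The writer is deterministic given identical inputs and configuration (no
#' timestamps); the reader validates the schema and returns the same
#' structure, so write-read round trips are lossless.
#'
#' @param report an evidence report list.
#' @param path output (or input) path.
#' @return \code{writeReport}: invisibly the path; \code{readReport}: the
#'   validated report list.
#' @export
writeReport <- function(report, path) {
  validateEvidenceReport(report)
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  report <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  validateEvidenceReport(report)
  structure(report, class = "evidenceReport")
}
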