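## Readers and writers for the tabular dialects: controls, assay instances,
## variant calls, and the mechanism/policy configuration. Delimiter sniffing
## is limited to tab and comma; decimal points only.

.sniffDelim <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header) || !nzchar(header))
    stop("empty file: ", path)
  if (grepl("\t", header)) "\t" else ","
}

.readTable <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- .sniffDelim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          blank.lines.skip = FALSE)
  nLines <- length(readLines(path))
  if (nrow(df) != nLines - 1L)
    stop("row-count mismatch in ", path, " (", nLines - 1L,
         " data line(s) but ", nrow(df), " parsed row(s)); the file may be ",
         "truncated or malformed")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L) stop("no data rows in ", path)
  df
}

#' Read a controls file
#'
#' Reads the controls dialect: tab- or comma-separated with header columns
#' \code{variant_id}, \code{gene}, \code{classification} (B/LB/P/LP),
#' \code{classification_basis} (semicolon-joined ACMG evidence codes),
#' \code{assay_instance_id}, \code{readout_value}, and optionally
#' \code{readout_units}; one row per (variant, assay instance). The
#' circularity guard is enforced at read time: any control whose
#' classification basis cites PS3 or BS3 is a hard error naming the
#' offending variants.
#'
#' @param path file path.
#' @return A validated controls data.frame.
#' @export
readControls <- function(path) {
  df <- .readTable(path, setdiff(.CONTROL_COLUMNS, "readout_units"))
  if (!is.numeric(df$readout_value)) {
    suppressWarnings(vals <- as.numeric(df$readout_value))
    if (anyNA(vals))
      stop("non-numeric readout_value in ", path, " at data row(s): ",
           paste(which(is.na(vals)), collapse = ", "))
    df$readout_value <- vals
  }
  .validateControls(df)
  df
}

#' Read an assay-instances file
#'
#' Columns: \code{instance_id}, \code{class_id}, \code{source_ref},
#' \code{readout_type}, \code{has_wildtype_control}, \code{has_null_control},
#' \code{has_technical_replicates}, \code{has_biological_replicates},
#' \code{basis}.
#'
#' @param path file path.
#' @return A list of \code{\link{AssayInstance}} objects keyed by instance id.
#' @export
readInstances <- function(path) {
  req <- c("instance_id", "class_id", "source_ref", "readout_type",
           "has_wildtype_control", "has_null_control",
           "has_technical_replicates", "has_biological_replicates", "basis")
  df <- .readTable(path, req)
  toFlag <- function(x) {
    out <- as.logical(x)
    if (anyNA(out)) out <- as.logical(as.integer(x))
    if (anyNA(out)) stop("unparseable boolean column in ", path)
    out
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    AssayInstance(instanceId = df$instance_id[i], classId = df$class_id[i],
                  sourceRef = df$source_ref[i],
                  readoutType = df$readout_type[i],
                  hasWildtypeControl = toFlag(df$has_wildtype_control)[i],
                  hasNullControl = toFlag(df$has_null_control)[i],
                  hasTechnicalReplicates = toFlag(df$has_technical_replicates)[i],
                  hasBiologicalReplicates = toFlag(df$has_biological_replicates)[i],
                  basis = df$basis[i])
  })
  names(out) <- df$instance_id
  out
}

#' Read a variant-calls file
#'
#' Columns: \code{variant_id}, \code{readout_value}; optional
#' \code{abnormal_subtype} and \code{context_flags} (semicolon-joined).
#'
#' @param path file path.
#' @return A data.frame of query variants.
#' @export
readCalls <- function(path) {
  df <- .readTable(path, c("variant_id", "readout_value"))
  if (!is.numeric(df$readout_value))
    stop("non-numeric readout_value in ", path)
  df
}

#' Read a mechanism/policy configuration file
#'
#' YAML (or JSON) with keys mirroring the structured disease-mechanism
#' narrative -- \code{gene_symbol}, \code{disease},
#' \code{mode_of_inheritance}, \code{molecular_mechanism}, \code{pathways} --
#' plus an optional \code{policy} block
#' (\code{allow_cross_class_stacking}, \code{hypomorph_downgrade},
#' \code{acknowledge_patient_derived}, \code{grid_step}, \code{polarity}).
#'
#' @param path file path.
#' @return A list with \code{mechanism}
#'   (\code{\link{DiseaseMechanismStatement}}) and \code{policy}
#'   (\code{\link{evidencePolicy}}).
#' @export
readMechanism <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  req <- c("gene_symbol", "disease", "mode_of_inheritance",
           "molecular_mechanism")
  missing <- setdiff(req, names(cfg))
  if (length(missing))
    stop(path, " is missing required key(s): ", paste(missing, collapse = ", "))
  mech <- DiseaseMechanismStatement(
    geneSymbol = cfg$gene_symbol, disease = cfg$disease,
    modeOfInheritance = cfg$mode_of_inheritance,
    molecularMechanism = cfg$molecular_mechanism,
    pathways = unlist(cfg$pathways))
  pol <- cfg$policy
  policy <- evidencePolicy(
    allowCrossClassStacking = isTRUE(pol$allow_cross_class_stacking),
    hypomorphDowngrade = !isFALSE(pol$hypomorph_downgrade),
    acknowledgePatientDerived = isTRUE(pol$acknowledge_patient_derived),
    gridStep = if (!is.null(pol$grid_step)) pol$grid_step else 5,
    polarity = pol$polarity)
  list(mechanism = mech, policy = policy)
}
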