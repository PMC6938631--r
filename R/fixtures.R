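## Deterministic, seeded generators for control/VUS datasets, including the
## pooled worked example (6 benign-class and 5 pathogenic-class controls, one
## benign control with an indeterminate readout, three VUS).

.BENIGN_BASIS     <- c("BA1", "BS1;BP4", "BS1", "BA1;BP7", "BS1;BP4", "BA1")
.PATHOGENIC_BASIS <- c("PVS1;PM2", "PS4;PM2;PP3", "PVS1;PM2;PP3", "PS4;PM1;PM2",
                       "PVS1;PS4")

.controlRow <- function(variant_id, gene, classification, basis,
                        instance_ids, values, units = "percent_wildtype") {
  data.frame(variant_id = variant_id, gene = gene,
             classification = classification, classification_basis = basis,
             assay_instance_id = instance_ids, readout_value = values,
             readout_units = units, stringsAsFactors = FALSE)
}

#' Seeded worked-example fixture: pooled controls and three VUS
#'
#' Generates the canonical pooled-control dataset used throughout the
#' package: six benign-class controls B1-B6 (B1-B5 with summarized readouts
#' in 62-90% of wild-type activity, B6 at 45%), five pathogenic-class
#' controls P1-P5 (summarized readouts in 5-28%; P1 is tested in three
#' instances, one of which reads 70% so that exactly one instance is
#' discordant while the median stays concordant), and three variants of
#' uncertain significance with readouts 75 / 45 / 12. Default threshold
#' calibration on this fixture selects cutoffs (60, 30), leaving B6
#' indeterminate, and yields OddsPath (5, 0.2) -- moderate evidence in both
#' directions.
#'
#' All readout jitter is drawn under the seed; the same seed always produces
#' identical tables. Control classifications carry only non-functional
#' evidence codes (circularity guard).
#'
#' @param seed integer seed (default 17).
#' @return A list with \code{controls} (one row per variant x instance) and
#'   \code{calls} (the VUS query table with columns \code{variant_id},
#'   \code{readout_value}).
#' @examples
#' fx <- exampleFixture()
#' nrow(unique(fx$controls[, c("variant_id", "classification")])) # 11 controls
#' @export
exampleFixture <- function(seed = 17L) {
  stopifnot(.isCount(seed))
  rng <- local({
    set.seed(seed)
    function(n, lo, hi) stats::runif(n, lo, hi)
  })
  gene <- "GENE1"
  benBases <- c(B1 = 63, B2 = 72, B3 = 78, B4 = 85, B5 = 89)
  patBases <- c(P2 = 8, P3 = 18, P4 = 22, P5 = 27)
  rows <- list()
  for (i in seq_along(benBases)) {
    id <- names(benBases)[i]
    vals <- benBases[[i]] + rng(2L, -1, 1)
    rows[[length(rows) + 1L]] <- .controlRow(
      id, gene, c("B", "LB", "B", "LB", "LB")[i], .BENIGN_BASIS[i],
      paste0("inst", seq_len(2L)), vals)
  }
  # B6: the benign control a curator would judge indeterminate
  rows[[length(rows) + 1L]] <- .controlRow(
    "B6", gene, "LB", .BENIGN_BASIS[6L], "inst1", 45)
  # P1: three instances, one discordant at 70; median 15 stays concordant
  rows[[length(rows) + 1L]] <- .controlRow(
    "P1", gene, "P", .PATHOGENIC_BASIS[1L],
    paste0("inst", 1:3), c(12, 15, 70))
  for (i in seq_along(patBases)) {
    id <- names(patBases)[i]
    vals <- patBases[[i]] + rng(2L, -1, 1)
    rows[[length(rows) + 1L]] <- .controlRow(
      id, gene, c("LP", "P", "P", "LP")[i], .PATHOGENIC_BASIS[i + 1L],
      paste0("inst", seq_len(2L)), vals)
  }
  controls <- do.call(rbind, rows)
  rownames(controls) <- NULL
  calls <- data.frame(variant_id = c("VUS1", "VUS2", "VUS3"),
                      readout_value = c(75, 45, 12),
                      stringsAsFactors = FALSE)
  list(controls = controls, calls = calls)
}

#' Randomized seeded control set
#'
#' Draws a controls table with configurable class separation and noise:
#' benign-class readouts uniform within \code{benignRange}, pathogenic-class
#' readouts uniform within \code{pathogenicRange} (optionally Gaussian around
#' a uniform per-variant base for stress tests), with
#' \code{nIndeterminateBenign} benign-class controls placed in the gap
#' between the class ranges so that calibration marks them indeterminate.
#' The seed fully determines the output, and generated tables are directly
#' consumable by \code{\link{calibrate}} and round-trip through
#' \code{\link{readControls}}.
#'
#' With disjoint default ranges and no planned indeterminates, calibration of
#' a generated set always reports zero discordant controls and OddsPath equal
#' to the closed forms (B, 1/P).
#'
#' @param nBenign,nPathogenic control counts per class (>= 1 each;
#'   \code{nBenign} must exceed \code{nIndeterminateBenign + 1}).
#' @param benignRange,pathogenicRange readout intervals per class; must be
#'   disjoint when no indeterminates are planned.
#' @param nIndeterminateBenign number of benign-class controls given
#'   readouts in the inter-class gap.
#' @param instancesPerVariant assay instances per control variant.
#' @param seed integer seed.
#' @param noise \code{"uniform"} (within the class range) or
#'   \code{"normal"} (Gaussian with \code{noiseSd} around a uniform base,
#'   clamped to the class range).
#' @param noiseSd standard deviation for \code{noise = "normal"}.
#' @param gene gene symbol stamped on every control.
#' @return A controls data.frame in the standard column dialect.
#' @examples
#' ctl <- randomControlSet(5, 5, seed = 1)
#' oddsPathPathogenic(oddsPath(calibrate(ctl))) # 5
#' @export
randomControlSet <- function(nBenign, nPathogenic,
                             benignRange = c(62, 90),
                             pathogenicRange = c(5, 28),
                             nIndeterminateBenign = 0L,
                             instancesPerVariant = 1L,
                             seed = 17L,
                             noise = c("uniform", "normal"),
                             noiseSd = 2,
                             gene = "GENE1") {
  noise <- match.arg(noise)
  if (!.isCount(nBenign) || nBenign < 1L)
    stop("nBenign must be >= 1")
  if (!.isCount(nPathogenic) || nPathogenic < 1L)
    stop("nPathogenic must be >= 1")
  if (!.isCount(nIndeterminateBenign) || nIndeterminateBenign > 0L &&
      nBenign < nIndeterminateBenign + 2L)
    stop("need at least two concordant benign controls alongside the planned ",
         "indeterminates (nBenign >= nIndeterminateBenign + 2)")
  overlap <- max(benignRange) >= min(pathogenicRange) &&
    max(pathogenicRange) >= min(benignRange)
  if (overlap && nIndeterminateBenign == 0L)
    stop("benignRange and pathogenicRange overlap; with no planned ",
         "indeterminate controls the classes would be inseparable")
  set.seed(seed)
  # gap placement that the calibration midpoint screen always demotes: just
  # past the snapped edge of the class range nearer the abnormal zone
  benignHigh <- mean(benignRange) >= mean(pathogenicRange)
  indetValue <- if (benignHigh) 5 * ceiling(max(pathogenicRange) / 5) + 2.5
                else 5 * floor(min(pathogenicRange) / 5) - 2.5

  draw <- function(n, range) {
    base <- stats::runif(n, range[1L], range[2L])
    if (noise == "uniform") return(base)
    pmin(pmax(stats::rnorm(n, base, noiseSd), range[1L]), range[2L])
  }
  rows <- list()
  benVals <- draw(nBenign - nIndeterminateBenign, benignRange)
  for (i in seq_len(nBenign - nIndeterminateBenign)) {
    vals <- if (instancesPerVariant == 1L) benVals[i]
            else draw(instancesPerVariant, benignRange)
    rows[[length(rows) + 1L]] <- .controlRow(
      paste0("B", i), gene, sample(c("B", "LB"), 1L),
      .BENIGN_BASIS[(i - 1L) %% length(.BENIGN_BASIS) + 1L],
      paste0("inst", seq_len(instancesPerVariant)), vals)
  }
  for (i in seq_len(nIndeterminateBenign)) {
    rows[[length(rows) + 1L]] <- .controlRow(
      paste0("B", nBenign - nIndeterminateBenign + i), gene, "LB",
      .BENIGN_BASIS[(i - 1L) %% length(.BENIGN_BASIS) + 1L],
      paste0("inst", seq_len(instancesPerVariant)),
      rep(indetValue, instancesPerVariant))
  }
  patVals <- draw(nPathogenic, pathogenicRange)
  for (i in seq_len(nPathogenic)) {
    vals <- if (instancesPerVariant == 1L) patVals[i]
            else draw(instancesPerVariant, pathogenicRange)
    rows[[length(rows) + 1L]] <- .controlRow(
      paste0("P", i), gene, sample(c("P", "LP"), 1L),
      .PATHOGENIC_BASIS[(i - 1L) %% length(.PATHOGENIC_BASIS) + 1L],
      paste0("inst", seq_len(instancesPerVariant)), vals)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a ready-to-run fixture directory
#'
#' Materializes a fixture as the four files consumed by the evidence
#' pipeline and its command-line wrapper: \code{controls.tsv},
#' \code{instances.tsv}, \code{calls.tsv} and \code{mechanism.yaml}.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed passed to \code{\link{exampleFixture}}.
#' @return Invisibly, the paths of the written files.
#' @export
writeFixture <- function(dir, seed = 17L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- exampleFixture(seed)
  paths <- c(controls = file.path(dir, "controls.tsv"),
             instances = file.path(dir, "instances.tsv"),
             calls = file.path(dir, "calls.tsv"),
             mechanism = file.path(dir, "mechanism.yaml"))
  controls <- fx$controls
  # 17 significant digits keep the readout doubles bit-identical on re-read
  controls$readout_value <- sprintf("%.17g", controls$readout_value)
  utils::write.table(controls, paths[["controls"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  instances <- data.frame(
    instance_id = "pooled", class_id = "enzymatic_activity",
    source_ref = "synthetic", readout_type = "quantitative",
    has_wildtype_control = TRUE, has_null_control = TRUE,
    has_technical_replicates = TRUE, has_biological_replicates = TRUE,
    basis = "documented", stringsAsFactors = FALSE)
  utils::write.table(instances, paths[["instances"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fx$calls, paths[["calls"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mech <- list(gene_symbol = "GENE1", disease = "MONDO:0000001",
               mode_of_inheritance = "autosomal_recessive",
               molecular_mechanism = "loss_of_function",
               pathways = list("GO:0003824"),
               policy = list(allow_cross_class_stacking = FALSE,
                             hypomorph_downgrade = TRUE,
                             grid_step = 5))
  yaml::write_yaml(mech, paths[["mechanism"]])
  invisible(paths)
}
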