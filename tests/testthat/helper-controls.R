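# Builds a minimal in-memory controls table from summarized class readouts.
# Each variant gets a single assay instance unless a value vector is supplied.
makeControls <- function(benign = numeric(), pathogenic = numeric(),
                         gene = "GENE1") {
  rows <- list()
  addRows <- function(values, prefix, cls, basis) {
    for (i in seq_along(values)) {
      vals <- values[[i]]
      rows[[length(rows) + 1L]] <<- data.frame(
        variant_id = paste0(prefix, i), gene = gene, classification = cls,
        classification_basis = basis,
        assay_instance_id = paste0("inst", seq_along(vals)),
        readout_value = vals, readout_units = "percent_wildtype",
        stringsAsFactors = FALSE)
    }
  }
  addRows(as.list(benign), "B", "LB", "BS1;BP4")
  addRows(as.list(pathogenic), "P", "LP", "PVS1;PM2")
  do.call(rbind, rows)
}

# An assay instance whose clinical validation comes from a generated control
# set; optionally with the calibration's OddsPath attached as formal.
makeInstance <- function(nBenign, nPathogenic, formal = FALSE, seed = 1L,
                         instanceId = "i1", classId = "c1", ...) {
  cal <- calibrate(randomControlSet(nBenign, nPathogenic, seed = seed))
  AssayInstance(instanceId, classId, calibration = cal,
                formalOddsPath = if (formal) oddsPath(cal) else NULL, ...)
}

lofMechanism <- function() {
  DiseaseMechanismStatement("GENE1", "MONDO:0000001",
                            "autosomal_recessive", "loss_of_function",
                            pathways = "GO:0003824")
}
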