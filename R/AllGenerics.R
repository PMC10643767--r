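#' Extract the beta matrix (CpGs x samples)
#' @param x a \linkS4class{MethylationCohort}.
#' @return numeric matrix of methylation fractions, NA where unmappable.
#' @export
setGeneric("betas", function(x) standardGeneric("betas"))

#' @rdname betas
#' @export
setMethod("betas", "MethylationCohort", function(x)
  SummarizedExperiment::assay(x, "beta"))

#' Extract the sample sheet
#' @param x a \linkS4class{MethylationCohort}.
#' @return data.frame with sample_id, animal_id, species_id, tissue, age, sex.
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

#' @rdname sampleSheet
#' @export
setMethod("sampleSheet", "MethylationCohort", function(x)
  as.data.frame(colData(x)))

#' Extract the CpG annotation
#' @param x a \linkS4class{MethylationCohort}.
#' @param mappability include the per-species mappable_* columns? Default TRUE.
#' @return data.frame keyed by cpg_id.
#' @export
setGeneric("cpgAnnotation", function(x, mappability = TRUE)
  standardGeneric("cpgAnnotation"))

#' @rdname cpgAnnotation
#' @export
setMethod("cpgAnnotation", "MethylationCohort", function(x, mappability = TRUE) {
  rd <- as.data.frame(rowData(x))
  if (!mappability) rd <- rd[, !grepl("^mappable_", names(rd)), drop = FALSE]
  rd
})

#' Extract the species life-history table
#' @param x a \linkS4class{MethylationCohort}.
#' @return data.frame as built by \code{\link{makeSpeciesTable}}.
#' @export
setGeneric("speciesTable", function(x) standardGeneric("speciesTable"))

#' @rdname speciesTable
#' @export
setMethod("speciesTable", "MethylationCohort", function(x)
  metadata(x)$species_table)

#' Extract the planted-truth record of a simulated cohort
#' @param x a \linkS4class{MethylationCohort}.
#' @return list of planted causal CpG sets (empty for real cohorts).
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname cohortTruth
#' @export
setMethod("cohortTruth", "MethylationCohort", function(x) metadata(x)$truth)

#' Per-species CpG mappability
#' @param x a \linkS4class{MethylationCohort}.
#' @return logical matrix CpGs x species.
#' @export
setGeneric("mappability", function(x) standardGeneric("mappability"))

#' @rdname mappability
#' @export
setMethod("mappability", "MethylationCohort", function(x) {
  rd <- rowData(x)
  cols <- grep("^mappable_", names(rd), value = TRUE)
  m <- as.matrix(as.data.frame(rd[cols]))
  colnames(m) <- sub("^mappable_", "", cols)
  m
})
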