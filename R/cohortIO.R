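#' Write a cohort bundle to a directory
#'
#' Writes the standard plain-text cohort bundle: \code{betas.csv} (rows =
#' samples, columns = CpG ids, full-precision), \code{samples.csv},
#' \code{species.csv}, \code{cpgs.bed} (BED-like, 0-based half-open:
#' chrom, start, end, cpg_id, gene, region_class, tss_distance, plus one
#' mappable_<species> 0/1 column per species) and, for simulated cohorts,
#' \code{truth.json}.
#'
#' @param cohort a \linkS4class{MethylationCohort}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  b <- t(betas(cohort))
  bdt <- data.table::data.table(sample_id = rownames(b))
  for (j in seq_len(ncol(b))) data.table::set(bdt, j = colnames(b)[j],
                                              value = b[, j])
  data.table::fwrite(bdt, file.path(dir, "betas.csv"))
  data.table::fwrite(sampleSheet(cohort), file.path(dir, "samples.csv"))
  data.table::fwrite(speciesTable(cohort), file.path(dir, "species.csv"))
  ann <- cpgAnnotation(cohort, mappability = FALSE)
  map <- mappability(cohort)
  bed <- data.frame(chrom = ann$chrom, start = ann$pos, end = ann$pos + 1L,
                    cpg_id = ann$cpg_id, gene = ann$gene,
                    region_class = ann$region_class,
                    tss_distance = ann$tss_distance)
  for (sp in colnames(map)) bed[[paste0("mappable_", sp)]] <- map[, sp] + 0L
  data.table::fwrite(bed, file.path(dir, "cpgs.bed"), sep = "\t")
  tr <- cohortTruth(cohort)
  if (length(tr))
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort bundle from a directory
#'
#' Inverse of \code{\link{writeCohort}}. Validation errors name the
#' offending rows: betas outside [0, 1] and samples present in the beta
#' matrix but missing from the sample sheet are rejected.
#'
#' @param dir directory written by \code{\link{writeCohort}}.
#' @return a \linkS4class{MethylationCohort}.
#' @export
readCohort <- function(dir) {
  bdt <- data.table::fread(file.path(dir, "betas.csv"))
  samples <- as.data.frame(data.table::fread(file.path(dir, "samples.csv")))
  species <- as.data.frame(data.table::fread(file.path(dir, "species.csv")))
  if ("n_animals" %in% names(species))
    species$n_animals <- as.integer(species$n_animals)
  bed <- as.data.frame(data.table::fread(file.path(dir, "cpgs.bed")))
  b <- as.matrix(bdt[, -1])
  rownames(b) <- bdt[[1]]
  bad <- which(b < 0 | b > 1, arr.ind = TRUE)
  if (nrow(bad))
    stop("beta value outside [0, 1] in betas.csv at row ", bad[1, 1],
         " (sample ", rownames(b)[bad[1, 1]], "), column ",
         colnames(b)[bad[1, 2]])
  missing <- setdiff(rownames(b), samples$sample_id)
  if (length(missing))
    stop("sample(s) in betas.csv missing from samples.csv: ",
         paste(missing, collapse = ", "))
  b <- b[samples$sample_id, , drop = FALSE]
  mapCols <- grep("^mappable_", names(bed), value = TRUE)
  mappable <- as.matrix(bed[mapCols]) == 1L
  colnames(mappable) <- sub("^mappable_", "", mapCols)
  cpgs <- data.frame(cpg_id = bed$cpg_id, chrom = bed$chrom,
                     pos = bed$start, gene = bed$gene,
                     region_class = bed$region_class,
                     tss_distance = bed$tss_distance,
                     stringsAsFactors = FALSE)
  b <- t(b)[cpgs$cpg_id, , drop = FALSE]
  truthPath <- file.path(dir, "truth.json")
  truth <- if (file.exists(truthPath)) {
    tr <- jsonlite::read_json(truthPath, simplifyVector = TRUE)
    for (f in c("sex_x", "sex_autosomal"))
      if (!is.null(tr[[f]])) tr[[f]] <- unlist(tr[[f]])
    tr
  } else list()
  methylationCohort(b, samples, cpgs, species, mappable, truth)
}
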