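#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

REGION_CLASSES <- c("promoter", "5'UTR", "exon", "3'UTR", "intron", "intergenic")

TRANSFORM_KINDS <- c("identity", "sqrt_offset", "loglinear", "relative")

#' Age transformation specification
#'
#' The dependent-variable transformations used when regressing age on
#' methylation: identity, square root with an offset (sqrt(age + offset),
#' offset 1 year by default so fetal samples with negative ages remain in
#' domain), the log-linear transform of the original human pan-tissue clock
#' (log(age + 1) - log(m + 1) up to the species' maturity age m, linear
#' (age - m)/(m + 1) thereafter), and relative age (age / species maximum
#' lifespan). Each transform has an exact inverse.
#'
#' @slot kind one of "identity", "sqrt_offset", "loglinear", "relative".
#' @slot offset offset in years for "sqrt_offset" (> 0, default 1).
#' @slot maturity named numeric, species_id -> maturity age ("loglinear").
#' @slot lifespan named numeric, species_id -> maximum lifespan ("relative").
#' @export
setClass("AgeTransform", representation(
  kind = "character",
  offset = "numeric",
  maturity = "numeric",
  lifespan = "numeric"
))

setValidity("AgeTransform", function(object) {
  msgs <- character()
  if (length(object@kind) != 1 || !object@kind %in% TRANSFORM_KINDS)
    msgs <- c(msgs, paste0("kind must be one of: ",
                           paste(TRANSFORM_KINDS, collapse = ", ")))
  if (identical(object@kind, "sqrt_offset") &&
      (length(object@offset) != 1 || object@offset <= 0))
    msgs <- c(msgs, "sqrt_offset requires a single offset > 0")
  if (identical(object@kind, "loglinear") &&
      length(object@maturity) && any(object@maturity <= 0))
    msgs <- c(msgs, "loglinear requires maturity_age > 0 for every species")
  if (identical(object@kind, "relative") &&
      length(object@lifespan) && any(object@lifespan <= 0))
    msgs <- c(msgs, "relative requires max_lifespan > 0 for every species")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AgeTransform", function(object) {
  cat("AgeTransform:", object@kind)
  if (object@kind == "sqrt_offset") cat(" (offset", object@offset, "years)")
  if (object@kind == "loglinear")
    cat(" (", length(object@maturity), "species maturities)")
  if (object@kind == "relative")
    cat(" (", length(object@lifespan), "species lifespans)")
  cat("\n")
})

#' Species table constructor
#'
#' Builds and validates the per-species life-history table used throughout the
#' package: maximum lifespan (years) for relative age, average age at sexual
#' maturity (years) for the log-linear transform, and gestation length (years)
#' for fetal-age simulation.
#'
#' @param species_id character vector of unique species labels.
#' @param max_lifespan maximum recorded lifespan in years (> 0).
#' @param maturity_age average age at sexual maturity in years
#'   (> 0, < max_lifespan).
#' @param gestation gestation length in years (must be < 1 for primates).
#' @param n_animals optional number of animals available per species
#'   (>= 0; defaults to NA meaning unconstrained).
#' @return a \code{data.frame} with one row per species.
#' @examples
#' makeSpeciesTable("human", 122.5, 13.5, 0.75)
#' @export
makeSpeciesTable <- function(species_id, max_lifespan, maturity_age,
                             gestation, n_animals = NA_integer_) {
  st <- data.frame(
    species_id = as.character(species_id),
    max_lifespan = as.numeric(max_lifespan),
    maturity_age = as.numeric(maturity_age),
    gestation = as.numeric(gestation),
    n_animals = as.integer(n_animals),
    stringsAsFactors = FALSE
  )
  validateSpeciesTable(st)
  st
}

validateSpeciesTable <- function(st) {
  need <- c("species_id", "max_lifespan", "maturity_age", "gestation")
  miss <- setdiff(need, names(st))
  if (length(miss))
    stop("species table is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(st$species_id))
    stop("species_id values must be unique within a species table")
  if (any(st$max_lifespan <= 0)) stop("max_lifespan must be > 0")
  if (any(st$maturity_age <= 0)) stop("maturity_age must be > 0")
  if (any(st$maturity_age >= st$max_lifespan))
    stop("maturity_age must be below max_lifespan for every species")
  if (any(st$gestation <= 0 | st$gestation >= 1))
    stop("gestation must lie in (0, 1) years for simulated primates")
  invisible(st)
}

#' MethylationCohort: beta matrix plus sample, species and CpG metadata
#'
#' The universal input bundle of the package, stored as a
#' \linkS4class{SummarizedExperiment} with CpGs as rows and samples as
#' columns. The single assay \code{"beta"} holds methylation fractions in
#' [0, 1]; entries are \code{NA} where a CpG is unmappable in the sample's
#' species. \code{colData} carries the sample sheet (sample_id, animal_id,
#' species_id, tissue, age in years — negative for fetal samples — and sex),
#' \code{rowData} the CpG annotation (chromosome, position, nearest gene,
#' region class, TSS distance) plus one logical \code{mappable_<species>}
#' column per species, and \code{metadata} the species table and, for
#' simulated cohorts, the planted-truth record.
#'
#' @export
setClass("MethylationCohort", contains = "SummarizedExperiment")

setValidity("MethylationCohort", function(object) {
  msgs <- character()
  cd <- colData(object)
  need <- c("sample_id", "animal_id", "species_id", "tissue", "age", "sex")
  miss <- setdiff(need, names(cd))
  if (length(miss))
    msgs <- c(msgs, paste0("colData is missing: ", paste(miss, collapse = ", ")))
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'beta' is required")
  st <- metadata(object)$species_table
  if (is.null(st)) {
    msgs <- c(msgs, "metadata$species_table is required")
  } else if (!length(miss)) {
    unknown <- setdiff(unique(cd$species_id), st$species_id)
    if (length(unknown))
      msgs <- c(msgs, paste0("samples reference species absent from the ",
                             "species table: ", paste(unknown, collapse = ", ")))
  }
  b <- SummarizedExperiment::assay(object, "beta")
  if (any(b < 0 | b > 1, na.rm = TRUE))
    msgs <- c(msgs, "beta values must lie in [0, 1]")
  if (!"cpg_id" %in% names(rowData(object)))
    msgs <- c(msgs, "rowData must contain cpg_id")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MethylationCohort
#'
#' @param betas numeric matrix, CpGs x samples, values in [0, 1] or NA.
#' @param samples data.frame sample sheet with columns sample_id, animal_id,
#'   species_id, tissue, age, sex ("F", "M" or "unknown").
#' @param cpgs data.frame CpG annotation with at least cpg_id; typically also
#'   chrom, pos, gene, region_class, tss_distance.
#' @param speciesTable data.frame as built by \code{\link{makeSpeciesTable}}.
#' @param mappable optional logical matrix CpGs x species (colnames =
#'   species_id); defaults to all-mappable.
#' @param truth optional list recording planted causal CpG sets (simulation).
#' @return a \linkS4class{MethylationCohort}.
#' @export
methylationCohort <- function(betas, samples, cpgs, speciesTable,
                              mappable = NULL, truth = list()) {
  validateSpeciesTable(speciesTable)
  betas <- as.matrix(betas)
  if (nrow(betas) != nrow(cpgs))
    stop("nrow(betas) must equal nrow(cpgs) (CpGs are rows)")
  if (ncol(betas) != nrow(samples))
    stop("ncol(betas) must equal nrow(samples)")
  if (is.null(mappable)) {
    mappable <- matrix(TRUE, nrow(cpgs), nrow(speciesTable),
                       dimnames = list(NULL, speciesTable$species_id))
  }
  rd <- DataFrame(cpgs)
  for (sp in colnames(mappable)) rd[[paste0("mappable_", sp)]] <- mappable[, sp]
  rownames(betas) <- cpgs$cpg_id
  colnames(betas) <- samples$sample_id
  se <- SummarizedExperiment(
    assays = list(beta = betas),
    rowData = rd,
    colData = DataFrame(samples, row.names = samples$sample_id)
  )
  metadata(se)$species_table <- speciesTable
  metadata(se)$truth <- truth
  new("MethylationCohort", se)
}

#' Penalized methylation age clock
#'
#' An elastic-net clock: an intercept plus sparse CpG coefficients on the beta
#' scale, together with the age transformation it was trained on. Per-CpG
#' training means are stored so missing betas can be imputed identically at
#' prediction time.
#'
#' @slot name clock label.
#' @slot intercept intercept on the transformed-age scale.
#' @slot weights named numeric vector of nonzero CpG coefficients.
#' @slot transform the \linkS4class{AgeTransform} used for the outcome.
#' @slot alpha elastic-net mixing parameter in (0, 1].
#' @slot lambda penalty selected by internal tenfold cross-validation.
#' @slot trainingMeans named per-CpG training means used for imputation.
#' @slot meta list of training metadata (species/tissue counts, fitted values).
#' @export
setClass("MethylationClock", representation(
  name = "character",
  intercept = "numeric",
  weights = "numeric",
  transform = "AgeTransform",
  alpha = "numeric",
  lambda = "numeric",
  trainingMeans = "numeric",
  meta = "list"
))

setValidity("MethylationClock", function(object) {
  msgs <- character()
  if (length(object@weights) && any(object@weights == 0))
    msgs <- c(msgs, "weights must not contain zero entries")
  if (length(object@weights) && is.null(names(object@weights)))
    msgs <- c(msgs, "weights must be named by cpg_id")
  if (length(object@alpha) == 1 &&
      (object@alpha <= 0 || object@alpha > 1))
    msgs <- c(msgs, "alpha must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Elastic-net methylation sex predictor
#'
#' Binomial elastic net on the female indicator; intercept and sparse CpG
#' weights live on the logit scale, the decision threshold is probability 0.5.
#'
#' @slot intercept logit-scale intercept.
#' @slot weights named numeric nonzero CpG coefficients (logit scale).
#' @slot alpha elastic-net mixing parameter.
#' @slot lambda selected penalty.
#' @slot trainingMeans per-CpG training means for imputation.
#' @slot meta training metadata.
#' @export
setClass("SexPredictor", representation(
  intercept = "numeric",
  weights = "numeric",
  alpha = "numeric",
  lambda = "numeric",
  trainingMeans = "numeric",
  meta = "list"
))

setMethod("show", "MethylationCohort", function(object) {
  cd <- colData(object)
  cat("MethylationCohort:", nrow(object), "CpGs x", ncol(object), "samples\n")
  cat("  species:", paste(unique(cd$species_id), collapse = ", "), "\n")
  cat("  tissues:", paste(unique(cd$tissue), collapse = ", "), "\n")
  ages <- cd$age
  cat(sprintf("  age range: %.2f to %.2f years (%d fetal)\n",
              min(ages), max(ages), sum(ages < 0)))
  tr <- metadata(object)$truth
  if (length(tr))
    cat("  planted truth:", sum(lengths(tr[c("age_gain", "age_loss",
        "sex_x", "sex_autosomal")])), "causal CpGs recorded\n")
})

setMethod("show", "MethylationClock", function(object) {
  cat("MethylationClock '", object@name, "': ", length(object@weights),
      " CpGs, transform ", object@transform@kind, "\n", sep = "")
  cat(sprintf("  alpha %.2f, lambda %.4g, trained on n = %s\n",
              object@alpha, object@lambda,
              if (!is.null(object@meta$n)) object@meta$n else "?"))
})

setMethod("show", "SexPredictor", function(object) {
  cat("SexPredictor:", length(object@weights), "CpGs, alpha",
      object@alpha, "\n")
})
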