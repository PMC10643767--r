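#' Fit an elastic-net methylation clock
#'
#' Regresses the transformed age of the selected samples on their beta values
#' with an elastic-net penalty (glmnet). The mixing parameter alpha defaults
#' to 0.5, the midpoint between ridge and lasso, and the penalty strength is
#' chosen automatically as the value minimizing mean squared prediction error
#' in an internal tenfold cross-validation (cv.glmnet's lambda.min). Missing
#' betas are mean-imputed per CpG and the training means are stored in the
#' model so prediction imputes identically; all-missing and constant CpG
#' columns are dropped (with a warning reporting the count for constant
#' columns). Coefficients are reported on the beta scale.
#'
#' @param cohort a \linkS4class{MethylationCohort}.
#' @param transform an \linkS4class{AgeTransform} for the outcome.
#' @param samples optional logical vector or character vector of sample_ids
#'   selecting the training samples (default: all).
#' @param alpha elastic-net mixing in (0, 1].
#' @param nfolds internal cross-validation folds for penalty selection.
#' @param seed seed for the internal fold assignment.
#' @param name clock label.
#' @return a \linkS4class{MethylationClock}.
#' @export
fitClock <- function(cohort, transform, samples = NULL, alpha = 0.5,
                     nfolds = 10, seed = 1L, name = "clock") {
  stopifnot(is(cohort, "MethylationCohort"), is(transform, "AgeTransform"))
  if (alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  sheet <- sampleSheet(cohort)
  keep <- selectSamples(sheet, samples)
  sheet <- sheet[keep, , drop = FALSE]
  n <- nrow(sheet)
  if (n < 20)
    stop("fitting a clock requires at least 20 samples; got ", n)
  X <- t(betas(cohort)[, keep, drop = FALSE])
  allNA <- colSums(!is.na(X)) == 0
  X <- X[, !allNA, drop = FALSE]
  imp <- imputeMatrix(X)
  X <- imp$X
  sds <- apply(X, 2, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    warning(sum(constant), " constant CpG column(s) dropped before fitting")
    X <- X[, !constant, drop = FALSE]
  }
  y <- transformAge(sheet$age, sheet$species_id, transform)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(nfolds), n))
  cv <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                          family = "gaussian")
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1]
  intercept <- unname(co["(Intercept)"])
  w <- co[-1]
  w <- w[w != 0]
  fitted <- if (length(w))
    as.vector(intercept + X[, names(w), drop = FALSE] %*% w)
  else rep(intercept, n)
  new("MethylationClock",
      name = name, intercept = intercept, weights = w,
      transform = transform, alpha = alpha, lambda = cv$lambda.min,
      trainingMeans = imp$means[names(w)],
      meta = list(
        n = n,
        species = table(sheet$species_id),
        tissues = table(sheet$tissue),
        fitted = stats::setNames(fitted, sheet$sample_id),
        seed = seed
      ))
}

selectSamples <- function(sheet, samples) {
  if (is.null(samples)) return(rep(TRUE, nrow(sheet)))
  if (is.logical(samples)) {
    stopifnot(length(samples) == nrow(sheet))
    return(samples)
  }
  if (is.character(samples)) return(sheet$sample_id %in% samples)
  if (is.function(samples)) return(vapply(seq_len(nrow(sheet)), function(i)
    isTRUE(samples(sheet[i, ])), logical(1)))
  stop("samples must be NULL, a logical mask, sample_ids, or a predicate")
}

#' Predict DNAm age with a fitted clock
#'
#' Computes the linear score intercept + sum(w * beta) for every sample, then
#' inverts the clock's age transformation per the sample's species to report
#' DNAm age in years. Missing beta entries (and model CpGs absent from the
#' cohort, which trigger a warning) are imputed from the stored training
#' means. For sqrt-transformed clocks, scores below zero are truncated at
#' zero before inversion, so the minimum reportable DNAm age is -offset.
#'
#' @param clock a \linkS4class{MethylationClock}.
#' @param cohort a \linkS4class{MethylationCohort}.
#' @return data.frame with sample_id, species_id, tissue, age, score (the
#'   transformed-scale prediction) and dnam_age (years).
#' @export
predictAge <- function(clock, cohort) {
  stopifnot(is(clock, "MethylationClock"), is(cohort, "MethylationCohort"))
  sheet <- sampleSheet(cohort)
  score <- linearScore(clock@intercept, clock@weights, clock@trainingMeans,
                       cohort)
  tr <- clock@transform
  inv <- score
  if (tr@kind == "sqrt_offset") inv <- pmax(score, 0)
  dnam <- inverseTransformAge(inv, sheet$species_id, tr)
  data.frame(sample_id = sheet$sample_id, species_id = sheet$species_id,
             tissue = sheet$tissue, animal_id = sheet$animal_id,
             age = sheet$age, score = score, dnam_age = dnam,
             stringsAsFactors = FALSE)
}

linearScore <- function(intercept, weights, trainingMeans, cohort) {
  if (!length(weights)) return(rep(intercept, ncol(cohort)))
  b <- betas(cohort)
  have <- names(weights) %in% rownames(b)
  if (!all(have))
    warning(sum(!have), " model CpG(s) absent from the cohort; ",
            "imputed from training means")
  X <- matrix(rep(trainingMeans, each = ncol(cohort)),
              ncol(cohort), length(weights),
              dimnames = list(colnames(b), names(weights)))
  present <- names(weights)[have]
  X[, present] <- t(b[present, , drop = FALSE])
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- trainingMeans[nas[, 2]]
  as.vector(intercept + X %*% weights)
}
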