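#' Assign cross-validation folds
#'
#' \code{LOOCV} gives every sample its own fold. \code{LOFO10} builds ten
#' folds balanced by species: within each species the samples are shuffled
#' (seeded) and dealt round-robin over a shuffled fold ordering, so for every
#' species the per-fold counts differ by at most one.
#'
#' @param cohort a \linkS4class{MethylationCohort}.
#' @param scheme "LOFO10" or "LOOCV".
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return integer vector of fold indices named by sample_id, with
#'   attributes \code{scheme} and \code{seed}.
#' @export
makeFolds <- function(cohort, scheme = c("LOFO10", "LOOCV"), seed = 1L) {
  scheme <- match.arg(scheme)
  sheet <- sampleSheet(cohort)
  n <- nrow(sheet)
  fold <- integer(n)
  if (scheme == "LOOCV") {
    fold <- seq_len(n)
  } else {
    K <- 10L
    if (n < K)
      stop("LOFO10 requires at least ", K, " samples; got ", n)
    set.seed(seed)
    for (sp in unique(sheet$species_id)) {
      ii <- which(sheet$species_id == sp)
      ii <- ii[sample.int(length(ii))]
      fold[ii] <- rep_len(sample.int(K), length(ii))
    }
  }
  structure(stats::setNames(fold, sheet$sample_id),
            scheme = scheme, seed = seed)
}

#' Cross-validated clock accuracy
#'
#' Runs the full clock-fitting procedure once per fold — each training fold
#' re-selects its own penalty by internal tenfold cross-validation, so no
#' information leaks from the held-out samples — and predicts every sample
#' exactly once from a model never trained on it. Accuracy is summarized as
#' the Pearson correlation R between DNAm age and chronological age and the
#' median absolute error in years, overall and per species and tissue.
#'
#' @inheritParams fitClock
#' @param scheme "LOFO10" or "LOOCV" (see \code{\link{makeFolds}}).
#' @param seed seed controlling both the fold assignment and the per-fold
#'   internal penalty-selection folds.
#' @return list with \code{predictions} (data.frame: sample_id, fold,
#'   species_id, tissue, animal_id, age, y_true, score, dnam_age) and
#'   \code{metrics} (see \code{\link{cvMetrics}}).
#' @export
runCV <- function(cohort, transform, scheme = c("LOFO10", "LOOCV"),
                  alpha = 0.5, seed = 1L) {
  scheme <- match.arg(scheme)
  fold <- makeFolds(cohort, scheme, seed)
  sheet <- sampleSheet(cohort)
  out <- vector("list", max(fold))
  for (k in sort(unique(fold))) {
    train <- fold != k
    if (sum(train) < 20)
      stop("training half of fold ", k, " has fewer than 20 samples; ",
           "use a larger cohort")
    clk <- fitClock(cohort, transform, samples = train, alpha = alpha,
                    seed = seed + k)
    test <- cohort[, !train]
    pr <- predictAge(clk, test)
    pr$fold <- k
    out[[k]] <- pr
  }
  pred <- do.call(rbind, out)
  pred <- pred[match(sheet$sample_id, pred$sample_id), ]
  rownames(pred) <- NULL
  pred$y_true <- transformAge(pred$age, pred$species_id, transform)
  pred <- pred[c("sample_id", "fold", "species_id", "tissue", "animal_id",
                 "age", "y_true", "score", "dnam_age")]
  list(predictions = pred, metrics = cvMetrics(pred))
}

#' Accuracy metrics from out-of-fold predictions
#'
#' @param predictions data.frame with age, dnam_age, species_id, tissue.
#' @return data.frame of Pearson R, median absolute error (years) and n for
#'   the whole set and for each species and tissue.
#' @export
cvMetrics <- function(predictions) {
  one <- function(d, grouping, level) data.frame(
    grouping = grouping, level = level, n = nrow(d),
    pearson_R = if (nrow(d) >= 3 && stats::sd(d$age) > 0 &&
                    stats::sd(d$dnam_age) > 0)
      stats::cor(d$dnam_age, d$age) else NA_real_,
    MAE = stats::median(abs(d$dnam_age - d$age)),
    stringsAsFactors = FALSE)
  res <- list(one(predictions, "overall", "all"))
  for (sp in unique(predictions$species_id))
    res <- c(res, list(one(predictions[predictions$species_id == sp, ],
                           "species", sp)))
  for (ti in unique(predictions$tissue))
    res <- c(res, list(one(predictions[predictions$tissue == ti, ],
                           "tissue", ti)))
  do.call(rbind, res)
}

#' Epigenetic age acceleration
#'
#' Adds both acceleration definitions to a prediction table: the raw
#' difference DNAmAge - Age (\code{accel_delta}) and the residual from the
#' least-squares regression of DNAmAge on Age (\code{accel_residual}), the
#' default in the clock literature because it is invariant to calibration
#' offsets. Residual acceleration has zero mean and zero correlation with
#' age by construction.
#'
#' @param predictions data.frame with at least age and dnam_age (as returned
#'   by \code{\link{runCV}} or \code{\link{predictAge}}).
#' @return the input with accel_delta and accel_residual columns appended.
#' @export
ageAcceleration <- function(predictions) {
  stopifnot(all(c("age", "dnam_age") %in% names(predictions)))
  if (nrow(predictions) < 3)
    stop("residual acceleration requires at least 3 samples")
  if (stats::sd(predictions$age) == 0)
    stop("ages are constant; the residual definition is degenerate")
  predictions$accel_delta <- predictions$dnam_age - predictions$age
  fit <- stats::lm(dnam_age ~ age, data = predictions)
  predictions$accel_residual <- unname(stats::resid(fit))
  predictions
}

#' Cross-tissue correlation of age acceleration
#'
#' Computes the tissue x tissue Pearson correlation matrix of per-animal
#' accelerations, joining tissues on shared animal_id. Pairs with fewer than
#' 3 shared animals are reported as NA; the diagonal is 1.
#'
#' @param acc data.frame from \code{\link{ageAcceleration}} with animal_id
#'   and tissue columns.
#' @param which acceleration definition: "residual" (default) or "delta".
#' @return symmetric correlation matrix with tissue dimnames.
#' @export
crossTissueAcceleration <- function(acc, which = c("residual", "delta")) {
  which <- match.arg(which)
  col <- paste0("accel_", which)
  stopifnot(all(c("animal_id", "tissue", col) %in% names(acc)))
  tissues <- unique(acc$tissue)
  wide <- stats::reshape(
    acc[c("animal_id", "tissue", col)],
    idvar = "animal_id", timevar = "tissue", direction = "wide")
  m <- as.matrix(wide[, -1, drop = FALSE])
  colnames(m) <- sub(paste0("^", col, "\\."), "", colnames(m))
  m <- m[, tissues, drop = FALSE]
  K <- length(tissues)
  r <- matrix(NA_real_, K, K, dimnames = list(tissues, tissues))
  diag(r) <- 1
  anyPair <- FALSE
  for (i in seq_len(K)) for (j in seq_len(K)) if (i < j) {
    ok <- stats::complete.cases(m[, c(i, j)])
    if (sum(ok) >= 3) {
      r[i, j] <- r[j, i] <- stats::cor(m[ok, i], m[ok, j])
      anyPair <- TRUE
    }
  }
  if (!anyPair && K > 1)
    warning("no tissue pair shares 3 or more animals; matrix is empty")
  r
}
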