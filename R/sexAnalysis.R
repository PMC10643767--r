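## vectorized OLS of many CpGs on a shared design, grouped by missingness
## pattern (missingness is species-block, so patterns are few). Returns the
## sex (last-column) coefficient, se, t, p per CpG.
sexOlsScreen <- function(B, age, female, minPerSex = 3) {
  pattern <- apply(is.na(B), 1, function(x) paste(which(x), collapse = ","))
  out <- data.frame(cpg_id = rownames(B), n = NA_real_, coef = NA_real_,
                    se = NA_real_, t = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (pat in unique(pattern)) {
    rows <- pattern == pat
    obs <- if (nzchar(pat))
      setdiff(seq_along(age), as.integer(strsplit(pat, ",")[[1]]))
    else seq_along(age)
    if (length(obs) < 4) next
    f <- female[obs]
    if (sum(f) < minPerSex || sum(!f) < minPerSex) next
    a <- age[obs]
    X <- if (stats::sd(a) > 0) cbind(1, a, f) else cbind(1, f)
    df <- length(obs) - ncol(X)
    if (df < 1) next
    XtXinv <- solve(crossprod(X))
    H <- XtXinv %*% t(X)
    Y <- t(B[rows, obs, drop = FALSE])
    cf <- H %*% Y
    res <- Y - X %*% cf
    sigma2 <- colSums(res^2) / df
    seSex <- sqrt(sigma2 * XtXinv[ncol(X), ncol(X)])
    bSex <- cf[ncol(X), ]
    tv <- ifelse(seSex > 0, bSex / seSex, 0)
    out$n[rows] <- length(obs)
    out$coef[rows] <- bSex
    out$se[rows] <- seSex
    out$t[rows] <- tv
    out$p[rows] <- ifelse(seSex > 0,
                          2 * stats::pt(abs(tv), df, lower.tail = FALSE), 1)
  }
  out[!is.na(out$p), , drop = FALSE]
}

#' Stratified EWAS of sex
#'
#' Within each stratum (species x tissue x age category), regresses each
#' CpG's methylation on chronological age and a female indicator by ordinary
#' least squares and reports the sex coefficient (female minus male, beta
#' units — positive means higher methylation in females), its t statistic,
#' two-sided p and Benjamini-Hochberg q within the stratum. Only samples
#' with known sex are used; strata without at least \code{minPerSex}
#' samples of each sex are skipped with a warning. The age covariate is
#' dropped when ages are constant within a stratum.
#'
#' @param cohort a \linkS4class{MethylationCohort}.
#' @param ageBreaks numeric breakpoints (years) defining age categories;
#'   the default 1 splits neonates (< 1 year) from older animals.
#' @param speciesGroups optional named character vector mapping species_id
#'   to an analysis group label (e.g. all strepsirrhines to "lemur");
#'   unlisted species form their own group.
#' @param minPerSex minimum samples per sex per stratum (default 3).
#' @return named list of per-stratum tables, each with attributes
#'   \code{species}, \code{tissue}, \code{age_category} and \code{n_samples}.
#' @export
sexEwas <- function(cohort, ageBreaks = 1, speciesGroups = NULL,
                    minPerSex = 3) {
  sheet <- sampleSheet(cohort)
  known <- sheet$sex %in% c("F", "M")
  sheet <- sheet[known, , drop = FALSE]
  B <- betas(cohort)[, known, drop = FALSE]
  grp <- sheet$species_id
  if (!is.null(speciesGroups)) {
    hit <- grp %in% names(speciesGroups)
    grp[hit] <- speciesGroups[grp[hit]]
  }
  breaks <- sort(unique(c(-Inf, ageBreaks, Inf)))
  ageCat <- as.character(cut(sheet$age, breaks))
  strata <- unique(data.frame(grp = grp, tissue = sheet$tissue,
                              ageCat = ageCat, stringsAsFactors = FALSE))
  out <- list()
  for (i in seq_len(nrow(strata))) {
    sel <- grp == strata$grp[i] & sheet$tissue == strata$tissue[i] &
      ageCat == strata$ageCat[i]
    f <- sheet$sex[sel] == "F"
    lab <- paste(strata$grp[i], strata$tissue[i], strata$ageCat[i],
                 sep = "|")
    if (sum(f) < minPerSex || sum(!f) < minPerSex) {
      warning("stratum ", lab, " skipped: fewer than ", minPerSex,
              " samples of one sex")
      next
    }
    tb <- sexOlsScreen(B[, sel, drop = FALSE], sheet$age[sel], f, minPerSex)
    tb$q <- stats::p.adjust(tb$p, method = "BH")
    tb$direction <- ifelse(tb$coef > 0, "up_in_female", "down_in_female")
    rownames(tb) <- NULL
    out[[lab]] <- structure(tb,
      species = unique(sheet$species_id[sel]),
      tissue = strata$tissue[i],
      age_category = strata$ageCat[i],
      n_samples = sum(sel))
  }
  out
}

#' Count sex-associated methylation positions per model
#'
#' Tallies CpGs significant at the FDR threshold in each stratified model,
#' split by chromosome class (autosome, X, Y) and direction of the female
#' effect.
#'
#' @param tables list of tables from \code{\link{sexEwas}}.
#' @param annotation CpG annotation with cpg_id and chrom columns.
#' @param qThreshold FDR threshold (default 0.05).
#' @return data.frame with one row per model and count columns
#'   \code{<class>_<direction>} plus total.
#' @export
countSmps <- function(tables, annotation, qThreshold = 0.05) {
  chromClass <- function(chrom)
    ifelse(chrom == "chrX", "X", ifelse(chrom == "chrY", "Y", "autosome"))
  cls <- stats::setNames(chromClass(annotation$chrom), annotation$cpg_id)
  rows <- lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    sig <- tb[tb$q < qThreshold, , drop = FALSE]
    cc <- cls[sig$cpg_id]
    up <- sig$coef > 0
    data.frame(model = nm,
               autosome_up = sum(cc == "autosome" & up),
               autosome_down = sum(cc == "autosome" & !up),
               X_up = sum(cc == "X" & up), X_down = sum(cc == "X" & !up),
               Y_up = sum(cc == "Y" & up), Y_down = sum(cc == "Y" & !up),
               total = nrow(sig), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Consensus sex-associated CpGs across models
#'
#' @param tables list of tables from \code{\link{sexEwas}}.
#' @param minModels minimum number of models in which a CpG must be
#'   significant (q below threshold).
#' @param qThreshold FDR threshold (default 0.05).
#' @return character vector of consensus cpg_ids.
#' @export
consensusSmps <- function(tables, minModels, qThreshold = 0.05) {
  if (minModels > length(tables))
    stop("minModels exceeds the number of models (", length(tables), ")")
  hits <- unlist(lapply(tables, function(tb)
    tb$cpg_id[tb$q < qThreshold]), use.names = FALSE)
  counts <- table(hits)
  names(counts)[counts >= minModels]
}

#' Pooled EWAS of sex ignoring species and tissue
#'
#' Runs the same age-adjusted sex regression on all known-sex samples at
#' once and splits significant CpGs by the sign of the female coefficient.
#' The default threshold is deliberately configurable: consortium-scale data
#' support extreme thresholds (down to 1e-300), desk-scale cohorts do not.
#'
#' @param cohort a \linkS4class{MethylationCohort}.
#' @param pThreshold nominal p-value threshold (default 1e-8).
#' @param excludeSpecies species to drop before pooling (e.g. a chimeric
#'   species whose sex signal is unreliable).
#' @return list with \code{hyper} (cpg_ids, higher in females),
#'   \code{hypo}, and the full \code{table}.
#' @export
pooledSexEwas <- function(cohort, pThreshold = 1e-8,
                          excludeSpecies = character()) {
  sheet <- sampleSheet(cohort)
  keep <- sheet$sex %in% c("F", "M") &
    !(sheet$species_id %in% excludeSpecies)
  if (sum(sheet$sex[keep] == "F") < 3 || sum(sheet$sex[keep] == "M") < 3)
    stop("pooled sex EWAS requires at least 3 samples per sex")
  tb <- sexOlsScreen(betas(cohort)[, keep, drop = FALSE],
                     sheet$age[keep], sheet$sex[keep] == "F")
  tb$q <- stats::p.adjust(tb$p, method = "BH")
  rownames(tb) <- NULL
  sig <- tb$p < pThreshold
  list(hyper = tb$cpg_id[sig & tb$coef > 0],
       hypo = tb$cpg_id[sig & tb$coef < 0],
       table = tb)
}

#' Fit an elastic-net sex predictor
#'
#' Binomial elastic net of the female indicator on beta values, with the
#' penalty chosen by internal tenfold cross-validation. The predictor is fit
#' on the full CpG set by default — in data with X-inactivation signal the
#' selected CpGs concentrate on the X chromosome by themselves — with an
#' optional restriction to X-chromosome CpGs.
#'
#' @param cohort a \linkS4class{MethylationCohort}; training uses samples
#'   with known sex (both sexes required).
#' @param alpha elastic-net mixing (default 0.5).
#' @param seed seed for the internal penalty-selection folds.
#' @param xOnly restrict features to chrX CpGs?
#' @return a \linkS4class{SexPredictor}.
#' @export
fitSexPredictor <- function(cohort, alpha = 0.5, seed = 1L, xOnly = FALSE) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  sheet <- sampleSheet(cohort)
  keep <- sheet$sex %in% c("F", "M")
  y <- as.integer(sheet$sex[keep] == "F")
  if (length(unique(y)) < 2)
    stop("training requires samples of both sexes")
  B <- betas(cohort)[, keep, drop = FALSE]
  if (xOnly) {
    onX <- cpgAnnotation(cohort)$chrom == "chrX"
    B <- B[onX, , drop = FALSE]
  }
  X <- t(B)
  X <- X[, colSums(!is.na(X)) > 0, drop = FALSE]
  imp <- imputeMatrix(X)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(10), length(y)))
  cv <- glmnet::cv.glmnet(imp$X, y, family = "binomial", alpha = alpha,
                          foldid = foldid)
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1]
  w <- co[-1]
  w <- w[w != 0]
  new("SexPredictor", intercept = unname(co["(Intercept)"]), weights = w,
      alpha = alpha, lambda = cv$lambda.min,
      trainingMeans = imp$means[names(w)],
      meta = list(n = length(y), nF = sum(y), seed = seed))
}

#' Predict sex from methylation
#'
#' Computes the logistic probability of female from the predictor's linear
#' score; labels are "F" above probability 0.5, "M" below, and "unknown" at
#' exactly 0.5.
#'
#' @param predictor a \linkS4class{SexPredictor}.
#' @param cohort a \linkS4class{MethylationCohort}.
#' @return data.frame with sample_id, species_id, prob_female and label.
#' @export
predictSex <- function(predictor, cohort) {
  stopifnot(is(predictor, "SexPredictor"))
  sheet <- sampleSheet(cohort)
  score <- linearScore(predictor@intercept, predictor@weights,
                       predictor@trainingMeans, cohort)
  prob <- stats::plogis(score)
  label <- ifelse(prob > 0.5, "F", ifelse(prob < 0.5, "M", "unknown"))
  data.frame(sample_id = sheet$sample_id, species_id = sheet$species_id,
             sex = sheet$sex, prob_female = prob, label = label,
             stringsAsFactors = FALSE)
}

#' Cross-validated sex-predictor accuracy
#'
#' Tenfold cross-validation stratified by species and sex: every known-sex
#' sample is predicted once by a predictor never trained on it. Reports
#' overall and per-species accuracy against the recorded sex.
#'
#' @inheritParams fitSexPredictor
#' @param k number of folds (default 10).
#' @return list with \code{predictions}, overall \code{accuracy}, and
#'   \code{perSpecies} accuracy.
#' @export
sexPredictorCV <- function(cohort, k = 10, alpha = 0.5, seed = 1L) {
  sheet <- sampleSheet(cohort)
  known <- which(sheet$sex %in% c("F", "M"))
  sub <- cohort[, known]
  sheet <- sheet[known, , drop = FALSE]
  set.seed(seed)
  fold <- integer(nrow(sheet))
  for (g in unique(paste(sheet$species_id, sheet$sex))) {
    ii <- which(paste(sheet$species_id, sheet$sex) == g)
    ii <- ii[sample.int(length(ii))]
    fold[ii] <- rep_len(sample.int(k), length(ii))
  }
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    train <- fold != f
    if (!any(!train)) next
    pr <- fitSexPredictor(sub[, train], alpha = alpha, seed = seed + f)
    preds[[f]] <- predictSex(pr, sub[, !train])
  }
  pred <- do.call(rbind, preds)
  pred <- pred[match(sheet$sample_id, pred$sample_id), ]
  rownames(pred) <- NULL
  correct <- pred$label == pred$sex
  perSpecies <- tapply(correct, pred$species_id, mean)
  list(predictions = pred, accuracy = mean(correct),
       perSpecies = perSpecies)
}
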