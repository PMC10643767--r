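#' Cohort simulation configuration
#'
#' @slot species data.frame species table (see \code{\link{makeSpeciesTable}}).
#' @slot tissues character vector of tissue labels.
#' @slot nCpgs total number of CpGs on the simulated array.
#' @slot nSharedAgeCpgs CpGs whose methylation tracks age in every tissue
#'   (first half gain, second half loss).
#' @slot nTissueAgeCpgs CpGs per tissue with tissue-specific age signal.
#' @slot nSexCpgs X-linked CpGs offset by sex.
#' @slot nAutosomalSexCpgs autosomal CpGs offset by sex.
#' @slot effectSize logit-scale slope per unit relative age.
#' @slot sexDelta beta-scale female minus male offset.
#' @slot noiseSd logit-scale Gaussian noise standard deviation.
#' @slot fracFetal fraction of animals sampled prenatally (negative age).
#' @slot mappabilityDropout probability a CpG is unmappable in a species.
#' @slot speciesBaselineSd logit-scale sd of per-(CpG, species) baseline
#'   divergence, emulating evolutionary divergence of baseline methylation.
#' @slot animalEffectSd years; sd of a per-animal age offset shared by all of
#'   that animal's tissues (a planted "fast/slow ager" effect).
#' @slot promoterBias multiplier on the promoter probability for shared gain
#'   CpGs (1 = unbiased background rate).
#' @slot chimericSpecies species whose planted sex signal is erased
#'   (emulating chimeric blood; empty character for none).
#' @slot seed integer; fully determines the simulated cohort.
#' @export
setClass("CohortConfig", representation(
  species = "data.frame",
  tissues = "character",
  nCpgs = "integer",
  nSharedAgeCpgs = "integer",
  nTissueAgeCpgs = "integer",
  nSexCpgs = "integer",
  nAutosomalSexCpgs = "integer",
  effectSize = "numeric",
  sexDelta = "numeric",
  noiseSd = "numeric",
  fracFetal = "numeric",
  mappabilityDropout = "numeric",
  speciesBaselineSd = "numeric",
  animalEffectSd = "numeric",
  promoterBias = "numeric",
  chimericSpecies = "character",
  seed = "integer"
))

setValidity("CohortConfig", function(object) {
  msgs <- character()
  v <- try(validateSpeciesTable(object@species), silent = TRUE)
  if (inherits(v, "try-error")) msgs <- c(msgs, conditionMessage(attr(v, "condition")))
  budget <- object@nSharedAgeCpgs +
    object@nTissueAgeCpgs * length(object@tissues) +
    object@nSexCpgs + object@nAutosomalSexCpgs
  if (budget > object@nCpgs)
    msgs <- c(msgs, sprintf(
      "causal CpG budget (%d) exceeds nCpgs (%d)", budget, object@nCpgs))
  for (p in c("fracFetal", "mappabilityDropout")) {
    val <- slot(object, p)
    if (val < 0 || val > 1) msgs <- c(msgs, paste0(p, " must lie in [0, 1]"))
  }
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (length(object@chimericSpecies) &&
      !all(object@chimericSpecies %in% object@species$species_id))
    msgs <- c(msgs, "chimericSpecies must appear in the species table")
  if (length(msgs)) msgs else TRUE
})

#' Default species table for simulations
#'
#' Five primates spanning the lifespan range of the clade, with anAge-style
#' life-history values: a small-bodied galago, vervet monkey, olive baboon,
#' rhesus macaque, and human (maximum lifespan 122.5 years).
#'
#' @return a species table data.frame.
#' @export
defaultSpeciesTable <- function() {
  makeSpeciesTable(
    species_id   = c("galago", "vervet", "baboon", "macaque", "human"),
    max_lifespan = c(10, 30.8, 37.5, 40, 122.5),
    maturity_age = c(1, 4, 5.5, 4, 13.5),
    gestation    = c(0.33, 0.45, 0.49, 0.45, 0.75)
  )
}

#' Build a cohort simulation configuration
#'
#' Defaults describe the study conditions used throughout the package's
#' recovery experiments: five species with lifespans from 10 to 122.5 years,
#' three tissues sampled from the same animals, 100 shared age CpGs (half
#' gain, half loss of methylation) with logit slope 3 per unit relative age,
#' 20 tissue-specific age CpGs per tissue, 50 X-linked and 5 autosomal sex
#' CpGs with a 0.3 beta-scale female offset, logit noise sd 0.3, 5% fetal
#' samples, 5% per-species mappability dropout, and species-divergent
#' baselines (logit sd 0.5).
#'
#' @param species species table (default \code{\link{defaultSpeciesTable}}).
#' @param tissues tissue labels.
#' @param nCpgs,nSharedAgeCpgs,nTissueAgeCpgs,nSexCpgs,nAutosomalSexCpgs
#'   CpG counts (see \linkS4class{CohortConfig}).
#' @param effectSize,sexDelta,noiseSd,fracFetal,mappabilityDropout
#'   signal and noise parameters.
#' @param speciesBaselineSd,animalEffectSd,promoterBias,chimericSpecies,seed
#'   see \linkS4class{CohortConfig}.
#' @return a \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(species = defaultSpeciesTable(),
                         tissues = c("blood", "liver", "cortex"),
                         nCpgs = 2000L,
                         nSharedAgeCpgs = 100L,
                         nTissueAgeCpgs = 20L,
                         nSexCpgs = 50L,
                         nAutosomalSexCpgs = 5L,
                         effectSize = 3,
                         sexDelta = 0.3,
                         noiseSd = 0.3,
                         fracFetal = 0.05,
                         mappabilityDropout = 0.05,
                         speciesBaselineSd = 0.5,
                         animalEffectSd = 0,
                         promoterBias = 1,
                         chimericSpecies = character(),
                         seed = 1L) {
  new("CohortConfig", species = species, tissues = tissues,
      nCpgs = as.integer(nCpgs),
      nSharedAgeCpgs = as.integer(nSharedAgeCpgs),
      nTissueAgeCpgs = as.integer(nTissueAgeCpgs),
      nSexCpgs = as.integer(nSexCpgs),
      nAutosomalSexCpgs = as.integer(nAutosomalSexCpgs),
      effectSize = effectSize, sexDelta = sexDelta, noiseSd = noiseSd,
      fracFetal = fracFetal, mappabilityDropout = mappabilityDropout,
      speciesBaselineSd = speciesBaselineSd,
      animalEffectSd = animalEffectSd,
      promoterBias = promoterBias,
      chimericSpecies = chimericSpecies,
      seed = as.integer(seed))
}

sampleRegionClasses <- function(n, promoterBias = 1) {
  base <- c(promoter = 0.15, `5'UTR` = 0.05, exon = 0.10,
            `3'UTR` = 0.05, intron = 0.35, intergenic = 0.30)
  p <- base
  p["promoter"] <- min(1, base["promoter"] * promoterBias)
  rest <- 1 - p["promoter"]
  others <- base[-1] / sum(base[-1]) * rest
  p[-1] <- others
  sample(names(base), n, replace = TRUE, prob = p)
}

#' Simulate a multi-species, multi-tissue methylation cohort
#'
#' Ages are drawn per animal, uniform on [0, max lifespan], with a fraction
#' of animals instead sampled prenatally (age uniform on [-gestation, 0)).
#' Every animal contributes one sample per tissue, so cross-tissue analyses
#' are animal-matched. Age-related CpGs follow
#' inverse-logit(baseline + species divergence + effectSize * direction *
#' relative age) with Gaussian logit noise; relative age is
#' (age + animal effect) / max lifespan. Sex CpGs receive a beta-scale
#' offset (direction * sexDelta) in females, erased for the chimeric species.
#' Betas are clamped to [0.001, 0.999] and set to NA where a CpG is
#' unmappable in the sample's species. The same config and seed always yield
#' a bit-identical cohort.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @param nPerStratum samples (= animals) per species x tissue stratum.
#' @return a \linkS4class{MethylationCohort} whose truth record lists the
#'   planted CpG sets and directions.
#' @examples
#' cfg <- cohortConfig(nCpgs = 200L, nSexCpgs = 10L, seed = 7L)
#' sim <- simulateCohort(cfg, nPerStratum = 5)
#' @export
simulateCohort <- function(config, nPerStratum) {
  stopifnot(is(config, "CohortConfig"), nPerStratum >= 1)
  validObject(config)
  set.seed(config@seed)
  st <- config@species
  nsp <- nrow(st)
  tissues <- config@tissues
  ncpg <- config@nCpgs

  ## ---- CpG annotation and planted index sets
  ids <- sprintf("cg%05d", seq_len(ncpg))
  nsh <- config@nSharedAgeCpgs
  nta <- config@nTissueAgeCpgs
  idxShared <- seq_len(nsh)
  gain <- idxShared[seq_len(floor(nsh / 2))]
  loss <- setdiff(idxShared, gain)
  idxTissue <- lapply(seq_along(tissues), function(t)
    nsh + (t - 1L) * nta + seq_len(nta))
  names(idxTissue) <- tissues
  off <- nsh + nta * length(tissues)
  idxSexX <- if (config@nSexCpgs) off + seq_len(config@nSexCpgs) else integer()
  off <- off + config@nSexCpgs
  idxSexA <- if (config@nAutosomalSexCpgs)
    off + seq_len(config@nAutosomalSexCpgs) else integer()

  chrom <- sample(paste0("chr", 1:20), ncpg, replace = TRUE)
  chrom[idxSexX] <- "chrX"
  pos <- sample.int(1e8, ncpg, replace = TRUE)
  region <- sampleRegionClasses(ncpg)
  if (config@promoterBias != 1 && length(gain))
    region[gain] <- sampleRegionClasses(length(gain), config@promoterBias)
  cpgs <- data.frame(
    cpg_id = ids, chrom = chrom, pos = pos,
    gene = sprintf("GENE%04d", sample.int(max(500, ncpg %/% 4), ncpg,
                                          replace = TRUE)),
    region_class = region,
    tss_distance = round(stats::rnorm(ncpg, 0, 2e4)),
    stringsAsFactors = FALSE
  )

  mappable <- matrix(stats::runif(ncpg * nsp) >= config@mappabilityDropout,
                     ncpg, nsp, dimnames = list(NULL, st$species_id))

  ## baselines: sex CpGs sit mid-range so +/- sexDelta stays inside (0, 1)
  b0 <- stats::qlogis(stats::runif(ncpg, 0.10, 0.90))
  sexIdx <- c(idxSexX, idxSexA)
  if (length(sexIdx))
    b0[sexIdx] <- stats::qlogis(stats::runif(length(sexIdx), 0.35, 0.65))
  div <- matrix(stats::rnorm(ncpg * nsp, 0, config@speciesBaselineSd),
                ncpg, nsp)

  dirShared <- integer(ncpg)
  dirShared[gain] <- 1L
  dirShared[loss] <- -1L
  dirTissue <- lapply(idxTissue, function(ii)
    stats::setNames(rep_len(c(1L, -1L), length(ii)), ids[ii]))
  dirSex <- stats::setNames(sample(c(1L, -1L), length(sexIdx), replace = TRUE),
                            ids[sexIdx])

  ## ---- samples: one animal contributes one sample per tissue
  sheets <- vector("list", nsp)
  for (s in seq_len(nsp)) {
    na <- nPerStratum
    fetal <- stats::runif(na) < config@fracFetal
    age <- stats::runif(na, 0, st$max_lifespan[s])
    age[fetal] <- -stats::runif(sum(fetal), 0, st$gestation[s])
    sex <- sample(c("F", "M"), na, replace = TRUE)
    eff <- stats::rnorm(na, 0, config@animalEffectSd)
    animal <- sprintf("%s_a%03d", st$species_id[s], seq_len(na))
    sheets[[s]] <- data.frame(
      animal_id = rep(animal, times = length(tissues)),
      species_id = st$species_id[s],
      tissue = rep(tissues, each = na),
      age = rep(age, times = length(tissues)),
      sex = rep(sex, times = length(tissues)),
      animal_effect = rep(eff, times = length(tissues)),
      stringsAsFactors = FALSE
    )
  }
  samples <- do.call(rbind, sheets)
  samples$sample_id <- sprintf("s%04d", seq_len(nrow(samples)))
  samples <- samples[c("sample_id", "animal_id", "species_id", "tissue",
                       "age", "sex", "animal_effect")]
  n <- nrow(samples)
  spIdx <- match(samples$species_id, st$species_id)
  relEff <- (samples$age + samples$animal_effect) / st$max_lifespan[spIdx]

  ## ---- logit-scale means, noise, inverse-logit, sex offset, clamping
  M <- matrix(b0, ncpg, n) + div[, spIdx]
  if (config@effectSize != 0) {
    if (length(idxShared))
      M[idxShared, ] <- M[idxShared, ] +
        config@effectSize * outer(dirShared[idxShared], relEff)
    for (t in tissues) {
      ii <- idxTissue[[t]]
      sel <- samples$tissue == t
      if (length(ii) && any(sel))
        M[ii, sel] <- M[ii, sel] +
          config@effectSize * outer(unname(dirTissue[[t]]), relEff[sel])
    }
  }
  beta <- stats::plogis(M + stats::rnorm(ncpg * n, 0, config@noiseSd))
  if (config@sexDelta != 0 && length(sexIdx)) {
    female <- samples$sex == "F" &
      !(samples$species_id %in% config@chimericSpecies)
    if (any(female))
      beta[sexIdx, female] <- beta[sexIdx, female] +
        unname(dirSex) * config@sexDelta
  }
  beta <- pmin(pmax(beta, 0.001), 0.999)
  for (s in seq_len(nsp))
    beta[!mappable[, s], spIdx == s] <- NA_real_

  planted <- config@effectSize != 0 || config@sexDelta != 0
  truth <- if (planted) list(
    age_gain = ids[gain],
    age_loss = ids[loss],
    tissue_age = dirTissue,
    sex_x = dirSex[ids[idxSexX]],
    sex_autosomal = dirSex[ids[idxSexA]],
    animal_effect_sd = config@animalEffectSd,
    chimeric_species = config@chimericSpecies,
    generative_model = "logit-linear in relative age"
  ) else list()
  if (config@effectSize == 0 && planted) {
    truth$age_gain <- character()
    truth$age_loss <- character()
    truth$tissue_age <- lapply(dirTissue, function(x) x[0])
  }
  if (config@sexDelta == 0 && planted) {
    truth$sex_x <- dirSex[0]
    truth$sex_autosomal <- dirSex[0]
  }

  samples$animal_effect <- NULL
  methylationCohort(beta, samples, cpgs, st, mappable, truth)
}

#' Simulate a cohort with no planted signal
#'
#' Identical sampling design to \code{\link{simulateCohort}} but with all
#' effect sizes forced to zero: betas are pure noise around per-CpG (and
#' per-species) baselines, and the truth record is empty. Used as the
#' calibration control for EWAS type-I error and FDR checks.
#'
#' @inheritParams simulateCohort
#' @return a \linkS4class{MethylationCohort} with an empty truth record.
#' @export
simulateNullCohort <- function(config, nPerStratum) {
  stopifnot(is(config, "CohortConfig"))
  nullCfg <- config
  nullCfg@effectSize <- 0
  nullCfg@sexDelta <- 0
  nullCfg@animalEffectSd <- 0
  simulateCohort(nullCfg, nPerStratum)
}
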