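sexCohort <- function(seed = 51, nPer = 30, sexDelta = 0.3,
                      chimeric = character()) {
  cohortConfig(nCpgs = 600L, nSharedAgeCpgs = 40L, nTissueAgeCpgs = 0L,
               nSexCpgs = 50L, nAutosomalSexCpgs = 5L, sexDelta = sexDelta,
               tissues = "blood", chimericSpecies = chimeric,
               seed = as.integer(seed))
}

test_that("the stratified sex coefficient matches a normal-equations oracle", {
  set.seed(71)
  n <- 25
  age <- runif(n, 2, 20)
  sex <- rep(c("F", "M"), length.out = n)
  b <- matrix(runif(8 * n, 0.2, 0.8), 8, n)
  coh <- handCohort(b, age, sex = sex)
  tabs <- sexEwas(coh, ageBreaks = numeric())
  expect_length(tabs, 1)
  tb <- tabs[[1]]
  for (j in sample(8, 4)) {
    fit <- summary(lm(b[j, ] ~ age + I(sex == "F")))
    row <- tb[tb$cpg_id == sprintf("cg%05d", j), ]
    expect_equal(row$coef, fit$coefficients[3, 1], tolerance = 1e-10)
    expect_equal(row$p, fit$coefficients[3, 4], tolerance = 1e-10)
  }
})

test_that("planted X-linked CpGs are recovered with the planted sign", {
  sim <- simulateCohort(sexCohort(), nPer = 30)
  tabs <- suppressWarnings(sexEwas(sim))
  truth <- cohortTruth(sim)$sex_x
  hits <- 0; total <- 0
  for (tb in tabs) {
    det <- tb[tb$q < 0.05 & tb$cpg_id %in% names(truth), ]
    total <- total + length(intersect(names(truth), tb$cpg_id))
    hits <- hits + nrow(det)
    if (nrow(det))
      expect_equal(sign(det$coef), as.numeric(truth[det$cpg_id]))
  }
  expect_gt(hits / total, 0.8)
})

test_that("SMP counts split by chromosome class and direction", {
  cfg <- cohortConfig(nCpgs = 400L, nSharedAgeCpgs = 0L, nTissueAgeCpgs = 0L,
                      nSexCpgs = 30L, nAutosomalSexCpgs = 0L,
                      tissues = "blood", seed = 52L)
  sim <- simulateCohort(cfg, nPerStratum = 40)
  tabs <- suppressWarnings(sexEwas(sim, ageBreaks = numeric()))
  counts <- countSmps(tabs, cpgAnnotation(sim))
  # only X-linked effects are planted; autosomal discoveries are BH noise
  expect_true(all(counts$X_up + counts$X_down > 20))
  expect_true(all(counts$autosome_up + counts$autosome_down <= 2))
  expect_true(all(counts$Y_up + counts$Y_down == 0))
})

test_that("null cohorts yield (almost) no SMPs at 5% FDR", {
  nul <- simulateNullCohort(sexCohort(seed = 53), nPer = 30)
  tabs <- suppressWarnings(sexEwas(nul))
  counts <- countSmps(tabs, cpgAnnotation(nul))
  expect_lte(sum(counts$total), 2)
})

test_that("consensus calling counts models per CpG", {
  mk <- function(ids, q) structure(
    data.frame(cpg_id = ids, n = 30, coef = 0.1, se = 0.01, t = 1, p = q,
               q = q, direction = "up_in_female", stringsAsFactors = FALSE),
    species = "spA", tissue = "t", age_category = "all", n_samples = 30)
  tabs <- list(mk(c("cgA", "cgB"), c(0.01, 0.2)),
               mk(c("cgA", "cgC"), c(0.02, 0.01)),
               mk(c("cgA", "cgB"), c(0.5, 0.01)))
  expect_setequal(consensusSmps(tabs, 1), c("cgA", "cgB", "cgC"))
  expect_equal(consensusSmps(tabs, 2), "cgA")
  expect_length(consensusSmps(tabs, 3), 0)
  expect_error(consensusSmps(tabs, 4), "exceeds")
})

test_that("pooled sex EWAS recovers planted CpGs and splits by sign", {
  sim <- simulateCohort(sexCohort(seed = 54), nPer = 30)
  res <- pooledSexEwas(sim, pThreshold = 1e-8)
  truth <- cohortTruth(sim)$sex_x
  found <- c(res$hyper, res$hypo)
  expect_gt(length(intersect(found, names(truth))) / length(truth), 0.8)
  expect_length(intersect(res$hyper, res$hypo), 0)
  expect_setequal(found, res$table$cpg_id[res$table$p < 1e-8])
  # signs agree with the planted directions
  det <- intersect(res$hyper, names(truth))
  if (length(det)) expect_true(all(truth[det] == 1))
})

test_that("the sex predictor recovers sex and serializes exactly", {
  sim <- simulateCohort(sexCohort(seed = 55), nPer = 20)
  pr <- fitSexPredictor(sim, seed = 2L)
  pred <- predictSex(pr, sim)
  expect_gt(mean(pred$label == pred$sex), 0.98)
  f <- tempfile()
  writeClock(pr, f)
  back <- readClock(f)
  expect_s4_class(back, "SexPredictor")
  expect_equal(back@weights, pr@weights)
  expect_equal(predictSex(back, sim)$prob_female, pred$prob_female,
               tolerance = 1e-12)
})

test_that("predictor weights concentrate on planted sex CpGs when noise vanishes", {
  cfg <- cohortConfig(nCpgs = 300L, nSharedAgeCpgs = 0L, nTissueAgeCpgs = 0L,
                      nSexCpgs = 20L, nAutosomalSexCpgs = 0L, noiseSd = 0.01,
                      effectSize = 0, tissues = "blood", seed = 56L)
  sim <- simulateCohort(cfg, nPerStratum = 30)
  pr <- fitSexPredictor(sim, seed = 3L)
  planted <- names(cohortTruth(sim)$sex_x)
  expect_true(all(names(pr@weights) %in% planted))
})

test_that("probability exactly 0.5 labels a sample unknown", {
  pr <- new("SexPredictor", intercept = 0,
            weights = setNames(numeric(), character()), alpha = 0.5,
            lambda = 0.1, trainingMeans = numeric(), meta = list())
  coh <- handCohort(matrix(0.5, 2, 4), age = 1:4)
  out <- predictSex(pr, coh)
  expect_equal(out$prob_female, rep(0.5, 4))
  expect_equal(out$label, rep("unknown", 4))
})

test_that("one-class training is rejected", {
  coh <- handCohort(matrix(runif(40), 2), age = 1:20,
                    sex = rep("F", 20))
  expect_error(fitSexPredictor(coh), "both sexes")
})
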