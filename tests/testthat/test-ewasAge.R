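test_that("exact-zero correlation gives t = 0, Z = 0, p = 1", {
  b <- rbind(c(0.2, 0.3, 0.3, 0.2), runif(4, 0.3, 0.7))
  coh <- handCohort(b, age = c(1, 2, 3, 4))
  ew <- correlationEwas(coh, "spA", minN = 4)
  row <- ew[ew$cpg_id == "cg00001", ]
  expect_equal(row$r, 0)
  expect_equal(row$t, 0)
  expect_equal(row$Z, 0)
  expect_equal(row$p, 1)
})

test_that("t statistic follows its closed form (n = 12, r = 0.6)", {
  r <- 0.6; n <- 12
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  expect_equal(t, 2.371708, tolerance = 1e-6)
})

test_that("a perfectly age-tracking CpG saturates Z with a flag", {
  age <- seq(1, 100)
  b <- rbind(0.04 + 0.9 * (age - 1) / 99, matrix(runif(200, .3, .7), 2))
  coh <- handCohort(b, age)
  ew <- correlationEwas(coh, "spA")
  row <- ew[ew$cpg_id == "cg00001", ]
  expect_equal(row$flag, "saturated")
  expect_true(is.finite(row$Z))
  expect_gt(row$Z, 38)
  expect_gt(row$p, 0)
})

test_that("zero-variance CpGs are flagged and neutral", {
  b <- rbind(rep(0.5, 10), matrix(runif(20, .2, .8), 2))
  coh <- handCohort(b, age = 1:10)
  ew <- correlationEwas(coh, "spA")
  row <- ew[ew$cpg_id == "cg00001", ]
  expect_equal(row$flag, "zero_variance")
  expect_equal(row$p, 1)
  expect_equal(row$Z, 0)
})

test_that("Stouffer combination matches its closed form", {
  expect_equal(stoufferZ(c(1.96, 1.96))$z, 3.92 / sqrt(2), tolerance = 1e-9)
  expect_equal(stoufferZ(2.5)$z, 2.5)
  expect_equal(stoufferZ(2.5)$p, 2 * pnorm(-2.5))
  expect_error(stoufferZ(numeric()), "at least one")
  expect_error(stoufferZ(c(1, Inf)), "finite")
})

test_that("null Stouffer meta Z scores are standard normal", {
  set.seed(61)
  zmeta <- replicate(800, stoufferZ(rnorm(4))$z)
  expect_gt(ks.test(zmeta, "pnorm")$p.value, 0.01)
})

mkTable <- function(ids, z, species, tissue, n = 30) {
  structure(data.frame(cpg_id = ids, n = n, r = 0, t = 0,
                       p = 2 * pnorm(-abs(z)), Z = z, q = NA, flag = "",
                       stringsAsFactors = FALSE),
            species = species, tissue = tissue, n_samples = n)
}

test_that("a one-stratum meta-analysis is the identity", {
  tb <- mkTable(c("cgA", "cgB"), c(1.2, -0.7), "spA", "blood")
  mr <- twoStageMeta(list(tb))
  expect_equal(mr$Z_meta, tb$Z)
  expect_equal(mr$k, c(1L, 1L))
})

test_that("equal Z in a 2x2 species-tissue grid meta-combines to 2z", {
  z <- 1.3
  tabs <- list(
    mkTable("cgA", z, "spA", "blood"), mkTable("cgA", z, "spA", "liver"),
    mkTable("cgA", z, "spB", "blood"), mkTable("cgA", z, "spB", "liver"))
  mr <- twoStageMeta(tabs)
  # stage 1 per species: 2z/sqrt(2) = z*sqrt(2); stage 2: 2*z*sqrt(2)/sqrt(2)
  expect_equal(mr$Z_meta, 2 * z)
  expect_equal(mr$k, 4L)
})

test_that("two-stage meta matches a brute-force tree traversal", {
  set.seed(31)
  ids <- sprintf("cg%03d", 1:40)
  strata <- expand.grid(sp = c("spA", "spB", "spC"),
                        ti = c("blood", "liver"), stringsAsFactors = FALSE)
  tabs <- lapply(seq_len(nrow(strata)), function(i) {
    keep <- sample(ids, 30)  # CpGs missing from some strata
    mkTable(keep, rnorm(30), strata$sp[i], strata$ti[i])
  })
  mr <- twoStageMeta(tabs)
  # independent oracle: walk the tree explicitly per CpG
  for (cg in sample(ids, 12)) {
    z1 <- c()
    for (sp in unique(strata$sp)) {
      zs <- unlist(lapply(tabs, function(tb) {
        if (!identical(attr(tb, "species"), sp)) return(NULL)
        tb$Z[tb$cpg_id == cg]
      }))
      if (length(zs)) z1 <- c(z1, sum(zs) / sqrt(length(zs)))
    }
    expected <- sum(z1) / sqrt(length(z1))
    expect_equal(mr$Z_meta[mr$cpg_id == cg], expected, tolerance = 1e-12)
  }
  # stratum order must not matter
  mr2 <- twoStageMeta(rev(tabs))
  expect_equal(mr2$Z_meta[match(mr$cpg_id, mr2$cpg_id)], mr$Z_meta)
})

test_that("a flat one-species tree equals plain Stouffer over tissues", {
  set.seed(17)
  ids <- sprintf("cg%03d", 1:20)
  tabs <- lapply(c("blood", "liver", "skin"), function(ti)
    mkTable(ids, rnorm(20), "spA", ti))
  mr <- twoStageMeta(tabs)
  plain <- vapply(seq_along(ids), function(i)
    stoufferZ(c(tabs[[1]]$Z[i], tabs[[2]]$Z[i], tabs[[3]]$Z[i]))$z,
    numeric(1))
  expect_equal(mr$Z_meta[match(ids, mr$cpg_id)], plain)
})

test_that("small strata are excluded by the N >= 10 rule", {
  tabs <- list(mkTable("cgA", 2, "spA", "blood", n = 30),
               mkTable("cgA", 9, "spA", "liver", n = 6))
  expect_message(mr <- twoStageMeta(tabs), "excluded")
  expect_equal(mr$Z_meta, 2)
})

test_that("pooled species merge into one pseudo-species at stage 1", {
  z <- 1.5
  tabs <- list(mkTable("cgA", z, "lemur1", "blood"),
               mkTable("cgA", z, "lemur2", "blood"),
               mkTable("cgA", z, "spB", "blood"))
  mr <- twoStageMeta(tabs, pooledSpecies = c("lemur1", "lemur2"))
  # pooled stage 1: 2z/sqrt(2); stage 2 over {pooled, spB}: (z*sqrt(2)+z)/sqrt(2)
  expect_equal(mr$Z_meta, (z * sqrt(2) + z) / sqrt(2))
})

test_that("top-CpG selection filters, orders and truncates deterministically", {
  set.seed(41)
  n <- 700
  tb <- data.frame(cpg_id = sprintf("cg%04d", 1:n),
                   p = runif(n, 1e-9, 5e-5),
                   Z = abs(rnorm(n)) + 0.1, stringsAsFactors = FALSE)
  got <- selectTopCpgs(tb, "gain", maxK = 500, pThreshold = 1e-4)
  expect_length(got, 500)
  expect_equal(got, tb$cpg_id[order(tb$p)][1:500])
  expect_length(selectTopCpgs(tb, "loss"), 0)  # all Z positive
  tb$p <- 0.5
  expect_length(selectTopCpgs(tb, "gain"), 0)
  # ties broken by |Z| then id
  tie <- data.frame(cpg_id = c("cgB", "cgA", "cgC"), p = c(1e-6, 1e-6, 1e-6),
                    Z = c(3, 3, 5), stringsAsFactors = FALSE)
  expect_equal(selectTopCpgs(tie, "gain"), c("cgC", "cgA", "cgB"))
})

test_that("top-list overlap machinery follows the hypergeometric model", {
  ids <- sprintf("cg%05d", 1:2000)
  a <- ids[1:500]
  expect_equal(overlapTopLists(a, a, 2000)$overlap, 500)
  dis <- overlapTopLists(ids[1:500], ids[501:1000], 2000)
  expect_equal(dis$overlap, 0)
  expect_gt(dis$p, 0.999)
  expect_error(overlapTopLists(c("a", "a"), "b", 100), "duplicate")
})
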