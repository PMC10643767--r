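# shared fixture builders; everything is generated in code at test time

tinySpecies <- function() {
  makeSpeciesTable(
    species_id = c("spA", "spB"),
    max_lifespan = c(20, 60),
    maturity_age = c(3, 8),
    gestation = c(0.4, 0.6)
  )
}

# hand-built cohort with full control over betas
handCohort <- function(betas, age, species = "spA", tissue = "t1",
                       sex = NULL, speciesTab = tinySpecies()) {
  n <- ncol(betas)
  if (is.null(sex)) sex <- rep(c("F", "M"), length.out = n)
  samples <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    animal_id = sprintf("a%03d", seq_len(n)),
    species_id = rep(species, length.out = n),
    tissue = rep(tissue, length.out = n),
    age = age, sex = sex,
    stringsAsFactors = FALSE
  )
  p <- nrow(betas)
  cpgs <- data.frame(
    cpg_id = sprintf("cg%05d", seq_len(p)),
    chrom = rep("chr1", p), pos = seq_len(p) * 1000L,
    gene = sprintf("G%03d", seq_len(p)),
    region_class = rep("intron", p), tss_distance = 0L,
    stringsAsFactors = FALSE
  )
  methylationCohort(betas, samples, cpgs, speciesTab)
}

# one causal CpG carrying a rescaled transform of age, the rest pure noise
causalCohort <- function(n = 100, p = 50, seed = 33) {
  set.seed(seed)
  age <- runif(n, 0, 20)
  y <- sqrt(age + 1)
  causal <- 0.05 + 0.9 * (y - min(y)) / diff(range(y))
  betas <- matrix(runif(p * n, 0.2, 0.8), p, n)
  betas[1, ] <- causal
  handCohort(betas, age)
}
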