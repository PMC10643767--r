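# independent oracle: exact two-sided Fisher p by hypergeometric enumeration
enumFisherP <- function(a, b, cc, d) {
  m <- a + cc; k <- a + b; N <- a + b + cc + d
  xs <- max(0, k - (N - m)):min(k, m)
  probs <- dhyper(xs, m, N - m, k)
  pobs <- dhyper(a, m, N - m, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

test_that("the worked 2x2 example reproduces its odds ratio and exact p", {
  # table [[10, 490], [490, 19010]] built from synthetic id sets
  universe <- sprintf("cg%05d", 1:20000)
  ann <- data.frame(cpg_id = universe,
                    region_class = c(rep("promoter", 500),
                                     rep("intron", 19500)),
                    stringsAsFactors = FALSE)
  top <- c(universe[1:10], universe[501:990])
  res <- regionEnrichment(top, ann)
  row <- res[res$region_class == "promoter", ]
  expect_equal(row$count_in_set, 10)
  expect_equal(row$odds_ratio, (10 * 19010) / (490 * 490), tolerance = 1e-12)
  expect_equal(row$fisher_p, enumFisherP(10, 490, 490, 19010),
               tolerance = 1e-12)
})

test_that("Fisher p matches exhaustive enumeration on random small tables", {
  set.seed(91)
  for (i in 1:60) {
    N <- sample(20:400, 1)
    m <- sample.int(min(200, N - 1), 1)
    k <- sample.int(min(200, N - 1), 1)
    xs <- max(0, k - (N - m)):min(k, m)
    for (a in sample(xs, min(4, length(xs)))) {
      b <- k - a; cc <- m - a; d <- N - m - b
      p <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
      expect_equal(p, enumFisherP(a, b, cc, d), tolerance = 1e-12)
    }
  }
})

test_that("a uniformly drawn top set shows no enrichment", {
  set.seed(92)
  ann <- data.frame(cpg_id = sprintf("cg%05d", 1:4000),
                    region_class = sample(c("promoter", "exon", "intron",
                                            "intergenic"), 4000, TRUE,
                                          prob = c(.15, .15, .4, .3)),
                    stringsAsFactors = FALSE)
  top <- sample(ann$cpg_id, 300)
  res <- regionEnrichment(top, ann)
  expect_true(all(res$odds_ratio > 0.5 & res$odds_ratio < 2))
  expect_gte(sum(res$fisher_p > 0.05), nrow(res) - 1)
  expect_equal(sum(res$count_in_set), 300)  # classes partition the set
})

test_that("zero cells get a flagged Haldane-corrected odds ratio", {
  ann <- data.frame(cpg_id = sprintf("cg%03d", 1:100),
                    region_class = c(rep("promoter", 10), rep("intron", 90)),
                    stringsAsFactors = FALSE)
  top <- ann$cpg_id[11:20]  # no promoter members
  res <- regionEnrichment(top, ann)
  row <- res[res$region_class == "promoter", ]
  expect_true(row$haldane)
  expect_equal(row$odds_ratio, (0.5 * 80.5) / (10.5 * 10.5))
  expect_warning(regionEnrichment(character(), ann), "empty")
  expect_error(regionEnrichment("not_there", ann), "background")
})

toyGenes <- function() {
  data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(10000, 50000, 8000), end = c(20000, 64000, 30000),
    strand = c("+", "-", "+"),
    gene = c("G1", "G2", "G3"),
    cds_start = c(12000, 52000, 9000), cds_end = c(18000, 62000, 29000),
    exon_starts = c("10000,15000", "50000,60000", "8000"),
    exon_ends = c("13000,17000", "53000,64000", "30000"),
    stringsAsFactors = FALSE
  )
}

test_that("promoter windows and precedence classify canonical positions", {
  gm <- toyGenes()
  cpgs <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr9"),
    pos = c(8000,   # 2 kb upstream of G1 (+) TSS -> promoter
            16000,  # inside exon 2 of G1, beyond promoter window -> exon
            14000,  # in G1 body, not in exon -> intron
            10500,  # exonic and < cds_start but within promoter window
            51000,  # exon 1 of minus-strand G2, below cds_start -> 3'UTR
            500))   # contig without genes -> intergenic, flagged
  cls <- annotateRegionClass(cpgs, gm)
  expect_equal(cls[1], "promoter")
  expect_equal(cls[2], "exon")
  expect_equal(cls[3], "intron")
  expect_equal(cls[4], "promoter")  # promoter outranks 5'UTR
  expect_equal(cls[5], "3'UTR")
  expect_equal(cls[6], "intergenic")
  expect_true(attr(cls, "unplaced_contig")[6])
})

test_that("classification equals an exhaustive per-gene membership oracle", {
  set.seed(93)
  gm <- toyGenes()
  cpgs <- data.frame(chrom = sample(c("chr1", "chr2"), 300, TRUE),
                     pos = sample.int(70000, 300))
  got <- annotateRegionClass(cpgs, gm)
  prec <- c(promoter = 1, `5'UTR` = 2, exon = 3, `3'UTR` = 4,
            intron = 5, intergenic = 6)
  for (i in seq_len(nrow(cpgs))) {
    best <- "intergenic"
    for (g in seq_len(nrow(gm))) {
      if (cpgs$chrom[i] != gm$chrom[g]) next
      p <- cpgs$pos[i]
      tss <- if (gm$strand[g] == "+") gm$start[g] else gm$end[g]
      promo <- if (gm$strand[g] == "+")
        p >= tss - 5000 && p < tss + 1000
      else p >= tss - 1000 && p < tss + 5000
      es <- as.numeric(strsplit(gm$exon_starts[g], ",")[[1]])
      ee <- as.numeric(strsplit(gm$exon_ends[g], ",")[[1]])
      inExon <- any(p >= es & p < ee) && p >= gm$start[g] && p < gm$end[g]
      inBody <- p >= gm$start[g] && p < gm$end[g]
      cls <- if (promo) "promoter"
      else if (inExon && gm$strand[g] == "+" && p < gm$cds_start[g]) "5'UTR"
      else if (inExon && gm$strand[g] == "-" && p >= gm$cds_end[g]) "5'UTR"
      else if (inExon && gm$strand[g] == "+" && p >= gm$cds_end[g]) "3'UTR"
      else if (inExon && gm$strand[g] == "-" && p < gm$cds_start[g]) "3'UTR"
      else if (inExon) "exon"
      else if (inBody) "intron"
      else "intergenic"
      if (prec[cls] < prec[best]) best <- cls
    }
    expect_equal(got[i], best, info = paste("cpg", i))
  }
})
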