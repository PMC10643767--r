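#' Per-stratum correlation EWAS of age
#'
#' For one species x tissue stratum, screens every mappable CpG for
#' correlation with age: pairwise-complete Pearson r, the t statistic
#' t = r * sqrt(n - 2) / sqrt(1 - r^2), a two-sided p from the t distribution
#' with n - 2 degrees of freedom, the signed Z statistic
#' Z = sign(r) * qnorm(1 - p/2) — standard normal under the null of zero
#' correlation, with positive values meaning age-related gain of
#' methylation — and Benjamini-Hochberg q within the stratum. Z is capped at
#' the largest finite normal quantile when p underflows (flag
#' \code{saturated}); zero-variance CpGs are emitted with p = 1, Z = 0 and
#' flag \code{zero_variance}.
#'
#' @param cohort a \linkS4class{MethylationCohort}.
#' @param species species_id, or a character vector of species to pool into
#'   one stratum (as done for strepsirrhines).
#' @param tissue optional tissue label; default uses all tissues of the
#'   species (one stratum).
#' @param minN minimum pairwise-complete samples per CpG (default 4).
#' @return data.frame (one row per tested CpG) with cpg_id, n, r, t, p, Z,
#'   q and flag, carrying attributes \code{species}, \code{tissue} and
#'   \code{n_samples}.
#' @export
correlationEwas <- function(cohort, species, tissue = NULL, minN = 4) {
  sheet <- sampleSheet(cohort)
  keep <- sheet$species_id %in% species
  if (!is.null(tissue)) keep <- keep & sheet$tissue %in% tissue
  if (!any(keep))
    stop("no samples in stratum ", paste(species, collapse = "+"),
         if (!is.null(tissue)) paste0(" / ", tissue))
  age <- sheet$age[keep]
  map <- mappability(cohort)[, intersect(species, colnames(mappability(cohort))),
                             drop = FALSE]
  testable <- rowSums(map) > 0
  B <- betas(cohort)[testable, keep, drop = FALSE]
  rc <- rowCorWithY(B, age)
  ok <- rc$n >= minN
  r <- rc$r[ok]
  n <- rc$n[ok]
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  flag <- rep("", length(r))
  zerovar <- is.na(r)
  degenerate <- !zerovar & abs(r) >= 1
  p[zerovar] <- 1
  tstat[zerovar] <- 0
  p[degenerate] <- 0
  sz <- signedZ(r, p)
  z <- sz$z
  z[zerovar] <- 0
  flag[zerovar] <- "zero_variance"
  flag[sz$saturated | degenerate] <- "saturated"
  p <- ifelse(zerovar, 1, pmax(p, 1e-320))
  res <- data.frame(
    cpg_id = rownames(B)[ok], n = n, r = r, t = tstat, p = p, Z = z,
    q = stats::p.adjust(p, method = "BH"), flag = flag,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, species = species, tissue = tissue,
            n_samples = sum(keep))
}

#' Unweighted Stouffer combination of Z scores
#'
#' @param z numeric vector of finite Z scores (k >= 1).
#' @return list with \code{z} = sum(z)/sqrt(k) and the two-sided
#'   \code{p} = 2 * pnorm(-|z|).
#' @examples
#' stoufferZ(c(1.96, 1.96))$z  # 2.7719
#' @export
stoufferZ <- function(z) {
  if (!length(z)) stop("stoufferZ requires at least one Z score")
  if (any(!is.finite(z))) stop("all Z scores must be finite")
  zm <- sum(z) / sqrt(length(z))
  list(z = zm, p = 2 * stats::pnorm(-abs(zm)))
}

#' Two-stage Stouffer meta-analysis of per-stratum EWAS results
#'
#' Stage 1 combines Z scores across tissues within each species; stage 2
#' combines the species-level Z scores into the final meta-analytic Z, both
#' by the unweighted Stouffer method (a single-stratum combination is the
#' identity). Strata with fewer than \code{minN} samples are excluded.
#' Species listed in \code{pooledSpecies} are merged into one pseudo-species
#' ("pooled") before stage 1, mirroring the treatment of strepsirrhine
#' species too small to analyze individually; a stratum that mixes pooled
#' and unpooled species is a configuration error. A CpG absent from a
#' stratum simply contributes nothing there.
#'
#' @param tables list of EWAS tables from \code{\link{correlationEwas}}.
#' @param pooledSpecies character vector of species to merge.
#' @param minN minimum per-stratum sample size (default 10).
#' @return data.frame with cpg_id, k (number of contributing strata),
#'   Z_meta and p_meta, with the stratification tree in attribute
#'   \code{tree}.
#' @export
twoStageMeta <- function(tables, pooledSpecies = character(), minN = 10) {
  stopifnot(length(tables) >= 1)
  nS <- vapply(tables, function(t) attr(t, "n_samples"), numeric(1))
  drop <- nS < minN
  if (any(drop)) {
    message(sum(drop), " stratum/strata excluded (fewer than ", minN,
            " samples)")
    tables <- tables[!drop]
  }
  if (!length(tables))
    stop("no stratum meets the minimum sample size of ", minN)
  key <- vapply(tables, function(t) {
    sp <- attr(t, "species")
    inPool <- sp %in% pooledSpecies
    if (any(inPool) && !all(inPool))
      stop("stratum mixes pooled and unpooled species: ",
           paste(sp, collapse = "+"))
    if (all(inPool) && length(pooledSpecies)) "pooled"
    else paste(sp, collapse = "+")
  }, character(1))
  tree <- split(vapply(tables, function(t) paste0(
    paste(attr(t, "species"), collapse = "+"), ":",
    if (is.null(attr(t, "tissue"))) "all" else attr(t, "tissue")),
    character(1)), key)

  ## stage 1: per species, Stouffer across its strata
  allCpgs <- unique(unlist(lapply(tables, `[[`, "cpg_id")))
  stage1 <- matrix(NA_real_, length(allCpgs), length(unique(key)),
                   dimnames = list(allCpgs, unique(key)))
  kContrib <- stats::setNames(integer(length(allCpgs)), allCpgs)
  for (sk in unique(key)) {
    zs <- matrix(NA_real_, length(allCpgs), sum(key == sk),
                 dimnames = list(allCpgs, NULL))
    for (j in seq_len(sum(key == sk))) {
      tb <- tables[key == sk][[j]]
      zs[tb$cpg_id, j] <- tb$Z
    }
    kHere <- rowSums(!is.na(zs))
    kContrib <- kContrib + kHere
    has <- kHere > 0
    stage1[has, sk] <- rowSums(zs[has, , drop = FALSE], na.rm = TRUE) /
      sqrt(kHere[has])
  }
  ## stage 2: Stouffer across species-level Zs
  k2 <- rowSums(!is.na(stage1))
  zMeta <- rowSums(stage1, na.rm = TRUE) / sqrt(pmax(k2, 1))
  keep <- k2 > 0
  res <- data.frame(
    cpg_id = allCpgs[keep],
    k = unname(kContrib[keep]),
    Z_meta = unname(zMeta[keep]),
    p_meta = 2 * stats::pnorm(-abs(unname(zMeta[keep]))),
    stringsAsFactors = FALSE)
  structure(res, tree = tree)
}

#' Select the top age-associated CpGs in one direction
#'
#' Keeps CpGs whose Z sign matches the requested direction (positive Z =
#' gain of methylation with age) and whose p-value is below the threshold,
#' sorts by p ascending with deterministic tie-breaking (larger |Z| first,
#' then lexicographic cpg_id) and truncates at \code{maxK}.
#'
#' @param x an EWAS table (columns p, Z) or meta-analysis result (columns
#'   p_meta, Z_meta).
#' @param direction "gain" or "loss".
#' @param maxK maximum list length (default 500).
#' @param pThreshold nominal p-value threshold (default 1e-4).
#' @return character vector of cpg_ids (possibly empty).
#' @export
selectTopCpgs <- function(x, direction = c("gain", "loss"), maxK = 500,
                          pThreshold = 1e-4) {
  direction <- match.arg(direction)
  p <- if ("p_meta" %in% names(x)) x$p_meta else x$p
  z <- if ("Z_meta" %in% names(x)) x$Z_meta else x$Z
  want <- if (direction == "gain") z > 0 else z < 0
  sel <- which(want & p < pThreshold)
  if (!length(sel)) return(character())
  ord <- order(p[sel], -abs(z[sel]), x$cpg_id[sel])
  utils::head(x$cpg_id[sel][ord], maxK)
}

#' Overlap of two top-CpG lists
#'
#' @param listA,listB character vectors of cpg_ids without duplicates, drawn
#'   from a shared universe.
#' @param universeSize number of CpGs in the shared universe.
#' @return list with \code{overlap}, the hypergeometric \code{expected}
#'   overlap |A||B|/N, and the upper-tail hypergeometric enrichment
#'   \code{p} for an overlap at least as large.
#' @export
overlapTopLists <- function(listA, listB, universeSize) {
  if (anyDuplicated(listA) || anyDuplicated(listB))
    stop("top lists must not contain duplicate cpg_ids")
  if (length(listA) > universeSize || length(listB) > universeSize)
    stop("lists cannot be larger than the universe")
  ov <- length(intersect(listA, listB))
  list(
    overlap = ov,
    expected = length(listA) * length(listB) / universeSize,
    p = stats::phyper(ov - 1, length(listA), universeSize - length(listA),
                      length(listB), lower.tail = FALSE))
}
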