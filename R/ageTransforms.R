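#' Create an age transformation
#'
#' Convenience constructor for \linkS4class{AgeTransform}. When a
#' \linkS4class{MethylationCohort} is supplied, the per-species maturity and
#' lifespan maps are filled from its species table.
#'
#' @param kind one of \code{"identity"}, \code{"sqrt_offset"},
#'   \code{"loglinear"}, \code{"relative"}.
#' @param offset offset in years for \code{"sqrt_offset"}; the default of 1
#'   year keeps fetal samples (negative ages) in domain.
#' @param maturity named numeric vector, species_id to maturity age in years
#'   (required for \code{"loglinear"} unless \code{cohort} is given).
#' @param lifespan named numeric vector, species_id to maximum lifespan in
#'   years (required for \code{"relative"} unless \code{cohort} is given).
#' @param cohort optional \linkS4class{MethylationCohort} whose species table
#'   supplies \code{maturity} and \code{lifespan}.
#' @return an \linkS4class{AgeTransform}.
#' @examples
#' tr <- ageTransform("sqrt_offset")
#' transformAge(3, "any", tr)  # sqrt(3 + 1) = 2
#' @export
ageTransform <- function(kind = c("identity", "sqrt_offset", "loglinear",
                                  "relative"),
                         offset = 1, maturity = numeric(),
                         lifespan = numeric(), cohort = NULL) {
  kind <- match.arg(kind)
  if (!is.null(cohort)) {
    st <- speciesTable(cohort)
    if (!length(maturity))
      maturity <- stats::setNames(st$maturity_age, st$species_id)
    if (!length(lifespan))
      lifespan <- stats::setNames(st$max_lifespan, st$species_id)
  }
  new("AgeTransform", kind = kind, offset = offset,
      maturity = maturity, lifespan = lifespan)
}

lookupSpecies <- function(map, species, what) {
  unknown <- setdiff(unique(species), names(map))
  if (length(unknown))
    stop("species absent from the transform's ", what, " map: ",
         paste(unknown, collapse = ", "))
  unname(map[species])
}

#' Transform chronological age
#'
#' Applies the transform to ages in years: identity returns age;
#' \code{sqrt_offset} returns sqrt(age + offset); \code{relative} returns
#' age / max lifespan of the species; \code{loglinear} returns
#' log(age + 1) - log(m + 1) for age <= m and (age - m)/(m + 1) above the
#' species' maturity age m. Every transform is continuous and strictly
#' increasing on its domain.
#'
#' @param age numeric vector of ages in years (negative for fetal samples).
#' @param species character vector of species_id (recycled if length 1);
#'   ignored by identity and sqrt_offset.
#' @param spec an \linkS4class{AgeTransform}.
#' @return numeric vector of transformed ages.
#' @export
transformAge <- function(age, species, spec) {
  stopifnot(is(spec, "AgeTransform"))
  if (length(species) == 1) species <- rep(species, length(age))
  switch(spec@kind,
    identity = age,
    sqrt_offset = {
      bad <- which(age < -spec@offset)
      if (length(bad))
        stop("age below -offset (", -spec@offset, " years) for sample(s): ",
             paste(bad, collapse = ", "))
      sqrt(age + spec@offset)
    },
    relative = age / lookupSpecies(spec@lifespan, species, "lifespan"),
    loglinear = {
      bad <- which(age <= -1)
      if (length(bad))
        stop("loglinear requires age > -1 year; offending sample(s): ",
             paste(bad, collapse = ", "))
      m <- lookupSpecies(spec@maturity, species, "maturity")
      ifelse(age <= m,
             log(age + 1) - log(m + 1),
             (age - m) / (m + 1))
    })
}

#' Invert an age transformation
#'
#' Exact inverse of \code{\link{transformAge}} on its domain, used to report
#' DNAm age in years: \code{sqrt_offset} maps y to y^2 - offset (requires
#' y >= 0); \code{relative} maps y to y * max lifespan; \code{loglinear}
#' inverts its piecewise form ((m + 1) * exp(y) - 1 for y <= 0,
#' y * (m + 1) + m above).
#'
#' @inheritParams transformAge
#' @param y numeric vector on the transformed scale.
#' @return numeric vector of ages in years.
#' @export
inverseTransformAge <- function(y, species, spec) {
  stopifnot(is(spec, "AgeTransform"))
  if (length(species) == 1) species <- rep(species, length(y))
  switch(spec@kind,
    identity = y,
    sqrt_offset = {
      bad <- which(y < 0)
      if (length(bad))
        stop("sqrt_offset inverse requires y >= 0; offending value(s) at: ",
             paste(bad, collapse = ", "))
      y^2 - spec@offset
    },
    relative = y * lookupSpecies(spec@lifespan, species, "lifespan"),
    loglinear = {
      m <- lookupSpecies(spec@maturity, species, "maturity")
      ifelse(y <= 0,
             (m + 1) * exp(y) - 1,
             y * (m + 1) + m)
    })
}
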