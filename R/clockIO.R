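#' Write a clock or sex predictor to a coefficient file
#'
#' The file mirrors published clock-coefficient tables: a commented header
#' (name, transform tag and parameters, alpha, selected penalty) followed by
#' CSV rows \code{cpg_id,coefficient,training_mean}, with the first row
#' carrying the intercept. All numbers are written with 17 significant
#' digits so save/load round-trips are exact. Sex predictors use the
#' transform tag \code{logit-sex}.
#'
#' @param model a \linkS4class{MethylationClock} or \linkS4class{SexPredictor}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeClock <- function(model, path) {
  if (is(model, "MethylationClock")) {
    tr <- model@transform
    hdr <- c(
      paste0("# name: ", model@name),
      paste0("# transform: ", tr@kind),
      paste0("# offset: ", fmtNum(tr@offset)),
      paste0("# maturity: ", fmtMap(tr@maturity)),
      paste0("# lifespan: ", fmtMap(tr@lifespan)),
      paste0("# alpha: ", fmtNum(model@alpha)),
      paste0("# lambda: ", fmtNum(model@lambda))
    )
  } else if (is(model, "SexPredictor")) {
    hdr <- c(
      "# name: sex_predictor",
      "# transform: logit-sex",
      paste0("# alpha: ", fmtNum(model@alpha)),
      paste0("# lambda: ", fmtNum(model@lambda))
    )
  } else stop("model must be a MethylationClock or SexPredictor")
  rows <- c(
    "cpg_id,coefficient,training_mean",
    paste0("Intercept,", fmtNum(model@intercept), ",NA"),
    if (length(model@weights))
      paste0(names(model@weights), ",", fmtNum(unname(model@weights)), ",",
             fmtNum(unname(model@trainingMeans[names(model@weights)])))
  )
  writeLines(c(hdr, rows), path)
  invisible(path)
}

fmtMap <- function(x) {
  if (!length(x)) return("")
  paste0(names(x), "=", fmtNum(unname(x)), collapse = ";")
}

parseMap <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric())
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
                  vapply(parts, `[`, character(1), 1))
}

#' Read a clock or sex predictor from a coefficient file
#'
#' @param path file written by \code{\link{writeClock}}.
#' @return a \linkS4class{MethylationClock}, or a \linkS4class{SexPredictor}
#'   when the transform tag is \code{logit-sex}.
#' @export
readClock <- function(path) {
  lines <- readLines(path)
  isHdr <- grepl("^#", lines)
  hdrLines <- lines[isHdr]
  kv <- regmatches(hdrLines, regexec("^# ([a-z]+): ?(.*)$", hdrLines))
  bad <- which(lengths(kv) != 3)
  if (length(bad))
    stop("malformed header at line ", which(isHdr)[bad[1]], " of ", path)
  hdr <- stats::setNames(vapply(kv, `[`, character(1), 3),
                         vapply(kv, `[`, character(1), 2))
  if (!"transform" %in% names(hdr))
    stop("missing transform tag in header of ", path)
  tag <- hdr[["transform"]]
  body <- lines[!isHdr]
  if (!length(body) || body[1] != "cpg_id,coefficient,training_mean")
    stop("expected column header at line ", sum(isHdr) + 1, " of ", path)
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  badRow <- which(lengths(rows) != 3)
  if (length(badRow))
    stop("malformed row at line ", sum(isHdr) + 1 + badRow[1], " of ", path)
  id <- vapply(rows, `[`, character(1), 1)
  coefv <- suppressWarnings(as.numeric(vapply(rows, `[`, character(1), 2)))
  if (anyNA(coefv))
    stop("non-numeric coefficient at line ",
         sum(isHdr) + 1 + which(is.na(coefv))[1], " of ", path)
  mean <- suppressWarnings(as.numeric(vapply(rows, `[`, character(1), 3)))
  if (id[1] != "Intercept")
    stop("first coefficient row must be the Intercept (line ",
         sum(isHdr) + 2, " of ", path, ")")
  intercept <- coefv[1]
  w <- stats::setNames(coefv[-1], id[-1])
  means <- stats::setNames(mean[-1], id[-1])
  if (identical(tag, "logit-sex")) {
    return(new("SexPredictor", intercept = intercept, weights = w,
               alpha = as.numeric(hdr[["alpha"]]),
               lambda = as.numeric(hdr[["lambda"]]),
               trainingMeans = means, meta = list()))
  }
  if (!tag %in% TRANSFORM_KINDS)
    stop("unknown transform tag '", tag, "' at line ",
         which(grepl("^# transform:", lines))[1], " of ", path)
  tr <- new("AgeTransform", kind = tag,
            offset = as.numeric(hdr[["offset"]]),
            maturity = parseMap(hdr[["maturity"]]),
            lifespan = parseMap(hdr[["lifespan"]]))
  new("MethylationClock",
      name = hdr[["name"]], intercept = intercept, weights = w,
      transform = tr, alpha = as.numeric(hdr[["alpha"]]),
      lambda = as.numeric(hdr[["lambda"]]), trainingMeans = means,
      meta = list())
}
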