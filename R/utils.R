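# internal numeric helpers shared across modules

## mean-impute a samples x CpGs design matrix; returns matrix + means used
imputeMatrix <- function(X, means = NULL) {
  if (is.null(means)) means <- colMeans(X, na.rm = TRUE)
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- means[nas[, 2]]
  list(X = X, means = means)
}

## Pearson r of each matrix row against y, pairwise-complete.
## Rows without missing values are handled in one matrix operation.
rowCorWithY <- function(B, y) {
  p <- nrow(B)
  r <- rep(NA_real_, p)
  n <- rowSums(!is.na(B))
  complete <- n == length(y)
  if (any(complete)) {
    Bc <- B[complete, , drop = FALSE]
    yc <- y - mean(y)
    Bm <- Bc - rowMeans(Bc)
    num <- as.vector(Bm %*% yc)
    den <- sqrt(rowSums(Bm^2) * sum(yc^2))
    r[complete] <- ifelse(den > 0, num / den, NA_real_)
  }
  for (j in which(!complete & n >= 3)) {
    ok <- !is.na(B[j, ])
    yj <- y[ok]
    bj <- B[j, ok]
    if (stats::sd(bj) > 0 && stats::sd(yj) > 0)
      r[j] <- stats::cor(bj, yj)
  }
  list(r = r, n = n)
}

## signed-Z conversion with underflow capping; returns list(z, saturated)
signedZ <- function(r, p) {
  zcap <- stats::qnorm(1e-320 / 2, lower.tail = FALSE)
  saturated <- !is.na(p) & p < 1e-320
  z <- ifelse(saturated, zcap,
              stats::qnorm(pmax(p, 1e-320) / 2, lower.tail = FALSE))
  z <- sign(r) * z
  z[is.na(r) | r == 0] <- 0
  list(z = z, saturated = saturated)
}

fmtNum <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}
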