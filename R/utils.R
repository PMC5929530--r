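# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific sub-seed from one master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the run's
#' master seed so that any stage can be reproduced in isolation. Values stay
#' below 2^31 - 1 (R's integer range).
#'
#' @param seed Master seed (single integer).
#' @param stage Integer stage index (>= 0).
#' @return An integer seed.
#' @export
split_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(stage) == 1L)
  # multiplicative congruential step (Park-Miller constants), offset by stage
  s <- (abs(as.numeric(seed)) + 1) * 48271 + 9973 * (as.numeric(stage) + 1)
  as.integer(s %% 2147483647)
}

#' Per-variant frequency of allele 1
#'
#' @param geno samples x variants dosage matrix (0/1/2, NA = missing).
#' @return Numeric vector of allele-1 frequencies (NA where fully missing).
#' @export
allele1_freq <- function(geno) {
  colMeans(geno, na.rm = TRUE) / 2
}

#' Per-variant minor allele frequency
#' @inheritParams allele1_freq
#' @export
variant_maf <- function(geno) {
  f <- allele1_freq(geno)
  pmin(f, 1 - f)
}

#' Per-variant call rate
#' @inheritParams allele1_freq
#' @export
variant_call_rate <- function(geno) colMeans(!is.na(geno))

#' Per-sample call rate
#' @inheritParams allele1_freq
#' @export
sample_call_rate <- function(geno) rowMeans(!is.na(geno))

# orient dosages so they count the minor allele of each variant
minor_dosage <- function(geno) {
  f <- allele1_freq(geno)
  flip <- which(!is.na(f) & f > 0.5)
  if (length(flip)) geno[, flip] <- 2L - geno[, flip, drop = FALSE]
  geno
}

# mean-impute missing dosages, column-wise
impute_mean <- function(geno) {
  if (!anyNA(geno)) return(geno)
  mu <- colMeans(geno, na.rm = TRUE)
  idx <- which(is.na(geno), arr.ind = TRUE)
  geno[idx] <- mu[idx[, 2L]]
  geno
}

# binary 0/1 outcome vector from a dichotomize() status vector (or pass-through)
as_case_indicator <- function(status) {
  if (is.numeric(status) || is.logical(status)) {
    y <- as.integer(status)
    if (!all(y %in% c(0L, 1L, NA))) stop("numeric outcome must be 0/1")
    return(y)
  }
  y <- rep(NA_integer_, length(status))
  y[status == "affected"] <- 1L
  y[status == "unaffected"] <- 0L
  names(y) <- names(status)
  y
}
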