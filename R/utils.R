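#' Haldane map function
#'
#' Convert between map distance (cM) and recombination fraction under the
#' Haldane (no-interference) model, the model used throughout this package
#' both when simulating crossovers and when estimating map distances.
#'
#' @param d Map distance in centiMorgans.
#' @return Recombination fraction in [0, 0.5).
#' @export
haldane <- function(d) {
  stopifnot(all(d >= 0))
  (1 - exp(-2 * d / 100)) / 2
}

#' @rdname haldane
#' @param r Recombination fraction in [0, 0.5).
#' @return Map distance in cM (capped where r approaches 0.5 by the caller).
#' @export
haldaneInverse <- function(r) {
  stopifnot(all(r >= 0), all(r < 0.5))
  -50 * log(1 - 2 * r)
}

## genotype codes used internally: 1 = AA, 2 = AB, 3 = BB (A = alfalfa allele)
GENO_LEVELS <- c("AA", "AB", "BB")

genoToCode <- function(x) {
  out <- match(x, GENO_LEVELS)
  out[x %in% c("NA", "", "-")] <- NA_integer_
  out
}

codeToGeno <- function(x) {
  out <- GENO_LEVELS[x]
  out[is.na(x)] <- "NA"
  out
}

## deterministic 32-bit polynomial hash of a string, for per-stage seeds
stableHash <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (k in v) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

#' Derive a per-stage child seed from a master seed
#'
#' Stage seeds are derived by stable string hashing so that toggling one
#' pipeline stage never shifts the randomness of another.
#'
#' @param master Master seed (integer).
#' @param stage Stage name (character scalar).
#' @return An integer seed below 2^31.
#' @export
childSeed <- function(master, stage) {
  as.integer((as.numeric(master) %% 2147483647 + stableHash(stage)) %% 2147483647)
}

## run code under a local RNG state
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## empirical quantile, type 7 (documented so permutation thresholds are
## reproducible across platforms)
quantile7 <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

fmtNum <- function(x) signif(x, 6)
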