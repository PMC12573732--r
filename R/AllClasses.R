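#' @import methods
NULL

#' F2 intercross container
#'
#' Holds the genotypes, marker map, phenotypes and (for simulated crosses)
#' the generating truth of an F2 intercross between two aphid host races.
#' Genotypes are coded 1 = AA, 2 = AB, 3 = BB with A the alfalfa-race allele;
#' missing calls are \code{NA}. The map is ordered within chromosome by
#' genetic position. Males are achiasmatic, so each individual's paternal
#' contribution is one intact F1 haplotype per chromosome; the X is modelled
#' with a single paternal haplotype genome-wide (hemizygous father), giving
#' two genotype classes at X markers.
#'
#' @slot geno integer matrix, individuals x markers.
#' @slot map data.frame with columns marker, chr, bp, cM (bp 1-based).
#' @slot pheno data.frame of clone phenotypes (may be empty).
#' @slot founders list describing F0/F1 genotypes and phase.
#' @slot truth list: simulation truth (crossovers, paternal haplotypes,
#'   marker flags, QTL genotypes), empty for real-format data.
#' @exportClass F2Cross
setClass("F2Cross", representation(
  geno = "matrix",
  map = "data.frame",
  pheno = "data.frame",
  founders = "list",
  truth = "list"
))

setValidity("F2Cross", function(object) {
  msg <- character()
  if (ncol(object@geno) != nrow(object@map))
    msg <- c(msg, "number of genotype columns must equal number of map rows")
  if (!all(c("marker", "chr", "bp", "cM") %in% names(object@map)))
    msg <- c(msg, "map must have columns marker, chr, bp, cM")
  g <- object@geno
  if (!all(g[!is.na(g)] %in% 1:3))
    msg <- c(msg, "genotype codes must be 1, 2, 3 or NA")
  bychr <- split(object@map$cM, object@map$chr)
  if (!all(vapply(bychr, function(x) !is.unsorted(x), TRUE)))
    msg <- c(msg, "map cM positions must be non-decreasing within chromosome")
  if (length(msg)) msg else TRUE
})

#' @describeIn F2Cross genotype matrix accessor
#' @param x,object an \code{F2Cross}
#' @export
genotypes <- function(x) x@geno

#' @describeIn F2Cross marker map accessor
#' @export
markerMap <- function(x) x@map

#' @describeIn F2Cross phenotype table accessor
#' @export
phenotypes <- function(x) x@pheno

#' @describeIn F2Cross simulation truth accessor
#' @export
truthRecord <- function(x) x@truth

#' @describeIn F2Cross founder genotypes accessor
#' @export
founders <- function(x) x@founders

#' @describeIn F2Cross number of F2 individuals
#' @export
nIndividuals <- function(x) nrow(x@geno)

setMethod("show", "F2Cross", function(object) {
  chr <- table(object@map$chr)
  cat("F2Cross:", nrow(object@geno), "individuals,",
      nrow(object@map), "markers on", length(chr), "chromosomes\n")
  cat("  markers/chr:", paste(names(chr), chr, sep = "=", collapse = ", "), "\n")
  if (ncol(object@pheno) > 1)
    cat("  phenotypes:", paste(setdiff(names(object@pheno), "id"), collapse = ", "), "\n")
  if (length(object@truth)) cat("  simulation truth attached\n")
  invisible(NULL)
})

#' Genotype probabilities from the achiasmatic-male intercross HMM
#'
#' Posterior genotype-class probabilities on an evaluation grid (markers plus
#' pseudo-positions), one array per chromosome (individuals x positions x
#' classes). Autosomes have three classes (AA/AB/BB), the X two.
#'
#' @slot prob list of 3-d arrays, one per chromosome.
#' @slot grid list of data.frames (pos cM, marker id or pseudo).
#' @slot error_prob genotyping error rate used in the emission model.
#' @exportClass GenoProb
setClass("GenoProb", representation(
  prob = "list", grid = "list", error_prob = "numeric"
))

setMethod("show", "GenoProb", function(object) {
  npos <- sum(vapply(object@grid, nrow, 1L))
  cat("GenoProb:", length(object@prob), "chromosomes,", npos,
      "evaluation positions, error rate", object@error_prob, "\n")
  invisible(NULL)
})

#' Single-QTL genome scan result
#'
#' Per-position LOD profile with the permutation threshold and significant
#' peaks (1.5-LOD support intervals).
#'
#' @slot lod data.frame: chr, pos, lod (plus lod_spike / lod_quant for the
#'   two-part model).
#' @slot model "nonparametric" or "twopart".
#' @slot trait trait name.
#' @slot threshold genome-wide permutation threshold (NA until computed).
#' @slot peaks data.frame of significant peaks with support intervals.
#' @slot n number of individuals used.
#' @exportClass ScanResult
setClass("ScanResult", representation(
  lod = "data.frame", model = "character", trait = "character",
  threshold = "numeric", peaks = "data.frame", n = "integer"
))

setMethod("show", "ScanResult", function(object) {
  cat("ScanResult [", object@model, "] trait:", object@trait,
      " n =", object@n, "\n")
  cat("  max LOD:", round(max(object@lod$lod), 3))
  if (!is.na(object@threshold))
    cat("  threshold:", round(object@threshold, 3))
  cat("\n")
  if (nrow(object@peaks)) {
    cat("  peaks:\n")
    print(object@peaks)
  }
  invisible(NULL)
})

#' @describeIn ScanResult LOD profile accessor
#' @param x a \code{ScanResult}
#' @export
lodProfile <- function(x) x@lod

#' @describeIn ScanResult significant peak table accessor
#' @export
scanPeaks <- function(x) x@peaks

#' @describeIn ScanResult permutation threshold accessor
#' @export
scanThreshold <- function(x) x@threshold
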