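## ---- plain-text interchange formats ----
##
## genotype CSV: rows = individuals, columns = markers, with two extra
## header rows under the marker names giving chromosome and cM (the rotated
## cross-table dialect common to QTL software); phenotype CSV: clone id +
## traits; map TSV: marker, chr, bp, cM. Floats at 6 significant digits,
## missing code "NA".

#' Write an F2 cross to genotype/phenotype/map files
#'
#' @param cross An \code{\linkS4class{F2Cross}}.
#' @param geno_file,pheno_file,map_file Output paths (NULL to skip).
#' @return Invisibly, the paths written.
#' @export
writeCross <- function(cross, geno_file = NULL, pheno_file = NULL,
                       map_file = NULL) {
  paths <- character()
  if (!is.null(geno_file)) {
    map <- cross@map
    g <- apply(cross@geno, 2, codeToGeno)
    hdr1 <- c("id", map$marker)
    hdr2 <- c("", map$chr)
    hdr3 <- c("", fmtNum(map$cM))
    body <- cbind(rownames(cross@geno), g)
    con <- file(geno_file, "w")
    writeLines(paste(hdr1, collapse = ","), con)
    writeLines(paste(hdr2, collapse = ","), con)
    writeLines(paste(hdr3, collapse = ","), con)
    apply(body, 1, function(r) writeLines(paste(r, collapse = ","), con))
    close(con)
    paths <- c(paths, geno_file)
  }
  if (!is.null(pheno_file)) {
    ph <- cross@pheno
    num <- vapply(ph, is.numeric, TRUE)
    ph[num] <- lapply(ph[num], fmtNum)
    utils::write.csv(ph, pheno_file, row.names = FALSE, quote = FALSE, na = "NA")
    paths <- c(paths, pheno_file)
  }
  if (!is.null(map_file)) {
    writeMapTSV(cross@map, map_file)
    paths <- c(paths, map_file)
  }
  invisible(paths)
}

#' Read a cross from genotype (and optional phenotype) files
#'
#' @param geno_file Genotype CSV in the dialect written by
#'   \code{\link{writeCross}}.
#' @param pheno_file Optional phenotype CSV.
#' @return An \code{\linkS4class{F2Cross}} (no founder/truth information).
#' @export
readCross <- function(geno_file, pheno_file = NULL) {
  lines <- readLines(geno_file)
  hdr <- strsplit(lines[1:3], ",")
  markers <- hdr[[1]][-1]
  chr <- hdr[[2]][-1]
  cM <- as.numeric(hdr[[3]][-1])
  body <- do.call(rbind, strsplit(lines[-(1:3)], ","))
  ids <- body[, 1]
  geno <- matrix(genoToCode(body[, -1, drop = FALSE]), nrow = nrow(body),
                 dimnames = list(ids, markers))
  map <- data.frame(marker = markers, chr = chr, bp = NA_integer_, cM = cM,
                    stringsAsFactors = FALSE)
  ph <- if (!is.null(pheno_file))
    utils::read.csv(pheno_file, stringsAsFactors = FALSE)
  else data.frame(id = ids, stringsAsFactors = FALSE)
  ord <- order(factor(map$chr, levels = unique(map$chr)), map$cM)
  new("F2Cross", geno = geno[, ord, drop = FALSE], map = map[ord, ],
      pheno = ph, founders = list(), truth = list())
}

#' @rdname writeCross
#' @param map Map data.frame (marker, chr, bp, cM).
#' @param path Output path.
#' @export
writeMapTSV <- function(map, path) {
  m <- map
  m$cM <- fmtNum(m$cM)
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname writeCross
#' @export
readMapTSV <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write suppressed regions as BED (0-based half-open)
#'
#' @param regions data.frame with chr, bp_start, bp_end (1-based inclusive
#'   marker positions; converted to 0-based half-open).
#' @param path Output path.
#' @export
writeSuppressedBED <- function(regions, path) {
  if (!nrow(regions)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  bed <- data.frame(chr = regions$chr, start = regions$bp_start - 1,
                    end = regions$bp_end)
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene table (TSV: gene, category, chr, bp)
#'
#' @param path Input path.
#' @return data.frame.
#' @export
readGeneTSV <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' Read regions from BED (bp, 0-based half-open) or a Mb-coordinate TSV
#'
#' The TSV dialect has columns region, chr, start_mb, end_mb and is
#' converted to bp (2-decimal Mb round-trips exactly).
#'
#' @param path Input path.
#' @param format "bed" or "mb_tsv".
#' @return data.frame: region, chr, start, end (bp, half-open).
#' @export
readRegions <- function(path, format = c("bed", "mb_tsv")) {
  format <- match.arg(format)
  if (format == "bed") {
    b <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    data.frame(region = if (ncol(b) >= 4) b[[4]] else sprintf("r%d", seq_len(nrow(b))),
               chr = b[[1]], start = b[[2]], end = b[[3]],
               stringsAsFactors = FALSE)
  } else {
    b <- utils::read.delim(path, stringsAsFactors = FALSE)
    data.frame(region = b$region, chr = b$chr,
               start = round(b$start_mb * 1e6), end = round(b$end_mb * 1e6),
               stringsAsFactors = FALSE)
  }
}
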