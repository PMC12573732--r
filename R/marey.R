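## ---- Marey-map rearrangement analysis ----
##
## A Marey map plots genetic position (cM) against physical position (bp)
## for one chromosome; a collinear chromosome is monotone. Blocks of markers
## that run against the trend, or jump in physical position, indicate
## rearrangements between the linkage map and the assembly.

#' Segment a Marey map into signed blocks
#'
#' Walks the physical-position sequence in map (cM) order, splitting at
#' direction changes and at physical jumps larger than
#' \code{jump_threshold_mb}; segments shorter than \code{min_block_markers}
#' are merged into their neighbours (so single displaced markers do not
#' fragment a block), and compatible adjacent segments are re-coalesced.
#' Each block's orientation is the sign of the Spearman correlation between
#' cM and bp within it; blocks of two or fewer markers inherit the
#' orientation of their neighbour. Block ids are assigned by physical order
#' in the assembly, so the returned signed sequence reads the assembly
#' arrangement in map order (e.g. \code{c(3, -1, -2)}).
#'
#' @param marey data.frame with columns cM and bp for one chromosome.
#' @param min_block_markers Minimum markers per block (default 5).
#' @param jump_threshold_mb Physical jump that forces a split (default 2).
#' @return list: \code{arrangement} (signed integer vector) and
#'   \code{blocks} (data.frame: id, sign, n, cM and bp extents).
#' @export
segmentMarey <- function(marey, min_block_markers = 5, jump_threshold_mb = 2) {
  stopifnot(all(c("cM", "bp") %in% names(marey)),
            nrow(marey) >= 2 * min_block_markers)
  m <- marey[order(marey$cM, marey$bp), ]
  bp <- m$bp
  n <- length(bp)
  jump <- jump_threshold_mb * 1e6

  ## initial split: direction change or large jump
  dirs <- sign(diff(bp))
  cut <- abs(diff(bp)) > jump
  last_dir <- 0
  for (k in seq_along(dirs)) {
    if (cut[k]) { last_dir <- 0; next }
    if (dirs[k] == 0) next
    if (last_dir != 0 && dirs[k] != last_dir) cut[k] <- TRUE
    last_dir <- dirs[k]
  }
  seg <- cumsum(c(TRUE, cut))

  merged <- TRUE
  while (merged) {
    merged <- FALSE
    sizes <- table(seg)
    small <- names(sizes)[sizes < min_block_markers]
    if (length(small) && length(sizes) > 1) {
      s <- as.integer(small[1])
      ids <- sort(unique(seg))
      pos <- match(s, ids)
      nb <- if (pos == 1) ids[2] else ids[pos - 1]
      seg[seg == s] <- nb
      merged <- TRUE
      next
    }
    ## coalesce compatible adjacent segments: same orientation and no jump
    ids <- sort(unique(seg))
    if (length(ids) > 1) {
      for (k in seq_len(length(ids) - 1)) {
        i1 <- which(seg == ids[k]); i2 <- which(seg == ids[k + 1])
        o1 <- segOrientation(m, i1); o2 <- segOrientation(m, i2)
        gap <- abs(bp[i2[1]] - bp[i1[length(i1)]])
        if (o1 == o2 && gap <= jump) {
          seg[seg == ids[k + 1]] <- ids[k]
          merged <- TRUE
          break
        }
      }
    }
  }

  ids <- sort(unique(seg))
  blocks <- do.call(rbind, lapply(ids, function(s) {
    i <- which(seg == s)
    data.frame(n = length(i), sign = segOrientation(m, i),
               cM_start = min(m$cM[i]), cM_end = max(m$cM[i]),
               bp_start = min(bp[i]), bp_end = max(bp[i]))
  }))
  ## neighbour inheritance for tiny/tied blocks
  for (k in which(blocks$sign == 0)) {
    nb <- if (k > 1) k - 1 else k + 1
    blocks$sign[k] <- if (nrow(blocks) > 1) blocks$sign[nb] else 1
    if (blocks$sign[k] == 0) blocks$sign[k] <- 1
  }
  phys_id <- rank(blocks$bp_start, ties.method = "first")
  blocks$id <- phys_id
  arrangement <- as.integer(blocks$id * blocks$sign)
  list(arrangement = arrangement,
       blocks = blocks[, c("id", "sign", "n", "cM_start", "cM_end",
                           "bp_start", "bp_end")])
}

## orientation of a marker index set: sign of Spearman cor(cM, bp); 0 if tied
segOrientation <- function(m, i) {
  if (length(i) <= 2) {
    d <- diff(m$bp[i])
    return(if (length(d) && d[1] != 0) sign(d[1]) else 0)
  }
  ct <- suppressWarnings(stats::cor(m$cM[i], m$bp[i], method = "spearman"))
  if (is.na(ct) || ct == 0) 0 else sign(ct)
}

#' Detect recombination-suppressed regions
#'
#' Maximal runs of at least 3 markers sharing one map position (identical
#' cM) whose physical span reaches \code{min_span_mb}: a stretch of genome
#' over which no crossovers were observed.
#'
#' @param marey data.frame with columns cM and bp for one chromosome.
#' @param min_span_mb Minimum physical span in Mb (default 2).
#' @return data.frame: cM, bp_start, bp_end, n_markers (possibly 0 rows).
#' @export
detectSuppression <- function(marey, min_span_mb = 2) {
  m <- marey[order(marey$cM, marey$bp), ]
  runs <- rle(m$cM)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- do.call(rbind, lapply(which(runs$lengths >= 3), function(k) {
    i <- starts[k]:ends[k]
    span <- max(m$bp[i]) - min(m$bp[i])
    if (span >= min_span_mb * 1e6)
      data.frame(cM = runs$values[k], bp_start = min(m$bp[i]),
                 bp_end = max(m$bp[i]), n_markers = length(i))
    else NULL
  }))
  if (is.null(out)) out <- data.frame(cM = numeric(), bp_start = numeric(),
                                      bp_end = numeric(), n_markers = integer())
  out
}

## apply a signed reversal of elements i..j to a signed permutation
applyReversal <- function(p, i, j) {
  p[i:j] <- -rev(p[i:j])
  p
}

#' Minimum number of inversion events explaining a block arrangement
#'
#' Minimum number of signed reversals transforming the observed signed
#' permutation into the identity (+1..+K), found by bidirectional
#' breadth-first search over signed permutations. Reversals are the only
#' move allowed (no translocation/fission/fusion), matching the counting of
#' rearrangements as inversion events.
#'
#' @param arrangement Signed integer vector; absolute values must be a
#'   permutation of 1..K, K <= 10.
#' @return Integer reversal distance.
#' @export
minInversionEvents <- function(arrangement) {
  K <- length(arrangement)
  if (!setequal(abs(arrangement), seq_len(K)))
    stop("arrangement must be a signed permutation of 1..K")
  if (K > 10)
    stop("more than 10 blocks: coarsen the segmentation before counting")
  ident <- seq_len(K)
  key <- function(p) paste(p, collapse = ",")
  if (identical(as.integer(arrangement), ident)) return(0L)
  neighbours <- function(p) {
    out <- vector("list", K * (K + 1) / 2)
    idx <- 0L
    for (i in seq_len(K)) for (j in i:K) {
      idx <- idx + 1L
      out[[idx]] <- applyReversal(p, i, j)
    }
    out
  }
  seen1 <- new.env(hash = TRUE); seen2 <- new.env(hash = TRUE)
  assign(key(arrangement), 0L, envir = seen1)
  assign(key(ident), 0L, envir = seen2)
  f1 <- list(as.integer(arrangement)); f2 <- list(ident)
  ## expand one full level of `frontier`/`own`, returning the smallest
  ## meeting distance with `other` seen in that level (or NULL)
  expandLevel <- function(frontier, own, other) {
    nxt <- list(); hit <- Inf
    for (p in frontier) {
      dp <- get(key(p), envir = own)
      for (q in neighbours(p)) {
        k <- key(q)
        if (exists(k, envir = other, inherits = FALSE))
          hit <- min(hit, dp + 1L + get(k, envir = other))
        if (!exists(k, envir = own, inherits = FALSE)) {
          assign(k, dp + 1L, envir = own)
          nxt[[length(nxt) + 1]] <- q
        }
      }
    }
    list(frontier = nxt, hit = if (is.finite(hit)) as.integer(hit) else NULL)
  }
  best <- Inf; extra <- 0L
  repeat {
    if (length(f1) <= length(f2)) {
      res <- expandLevel(f1, seen1, seen2); f1 <- res$frontier
    } else {
      res <- expandLevel(f2, seen2, seen1); f2 <- res$frontier
    }
    if (!is.null(res$hit)) best <- min(best, res$hit)
    ## one extra level after the first meeting guards against the classic
    ## bidirectional off-by-one
    if (is.finite(best)) {
      extra <- extra + 1L
      if (extra >= 2L || (!length(f1) && !length(f2))) return(as.integer(best))
    }
    if (!length(f1) || !length(f2)) {
      if (is.finite(best)) return(as.integer(best))
      stop("search exhausted without meeting")
    }
  }
}
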