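## ---- marker QC ----

#' Marker quality-control filters for F2 map building
#'
#' Applies, in order: (1) the informativeness rule - both founders of one
#' race homozygous for one allele, both founders of the other race
#' homozygous for the other, both F1s heterozygous; (2) a segregation
#' distortion chi-square against 1:2:1 (autosomes, 2 df) or the 1:1
#' two-class expectation (X, 1 df), removing markers with p below the
#' tolerance; (3) redundancy collapse - among markers with identical F2
#' genotype signatures the one with least missing data is kept. Markers with
#' an all-missing F2 column are removed first ("no_data"); markers whose
#' founder genotypes are partially missing are evaluated on the available
#' individuals and annotated "imputed_parentage".
#'
#' @param cross An \code{\linkS4class{F2Cross}} carrying founder genotypes.
#' @param p_threshold Distortion tolerance (default 0.001).
#' @return list: \code{retained} marker ids, \code{report} per-marker status
#'   table, \code{counts} removed per rule.
#' @export
filterMarkers <- function(cross, p_threshold = 0.001) {
  geno <- cross@geno
  map <- cross@map
  f0 <- cross@founders$f0
  f1 <- cross@founders$f1
  M <- ncol(geno)
  status <- rep("retained", M)
  note <- rep("", M)
  names(status) <- colnames(geno)

  hom <- c("AA", "BB")
  for (j in seq_len(M)) {
    g0 <- f0[, j]; g1 <- f1[, j]
    if (any(is.na(c(g0, g1)))) note[j] <- "imputed_parentage"
    r1 <- g0[1:2][!is.na(g0[1:2])]
    r2 <- g0[3:4][!is.na(g0[3:4])]
    fh <- g1[!is.na(g1)]
    informative <-
      length(r1) > 0 && length(r2) > 0 &&
      length(unique(r1)) == 1 && length(unique(r2)) == 1 &&
      r1[1] %in% hom && r2[1] %in% hom && r1[1] != r2[1] &&
      all(fh == "AB") && length(fh) > 0
    if (!informative) status[j] <- "uninformative"
  }
  all_missing <- colSums(!is.na(geno)) == 0
  status[all_missing] <- "no_data"

  ## (2) segregation distortion on rule-1 survivors
  isX <- map$chr %in% "X"
  for (j in which(status == "retained")) {
    g <- geno[, j]; g <- g[!is.na(g)]
    if (isX[j]) {
      cls <- sort(unique(g))
      if (length(cls) > 2) cls <- order(tabulate(g, 3), decreasing = TRUE)[1:2]
      o <- c(sum(g == cls[1]), sum(g == cls[2]))
      e <- sum(o) / 2
      stat <- sum((o - e)^2 / e)
      p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    } else {
      o <- tabulate(g, 3)
      e <- sum(o) * c(.25, .5, .25)
      stat <- sum((o - e)^2 / e)
      p <- stats::pchisq(stat, df = 2, lower.tail = FALSE)
    }
    if (p < p_threshold) status[j] <- "distorted"
  }

  ## (3) redundancy collapse on survivors
  keep <- which(status == "retained")
  sig <- apply(geno[, keep, drop = FALSE], 2, function(g)
    paste(ifelse(is.na(g), "N", g), collapse = ""))
  for (s in unique(sig[duplicated(sig)])) {
    grp <- keep[sig == s]
    nmiss <- colSums(is.na(geno[, grp, drop = FALSE]))
    drop_ <- grp[-which.min(nmiss)]
    status[drop_] <- "redundant"
  }

  report <- data.frame(marker = colnames(geno), chr = map$chr,
                       status = status, note = note,
                       stringsAsFactors = FALSE, row.names = NULL)
  counts <- table(status)
  list(retained = colnames(geno)[status == "retained"],
       report = report, counts = counts)
}

## ---- pairwise recombination fractions ----

## marker "type": 3-class autosomal, or two-class X with paternal allele A
## ("XA": classes AA/AB) or B ("XB": classes AB/BB)
markerTypes <- function(geno) {
  apply(geno, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return("auto")
    tab <- tabulate(g, 3); n <- sum(tab)
    if (tab[3] / n < 0.02 && tab[1] / n >= 0.02) "XA"
    else if (tab[1] / n < 0.02 && tab[3] / n >= 0.02) "XB"
    else "auto"
  })
}

## 3x3 cell probability tables, linear in r: T(r) = (1-r) a + r b.
## Enumerates maternal allele at locus 1, maternal recombination z, and the
## paternal configuration: one shared coin for an autosome pair (achiasmatic
## father transmits whole haplotypes), independent coin x fixed allele
## otherwise.
cellTables <- function(t1, t2) {
  codeOf <- function(ty, m, p) {
    p <- if (ty == "auto") p else substr(ty, 2, 2)
    (m == "B") + (p == "B") + 1L
  }
  a <- matrix(0, 3, 3); b <- matrix(0, 3, 3)
  for (m1 in c("A", "B")) for (z in 0:1) {
    m2 <- if (z == 0) m1 else c(A = "B", B = "A")[[m1]]
    if (t1 == "auto" && t2 == "auto") {
      pconf <- list(c("A", "A"), c("B", "B")); w <- 0.5
    } else {
      p1s <- if (t1 == "auto") c("A", "B") else "A"  # fixed allele ignored by codeOf
      p2s <- if (t2 == "auto") c("A", "B") else "A"
      pconf <- list()
      for (p1 in p1s) for (p2 in p2s) pconf[[length(pconf) + 1]] <- c(p1, p2)
      w <- 1 / length(pconf)
    }
    for (pc in pconf) {
      c1 <- codeOf(t1, m1, pc[1]); c2 <- codeOf(t2, m2, pc[2])
      if (z == 0) a[c1, c2] <- a[c1, c2] + 0.5 * w
      else        b[c1, c2] <- b[c1, c2] + 0.5 * w
    }
  }
  list(a = a, b = b)
}

#' Pairwise female recombination fractions and linkage LODs
#'
#' Maximum-likelihood female recombination fraction for every marker pair
#' under the achiasmatic-male F2 model: the maternal gamete recombines with
#' probability r, the paternal contribution is one intact haplotype
#' (probability 1/2 each for an autosome pair, fixed on the X). Cell
#' probabilities are linear in r, so the ML fit is a vectorised EM over all
#' pairs simultaneously; a small fixed contamination floor (2 x error rate)
#' absorbs genotyping-error cells that are otherwise impossible (e.g. AA x
#' BB at r = 0). LOD = log10 L(r-hat) - log10 L(0.5).
#'
#' @param geno Integer genotype matrix (individuals x markers).
#' @param error_rate Genotyping error rate (sets the contamination floor).
#' @param maxit EM iterations.
#' @return list: matrices \code{r}, \code{lod}, \code{n} (joint non-missing
#'   counts) and the per-marker \code{types}.
#' @export
estimateRFMatrix <- function(geno, error_rate = 1e-3, maxit = 80) {
  M <- ncol(geno)
  stopifnot(M >= 2)
  types <- markerTypes(geno)
  I <- lapply(1:3, function(k) {
    m <- (geno == k); m[is.na(m)] <- FALSE; storage.mode(m) <- "double"; m
  })
  ut <- which(upper.tri(matrix(0, M, M)))
  P <- length(ut)
  N <- matrix(0, P, 9)
  for (k in 1:3) for (l in 1:3) {
    N[, (k - 1) * 3 + l] <- crossprod(I[[k]], I[[l]])[ut]
  }
  tyidx <- c(auto = 1L, XA = 2L, XB = 3L)[types]
  TA <- array(0, c(3, 3, 9)); TB <- array(0, c(3, 3, 9))
  tynames <- c("auto", "XA", "XB")
  for (u in 1:3) for (v in 1:3) {
    ct <- cellTables(tynames[u], tynames[v])
    TA[u, v, ] <- as.numeric(t(ct$a))  # cell (k,l) -> column (k-1)*3+l
    TB[u, v, ] <- as.numeric(t(ct$b))
  }
  pr <- ((ut - 1) %% M) + 1   # row index (marker i)
  pc <- ((ut - 1) %/% M) + 1  # col index (marker j)
  A <- TA[cbind(rep(tyidx[pr], 9), rep(tyidx[pc], 9), rep(1:9, each = P))]
  B <- TB[cbind(rep(tyidx[pr], 9), rep(tyidx[pc], 9), rep(1:9, each = P))]
  A <- matrix(A, P, 9); B <- matrix(B, P, 9)
  kap <- 2 * error_rate + 1e-6

  r <- rep(0.25, P)
  for (it in seq_len(maxit)) {
    num <- den <- rep(0, P)
    for (c9 in 1:9) {
      pa <- (1 - kap) * (1 - r) * A[, c9]
      pb <- (1 - kap) * r * B[, c9]
      Tc <- pa + pb + kap / 9
      num <- num + N[, c9] * pb / Tc
      den <- den + N[, c9] * (pa + pb) / Tc
    }
    r_new <- pmin(0.5, pmax(1e-9, num / pmax(den, 1e-12)))
    if (max(abs(r_new - r)) < 1e-7) { r <- r_new; break }
    r <- r_new
  }
  ll <- function(rv) {
    out <- rep(0, P)
    for (c9 in 1:9) {
      Tc <- (1 - kap) * ((1 - rv) * A[, c9] + rv * B[, c9]) + kap / 9
      out <- out + N[, c9] * log10(Tc)
    }
    out
  }
  lod <- pmax(0, ll(r) - ll(rep(0.5, P)))
  nj <- rowSums(N)

  mk <- colnames(geno)
  toM <- function(v, diagval) {
    m <- matrix(diagval, M, M, dimnames = list(mk, mk))
    m[ut] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  list(r = toM(r, 0), lod = toM(lod, 0), n = toM(nj, 0), types = types)
}

#' Recombination fraction for a single marker pair
#'
#' @param g1,g2 Genotype code vectors for the two markers.
#' @param error_rate Genotyping error rate.
#' @param min_n Minimum jointly non-missing F2s before the estimate is
#'   flagged "low_support".
#' @return list: \code{r}, \code{lod}, \code{n}, \code{flag}.
#' @export
estimateRF <- function(g1, g2, error_rate = 1e-3, min_n = 10) {
  geno <- cbind(m1 = g1, m2 = g2)
  res <- estimateRFMatrix(geno, error_rate)
  n <- res$n[1, 2]
  list(r = res$r[1, 2], lod = res$lod[1, 2], n = n,
       flag = if (n < min_n) "low_support" else "ok")
}

## ---- linkage grouping ----

#' Group markers into linkage groups by a LOD threshold
#'
#' Single-linkage clustering: markers are joined whenever their pairwise LOD
#' reaches \code{lod_limit}; groups smaller than \code{size_limit} are
#' dissolved into singletons; singletons are then re-attached to the group
#' holding their best LOD when that LOD reaches \code{join_lod}.
#'
#' @param lod Symmetric pairwise LOD matrix.
#' @param lod_limit Grouping threshold (> 0).
#' @param size_limit Minimum group size before dissolution.
#' @param join_lod Threshold for re-attaching singletons.
#' @return list: \code{assignment} (named integer, NA = unplaced),
#'   \code{groups} (list of marker-id vectors, largest first).
#' @export
groupMarkers <- function(lod, lod_limit, size_limit = 20, join_lod = 3) {
  if (lod_limit <= 0) stop("lod_limit must be positive")
  mk <- colnames(lod)
  adj <- (lod >= lod_limit) * 1
  diag(adj) <- 0
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(gr)$membership
  sizes <- table(memb)
  small <- names(sizes)[sizes < size_limit]
  assignment <- ifelse(memb %in% as.integer(small), NA_integer_, memb)
  names(assignment) <- mk
  kept <- sort(unique(assignment[!is.na(assignment)]))
  assignment <- match(assignment, kept)
  names(assignment) <- mk
  for (j in which(is.na(assignment))) {
    best_lod <- -Inf; best_g <- NA_integer_
    for (g in seq_along(kept)) {
      members <- which(assignment == g)
      if (!length(members)) next
      bl <- max(lod[j, members])
      if (bl > best_lod) { best_lod <- bl; best_g <- g }
    }
    if (is.finite(best_lod) && best_lod >= join_lod) assignment[j] <- best_g
  }
  tabs <- sort(table(assignment), decreasing = TRUE)
  newlab <- stats::setNames(seq_along(tabs), names(tabs))
  assignment <- unname(newlab[as.character(assignment)])
  names(assignment) <- mk
  groups <- split(mk[!is.na(assignment)], assignment[!is.na(assignment)])
  names(groups) <- sprintf("LG%d", seq_along(groups))
  list(assignment = assignment, groups = groups)
}

#' Group count as a function of the LOD threshold
#'
#' Threshold scan used to locate the plateau where the expected number of
#' chromosomes is recovered.
#'
#' @param lod Pairwise LOD matrix.
#' @param limits Vector of thresholds to scan.
#' @param size_limit Minimum group size.
#' @return data.frame: lod_limit, n_groups.
#' @export
lodThresholdScan <- function(lod, limits, size_limit = 20) {
  data.frame(lod_limit = limits,
             n_groups = vapply(limits, function(l)
               length(groupMarkers(lod, l, size_limit, join_lod = Inf)$groups), 1L))
}

## ---- marker ordering ----

## greedy chain + 2-opt on the sum of adjacent recombination fractions
orderOnce <- function(r, start) {
  M <- nrow(r)
  used <- rep(FALSE, M)
  path <- c(start); used[start] <- TRUE
  while (sum(used) < M) {
    ends <- c(path[1], path[length(path)])
    cand <- which(!used)
    d_head <- r[ends[1], cand]; d_tail <- r[ends[2], cand]
    if (min(d_head) < min(d_tail)) {
      nb <- cand[which.min(d_head)]; path <- c(nb, path)
    } else {
      nb <- cand[which.min(d_tail)]; path <- c(path, nb)
    }
    used[nb] <- TRUE
  }
  ## 2-opt
  improved <- TRUE; pass <- 0
  while (improved && pass < 40) {
    improved <- FALSE; pass <- pass + 1
    for (i in 1:(M - 1)) for (j in (i + 1):M) {
      a <- if (i > 1) r[path[i - 1], path[i]] else 0
      b <- if (j < M) r[path[j], path[j + 1]] else 0
      a2 <- if (i > 1) r[path[i - 1], path[j]] else 0
      b2 <- if (j < M) r[path[i], path[j + 1]] else 0
      if (a2 + b2 < a + b - 1e-12) {
        path[i:j] <- rev(path[i:j])
        improved <- TRUE
      }
    }
  }
  path
}

#' Order markers within a linkage group
#'
#' Minimises the sum of adjacent recombination fractions by greedy chaining
#' plus 2-opt refinement from randomised starts, repeated \code{n_runs}
#' times; markers whose rank varies by more than \code{tol} positions across
#' runs are flagged as inconsistently placed and removed from the final
#' order. Orientation is fixed by physical position when available (the
#' order is reversed if cM rank anti-correlates with bp), else the
#' lexicographically first marker is anchored to the first half.
#'
#' @param r Pairwise recombination-fraction matrix for the group.
#' @param bp Optional named physical positions for orientation.
#' @param n_runs Number of randomised runs (default 10).
#' @param tol Maximum allowed rank range across runs (default 2).
#' @param seed Integer seed.
#' @return list: \code{order} (marker ids, flagged markers removed),
#'   \code{flagged}, \code{ranks} (marker x run rank matrix).
#' @export
orderMarkers <- function(r, bp = NULL, n_runs = 10, tol = 2, seed = 1L) {
  mk <- colnames(r)
  M <- length(mk)
  stopifnot(M >= 3)
  withSeed(seed, {
    ranks <- matrix(NA_real_, M, n_runs, dimnames = list(mk, NULL))
    best <- NULL; best_score <- Inf
    for (run in seq_len(n_runs)) {
      path <- orderOnce(r, sample.int(M, 1))
      ## orient
      if (!is.null(bp)) {
        if (stats::cor(seq_len(M), bp[mk[path]], method = "spearman") < 0)
          path <- rev(path)
      } else if (match(min(mk), mk[path]) > M / 2) path <- rev(path)
      ranks[path, run] <- seq_len(M)
      score <- sum(r[cbind(path[-M], path[-1])])
      if (score < best_score) { best_score <- score; best <- path }
    }
    rng <- apply(ranks, 1, function(x) diff(range(x)))
    flagged <- mk[rng > tol]
    ord <- mk[best]
    list(order = setdiff(ord, flagged), flagged = flagged, ranks = ranks,
         co_segregating = all(r[upper.tri(r)] < 1e-9))
  })
}

#' Build a genetic map from ordered linkage groups
#'
#' Converts adjacent recombination fractions to Haldane distances
#' d = -50 ln(1 - 2r) cM and accumulates positions from 0 at each group's
#' first marker. Co-segregating markers (r = 0) share a map position.
#' Adjacent fractions at or above 0.5 are capped at \code{max_gap} cM and
#' flagged.
#'
#' @param orders Named list of ordered marker-id vectors (one per group).
#' @param r Pairwise recombination-fraction matrix.
#' @param bp Optional named physical positions carried into the map.
#' @param max_gap Distance cap (cM) for unlinked adjacencies.
#' @return data.frame: marker, chr (group name), order, cM, bp, capped.
#' @export
buildGeneticMap <- function(orders, r, bp = NULL, max_gap = 50) {
  if (!length(orders))
    return(data.frame(marker = character(), chr = character(),
                      order = integer(), cM = numeric(), bp = integer(),
                      capped = logical()))
  do.call(rbind, lapply(names(orders), function(g) {
    o <- orders[[g]]
    radj <- r[cbind(o[-length(o)], o[-1])]
    capped <- radj >= 0.5
    d <- ifelse(capped, max_gap, haldaneInverse(pmin(radj, 0.5 - 1e-12)))
    data.frame(marker = o, chr = g, order = seq_along(o),
               cM = cumsum(c(0, d)),
               bp = if (!is.null(bp)) unname(bp[o]) else NA_integer_,
               capped = c(FALSE, capped), stringsAsFactors = FALSE)
  }))
}

#' Flag genotypes and markers by error LOD
#'
#' Per-genotype error LOD: the log10 posterior odds, against the prior odds,
#' that an observed call is a genotyping error given the flanking markers
#' (leave-one-out posterior from the intercross HMM). Markers whose maximum
#' error LOD exceeds the threshold are flagged for removal; chromosomes with
#' fewer than 3 markers have no usable flanking information and are flagged
#' "too_sparse".
#'
#' @param cross An \code{\linkS4class{F2Cross}}.
#' @param error_prob HMM emission error rate (must be > 0).
#' @param threshold Flagging threshold on the per-marker maximum (default 5).
#' @param x_chr Chromosome name(s) given the two-class X treatment.
#' @return list: \code{errorlod} (individuals x markers), \code{flagged}
#'   marker ids, \code{too_sparse} chromosome names.
#' @export
errorLodFlag <- function(cross, error_prob = 1e-3, threshold = 5, x_chr = "X") {
  stopifnot(error_prob > 0)
  map <- cross@map
  geno <- cross@geno
  errlod <- matrix(NA_real_, nrow(geno), ncol(geno),
                   dimnames = dimnames(geno))
  sparse <- character()
  for (chr in unique(map$chr)) {
    idx <- which(map$chr == chr)
    if (length(idx) < 3) { sparse <- c(sparse, chr); next }
    g <- geno[, idx, drop = FALSE]
    hp <- hmmPosterior(g, map$cM[idx], map$cM[idx],
                       x_classes = if (chr %in% x_chr) detectXClasses(g) else NULL,
                       eps = error_prob,
                       return_loo = TRUE)
    errlod[, idx] <- hp$loo
  }
  mx <- suppressWarnings(apply(errlod, 2, max, na.rm = TRUE))
  flagged <- colnames(geno)[is.finite(mx) & mx > threshold |
                              !is.finite(mx) & mx > 0]
  list(errorlod = errlod, flagged = flagged, too_sparse = sparse)
}
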