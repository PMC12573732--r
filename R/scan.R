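## ---- intercross HMM under achiasmatic males ----
##
## Hidden state on autosomes = (maternal allele, paternal haplotype); the
## maternal component recombines with Haldane probability per interval, the
## paternal component is constant along a chromosome (no male crossovers).
## On the X the father is hemizygous: a single known paternal allele, two
## hidden states. Emission confuses genotype classes by single steps at rate
## error_prob (AA<->AB, AB<->either homozygote).

## emission matrix rows = true class code (1,2,3), cols = observed code
emissionMatrix <- function(eps) {
  matrix(c(1 - eps, eps, 0,
           eps / 2, 1 - eps, eps / 2,
           0, eps, 1 - eps), 3, 3, byrow = TRUE)
}

## is a chromosome X-like (one homozygote class essentially absent)?
detectXClasses <- function(g) {
  tab <- tabulate(g[!is.na(g)], 3)
  n <- sum(tab)
  if (n == 0) return(NULL)
  if (tab[1] / n < 0.02 && tab[3] / n >= 0.02) return(c(2L, 3L))
  if (tab[3] / n < 0.02 && tab[1] / n >= 0.02) return(c(1L, 2L))
  NULL
}

## forward-backward for one chromosome; geno n x M (codes/NA), pos = marker
## cM, grid = evaluation positions (superset of pos), marker_at = index of
## marker at each grid row (NA for pseudo-positions)
## classes: integer codes of the genotype class of each hidden state
hmmPosterior <- function(geno, pos, grid, x_classes = NULL, eps = 1e-3,
                         return_loo = FALSE) {
  n <- nrow(geno); M <- ncol(geno)
  E <- emissionMatrix(max(eps, 1e-12))
  if (is.null(x_classes)) {
    state_class <- c(1L, 2L, 2L, 3L)   # (mA,pA),(mA,pB),(mB,pA),(mB,pB)
    mat_of_state <- c(1L, 1L, 2L, 2L)
  } else {
    state_class <- x_classes           # maternal A then maternal B
    mat_of_state <- c(1L, 2L)
  }
  S <- length(state_class)
  G <- length(grid)
  marker_at <- match(round(grid, 9), round(pos, 9))

  ## per-individual emission at a grid row: n x S
  emitAt <- function(gidx) {
    m <- marker_at[gidx]
    out <- matrix(1, n, S)
    if (!is.na(m)) {
      obs <- geno[, m]
      ok <- !is.na(obs)
      if (any(ok)) out[ok, ] <- t(E[state_class, obs[ok], drop = FALSE])
    }
    out
  }
  ## transition applied to an n x S matrix over interval d cM (row-vector form)
  trans <- function(A, d) {
    r <- haldane(d)
    if (S == 2L) {
      cbind(A[, 1] * (1 - r) + A[, 2] * r, A[, 1] * r + A[, 2] * (1 - r))
    } else {
      ## maternal mixes within the same paternal state
      cbind(A[, 1] * (1 - r) + A[, 3] * r,
            A[, 2] * (1 - r) + A[, 4] * r,
            A[, 1] * r + A[, 3] * (1 - r),
            A[, 2] * r + A[, 4] * (1 - r))
    }
  }

  alpha <- vector("list", G); beta <- vector("list", G)
  pred <- vector("list", G)   # forward prediction before emission (for LOO)
  a <- matrix(1 / S, n, S)
  for (g in seq_len(G)) {
    if (g > 1) a <- trans(a, grid[g] - grid[g - 1])
    pred[[g]] <- a
    a <- a * emitAt(g)
    sc <- rowSums(a)
    sc[sc == 0] <- 1e-300
    a <- a / sc
    alpha[[g]] <- a
  }
  b <- matrix(1, n, S)
  for (g in rev(seq_len(G))) {
    beta[[g]] <- b
    if (g > 1) {
      b <- trans(b * emitAt(g), grid[g] - grid[g - 1])
      sc <- rowSums(b); sc[sc == 0] <- 1e-300
      b <- b / sc
    }
  }
  nclass <- length(unique(state_class))
  cls <- sort(unique(state_class))
  post <- array(0, c(n, G, nclass))
  loo <- if (return_loo) matrix(NA_real_, n, M) else NULL
  for (g in seq_len(G)) {
    p <- alpha[[g]] * beta[[g]]
    p <- p / rowSums(p)
    for (k in seq_len(nclass))
      post[, g, k] <- rowSums(p[, state_class == cls[k], drop = FALSE])
    if (return_loo && !is.na(marker_at[g])) {
      q <- pred[[g]] * beta[[g]]
      q <- q / pmax(rowSums(q), 1e-300)
      qc <- vapply(cls, function(k)
        rowSums(q[, state_class == k, drop = FALSE]), numeric(n))
      m <- marker_at[g]
      obs <- geno[, m]
      ok <- which(!is.na(obs))
      for (i in ok) {
        o <- match(obs[i], cls)
        if (is.na(o)) { loo[i, m] <- Inf; next }  # impossible class observed
        num <- sum(qc[i, -o] * E[cls[-o], obs[i]])
        den <- qc[i, o] * E[cls[o], obs[i]]
        loo[i, m] <- log10(num / max(den, 1e-300)) + log10((1 - eps) / eps)
      }
    }
  }
  dimnames(post)[[3]] <- GENO_LEVELS[cls]
  list(post = post, classes = GENO_LEVELS[cls], loo = loo)
}

#' Genotype probabilities for an F2 cross
#'
#' Forward-backward posterior genotype-class probabilities from the
#' achiasmatic-male intercross HMM, evaluated at markers and at
#' pseudo-positions on a regular step. Chromosomes on which one homozygote
#' class is essentially absent are treated as X-like (two classes, fixed
#' paternal haplotype).
#'
#' @param cross An \code{\linkS4class{F2Cross}}.
#' @param step Pseudo-position spacing in cM (default 1).
#' @param error_prob Genotyping error rate used in the emission model.
#' @param x_chr Chromosome name(s) given the two-class X treatment; which
#'   two classes segregate is read off the data (which homozygote the
#'   hemizygous father contributed).
#' @return A \code{\linkS4class{GenoProb}}.
#' @export
calcGenoprob <- function(cross, step = 1, error_prob = 1e-3, x_chr = "X") {
  stopifnot(step > 0)
  if (error_prob < 0 || error_prob >= 0.5)
    stop("error_prob must be in [0, 0.5)")
  map <- cross@map
  geno <- cross@geno
  prob <- list(); grid_l <- list()
  for (chr in unique(map$chr)) {
    idx <- which(map$chr == chr)
    pos <- map$cM[idx]
    g <- geno[, idx, drop = FALSE]
    pseudo <- seq(min(pos), max(pos), by = step)
    grid <- sort(unique(round(c(pos, pseudo), 9)))
    xc <- if (chr %in% x_chr) detectXClasses(g) else NULL
    hp <- hmmPosterior(g, pos, grid, x_classes = xc, eps = error_prob)
    prob[[chr]] <- hp$post
    grid_l[[chr]] <- data.frame(
      pos = grid,
      marker = map$marker[idx][match(round(grid, 9), round(pos, 9))],
      stringsAsFactors = FALSE)
  }
  new("GenoProb", prob = prob, grid = grid_l, error_prob = error_prob)
}

## ---- nonparametric (rank) scan ----

## Kruskal-Wallis H generalised to soft genotype assignments, with midranks
## and tie correction; at a fully typed marker this is exactly the standard H
softKruskalH <- function(P, R) {
  n <- length(R)
  ng <- colSums(P)
  keep <- ng > 1e-9
  if (sum(keep) < 2) return(0)
  Rbar <- as.numeric(crossprod(P[, keep, drop = FALSE], R)) / ng[keep]
  H <- 12 / (n * (n + 1)) * sum(ng[keep] * (Rbar - (n + 1) / 2)^2)
  t_ <- table(R)
  D <- 1 - sum(t_^3 - t_) / (n^3 - n)
  if (D <= 0) return(0)
  H / D
}

#' Nonparametric single-QTL genome scan
#'
#' Rank-based scan for traits (such as acceptance proportions) that are not
#' normally distributed: at each evaluation position a Kruskal-Wallis-type
#' statistic generalised to probability-weighted genotype classes, with
#' midranks and tie correction; LOD = H / (2 ln 10). At a fully informative
#' typed marker the statistic equals the standard Kruskal-Wallis H.
#'
#' @param gp A \code{\linkS4class{GenoProb}}.
#' @param y Numeric trait vector (one value per individual; NAs dropped).
#' @param trait Trait name carried into the result.
#' @return A \code{\linkS4class{ScanResult}}.
#' @export
scanNonparametric <- function(gp, y, trait = "trait") {
  ok <- !is.na(y)
  if (length(unique(y[ok])) < 2) {
    warning("constant trait: LOD is 0 everywhere")
  }
  R <- rank(y[ok])
  out <- do.call(rbind, lapply(names(gp@prob), function(chr) {
    P <- gp@prob[[chr]][ok, , , drop = FALSE]
    lod <- vapply(seq_len(dim(P)[2]), function(j)
      softKruskalH(P[, j, , drop = TRUE], R) / (2 * log(10)), 0)
    data.frame(chr = chr, pos = gp@grid[[chr]]$pos,
               marker = gp@grid[[chr]]$marker, lod = lod,
               stringsAsFactors = FALSE)
  }))
  new("ScanResult", lod = out, model = "nonparametric", trait = trait,
      threshold = NA_real_, peaks = data.frame(), n = sum(ok))
}

## ---- two-part (spike) scan ----

## closed-form null log-likelihood for the two-part model
twopartNullLL <- function(z, yq_all) {
  n <- length(z)
  pi0 <- mean(z)
  ll <- 0
  if (pi0 > 0) ll <- ll + sum(z) * log(pi0)
  if (pi0 < 1) {
    yq <- yq_all[!z]
    mu <- mean(yq); s <- sqrt(mean((yq - mu)^2))
    s <- max(s, 1e-8)
    ll <- ll + sum(!z) * log(1 - pi0) + sum(dnorm(yq, mu, s, log = TRUE))
  }
  ll
}

## Batched EM fit of the genotype-specific two-part mixture, synchronously
## across all evaluation positions of one chromosome. A is the genotype
## probability array (n x npos x G); returns the maximised log-likelihood per
## position. spike_only fits the binomial part alone; quant_only the normal
## part among non-spike individuals.
twopartEMBatch <- function(A, z, y, tol = 1e-8, maxit = 200,
                           spike_only = FALSE, quant_only = FALSE) {
  if (quant_only) {
    A <- A[!z, , , drop = FALSE]
    y <- y[!z]
    z <- rep(FALSE, length(y))
  }
  n <- dim(A)[1]; npos <- dim(A)[2]; G <- dim(A)[3]
  if (n == 0) return(rep(0, npos))
  zq <- 1 - z
  pi0 <- mean(z)
  mu0 <- if (!all(z)) mean(y[!z]) else 0
  s0 <- if (!all(z)) max(sqrt(mean((y[!z] - mu0)^2)), 1e-6) else 1
  PI <- matrix(pi0, G, npos)
  MU <- matrix(mu0, G, npos)
  SG <- rep(s0, npos)
  ll_old <- rep(-Inf, npos)
  ll <- rep(0, npos)
  for (it in seq_len(maxit)) {
    num <- array(0, c(n, npos, G))
    for (g in seq_len(G)) {
      Lg <- if (spike_only) {
        outer(z, PI[g, ]) + outer(zq, 1 - PI[g, ])
      } else {
        D <- stats::dnorm(matrix(y, n, npos),
                          matrix(MU[g, ], n, npos, byrow = TRUE),
                          matrix(SG, n, npos, byrow = TRUE))
        outer(z, PI[g, ]) + zq * D * matrix(1 - PI[g, ], n, npos, byrow = TRUE)
      }
      num[, , g] <- A[, , g] * Lg
    }
    tot <- rowSums(num, dims = 2)           # n x npos
    tot[tot <= 0] <- 1e-300
    ll <- colSums(log(tot))
    active <- which(abs(ll - ll_old) >= tol)
    if (!length(active)) break
    ll_old <- ll
    W <- num / as.vector(tot)               # recycle over G
    wg <- colSums(W)                        # npos x G
    if (!quant_only) {
      wz <- colSums(W * z)
      ## keep the matrix first: pmin/pmax take dims from their first argument
      PI <- t(pmax(pmin(wz / pmax(wg, 1e-12), 1 - 1e-12), 1e-12))
    }
    if (!spike_only && !all(z)) {
      wq_y <- colSums(W * (zq * y))
      wq <- colSums(W * zq)
      MUn <- wq_y / pmax(wq, 1e-12)
      MU <- t(ifelse(wq > 1e-12, MUn, t(MU)))
      ss <- rep(0, npos)
      for (g in seq_len(G)) {
        R2 <- (matrix(y, n, npos) - matrix(MU[g, ], n, npos, byrow = TRUE))^2
        ss <- ss + colSums(W[, , g] * zq * R2)
      }
      SG <- pmax(sqrt(ss / pmax(rowSums(wq), 1e-12)), 1e-8)
    }
  }
  ll
}

#' Two-part (spike) single-QTL genome scan
#'
#' Scan model for survival-type traits with a point mass at one boundary
#' (here, clones alive through all 17 observation steps): at each position a
#' mixture over genotype classes of a class-specific spike probability and,
#' among non-spike individuals, a class-specific normal component with
#' common SD, fitted by EM over the genotype-probability mixture. The joint
#' LOD is the scan statistic; spike-only and quantitative-only component
#' LODs are reported alongside.
#'
#' @param gp A \code{\linkS4class{GenoProb}}.
#' @param y Numeric trait with a spike at its maximum (or minimum).
#' @param spike_at_upper Spike at the maximum (TRUE) or minimum.
#' @param trait Trait name.
#' @return A \code{\linkS4class{ScanResult}}; the lod table carries
#'   \code{lod} (joint), \code{lod_spike} and \code{lod_quant}.
#' @export
scanTwopart <- function(gp, y, spike_at_upper = TRUE, trait = "trait") {
  ok <- !is.na(y)
  yv <- y[ok]
  spike <- if (spike_at_upper) max(yv) else min(yv)
  z <- yv == spike
  all_spike <- all(z)
  ll0 <- twopartNullLL(z, yv)
  ll0_spike <- {
    p0 <- mean(z)
    sum(z) * log(max(p0, 1e-300)) + sum(!z) * log(max(1 - p0, 1e-300))
  }
  ll0_quant <- if (all_spike) 0 else {
    yq <- yv[!z]; mu <- mean(yq); s <- max(sqrt(mean((yq - mu)^2)), 1e-8)
    sum(dnorm(yq, mu, s, log = TRUE))
  }
  out <- do.call(rbind, lapply(names(gp@prob), function(chr) {
    Pa <- gp@prob[[chr]][ok, , , drop = FALSE]
    l_spike <- pmax((twopartEMBatch(Pa, z, yv, spike_only = TRUE) -
                       ll0_spike) / log(10), 0)
    if (all_spike) {
      l_joint <- l_spike; l_quant <- rep(0, length(l_spike))
    } else {
      l_joint <- pmax((twopartEMBatch(Pa, z, yv) - ll0) / log(10), 0)
      l_quant <- pmax((twopartEMBatch(Pa, z, yv, quant_only = TRUE) -
                         ll0_quant) / log(10), 0)
    }
    data.frame(chr = chr, pos = gp@grid[[chr]]$pos,
               marker = gp@grid[[chr]]$marker,
               lod = l_joint, lod_spike = l_spike, lod_quant = l_quant,
               stringsAsFactors = FALSE)
  }))
  if (all_spike) out$lod <- 0 * out$lod  # no variation: nothing to map
  new("ScanResult", lod = out, model = "twopart", trait = trait,
      threshold = NA_real_, peaks = data.frame(), n = sum(ok))
}

#' Genome-wide permutation threshold for a scan
#'
#' Permutes trait values across individuals, rescans the genome, and takes
#' the 95th percentile (empirical quantile type 7) of the genome-wide
#' maximum LODs as the significance threshold.
#'
#' @param gp A \code{\linkS4class{GenoProb}}.
#' @param y Trait vector.
#' @param model "nonparametric" or "twopart".
#' @param B Number of permutations (>= 100).
#' @param alpha Genome-wide type-I error (default 0.05).
#' @param seed Integer seed.
#' @param spike_at_upper Passed to the two-part scan.
#' @return The threshold, with the vector of permutation maxima as
#'   attribute \code{"maxima"}.
#' @export
scanPermutationThreshold <- function(gp, y, model = c("nonparametric", "twopart"),
                                     B = 1000, alpha = 0.05, seed = 1L,
                                     spike_at_upper = TRUE) {
  model <- match.arg(model)
  stopifnot(B >= 100)
  withSeed(seed, {
    maxima <- vapply(seq_len(B), function(b) {
      yp <- y
      yp[!is.na(y)] <- sample(y[!is.na(y)])
      sc <- if (model == "nonparametric") scanNonparametric(gp, yp)
            else scanTwopart(gp, yp, spike_at_upper = spike_at_upper)
      max(sc@lod$lod)
    }, 0)
    structure(quantile7(maxima, 1 - alpha), maxima = maxima)
  })
}

#' 1.5-LOD support interval around a peak
#'
#' The widest contiguous interval around the chromosome peak over which LOD
#' stays within \code{drop} of the peak LOD, expanded outward to the nearest
#' flanking markers.
#'
#' @param scan A \code{\linkS4class{ScanResult}}.
#' @param chr Chromosome of the peak.
#' @param drop LOD drop (default 1.5); must be positive.
#' @return data.frame with peak position/LOD and interval bounds (cM).
#' @export
lodInterval <- function(scan, chr, drop = 1.5) {
  if (drop <= 0) stop("drop must be positive")
  d <- scan@lod[scan@lod$chr == chr, ]
  pk <- which.max(d$lod)
  thr <- d$lod[pk] - drop
  lo <- pk; hi <- pk
  while (lo > 1 && d$lod[lo - 1] >= thr) lo <- lo - 1
  while (hi < nrow(d) && d$lod[hi + 1] >= thr) hi <- hi + 1
  ## expand outward to nearest flanking typed markers
  mk <- which(!is.na(d$marker))
  lo_m <- mk[mk <= lo]
  hi_m <- mk[mk >= hi]
  lo <- if (length(lo_m)) max(lo_m) else lo
  hi <- if (length(hi_m)) min(hi_m) else hi
  data.frame(chr = chr, peak = d$pos[pk], peak_lod = d$lod[pk],
             lo = d$pos[lo], hi = d$pos[hi], stringsAsFactors = FALSE)
}

#' Proportion of phenotypic variance explained by a QTL
#'
#' PVE = 1 - 10^(-(2/n) LOD).
#'
#' @param lod LOD score (>= 0).
#' @param n Number of individuals.
#' @return Proportion in [0, 1).
#' @export
varianceExplained <- function(lod, n) {
  stopifnot(all(lod >= 0), n >= 1)
  1 - 10^(-(2 / n) * lod)
}

#' Significant peaks of a scan
#'
#' One peak per chromosome whose maximum LOD exceeds the threshold, with the
#' 1.5-LOD support interval and PVE.
#'
#' @param scan A \code{\linkS4class{ScanResult}}.
#' @param threshold Genome-wide threshold (e.g. from
#'   \code{\link{scanPermutationThreshold}}).
#' @param drop LOD-drop for the support interval.
#' @return The scan with its \code{peaks} table and threshold filled in.
#' @export
scanSignificantPeaks <- function(scan, threshold, drop = 1.5) {
  pk <- do.call(rbind, lapply(unique(scan@lod$chr), function(chr) {
    d <- scan@lod[scan@lod$chr == chr, ]
    if (max(d$lod) <= threshold) return(NULL)
    iv <- lodInterval(scan, chr, drop)
    iv$pve <- varianceExplained(iv$peak_lod, scan@n)
    iv
  }))
  if (is.null(pk)) pk <- data.frame()
  initialize(scan, peaks = pk, threshold = threshold)
}
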