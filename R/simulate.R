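#' Configuration for a synthetic F2 host-race cross
#'
#' Defaults mirror the study design this package emulates: 192 F2 clones
#' from a cross between alfalfa- and pea-specialised aphid races, four
#' chromosomes (A1 172 cM / 160 Mb, A2 112 / 130, A3 114 / 135, X 204 / 133),
#' marker counts matching the filtered scan set (170/112/62/140), genotyping
#' error rate 0.001 and missing-call rate 0.05. Males are achiasmatic: all
#' crossovers are maternal, and the father contributes one intact haplotype
#' per chromosome (a single haplotype genome-wide on the X, i.e. a
#' hemizygous father, so X markers segregate in two genotype classes).
#'
#' @param n_f2 Number of F2 clones.
#' @param chromosomes data.frame with columns chr, len_cM, len_mb.
#' @param n_markers Integer vector of marker counts, one per chromosome.
#' @param error_rate Symmetric single-step genotyping error rate (AA<->AB,
#'   AB<->either homozygote; homozygote-to-opposite-homozygote miscalls do
#'   not occur).
#' @param missing_rate Missing-call rate.
#' @param prop_uninformative Fraction of markers monomorphic across races.
#' @param prop_f0_het Fraction of markers with a heterozygous grandparent.
#' @param prop_distorted Fraction of markers with distorted segregation.
#' @param rearrangements Named list (by chr) of signed block arrangements
#'   relating map order to assembly order, e.g. \code{c(3, -1, -2)}.
#' @param suppression Named list (by chr) of c(start_mb, end_mb) intervals
#'   with recombination suppressed (flat Marey segment).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list of class \code{CrossConfig}.
#' @export
crossConfig <- function(n_f2 = 192,
                        chromosomes = data.frame(
                          chr = c("A1", "A2", "A3", "X"),
                          len_cM = c(172, 112, 114, 204),
                          len_mb = c(160, 130, 135, 133),
                          stringsAsFactors = FALSE),
                        n_markers = c(170, 112, 62, 140),
                        error_rate = 0.001,
                        missing_rate = 0.05,
                        prop_uninformative = 0,
                        prop_f0_het = 0,
                        prop_distorted = 0,
                        rearrangements = list(),
                        suppression = list(),
                        seed = 1L) {
  stopifnot(n_f2 >= 2,
            all(chromosomes$len_cM > 0), all(chromosomes$len_mb > 0),
            length(n_markers) == nrow(chromosomes), all(n_markers >= 2),
            error_rate >= 0, error_rate < 1,
            missing_rate >= 0, missing_rate < 1,
            prop_uninformative >= 0, prop_uninformative < 1,
            prop_f0_het >= 0, prop_f0_het < 1,
            prop_distorted >= 0, prop_distorted < 1)
  structure(list(
    n_f2 = as.integer(n_f2), chromosomes = chromosomes,
    n_markers = as.integer(n_markers), error_rate = error_rate,
    missing_rate = missing_rate, prop_uninformative = prop_uninformative,
    prop_f0_het = prop_f0_het, prop_distorted = prop_distorted,
    rearrangements = rearrangements, suppression = suppression,
    seed = as.integer(seed)), class = "CrossConfig")
}

## piecewise-linear Marey function: bp -> cM, flat over suppressed intervals
mareyFunction <- function(len_bp, len_cM, suppressed_bp = NULL) {
  if (is.null(suppressed_bp)) {
    return(function(bp) bp / len_bp * len_cM)
  }
  s0 <- suppressed_bp[1]; s1 <- suppressed_bp[2]
  active <- len_bp - (s1 - s0)
  function(bp) {
    eff <- ifelse(bp <= s0, bp, ifelse(bp >= s1, bp - (s1 - s0), s0))
    eff / active * len_cM
  }
}

## map a vector of "ancestral" bp to assembly bp under a signed block
## arrangement: the map (cM order) is partitioned into K equal blocks;
## map block j occupies assembly block |arr[j]|, reversed when arr[j] < 0
applyRearrangement <- function(bp, len_bp, arr) {
  K <- length(arr)
  bl <- len_bp / K
  j <- pmin(K, findInterval(bp, seq(0, len_bp, length.out = K + 1),
                            rightmost.closed = TRUE))
  within <- bp - (j - 1) * bl
  tgt <- abs(arr)[j]
  flip <- arr[j] < 0
  within[flip] <- bl - within[flip]
  (tgt - 1) * bl + within
}

#' Simulate founder (F0) genomes and the F1 pair
#'
#' Generates the marker table (positions on four chromosomes) and the
#' grandparental genotypes: two alfalfa-race founders fixed for the A allele
#' and two pea-race founders fixed for B at informative markers, with
#' configurable fractions of markers made uninformative (monomorphic across
#' races), heterozygous in an F0, or destined for distorted segregation, to
#' exercise the downstream QC filters. Both F1s are heterozygous at all
#' informative markers with known (coupling) phase.
#'
#' @param config A \code{\link{crossConfig}}.
#' @return A list with elements \code{markers} (marker table with truth
#'   status), \code{f0} (4 x M genotype matrix: Ms5, Ms10, Ps3, Ps19),
#'   \code{f1} (2 x M), and \code{config}.
#' @export
simulateFounders <- function(config) {
  stopifnot(inherits(config, "CrossConfig"))
  withSeed(childSeed(config$seed, "founders"), {
    chrs <- config$chromosomes
    mk <- do.call(rbind, lapply(seq_len(nrow(chrs)), function(ci) {
      chr <- chrs$chr[ci]; M <- config$n_markers[ci]
      len_bp <- chrs$len_mb[ci] * 1e6
      anc_bp <- sort(sample.int(len_bp, M))
      supp <- config$suppression[[chr]]
      phi <- mareyFunction(len_bp, chrs$len_cM[ci],
                           if (!is.null(supp)) supp * 1e6 else NULL)
      cM <- phi(anc_bp)
      bp <- anc_bp
      arr <- config$rearrangements[[chr]]
      if (!is.null(arr)) bp <- round(applyRearrangement(anc_bp, len_bp, arr))
      data.frame(marker = sprintf("%s_m%03d", chr, seq_len(M)), chr = chr,
                 bp = bp, cM = cM, stringsAsFactors = FALSE)
    }))
    M <- nrow(mk)
    status <- rep("informative", M)
    pick <- function(p, from) {
      cand <- which(status %in% from)
      n <- min(round(p * M), length(cand))
      cand[sample.int(length(cand), n)]
    }
    status[pick(config$prop_uninformative, "informative")] <- "uninformative"
    status[pick(config$prop_f0_het, "informative")] <- "f0_het"
    status[pick(config$prop_distorted, "informative")] <- "distorted"
    mk$status <- status

    f0 <- matrix("AA", 4, M,
                 dimnames = list(c("Ms5", "Ms10", "Ps3", "Ps19"), mk$marker))
    f1 <- matrix("AB", 2, M, dimnames = list(c("F1a", "F1b"), mk$marker))
    inf <- status %in% c("informative", "distorted")
    f0[3:4, inf] <- "BB"
    f0[, status == "uninformative"] <- "AA"
    f1[, status == "uninformative"] <- "AA"
    het_f0 <- sample(1:4, sum(status == "f0_het"), replace = TRUE)
    for (k in seq_along(het_f0)) {
      j <- which(status == "f0_het")[k]
      f0[3:4, j] <- "BB"
      f0[het_f0[k], j] <- "AB"
    }
    list(markers = mk, f0 = f0, f1 = f1, config = config)
  })
}

## maternal allele ("A"/"B") at position pos given start allele and crossover
## positions: parity of crossovers to the left
maternalAllele <- function(start, xo, pos) {
  flips <- vapply(pos, function(p) sum(xo < p), 0L)
  ifelse(flips %% 2 == 0, start, c(A = "B", B = "A")[start])
}

#' Simulate F2 genotypes under female-only recombination
#'
#' Each F2 receives a recombinant maternal gamete (crossovers from a
#' no-interference Poisson process on the cM scale, Haldane-consistent) and
#' one intact paternal F1 haplotype per chromosome (fair coin on autosomes;
#' on the X the father is hemizygous, so a single haplotype is transmitted
#' genome-wide and X markers show two genotype classes). Genotyping errors
#' are applied as symmetric single-step confusions at the configured rate,
#' then missing calls are injected.
#'
#' @param founders Output of \code{\link{simulateFounders}}.
#' @param config A \code{\link{crossConfig}} (defaults to the one stored in
#'   \code{founders}).
#' @return An \code{\linkS4class{F2Cross}} with the truth record attached.
#' @export
simulateF2Genotypes <- function(founders, config = founders$config) {
  mk <- founders$markers
  bychr <- split(seq_len(nrow(mk)), mk$chr)
  for (chr in names(bychr)) {
    if (is.unsorted(mk$cM[bychr[[chr]]]))
      stop("map positions not sorted on chromosome ", chr)
  }
  withSeed(childSeed(config$seed, "f2"), {
    n <- config$n_f2
    chrs <- config$chromosomes
    nchr <- nrow(chrs)
    x_pat <- sample(c("A", "B"), 1)
    mat_start <- matrix(sample(c("A", "B"), n * nchr, replace = TRUE), n, nchr,
                        dimnames = list(NULL, chrs$chr))
    pat_hap <- matrix(sample(c("A", "B"), n * nchr, replace = TRUE), n, nchr,
                      dimnames = list(NULL, chrs$chr))
    pat_hap[, chrs$chr == "X"] <- x_pat
    crossovers <- lapply(seq_len(n), function(i) {
      out <- lapply(seq_len(nchr), function(ci) {
        L <- chrs$len_cM[ci]
        sort(runif(rpois(1, L / 100), 0, L))
      })
      names(out) <- chrs$chr
      out
    })

    geno <- matrix(NA_integer_, n, nrow(mk),
                   dimnames = list(sprintf("o%03d", seq_len(n)), mk$marker))
    for (ci in seq_len(nchr)) {
      chr <- chrs$chr[ci]
      idx <- bychr[[chr]]
      pos <- mk$cM[idx]
      for (i in seq_len(n)) {
        mat <- maternalAllele(mat_start[i, ci], crossovers[[i]][[ci]], pos)
        nB <- (mat == "B") + (pat_hap[i, ci] == "B")
        geno[i, idx] <- nB + 1L
      }
    }
    ## markers constructed to violate QC rules overwrite the map-linked truth
    unin <- which(mk$status == "uninformative")
    if (length(unin)) geno[, unin] <- 1L
    fh <- which(mk$status == "f0_het")
    if (length(fh))
      geno[, fh] <- sample(1:3, n * length(fh), replace = TRUE,
                           prob = c(.25, .5, .25))
    dis <- which(mk$status == "distorted")
    for (j in dis) {
      if (mk$chr[j] == "X") {
        cls <- sort(unique(geno[, j]))
        geno[, j] <- sample(cls, n, replace = TRUE, prob = c(.85, .15))
      } else {
        geno[, j] <- sample(1:3, n, replace = TRUE, prob = c(.45, .45, .10))
      }
    }
    true_geno <- geno

    if (config$error_rate > 0) {
      err <- matrix(runif(length(geno)) < config$error_rate, nrow(geno))
      ## single-step confusion: hom -> AB; AB -> either hom
      flip_to <- ifelse(geno == 2L,
                        ifelse(matrix(runif(length(geno)), nrow(geno)) < .5, 1L, 3L),
                        2L)
      geno[err] <- flip_to[err]
    }
    if (config$missing_rate > 0) {
      geno[matrix(runif(length(geno)) < config$missing_rate, nrow(geno))] <- NA_integer_
    }

    truth <- list(crossovers = crossovers, mat_start = mat_start,
                  pat_hap = pat_hap, x_pat = x_pat,
                  marker_flags = mk[, c("marker", "chr", "status")],
                  true_geno = true_geno, config = config)
    new("F2Cross", geno = geno,
        map = mk[, c("marker", "chr", "bp", "cM")],
        pheno = data.frame(id = rownames(geno), stringsAsFactors = FALSE),
        founders = founders[c("f0", "f1")], truth = truth)
  })
}

## additive genotype score (count of B alleles, 0..2; 0..1 maternal classes
## plus the constant paternal allele on X) at an arbitrary map position
qtlGenotypeScore <- function(truth, chr, pos) {
  ci <- match(chr, colnames(truth$mat_start))
  n <- nrow(truth$mat_start)
  vapply(seq_len(n), function(i) {
    mat <- maternalAllele(truth$mat_start[i, ci], truth$crossovers[[i]][[ci]], pos)
    (mat == "B") + (truth$pat_hap[i, ci] == "B")
  }, 0)
}

#' Phenotype model for the synthetic cross
#'
#' Describes the four behavioural/performance traits emulated by the
#' generator: acceptance of pea and of alfalfa (proportion of probing
#' observations among observations alive, over 17 timepoints x 4
#' replicates), survival as mean time-steps alive (spike at the upper bound
#' of 17), and survival count out of 4 replicate trials. Default target
#' heritabilities are the study's genome-wide estimates (pea acceptance
#' 0.097, alfalfa acceptance 0.299, pea survival 0.388, alfalfa survival
#' 0.148), and the default architectures place the reported moderate-effect
#' QTL: alfalfa acceptance A3 @ 68 cM (~15% PVE) and alfalfa survival A1 @
#' 171 cM (~10%) plus A3 @ 77 cM (~7%), with the remaining heritability
#' polygenic.
#'
#' @param traits Named list; each element has fields h2, qtl (data.frame
#'   chr, pos, pve, dom), and type ("acceptance", "survival").
#' @param mode "direct" (clone means: QTL effects + polygenic value +
#'   environmental noise, genetic and environmental variance rescaled so the
#'   realized heritability equals the target) or "mechanistic" (per-replicate
#'   per-timestep alive/dead hazard and probing-given-alive liability).
#' @param n_timepoints,n_replicates Observation schedule.
#' @param base_hazard Per-step death probability at genetic value 0
#'   (mechanistic mode); 0 gives certain survival.
#' @param base_probing Probing probability per alive observation at genetic
#'   value 0 (mechanistic mode); 1 gives certain probing.
#' @param hazard_scale Multiplier from genetic value to log-odds hazard shift.
#' @return List of class \code{PhenotypeModel}.
#' @export
phenotypeModel <- function(traits = list(
                             acceptance_pea = list(h2 = 0.097, type = "acceptance",
                               qtl = NULL),
                             acceptance_alfalfa = list(h2 = 0.299, type = "acceptance",
                               qtl = data.frame(chr = "A3", pos = 68, pve = 0.15, dom = 0)),
                             survival_pea = list(h2 = 0.388, type = "survival",
                               qtl = NULL),
                             ## the reported per-QTL PVEs (10%, 7%) exceed this
                             ## trait's heritability (Beavis inflation); they are
                             ## scaled proportionally into the h2 budget
                             survival_alfalfa = list(h2 = 0.148, type = "survival",
                               qtl = data.frame(chr = c("A1", "A3"), pos = c(171, 77),
                                                pve = c(0.087, 0.061), dom = c(0, 0)))),
                           mode = c("direct", "mechanistic"),
                           n_timepoints = 17L, n_replicates = 4L,
                           base_hazard = 0.01, base_probing = 0.4,
                           hazard_scale = 1) {
  mode <- match.arg(mode)
  for (tr in traits) {
    stopifnot(tr$h2 >= 0, tr$h2 < 1)
    if (!is.null(tr$qtl)) stopifnot(all(tr$qtl$pve >= 0), sum(tr$qtl$pve) <= tr$h2)
  }
  stopifnot(base_hazard >= 0, base_hazard <= 1, base_probing >= 0, base_probing <= 1)
  structure(list(traits = traits, mode = mode, n_timepoints = as.integer(n_timepoints),
                 n_replicates = as.integer(n_replicates), base_hazard = base_hazard,
                 base_probing = base_probing,
                 hazard_scale = hazard_scale), class = "PhenotypeModel")
}

## genetic values for one trait: QTL part (additive + dominance scores at the
## truth-record haplotypes) plus a genomic polygenic part (iid effects at all
## informative markers), jointly rescaled to exact variance h2 (total
## phenotypic variance 1 on the latent scale)
traitGeneticValues <- function(truth, tr) {
  n <- nrow(truth$mat_start)
  g_qtl <- rep(0, n)
  if (!is.null(tr$qtl) && nrow(tr$qtl) > 0) {
    for (k in seq_len(nrow(tr$qtl))) {
      x <- qtlGenotypeScore(truth, tr$qtl$chr[k], tr$qtl$pos[k])
      a <- sqrt(2 * tr$qtl$pve[k])
      g_qtl <- g_qtl + a * (x - 1) + tr$qtl$dom[k] * (x == 1)
    }
  }
  h2_poly <- tr$h2 - if (is.null(tr$qtl)) 0 else sum(tr$qtl$pve)
  g_poly <- rep(0, n)
  if (h2_poly > 0) {
    inf <- truth$marker_flags$status == "informative"
    X <- truth$true_geno[, inf, drop = FALSE] - 1
    beta <- rnorm(ncol(X))
    g_poly <- as.numeric(X %*% beta)
    if (stats::sd(g_poly) > 0)
      g_poly <- g_poly / stats::sd(g_poly) * sqrt(h2_poly)
  }
  g <- g_qtl + g_poly
  if (tr$h2 > 0 && stats::sd(g) > 0) g <- g / stats::sd(g) * sqrt(tr$h2)
  g - mean(g)
}

#' Simulate clone phenotypes for an F2 cross
#'
#' Two generation modes. Direct: each trait is a clone mean, QTL effects plus
#' polygenic value plus environmental noise, with the genetic and residual
#' parts rescaled so the realized latent heritability equals the target
#' exactly; acceptance traits are emitted on the proportion scale (base 0.4,
#' phenotypic SD 0.12, clipped to [0,1]), survival as a spike-at-17 clone
#' mean, and survival counts as binomial(4) draws on a logit scale.
#' Mechanistic: per replicate and timepoint an alive/dead step hazard
#' (QTL-shifted for survival traits) and a probing-given-alive clone
#' liability generate the raw observation grid, from which acceptance =
#' probing / alive observations, survival = mean time-steps alive, count =
#' replicates alive at the end.
#'
#' @param cross An \code{\linkS4class{F2Cross}} with a truth record.
#' @param model A \code{\link{phenotypeModel}}.
#' @param seed Integer seed.
#' @return The cross with its phenotype table filled in (columns: id, the
#'   four trait means, and count_pea / count_alfalfa out of 4) and latent
#'   genetic/environmental values stored in the truth record.
#' @export
simulatePhenotypes <- function(cross, model = phenotypeModel(), seed = 1L) {
  stopifnot(inherits(model, "PhenotypeModel"), length(cross@truth) > 0)
  truth <- cross@truth
  n <- nrow(truth$mat_start)
  withSeed(seed, {
    ph <- data.frame(id = rownames(cross@geno), stringsAsFactors = FALSE)
    gv <- list()
    for (nm in names(model$traits)) {
      tr <- model$traits[[nm]]
      g <- traitGeneticValues(truth, tr)
      e <- rnorm(n)
      e <- (e - mean(e)) / stats::sd(e) * sqrt(1 - tr$h2)
      l <- g + e
      gv[[nm]] <- list(g = g, e = e)
      if (model$mode == "direct") {
        if (tr$type == "acceptance") {
          ph[[nm]] <- pmin(1, pmax(0, 0.4 + 0.12 * l))
        } else {
          ph[[nm]] <- pmin(model$n_timepoints, model$n_timepoints + 0.2 + 1.2 * l)
          cnm <- sub("survival", "count", nm)
          p <- stats::plogis(stats::qlogis(0.85) + 1.5 * l)
          ph[[cnm]] <- rbinom(n, model$n_replicates, p)
        }
      } else {
        R <- model$n_replicates; TT <- model$n_timepoints
        acc <- surv <- cnt <- numeric(n)
        for (i in seq_len(n)) {
          alive_obs <- 0L; probe_obs <- 0L; steps <- 0; alive_end <- 0L
          h_i <- stats::plogis(stats::qlogis(model$base_hazard) -
                               model$hazard_scale * l[i] * (tr$type == "survival"))
          p_i <- stats::plogis(stats::qlogis(model$base_probing) +
                               l[i] * (tr$type == "acceptance"))
          for (r in seq_len(R)) {
            alive <- TRUE
            for (t in seq_len(TT)) {
              if (alive && runif(1) < h_i) alive <- FALSE
              if (alive) {
                alive_obs <- alive_obs + 1L
                steps <- steps + 1
                if (runif(1) < p_i) probe_obs <- probe_obs + 1L
              }
            }
            if (alive) alive_end <- alive_end + 1L
          }
          acc[i] <- if (alive_obs > 0) probe_obs / alive_obs else NA_real_
          surv[i] <- steps / R
          cnt[i] <- alive_end
        }
        if (tr$type == "acceptance") ph[[nm]] <- acc
        else {
          ph[[nm]] <- surv
          ph[[sub("survival", "count", nm)]] <- cnt
        }
      }
    }
    truth$genetic_values <- gv
    initialize(cross, pheno = ph, truth = truth)
  })
}

#' Simulate chemosensory gene positions
#'
#' Places genes of the six chemosensory categories on the four chromosomes,
#' by default with the study's census of 179 genes (70 ORs, 60 GRs, 19 IRs,
#' 11 OBPs, 10 CSPs, 9 SNMPs). With \code{clustering = 0} positions are
#' uniform; otherwise each gene is, with probability \code{clustering},
#' placed around one of a set of Poisson-process cluster centres (normal
#' scatter, SD 0.5 Mb), emulating the tandem-array clustering of
#' chemosensory genes in aphid genomes.
#'
#' @param config A \code{\link{crossConfig}} (for chromosome lengths).
#' @param counts Named integer vector of genes per category.
#' @param clustering Clustering factor in [0, 1].
#' @param seed Integer seed.
#' @return data.frame: gene, category, chr, bp.
#' @export
simulateGenePositions <- function(config = crossConfig(),
                                  counts = c(OR = 70, GR = 60, IR = 19,
                                             OBP = 11, CSP = 10, SNMP = 9),
                                  clustering = 0, seed = 1L) {
  stopifnot(all(counts >= 0), clustering >= 0, clustering <= 1)
  withSeed(seed, {
    chrs <- config$chromosomes
    len_bp <- chrs$len_mb * 1e6
    centres <- lapply(seq_along(len_bp), function(ci)
      runif(max(1, rpois(1, chrs$len_mb[ci] / 20)), 0, len_bp[ci]))
    total <- sum(counts)
    category <- rep(names(counts), counts)
    chr_i <- sample(seq_len(nrow(chrs)), total, replace = TRUE,
                    prob = len_bp / sum(len_bp))
    bp <- vapply(chr_i, function(ci) {
      if (runif(1) < clustering) {
        ctr <- centres[[ci]][sample.int(length(centres[[ci]]), 1)]
        min(max(1, round(ctr + rnorm(1, 0, 5e5))), len_bp[ci])
      } else round(runif(1, 1, len_bp[ci]))
    }, 0)
    data.frame(gene = sprintf("%s%02d", category, stats::ave(seq_len(total),
                                                             category, FUN = seq_along)),
               category = category, chr = chrs$chr[chr_i], bp = bp,
               stringsAsFactors = FALSE)
  })
}

#' One-call synthetic cross
#'
#' Convenience wrapper running \code{\link{simulateFounders}},
#' \code{\link{simulateF2Genotypes}} and \code{\link{simulatePhenotypes}}.
#'
#' @param config A \code{\link{crossConfig}}.
#' @param model A \code{\link{phenotypeModel}}.
#' @return An \code{\linkS4class{F2Cross}}.
#' @export
simulateCross <- function(config = crossConfig(), model = phenotypeModel()) {
  fd <- simulateFounders(config)
  cr <- simulateF2Genotypes(fd, config)
  simulatePhenotypes(cr, model, seed = childSeed(config$seed, "phenotypes"))
}
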