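test_that("GRM matches the hand-computed VanRaden form and its invariants", {
  # one SNP, p = 0.5, dosages (0,1,2): centred codes (-1,0,1), scale 0.5
  X <- matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "s1"))
  K <- computeGRM(X, ridge = 0)
  expect_equal(unname(K), matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3, 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  # identical genotype rows: off-diagonal equals diagonal (ridge aside)
  set.seed(2)
  X2 <- matrix(sample(0:2, 40, TRUE), 4, 10)[c(1, 1, 2, 3), ]
  K2 <- computeGRM(X2, ridge = 0)
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-12)
  # symmetric, PSD after ridge, invariant to SNP order
  cr <- cleanCross(n_f2 = 80, seed = 71)
  K3 <- computeGRM(genotypes(cr))
  expect_true(isSymmetric(K3))
  expect_gte(min(eigen(K3, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  perm <- sample(ncol(genotypes(cr)))
  K4 <- computeGRM(genotypes(cr)[, perm])
  expect_equal(unname(K3), unname(K4), tolerance = 1e-12, ignore_attr = TRUE)
  # mean diagonal near 1 on simulated F2 data
  expect_lt(abs(mean(diag(K3)) - 1), 0.1)
  expect_error(computeGRM(matrix(1L, 5, 3)), "polymorphic")
})

test_that("window tiling follows the width/slide convention", {
  map <- data.frame(marker = sprintf("m%d", 1:120), chr = "A3",
                    bp = 1:120, cM = seq(0, 114, length.out = 120))
  w <- defineWindows(map, 20, 10)
  expect_equal(nrow(w), 11)
  expect_equal(w$start, c(seq(0, 90, 10), 94))
  expect_equal(w$end - w$start, rep(20, 11))
  # length exactly = width: a single [0, 20) window
  map2 <- data.frame(marker = sprintf("m%d", 1:10), chr = "c", bp = 1:10,
                     cM = seq(0, 20, length.out = 10))
  w2 <- defineWindows(map2, 20, 10)
  expect_equal(nrow(w2), 1)
  expect_equal(c(w2$start, w2$end), c(0, 20))
  # chromosome shorter than the width: whole-chromosome window, flagged
  map3 <- data.frame(marker = sprintf("m%d", 1:5), chr = "c", bp = 1:5,
                     cM = seq(0, 12, length.out = 5))
  w3 <- defineWindows(map3, 20, 10)
  expect_equal(w3$flag, "whole_chromosome")
  expect_error(defineWindows(map, 10, 10), "width")
  # study map lengths: window count reported by this tiling
  map4 <- do.call(rbind, mapply(function(chr, len) {
    data.frame(marker = paste0(chr, 1:50), chr = chr, bp = 1:50,
               cM = seq(0, len, length.out = 50))
  }, c("A1", "A2", "A3", "X"), c(172, 112, 114, 204), SIMPLIFY = FALSE))
  w4 <- defineWindows(map4, 20, 10)
  expect_equal(nrow(w4), 17 + 11 + 11 + 20)
})

test_that("REML recovers planted variance components and flags edge cases", {
  set.seed(5)
  cr <- cleanCross(n_f2 = 192, n_markers = c(40, 30, 30, 40), seed = 4)
  map <- markerMap(cr)
  w <- map$chr == "A1" & map$cM >= 50 & map$cM < 70
  Kr <- computeGRM(genotypes(cr), map$marker[w])
  Kb <- computeGRM(genotypes(cr), map$marker[!w])
  n <- nrow(Kr)
  L1 <- chol(Kr); L2 <- chol(Kb)
  est <- replicate(12, {
    y <- sqrt(0.3) * as.numeric(t(L1) %*% rnorm(n)) +
      sqrt(0.2) * as.numeric(t(L2) %*% rnorm(n)) + rnorm(n, 0, sqrt(0.5))
    fitVarianceComponents(y, list(Kr, Kb))$sigma2
  })
  expect_lt(max(abs(rowMeans(est) - c(0.3, 0.2, 0.5))), 0.1)
  # pure-noise trait: genetic components near zero
  null_frac <- replicate(10, {
    f <- fitVarianceComponents(rnorm(n), list(Kr, Kb))
    sum(f$sigma2[1:2]) / sum(f$sigma2)
  })
  expect_lt(median(null_frac), 0.05)
  # identical matrices: flagged non-identifiable, total still recovered
  y <- sqrt(0.5) * as.numeric(t(L1) %*% rnorm(n)) + rnorm(n, 0, sqrt(0.5))
  f2 <- fitVarianceComponents(y, list(Kr, Kr))
  expect_false(f2$identifiable)
  expect_lt(abs(sum(f2$sigma2[1:2]) / sum(f2$sigma2) - 0.5), 0.2)
  # components are non-negative and heritabilities in [0, 1]
  expect_true(all(f2$sigma2 >= 0))
  expect_true(f2$h2_total >= 0 && f2$h2_total <= 1)
})

test_that("binomial PQL approaches the Gaussian fit for informative counts", {
  set.seed(8)
  cr <- cleanCross(n_f2 = 160, n_markers = c(30, 20, 20, 26), seed = 9)
  K <- computeGRM(genotypes(cr))
  n <- nrow(K)
  g <- sqrt(0.4) * as.numeric(t(chol(K)) %*% rnorm(n))
  p <- plogis(g + rnorm(n, 0, sqrt(0.6)))
  big <- 400   # large denominator: observed proportions are nearly exact
  y <- rbinom(n, big, p)
  fb <- fitVarianceComponents(y, list(K), family = "binomial", denom = big)
  fg <- fitVarianceComponents(qlogis((y + 0.5) / (big + 1)), list(K))
  expect_lt(abs(fb$h2_total - fg$h2_total), 0.1)
  # and the count-of-4 survival trait runs end to end
  y4 <- rbinom(n, 4, p)
  f4 <- fitVarianceComponents(y4, list(K), family = "binomial", denom = 4)
  expect_true(f4$h2_total >= 0 && f4$h2_total <= 1)
})

test_that("regional scan ranks a causal window highly and reports overall h2", {
  hits <- 0; nrep <- 5
  for (s in seq_len(nrep)) {
    cc <- crossConfig(n_f2 = 150, n_markers = c(30, 20, 20, 26), seed = 500 + s,
                      error_rate = 0, missing_rate = 0)
    cr <- simulateF2Genotypes(simulateFounders(cc), cc)
    # a 20 cM cluster of 10 small-effect loci jointly explaining ~15%
    qtl <- data.frame(chr = "A2", pos = seq(40, 58, 2), pve = 0.015, dom = 0)
    model <- phenotypeModel(traits = list(
      acc = list(h2 = 0.30, type = "acceptance", qtl = qtl)))
    cr <- simulatePhenotypes(cr, model, seed = s)
    rs <- regionalScan(phenotypes(cr)$acc, genotypes(cr), markerMap(cr))
    top <- rs$windows[order(rs$windows$Vr, decreasing = TRUE)[1:3], ]
    if (any(top$chr == "A2" & top$start < 60 & top$end > 40)) hits <- hits + 1
  }
  expect_gte(hits, 3)
})

test_that("overall heritability is recovered at the study's alfalfa-acceptance value", {
  est <- vapply(1:10, function(s) {
    cc <- crossConfig(n_f2 = 192, n_markers = c(30, 20, 20, 26), seed = 600 + s,
                      error_rate = 0, missing_rate = 0)
    cr <- simulateF2Genotypes(simulateFounders(cc), cc)
    model <- phenotypeModel(traits = list(
      acc = list(h2 = 0.299, type = "acceptance",
                 qtl = data.frame(chr = "A3", pos = 60, pve = 0.15, dom = 0))))
    cr <- simulatePhenotypes(cr, model, seed = s)
    K <- computeGRM(genotypes(cr))
    fitVarianceComponents(phenotypes(cr)$acc, list(K))$h2_total
  }, 0)
  expect_lt(abs(mean(est) - 0.299), 0.08)
})

test_that("regional permutation is deterministic and detects a strong signal", {
  set.seed(12)
  cr <- cleanCross(n_f2 = 96, n_markers = c(24, 16, 16, 20), seed = 13)
  map <- markerMap(cr)
  w <- map$chr == "A1" & map$cM >= 40 & map$cM < 60
  Kr <- computeGRM(genotypes(cr), map$marker[w])
  Kb <- computeGRM(genotypes(cr), map$marker[!w])
  n <- nrow(Kr)
  y <- sqrt(0.5) * as.numeric(t(chol(Kr)) %*% rnorm(n)) + rnorm(n, 0, sqrt(0.5))
  p1 <- regionalPermutationTest(y, Kr, Kb, B = 60, seed = 3, force = TRUE)
  p2 <- regionalPermutationTest(y, Kr, Kb, B = 60, seed = 3, force = TRUE)
  expect_identical(p1$cutoff, p2$cutoff)
  expect_true(p1$exceeds)
  expect_error(regionalPermutationTest(y, Kr, Kb, B = 50), "force")
})
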