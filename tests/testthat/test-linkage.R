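test_that("marker filters remove exactly the constructed violations", {
  cc <- crossConfig(n_f2 = 192, n_markers = c(40, 30, 30, 40), seed = 11,
                    prop_uninformative = 0.1, prop_f0_het = 0.05,
                    prop_distorted = 0.05, error_rate = 0.001,
                    missing_rate = 0.05)
  cr <- simulateF2Genotypes(simulateFounders(cc), cc)
  fm <- filterMarkers(cr)
  truth <- truthRecord(cr)$marker_flags
  called <- fm$report$status
  # rule 1 catches monomorphic and het-founder markers
  expect_true(all(called[truth$status %in% c("uninformative", "f0_het")] ==
                    "uninformative"))
  # rule 2 catches the distorted markers
  expect_true(all(called[truth$status == "distorted"] == "distorted"))
  # informative markers survive (redundant collapse aside)
  expect_true(all(called[truth$status == "informative"] %in%
                    c("retained", "redundant")))
})

test_that("textbook filter cases behave as specified", {
  # exact 1:2:1 retained; (96, 96, 0) distorted; duplicate column collapsed
  geno <- cbind(
    clean = rep(1:3, c(48, 96, 48)),
    skew = rep(c(1L, 2L), c(96, 96)),
    dup = rep(1:3, c(48, 96, 48)))
  map <- data.frame(marker = colnames(geno), chr = "A1",
                    bp = c(1e6, 2e6, 3e6), cM = c(0, 1, 2))
  f0 <- matrix("AA", 4, 3, dimnames = list(NULL, colnames(geno)))
  f0[3:4, ] <- "BB"
  f1 <- matrix("AB", 2, 3, dimnames = list(NULL, colnames(geno)))
  cr <- new("F2Cross", geno = geno, map = map,
            pheno = data.frame(id = as.character(seq_len(192))),
            founders = list(f0 = f0, f1 = f1), truth = list())
  fm <- filterMarkers(cr)
  st <- setNames(fm$report$status, fm$report$marker)
  expect_equal(unname(st["clean"]), "retained")
  expect_equal(unname(st["skew"]), "distorted")
  expect_equal(unname(st["dup"]), "redundant")
  # all-missing column flagged no_data
  geno2 <- geno; geno2[, 2] <- NA_integer_
  cr2 <- initialize(cr, geno = geno2)
  expect_equal(filterMarkers(cr2)$report$status[2], "no_data")
})

test_that("recombination-fraction estimator is consistent and bounded", {
  # identical columns: r = 0, LOD near the cosegregation maximum n*log10(2)
  g <- cleanCross(n_f2 = 100, seed = 13)
  i <- which(markerMap(g)$chr == "A1")[1]
  est <- estimateRF(genotypes(g)[, i], genotypes(g)[, i])
  expect_lt(est$r, 1e-4)
  expect_gt(est$lod, 100 * log10(2) * 0.95)
  # unlinked markers: r ~ 0.5, LOD below 3
  cc <- crossConfig(n_f2 = 188, n_markers = c(2, 2, 2, 2), seed = 17,
                    error_rate = 0, missing_rate = 0)
  cr <- simulateF2Genotypes(simulateFounders(cc), cc)
  m <- markerMap(cr)
  a <- which(m$chr == "A1")[1]; b <- which(m$chr == "A2")[1]
  est2 <- estimateRF(genotypes(cr)[, a], genotypes(cr)[, b])
  expect_gt(est2$r, 0.4)
  expect_lt(est2$lod, 3)
  # consistency at true female r = 0.10 (10.54 cM), n = 2000
  d <- haldaneInverse(0.10)
  rhats <- vapply(1:15, function(s) {
    cc <- crossConfig(n_f2 = 2000, n_markers = c(2, 2, 2, 2), seed = 100 + s,
                      error_rate = 0, missing_rate = 0)
    fd <- simulateFounders(cc)
    fd$markers$cM[1:2] <- c(10, 10 + d)
    cr <- simulateF2Genotypes(fd, cc)
    estimateRF(genotypes(cr)[, 1], genotypes(cr)[, 2])$r
  }, 0)
  expect_lt(abs(mean(rhats) - 0.10), 0.01)
  # low-support flag
  expect_equal(estimateRF(c(1L, 2L, 3L, rep(NA_integer_, 5)),
                          c(1L, 2L, 3L, rep(NA_integer_, 5)))$flag,
               "low_support")
})

test_that("rf invariants hold on a simulated marker panel", {
  cr <- cleanCross(n_f2 = 150, n_markers = c(12, 8, 8, 10), seed = 19)
  rf <- estimateRFMatrix(genotypes(cr))
  expect_true(all(rf$r >= 0 & rf$r <= 0.5))
  expect_true(all(rf$lod >= 0))
  expect_true(isSymmetric(rf$r))
})

test_that("LOD-threshold grouping recovers the four chromosomes with a plateau", {
  cr <- cleanCross(n_f2 = 192, n_markers = c(30, 20, 20, 25), seed = 23)
  rf <- estimateRFMatrix(genotypes(cr))
  scan <- lodThresholdScan(rf$lod, limits = seq(5, 50, by = 5), size_limit = 10)
  expect_true(any(scan$n_groups == 4))
  plateau <- scan$lod_limit[scan$n_groups == 4]
  grp <- groupMarkers(rf$lod, plateau[1], size_limit = 10)
  expect_equal(length(grp$groups), 4)
  truth_chr <- markerMap(cr)$chr
  for (g in grp$groups)
    expect_equal(length(unique(truth_chr[match(g, markerMap(cr)$marker)])), 1)
  # grouping invariant to marker input order
  perm <- sample(ncol(rf$lod))
  grp2 <- groupMarkers(rf$lod[perm, perm], plateau[1], size_limit = 10)
  expect_setequal(
    unname(vapply(grp2$groups, function(x) paste(sort(x), collapse = ","), "")),
    unname(vapply(grp$groups, function(x) paste(sort(x), collapse = ","), "")))
  # degenerate threshold: everything dissolves
  expect_equal(length(groupMarkers(rf$lod, 1e6, size_limit = 10,
                                   join_lod = Inf)$groups), 0)
  expect_error(groupMarkers(rf$lod, 0), "positive")
})

test_that("singletons rejoin their best group when the join LOD allows", {
  lod <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  lod[1, 2] <- lod[2, 1] <- 50
  lod[1, 3] <- lod[3, 1] <- 50
  lod[4, 2] <- lod[2, 4] <- 3.2
  grp <- groupMarkers(lod, lod_limit = 10, size_limit = 3, join_lod = 3)
  expect_equal(unname(grp$assignment["d"]), unname(grp$assignment["b"]))
  grp2 <- groupMarkers(lod, lod_limit = 10, size_limit = 3, join_lod = 4)
  expect_true(is.na(grp2$assignment["d"]))
})

test_that("marker ordering recovers a known order and flags instability", {
  # triangle: r(AB) = r(BC) = 0.1, r(AC) = 0.18 -> order A-B-C
  r3 <- matrix(c(0, .1, .18, .1, 0, .1, .18, .1, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  om <- orderMarkers(r3, n_runs = 5, seed = 2)
  expect_true(identical(om$order, c("A", "B", "C")) ||
                identical(om$order, c("C", "B", "A")))
  # simulated chain with r = 0.05 spacing, n = 500
  d <- haldaneInverse(0.05)
  cc <- crossConfig(n_f2 = 500, n_markers = c(10, 2, 2, 2), seed = 29,
                    error_rate = 0, missing_rate = 0)
  fd <- simulateFounders(cc)
  i <- which(fd$markers$chr == "A1")
  fd$markers$cM[i] <- seq(0, by = d, length.out = 10)
  cr <- simulateF2Genotypes(fd, cc)
  rf <- estimateRFMatrix(genotypes(cr)[, i])
  om2 <- orderMarkers(rf$r, n_runs = 6, seed = 3)
  truth <- fd$markers$marker[i]
  expect_true(identical(om2$order, truth) || identical(om2$order, rev(truth)))
  # rank-range bookkeeping: flagged set is exactly markers with range > tol
  rng <- apply(om2$ranks, 1, function(x) diff(range(x)))
  expect_setequal(om2$flagged, names(rng)[rng > 2])
})

test_that("genetic map distances follow the Haldane transform", {
  expect_equal(haldaneInverse(0), 0)
  expect_equal(haldaneInverse(0.0906), -50 * log(1 - 0.1812), tolerance = 1e-12)
  expect_equal(haldaneInverse(0.0906), 10.0, tolerance = 0.01)
  r <- matrix(c(0, .0906, .5, .0906, 0, .2, .5, .2, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  gm <- buildGeneticMap(list(LG1 = c("A", "B", "C")), r)
  expect_equal(gm$cM, c(0, 10.0, 10.0 + haldaneInverse(0.2)), tolerance = 0.01)
  # unlinked adjacency capped and flagged
  gm2 <- buildGeneticMap(list(LG1 = c("A", "C", "B")), r, max_gap = 50)
  expect_true(any(gm2$capped))
  expect_equal(max(diff(gm2$cM)), 50)
})

test_that("error-LOD flags planted impossible calls and spares clean data", {
  cr <- cleanCross(n_f2 = 30, n_markers = c(20, 5, 5, 5), seed = 3)
  # calls concordant with both flanking markers have negative error LOD
  el0 <- errorLodFlag(cr)
  idx <- which(markerMap(cr)$chr == "A1")
  g0 <- genotypes(cr)
  for (k in idx[c(-1, -length(idx))]) {
    conc <- g0[, k] == g0[, k - 1] & g0[, k] == g0[, k + 1]
    expect_true(all(el0$errorlod[conc, k] < 0))
  }
  # a homozygote flipped to the opposite homozygote between tight flanks
  g <- genotypes(cr)
  i <- which(markerMap(cr)$chr == "A1")[10]
  g[1, i] <- c(3L, 3L, 1L)[g[1, i]]
  cr2 <- initialize(cr, geno = g)
  el <- errorLodFlag(cr2)
  expect_gt(el$errorlod[1, i], 5)
  expect_true(markerMap(cr)$marker[i] %in% el$flagged)
  # error-free data: no flags across seeds
  flags <- vapply(1:5, function(s) {
    length(errorLodFlag(cleanCross(n_f2 = 40, seed = 200 + s))$flagged)
  }, 0L)
  expect_true(all(flags == 0))
  # chromosome with < 3 markers flagged too_sparse
  cc <- crossConfig(n_f2 = 30, n_markers = c(5, 2, 4, 4), seed = 2,
                    error_rate = 0, missing_rate = 0)
  cr3 <- simulateF2Genotypes(simulateFounders(cc), cc)
  expect_true("A2" %in% errorLodFlag(cr3)$too_sparse)
})
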