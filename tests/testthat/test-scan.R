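test_that("genotype probabilities normalise and honour typed markers", {
  cr <- cleanCross(n_f2 = 60, seed = 51)
  gp <- calcGenoprob(cr, step = 2, error_prob = 0)
  for (chr in names(gp@prob)) {
    s <- apply(gp@prob[[chr]], c(1, 2), sum)
    expect_lt(max(abs(s - 1)), 1e-12)
  }
  # with eps = 0 the posterior at a typed marker is 1 on the observed class
  m <- markerMap(cr)
  i1 <- which(m$chr == "A1")
  grid <- gp@grid[["A1"]]
  at <- match(m$marker[i1], grid$marker)
  P <- gp@prob[["A1"]]
  for (k in seq_along(i1)[1:5]) {
    obs <- genotypes(cr)[, i1[k]]
    expect_equal(P[cbind(seq_len(60), at[k], obs)], rep(1, 60))
  }
})

test_that("HMM posterior between flanking markers matches path enumeration", {
  # two markers 20 cM apart, individual typed AA then AB; query the midpoint.
  # (AA then BB is impossible under achiasmatic males: the paternal
  # haplotype cannot switch within a chromosome.)
  geno <- matrix(c(1L, 2L), 1, 2, dimnames = list("i1", c("m1", "m2")))
  map <- data.frame(marker = c("m1", "m2"), chr = "A1", bp = c(1, 2e6),
                    cM = c(0, 20))
  cr <- new("F2Cross", geno = geno, map = map,
            pheno = data.frame(id = "i1"), founders = list(), truth = list())
  gp <- calcGenoprob(cr, step = 10, error_prob = 0)
  mid <- which(gp@grid[["A1"]]$pos == 10)
  got <- gp@prob[["A1"]][1, mid, ]
  want <- enumPosteriorBetween(10, 10, 1L, 2L)
  expect_equal(unname(got), want, tolerance = 1e-9)
  # and at an asymmetric query point
  gp2 <- calcGenoprob(cr, step = 5, error_prob = 0)
  q <- which(gp2@grid[["A1"]]$pos == 5)
  expect_equal(unname(gp2@prob[["A1"]][1, q, ]),
               enumPosteriorBetween(5, 15, 1L, 2L), tolerance = 1e-9)
})

test_that("nonparametric scan equals the Kruskal-Wallis oracle at typed markers", {
  set.seed(7)
  cr <- cleanCross(n_f2 = 120, seed = 53)
  y <- rnorm(120) + 0.5 * (genotypes(cr)[, 3] - 2)
  y[sample(120, 10)] <- round(y[sample(120, 10)], 1)  # introduce ties
  gp <- calcGenoprob(cr, step = 1000, error_prob = 0)
  sc <- scanNonparametric(gp, y)
  m <- markerMap(cr)
  for (j in c(1, 3, 20, 30)) {
    kw <- kruskal.test(y, factor(genotypes(cr)[, j]))
    row <- sc@lod$marker == m$marker[j] & !is.na(sc@lod$marker)
    expect_equal(sc@lod$lod[which(row)], unname(kw$statistic) / (2 * log(10)),
                 tolerance = 1e-10)
  }
  # X markers scan with 2 classes
  jX <- which(m$chr == "X")[1]
  kwX <- kruskal.test(y, factor(genotypes(cr)[, jX]))
  rowX <- which(sc@lod$marker == m$marker[jX])
  expect_equal(sc@lod$lod[rowX], unname(kwX$statistic) / (2 * log(10)),
               tolerance = 1e-10)
  # perfect monotone signal peaks at its marker
  y2 <- as.numeric(genotypes(cr)[, 10])
  sc2 <- scanNonparametric(calcGenoprob(cr, step = 1, error_prob = 0), y2)
  expect_equal(sc2@lod$marker[which.max(sc2@lod$lod)], m$marker[10])
  # constant trait: warning and zero LOD
  expect_warning(sc3 <- scanNonparametric(gp, rep(1, 120)), "constant")
  expect_true(all(sc3@lod$lod == 0))
})

test_that("two-part scan equals closed-form marker ML and handles the all-spike edge", {
  set.seed(11)
  cr <- cleanCross(n_f2 = 150, seed = 57)
  g <- genotypes(cr)[, 5]
  y <- ifelse(runif(150) < 0.3 + 0.15 * (g - 2), 17,
              14 + 0.8 * (g - 2) + rnorm(150, 0, 0.8))
  y <- pmin(y, 17)
  gp <- calcGenoprob(cr, step = 1000, error_prob = 0)
  sc <- scanTwopart(gp, y, spike_at_upper = TRUE)
  z <- y == max(y)
  m <- markerMap(cr)
  for (j in c(2, 5, 25)) {
    cls <- genotypes(cr)[, j]
    ll1 <- closedFormTwopartLL(cls, z, y)
    ll0 <- closedFormTwopartLL(rep(1L, 150), z, y)
    row <- which(sc@lod$marker == m$marker[j])
    expect_equal(sc@lod$lod[row], (ll1 - ll0) / log(10), tolerance = 1e-6)
  }
  # component LODs are reported and joint >= 0
  expect_true(all(c("lod_spike", "lod_quant") %in% names(sc@lod)))
  expect_true(all(sc@lod$lod >= 0))
  # everyone in the spike: flat zero joint LOD
  sc0 <- scanTwopart(gp, rep(17, 150))
  expect_true(all(sc0@lod$lod == 0))
})

test_that("permutation thresholds are deterministic and rank-invariant", {
  cr <- cleanCross(n_f2 = 80, n_markers = c(10, 6, 6, 8), seed = 61)
  set.seed(1); y <- rnorm(80)
  gp <- calcGenoprob(cr, step = 20, error_prob = 0)
  t1 <- scanPermutationThreshold(gp, y, "nonparametric", B = 120, seed = 9)
  t2 <- scanPermutationThreshold(gp, y, "nonparametric", B = 120, seed = 9)
  expect_identical(as.numeric(t1), as.numeric(t2))
  # monotone transform of the trait leaves the rank-based threshold unchanged
  t3 <- scanPermutationThreshold(gp, exp(y), "nonparametric", B = 120, seed = 9)
  expect_equal(as.numeric(t1), as.numeric(t3))
  expect_error(scanPermutationThreshold(gp, y, B = 50), "B")
})

test_that("LOD support intervals contain their peak and widen with the drop", {
  prof <- data.frame(chr = "A1", pos = seq(0, 100, 1), marker = NA_character_)
  prof$lod <- 8 - 1.5 * ((prof$pos - 50) / 10)^2
  prof$marker[seq(1, 101, 5)] <- sprintf("m%d", seq(1, 101, 5))
  sc <- new("ScanResult", lod = prof, model = "nonparametric", trait = "t",
            threshold = NA_real_, peaks = data.frame(), n = 100L)
  iv <- lodInterval(sc, "A1", drop = 1.5)
  expect_equal(iv$peak, 50)
  # 1.5 drop at +-10 cM, expanded outward to flanking typed markers
  expect_lte(iv$lo, 40); expect_gte(iv$hi, 60)
  expect_lte(iv$hi - iv$lo, 30)
  # monotone LOD to the chromosome end clips at the boundary
  prof2 <- prof; prof2$lod <- prof2$pos / 10
  sc2 <- initialize(sc, lod = prof2)
  iv2 <- lodInterval(sc2, "A1")
  expect_equal(iv2$hi, 100)
  # interval always contains the peak and widens as drop increases
  set.seed(3)
  for (k in 1:10) {
    prof3 <- prof
    prof3$lod <- abs(cumsum(rnorm(101, 0, 0.5)))
    sc3 <- initialize(sc, lod = prof3)
    a <- lodInterval(sc3, "A1", 1); b <- lodInterval(sc3, "A1", 2)
    expect_true(a$lo <= a$peak && a$peak <= a$hi)
    expect_true(b$lo <= a$lo && b$hi >= a$hi)
  }
  expect_error(lodInterval(sc, "A1", drop = 0), "positive")
})

test_that("variance explained follows the LOD transform", {
  expect_equal(varianceExplained(0, 192), 0)
  expect_equal(varianceExplained(6.63, 188), 1 - 10^(-(2 / 188) * 6.63))
  expect_equal(varianceExplained(6.63, 188), 0.150, tolerance = 0.005)
  lods <- seq(0, 20, 0.5)
  pve <- varianceExplained(lods, 188)
  expect_true(all(diff(pve) > 0))
  expect_true(all(pve < 1))
})

test_that("simulated moderate QTL is localised by the scans", {
  hits_np <- 0; hits_tp <- 0; nrep <- 8
  for (s in seq_len(nrep)) {
    cc <- crossConfig(n_f2 = 192, n_markers = c(20, 12, 20, 16), seed = 400 + s)
    cr <- simulateF2Genotypes(simulateFounders(cc), cc)
    model <- phenotypeModel(traits = list(
      acc = list(h2 = 0.20, type = "acceptance",
                 qtl = data.frame(chr = "A3", pos = 60, pve = 0.15, dom = 0)),
      surv = list(h2 = 0.15, type = "survival",
                  qtl = data.frame(chr = "A3", pos = 60, pve = 0.10, dom = 0))))
    cr <- simulatePhenotypes(cr, model, seed = s)
    gp <- calcGenoprob(cr, step = 5, error_prob = 1e-3)
    sc <- scanNonparametric(gp, phenotypes(cr)$acc)
    top <- sc@lod[which.max(sc@lod$lod), ]
    if (top$chr == "A3" && abs(top$pos - 60) <= 15) hits_np <- hits_np + 1
    st <- scanTwopart(gp, phenotypes(cr)$surv)
    topt <- st@lod[which.max(st@lod$lod), ]
    if (topt$chr == "A3" && abs(topt$pos - 60) <= 20) hits_tp <- hits_tp + 1
  }
  expect_gte(hits_np, nrep * 0.6)
  expect_gte(hits_tp, nrep * 0.5)
})
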