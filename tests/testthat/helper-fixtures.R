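# shared fixtures and independent oracles

# small clean cross: no genotyping error, no missing data
cleanCross <- function(n_f2 = 100, n_markers = c(20, 12, 12, 16), seed = 42,
                       ...) {
  cc <- crossConfig(n_f2 = n_f2, n_markers = n_markers, seed = seed,
                    error_rate = 0, missing_rate = 0, ...)
  simulateF2Genotypes(simulateFounders(cc), cc)
}

# brute-force double-loop gene/region containment oracle (half-open bp)
bruteGenesInRegions <- function(genes, regions) {
  out <- rep(FALSE, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(regions))) {
      if (genes$chr[i] == regions$chr[j] &&
          genes$bp[i] >= regions$start[j] && genes$bp[i] < regions$end[j]) {
        out[i] <- TRUE
      }
    }
  }
  genes$gene[out]
}

# exact two-sided Fisher p by full enumeration over the hypergeometric
# support (minimum-likelihood rule)
enumFisherP <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Cayley-graph signed-reversal distances via igraph (independent of the
# package's bidirectional BFS)
cayleyReversalDistances <- function(K) {
  perms <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == K), , drop = FALSE]
  states <- list()
  for (i in seq_len(nrow(perms))) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), K)))
    for (s in seq_len(nrow(signs)))
      states[[length(states) + 1]] <- perms[i, ] * signs[s, ]
  }
  key <- vapply(states, paste, "", collapse = ",")
  idx <- stats::setNames(seq_along(states), key)
  edges <- NULL
  for (s in seq_along(states)) {
    p <- states[[s]]
    for (i in seq_len(K)) for (j in i:K) {
      q <- p; q[i:j] <- -rev(q[i:j])
      t <- idx[[paste(q, collapse = ",")]]
      if (t > s) edges <- rbind(edges, c(s, t))
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  d <- igraph::distances(g, v = idx[[paste(seq_len(K), collapse = ",")]])
  list(states = states, dist = as.numeric(d))
}

# 4-state path enumeration oracle for the autosomal HMM posterior at a
# query position between two typed flanking markers (error-free emission)
enumPosteriorBetween <- function(d_left, d_right, g_left, g_right) {
  r1 <- haldane(d_left); r2 <- haldane(d_right)
  classOf <- function(m, p) (m == "B") + (p == "B") + 1L
  states <- expand.grid(m = c("A", "B"), p = c("A", "B"),
                        stringsAsFactors = FALSE)
  post <- numeric(3)
  for (p in c("A", "B")) {
    for (mL in c("A", "B")) for (mM in c("A", "B")) for (mR in c("A", "B")) {
      if (classOf(mL, p) != g_left || classOf(mR, p) != g_right) next
      pr <- 0.25 * 0.5 *
        (if (mM == mL) 1 - r1 else r1) *
        (if (mR == mM) 1 - r2 else r2)
      cl <- classOf(mM, p)
      post[cl] <- post[cl] + pr
    }
  }
  post / sum(post)
}

# closed-form marker-level ML for the two-part model with hard genotype
# classes: per-class binomial spike + per-class normal with pooled MLE sigma
closedFormTwopartLL <- function(cls, z, y) {
  ll <- 0
  for (g in unique(cls)) {
    i <- cls == g
    pg <- mean(z[i])
    if (pg > 0) ll <- ll + sum(z[i]) * log(pg)
    if (pg < 1) ll <- ll + sum(i & !z) * log(1 - pg)
  }
  yq <- y[!z]; cq <- cls[!z]
  mus <- tapply(yq, cq, mean)
  s2 <- mean((yq - mus[as.character(cq)])^2)
  ll + sum(dnorm(yq, mus[as.character(cq)], sqrt(s2), log = TRUE))
}
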