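# Independent scalar-loop oracles. These deliberately avoid the package's
# vectorized code paths: every quantity is accumulated element by element so
# the implementations can be checked against a spelled-out reading of the
# model equations.

oracleSigmoid <- function(x) 1 / (1 + exp(-x))

# GRU-gated propagation, one node and one dimension at a time.
oraclePropagate <- function(X, A, w, steps) {
  n <- nrow(X); d <- ncol(X)
  H <- X
  for (t in seq_len(steps)) {
    O <- matrix(0, n, d); Z <- O; R <- O; C <- O; Hn <- O
    for (i in seq_len(n)) {
      agg <- numeric(d)
      for (j in seq_len(n)) for (b in seq_len(d))
        agg[b] <- agg[b] + A[i, j] * H[j, b]
      for (a in seq_len(d)) {
        o <- w$b_o[a]
        for (b in seq_len(d)) o <- o + agg[b] * w$W_o[b, a]
        O[i, a] <- o
      }
    }
    for (i in seq_len(n)) for (a in seq_len(d)) {
      z <- w$b_z[a]; r <- w$b_r[a]
      for (b in seq_len(d)) {
        z <- z + O[i, b] * w$W_z[b, a] + H[i, b] * w$U_z[b, a]
        r <- r + O[i, b] * w$W_r[b, a] + H[i, b] * w$U_r[b, a]
      }
      Z[i, a] <- oracleSigmoid(z); R[i, a] <- oracleSigmoid(r)
    }
    for (i in seq_len(n)) for (a in seq_len(d)) {
      cc <- w$b_h[a]
      for (b in seq_len(d))
        cc <- cc + O[i, b] * w$W_h[b, a] + R[i, b] * H[i, b] * w$U_h[b, a]
      C[i, a] <- tanh(cc)
      Hn[i, a] <- C[i, a] * Z[i, a] + H[i, a] * (1 - Z[i, a])
    }
    H <- Hn
  }
  H
}

# Gated readout: sigmoid(f1) * tanh(f2) per node, shrunken mean + max-pool.
oracleReadout <- function(H, w, pooling = "fused") {
  n <- nrow(H); d <- ncol(H)
  G <- matrix(0, n, d)
  for (i in seq_len(n)) {
    t1 <- numeric(d); t2 <- numeric(d)
    for (a in seq_len(d)) {
      s1 <- w$a1[a]; s2 <- w$b1[a]
      for (b in seq_len(d)) {
        s1 <- s1 + H[i, b] * w$A1[b, a]
        s2 <- s2 + H[i, b] * w$B1[b, a]
      }
      t1[a] <- tanh(s1); t2[a] <- tanh(s2)
    }
    for (a in seq_len(d)) {
      f1 <- w$a2[a]; f2 <- w$b2[a]
      for (b in seq_len(d)) {
        f1 <- f1 + t1[b] * w$A2[b, a]
        f2 <- f2 + t2[b] * w$B2[b, a]
      }
      G[i, a] <- oracleSigmoid(f1) * tanh(f2)
    }
  }
  meanPart <- numeric(d); maxPart <- numeric(d)
  for (a in seq_len(d)) {
    meanPart[a] <- sum(G[, a]) / (n + 1)
    maxPart[a] <- max(G[, a])
  }
  switch(pooling, fused = meanPart + maxPart, mean = meanPart,
         max = maxPart)
}

# Additive attention over the parent vector and substructure vectors.
oracleFuse <- function(vectors, w) {
  e <- numeric(length(vectors))
  for (j in seq_along(vectors)) {
    s <- 0
    for (a in seq_along(w$cf)) {
      u <- w$bf[a]
      for (b in seq_along(vectors[[j]]))
        u <- u + w$Wf[a, b] * vectors[[j]][b]
      s <- s + w$cf[a] * tanh(u)
    }
    e[j] <- s
  }
  wts <- exp(e - max(e)); wts <- wts / sum(wts)
  h <- numeric(length(vectors[[1]]))
  for (j in seq_along(vectors)) h <- h + wts[j] * vectors[[j]]
  list(h = h, weights = wts)
}

# Per-position descriptor attention followed by the affine projection.
oracleDescriptorReadout <- function(m, w) {
  k <- length(m); da <- length(w$cm); d <- nrow(w$Wp)
  e <- numeric(k)
  for (j in seq_len(k)) {
    s <- 0
    for (a in seq_len(da))
      s <- s + w$cm[a] * tanh(w$P[a, j] * m[j] + w$Q[a, j])
    e[j] <- s
  }
  wts <- exp(e - max(e)); wts <- wts / sum(wts)
  hm <- numeric(d)
  for (a in seq_len(d)) {
    s <- w$bp[a]
    for (j in seq_len(k)) s <- s + w$Wp[a, j] * wts[j] * m[j]
    hm[a] <- s
  }
  list(hm = hm, weights = wts)
}

# Brute-force byte-pair learning over a toy corpus: explicit pair counting
# with nested loops, max by scan, lexicographic tie-break.
oracleBpe <- function(corpus, maxVocab, minFrequency) {
  seqs <- lapply(corpus, function(s) tokenizeSmiles(s)$token)
  merges <- list()
  for (step in seq_len(maxVocab)) {
    counts <- list()
    for (s in seqs) {
      if (length(s) < 2) next
      for (i in seq_len(length(s) - 1)) {
        key <- paste(s[i], s[i + 1], sep = "\r")
        counts[[key]] <- (counts[[key]] %||% 0) + 1
      }
    }
    if (!length(counts)) break
    bestKey <- NULL; bestN <- -1
    for (key in sort(names(counts))) {
      if (counts[[key]] > bestN) { bestN <- counts[[key]]; bestKey <- key }
    }
    if (bestN < minFrequency) break
    pr <- strsplit(bestKey, "\r", fixed = TRUE)[[1]]
    merges[[step]] <- c(pr, bestN)
    seqs <- lapply(seqs, function(s) {
      i <- 1
      while (i < length(s)) {
        if (s[i] == pr[1] && s[i + 1] == pr[2]) {
          s[i] <- paste0(pr[1], pr[2]); s <- s[-(i + 1)]
        }
        i <- i + 1
      }
      s
    })
  }
  merges
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct spreadsheet-style evaluation of the scorecard formula.
oracleScore <- function(woeRow, beta, a, factor, offset) {
  n <- length(woeRow)
  s <- 0
  for (i in seq_len(n))
    s <- s + (woeRow[i] * beta[i] + a / n) * factor + offset / n
  s
}

# Tiny deterministic parameter set builder for oracle comparisons.
tinyParams <- function(task = "regression", steps = 2L, k = 4L, seed = 7L) {
  p <- ggnnParameters(hiddenDim = 39L, interactionSteps = steps,
                      descriptorK = k, task = task, seed = seed)
  p
}
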