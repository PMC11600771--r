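# Independent oracles used by the property tests. These deliberately share no
# code with the package: the aligner oracle is a plain-R score-only affine
# dynamic program, and the t-distribution oracle evaluates the regularized
# incomplete beta function by Lentz's continued fraction.

# best local affine-gap score; gap of length L costs -(gap_open + L*gap_extend)
oracle_affine_local <- function(q, t, match = 2, mismatch = -4,
                                gap_open = -4, gap_extend = -2) {
  qv <- strsplit(q, "", fixed = TRUE)[[1]]
  tv <- strsplit(t, "", fixed = TRUE)[[1]]
  n <- length(qv); m <- length(tv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend, E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + gap_open + gap_extend, F[i - 1, j] + gap_extend)
      s <- if (qv[i - 1] == tv[j - 1] && qv[i - 1] != "N") match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# continued fraction for the incomplete beta function (modified Lentz)
oracle_betacf <- function(a, b, x) {
  qab <- a + b; qap <- a + 1; qam <- a - 1
  cc <- 1
  d <- 1 - qab * x / qap
  if (abs(d) < 1e-30) d <- 1e-30
  d <- 1 / d
  h <- d
  for (m in 1:300) {
    m2 <- 2 * m
    aa <- m * (b - m) * x / ((qam + m2) * (a + m2))
    d <- 1 + aa * d; if (abs(d) < 1e-30) d <- 1e-30
    cc <- 1 + aa / cc; if (abs(cc) < 1e-30) cc <- 1e-30
    d <- 1 / d
    h <- h * d * cc
    aa <- -(a + m) * (qab + m) * x / ((a + m2) * (qap + m2))
    d <- 1 + aa * d; if (abs(d) < 1e-30) d <- 1e-30
    cc <- 1 + aa / cc; if (abs(cc) < 1e-30) cc <- 1e-30
    d <- 1 / d
    del <- d * cc
    h <- h * del
    if (abs(del - 1) < 1e-14) break
  }
  h
}

oracle_ibeta <- function(x, a, b) {
  if (x <= 0) return(0)
  if (x >= 1) return(1)
  bt <- exp(lgamma(a + b) - lgamma(a) - lgamma(b) + a * log(x) + b * log1p(-x))
  if (x < (a + 1) / (a + b + 2)) bt * oracle_betacf(a, b, x) / a
  else 1 - bt * oracle_betacf(b, a, 1 - x) / b
}

# two-sided p-value of a t statistic: P(|T| > t) = I_{df/(df+t^2)}(df/2, 1/2)
oracle_t_p2 <- function(tstat, df) {
  oracle_ibeta(df / (df + tstat^2), df / 2, 0.5)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# corrupt a sequence with a few random edits (for aligner property cases)
mutate_dna <- function(s, n_edits) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  for (k in seq_len(n_edits)) {
    pos <- sample(length(v), 1)
    v[pos] <- switch(sample(3, 1),
                     sample(c("A", "C", "G", "T"), 1),          # substitute
                     paste0(v[pos], sample(c("A", "C", "G", "T"), 1)),  # insert
                     "")                                        # delete
  }
  paste(v, collapse = "")
}
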