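# Independent brute-force oracles. Deliberately naive: direct enumeration,
# no shared code with the package internals they check.

# Exact HWE p-value by enumeration of the unconditional genotype multinomial,
# conditioned on the observed allele-1 count. The conditional distribution is
# free of the allele frequency (sufficiency), so any p in (0,1) works.
oracle_hwe <- function(n_het, n_hom1, n_hom2, p = 0.3) {
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(1)
  allele1 <- 2 * n_hom1 + n_het
  triples <- expand.grid(aa = 0:n, ab = 0:n)
  triples$bb <- n - triples$aa - triples$ab
  triples <- triples[triples$bb >= 0, ]
  w <- apply(triples, 1, function(t) {
    exp(lgamma(n + 1) - lgamma(t[1] + 1) - lgamma(t[2] + 1) -
          lgamma(t[3] + 1)) *
      (p^2)^t[1] * (2 * p * (1 - p))^t[2] * ((1 - p)^2)^t[3]
  })
  cond <- 2 * triples$aa + triples$ab == allele1
  w <- w[cond] / sum(w[cond])
  tr <- triples[cond, ]
  obs <- which(tr$aa == n_hom1 & tr$ab == n_het)
  sum(w[w <= w[obs] * (1 + 1e-9)])
}

# Binomial upper tail by explicit term-wise summation.
oracle_binom_tail <- function(count, n, p) {
  if (count > n) return(0)
  k <- count:n
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log(1 - p)))
}

# Direct window-scan ROH caller: enumerate windows, score each SNP's hit
# fraction, walk runs one SNP at a time.
oracle_roh <- function(g, pos, params) {
  empty <- data.frame(start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer())
  L <- length(g)
  W <- params$window_snps
  if (L < W) return(empty)
  wins <- seq_len(L - W + 1)
  hom <- vapply(wins, function(i) {
    win <- g[i:(i + W - 1)]
    sum(win == 1L, na.rm = TRUE) <= params$window_max_het &&
      sum(is.na(win)) <= params$window_max_missing
  }, logical(1))
  state <- logical(L)
  for (j in seq_len(L)) {
    cov <- wins[wins <= j & wins + W - 1 >= j]
    state[j] <- mean(hom[cov]) >= params$window_hit_threshold
  }
  runs <- list()
  cur <- integer(0)
  for (j in seq_len(L)) {
    if (state[j]) {
      if (length(cur) &&
          pos[j] - pos[cur[length(cur)]] > params$max_gap_kb * 1000) {
        runs[[length(runs) + 1]] <- cur
        cur <- integer(0)
      }
      cur <- c(cur, j)
    } else if (length(cur)) {
      runs[[length(runs) + 1]] <- cur
      cur <- integer(0)
    }
  }
  if (length(cur)) runs[[length(runs) + 1]] <- cur
  out <- empty
  for (r in runs) {
    s <- r[1]; e <- r[length(r)]
    len <- pos[e] - pos[s] + 1
    if (length(r) >= params$min_snps_segment &&
        len >= params$min_length_kb * 1000 &&
        len / length(r) <= params$max_kb_per_snp * 1000)
      out <- rbind(out, data.frame(
        start_bp = pos[s], end_bp = pos[e], n_snps = e - s + 1L,
        n_het = sum(g[s:e] == 1L, na.rm = TRUE),
        n_missing = sum(is.na(g[s:e]))))
  }
  out
}

# Random single-chromosome genotype instances rich in homozygous stretches.
random_roh_instance <- function(max_snps = 1000, max_samples = 5) {
  L <- sample(50:max_snps, 1)
  n <- sample(1:max_samples, 1)
  gaps <- sample(c(5e3, 1e4, 2e4, 4e4), L, replace = TRUE)
  # occasional oversized gap to exercise run splitting
  big <- runif(L) < 0.005
  gaps[big] <- sample(c(1.2e6, 2e6), sum(big), replace = TRUE)
  pos <- cumsum(gaps)
  p_het <- runif(1, 0.01, 0.25)
  p_mis <- runif(1, 0, 0.08)
  g <- matrix(sample(c(0L, 2L), n * L, replace = TRUE), nrow = n)
  g[matrix(runif(n * L) < p_het, nrow = n)] <- 1L
  g[matrix(runif(n * L) < p_mis, nrow = n)] <- NA_integer_
  list(g = g, pos = pos, n = n, L = L)
}
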