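# Independent brute-force oracles, kept deliberately naive: straight loops
# and enumeration, no sharing with the package's computation paths.

# EHH at every site reached from the core, by all-pairs comparison of the
# carrier haplotype matrix.  X: sites x haplotypes; carriers: column ids.
ehhBrute <- function(X, core, carriers, at_site) {
  lo <- min(core, at_site)
  hi <- max(core, at_site)
  n <- length(carriers)
  same <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (all(X[lo:hi, carriers[i]] == X[lo:hi, carriers[j]]))
        same <- same + 1L
    }
  }
  same / choose(n, 2)
}

# Raw nucleotide diversity of a window: average pairwise difference count
# over all haplotype pairs.
thetaPiBrute <- function(X) {
  n <- ncol(X)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) tot <- tot + sum(X[, i] != X[, j])
  }
  tot / choose(n, 2)
}

# Weir-Cockerham components via the ANOVA mean-squares route (population /
# individual / gamete), an algebraically different organization from the
# package's direct component formulas.  g1, g2: 0/1/2 genotype vectors.
wcAnovaOracle <- function(g1, g2) {
  r <- 2
  n <- c(length(g1), length(g2))
  N <- sum(n)
  p <- c(mean(g1) / 2, mean(g2) / 2)
  h <- c(mean(g1 == 1), mean(g2 == 1))
  pw <- sum(n * p) / N
  MSP <- sum(2 * n * (p - pw)^2) / (r - 1)
  MSI <- sum(2 * n * p * (1 - p) - n * h / 2) / (N - r)
  MSG <- sum(n * h / 2) / N
  nc <- (N - sum(n^2) / N) / (r - 1)
  a <- (MSP - MSI) / (2 * nc)
  b <- (MSI - MSG) / 2
  cc <- MSG
  list(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

# Average-tie ranks by explicit sorting and duplicate averaging.
rankBrute <- function(x) {
  ord <- order(x)
  rk <- numeric(length(x))
  pos <- 1L
  while (pos <= length(x)) {
    v <- x[ord[pos]]
    run <- which(x[ord] == v)
    rk[ord[run]] <- mean(run)
    pos <- max(run) + 1L
  }
  rk
}

# CMS by independent rank computation and explicit per-site loop.
cmsBrute <- function(stats, min_stats = 3) {
  n <- nrow(stats)
  rf <- matrix(NA_real_, n, ncol(stats))
  for (j in seq_len(ncol(stats))) {
    ok <- !is.na(stats[[j]])
    rf[ok, j] <- rankBrute(stats[[j]][ok]) / (sum(ok) + 1)
  }
  cms <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    avail <- which(!is.na(rf[i, ]))
    if (length(avail))
      cms[i] <- 4 / length(avail) * sum(-log(1 - rf[i, avail]))
  }
  list(cms = cms, valid = rowSums(!is.na(rf)) >= min_stats)
}

# Step-by-step running-sum enrichment score.
esBrute <- function(scores, members, p = 1) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  run <- 0
  best <- 0
  hit <- names(s) %in% members
  NR <- sum(s[hit]^p)
  miss_step <- 1 / (length(s) - sum(hit))
  for (i in seq_along(s)) {
    if (hit[i]) run <- run + unname(s[i])^p / NR else run <- run - miss_step
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# U statistic by per-site inspection.
uBrute <- function(p_target, p_outgroup, arc_frac, w, x, y) {
  u <- 0L
  for (i in seq_along(p_target)) {
    if (is.na(p_target[i]) || is.na(p_outgroup[i]) || is.na(arc_frac[i]))
      next
    if (p_outgroup[i] < w && p_target[i] > x && arc_frac[i] == y)
      u <- u + 1L
  }
  u
}

# Maximal homozygous runs by scanning every subinterval.
rohBrute <- function(het, pos, window_snps, allowance, min_length_bp) {
  m <- length(het)
  ok_run <- function(a, b) {
    if (b - a + 1 < window_snps) return(FALSE)
    for (k in a:(b - window_snps + 1)) {
      if (sum(het[k:(k + window_snps - 1)]) > allowance) return(FALSE)
    }
    TRUE
  }
  runs <- list()
  for (a in seq_len(m)) {
    for (b in a:m) {
      if (ok_run(a, b)) {
        maximal <- !( (a > 1 && ok_run(a - 1, b)) ||
                      (b < m && ok_run(a, b + 1)) )
        if (maximal && pos[b] - pos[a] + 1 >= min_length_bp)
          runs[[length(runs) + 1L]] <- c(start = pos[a], end = pos[b])
      }
    }
  }
  runs
}
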