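# Independent oracles used across the suite.  Each recomputes the
# quantity under test by brute force (explicit enumeration, per-base
# accumulation, graph components), deliberately avoiding the code path
# it checks.

# NB pmf from the gamma-function formula (not dnbinom)
nb_pmf_lgamma <- function(k, r, mu) {
  exp(lgamma(k + r) - lgamma(r) - lfactorial(k) +
        r * log(r / (r + mu)) + k * log(mu / (mu + r)))
}

pois_pmf_lfact <- function(k, mu) {
  if (mu == 0) return(as.numeric(k == 0))
  exp(-mu + k * log(mu) - lfactorial(k))
}

# exhaustive conditional enumeration of the two-sided exact NB test
oracle_nb_exact <- function(pa, pb, n_a, n_b, phi) {
  t <- pa + pb
  if (t == 0) return(1)
  mu <- t / (n_a + n_b)
  a <- 0:t
  pr <- if (phi == 0) {
    pois_pmf_lfact(a, n_a * mu) * pois_pmf_lfact(t - a, n_b * mu)
  } else {
    nb_pmf_lgamma(a, n_a / phi, n_a * mu) *
      nb_pmf_lgamma(t - a, n_b / phi, n_b * mu)
  }
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[pa + 1] * (1 + 1e-10)]))
}

# exhaustive binomial enumeration of the two-sided sign test
oracle_sign_test <- function(n_pos, n) {
  pr <- choose(n, 0:n) / 2^n
  lo <- sum(pr[seq_len(n_pos + 1)])
  hi <- sum(pr[(n_pos + 1):(n + 1)])
  min(1, 2 * min(lo, hi))
}

# Fisher exact p by enumerating every table with the observed margins,
# probabilities from explicit log-factorials
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; n <- a + b + c + d
  lo <- max(0, k - m2); hi <- min(k, m1)
  logp <- function(x) {
    lfactorial(m1) + lfactorial(m2) + lfactorial(k) +
      lfactorial(n - k) - lfactorial(n) - lfactorial(x) -
      lfactorial(m1 - x) - lfactorial(k - x) -
      lfactorial(m2 - k + x)
  }
  pr <- exp(vapply(lo:hi, logp, 0))
  obs <- pr[a - lo + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]) / sum(pr))
}

# median-of-ratios by explicit loops
oracle_size_factors <- function(m) {
  keep <- apply(m, 1, function(r) all(r > 0))
  mm <- m[keep, , drop = FALSE]
  ref <- apply(mm, 1, function(r) prod(r)^(1 / length(r)))
  f <- vapply(seq_len(ncol(mm)), function(j)
    stats::median(mm[, j] / ref), 0)
  f / prod(f)^(1 / length(f))
}

# O(n * m) containment scan for coding variants
oracle_coding <- function(variants, annotation) {
  ex <- attr(annotation, "exons")
  chrom <- annotation$chrom[match(ex$gene, annotation$gene)]
  vapply(seq_len(nrow(variants)), function(i) {
    any(chrom == variants$chrom[i] &
          ex$start < variants$pos[i] & variants$pos[i] <= ex$end)
  }, TRUE)
}

# region calling as connected components of the "hot window" graph:
# consecutive hot windows are linked when separated by <= gap cold ones
oracle_call_regions <- function(counts, threshold, gap, min_span) {
  hot <- which(counts >= threshold)
  if (length(hot) == 0) return(matrix(numeric(0), ncol = 2))
  comp <- cumsum(c(1, diff(hot) - 1 > gap))
  out <- t(vapply(split(hot, comp), range, c(0, 0)))
  out[out[, 2] - out[, 1] + 1 >= min_span, , drop = FALSE]
}

# per-base accumulation of coverage mass over elements (toy genomes)
oracle_element_loads <- function(coverage, elements_df, genome_len) {
  base <- stats::setNames(
    lapply(unique(elements_df$chrom), function(x) numeric(genome_len)),
    unique(elements_df$chrom))
  for (i in seq_len(nrow(coverage))) {
    cc <- coverage$chrom[i]
    if (!cc %in% names(base)) next
    idx <- (coverage$start[i] + 1):coverage$end[i]
    idx <- idx[idx >= 1 & idx <= genome_len]
    base[[cc]][idx] <- base[[cc]][idx] + coverage$value[i]
  }
  vapply(seq_len(nrow(elements_df)), function(i) {
    v <- base[[elements_df$chrom[i]]]
    s <- elements_df$start[i]; e <- elements_df$end[i]
    sum(v[(s + 1):e]) / (e - s)
  }, 0)
}
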