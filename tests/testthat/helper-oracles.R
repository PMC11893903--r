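# Independent oracles used to validate the package's statistics.

# brute-force percentile index: explicit loop counting, midrank ties
oracle_index <- function(value, group) {
  lower <- 0
  equal <- 0
  for (w in group) {
    if (w < value) lower <- lower + 1
    if (w == value) equal <- equal + 1
  }
  100 * (lower + equal / 2) / length(group)
}

# two-sided Fisher exact p by exhaustive hypergeometric enumeration over
# all tables with the observed margins
oracle_fisher <- function(a, b, c, d) {
  m <- a + b        # row 1 total
  n <- c + d        # row 2 total
  k <- a + c        # column 1 total
  ks <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(ks, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# sorted-rank percentile (linear interpolation between order statistics,
# the type-7 definition) computed from first principles
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

# small default config reused across tests (kept light for speed);
# arguments in ... override the light defaults
tiny_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_strains = 24, n_genes = 40,
               genome_length = 120000, n_images = 2, n_nuclei = 5,
               seq_depth = 5e5)
  dots <- list(...)
  args <- c(dots, args[setdiff(names(args), names(dots))])
  do.call(sim_config, args)
}
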