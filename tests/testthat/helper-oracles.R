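# Independent brute-force oracles used to check the package's statistics.
# These never call the functions they validate.

# Exact two-sided Mann-Whitney p-value by full enumeration of the C(n, nx)
# assignments of the pooled (untied) values to the first group.
mw_exact_enum <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(n, nx)
  u_all <- apply(sets, 2, function(ix) sum(r[ix])) - nx * (nx + 1) / 2
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# Kruskal-Wallis H with tie correction, straight from the rank formula.
kw_by_hand <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  n_tot <- length(values)
  r <- rank(values)
  sizes <- lengths(groups)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  rank_sums <- mapply(function(a, b) sum(r[a:b]), starts, ends)
  h <- 12 / (n_tot * (n_tot + 1)) * sum(rank_sums^2 / sizes) - 3 * (n_tot + 1)
  tie_counts <- table(values)
  correction <- 1 - sum(tie_counts^3 - tie_counts) / (n_tot^3 - n_tot)
  h / correction
}

# Pearson chi-square by an explicit cell loop.
chisq_by_loop <- function(tab) {
  n <- sum(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  total <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- rs[i] * cs[j] / n
      total <- total + (tab[i, j] - e)^2 / e
    }
  }
  unname(total)
}

# One-sample KS sup-distance against N(mu, sd), enumerated at the sample
# points (the supremum is attained at a jump of the empirical CDF).
ks_stat_by_hand <- function(x, mu, sd) {
  x <- sort(x)
  n <- length(x)
  cdf <- pnorm(x, mu, sd)
  max(pmax(abs(seq_len(n) / n - cdf), abs(cdf - (seq_len(n) - 1) / n)))
}

# A small cohort for property tests; seeds keep the loops reproducible.
small_cohort <- function(seed, n = 24, groups = 10,
                         effect_spec = default_effect_spec()) {
  generate_cohort(generator_config(n_respondents = n, n_groups = groups,
                                   seed = seed, effect_spec = effect_spec))
}
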