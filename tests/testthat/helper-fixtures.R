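# Shared fixtures: small random tables, compositions, trees, and planted
# one-subject cohorts used across the module tests.

random_count_table <- function(n_samples, n_otus, max_count = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n_samples * n_otus, lambda = max_count / 5),
              nrow = n_samples,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("o%03d", seq_len(n_otus))))
  # guarantee positive sample totals
  m[, 1] <- m[, 1] + 1L
  otu_tibble(m, "count")
}

random_composition <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rgamma(n, shape = 0.7)
  x / sum(x)
}

# one-subject cohort with evenly sized planted regimes
planted_series <- function(n_regimes, samples_per_regime = 5, n_otus = 150,
                           concentration = 500, seed = 1) {
  n <- n_regimes * samples_per_regime
  days <- as.integer(seq(0, (n - 1) * 10, by = 10))
  switch_days <- days[seq(1, by = samples_per_regime, length.out = n_regimes)]
  sched <- list("5001" = data.frame(day = switch_days, regime = seq_len(n_regimes)))
  spec <- cohort_spec(n_subjects = 1, n_otus = n_otus, day_grid = days,
                      regimes_per_subject = n_regimes, regime_schedule = sched,
                      dirichlet_concentration = concentration,
                      injection_events = "none", convergence_rate = 0,
                      seed = seed)
  generate_cohort(spec)
}

# two disjoint-support source compositions over a common taxon universe
disjoint_sources <- function(n_taxa = 200, seed = 1) {
  set.seed(seed)
  half <- n_taxa / 2
  pa <- c(rgamma(half, 1), rep(0, half)); pa <- pa / sum(pa)
  pb <- c(rep(0, half), rgamma(half, 1)); pb <- pb / sum(pb)
  taxa <- sprintf("t%03d", seq_len(n_taxa))
  names(pa) <- names(pb) <- taxa
  rbind(A = pa, B = pb)
}

# brute-force Kendall tau-b and enumeration p-value
brute_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1
    if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
  ty <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

brute_kendall_p <- function(x, y) {
  t_obs <- brute_kendall(x, y)
  perms <- gtools_permutations(length(y))
  ts <- apply(perms, 1, function(p) brute_kendall(x, y[p]))
  mean(abs(ts) >= abs(t_obs) - 1e-12)
}

# all n! permutations, rows = permutations (small n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    cbind(sub, n)[, append(seq_len(n - 1), n, after = pos - 1), drop = FALSE]
  }))
}

# brute-force UniFrac by walking every branch and collecting its tips
brute_unifrac <- function(a, b, tree, weighted = FALSE) {
  tips_below <- function(node) {
    ntip <- length(tree$tip.label)
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  a <- a / sum(a); b <- b / sum(b)
  num <- den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tips_below(tree$edge[e, 2])
    bl <- tree$edge.length[e]
    Aa <- sum(a[tips], na.rm = TRUE); Bb <- sum(b[tips], na.rm = TRUE)
    if (weighted) {
      num <- num + bl * abs(Aa - Bb)
      den <- den + bl * (Aa + Bb)
    } else {
      inA <- Aa > 0; inB <- Bb > 0
      if (xor(inA, inB)) num <- num + bl
      if (inA || inB) den <- den + bl
    }
  }
  if (den == 0) 0 else num / den
}
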