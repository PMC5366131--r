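# Co-abundance groups: Kendall structure, group assignment, edges,
# over-abundance.

test_that("Kendall tau matches canonical and brute-force values", {
  m <- cbind(a = 1:4, b = 1:4, c = 4:1, d = c(1, 3, 2, 4))
  rownames(m) <- 1:4
  km <- kendall_matrix(m)
  expect_equal(km$tau["a", "b"], 1)
  expect_equal(km$tau["a", "c"], -1)
  expect_equal(km$tau["a", "d"], 4 / 6, tolerance = 1e-12)
  # exact p by enumeration over all 24 permutations
  expect_equal(km$p["a", "d"], brute_kendall_p(1:4, c(1, 3, 2, 4)))
  expect_true(isSymmetric(km$tau))
  expect_equal(unname(diag(km$tau)), rep(1, 4))
})

test_that("Kendall matrix agrees with a brute-force pair counter on 8-vectors", {
  set.seed(3)
  m <- matrix(sample(1:5, 8 * 5, replace = TRUE), nrow = 8,
              dimnames = list(1:8, sprintf("o%d", 1:5)))
  m[, 1] <- m[, 1] + seq_len(8)  # ensure non-constant
  km <- kendall_matrix(m, exact_max = 8)
  for (i in 1:4) for (j in (i + 1):5) {
    x <- m[, i]; y <- m[, j]
    if (length(unique(x)) < 2 || length(unique(y)) < 2) {
      expect_true(is.na(km$tau[i, j]))
    } else {
      expect_equal(km$tau[i, j], brute_kendall(x, y), tolerance = 1e-12)
    }
  }
})

test_that("constant OTU vectors are recorded as missing", {
  m <- cbind(a = 1:4, b = rep(2, 4), c = c(2, 1, 4, 3))
  rownames(m) <- 1:4
  km <- kendall_matrix(m)
  expect_true(is.na(km$tau["a", "b"]))
  expect_false(is.na(km$tau["a", "c"]))
})

test_that("planted correlation blocks are recovered exactly", {
  set.seed(8)
  n_states <- 10
  base <- matrix(rnorm(n_states * 3), ncol = 3)
  m <- do.call(cbind, lapply(1:3, function(block) {
    sapply(1:4, function(i) base[, block] + rnorm(n_states, sd = 0.05))
  }))
  colnames(m) <- sprintf("o%02d", 1:12); rownames(m) <- 1:n_states
  res <- assign_cao(m, k_candidates = c(3, 4), n_perm = 199, seed = 1)
  truth <- rep(1:3, each = 4)
  expect_equal(res$k, 3)
  expect_equal(adjusted_rand_index(res$groups$group, truth), 1)
})

test_that("independent noise is not certified as CAO structure", {
  set.seed(9)
  hits <- 0
  for (rep in 1:30) {
    m <- matrix(rnorm(8 * 10), nrow = 8,
                dimnames = list(1:8, sprintf("o%d", 1:10)))
    res <- assign_cao(m, n_perm = 199, seed = rep)
    if (res$certification$p_value >= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 27)
})

test_that("degenerate k requests fail cleanly", {
  m <- matrix(rnorm(8 * 6), nrow = 8, dimnames = list(1:8, sprintf("o%d", 1:6)))
  expect_error(assign_cao(m, k_candidates = 6), "no valid k")
  expect_error(assign_cao(m[, 1:5, drop = FALSE]), ">= 6")
})

test_that("edge filtering keeps positive significant pairs only", {
  tau <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.2, -0.9, 0.2, 1), 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  p <- matrix(0.01, 3, 3, dimnames = dimnames(tau)); diag(p) <- 0
  p["b", "c"] <- p["c", "b"] <- 0.5
  edges <- cao_edges(list(tau = tau, p = p))
  expect_equal(nrow(edges), 1)
  expect_equal(edges$source, "a")
  expect_equal(edges$target, "b")
  expect_equal(edges$weight, 0.9)

  # filter oracle on a random matrix
  set.seed(10)
  n <- 8
  tau <- matrix(runif(n * n, -1, 1), n); tau <- (tau + t(tau)) / 2; diag(tau) <- 1
  p <- matrix(runif(n * n), n); p <- (p + t(p)) / 2; diag(p) <- 0
  dimnames(tau) <- dimnames(p) <- list(sprintf("o%d", 1:n), sprintf("o%d", 1:n))
  edges <- cao_edges(list(tau = tau, p = p))
  want <- sum(tau[upper.tri(tau)] > 0 & p[upper.tri(p)] < 0.05)
  expect_equal(nrow(edges), want)
})

test_that("over-abundance ratios behave at their reference points", {
  profiles <- tibble::tibble(
    state = rep(1:3, each = 2),
    otu_id = rep(c("a", "b"), 3),
    abundance = c(0.2, 0.8, 0.1, 0.9, 0.1, 0.9))
  oa <- state_overabundance(profiles)
  # background medians: a = 0.1, b = 0.9
  expect_equal(oa$ratio[oa$state == 1 & oa$otu_id == "a"], 2, tolerance = 1e-4)
  expect_equal(oa$ratio[oa$state == 2 & oa$otu_id == "b"], 1, tolerance = 1e-6)
  # zero background stays finite
  profiles2 <- tibble::tibble(state = rep(1:3, each = 2),
                              otu_id = rep(c("a", "b"), 3),
                              abundance = c(0.5, 0.5, 1, 0, 1, 0))
  oa2 <- state_overabundance(profiles2)
  expect_true(all(is.finite(oa2$ratio)))
})

test_that("the full model filters by mean abundance and is order-invariant", {
  set.seed(11)
  n_states <- 8
  strong <- matrix(rgamma(n_states * 8, 5), ncol = 8)
  weak <- matrix(rgamma(n_states * 4, 0.001), ncol = 4)
  m <- cbind(strong, weak)
  m <- m / rowSums(m)
  colnames(m) <- sprintf("o%02d", 1:12); rownames(m) <- 1:n_states
  profiles <- purrr::map_dfr(1:n_states, function(s) tibble::tibble(
    state = s, otu_id = colnames(m), abundance = unname(m[s, ])))
  fit <- cao_model(profiles, n_perm = 199, seed = 2)
  keep_oracle <- colnames(m)[colMeans(m) > 0.001]
  expect_setequal(fit$otu_ids, keep_oracle)

  perm_profiles <- profiles[sample(nrow(profiles)), ]
  fit2 <- cao_model(perm_profiles, n_perm = 199, seed = 2)
  g1 <- setNames(fit$groups$group, fit$groups$otu_id)
  g2 <- setNames(fit2$groups$group, fit2$groups$otu_id)
  expect_equal(adjusted_rand_index(g1[names(g2)], g2), 1)
})
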