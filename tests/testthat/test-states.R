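# Ward linkage, state cutting, validation, profiles, succession.

states_from_labels <- function(labels, days) {
  lab <- tibble::tibble(sample_id = sprintf("s%d", seq_along(labels)),
                        day = as.integer(days), state = labels)
  mbtraj:::new_states(lab, h = 1, subject_id = "X")
}

test_that("two-point Ward merge height is monotone in the distance", {
  hts <- sapply(c(0.1, 0.5, 1, 2), function(d0) {
    d <- matrix(c(0, d0, d0, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
    ward_linkage(d)$height
  })
  expect_true(all(diff(hts) > 0))
})

test_that("Ward merge order matches brute-force variance-increase agglomeration", {
  set.seed(15)
  for (rep in 1:10) {
    pts <- matrix(rnorm(8 * 3), nrow = 8)
    rownames(pts) <- sprintf("p%d", 1:8)
    d <- as.matrix(dist(pts))
    hc <- ward_linkage(d)
    # brute force: at each step merge the cluster pair with the smallest
    # increase in total within-cluster sum of squares
    clusters <- lapply(seq_len(8), identity)
    merges <- list()
    while (length(clusters) > 1) {
      best <- NULL; best_cost <- Inf
      for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
        if (j <= i) next
        A <- pts[clusters[[i]], , drop = FALSE]
        B <- pts[clusters[[j]], , drop = FALSE]
        cost <- nrow(A) * nrow(B) / (nrow(A) + nrow(B)) *
          sum((colMeans(A) - colMeans(B))^2)
        if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
      }
      merges[[length(merges) + 1]] <- list(
        members = sort(c(clusters[[best[1]]], clusters[[best[2]]])),
        height = sqrt(2 * best_cost))
      clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
      clusters[[best[2]]] <- NULL
    }
    # compare member sets at each merge and the ward.D2 heights
    hc_members <- list()
    for (k in seq_len(nrow(hc$merge))) {
      mem <- c()
      for (col in 1:2) {
        v <- hc$merge[k, col]
        mem <- c(mem, if (v < 0) -v else hc_members[[v]])
      }
      hc_members[[k]] <- sort(mem)
      expect_equal(hc_members[[k]], merges[[k]]$members)
      expect_equal(hc$height[k], merges[[k]]$height, tolerance = 1e-8)
    }
  }
})

test_that("trivial cuts give one state or all singletons; cuts are monotone", {
  set.seed(25)
  m <- matrix(runif(40), nrow = 8,
              dimnames = list(sprintf("s%d", 1:8), sprintf("o%d", 1:5)))
  m <- m / rowSums(m)
  d <- distance_matrix(m, "jsd")
  hc <- ward_linkage(d)
  days <- setNames(seq(0, 70, by = 10), rownames(m))
  top <- cut_states(hc, max(hc$height) + 1, days)
  expect_equal(top$n_states, 1)
  expect_equal(nrow(top$episodes), 1)
  bottom <- cut_states(hc, min(hc$height) / 2, days)
  expect_equal(bottom$n_states, 8)
  hs <- sort(c(hc$height, max(hc$height) + 1))
  ks <- sapply(hs, function(h) cut_states(hc, h, days)$n_states)
  expect_true(all(diff(ks) <= 0))
})

test_that("state labels are numbered by first appearance in time", {
  set.seed(26)
  m <- rbind(matrix(rep(c(10, 1, 1), 3), nrow = 3, byrow = TRUE),
             matrix(rep(c(1, 10, 1), 3), nrow = 3, byrow = TRUE))
  m <- m + matrix(runif(18, 0, 0.1), nrow = 6)
  m <- m / rowSums(m)
  rownames(m) <- sprintf("s%d", 1:6); colnames(m) <- c("a", "b", "c")
  d <- distance_matrix(m, "jsd")
  hc <- ward_linkage(d)
  # day order reversed relative to row order: cluster of s4..s6 comes first
  days <- setNames(c(40, 50, 60, 10, 20, 30), rownames(m))
  st <- cut_states(hc, mean(range(hc$height)), days)
  expect_equal(st$labels$state[1], 1L)
  expect_equal(st$labels$sample_id[1], "s4")
})

test_that("succession summary counts episodes and recurrences correctly", {
  st <- states_from_labels(c(1L, 1L, 2L, 2L, 1L), c(0, 10, 20, 30, 40))
  s <- succession_summary(st)
  expect_equal(s$per_state$recurrences[s$per_state$state == 1], 2)
  expect_equal(s$per_state$recurrences[s$per_state$state == 2], 1)
  expect_true(s$returned_to_initial)
  ep1 <- s$episodes[s$episodes$state == 1, ]
  expect_equal(ep1$start_day, c(0, 40))
  expect_equal(ep1$end_day, c(10, 40))

  const <- states_from_labels(rep(1L, 6), seq(0, 50, by = 10))
  sc <- succession_summary(const)
  expect_equal(nrow(sc$episodes), 1)
  expect_equal(sc$mean_persistence, 50)

  # RLE oracle on random label sequences
  set.seed(33)
  for (rep in 1:20) {
    labs <- sample(1:3, 12, replace = TRUE)
    labs <- as.integer(match(labs, unique(labs)))  # first-appearance order
    st <- states_from_labels(labs, seq(0, 110, by = 10))
    r <- rle(labs)
    expect_equal(nrow(st$episodes), length(r$lengths))
    expect_equal(st$episodes$n_samples, r$lengths)
  }
})

test_that("state profiles are renormalized per-OTU medians", {
  st <- states_from_labels(c(1L, 1L, 1L), c(0, 10, 20))
  frac <- tibble::tibble(
    sample_id = rep(sprintf("s%d", 1:3), each = 2),
    otu_id = rep(c("a", "b"), 3),
    abundance = c(0.1, 0.9, 0.2, 0.8, 0.9, 0.1))
  prof <- state_profiles(st, frac)
  # medians: a = 0.2, b = 0.8 -> already sum to 1
  expect_equal(prof$abundance[prof$otu_id == "a"], 0.2)
  expect_equal(prof$abundance[prof$otu_id == "b"], 0.8)

  set.seed(44)
  m <- matrix(runif(50), nrow = 5,
              dimnames = list(sprintf("s%d", 1:5), sprintf("o%d", 1:10)))
  m <- m / rowSums(m)
  st2 <- states_from_labels(c(1L, 1L, 1L, 2L, 2L), seq(0, 40, 10))
  prof2 <- state_profiles(st2, otu_tibble(m, "abundance", drop_zero = FALSE))
  med <- apply(m[1:3, ], 2, median); med <- med / sum(med)
  expect_equal(prof2$abundance[prof2$state == 1], unname(med[sort(names(med))]))
})

test_that("PERMANOVA separates planted clouds and enumerates exactly", {
  set.seed(55)
  pts <- rbind(matrix(rnorm(15, 0), ncol = 3), matrix(rnorm(15, 8), ncol = 3))
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- sprintf("s%d", 1:10)
  res <- permanova(d, rep(c("a", "b"), each = 5), n_perm = 999, seed = 1)
  # random permutations re-draw the maximal split with prob 2/choose(10,5),
  # so the permutation p cannot go below that; it must still be small
  expect_lt(res$p_value, 0.05)
  expect_gte(res$p_value, 1 / 1000)
  ex <- permanova(d, rep(c("a", "b"), each = 5), exact = TRUE)
  expect_equal(ex$n_perm, choose(10, 5))
  expect_equal(ex$p_value, 2 / choose(10, 5))  # identity + mirror split

  skip_if_not_installed("vegan")
  ref <- vegan::adonis2(as.dist(d) ~ g,
                        data = data.frame(g = rep(c("a", "b"), each = 5)),
                        permutations = 99)
  expect_equal(res$pseudo_f, ref$F[1], tolerance = 1e-10)
})

test_that("state validation passes well-separated groups, flags singletons", {
  set.seed(66)
  base1 <- random_composition(30); base2 <- rev(base1)
  m <- rbind(t(sapply(1:4, function(i) prop.table(base1 + runif(30, 0, 0.01)))),
             t(sapply(1:4, function(i) prop.table(base2 + runif(30, 0, 0.01)))))
  rownames(m) <- sprintf("s%d", 1:8); colnames(m) <- sprintf("o%d", 1:30)
  d <- distance_matrix(m, "jsd")
  st <- states_from_labels(rep(1:2, each = 4L), seq(0, 70, 10))
  frac <- otu_tibble(m, "abundance", drop_zero = FALSE)
  v <- validate_states(st, frac, d, n_perm = 199, seed = 2)
  expect_true(v$all_pass)
  expect_equal(v$pairwise$method, "exact")

  st2 <- states_from_labels(c(rep(1L, 4), rep(2L, 3), 3L), seq(0, 70, 10))
  v2 <- validate_states(st2, frac, d, n_perm = 199, seed = 2)
  expect_equal(v2$singleton_states, 3L)
  expect_false(v2$all_pass)
})

test_that("auto-height detection recovers a planted 3-regime series", {
  co <- planted_series(3, samples_per_regime = 5, seed = 7)
  frac <- to_fractional(co$counts)
  ser <- subject_series(frac, co$metadata, "5001")
  st <- detect_states(ser, n_perm = 199, seed = 7)
  truth <- co$truth$regimes
  ari <- adjusted_rand_index(
    st$labels$state[match(truth$sample_id, st$labels$sample_id)], truth$regime)
  expect_equal(st$n_states, 3)
  expect_gte(ari, 0.9)
  expect_true(st$validated)
})

test_that("adjusted Rand index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  set.seed(77)
  a <- sample(1:3, 30, TRUE); b <- sample(1:3, 30, TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.5)
})
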