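# High-abundance selection, weighted median, reference normalization.

make_series <- function(m, days = NULL) {
  # wrap a samples x OTUs fractional matrix as a subject series
  days <- days %||% seq(0, by = 10, length.out = nrow(m))
  frac <- otu_tibble(m, "abundance", drop_zero = FALSE)
  meta <- tibble::tibble(sample_id = rownames(m), subject_id = "X",
                         day = as.integer(days),
                         phase = phase_for_day(days))
  subject_series(frac, meta, "X")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("high-abundance selection follows the cumulative-median rule", {
  m <- rbind(s1 = c(0.6, 0.3, 0.1), s2 = c(0.6, 0.3, 0.1),
             s3 = c(0.6, 0.3, 0.1), s4 = c(0.6, 0.3, 0.1))
  colnames(m) <- c("OTU1", "OTU2", "OTU3")
  h <- select_high_abundance(make_series(m))
  expect_equal(sort(h$otu_id), c("OTU1", "OTU2"))
  expect_equal(attr(h, "coverage"), 0.9)

  m1 <- m[, 1, drop = FALSE]
  h1 <- select_high_abundance(make_series(m1))
  expect_equal(h1$otu_id, "OTU1")
  expect_equal(attr(h1, "coverage"), 1)
})

test_that("selection matches a brute-force prefix oracle on random series", {
  set.seed(21)
  for (rep in 1:20) {
    m <- matrix(rgamma(8 * 20, 0.5), nrow = 8,
                dimnames = list(sprintf("s%d", 1:8), sprintf("o%02d", 1:20)))
    m <- m / rowSums(m)
    h <- select_high_abundance(make_series(m))
    med <- apply(m, 2, median)
    ord <- order(-med, colnames(m))
    # oracle: walk prefixes until the coverage target is reached
    k <- 0; acc <- 0
    while (acc < 0.9 * sum(med)) { k <- k + 1; acc <- acc + med[ord[k]] }
    expect_equal(h$otu_id, colnames(m)[ord[seq_len(k)]])
    # minimality: one fewer OTU would miss the target
    expect_lt(sum(med[ord[seq_len(k - 1)]]), 0.9 * sum(med))
  }
})

test_that("weighted median follows the cumulative-weight rule", {
  expect_equal(weighted_median(c(1, 2, 3), c(1, 1, 1)), 2)
  expect_equal(weighted_median(c(1, 2, 10), c(0.1, 0.2, 0.7)), 10)
  expect_equal(weighted_median(5, 2), 5)
  expect_error(weighted_median(c(1, 2), c(0, 0)), "zero")

  # oracle: the lower weighted median minimizes the weighted L1 objective
  set.seed(5)
  for (rep in 1:50) {
    v <- rnorm(7); w <- runif(7)
    wm <- weighted_median(v, w)
    obj <- sapply(v, function(c) sum(w * abs(v - c)))
    best <- min(obj)
    expect_true(abs(sum(w * abs(v - wm)) - best) < 1e-12)
    expect_equal(wm, min(v[obj <= best + 1e-12]))
  }
})

test_that("reference normalization fixes identical series and tames outliers", {
  prof <- random_composition(10, seed = 2)
  m <- matrix(rep(prof, each = 6), nrow = 6,
              dimnames = list(sprintf("s%d", 1:6), sprintf("o%02d", 1:10)))
  rn <- reference_normalize(make_series(m), colnames(m))
  expect_equal(unname(rn$scale_factors), rep(1, 6))
  expect_equal(rn$normalized, m)

  # one shifted sample among 9 identical: its reference is the majority profile
  m2 <- rbind(m[rep(1, 9), ], outlier = prof * c(3, rep(1, 9)) / sum(prof * c(3, rep(1, 9))))
  rownames(m2) <- c(sprintf("s%d", 1:9), "outlier")
  rn2 <- reference_normalize(make_series(m2), colnames(m2))
  expect_true(max(abs(rn2$reference["outlier", ] - prof)) < 1e-9)
})

test_that("reference normalization matches a straight-line re-implementation", {
  set.seed(31)
  m <- matrix(rgamma(8 * 12, 1), nrow = 8,
              dimnames = list(sprintf("s%d", 1:8), sprintf("o%02d", 1:12)))
  m <- m / rowSums(m)
  rn <- reference_normalize(make_series(m), colnames(m))

  # independent implementation, step by step
  p <- m / rowSums(m)
  for (s in seq_len(nrow(m))) {
    w <- sapply(seq_len(nrow(m)), function(t) {
      pt <- p[t, ]; ps <- p[s, ]; mm <- (pt + ps) / 2
      kl <- function(x, y) { i <- x > 0; sum(x[i] * log2(x[i] / y[i])) }
      (1 - sqrt(0.5 * kl(pt, mm) + 0.5 * kl(ps, mm)))^2
    })
    ref <- sapply(seq_len(ncol(m)), function(o) {
      ord <- order(m[, o]); cw <- cumsum(w[ord])
      m[ord, o][which(cw >= sum(w) / 2)[1]]
    })
    ok <- ref > 0 & m[s, ] > 0
    cs <- median(ref[ok] / m[s, ok])
    expect_equal(unname(rn$reference[s, ]), unname(ref), tolerance = 1e-12)
    expect_equal(unname(rn$scale_factors[s]), cs, tolerance = 1e-12)
    expect_equal(unname(rn$normalized[s, ]), unname(cs * m[s, ]), tolerance = 1e-12)
  }
})

test_that("normalization is invariant to OTU relabeling and weights behave", {
  set.seed(41)
  m <- matrix(rgamma(6 * 10, 1), nrow = 6,
              dimnames = list(sprintf("s%d", 1:6), sprintf("o%02d", 1:10)))
  m <- m / rowSums(m)
  rn <- reference_normalize(make_series(m), colnames(m))
  perm <- sample(ncol(m))
  m2 <- m[, perm]
  rn2 <- reference_normalize(make_series(m2), colnames(m2))
  expect_equal(rn2$normalized, rn$normalized[, perm])
  expect_true(all(rn$weights >= 0 & rn$weights <= 1))
  expect_equal(unname(diag(rn$weights)), rep(1, 6))  # self-JSD = 0 -> weight 1
})
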