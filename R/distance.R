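# Beta-diversity distances: Jensen-Shannon distance and (un)weighted
# UniFrac, plus matched-day inter-subject distance series.

#' Jensen-Shannon distance between two compositions
#'
#' Square root of the Jensen-Shannon divergence with base-2 logarithms, so
#' the distance lies in `[0, 1]`. Inputs are renormalized internally;
#' `0 * log 0 = 0`.
#'
#' @param p,q non-negative numeric vectors of equal length
#' @return distance in `[0, 1]`
#' @export
jensen_shannon_distance <- function(p, q) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(x, y) {
    i <- x > 0
    sum(x[i] * log2(x[i] / y[i]))
  }
  d2 <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  sqrt(max(0, min(1, d2)))
}

#' Pairwise distance matrix over samples
#'
#' @param fractions long fractional table (`sample_id`, `otu_id`,
#'   `abundance`), or a samples x OTUs matrix
#' @param metric `"jsd"`, `"unifrac-u"` or `"unifrac-w"`
#' @param tree rooted `phylo` (required for UniFrac)
#' @return symmetric numeric matrix with sample dimnames and attribute
#'   `metric`
#' @export
distance_matrix <- function(fractions, metric = c("jsd", "unifrac-u", "unifrac-w"),
                            tree = NULL) {
  metric <- match.arg(metric)
  m <- if (is.matrix(fractions)) fractions else
    otu_matrix(fractions, "abundance")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (metric == "jsd") {
    for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
      d[i, j] <- d[j, i] <- jensen_shannon_distance(m[i, ], m[j, ])
    }
  } else {
    if (is.null(tree)) stop("UniFrac requires a tree", call. = FALSE)
    br <- unifrac_branches(tree, colnames(m))
    for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
      d[i, j] <- d[j, i] <- unifrac_from_branches(m[i, ], m[j, ], br,
                                                  weighted = metric == "unifrac-w")
    }
  }
  attr(d, "metric") <- metric
  d
}

# Precompute, for each branch, its length and which OTU columns descend
# from it. Returns a list(blen, desc) where desc is a branches x otus
# logical matrix over the requested otu universe.
unifrac_branches <- function(tree, otu_ids) {
  validate_tree(tree)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  # children-first accumulation of tip sets per node
  desc <- matrix(FALSE, nrow = ntip + nnode, ncol = length(otu_ids))
  tipcol <- match(tree$tip.label, otu_ids)
  for (i in seq_len(ntip)) if (!is.na(tipcol[i])) desc[i, tipcol[i]] <- TRUE
  # postorder: ape's reorder guarantees children before parents
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    desc[eo[k, 1], ] <- desc[eo[k, 1], ] | desc[eo[k, 2], ]
  }
  list(blen = tree$edge.length,
       desc = desc[tree$edge[, 2], , drop = FALSE],
       tips = tree$tip.label)
}

unifrac_from_branches <- function(a, b, br, weighted, normalized = TRUE) {
  miss <- unique(c(names(a)[a > 0], names(b)[b > 0]))
  miss <- setdiff(miss, br$tips)
  if (length(miss) > 0) {
    stop(sprintf("OTU(s) absent from the tree: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  A <- as.vector(br$desc %*% (a / sum(a)))
  B <- as.vector(br$desc %*% (b / sum(b)))
  if (weighted) {
    num <- sum(br$blen * abs(A - B))
    if (!normalized) return(num)
    den <- sum(br$blen * (A + B))
    if (den == 0) return(0)
    num / den
  } else {
    inA <- A > 0; inB <- B > 0
    den <- sum(br$blen[inA | inB])
    if (den == 0) return(0)
    sum(br$blen[xor(inA, inB)]) / den
  }
}

#' UniFrac distance between two samples
#'
#' Unweighted UniFrac is the fraction of branch length leading exclusively
#' to leaves present in only one of the two samples; weighted UniFrac is
#' the abundance-weighted branch-length difference, by default normalized
#' (Lozupone variant) so it lies in `[0, 1]`.
#'
#' @param a,b named non-negative abundance vectors (names = OTU ids)
#' @param tree rooted `phylo` whose tips cover all present OTUs
#' @param weighted use abundances (TRUE) or presence/absence (FALSE)
#' @param normalized for the weighted variant, divide by the total
#'   abundance-weighted branch length (raw variant when FALSE)
#' @return a distance (in `[0, 1]` unless `weighted` and not `normalized`)
#' @export
unifrac <- function(a, b, tree, weighted = FALSE, normalized = TRUE) {
  stopifnot(!is.null(names(a)), !is.null(names(b)))
  universe <- unique(c(names(a), names(b), tree$tip.label))
  av <- setNames(numeric(length(universe)), universe); av[names(a)] <- a
  bv <- setNames(numeric(length(universe)), universe); bv[names(b)] <- b
  br <- unifrac_branches(tree, universe)
  unifrac_from_branches(av, bv, br, weighted = weighted, normalized = normalized)
}

#' Matched-day inter-subject distance series
#'
#' For each collection day at which at least two subjects have a sample
#' (nearest-day matching within `tolerance` days), computes all pairwise
#' between-subject distances.
#'
#' @param fractions long fractional table
#' @param metadata metadata tibble
#' @param metric as in [distance_matrix()]
#' @param tree tree for UniFrac metrics
#' @param tolerance day-matching window (+/- days)
#' @return tibble (`day`, `subject_a`, `subject_b`, `sample_a`, `sample_b`,
#'   `distance`)
#' @export
inter_subject_distance_series <- function(fractions, metadata,
                                          metric = c("jsd", "unifrac-u", "unifrac-w"),
                                          tree = NULL, tolerance = 3) {
  metric <- match.arg(metric)
  assert_cols(metadata, c("sample_id", "subject_id", "day"), "metadata")
  subjects <- unique(metadata$subject_id)
  if (length(subjects) < 2) stop("need at least 2 subjects", call. = FALSE)
  ref_days <- sort(unique(metadata$day))
  d <- distance_matrix(fractions, metric, tree)
  rows <- list()
  used <- character(0)
  for (day in ref_days) {
    picks <- purrr::map_dfr(subjects, function(s) {
      sm <- metadata[metadata$subject_id == s, ]
      k <- which.min(abs(sm$day - day))
      if (length(k) == 0 || abs(sm$day[k] - day) > tolerance) return(NULL)
      tibble::tibble(subject_id = s, sample_id = sm$sample_id[k])
    })
    if (nrow(picks) < 2) next
    key <- paste(sort(picks$sample_id), collapse = "|")
    if (key %in% used) next   # avoid re-emitting the same matched set
    used <- c(used, key)
    pairs <- utils::combn(nrow(picks), 2)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      rows[[length(rows) + 1]] <- tibble::tibble(
        day = day,
        subject_a = picks$subject_id[i], subject_b = picks$subject_id[j],
        sample_a = picks$sample_id[i], sample_b = picks$sample_id[j],
        distance = d[picks$sample_id[i], picks$sample_id[j]])
    }
  }
  if (length(rows) == 0) stop("no matched days across subjects", call. = FALSE)
  dplyr::bind_rows(rows)
}
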