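# Per-subject microbiota steady states: Ward clustering of the
# Jensen-Shannon distance matrix, height-based cutting, statistical
# validation (within-state correlations with q-values; between-state
# PERMANOVA), median state profiles, and the succession timeline.

#' Ward linkage over a distance matrix
#'
#' Agglomerative Ward clustering (Lance-Williams update on squared
#' dissimilarities, `stats::hclust` method `"ward.D2"`).
#'
#' @param d symmetric distance matrix (e.g. from [distance_matrix()])
#' @return an `hclust` object
#' @export
ward_linkage <- function(d) {
  if (any(is.na(d))) stop("distance matrix contains NA", call. = FALSE)
  stats::hclust(as.dist(d), method = "ward.D2")
}

#' Cut a linkage tree into steady states
#'
#' Removes merges above height `h`; the resulting clusters are the steady
#' states. States are renumbered by first appearance in time, and maximal
#' runs of consecutive same-state samples become episodes.
#'
#' @param linkage `hclust` from [ward_linkage()]
#' @param h cut height (> 0) on the linkage's height scale
#' @param days integer days named by sample id (or in linkage label order)
#' @param subject_id optional subject label carried through
#' @return object of class `mb_states` with `labels` (tibble `sample_id`,
#'   `day`, `state`), `episodes`, `cut_height`, `n_states`
#' @export
cut_states <- function(linkage, h, days, subject_id = NULL) {
  stopifnot(inherits(linkage, "hclust"), h > 0)
  raw <- cutree(linkage, h = h)
  if (!is.null(names(days))) days <- days[linkage$labels]
  ord <- order(days)
  lab <- tibble::tibble(sample_id = linkage$labels[ord],
                        day = as.integer(days[ord]),
                        raw = unname(raw[ord]))
  lab$state <- match(lab$raw, unique(lab$raw))
  lab$raw <- NULL
  new_states(lab, h, subject_id)
}

new_states <- function(lab, h, subject_id) {
  r <- rle(lab$state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  episodes <- tibble::tibble(
    state = r$values,
    episode = stats::ave(r$values, r$values, FUN = seq_along),
    start_day = lab$day[starts], end_day = lab$day[ends],
    n_samples = r$lengths)
  structure(list(
    subject_id = subject_id,
    labels = lab,
    episodes = episodes,
    cut_height = h,
    n_states = length(unique(lab$state))
  ), class = "mb_states")
}

#' @export
print.mb_states <- function(x, ...) {
  cat(sprintf("<mb_states>%s %d samples in %d states (cut height %.3g)\n",
              if (!is.null(x$subject_id)) paste0(" subject ", x$subject_id) else "",
              nrow(x$labels), x$n_states, x$cut_height))
  cat("  timeline:", paste(x$labels$state, collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.mb_states <- function(x, ...) x$labels

#' @export
glance.mb_states <- function(x, ...) {
  s <- succession_summary(x)
  tibble::tibble(n_states = x$n_states, n_samples = nrow(x$labels),
                 cut_height = x$cut_height,
                 mean_persistence_days = s$mean_persistence,
                 max_recurrence = max(s$per_state$recurrences),
                 returned_to_initial = s$returned_to_initial)
}

#' @export
autoplot.mb_states <- function(object, ...) {
  ggplot2::ggplot(object$labels,
                  ggplot2::aes(x = .data$day, y = 1, fill = factor(.data$state))) +
    ggplot2::geom_tile(height = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = .data$state), size = 2.5, vjust = -2) +
    ggplot2::labs(title = sprintf("Steady-state succession%s",
                                  if (!is.null(object$subject_id))
                                    paste0(", subject ", object$subject_id) else ""),
                  x = "day", y = NULL, fill = "state") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Median composition profile of each steady state
#'
#' Per-OTU median relative abundance across the state's member samples,
#' renormalized to sum to one.
#'
#' @param states an `mb_states` object
#' @param fractions long fractional table covering the member samples
#' @return tibble (`state`, `otu_id`, `abundance`); per-state sums are 1
#' @export
state_profiles <- function(states, fractions) {
  m <- otu_matrix(fractions[fractions$sample_id %in% states$labels$sample_id, ],
                  "abundance")
  purrr::map_dfr(sort(unique(states$labels$state)), function(s) {
    ids <- states$labels$sample_id[states$labels$state == s]
    prof <- apply(m[ids, , drop = FALSE], 2, median)
    if (sum(prof) > 0) prof <- prof / sum(prof)
    tibble::tibble(state = s, otu_id = colnames(m), abundance = unname(prof))
  })
}

#' Succession summary of a steady-state timeline
#'
#' @param states an `mb_states` object
#' @return list with `per_state` (episodes, recurrences, persistence days),
#'   `mean_persistence`, and `returned_to_initial` (does the final sample
#'   share the first sample's state?)
#' @export
succession_summary <- function(states) {
  ep <- states$episodes
  per_state <- ep %>%
    dplyr::group_by(.data$state) %>%
    dplyr::summarise(
      recurrences = dplyr::n(),
      total_persistence_days = sum(.data$end_day - .data$start_day),
      n_samples = sum(.data$n_samples), .groups = "drop")
  list(
    per_state = per_state,
    episodes = ep,
    mean_persistence = mean(ep$end_day - ep$start_day),
    returned_to_initial =
      states$labels$state[nrow(states$labels)] == states$labels$state[1]
  )
}

#' Permutational MANOVA (PERMANOVA) on a distance matrix
#'
#' Anderson's pseudo-F computed directly from the distance matrix
#' (between/within sums of squared distances), with a permutation p-value.
#' With `exact = TRUE` all distinct label arrangements are enumerated and
#' the p-value is the exact fraction of arrangements with `F* >= F`
#' (the observed arrangement included).
#'
#' @param d symmetric distance matrix
#' @param groups group labels, one per row of `d`
#' @param n_perm number of random permutations (ignored when exact)
#' @param seed seed for the permutations
#' @param exact enumerate all distinct label arrangements (feasible for
#'   small n; an error if more than `max_exact` arrangements)
#' @param max_exact enumeration cap
#' @return tibble (`pseudo_f`, `p_value`, `n_perm`, `method`)
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1,
                      exact = FALSE, max_exact = 100000) {
  groups <- as.character(groups)
  n <- length(groups)
  stopifnot(nrow(d) == n)
  if (length(unique(groups)) < 2) stop("need at least 2 groups", call. = FALSE)
  d2 <- d^2
  f_obs <- pseudo_f(d2, groups)
  if (exact) {
    perms <- multiset_permutations(groups, max_exact)
    fs <- vapply(perms, function(g) pseudo_f(d2, g), numeric(1))
    p <- mean(fs >= f_obs - 1e-12)
    return(tibble::tibble(pseudo_f = f_obs, p_value = p,
                          n_perm = length(perms), method = "exact"))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  count <- 0L
  for (k in seq_len(n_perm)) {
    if (pseudo_f(d2, sample(groups)) >= f_obs - 1e-12) count <- count + 1L
  }
  tibble::tibble(pseudo_f = f_obs,
                 p_value = (count + 1) / (n_perm + 1),
                 n_perm = n_perm, method = "permutation")
}

# Anderson's pseudo-F from squared distances: total and within-group sums
# of squared distances divided by group sizes.
pseudo_f <- function(d2, groups) {
  n <- nrow(d2)
  k <- length(unique(groups))
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ssa <- sst - ssw
  (ssa / (k - 1)) / (ssw / (n - k))
}

# All distinct arrangements of a label multiset (positions of each label).
multiset_permutations <- function(groups, max_n = 100000) {
  labs <- unique(groups)
  counts <- table(factor(groups, levels = labs))
  total <- factorial(length(groups)) / prod(factorial(counts))
  if (total > max_n) {
    stop(sprintf("exact enumeration would need %.0f arrangements (cap %d)",
                 total, max_n), call. = FALSE)
  }
  out <- list()
  recur <- function(positions, remaining_labs, assignment) {
    if (length(remaining_labs) == 1) {
      assignment[positions] <- remaining_labs[1]
      out[[length(out) + 1]] <<- assignment
      return(invisible())
    }
    lab <- remaining_labs[1]
    for (sel in utils::combn(length(positions), counts[[lab]], simplify = FALSE)) {
      a2 <- assignment
      a2[positions[sel]] <- lab
      recur(positions[-sel], remaining_labs[-1], a2)
    }
  }
  recur(seq_along(groups), labs, character(length(groups)))
  out
}

#' Validate steady states statistically
#'
#' Two-part check: (i) every within-state sample pair must show a
#' significant Spearman correlation of OTU profiles after
#' Benjamini-Hochberg correction across all pairs (q < `q_threshold`);
#' (ii) states must differ from each other by PERMANOVA on the distance
#' matrix, overall and for every state pair (p < `p_threshold`). Singleton
#' states are flagged and excluded from (i).
#'
#' @param states an `mb_states` object
#' @param fractions long fractional table (correlations are computed on
#'   these profiles; pass the high-abundance subset to mirror the
#'   normalization support)
#' @param d the distance matrix the states were cut from
#' @param n_perm PERMANOVA permutations; pairwise tests switch to exact
#'   enumeration when all distinct label arrangements fit under
#'   `exact_limit` (a permutation test on two small states otherwise
#'   cannot resolve small p-values)
#' @param seed seed
#' @param q_threshold,p_threshold significance thresholds
#' @param adjust_pairwise BH-adjust the pairwise PERMANOVA p-values
#' @param exact_limit arrangement cap for exact pairwise enumeration
#' @return object of class `mb_state_validation`
#' @export
validate_states <- function(states, fractions, d, n_perm = 999, seed = 1,
                            q_threshold = 0.05, p_threshold = 0.05,
                            adjust_pairwise = FALSE, exact_limit = 20000) {
  lab <- states$labels
  if (length(unique(lab$state)) < 2) {
    stop("validation needs at least 2 states", call. = FALSE)
  }
  m <- otu_matrix(fractions[fractions$sample_id %in% lab$sample_id, ], "abundance")
  sizes <- table(lab$state)
  singletons <- as.integer(names(sizes)[sizes < 2])

  pair_rows <- list()
  for (s in as.integer(names(sizes)[sizes >= 2])) {
    ids <- lab$sample_id[lab$state == s]
    for (pr in utils::combn(length(ids), 2, simplify = FALSE)) {
      ct <- suppressWarnings(cor.test(m[ids[pr[1]], ], m[ids[pr[2]], ],
                                      method = "spearman", exact = FALSE))
      pair_rows[[length(pair_rows) + 1]] <- tibble::tibble(
        state = s, sample_a = ids[pr[1]], sample_b = ids[pr[2]],
        rho = unname(ct$estimate), p = ct$p.value)
    }
  }
  pairs <- dplyr::bind_rows(pair_rows)
  pairs$q <- p.adjust(pairs$p, method = "BH")
  within_pass <- pairs %>%
    dplyr::group_by(.data$state) %>%
    dplyr::summarise(pass = all(.data$q < q_threshold), .groups = "drop")

  dsub <- d[lab$sample_id, lab$sample_id]
  overall <- permanova(dsub, lab$state, n_perm = n_perm, seed = seed)

  pw_rows <- list()
  st <- sort(unique(lab$state[!lab$state %in% singletons]))
  for (pr in utils::combn(length(st), 2, simplify = FALSE)) {
    a <- st[pr[1]]; b <- st[pr[2]]
    idx <- lab$state %in% c(a, b)
    na <- sum(lab$state == a); nb <- sum(lab$state == b)
    use_exact <- choose(na + nb, na) <= exact_limit
    res <- permanova(dsub[idx, idx], lab$state[idx],
                     n_perm = n_perm, seed = seed + a * 131L + b,
                     exact = use_exact, max_exact = exact_limit)
    pw_rows[[length(pw_rows) + 1]] <- tibble::tibble(
      state_a = a, state_b = b, pseudo_f = res$pseudo_f, p = res$p_value,
      method = res$method)
  }
  pairwise <- dplyr::bind_rows(pw_rows)
  if (adjust_pairwise && nrow(pairwise) > 0) {
    pairwise$p <- p.adjust(pairwise$p, method = "BH")
  }
  structure(list(
    pair_correlations = pairs,
    within_pass = within_pass,
    overall = overall,
    pairwise = pairwise,
    singleton_states = singletons,
    all_pass = all(within_pass$pass) &&
      (nrow(pairwise) == 0 || all(pairwise$p < p_threshold)) &&
      length(singletons) == 0
  ), class = "mb_state_validation")
}

#' @export
print.mb_state_validation <- function(x, ...) {
  cat(sprintf("<mb_state_validation> overall PERMANOVA F = %.2f, p = %.3g\n",
              x$overall$pseudo_f, x$overall$p_value))
  cat(sprintf("  within-state correlation pass: %d/%d states; pairwise PERMANOVA max p = %.3g\n",
              sum(x$within_pass$pass), nrow(x$within_pass),
              if (nrow(x$pairwise)) max(x$pairwise$p) else NA))
  if (length(x$singleton_states)) {
    cat("  singleton states:", paste(x$singleton_states, collapse = ", "), "\n")
  }
  cat(sprintf("  all_pass: %s\n", x$all_pass))
  invisible(x)
}

#' Detect steady states for one subject
#'
#' Builds the subject's JSD matrix and Ward linkage and cuts it at
#' `height`. With `height = "auto"`, every distinct clustering on the
#' merge-height grid whose states all have at least two samples is scored
#' by mean silhouette width against the JSD matrix, and the
#' best-silhouette cut is chosen; [validate_states()] then certifies the
#' chosen states (a data-driven split always looks separated to a naive
#' pairwise test, so cut selection and statistical certification are kept
#' distinct). If no cut qualifies, the two-cluster cut is returned with
#' `validated = FALSE`.
#'
#' @param series a [subject_series()] table
#' @param height numeric cut height or `"auto"`
#' @param hset optional high-abundance set used for the within-state
#'   correlation check (default: all OTUs in the series)
#' @param n_perm,seed validation PERMANOVA settings
#' @return `mb_states` with `validation` and `validated` elements attached
#' @export
detect_states <- function(series, height = "auto", hset = NULL,
                          n_perm = 999, seed = 1) {
  m <- series_matrix(series)
  frac <- series[, c("sample_id", "otu_id", "abundance")]
  d <- distance_matrix(m, "jsd")
  days <- setNames(attr(series, "days"), rownames(m))
  hc <- ward_linkage(d)
  dd <- as.dist(d)
  validate_cut <- function(st) {
    tryCatch(validate_states(st, frac, d, n_perm = n_perm, seed = seed),
             error = function(e) NULL)
  }
  if (is.character(height) && height == "auto") {
    hs <- sort(unique(hc$height))
    # cutting just above each merge height walks all distinct clusterings
    candidates <- (hs + c(hs[-1], hs[length(hs)] + 1)) / 2
    best <- NULL; best_sil <- -Inf
    for (h in candidates) {
      st <- cut_states(hc, h, days, attr(series, "subject_id"))
      if (st$n_states < 2) next
      if (min(table(st$labels$state)) < 2) next
      lab <- st$labels$state[match(rownames(m), st$labels$sample_id)]
      sil <- mean(cluster::silhouette(lab, dd)[, "sil_width"])
      if (sil > best_sil) { best_sil <- sil; best <- st }
    }
    if (is.null(best)) {
      h <- candidates[length(candidates) - 1]
      st <- cut_states(hc, h, days, attr(series, "subject_id"))
      st$validation <- validate_cut(st)
      st$validated <- FALSE
      warning("no qualifying cut height; returning the two-cluster cut")
      return(st)
    }
    best$silhouette <- best_sil
    best$validation <- validate_cut(best)
    best$validated <- if (!is.null(best$validation)) best$validation$all_pass else NA
    return(best)
  }
  st <- cut_states(hc, height, days, attr(series, "subject_id"))
  st$validation <- validate_cut(st)
  st$validated <- if (!is.null(st$validation)) st$validation$all_pass else NA
  st
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b equal-length label vectors
#' @return the adjusted Rand index (1 = identical partitions)
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  mx <- (ai + bj) / 2
  if (mx == expected) return(1)
  (nij - expected) / (mx - expected)
}
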