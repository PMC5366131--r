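# Co-abundance groups (CAO) over steady-state profiles: Kendall tau-b
# correlation structure, Spearman/Ward clustering into 3-4 groups selected
# by silhouette, PERMANOVA certification, positive significant edges, and
# per-state over-abundance ratios.

profiles_matrix <- function(profiles) {
  assert_cols(profiles, c("state", "otu_id", "abundance"), "state profiles")
  m <- otu_matrix(
    tibble::tibble(sample_id = as.character(profiles$state),
                   otu_id = profiles$otu_id,
                   abundance = profiles$abundance), "abundance")
  m[order(as.integer(rownames(m))), , drop = FALSE]
}

#' Kendall correlation matrix over steady-state profiles
#'
#' Pairwise Kendall tau-b between OTU abundance vectors across states, with
#' two-sided p-values by exhaustive permutation enumeration for small
#' numbers of observations (exact even under ties) and the tie-corrected
#' normal approximation above `exact_max`. Constant vectors yield `NA`
#' (tau undefined).
#'
#' @param profiles tibble (`state`, `otu_id`, `abundance`) or a
#'   states x OTUs matrix
#' @param exact_max enumerate all permutations for n observations up to
#'   this (n! grows fast; 8 means at most 40,320 arrangements per pair)
#' @return list with `tau` and `p` matrices (OTU x OTU) and `n_obs`
#' @export
kendall_matrix <- function(profiles, exact_max = 8) {
  m <- if (is.matrix(profiles)) profiles else profiles_matrix(profiles)
  n <- nrow(m)
  if (n < 3) stop("need >= 3 states (observations) for correlations", call. = FALSE)
  otus <- colnames(m)
  K <- ncol(m)
  tau <- matrix(NA_real_, K, K, dimnames = list(otus, otus))
  pm <- matrix(NA_real_, K, K, dimnames = list(otus, otus))
  diag(tau) <- 1; diag(pm) <- 0
  perms <- if (n <= exact_max) all_permutations(n) else NULL
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    x <- m[, i]; y <- m[, j]
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    t_obs <- cor(x, y, method = "kendall")
    tau[i, j] <- tau[j, i] <- t_obs
    if (!is.null(perms)) {
      p <- kendall_perm_p(x, y, t_obs, perms)
    } else {
      p <- suppressWarnings(
        cor.test(x, y, method = "kendall", exact = FALSE)$p.value)
    }
    pm[i, j] <- pm[j, i] <- p
  }
  list(tau = tau, p = pm, n_obs = n)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1), n, after = pos - 1),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

# two-sided exact permutation p for Kendall tau under ties:
# fraction of arrangements with |tau*| >= |tau_obs|
kendall_perm_p <- function(x, y, t_obs, perms) {
  ts <- vapply(seq_len(nrow(perms)),
               function(k) cor(x, y[perms[k, ]], method = "kendall"),
               numeric(1))
  mean(abs(ts) >= abs(t_obs) - 1e-12)
}

#' Assign OTUs to co-abundance groups
#'
#' Clusters OTU abundance vectors (observations = steady-state profiles)
#' by Ward linkage on `1 - Spearman rho`, cutting into each candidate k and
#' keeping the k with the highest mean silhouette width (ties favor the
#' smaller k).
#'
#' The grouping is then certified by a permutational MANOVA whose null
#' accounts for the data-driven grouping: the test statistic is the
#' pseudo-F of the chosen partition on the correlation distance matrix,
#' and each permutation shuffles every OTU's abundance vector across
#' states independently (destroying inter-OTU correlation), then re-runs
#' the full clustering on the permuted data and records the best
#' achievable pseudo-F. A naive label-permutation test is anti-conservative
#' here because Ward groups are by construction the most separated
#' partition of the observed matrix.
#'
#' @param profiles tibble (`state`, `otu_id`, `abundance`) or matrix
#' @param k_candidates candidate group counts (default 3 and 4)
#' @param n_perm permutations for the certification null
#' @param seed seed
#' @param p_threshold certification threshold (`n_perm` must exceed
#'   `1/p_threshold` for certification to be attainable)
#' @param sil_margin parsimony margin: the smallest k whose mean silhouette
#'   is within this of the maximum is chosen (sub-splitting a tight group
#'   can inflate silhouette by a sliver; the margin prefers the coarser
#'   partition unless the finer one is clearly better)
#' @return list: `groups` tibble (`otu_id`, `group`), `k`,
#'   `silhouette` (per-candidate mean widths), `certification`
#'   (tibble `pseudo_f`, `p_value`, `n_perm`, `method`), `certified`
#' @export
assign_cao <- function(profiles, k_candidates = c(3, 4), n_perm = 1999,
                       seed = 1, p_threshold = 0.001, sil_margin = 0.02) {
  m <- if (is.matrix(profiles)) profiles else profiles_matrix(profiles)
  if (ncol(m) < 6) stop("need >= 6 included OTUs", call. = FALSE)
  ks <- k_candidates[k_candidates >= 2 & k_candidates < ncol(m)]
  if (length(ks) == 0) {
    stop("no valid k: candidates must satisfy 2 <= k < number of OTUs",
         call. = FALSE)
  }
  spearman_dist <- function(mat) {
    rho <- suppressWarnings(cor(mat, method = "spearman"))
    rho[is.na(rho)] <- 0
    dmat <- 1 - rho
    diag(dmat) <- 0
    dmat
  }
  dmat <- spearman_dist(m)
  dd <- as.dist(dmat)
  hc <- hclust(dd, method = "ward.D2")
  sil <- setNames(numeric(length(ks)), ks)
  cuts <- list()
  for (i in seq_along(ks)) {
    lab <- cutree(hc, k = ks[i])
    cuts[[i]] <- lab
    sil[i] <- mean(cluster::silhouette(lab, dd)[, "sil_width"])
  }
  best <- which(sil >= max(sil) - sil_margin)[1]  # parsimony: smallest good k
  lab <- cuts[[best]]
  f_obs <- pseudo_f(dmat^2, lab)

  # selection-consistent null: best pseudo-F over re-clustered permutations
  null_stat <- function(mat) {
    dp <- spearman_dist(mat)
    hcp <- hclust(as.dist(dp), method = "ward.D2")
    max(vapply(ks, function(k) pseudo_f(dp^2, cutree(hcp, k)), numeric(1)))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    mp <- apply(m, 2, function(col) col[sample.int(length(col))])
    if (null_stat(mp) >= f_obs - 1e-12) count <- count + 1L
  }
  p <- (count + 1) / (n_perm + 1)
  list(
    groups = tibble::tibble(otu_id = colnames(m), group = unname(lab)),
    k = ks[best],
    silhouette = sil,
    linkage = hc,
    certification = tibble::tibble(pseudo_f = f_obs, p_value = p,
                                   n_perm = n_perm,
                                   method = "recluster-permutation"),
    certified = p < p_threshold
  )
}

#' Positive significant co-abundance edges
#'
#' @param km a [kendall_matrix()] result (or list with `tau` and `p`)
#' @param p_threshold edge significance cutoff
#' @return tibble (`source`, `target`, `weight`) with `weight = tau` for
#'   pairs with `tau > 0` and `p < p_threshold`
#' @export
cao_edges <- function(km, p_threshold = 0.05) {
  tau <- km$tau; p <- km$p
  otus <- colnames(tau)
  rows <- list()
  for (i in seq_len(ncol(tau) - 1)) for (j in (i + 1):ncol(tau)) {
    if (!is.na(tau[i, j]) && !is.na(p[i, j]) &&
        tau[i, j] > 0 && p[i, j] < p_threshold) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        source = otus[i], target = otus[j], weight = tau[i, j])
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(source = character(), target = character(),
                          weight = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Per-state over-abundance relative to background
#'
#' Ratio of each OTU's abundance in a state profile to its background
#' abundance (across-state median), with a small pseudocount guarding
#' zeros.
#'
#' @param profiles tibble (`state`, `otu_id`, `abundance`)
#' @param background optional named background vector (default: per-OTU
#'   median across states)
#' @param eps pseudocount added to numerator and denominator
#' @return tibble (`state`, `otu_id`, `ratio`)
#' @export
state_overabundance <- function(profiles, background = NULL, eps = 1e-6) {
  m <- profiles_matrix(profiles)
  bg <- background %||% apply(m, 2, median)
  bg <- bg[colnames(m)]
  purrr::map_dfr(rownames(m), function(s) {
    tibble::tibble(state = as.integer(s), otu_id = colnames(m),
                   ratio = unname((m[s, ] + eps) / (bg + eps)))
  })
}

#' Fit the full co-abundance group model for one subject
#'
#' Filters OTUs to those with mean relative abundance above
#' `min_mean_abundance` across the subject's steady-state profiles, then
#' computes the Kendall correlation structure, group assignment, edges,
#' and per-state over-abundance.
#'
#' @param profiles tibble (`state`, `otu_id`, `abundance`) for one subject
#' @param min_mean_abundance inclusion filter (default 0.001, i.e. 0.1%)
#' @param k_candidates,n_perm,seed,p_threshold passed to [assign_cao()]
#' @param exact_max passed to [kendall_matrix()]
#' @param edge_p passed to [cao_edges()]
#' @return object of class `mb_cao`
#' @export
cao_model <- function(profiles, min_mean_abundance = 0.001,
                      k_candidates = c(3, 4), n_perm = 1999, seed = 1,
                      p_threshold = 0.001, exact_max = 8, edge_p = 0.05) {
  m <- profiles_matrix(profiles)
  keep <- colMeans(m) > min_mean_abundance
  if (sum(keep) < 6) {
    stop(sprintf("only %d OTUs pass the %.3g mean-abundance filter (need >= 6)",
                 sum(keep), min_mean_abundance), call. = FALSE)
  }
  m <- m[, keep, drop = FALSE]
  km <- kendall_matrix(m, exact_max = exact_max)
  grp <- assign_cao(m, k_candidates = k_candidates, n_perm = n_perm,
                    seed = seed, p_threshold = p_threshold)
  prof_kept <- profiles[profiles$otu_id %in% colnames(m), ]
  structure(list(
    otu_ids = colnames(m),
    n_obs = nrow(m),
    tau = km$tau, p = km$p,
    groups = grp$groups, k = grp$k, silhouette = grp$silhouette,
    certification = grp$certification, certified = grp$certified,
    edges = cao_edges(km, edge_p),
    overabundance = state_overabundance(prof_kept)
  ), class = "mb_cao")
}

#' @export
print.mb_cao <- function(x, ...) {
  cat(sprintf("<mb_cao> %d OTUs over %d state profiles -> %d groups (certified: %s)\n",
              length(x$otu_ids), x$n_obs, x$k, x$certified))
  cat(sprintf("  %d positive significant edges; PERMANOVA p = %.3g\n",
              nrow(x$edges), x$certification$p_value))
  invisible(x)
}

#' @export
tidy.mb_cao <- function(x, ...) x$groups

#' @export
glance.mb_cao <- function(x, ...) {
  tibble::tibble(n_otus = length(x$otu_ids), k = x$k,
                 mean_silhouette = max(x$silhouette),
                 n_edges = nrow(x$edges),
                 permanova_p = x$certification$p_value,
                 certified = x$certified)
}

#' @export
autoplot.mb_cao <- function(object, ...) {
  ord <- object$groups$otu_id[order(object$groups$group)]
  df <- tibble::as_tibble(as.data.frame(as.table(object$tau[ord, ord])))
  names(df) <- c("otu_a", "otu_b", "tau")
  ggplot2::ggplot(df, ggplot2::aes(.data$otu_a, .data$otu_b, fill = .data$tau)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  high = "#b2182b") +
    ggplot2::labs(title = sprintf("Kendall correlation, %d co-abundance groups",
                                  object$k), x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}
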