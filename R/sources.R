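# Bayesian source tracking of steady-state transitions: a collapsed Gibbs
# sampler estimating the mixing proportions by which candidate source
# communities (plus an "unknown" source) compose a sink community, the
# exogenous score of each transition, and the within-subject z-score that
# flags major change events.

#' Gibbs-sampler settings for source tracking
#'
#' Defaults follow the published SourceTracker values: Dirichlet
#' hyperparameters `alpha1` (known-source emissions) and `alpha2`
#' (unknown-source emissions), assignment prior `beta`, 100 burn-in
#' sweeps, 10 retained draws spaced 10 sweeps apart, 10 restarts, and a
#' pseudo-depth of 10,000 reads used to turn compositions into counts.
#'
#' @param alpha1,alpha2,beta Dirichlet/assignment hyperparameters
#' @param burnin,n_draws,spacing,restarts sampler schedule
#' @param depth pseudo-depth for composition-to-count rescaling
#' @return list of settings
#' @export
gibbs_settings <- function(alpha1 = 0.001, alpha2 = 0.1, beta = 10,
                           burnin = 100, n_draws = 10, spacing = 10,
                           restarts = 10, depth = 10000) {
  list(alpha1 = alpha1, alpha2 = alpha2, beta = beta, burnin = burnin,
       n_draws = n_draws, spacing = spacing, restarts = restarts,
       depth = depth)
}

# Largest-remainder rounding of a composition to integer counts at `depth`.
largest_remainder <- function(p, depth) {
  p <- p / sum(p)
  raw <- p * depth
  base <- floor(raw)
  rem <- depth - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Estimate source mixing proportions for a sink community
#'
#' Collapsed Gibbs sampling of per-read source assignments: each sink read
#' is attributed to one of the named sources or to an implicit "unknown"
#' source whose emission distribution is learned alongside. The returned
#' proportions are posterior means of assignment fractions over retained
#' draws, averaged over restarts. Deterministic given `seed`.
#'
#' @param sink named non-negative vector: the sink composition (or counts)
#' @param sources matrix (sources x taxa, rownames = source names) or named
#'   list of compositions on the same taxon universe as `sink`
#' @param settings a [gibbs_settings()] list
#' @param seed integer seed
#' @return object of class `mb_mixing`: `proportions` tibble
#'   (`source`, `pi`) including `"unknown"`, `trace` matrix, `settings`
#' @export
gibbs_mixing <- function(sink, sources, settings = gibbs_settings(), seed = 1) {
  if (is.list(sources) && !is.matrix(sources)) {
    sources <- do.call(rbind, sources)
  }
  stopifnot(is.matrix(sources), !is.null(rownames(sources)))
  if (is.null(names(sink))) {
    stopifnot(length(sink) == ncol(sources))
  } else {
    stopifnot(!is.null(colnames(sources)))
    universe <- union(names(sink), colnames(sources))
    s2 <- setNames(numeric(length(universe)), universe); s2[names(sink)] <- sink
    m2 <- matrix(0, nrow(sources), length(universe),
                 dimnames = list(rownames(sources), universe))
    m2[, colnames(sources)] <- sources
    sink <- s2; sources <- m2
  }
  if (sum(sink) <= 0) stop("empty sink", call. = FALSE)
  sink_counts <- largest_remainder(sink, settings$depth)
  if (sum(sink_counts) < 100) stop("sink depth must be >= 100 reads", call. = FALSE)
  src_counts <- t(apply(sources, 1, largest_remainder, depth = settings$depth))
  read_taxon <- rep.int(seq_along(sink_counts) - 1L, sink_counts)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  res <- gibbs_st_cpp(read_taxon, src_counts,
                      settings$alpha1, settings$alpha2, settings$beta,
                      settings$burnin, settings$n_draws, settings$spacing,
                      settings$restarts)
  src_names <- c(rownames(sources), "unknown")
  pi <- setNames(as.numeric(res$pi), src_names)
  trace <- res$trace
  colnames(trace) <- src_names
  structure(list(
    proportions = tibble::tibble(source = src_names, pi = unname(pi)),
    trace = trace,
    settings = settings,
    seed = seed
  ), class = "mb_mixing")
}

#' @export
print.mb_mixing <- function(x, ...) {
  cat("<mb_mixing> estimated source proportions:\n")
  for (i in seq_len(nrow(x$proportions))) {
    cat(sprintf("  %-20s %.3f\n", x$proportions$source[i], x$proportions$pi[i]))
  }
  invisible(x)
}

#' @export
tidy.mb_mixing <- function(x, ...) x$proportions

#' Exogenous scores and z-scores of steady-state transitions
#'
#' For each subject's transition from state `i` to state `i+1`, the state
#' `i+1` profile is treated as a sink with the subject's own state `i`
#' profile plus every other subject's state profiles as sources. The
#' exogenous score is `e = 1 - pi(own preceding state)` — the fraction of
#' the new state not deriving from the immediately preceding one. Within
#' each subject, `e` is standardized to a z-score (population standard
#' deviation), so `z = 0` means a transition of average magnitude;
#' transitions with `z > threshold` are flagged as major change events.
#'
#' @param profiles tibble (`subject_id`, `state`, `otu_id`, `abundance`):
#'   state profiles for every subject, states numbered in temporal order of
#'   first appearance
#' @param settings a [gibbs_settings()] list
#' @param seed integer seed (each transition derives its own stream)
#' @param threshold z-score above which a transition is a major change
#' @return object of class `mb_change_scores`: `scores` tibble
#'   (`subject_id`, `from_state`, `to_state`, `e`, `z`, `major_change`)
#'   and the per-transition `mixing` list
#' @export
exogenous_scores <- function(profiles, settings = gibbs_settings(), seed = 1,
                             threshold = 1.5) {
  assert_cols(profiles, c("subject_id", "state", "otu_id", "abundance"),
              "state profiles")
  subjects <- unique(profiles$subject_id)
  universe <- sort(unique(profiles$otu_id))
  prof_mat <- function(sub) {
    p <- profiles[profiles$subject_id == sub, ]
    states <- sort(unique(p$state))
    m <- matrix(0, length(states), length(universe),
                dimnames = list(paste0(sub, ":", states), universe))
    m[cbind(match(paste0(sub, ":", p$state), rownames(m)),
            match(p$otu_id, universe))] <- p$abundance
    m
  }
  mats <- lapply(setNames(subjects, subjects), prof_mat)

  rows <- list(); mixings <- list()
  for (sub in subjects) {
    m <- mats[[sub]]
    if (nrow(m) < 2) {
      warning(sprintf("subject %s has a single state; skipped", sub))
      next
    }
    others <- do.call(rbind, mats[setdiff(subjects, sub)])
    for (i in seq_len(nrow(m) - 1)) {
      own_name <- sprintf("%s:prev", sub)
      sources <- rbind(m[i, , drop = FALSE], others)
      rownames(sources)[1] <- own_name
      fit <- gibbs_mixing(m[i + 1, ], sources, settings,
                          seed = stage_seed(seed, paste0("st:", sub, ":", i)))
      e <- 1 - fit$proportions$pi[fit$proportions$source == own_name]
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = sub, from_state = i, to_state = i + 1, e = e)
      mixings[[paste0(sub, ":", i)]] <- fit
    }
  }
  if (length(rows) == 0) stop("no subject with >= 2 states", call. = FALSE)
  scores <- dplyr::bind_rows(rows) %>%
    dplyr::group_by(.data$subject_id) %>%
    dplyr::mutate(z = zscore_pop(.data$e)) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(major_change = .data$z > threshold)
  structure(list(scores = scores, mixing = mixings,
                 settings = settings, threshold = threshold),
            class = "mb_change_scores")
}

# Population (n-denominator) z-score; all-equal input maps to all zeros.
zscore_pop <- function(x) {
  if (length(x) < 2) return(rep(0, length(x)))
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' @export
print.mb_change_scores <- function(x, ...) {
  cat(sprintf("<mb_change_scores> %d transitions, %d flagged major (z > %.2f)\n",
              nrow(x$scores), sum(x$scores$major_change), x$threshold))
  invisible(x)
}

#' @export
tidy.mb_change_scores <- function(x, ...) x$scores

#' @export
autoplot.mb_change_scores <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$to_state, y = .data$z,
                               fill = .data$major_change)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~subject_id) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "state (transition target)", y = "z-score of exogenous share",
                  fill = "major change") +
    ggplot2::theme_minimal(base_size = 9)
}
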