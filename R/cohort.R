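# Synthetic longitudinal cohort generator with planted ground truth.
#
# Emulates a six-subject confinement study: per-subject regime (steady-state)
# schedules, Dirichlet-multinomial sampling noise, allochthonous injection
# events, and a slow growth of shared rare taxa across subjects.

#' Specify a synthetic cohort
#'
#' Builds a cohort specification with defaults mirroring a 6-subject,
#' 520-day confinement study: 27 samples per subject spanning days -10 to
#' 700 (entry day 0, exit day 520), sequencing depths uniform in
#' 7,759-91,366 reads, 5-7 steady-state regimes per subject, and one large
#' allochthonous injection event per subject during confinement.
#'
#' @param n_subjects number of subjects
#' @param n_otus size of the OTU universe
#' @param shared_otu_fraction fraction of OTUs drawn from a cohort-wide pool
#'   (available to every subject); the rest are subject-private
#' @param day_grid ordered integer collection days, common to all subjects
#' @param depth_range integer `c(min, max)` sequencing depth
#' @param regimes_per_subject integer vector (recycled) of planted regime
#'   counts; default samples 5-7 per subject
#' @param regime_schedule optional named list (by subject) of data frames
#'   with columns `day`, `regime`: regime switch points. `NULL` = auto.
#' @param dirichlet_concentration Dirichlet concentration for per-sample
#'   compositional noise around the regime baseline (higher = tighter)
#' @param injection_events `NULL` for the default (one 0.9-fraction
#'   other-subject event per subject at a day in 330-360), a data frame with
#'   columns `subject_id`, `day`, `fraction`, `source`
#'   (`"other_subject"`/`"environment"`), or `"none"`
#' @param convergence_rate per-day increase of the shared rare-taxon blend
#'   weight (0 disables the convergence trend)
#' @param entry_day,exit_day confinement boundaries defining phases
#' @param seed integer seed; all randomness flows from it
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_subjects = 6,
                        n_otus = 200,
                        shared_otu_fraction = 0.3,
                        day_grid = default_day_grid(),
                        depth_range = c(7759L, 91366L),
                        regimes_per_subject = NULL,
                        regime_schedule = NULL,
                        dirichlet_concentration = 500,
                        injection_events = NULL,
                        convergence_rate = 2e-4,
                        entry_day = 0L, exit_day = 520L,
                        seed = 1L) {
  stopifnot(n_subjects >= 1, n_otus >= 5,
            shared_otu_fraction >= 0, shared_otu_fraction <= 1,
            length(depth_range) == 2, depth_range[1] >= 1,
            depth_range[2] >= depth_range[1],
            dirichlet_concentration > 0, convergence_rate >= 0,
            !is.unsorted(day_grid, strictly = TRUE))
  if (!is.null(regimes_per_subject) && any(regimes_per_subject < 1)) {
    stop("regimes_per_subject must be >= 1", call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_otus = as.integer(n_otus),
    shared_otu_fraction = shared_otu_fraction,
    day_grid = as.integer(day_grid),
    depth_range = as.integer(depth_range),
    regimes_per_subject = regimes_per_subject,
    regime_schedule = regime_schedule,
    dirichlet_concentration = dirichlet_concentration,
    injection_events = injection_events,
    convergence_rate = convergence_rate,
    entry_day = as.integer(entry_day), exit_day = as.integer(exit_day),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Default 27-point collection-day grid (days -10 to 700)
#' @return integer vector of length 27
#' @export
default_day_grid <- function() {
  as.integer(c(-10, -5, round(seq(15, 520, length.out = 21)), 550, 600, 650, 700))
}

# sample() misbehaves on numeric scalars; always index into the vector
sample_vec <- function(x, size = 1, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Blend a composition with a source composition
#'
#' Models an allochthonous injection: `(1 - fraction) * profile +
#' fraction * source_profile`. Both inputs and the output sum to one.
#'
#' @param profile,source_profile non-negative numeric vectors summing to 1
#' @param fraction mixing fraction in `[0, 1]`
#' @return blended composition
#' @export
inject_event <- function(profile, source_profile, fraction) {
  stopifnot(fraction >= 0, fraction <= 1,
            length(profile) == length(source_profile))
  (1 - fraction) * profile + fraction * source_profile
}

#' Generate a synthetic cohort with planted ground truth
#'
#' For each subject, each planted regime has a distinct Dirichlet baseline
#' composition over the subject's OTU support; each sample's composition is
#' drawn `Dirichlet(concentration x regime baseline)` and counts are drawn
#' multinomially at a depth uniform in `depth_range`. Injection events
#' replace the stated fraction of a sample's composition with the source
#' subject's (or an environmental) baseline. With `convergence_rate > 0`, a
#' small cohort-wide rare-taxon blend grows linearly after entry, so
#' subjects slowly share more rare taxa. Deterministic under `spec$seed`.
#'
#' @param spec a [cohort_spec()]
#' @return list with elements `counts` (long count tibble), `metadata`,
#'   `taxonomy`, `tree` (`phylo`), and `truth` (regime labels per sample,
#'   per-subject regime baselines, injection events, phylum weights)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  subjects <- sprintf("%d", 5000L + seq_len(spec$n_subjects))
  otus <- sprintf("OTU_%04d", seq_len(spec$n_otus))
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
             "Actinobacteria", "Verrucomicrobia")
  otu_phylum <- sample(phyla, spec$n_otus, replace = TRUE,
                       prob = c(0.50, 0.20, 0.12, 0.12, 0.06))

  n_shared <- round(spec$shared_otu_fraction * spec$n_otus)
  shared_idx <- sort(sample(spec$n_otus, n_shared))
  private_idx <- setdiff(seq_len(spec$n_otus), shared_idx)
  private_owner <- sample(rep_len(seq_len(spec$n_subjects), length(private_idx)))

  # subject-skewed phylum signatures: per-subject multiplicative weight on
  # each phylum, so e.g. one subject is Proteobacteria-rich, another
  # Bacteroidetes-poor
  phylum_w <- matrix(rgamma(spec$n_subjects * 5, shape = 1.2, rate = 1) + 0.05,
                     nrow = spec$n_subjects, dimnames = list(subjects, phyla))

  n_reg <- spec$regimes_per_subject %||% sample(5:7, spec$n_subjects, replace = TRUE)
  n_reg <- rep_len(n_reg, spec$n_subjects)

  schedule <- spec$regime_schedule %||% auto_schedule(subjects, n_reg, spec$day_grid)
  if (!all(subjects %in% names(schedule))) {
    stop("regime_schedule must name every subject", call. = FALSE)
  }
  for (s in subjects) {
    if (!all(schedule[[s]]$day %in% spec$day_grid)) {
      stop(sprintf("regime_schedule for subject %s references days outside day_grid", s),
           call. = FALSE)
    }
  }
  if (!is.null(spec$regime_schedule)) {
    extra <- setdiff(names(spec$regime_schedule), subjects)
    if (length(extra) > 0) stop(sprintf("regime_schedule references unknown subject(s): %s",
                                        paste(extra, collapse = ", ")), call. = FALSE)
  }

  # per-subject, per-regime baselines over the subject's support
  baselines <- list()
  for (si in seq_len(spec$n_subjects)) {
    s <- subjects[si]
    support <- sort(c(shared_idx, private_idx[private_owner == si]))
    alpha <- 0.4 * phylum_w[si, otu_phylum[support]]
    B <- matrix(0, nrow = max(schedule[[s]]$regime), ncol = spec$n_otus,
                dimnames = list(NULL, otus))
    for (r in seq_len(nrow(B))) B[r, support] <- rdirichlet1(alpha)
    baselines[[s]] <- B
  }

  # cohort-wide rare pool for the convergence trend: uniform over shared OTUs
  rare_pool <- numeric(spec$n_otus)
  if (n_shared > 0) rare_pool[shared_idx] <- 1 / n_shared

  events <- cohort_injections(spec, subjects)

  rows <- list(); meta <- list(); truth_lab <- list()
  for (si in seq_len(spec$n_subjects)) {
    s <- subjects[si]
    sched <- schedule[[s]]
    for (d in spec$day_grid) {
      regime <- sched$regime[max(which(sched$day <= d))]
      base <- baselines[[s]][regime, ]
      w <- min(0.05, spec$convergence_rate * max(0, d - spec$entry_day))
      base_c <- (1 - w) * base + w * rare_pool
      comp <- rdirichlet1(spec$dirichlet_concentration * base_c +
                            1e-8 * (base_c > 0))
      ev <- events[events$subject_id == s & events$day == d, ]
      if (nrow(ev) > 0) {
        for (k in seq_len(nrow(ev))) {
          src <- if (ev$source[k] == "environment") {
            k <- min(20, spec$n_otus)
            env <- rep(0, spec$n_otus)
            env[sample.int(spec$n_otus, k)] <- rdirichlet1(rep(1, k))
            env
          } else {
            osub <- sample_vec(setdiff(subjects, s))
            baselines[[osub]][1, ]
          }
          comp <- inject_event(comp, src, ev$fraction[k])
        }
      }
      depth <- sample_vec(spec$depth_range[1]:spec$depth_range[2])
      cnt <- as.vector(rmultinom(1, size = depth, prob = comp))
      sid <- paste0(s, "_d", d)
      nz <- which(cnt > 0)
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = sid, otu_id = otus[nz], count = cnt[nz])
      meta[[length(meta) + 1]] <- tibble::tibble(
        sample_id = sid, subject_id = s, day = d,
        phase = phase_for_day(d, spec$entry_day, spec$exit_day))
      truth_lab[[length(truth_lab) + 1]] <- tibble::tibble(
        sample_id = sid, subject_id = s, day = d, regime = regime)
    }
  }

  tree <- ape::rcoal(spec$n_otus, tip.label = otus)
  tree$edge.length <- rexp(length(tree$edge.length), rate = 10)

  lineage <- paste0("k__Bacteria; p__", otu_phylum,
                    "; c__; o__; f__; g__; s__")
  list(
    counts = dplyr::bind_rows(rows),
    metadata = dplyr::bind_rows(meta),
    taxonomy = parse_taxonomy(otus, lineage),
    tree = tree,
    truth = list(
      regimes = dplyr::bind_rows(truth_lab),
      baselines = baselines,
      schedule = schedule,
      injection_events = events,
      phylum_weights = phylum_w,
      shared_otus = otus[shared_idx]
    )
  )
}

# Random regime schedule: contiguous segments over the day grid, labels
# 1..R appearing in order of first use, some regimes recurring.
auto_schedule <- function(subjects, n_reg, day_grid) {
  out <- list()
  for (si in seq_along(subjects)) {
    R <- min(n_reg[si], length(day_grid))  # cannot plant more regimes than days
    if (R == 1) {
      out[[subjects[si]]] <- data.frame(day = day_grid[1], regime = 1L)
      next
    }
    n_seg <- min(R + sample_vec(0:2), length(day_grid))  # a few recurrences
    labs <- integer(n_seg)
    labs[seq_len(R)] <- sample(R)            # every regime appears
    if (n_seg > R) {
      for (k in (R + 1):n_seg) {
        labs[k] <- sample_vec(setdiff(seq_len(R), labs[k - 1]))
      }
    }
    # avoid adjacent duplicates after the initial block too
    for (k in seq_len(n_seg)[-1]) {
      if (labs[k] == labs[k - 1]) labs[k] <- sample_vec(setdiff(seq_len(R), labs[k - 1]))
    }
    cuts <- sort(sample_vec(2:length(day_grid), n_seg - 1))
    start_idx <- c(1, cuts)
    out[[subjects[si]]] <- data.frame(day = day_grid[start_idx], regime = labs)
  }
  out
}

cohort_injections <- function(spec, subjects) {
  if (identical(spec$injection_events, "none")) {
    return(tibble::tibble(subject_id = character(), day = integer(),
                          fraction = numeric(), source = character()))
  }
  if (is.null(spec$injection_events)) {
    conf_days <- spec$day_grid[spec$day_grid >= 330 & spec$day_grid <= 360]
    if (length(conf_days) == 0) {
      conf_days <- spec$day_grid[spec$day_grid > spec$entry_day &
                                   spec$day_grid < spec$exit_day]
    }
    if (length(conf_days) == 0 || spec$n_subjects < 2) {
      return(tibble::tibble(subject_id = character(), day = integer(),
                            fraction = numeric(), source = character()))
    }
    return(tibble::tibble(
      subject_id = subjects,
      day = sample_vec(conf_days, spec$n_subjects, replace = TRUE),
      fraction = 0.9,
      source = "other_subject"))
  }
  ev <- tibble::as_tibble(spec$injection_events)
  assert_cols(ev, c("subject_id", "day", "fraction", "source"), "injection_events")
  bad <- setdiff(ev$subject_id, subjects)
  if (length(bad) > 0) stop(sprintf("injection event references unknown subject(s): %s",
                                    paste(bad, collapse = ", ")), call. = FALSE)
  if (!all(ev$day %in% spec$day_grid)) {
    stop("injection event references a day outside day_grid", call. = FALSE)
  }
  ev
}
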