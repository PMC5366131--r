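# End-to-end orchestration: simulate or ingest, normalize, distances and
# trend, steady states, source attribution, co-abundance groups — with a
# manifest recording every parameter and output hash for reproducibility.

#' Build a pipeline run configuration
#'
#' @param input `NULL` to simulate a synthetic cohort, or a list of paths
#'   (`counts`, `metadata`, `taxonomy`, `tree`)
#' @param cohort a [cohort_spec()] (used when `input` is `NULL`)
#' @param out_dir output directory
#' @param seed global seed; each stochastic stage derives its own stream
#' @param height steady-state cut height or `"auto"`
#' @param n_perm PERMANOVA permutations
#' @param n_boot trend bootstrap resamples
#' @param trend_metric metric for the inter-subject trend test
#' @param day_tolerance matched-day window for inter-subject distances
#' @param gibbs a [gibbs_settings()] list
#' @param z_threshold major-change z cutoff
#' @param run_sources,run_cao,run_trend stage switches
#' @return list of class `mb_config`
#' @export
pipeline_config <- function(input = NULL, cohort = cohort_spec(),
                            out_dir = tempfile("mbtraj_run_"), seed = 1,
                            height = "auto", n_perm = 999, n_boot = 999,
                            trend_metric = "unifrac-u", day_tolerance = 3,
                            gibbs = gibbs_settings(), z_threshold = 1.5,
                            run_sources = TRUE, run_cao = TRUE,
                            run_trend = TRUE) {
  cfg <- list(input = input, cohort = cohort, out_dir = out_dir,
              seed = as.integer(seed), height = height, n_perm = n_perm,
              n_boot = n_boot, trend_metric = trend_metric,
              day_tolerance = day_tolerance, gibbs = gibbs,
              z_threshold = z_threshold, run_sources = run_sources,
              run_cao = run_cao, run_trend = run_trend)
  class(cfg) <- "mb_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `cohort` and
#' `gibbs` are nested maps passed to [cohort_spec()] / [gibbs_settings()].
#'
#' @param path YAML file
#' @return `mb_config`
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("cohort", "gibbs"))]
  if (!is.null(y$cohort)) args$cohort <- do.call(cohort_spec, y$cohort)
  if (!is.null(y$gibbs)) args$gibbs <- do.call(gibbs_settings, y$gibbs)
  do.call(pipeline_config, args)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: ingest/simulate, fractional
#' normalization, per-subject high-abundance selection and reference
#' normalization, shared-OTU analysis, inter-subject beta-diversity trend,
#' steady-state detection and validation, source attribution of state
#' transitions, and co-abundance groups. All tabular outputs are written
#' under `config$out_dir` and listed (with md5 hashes) in
#' `manifest.json`; rerunning with the same config and seed reproduces
#' identical hashes.
#'
#' @param config an `mb_config` from [pipeline_config()] / [read_config()]
#' @return the manifest (list), invisibly; also written as JSON
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mb_config"))
  # fail on configuration errors before any computation
  if (config$run_trend && grepl("^unifrac", config$trend_metric) &&
      !is.null(config$input) && is.null(config$input$tree)) {
    stop("configuration error: UniFrac trend requested but no tree supplied",
         call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # -- ingest / simulate ------------------------------------------------
  if (is.null(config$input)) {
    spec <- config$cohort
    spec$seed <- stage_seed(config$seed, "simulate")
    cohort <- stage("simulate", generate_cohort(spec))
    counts <- cohort$counts; metadata <- cohort$metadata
    taxonomy <- cohort$taxonomy; tree <- cohort$tree
    truth <- cohort$truth
  } else {
    counts <- stage("ingest", read_otu_table(config$input$counts))
    metadata <- stage("ingest", read_metadata(config$input$metadata))
    taxonomy <- if (!is.null(config$input$taxonomy))
      stage("ingest", read_taxonomy(config$input$taxonomy)) else NULL
    tree <- if (!is.null(config$input$tree))
      stage("ingest", read_tree(config$input$tree)) else NULL
    truth <- NULL
  }
  files <- c(files, write_tsv(counts, out("counts.tsv")),
             write_tsv(metadata, out("metadata.tsv")))

  fractions <- stage("normalize", to_fractional(counts))
  subjects <- unique(metadata$subject_id)

  # -- per-subject normalization ---------------------------------------
  hsets <- list(); normalized <- list(); all_series <- list()
  for (s in subjects) {
    ser <- stage("normalize", subject_series(fractions, metadata, s))
    all_series[[s]] <- ser
    hsets[[s]] <- stage("normalize", select_high_abundance(ser))
    normalized[[s]] <- stage("normalize", reference_normalize(ser, hsets[[s]]))
  }
  norm_tbl <- purrr::map_dfr(subjects, function(s) {
    dplyr::mutate(tidy(normalized[[s]]), subject_id = s, .before = 1)
  })
  files <- c(files, write_tsv(norm_tbl, out("normalized.tsv")))

  shared <- stage("shared", shared_otu_sets(hsets))
  shared_json <- list(
    core_otus = attr(shared, "core_otus"),
    core_fraction = as.list(attr(shared, "core_fraction")),
    subset_counts = dplyr::select(shared, "label", "size", "n_shared"))
  jsonlite::write_json(shared_json, out("shared_otus.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, out("shared_otus.json"))

  # -- inter-subject trend ---------------------------------------------
  trend <- NULL
  if (config$run_trend) {
    series <- stage("trend", inter_subject_distance_series(
      fractions, metadata, config$trend_metric, tree,
      tolerance = config$day_tolerance))
    trend <- stage("trend", median_regression_trend(
      series, n_boot = config$n_boot,
      seed = stage_seed(config$seed, "trend")))
    jsonlite::write_json(as.list(glance(trend)), out("trend.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, out("trend.json"))
  }

  # -- steady states ----------------------------------------------------
  states <- list(); profiles <- list()
  for (s in subjects) {
    st <- stage("states", detect_states(
      all_series[[s]], height = config$height,
      n_perm = config$n_perm, seed = stage_seed(config$seed, paste0("states:", s))))
    states[[s]] <- st
    profiles[[s]] <- dplyr::mutate(
      state_profiles(st, fractions), subject_id = s, .before = 1)
  }
  labels_tbl <- purrr::map_dfr(subjects, function(s) {
    dplyr::mutate(states[[s]]$labels, subject_id = s, .before = 1)
  })
  prof_tbl <- dplyr::bind_rows(profiles)
  state_summary <- purrr::map_dfr(subjects, function(s) {
    dplyr::mutate(glance(states[[s]]), subject_id = s,
                  validated = isTRUE(states[[s]]$validated), .before = 1)
  })
  files <- c(files, write_tsv(labels_tbl, out("state_labels.tsv")),
             write_tsv(prof_tbl, out("state_profiles.tsv")),
             write_tsv(state_summary, out("state_summary.tsv")))

  # -- source attribution ----------------------------------------------
  change <- NULL
  if (config$run_sources) {
    eligible <- subjects[vapply(subjects, function(s) states[[s]]$n_states >= 2,
                                logical(1))]
    if (length(eligible) >= 1) {
      change <- stage("sources", exogenous_scores(
        prof_tbl[prof_tbl$subject_id %in% eligible, ],
        settings = config$gibbs,
        seed = stage_seed(config$seed, "sources"),
        threshold = config$z_threshold))
      files <- c(files, write_tsv(change$scores, out("change_scores.tsv")))
    }
  }

  # -- co-abundance groups ---------------------------------------------
  cao <- list()
  if (config$run_cao) {
    for (s in subjects) {
      cao[[s]] <- tryCatch(
        cao_model(profiles[[s]],
                  n_perm = config$n_perm,
                  seed = stage_seed(config$seed, paste0("cao:", s))),
        error = function(e) NULL)
    }
    cao_tbl <- purrr::map_dfr(subjects, function(s) {
      if (is.null(cao[[s]])) return(NULL)
      dplyr::mutate(cao[[s]]$groups, subject_id = s,
                    k = cao[[s]]$k, certified = cao[[s]]$certified,
                    .before = 1)
    })
    if (nrow(cao_tbl) > 0) files <- c(files, write_tsv(cao_tbl, out("cao_groups.tsv")))
  }

  manifest <- list(
    package = "mbtraj",
    seed = config$seed,
    parameters = config[setdiff(names(config), c("input", "cohort"))],
    cohort = if (is.null(config$input)) unclass(config$cohort) else NULL,
    input = config$input,
    subjects = subjects,
    n_states = as.list(setNames(vapply(states, function(x) x$n_states,
                                       numeric(1)), subjects)),
    files = lapply(files, function(f) list(
      name = basename(f), md5 = unname(tools::md5sum(f)))),
    stages_run = c("ingest", "normalize", "shared",
                   if (config$run_trend) "trend", "states",
                   if (!is.null(change)) "sources",
                   if (config$run_cao) "cao")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  result <- list(manifest = manifest, states = states, trend = trend,
                 change = change, cao = cao, shared = shared,
                 truth = truth, out_dir = config$out_dir)
  class(result) <- "mb_run"
  invisible(result)
}

#' Render a plain-text report from a pipeline run
#'
#' Summarizes the stage outputs recorded under an output directory without
#' recomputing anything; stages that were not run are flagged as such.
#'
#' @param out_dir a [run_pipeline()] output directory (or an `mb_run`)
#' @return character vector of report lines, invisibly; also printed
#' @export
render_report <- function(out_dir) {
  if (inherits(out_dir, "mb_run")) out_dir <- out_dir$out_dir
  mf_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json under ", out_dir, call. = FALSE)
  mf <- jsonlite::fromJSON(mf_path, simplifyVector = TRUE)
  lines <- c(
    "== mbtraj pipeline report ==",
    sprintf("seed: %s", mf$seed),
    sprintf("subjects: %s", paste(mf$subjects, collapse = ", ")),
    "",
    "-- steady states --",
    sprintf("  %s: %d states", names(mf$n_states), unlist(mf$n_states)))
  trend_path <- file.path(out_dir, "trend.json")
  if (file.exists(trend_path)) {
    tr <- jsonlite::fromJSON(trend_path)
    lines <- c(lines, "", "-- beta-diversity trend --",
               sprintf("  slope %.4g per day (rc_range %.4g, rc_sd %.4g), bootstrap p = %.3g",
                       tr$slope, tr$rc_range, tr$rc_sd, tr$p_value))
  } else {
    lines <- c(lines, "", "-- beta-diversity trend --", "  not run")
  }
  cs_path <- file.path(out_dir, "change_scores.tsv")
  if (file.exists(cs_path)) {
    cs <- read.delim(cs_path)
    flagged <- cs[cs$major_change == TRUE | cs$major_change == "TRUE", ]
    lines <- c(lines, "", "-- source attribution --",
               sprintf("  %d transitions scored; %d major change events (z > threshold)",
                       nrow(cs), nrow(flagged)))
    if (nrow(flagged) > 0) {
      lines <- c(lines, sprintf("    subject %s: state %d -> %d, e = %.2f, z = %.2f",
                                flagged$subject_id, flagged$from_state,
                                flagged$to_state, flagged$e, flagged$z))
    }
  } else {
    lines <- c(lines, "", "-- source attribution --", "  not run")
  }
  cao_path <- file.path(out_dir, "cao_groups.tsv")
  if (file.exists(cao_path)) {
    cg <- read.delim(cao_path)
    per <- unique(cg[, c("subject_id", "k", "certified")])
    lines <- c(lines, "", "-- co-abundance groups --",
               sprintf("  subject %s: %d groups (certified: %s)",
                       per$subject_id, per$k, per$certified))
  } else {
    lines <- c(lines, "", "-- co-abundance groups --", "  not run")
  }
  sh_path <- file.path(out_dir, "shared_otus.json")
  if (file.exists(sh_path)) {
    sh <- jsonlite::fromJSON(sh_path)
    lines <- c(lines, "", "-- shared high-abundance OTUs --",
               sprintf("  all-subject core: %d OTUs", length(sh$core_otus)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
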