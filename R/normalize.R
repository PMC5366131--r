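# Per-subject time-series preparation: high-abundance OTU selection and
# reference-community normalization (David-style three-step procedure).
#
# Step (i) is to_fractional(); step (ii) selects the highly abundant OTUs
# that account for 90% of the summed per-OTU median abundances; step (iii)
# rescales each time point to a reference community built from similar time
# points, with similarity weights (1 - JSD)^2.

#' Extract one subject's time-ordered series
#'
#' @param fractions long fractional table (`sample_id`, `otu_id`, `abundance`)
#' @param metadata metadata tibble (`sample_id`, `subject_id`, `day`, `phase`)
#' @param subject subject identifier
#' @param min_samples minimum number of time points (downstream stages need
#'   several similar time points to build references)
#' @return long tibble (`sample_id`, `day`, `phase`, `otu_id`, `abundance`)
#'   ordered by day, with attributes `subject_id` and `days`
#' @export
subject_series <- function(fractions, metadata, subject, min_samples = 4) {
  assert_cols(fractions, c("sample_id", "otu_id", "abundance"), "fraction table")
  assert_cols(metadata, c("sample_id", "subject_id", "day"), "metadata")
  meta <- metadata[metadata$subject_id == subject, ]
  if (nrow(meta) < min_samples) {
    stop(sprintf("subject %s has %d samples; at least %d required",
                 subject, nrow(meta), min_samples), call. = FALSE)
  }
  if (anyDuplicated(meta$day) > 0) {
    stop(sprintf("subject %s has duplicate collection days", subject), call. = FALSE)
  }
  meta <- dplyr::arrange(meta, .data$day)
  out <- fractions %>%
    dplyr::inner_join(meta[, c("sample_id", "day", "phase")], by = "sample_id") %>%
    dplyr::arrange(.data$day, .data$otu_id) %>%
    dplyr::select("sample_id", "day", "phase", "otu_id", "abundance")
  attr(out, "subject_id") <- subject
  attr(out, "days") <- meta$day
  attr(out, "sample_ids") <- meta$sample_id
  out
}

series_matrix <- function(series) {
  m <- otu_matrix(series[, c("sample_id", "otu_id", "abundance")], "abundance")
  m[match(attr(series, "sample_ids") %||% unique(series$sample_id), rownames(m)), ,
    drop = FALSE]
}

#' Select highly abundant OTUs covering 90% of median abundance
#'
#' Computes each OTU's median fractional abundance across the subject's time
#' points, ranks OTUs by that median (descending; ties broken by OTU id),
#' and returns the smallest prefix whose summed medians reach `coverage`
#' of the total summed medians.
#'
#' @param series a [subject_series()] table
#' @param coverage target fraction of summed per-OTU medians (default 0.9)
#' @return tibble (`otu_id`, `median_abundance`) in selection order, with
#'   attributes `coverage` (achieved) and `subject_id`
#' @export
select_high_abundance <- function(series, coverage = 0.9) {
  m <- series_matrix(series)
  med <- apply(m, 2, median)
  total <- sum(med)
  if (total <= 0) stop("all per-OTU medians are zero; cannot select", call. = FALSE)
  ord <- order(-med, colnames(m))
  cum <- cumsum(med[ord])
  # small tolerance so exact-coverage prefixes are not missed to rounding
  k <- which(cum >= coverage * total - 1e-9)[1]
  sel <- ord[seq_len(k)]
  out <- tibble::tibble(otu_id = colnames(m)[sel],
                        median_abundance = unname(med[sel]))
  attr(out, "coverage") <- unname(cum[k] / total)
  attr(out, "subject_id") <- attr(series, "subject_id")
  out
}

#' Weighted median (lower weighted median)
#'
#' Sorts values ascending carrying their weights and returns the smallest
#' value whose cumulative weight reaches half the total weight.
#'
#' @param values numeric vector
#' @param weights non-negative weights, at least one positive
#' @return the weighted median value
#' @export
weighted_median <- function(values, weights) {
  stopifnot(length(values) >= 1, length(values) == length(weights),
            all(weights >= 0))
  if (sum(weights) <= 0) stop("all weights are zero", call. = FALSE)
  ord <- order(values)
  cw <- cumsum(weights[ord])
  values[ord][which(cw >= sum(weights) / 2)[1]]
}

#' Normalize a subject's series to sample-specific reference communities
#'
#' For each target sample `s`: similarity weights to every time point `t`
#' are `w(t) = (1 - j(t, s))^2` with `j` the Jensen-Shannon distance between
#' the two samples' high-abundance profiles (renormalized over the selected
#' OTUs; the target's own time point participates with weight 1). The
#' reference value of each OTU is the weighted median of its abundances
#' across time points; the sample's scale factor is the median of
#' reference/observed ratios over OTUs nonzero in both; normalized values
#' are the observed abundances times that factor.
#'
#' @param series a [subject_series()] table (>= 4 time points)
#' @param hset a [select_high_abundance()] result (or character vector of
#'   OTU ids); `NULL` computes it with defaults
#' @return object of class `mb_normalized`: list with `normalized` and
#'   `reference` matrices (samples x high-abundance OTUs), `scale_factors`,
#'   `weights` (samples x samples, `[t, s]` = weight of t for target s),
#'   `days`, `subject_id`
#' @export
reference_normalize <- function(series, hset = NULL) {
  days <- attr(series, "days")
  if (length(unique(series$sample_id)) < 4) {
    stop("reference normalization needs at least 4 time points", call. = FALSE)
  }
  if (is.null(hset)) hset <- select_high_abundance(series)
  otus <- if (is.character(hset)) hset else hset$otu_id
  m <- series_matrix(series)
  missing <- setdiff(otus, colnames(m))
  if (length(missing) > 0) {
    stop(sprintf("high-abundance OTUs absent from series: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  a <- m[, otus, drop = FALSE]                    # raw fractional values
  rs <- rowSums(a)
  if (any(rs == 0)) {
    stop(sprintf("sample(s) with zero abundance over the high-abundance set: %s",
                 paste(rownames(a)[rs == 0], collapse = ", ")), call. = FALSE)
  }
  p <- a / rs                                     # renormalized for JSD
  n <- nrow(a)
  jsd <- matrix(0, n, n, dimnames = list(rownames(a), rownames(a)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) jsd[i, j] <- jsd[j, i] <- jensen_shannon_distance(p[i, ], p[j, ])
  }
  w <- (1 - jsd)^2
  ref <- matrix(NA_real_, n, ncol(a), dimnames = dimnames(a))
  for (s in seq_len(n)) {
    for (o in seq_len(ncol(a))) ref[s, o] <- weighted_median(a[, o], w[, s])
  }
  scale_f <- numeric(n)
  for (s in seq_len(n)) {
    ok <- ref[s, ] > 0 & a[s, ] > 0
    if (!any(ok)) {
      stop(sprintf("no OTU shared between sample %s and its reference", rownames(a)[s]),
           call. = FALSE)
    }
    scale_f[s] <- median(ref[s, ok] / a[s, ok])
  }
  structure(list(
    subject_id = attr(series, "subject_id"),
    otu_ids = otus,
    sample_ids = rownames(a),
    days = days,
    normalized = a * scale_f,
    reference = ref,
    scale_factors = setNames(scale_f, rownames(a)),
    weights = w
  ), class = "mb_normalized")
}

#' @export
print.mb_normalized <- function(x, ...) {
  cat(sprintf("<mb_normalized> subject %s: %d time points x %d high-abundance OTUs\n",
              x$subject_id %||% "?", length(x$sample_ids), length(x$otu_ids)))
  cat(sprintf("  scale factors: median %.3f, range [%.3f, %.3f]\n",
              median(x$scale_factors), min(x$scale_factors), max(x$scale_factors)))
  invisible(x)
}

#' Tidy a normalized series into a long tibble
#' @param x an `mb_normalized` object
#' @param ... unused
#' @return tibble (`sample_id`, `day`, `otu_id`, `abundance`, `reference`)
#' @export
tidy.mb_normalized <- function(x, ...) {
  out <- otu_tibble(x$normalized, "abundance", drop_zero = FALSE)
  ref <- otu_tibble(x$reference, "reference", drop_zero = FALSE)
  out$reference <- ref$reference[match(paste(out$sample_id, out$otu_id),
                                       paste(ref$sample_id, ref$otu_id))]
  out$day <- x$days[match(out$sample_id, x$sample_ids)]
  dplyr::select(out, "sample_id", "day", "otu_id", "abundance", "reference")
}
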