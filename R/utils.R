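# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a long table to a dense samples-by-OTU matrix
#'
#' Most statistics in the package work on a dense numeric matrix internally;
#' the user-facing currency is a long tibble with one row per
#' (sample, OTU) pair. Absent pairs are filled with zero.
#'
#' @param data tibble with columns `sample_id`, `otu_id` and the value column
#' @param value name of the value column (`"count"` or `"abundance"`)
#' @return numeric matrix, rows = samples, columns = OTUs, dimnames set;
#'   row/column order follows first appearance unless the inputs are factors
#' @export
otu_matrix <- function(data, value = c("count", "abundance")) {
  value <- match.arg(value, c("count", "abundance", names(data)[3]))
  stopifnot(all(c("sample_id", "otu_id", value) %in% names(data)))
  samples <- unique(data$sample_id)
  otus <- unique(data$otu_id)
  m <- matrix(0, nrow = length(samples), ncol = length(otus),
              dimnames = list(samples, otus))
  m[cbind(match(data$sample_id, samples), match(data$otu_id, otus))] <-
    data[[value]]
  m
}

#' Convert a samples-by-OTU matrix to the long tibble form
#'
#' @param m numeric matrix with sample row names and OTU column names
#' @param value name for the value column
#' @param drop_zero drop zero entries (keeps long tables sparse)
#' @return tibble with columns `sample_id`, `otu_id`, `<value>`
#' @export
otu_tibble <- function(m, value = "count", drop_zero = TRUE) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  out <- tibble::tibble(
    sample_id = rep(rownames(m), times = ncol(m)),
    otu_id = rep(colnames(m), each = nrow(m)),
    v = as.vector(m)
  )
  if (drop_zero) out <- out[out$v != 0, ]
  names(out)[3] <- value
  dplyr::arrange(out, .data$sample_id, .data$otu_id)
}

# Stable per-stage seed derivation: independent streams from one global seed.
# Hash the stage name into an offset so adding stages never shifts others.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) + (h %% 10000L) * 1009L) %% .Machine$integer.max
}

assert_cols <- function(data, cols, what = deparse(substitute(data))) {
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(data)
}
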