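# Core table types and elementary transformations.
#
# The package's universal input is a long count table: one row per
# (sample, OTU) pair with a non-negative integer count. Fractional tables
# carry an `abundance` column with per-sample sums equal to 1.

#' Validate a long OTU count table
#'
#' Checks the count-table contract: columns `sample_id`, `otu_id`, `count`;
#' counts non-negative integers; no duplicate (sample, OTU) pairs; every
#' sample with a positive total.
#'
#' @param counts tibble with columns `sample_id`, `otu_id`, `count`
#' @return the input, invisibly, if valid; otherwise an error
#' @export
validate_counts <- function(counts) {
  assert_cols(counts, c("sample_id", "otu_id", "count"), "count table")
  if (any(is.na(counts$count))) stop("count table contains NA counts", call. = FALSE)
  if (any(counts$count < 0)) {
    bad <- counts[counts$count < 0, ][1, ]
    stop(sprintf("negative count for sample '%s', OTU '%s'",
                 bad$sample_id, bad$otu_id), call. = FALSE)
  }
  if (any(counts$count != round(counts$count))) {
    bad <- counts[counts$count != round(counts$count), ][1, ]
    stop(sprintf("non-integer count for sample '%s', OTU '%s'",
                 bad$sample_id, bad$otu_id), call. = FALSE)
  }
  if (anyDuplicated(counts[c("sample_id", "otu_id")]) > 0) {
    stop("duplicate (sample_id, otu_id) pairs in count table", call. = FALSE)
  }
  totals <- tapply(counts$count, counts$sample_id, sum)
  if (any(totals == 0)) {
    stop(sprintf("sample(s) with zero total count: %s",
                 paste(names(totals)[totals == 0], collapse = ", ")),
         call. = FALSE)
  }
  invisible(counts)
}

#' Convert counts to fractional (relative) abundances
#'
#' Each sample's counts are divided by its total, so per-sample abundances
#' sum to one — the standard first normalization step for compositional
#' amplicon data.
#'
#' @param counts long count table (see [validate_counts()])
#' @return tibble with columns `sample_id`, `otu_id`, `abundance`
#' @export
#' @examples
#' counts <- tibble::tibble(sample_id = "s1", otu_id = c("a", "b"),
#'                          count = c(1L, 3L))
#' to_fractional(counts)
to_fractional <- function(counts) {
  validate_counts(counts)
  counts %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::mutate(abundance = .data$count / sum(.data$count)) %>%
    dplyr::ungroup() %>%
    dplyr::select("sample_id", "otu_id", "abundance")
}

#' Aggregate fractional abundances at a taxonomic rank
#'
#' Sums member-OTU abundances per taxon at the requested rank. OTUs without
#' an assignment at that rank pool into `"unclassified"`. Per-sample mass is
#' conserved exactly.
#'
#' @param fractions tibble with `sample_id`, `otu_id`, `abundance`
#' @param taxonomy tibble as returned by [parse_taxonomy()] (columns
#'   `otu_id` plus the seven rank columns)
#' @param rank one of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`
#' @return tibble with columns `sample_id`, `taxon`, `abundance`
#' @export
aggregate_by_rank <- function(fractions, taxonomy,
                              rank = c("phylum", "kingdom", "class", "order",
                                       "family", "genus", "species")) {
  rank <- match.arg(rank)
  assert_cols(fractions, c("sample_id", "otu_id", "abundance"), "fraction table")
  assert_cols(taxonomy, c("otu_id", rank), "taxonomy")
  tax <- taxonomy[, c("otu_id", rank)]
  names(tax)[2] <- "taxon"
  fractions %>%
    dplyr::left_join(tax, by = "otu_id") %>%
    dplyr::mutate(taxon = dplyr::if_else(
      is.na(.data$taxon) | .data$taxon == "", "unclassified", .data$taxon)) %>%
    dplyr::group_by(.data$sample_id, .data$taxon) %>%
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop")
}

#' Parse Greengenes-style lineage strings into rank columns
#'
#' Lineages of the form `"k__Bacteria; p__Firmicutes; ..."` are split into
#' the seven canonical ranks. Prefixes (`k__` ... `s__`) are stripped; empty
#' fields become `""`. A string that does not look like a prefixed lineage is
#' stored verbatim in the `species` column.
#'
#' @param otu_id character vector of OTU identifiers
#' @param lineage character vector of lineage strings, parallel to `otu_id`
#' @return tibble with columns `otu_id`, `kingdom`, ..., `species`, `lineage`
#' @export
parse_taxonomy <- function(otu_id, lineage) {
  stopifnot(length(otu_id) == length(lineage))
  if (anyDuplicated(otu_id) > 0) stop("duplicate otu_id in taxonomy", call. = FALSE)
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  out <- matrix("", nrow = length(otu_id), ncol = 7,
                dimnames = list(NULL, ranks))
  for (i in seq_along(lineage)) {
    parts <- trimws(strsplit(lineage[i], ";", fixed = TRUE)[[1]])
    if (length(parts) == 0 || !any(startsWith(parts, prefixes))) {
      # unparseable: keep verbatim as a species-level label
      out[i, "species"] <- lineage[i]
      next
    }
    for (j in seq_along(parts)) {
      p <- parts[j]
      k <- match(substr(p, 1, 3), prefixes)
      if (!is.na(k)) out[i, k] <- substring(p, 4)
    }
  }
  dplyr::bind_cols(tibble::tibble(otu_id = otu_id),
                   tibble::as_tibble(out),
                   tibble::tibble(lineage = lineage))
}
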