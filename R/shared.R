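# Shared-OTU set analysis across subjects (Venn-style subset counts).

#' Shared OTUs across subjects' high-abundance sets
#'
#' Computes, for every non-empty subset of subjects, the number of OTUs
#' present in all members' high-abundance sets (exact intersections, the
#' counts behind a Venn diagram), the all-subjects core, and each subject's
#' fraction of its own set found in every other subject.
#'
#' @param hsets named list: subject -> character vector of OTU ids (or
#'   [select_high_abundance()] tibbles)
#' @return tibble (`subjects` list-column, `label`, `size`, `n_shared`)
#'   with attributes `core_otus` (character) and `core_fraction` (named
#'   numeric, per subject)
#' @export
shared_otu_sets <- function(hsets) {
  if (length(hsets) < 2) stop("need at least 2 subjects", call. = FALSE)
  sets <- lapply(hsets, function(h) if (is.character(h)) h else h$otu_id)
  subs <- names(sets)
  if (is.null(subs)) stop("hsets must be a named list", call. = FALSE)
  rows <- list()
  for (k in seq_along(subs)) {
    for (idx in utils::combn(seq_along(subs), k, simplify = FALSE)) {
      inter <- Reduce(intersect, sets[idx])
      rows[[length(rows) + 1]] <- tibble::tibble(
        subjects = list(subs[idx]),
        label = paste(subs[idx], collapse = "+"),
        size = k, n_shared = length(inter))
    }
  }
  core <- Reduce(intersect, sets)
  core_frac <- vapply(seq_along(subs), function(i) {
    others <- Reduce(intersect, sets[-i])
    length(intersect(sets[[i]], others)) / length(sets[[i]])
  }, numeric(1))
  out <- dplyr::bind_rows(rows)
  attr(out, "core_otus") <- core
  attr(out, "core_fraction") <- setNames(core_frac, subs)
  out
}
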