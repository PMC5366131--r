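# File I/O for the standard formats the pipeline touches: classic QIIME-style
# TSV OTU tables, BIOM-JSON v1.0, metadata/taxonomy TSV, Newick trees.

#' Read an OTU count table
#'
#' Supports the classic TSV convention (OTUs as rows, samples as columns,
#' first header `#OTU ID`) and BIOM-JSON v1.0. A transposed TSV (samples as
#' rows) is detected from the header and accepted; the orientation used is
#' reported via `message()`.
#'
#' @param path file path
#' @param format `"tsv"` or `"biom-json"`; default guessed from the extension
#' @return long count tibble (`sample_id`, `otu_id`, `count`), validated
#' @export
read_otu_table <- function(path, format = c("auto", "tsv", "biom-json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.biom$|\\.json$", path, ignore.case = TRUE))
      "biom-json" else "tsv"
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  counts <- switch(format,
    "tsv" = read_otu_tsv(path),
    "biom-json" = read_otu_biom_json(path)
  )
  validate_counts(counts)
  counts
}

read_otu_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^# Constructed from biom", first)) {
    df <- read.delim(path, skip = 1, check.names = FALSE,
                     comment.char = "", stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, check.names = FALSE, comment.char = "",
                     stringsAsFactors = FALSE)
  }
  if (ncol(df) < 2) stop(sprintf("malformed TSV '%s': fewer than 2 columns", path),
                         call. = FALSE)
  id_col <- names(df)[1]
  otus_as_rows <- grepl("OTU", id_col, ignore.case = TRUE) ||
    id_col %in% c("#OTU ID", "otu_id", "OTU_ID")
  samples_as_rows <- id_col %in% c("sample_id", "#SampleID", "SampleID", "sample")
  if (!otus_as_rows && !samples_as_rows) {
    # default to the QIIME classic convention
    otus_as_rows <- TRUE
  }
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_len(ncol(vals))) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("malformed TSV '%s': non-numeric value '%s' at data row %d, column '%s'",
                   path, v[bad], bad, names(vals)[j]), call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (otus_as_rows) {
    message(sprintf("read_otu_table: '%s' read as OTUs-as-rows (%d OTUs x %d samples)",
                    basename(path), nrow(m), ncol(m)))
    m <- t(m)
  } else {
    message(sprintf("read_otu_table: '%s' read as samples-as-rows (%d samples x %d OTUs)",
                    basename(path), nrow(m), ncol(m)))
  }
  otu_tibble(m, value = "count")
}

read_otu_biom_json <- function(path) {
  b <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) stop(sprintf("malformed BIOM-JSON '%s': %s",
                                                 path, conditionMessage(e)),
                                         call. = FALSE))
  for (f in c("rows", "columns", "data", "matrix_type", "shape")) {
    if (is.null(b[[f]])) stop(sprintf("malformed BIOM-JSON '%s': missing field '%s'",
                                      path, f), call. = FALSE)
  }
  otus <- vapply(b$rows, function(r) r$id, character(1))
  samples <- vapply(b$columns, function(cc) cc$id, character(1))
  m <- matrix(0, nrow = length(otus), ncol = length(samples),
              dimnames = list(otus, samples))
  if (identical(b$matrix_type, "sparse")) {
    for (e in b$data) m[e[[1]] + 1L, e[[2]] + 1L] <- e[[3]]
  } else {
    for (i in seq_along(b$data)) m[i, ] <- unlist(b$data[[i]])
  }
  message(sprintf("read_otu_table: '%s' read as BIOM-JSON (%d OTUs x %d samples)",
                  basename(path), nrow(m), ncol(m)))
  otu_tibble(t(m), value = "count")
}

#' Write an OTU count table
#'
#' @param counts long count tibble
#' @param path output path
#' @param format `"tsv"` (classic OTUs-as-rows layout) or `"biom-json"` (v1.0)
#' @return `path`, invisibly
#' @export
write_otu_table <- function(counts, path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  validate_counts(counts)
  m <- t(otu_matrix(counts, "count"))  # OTUs x samples
  if (format == "tsv") {
    df <- data.frame(`#OTU ID` = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    nz <- which(m != 0, arr.ind = TRUE)
    biom <- list(
      id = "mbtraj",
      format = "Biological Observation Matrix 1.0.0",
      format_url = "http://biom-format.org",
      type = "OTU table",
      generated_by = "mbtraj",
      date = "1970-01-01T00:00:00",
      matrix_type = "sparse",
      matrix_element_type = "int",
      shape = c(nrow(m), ncol(m)),
      rows = lapply(rownames(m), function(i) list(id = i, metadata = NULL)),
      columns = lapply(colnames(m), function(i) list(id = i, metadata = NULL)),
      data = lapply(seq_len(nrow(nz)), function(k) {
        list(nz[k, 1] - 1L, nz[k, 2] - 1L, unname(m[nz[k, 1], nz[k, 2]]))
      })
    )
    jsonlite::write_json(biom, path, auto_unbox = TRUE, null = "null",
                         digits = NA)
  }
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a TSV with columns `sample_id`, `subject_id`, `day` (integer, days
#' relative to module entry; negative = pre-entry) and `phase`
#' (`pre`/`confinement`/`post`). Phase consistency with `day` is checked
#' against the supplied entry/exit days.
#'
#' @param path TSV path
#' @param entry_day,exit_day confinement boundaries used for the phase check
#' @return metadata tibble
#' @export
read_metadata <- function(path, entry_day = 0L, exit_day = 520L) {
  df <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  validate_metadata(df, entry_day, exit_day)
  df$day <- as.integer(df$day)
  df
}

#' Validate a metadata table
#' @param meta metadata tibble
#' @param entry_day,exit_day confinement boundaries
#' @return the input, invisibly
#' @export
validate_metadata <- function(meta, entry_day = 0L, exit_day = 520L) {
  assert_cols(meta, c("sample_id", "subject_id", "day", "phase"), "metadata")
  if (anyDuplicated(meta[c("subject_id", "day")]) > 0) {
    stop("duplicate (subject_id, day) in metadata", call. = FALSE)
  }
  expected <- phase_for_day(meta$day, entry_day, exit_day)
  bad <- which(meta$phase != expected)
  if (length(bad) > 0) {
    stop(sprintf("phase inconsistent with day for sample(s): %s",
                 paste(meta$sample_id[bad], collapse = ", ")), call. = FALSE)
  }
  invisible(meta)
}

#' Phase label for a collection day
#' @param day integer day(s) relative to module entry
#' @param entry_day,exit_day confinement boundaries
#' @return character vector in `{"pre","confinement","post"}`
#' @export
phase_for_day <- function(day, entry_day = 0L, exit_day = 520L) {
  ifelse(day < entry_day, "pre",
         ifelse(day <= exit_day, "confinement", "post"))
}

#' Read a taxonomy TSV (columns `otu_id`, `lineage`)
#' @param path TSV path
#' @return parsed taxonomy tibble (see [parse_taxonomy()])
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_cols(df, c("otu_id", "lineage"), "taxonomy file")
  parse_taxonomy(as.character(df$otu_id), as.character(df$lineage))
}

#' Read a rooted phylogenetic tree (Newick)
#'
#' Thin wrapper over [ape::read.tree()] that checks the branch-length and
#' unique-leaf contracts.
#'
#' @param path Newick file
#' @return an `ape` `phylo` object
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  validate_tree(tree)
  tree
}

#' Validate a phylogenetic tree for UniFrac use
#' @param tree `phylo` object
#' @return the tree, invisibly
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object", call. = FALSE)
  if (anyDuplicated(tree$tip.label) > 0) stop("tree has duplicate leaf labels", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths", call. = FALSE)
  invisible(tree)
}
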