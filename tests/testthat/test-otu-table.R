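# Core table contracts: I/O round trips, fractional normalization,
# taxonomic aggregation.

test_that("TSV and BIOM-JSON reads agree and round-trip losslessly", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\tsampleA\tsampleB",
               "otu1\t1\t4", "otu2\t2\t0", "otu3\t3\t6"), tf)
  counts <- suppressMessages(read_otu_table(tf))
  totals <- tapply(counts$count, counts$sample_id, sum)
  expect_equal(as.numeric(totals[c("sampleA", "sampleB")]), c(6, 10))

  bf <- withr::local_tempfile(fileext = ".biom")
  write_otu_table(counts, bf, "biom-json")
  counts2 <- suppressMessages(read_otu_table(bf, "biom-json"))
  expect_equal(dplyr::arrange(counts, sample_id, otu_id),
               dplyr::arrange(counts2, sample_id, otu_id))

  # independent reader cross-check on the written BIOM
  skip_if_not_installed("biomformat")
  bm <- biomformat::read_biom(bf)
  m_ref <- as.matrix(biomformat::biom_data(bm))
  m_own <- t(otu_matrix(counts, "count"))
  expect_equal(unname(m_ref[rownames(m_own), colnames(m_own)]),
               unname(m_own))
})

test_that("round trips are lossless on random tables in both formats", {
  set.seed(11)
  for (rep in 1:25) {
    counts <- random_count_table(sample(2:6, 1), sample(3:10, 1))
    for (fmt in c("tsv", "biom-json")) {
      f <- withr::local_tempfile(fileext = if (fmt == "tsv") ".tsv" else ".biom")
      write_otu_table(counts, f, fmt)
      back <- suppressMessages(read_otu_table(f, fmt))
      expect_equal(dplyr::arrange(back, sample_id, otu_id),
                   dplyr::arrange(counts, sample_id, otu_id))
    }
  }
})

test_that("malformed inputs are rejected with informative errors", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\ts1\ts2", "otu1\t1\t-1"), tf)
  expect_error(suppressMessages(read_otu_table(tf)), "negative count")
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\ts1", "otu1\tabc"), tf2)
  expect_error(suppressMessages(read_otu_table(tf2)), "non-numeric")
  expect_error(read_otu_table("/nonexistent/file.tsv"), "not found")
  counts <- tibble::tibble(sample_id = "s1", otu_id = c("a", "b"),
                           count = c(0L, 0L))
  expect_error(validate_counts(counts), "zero total")
})

test_that("transposed (samples-as-rows) TSV is detected and accepted", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\totu1\totu2", "sA\t1\t2", "sB\t3\t4"), tf)
  expect_message(counts <- read_otu_table(tf), "samples-as-rows")
  expect_equal(counts$count[counts$sample_id == "sA" & counts$otu_id == "otu2"], 2)
})

test_that("to_fractional normalizes each sample to unit sum", {
  bad <- tibble::tibble(sample_id = c("s1", "s1", "s2"),
                        otu_id = c("a", "b", "a"),
                        count = c(1L, 3L, 0L))
  expect_error(to_fractional(bad), "zero total")
  counts <- tibble::tibble(sample_id = c("s1", "s1", "s2"),
                           otu_id = c("a", "b", "a"),
                           count = c(1L, 3L, 5L))
  frac <- to_fractional(counts)
  expect_equal(frac$abundance[frac$sample_id == "s1"], c(0.25, 0.75))
  expect_equal(frac$abundance[frac$sample_id == "s2"], 1)

  # law: any valid table sums to 1 per sample; idempotent up to rescaling
  counts <- random_count_table(5, 12, seed = 3)
  frac <- to_fractional(counts)
  sums <- tapply(frac$abundance, frac$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  rescaled <- dplyr::mutate(frac, count = round(abundance * 1e6))
  frac2 <- to_fractional(rescaled[rescaled$count > 0,
                                  c("sample_id", "otu_id", "count")])
  merged <- dplyr::inner_join(frac, frac2, by = c("sample_id", "otu_id"))
  expect_true(all(abs(merged$abundance.x - merged$abundance.y) < 1e-5))
})

test_that("aggregate_by_rank sums members, pools unassigned, conserves mass", {
  tax <- parse_taxonomy(c("a", "b", "c"),
                        c("k__Bacteria; p__Firmicutes",
                          "k__Bacteria; p__Firmicutes",
                          "k__Bacteria; p__"))
  frac <- tibble::tibble(sample_id = "s1", otu_id = c("a", "b", "c"),
                         abundance = c(0.2, 0.3, 0.5))
  agg <- aggregate_by_rank(frac, tax, "phylum")
  expect_equal(agg$abundance[agg$taxon == "Firmicutes"], 0.5)
  expect_equal(agg$abundance[agg$taxon == "unclassified"], 0.5)

  counts <- random_count_table(4, 20, seed = 8)
  otus <- unique(counts$otu_id)
  tax <- parse_taxonomy(otus, paste0("k__Bacteria; p__P",
                                     sample(1:4, length(otus), replace = TRUE)))
  agg <- aggregate_by_rank(to_fractional(counts), tax, "phylum")
  sums <- tapply(agg$abundance, agg$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("taxonomy parsing handles Greengenes lineages and fallbacks", {
  tax <- parse_taxonomy(c("x", "y"),
                        c("k__Bacteria; p__Bacteroidetes; c__Bacteroidia",
                          "some unparseable label"))
  expect_equal(tax$phylum[1], "Bacteroidetes")
  expect_equal(tax$class[1], "Bacteroidia")
  expect_equal(tax$species[2], "some unparseable label")
  expect_error(parse_taxonomy(c("x", "x"), c("a", "b")), "duplicate")
})

test_that("metadata phase labels must match collection days", {
  meta <- tibble::tibble(sample_id = c("a", "b", "c"),
                         subject_id = "5001", day = c(-5L, 100L, 600L),
                         phase = c("pre", "confinement", "post"))
  expect_silent(validate_metadata(meta))
  meta$phase[2] <- "post"
  expect_error(validate_metadata(meta), "inconsistent")
  expect_equal(phase_for_day(c(-1, 0, 520, 521)),
               c("pre", "confinement", "confinement", "post"))
})
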