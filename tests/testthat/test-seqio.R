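test_that("FASTA reading preserves order, normalises case and round-trips", {
  path <- tmp_fasta(c("t1", "t2"), c("acgt", "GGTTAA"))
  recs <- read_fasta(path)
  expect_equal(recs$id, c("t1", "t2"))
  expect_equal(recs$residues, c("ACGT", "GGTTAA"))
  expect_equal(recs$alphabet, c("nucleotide", "nucleotide"))

  out <- tempfile(fileext = ".fasta")
  write_fasta(recs, out)
  again <- read_fasta(out)
  expect_identical(again[, c("id", "residues")],
                   recs[, c("id", "residues")])
})

test_that("FASTA error contracts: empty file, bad residue, duplicate id", {
  empty <- tempfile(); file.create(empty)
  expect_error(read_fasta(empty), "empty")
  bad <- tmp_fasta("p1", "GLJV")
  expect_error(read_fasta(bad, "protein"), "'J'.*p1|p1.*'J'")
  # the error names the offending position
  expect_error(read_fasta(bad, "protein"), "position 3")
  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), dup)
  expect_error(read_fasta(dup), "duplicate")
})

test_that("auto alphabet inference separates nucleotide from protein", {
  path <- tmp_fasta(c("nt", "aa"), c("ACGTACGTN", "MKVLITAEW"))
  recs <- read_fasta(path, "auto")
  expect_equal(recs$alphabet, c("nucleotide", "protein"))
})

test_that("peak tables parse, drop non-positive intensities and sort", {
  df <- data.frame(rt = c(5.2, 1.1, 3.3), mz = c(1200, 1500, 1100),
                   intensity = c(10, 20, 30))
  pt <- suppressMessages(read_peak_table(tmp_peaks(df)))
  expect_s3_class(pt, "peak_table")
  expect_equal(nrow(pt), 3L)
  expect_equal(pt$rt, sort(df$rt))

  df0 <- df; df0$intensity[2] <- 0
  expect_message(pt0 <- read_peak_table(tmp_peaks(df0)), "dropped 1")
  expect_equal(nrow(pt0), 2L)

  # permutation invariance
  shuf <- df[c(3, 1, 2), ]
  expect_equal(suppressMessages(read_peak_table(tmp_peaks(shuf))), pt)

  # comma-delimited input is auto-detected
  expect_equal(suppressMessages(read_peak_table(tmp_peaks(df, sep = ","))),
               pt)
})

test_that("peak table error contracts: missing column, non-numeric cell", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("rt_min\tintensity", "1.0\t5"), path)
  expect_error(read_peak_table(path), "mz")
  path2 <- tempfile(fileext = ".tsv")
  writeLines(c("rt_min\tmz\tintensity", "1.0\toops\t5"), path2)
  expect_error(read_peak_table(path2), "line 2")
})

test_that("the shipped reference bundle satisfies its invariants", {
  b <- the_bundle()
  expect_s3_class(b, "ref_bundle")
  expect_equal(sum(b$column_map == 0L), 1L)
  expect_true(all(diff(b$column_map) > 0L))
  cys_cols <- match(b$layout$cys_cols, b$column_map)
  for (row in strsplit(b$alignment, "", fixed = TRUE))
    expect_true(all(row[cys_cols] == "C"))
  expect_true(all(b$mature_refs$label %in%
                    c("archetypal_moebius", "archetypal_bracelet",
                      "hybrid", "linear")))
})

test_that("corrupt bundles are rejected, never repaired", {
  src <- system.file("extdata", "refbundle", package = "cyclominer")
  copy_bundle <- function() {
    d <- tempfile(); dir.create(d)
    file.copy(list.files(src, full.names = TRUE), d)
    d
  }
  # duplicated consensus position
  d1 <- copy_bundle()
  map <- read.table(file.path(d1, "column_map.tsv"), header = TRUE)
  map$consensus_position[2] <- map$consensus_position[1]
  write.table(map, file.path(d1, "column_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(load_reference_bundle(d1), "injective|increasing")
  # no column 0
  d2 <- copy_bundle()
  map <- read.table(file.path(d2, "column_map.tsv"), header = TRUE)
  map$consensus_position <- map$consensus_position + 200L
  write.table(map, file.path(d2, "column_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(load_reference_bundle(d2), "position 0")
  # a curated domain missing a cysteine on a cysteine column
  d3 <- copy_bundle()
  aln <- readLines(file.path(d3, "anchored_alignment.fasta"))
  i <- which(!startsWith(aln, ">"))[1]
  aln[i] <- sub("C", "A", aln[i])
  writeLines(aln, file.path(d3, "anchored_alignment.fasta"))
  expect_error(load_reference_bundle(d3), "cysteine")
})
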