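test_that("six-frame ORF extraction translates and maps coordinates", {
  tr <- list(id = "t", residues = "ATGGGTTGA")
  orfs <- six_frame_orfs(tr, min_orf_len = 1L, min_transcript_len = 1L)
  fwd1 <- orfs[orfs$frame == 1L, ]
  expect_true("MG" %in% fwd1$protein)
  row <- fwd1[fwd1$protein == "MG", ]
  expect_equal(row$nt_end - row$nt_start, 3L * nchar(row$protein))

  # a CDS embedded on the reverse strand is recovered in a negative frame
  cds <- "ATGAAGGTTCTTATCACTGCT"   # MKVLITA
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    paste0("TAA", cds, "TAA"))))
  orfs2 <- six_frame_orfs(list(id = "r", residues = paste0("GG", rc, "CC")),
                          min_orf_len = 5L, min_transcript_len = 1L)
  expect_true("MKVLITA" %in% orfs2$protein)
  expect_true(all(orfs2$frame[orfs2$protein == "MKVLITA"] < 0L))

  # short transcripts yield nothing at the default length cutoff
  short <- list(id = "s", residues = paste(rep("ACG", 50), collapse = ""))
  expect_equal(nrow(six_frame_orfs(short, min_orf_len = 1L)), 0L)
})

test_that("ORF nt spans slice back to the reported protein", {
  set.seed(42)
  nt <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  orfs <- six_frame_orfs(list(id = "x", residues = nt), min_orf_len = 10L)
  for (i in seq_len(nrow(orfs))) {
    sub <- substr(nt, orfs$nt_start[i] + 1L, orfs$nt_end[i])
    if (orfs$frame[i] < 0L)
      sub <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                             if.fuzzy.codon = "X",
                                             no.init.codon = TRUE))
    expect_equal(aa, orfs$protein[i])
  }
})

test_that("motif scan finds the kalata B1 cysteine spacing", {
  hits <- scan_cd_motif(KB1)
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$loop_lengths, c(3L, 4L, 4L, 1L, 4L))
  expect_equal(scan_cd_motif("CCCCCC"), list())
  expect_error(scan_cd_motif(KB1, list(c(2, 1), c(3, 6), c(2, 8), c(1, 2),
                                       c(3, 6))), "malformed")
})

test_that("two disjoint cysteine sextets give two non-overlapping hits", {
  protein <- paste0(KB1, paste(rep("A", 20), collapse = ""), KB1)
  hits <- scan_cd_motif(protein)
  expect_length(hits, 2L)
  expect_true(hits[[1]]$span[2] <= hits[[2]]$span[1])
  oracle <- motif_oracle(protein, default_loop_windows())
  expect_length(oracle, 2L)
  expect_equal(hits[[2]]$cys_positions, oracle[[2]] - 1L)
})

test_that("motif scan agrees with the exhaustive enumeration oracle", {
  # narrow windows so that short strings can carry hits
  tight <- list(c(0L, 1L), c(0L, 1L), c(0L, 1L), c(0L, 1L), c(0L, 1L))
  set.seed(7)
  for (i in 1:300) {
    n <- sample(6:14, 1)
    p <- paste(sample(c("C", "A", "G"), n, TRUE, prob = c(.5, .25, .25)),
               collapse = "")
    got <- lapply(scan_cd_motif(p, tight), function(h) h$cys_positions)
    want <- lapply(motif_oracle(p, tight), function(x) as.integer(x) - 1L)
    expect_identical(got, want)
  }
  # default windows on longer C-enriched strings
  for (i in 1:200) {
    n <- sample(17:30, 1)
    p <- paste(sample(c("C", "A", "G"), n, TRUE, prob = c(.4, .3, .3)),
               collapse = "")
    got <- lapply(scan_cd_motif(p), function(h) h$cys_positions)
    want <- lapply(motif_oracle(p, default_loop_windows()),
                   function(x) as.integer(x) - 1L)
    expect_identical(got, want)
  }
})

test_that("similarity score honours the self-alignment and zero contracts", {
  b62 <- blosum62()
  refs <- c(a = KB1)
  self <- similarity_score(KB1, refs)
  diag_sum <- sum(diag(b62[strsplit(KB1, "")[[1]], strsplit(KB1, "")[[1]]]))
  expect_equal(self$score, diag_sum)
  # no positive-scoring residue pair at all
  polyg <- paste(rep("G", 12), collapse = "")
  polyw <- c(w = paste(rep("W", 12), collapse = ""))
  expect_equal(similarity_score(polyg, polyw)$score, 0)
  expect_error(similarity_score("", refs), "empty")
  expect_equal(similarity_score(KB1, c(b = CYO2))$score,
               sw_oracle(KB1, CYO2, b62))
})

test_that("similarity equals the brute-force DP oracle on random pairs", {
  b62 <- blosum62()
  set.seed(11)
  for (i in 1:40) {
    a <- paste(sample(rownames(b62)[1:20], sample(5:40, 1), TRUE),
               collapse = "")
    b <- paste(sample(rownames(b62)[1:20], sample(5:40, 1), TRUE),
               collapse = "")
    expect_equal(similarity_score(a, c(r = b))$score, sw_oracle(a, b, b62))
  }
})

test_that("mining recovers a synthetic precursor and rejects decoys", {
  tpls <- the_templates()
  sim <- build_transcriptome(tpls["HS2"], n_per_species = 1L,
                             n_decoys = 60L, seed = 31L)
  cand <- mine_precursors(sim$transcripts, the_bundle())
  expect_length(cand, 1L)
  expect_length(cand[[1]]$motif_hits, 1L)
  expect_equal(cand[[1]]$provenance$transcript_id, "tr_HS2_1")
  expect_true(cand[[1]]$similarity >= mining_config()$min_similarity)
})

test_that("identical precursors on two transcripts are deduplicated", {
  tpl <- the_templates()$GA1
  smp <- sample_precursor(tpl, seed = 5L, n_repeats = 1L)
  nt <- paste0("AAACCC", smp$cds, "GGGTTT")
  recs <- data.frame(id = c("x1", "x2"), description = "",
                     alphabet = "nucleotide",
                     residues = c(nt, paste0("TTT", nt)),
                     stringsAsFactors = FALSE)
  class(recs) <- c("seq_records", "data.frame")
  cand <- mine_precursors(recs, the_bundle())
  expect_length(cand, 1L)
  expect_setequal(cand[[1]]$provenance$transcript_id, c("x1", "x2"))
})
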