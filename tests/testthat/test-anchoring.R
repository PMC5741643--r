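test_that("re-anchoring a bundle member reproduces its stored columns", {
  b <- the_bundle()
  all_pos <- b$column_map
  for (nm in c("syn_YS1", "syn_HS4", "syn_PN1", "syn_YY2")) {
    row <- strsplit(b$alignment[[nm]], "", fixed = TRUE)[[1]]
    occupied <- which(row != "-")
    protein <- paste(row[occupied], collapse = "")
    stored <- all_pos[occupied]
    a <- anchor_to_profile(as_candidate(protein), b)
    expect_equal(a$cons_pos, stored, info = nm)
  }
})

test_that("archetypal Moebius precursors show the diagnostic NTPP gaps", {
  a <- anchored_from_template(the_templates()$YS3, seed = 91L)
  expect_true(all(-56:-54 %in% a$gap_positions))
  expect_true(all(-50:-38 %in% a$gap_positions))
  expect_true(all(-32:-31 %in% a$gap_positions))  # archetypal deletion
  expect_false("partial" %in% a$flags)
})

test_that("truncated precursors anchor from position 0 and are flagged", {
  smp <- sample_precursor(the_templates()$HS1, seed = 3L, n_repeats = 1L)
  cd_start <- smp$domains$start[smp$domains$domain == "CD1"]
  # keep only 5 residues upstream of the domain (truncation at -5)
  trunc <- substr(smp$protein, cd_start - 5L, nchar(smp$protein))
  a <- anchor_to_profile(as_candidate(trunc), the_bundle())
  expect_true("partial" %in% a$flags)
  expect_equal(a$cons_pos[a$cd_units[[1]]$cd_start], 0L)
  expect_true(all(-57:-20 %in% a$gap_positions))
})

test_that("segment_domains covers the protein exactly once", {
  for (nm in c("YA1", "NL2", "QD1")) {
    a <- anchored_from_template(the_templates()[[nm]], seed = 17L)
    seg <- segment_domains(a)
    d <- seg$domains
    expect_equal(d$start[1], 1L)
    expect_equal(d$end[nrow(d)], nchar(a$protein))
    expect_true(all(d$start[-1] == d$end[-nrow(d)] + 1L))
  }
})

test_that("repeated NTR/CD units are segmented and alternate", {
  a <- anchored_from_template(the_templates()$YS1, seed = 8L, n_repeats = 3L)
  seg <- segment_domains(a)
  expect_equal(seg$repeat_count, 3L)
  d <- seg$domains
  expect_equal(sum(d$domain == "CD"), 3L)
  expect_equal(sum(d$domain == "NTR"), 3L)
  inner <- d[d$domain %in% c("NTR", "CD"), ]
  expect_equal(inner$domain, rep(c("NTR", "CD"), 3L))
  # the generator's true boundaries are recovered exactly
  smp <- sample_precursor(the_templates()$YS1, seed = 8L, n_repeats = 3L)
  truth <- smp$domains[smp$domains$domain %in%
                         paste0(rep(c("NTR", "CD"), 3), rep(1:3, each = 2)), ]
  expect_equal(inner$start, truth$start[order(truth$start)])
  expect_equal(inner$end, truth$end[order(truth$start)])
})

test_that("loop decomposition reports kalata-like loops and loop 6 join", {
  protein <- graft_cd(KB1)
  a <- anchor_to_profile(as_candidate(protein), the_bundle())
  loops <- decompose_loops(a, 1L)
  expect_equal(nchar(loops$loops[1:5]), c(3L, 4L, 4L, 1L, 4L))
  expect_equal(loops$loops[6], "TRNGLPV")  # after Cys VI joined with pre-Cys I
  expect_equal(substr(protein, loops$nd_site, loops$nd_site), "N")
  expect_equal(loops$flags, character(0))
})

test_that("abnormal domains get flags, not errors", {
  # extra cysteine in loop 2 and no N/D in loop 6 (valt1-FS3U-like)
  abnormal <- "GLPVCGETCVCGTCNTPGCTCSWPVCTRG"
  protein <- graft_cd(abnormal)
  hits <- scan_cd_motif(protein)
  expect_length(hits, 1L)
  a <- anchor_to_profile(list(protein = protein, motif_hits = hits),
                         the_bundle())
  loops <- decompose_loops(a, 1L)
  expect_true("uneven_cysteines" %in% loops$flags)
  expect_true("missing_ND" %in% loops$flags)
  expect_null(loops$nd_site)
})

test_that("the consensus-column residue wins when loop 6 has two N", {
  # loop-6 tail TNRAN: two N, the later one lands on the nd column
  protein <- graft_cd("GLPVCGETCVGGTCNTPGCTCSWPVCTNRAN")
  a <- anchor_to_profile(as_candidate(protein), the_bundle())
  u <- a$cd_units[[1]]
  expect_equal(u$nd, nchar(protein))
  expect_equal(a$cons_pos[u$nd], a$layout$nd_col)
})

test_that("loops that cannot fit the consensus blocks are unanchorable", {
  # loop 3 of length 12 passes a permissive scan but exceeds the block
  wide <- list(c(2, 7), c(3, 6), c(2, 14), c(1, 2), c(3, 6))
  cd <- "GLPVCGETCVGGTCAAAANTPGAAAACTCSWPVCTRN"
  protein <- graft_cd(cd)
  hits <- scan_cd_motif(protein, wide)
  expect_length(hits, 1L)
  expect_error(anchor_to_profile(list(protein = protein, motif_hits = hits),
                                 the_bundle()), "unanchorable")
})
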