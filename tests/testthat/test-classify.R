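# helper to fabricate a signature profile without running the aligner
make_sig <- function(occ_positions = integer(0), residues = list(),
                     marks = c("-49" = "?", "-48" = "?", "-39" = "?"),
                     hybrid = c("-32" = "0", "-31" = "0"),
                     dipeptide = "HS", partial = FALSE,
                     unknown = integer(0)) {
  win <- -56:-38
  occ <- setNames(rep("0", length(win)), as.character(win))
  occ[as.character(occ_positions)] <- "1"
  occ[as.character(unknown)] <- "?"
  wres <- setNames(rep("?", length(win)), as.character(win))
  for (p in names(residues)) wres[p] <- residues[[p]]
  out <- list(ntpp_occupancy = occ, window_residues = wres,
              linear_bracelet_marks = marks, hybrid_mark = hybrid,
              ntr_dipeptide = dipeptide, partial = partial)
  class(out) <- "signature_profile"
  out
}

test_that("lineage rules: gapped deletions, occupied insertions, boundary", {
  expect_equal(assign_lineage(make_sig())$lineage, "moebius")
  expect_equal(assign_lineage(make_sig(occ_positions = -50:-38))$lineage,
               "bracelet")
  # exactly half-occupied insertion region, deletions not gapped enough
  half <- make_sig(occ_positions = c(-56:-54, -50:-45))
  expect_equal(assign_lineage(half)$lineage, "unclassified")
  # all-unknown NTPP: partial, never guessed
  expect_equal(assign_lineage(make_sig(unknown = -56:-38))$rationale,
               "partial")
})

test_that("linear-bracelet marks rescue the lineage despite low occupancy", {
  sig <- make_sig(occ_positions = c(-56:-51, -49, -48, -39, -38),
                  marks = c("-49" = "P", "-48" = "N", "-39" = "D"))
  got <- assign_lineage(sig)
  expect_equal(got$lineage, "bracelet")
  expect_match(got$rationale, "linear-bracelet")
})

test_that("subfamily rules follow the dipeptide and insertion marks", {
  moe <- function(dip, hyb)
    assign_subfamily("moebius",
                     make_sig(dipeptide = dip,
                              hybrid = c("-32" = hyb, "-31" = hyb)))$subfamily
  expect_equal(moe("YY", "0"), "linear_moebius")
  expect_equal(moe("YS", "1"), "hybrid")
  expect_equal(moe("YS", "0"), "archetypal_moebius")
  expect_equal(moe("ZZ", "0"), "unassigned")

  brl <- make_sig(occ_positions = c(-56:-51, -49, -48, -39, -38),
                  marks = c("-49" = "P", "-48" = "N", "-39" = "D"),
                  dipeptide = "QD")
  expect_equal(assign_subfamily("bracelet", brl)$subfamily,
               "linear_bracelet")
  expect_equal(assign_subfamily(
    "bracelet", make_sig(dipeptide = "HS"))$subfamily, "cyclic_bracelet")
})

test_that("series and species grouping follows occupancy then identity", {
  # same dipeptide, different occupancy patterns: same series, two species
  a <- make_sig(occ_positions = -50:-38,
                residues = as.list(setNames(strsplit("LASNTKLQESVAG", "")[[1]],
                                            as.character(-50:-38))))
  b <- make_sig(occ_positions = -50:-39,
                residues = as.list(setNames(strsplit("LASNTKLQESVA", "")[[1]],
                                            as.character(-50:-39))))
  grp <- group_species_series(list(a, b, a))
  expect_equal(grp$series_key, c("HS", "HS", "HS"))
  expect_equal(grp$species_key, c("HS1", "HS2", "HS1"))
  # below the identity threshold: same occupancy, different species
  c_res <- as.list(setNames(strsplit("IVTQENVRDAWFM", "")[[1]],
                            as.character(-50:-38)))
  cc <- make_sig(occ_positions = -50:-38, residues = c_res)
  grp2 <- group_species_series(list(a, cc))
  expect_equal(grp2$species_key, c("HS1", "HS2"))
  # unknown NTPP: series only
  partial <- make_sig(unknown = -56:-38)
  expect_true(is.na(group_species_series(list(partial))$species_key))
  expect_equal(group_species_series(list(partial))$series_key, "HS")
})

test_that("sampled precursors from k templates recover exactly k species", {
  tpls <- the_templates()[c("YS1", "HS2", "NL1", "QD1")]
  anchored <- list(); truth <- character(0)
  for (nm in names(tpls)) for (s in 1:3) {
    anchored[[length(anchored) + 1L]] <-
      anchored_from_template(tpls[[nm]], seed = 1000L + 17L * s)
    truth <- c(truth, nm)
  }
  cl <- classify_precursors(anchored)
  expect_equal(length(unique(cl$species)), 4L)
  expect_true(all(tapply(cl$species, truth, function(x)
    length(unique(x))) == 1L))
})

test_that("tripartite names follow the organism code and rank rules", {
  cls <- data.frame(id = c("p1", "p2", "p3", "p4"),
                    species = c("HS4", "HS4", "YS1", NA),
                    stringsAsFactors = FALSE)
  nm <- assign_names(cls, "Viola acuminata", "cyclotide")
  expect_equal(nm$full_name[1:3], c("vacum1-HS4", "vacum2-HS4",
                                    "vacum1-YS1"))
  expect_true(is.na(nm$full_name[4]))
  prc <- assign_names(cls, "Viola acuminata", "precursor")
  expect_equal(prc$full_name[1], "prc-vacum1-HS4")
  # previously published names are reused verbatim, prc- prefixed for
  # precursor entities
  withnm <- assign_names(cls, "Viola uliginosa", "precursor",
                         existing_names = c(p1 = "viul A"))
  expect_equal(withnm$full_name[1], "prc-viul A")
  # fallback code derivation for an organism not in the table
  fb <- assign_names(cls[3, , drop = FALSE], "Viola canadensis")
  expect_equal(fb$full_name, "vcana1-YS1")
  expect_error(assign_names(cls, "Viola acuminatus"), "collides")
})

test_that("classification is order-independent except species numbering", {
  tpls <- the_templates()[c("GA1", "GA2", "FA1")]
  anchored <- lapply(names(tpls), function(nm)
    anchored_from_template(tpls[[nm]], seed = 55L))
  cl_fwd <- classify_precursors(anchored, ids = c("a", "b", "c"))
  cl_rev <- classify_precursors(rev(anchored), ids = c("c", "b", "a"))
  rev_ord <- cl_rev[match(cl_fwd$id, cl_rev$id), ]
  expect_equal(rev_ord$lineage, cl_fwd$lineage)
  expect_equal(rev_ord$subfamily, cl_fwd$subfamily)
  expect_equal(rev_ord$series, cl_fwd$series)
})
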