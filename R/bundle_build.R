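# Construction of the shipped synthetic reference bundle.

#' Build a synthetic reference bundle
#'
#' Writes the three bundle files (anchored alignment, column map, mature
#' references) to a directory.  One representative precursor is sampled
#' per species template (single NTR/CD unit) and laid out in the shared
#' consensus column space; the mature reference table contains every
#' representative's cyclotide domain plus the two published mature
#' sequences of kalata B1 and cycloviolacin O2.  All template-derived rows
#' carry a `syn_` prefix to mark them as synthetic stand-ins for curated
#' sequences.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for representative sampling.
#' @param templates Template library.
#' @return `dir`, invisibly.
#' @export
build_reference_bundle <- function(dir, seed = 20171218,
                                   templates = cyclotide_templates()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lay <- .consensus_layout()
  all_pos <- lay$er[1]:lay$ctr[2]
  aln <- character(0)
  mature <- list()
  for (ti in seq_along(templates)) {
    tpl <- templates[[ti]]
    smp <- sample_precursor(tpl, seed = .subseed(seed, ti), n_repeats = 1L)
    aa <- strsplit(smp$protein, "", fixed = TRUE)[[1]]
    row <- rep("-", length(all_pos))
    keep <- !is.na(smp$cons_pos)
    row[match(smp$cons_pos[keep], all_pos)] <- aa[keep]
    aln[[paste0("syn_", tpl$species)]] <- paste(row, collapse = "")
    label <- switch(tpl$subfamily,
                    archetypal_moebius = "archetypal_moebius",
                    cyclic_bracelet = "archetypal_bracelet",
                    hybrid = "hybrid",
                    "linear")
    mature[[ti]] <- data.frame(
      id = paste0("syn_", tpl$species, "_m"), label = label,
      residues = smp$matures$sequence[1], stringsAsFactors = FALSE)
  }
  mature <- do.call(rbind, mature)
  mature <- rbind(
    data.frame(id = "kalata_B1", label = "archetypal_moebius",
               residues = "GLPVCGETCVGGTCNTPGCTCSWPVCTRN",
               stringsAsFactors = FALSE),
    data.frame(id = "cycloviolacin_O2", label = "archetypal_bracelet",
               residues = "GIPCGESCVWIPCISSAIGCSCKSKVCYRN",
               stringsAsFactors = FALSE),
    mature)
  recs <- data.frame(id = names(aln), description = "",
                     alphabet = "protein",
                     residues = unname(unlist(aln)),
                     stringsAsFactors = FALSE)
  # write_fasta validates nothing about gaps; rows are gapped on purpose
  con <- file(file.path(dir, "anchored_alignment.fasta"), "wt")
  for (i in seq_len(nrow(recs))) {
    writeLines(paste0(">", recs$id[i]), con)
    writeLines(recs$residues[i], con)
  }
  close(con)
  .write_tsv(data.frame(column = seq_along(all_pos),
                        consensus_position = all_pos),
             file.path(dir, "column_map.tsv"))
  .write_tsv(mature, file.path(dir, "mature_refs.tsv"))
  invisible(dir)
}
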