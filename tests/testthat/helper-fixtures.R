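# Fixture builders shared across test files.

the_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_bundle()
    cache
  }
})

the_templates <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- cyclotide_templates()
    cache
  }
})

# write records to a temporary FASTA and return the path
tmp_fasta <- function(ids, seqs, descriptions = "") {
  path <- tempfile(fileext = ".fasta")
  recs <- data.frame(id = ids, description = descriptions,
                     residues = seqs, stringsAsFactors = FALSE)
  write_fasta(recs, path)
  path
}

tmp_peaks <- function(df, sep = "\t") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  names(df) <- c("rt_min", "mz", "intensity")
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# a motif-scan candidate built straight from a protein string
as_candidate <- function(protein) {
  list(protein = protein, motif_hits = scan_cd_motif(protein))
}

# an anchored precursor sampled from a template
anchored_from_template <- function(template, seed, n_repeats = NULL) {
  smp <- sample_precursor(template, seed, n_repeats = n_repeats)
  anchor_to_profile(as_candidate(smp$protein), the_bundle())
}

# prodomain of a Moebius template instance with an arbitrary CD grafted on
graft_cd <- function(cd_residues, template = the_templates()$YS3,
                     seed = 404) {
  smp <- sample_precursor(template, seed, n_repeats = 1L)
  dom <- smp$domains
  pro_end <- dom$end[dom$domain == "NTR1"]
  paste0(substr(smp$protein, 1, pro_end), cd_residues)
}

# simulated peak rows for one neutral mass (one envelope per charge)
envelope_rows <- function(M, rt, z, n = 5, base = 1500, jitter = 0) {
  cst <- mass_constants()
  mz <- (M + z * cst$proton) / z + (seq_len(n) - 1) * 1.00336 / z + jitter
  w <- 0.8^(seq_len(n) - 1)
  data.frame(rt = rt, mz = mz, intensity = base * w / sum(w))
}

as_peak_table <- function(...) {
  tab <- rbind(...)
  tab <- tab[order(tab$rt, tab$mz), ]
  rownames(tab) <- NULL
  class(tab) <- c("peak_table", "data.frame")
  tab
}
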