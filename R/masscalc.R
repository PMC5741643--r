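# Monoisotopic mass arithmetic for mature cyclotide candidates.

#' Monoisotopic mass of a peptide
#'
#' For a head-to-tail cyclic peptide the mass is the sum of residue masses
#' (no terminal water) minus two hydrogens per disulfide bond; a linear
#' peptide additionally carries one water.
#'
#' @param residues Residue sequence (single string).
#' @param topology `"cyclic"` or `"linear"`.
#' @param n_disulfide Number of disulfide bonds.
#' @return Monoisotopic mass in Da (unrounded).
#' @examples
#' # cycloviolacin O2, three disulfides: 3138.4 Da at reporting precision
#' monoisotopic_mass("GIPCGESCVWIPCISSAIGCSCKSKVCYRN", "cyclic", 3)
#' @export
monoisotopic_mass <- function(residues, topology = c("cyclic", "linear"),
                              n_disulfide = 0L) {
  topology <- match.arg(topology)
  if (!nzchar(residues)) stop("empty residue sequence")
  cst <- mass_constants()
  aa <- strsplit(toupper(residues), "", fixed = TRUE)[[1]]
  unknown <- setdiff(aa, names(cst$residues))
  if (length(unknown) > 0L)
    stop("mass-indeterminate: residue '", unknown[1L],
         "' has no monoisotopic mass")
  m <- sum(cst$residues[aa]) - n_disulfide * 2 * cst$hydrogen
  if (topology == "linear") m <- m + cst$water
  m
}

#' Mass shift upon reduction and carbamidomethylation
#'
#' Reduction of disulfides adds one hydrogen per cysteine; alkylation with
#' iodoacetamide adds one carbamidomethyl group per cysteine.  For the six
#' cysteines of a cyclotide the shift is 348.18 Da, which is the diagnostic
#' used to confirm three disulfide bonds.
#'
#' @param n_cys Number of cysteines.
#' @return Mass shift in Da.
#' @export
alkylation_delta <- function(n_cys) {
  stopifnot(n_cys >= 0)
  cst <- mass_constants()
  n_cys * (cst$carbamidomethyl + cst$hydrogen)
}

#' m/z of a protonated ion
#'
#' @param M Neutral monoisotopic mass in Da.
#' @param z Positive integer charge.
#' @return (M + z protons) / z.
#' @export
mz_for_charge <- function(M, z) {
  stopifnot(all(z >= 1), all(z == as.integer(z)))
  cst <- mass_constants()
  (M + z * cst$proton) / z
}

#' Enumerate mature-peptide candidates from an anchored precursor
#'
#' For every cyclotide domain, candidates are generated at the six
#' N-terminal start offsets -3..2 relative to the domain's consensus
#' position 0 (negative offsets pull in up to three NTR residues).  Cyclic
#' candidates end at the loop-6 N/D cyclization residue; when no N/D is
#' present the domain is linear and candidates run to the domain's last
#' residue.  Candidates containing X are mass-indeterminate and flagged
#' (calc_mass is NA).
#'
#' @param anchored An `anchored_precursor`.
#' @param precursor_id Identifier copied into the output.
#' @param offsets Integer start offsets (default -3..2, both ends
#'   inclusive).
#' @return Data frame with one row per candidate: `precursor_id`,
#'   `cd_index`, `start_offset`, `topology`, `sequence`, `n_cys`,
#'   `n_disulfide`, `calc_mass`, `calc_mass_alkylated`, `mz2`, `mz3`,
#'   `flags`.
#' @export
enumerate_matures <- function(anchored, precursor_id = "precursor",
                              offsets = -3:2) {
  stopifnot(inherits(anchored, "anchored_precursor"))
  aa <- strsplit(anchored$protein, "", fixed = TRUE)[[1]]
  rows <- list()
  for (k in seq_along(anchored$cd_units)) {
    unit <- anchored$cd_units[[k]]
    loops <- decompose_loops(anchored, k)
    cyclic <- !is.null(loops$nd_site)
    end <- if (cyclic) loops$nd_site else unit$cd_end
    for (off in offsets) {
      start <- unit$cd_start + off
      if (start < 1L || start > end) next
      seqr <- paste(aa[start:end], collapse = "")
      n_cys <- sum(aa[start:end] == "C")
      n_ss <- n_cys %/% 2L
      flags <- character(0)
      if (n_cys %% 2L == 1L) flags <- c(flags, "odd_cysteines")
      topo <- if (cyclic) "cyclic" else "linear"
      m <- tryCatch(monoisotopic_mass(seqr, topo, n_ss),
                    error = function(e) NA_real_)
      if (is.na(m)) flags <- c(flags, "mass_indeterminate")
      rows[[length(rows) + 1L]] <- data.frame(
        precursor_id = precursor_id, cd_index = k, start_offset = off,
        topology = topo, sequence = seqr, n_cys = n_cys,
        n_disulfide = n_ss, calc_mass = m,
        calc_mass_alkylated = if (is.na(m)) NA_real_
                              else m + alkylation_delta(n_cys),
        mz2 = if (is.na(m)) NA_real_ else mz_for_charge(m, 2L),
        mz3 = if (is.na(m)) NA_real_ else mz_for_charge(m, 3L),
        flags = paste(flags, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(precursor_id = character(0), cd_index = integer(0),
                      start_offset = integer(0), topology = character(0),
                      sequence = character(0), n_cys = integer(0),
                      n_disulfide = integer(0), calc_mass = numeric(0),
                      calc_mass_alkylated = numeric(0), mz2 = numeric(0),
                      mz3 = numeric(0), flags = character(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
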