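# Synthetic transcriptome / peptidome generator with ground truth.

# evaluate expr under a fixed RNG state without disturbing the caller's
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.subseed <- function(seed, k) (as.numeric(seed) * 7919 + 104729 * k) %% 2147483629

# draw one residue from each pool of a spec list
.sample_specs <- function(specs) {
  vapply(specs, function(p) if (length(p) == 1L) p else sample(p, 1L),
         character(1))
}

# consensus columns, in residue order, for one cyclotide domain with the
# given segment lengths.  Loop residues are left-justified in their column
# blocks; the pre-Cys-I stretch (loop6b) is right-justified against Cys I;
# for cyclic domains the terminal N/D sits on the dedicated nd column.
.cd_columns <- function(loops, cyclic) {
  lay <- .consensus_layout()
  blk <- lay$loop_blocks
  cys <- lay$cys_cols
  cols <- integer(0)
  l6b <- loops[["loop6b"]]
  if (l6b > blk$loop6b[2] - blk$loop6b[1] + 1L)
    stop("unanchorable: ", l6b, " residues before Cys I exceed the ",
         "consensus block")
  if (l6b > 0L) cols <- (blk$loop6b[2] - l6b + 1L):blk$loop6b[2]
  for (k in 1:5) {
    nm <- paste0("loop", k)
    lk <- loops[[nm]]
    cap <- blk[[nm]][2] - blk[[nm]][1] + 1L
    if (lk > cap) stop("unanchorable: loop ", k, " length ", lk,
                       " exceeds its consensus block (", cap, ")")
    cols <- c(cols, cys[k])
    if (lk > 0L) cols <- c(cols, blk[[nm]][1] + seq_len(lk) - 1L)
  }
  cols <- c(cols, cys[6])
  l6a <- loops[["loop6a"]]
  if (l6a > 0L) {
    if (cyclic) {
      if (l6a > 1L) {
        if (l6a - 1L > lay$nd_col - blk$loop6a[1])
          stop("unanchorable: loop 6 tail exceeds its consensus block")
        cols <- c(cols, blk$loop6a[1] + seq_len(l6a - 1L) - 1L)
      }
      cols <- c(cols, lay$nd_col)
    } else {
      cols <- c(cols, blk$loop6a[1] + seq_len(l6a) - 1L)
    }
  }
  cols
}

# sample residues for one cyclotide domain from a template
.sample_cd <- function(cd) {
  res <- .sample_specs(cd$specs)
  paste(res, collapse = "")
}

#' Sample a synthetic precursor from a species template
#'
#' Draws residues from the template's per-position pools, assembles the
#' full precursor protein (ER + NTPP + (NTR + CD) x repeats + CTR), and
#' back-translates it into a CDS with uniformly sampled synonymous codons,
#' flanked on both sides by stop codons.
#'
#' @param template A `species_template` from [cyclotide_templates()].
#' @param seed Integer seed; identical seeds give identical output.
#' @param n_repeats Number of NTR+CD units; `NULL` samples uniformly from
#'   the template's `repeat_choices`.
#' @return A list with `protein`, `cds`, `domains` (data frame of residue
#'   spans), `matures` (one row per cyclotide domain with the true mature
#'   sequence, topology and monoisotopic mass), `cons_pos` (consensus
#'   position of each residue of the first NTR/CD unit and the flanking
#'   domains; `NA` for repeat units) and `n_repeats`.
#' @export
sample_precursor <- function(template, seed, n_repeats = NULL) {
  stopifnot(inherits(template, "species_template"))
  .with_seed(seed, {
    r <- n_repeats %||%
      (if (length(template$repeat_choices) == 1L) template$repeat_choices
       else sample(template$repeat_choices, 1L))
    er <- .sample_specs(template$er)
    ntpp <- .sample_specs(template$ntpp)
    segs <- list(ER = er, NTPP = ntpp)
    cons <- list(as.integer(names(template$er)),
                 as.integer(names(template$ntpp)))
    cyclic <- template$topology == "cyclic"
    cd_cols <- .cd_columns(template$cd$loops, cyclic)
    matures <- list()
    for (k in seq_len(r)) {
      ntr <- .sample_specs(template$ntr)
      cdres <- .sample_specs(template$cd$specs)
      segs[[paste0("NTR", k)]] <- ntr
      segs[[paste0("CD", k)]] <- cdres
      if (k == 1L) {
        cons <- c(cons, list(as.integer(names(template$ntr)), cd_cols))
      } else {
        cons <- c(cons, list(rep(NA_integer_, length(ntr)),
                             rep(NA_integer_, length(cdres))))
      }
      mat <- paste(cdres, collapse = "")
      matures[[k]] <- data.frame(
        cd_index = k, sequence = mat, topology = template$topology,
        n_cys = sum(cdres == "C"),
        true_mass = monoisotopic_mass(mat, template$topology,
                                      sum(cdres == "C") %/% 2L),
        stringsAsFactors = FALSE)
    }
    if (length(template$ctr) > 0L) {
      ctr <- .sample_specs(template$ctr)
      segs$CTR <- ctr
      lay <- .consensus_layout()
      cons <- c(cons, list(lay$ctr[1] + seq_along(ctr) - 1L))
    }
    protein <- paste(unlist(segs), collapse = "")
    lens <- vapply(segs, length, integer(1))
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    domains <- data.frame(domain = names(segs), start = unname(starts),
                          end = unname(ends), stringsAsFactors = FALSE)
    list(protein = protein,
         cds = .back_translate(protein),
         domains = domains,
         matures = do.call(rbind, matures),
         cons_pos = unlist(cons, use.names = FALSE),
         n_repeats = r)
  })
}

.codon_choices <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc0 <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc0), unname(gc0))
    }
    cache
  }
})

.back_translate <- function(protein) {
  choices <- .codon_choices()
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(aa, function(a) {
    cs <- choices[[a]]
    if (length(cs) == 1L) cs else sample(cs, 1L)
  }, character(1))
  paste0("TAA", paste(codons, collapse = ""), "TAA")
}

.random_nt <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                                collapse = "")

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Build a synthetic transcriptome with ground truth
#'
#' Embeds sampled precursor CDSs in transcripts with random UTRs and
#' randomised strand, adds length-matched random decoy transcripts, draws
#' log-normal FPKM values for every transcript, and assigns each expressed
#' precursor a peptidome abundance tier.  Everything is recorded in a truth
#' ledger for recovery tests.
#'
#' @param templates List of `species_template` objects.
#' @param n_per_species Precursor transcripts generated per template.
#' @param n_decoys Number of random decoy transcripts.
#' @param organisms Optional data frame with columns `organism`, `section`;
#'   precursor transcripts are assigned to organisms round-robin.
#' @param utr_len Integer range (min, max) for random UTR lengths.
#' @param fpkm_meanlog,fpkm_sdlog Log-normal FPKM parameters.
#' @param tier_probs Sampling weights for abundance tiers low/medium/high.
#' @param expressed_fraction Fraction of precursors expressed at the
#'   peptide level (per-precursor Bernoulli draw).
#' @param seed Integer seed.
#' @return List with `transcripts` (a `seq_records` data frame), `fpkm`
#'   (data frame `transcript_id`, `fpkm`) and `truth` (list of data frames
#'   `precursors` and `matures`), of class `sim_transcriptome`.
#' @export
build_transcriptome <- function(templates, n_per_species = 2L,
                                n_decoys = 0L, organisms = NULL,
                                utr_len = c(15L, 60L),
                                fpkm_meanlog = 4.5, fpkm_sdlog = 1.5,
                                tier_probs = c(low = 0.25, medium = 0.35,
                                               high = 0.40),
                                expressed_fraction = 1,
                                seed = 1L) {
  stopifnot(length(templates) >= 1L || n_decoys > 0L)
  .with_seed(seed, {
    recs <- list(); prec <- list(); mats <- list()
    idx <- 0L
    org_i <- 0L
    for (tpl in templates) {
      for (j in seq_len(n_per_species)) {
        idx <- idx + 1L
        id <- sprintf("tr_%s_%d", tpl$species, j)
        smp <- sample_precursor(tpl, seed = sample.int(2^30, 1L))
        u5 <- .random_nt(sample(utr_len[1]:utr_len[2], 1L))
        u3 <- .random_nt(sample(utr_len[1]:utr_len[2], 1L))
        nt <- paste0(u5, smp$cds, u3)
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") nt <- .revcomp(nt)
        org <- sec <- NA_character_
        if (!is.null(organisms)) {
          org_i <- org_i %% nrow(organisms) + 1L
          org <- organisms$organism[org_i]
          sec <- organisms$section[org_i]
        }
        fpkm <- stats::rlnorm(1L, fpkm_meanlog, fpkm_sdlog)
        tier <- sample(names(tier_probs), 1L, prob = tier_probs)
        expressed <- stats::runif(1L) < expressed_fraction
        recs[[id]] <- nt
        prec[[id]] <- data.frame(
          transcript_id = id, organism = org, section = sec,
          species = tpl$species, series = tpl$series,
          lineage = tpl$lineage, subfamily = tpl$subfamily,
          topology = tpl$topology, n_repeats = smp$n_repeats,
          strand = strand, protein = smp$protein, fpkm = fpkm,
          tier = tier, expressed = expressed, stringsAsFactors = FALSE)
        m <- smp$matures
        m$transcript_id <- id
        m$species <- tpl$species
        m$tier <- tier
        m$expressed <- expressed
        mats[[id]] <- m
      }
    }
    cds_lens <- if (length(recs)) nchar(unlist(recs)) else 600L
    for (d in seq_len(n_decoys)) {
      id <- sprintf("decoy_%04d", d)
      recs[[id]] <- .random_nt(sample(cds_lens, 1L))
    }
    transcripts <- data.frame(
      id = names(recs), description = "",
      alphabet = "nucleotide", residues = unlist(recs, use.names = FALSE),
      stringsAsFactors = FALSE)
    class(transcripts) <- c("seq_records", "data.frame")
    fpkm <- data.frame(
      transcript_id = names(recs),
      fpkm = c(if (length(prec)) vapply(prec, function(p) p$fpkm, numeric(1))
               else numeric(0),
               stats::rlnorm(n_decoys, fpkm_meanlog, fpkm_sdlog)),
      stringsAsFactors = FALSE)
    out <- list(transcripts = transcripts, fpkm = fpkm,
                truth = list(
                  precursors = if (length(prec)) do.call(rbind, c(prec, list(make.row.names = FALSE))) else NULL,
                  matures = if (length(mats)) do.call(rbind, c(mats, list(make.row.names = FALSE))) else NULL))
    class(out) <- "sim_transcriptome"
    out
  })
}

#' Simulate an LC-MS peak list from ground truth
#'
#' For every expressed mature peptide a doubly- and a triply-charged
#' isotope envelope is emitted at the theoretical m/z with spacings of
#' 1.00336/z.  The mass jitter (instrument calibration error) is drawn once
#' per envelope and shifts all member peaks coherently.  Intensities are
#' scaled so the triply-charged envelope sums to the tier's signal
#' intensity.  Uniform noise peaks are added over the m/z window.
#'
#' @param sim A `sim_transcriptome` (or its `truth` element).
#' @param jitter_sd Per-envelope m/z jitter standard deviation in Da.
#' @param n_isotope_peaks Peaks per envelope.
#' @param tier_si Summed signal intensity of the 3+ envelope per tier.
#' @param noise_peaks Number of uniform noise peaks.
#' @param rt_range Retention-time range in minutes.
#' @param mz_window m/z acquisition window.
#' @param alkylated If `TRUE`, also simulate the
#'   reduced-and-carbamidomethylated companion peak list (every mass
#'   shifted by [alkylation_delta()] of the peptide's cysteine count).
#' @param seed Integer seed.
#' @return A list with `native` (a `peak_table`) and, when requested,
#'   `alkylated`.
#' @export
simulate_peaklist <- function(sim, jitter_sd = 0.05, n_isotope_peaks = 5L,
                              tier_si = c(low = 100, medium = 500,
                                          high = 1500),
                              noise_peaks = 200L, rt_range = c(5, 45),
                              mz_window = c(1000, 2000),
                              alkylated = FALSE, seed = 1L) {
  truth <- if (inherits(sim, "sim_transcriptome")) sim$truth else sim
  mats <- truth$matures
  mats <- mats[mats$expressed, , drop = FALSE]
  if (nrow(mats) == 0L) stop("truth ledger has no expressed mature peptides")
  cst <- mass_constants()
  w <- 0.8^(seq_len(n_isotope_peaks) - 1L)
  w <- w / sum(w)
  .with_seed(seed, {
    build <- function(shift_by_cys) {
      rows <- vector("list", nrow(mats) * 2L)
      ri <- 0L
      for (i in seq_len(nrow(mats))) {
        M <- mats$true_mass[i]
        if (shift_by_cys) M <- M + alkylation_delta(mats$n_cys[i])
        rt <- stats::runif(1L, rt_range[1], rt_range[2])
        si <- tier_si[[mats$tier[i]]]
        for (z in c(3L, 2L)) {
          eps <- stats::rnorm(1L, 0, jitter_sd)
          mzs <- (M + z * cst$proton) / z +
            (seq_len(n_isotope_peaks) - 1L) * .ISOTOPE_SPACING / z + eps
          ints <- si * w * if (z == 2L) 0.6 else 1
          ri <- ri + 1L
          rows[[ri]] <- data.frame(rt = rt, mz = mzs, intensity = ints)
        }
      }
      noise <- data.frame(
        rt = stats::runif(noise_peaks, rt_range[1], rt_range[2]),
        mz = stats::runif(noise_peaks, mz_window[1], mz_window[2]),
        intensity = stats::runif(noise_peaks, 20, 80))
      tab <- rbind(do.call(rbind, rows[seq_len(ri)]), noise)
      tab <- tab[order(tab$rt, tab$mz), , drop = FALSE]
      rownames(tab) <- NULL
      class(tab) <- c("peak_table", "data.frame")
      tab
    }
    native <- build(FALSE)
    out <- list(native = native)
    if (alkylated) out$alkylated <- build(TRUE)
    out
  })
}

#' @export
print.sim_transcriptome <- function(x, ...) {
  np <- if (is.null(x$truth$precursors)) 0L else nrow(x$truth$precursors)
  cat("Synthetic transcriptome:", nrow(x$transcripts), "transcripts (",
      np, "precursors,", nrow(x$transcripts) - np, "decoys )\n")
  invisible(x)
}
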