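# Synthetic molecular-species templates.
#
# The template library encodes 46 molecular species (14 Moebius across 5
# series, 32 bracelet across 8 series) at consensus fidelity: conserved
# residues are fixed, variable positions carry small residue pools sampled
# at generation time.  Signature-window residues (NTPP [-56,-38], the
# hybrid-insertion pair [-32,-31] and the NTR dipeptide [-9,-8]) are fixed
# per template so that every instantiation classifies back to its template's
# lineage, subfamily and series.

# -- shared per-position residue pools ---------------------------------------

.er_specs <- function() {
  pools <- list(
    "M",
    c("K","R"), c("L","I"), c("F","L"), c("A","V"), c("L","I"), c("V","A"),
    c("L","M"), c("A","S"), c("L","I"), c("A","V"), c("L","F"), c("V","I"),
    c("S","A"), c("A","T"), c("A","S"), c("E","D"), c("A","S"), c("G","A")
  )
  names(pools) <- as.character(-76:-58)
  pools
}

.ntr_specs <- function(dipeptide) {
  pools <- list(
    c("S","T"), c("L","I"), "A", c("E","D"), c("K","R"), c("T","S"),
    c("L","V"), c("A","G"), c("E","Q"), c("N","S"),
    substr(dipeptide, 1, 1), substr(dipeptide, 2, 2),
    c("L","V"), c("Q","E"), c("K","R"), c("A","S"), c("L","I"), c("T","S"),
    c("K","R")
  )
  names(pools) <- as.character(-19:-1)
  pools
}

# base residues for the NTPP signature window [-56, -38]
.window_base <- function() {
  w <- c("T","I","P","K","D","E","L","A","S","N","T","K","L","Q","E","S",
         "V","A","G")
  names(w) <- as.character(-56:-38)
  w
}

.ntpp_tail_specs <- function(hybrid_occupied) {
  pools <- list(
    c("E","D"), c("T","S"), c("V","I"), c("K","R"), c("A","S")   # -37..-33
  )
  names(pools) <- as.character(-37:-33)
  if (hybrid_occupied) {
    pools[["-32"]] <- "E"
    pools[["-31"]] <- "T"
  }
  tail2 <- list(
    c("L","V"), c("P","A"), c("S","T"), c("E","D"), c("K","R"), c("V","I"),
    "A", c("Q","E"), c("N","S"), c("T","S"), c("L","V")           # -30..-20
  )
  names(tail2) <- as.character(-30:-20)
  c(pools, tail2)
}

# NTPP specs for a Moebius template: deletion windows [-56,-54] and
# [-50,-38] are fully gapped; the species signature is the fixed residue
# triple at [-53,-51].
.ntpp_moebius <- function(triple, hybrid_occupied) {
  specs <- list("-57" = c("S","T"))
  tri <- strsplit(triple, "", fixed = TRUE)[[1]]
  specs[["-53"]] <- tri[1]; specs[["-52"]] <- tri[2]; specs[["-51"]] <- tri[3]
  c(specs, .ntpp_tail_specs(hybrid_occupied))
}

# NTPP specs for a cyclic bracelet: insertion region occupied except at the
# species' minor-gap positions; `mutations` are the species-specific fixed
# residue variations of the insertion region (real molecular species vary
# in residue content there, not only in gap placement, and these
# variations are what identifies a precursor's species during anchoring).
.ntpp_bracelet_cyclic <- function(gap_positions, mutations = character(0)) {
  specs <- list("-57" = c("S","T"))
  w <- .window_base()
  w[names(mutations)] <- mutations
  keep <- setdiff(as.integer(names(w)), gap_positions)
  for (p in keep) specs[[as.character(p)]] <- unname(w[as.character(p)])
  c(specs, .ntpp_tail_specs(TRUE))
}

# deterministic species-specific window variation: the g-th cyclic
# bracelet species gets a unique residue 5-tuple at five positions that no
# minor-gap pattern ever deletes
.bracelet_window_mutation <- function(g) {
  pools <- list(
    "-55" = c("I","V","L","M","F"),
    "-53" = c("K","R","Q","E","N"),
    "-50" = c("L","I","V","F","M"),
    "-48" = c("S","T","A","N","G"),
    "-41" = c("S","T","A","N","Q"))
  # evaluate the degree-2 polynomial a + b k + c k^2 over GF(5): any two
  # species codes differ at >= 3 of the 5 positions, so the nearest
  # curated row is identified with a comfortable alignment-score margin
  a <- g %% 5L; b <- (g %/% 5L) %% 5L; cc <- (g %/% 25L) %% 5L
  k <- 0:4
  digit <- (a + b * k + cc * k^2) %% 5L
  out <- character(0)
  for (i in seq_along(pools)) out[names(pools)[i]] <- pools[[i]][digit[i] + 1L]
  out
}

# NTPP specs for a linear bracelet: deletion at [-50] and [-47,-40], flanking
# insertions fixed at [-49,-48] and [-39]; the 6-residue tag at [-56,-51]
# plus the marks distinguish species within a series.
.ntpp_bracelet_linear <- function(tag6, marks) {
  specs <- list("-57" = c("S","T"))
  tag <- strsplit(tag6, "", fixed = TRUE)[[1]]
  for (i in seq_len(6)) specs[[as.character(-57L + i)]] <- tag[i]
  mk <- strsplit(marks, "", fixed = TRUE)[[1]]  # residues for -49,-48,-39,-38
  specs[["-49"]] <- mk[1]; specs[["-48"]] <- mk[2]
  specs[["-39"]] <- mk[3]; specs[["-38"]] <- mk[4]
  c(specs, .ntpp_tail_specs(TRUE))
}

# -- cyclotide-domain templates ----------------------------------------------

# kalata-like Moebius domain, loops (3,4,4,1,4), loop6 of 4+3 with terminal N
.cd_moebius <- function(linear = FALSE) {
  specs <- list(
    "G", "L", "P", c("V","I","A","T"),              # loop6b
    "C", "G", c("E","D","Q"), "T",                  # Cys I, loop 1
    "C", c("V","I","L"), "G", "G", c("T","S","A"),  # Cys II, loop 2
    "C", "N", c("T","S"), "P", "G",                 # Cys III, loop 3
    "C", c("T","S","N"),                            # Cys IV, loop 4
    "C", c("S","T"), "W", "P", c("V","I"),          # Cys V, loop 5
    "C"                                             # Cys VI
  )
  tail <- if (linear) list(c("T","S"), "R", c("G","S"))
          else list(c("T","S","A"), "R", "N")
  list(specs = c(specs, tail),
       loops = c(loop6b = 4L, loop1 = 3L, loop2 = 4L, loop3 = 4L,
                 loop4 = 1L, loop5 = 4L, loop6a = 3L),
       nd = !linear)
}

# cycloviolacin-like bracelet domain, loops (3,4,6,1,3), loop6 of 4+3
.cd_bracelet <- function(linear = FALSE) {
  specs <- list(
    "G", c("I","V"), "P", c("A","V","T"),                      # loop6b
    "C", "G", c("E","D"), "S",                                 # Cys I, loop 1
    "C", c("V","I"), "W", c("I","L"), "P",                     # Cys II, loop 2
    "C", c("I","V"), "S", "S", c("A","G"), c("I","L"), "G",    # Cys III, loop 3
    "C", c("S","T"),                                           # Cys IV, loop 4
    "C", "K", c("S","T"), "K",                                 # Cys V, loop 5
    "C"                                                        # Cys VI
  )
  tail <- if (linear) list(c("S","T"), "K", c("G","S"))
          else list(c("Y","F"), "R", "N")
  list(specs = c(specs, tail),
       loops = c(loop6b = 4L, loop1 = 3L, loop2 = 4L, loop3 = 6L,
                 loop4 = 1L, loop5 = 3L, loop6a = 3L),
       nd = !linear)
}

.ctr_specs <- function() list("S", "L", c("A","S"), c("A","T","G"))

# minor-gap patterns used to distinguish cyclic bracelet species of the
# same series (all keep the insertion region >= 50% occupied)
.bracelet_gap_patterns <- function() {
  list(integer(0), -47L, -45L, -43L, c(-46L, -42L), c(-44L, -40L))
}

#' The shipped molecular-species template library
#'
#' Returns the 46 synthetic species templates: 14 Moebius species over 5
#' molecular series and 32 bracelet species over 8 series, mirroring the
#' published tally (the real consensus alignment is not redistributable, so
#' the templates are synthetic stand-ins that satisfy the same signature
#' system).  Each template fixes its signature residues and carries small
#' residue pools at variable positions.
#'
#' @return A named list of template objects (class `species_template`).
#' @export
cyclotide_templates <- function() {
  out <- list()
  # Prodomain positions are consensus-fixed (first letter of each pool):
  # the signature system reads the prodomain, so instances of a species
  # share its prodomain consensus exactly, while sequence variation is
  # sampled in the cyclotide-domain loops (where mature-mass diversity
  # lives).
  fix1 <- function(specs) lapply(specs, function(p) p[1])
  add <- function(species, series, lineage, subfamily, topology, ntpp, cd,
                  repeat_choices) {
    dip <- paste0(substr(series, 1, 1), substr(series, 2, 2))
    tpl <- list(
      species = species, series = series, lineage = lineage,
      subfamily = subfamily, topology = topology,
      er = fix1(.er_specs()), ntpp = fix1(ntpp),
      ntr = fix1(.ntr_specs(dip)),
      cd = cd, ctr = if (topology == "cyclic") .ctr_specs() else list(),
      repeat_choices = repeat_choices
    )
    class(tpl) <- "species_template"
    out[[species]] <<- tpl
  }

  # --- Moebius lineage: 5 series, 14 species -------------------------------
  moebius <- list(
    # species, triple at [-53,-51], subfamily
    c("YS1", "KDS", "hybrid"),            c("YS2", "RET", "hybrid"),
    c("YS3", "KNA", "archetypal_moebius"), c("YS4", "RQS", "archetypal_moebius"),
    c("YY1", "KDT", "linear_moebius"),     c("YY2", "RES", "linear_moebius"),
    c("YA1", "KES", "hybrid"),             c("YA2", "RNT", "archetypal_moebius"),
    c("HF1", "KQS", "hybrid"),             c("HF2", "RDT", "archetypal_moebius"),
    c("FA1", "KDA", "hybrid"),             c("FA2", "RET", "archetypal_moebius"),
    c("FA3", "KNS", "archetypal_moebius"), c("FA4", "RQT", "hybrid")
  )
  for (m in moebius) {
    series <- substr(m[1], 1, 2)
    linear <- m[3] == "linear_moebius"
    hybrid_occ <- m[3] %in% c("hybrid", "linear_moebius")
    add(m[1], series, "moebius", m[3],
        if (linear) "linear" else "cyclic",
        .ntpp_moebius(m[2], hybrid_occ),
        .cd_moebius(linear = linear),
        repeat_choices = if (linear) 1L else 1:3)
  }

  # --- bracelet lineage: 8 series, 32 species ------------------------------
  gaps <- .bracelet_gap_patterns()
  cyc <- list(HS = 6L, NS = 5L, NL = 3L, GA = 3L, GP = 2L, RS = 6L)
  g <- 0L
  for (series in names(cyc)) {
    for (i in seq_len(cyc[[series]])) {
      g <- g + 1L
      add(paste0(series, i), series, "bracelet", "cyclic_bracelet", "cyclic",
          .ntpp_bracelet_cyclic(gaps[[i]], .bracelet_window_mutation(g)),
          .cd_bracelet(), 1L)
    }
  }
  lin <- list(
    PN = list(c("AESLVK", "PNDS"), c("TQAIEN", "ANDT"), c("SKDVLT", "LNES"),
              c("ENSAKL", "PAET")),
    QD = list(c("ELTNKA", "PNDS"), c("QANEIT", "AAET"), c("DLSKTV", "LNDA"))
  )
  for (series in names(lin)) {
    for (i in seq_along(lin[[series]])) {
      spec <- lin[[series]][[i]]
      add(paste0(series, i), series, "bracelet", "linear_bracelet", "linear",
          .ntpp_bracelet_linear(spec[1], spec[2]),
          .cd_bracelet(linear = TRUE), 1L)
    }
  }
  out
}

#' @export
print.species_template <- function(x, ...) {
  cat("Species template", x$species, "-", x$lineage, "/", x$subfamily,
      "(series", paste0(x$series, ","), x$topology, "domain)\n")
  invisible(x)
}
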