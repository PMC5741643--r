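# Prodomain sequence-signature classification: lineage, structural
# subfamily, molecular series and molecular species, plus tripartite names.

#' Default classification thresholds
#'
#' The deletion windows must be at least `gap_fraction` gapped for a
#' Moebius call; the insertion region must be at least `occ_fraction`
#' occupied for a bracelet call; two same-series precursors with identical
#' occupancy patterns belong to the same molecular species when their
#' NTPP-window residue identity reaches `species_identity`.
#'
#' @return Named list of thresholds.
#' @export
classify_config <- function() {
  list(gap_fraction = 0.8, occ_fraction = 0.5, species_identity = 0.8)
}

#' Extract the prodomain sequence signature
#'
#' Reads occupancy and residues at the signature windows directly from the
#' anchored consensus assignment.  Positions outside the candidate's
#' covered consensus range are reported as `"?"` (unknown), never guessed.
#'
#' @param anchored An `anchored_precursor`.
#' @return List of class `signature_profile` with `ntpp_occupancy`
#'   (named "1"/"0"/"?" vector over the indel window), `window_residues`
#'   (residues at occupied window positions), `linear_bracelet_marks`,
#'   `hybrid_mark`, `ntr_dipeptide` and `partial`.
#' @export
extract_signature <- function(anchored) {
  stopifnot(inherits(anchored, "anchored_precursor"))
  lay <- anchored$layout
  aa <- strsplit(anchored$protein, "", fixed = TRUE)[[1]]
  cons <- anchored$cons_pos
  known <- cons[!is.na(cons)]
  lo <- if (length(known) > 0L) min(known) else 1L
  hi <- if (length(known) > 0L) max(known) else 0L
  state_at <- function(p) {
    if (p < lo || p > hi) return("?")
    if (p %in% known) "1" else "0"
  }
  residue_at <- function(p) {
    i <- which(cons == p)
    if (length(i) == 1L) aa[i] else "?"
  }
  win <- lay$indel_window[1]:lay$indel_window[2]
  occ <- vapply(win, state_at, character(1))
  names(occ) <- as.character(win)
  wres <- vapply(win, residue_at, character(1))
  names(wres) <- as.character(win)
  marks <- vapply(lay$linear_marks, residue_at, character(1))
  names(marks) <- as.character(lay$linear_marks)
  hyb <- vapply(lay$hybrid_ins[1]:lay$hybrid_ins[2], state_at, character(1))
  names(hyb) <- as.character(lay$hybrid_ins[1]:lay$hybrid_ins[2])
  dip <- paste0(residue_at(lay$ntr_sig[1]), residue_at(lay$ntr_sig[2]))
  out <- list(ntpp_occupancy = occ, window_residues = wres,
              linear_bracelet_marks = marks, hybrid_mark = hyb,
              ntr_dipeptide = dip,
              partial = "partial" %in% anchored$flags)
  class(out) <- "signature_profile"
  out
}

.frac <- function(occ, positions, value) {
  s <- occ[as.character(positions)]
  s <- s[s != "?"]
  if (length(s) == 0L) return(NA_real_)
  mean(s == value)
}

#' Assign the lineage from a prodomain signature
#'
#' Moebius when both NTPP deletion windows are predominantly gapped;
#' bracelet when the insertion region is predominantly occupied, or when
#' the linear-bracelet deletion-flanked-by-insertions signature is present
#' (those precursors occupy too little of the insertion region to pass the
#' occupancy rule, but their marks identify the lineage unambiguously).
#'
#' @param sig A `signature_profile`.
#' @param config Thresholds from [classify_config()].
#' @return List with `lineage` (`"moebius"`, `"bracelet"` or
#'   `"unclassified"`) and `rationale` (character vector of fired rules).
#' @export
assign_lineage <- function(sig, config = classify_config()) {
  lay <- .consensus_layout()
  occ <- sig$ntpp_occupancy
  g1 <- .frac(occ, lay$moebius_del1[1]:lay$moebius_del1[2], "0")
  g2 <- .frac(occ, lay$moebius_del2[1]:lay$moebius_del2[2], "0")
  o2 <- .frac(occ, lay$moebius_del2[1]:lay$moebius_del2[2], "1")
  if (all(occ == "?"))
    return(list(lineage = "unclassified", rationale = "partial"))
  if (!is.na(g1) && !is.na(g2) && g1 >= config$gap_fraction &&
      g2 >= config$gap_fraction)
    return(list(lineage = "moebius",
                rationale = "NTPP deletion windows gapped"))
  if (!is.na(o2) && o2 >= config$occ_fraction)
    return(list(lineage = "bracelet",
                rationale = "NTPP insertion region occupied"))
  if (.has_linear_bracelet_marks(sig))
    return(list(lineage = "bracelet",
                rationale = "linear-bracelet deletion signature"))
  list(lineage = "unclassified", rationale = "no lineage signature")
}

.has_linear_bracelet_marks <- function(sig) {
  p <- .sig_pools()
  m <- sig$linear_bracelet_marks
  m[["-49"]] %in% p$linear_mark_49 && m[["-48"]] %in% p$linear_mark_48 &&
    m[["-39"]] %in% p$linear_mark_39 &&
    isTRUE(.frac(sig$ntpp_occupancy, -47:-40, "0") > 0.5)
}

#' Assign the structural subfamily within a lineage
#'
#' Moebius: the NTR dipeptide YY marks linear precursors; dipeptides from
#' the cyclic pool are hybrid when the [-32,-31] insertion is occupied and
#' archetypal Moebius when it is deleted.  Bracelet: a linear-pool
#' dipeptide together with the NTPP marks gives linear bracelet, a
#' cyclic-pool dipeptide gives cyclic bracelet.  Abnormality flags are
#' copied from the loop decomposition.
#'
#' @param lineage Lineage string from [assign_lineage()].
#' @param sig A `signature_profile`.
#' @param loops Optional loop decomposition from [decompose_loops()].
#' @return List with `subfamily`, `flags` and `rationale`.
#' @export
assign_subfamily <- function(lineage, sig, loops = NULL) {
  p <- .sig_pools()
  d1 <- substr(sig$ntr_dipeptide, 1, 1)
  d2 <- substr(sig$ntr_dipeptide, 2, 2)
  subfam <- "unassigned"
  why <- "dipeptide unmatched"
  if (lineage == "moebius") {
    if (d1 == "Y" && d2 == "Y") {
      subfam <- "linear_moebius"; why <- "Y-9 Y-8"
    } else if (d1 %in% p$moebius_cyclic_9 && d2 %in% p$moebius_cyclic_8) {
      if (any(sig$hybrid_mark == "1")) {
        subfam <- "hybrid"; why <- "cyclic dipeptide, [-32,-31] insertion"
      } else {
        subfam <- "archetypal_moebius"
        why <- "cyclic dipeptide, [-32,-31] deletion"
      }
    }
  } else if (lineage == "bracelet") {
    if (d1 %in% p$bracelet_linear_9 && d2 %in% p$bracelet_linear_8 &&
        .has_linear_bracelet_marks(sig)) {
      subfam <- "linear_bracelet"; why <- "linear dipeptide and NTPP marks"
    } else if (d1 %in% p$bracelet_cyclic_9 && d2 %in% p$bracelet_cyclic_8) {
      subfam <- "cyclic_bracelet"; why <- "cyclic dipeptide"
    }
  }
  flags <- character(0)
  if (!is.null(loops)) {
    flags <- loops$flags
    linear_sub <- subfam %in% c("linear_moebius", "linear_bracelet")
    if (linear_sub) flags <- setdiff(flags, "missing_ND")
    if (linear_sub && !is.null(loops$nd_site))
      flags <- c(flags, "unexpected_nd")
  }
  if (sig$partial) flags <- c(flags, "partial")
  list(subfamily = subfam, flags = unique(flags), rationale = why)
}

#' Group classified precursors into molecular series and species
#'
#' The molecular series is keyed by the NTR dipeptide.  Within a series,
#' molecular species are the connected components of the relation "same
#' NTPP occupancy pattern over the indel window and window-residue
#' identity at least the species threshold".  Species are numbered in
#' first-seen input order within each series.  Precursors whose NTPP
#' signature is partially unknown receive a series but no species.
#'
#' @param profiles List of `signature_profile` objects.
#' @param config Thresholds from [classify_config()].
#' @return Data frame with `series_key` and `species_key` (NA when only
#'   the series can be assigned), one row per input profile.
#' @export
group_species_series <- function(profiles, config = classify_config()) {
  n <- length(profiles)
  series <- vapply(profiles, function(s) s$ntr_dipeptide, character(1))
  series[grepl("?", series, fixed = TRUE)] <- NA_character_
  species <- rep(NA_character_, n)
  for (sk in unique(series[!is.na(series)])) {
    idx <- which(series == sk)
    eligible <- idx[vapply(idx, function(i)
      !any(profiles[[i]]$ntpp_occupancy == "?"), logical(1))]
    if (length(eligible) == 0L) next
    parent <- stats::setNames(eligible, eligible)
    find <- function(x) {
      while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]
      x
    }
    for (a_i in seq_along(eligible)) {
      for (b_i in seq_len(a_i - 1L)) {
        a <- eligible[a_i]; b <- eligible[b_i]
        if (.same_species(profiles[[a]], profiles[[b]],
                          config$species_identity)) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[[as.character(max(ra, rb))]] <- min(ra, rb)
        }
      }
    }
    roots <- vapply(eligible, find, numeric(1))
    first_seen <- unique(roots)
    num <- match(roots, first_seen)
    species[eligible] <- paste0(sk, num)
  }
  data.frame(series_key = series, species_key = species,
             stringsAsFactors = FALSE)
}

.same_species <- function(a, b, threshold) {
  if (!identical(a$ntpp_occupancy, b$ntpp_occupancy)) return(FALSE)
  occ <- names(a$ntpp_occupancy)[a$ntpp_occupancy == "1"]
  if (length(occ) == 0L) return(TRUE)
  mean(a$window_residues[occ] == b$window_residues[occ]) >= threshold
}

#' Classify a set of anchored precursors
#'
#' Convenience wrapper running signature extraction, lineage, subfamily
#' and series/species assignment over a list of anchored precursors.
#'
#' @param anchored_list List of `anchored_precursor` objects.
#' @param ids Character vector of precursor ids.
#' @param config Thresholds from [classify_config()].
#' @return Data frame of class `cyclotide_classification` with one row per
#'   precursor: id, lineage, subfamily, series, species, flags, rationale.
#' @export
classify_precursors <- function(anchored_list,
                                ids = paste0("prec", seq_along(anchored_list)),
                                config = classify_config()) {
  profiles <- lapply(anchored_list, extract_signature)
  lin <- lapply(profiles, assign_lineage, config = config)
  sub <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    loops <- if (length(anchored_list[[i]]$cd_units) > 0L)
      decompose_loops(anchored_list[[i]], 1L) else NULL
    sub[[i]] <- assign_subfamily(lin[[i]]$lineage, profiles[[i]], loops)
  }
  grp <- group_species_series(profiles, config)
  classified <- lin_ok <- vapply(lin, function(l)
    l$lineage != "unclassified", logical(1))
  grp$series_key[!lin_ok] <- NA_character_
  grp$species_key[!lin_ok] <- NA_character_
  out <- data.frame(
    id = ids,
    lineage = vapply(lin, `[[`, character(1), "lineage"),
    subfamily = vapply(sub, `[[`, character(1), "subfamily"),
    series = grp$series_key,
    species = grp$species_key,
    flags = vapply(sub, function(s) paste(s$flags, collapse = ";"),
                   character(1)),
    rationale = vapply(seq_along(lin), function(i)
      paste(c(lin[[i]]$rationale, sub[[i]]$rationale), collapse = "; "),
      character(1)),
    stringsAsFactors = FALSE)
  attr(out, "profiles") <- profiles
  class(out) <- c("cyclotide_classification", "data.frame")
  out
}

#' Organism five-letter code table
#'
#' Codes for the violet species studied at the transcriptome level, plus a
#' deterministic fallback (lowercase genus initial followed by the first
#' four letters of the species epithet) for organisms not in the table.
#'
#' @return Named character vector (names are Latin binomials).
#' @export
organism_codes <- function() {
  c("Viola albida var. takahashii" = "valta",
    "Viola mandshurica" = "viman",
    "Viola orientalis" = "vorie",
    "Viola verecunda" = "viver",
    "Viola acuminata" = "vacum")
}

.organism_code <- function(organism, table = organism_codes()) {
  if (organism %in% names(table)) return(unname(table[organism]))
  parts <- strsplit(organism, "\\s+")[[1]]
  if (length(parts) < 2L) stop("cannot derive organism code from '",
                               organism, "'")
  code <- tolower(paste0(substr(parts[1], 1, 1), substr(parts[2], 1, 4)))
  if (code %in% table)
    stop("fallback organism code '", code, "' collides with table entry ",
         names(table)[table == code])
  code
}

#' Assign tripartite names to classified cyclotides or precursors
#'
#' A cyclotide name is organism code + rank + "-" + molecular species
#' (e.g. vacum2-HS4 is the second HS4 cyclotide of Viola acuminata); ranks
#' count per (organism, species) in input order.  Previously published
#' names are reused verbatim from `existing_names`; previously unnamed
#' precursors carry the "prc-" prefix.
#'
#' @param classified A `cyclotide_classification` data frame (needs
#'   columns `id` and `species`).
#' @param organism Latin binomial, recycled over rows, or a vector.
#' @param entity `"cyclotide"` or `"precursor"`.
#' @param existing_names Optional named character vector id -> published
#'   name.
#' @return Data frame with `id`, `organism_code`, `rank`, `entity`,
#'   `full_name`.
#' @export
assign_names <- function(classified, organism,
                         entity = c("cyclotide", "precursor"),
                         existing_names = NULL) {
  entity <- match.arg(entity)
  n <- nrow(classified)
  organism <- rep_len(organism, n)
  codes <- vapply(organism, .organism_code, character(1))
  counter <- new.env(parent = emptyenv())
  rank <- integer(n)
  full <- character(n)
  for (i in seq_len(n)) {
    id <- classified$id[i]
    if (!is.null(existing_names) && id %in% names(existing_names)) {
      nm <- existing_names[[id]]
      full[i] <- if (entity == "precursor" && !startsWith(nm, "prc-"))
        paste0("prc-", nm) else nm
      rank[i] <- NA_integer_
      next
    }
    sp <- classified$species[i]
    if (is.na(sp)) {
      full[i] <- NA_character_
      rank[i] <- NA_integer_
      next
    }
    key <- paste(codes[i], sp, sep = "|")
    rank[i] <- (if (is.null(counter[[key]])) 0L else counter[[key]]) + 1L
    counter[[key]] <- rank[i]
    base <- paste0(codes[i], rank[i], "-", sp)
    full[i] <- if (entity == "precursor") paste0("prc-", base) else base
  }
  data.frame(id = classified$id, organism_code = codes, rank = rank,
             entity = entity, full_name = full, stringsAsFactors = FALSE,
             row.names = NULL)
}
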