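# Integrating transcript-level abundance (FPKM) with peptide-level
# detection, and summarising molecular-species sharing across taxa.

#' FPKM expression tier
#'
#' @param fpkm Non-negative FPKM value(s).
#' @param cutoff Tier cutoff; a transcript is `"above"` only when its FPKM
#'   strictly exceeds the cutoff.
#' @return Character vector of `"above"`/`"below"`.
#' @export
fpkm_tier <- function(fpkm, cutoff = 150) {
  if (any(fpkm < 0)) stop("negative FPKM value")
  ifelse(fpkm > cutoff, "above", "below")
}

#' Cross-level expression table
#'
#' Joins the classification with FPKM tiers and peptide-level detections.
#' A precursor counts as peptide-detected only through a best
#' (minimal-|delta|) match, so many-to-many mass coincidences do not
#' inflate concordance.  Precursors without an FPKM record get tier
#' `"unknown"` and a flag; unmatched FPKM ids are listed, not silently
#' dropped.
#'
#' @param classification A `cyclotide_classification` data frame with an
#'   `id` column.
#' @param expression Data frame with `precursor_id` (or `transcript_id`)
#'   and `fpkm`.
#' @param matches Match table from [match_predicted()] (may be empty).
#' @param cutoff FPKM cutoff for [fpkm_tier()].
#' @return List with `table` (one row per classified precursor),
#'   `summary` (per-organism counts when an `organism` column is present)
#'   and `unmatched_expression_ids`.
#' @export
cross_level_table <- function(classification, expression, matches,
                              cutoff = 150) {
  idcol <- intersect(c("precursor_id", "transcript_id"), names(expression))
  if (length(idcol) == 0L)
    stop("expression table needs a precursor_id or transcript_id column")
  ex <- stats::setNames(expression$fpkm, expression[[idcol[1]]])
  detected_ids <- if (nrow(matches) > 0L)
    unique(matches$precursor_id[matches$best]) else character(0)
  fpkm <- unname(ex[classification$id])
  tier <- rep("unknown", length(fpkm))
  known <- !is.na(fpkm)
  tier[known] <- fpkm_tier(fpkm[known], cutoff)
  tab <- data.frame(
    id = classification$id,
    lineage = classification$lineage,
    subfamily = classification$subfamily,
    series = classification$series,
    species = classification$species,
    fpkm = fpkm, fpkm_tier = tier,
    peptide_detected = classification$id %in% detected_ids,
    flags = ifelse(is.na(fpkm), "no_fpkm", ""),
    stringsAsFactors = FALSE)
  if ("organism" %in% names(classification))
    tab$organism <- classification$organism
  summary <- NULL
  if ("organism" %in% names(tab)) {
    summary <- do.call(rbind, lapply(split(tab, tab$organism), function(d) {
      data.frame(organism = d$organism[1], n = nrow(d),
                 n_above = sum(d$fpkm_tier == "above"),
                 n_detected = sum(d$peptide_detected),
                 n_both = sum(d$fpkm_tier == "above" & d$peptide_detected),
                 frac_both = mean(d$fpkm_tier == "above" &
                                    d$peptide_detected),
                 stringsAsFactors = FALSE)
    }))
    rownames(summary) <- NULL
  }
  list(table = tab,
       summary = summary,
       unmatched_expression_ids = setdiff(names(ex), classification$id))
}

#' Molecular-species sharing across taxonomic sections
#'
#' For each molecular species, the set of sections it occurs in is
#' computed, then the proportions of species found in exactly k sections
#' (and at least k), both by species count and by precursor-sequence
#' count.
#'
#' @param assignments Data frame with `species` and `organism` columns
#'   (one row per precursor).
#' @param taxa Data frame with `organism` and `section`.
#' @return List with `per_species` (species, sections, n_sections,
#'   n_precursors) and `distribution` (k, n_species, pct_species,
#'   n_precursors, pct_precursors, pct_species_at_least,
#'   pct_precursors_at_least).
#' @export
section_sharing <- function(assignments, taxa) {
  stopifnot(nrow(taxa) >= 1L)
  sec <- stats::setNames(taxa$section, taxa$organism)
  a <- assignments[!is.na(assignments$species), , drop = FALSE]
  a$section <- unname(sec[a$organism])
  a$section[is.na(a$section)] <- "unknown"
  per <- do.call(rbind, lapply(split(a, a$species), function(d) {
    data.frame(species = d$species[1],
               sections = paste(sort(unique(d$section)), collapse = ";"),
               n_sections = length(unique(d$section)),
               n_precursors = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  ks <- seq_len(max(per$n_sections))
  dist <- do.call(rbind, lapply(ks, function(k) {
    at_k <- per$n_sections == k
    ge_k <- per$n_sections >= k
    data.frame(
      k = k,
      n_species = sum(at_k),
      pct_species = 100 * sum(at_k) / nrow(per),
      n_precursors = sum(per$n_precursors[at_k]),
      pct_precursors = 100 * sum(per$n_precursors[at_k]) /
        sum(per$n_precursors),
      pct_species_at_least = 100 * sum(ge_k) / nrow(per),
      pct_precursors_at_least = 100 * sum(per$n_precursors[ge_k]) /
        sum(per$n_precursors),
      stringsAsFactors = FALSE)
  }))
  list(per_species = per, distribution = dist)
}
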