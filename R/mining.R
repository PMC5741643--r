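# Mining cyclotide-precursor ORFs from transcripts: six-frame translation,
# cystine-knot motif scanning and local-alignment similarity to curated
# references.

#' Default inter-cysteine loop-length windows
#'
#' Inclusive (min, max) windows for the five internal loops of the
#' cystine-knot motif.  Loop 6 spans the domain boundary and is
#' unconstrained at scan time.
#'
#' @return Named list of length-2 integer vectors.
#' @export
default_loop_windows <- function() {
  list(loop1 = c(2L, 7L), loop2 = c(3L, 6L), loop3 = c(2L, 8L),
       loop4 = c(1L, 2L), loop5 = c(3L, 6L))
}

#' Six-frame ORF extraction
#'
#' Translates a nucleotide transcript in all six reading frames and
#' reports maximal stop-to-stop open reading frames (not ATG-anchored,
#' since assemblies may truncate 5' ends).  Codons containing N translate
#' to X.  Transcripts shorter than `min_transcript_len` yield nothing.
#'
#' @param transcript One row of a `seq_records` data frame (or a list with
#'   `id` and `residues`), nucleotide alphabet.
#' @param min_orf_len Minimum ORF length in residues.
#' @param min_transcript_len Minimum transcript length in nucleotides.
#' @return Data frame with columns `transcript_id`, `frame` (+1..+3,
#'   -1..-3), `nt_start`, `nt_end` (0-based half-open on the forward
#'   strand) and `protein`.
#' @export
six_frame_orfs <- function(transcript, min_orf_len = 40L,
                           min_transcript_len = 200L) {
  stopifnot(min_orf_len >= 1L)
  nt <- toupper(transcript$residues)
  id <- transcript$id
  L <- nchar(nt)
  empty <- data.frame(transcript_id = character(0), frame = integer(0),
                      nt_start = integer(0), nt_end = integer(0),
                      protein = character(0), stringsAsFactors = FALSE)
  if (L < min_transcript_len) return(empty)
  fwd <- Biostrings::DNAString(nt)
  rev <- Biostrings::reverseComplement(fwd)
  rows <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) fwd else rev
    for (off in 0:2) {
      n_cod <- (length(s) - off) %/% 3L
      if (n_cod < 1L) next
      sub <- Biostrings::subseq(s, start = off + 1L,
                                width = n_cod * 3L)
      aa <- as.character(Biostrings::translate(sub, if.fuzzy.codon = "X",
                                               no.init.codon = TRUE))
      # maximal stop-free stretches
      parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
      pos <- 0L
      for (p in parts) {
        w <- nchar(p)
        if (w >= min_orf_len) {
          # 0-based codon interval on the translated strand
          c0 <- pos
          c1 <- pos + w
          s0 <- off + 3L * c0
          s1 <- off + 3L * c1
          if (strand == 1L) {
            nt_start <- s0; nt_end <- s1
          } else {
            nt_start <- L - s1; nt_end <- L - s0
          }
          rows[[length(rows) + 1L]] <- data.frame(
            transcript_id = id,
            frame = strand * (off + 1L),
            nt_start = nt_start, nt_end = nt_end, protein = p,
            stringsAsFactors = FALSE)
        }
        pos <- pos + w + 1L
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Scan a protein for the six-cysteine cystine-knot motif
#'
#' Finds placements of six cysteines whose five internal gaps fall inside
#' the loop windows.  Overlapping alternatives are resolved by preferring
#' the placement with the smaller total span, then the leftmost; accepted
#' placements never overlap.
#'
#' @param protein Residue sequence (single string).
#' @param loop_windows Named list of five inclusive (min, max) windows, as
#'   from [default_loop_windows()].
#' @return List of motif hits, each a list with `cys_positions` (six
#'   0-based indices), `loop_lengths` (five gaps) and `span` (0-based
#'   half-open interval covering Cys I..VI).
#' @export
scan_cd_motif <- function(protein, loop_windows = default_loop_windows()) {
  stopifnot(length(loop_windows) == 5L)
  for (wd in loop_windows)
    if (wd[1] > wd[2]) stop("malformed loop window: min > max")
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  cpos <- which(aa == "C")  # 1-based
  placements <- .enumerate_placements(cpos, loop_windows)
  if (length(placements) == 0L) return(list())
  # greedy selection: smallest span first, then leftmost
  spans <- vapply(placements, function(p) p[6] - p[1], numeric(1))
  starts <- vapply(placements, `[`, numeric(1), 1L)
  ord <- order(spans, starts)
  accepted <- list()
  for (i in ord) {
    p <- placements[[i]]
    overlaps <- any(vapply(accepted, function(a)
      p[1] <= a[6] && a[1] <= p[6], logical(1)))
    if (!overlaps) accepted[[length(accepted) + 1L]] <- p
  }
  accepted <- accepted[order(vapply(accepted, `[`, numeric(1), 1L))]
  lapply(accepted, function(p) {
    list(cys_positions = as.integer(p) - 1L,
         loop_lengths = as.integer(diff(p) - 1L),
         span = c(p[1] - 1L, p[6]))
  })
}

# depth-first enumeration of all six-cysteine placements whose gaps fall in
# the windows
.enumerate_placements <- function(cpos, windows) {
  out <- list()
  wins <- lapply(windows, as.integer)
  recurse <- function(chain) {
    k <- length(chain)
    if (k == 6L) {
      out[[length(out) + 1L]] <<- chain
      return()
    }
    w <- wins[[k]]
    lo <- chain[k] + w[1] + 1L
    hi <- chain[k] + w[2] + 1L
    for (nxt in cpos[cpos >= lo & cpos <= hi]) recurse(c(chain, nxt))
  }
  for (c1 in cpos) recurse(c1)
  out
}

#' Best local-alignment similarity to a reference set
#'
#' Smith-Waterman local alignment (via Biostrings) of a candidate protein
#' against each reference sequence; returns the best score and the
#' best-matching reference id (ties broken by lexicographic reference id).
#' A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param candidate_protein Residue sequence.
#' @param refs Named character vector of reference sequences (names are
#'   ids), or the `mature_refs` data frame of a `ref_bundle`.
#' @param matrix Substitution matrix name (default BLOSUM62).
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @return List with `score` and `best_ref`.
#' @export
similarity_score <- function(candidate_protein, refs, matrix = "BLOSUM62",
                             gap_open = 11, gap_extend = 1) {
  if (!nzchar(candidate_protein)) stop("empty candidate protein")
  if (is.data.frame(refs)) refs <- stats::setNames(refs$residues, refs$id)
  if (length(refs) == 0L) stop("empty reference set")
  mat <- .sub_matrix(matrix)
  ord <- order(names(refs))
  refs <- refs[ord]
  scores <- pmax(0, Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(refs), Biostrings::AAString(candidate_protein),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE))
  names(scores) <- names(refs)
  best <- which.max(scores)  # first max = lexicographically smallest id
  list(score = unname(scores[best]), best_ref = names(refs)[best])
}

.sub_matrix <- local({
  cache <- list()
  function(name) {
    if (is.null(cache[[name]])) {
      e <- new.env()
      utils::data(list = name, package = "Biostrings", envir = e)
      cache[[name]] <<- get(name, envir = e)
    }
    cache[[name]]
  }
})

#' Default mining configuration
#'
#' `min_similarity` is calibrated as the smallest integer score exceeding
#' the maximum Smith-Waterman score observed for 10,000 shuffled decoy
#' proteins against the bundled mature references (zero false positives on
#' the calibration set).
#'
#' @return Named list of mining parameters.
#' @export
mining_config <- function() {
  list(min_orf_len = 40L, min_transcript_len = 200L,
       loop_windows = default_loop_windows(),
       matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
       min_similarity = 77, min_prodomain_similarity = 150)
}

#' Mine cyclotide precursor candidates from transcripts
#'
#' Pipeline: six-frame ORF extraction, cystine-knot motif scan, then
#' local-alignment similarity against the bundle's mature references (and,
#' as a rescue for divergent domains, against the curated precursor
#' prodomains).  A candidate passes if it has at least one motif hit and
#' either similarity threshold is met.  Exact-duplicate proteins are
#' collapsed, keeping all transcript provenances.
#'
#' @param transcripts A `seq_records` data frame of nucleotide records.
#' @param bundle A `ref_bundle`.
#' @param params Mining configuration, as from [mining_config()].
#' @return A list of class `precursor_set`; each element has `protein`,
#'   `motif_hits`, `similarity`, `best_ref`, `prodomain_similarity`,
#'   `passed_filters` and `provenance` (data frame of transcript hits).
#' @export
mine_precursors <- function(transcripts, bundle, params = mining_config()) {
  stopifnot(all(transcripts$alphabet == "nucleotide"))
  prodomains <- .bundle_prodomains(bundle)
  by_protein <- list()
  for (i in seq_len(nrow(transcripts))) {
    orfs <- six_frame_orfs(transcripts[i, ], params$min_orf_len,
                           params$min_transcript_len)
    for (j in seq_len(nrow(orfs))) {
      protein <- orfs$protein[j]
      hits <- scan_cd_motif(protein, params$loop_windows)
      if (length(hits) == 0L) next
      key <- protein
      if (is.null(by_protein[[key]])) {
        sim <- similarity_score(protein, bundle$mature_refs,
                                params$matrix, params$gap_open,
                                params$gap_extend)
        psim <- similarity_score(protein, prodomains, params$matrix,
                                 params$gap_open, params$gap_extend)
        passed <- c("motif",
                    if (sim$score >= params$min_similarity) "similarity",
                    if (psim$score >= params$min_prodomain_similarity)
                      "prodomain_similarity")
        if (length(passed) < 2L) next  # motif alone is not enough
        by_protein[[key]] <- list(
          protein = protein, motif_hits = hits,
          similarity = sim$score, best_ref = sim$best_ref,
          prodomain_similarity = psim$score,
          passed_filters = passed,
          provenance = orfs[j, c("transcript_id", "frame", "nt_start",
                                 "nt_end")])
      } else {
        by_protein[[key]]$provenance <- rbind(
          by_protein[[key]]$provenance,
          orfs[j, c("transcript_id", "frame", "nt_start", "nt_end")])
      }
    }
  }
  out <- unname(by_protein)
  class(out) <- "precursor_set"
  out
}

.bundle_prodomains <- function(bundle) {
  pro_cols <- which(bundle$column_map < 0L)
  rows <- vapply(bundle$alignment, function(r) {
    gsub("-", "", paste(strsplit(r, "", fixed = TRUE)[[1]][pro_cols],
                        collapse = ""), fixed = TRUE)
  }, character(1))
  rows[nzchar(rows)]
}

#' @export
`[.precursor_set` <- function(x, i) {
  out <- unclass(x)[i]
  class(out) <- "precursor_set"
  out
}

#' @export
print.precursor_set <- function(x, ...) {
  cat("Precursor candidate set:", length(x), "candidates\n")
  invisible(x)
}

#' @export
as.data.frame.precursor_set <- function(x, ...) {
  if (length(x) == 0L)
    return(data.frame(protein = character(0), n_motif_hits = integer(0),
                      similarity = numeric(0), best_ref = character(0),
                      transcripts = character(0)))
  data.frame(
    protein = vapply(x, `[[`, character(1), "protein"),
    n_motif_hits = vapply(x, function(p) length(p$motif_hits), integer(1)),
    similarity = vapply(x, `[[`, numeric(1), "similarity"),
    best_ref = vapply(x, `[[`, character(1), "best_ref"),
    transcripts = vapply(x, function(p)
      paste(unique(p$provenance$transcript_id), collapse = ";"),
      character(1)),
    stringsAsFactors = FALSE)
}
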