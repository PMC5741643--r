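#' Read a FASTA file into a set of sequence records
#'
#' Records are returned as a data frame with one row per entry, in file
#' order.  Residues are normalised to upper case and validated against the
#' declared alphabet: nucleotide records may contain only ACGTN, protein
#' records only the 20 amino-acid letters plus X.  Gap characters are never
#' legal in a sequence record.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"`, `"protein"` or `"auto"`.  Auto mode calls
#'   a record nucleotide when at least 90% of its residues are ACGTN.
#' @return A data frame of class `seq_records` with columns `id`,
#'   `description`, `alphabet`, `residues`.
#' @export
read_fasta <- function(path, alphabet = c("auto", "nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence id in ", path, ": ",
         ids[duplicated(ids)][1L])
  residues <- toupper(as.character(set))
  ab <- vapply(seq_along(ids), function(i) {
    infer_alphabet(residues[i], alphabet, ids[i])
  }, character(1))
  out <- data.frame(id = ids, description = desc, alphabet = ab,
                    residues = unname(residues), stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

infer_alphabet <- function(res, alphabet, id) {
  if (nchar(res) == 0L) stop("empty sequence for record '", id, "'")
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  nt_ok <- chars %in% c("A", "C", "G", "T", "N")
  aa_ok <- chars %in% c(.AA20, "X")
  if (alphabet == "auto")
    alphabet <- if (mean(nt_ok) >= 0.9) "nucleotide" else "protein"
  ok <- if (alphabet == "nucleotide") nt_ok else aa_ok
  if (!all(ok)) {
    pos <- which(!ok)[1L]
    stop("illegal ", alphabet, " residue '", chars[pos], "' in record '",
         id, "' at position ", pos)
  }
  alphabet
}

#' Write sequence records to FASTA
#'
#' @param records A `seq_records` data frame (or any data frame with `id`,
#'   `residues` and optionally `description` columns).
#' @param path Output file path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[i]
    d <- if ("description" %in% names(records)) records$description[i] else ""
    if (nzchar(d)) hdr <- paste(hdr, d)
    writeLines(paste0(">", hdr), con)
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a centroided LC-MS peak table
#'
#' Accepts comma- or tab-delimited text (auto-detected from the header
#' line) with columns for retention time in minutes, m/z and intensity.
#' Rows with non-positive intensity are dropped (their count is reported via
#' a message); the result is sorted by (rt, mz) so that row order in the
#' input file is irrelevant.
#'
#' @param path Path to the delimited file.
#' @param columns Named character vector mapping the required fields
#'   (`rt`, `mz`, `intensity`) to header names in the file.
#' @return A data frame of class `peak_table` with columns `rt`, `mz`,
#'   `intensity`.
#' @export
read_peak_table <- function(path,
                            columns = c(rt = "rt_min", mz = "mz",
                                        intensity = "intensity")) {
  if (!file.exists(path)) stop("peak table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- columns[c("rt", "mz", "intensity")]
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L)
    stop("peak table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  num <- lapply(need, function(cn) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    bad <- which(is.na(v) & !is.na(tab[[cn]]) & nzchar(tab[[cn]]))
    if (length(bad) > 0L)
      stop("non-numeric value in column '", cn, "' at line ",
           bad[1L] + 1L, " of ", path)
    v
  })
  out <- data.frame(rt = num[[1]], mz = num[[2]], intensity = num[[3]])
  if (anyNA(out)) stop("missing value in peak table ", path)
  if (any(out$rt < 0)) stop("negative retention time in ", path)
  if (any(out$mz <= 0)) stop("non-positive m/z in ", path)
  n_drop <- sum(out$intensity <= 0)
  if (n_drop > 0L) {
    message("read_peak_table: dropped ", n_drop,
            " row(s) with non-positive intensity")
    out <- out[out$intensity > 0, , drop = FALSE]
  }
  out <- out[order(out$rt, out$mz), , drop = FALSE]
  if (anyDuplicated(out[, c("rt", "mz")]))
    out <- out[!duplicated(out[, c("rt", "mz")]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Load a reference bundle
#'
#' A reference bundle directory holds three plain-text files:
#' `anchored_alignment.fasta` (gapped protein sequences of curated
#' precursors sharing one column space), `column_map.tsv` (alignment column
#' to consensus-position map) and `mature_refs.tsv` (known mature cyclotide
#' sequences with structural labels).  All bundle invariants are verified at
#' load time; a violation is an error, never silently repaired.
#'
#' @param path Directory containing the three bundle files.
#' @return A list of class `ref_bundle` with elements `alignment` (named
#'   character vector of gapped rows), `column_map` (integer vector, one
#'   consensus position per alignment column), `mature_refs` (data frame
#'   with `id`, `label`, `residues`), and `layout` (the consensus layout).
#' @export
load_reference_bundle <- function(path) {
  f_aln <- file.path(path, "anchored_alignment.fasta")
  f_map <- file.path(path, "column_map.tsv")
  f_mat <- file.path(path, "mature_refs.tsv")
  for (f in c(f_aln, f_map, f_mat))
    if (!file.exists(f)) stop("reference bundle file missing: ", f)

  set <- Biostrings::readBStringSet(f_aln)
  aln <- toupper(as.character(set))
  names(aln) <- sub("\\s.*$", "", names(set))
  if (any(grepl(".", aln, fixed = TRUE)))
    stop("reference alignment uses '.' gaps; only '-' is accepted")
  widths <- nchar(aln)
  if (length(unique(widths)) != 1L)
    stop("reference alignment rows differ in width")

  map <- utils::read.table(f_map, header = TRUE, sep = "\t")
  if (!all(c("column", "consensus_position") %in% names(map)))
    stop("column map must have columns 'column' and 'consensus_position'")
  map <- map[order(map$column), , drop = FALSE]
  if (nrow(map) != widths[1L])
    stop("column map length (", nrow(map),
         ") does not match alignment width (", widths[1L], ")")
  cons <- as.integer(map$consensus_position)
  if (anyDuplicated(cons)) stop("column map is not injective")
  if (any(diff(cons) <= 0L)) stop("column map is not strictly increasing")
  if (sum(cons == 0L) != 1L)
    stop("column map must map exactly one column to consensus position 0")

  layout <- .consensus_layout()
  cys_cols <- match(layout$cys_cols, cons)
  if (anyNA(cys_cols)) stop("column map lacks a cysteine consensus column")
  rows <- strsplit(aln, "", fixed = TRUE)
  for (i in seq_along(rows)) {
    if (!all(rows[[i]][cys_cols] == "C"))
      stop("curated precursor '", names(aln)[i],
           "' lacks a cysteine on a conserved cysteine column")
    letters_only <- setdiff(unique(rows[[i]]), "-")
    bad <- setdiff(letters_only, c(.AA20, "X"))
    if (length(bad) > 0L)
      stop("illegal residue '", bad[1L], "' in curated precursor '",
           names(aln)[i], "'")
  }

  mat <- utils::read.table(f_mat, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("id", "label", "residues") %in% names(mat)))
    stop("mature_refs.tsv must have columns id, label, residues")
  ok_labels <- c("archetypal_moebius", "archetypal_bracelet", "hybrid",
                 "linear")
  if (!all(mat$label %in% ok_labels))
    stop("unknown mature reference label: ",
         setdiff(mat$label, ok_labels)[1L])
  mat$residues <- toupper(mat$residues)

  out <- list(alignment = aln, column_map = cons, mature_refs = mat,
              layout = layout)
  class(out) <- "ref_bundle"
  out
}

#' Load the reference bundle shipped with the package
#'
#' The shipped bundle is a synthetic curated set: one anchored
#' representative of each of the 46 molecular-species templates (see
#' [cyclotide_templates()]) plus the two published mature sequences of
#' kalata B1 and cycloviolacin O2.
#'
#' @return A `ref_bundle` object.
#' @export
default_bundle <- function() {
  path <- system.file("extdata", "refbundle", package = "cyclominer")
  if (!nzchar(path)) stop("shipped reference bundle not found")
  load_reference_bundle(path)
}

#' @export
print.ref_bundle <- function(x, ...) {
  cat("Reference bundle:", length(x$alignment), "anchored precursors,",
      length(x$column_map), "columns (consensus",
      min(x$column_map), "..", max(x$column_map), "),",
      nrow(x$mature_refs), "mature references\n")
  invisible(x)
}
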