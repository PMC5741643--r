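# End-to-end pipeline: mine -> anchor/segment -> classify -> masses ->
# match -> expression summaries, with a manifest and plain-text report.

#' Assemble the full pipeline configuration
#'
#' Collects the per-stage defaults (mining thresholds and loop windows,
#' anchoring penalties, classification thresholds, matching parameters,
#' the FPKM cutoff and the seed) into one validated list.  Unknown keys
#' are an error, so a typo in an override cannot silently fall back to a
#' default.
#'
#' @param ... Named overrides of top-level keys (lists are merged one
#'   level deep).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    mining = mining_config(),
    anchoring = list(gap_open = 2, gap_extend = 2),
    classify = classify_config(),
    match = match_params(),
    fpkm_cutoff = 150,
    mature_offsets = -3:2,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0L)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (k in names(over)) {
    if (is.list(defaults[[k]]) && is.list(over[[k]])) {
      bad2 <- setdiff(names(over[[k]]), names(defaults[[k]]))
      if (length(bad2) > 0L)
        stop("unknown configuration key(s) under '", k, "': ",
             paste(bad2, collapse = ", "))
      defaults[[k]][names(over[[k]])] <- over[[k]]
    } else {
      defaults[[k]] <- over[[k]]
    }
  }
  class(defaults) <- c("pipeline_config", "list")
  defaults
}

#' Run the whole analysis pipeline
#'
#' Mines precursor candidates from the transcripts, anchors and segments
#' them, classifies them by prodomain signature, enumerates mature
#' candidates with masses, and - when a peak table is supplied -
#' deconvolutes and matches the observations and summarises cross-level
#' expression.  All stage outputs are written as TSV under `out_dir`
#' together with a JSON manifest (input checksums and configuration) and
#' a plain-text report.  Outputs are byte-reproducible for a fixed
#' configuration and inputs.
#'
#' @param transcripts A `seq_records` data frame, or path to a FASTA file.
#' @param bundle A `ref_bundle` (default: the shipped bundle).
#' @param peaks,alk_peaks Optional `peak_table`s (or file paths).
#' @param fpkm Optional data frame (`transcript_id`, `fpkm`) or TSV path.
#' @param taxa Optional data frame (`organism`, `section`).
#' @param organism Latin binomial used for naming, recycled.
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created); NULL skips file output.
#' @return List of class `cyclotide_run` with elements `candidates`,
#'   `anchored`, `classification`, `matures`, `observations`, `matches`,
#'   `expression`, `config`.
#' @export
run_pipeline <- function(transcripts, bundle = default_bundle(),
                         peaks = NULL, alk_peaks = NULL, fpkm = NULL,
                         taxa = NULL, organism = "Viola acuminata",
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(transcripts))
    transcripts <- read_fasta(transcripts, "nucleotide")
  if (is.character(peaks)) peaks <- read_peak_table(peaks)
  if (is.character(alk_peaks)) alk_peaks <- read_peak_table(alk_peaks)
  if (is.character(fpkm))
    fpkm <- utils::read.table(fpkm, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)

  candidates <- mine_precursors(transcripts, bundle, config$mining)
  anchored <- list()
  ok <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    a <- tryCatch(
      anchor_to_profile(candidates[[i]], bundle,
                        config$anchoring$gap_open,
                        config$anchoring$gap_extend),
      error = function(e) e)
    if (inherits(a, "error")) {
      message("run_pipeline: candidate ", i, " excluded (",
              conditionMessage(a), ")")
    } else {
      anchored[[length(anchored) + 1L]] <- a
      ok[i] <- TRUE
    }
  }
  candidates <- candidates[ok]
  ids <- vapply(candidates, function(p)
    p$provenance$transcript_id[1], character(1))
  # disambiguate duplicated provenance ids (several ORFs on one transcript)
  ids <- make.unique(ids, sep = ".orf")
  classification <- classify_precursors(anchored, ids, config$classify)

  matures <- do.call(rbind, c(lapply(seq_along(anchored), function(i)
    enumerate_matures(anchored[[i]], ids[i], config$mature_offsets)),
    list(make.row.names = FALSE)))

  observations <- matches <- NULL
  if (!is.null(peaks)) {
    env <- detect_envelopes(peaks, config$match)
    observations <- deconvolute(env, config$match)
    alk_obs <- NULL
    if (!is.null(alk_peaks)) {
      alk_env <- detect_envelopes(alk_peaks, config$match)
      alk_obs <- deconvolute(alk_env, config$match, alkylated = TRUE)
    }
    observations <- confirm_alkylation(observations, alk_obs, config$match)
    matches <- match_predicted(matures, observations, config$match)
  }

  expr <- NULL
  if (!is.null(fpkm)) {
    cl2 <- classification
    cl2$organism <- rep_len(organism, nrow(cl2))
    expr <- cross_level_table(
      cl2, fpkm,
      matches %||% data.frame(precursor_id = character(0),
                              best = logical(0)),
      config$fpkm_cutoff)
    if (!is.null(taxa)) {
      expr$sharing <- section_sharing(
        data.frame(species = classification$species,
                   organism = rep_len(organism, nrow(classification)),
                   stringsAsFactors = FALSE), taxa)
    }
  }

  run <- list(candidates = candidates, anchored = anchored,
              classification = classification, matures = matures,
              observations = observations, matches = matches,
              expression = expr, config = config)
  class(run) <- "cyclotide_run"
  if (!is.null(out_dir)) .write_run(run, out_dir, transcripts)
  run
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.write_run <- function(run, out_dir, transcripts) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cand <- as.data.frame(run$candidates)
  .write_tsv(cand, file.path(out_dir, "candidates.tsv"))
  cls <- run$classification
  attr(cls, "profiles") <- NULL
  .write_tsv(as.data.frame(cls), file.path(out_dir, "classification.tsv"))
  .write_tsv(run$matures, file.path(out_dir, "matures.tsv"))
  if (!is.null(run$observations))
    .write_tsv(run$observations, file.path(out_dir, "observations.tsv"))
  if (!is.null(run$matches))
    .write_tsv(run$matches, file.path(out_dir, "matches.tsv"))
  if (!is.null(run$expression))
    .write_tsv(run$expression$table, file.path(out_dir, "cross_level.tsv"))
  # manifest: configuration and input checksum
  tf <- tempfile()
  .write_tsv(transcripts, tf)
  manifest <- list(
    package = "cyclominer",
    version = as.character(utils::packageVersion("cyclominer")),
    input_md5 = unname(tools::md5sum(tf)),
    config = .flatten_config(run$config))
  unlink(tf)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(.run_report(run), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

.flatten_config <- function(cfg) {
  cfg <- unclass(cfg)
  rapply(cfg, function(x) x, how = "replace")
}

.run_report <- function(run) {
  cls <- run$classification
  lines <- c("cyclominer run report", "=====================", "",
             sprintf("precursor candidates : %d", length(run$candidates)),
             sprintf("classified (lineage) : %d",
                     sum(cls$lineage != "unclassified")),
             "", "lineage tally:")
  tl <- table(cls$lineage)
  lines <- c(lines, sprintf("  %-12s %d", names(tl), as.integer(tl)))
  if (any(!is.na(cls$species))) {
    lines <- c(lines, "",
               sprintf("molecular series  : %d",
                       length(unique(stats::na.omit(cls$series)))),
               sprintf("molecular species : %d",
                       length(unique(stats::na.omit(cls$species)))))
  }
  if (!is.null(run$observations))
    lines <- c(lines, "",
               sprintf("neutral observations : %d", nrow(run$observations)),
               sprintf("mass matches         : %d (%d best)",
                       nrow(run$matches), sum(run$matches$best)))
  lines
}

#' @export
print.cyclotide_run <- function(x, ...) {
  writeLines(.run_report(x))
  invisible(x)
}

#' @export
summary.cyclotide_run <- function(object, ...) {
  cls <- object$classification
  out <- list(
    n_candidates = length(object$candidates),
    lineages = table(cls$lineage),
    n_series = length(unique(stats::na.omit(cls$series))),
    n_species = length(unique(stats::na.omit(cls$species))),
    n_observations = if (is.null(object$observations)) NA_integer_
                     else nrow(object$observations),
    n_matches = if (is.null(object$matches)) NA_integer_
                else nrow(object$matches))
  class(out) <- "summary.cyclotide_run"
  out
}

#' @export
print.summary.cyclotide_run <- function(x, ...) {
  cat("cyclotide_run:", x$n_candidates, "candidates;",
      x$n_species, "molecular species in", x$n_series, "series\n")
  print(x$lineages)
  invisible(x)
}
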