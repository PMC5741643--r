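# Anchoring precursor candidates onto the consensus coordinate system
# (position 0 = N-terminal cleavage site of the first cyclotide domain) and
# segmenting them into ER / NTPP / NTR / CD / CTR domains.

#' Anchor a precursor candidate to the consensus profile
#'
#' The cyclotide domain is anchored by convention from its motif hit: the
#' six cysteines land on the six curated cysteine columns, loop residues
#' are left-justified in their column blocks, the pre-Cys-I stretch is
#' right-justified against Cys I, and a cyclic domain's terminal N/D sits
#' on the dedicated nd column.  The fixed-width NTR window occupies the
#' consensus positions immediately upstream of the domain.  The remaining
#' N-terminal stretch (ER + NTPP) is aligned globally against a
#' position-specific profile built from the bundle's column frequencies,
#' with per-column deletion costs weighted by column occupancy, so that
#' the bundle's indel structure is recovered.  Repeated NTR/CD units reuse
#' the single consensus CD block; only the first unit (plus the flanking
#' domains) carries primary consensus positions.
#'
#' @param candidate A candidate from [mine_precursors()] (a list with
#'   `protein` and `motif_hits`), or a plain list with those fields.
#' @param bundle A `ref_bundle`.
#' @param gap_open Weight of skipping a consensus column, scaled by the
#'   column's occupancy in the bundle.
#' @param gap_extend Cost per inserted residue (a residue assigned to no
#'   consensus column).
#' @return An object of class `anchored_precursor`.
#' @export
anchor_to_profile <- function(candidate, bundle, gap_open = 2,
                              gap_extend = 2) {
  protein <- candidate$protein
  hits <- candidate$motif_hits
  if (length(hits) == 0L) stop("candidate has no motif hit; cannot anchor")
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(aa)
  lay <- bundle$layout
  cons <- rep(NA_integer_, n)
  ins_after <- rep(NA_integer_, n)
  flags <- character(0)

  # ---- cyclotide-domain units, processed left to right --------------------
  k_units <- length(hits)
  units <- vector("list", k_units)
  for (k in seq_len(k_units)) {
    cys <- hits[[k]]$cys_positions + 1L  # 1-based
    cys1 <- cys[1]; cys6 <- cys[6]
    prev_end <- if (k == 1L) 0L else units[[k - 1L]]$unit_end
    l6b <- min(4L, cys1 - 1L - prev_end)
    if (l6b < 0L) stop("unanchorable: overlapping cyclotide domains")
    cd_start <- cys1 - l6b
    tail_limit <- if (k < k_units) hits[[k + 1L]]$cys_positions[1] else n
    # loop-6 N/D: last N or D within the consensus loop-6 block capacity
    cap <- lay$nd_col - lay$loop_blocks$loop6a[1] + 1L
    win <- seq(cys6 + 1L, min(cys6 + cap, tail_limit))
    win <- win[win <= n]
    nd_pos <- NULL
    if (length(win) > 0L) {
      ndc <- win[aa[win] %in% c("N", "D")]
      if (length(ndc) > 0L) nd_pos <- ndc[length(ndc)]
    }
    cyclic <- !is.null(nd_pos)
    if (cyclic) {
      l6a <- nd_pos - cys6
      cd_end <- nd_pos
    } else {
      l6a <- (if (k < k_units) 0L else n - cys6)
      cd_end <- cys6 + l6a
      flags <- c(flags, "missing_ND")
    }
    loops <- c(loop6b = l6b,
               stats::setNames(hits[[k]]$loop_lengths,
                               paste0("loop", 1:5)),
               loop6a = l6a)
    units[[k]] <- list(cd_start = cd_start, cd_end = cd_end,
                       cys_idx = cys, loops = loops, cyclic = cyclic,
                       nd = nd_pos, unit_end = cd_end,
                       cd_cols = .cd_columns(loops, cyclic))
  }
  # NTR windows: fixed width immediately upstream of each unit
  ntr_w <- lay$ntr[2] - lay$ntr[1] + 1L
  for (k in seq_len(k_units)) {
    prev_end <- if (k == 1L) 0L else units[[k - 1L]]$unit_end
    avail <- units[[k]]$cd_start - 1L - prev_end
    ntr_len <- if (k == 1L) min(ntr_w, avail) else avail
    units[[k]]$ntr_start <- units[[k]]$cd_start - ntr_len
    units[[k]]$ntr_end <- units[[k]]$cd_start - 1L
    if (k > 1L && ntr_len > ntr_w) flags <- c(flags, "wide_ntr")
  }

  u1 <- units[[1L]]
  # primary consensus assignment: first unit CD
  idx_cd1 <- seq(u1$cd_start, u1$cd_end)
  cons[idx_cd1] <- u1$cd_cols
  # first NTR (possibly truncated): ends at consensus -1
  if (u1$ntr_end >= u1$ntr_start) {
    len1 <- u1$ntr_end - u1$ntr_start + 1L
    cons[seq(u1$ntr_start, u1$ntr_end)] <- seq(-len1, -1L)
  }
  # CTR after the last unit (cyclic only; a linear domain runs to the end)
  last <- units[[k_units]]
  if (last$cyclic && last$cd_end < n) {
    ctr_idx <- seq(last$cd_end + 1L, n)
    ctr_cols <- lay$ctr[1] + seq_along(ctr_idx) - 1L
    over <- ctr_cols > lay$ctr[2]
    if (k_units == 1L) {
      cons[ctr_idx[!over]] <- ctr_cols[!over]
      if (any(over)) {
        ins_after[ctr_idx[over]] <- lay$ctr[2]
        flags <- c(flags, "long_ctr")
      }
    }
  }

  # ---- prodomain: ER + NTPP profile alignment -----------------------------
  # The profile is conditioned on the nearest curated precursor (by local
  # alignment of the N-terminal stretch): that row carries most of the
  # weight, the remaining rows supply a BLOSUM62-backed background.  This
  # makes the bundle's lineage-specific indel blocks decisive.
  q_end <- u1$ntr_start - 1L
  if (q_end >= 1L) {
    # Shortlist nearest rows on the whole prodomain (ER+NTPP+NTR: the NTR
    # carries the series dipeptide, the NTPP window the species
    # variation), then align under each shortlisted row's conditioned
    # profile and keep the highest-scoring alignment.
    pro_seq <- paste(aa[seq_len(u1$cd_start - 1L)], collapse = "")
    pre <- .bundle_region_seqs(bundle, lay$er[1], -1L)
    w <- rep(0.3 / length(bundle$alignment), length(bundle$alignment))
    names(w) <- names(bundle$alignment)
    if (length(pre) > 0L) {
      best <- similarity_score(pro_seq, pre)$best_ref
      w[best] <- w[best] + 0.7
    }
    prof <- .bundle_profile(bundle, lay$er[1], lay$ntpp[2], weights = w)
    aln <- .profile_nw(aa[seq_len(q_end)], prof, gap_open, gap_extend)
    cons[seq_len(q_end)] <- aln$cons
    ins_after[seq_len(q_end)] <- aln$ins_after
  }

  assigned <- cons[!is.na(cons)]
  if (length(assigned) > 0L && any(diff(sort(assigned)) == 0L))
    stop("internal error: duplicate consensus assignment")
  all_pos <- lay$er[1]:lay$ctr[2]
  gap_positions <- setdiff(all_pos, assigned)
  if (length(assigned) == 0L || min(assigned) > lay$ntpp[1])
    flags <- c(flags, "partial")

  out <- list(protein = protein, cons_pos = cons, ins_after = ins_after,
              gap_positions = gap_positions, cd_units = units,
              motif_hits = hits, flags = unique(flags), layout = lay)
  class(out) <- "anchored_precursor"
  out
}

# ungapped row sequences restricted to a consensus range
.bundle_region_seqs <- function(bundle, from, to) {
  sel <- which(bundle$column_map >= from & bundle$column_map <= to)
  seqs <- vapply(bundle$alignment, function(r) {
    gsub("-", "", paste(strsplit(r, "", fixed = TRUE)[[1]][sel],
                        collapse = ""), fixed = TRUE)
  }, character(1))
  seqs[nzchar(seqs)]
}

# Row-weighted per-column scores and occupancy for a consensus range.
# score[res, col] = sum over rows occupying col of w_row * BLOSUM62[res,
# row residue]; occ[col] = total weight of rows occupying col.  Weighted
# frequencies are deliberately not renormalised, so columns occupied by
# few (or lightly weighted) rows both score low and are cheap to skip.
.bundle_profile <- function(bundle, from, to, weights = NULL) {
  sel <- which(bundle$column_map >= from & bundle$column_map <= to)
  rows <- do.call(rbind, strsplit(unname(bundle$alignment), "", fixed = TRUE))
  rows <- rows[, sel, drop = FALSE]
  n_rows <- nrow(rows)
  if (is.null(weights)) weights <- rep(1 / n_rows, n_rows)
  weights <- unname(weights[names(bundle$alignment)] %||% weights)
  n_col <- length(sel)
  b62 <- .sub_matrix("BLOSUM62")[.AA20, .AA20]
  score <- matrix(0, nrow = length(.AA20), ncol = n_col,
                  dimnames = list(.AA20, NULL))
  occ <- numeric(n_col)
  for (j in seq_len(n_col)) {
    col <- rows[, j]
    keep <- col != "-" & col %in% .AA20
    occ[j] <- sum(weights[keep])
    if (any(keep))
      score[, j] <- b62[, col[keep], drop = FALSE] %*% weights[keep]
  }
  list(cons = bundle$column_map[sel], score = score, occ = occ)
}

# Global alignment of a residue vector against profile columns
# (maximising), with affine deletions: opening a block of skipped columns
# costs gap_open, and each skipped column adds gap_extend scaled by its
# occupancy (skipping a mostly-gapped column is nearly free, so the
# bundle's indel blocks are recovered as contiguous deletions).  Inserted
# residues (assigned to no column) cost gap_open + gap_extend each.
# Returns per-residue consensus position or NA plus, for inserted
# residues, the consensus position they follow.
.profile_nw <- function(res, prof, gap_open, gap_extend) {
  m <- length(res)
  n <- length(prof$cons)
  ext <- gap_extend * prof$occ
  ins_cost <- gap_open + gap_extend
  NEG <- -1e9
  M <- D <- I <- matrix(NEG, m + 1L, n + 1L)
  tbM <- tbD <- tbI <- matrix(0L, m + 1L, n + 1L)  # 1=M, 2=D, 3=I
  M[1L, 1L] <- 0
  for (j in seq_len(n)) {
    open_s <- M[1L, j] - gap_open
    D[1L, j + 1L] <- max(open_s, D[1L, j]) - ext[j]
    tbD[1L, j + 1L] <- if (open_s >= D[1L, j]) 1L else 2L
  }
  for (i in seq_len(m)) {
    prev <- c(M[i, 1L], NEG, I[i, 1L])
    I[i + 1L, 1L] <- max(prev) - ins_cost
    tbI[i + 1L, 1L] <- which.max(prev)
  }
  sc <- prof$score
  for (i in seq_len(m)) {
    ri <- res[i]
    mrow <- if (ri %in% rownames(sc)) sc[ri, ] else rep(0, n)
    for (j in seq_len(n)) {
      pm <- c(M[i, j], D[i, j], I[i, j])
      M[i + 1L, j + 1L] <- max(pm) + mrow[j]
      tbM[i + 1L, j + 1L] <- which.max(pm)
      pd <- c(M[i + 1L, j] - gap_open, D[i + 1L, j],
              I[i + 1L, j] - gap_open)
      D[i + 1L, j + 1L] <- max(pd) - ext[j]
      tbD[i + 1L, j + 1L] <- which.max(pd)
      pi_ <- c(M[i, j + 1L], D[i, j + 1L], I[i, j + 1L])
      I[i + 1L, j + 1L] <- max(pi_) - ins_cost
      tbI[i + 1L, j + 1L] <- which.max(pi_)
    }
  }
  cons <- rep(NA_integer_, m)
  ins_after <- rep(NA_integer_, m)
  fin <- c(M[m + 1L, n + 1L], D[m + 1L, n + 1L], I[m + 1L, n + 1L])
  state <- which.max(fin)
  i <- m; j <- n
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      cons[i] <- prof$cons[j]
      state <- tbM[i + 1L, j + 1L]
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      state <- tbD[i + 1L, j + 1L]
      j <- j - 1L
    } else {
      ins_after[i] <- if (j > 0L) prof$cons[j] else NA_integer_
      state <- tbI[i + 1L, j + 1L]
      i <- i - 1L
    }
  }
  list(cons = cons, ins_after = ins_after, score = max(fin))
}

#' Segment an anchored precursor into domains
#'
#' @param anchored An `anchored_precursor`.
#' @return List with `domains` (data frame: `domain`, `cd_index`, `start`,
#'   `end`, `cons_start`, `cons_end`) and `repeat_count`.  Every residue of
#'   the protein belongs to exactly one span.
#' @export
segment_domains <- function(anchored) {
  stopifnot(inherits(anchored, "anchored_precursor"))
  units <- anchored$cd_units
  n <- nchar(anchored$protein)
  lay <- anchored$layout
  rows <- list()
  add <- function(domain, cd_index, start, end) {
    if (end < start) return()
    span_cons <- anchored$cons_pos[start:end]
    rows[[length(rows) + 1L]] <<- data.frame(
      domain = domain, cd_index = cd_index, start = start, end = end,
      cons_start = if (all(is.na(span_cons))) NA_integer_
                   else min(span_cons, na.rm = TRUE),
      cons_end = if (all(is.na(span_cons))) NA_integer_
                 else max(span_cons, na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  q_end <- units[[1L]]$ntr_start - 1L
  if (q_end >= 1L) {
    cons_q <- anchored$cons_pos[seq_len(q_end)]
    er_end <- {
      er_idx <- which(!is.na(cons_q) & cons_q <= lay$er[2])
      if (length(er_idx) > 0L) max(er_idx) else 0L
    }
    add("ER", NA_integer_, 1L, er_end)
    add("NTPP", NA_integer_, er_end + 1L, q_end)
  }
  for (k in seq_along(units)) {
    u <- units[[k]]
    add("NTR", k, u$ntr_start, u$ntr_end)
    add("CD", k, u$cd_start, u$cd_end)
  }
  last <- units[[length(units)]]
  add("CTR", NA_integer_, last$cd_end + 1L, n)
  domains <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  # coverage invariant: contiguous, non-overlapping, complete
  stopifnot(domains$start[1] == 1L, domains$end[nrow(domains)] == n,
            all(domains$start[-1] == domains$end[-nrow(domains)] + 1L))
  list(domains = domains, repeat_count = length(units))
}

#' Decompose one cyclotide domain into its six loops
#'
#' Loops 1..5 are the inter-cysteine stretches; loop 6 spans the
#' cyclization point (residues after Cys VI up to the domain end, joined
#' with the residues preceding Cys I for cyclic domains).  The N/D
#' cyclization residue, when present, lies in loop 6.  A domain whose span
#' carries more or fewer than six cysteines is reported with an
#' `uneven_cysteines` abnormality flag, not an error.
#'
#' @param anchored An `anchored_precursor`.
#' @param cd_index Which cyclotide domain (1-based).
#' @param loop_windows Windows used to flag aberrant loop lengths.
#' @return List with `cys_idx`, `loops` (six residue strings), `nd_site`
#'   (residue index or NULL) and `flags`.
#' @export
decompose_loops <- function(anchored, cd_index = 1L,
                            loop_windows = default_loop_windows()) {
  stopifnot(inherits(anchored, "anchored_precursor"))
  units <- anchored$cd_units
  if (cd_index < 1L || cd_index > length(units))
    stop("no cyclotide domain with index ", cd_index)
  u <- units[[cd_index]]
  aa <- strsplit(anchored$protein, "", fixed = TRUE)[[1]]
  sub <- function(a, b) if (b < a) "" else paste(aa[a:b], collapse = "")
  cys <- u$cys_idx
  loops <- character(6)
  for (k in 1:5) loops[k] <- sub(cys[k] + 1L, cys[k + 1L] - 1L)
  after <- sub(cys[6] + 1L, u$cd_end)
  before <- sub(u$cd_start, cys[1] - 1L)
  loops[6] <- if (u$cyclic) paste0(after, before) else after
  flags <- character(0)
  n_c <- sum(aa[u$cd_start:u$cd_end] == "C")
  if (n_c != 6L) flags <- c(flags, "uneven_cysteines")
  if (!u$cyclic) flags <- c(flags, "missing_ND")
  lens <- vapply(loops[1:5], nchar, integer(1))
  for (k in 1:5) {
    wd <- loop_windows[[k]]
    if (lens[k] < wd[1] || lens[k] > wd[2])
      flags <- c(flags, "aberrant_loop_length")
  }
  list(cys_idx = cys, loops = unname(loops),
       nd_site = u$nd, flags = unique(flags))
}

#' @export
print.anchored_precursor <- function(x, ...) {
  ncd <- length(x$cd_units)
  cat("Anchored precursor:", nchar(x$protein), "residues,", ncd,
      "cyclotide domain(s)")
  if (length(x$flags) > 0L) cat(" [", paste(x$flags, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}
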