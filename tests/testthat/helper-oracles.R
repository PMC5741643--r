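# Independent oracles used to verify the implementation.

# Brute-force Smith-Waterman (Gotoh) with affine gaps; a gap of length L
# costs open + L * ext.  Written independently of the Biostrings-backed
# similarity_score().
sw_oracle <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(A); n <- length(B)
  H <- E <- F <- matrix(0, m + 1, n + 1)
  best <- 0
  for (i in 1:m) {
    for (j in 1:n) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, E[i + 1, j] - ext)
      F[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, F[i, j + 1] - ext)
      H[i + 1, j + 1] <- max(0, H[i, j] + mat[A[i], B[j]],
                             E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# Exhaustive enumeration oracle for the cystine-knot motif scan: every
# 6-subset of cysteine positions is tested against the loop windows, then
# the same smallest-span / leftmost greedy selection is applied.  The
# enumeration is independent (combn over all cysteines, no windowed DFS).
motif_oracle <- function(protein, windows) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  cpos <- which(aa == "C")
  if (length(cpos) < 6) return(list())
  combs <- utils::combn(cpos, 6, simplify = FALSE)
  valid <- Filter(function(p) {
    gaps <- diff(p) - 1
    all(vapply(1:5, function(k)
      gaps[k] >= windows[[k]][1] && gaps[k] <= windows[[k]][2],
      logical(1)))
  }, combs)
  if (length(valid) == 0) return(list())
  spans <- vapply(valid, function(p) p[6] - p[1], numeric(1))
  starts <- vapply(valid, `[`, numeric(1), 1)
  ord <- order(spans, starts)
  accepted <- list()
  for (i in ord) {
    p <- valid[[i]]
    if (!any(vapply(accepted, function(a) p[1] <= a[6] && a[1] <= p[6],
                    logical(1))))
      accepted[[length(accepted) + 1]] <- p
  }
  accepted[order(vapply(accepted, `[`, numeric(1), 1))]
}

# Independent monoisotopic summation oracle (its own residue table).
mass_oracle <- function(seqs, topology = "cyclic", n_ss = 3) {
  tab <- c(A = 71.037114, R = 156.101111, N = 114.042927, D = 115.026943,
           C = 103.009185, E = 129.042593, Q = 128.058578, G = 57.021464,
           H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
           M = 131.040485, F = 147.068414, P = 97.052764, S = 87.032028,
           T = 101.047678, W = 186.079313, Y = 163.063329, V = 99.068414)
  vapply(seqs, function(s) {
    m <- sum(tab[strsplit(s, "", fixed = TRUE)[[1]]]) - n_ss * 2 * 1.007825
    if (topology == "linear") m <- m + 18.010565
    m
  }, numeric(1))
}

KB1 <- "GLPVCGETCVGGTCNTPGCTCSWPVCTRN"
CYO2 <- "GIPCGESCVWIPCISSAIGCSCKSKVCYRN"
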