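# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Column-by-column conserved-region scan on gapped sequences.
naive_conserved_regions <- function(seqs, ref_id, min_len, circular) {
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  ref <- strsplit(seqs[[ref_id]], "")[[1]]
  ncol_aln <- ncol(mat)
  cons <- logical(ncol_aln)
  for (j in seq_len(ncol_aln)) {
    col <- mat[, j]
    cons[j] <- length(unique(col)) == 1 && col[1] %in% c("A", "C", "G", "T")
  }
  refpos <- cumsum(ref != "-")
  # collect maximal runs
  regions <- list()
  j <- 1
  while (j <= ncol_aln) {
    if (cons[j]) {
      k <- j
      while (k < ncol_aln && cons[k + 1]) k <- k + 1
      regions[[length(regions) + 1]] <- c(start = refpos[j], end = refpos[k])
      j <- k + 1
    } else j <- j + 1
  }
  if (length(regions) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), wraps = logical(0)))
  }
  df <- as.data.frame(do.call(rbind, regions))
  df$wraps <- FALSE
  df$length <- df$end - df$start + 1
  if (circular && nrow(df) >= 2 && cons[1] && cons[ncol_aln]) {
    n <- nrow(df)
    merged <- data.frame(start = df$start[n], end = df$end[1],
                         wraps = TRUE, length = df$length[n] + df$length[1])
    df <- rbind(df[-c(1, n), ], merged)
  }
  df <- df[df$length >= min_len, , drop = FALSE]
  df[order(df$start), c("start", "end", "length", "wraps")]
}

# Per-offset pairing scan: slide p2 (reversed) against p1 and score every
# antiparallel offset independently.
naive_dimer_pairings <- function(p1, p2, mode = "contiguous") {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  b1 <- strsplit(p1, "")[[1]]
  b2 <- strsplit(p2, "")[[1]]
  n1 <- length(b1); n2 <- length(b2)
  best <- 0
  for (s in 2:(n1 + n2)) {
    hits <- logical(0)
    for (i in seq_len(n1)) {
      j <- s - i
      if (j >= 1 && j <= n2) hits <- c(hits, unname(comp[b1[i]]) == b2[j])
    }
    if (length(hits) == 0) next
    score <- if (mode == "total") sum(hits) else {
      r <- rle(hits); m <- r$lengths[r$values]
      if (length(m)) max(m) else 0
    }
    best <- max(best, score)
  }
  best
}

# Exhaustive stem/loop enumeration for hairpins.
naive_hairpin <- function(p, min_stem = 4, min_loop = 3) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  b <- strsplit(p, "")[[1]]
  n <- length(b)
  for (k in min_stem:max(min_stem, floor((n - min_loop) / 2))) {
    if (2 * k + min_loop > n) break
    for (i in 1:(n - 2 * k - min_loop + 1)) {
      for (j in (i + k + min_loop):(n - k + 1)) {
        ok <- TRUE
        for (t in 0:(k - 1)) {
          if (unname(comp[b[i + t]]) != b[j + k - 1 - t]) { ok <- FALSE; break }
        }
        if (ok) return(1)
      }
    }
  }
  0
}

# Rotation scan: count primer occurrences over every rotation start of the
# circular template, both strands.
naive_specificity <- function(p, template_seq, circular = TRUE) {
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  L <- nchar(template_seq)
  k <- nchar(p)
  ext <- if (circular) paste0(template_seq, substr(template_seq, 1, k - 1)) else template_seq
  n <- 0
  for (i in 1:(nchar(ext) - k + 1)) {
    s <- substr(ext, i, i + k - 1)
    if (s == p) n <- n + 1
    if (s == rc(p)) n <- n + 1
  }
  max(0, n - 1)
}

# Small fully conserved random family used by several tests.
make_conserved_family <- function(genome_len, seed) {
  simulate_family(sim_spec(genome_len = genome_len, divergence = 0,
                           seed = seed))
}
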