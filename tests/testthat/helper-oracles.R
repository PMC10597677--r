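# Independent oracles: deliberately naive implementations used only to
# check package results. They share no code with the package internals.

# Double-bond positions by brute force: enumerate every placement of D
# bonds that is anchored at the omega position and 3-spaced (methylene
# interrupted), and return the unique feasible placement.
ora_delta_positions <- function(carbons, double_bonds, omega) {
  if (double_bonds == 0) return(integer(0))
  anchor <- carbons - omega
  placements <- list()
  # candidate positions descend from the anchor in steps of 3
  cand <- seq(anchor, 1, by = -3)
  if (length(cand) >= double_bonds) {
    pl <- sort(cand[seq_len(double_bonds)])
    if (min(pl) >= 2) placements[[1]] <- pl
  }
  stopifnot(length(placements) == 1)
  placements[[1]]
}

# Exhaustive motif-existence check: all hit positions of `pattern` in
# `protein` (X wildcard), found by testing every window.
ora_motif_starts <- function(protein, pattern) {
  pl <- nchar(pattern)
  pp <- strsplit(pattern, "")[[1]]
  n <- nchar(protein)
  if (n < pl) return(integer(0))
  starts <- integer(0)
  for (s in 0:(n - pl)) {
    win <- strsplit(substr(protein, s + 1, s + pl), "")[[1]]
    if (all(pp == "X" | pp == win)) starts <- c(starts, s)
  }
  starts
}

# Does an ordered, non-overlapping combination of hits exist for the given
# patterns? Enumerates every combination of occurrence indices.
ora_exists_chain <- function(protein, patterns, from = 0) {
  hits <- lapply(patterns, function(p) ora_motif_starts(protein, p))
  lens <- nchar(patterns)
  rec <- function(k, minpos) {
    if (k > length(patterns)) return(TRUE)
    for (s in hits[[k]]) {
      if (s >= minpos && rec(k + 1, s + lens[k])) return(TRUE)
    }
    FALSE
  }
  rec(1, from)
}

# Family decision re-derived from the rules, via exhaustive existence
# checks (the package uses a leftmost-greedy procedure instead).
ora_classify <- function(protein) {
  if (ora_exists_chain(protein, c("KXXEXXDT", "NXXXHXXMYXYY", "HXXHH",
                                  "TXXQXXQ"))) {
    return("ELOVL")
  }
  has_hpgg <- length(ora_motif_starts(protein, "HPGG")) > 0
  if (has_hpgg) {
    for (b2 in c("HXXXHH", "HXXHH")) {
      if (ora_exists_chain(protein, c("HPGG", "HXXXH", b2, "QXXHH"))) {
        return("FED")
      }
    }
    for (b2 in c("HXXXHH", "HXXHH")) {
      if (ora_exists_chain(protein, c("HPGG", "HXXXH", b2, "HXXHH"))) {
        return("DESATURASE_OTHER")
      }
    }
  } else {
    if (ora_exists_chain(protein, c("HXXXH", "HXXHH", "HXXHH"))) {
      return("OMEGA_X")
    }
  }
  "UNCLASSIFIED"
}

# Plain-loop global alignment with the same scoring contract (match +1,
# mismatch -1, linear gap -2, terminal gaps penalized, diagonal > up > left
# on traceback, N never a match), returning percent identity.
ora_nw_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  H[, 1] <- (0:n) * gap
  H[1, ] <- (0:m) * gap
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (A[i] == B[j] && A[i] != "N") match else mismatch
      H[i + 1, j + 1] <- max(H[i, j] + s, H[i, j + 1] + gap, H[i + 1, j] + gap)
    }
  }
  # traceback with fixed preference
  i <- n; j <- m; cols <- 0; matches <- 0
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      s <- if (A[i] == B[j] && A[i] != "N") match else mismatch
      if (H[i + 1, j + 1] == H[i, j] + s) {
        if (A[i] == B[j] && A[i] != "N") matches <- matches + 1
        i <- i - 1; j <- j - 1; cols <- cols + 1; next
      }
      if (H[i + 1, j + 1] == H[i, j + 1] + gap) {
        i <- i - 1; cols <- cols + 1; next
      }
      j <- j - 1; cols <- cols + 1; next
    }
    if (i > 0) { i <- i - 1 } else { j <- j - 1 }
    cols <- cols + 1
  }
  100 * matches / cols
}

# Brute-force shared canonical k-mer count between two sequences.
ora_shared_kmers <- function(a, b, k) {
  canon <- function(seq) {
    n <- nchar(seq)
    if (n < k) return(character(0))
    starts <- seq_len(n - k + 1)
    f <- substring(seq, starts, starts + k - 1)
    f <- f[!grepl("N", f)]
    r <- vapply(f, function(x) {
      paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])), collapse = "")
    }, "", USE.NAMES = FALSE)
    unique(pmin(f, r))
  }
  length(intersect(canon(toupper(a)), canon(toupper(b))))
}

random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}

random_dna_chr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

quiet_config <- function(...) default_config(log_level = "warn", ...)
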