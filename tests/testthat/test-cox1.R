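# cox1 contamination screen: recruitment, identity scoring, positivity rule.

panel_path <- bundled_cox1_panel()
panel_seqs <- local({
  p <- Biostrings::readDNAStringSet(panel_path)
  names(p) <- sub("\\s.*$", "", names(p))
  p
})

test_that("recruit_reads uses canonical k-mers", {
  ref <- as.character(panel_seqs[[1]])
  reads <- c(verbatim = substr(ref, 100, 250),
             revcomp = as.character(Biostrings::reverseComplement(
               Biostrings::DNAString(substr(ref, 300, 450)))),
             short = substr(ref, 1, 20))
  set.seed(10)
  # a random read with no shared 31-mer, verified by brute force
  repeat {
    rnd <- random_dna_chr(150)
    if (ora_shared_kmers(rnd, ref, 31) == 0 &&
        all(vapply(seq_along(panel_seqs), function(i) {
          ora_shared_kmers(rnd, as.character(panel_seqs[[i]]), 31) == 0
        }, TRUE))) break
  }
  reads <- c(reads, random = rnd)
  got <- recruit_reads(reads, panel_seqs, k = 31)
  expect_setequal(names(got), c("verbatim", "revcomp"))
  expect_error(recruit_reads(reads, panel_seqs, k = 30),
               class = "pufa_input_error")
  expect_error(recruit_reads(reads, Biostrings::DNAStringSet(), k = 31),
               class = "pufa_config_error")
})

test_that("recruitment recall is 1 for error-free reads from the panel", {
  set.seed(22)
  reads <- character(0)
  for (i in 1:20) {
    ref <- as.character(panel_seqs[[sample.int(length(panel_seqs), 1)]])
    start <- sample.int(nchar(ref) - 80, 1)
    frag <- substr(ref, start, start + sample(40:80, 1))
    if (runif(1) < 0.5) frag <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(frag)))
    reads[paste0("r", i)] <- frag
  }
  expect_equal(length(recruit_reads(reads, panel_seqs)), length(reads))
})

test_that("identity is exact on identical and substitution-only contigs", {
  ref <- as.character(panel_seqs[[2]])
  hit <- best_identity(ref, panel_seqs)
  expect_equal(hit$percent_identity, 100)
  expect_equal(hit$aligned_length, nchar(ref))
  expect_equal(hit$reference_id, names(panel_seqs)[2])

  # plant exactly 12 substitutions over the first 600 nt: identity 98.0
  contig <- substr(ref, 1, 600)
  set.seed(7)
  pos <- sample.int(600, 12)
  ch <- strsplit(contig, "")[[1]]
  ch[pos] <- vapply(ch[pos], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  mut <- paste(ch, collapse = "")
  hit <- best_identity(mut, panel_seqs)
  expect_equal(hit$percent_identity, 98.0, tolerance = 1e-12)
  expect_equal(hit$aligned_length, 600L)
})

test_that("identity is strand-invariant", {
  ref <- as.character(panel_seqs[[3]])
  mut <- mutate_sequence(ref, 0.02, seed = 5)$sequence
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mut)))
  h1 <- best_identity(mut, panel_seqs)
  h2 <- best_identity(rc, panel_seqs)
  expect_equal(h2$percent_identity, h1$percent_identity)
  expect_equal(h2$reference_id, h1$reference_id)
})

test_that("expected identity degrades as 100(1-p) under substitutions", {
  ids <- vapply(1:20, function(s) {
    ref <- as.character(panel_seqs[[1 + (s %% length(panel_seqs))]])
    mut <- mutate_sequence(ref, 0.1, seed = s)$sequence
    best_identity(mut, panel_seqs)$percent_identity
  }, 1)
  expect_lt(abs(mean(ids) - 90), 2)
})

test_that("random contigs never come out positive", {
  # scaled down to 30 seeds to keep the suite fast
  set.seed(606)
  for (i in 1:30) {
    rep <- screen_cox1(stats::setNames(random_dna_chr(600), "r"), panel_seqs)
    expect_false(rep$positive, info = i)
  }
})

test_that("the 75% rule is strictly exclusive and empty hits are negative", {
  hits <- data.frame(contig_id = "c1", reference_id = "r1",
                     percent_identity = 99.6, aligned_length = 600L,
                     positive = NA)
  expect_true(flag_contamination(hits)$positive)

  hits$percent_identity <- 75.0
  expect_false(flag_contamination(hits)$positive)

  hits$percent_identity <- 75.0001
  expect_true(flag_contamination(hits)$positive)

  empty <- hits[0, ]
  expect_false(flag_contamination(empty)$positive)
})

test_that("positives are sorted by identity descending", {
  hits <- data.frame(contig_id = c("a", "b", "c"),
                     reference_id = "r",
                     percent_identity = c(80, 99, 60),
                     aligned_length = 600L, positive = NA)
  rep <- flag_contamination(hits)
  expect_equal(rep$positives$contig_id, c("b", "a"))
})
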