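# Synthetic-data generator: determinism, truth validity, mutation model.

test_that("generation is fully deterministic under (arguments, seed)", {
  p1 <- make_family_protein("fed", 300, seed = 42)
  p2 <- make_family_protein("fed", 300, seed = 42)
  expect_identical(p1, p2)

  s1 <- make_sample("freshwater", seed = 13)
  s2 <- make_sample("freshwater", seed = 13)
  expect_identical(as.character(s1$contigs), as.character(s2$contigs))
  expect_identical(s1$truth$planted_genes, s2$truth$planted_genes)

  g1 <- make_genome_fixture(seed = 3)
  g2 <- make_genome_fixture(seed = 3)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$gff, g2$gff)

  # written FASTA is byte-identical across runs
  d1 <- tempfile(); d2 <- tempfile()
  write_sample(make_sample("freshwater", seed = 4), d1)
  write_sample(make_sample("freshwater", seed = 4), d2)
  expect_identical(readLines(file.path(d1, "contigs.fasta")),
                   readLines(file.path(d2, "contigs.fasta")))
})

test_that("omega-x proteins never contain HPGG; lengths are respected", {
  for (s in 1:10) {
    p <- make_family_protein("wx", 250, seed = s)
    expect_false(grepl("HPGG", p$protein, fixed = TRUE))
    expect_equal(nchar(p$protein), 250)
    expect_equal(nchar(p$cds), 3 * (250 + 1)) # ATG..codons..stop
  }
  expect_error(make_family_protein("fed", 100), class = "pufa_parameter_error")
})

test_that("mutation counts follow the binomial model", {
  m0 <- mutate_sequence(strrep("ACGT", 250), 0, seed = 1)
  expect_equal(m0$sequence, strrep("ACGT", 250))
  expect_equal(nrow(m0$edits), 0)

  seq <- strrep("ACGT", 250) # 1000 nt
  q <- stats::qbinom(c(0.005, 0.995), 1000, 0.02)
  counts <- vapply(1:100, function(s) {
    nrow(mutate_sequence(seq, 0.02, seed = s)$edits)
  }, 1L)
  # each seed should land in the 99% interval; allow the nominal miss rate
  expect_gte(sum(counts >= q[1] & counts <= q[2]), 95)

  # identity closed form holds (no indels by construction)
  mut <- mutate_sequence(seq, 0.05, seed = 9)
  expect_equal(global_percent_identity(seq, mut$sequence),
               100 * (1 - nrow(mut$edits) / 1000))
  # every recorded edit is a real difference
  ch <- strsplit(mut$sequence, "")[[1]]
  orig <- strsplit(seq, "")[[1]]
  expect_equal(which(ch != orig), mut$edits$pos)
  expect_equal(ch[mut$edits$pos], mut$edits$alt)
  expect_error(mutate_sequence(seq, 0.7), class = "pufa_parameter_error")
})

test_that("truth files resolve against the emitted FASTA", {
  s <- make_sample("freshwater", seed = 21)
  truth <- s$truth
  for (k in seq_len(nrow(truth$planted_genes))) {
    row <- truth$planted_genes[k, ]
    contig <- as.character(s$contigs[[row$contig_id]])
    cds <- substr(contig, row$cds_start + 1, row$cds_end)
    if (row$strand == "-") {
      cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    }
    expect_equal(substr(cds, 1, 3), "ATG")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(sub("\\*$", "", aa), row$protein)
  }
  # the planted cox1 contig differs from its source at exactly the
  # recorded positions
  cox <- truth$planted_cox1[1, ]
  panel <- Biostrings::readDNAStringSet(bundled_cox1_panel())
  names(panel) <- sub("\\s.*$", "", names(panel))
  ref <- strsplit(as.character(panel[[cox$reference_id]]), "")[[1]]
  var <- strsplit(as.character(s$contigs[[cox$contig_id]]), "")[[1]]
  expect_equal(which(ref != var), sort(cox$substitution_positions[[1]]))
})

test_that("marine samples are clean by construction", {
  s <- make_sample("marine", seed = 31)
  expect_equal(nrow(s$truth$planted_genes), 0)
  expect_equal(nrow(s$truth$planted_cox1), 0)
  expect_equal(length(s$contigs), s$truth$n_host)
})

test_that("genome fixture truth matches its annotation", {
  fix <- make_genome_fixture(seed = 8)
  d <- tempfile()
  write_genome_fixture(fix, d)
  expect_true(all(file.exists(file.path(d, c("genome.fasta",
                                             "annotation.gff3", "truth.json")))))
  structs <- structures_from_gff(file.path(d, "annotation.gff3"))
  expect_true(is_intronless(structs[["fed3s"]]))
  ints <- introns_from_structure(structs[["fed4s"]], fix$genome)
  expect_equal(ints[[3]]$length, 940L)
  expect_equal(check_splice_sites(ints[[3]]), "canonical")
  tr <- find_polypyrimidine_tract(ints[[3]])
  expect_equal(c(tr$start, tr$end),
               c(fix$truth$genes$fed4s$third_intron$tract_start,
                 fix$truth$genes$fed4s$third_intron$tract_end))
})
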