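# Exon-intron structures, splice sites, tracts, introner classification.

fixture <- make_genome_fixture(seed = 1)
fix_dir <- tempfile("genome_fixture_")
write_genome_fixture(fixture, fix_dir)
structs <- structures_from_gff(file.path(fix_dir, "annotation.gff3"))
genome <- local({
  g <- Biostrings::readDNAStringSet(file.path(fix_dir, "genome.fasta"))
  names(g) <- sub("\\s.*$", "", names(g))
  g
})

test_that("introns are the gaps between exons; lengths add up", {
  g <- structs[["fed4s"]]
  ints <- introns_from_structure(g, genome)
  expect_length(ints, 4)
  expect_equal(vapply(ints, function(i) i$length, 1L),
               fixture$truth$genes$fed4s$intron_lengths)
  span <- max(g$exons[, "end"]) - min(g$exons[, "start"])
  expect_equal(sum(g$exons[, "end"] - g$exons[, "start"]) +
                 sum(vapply(ints, function(i) i$length, 1L)), span)
})

test_that("a single-exon gene is intronless", {
  g <- structs[["fed3s"]]
  expect_true(is_intronless(g))
  expect_length(introns_from_structure(g, genome), 0)
})

test_that("minus-strand introns follow the transcription convention", {
  g <- structs[["ctrl"]]
  expect_equal(g$strand, "-")
  ints <- introns_from_structure(g, genome)
  expect_length(ints, 1)
  i <- ints[[1]]
  # the stored sequence is reverse-complemented: forward-strand gap
  fwd_gap <- substr(as.character(genome[[g$scaffold_id]]), i$start + 1, i$end)
  expect_equal(i$sequence,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(fwd_gap))))
  expect_equal(check_splice_sites(i), "non_canonical")
  expect_false(classify_introner_like(i)$introner_like)
})

test_that("strand invariance: mirrored annotation on the reverse complement", {
  g <- structs[["fed4s"]]
  scaffold <- as.character(genome[[g$scaffold_id]])
  L <- nchar(scaffold)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(scaffold)))
  mirrored <- gene_structure(g$gene_id, g$scaffold_id, "-",
                             cbind(L - g$exons[, "end"], L - g$exons[, "start"]))
  ints <- introns_from_structure(g, scaffold)
  ints_m <- introns_from_structure(mirrored, rc)
  expect_equal(vapply(ints_m, function(i) i$sequence, ""),
               vapply(ints, function(i) i$sequence, ""))
  expect_equal(vapply(ints_m, function(i) classify_introner_like(i)$introner_like,
                      TRUE),
               vapply(ints, function(i) classify_introner_like(i)$introner_like,
                      TRUE))
})

test_that("splice-site calls are literal GT..AG checks", {
  expect_equal(check_splice_sites(intron_from_sequence(
    paste0("GT", strrep("A", 50), "AG"))), "canonical")
  expect_equal(check_splice_sites(intron_from_sequence(
    paste0("AT", strrep("A", 50), "AC"))), "non_canonical")
})

test_that("polypyrimidine tract search finds planted and obvious tracts", {
  i <- intron_from_sequence(paste0("GT", strrep("A", 60), "TTTCTTTTCAG"))
  tr <- find_polypyrimidine_tract(i)
  expect_false(is.null(tr))
  expect_gte(tr$length, 8)
  expect_gte(tr$pyrimidine_fraction, 0.8)

  # pure purine 3' region: absent
  i2 <- intron_from_sequence(paste0("GT", strrep("A", 30), strrep("G", 40), "AG"))
  expect_null(find_polypyrimidine_tract(i2))

  # planted fixture tract: span equals the recorded coordinates
  ints <- introns_from_structure(structs[["fed4s"]], genome)
  tr3 <- find_polypyrimidine_tract(ints[[3]])
  third <- fixture$truth$genes$fed4s$third_intron
  expect_equal(tr3$start, third$tract_start)
  expect_equal(tr3$end, third$tract_end)
})

test_that("introner-like calls combine length, splice sites and tract", {
  ints <- introns_from_structure(structs[["fed4s"]], genome)
  cl <- classify_introner_like(ints[[3]])
  expect_true(cl$introner_like)
  expect_equal(ints[[3]]$length, 940L)
  expect_true(all(unlist(cl$criteria)))

  # short canonical intron with a tract: fails the length criterion
  short <- intron_from_sequence(paste0("GT", strrep("A", 40), "TTTTTTTTTTCAG"))
  cl2 <- classify_introner_like(short)
  expect_false(cl2$introner_like)
  expect_true(cl2$criteria$tract_found)
  expect_false(cl2$criteria$long_enough)

  # 940-bp tract-less generator variant: fails only the tract criterion
  no_tract <- make_genome_fixture(seed = 1, third_intron_tract = FALSE)
  gff2 <- tempfile(fileext = ".gff3")
  writeLines(no_tract$gff, gff2)
  s2 <- structures_from_gff(gff2)
  ints2 <- introns_from_structure(s2[["fed4s"]], no_tract$genome)
  cl3 <- classify_introner_like(ints2[[3]])
  expect_false(cl3$introner_like)
  expect_false(cl3$criteria$tract_found)
  expect_true(cl3$criteria$canonical_splice_sites)
  expect_true(cl3$criteria$long_enough)
})

test_that("relaxing min_frac never flips introner-like true to false", {
  set.seed(64)
  for (rep in 1:10) {
    seq <- paste0("GT", random_dna_chr(200),
                  paste(sample(c("C", "T", "A"), 30, replace = TRUE,
                               prob = c(.4, .4, .2)), collapse = ""), "AG")
    i <- intron_from_sequence(seq)
    hi <- classify_introner_like(i, min_frac = 0.9)$introner_like
    lo <- classify_introner_like(i, min_frac = 0.75)$introner_like
    if (hi) expect_true(lo)
  }
})

test_that("out-of-bounds exons and bad structures are rejected", {
  expect_error(introns_from_structure(
    gene_structure("g", "scaffold_1", "+", cbind(0, 10^7)), genome),
    class = "pufa_input_error")
  expect_error(gene_structure("g", "s", "+", cbind(c(0, 5), c(10, 15))),
               class = "pufa_input_error") # overlap
  expect_error(gene_structure("g", "s", "*", cbind(0, 10)),
               class = "pufa_input_error")
})

test_that("the analysis table matches the fixture truth", {
  res <- analyze_gene_structures(genome, file.path(fix_dir, "annotation.gff3"))
  expect_setequal(res$genes$gene_id, c("fed3s", "fed4s", "ctrl"))
  expect_true(res$genes$intronless[res$genes$gene_id == "fed3s"])
  third <- res$introns[res$introns$gene_id == "fed4s" & res$introns$index == 3, ]
  expect_equal(third$length, 940L)
  expect_true(third$introner_like)
})
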