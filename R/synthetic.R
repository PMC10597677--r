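# Seeded, truth-annotated synthetic fixtures.
#
# The generator emulates the statistical structure the screens assume:
# "marine"-profile samples are host contigs free of diagnostic genes;
# "freshwater"-profile samples additionally carry motif-complete
# desaturase/elongase CDSs (by default 1 elovl, 4 fed and 2 omega-x, the
# typical freshwater complement) and at least one diverged cox1 fragment;
# the genome fixture carries an intronless gene and an introner-like
# intron-bearing gene on one scaffold. All outputs are deterministic under
# (arguments, seed), and every planted element is verified against the
# corresponding screen at generation time.

SAFE_RESIDUES <- c("A", "S", "L", "V", "G", "I", "P", "F")
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

FAMILY_MOTIF_PLAN <- list(
  fed = c("HPGG", "HXXXH", "HXXXHH", "QXXHH"),
  desaturase_other = c("HPGG", "HXXXH", "HXXHH", "HXXHH"),
  wx = c("HXXXH", "HXXHH", "HXXHH"),
  elovl = c("KXXEXXDT", "NXXXHXXMYXYY", "HXXHH", "TXXQXXQ"))

FAMILY_EXPECTED <- c(fed = "FED", desaturase_other = "DESATURASE_OTHER",
                     wx = "OMEGA_X", elovl = "ELOVL")

motif_instance <- function(pattern) {
  ch <- strsplit(pattern, "")[[1]]
  ch[ch == "X"] <- sample(SAFE_RESIDUES, sum(ch == "X"), replace = TRUE)
  paste(ch, collapse = "")
}

reverse_codon_table <- function() {
  gc <- genetic_code()
  split(names(gc), unname(gc))
}

reverse_translate <- function(protein) {
  tab <- reverse_codon_table()
  codons <- vapply(strsplit(protein, "")[[1]], function(aa) {
    opts <- tab[[aa]]
    opts[sample.int(length(opts), 1)]
  }, "", USE.NAMES = FALSE)
  paste(c(codons, sample(c("TAA", "TAG", "TGA"), 1)), collapse = "")
}

#' Generate a motif-complete protein and its CDS
#'
#' Draws a uniform-random protein of the requested length with the family's
#' diagnostic motif boxes planted in order at randomized, recorded,
#' non-overlapping positions (FED variants get the HPGG heme motif
#' upstream of the first H-box; omega-x proteins are guaranteed HPGG-free).
#' The CDS is a reverse translation with uniformly chosen synonymous
#' codons, starting ATG and ending with a stop codon. The draw is repeated
#' until [classify_protein()] returns the intended family, so generated
#' truth is exact by construction.
#'
#' @param family one of `"fed"`, `"wx"`, `"elovl"`, `"desaturase_other"`.
#' @param length protein length in amino acids (leading M included); at
#'   least 150 so all boxes fit with realistic spacing.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return List with `protein`, `cds`, `family` (expected classification),
#'   and `motifs` (data frame of planted pattern, 0-based start, instance).
#' @export
make_family_protein <- function(family, length = 330, seed = NULL) {
  family <- match.arg(family, names(FAMILY_MOTIF_PLAN))
  length <- as.integer(length)
  if (length < 150) abort("length must be >= 150 aa", "pufa_parameter_error")
  plan <- FAMILY_MOTIF_PLAN[[family]]
  total <- sum(nchar(plan))
  with_seed(seed, {
    for (attempt in 1:100) {
      body_len <- length - 1L
      slack <- body_len - total
      gaps <- as.vector(stats::rmultinom(1, slack, rep(1, length(plan) + 1L)))
      instances <- vapply(plan, motif_instance, "")
      body <- sample(AA20, body_len, replace = TRUE)
      pos <- integer(length(plan))
      cursor <- 1L + gaps[1]
      for (k in seq_along(plan)) {
        pos[k] <- cursor
        idx <- cursor:(cursor + nchar(instances[k]) - 1L)
        body[idx] <- strsplit(instances[k], "")[[1]]
        cursor <- cursor + nchar(instances[k]) + gaps[k + 1L]
      }
      protein <- paste(c("M", body), collapse = "")
      if (classify_protein(protein)$family == FAMILY_EXPECTED[[family]]) {
        return(list(protein = protein,
                    cds = paste0("ATG", reverse_translate(
                      substr(protein, 2, nchar(protein)))),
                    family = FAMILY_EXPECTED[[family]],
                    motifs = data.frame(pattern = plan, start = pos,
                                        instance = unname(instances),
                                        stringsAsFactors = FALSE)))
      }
    }
    abort("failed to generate a protein with the requested classification",
          "pufa_parameter_error")
  })
}

#' Mutate a sequence with i.i.d. substitutions
#'
#' Each site is substituted, independently with probability
#' `substitution_rate`, to a uniformly chosen different base. No indels are
#' introduced, so the identity of variant versus original has the closed
#' form `100 * (1 - edits/length)`.
#'
#' @param seq nucleotide sequence (character).
#' @param substitution_rate per-site substitution probability in `[0, 0.5]`.
#' @param seed optional integer seed.
#' @return List with `sequence` (the variant) and `edits` (data frame of
#'   1-based `pos`, `ref`, `alt`).
#' @export
mutate_sequence <- function(seq, substitution_rate, seed = NULL) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (substitution_rate < 0 || substitution_rate > 0.5) {
    abort("substitution_rate must be in [0, 0.5]", "pufa_parameter_error")
  }
  seq <- toupper(seq)
  with_seed(seed, {
    ch <- strsplit(seq, "")[[1]]
    hit <- which(stats::runif(length(ch)) < substitution_rate)
    edits <- data.frame(pos = integer(0), ref = character(0),
                        alt = character(0), stringsAsFactors = FALSE)
    if (length(hit) > 0) {
      alts <- vapply(ch[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, "", USE.NAMES = FALSE)
      edits <- data.frame(pos = hit, ref = ch[hit], alt = alts,
                          stringsAsFactors = FALSE)
      ch[hit] <- alts
    }
    list(sequence = paste(ch, collapse = ""), edits = edits)
  })
}

# One host contig guaranteed to yield no classified ORF.
make_host_contig <- function(len_range = c(800, 2500), min_codons = 100) {
  for (attempt in 1:50) {
    seq <- random_dna(sample(len_range[1]:len_range[2], 1))
    orfs <- find_orfs(seq, min_codons = min_codons)
    ok <- nrow(orfs) == 0 ||
      all(vapply(orfs$protein,
                 function(p) classify_protein(p)$family == "UNCLASSIFIED", TRUE))
    if (ok) return(seq)
  }
  abort("failed to draw a clean host contig", "pufa_parameter_error")
}

# Embed a CDS in a contig with random flanks; an in-frame stop codon is
# placed immediately upstream of the ATG so the planted ORF start is exact.
embed_cds <- function(cds, strand = "+") {
  up_codons <- sample(5:20, 1)
  up <- paste0(random_dna(3L * (up_codons - 1L)), "TAA")
  down <- random_dna(sample(15:60, 1))
  contig <- paste0(up, cds, down)
  start <- nchar(up)
  end <- start + nchar(cds)
  if (strand == "-") {
    L <- nchar(contig)
    contig <- revcomp_chr(contig)
    tmp <- start
    start <- L - end
    end <- L - tmp
  }
  list(contig = contig, cds_start = start, cds_end = end)
}

#' Generate a truth-annotated synthetic sample
#'
#' Emits contigs emulating a transcriptome assembly. Host contigs are
#' random sequences screened at generation time to contain no classifiable
#' ORF. Under the `"freshwater"` profile, contaminant contigs carrying
#' motif-complete desaturase/elongase CDSs (default plan: 1 elovl, 4 fed,
#' 2 omega-x, on random strands) and one cox1 fragment diverged from a
#' bundled reference at `cox1_divergence` are planted; the `"marine"`
#' profile forces zero contaminants. Every planted CDS is verified to be
#' recovered exactly by [screen_assembly()] before being accepted.
#'
#' @param profile `"freshwater"` or `"marine"`.
#' @param n_host number of host contigs (default 15).
#' @param n_contaminant_genes number of planted gene CDSs under the
#'   freshwater profile; the family plan `elovl, fed x4, wx x2` is recycled
#'   to this length. Default 7.
#' @param cox1_divergence per-site substitution rate of the planted cox1
#'   fragment; the default 0.004 mirrors a near-identical barcode hit
#'   (about 99.6% identity).
#' @param seed integer seed; the whole sample is a deterministic function
#'   of the arguments and the seed.
#' @param min_codons ORF length threshold used for generation-time
#'   verification (keep equal to the screening threshold).
#' @return An object of class `pufa_sample`: list with `contigs`
#'   (named `DNAStringSet`) and `truth` (sample id, profile, seed,
#'   `planted_genes` and `planted_cox1` data frames).
#' @export
make_sample <- function(profile = c("freshwater", "marine"), n_host = 15,
                        n_contaminant_genes = 7, cox1_divergence = 0.004,
                        seed = 1, min_codons = 100) {
  profile <- match.arg(profile)
  if (profile == "marine") n_contaminant_genes <- 0L
  n_host <- as.integer(n_host)

  with_seed(seed, {
    contigs <- character(0)
    genes <- list()
    cox1 <- list()

    for (i in seq_len(n_host)) {
      contigs <- c(contigs, make_host_contig(min_codons = min_codons))
    }

    if (n_contaminant_genes > 0) {
      plan <- rep(c("elovl", "fed", "fed", "fed", "fed", "wx", "wx"),
                  length.out = n_contaminant_genes)
      for (fam in plan) {
        repeat {
          gene <- make_family_protein(fam, length = sample(260:380, 1))
          strand <- sample(c("+", "-"), 1)
          emb <- embed_cds(gene$cds, strand)
          scr <- screen_assembly(stats::setNames(emb$contig, "tmp"),
                                 min_codons = min_codons)
          uniq <- scr$candidates[!scr$candidates$duplicate, , drop = FALSE]
          ok <- nrow(uniq) == 1 && uniq$family == gene$family &&
            uniq$protein == gene$protein && uniq$strand == strand &&
            uniq$nt_start == emb$cds_start && uniq$nt_end == emb$cds_end
          if (ok) {
            contigs <- c(contigs, emb$contig)
            genes[[length(genes) + 1L]] <- data.frame(
              idx = length(contigs), family = gene$family, strand = strand,
              cds_start = emb$cds_start, cds_end = emb$cds_end,
              protein = gene$protein, stringsAsFactors = FALSE)
            break
          }
        }
      }

      panel <- as_dna_set(bundled_cox1_panel())
      ref_i <- sample.int(length(panel), 1)
      mut <- mutate_sequence(as.character(panel[[ref_i]]), cox1_divergence)
      contigs <- c(contigs, mut$sequence)
      cox1[[1]] <- data.frame(
        idx = length(contigs), reference_id = names(panel)[ref_i],
        n_substitutions = nrow(mut$edits),
        substitution_positions = I(list(mut$edits$pos)),
        divergence = cox1_divergence, stringsAsFactors = FALSE)
    }

    ord <- sample.int(length(contigs))
    ids <- sprintf("NODE_%03d", seq_along(contigs))
    names(contigs)[ord] <- ids
    dna <- Biostrings::DNAStringSet(contigs[order(names(contigs))])

    remap <- stats::setNames(names(contigs), as.character(seq_along(contigs)))
    planted_genes <- if (length(genes)) {
      df <- do.call(rbind, genes)
      df$contig_id <- unname(remap[as.character(df$idx)])
      df[, c("contig_id", "family", "strand", "cds_start", "cds_end", "protein")]
    } else data.frame(contig_id = character(0), family = character(0),
                      strand = character(0), cds_start = integer(0),
                      cds_end = integer(0), protein = character(0),
                      stringsAsFactors = FALSE)
    planted_cox1 <- if (length(cox1)) {
      df <- do.call(rbind, cox1)
      df$contig_id <- unname(remap[as.character(df$idx)])
      df[, c("contig_id", "reference_id", "n_substitutions",
             "substitution_positions", "divergence")]
    } else data.frame(contig_id = character(0), reference_id = character(0),
                      n_substitutions = integer(0),
                      substitution_positions = I(list()),
                      divergence = numeric(0), stringsAsFactors = FALSE)

    structure(list(
      contigs = dna,
      truth = list(sample_id = sprintf("%s_seed%d", profile, seed),
                   profile = profile, seed = seed,
                   planted_genes = planted_genes,
                   planted_cox1 = planted_cox1,
                   n_host = n_host)),
      class = "pufa_sample")
  })
}

#' @export
print.pufa_sample <- function(x, ...) {
  cat(sprintf("<pufa_sample %s: %d contigs, %d planted genes, %d cox1>\n",
              x$truth$sample_id, length(x$contigs),
              nrow(x$truth$planted_genes), nrow(x$truth$planted_cox1)))
  invisible(x)
}

#' Write a synthetic sample to disk
#'
#' @param sample a [make_sample()] result.
#' @param out_dir output directory (created if needed); writes
#'   `contigs.fasta` and `truth.json`.
#' @return Invisibly, the written paths.
#' @export
write_sample <- function(sample, out_dir) {
  stopifnot(inherits(sample, "pufa_sample"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(out_dir, "contigs.fasta")
  Biostrings::writeXStringSet(sample$contigs, fa)
  tj <- file.path(out_dir, "truth.json")
  truth <- sample$truth
  truth$planted_cox1$substitution_positions <-
    lapply(truth$planted_cox1$substitution_positions, as.integer)
  jsonlite::write_json(truth, tj, auto_unbox = TRUE, digits = NA)
  invisible(c(fa, tj))
}

# ---- genomic fixture -------------------------------------------------------

canonical_intron <- function(len) {
  paste0("GT", random_dna(len - 4L), "AG")
}

# 40-nt window (purines / 12-nt tract / purines) preceding the terminal AG.
# The tract holds 10 pyrimidines and 2 internal purines so that it is the
# unique longest run with pyrimidine fraction >= 0.8: extending it by one
# purine gives 10/13 < 0.8.
tract_window <- function(with_tract = TRUE) {
  purine <- function(n) paste(sample(c("A", "G"), n, replace = TRUE),
                              collapse = "")
  if (!with_tract) return(purine(40L))
  pyr <- sample(c("C", "T"), 12, replace = TRUE)
  pyr[c(4, 8)] <- sample(c("A", "G"), 2, replace = TRUE)
  paste0(purine(20L), paste(pyr, collapse = ""), purine(8L))
}

#' Generate an annotated genomic scaffold fixture
#'
#' One scaffold carrying three genes: an intronless gene (`fed3s`; the
#' motivating genome has an intronless fed3), a plus-strand four-intron
#' gene (`fed4s`) whose third intron is 940 bp with canonical GT/AG splice
#' sites and a planted 3' polypyrimidine tract (the introner-like
#' configuration), and a minus-strand control gene (`ctrl`) with a
#' non-canonical AT..AC intron. Emitted together with a GFF3 annotation
#' and a truth list.
#'
#' @param seed integer seed.
#' @param third_intron_tract set `FALSE` to emit the `fed4s` third intron
#'   without a polypyrimidine tract (negative-control variant).
#' @return An object of class `pufa_genome_fixture`: list with `genome`
#'   (named `DNAStringSet`), `gff` (character vector of GFF3 lines) and
#'   `truth`.
#' @export
make_genome_fixture <- function(seed = 1, third_intron_tract = TRUE) {
  with_seed(seed, {
    scaffold_id <- "scaffold_1"
    parts <- character(0)
    cursor <- 0L
    append_part <- function(seq) {
      parts[[length(parts) + 1L]] <<- seq
      start <- cursor
      cursor <<- cursor + nchar(seq)
      c(start, cursor) # 0-based half-open
    }

    append_part(random_dna(200))

    # fed3s: intronless, +
    fed3_exon <- append_part(random_dna(1200))
    append_part(random_dna(300))

    # fed4s: 5 exons / 4 introns, +; third intron 940 bp introner-like
    exon_lens <- c(220L, 180L, 160L, 150L, 140L)
    intron_lens <- c(120L, 95L, 940L, 110L)
    fed4_exons <- list(); fed4_introns <- list()
    tract_local <- NULL
    for (k in 1:5) {
      fed4_exons[[k]] <- append_part(random_dna(exon_lens[k]))
      if (k < 5) {
        if (k == 3) {
          mid_len <- 940L - 2L - 40L - 2L
          w <- tract_window(third_intron_tract)
          iseq <- paste0("GT", random_dna(mid_len), w, "AG")
          if (third_intron_tract) {
            tract_local <- c(start = 2L + mid_len + 20L + 1L,
                             end = 2L + mid_len + 20L + 12L)
          }
        } else {
          iseq <- canonical_intron(intron_lens[k])
        }
        fed4_introns[[k]] <- append_part(iseq)
      }
    }
    append_part(random_dna(250))

    # ctrl: 2 exons, -; non-canonical intron (AT..AC in transcription sense)
    ctrl_exon1 <- append_part(random_dna(300))
    ctrl_intron_tx <- paste0("AT", random_dna(196), "AC")
    ctrl_intron <- append_part(revcomp_chr(ctrl_intron_tx))
    ctrl_exon2 <- append_part(random_dna(280))
    append_part(random_dna(150))

    genome <- stats::setNames(
      Biostrings::DNAStringSet(paste(unlist(parts), collapse = "")),
      scaffold_id)

    gff1 <- function(id, parent, type, span, strand) {
      attrs <- if (is.na(parent)) sprintf("ID=%s", id)
               else sprintf("ID=%s;Parent=%s", id, parent)
      sprintf("%s\tpufascreen\t%s\t%d\t%d\t.\t%s\t.\t%s",
              scaffold_id, type, span[1] + 1L, span[2], strand, attrs)
    }
    gene_block <- function(name, strand, exon_spans) {
      span <- c(min(vapply(exon_spans, `[`, 0L, 1)),
                max(vapply(exon_spans, `[`, 0L, 2)))
      c(gff1(paste0("gene:", name), NA, "gene", span, strand),
        gff1(name, paste0("gene:", name), "mRNA", span, strand),
        vapply(seq_along(exon_spans), function(e) {
          gff1(sprintf("%s.exon%d", name, e), name, "exon",
               exon_spans[[e]], strand)
        }, ""))
    }
    gff <- c("##gff-version 3",
             gene_block("fed3s", "+", list(fed3_exon)),
             gene_block("fed4s", "+", fed4_exons),
             gene_block("ctrl", "-", list(ctrl_exon1, ctrl_exon2)))

    truth <- list(
      scaffold_id = scaffold_id, seed = seed,
      genes = list(
        fed3s = list(intronless = TRUE, n_exons = 1),
        fed4s = list(intronless = FALSE, n_exons = 5,
                     intron_lengths = intron_lens,
                     third_intron = list(
                       length = 940L,
                       start = fed4_introns[[3]][1],
                       end = fed4_introns[[3]][2],
                       canonical = TRUE,
                       tract_present = isTRUE(third_intron_tract),
                       tract_start = unname(tract_local["start"]),
                       tract_end = unname(tract_local["end"]))),
        ctrl = list(intronless = FALSE, n_exons = 2, canonical = FALSE)))

    structure(list(genome = genome, gff = gff, truth = truth),
              class = "pufa_genome_fixture")
  })
}

#' Write a genome fixture to disk
#'
#' @param fixture a [make_genome_fixture()] result.
#' @param out_dir output directory; writes `genome.fasta`,
#'   `annotation.gff3` and `truth.json`.
#' @return Invisibly, the written paths.
#' @export
write_genome_fixture <- function(fixture, out_dir) {
  stopifnot(inherits(fixture, "pufa_genome_fixture"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(out_dir, "genome.fasta")
  Biostrings::writeXStringSet(fixture$genome, fa)
  gff <- file.path(out_dir, "annotation.gff3")
  writeLines(fixture$gff, gff)
  tj <- file.path(out_dir, "truth.json")
  jsonlite::write_json(fixture$truth, tj, auto_unbox = TRUE, digits = NA)
  invisible(c(fa, gff, tj))
}
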