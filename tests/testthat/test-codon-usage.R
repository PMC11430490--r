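test_that("vertebrate mitochondrial code has its diagnostic reassignments", {
  code <- mito_genetic_code()
  expect_equal(unname(code$codon_to_aa[c("TGA", "ATA")]), c("W", "M"))
  expect_setequal(code$stop_codons, c("TAA", "TAG", "AGA", "AGG"))
})

test_that("translate_cds translates, flags stops, reports remainders", {
  expect_equal(translate_cds("ATGTGA")$protein, "MW")
  tr <- translate_cds("ATAAGA")
  expect_equal(tr$protein, "M*")
  expect_equal(tr$remainder, "")
  tr2 <- translate_cds("ATGTAAATG")  # stop at codon 2 of 3
  expect_equal(tr2$internal_stops, 2L)
  tr3 <- translate_cds("ATGGCCTA")
  expect_equal(tr3$protein, "MA")
  expect_equal(tr3$remainder, "TA")
  expect_error(translate_cds("AT"), "shorter")

  # per-codon oracle via Biostrings on a random 300-codon CDS
  withr::with_seed(41L, {
    cds <- random_dna(900)
    expect_equal(
      translate_cds(cds)$protein,
      as.character(Biostrings::translate(
        Biostrings::DNAString(cds),
        genetic.code = Biostrings::getGeneticCode("2"))))
  })
})

test_that("terminal codon classification covers the biological classes", {
  build <- function(cds) {
    g <- circular_sequence(paste0(cds, "ACGTACGTACGT"))
    ann <- mitogenome_annotation(rbind(
      gene_feature("p", "PCG", 1, nchar(cds), "+"),
      gene_feature("cr", "control_region", nchar(cds) + 1, g$length, "+")),
      g$length)
    classify_terminal_codons(ann, g)
  }
  canonical <- build("ATGCCCAAATAA")
  expect_equal(canonical$start_class, "canonical-ATN")
  expect_equal(canonical$stop_class, "complete")
  alt <- build("TTGCCCAAATAA")
  expect_equal(alt$start_class, "alternative")
  incomplete <- build("ATGCCCAAAT")  # 1-base T remainder
  expect_equal(incomplete$stop_class, "incomplete")
  expect_equal(incomplete$stop_codon, "T")
  bad <- build("CCGCCCAAACCC")
  expect_equal(bad$start_class, "invalid")
  expect_equal(bad$stop_class, "invalid")
})

test_that("RSCU follows the family-size formula", {
  code <- mito_genetic_code()
  counts <- setNames(integer(64), mitoprofile:::all_codon_names())
  counts[c("ATG", "ATA")] <- c(2L, 2L)  # Met family, uniform
  r <- rscu(counts, code)
  expect_equal(unname(r[c("ATG", "ATA")]), c(1, 1))
  counts[] <- 0L
  counts[c("TGA", "TGG")] <- c(3L, 1L)  # Trp family under table 2
  r <- rscu(counts, code)
  expect_equal(unname(r[c("TGA", "TGG")]), c(1.5, 0.5))
  counts[] <- 0L
  leu <- names(code$codon_to_aa)[code$codon_to_aa == "L"]
  expect_length(leu, 6L)
  counts[leu[1]] <- 6L
  r <- rscu(counts, code)
  expect_equal(unname(r[leu[1]]), 6)
  expect_true(all(r[leu[-1]] == 0))
  counts[1] <- -1L
  expect_error(rscu(counts, code), "negative")
})

test_that("RSCU family sums equal family size on random counts", {
  code <- mito_genetic_code()
  sense <- setdiff(names(code$codon_to_aa), code$stop_codons)
  withr::with_seed(51L, {
    for (i in 1:50) {
      counts <- setNames(rpois(64, sample(c(0.5, 3, 20), 1)),
                         mitoprofile:::all_codon_names())
      r <- rscu(counts, code)
      aa <- code$codon_to_aa[sense]
      for (a in unique(aa)) {
        fam <- sense[aa == a]
        if (sum(counts[fam]) > 0) {
          expect_equal(sum(r[fam]), length(fam))
        } else {
          expect_true(all(r[fam] == 0))
        }
      }
    }
  })
})

test_that("amino-acid frequencies are percentages over PCG residues", {
  toy <- toy_pcg_genome("ATGGCTGCATAA")
  freq <- aa_frequencies(toy$annotation, toy$genome)
  expect_equal(unname(freq["M"]), 100 / 3, tolerance = 1e-12)
  expect_equal(unname(freq["A"]), 200 / 3, tolerance = 1e-12)
  expect_equal(sum(freq), 100, tolerance = 1e-9)

  uniform <- toy_pcg_genome(paste0("ATG", strrep("CCC", 20), "TAA"))
  f2 <- aa_frequencies(uniform$annotation, uniform$genome)
  expect_equal(unname(f2["P"]), 100 * 20 / 21)  # 21 residues, stop excluded

  sim <- default_sim()
  expect_equal(sum(aa_frequencies(sim$annotation, sim$genome)), 100,
               tolerance = 1e-9)
})

test_that("codon counts are additive over genes", {
  sim <- default_sim()
  seqs <- mitoprofile:::pcg_sequences(sim$annotation, sim$genome)
  total <- codon_counts(seqs)
  per_gene <- lapply(seqs, codon_counts)
  summed <- Reduce(`+`, per_gene)
  expect_equal(as.vector(total), as.vector(summed))
  cut <- codon_usage_table(sim$annotation, sim$genome)
  expect_equal(sum(cut$table$count), sum(total[cut$table$codon]))
})
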