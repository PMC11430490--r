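test_that("global alignment scores and tie-breaks deterministically", {
  a <- global_align("ACGT", "ACGT")
  expect_equal(a$score, 4)
  expect_equal(a$ref, "ACGT")
  expect_equal(a$query, "ACGT")
  b <- global_align("ACGT", "AGGT")
  expect_equal(b$score, 2)
  expect_equal(nchar(b$ref), 4L)  # one substitution column, no gaps
  g <- global_align("ACGTACGT", "ACGTTACGT")
  expect_equal(g$score, 8 - 5)  # one 1-bp gap: open -4, extend -1
  expect_error(global_align("", "ACGT"), "non-empty")
})

test_that("alignment equals an independent implementation on random pairs", {
  withr::with_seed(81L, {
    for (i in 1:25) {
      n <- sample(30:120, 1)
      a <- random_dna(n)
      # mutate a into b: a few substitutions and indels
      b <- a
      for (k in 1:3) {
        p <- sample(nchar(b) - 4, 1)
        b <- paste0(substr(b, 1, p - 1),
                    sample(c("A", "C", "G", "T"), 1),
                    substr(b, p + 1, nchar(b)))
      }
      p <- sample(nchar(b) - 6, 1)
      b <- paste0(substr(b, 1, p), random_dna(2), substr(b, p + 1, nchar(b)))
      expect_equal(global_align(a, b)$score, oracle_align_score(a, b))
    }
    # a 2 kb pair with known edits: same optimal score as the oracle
    a <- random_dna(2000)
    b <- paste0(substr(a, 1, 700), substr(a, 704, 1400), "GGAT",
                substr(a, 1401, 2000))
    expect_equal(global_align(a, b)$score, oracle_align_score(a, b))
    # banded result matches the unbanded optimum when the band is ample
    expect_equal(global_align(a, b, band = 50)$score,
                 global_align(a, b)$score)
  })
})

test_that("gap removal recovers the aligned inputs", {
  withr::with_seed(91L, {
    a <- random_dna(200)
    b <- paste0(substr(a, 1, 90), substr(a, 95, 200))
    aln <- global_align(a, b)
    expect_equal(gsub("-", "", aln$ref), a)
    expect_equal(gsub("-", "", aln$query), b)
    expect_equal(nchar(aln$ref), nchar(aln$query))
  })
})

test_that("call_variants merges indel runs and assigns features", {
  ann <- mitogenome_annotation(rbind(
    gene_feature("nad1", "PCG", 50, 250, "+"),
    gene_feature("cr", "control_region", 260, 300, "+")), 300)
  withr::with_seed(101L, {
    ref <- random_dna(300)
    # single mismatch at position 100 (inside nad1)
    q <- ref
    old <- substr(ref, 100, 100)
    substr(q, 100, 100) <- setdiff(c("A", "C", "G", "T"), old)[1]
    v <- call_variants(global_align(ref, q), ann)
    expect_equal(nrow(v), 1L)
    expect_equal(v$type, "substitution")
    expect_equal(v$ref_position, 100L)
    expect_equal(v$feature_name, "nad1")
    # three adjacent deleted bases collapse to one record
    q2 <- paste0(substr(ref, 1, 150), substr(ref, 154, 300))
    v2 <- call_variants(global_align(ref, q2), ann)
    expect_equal(nrow(v2), 1L)
    expect_equal(v2$type, "deletion")
    expect_equal(nchar(v2$ref_allele), 3L)
    expect_equal(v2$alt_allele, ".")
    # identical inputs: no variants
    expect_equal(nrow(call_variants(global_align(ref, ref), ann)), 0L)
  })
})

test_that("indels are left-aligned to canonical positions", {
  # deleting either TA from TATA is reported at the leftmost position
  ref <- "GGGTATACCC"
  q <- "GGGTACCC"
  v <- call_variants(global_align(ref, q))
  expect_equal(v$type, "deletion")
  expect_equal(v$ref_position, 4L)
  # inserting an extra A into an A-run anchors before the run
  ref2 <- "GGCAAAGG"
  q2 <- "GGCAAAAGG"
  v2 <- call_variants(global_align(ref2, q2))
  expect_equal(v2$type, "insertion")
  expect_equal(v2$ref_position, 3L)
  expect_equal(v2$alt_allele, "A")
})

test_that("called variants reapply to reconstruct the query", {
  withr::with_seed(111L, {
    for (i in 1:20) {
      ref <- random_dna(400)
      g <- circular_sequence(ref)
      mut <- mutate_genome(g, NULL, mutation_plan(4, 1, 2, 3, 30, seed = i))
      aln <- global_align(ref, mut$genome$residues)
      v <- call_variants(aln)
      expect_identical(apply_variants(ref, v), mut$genome$residues)
    }
  })
})

test_that("consequences classify codon changes under the mito code", {
  # gene of 30 codons; codon 12 is ACT (Thr)
  cds <- paste0("ATG", strrep("GGA", 10), "ACT", strrep("GGA", 17), "TAA")
  g <- circular_sequence(paste0(cds, "ACGTACGTACGTACGT"))
  ann <- mitogenome_annotation(rbind(
    gene_feature("p", "PCG", 1, nchar(cds), "+"),
    gene_feature("cr", "control_region", nchar(cds) + 1, g$length, "+")),
    g$length)
  pos_mid <- 3 * 11 + 2  # middle base of codon 12
  v <- data.frame(ref_position = pos_mid, type = "substitution",
                  ref_allele = "C", alt_allele = "T",
                  feature_name = "p", stringsAsFactors = FALSE)
  cons <- annotate_consequences(v, ann, g)
  expect_equal(cons$effect, "missense")
  expect_equal(cons$codon_index, 12L)
  expect_equal(cons$ref_aa, "T")  # threonine
  expect_equal(cons$alt_aa, "I")  # isoleucine

  # ATG -> ATA at codon 1 is synonymous (both Met under table 2)
  v2 <- data.frame(ref_position = 3, type = "substitution",
                   ref_allele = "G", alt_allele = "A",
                   feature_name = "p", stringsAsFactors = FALSE)
  cons2 <- annotate_consequences(v2, ann, g)
  expect_equal(cons2$effect, "synonymous")
  expect_equal(cons2$ref_aa, "M")
  expect_equal(cons2$alt_aa, "M")

  # 1-bp deletion: frameshift; 3-bp: inframe
  v3 <- data.frame(ref_position = c(40, 70),
                   type = "deletion",
                   ref_allele = c("G", "GGA"), alt_allele = ".",
                   feature_name = "p", stringsAsFactors = FALSE)
  cons3 <- annotate_consequences(v3, ann, g)
  expect_equal(cons3$effect, c("frameshift", "inframe"))

  # control-region variant is noncoding
  v4 <- data.frame(ref_position = nchar(cds) + 5, type = "substitution",
                   ref_allele = "C", alt_allele = "G",
                   feature_name = "cr", stringsAsFactors = FALSE)
  expect_equal(annotate_consequences(v4, ann, g)$effect, "noncoding")
  v5 <- v4
  v5$ref_position <- 99999L
  expect_error(annotate_consequences(v5, ann, g), "outside")
})

test_that("minus-strand genes are evaluated on the coding strand", {
  cds <- paste0("ATG", strrep("CAT", 8), "TAA")  # His codons
  g <- circular_sequence(paste0("AAGGTT", revcomp(cds), "GGCCTTA"))
  ann <- mitogenome_annotation(rbind(
    gene_feature("m", "PCG", 7, 6 + nchar(cds), "-"),
    gene_feature("cr", "control_region", 7 + nchar(cds), g$length, "+")),
    g$length)
  expect_equal(translate_cds(extract_feature_sequence(
    g, ann$features[ann$features$name == "m", ]))$protein,
    paste0("M", strrep("H", 8), "*"))
  # substitute the H-strand base pairing with codon 2 position 1 (C on
  # the coding strand): genome position = start + (len - 4)
  f <- ann$features[ann$features$name == "m", ]
  h_pos <- f$stop - 3L  # coding offset 4
  ref_b <- substr(g$residues, h_pos, h_pos)
  alt_coding <- "T"  # CAT -> TAT: His -> Tyr
  v <- data.frame(ref_position = h_pos, type = "substitution",
                  ref_allele = ref_b,
                  alt_allele = chartr("ACGTN", "TGCAN", alt_coding),
                  feature_name = "m", stringsAsFactors = FALSE)
  cons <- annotate_consequences(v, ann, g)
  expect_equal(cons$codon_index, 2L)
  expect_equal(cons$ref_aa, "H")
  expect_equal(cons$alt_aa, "Y")
  expect_equal(cons$effect, "missense")
})

test_that("variants in overlapping genes yield one record per gene", {
  sim <- default_sim()
  f <- sim$annotation$features
  atp8 <- f[f$name == "atp8", ]
  pos <- atp8$stop - 10L  # inside the atp8/atp6 overlap
  ref_b <- substr(sim$genome$residues, pos, pos)
  v <- data.frame(ref_position = pos, type = "substitution",
                  ref_allele = ref_b,
                  alt_allele = setdiff(c("A", "C", "G", "T"), ref_b)[1],
                  feature_name = "atp8", stringsAsFactors = FALSE)
  cons <- annotate_consequences(v, sim$annotation, sim$genome)
  expect_setequal(cons$gene, c("atp8", "atp6"))
})

test_that("diff_summary tabulates types, classes and changing positions", {
  sim <- default_sim()
  mut <- mutate_genome(sim$genome, sim$annotation,
                       mutation_plan(5, 2, 3, 2, 100, seed = 3))
  cmp <- compare_genomes(sim$genome, sim$annotation, mut$genome)
  s <- cmp$summary
  expect_equal(s$n_variants, 10L)
  expect_equal(s$n_substitutions, 5L)
  expect_equal(s$n_insertions, 2L)
  expect_equal(s$n_deletions, 3L)
  expect_equal(s$n_variants,
               s$n_substitutions + s$n_insertions + s$n_deletions)
  expect_true(s$n_aa_changing <= s$n_variants)
  empty <- diff_summary(mitoprofile:::empty_variants(),
                        annotate_consequences(
                          mitoprofile:::empty_variants(),
                          sim$annotation, sim$genome))
  expect_equal(empty$n_variants, 0L)
  expect_equal(empty$n_aa_changing, 0L)
})

test_that("VCF and TSV variant reports are written", {
  sim <- default_sim()
  mut <- mutate_genome(sim$genome, sim$annotation,
                       mutation_plan(3, 1, 1, 2, 200, seed = 9))
  cmp <- compare_genomes(sim$genome, sim$annotation, mut$genome)
  dir <- withr::local_tempdir()
  paths <- write_variant_reports(cmp, sim$genome, dir)
  expect_true(all(file.exists(paths)))
  vcf <- readLines(file.path(dir, "variants.vcf"))
  expect_equal(vcf[1], "##fileformat=VCFv4.2")
  body <- vcf[!startsWith(vcf, "#")]
  expect_equal(length(body), 5L)
  expect_true(all(grepl("TYPE=", body)))
})
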