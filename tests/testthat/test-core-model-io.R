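test_that("circular_sequence validates and normalizes residues", {
  g <- circular_sequence("acgtn", id = "t")
  expect_equal(g$residues, "ACGTN")
  expect_equal(g$length, 5L)
  expect_error(circular_sequence("ACGX"), "position 4")
  expect_error(circular_sequence(""), "at least one residue")
})

test_that("FASTA round-trips, including a full-size synthetic genome", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  g <- circular_sequence("ACGT", id = "mini")
  write_fasta(g, tmp)
  expect_equal(read_fasta(tmp)$residues, "ACGT")
  expect_equal(read_fasta(tmp)$length, 4L)

  # lowercase input is uppercased on construction, so identical after read
  writeLines(c(">x", "acgtn"), tmp)
  expect_equal(read_fasta(tmp)$residues, "ACGTN")

  sim <- default_sim()
  write_fasta(sim$genome, tmp)
  back <- read_fasta(tmp)
  expect_identical(back$residues, sim$genome$residues)
  expect_equal(back$length, 16541L)

  writeLines(c(">a", "ACGT", ">b", "ACGT"), tmp)
  expect_error(read_fasta(tmp), "found 2")
})

test_that("feature table reader handles the published layout verbatim", {
  ann <- douc_annotation()
  expect_s3_class(ann, "MitogenomeAnnotation")
  expect_equal(nrow(ann$features), 38L)  # 37 genes + control region
  nad4l <- ann$features[ann$features$name == "nad4l", ]
  expect_equal(nad4l$start, 10032L)  # read through thousands separators
  expect_equal(nad4l$stop, 10325L)
  lens <- vapply(names(table1_lengths), function(nm) {
    feature_length(ann$features[ann$features$name == nm, ], 16541L)
  }, integer(1))
  expect_equal(lens, table1_lengths[names(lens)], ignore_attr = FALSE)
})

test_that("feature table validation rejects malformed rows", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tclass\tstart\tstop\tstrand",
               "g1\tPCG\t1\t9\tx"), tmp)
  expect_error(read_feature_table(tmp, 100), "strand")
  writeLines(c("name\tclass\tstart\tstop\tstrand",
               "g1\tPCG\t1\t200\t+"), tmp)
  expect_error(read_feature_table(tmp, 100), "outside")
  writeLines(c("name\tclass\tstart\tstop\tstrand",
               "g1\tPCG\t1\t9\t+", "g1\tPCG\t20\t28\t+"), tmp)
  expect_error(read_feature_table(tmp, 100), "duplicate")
})

test_that("feature table writing round-trips the record set", {
  ann <- douc_annotation()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ann, tmp)
  back <- read_feature_table(tmp, 16541)
  expect_equal(back$features, ann$features)
})

test_that("feature_length handles wrapping and degenerate spans", {
  expect_equal(feature_length(
    gene_feature("nad5", "PCG", 11902, 13701, "+"), 16541), 1800L)
  expect_equal(feature_length(
    gene_feature("cr", "control_region", 15584, 136, "+"), 16541), 1094L)
  expect_equal(feature_length(gene_feature("x", "tRNA", 5, 5, "+"), 10), 1L)
})

test_that("extract_feature_sequence respects strand and wrapping", {
  g <- circular_sequence("AAACCC")
  expect_equal(extract_feature_sequence(
    g, gene_feature("a", "tRNA", 1, 3, "+")), "AAA")
  expect_equal(extract_feature_sequence(
    g, gene_feature("a", "tRNA", 1, 3, "-")), "TTT")
  expect_equal(extract_feature_sequence(
    g, gene_feature("a", "tRNA", 5, 2, "+")), "CCAA")
  # brute-force check of every (start, stop, strand) on the 6-mer
  chars <- strsplit(g$residues, "")[[1L]]
  for (s in 1:6) for (e in 1:6) {
    f <- gene_feature("f", "tRNA", s, e, "+")
    idx <- if (e >= s) s:e else c(s:6, 1:e)
    expect_equal(extract_feature_sequence(g, f),
                 paste(chars[idx], collapse = ""))
    fm <- gene_feature("f", "tRNA", s, e, "-")
    expect_equal(extract_feature_sequence(g, fm),
                 revcomp(paste(chars[idx], collapse = "")))
    # reverse-complementing a minus-strand extraction twice is the identity
    expect_equal(revcomp(revcomp(extract_feature_sequence(g, fm))),
                 extract_feature_sequence(g, fm))
  }
})

test_that("rotate_to_anchor rotates, flips and shifts annotation", {
  g <- circular_sequence("CCAATT")
  expect_equal(rotate_to_anchor(g, "AA")$residues, "AATTCC")
  expect_equal(rotate_to_anchor(circular_sequence("AATTCC"), "AA")$residues,
               "AATTCC")
  expect_error(rotate_to_anchor(g, "C"), "2 times")
  expect_error(rotate_to_anchor(g, "GGG"), "not found")

  # a randomly rotated synthetic genome re-anchors to the original
  sim <- default_sim()
  anchor <- substr(sim$genome$residues, 1, 40)
  rotated <- mitoprofile:::rotate_genome(sim$genome, 5000L)
  back <- rotate_to_anchor(rotated, anchor, sim$annotation)
  expect_identical(back$genome$residues, sim$genome$residues)

  # reverse-strand anchor: genome is flipped first
  rc <- circular_sequence(revcomp(sim$genome$residues))
  back2 <- rotate_to_anchor(rc, anchor)
  expect_identical(back2$residues, sim$genome$residues)
})

test_that("GenBank reader maps CDS/tRNA/rRNA/D-loop onto the model", {
  gb <- c(
    "LOCUS       TOY0001     60 bp    DNA     circular",
    "FEATURES             Location/Qualifiers",
    "     CDS             5..22",
    "                     /gene=\"nad9\"",
    "     tRNA            complement(25..40)",
    "                     /product=\"tRNA-Phe\"",
    "     D-loop          join(51..60,1..4)",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac",
    "       51 acgtacgtac",
    "//")
  tmp <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, tmp)
  out <- read_genbank(tmp)
  expect_equal(out$genome$length, 60L)
  f <- out$annotation$features
  expect_setequal(f$name, c("nad9", "tRNA-Phe", "control_region"))
  expect_equal(f$strand[f$name == "tRNA-Phe"], "-")
  cr <- f[f$name == "control_region", ]
  expect_equal(c(cr$start, cr$stop), c(51L, 4L))  # collapsed wrap
  expect_equal(f$class[f$name == "nad9"], "PCG")
})
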