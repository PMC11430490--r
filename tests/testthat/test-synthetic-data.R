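test_that("default layout realizes the published genome accounting", {
  lay <- default_layout()
  expect_equal(attr(lay, "genome_length"), 16541L)
  expect_equal(sum(lay$class == "PCG"), 13L)
  expect_equal(sum(lay$length[lay$class == "PCG"]), 11292L)
  expect_equal(sum(lay$class == "tRNA"), 22L)
  expect_equal(sum(lay$class == "rRNA"), 2L)
  expect_equal(lay$gap_to_next[lay$name == "atp8"], -22L)
  expect_equal(lay$length[lay$name == "control_region"], 1094L)
  # every protein-coding length is a whole number of codons
  expect_true(all(lay$length[lay$class == "PCG"] %% 3L == 0L))
})

test_that("layout_spec rejects infeasible layouts", {
  bad <- data.frame(name = c("a", "b"), class = c("PCG", "tRNA"),
                    length = c(30L, 10L), strand = "+",
                    gap_to_next = c(-15L, 0L))
  expect_error(layout_spec(bad), "overlap longer")
  bad2 <- data.frame(name = "a", class = "PCG", length = -3L,
                     strand = "+", gap_to_next = 0L)
  expect_error(layout_spec(bad2), "positive")
})

test_that("generation is deterministic and realizes the layout exactly", {
  lay <- default_layout()
  s1 <- suppressWarnings(generate_genome(lay, 0.614, seed = 42))
  s2 <- suppressWarnings(generate_genome(lay, 0.614, seed = 42))
  expect_identical(s1$genome$residues, s2$genome$residues)
  s3 <- suppressWarnings(generate_genome(lay, 0.614, seed = 43))
  expect_false(identical(s1$genome$residues, s3$genome$residues))

  expect_equal(s1$genome$length, 16541L)
  sp <- spacer_overlap_table(s1$annotation)
  expect_equal(setNames(sp$gap, sp$upstream_name)[lay$name],
               setNames(lay$gap_to_next, lay$name))
})

test_that("generated coding genes satisfy the mito-code constraints", {
  sim <- default_sim()
  tc <- classify_terminal_codons(sim$annotation, sim$genome)
  expect_true(all(tc$start_codon == "ATG"))
  expect_equal(sum(tc$n_internal_stops), 0L)
  # nad4l's stop is provably unrealizable: nad4's ATG overlaps its last
  # codon, fixing it to TG|A - exactly as in the real annotation
  expect_true(all(tc$stop_class[tc$gene != "nad4l"] == "complete"))
  expect_warning(
    generate_genome(default_layout(), 0.614, seed = 5),
    "nad4l")
})

test_that("A+T targeting works across targets and toy layouts", {
  toy <- layout_spec(data.frame(
    name = c("p1", "cr"), class = c("PCG", "control_region"),
    length = c(600L, 400L), strand = "+", gap_to_next = c(0L, 0L)))
  for (target in c(0.5, 0.65)) {
    sim <- generate_genome(toy, target, seed = 8, first_start = 1)
    at <- skew_profile(sim$genome$residues)$at_content
    expect_lt(abs(at - target), 0.02)
  }
})

test_that("background skew balances are tunable", {
  toy <- layout_spec(data.frame(
    name = c("t1", "cr"), class = c("tRNA", "control_region"),
    length = c(2000L, 2000L), strand = "+", gap_to_next = c(0L, 0L)))
  sim <- generate_genome(toy, 0.6, seed = 9, a_balance = 0.7,
                         g_balance = 0.5, first_start = 1)
  p <- skew_profile(sim$genome$residues)
  expect_gt(p$at_skew, 0.3)  # 0.7 vs 0.3 split implies skew ~ 0.4
  expect_lt(abs(p$gc_skew), 0.1)
})

test_that("mutation plans implant exactly the requested truth set", {
  sim <- default_sim()
  plan <- mutation_plan(30, 4, 9, max_indel = 3, min_spacing = 50, seed = 7)
  mut <- mutate_genome(sim$genome, sim$annotation, plan)
  expect_equal(nrow(mut$truth), 43L)
  expect_equal(sum(mut$truth$type == "substitution"), 30L)
  expect_equal(sum(mut$truth$type == "insertion"), 4L)
  expect_equal(sum(mut$truth$type == "deletion"), 9L)
  # determinism
  mut2 <- mutate_genome(sim$genome, sim$annotation, plan)
  expect_identical(mut$genome$residues, mut2$genome$residues)
  expect_equal(mut$truth, mut2$truth)
  # spacing respected
  expect_true(all(diff(sort(mut$truth$ref_position)) >= 40L))

  none <- mutate_genome(sim$genome, sim$annotation,
                        mutation_plan(0, 0, 0, seed = 1))
  expect_identical(none$genome$residues, sim$genome$residues)
  expect_equal(nrow(none$truth), 0L)

  tiny <- circular_sequence(strrep("ACGT", 30))
  expect_error(
    mutate_genome(tiny, NULL, mutation_plan(50, 0, 0, min_spacing = 50)),
    "infeasible")
})

test_that("simulation bundle writes FASTA, features and truth", {
  dir <- withr::local_tempdir()
  cfg <- run_config(seed = 4L, n_substitutions = 3L, n_insertions = 1L,
                    n_deletions = 1L)
  out <- suppressWarnings(simulate_files(dir, cfg))
  expect_true(file.exists(file.path(dir, "genome.fasta")))
  expect_true(file.exists(file.path(dir, "features.tsv")))
  expect_true(file.exists(file.path(dir, "truth_variants.tsv")))
  expect_true(file.exists(file.path(dir, "mutated.fasta")))
  back <- read_fasta(file.path(dir, "genome.fasta"))
  expect_identical(back$residues, out$genome$residues)
  ann <- read_feature_table(file.path(dir, "features.tsv"), back$length)
  expect_equal(ann$features, out$annotation$features)
  expect_equal(nrow(out$truth), 5L)
})
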