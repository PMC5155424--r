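test_that("classification precedence assigns one class per variant", {
  # fixture: residue 1 contacts the heme (4.31 A, toward), residues 2-5 are
  # far from it; positions beyond 5 are unresolved
  placements <- tibble::tibble(
    residue_name = c("LEU", "ALA", "VAL", "ILE", "MET"),
    target_distance = c(4.31, 20, 22, 24, 26),
    toward_heme = c(TRUE, rep(FALSE, 4))
  )
  ctx <- load_structure(toy_structure_file(placements))
  motifs <- motif_annotation(degradation = 3L, meander_err_triad = 4L,
                             excluded = 2L)

  expect_equal(as.character(classify_variant("p.Q318X", ctx, motifs)$class),
               "nonsense_indel_del_dup")
  expect_equal(as.character(classify_variant("p.H466fs", ctx, motifs)$class),
               "nonsense_indel_del_dup")
  heme <- classify_variant("p.L1Q", ctx, motifs)
  expect_equal(as.character(heme$class), "heme_or_ligand_interaction")
  expect_equal(heme$distance, 4.31, tolerance = 0.01)
  expect_equal(as.character(classify_variant("p.A2V", ctx, motifs)$class),
               "excluded_low_resolution")   # annotated exclusion wins
  expect_equal(as.character(classify_variant("p.V3M", ctx, motifs)$class),
               "protein_degradation")
  expect_equal(as.character(classify_variant("p.I4L", ctx, motifs)$class),
               "meander_err_triad")
  expect_equal(as.character(classify_variant("p.M5T", ctx, motifs)$class),
               "stability")                 # default branch
  expect_equal(as.character(classify_variant("p.L9Q", ctx, motifs)$class),
               "excluded_low_resolution")   # not resolved in the structure
})

test_that("classify_table composes counts, keeps order, and survives row errors", {
  placements <- tibble::tibble(
    residue_name = c("LEU", "ALA", "VAL"),
    target_distance = c(4.31, 20, 22),
    toward_heme = c(TRUE, FALSE, FALSE)
  )
  ctx <- load_structure(toy_structure_file(placements))
  labels <- c("p.Q318X", "p.L1Q", "p.A2V")
  out <- classify_table(labels, ctx)
  cc <- class_counts(out)
  expect_equal(as.integer(cc[c("nonsense_indel_del_dup",
                               "heme_or_ligand_interaction", "stability")]),
               c(1L, 1L, 1L))
  # permuting input rows never changes any class
  perm <- c(3, 1, 2)
  out2 <- classify_table(labels[perm], ctx)
  expect_equal(as.character(out2$class),
               as.character(out$class)[perm])
  # empty input
  empty <- classify_table(character(0), ctx)
  expect_equal(nrow(empty), 0)
  expect_equal(sum(class_counts(empty)), 0L)
})

test_that("with no heme and empty motifs every resolved missense is stability", {
  placements <- tibble::tibble(
    residue_name = c("LEU", "ALA", "VAL"),
    target_distance = c(6, 20, 22),
    toward_heme = FALSE
  )
  txt <- generate_toy_structure(placements)
  lines <- strsplit(txt, "\n")[[1]]
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[!grepl("^HETATM", lines)], path)
  suppressWarnings(ctx <- load_structure(path))
  out <- classify_table(c("p.L1Q", "p.A2V", "p.V3M"), ctx)
  expect_true(all(out$class == "stability"))
})

test_that("mutant identity drives the POR rule and heme precedes POR", {
  ctx <- load_structure(por_fixture_file())
  # position 3 holds a Leu 5.5 A from core residue 124; mutating it to Glu
  # lands in the interface, mutating to Met does not
  expect_equal(as.character(classify_variant("p.L3E", ctx)$class),
               "por_interaction")
  expect_equal(as.character(classify_variant("p.L3M", ctx)$class),
               "stability")
  # a core position classifies as POR whatever the replacement
  expect_equal(as.character(classify_variant("p.R124H", ctx)$class),
               "por_interaction")
})

test_that("motif sets must be disjoint and load from config text", {
  expect_error(motif_annotation(degradation = 1:3, excluded = 3L),
               "disjoint")
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# motif sets", "degradation = 10, 11",
               "meander_err_triad = 20"), path)
  m <- read_motif_config(path)
  expect_equal(m$degradation, c(10L, 11L))
  expect_equal(m$meander_err_triad, 20L)
  expect_equal(m$excluded, integer(0))
})
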