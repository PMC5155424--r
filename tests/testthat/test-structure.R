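test_that("toy fixtures load with residues, heme atoms and exposures", {
  path <- toy_structure_file(default_placements())
  ctx <- load_structure(path)
  expect_s3_class(ctx, "structure_context")
  expect_equal(nrow(ctx$residues), 3)
  expect_gt(nrow(ctx$heme_atoms), 0)
  expect_true(all(ctx$residues$exposure >= 0 & ctx$residues$exposure <= 1))
  expect_false(any(ctx$residues$incomplete))
})

test_that("a structure without heteroatoms warns and disables heme predicates", {
  path <- withr::local_tempfile(fileext = ".pdb")
  txt <- generate_toy_structure(default_placements())
  lines <- strsplit(txt, "\n")[[1]]
  writeLines(lines[!grepl("^HETATM", lines)], path)
  expect_warning(ctx <- load_structure(path), "no heme")
  expect_equal(nrow(ctx$heme_atoms), 0)
  res <- is_heme_or_ligand_contact(ctx, 1)
  expect_false(res$contact)
})

test_that("minimum side-chain distance equals the brute-force pairwise minimum", {
  path <- toy_structure_file(default_placements())
  ctx <- load_structure(path)
  for (pos in ctx$residues$resno) {
    sc <- ctx$atoms[ctx$atoms$resno == pos & ctx$atoms$is_sidechain, ]
    brute <- Inf
    for (i in seq_len(nrow(sc))) {
      for (j in seq_len(nrow(ctx$heme_atoms))) {
        d <- sqrt(sum((as.numeric(sc[i, c("x", "y", "z")]) -
                         ctx$heme_atoms[j, ])^2))
        brute <- min(brute, d)
      }
    }
    expect_equal(min_sidechain_distance(ctx, pos, "heme"), brute,
                 tolerance = 1e-10)
  }
  # symmetry in atom order: distance to an explicit matrix matches
  m <- ctx$heme_atoms[rev(seq_len(nrow(ctx$heme_atoms))), ]
  expect_equal(min_sidechain_distance(ctx, 1, m),
               min_sidechain_distance(ctx, 1, "heme"))
  expect_error(min_sidechain_distance(ctx, 1, "ligand"),
               class = "cyp21act_domain_error")
})

test_that("heme-contact predicate honours distance, orientation and the boundary", {
  placements <- tibble::tibble(
    residue_name = c("LEU", "ALA", "ARG", "MET"),
    target_distance = c(4.31, 20.0, 5.0, 4.5),
    toward_heme = c(TRUE, TRUE, TRUE, FALSE)
  )
  ctx <- load_structure(toy_structure_file(placements))
  r1 <- is_heme_or_ligand_contact(ctx, 1)
  expect_true(r1$contact)
  expect_equal(r1$distance, 4.31, tolerance = 0.01)
  expect_false(is_heme_or_ligand_contact(ctx, 2)$contact)   # 20 A away
  expect_true(is_heme_or_ligand_contact(ctx, 3)$contact)    # boundary <= 5.0
  r4 <- is_heme_or_ligand_contact(ctx, 4)                   # close but averted
  expect_false(r4$contact)
  expect_gt(r4$angle_deg, 90)
})

test_that("contact truth is monotone in the distance cutoff", {
  ctx <- load_structure(toy_structure_file(default_placements()))
  cutoffs <- c(3, 4.31, 5, 8, 20, 30)
  for (pos in ctx$residues$resno) {
    hits <- vapply(cutoffs, function(cc) {
      is_heme_or_ligand_contact(ctx, pos,
                                geometry_config(heme_contact_cutoff = cc))$contact
    }, logical(1))
    expect_true(all(diff(hits) >= 0))  # once a contact, always a contact
  }
})

test_that("predicates are independent of atom ordering in the file", {
  path <- toy_structure_file(default_placements())
  lines <- readLines(path)
  atoms <- grepl("^(ATOM|HETATM)", lines)
  set.seed(1)
  shuffled <- c(sample(lines[atoms]), "END")
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(shuffled, path2)
  ctx1 <- load_structure(path)
  ctx2 <- load_structure(path2)
  for (pos in 1:3) {
    expect_equal(is_heme_or_ligand_contact(ctx2, pos)$contact,
                 is_heme_or_ligand_contact(ctx1, pos)$contact)
    expect_equal(min_sidechain_distance(ctx2, pos, "heme"),
                 min_sidechain_distance(ctx1, pos, "heme"), tolerance = 1e-9)
  }
})

test_that("glycine falls back to the C-alpha proxy", {
  placements <- tibble::tibble(residue_name = "GLY", target_distance = 4.0,
                               toward_heme = TRUE)
  ctx <- load_structure(toy_structure_file(placements))
  expect_false(ctx$residues$incomplete[1])
  d <- min_sidechain_distance(ctx, 1, "heme")
  expect_true(is.finite(d))
  expect_true(is_heme_or_ligand_contact(ctx, 1)$contact)
})

test_that("POR-interface predicate covers the core set and charged neighbours", {
  # residue 124 is core regardless of identity; an exposed Arg with its side
  # chain 5.5 A from the core side chain on the same (+x) face satisfies
  # clause (b); a Leu in the same spot does not. Residues 50/51 on the -x
  # side keep the protein centre near the origin so both +x side chains
  # point outward on the same face.
  ctx <- load_structure(por_fixture_file())
  expect_true(is_por_interface(ctx, 124)$por_interface)    # core by position
  r2 <- is_por_interface(ctx, 2)
  expect_true(r2$por_interface)                            # exposed Arg nearby
  expect_equal(r2$min_core_distance, 5.5, tolerance = 1e-6)
  expect_true(r2$same_face)
  expect_false(is_por_interface(ctx, 3)$por_interface)     # Leu: not charged
  # identity override: the replacement residue decides clause (b)
  expect_false(is_por_interface(ctx, 2, residue_name = "LEU")$por_interface)
  expect_true(is_por_interface(ctx, 3, residue_name = "GLU")$por_interface)
  # proximity clause is configurable
  tight <- geometry_config(por_proximity_cutoff = 2)
  expect_false(is_por_interface(ctx, 2, cfg = tight)$por_interface)
})
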