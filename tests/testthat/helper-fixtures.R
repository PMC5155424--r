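# Shared fixtures built in code at test time.

toy_structure_file <- function(placements, ...) {
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  generate_toy_structure(placements, path = path, ...)
  path
}

default_placements <- function() {
  tibble::tibble(
    residue_name = c("LEU", "ALA", "ARG"),
    target_distance = c(4.31, 20.0, 5.0),
    toward_heme = c(TRUE, TRUE, TRUE)
  )
}

# hand-placed fixture for the POR-interface predicate: core residue 124 and
# two neighbours on the +x face, counterweight residues on the -x side, and
# a far-away heme so loading emits no warning
por_fixture_file <- function() {
  line <- cyp21act:::pdb_atom_line
  serial <- 0L
  lines <- character(0)
  add <- function(name, resn, resno, xyz, elem, type = "ATOM") {
    serial <<- serial + 1L
    lines <<- c(lines, line(type, serial, name, resn, "A", resno, xyz, elem))
  }
  residue <- function(resn, resno, shift) {
    add("N", resn, resno, c(12, 1.45, 0) + shift, "N")
    add("CA", resn, resno, c(12, 0, 0) + shift, "C")
    add("C", resn, resno, c(12, -1.52, 0) + shift, "C")
    add("O", resn, resno, c(12, -1.52, 1.23) + shift, "O")
    if (resn != "GLY") {
      add("CB", resn, resno, c(13.5, 0, 0) + shift, "C")
      add("CG", resn, resno, c(14.2, 0, 0) + shift, "C")
      add("CD", resn, resno, c(15.0, 0, 0) + shift, "C")
    }
  }
  residue("ARG", 124L, c(0, 0, 0))
  residue("ARG", 2L, c(0, 5.5, 0))
  residue("LEU", 3L, c(0, 0, 5.5))
  residue("LEU", 50L, c(-26, 3, 0))
  residue("LEU", 51L, c(-26, -3, 0))
  add("FE", "HEM", 900L, c(0, 0, -20), "FE", type = "HETATM")
  path <- withr::local_tempfile(fileext = ".pdb",
                                .local_envir = parent.frame())
  writeLines(c(lines, "END"), path)
  path
}

# brute-force midrank Spearman, independent of rank()/cor()
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force least squares via the closed-form normal equations
oracle_lsq <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# independent permutation enumerator (Heap's algorithm)
oracle_permutations <- function(n) {
  res <- list()
  a <- seq_len(n)
  gen <- function(k) {
    if (k == 1) { res[[length(res) + 1]] <<- a; return(invisible()) }
    for (i in seq_len(k)) {
      gen(k - 1)
      j <- if (k %% 2 == 0) i else 1
      tmp <- a[j]; a[j] <<- a[k]; a[k] <<- tmp
    }
  }
  gen(n)
  do.call(rbind, res)
}

all_scenarios <- c("both_above", "additive_pathogenic", "combined_rescue",
                   "negative_synergy", "positive_synergy",
                   "synergy_subthreshold_pathogenic",
                   "additive_nonpathogenic")
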