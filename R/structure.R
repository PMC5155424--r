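# Structural context for variant classification: PDB parsing (via bio3d),
# heme/ligand proximity and orientation, POR-interface membership, and
# per-residue relative side-chain solvent accessibility.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# van der Waals radii (Angstrom) by element for accessibility calculations.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
               FE = 1.80, SE = 1.90)

# Reference maximum side-chain accessible surface areas (Angstrom^2) used to
# normalize side-chain accessibility into [0, 1] (theoretical Gly-X-Gly
# maxima; glycine uses the C-alpha proxy value).
MAX_SIDECHAIN_ASA <- c(
  ALA = 67, ARG = 196, ASN = 113, ASP = 106, CYS = 104, GLN = 144,
  GLU = 138, GLY = 47, HIS = 151, ILE = 140, LEU = 137, LYS = 167,
  MET = 160, PHE = 175, PRO = 105, SER = 80, THR = 102, TRP = 217,
  TYR = 187, VAL = 117
)

#' Residues forming the core POR-interaction surface
#'
#' The nine charged residues of the redox-partner (P450 oxidoreductase)
#' interface: R124, E140, E320, R341, R356, R366, R369, R431, R444.
#'
#' @return Integer vector of residue numbers.
#' @export
por_core_residues <- function() {
  c(124L, 140L, 320L, 341L, 356L, 366L, 369L, 431L, 444L)
}

#' Geometry configuration for structural predicates
#'
#' @param heme_contact_cutoff Maximum heavy-atom distance (Angstrom) between
#'   a side chain and the heme/ligand atoms for a contact; default 5.
#' @param por_proximity_cutoff Maximum side-chain distance (Angstrom) to the
#'   core POR-interface residues; default 8.
#' @param exposure_threshold Minimum relative side-chain solvent
#'   accessibility (fraction in \[0,1\]) to count a residue as exposed;
#'   default 0.25.
#' @param orientation_max_angle Maximum angle (degrees) at the C-alpha
#'   between the side-chain centroid direction and the direction to the
#'   nearest heme/ligand atom for "pointing towards"; default 90.
#' @return A list of class `geometry_config`.
#' @export
geometry_config <- function(heme_contact_cutoff = 5.0,
                            por_proximity_cutoff = 8.0,
                            exposure_threshold = 0.25,
                            orientation_max_angle = 90.0) {
  vals <- c(heme_contact_cutoff, por_proximity_cutoff, exposure_threshold,
            orientation_max_angle)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all geometry cutoffs must be positive and finite",
          class = "cyp21act_config_error")
  }
  structure(list(heme_contact_cutoff = heme_contact_cutoff,
                 por_proximity_cutoff = por_proximity_cutoff,
                 exposure_threshold = exposure_threshold,
                 orientation_max_angle = orientation_max_angle),
            class = "geometry_config")
}

atom_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.80
  unname(r)
}

# Shrake-Rupley accessible surface area per atom. `xyz` is an n x 3 matrix
# of heavy-atom coordinates, `radii` the matching vdW radii. Returns the
# accessible area (Angstrom^2) of each atom's solvent-expanded sphere.
shrake_rupley_asa <- function(xyz, radii, probe = 1.4, n_points = 120L) {
  n <- nrow(xyz)
  # golden-spiral points on the unit sphere
  k <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * k / n_points)
  theta <- pi * (1 + sqrt(5)) * k
  sphere <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  rs <- radii + probe
  asa <- numeric(n)
  maxr <- max(rs)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < rs[i] + maxr & di > 1e-9)
    nb <- nb[di[nb] < rs[i] + rs[nb]]
    pts <- sphere * rs[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      d2 <- (pts[acc, 1] - xyz[j, 1])^2 + (pts[acc, 2] - xyz[j, 2])^2 +
        (pts[acc, 3] - xyz[j, 3])^2
      acc[acc] <- d2 > rs[j]^2
    }
    asa[i] <- 4 * pi * rs[i]^2 * sum(acc) / n_points
  }
  asa
}

#' Load a structure and derive its variant-classification context
#'
#' Parses a PDB file (first model of multi-model files; coordinates used
#' as-is, no symmetry expansion), collects the protein chain's residues with
#' their side-chain heavy atoms, the heme and optional ligand heteroatom
#' sets, and computes each residue's relative side-chain solvent
#' accessibility by the Shrake-Rupley method, normalized by per-residue
#' reference maxima and clamped to \[0,1\]. Glycine uses the C-alpha atom as
#' its side-chain proxy.
#'
#' @param path PDB file.
#' @param chain Chain identifier; defaults to the first protein chain.
#' @param heme_resnames Heteroatom residue names treated as heme
#'   (default `"HEM"`).
#' @param ligand_resnames Heteroatom residue names treated as bound
#'   substrate (deposition-dependent; default none).
#' @param probe Solvent probe radius in Angstrom.
#' @param n_sphere_points Shrake-Rupley sphere resolution.
#' @return An object of class `structure_context` with elements `atoms`
#'   (tibble of chain atoms), `residues` (per-residue tibble with exposure
#'   and completeness flags), `heme_atoms`, `ligand_atoms` (coordinate
#'   matrices), `por_core_set`, `center` and `source`.
#' @export
load_structure <- function(path, chain = NULL, heme_resnames = "HEM",
                           ligand_resnames = character(),
                           probe = 1.4, n_sphere_points = 120L) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- as_tibble(pdb$atom)
  at$element <- ifelse(is.na(at$elesy) | at$elesy == "",
                       substr(gsub("[^A-Za-z]", "", at$elety), 1, 1),
                       at$elesy)
  heavy <- toupper(at$element) != "H"
  at <- at[heavy, , drop = FALSE]

  prot <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- prot$chain[1]
  if (!chain %in% prot$chain) {
    abort(sprintf("chain '%s' not found in %s", chain, path),
          class = "cyp21act_structure_error")
  }
  prot <- prot[prot$chain == chain, , drop = FALSE]

  het <- at[at$type == "HETATM", , drop = FALSE]
  heme <- het[het$resid %in% heme_resnames, , drop = FALSE]
  lig <- het[het$resid %in% ligand_resnames, , drop = FALSE]
  if (nrow(heme) == 0) {
    warn(sprintf("no heme heteroatoms (%s) found in %s; heme predicates will be false",
                 paste(heme_resnames, collapse = ","), path))
  }

  # accessibility computed in the context of the chain plus cofactors
  env_xyz <- rbind(as.matrix(prot[, c("x", "y", "z")]),
                   as.matrix(heme[, c("x", "y", "z")]),
                   as.matrix(lig[, c("x", "y", "z")]))
  env_rad <- atom_radius(c(prot$element, heme$element, lig$element))
  asa <- shrake_rupley_asa(env_xyz, env_rad, probe = probe,
                          n_points = n_sphere_points)
  prot$asa <- asa[seq_len(nrow(prot))]
  prot$is_sidechain <- !(prot$elety %in% BACKBONE_ATOMS)
  gly <- prot$resid == "GLY"
  prot$is_sidechain[gly] <- prot$elety[gly] == "CA" # C-alpha proxy

  residues <- prot |>
    dplyr::group_by(.data$resno, .data$resid) |>
    dplyr::summarise(
      n_atoms = dplyr::n(),
      n_sidechain = sum(.data$is_sidechain),
      sidechain_asa = sum(.data$asa[.data$is_sidechain]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$resno)
  maxasa <- MAX_SIDECHAIN_ASA[residues$resid]
  maxasa[is.na(maxasa)] <- mean(MAX_SIDECHAIN_ASA)
  residues$exposure <- pmin(1, pmax(0, residues$sidechain_asa / maxasa))
  residues$incomplete <- residues$n_sidechain == 0

  structure(list(
    atoms = prot,
    residues = residues,
    heme_atoms = as.matrix(heme[, c("x", "y", "z")]),
    heme_labels = if (nrow(heme)) paste0(heme$resid, "/", heme$elety) else character(0),
    ligand_atoms = as.matrix(lig[, c("x", "y", "z")]),
    ligand_labels = if (nrow(lig)) paste0(lig$resid, "/", lig$elety) else character(0),
    por_core_set = por_core_residues(),
    center = colMeans(as.matrix(prot[, c("x", "y", "z")])),
    chain = chain,
    source = path
  ), class = "structure_context")
}

#' @export
print.structure_context <- function(x, ...) {
  cat(sprintf("<structure_context> chain %s: %d residues, %d heme atoms, %d ligand atoms\n",
              x$chain, nrow(x$residues), nrow(x$heme_atoms),
              nrow(x$ligand_atoms)))
  invisible(x)
}

residue_atoms <- function(ctx, residue_position, sidechain_only = TRUE) {
  a <- ctx$atoms[ctx$atoms$resno == residue_position, , drop = FALSE]
  if (nrow(a) == 0) {
    abort(sprintf("residue %d not resolved in the structure", residue_position),
          class = "cyp21act_structure_error")
  }
  if (sidechain_only) {
    sc <- a[a$is_sidechain, , drop = FALSE]
    if (nrow(sc) == 0) {
      abort(sprintf("incomplete residue %d: no side-chain atoms", residue_position),
            class = "cyp21act_incomplete_residue")
    }
    return(sc)
  }
  a
}

target_atom_matrix <- function(ctx, atom_set) {
  if (is.matrix(atom_set)) {
    if (nrow(atom_set) == 0) abort("empty atom set", class = "cyp21act_domain_error")
    return(list(xyz = atom_set, labels = rep(NA_character_, nrow(atom_set))))
  }
  atom_set <- match.arg(atom_set, c("heme", "ligand", "heme_ligand"))
  xyz <- switch(atom_set,
                heme = ctx$heme_atoms,
                ligand = ctx$ligand_atoms,
                heme_ligand = rbind(ctx$heme_atoms, ctx$ligand_atoms))
  labels <- switch(atom_set,
                   heme = ctx$heme_labels,
                   ligand = ctx$ligand_labels,
                   heme_ligand = c(ctx$heme_labels, ctx$ligand_labels))
  if (is.null(xyz) || nrow(xyz) == 0) {
    abort(sprintf("atom set '%s' is empty", atom_set),
          class = "cyp21act_domain_error")
  }
  list(xyz = xyz, labels = labels)
}

#' Minimum side-chain distance to an atom set
#'
#' Minimum Euclidean heavy-atom distance (Angstrom) between a residue's
#' side-chain atoms (C-alpha proxy for glycine) and a target atom set.
#'
#' @param ctx A `structure_context`.
#' @param residue_position Residue number on the loaded chain.
#' @param atom_set `"heme"`, `"ligand"`, `"heme_ligand"`, or an n x 3
#'   coordinate matrix.
#' @return A single number (Angstrom).
#' @export
min_sidechain_distance <- function(ctx, residue_position, atom_set = "heme") {
  sc <- residue_atoms(ctx, residue_position)
  tgt <- target_atom_matrix(ctx, atom_set)
  sxyz <- as.matrix(sc[, c("x", "y", "z")])
  d2 <- outer(rowSums(sxyz^2), rowSums(tgt$xyz^2), "+") -
    2 * sxyz %*% t(tgt$xyz)
  sqrt(max(0, min(d2)))
}

sidechain_centroid <- function(ctx, residue_position) {
  sc <- residue_atoms(ctx, residue_position)
  colMeans(as.matrix(sc[, c("x", "y", "z")]))
}

ca_coord <- function(ctx, residue_position) {
  a <- residue_atoms(ctx, residue_position, sidechain_only = FALSE)
  ca <- a[a$elety == "CA", c("x", "y", "z"), drop = FALSE]
  if (nrow(ca) == 0) {
    abort(sprintf("incomplete residue %d: no C-alpha atom", residue_position),
          class = "cyp21act_incomplete_residue")
  }
  as.numeric(ca[1, ])
}

angle_deg <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9) return(0) # orientation indeterminate
  acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Heme/ligand contact predicate
#'
#' A residue contacts the heme (or bound substrate) when its minimum
#' side-chain heavy-atom distance to the heme-plus-ligand atom set is at or
#' below the contact cutoff (boundary counts as contact) AND the side chain
#' points towards it: the angle at the C-alpha between the side-chain
#' centroid direction and the nearest heme/ligand atom direction is at most
#' `orientation_max_angle`.
#'
#' @param ctx A `structure_context`.
#' @param residue_position Residue number.
#' @param cfg A [geometry_config()].
#' @return One-row tibble: `contact`, `distance`, `angle_deg`,
#'   `nearest_atom`, `exposure`.
#' @export
is_heme_or_ligand_contact <- function(ctx, residue_position,
                                      cfg = geometry_config()) {
  xyz <- rbind(ctx$heme_atoms, ctx$ligand_atoms)
  if (is.null(xyz) || nrow(xyz) == 0) {
    return(tibble(contact = FALSE, distance = NA_real_, angle_deg = NA_real_,
                  nearest_atom = NA_character_,
                  exposure = residue_exposure(ctx, residue_position)))
  }
  labels <- c(ctx$heme_labels, ctx$ligand_labels)
  sc <- residue_atoms(ctx, residue_position)
  sxyz <- as.matrix(sc[, c("x", "y", "z")])
  d2 <- outer(rowSums(sxyz^2), rowSums(xyz^2), "+") - 2 * sxyz %*% t(xyz)
  d2[d2 < 0] <- 0
  idx <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  dist <- sqrt(d2[idx[1], idx[2]])
  nearest <- xyz[idx[2], ]
  ca <- ca_coord(ctx, residue_position)
  ang <- angle_deg(sidechain_centroid(ctx, residue_position) - ca, nearest - ca)
  tibble(
    contact = dist <= cfg$heme_contact_cutoff && ang <= cfg$orientation_max_angle,
    distance = dist,
    angle_deg = ang,
    nearest_atom = labels[idx[2]],
    exposure = residue_exposure(ctx, residue_position)
  )
}

residue_exposure <- function(ctx, residue_position) {
  e <- ctx$residues$exposure[ctx$residues$resno == residue_position]
  if (length(e) == 0) NA_real_ else e[1]
}

#' POR-interface predicate
#'
#' A residue belongs to the redox-partner (POR) interface when (a) its
#' position is one of the nine core interface residues, or (b) it is an
#' arginine or glutamic acid whose side chain lies within
#' `por_proximity_cutoff` of a core residue's side chain, is solvent-exposed
#' (relative side-chain accessibility at or above `exposure_threshold`), and
#' sits on the same face of the protein as the core set (positive projection
#' of its outward direction onto the mean outward direction of the core
#' side chains).
#'
#' @param ctx A `structure_context`.
#' @param residue_position Residue number.
#' @param residue_name Residue identity to test; defaults to the residue in
#'   the structure. Pass the replacement residue when classifying a variant.
#' @param cfg A [geometry_config()].
#' @return One-row tibble: `por_interface`, `rule`, `min_core_distance`,
#'   `exposure`, `same_face`.
#' @export
is_por_interface <- function(ctx, residue_position, residue_name = NULL,
                             cfg = geometry_config()) {
  if (residue_position %in% ctx$por_core_set) {
    return(tibble(por_interface = TRUE, rule = "core_set",
                  min_core_distance = 0, exposure =
                    residue_exposure(ctx, residue_position),
                  same_face = TRUE))
  }
  if (is.null(residue_name)) {
    residue_name <- ctx$residues$resid[ctx$residues$resno == residue_position][1]
  }
  rn <- toupper(residue_name)
  one2three <- c(R = "ARG", E = "GLU")
  if (rn %in% names(one2three)) rn <- one2three[[rn]]
  if (is.na(rn) || !rn %in% c("ARG", "GLU")) {
    return(tibble(por_interface = FALSE, rule = "not_charged",
                  min_core_distance = NA_real_,
                  exposure = residue_exposure(ctx, residue_position),
                  same_face = NA))
  }
  core_present <- intersect(ctx$por_core_set, ctx$residues$resno)
  if (length(core_present) == 0) {
    return(tibble(por_interface = FALSE, rule = "no_core_residues",
                  min_core_distance = NA_real_,
                  exposure = residue_exposure(ctx, residue_position),
                  same_face = NA))
  }
  dmin <- min(vapply(core_present, function(p) {
    sc <- residue_atoms(ctx, p)
    min_sidechain_distance(ctx, residue_position,
                           as.matrix(sc[, c("x", "y", "z")]))
  }, numeric(1)))
  expo <- residue_exposure(ctx, residue_position)
  out_dir <- function(p) {
    v <- sidechain_centroid(ctx, p) - ctx$center
    n <- sqrt(sum(v^2)); if (n < 1e-9) c(0, 0, 0) else v / n
  }
  core_mean <- colMeans(do.call(rbind, lapply(core_present, out_dir)))
  same_face <- sum(out_dir(residue_position) * core_mean) > 0
  ok <- dmin <= cfg$por_proximity_cutoff && !is.na(expo) &&
    expo >= cfg$exposure_threshold && same_face
  tibble(por_interface = ok, rule = if (ok) "charged_proximal" else "proximity_fail",
         min_core_distance = dmin, exposure = expo, same_face = same_face)
}
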