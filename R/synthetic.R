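# Synthetic-data generators: calibration pairs under the log-linear model,
# replica ddG sets, double-variant scenario sets, and toy PDB fixtures with
# controlled heme geometry. All generators are pure functions of their
# arguments plus a seed: repeated calls are byte-identical.

#' Specification for synthetic calibration data
#'
#' Defaults emulate the statistical structure of the real calibration:
#' intercept about 5.35 ln-percent and slope about -1.53 per kcal/mol (the
#' log-linear line traced by the published activity table), ddG drawn
#' uniformly on (-2, 10) kcal/mol spanning the observed range, replicate SD
#' 0.8 kcal/mol (the stability predictor's stated SD), five replicas, and
#' ln-scale noise SD 0.35 chosen so the synthetic scatter resembles the
#' published calibration spread (a cosmetic, not inferential, choice).
#'
#' @param a_true Intercept, ln(percent) units.
#' @param b_true Slope, per kcal/mol.
#' @param noise_sd SD of Gaussian noise on the ln scale; non-negative.
#' @param n_pairs Number of pairs.
#' @param ddg_range Length-2 numeric, low < high (kcal/mol).
#' @param replica_sd Replicate SD (kcal/mol).
#' @param replica_count Replicas per variant; default 5.
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(a_true = 5.35, b_true = -1.53, noise_sd = 0.35,
                           n_pairs = 30L, ddg_range = c(-2, 10),
                           replica_sd = 0.8, replica_count = 5L, seed = 1L) {
  if (noise_sd < 0) abort("noise_sd must be non-negative",
                          class = "cyp21act_config_error")
  if (length(ddg_range) != 2 || ddg_range[1] >= ddg_range[2]) {
    abort("ddg_range must be (low, high) with low < high",
          class = "cyp21act_config_error")
  }
  if (replica_count < 1 || n_pairs < 0) {
    abort("replica_count must be >= 1 and n_pairs >= 0",
          class = "cyp21act_config_error")
  }
  structure(list(a_true = a_true, b_true = b_true, noise_sd = noise_sd,
                 n_pairs = as.integer(n_pairs), ddg_range = ddg_range,
                 replica_sd = replica_sd,
                 replica_count = as.integer(replica_count),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate calibration pairs under the log-linear model
#'
#' Draws ddG uniformly on `ddg_range` and activities from
#' `exp(a + b*ddg + eps)`, `eps ~ N(0, noise_sd^2)`. Activities above 100%
#' are clamped to 100 and flagged `capped`.
#'
#' @param spec A [synthetic_spec()].
#' @return Tibble: `variant` (synthetic labels), `ddg`, `activity_pct`,
#'   `capped`, `substrate`, `template`.
#' @export
generate_calibration_pairs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_pairs
  if (n == 0L) {
    return(tibble(variant = character(0), ddg = numeric(0),
                  activity_pct = numeric(0), capped = logical(0),
                  substrate = character(0), template = character(0)))
  }
  with_seed(spec$seed, {
    ddg <- stats::runif(n, spec$ddg_range[1], spec$ddg_range[2])
    eps <- if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd) else 0
    raw <- exp(spec$a_true + spec$b_true * ddg + eps)
    capped <- raw > 100
    tibble(
      variant = paste0("p.A", seq_len(n) + 1L, "V"),
      ddg = ddg,
      activity_pct = pmin(raw, 100),
      capped = capped,
      substrate = "OHP17",
      template = "bovine_3QZ1_model"
    )
  })
}

#' Generate replica ddG values
#'
#' Normal draws around a true ddG, emulating repeated stability-predictor
#' runs for one mutation.
#'
#' @param true_ddg Centre (kcal/mol).
#' @param replica_sd Replicate SD (kcal/mol).
#' @param replica_count Number of replicas (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of length `replica_count`.
#' @export
generate_replicas <- function(true_ddg, replica_sd = 0.8, replica_count = 5L,
                              seed = 1L) {
  stopifnot(replica_count >= 1)
  if (replica_sd == 0) return(rep(true_ddg, replica_count))
  with_seed(seed, stats::rnorm(replica_count, true_ddg, replica_sd))
}

# --- toy PDB fixtures -------------------------------------------------------

# heme proxy group centred at the origin (iron plus propionate-like oxygens)
TOY_HEME <- list(
  names = c("FE", "O1A", "O2A", "CHA"),
  elements = c("FE", "O", "O", "C"),
  xyz = rbind(c(0, 0, 0), c(1.5, 0, 0), c(-1.5, 0, 0), c(0, 1.5, 0))
)

pdb_atom_line <- function(type, serial, name, resn, chain, resno, xyz, element) {
  nm <- if (nchar(element) >= 2) sprintf("%-4s", name) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, nm, "", resn, chain, resno, "",
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, element)
}

# unit directions spread over the sphere (golden spiral)
sphere_directions <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# radial offset along direction u at which a point sits exactly `target`
# Angstrom from the nearest heme atom
solve_radius <- function(u, target, heme_xyz) {
  f <- function(r) {
    p <- r * u
    min(sqrt(colSums((t(heme_xyz) - p)^2))) - target
  }
  stats::uniroot(f, lower = target, upper = target + 5, tol = 1e-9)$root
}

#' Generate a toy PDB structure with controlled heme geometry
#'
#' Emits a minimal PDB with one HEM heterogroup near the origin and one
#' residue per requested placement, each on its own radial direction so
#' residues do not clash. Every residue carries a backbone (N, CA, C, O)
#' and a three-atom side-chain proxy whose nearest atom sits exactly
#' `target_distance` Angstrom from the nearest heme atom. With
#' `toward_heme = TRUE` the side chain lies between the C-alpha and the
#' heme (orientation angle about 0 degrees); with `FALSE` it lies on the
#' far side (about 180 degrees), so the contact predicate's answer under
#' the default geometry config is fixed by construction. Placements whose
#' geometry cannot be built without atom overlap (distances below about
#' 2 Angstrom from the heme envelope for away-pointing residues) raise a
#' generation error.
#'
#' @param placements Tibble (or data.frame) with columns `residue_name`
#'   (three-letter code), `target_distance` (Angstrom, > 0), `toward_heme`
#'   (logical), and optional `resno`.
#' @param seed Accepted for interface uniformity; the construction is
#'   deterministic.
#' @param path Optional file path; when given the text is also written
#'   there.
#' @return PDB-format text as a single string (invisibly when `path` is
#'   given).
#' @export
generate_toy_structure <- function(placements, seed = 1L, path = NULL) {
  placements <- as_tibble(placements)
  stopifnot(all(c("residue_name", "target_distance", "toward_heme") %in%
                  names(placements)))
  if (any(placements$target_distance <= 0)) {
    abort("target distances must be positive", class = "cyp21act_generation_error")
  }
  n <- nrow(placements)
  if (!"resno" %in% names(placements)) placements$resno <- seq_len(n)
  dirs <- sphere_directions(max(n, 2L))
  lines <- character(0)
  serial <- 0L
  add <- function(type, name, resn, resno, xyz, element) {
    serial <<- serial + 1L
    lines <<- c(lines, pdb_atom_line(type, serial, name, resn, "A", resno,
                                     xyz, element))
  }
  for (i in seq_len(n)) {
    u <- dirs[i, ]
    tgt <- placements$target_distance[i]
    toward <- isTRUE(placements$toward_heme[i])
    resn <- toupper(placements$residue_name[i])
    resno <- placements$resno[i]
    r_tip <- solve_radius(u, tgt, TOY_HEME$xyz)
    # toward-pointing tips sit just inside the requested distance (by more
    # than the PDB coordinate precision of 0.001 A) so a placement at
    # exactly the contact cutoff stays on the contact side after writing
    if (toward) r_tip <- r_tip - 0.003
    sc_r <- r_tip + c(0, 0.7, 1.4)          # proxy side-chain radii
    # glycine's contact proxy is the C-alpha itself: put it at the tip
    ca_r <- if (resn == "GLY") r_tip
            else if (toward) r_tip + 2.6 else r_tip - 2.6
    if (!toward && ca_r < 2.0) {
      abort(sprintf("infeasible placement: residue %d at %.2f A pointing away overlaps the heme",
                    resno, tgt), class = "cyp21act_generation_error")
    }
    # perpendicular unit vector for backbone offsets
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    v <- ref - sum(ref * u) * u
    v <- v / sqrt(sum(v^2))
    ca <- ca_r * u
    add("ATOM", "N", resn, resno, ca + 1.45 * v, "N")
    add("ATOM", "CA", resn, resno, ca, "C")
    add("ATOM", "C", resn, resno, ca - 1.52 * v, "C")
    add("ATOM", "O", resn, resno, ca - 1.52 * v + 1.23 * u, "O")
    if (resn != "GLY") {
      sc_names <- c("CB", "CG", "CD")
      for (k in 1:3) add("ATOM", sc_names[k], resn, resno, sc_r[k] * u, "C")
    }
  }
  lines <- c(lines, "TER")
  for (k in seq_along(TOY_HEME$names)) {
    serial <- serial + 1L
    lines <- c(lines, pdb_atom_line("HETATM", serial, TOY_HEME$names[k],
                                    "HEM", "A", 900L, TOY_HEME$xyz[k, ],
                                    TOY_HEME$elements[k]))
  }
  lines <- c(lines, "END")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(txt))
  }
  txt
}

#' Generate double-variant records for requested scenarios
#'
#' For each requested scenario, samples (ddg_1, ddg_2, ddg_double) triples
#' from the region of ddG space that [classify_double()] maps to that
#' scenario, so generation is rejection-free and the classifier recognizes
#' every generated record as its requested scenario. Additive scenarios are
#' generated with `ddg_double` equal to the additive sum.
#'
#' @param scenario_mix Named integer vector/list, scenario -> count.
#' @param cfg An [analysis_config()].
#' @param synergy_tolerance As in [classify_double()].
#' @param seed Integer seed.
#' @return Tibble: `variant_1`, `variant_2`, `ddg_1`, `ddg_2`,
#'   `ddg_double`, `scenario_requested`.
#' @export
generate_double_variant_set <- function(scenario_mix,
                                        cfg = analysis_config(),
                                        synergy_tolerance = 0.8,
                                        seed = 1L) {
  scenario_mix <- unlist(scenario_mix)
  if (length(scenario_mix) == 0 || sum(scenario_mix) == 0) {
    return(tibble(variant_1 = character(0), variant_2 = character(0),
                  ddg_1 = numeric(0), ddg_2 = numeric(0),
                  ddg_double = numeric(0), scenario_requested = character(0)))
  }
  bad <- setdiff(names(scenario_mix), SYNERGY_SCENARIOS)
  if (length(bad)) {
    abort(sprintf("unknown scenario(s): %s", paste(bad, collapse = ", ")),
          class = "cyp21act_config_error")
  }
  thr <- cfg$destabilization_threshold
  tol <- synergy_tolerance
  gen_one <- function(scn) {
    switch(scn,
      both_above = {
        d1 <- stats::runif(1, thr + 0.1, thr + 3)
        d2 <- stats::runif(1, thr + 0.1, thr + 3)
        c(d1, d2, d1 + d2)
      },
      additive_pathogenic = {
        d1 <- stats::runif(1, thr / 2 + 0.05, thr - 0.05)
        d2 <- stats::runif(1, thr / 2 + 0.05, thr - 0.05)
        c(d1, d2, d1 + d2)
      },
      combined_rescue = {
        d1 <- stats::runif(1, thr + 0.5, thr + 2)
        d2 <- stats::runif(1, -3, thr - d1 - 0.1)
        c(d1, d2, d1 + d2)
      },
      negative_synergy = {
        d1 <- stats::runif(1, thr - 0.3, thr - 0.01)
        d2 <- stats::runif(1, thr - 0.3, thr - 0.01)
        s <- d1 + d2 # in (2*thr - 0.6, 2*thr), above thr
        dd <- stats::runif(1, 0.1, min(thr - 0.05, s - tol - 0.05))
        c(d1, d2, dd)
      },
      positive_synergy = {
        d1 <- stats::runif(1, thr + 0.3, thr + 1.5)
        d2 <- stats::runif(1, -d1, thr - 0.1 - d1)
        dd <- thr + tol + stats::runif(1, 0.1, 1)
        c(d1, d2, dd)
      },
      synergy_subthreshold_pathogenic = {
        d1 <- stats::runif(1, 0.1, thr / 2 - 0.1)
        d2 <- stats::runif(1, 0.1, thr / 2 - 0.1)
        dd <- max(thr, d1 + d2 + tol) + stats::runif(1, 0.05, 1)
        c(d1, d2, dd)
      },
      additive_nonpathogenic = {
        d1 <- stats::runif(1, -1, thr / 2 - 0.05)
        d2 <- stats::runif(1, -1, thr / 2 - 0.05)
        c(d1, d2, d1 + d2)
      })
  }
  with_seed(seed, {
    rows <- list(); idx <- 0L
    for (scn in names(scenario_mix)) {
      cnt <- scenario_mix[[scn]]
      for (j in seq_len(cnt)) {
        idx <- idx + 1L
        trip <- gen_one(scn)
        rows[[idx]] <- tibble(
          variant_1 = paste0("p.L", 2L * idx, "P"),
          variant_2 = paste0("p.V", 2L * idx + 1L, "M"),
          ddg_1 = trip[1], ddg_2 = trip[2], ddg_double = trip[3],
          scenario_requested = scn)
      }
    }
    dplyr::bind_rows(rows)
  })
}
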