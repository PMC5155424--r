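# Variant classification: assign each variant to exactly one category, so
# that only the "stability" subset enters the ddG -> activity machinery.

VARIANT_CLASSES <- c("nonsense_indel_del_dup", "excluded_low_resolution",
                     "heme_or_ligand_interaction", "por_interaction",
                     "protein_degradation", "meander_err_triad", "stability")

#' Motif annotation sets
#'
#' Residue-number sets for the sequence/structure motifs the classifier
#' consults: degradation-related positions, the meander/ERR-triad positions,
#' and positions excluded for poor structural resolution. The sets must be
#' pairwise disjoint; all default to empty (they are supplied from external
#' curation, not derivable from the structure).
#'
#' @param degradation,meander_err_triad,excluded Integer vectors of residue
#'   numbers.
#' @return A list of class `motif_annotation`.
#' @export
motif_annotation <- function(degradation = integer(),
                             meander_err_triad = integer(),
                             excluded = integer()) {
  degradation <- as.integer(degradation)
  meander_err_triad <- as.integer(meander_err_triad)
  excluded <- as.integer(excluded)
  sets <- list(degradation, meander_err_triad, excluded)
  for (i in 1:2) for (j in (i + 1):3) {
    if (length(intersect(sets[[i]], sets[[j]]))) {
      abort("motif annotation sets must be pairwise disjoint",
            class = "cyp21act_config_error")
    }
  }
  structure(list(degradation = degradation,
                 meander_err_triad = meander_err_triad,
                 excluded = excluded),
            class = "motif_annotation")
}

#' Read a motif annotation config file
#'
#' Plain `key = v1, v2, ...` lines with keys `degradation`,
#' `meander_err_triad`, `excluded`; missing keys give empty sets.
#'
#' @param path Config file.
#' @return A [motif_annotation()].
#' @export
read_motif_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(
    lapply(kv, function(p) as.integer(strsplit(trimws(p[2]), "[,; ]+")[[1]])),
    vapply(kv, function(p) trimws(p[1]), character(1)))
  motif_annotation(degradation = vals[["degradation"]] %||% integer(),
                   meander_err_triad = vals[["meander_err_triad"]] %||% integer(),
                   excluded = vals[["excluded"]] %||% integer())
}

#' Classify one variant by structural context
#'
#' Applies the category precedence: (1) non-missense kinds are
#' `nonsense_indel_del_dup`; (2) positions annotated as poorly resolved (or
#' missing from the structure) are `excluded_low_resolution`; (3) heme/ligand
#' contact; (4) POR interface (tested with the replacement residue identity,
#' so a substitution introducing Arg/Glu at the interface counts); (5)
#' degradation motif; (6) meander/ERR-triad motif; (7) otherwise
#' `stability`. Functional categories precede stability because variants at
#' functional residues are excluded from the stability analysis; when both
#' heme and POR rules fire, heme wins (the stronger functional claim).
#'
#' @param variant One-row tibble from [parse_protein_variant()] or a label.
#' @param ctx A `structure_context`, or `NULL` when no structure is
#'   available (geometric rules then never fire and a warning is emitted).
#' @param motifs A [motif_annotation()].
#' @param cfg A [geometry_config()].
#' @return One-row tibble: `class`, `rule`, and the geometric evidence
#'   columns (`distance`, `angle_deg`, `nearest_atom`, `exposure`).
#' @export
classify_variant <- function(variant, ctx = NULL, motifs = motif_annotation(),
                             cfg = geometry_config()) {
  if (is.character(variant)) variant <- parse_protein_variant(variant)
  stopifnot(nrow(variant) == 1)
  ev <- tibble(class = NA_character_, rule = NA_character_,
               distance = NA_real_, angle_deg = NA_real_,
               nearest_atom = NA_character_, exposure = NA_real_)
  fill <- function(class, rule) {
    ev$class <<- class; ev$rule <<- rule; ev
  }
  if (variant$kind != "missense" && variant$kind != "synonymous") {
    return(fill("nonsense_indel_del_dup", paste0("kind=", variant$kind)))
  }
  if (variant$kind == "synonymous") {
    return(fill("nonsense_indel_del_dup", "kind=synonymous (no protein change)"))
  }
  pos <- variant$position
  if (pos %in% motifs$excluded) {
    return(fill("excluded_low_resolution", "annotated poor resolution"))
  }
  if (is.null(ctx)) {
    warn(sprintf("no structure context: geometric rules skipped for %s",
                 variant$raw_label))
  } else {
    if (!pos %in% ctx$residues$resno) {
      return(fill("excluded_low_resolution", "not resolved in structure"))
    }
    heme <- is_heme_or_ligand_contact(ctx, pos, cfg)
    ev$distance <- heme$distance; ev$angle_deg <- heme$angle_deg
    ev$nearest_atom <- heme$nearest_atom; ev$exposure <- heme$exposure
    if (isTRUE(heme$contact)) {
      return(fill("heme_or_ligand_interaction",
                  sprintf("side chain %.2f A from %s, angle %.0f deg",
                          heme$distance, heme$nearest_atom, heme$angle_deg)))
    }
    por <- is_por_interface(ctx, pos, residue_name = variant$mut_residue,
                            cfg = cfg)
    if (isTRUE(por$por_interface)) {
      return(fill("por_interaction", por$rule))
    }
    # a core-interface position mutated away from the interface residue
    # still belongs to the POR category by position
    if (pos %in% ctx$por_core_set) {
      return(fill("por_interaction", "core_set"))
    }
  }
  if (pos %in% motifs$degradation) {
    return(fill("protein_degradation", "degradation motif"))
  }
  if (pos %in% motifs$meander_err_triad) {
    return(fill("meander_err_triad", "meander/ERR-triad motif"))
  }
  fill("stability", "default: no functional annotation fired")
}

#' Classify a table of variants
#'
#' Row-wise [classify_variant()]; per-row errors are captured in the `note`
#' column and never abort the batch. The class-count summary is attached as
#' the `"class_counts"` attribute (see [class_counts()]).
#'
#' @param variants Tibble of parsed variants (or character labels).
#' @inheritParams classify_variant
#' @return The input tibble with `class`, `rule`, evidence columns and
#'   `note` appended, rows in input order.
#' @export
classify_table <- function(variants, ctx = NULL, motifs = motif_annotation(),
                           cfg = geometry_config()) {
  if (is.character(variants)) variants <- parse_protein_variant(variants)
  variants <- as_tibble(variants)
  if (nrow(variants) == 0) {
    out <- variants
    out$class <- factor(character(0), levels = VARIANT_CLASSES)
    attr(out, "class_counts") <- table(factor(character(0), levels = VARIANT_CLASSES))
    return(out)
  }
  res <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    res[[i]] <- tryCatch({
      ev <- classify_variant(variants[i, , drop = FALSE], ctx, motifs, cfg)
      ev$note <- NA_character_
      ev
    }, error = function(e) {
      tibble(class = NA_character_, rule = "error", distance = NA_real_,
             angle_deg = NA_real_, nearest_atom = NA_character_,
             exposure = NA_real_, note = conditionMessage(e))
    })
  }
  ann <- dplyr::bind_rows(res)
  out <- dplyr::bind_cols(variants, ann)
  out$class <- factor(out$class, levels = VARIANT_CLASSES)
  attr(out, "class_counts") <- table(out$class, useNA = "no")
  out
}

#' Class counts of a classified table
#'
#' @param classified Output of [classify_table()].
#' @return Named table of counts over the seven variant classes.
#' @export
class_counts <- function(classified) {
  cc <- attr(classified, "class_counts")
  if (is.null(cc)) cc <- table(factor(classified$class, levels = VARIANT_CLASSES))
  cc
}
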