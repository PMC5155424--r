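# Protein-level variant labels ("p.L107Q", "p.Leu107Gln", "p.Q318X",
# "p.H466fs") and the tab-separated variant/activity tables the pipeline
# consumes and emits. Positions are 1-based on the reference protein
# sequence; no transcript or genomic coordinates appear anywhere.

AA3_TO_1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "X"
)
AA1 <- setdiff(unname(AA3_TO_1), "X")

VARIANT_KINDS <- c("missense", "nonsense", "frameshift", "synonymous",
                   "indel_or_other")

normalize_aa <- function(tok, what, label) {
  if (tok %in% AA1) return(tok)
  t3 <- paste0(toupper(substr(tok, 1, 1)), tolower(substr(tok, 2, 3)))
  if (nchar(tok) == 3 && t3 %in% names(AA3_TO_1)) return(unname(AA3_TO_1[[t3]]))
  if (tok %in% c("X", "*", "Ter")) return("X")
  abort(sprintf("cannot parse %s residue token '%s' in variant label '%s'",
                what, tok, label), class = "cyp21act_parse_error")
}

#' Parse protein-level variant labels
#'
#' Parses labels of the form `"p.<wt><pos><mut>"` where the residue codes are
#' one- or three-letter amino-acid codes, the replacement may be a stop token
#' (`"X"`, `"*"`, `"Ter"`) or the frameshift suffix `"fs"`, and the position
#' is a 1-based integer on the reference protein sequence. Three-letter codes
#' are normalized to one-letter. The variant kind is derived
#' deterministically: wild type equal to replacement gives `synonymous`, a
#' stop token gives `nonsense`, `"fs"` gives `frameshift`, anything else
#' `missense`.
#'
#' @param label Character vector of variant labels, e.g. `"p.L107Q"`.
#' @param max_position Upper bound for the residue position (the protein is
#'   494-495 residues long depending on the reference; the bound is
#'   configurable rather than hard-coded).
#' @return A tibble with one row per label and columns `wt_residue`,
#'   `position`, `mut_residue` (`"X"` for stop, `NA` for frameshift), `kind`
#'   and `raw_label`.
#' @examples
#' parse_protein_variant(c("p.L107Q", "p.H466fs", "p.Gln318Ter"))
#' @export
parse_protein_variant <- function(label, max_position = 495L) {
  stopifnot(is.character(label))
  rows <- lapply(label, parse_one_variant, max_position = max_position)
  dplyr::bind_rows(rows)
}

parse_one_variant <- function(label, max_position = 495L) {
  raw <- label
  lab <- trimws(label)
  core <- sub("^p\\.", "", lab)
  if (identical(core, lab)) {
    abort(sprintf("variant label '%s' lacks the 'p.' prefix", raw),
          class = "cyp21act_parse_error")
  }
  parts <- regmatches(core, regexec("^([A-Za-z]{1,3})(\\d+)([A-Za-z]{1,3}|\\*)$", core))[[1]]
  if (length(parts) == 0) {
    abort(sprintf("malformed variant label '%s'", raw),
          class = "cyp21act_parse_error")
  }
  wt_tok <- parts[2]; pos_tok <- parts[3]; mut_tok <- parts[4]
  position <- suppressWarnings(as.integer(pos_tok))
  if (is.na(position) || position < 1L) {
    abort(sprintf("invalid position '%s' in variant label '%s'", pos_tok, raw),
          class = "cyp21act_parse_error")
  }
  if (position > max_position) {
    abort(sprintf("position %d in '%s' exceeds the protein length bound %d",
                  position, raw, max_position),
          class = "cyp21act_parse_error")
  }
  wt <- normalize_aa(wt_tok, "wild-type", raw)
  if (identical(wt, "X")) {
    abort(sprintf("wild-type residue cannot be a stop token in '%s'", raw),
          class = "cyp21act_parse_error")
  }
  if (tolower(mut_tok) == "fs") {
    return(tibble(wt_residue = wt, position = position,
                  mut_residue = NA_character_, kind = "frameshift",
                  raw_label = raw))
  }
  mut <- normalize_aa(mut_tok, "replacement", raw)
  kind <- if (identical(mut, "X")) "nonsense"
          else if (identical(mut, wt)) "synonymous"
          else "missense"
  tibble(wt_residue = wt, position = position, mut_residue = mut,
         kind = kind, raw_label = raw)
}

#' Format parsed variants back into canonical labels
#'
#' Inverse of [parse_protein_variant()]: `parse_protein_variant(format_protein_variant(v))`
#' reproduces `v` for every valid variant.
#'
#' @param variants Tibble as returned by [parse_protein_variant()].
#' @return Character vector of canonical one-letter labels (`"p.L107Q"`,
#'   `"p.Q318X"`, `"p.H466fs"`).
#' @export
format_protein_variant <- function(variants) {
  stopifnot(all(c("wt_residue", "position", "kind") %in% names(variants)))
  mut <- ifelse(variants$kind == "frameshift", "fs", variants$mut_residue)
  paste0("p.", variants$wt_residue, variants$position, mut)
}

SUBSTRATE_LEVELS <- c("OHP17", "progesterone")

normalize_substrate <- function(x) {
  key <- gsub("[^a-z0-9]", "", tolower(x))
  out <- dplyr::case_when(
    key %in% c("17ohp", "ohp17", "17hydroxyprogesterone") ~ "OHP17",
    key %in% c("p", "prog", "progesterone") ~ "progesterone",
    TRUE ~ NA_character_
  )
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) {
    abort(sprintf("unknown substrate value(s): %s",
                  paste(unique(x[bad]), collapse = ", ")),
          class = "cyp21act_format_error")
  }
  out
}

# Display convention for activity percentages: "≥100" when capped, integers
# unchanged, one decimal at or above 0.1, two decimals below 0.1.
#' Format activity percentages for report tables
#'
#' @param x Numeric activity percentages.
#' @param capped Logical vector; `TRUE` marks predictions clamped at the
#'   100% cap, displayed as `">=100"` (rendered with the Unicode >= sign).
#' @return Character vector.
#' @export
format_activity_display <- function(x, capped = rep(FALSE, length(x))) {
  stopifnot(length(x) == length(capped))
  out <- character(length(x))
  for (i in seq_along(x)) {
    if (is.na(x[i])) { out[i] <- NA_character_; next }
    if (isTRUE(capped[i])) { out[i] <- "≥100"; next }
    if (abs(x[i] - round(x[i])) < 1e-9) out[i] <- format(round(x[i]), scientific = FALSE)
    else if (x[i] >= 0.1) out[i] <- sprintf("%.1f", x[i])
    else out[i] <- sprintf("%.2f", x[i])
  }
  out
}

parse_activity_display <- function(x) {
  capped <- grepl("^≥", x) | grepl("^>=", x)
  val <- suppressWarnings(as.numeric(sub("^(≥|>=)", "", x)))
  list(value = val, capped = capped & !is.na(val))
}

#' Read a variant/activity table
#'
#' Reads a tab- or comma-separated table with a header row, parses the
#' variant labels, and validates optional activity measurements. Empty
#' activity cells yield absent measurements (`NA`), never zeros. A cell of
#' the form `">=100"` / `"≥100"` is parsed as 100 with `capped = TRUE`.
#'
#' @param path File path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param col_map Named list mapping the roles `variant`, `activity`,
#'   `substrate`, `sd`, `source` to column names in the file. Roles absent
#'   from the file may be omitted.
#' @param max_position Passed to [parse_protein_variant()].
#' @return Tibble with the parsed variant columns, `activity_pct`, `capped`,
#'   `substrate`, `sd_pct`, `source`, plus any unmapped columns carried
#'   through as annotations.
#' @details Rows whose variant label fails to parse are reported with their
#'   line number in a single error. Duplicate variant+substrate rows trigger
#'   a warning and the last row wins. Negative activities are a validation
#'   error, and a row with an activity but no substrate is rejected: the
#'   substrate is never defaulted silently.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "csv"),
                               col_map = list(variant = "variant",
                                              activity = "activity",
                                              substrate = "substrate",
                                              sd = "sd", source = "source"),
                               max_position = 495L) {
  dialect <- match.arg(dialect)
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  if (!col_map$variant %in% names(raw)) {
    abort(sprintf("mandatory variant column '%s' missing from %s",
                  col_map$variant, path), class = "cyp21act_format_error")
  }
  labels <- raw[[col_map$variant]]
  parsed <- vector("list", length(labels))
  bad <- integer(0)
  for (i in seq_along(labels)) {
    parsed[[i]] <- tryCatch(parse_one_variant(labels[i], max_position),
                            error = function(e) {bad <<- c(bad, i); NULL})
  }
  if (length(bad)) {
    abort(sprintf("unparseable variant label(s) at line(s) %s of %s: %s",
                  paste(bad + 1L, collapse = ", "), path,
                  paste(labels[bad], collapse = ", ")),
          class = "cyp21act_parse_error")
  }
  out <- if (length(parsed) == 0) {
    tibble(wt_residue = character(0), position = integer(0),
           mut_residue = character(0), kind = character(0),
           raw_label = character(0))
  } else {
    dplyr::bind_rows(parsed)
  }

  act_col <- col_map$activity %||% "activity"
  if (act_col %in% names(raw)) {
    disp <- parse_activity_display(raw[[act_col]])
    blank <- is.na(raw[[act_col]]) | raw[[act_col]] == ""
    if (any(!blank & is.na(disp$value))) {
      abort(sprintf("non-numeric activity at line(s) %s of %s",
                    paste(which(!blank & is.na(disp$value)) + 1L, collapse = ", "),
                    path), class = "cyp21act_format_error")
    }
    if (any(disp$value < 0, na.rm = TRUE)) {
      abort(sprintf("negative activity percentage at line(s) %s of %s",
                    paste(which(disp$value < 0) + 1L, collapse = ", "), path),
            class = "cyp21act_format_error")
    }
    out$activity_pct <- disp$value
    out$capped <- disp$capped
  } else {
    out$activity_pct <- NA_real_
    out$capped <- FALSE
  }

  sub_col <- col_map$substrate %||% "substrate"
  if (sub_col %in% names(raw)) {
    out$substrate <- normalize_substrate(raw[[sub_col]])
  } else {
    out$substrate <- NA_character_
  }
  if (any(!is.na(out$activity_pct) & is.na(out$substrate))) {
    abort("rows with an activity measurement must state the substrate explicitly",
          class = "cyp21act_format_error")
  }

  sd_col <- col_map$sd %||% "sd"
  out$sd_pct <- if (sd_col %in% names(raw))
    suppressWarnings(as.numeric(raw[[sd_col]])) else NA_real_
  if (any(out$sd_pct < 0, na.rm = TRUE)) {
    abort("negative activity SD", class = "cyp21act_format_error")
  }
  src_col <- col_map$source %||% "source"
  out$source <- if (src_col %in% names(raw)) raw[[src_col]] else NA_character_

  mapped <- unlist(col_map, use.names = FALSE)
  extra <- setdiff(names(raw), mapped)
  for (nm in extra) out[[nm]] <- raw[[nm]]

  dup <- duplicated(paste(out$raw_label, out$substrate), fromLast = TRUE) &
    !is.na(out$activity_pct)
  if (any(dup)) {
    warn(sprintf("duplicate variant+substrate rows (%s): keeping the last occurrence",
                 paste(unique(out$raw_label[dup]), collapse = ", ")))
    out <- out[!dup, , drop = FALSE]
  }
  out
}

#' Write a report table
#'
#' Writes records in a deterministic column order with activities rendered by
#' the display convention of [format_activity_display()]. The file is
#' re-readable by [read_variant_table()], preserving variant identity and
#' numeric values to displayed precision.
#'
#' @param records Tibble; must carry `raw_label` (or the parsed variant
#'   columns) and may carry `activity_pct`/`activity_pred_pct`, `capped`,
#'   `substrate`, `sd_pct`, `source` and further annotation columns.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report_table <- function(records, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  records <- as_tibble(records)
  if (!"raw_label" %in% names(records)) {
    if (all(c("wt_residue", "position", "kind") %in% names(records))) {
      records$raw_label <- format_protein_variant(records)
    } else {
      abort("records must carry 'raw_label' or parsed variant columns",
            class = "cyp21act_format_error")
    }
  }
  act <- col_or(records, "activity_pred_pct",
                col_or(records, "activity_pct", rep(NA_real_, nrow(records))))
  capped <- col_or(records, "capped", rep(FALSE, nrow(records)))
  out <- tibble(
    variant = records$raw_label,
    substrate = col_or(records, "substrate", rep(NA_character_, nrow(records))),
    activity = format_activity_display(act, capped),
    sd = col_or(records, "sd_pct", rep(NA_real_, nrow(records))),
    source = col_or(records, "source", rep(NA_character_, nrow(records)))
  )
  carry <- setdiff(names(records),
                   c("variant", "raw_label", "wt_residue", "position",
                     "mut_residue", "kind", "activity_pct",
                     "activity_pred_pct", "capped", "substrate", "sd_pct",
                     "source", "activity", "sd"))
  for (nm in carry) out[[nm]] <- records[[nm]]
  writer <- if (dialect == "tsv") readr::write_tsv else readr::write_csv
  writer(out, path, progress = FALSE)
  invisible(path)
}
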