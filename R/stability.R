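# Ingestion of stability-predictor output (FoldX-style) and replica
# aggregation into mean +/- SD ddG per variant per template. Sign
# convention throughout: positive ddG (kcal/mol) = destabilizing.

TEMPLATE_LEVELS <- c("human_4Y8W", "bovine_3QZ1_model")

#' Analysis configuration: thresholds of the activity pipeline
#'
#' @param destabilization_threshold ddG (kcal/mol) above which a variant is
#'   called significantly destabilizing; default 1.6 (twice the predictor's
#'   standard deviation). The comparison is strict: exactly 1.6 is not
#'   destabilizing.
#' @param ddg_fit_cap Maximum ddG (kcal/mol) used when fitting the
#'   calibration; default 5.5, where measured activities saturate near 0%.
#' @param nonpathogenic_activity_threshold Residual activity (%) above which
#'   a variant is called non-pathogenic; default 75.
#' @param activity_cap Display/prediction cap on residual activity (%);
#'   default 100.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(destabilization_threshold = 1.6,
                            ddg_fit_cap = 5.5,
                            nonpathogenic_activity_threshold = 75,
                            activity_cap = 100) {
  vals <- c(destabilization_threshold, ddg_fit_cap,
            nonpathogenic_activity_threshold, activity_cap)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all analysis thresholds must be positive and finite",
          class = "cyp21act_config_error")
  }
  structure(list(destabilization_threshold = destabilization_threshold,
                 ddg_fit_cap = ddg_fit_cap,
                 nonpathogenic_activity_threshold = nonpathogenic_activity_threshold,
                 activity_cap = activity_cap),
            class = "analysis_config")
}

#' Aggregate replica ddG values
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator; 0 for a
#' single replica) of per-replica ddG estimates.
#'
#' @param values Numeric vector of ddG values (kcal/mol), at least one.
#' @return One-row tibble with `ddg_mean`, `ddg_sd`, `n_replicas`.
#' @examples
#' aggregate_replicas(c(1, 2, 3, 4, 5)) # mean 3, sd 1.5811
#' @export
aggregate_replicas <- function(values) {
  if (length(values) == 0 || any(!is.finite(values))) {
    abort("aggregate_replicas requires at least one finite value",
          class = "cyp21act_domain_error")
  }
  tibble(ddg_mean = mean(values),
         ddg_sd = if (length(values) == 1L) 0 else stats::sd(values),
         n_replicas = length(values))
}

#' Destabilization call
#'
#' `TRUE` when the mean ddG strictly exceeds the destabilization threshold.
#'
#' @param estimate Numeric vector of mean ddG values, or a tibble with a
#'   `ddg_mean` column.
#' @param cfg An [analysis_config()].
#' @return Logical vector.
#' @export
is_destabilizing <- function(estimate, cfg = analysis_config()) {
  x <- if (is.data.frame(estimate)) estimate$ddg_mean else estimate
  x > cfg$destabilization_threshold
}

normalize_template <- function(x) {
  key <- gsub("[^a-z0-9]", "", tolower(x))
  out <- dplyr::case_when(
    key %in% c("human4y8w", "human", "4y8w", "crystal") ~ "human_4Y8W",
    key %in% c("bovine3qz1model", "bovine", "3qz1", "bovinemodel",
               "bovine3qz1") ~ "bovine_3QZ1_model",
    TRUE ~ NA_character_
  )
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    abort(sprintf("unknown template value(s): %s",
                  paste(unique(x[bad]), collapse = ", ")),
          class = "cyp21act_format_error")
  }
  out
}

# FoldX mutant codes are chain-qualified one-letter strings such as
# "LA107Q" (Leu, chain A, 107 -> Gln). Translate to the protein-level label.
foldx_code_to_label <- function(code) {
  code <- sub("_\\d+$", "", sub("\\.pdb$", "", code))
  m <- regmatches(code, regexec("^([A-Za-z])([A-Za-z])(\\d+)([A-Za-z])$", code))[[1]]
  if (length(m) == 0) {
    abort(sprintf("cannot translate FoldX mutant code '%s'", code),
          class = "cyp21act_parse_error")
  }
  paste0("p.", toupper(m[2]), m[4], toupper(m[5]))
}

read_fxout_rows <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^Pdb\\t", lines)
  if (length(hdr) == 0) {
    abort(sprintf("no 'Pdb' column header found in %s: not an fxout file", path),
          class = "cyp21act_format_error")
  }
  body <- lines[seq(hdr[1] + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(body, "\t", fixed = TRUE)
  list(header = strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]],
       fields = fields)
}

#' Read a ddG table and aggregate replicas
#'
#' Supported dialects:
#' \describe{
#'   \item{`generic_tsv`}{Columns `variant`, `template`, and either `ddg`
#'     (long form, one row per replica) or precomputed `ddg_mean` with
#'     optional `ddg_sd`.}
#'   \item{`foldx_dif`}{A `Dif_*.fxout` layout: banner lines, then a
#'     tab-separated table headed by `Pdb`, one row per replica with the
#'     mutant's chain-qualified code (e.g. `LA107Q_1.pdb`) and the energy
#'     difference in the second column.}
#'   \item{`foldx_average`}{An `Average_*.fxout` layout: one row per mutant
#'     with the pre-averaged energy difference and its SD.}
#' }
#' Replica counts other than the canonical five produce a warning, not an
#' error. The package never runs FoldX itself; for users who have it, the
#' expected upstream commands are RepairPDB followed by BuildModel with
#' `numberOfRuns=5`.
#'
#' @param path Input file.
#' @param dialect One of `"generic_tsv"`, `"foldx_dif"`, `"foldx_average"`.
#' @param template Template label applied to fxout dialects (which do not
#'   record it); one of `"human_4Y8W"`, `"bovine_3QZ1_model"`.
#' @return Tibble with one row per variant+template: parsed variant columns,
#'   `template`, `replicas` (list-column), `ddg_mean`, `ddg_sd`,
#'   `n_replicas`. Provenance (file, dialect) is kept in attributes.
#' @export
read_ddg_table <- function(path, dialect = c("generic_tsv", "foldx_dif",
                                             "foldx_average"),
                           template = NULL) {
  dialect <- match.arg(dialect)
  out <- switch(dialect,
    generic_tsv = read_ddg_generic(path),
    foldx_dif = read_ddg_foldx_dif(path, template),
    foldx_average = read_ddg_foldx_average(path, template))
  short <- out$n_replicas != 5L
  if (any(short)) {
    warn(sprintf("replica count differs from the canonical 5 for: %s",
                 paste(out$raw_label[short], collapse = ", ")))
  }
  attr(out, "source_file") <- path
  attr(out, "dialect") <- dialect
  out
}

read_ddg_generic <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("variant", "template") %in% names(raw))) {
    abort(sprintf("generic ddG table %s needs 'variant' and 'template' columns",
                  path), class = "cyp21act_format_error")
  }
  raw$template <- normalize_template(raw$template)
  if ("ddg" %in% names(raw)) {
    ddg <- suppressWarnings(as.numeric(raw$ddg))
    bad <- which(is.na(ddg) & !is.na(raw$ddg))
    if (length(bad)) {
      abort(sprintf("unparseable ddG value at line(s) %s of %s",
                    paste(bad + 1L, collapse = ", "), path),
            class = "cyp21act_format_error")
    }
    raw$ddg <- ddg
    grouped <- raw |>
      dplyr::group_by(.data$variant, .data$template) |>
      dplyr::summarise(replicas = list(.data$ddg), .groups = "drop")
    agg <- dplyr::bind_rows(lapply(grouped$replicas, aggregate_replicas))
    est <- dplyr::bind_cols(grouped, agg)
  } else if ("ddg_mean" %in% names(raw)) {
    est <- tibble(variant = raw$variant, template = raw$template,
                  replicas = lapply(as.numeric(raw$ddg_mean), identity),
                  ddg_mean = as.numeric(raw$ddg_mean),
                  ddg_sd = if ("ddg_sd" %in% names(raw))
                    dplyr::coalesce(as.numeric(raw$ddg_sd), 0) else 0,
                  n_replicas = 1L)
  } else {
    abort(sprintf("%s has neither 'ddg' nor 'ddg_mean' columns", path),
          class = "cyp21act_format_error")
  }
  parsed <- parse_protein_variant(est$variant)
  dplyr::bind_cols(parsed, est[, setdiff(names(est), "variant")])
}

require_template <- function(template) {
  if (is.null(template) || is.na(template)) {
    abort("a template label must be stated when reading fxout dialects",
          class = "cyp21act_format_error")
  }
  template
}

read_ddg_foldx_dif <- function(path, template) {
  require_template(template)
  rows <- read_fxout_rows(path)
  codes <- vapply(rows$fields, `[[`, character(1), 1L)
  ddg <- vapply(rows$fields, function(f) suppressWarnings(as.numeric(f[2])),
                numeric(1))
  if (any(is.na(ddg))) {
    abort(sprintf("unparseable energy value in %s", path),
          class = "cyp21act_format_error")
  }
  labels <- vapply(codes, foldx_code_to_label, character(1))
  grouped <- tibble(variant = labels, ddg = ddg) |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(replicas = list(.data$ddg), .groups = "drop")
  agg <- dplyr::bind_rows(lapply(grouped$replicas, aggregate_replicas))
  est <- dplyr::bind_cols(grouped, agg)
  est$template <- normalize_template(template %||% NA_character_)
  parsed <- parse_protein_variant(est$variant)
  out <- dplyr::bind_cols(parsed, est[, setdiff(names(est), "variant")])
  out[, c(names(parsed), "template", "replicas", "ddg_mean", "ddg_sd",
          "n_replicas")]
}

read_ddg_foldx_average <- function(path, template) {
  require_template(template)
  rows <- read_fxout_rows(path)
  codes <- vapply(rows$fields, `[[`, character(1), 1L)
  mu <- vapply(rows$fields, function(f) suppressWarnings(as.numeric(f[2])),
               numeric(1))
  sdv <- vapply(rows$fields, function(f) suppressWarnings(as.numeric(f[3])),
                numeric(1))
  if (any(is.na(mu))) {
    abort(sprintf("unparseable energy value in %s", path),
          class = "cyp21act_format_error")
  }
  labels <- vapply(codes, foldx_code_to_label, character(1))
  parsed <- parse_protein_variant(labels)
  out <- dplyr::bind_cols(parsed, tibble(
    template = normalize_template(rep(template %||% NA_character_, length(mu))),
    replicas = lapply(mu, identity),
    ddg_mean = mu,
    ddg_sd = dplyr::coalesce(sdv, 0),
    n_replicas = 5L  # Average fxout summarises the canonical five runs
  ))
  out
}
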