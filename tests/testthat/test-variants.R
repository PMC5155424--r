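test_that("variant labels parse with the right kind and round-trip", {
  cases <- tibble::tribble(
    ~label,         ~wt,  ~pos, ~mut,          ~kind,
    "p.L107Q",      "L",  107L, "Q",           "missense",
    "p.L122R",      "L",  122L, "R",           "missense",
    "p.R132H",      "R",  132L, "H",           "missense",
    "p.P335L",      "P",  335L, "L",           "missense",
    "p.H466fs",     "H",  466L, NA_character_, "frameshift",
    "p.Q318X",      "Q",  318L, "X",           "nonsense",
    "p.A100A",      "A",  100L, "A",           "synonymous",
    "p.Leu107Gln",  "L",  107L, "Q",           "missense",
    "p.Gln318Ter",  "Q",  318L, "X",           "nonsense",
    " p.V281L ",    "V",  281L, "L",           "missense"
  )
  parsed <- parse_protein_variant(cases$label)
  expect_equal(parsed$wt_residue, cases$wt)
  expect_equal(parsed$position, cases$pos)
  expect_equal(parsed$mut_residue, cases$mut)
  expect_equal(parsed$kind, cases$kind)
  # canonical round trip (three-letter normalizes to one-letter)
  canon <- format_protein_variant(parsed)
  expect_identical(parse_protein_variant(canon)[, 1:4], parsed[, 1:4])
})

test_that("malformed labels are rejected with informative errors", {
  expect_error(parse_protein_variant("L107Q"), "prefix")
  expect_error(parse_protein_variant("p.L0Q"), "position")
  expect_error(parse_protein_variant("p.L999Q"), "exceeds")
  expect_error(parse_protein_variant("p.107Q"), class = "cyp21act_parse_error")
  expect_error(parse_protein_variant("p.LxQ"), class = "cyp21act_parse_error")
  expect_error(parse_protein_variant("p.B107Q"), "residue token")
  expect_error(parse_protein_variant("p.X107Q"), class = "cyp21act_parse_error")
  # configurable length bound
  expect_silent(parse_protein_variant("p.L600Q", max_position = 600L))
})

test_that("parser accepts exactly the grammar (property over random labels)", {
  set.seed(42)
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  for (i in 1:50) {
    wt <- sample(aa, 1); pos <- sample(1:495, 1)
    mut <- sample(c(aa, "X", "fs"), 1)
    lab <- paste0("p.", wt, pos, mut)
    v <- parse_protein_variant(lab)
    expect_identical(format_protein_variant(v), lab)
  }
  for (bad in c("p.", "pL107Q", "p.L1 07Q", "p.LQ", "p.L107", "q.L107Q")) {
    expect_error(parse_protein_variant(bad), class = "cyp21act_parse_error")
  }
})

test_that("activity display uses the table's mixed precision", {
  expect_identical(format_activity_display(c(4.4, 22.5, 100, 0.0569, 0.1, 1)),
                   c("4.4", "22.5", "100", "0.06", "0.1", "1"))
  expect_identical(format_activity_display(100, capped = TRUE), "≥100")
})

test_that("variant tables read, validate, and round-trip through reports", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant\tactivity\tsubstrate",
               "p.Y59N\t\t",
               "p.V69L\t22.5\t17-OHP"), path)
  tbl <- read_variant_table(path)
  expect_equal(nrow(tbl), 2)
  expect_true(is.na(tbl$activity_pct[1]))   # absent, not zero
  expect_equal(tbl$activity_pct[2], 22.5)
  expect_equal(tbl$substrate[2], "OHP17")

  # negative percent rejected
  writeLines(c("variant\tactivity\tsubstrate", "p.Y59N\t-3\t17-OHP"), path)
  expect_error(read_variant_table(path), "negative")
  # activity without substrate rejected (never defaulted)
  writeLines(c("variant\tactivity", "p.Y59N\t20"), path)
  expect_error(read_variant_table(path), "substrate")
  # missing variant column
  writeLines(c("mutant\tactivity", "p.Y59N\t20"), path)
  expect_error(read_variant_table(path), "variant column")
  # duplicates: warning, last wins
  writeLines(c("variant\tactivity\tsubstrate",
               "p.Y59N\t10\t17-OHP", "p.Y59N\t20\t17-OHP"), path)
  expect_warning(tbl <- read_variant_table(path), "last")
  expect_equal(tbl$activity_pct, 20)

  # report round trip preserves identity and displayed precision
  out <- withr::local_tempfile(fileext = ".tsv")
  recs <- tibble::tibble(raw_label = c("p.K102R", "p.S165P", "p.F404S"),
                         activity_pred_pct = c(100, 0.1055, 0.0569),
                         capped = c(TRUE, FALSE, FALSE),
                         substrate = "OHP17")
  write_report_table(recs, out)
  back <- read_variant_table(out, col_map = list(variant = "variant",
                                                 activity = "activity",
                                                 substrate = "substrate"))
  expect_equal(back$raw_label, recs$raw_label)
  expect_equal(back$activity_pct, c(100, 0.1, 0.06))
  expect_equal(back$capped, c(TRUE, FALSE, FALSE))

  # empty record list -> header-only file
  write_report_table(recs[0, ], out)
  expect_equal(nrow(read_variant_table(out, col_map = list(variant = "variant",
                                                           activity = "activity",
                                                           substrate = "substrate"))), 0)
})
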