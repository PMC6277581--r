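#' @importFrom rlang .data abort warn
#' @importFrom dplyr mutate filter arrange group_by ungroup summarise n left_join bind_rows row_number select
#' @importFrom purrr map map_int map_dbl map_chr map_lgl map2 pmap
#' @importFrom tibble tibble as_tibble
NULL

# FMR1 CGG-repeat category boundaries (repeats):
#   normal 5-44, intermediate/gray zone 45-54, premutation 55-199,
#   full mutation >= 200. Counts 1-4 are below the conventional normal floor
# but are still non-expanded; they map to NL with a warning.
.category_levels <- c("NL", "IM_GZ", "PM", "FM")

#' Repeat-count category of an FMR1 CGG allele
#'
#' Maps CGG-repeat counts to the standard fragile X allele classes:
#' normal (`NL`, 5--44), intermediate/gray zone (`IM_GZ`, 45--54),
#' premutation (`PM`, 55--199) and full mutation (`FM`, >= 200).
#' Counts of 1--4 repeats, below the conventional normal floor, are mapped
#' to `NL` with a warning: the screen only distinguishes expanded from
#' non-expanded alleles, and very short alleles behave as normal.
#'
#' @param repeats Integer vector of CGG repeat counts (>= 1).
#' @return A factor with levels `NL`, `IM_GZ`, `PM`, `FM`, same length as
#'   `repeats`.
#' @examples
#' repeat_category(c(30, 45, 54, 55, 199, 200, 545))
#' @export
repeat_category <- function(repeats) {
  if (length(repeats) == 0) {
    return(factor(character(), levels = .category_levels))
  }
  if (any(!is.finite(repeats)) || any(repeats < 1)) {
    abort("`repeats` must be finite and >= 1.")
  }
  if (any(repeats > 2000)) {
    abort("`repeats` beyond 2000 exceeds the sanity cap for this assay.")
  }
  if (any(repeats < 5)) {
    warn("repeat counts below 5 are below the normal floor; mapped to NL.")
  }
  cut(as.numeric(repeats),
    breaks = c(-Inf, 44, 54, 199, Inf),
    labels = .category_levels, right = TRUE
  )
}

# rank helper used by monotonicity checks
category_rank <- function(category) match(as.character(category), .category_levels)

# Parse one allele token: either an integer repeat count or a range "a-b"
# (repeat-size smear, e.g. "423-850"); a range is represented by its upper
# bound, the species the screen responds to.
parse_allele_token <- function(token) {
  token <- trimws(token)
  if (grepl("^\\d+$", token)) {
    return(as.integer(token))
  }
  if (grepl("^\\d+\\s*-\\s*\\d+$", token)) {
    bounds <- as.integer(strsplit(token, "-")[[1]])
    return(max(bounds))
  }
  abort(paste0("cannot parse allele token '", token, "'"))
}

# Parse a ";"-joined allele string into a component table. The first allele
# (males) or first two (females) are primary; remaining species are mosaic
# components sharing `mosaic_mass` of the template in equal fractions (0.3:
# a visible minority population whose ladder still clears detection floors
# while leaving the primary alleles' amplitude steps callable).
parse_genotype <- function(alleles, sex, mosaic_mass = 0.3) {
  tokens <- strsplit(alleles, ";", fixed = TRUE)[[1]]
  reps <- vapply(tokens, parse_allele_token, integer(1), USE.NAMES = FALSE)
  if (length(reps) == 0) abort("empty allele list")
  n_primary <- if (sex == "M") 1L else 2L
  n_primary <- min(n_primary, length(reps))
  n_mosaic <- length(reps) - n_primary
  if (n_mosaic > 0) {
    frac_primary <- (1 - mosaic_mass) / n_primary
    frac_mosaic <- mosaic_mass / n_mosaic
  } else {
    frac_primary <- 1 / n_primary
    frac_mosaic <- numeric()
  }
  tibble(
    repeats = reps,
    fraction = c(rep(frac_primary, n_primary), rep(frac_mosaic, n_mosaic)),
    role = c(rep("primary", n_primary), rep("mosaic", n_mosaic))
  )
}

# Validation notes for one record; genotype irregularities are flagged, never
# silently repaired (e.g. the reference cohort carries one male listed with
# two alleles).
genotype_notes <- function(parsed, sex) {
  notes <- character()
  raw_n <- nrow(parsed)
  if (sex == "M" && raw_n != 1L) notes <- c(notes, "sex_allele_mismatch")
  if (sex == "F" && raw_n < 2L) notes <- c(notes, "sex_allele_mismatch")
  if (any(parsed$repeats < 5)) notes <- c(notes, "short_allele")
  if (length(notes) == 0) NA_character_ else paste(notes, collapse = ";")
}

#' Construct a genotype table row
#'
#' Convenience constructor for a one-row cohort-style tibble, handy for
#' simulating single samples.
#'
#' @param sample_id Sample identifier.
#' @param sex `"M"` or `"F"`.
#' @param alleles Allele string: `";"`-joined repeat counts, e.g. `"29;128"`.
#'   Males have one primary allele, females two; additional entries are
#'   treated as mosaic species. A token `"a-b"` denotes a repeat-size smear
#'   and is represented by its upper bound.
#' @param dna_conc DNA concentration in ng/uL (default 25).
#' @param status Optional known category label (`NL`, `PM`, `FM`).
#' @return A one-row tibble with parsed `genotype` list-column.
#' @examples
#' genotype_tbl("S1", "F", "29;128")
#' @export
genotype_tbl <- function(sample_id, sex, alleles, dna_conc = 25, status = NA_character_) {
  as_cohort(tibble(
    sample_id = as.character(sample_id), sex = sex,
    alleles = as.character(alleles), status = status, dna_conc = dna_conc
  ))
}

# Attach parsed genotype list-column and validation notes to a raw cohort
# data frame.
as_cohort <- function(df) {
  needed <- c("sample_id", "sex", "alleles")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(paste("cohort table lacks column(s):", paste(missing_cols, collapse = ", ")))
  }
  if (!all(df$sex %in% c("M", "F"))) {
    bad <- df$sample_id[!df$sex %in% c("M", "F")]
    abort(paste("sex must be M or F; offending sample(s):", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) {
    abort("duplicate sample_id values in cohort table")
  }
  df <- as_tibble(df)
  if (!"status" %in% names(df)) df$status <- NA_character_
  if (!"dna_conc" %in% names(df)) df$dna_conc <- 25
  df$dna_conc[is.na(df$dna_conc)] <- 25
  parsed <- map2(df$alleles, df$sex, function(a, s) {
    tryCatch(parse_genotype(a, s), error = function(e) e)
  })
  bad <- map_lgl(parsed, inherits, "error")
  if (any(bad)) {
    abort(paste(
      "malformed allele string for sample(s):",
      paste(df$sample_id[bad], collapse = ", ")
    ))
  }
  df$genotype <- parsed
  df$qc_note <- purrr::map2_chr(parsed, df$sex, genotype_notes)
  if (any(!is.na(df$qc_note))) {
    warn(paste(
      "genotype irregularities flagged for sample(s):",
      paste(df$sample_id[!is.na(df$qc_note)], collapse = ", ")
    ))
  }
  df
}

#' Largest repeat species per sample
#'
#' Adds a `max_allele` column: the largest repeat count across primary
#' alleles and mosaic components. The screen responds to the largest
#' species present, so classification of a genotype is
#' `repeat_category(max_allele)`.
#'
#' @param cohort A cohort tibble (see [load_cohort()] or [genotype_tbl()]).
#' @return `cohort` with an integer `max_allele` column.
#' @export
max_allele <- function(cohort) {
  cohort <- ensure_cohort(cohort)
  cohort$max_allele <- map_int(cohort$genotype, function(g) {
    if (nrow(g) == 0) abort("empty allele list")
    max(g$repeats)
  })
  cohort
}

ensure_cohort <- function(df) {
  if (!"genotype" %in% names(df)) df <- suppressWarnings(as_cohort(df)) else df
}

#' Read a cohort genotype table
#'
#' Reads a UTF-8 CSV/TSV with columns `sample_id`, `sex` (`M`/`F`),
#' `alleles` (`";"`-joined repeat counts) and `status` (`NL`/`PM`/`FM`),
#' parses genotypes and validates the records. Irregular records (e.g. a
#' male listed with two alleles) are retained with a `qc_note` flag and a
#' warning, never dropped.
#'
#' @param path Path to the table. Delimiter is inferred from the extension
#'   (`.tsv` = tab, otherwise comma).
#' @return A cohort tibble with `genotype` list-column and `qc_note`.
#' @seealso [fxs_cohort()] for the packaged 151-sample reference cohort.
#' @export
load_cohort <- function(path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- tryCatch(
    readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste("cannot parse cohort table:", conditionMessage(e)))
  )
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(paste("malformed row at line(s):", paste(unique(prob$row), collapse = ", ")))
  }
  needed <- c("sample_id", "sex", "alleles", "status")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste("cohort table lacks column(s):", paste(missing_cols, collapse = ", ")))
  }
  raw$sample_id <- as.character(raw$sample_id)
  as_cohort(raw)
}

#' Write a cohort genotype table
#'
#' Writes the plain tabular columns of a cohort tibble (everything except
#' derived list-columns) so that `load_cohort(write_cohort(x, f))`
#' round-trips content-identically.
#'
#' @param cohort Cohort tibble.
#' @param path Output path (`.tsv` for tab-separated, otherwise CSV).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  keep <- setdiff(names(cohort), c("genotype", "qc_note", "max_allele"))
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(cohort[keep], path, delim = delim)
  invisible(path)
}

#' The packaged 151-sample reference cohort
#'
#' The dried-blood-spot validation cohort: 151 previously genotyped samples
#' (75 male, 76 female) with known FMR1 repeat genotypes, including
#' premutation and full-mutation carriers, mosaic genotypes, one male
#' recorded with two alleles (flagged, not repaired) and per-sample DNA
#' concentration annotations for the two samples with documented
#' low-template behaviour.
#'
#' @return A cohort tibble of 151 records.
#' @export
fxs_cohort <- function() {
  path <- system.file("extdata", "table1_cohort.csv", package = "fxscreen")
  suppressWarnings(load_cohort(path))
}

#' Intermediate/gray-zone boundary control DNAs
#'
#' The four reference genomic DNAs that demarcate the 46--54-repeat
#' intermediate/gray-zone boundary in every run. Their melt peaks bracket the
#' decision zone: samples melting clearly above the hottest control are
#' expansion-positive, clearly below the coolest control expansion-negative.
#' Exact repeat counts across the set span the 46--54 interval.
#'
#' @return A 4-row cohort tibble.
#' @export
boundary_controls <- function() {
  as_cohort(tibble(
    sample_id = c("NA20230", "NA20232", "NA20234", "NA20236"),
    sex = "M",
    alleles = c("46", "49", "51", "54"),
    status = "IM_GZ",
    dna_conc = 25
  ))
}
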