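# Cohort table ingestion, validation and descriptive counts.

COHORT_COLUMNS <- c("sample_id", "sex", "age_years", "histology",
                    "localization", "methylation_class", "classifier_score",
                    "alteration", "detection_method")

#' Path to the packaged pLGG cohort fixture
#'
#' An 18-sample pediatric low-grade glioma cohort (id, sex, age, histology,
#' localization, methylation class and classifier score, BRAF/MAPK alteration
#' and its detection method), shipped as a tab-separated file.
#'
#' @return Path to the TSV file.
#' @export
#' @examples
#' cohort <- read_cohort(plgg_cohort_path())
#' nrow(cohort)
plgg_cohort_path <- function() {
  system.file("extdata", "plgg_cohort.tsv", package = "plggtcf",
              mustWork = TRUE)
}

normalize_alteration <- function(x) {
  key <- tolower(gsub("[^a-z0-9]+", "", tolower(x)))
  dplyr::case_when(
    grepl("kiaa1549", key) ~ "KIAA1549_BRAF_FUSION",
    grepl("v600e", key) ~ "BRAF_V600E",
    grepl("prkar2b", key) ~ "PRKAR2B_BRAF_FUSION",
    grepl("ros1", key) ~ "COPC_ROS1_FUSION",
    grepl("599tt", key) ~ "BRAF_599TT_INS",
    grepl("brafduplication|duplication", key) ~ "BRAF_DUPLICATION",
    TRUE ~ "OTHER"
  )
}

normalize_methylation_class <- function(x) {
  key <- tolower(trimws(x))
  out <- x
  out[is.na(x) | key == "not done" | key == ""] <- METHYLATION_NOT_DONE
  out[!is.na(x) & grepl("^not classifiable", key)] <- METHYLATION_NOT_CLASSIFIABLE
  out
}

#' Read a cohort table
#'
#' Parses a cohort file into a validated tibble, one row per sample.
#' Alteration strings are normalized case-insensitively to the codes in
#' [alteration_levels()] (punctuation variants such as
#' `"KIAA1549:BRAF-fusion"` are tolerated); the methylation class strings
#' `"Not done"` / `"Not classifiable"` are mapped to the sentinels
#' `"NOT_DONE"` / `"NOT_CLASSIFIABLE"`. A missing classifier score is `NA`.
#'
#' @param path Path to the file. Header must carry the canonical columns:
#'   sample_id, sex, age_years, histology, localization, methylation_class,
#'   classifier_score, alteration, detection_method.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return Tibble with one validated record per row; `alteration` holds the
#'   normalized code, `alteration_label` the original string.
#' @export
read_cohort <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("cohort file not found: ", path), class = "plgg_io_error")
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  missing <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing) > 0) {
    abort(paste0("cohort file is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "plgg_schema_error")
  }
  if (nrow(raw) == 0) {
    return(tibble(
      sample_id = character(), sex = character(), age_years = numeric(),
      histology = character(), localization = character(),
      methylation_class = character(), classifier_score = numeric(),
      alteration = character(), alteration_label = character(),
      detection_method = character()
    ))
  }

  age <- suppressWarnings(as.numeric(raw$age_years))
  bad_age <- which(is.na(age) & !is.na(raw$age_years) |
                     (!is.na(age) & age < 0))
  if (length(bad_age) > 0) {
    abort(paste0("unparseable or negative age for sample(s): ",
                 paste(raw$sample_id[bad_age], collapse = ", ")),
          class = "plgg_row_error")
  }
  score_chr <- raw$classifier_score
  score_chr[score_chr %in% c("NA", "")] <- NA_character_
  score <- suppressWarnings(as.numeric(score_chr))
  bad_score <- which((is.na(score) & !is.na(score_chr)) |
                       (!is.na(score) & (score < 0 | score > 1)))
  if (length(bad_score) > 0) {
    abort(paste0("classifier score unparseable or outside [0, 1] for sample(s): ",
                 paste(raw$sample_id[bad_score], collapse = ", ")),
          class = "plgg_row_error")
  }
  if (anyDuplicated(raw$sample_id)) {
    abort(paste0("duplicate sample_id: ",
                 paste(unique(raw$sample_id[duplicated(raw$sample_id)]),
                       collapse = ", ")),
          class = "plgg_row_error")
  }
  bad_sex <- which(!raw$sex %in% c("F", "M"))
  if (length(bad_sex) > 0) {
    abort(paste0("sex must be F or M for sample(s): ",
                 paste(raw$sample_id[bad_sex], collapse = ", ")),
          class = "plgg_row_error")
  }

  tibble(
    sample_id = raw$sample_id,
    sex = raw$sex,
    age_years = age,
    histology = raw$histology,
    localization = raw$localization,
    methylation_class = normalize_methylation_class(raw$methylation_class),
    classifier_score = score,
    alteration = normalize_alteration(raw$alteration),
    alteration_label = raw$alteration,
    detection_method = raw$detection_method
  )
}

#' Write a cohort table
#'
#' Inverse of [read_cohort()]: serializes the normalized records so that a
#' write/read round trip reproduces them exactly. The original
#' `alteration_label` strings are written to the `alteration` column.
#'
#' @param records Cohort tibble from [read_cohort()].
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  out <- tibble(
    sample_id = records$sample_id,
    sex = records$sex,
    age_years = records$age_years,
    histology = records$histology,
    localization = records$localization,
    methylation_class = ifelse(
      records$methylation_class == METHYLATION_NOT_DONE, "Not done",
      ifelse(records$methylation_class == METHYLATION_NOT_CLASSIFIABLE,
             "Not classifiable", records$methylation_class)),
    classifier_score = records$classifier_score,
    alteration = if ("alteration_label" %in% names(records))
      records$alteration_label else records$alteration,
    detection_method = records$detection_method
  )
  writer <- if (dialect == "tsv") readr::write_tsv else readr::write_csv
  writer(out, path, progress = FALSE)
  invisible(path)
}

#' Count records with a given alteration
#'
#' @param records Cohort tibble.
#' @param target One of [alteration_levels()].
#' @return Integer count.
#' @export
#' @examples
#' cohort <- read_cohort(plgg_cohort_path())
#' count_by_alteration(cohort, "KIAA1549_BRAF_FUSION")  # 11
count_by_alteration <- function(records, target) {
  target <- match.arg(target, alteration_levels())
  sum(records$alteration == target)
}

#' Count samples trackable by ddPCR
#'
#' A sample can be followed longitudinally by ddPCR when its driver
#' alteration is detectable by one of the two assays: the exon-14/exon-3
#' duplication duplex (KIAA1549:BRAF fusion or plain BRAF duplication) or
#' the V600E mutation duplex. See [trackable_alterations()].
#'
#' @param records Cohort tibble.
#' @return Integer count of trackable samples.
#' @export
count_ddpcr_trackable <- function(records) {
  sum(records$alteration %in% trackable_alterations())
}

#' Default localization grouping
#'
#' Lookup from the anatomical site strings used in cohort tables to the
#' supratentorial / infratentorial dichotomy; sites outside the cranial
#' compartments (spinal) fall into `"other"`. Matching is case-insensitive
#' on a punctuation-stripped key.
#'
#' @return Named character vector: site key -> group.
#' @export
default_localization_map <- function() {
  c(
    "posterior fossa" = "infratentorial",
    "cerebellum" = "infratentorial",
    "brain stem" = "infratentorial",
    "brainstem" = "infratentorial",
    "midbrain" = "infratentorial",
    "parietooccipital" = "supratentorial",
    "parieto-occipital" = "supratentorial",
    "temporal" = "supratentorial",
    "left temporal" = "supratentorial",
    "right temporal" = "supratentorial",
    "optic pathway" = "supratentorial",
    "spinal" = "other"
  )
}

localization_group <- function(localization, map = default_localization_map()) {
  key <- tolower(trimws(localization))
  grp <- unname(map[key])
  grp[is.na(grp)] <- "other"
  grp
}

#' Summarize a cohort
#'
#' Descriptive counts over a validated cohort: totals by alteration, sex and
#' localization group, the five-number age summary, how many samples had
#' methylation profiling done and how many received an assigned methylation
#' class, and how many are trackable by the two ddPCR assays.
#'
#' @param records Nonempty cohort tibble from [read_cohort()].
#' @param localization_map Site-to-group lookup; see
#'   [default_localization_map()].
#' @return A list of class `"cohort_summary"`.
#' @export
#' @examples
#' summarize_cohort(read_cohort(plgg_cohort_path()))
summarize_cohort <- function(records,
                             localization_map = default_localization_map()) {
  if (nrow(records) == 0) {
    abort("cannot summarize an empty cohort", class = "plgg_empty_error")
  }
  counts_alt <- table(factor(records$alteration, levels = alteration_levels()))
  groups <- localization_group(records$localization, localization_map)
  structure(list(
    n = nrow(records),
    counts_by_alteration = as.list(counts_alt[counts_alt > 0]),
    counts_by_sex = as.list(table(records$sex)),
    counts_by_localization_group = as.list(
      table(factor(groups, levels = c("supratentorial", "infratentorial",
                                      "other")))),
    age_summary = five_number_summary(records$age_years),
    n_methylation_done = sum(records$methylation_class != METHYLATION_NOT_DONE),
    n_methylation_classified = sum(
      !records$methylation_class %in% c(METHYLATION_NOT_DONE,
                                        METHYLATION_NOT_CLASSIFIABLE)),
    n_ddpcr_trackable = count_ddpcr_trackable(records)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (n = ", x$n, ")\n", sep = "")
  cat("  alterations: ",
      paste(names(x$counts_by_alteration), unlist(x$counts_by_alteration),
            sep = "=", collapse = ", "), "\n", sep = "")
  cat("  sex: ", paste(names(x$counts_by_sex), unlist(x$counts_by_sex),
                       sep = "=", collapse = ", "), "\n", sep = "")
  cat("  localization: ",
      paste(names(x$counts_by_localization_group),
            unlist(x$counts_by_localization_group),
            sep = "=", collapse = ", "), "\n", sep = "")
  a <- x$age_summary
  cat(sprintf("  age (years): min %.3g, q1 %.3g, median %.3g, q3 %.3g, max %.3g\n",
              a$minimum, a$q1, a$median, a$q3, a$maximum))
  cat("  methylation done/classified: ", x$n_methylation_done, "/",
      x$n_methylation_classified, "\n", sep = "")
  cat("  ddPCR-trackable: ", x$n_ddpcr_trackable, "\n", sep = "")
  invisible(x)
}
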