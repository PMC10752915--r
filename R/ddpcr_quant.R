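# Poisson quantification of droplet digital PCR wells.
#
# A reaction is partitioned into ~20,000 droplets of fixed volume v; a
# droplet is positive when it received >= 1 template. With target
# concentration c (copies/ul) the per-droplet occupancy is Poisson with
# mean lambda = c * v, so the positive fraction is 1 - exp(-lambda) and
# lambda is recovered as -log(1 - k/N).

#' Default droplet volume in microliters
#'
#' 0.85 nl, the partition volume convention of the QX droplet generator
#' family used for BRAF duplication/V600E assays.
#' @export
DEFAULT_DROPLET_VOLUME_UL <- 0.00085

#' Construct a droplet well
#'
#' One ddPCR well of a two-channel duplex. `CNV_DUPLEX` carries the
#' copy-number channels `TARGET_EXON14` (BRAF exon 14) and `REF_EXON3`
#' (BRAF exon 3 reference); `MUT_DUPLEX` carries `MUT_V600E` and `WT_BRAF`.
#' Both channels of a duplex are read from the same droplets and therefore
#' share the same total count.
#'
#' @param well_id Well identifier.
#' @param assay `"CNV_DUPLEX"` or `"MUT_DUPLEX"`.
#' @param positives Named integer vector of positive-droplet counts, one
#'   entry per channel of the assay.
#' @param total Total droplet count (shared by both channels).
#' @param sample_id Optional sample the well belongs to (defaults to
#'   `well_id`).
#' @return Object of class `"droplet_well"`.
#' @export
#' @examples
#' droplet_well("A01", "CNV_DUPLEX",
#'              c(TARGET_EXON14 = 2400, REF_EXON3 = 2000), total = 20000)
droplet_well <- function(well_id, assay = c("CNV_DUPLEX", "MUT_DUPLEX"),
                         positives, total, sample_id = well_id) {
  assay <- match.arg(assay)
  expected <- ASSAY_CHANNELS[[assay]]
  if (!setequal(names(positives), expected)) {
    abort(paste0("assay ", assay, " requires channels ",
                 paste(expected, collapse = ", ")),
          class = "plgg_schema_error")
  }
  positives <- positives[expected]
  if (length(total) != 1 || is.na(total) || total <= 0) {
    abort("total droplet count must be a single positive number",
          class = "plgg_validation_error")
  }
  if (any(is.na(positives)) || any(positives < 0) || any(positives > total)) {
    abort("positive counts must satisfy 0 <= k <= N in every channel",
          class = "plgg_validation_error")
  }
  structure(list(well_id = well_id, sample_id = sample_id, assay = assay,
                 positives = positives, total = as.numeric(total)),
            class = "droplet_well")
}

#' @export
print.droplet_well <- function(x, ...) {
  cat("ddPCR well ", x$well_id, " [", x$assay, "], N = ", x$total, "\n",
      sep = "")
  for (ch in names(x$positives)) {
    cat(sprintf("  %-14s k = %d\n", ch, as.integer(x$positives[[ch]])))
  }
  invisible(x)
}

#' Mean copies per droplet from droplet counts
#'
#' Inverts the Poisson occupancy model: `lambda = -log(1 - k/N)`. A fully
#' positive well carries no upper bound on concentration and raises a
#' saturation error rather than silently correcting; pre-apply a k - 0.5
#' continuity correction upstream if a numeric answer is required.
#'
#' @param k Positive droplet count, `0 <= k < N`.
#' @param N Total droplet count, `> 0`.
#' @return Mean copies per droplet (0 when `k = 0`).
#' @export
#' @examples
#' estimate_lambda(2000, 20000)  # -log(0.9)
estimate_lambda <- function(k, N) {
  if (length(k) != 1 || length(N) != 1 || is.na(k) || is.na(N) ||
      N <= 0 || k < 0 || k > N) {
    abort("need 0 <= k <= N with N > 0", class = "plgg_validation_error")
  }
  if (k == N) {
    abort(paste0("well saturated (k = N = ", N,
                 "): concentration unbounded"),
          class = "plgg_saturation_error")
  }
  -log1p(-k / N)
}

# bootstrap lambdas for one channel; resampled fully-positive draws get a
# half-droplet continuity correction so quantiles remain finite
boot_lambda <- function(k, N, n_boot) {
  ks <- rbinom(n_boot, size = N, prob = k / N)
  ks[ks == N] <- N - 0.5
  -log1p(-ks / N)
}

#' Concentration of a target from one channel
#'
#' Point estimate `lambda / v` in copies/ul with a parametric-bootstrap
#' confidence interval: positives are resampled as Binomial(N, k/N), the
#' estimator re-applied, and empirical quantiles taken. Deterministic for a
#' given seed.
#'
#' @param k,N Positive and total droplet counts.
#' @param droplet_volume_ul Droplet volume in ul.
#' @param ci_level Two-sided confidence level.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed (required; the interval is part of the record
#'   and must be reproducible).
#' @return Object of class `"concentration_estimate"` with fields
#'   `copies_per_ul`, `lambda`, `ci_low`, `ci_high`, `droplet_volume_ul`,
#'   `saturated`.
#' @export
#' @examples
#' concentration(2000, 20000, seed = 1)
concentration <- function(k, N, droplet_volume_ul = DEFAULT_DROPLET_VOLUME_UL,
                          ci_level = 0.95, n_boot = 2000, seed) {
  if (droplet_volume_ul <= 0) {
    abort("droplet volume must be positive", class = "plgg_validation_error")
  }
  lambda <- estimate_lambda(k, N)
  est <- lambda / droplet_volume_ul
  if (k == 0) {
    ci <- c(0, 0)
    # an upper bound still exists for an all-negative well (rule of three),
    # but the bootstrap degenerates; report the point mass
  } else {
    lams <- withr::with_seed(seed, boot_lambda(k, N, n_boot))
    ci <- unname(quantile(lams / droplet_volume_ul,
                          probs = c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)))
  }
  structure(list(copies_per_ul = est, lambda = lambda,
                 ci_low = ci[1], ci_high = ci[2],
                 droplet_volume_ul = droplet_volume_ul,
                 saturated = FALSE),
            class = "concentration_estimate")
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf("%.4g copies/ul (lambda = %.4g; 95%% CI %.4g-%.4g)\n",
              x$copies_per_ul, x$lambda, x$ci_low, x$ci_high))
  invisible(x)
}

#' Merge replicate wells
#'
#' Pools droplets across wells of the same assay by summing per-channel
#' positives and totals, the standard way technical replicates are combined
#' before Poisson inversion.
#'
#' @param wells List of [droplet_well()] objects sharing one assay.
#' @return A single merged `droplet_well`.
#' @export
merge_wells <- function(wells) {
  if (length(wells) == 0) {
    abort("no wells to merge", class = "plgg_validation_error")
  }
  assays <- vapply(wells, function(w) w$assay, character(1))
  if (length(unique(assays)) > 1) {
    abort("cannot merge wells of different assays", class = "plgg_validation_error")
  }
  positives <- Reduce(`+`, lapply(wells, function(w) w$positives))
  total <- sum(vapply(wells, function(w) w$total, numeric(1)))
  droplet_well(paste(vapply(wells, function(w) w$well_id, character(1)),
                     collapse = "+"),
               assay = assays[1], positives = positives, total = total,
               sample_id = wells[[1]]$sample_id)
}

#' Read droplet wells from CSV
#'
#' Schema: `well_id, assay, channel, positives, total`, one row per channel
#' (an optional `sample_id` column is carried through; it defaults to the
#' well id). Rows are grouped into one [droplet_well()] per well id.
#'
#' @param path CSV path.
#' @return List of `droplet_well` objects, in order of first appearance.
#' @export
read_droplet_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("droplet file not found: ", path), class = "plgg_io_error")
  }
  # columns are validated below; suppress readr's complaint when a typed
  # column is absent so the schema error names the column instead
  raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    well_id = readr::col_character(),
    assay = readr::col_character(),
    channel = readr::col_character(),
    positives = readr::col_double(),
    total = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE))
  needed <- c("well_id", "assay", "channel", "positives", "total")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(paste0("droplet file is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "plgg_schema_error")
  }
  ids <- unique(raw$well_id)
  lapply(ids, function(id) {
    rows <- raw[raw$well_id == id, ]
    totals <- unique(rows$total)
    if (length(totals) != 1) {
      abort(paste0("well ", id, ": channels disagree on total droplet count"),
            class = "plgg_schema_error")
    }
    droplet_well(id, assay = rows$assay[1],
                 positives = setNames(rows$positives, rows$channel),
                 total = totals,
                 sample_id = if ("sample_id" %in% names(rows))
                   rows$sample_id[1] else id)
  })
}

#' Write droplet wells to CSV
#'
#' @param wells List of `droplet_well` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_droplet_csv <- function(wells, path) {
  rows <- dplyr::bind_rows(lapply(wells, function(w) {
    tibble(sample_id = w$sample_id, well_id = w$well_id, assay = w$assay,
           channel = names(w$positives),
           positives = as.numeric(w$positives), total = w$total)
  }))
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}
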