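# Tumor cell fraction (TCF) from ddPCR concentrations.
#
# Two estimators, one per assay:
#
# Duplication assay. Tumor cells carrying the 7q34 tandem duplication have
# 3 copies of BRAF exon 14 against 2 copies of the exon 3 reference; normal
# microenvironmental cells have 2 of each. A mixture with tumor fraction f
# therefore has mean exon-14 copy number CN = 2 + f, so
#   CN  = 2 * conc(exon14) / conc(exon3)      and      TCF = CN - 2.
#
# Mutation assay. The V600E mutation is assumed heterozygous and the locus
# diploid: a tumor cell contributes 1 mutant + 1 wild-type allele, a normal
# cell 2 wild-type. At tumor fraction f the mutant/wild-type concentration
# ratio is r = f / (2 - f), inverted as
#   TCF = 2 r / (1 + r).

clamp01 <- function(x) pmin(pmax(x, 0), 1)

new_tcf_estimate <- function(tcf_raw, assay, copy_number = NA_real_,
                             ratio = NA_real_, ci_low = NA_real_,
                             ci_high = NA_real_) {
  structure(list(
    tcf = clamp01(tcf_raw),
    tcf_percent = 100 * clamp01(tcf_raw),
    assay = assay,
    copy_number = copy_number,
    ratio = ratio,
    ci_low = ci_low,
    ci_high = ci_high,
    clamped = tcf_raw < 0 || tcf_raw > 1
  ), class = "tcf_estimate")
}

#' @export
print.tcf_estimate <- function(x, ...) {
  cat(sprintf("TCF = %.1f%% [%s assay]%s\n", x$tcf_percent, x$assay,
              if (isTRUE(x$clamped)) " (clamped)" else ""))
  if (!is.na(x$copy_number)) {
    cat(sprintf("  exon-14 copy number = %.3f\n", x$copy_number))
  }
  if (!is.na(x$ratio)) cat(sprintf("  mutant/wild-type ratio = %.4f\n", x$ratio))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  CI: [%.3f, %.3f]\n", x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' BRAF exon-14 copy number from the duplication duplex
#'
#' `2 * conc(exon 14) / conc(exon 3)`: the reference locus is present at two
#' copies per genome in every cell, so twice the concentration ratio is the
#' mean exon-14 copy number of the cell mixture.
#'
#' @param conc_exon14 Exon-14 concentration (copies/ul), `>= 0`.
#' @param conc_exon3 Exon-3 reference concentration (copies/ul), `> 0`.
#' @return Mean copy number (2 in pure normal cells, 3 in pure duplicated
#'   tumor).
#' @export
#' @examples
#' copy_number_from_duplex(62.5, 50)  # 2.5: a 50/50 tumor:normal mixture
copy_number_from_duplex <- function(conc_exon14, conc_exon3) {
  if (any(conc_exon3 <= 0)) {
    abort("no reference signal: exon-3 concentration must be positive",
          class = "plgg_validation_error")
  }
  if (any(conc_exon14 < 0)) {
    abort("exon-14 concentration must be non-negative",
          class = "plgg_validation_error")
  }
  2 * conc_exon14 / conc_exon3
}

#' TCF from the duplication assay
#'
#' `TCF = copy_number - 2`, clamped to `[0, 1]` with `clamped = TRUE`
#' recorded when the raw value fell outside (noisy wells stay analyzable
#' but auditable).
#'
#' @inheritParams copy_number_from_duplex
#' @return A `tcf_estimate`.
#' @export
#' @examples
#' tcf_from_duplication(75, 50)$tcf_percent   # 100: pure tumor, CN = 3
#' tcf_from_duplication(62.5, 50)$tcf         # 0.5
tcf_from_duplication <- function(conc_exon14, conc_exon3) {
  cn <- copy_number_from_duplex(conc_exon14, conc_exon3)
  new_tcf_estimate(cn - 2, assay = "DUPLICATION", copy_number = cn)
}

#' TCF from the V600E mutation assay
#'
#' With mutant/wild-type concentration ratio `r`, `TCF = 2r / (1 + r)`
#' under heterozygosity and diploidy of the locus. `r > 1` is impossible
#' under those assumptions; the estimate is clamped to 1 and flagged.
#'
#' @param conc_mut Mutant-allele concentration (copies/ul), `>= 0`.
#' @param conc_wt Wild-type concentration (copies/ul), `> 0` whenever
#'   mutant signal is present (a mutant-only well would imply a
#'   hemizygous/homozygous state outside the model).
#' @return A `tcf_estimate`.
#' @export
#' @examples
#' tcf_from_mutation(100, 100)$tcf  # 1: pure heterozygous tumor
#' tcf_from_mutation(40, 120)$tcf   # 0.5
tcf_from_mutation <- function(conc_mut, conc_wt) {
  if (any(conc_mut < 0)) {
    abort("mutant concentration must be non-negative",
          class = "plgg_validation_error")
  }
  if (any(conc_wt <= 0)) {
    if (all(conc_mut == 0)) {
      return(new_tcf_estimate(0, assay = "MUTATION", ratio = 0))
    }
    abort(paste0("no wild-type signal with mutant present: ",
                 "hemizygous/homozygous state outside the heterozygous model"),
          class = "plgg_validation_error")
  }
  r <- conc_mut / conc_wt
  new_tcf_estimate(2 * r / (1 + r), assay = "MUTATION", ratio = r)
}

#' Point TCF from a droplet well
#'
#' Poisson-inverts both channels of the duplex and applies the estimator
#' matching the well's assay.
#'
#' @param well A [droplet_well()].
#' @param droplet_volume_ul Droplet volume in ul.
#' @return A `tcf_estimate` (no confidence interval; see
#'   [tcf_confidence_interval()]).
#' @export
tcf_from_well <- function(well, droplet_volume_ul = DEFAULT_DROPLET_VOLUME_UL) {
  lam <- vapply(names(well$positives),
                function(ch) estimate_lambda(well$positives[[ch]], well$total),
                numeric(1))
  conc <- lam / droplet_volume_ul
  if (well$assay == "CNV_DUPLEX") {
    tcf_from_duplication(conc[["TARGET_EXON14"]], conc[["REF_EXON3"]])
  } else {
    tcf_from_mutation(conc[["MUT_V600E"]], conc[["WT_BRAF"]])
  }
}

#' TCF with a parametric-bootstrap confidence interval
#'
#' Both channels' positives are jointly resampled as Binomial(N, k/N), the
#' full estimator (Poisson inversion then the assay's TCF formula, with
#' clamping) is re-applied to every resample, and empirical quantiles give
#' the interval. Deterministic for a given seed. Resamples whose reference
#' channel draws zero positives carry no TCF information and are dropped
#' from the quantile computation.
#'
#' @param well A [droplet_well()], unsaturated in both channels.
#' @param droplet_volume_ul Droplet volume in ul.
#' @param ci_level Two-sided confidence level.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed (required).
#' @return A `tcf_estimate` with `ci_low`/`ci_high` filled in.
#' @export
tcf_confidence_interval <- function(well,
                                    droplet_volume_ul = DEFAULT_DROPLET_VOLUME_UL,
                                    ci_level = 0.95, n_boot = 2000, seed) {
  point <- tcf_from_well(well, droplet_volume_ul)
  k <- well$positives
  N <- well$total
  target_ch <- if (well$assay == "CNV_DUPLEX") "TARGET_EXON14" else "MUT_V600E"
  ref_ch <- if (well$assay == "CNV_DUPLEX") "REF_EXON3" else "WT_BRAF"
  if (k[[target_ch]] == 0) {
    point$ci_low <- 0
    point$ci_high <- 0
    return(point)
  }
  tcfs <- withr::with_seed(seed, {
    lam_t <- boot_lambda(k[[target_ch]], N, n_boot)
    lam_r <- boot_lambda(k[[ref_ch]], N, n_boot)
    keep <- lam_r > 0
    if (well$assay == "CNV_DUPLEX") {
      clamp01(2 * lam_t[keep] / lam_r[keep] - 2)
    } else {
      r <- lam_t[keep] / lam_r[keep]
      clamp01(2 * r / (1 + r))
    }
  })
  ci <- unname(quantile(tcfs, probs = c((1 - ci_level) / 2,
                                        1 - (1 - ci_level) / 2)))
  point$ci_low <- ci[1]
  point$ci_high <- ci[2]
  point
}

#' Convert a TCF fraction to percent
#'
#' @param tcf Number in `[0, 1]`.
#' @return `100 * tcf`.
#' @export
tcf_percent <- function(tcf) {
  if (any(is.na(tcf)) || any(tcf < 0) || any(tcf > 1)) {
    abort("tcf must lie in [0, 1]", class = "plgg_validation_error")
  }
  100 * tcf
}

#' Tabulate TCF estimates as a report
#'
#' Flattens a list of wells into the report schema: `sample_id, well_id,
#' assay, tcf, tcf_percent, ci_low, ci_high, copy_number, ratio,
#' clamped_flag`.
#'
#' @param wells List of [droplet_well()] objects.
#' @param droplet_volume_ul Droplet volume in ul.
#' @param ci_level,n_boot,seed Bootstrap settings; per-well seeds are
#'   derived deterministically from `seed`.
#' @return Tibble, one row per well.
#' @export
tcf_report <- function(wells, droplet_volume_ul = DEFAULT_DROPLET_VOLUME_UL,
                       ci_level = 0.95, n_boot = 2000, seed) {
  seeds <- derive_seeds(seed, length(wells))
  rows <- lapply(seq_along(wells), function(i) {
    w <- wells[[i]]
    est <- tcf_confidence_interval(w, droplet_volume_ul, ci_level, n_boot,
                                   seed = seeds[i])
    tibble(sample_id = w$sample_id, well_id = w$well_id,
           assay = est$assay, tcf = est$tcf, tcf_percent = est$tcf_percent,
           ci_low = est$ci_low, ci_high = est$ci_high,
           copy_number = est$copy_number, ratio = est$ratio,
           clamped_flag = est$clamped)
  })
  dplyr::bind_rows(rows)
}
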