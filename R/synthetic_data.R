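# Synthetic data with the statistical structure the analysis assumes:
# exact cell-mixture concentrations at known TCF, binomial droplet
# partitioning, growth-competition trajectories, and cohorts emulating an
# 18-sample pLGG study.
#
# Growth competition between tumor and microenvironmental cells is a
# discrete replicator map on the tumor fraction f:
#   f' = f * wT / (f * wT + (1 - f) * wE)
# with per-passage fitness multipliers wT (tumor) and wE (environment).
# It is the simplest model whose long-run behavior matches what monitored
# cultures show: every trajectory is absorbed at 0 or 1 unless wT = wE.

#' Exact channel concentrations for a tumor/normal mixture
#'
#' Deterministic expected concentrations from the per-cell copy
#' stoichiometry: a duplicated tumor genome carries 3 exon-14 and 2 exon-3
#' copies (normal: 2 and 2), a V600E tumor genome 1 mutant + 1 wild-type
#' allele (normal: 0 + 2). At tumor fraction `f` with `g` genomes/ul the
#' duplication duplex sees exon14/exon3 = (2 + f)/2 and the mutation duplex
#' MUT/WT = f/(2 - f).
#'
#' @param tcf_true Tumor cell fraction in `[0, 1]`.
#' @param assay `"DUPLICATION"` or `"MUTATION"`.
#' @param total_genomes_per_ul Genome-equivalents per ul in the reaction
#'   (default 800, a typical gDNA load that puts the reference channel near
#'   the precision-optimal mean occupancy of ~1.4 copies/droplet).
#' @return Named numeric vector of copies/ul, one entry per duplex channel.
#' @export
#' @examples
#' mixture_concentrations(0.5, "MUTATION")  # MUT/WT ratio 1/3
mixture_concentrations <- function(tcf_true,
                                   assay = c("DUPLICATION", "MUTATION"),
                                   total_genomes_per_ul = 800) {
  assay <- match.arg(assay)
  if (is.na(tcf_true) || tcf_true < 0 || tcf_true > 1) {
    abort("tcf_true must lie in [0, 1]", class = "plgg_validation_error")
  }
  if (total_genomes_per_ul <= 0) {
    abort("total_genomes_per_ul must be positive",
          class = "plgg_validation_error")
  }
  g <- total_genomes_per_ul
  f <- tcf_true
  if (assay == "DUPLICATION") {
    c(TARGET_EXON14 = g * (2 + f), REF_EXON3 = g * 2)
  } else {
    c(MUT_V600E = g * f, WT_BRAF = g * (2 - f))
  }
}

#' Simulate one droplet well
#'
#' Binomial droplet partitioning: each channel's positive count is drawn
#' as Binomial(n_droplets, 1 - exp(-c * v)). Reproducible given a seed.
#'
#' @param concs Named concentrations (copies/ul) as produced by
#'   [mixture_concentrations()]; names decide the assay.
#' @param n_droplets Droplets per well.
#' @param droplet_volume_ul Droplet volume in ul.
#' @param seed Integer seed.
#' @param well_id,sample_id Identifiers for the generated well.
#' @return A [droplet_well()].
#' @export
simulate_well <- function(concs, n_droplets = 20000,
                          droplet_volume_ul = DEFAULT_DROPLET_VOLUME_UL,
                          seed, well_id = "sim", sample_id = well_id) {
  if (n_droplets <= 0) {
    abort("n_droplets must be positive", class = "plgg_validation_error")
  }
  assay <- if (setequal(names(concs), ASSAY_CHANNELS$CNV_DUPLEX))
    "CNV_DUPLEX"
  else if (setequal(names(concs), ASSAY_CHANNELS$MUT_DUPLEX))
    "MUT_DUPLEX"
  else abort("channel names do not match a known duplex",
             class = "plgg_schema_error")
  p <- 1 - exp(-concs * droplet_volume_ul)
  ks <- withr::with_seed(seed,
                         rbinom(length(p), size = n_droplets, prob = p))
  droplet_well(well_id, assay = assay,
               positives = setNames(ks, names(concs)), total = n_droplets,
               sample_id = sample_id)
}

#' One passage of the growth-competition map
#'
#' @param f Tumor fraction at the current passage.
#' @param fitness_tumor,fitness_env Per-passage growth multipliers, `> 0`.
#' @return Tumor fraction after one passage.
#' @export
replicator_step <- function(f, fitness_tumor, fitness_env) {
  if (any(fitness_tumor <= 0) || any(fitness_env <= 0)) {
    abort("fitness values must be positive", class = "plgg_validation_error")
  }
  f * fitness_tumor / (f * fitness_tumor + (1 - f) * fitness_env)
}

#' Trajectory simulation parameters
#'
#' Defaults encode the monitored-culture world: initial TCF near the
#' observed p0 distribution, a modest intrinsic tumor growth deficit or
#' advantage that declines linearly with patient age (floored), and a
#' fitness boost from the transduction passage onward. None of these rates
#' are measured quantities; they are the generator's stated world.
#'
#' @param f0 Initial TCF.
#' @param fitness_tumor Per-passage tumor multiplier before transduction.
#' @param fitness_env Microenvironment multiplier (reference, 1.0).
#' @param transduction_passage Passage at which SV40-TAg transduction takes
#'   effect, or `NA` for an untransduced culture.
#' @param transduction_boost Multiplier applied to `fitness_tumor` from the
#'   transduction passage onward (`>= 1`).
#' @param n_passages Passages to simulate.
#' @param assay `"DUPLICATION"` or `"MUTATION"`.
#' @return List of class `"trajectory_params"`.
#' @export
trajectory_params <- function(f0 = 0.55, fitness_tumor = 1.0,
                              fitness_env = 1.0, transduction_passage = 2L,
                              transduction_boost = 1.2, n_passages = 20L,
                              assay = c("DUPLICATION", "MUTATION")) {
  assay <- match.arg(assay)
  if (f0 < 0 || f0 > 1) {
    abort("f0 must lie in [0, 1]", class = "plgg_validation_error")
  }
  if (fitness_tumor <= 0 || fitness_env <= 0 || transduction_boost < 1) {
    abort("fitness multipliers must be positive and boost >= 1",
          class = "plgg_validation_error")
  }
  structure(list(f0 = f0, fitness_tumor = fitness_tumor,
                 fitness_env = fitness_env,
                 transduction_passage = transduction_passage,
                 transduction_boost = transduction_boost,
                 n_passages = as.integer(n_passages), assay = assay),
            class = "trajectory_params")
}

#' Simulate a culture trajectory with droplet readouts
#'
#' Iterates the replicator map from `f0` over `n_passages` passages,
#' applying the transduction boost from `transduction_passage` onward, and
#' emits one simulated droplet well at the true TCF of every passage.
#'
#' @param params A [trajectory_params()].
#' @param n_droplets,droplet_volume_ul,total_genomes_per_ul Well settings.
#' @param seed Integer seed; per-passage well seeds are derived from it.
#' @return Tibble: `passage`, `tcf_true`, `well` (list column of
#'   [droplet_well()]).
#' @export
simulate_trajectory <- function(params, n_droplets = 20000,
                                droplet_volume_ul = DEFAULT_DROPLET_VOLUME_UL,
                                total_genomes_per_ul = 800, seed) {
  n <- params$n_passages
  f <- numeric(n + 1)
  f[1] <- params$f0
  for (t in seq_len(n)) {
    wT <- params$fitness_tumor
    if (!is.na(params$transduction_passage) &&
        (t - 1) >= params$transduction_passage) {
      wT <- wT * params$transduction_boost
    }
    f[t + 1] <- replicator_step(f[t], wT, params$fitness_env)
  }
  seeds <- derive_seeds(seed, n + 1)
  wells <- lapply(seq_len(n + 1), function(i) {
    simulate_well(
      mixture_concentrations(f[i], params$assay, total_genomes_per_ul),
      n_droplets = n_droplets, droplet_volume_ul = droplet_volume_ul,
      seed = seeds[i], well_id = paste0("p", i - 1))
  })
  tibble(passage = 0:n, tcf_true = f, well = wells)
}

# truncated-normal draw by rejection; bounds are wide relative to sd so
# acceptance is high
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Cohort-level simulation defaults
#'
#' The stated world of the generator: patient ages 7.9 +/- 5.4 years
#' (truncated to 0-18), initial TCF 0.55 +/- 0.23 (truncated to the
#' observed 0.20-0.95 p0 range), alteration frequencies 11:3:4
#' (fusion : V600E : other), per-passage tumor fitness declining linearly
#' with age from 1.2 at age 0 by 0.06/year, floored at 0.6, against a
#' microenvironment fitness of 1.0; transduction multiplies tumor fitness
#' by 1.2 from passage 2 onward. Viability and transduction probabilities
#' follow the observed workflow attrition (17/18 viable at p1; 10/17
#' transduced in ABM, none in NSM).
#'
#' @return Named list of defaults, overridable via [simulate_cohort()].
#' @export
cohort_sim_defaults <- function() {
  list(
    age_mean = 7.9, age_sd = 5.4, age_min = 0, age_max = 18,
    f0_mean = 0.55, f0_sd = 0.23, f0_min = 0.20, f0_max = 0.95,
    p_alteration = c(KIAA1549_BRAF_FUSION = 11 / 18, BRAF_V600E = 3 / 18,
                     OTHER = 4 / 18),
    other_alterations = c("BRAF_DUPLICATION", "BRAF_599TT_INS",
                          "COPC_ROS1_FUSION", "PRKAR2B_BRAF_FUSION"),
    fitness_base = 1.2, fitness_age_slope = 0.06, fitness_floor = 0.6,
    fitness_env = 1.0, transduction_boost = 1.2,
    transduction_passage = 2L, n_passages = 20L,
    p_viable_p1 = 17 / 18, p_transduced_abm = 10 / 17, p_transduced_nsm = 0,
    n_droplets = 20000, total_genomes_per_ul = 800
  )
}

#' Simulate a monitored cohort
#'
#' Draws a cohort of samples (age, sex, alteration) and, for each, ABM and
#' NSM culture arms followed through the monitoring stages. Tumor fitness
#' is linked negatively to age, so samples from younger patients are
#' likelier to classify as established. Samples whose alteration is not
#' trackable by the two ddPCR assays get trajectories without TCF
#' measurements. Fully seeded: identical seeds give identical output.
#'
#' @param n_samples Number of samples (>= 1).
#' @param seed Integer seed.
#' @param params Overrides of [cohort_sim_defaults()] entries.
#' @param droplet_volume_ul Droplet volume in ul.
#' @return List with `records` (cohort tibble as from [read_cohort()]),
#'   `trajectories` (list of `culture_trajectory`), and `truth` (tibble of
#'   the latent per-sample values: age, f0, fitness, assay, per-arm
#'   milestones and true final TCF in ABM).
#' @export
simulate_cohort <- function(n_samples = 18, seed, params = list(),
                            droplet_volume_ul = DEFAULT_DROPLET_VOLUME_UL) {
  if (n_samples < 1) {
    abort("n_samples must be >= 1", class = "plgg_validation_error")
  }
  p <- utils::modifyList(cohort_sim_defaults(), params)
  seeds <- derive_seeds(seed, 2L)

  draw <- withr::with_seed(seeds[1], {
    age <- rtruncnorm(n_samples, p$age_mean, p$age_sd, p$age_min, p$age_max)
    f0 <- rtruncnorm(n_samples, p$f0_mean, p$f0_sd, p$f0_min, p$f0_max)
    sex <- sample(c("F", "M"), n_samples, replace = TRUE)
    alt_class <- sample(names(p$p_alteration), n_samples, replace = TRUE,
                        prob = p$p_alteration)
    alteration <- ifelse(
      alt_class == "OTHER",
      sample(p$other_alterations, n_samples, replace = TRUE),
      alt_class)
    viable <- runif(n_samples) < p$p_viable_p1
    transduced_abm <- viable & (runif(n_samples) < p$p_transduced_abm)
    transduced_nsm <- viable & (runif(n_samples) < p$p_transduced_nsm)
    list(age = age, f0 = f0, sex = sex, alteration = alteration,
         viable = viable, transduced_abm = transduced_abm,
         transduced_nsm = transduced_nsm)
  })

  ids <- sprintf("SIM%02d", seq_len(n_samples))
  fitness <- pmax(p$fitness_base - p$fitness_age_slope * draw$age,
                  p$fitness_floor)
  assay <- ifelse(draw$alteration == "BRAF_V600E", "MUTATION", "DUPLICATION")
  trackable <- draw$alteration %in% trackable_alterations()

  records <- tibble(
    sample_id = ids, sex = draw$sex, age_years = draw$age,
    histology = "Pilocytic astrocytoma", localization = "Posterior fossa",
    methylation_class = "PA_PF", classifier_score = NA_real_,
    alteration = draw$alteration, alteration_label = draw$alteration,
    detection_method = "simulation"
  )

  traj_seeds <- derive_seeds(seeds[2], 2L * n_samples)
  trajectories <- list()
  truth_final <- rep(NA_real_, n_samples)
  for (i in seq_len(n_samples)) {
    for (arm in c("ABM", "NSM")) {
      transduced <- if (arm == "ABM") draw$transduced_abm[i]
      else draw$transduced_nsm[i]
      tp <- trajectory_params(
        f0 = draw$f0[i], fitness_tumor = fitness[i],
        fitness_env = p$fitness_env,
        transduction_passage = if (transduced) p$transduction_passage else NA,
        transduction_boost = p$transduction_boost,
        n_passages = p$n_passages,
        assay = assay[i])
      s <- traj_seeds[2 * (i - 1) + (arm == "NSM") + 1]
      sim <- simulate_trajectory(tp, n_droplets = p$n_droplets,
                                 droplet_volume_ul = droplet_volume_ul,
                                 total_genomes_per_ul = p$total_genomes_per_ul,
                                 seed = s)
      measure <- function(passage) {
        if (!trackable[i]) return(NA_real_)
        w <- sim$well[[which(sim$passage == passage)]]
        tcf_from_well(w, droplet_volume_ul)$tcf
      }
      tps <- culture_timepoint("P0", 0L, "NONE", measure(0))
      if (draw$viable[i]) {
        tps <- dplyr::bind_rows(tps,
                                culture_timepoint("P1", 1L, arm, measure(1)))
      }
      if (transduced) {
        tps <- dplyr::bind_rows(
          tps,
          culture_timepoint("TRANSDUCED", p$transduction_passage + 1L, arm,
                            measure(p$transduction_passage + 1L)),
          culture_timepoint("FINAL", p$n_passages, arm,
                            measure(p$n_passages)))
        if (arm == "ABM") truth_final[i] <- sim$tcf_true[p$n_passages + 1]
      }
      trajectories[[paste(ids[i], arm, sep = "/")]] <-
        build_trajectory(ids[i], arm, tps)
    }
  }

  truth <- tibble(
    sample_id = ids, age_years = draw$age, f0 = draw$f0,
    fitness_tumor = fitness, assay = assay, trackable = trackable,
    viable_at_p1 = draw$viable, transduced_abm = draw$transduced_abm,
    final_tcf_true_abm = truth_final
  )
  list(records = records, trajectories = trajectories, truth = truth)
}
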