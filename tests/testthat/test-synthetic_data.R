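test_that("mixture concentrations follow the per-cell copy stoichiometry", {
  dup0 <- mixture_concentrations(0, "DUPLICATION", 500)
  expect_equal(dup0[["TARGET_EXON14"]] / dup0[["REF_EXON3"]], 1)
  mut1 <- mixture_concentrations(1, "MUTATION", 500)
  expect_equal(mut1[["MUT_V600E"]], mut1[["WT_BRAF"]])
  mut05 <- mixture_concentrations(0.5, "MUTATION", 500)
  expect_equal(mut05[["MUT_V600E"]] / mut05[["WT_BRAF"]], 1 / 3)
  # ratio laws over the full range
  for (f in seq(0, 1, by = 0.25)) {
    dup <- mixture_concentrations(f, "DUPLICATION", 300)
    expect_equal(dup[["TARGET_EXON14"]] / dup[["REF_EXON3"]], (2 + f) / 2)
  }
  expect_error(mixture_concentrations(1.5, "MUTATION"),
               class = "plgg_validation_error")
})

test_that("simulated wells follow binomial occupancy and are seeded", {
  zero <- simulate_well(c(MUT_V600E = 0, WT_BRAF = 500), seed = 1)
  expect_equal(unname(zero$positives[["MUT_V600E"]]), 0)

  w1 <- simulate_well(mixture_concentrations(0.4, "DUPLICATION"), seed = 33)
  expect_identical(
    w1, simulate_well(mixture_concentrations(0.4, "DUPLICATION"), seed = 33))

  # occupancy moment check: lambda = 0.1053605 -> positive fraction 0.1
  c_target <- 0.105360515657826301 / DEFAULT_DROPLET_VOLUME_UL
  N <- 20000
  w <- simulate_well(c(MUT_V600E = c_target, WT_BRAF = c_target),
                     n_droplets = N, seed = 17)
  sd3 <- 3 * sqrt(0.1 * 0.9 / N)
  for (ch in names(w$positives)) {
    expect_lt(abs(w$positives[[ch]] / N - 0.1), sd3)
  }
})

test_that("the replicator map is absorbing at 0 and 1 and monotone", {
  adv <- trajectory_params(f0 = 0.55, fitness_tumor = 1.0,
                           transduction_boost = 1.3, n_passages = 20,
                           assay = "MUTATION")
  sim <- simulate_trajectory(adv, seed = 3)
  # neutral until the transduction passage, strictly increasing after it
  expect_true(all(sim$tcf_true[1:3] == 0.55))
  expect_true(all(diff(sim$tcf_true[3:21]) > 0))
  expect_gt(sim$tcf_true[21], 0.95)

  dis <- trajectory_params(f0 = 0.55, fitness_tumor = 0.75,
                           transduction_boost = 1.0, n_passages = 20,
                           assay = "MUTATION")
  sim2 <- simulate_trajectory(dis, seed = 3)
  expect_true(all(diff(sim2$tcf_true) < 0))
  expect_lt(sim2$tcf_true[21], 0.05)

  for (f0 in c(0, 1)) {
    absorbing <- simulate_trajectory(
      trajectory_params(f0 = f0, fitness_tumor = 1.1, n_passages = 5,
                        assay = "MUTATION"), seed = 4)
    expect_true(all(absorbing$tcf_true == f0))
  }

  # neutral fitness (wT * boost = wE) is the only non-absorbed line
  neutral <- simulate_trajectory(
    trajectory_params(f0 = 0.3, fitness_tumor = 1.0, transduction_boost = 1.0,
                      n_passages = 10, assay = "MUTATION"), seed = 5)
  expect_true(all(neutral$tcf_true == 0.3))
})

test_that("trajectory wells track the true TCF they were emitted at", {
  params <- trajectory_params(f0 = 0.5, fitness_tumor = 1.0,
                              transduction_boost = 1.2, n_passages = 6,
                              assay = "MUTATION")
  sim <- simulate_trajectory(params, seed = 88)
  measured <- vapply(seq_len(nrow(sim)),
                     function(i) tcf_from_well(sim$well[[i]])$tcf, numeric(1))
  expect_true(all(abs(measured - sim$tcf_true) < 0.05))
})

test_that("simulated cohorts are reproducible and match stated frequencies", {
  sim <- simulate_cohort(18, seed = 2024)
  expect_equal(nrow(sim$records), 18)
  expect_equal(length(sim$trajectories), 36)  # ABM and NSM arm per sample

  again <- simulate_cohort(18, seed = 2024)
  expect_identical(sim$records, again$records)
  expect_identical(sim$truth, again$truth)

  # alteration counts within the multinomial 95% band around (11, 3, 4)/18
  n_fus <- sum(sim$records$alteration == "KIAA1549_BRAF_FUSION")
  n_mut <- sum(sim$records$alteration == "BRAF_V600E")
  n_other <- 18 - n_fus - n_mut
  expect_true(n_fus >= qbinom(0.025, 18, 11 / 18) &&
                n_fus <= qbinom(0.975, 18, 11 / 18))
  expect_true(n_mut >= qbinom(0.025, 18, 3 / 18) &&
                n_mut <= qbinom(0.975, 18, 3 / 18))
  expect_true(n_other >= qbinom(0.025, 18, 4 / 18) &&
                n_other <= qbinom(0.975, 18, 4 / 18))

  single <- simulate_cohort(1, seed = 7)
  expect_equal(nrow(single$records), 1)
  expect_equal(length(single$trajectories), 2)

  # milestone monotonicity holds on every simulated row
  tab <- milestone_table(sim$trajectories)
  expect_true(all(!tab$transduced | tab$viable_at_p1))
})

test_that("younger samples gain TCF faster in early culture", {
  sim <- simulate_cohort(200, seed = 515)
  tr <- sim$trajectories
  rows <- lapply(sim$truth$sample_id, function(id) {
    t_abm <- tr[[paste0(id, "/ABM")]]
    tp <- t_abm$timepoints
    if (!all(c("P0", "P1") %in% tp$stage)) return(NULL)
    p0 <- tp$tcf[tp$stage == "P0"]
    p1 <- tp$tcf[tp$stage == "P1"]
    if (is.na(p0) || is.na(p1) || p0 == 0) return(NULL)
    data.frame(age = sim$truth$age_years[sim$truth$sample_id == id],
               change = relative_change(p0, p1))
  })
  dat <- do.call(rbind, rows)
  expect_gt(nrow(dat), 100)
  res <- pearson_correlation(dat$age, dat$change)
  expect_lt(res$statistic, 0)
  expect_lt(res$p_value, 0.01)
})
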