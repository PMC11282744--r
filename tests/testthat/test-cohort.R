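# Inclusion/exclusion, stage assignment and cohort construction.

test_that("flowchart accounting conserves patients across sequential filters", {
  set.seed(9)
  for (r in 1:5) {
    reg <- generate_registry(sim_config(n_patients = 300, seed = r))
    filt <- apply_inclusion_exclusion(reg)
    fc <- filt$counts
    expect_equal(fc$n_input, fc$n_remaining + sum(fc$exclusions))
    expect_equal(nrow(filt$registry$patients), fc$n_remaining)
    # filtered registries keep visit/truth tables aligned to patients
    expect_true(all(filt$registry$visits$patient_id %in%
      filt$registry$patients$patient_id))
    expect_equal(nrow(filt$registry$truth), fc$n_remaining)
  }
  expect_equal(flowchart_counts(10, c(a = 3, b = 2))$n_remaining, 5)
  expect_error(flowchart_counts(5, c(a = 7)))
})

test_that("hand-built fixture is filtered exactly as enumerated", {
  # 10 patients: 2 with a Parkinson-type excluded label, 1 single-visit,
  # 1 aged 92 -> 6 remain
  ages <- c(70, 71, 72, 73, 74, 75, 76, 77, 92, 60)
  visits <- c(
    replicate(7, visit_df(c(0, 300), c("MCI", "dementia_AD"), c(25, 22)),
      simplify = FALSE
    ),
    list(visit_df(0, "MCI", 25)), # single visit
    list(visit_df(c(0, 280), c("MCI", "MCI"), c(26, 25))), # aged 92
    list(visit_df(c(0, 320), c("MCI", "dementia_AD"), c(24, 21)))
  )
  # make patients 1 and 2 carry an excluded etiology at a visit
  visits[[1]]$diagnosis[2] <- "excluded_etiology"
  visits[[2]]$diagnosis[1] <- "excluded_etiology"
  reg <- make_registry(ages, visits)
  filt <- apply_inclusion_exclusion(reg)
  expect_equal(filt$counts$n_input, 10)
  expect_equal(unname(filt$counts$exclusions[["age"]]), 1)
  expect_equal(unname(filt$counts$exclusions[["excluded_comorbidity"]]), 2)
  expect_equal(unname(filt$counts$exclusions[["fewer_than_min_visits"]]), 1)
  expect_equal(filt$counts$n_remaining, 6)
  # age boundaries are inclusive: 50 and 90 stay, 49 goes
  reg2 <- make_registry(
    c(49, 50, 90),
    replicate(3, visit_df(c(0, 200), c("MCI", "MCI"), c(25, 24)), simplify = FALSE)
  )
  f2 <- apply_inclusion_exclusion(reg2)
  expect_equal(unname(f2$counts$exclusions[["age"]]), 1)
  expect_equal(f2$counts$n_remaining, 2)
})

test_that("stage assignment follows the MMSE bands with strict boundaries", {
  expect_equal(assign_stage("dementia_AD", 20), "mild")
  expect_equal(assign_stage("dementia_AD", 26), "mild")
  expect_equal(assign_stage("dementia_AD", 19), "moderate")
  expect_equal(assign_stage("dementia_AD", 11), "moderate")
  expect_equal(assign_stage("dementia_AD", 10), "severe")
  expect_equal(assign_stage("dementia_AD", 0), "severe")
  expect_equal(assign_stage("dementia_AD", 27), "ineligible") # outside all bands
  expect_equal(assign_stage("MCI", 21), "MCI")
  expect_equal(assign_stage("MCI", 20), "ineligible") # strictly above 20 required
  expect_equal(assign_stage("other", 25), "ineligible")
  expect_true(is.na(assign_stage("MCI", NA)))
  expect_error(assign_stage("MCI", 31), "\\[0, 30\\]")
  # vectorized
  expect_equal(
    assign_stage(c("MCI", "dementia_AD"), c(25, 15)),
    c("MCI", "moderate")
  )
})

test_that("time to conversion and censoring follow the first-passage definition", {
  reg <- make_registry(
    c(70, 70, 70),
    list(
      visit_df(c(0, 300, 600), c("MCI", "MCI", "dementia_AD"), c(25, 24, 22)),
      visit_df(c(0, 400), c("dementia_AD", "dementia_AD"), c(22, 21)),
      # moderate -> severe, with an earlier mild visit
      visit_df(
        c(0, 250, 500), c("dementia_AD", "dementia_AD", "dementia_AD"),
        c(22, 15, 8)
      )
    )
  )
  mci <- build_cohort(reg, "mci_to_dementia")
  expect_equal(mci$time[mci$patient_id == "P001"], 600)
  expect_equal(mci$event[mci$patient_id == "P001"], 1L)
  mild <- build_cohort(reg, "mild_to_moderate_severe")
  p2 <- mild[mild$patient_id == "P002", ]
  expect_equal(p2$time, 400)
  expect_equal(p2$event, 0L) # censored at last visit
  # patient 3 contributes to both the mild and the moderate cohort
  p3mild <- mild[mild$patient_id == "P003", ]
  expect_equal(p3mild$time, 250) # mild -> moderate at day 250
  expect_equal(p3mild$event, 1L)
  mod <- build_cohort(reg, "moderate_to_severe")
  p3mod <- mod[mod$patient_id == "P003", ]
  expect_equal(p3mod$index_day, 250) # different index date
  expect_equal(p3mod$time, 250)
  expect_equal(p3mod$event, 1L)
  expect_error(build_cohort(reg, "bogus"), "must be one of")
})

test_that("nursing-home admission truncates follow-up at the last prior visit", {
  reg <- make_registry(
    c(70), list(visit_df(c(0, 300, 600), rep("MCI", 3), c(25, 24, 23))),
    nh = c(450)
  )
  co <- build_cohort(reg, "mci_to_dementia")
  expect_equal(co$time, 300) # the day-600 visit is after admission
  expect_equal(co$event, 0L)
})

test_that("nonpositive follow-up rows are dropped and counted", {
  reg <- make_registry(
    c(70, 70),
    list(
      visit_df(c(0, 300), c("dementia_AD", "dementia_AD"), c(22, 15)),
      visit_df(c(0, 250), c("MCI", "dementia_AD"), c(25, 22))
    )
  )
  # patient 1 has only one mild visit (index) and converts at the same-path
  # next visit; patient 2 enters mild at its last visit -> zero follow-up
  mild <- build_cohort(reg, "mild_to_moderate_severe")
  expect_equal(nrow(mild), 1)
  expect_equal(attr(mild, "n_dropped_nonpositive"), 1L)
})

test_that("on uncensored synthetic data the cohort event time matches a direct latent scan", {
  cfg <- sim_config(
    n_patients = 150, seed = 17,
    stage_distribution = c(MCI = 1, mild = 0, moderate = 0),
    dropout = c(nursing_home = 0, death = 0),
    followup_end = 20000, entry_span = 1,
    baseline_hazards = c(
      mci_to_dementia = 1 / 700,
      mild_to_moderate_severe = 1 / 700, moderate_to_severe = 1 / 900
    ),
    excluded_etiology_rate = 0
  )
  reg <- generate_registry(cfg)
  co <- build_cohort(reg, "mci_to_dementia")
  expect_true(all(co$event == 1))
  for (i in seq_len(nrow(co))) {
    pid <- co$patient_id[i]
    conv_latent <- reg$truth$mci_to_dementia[reg$truth$patient_id == pid]
    v <- reg$visits[reg$visits$patient_id == pid, ]
    expected_day <- min(v$visit_day[v$visit_day >= conv_latent])
    expect_equal(co$time[i], expected_day - min(v$visit_day))
  }
})

test_that("cohort covariates are anchored at the index date", {
  reg <- make_registry(
    c(70),
    list(visit_df(c(0, 400, 800), rep("dementia_AD", 3), c(24, 15, 9)))
  )
  mod <- build_cohort(reg, "moderate_to_severe")
  expect_equal(mod$index_day, 400)
  expect_equal(mod$mmse_at_index, 15)
  expect_equal(mod$age_at_index, 70 + 400 / 365.25, tolerance = 1e-9)
})
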