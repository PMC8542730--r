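# Synthetic cohort generator: reproducibility, calibration, planted effects.

test_that("row counts and determinism are forced by the spec", {
  trials <- data.frame(trial_id = c("A", "B"), n_patients = c(100L, 200L),
                       af_prob = 0.2, followup_scale = 1)
  cl <- list(SR = list(cluster_spec("s1", 0.5, treatment_log_or = log(0.7)),
                       cluster_spec("s2", 0.5)),
             AF = list(cluster_spec("a1", 1)))
  spec <- cohort_spec(trials, cl, seed = 99L)
  tab <- generate_cohort(spec)
  expect_equal(nrow(tab), 300L)
  expect_identical(tab, generate_cohort(spec))
  expect_true(all(tab$followup_years > 0))
  expect_true(all(tab$death %in% 0:1))
  expect_true(all(tab$arm %in% c("bb", "placebo")))
})

test_that("invalid specifications are rejected", {
  trials <- data.frame(trial_id = c("A", "B"), n_patients = c(10L, 10L),
                       af_prob = 0, followup_scale = 1)
  expect_error(cohort_spec(trials, list(SR = list(cluster_spec("s1", 0.6),
                                                  cluster_spec("s2", 0.5)))),
               "sum")
  bad <- trials; bad$n_patients[1] <- 0L
  expect_error(cohort_spec(bad, list(SR = list(cluster_spec("s1", 1)))),
               "n_patients")
  expect_error(cohort_spec(trials[1, ], list(SR = list(cluster_spec("s1", 1)))),
               "2 trials")
  expect_error(cluster_spec("x", 1.2), "\\[0, 1\\]")
})

test_that("analytic cluster OR is exp of the planted log odds ratio", {
  expect_identical(analytic_cluster_or(cluster_spec("x", 1)), 1)
  expect_equal(analytic_cluster_or(
    cluster_spec("x", 1, treatment_log_or = log(0.57))), 0.57)
  expect_equal(round(analytic_cluster_or(
    cluster_spec("x", 1, treatment_log_or = -0.3011)), 2), 0.74)
})

test_that("empirical per-cluster ORs recover the planted generative ORs", {
  # large-sample Monte-Carlo check; tolerance from the binomial delta method
  base <- default_cohort_spec(seed = 404L)
  trials <- data.frame(trial_id = c("A", "B"),
                       n_patients = c(250000L, 250000L),
                       af_prob = 0, followup_scale = 1)
  spec <- cohort_spec(trials, base$cluster_specs["SR"],
                      covariate_base = base$covariate_base, seed = 404L)
  tab <- generate_cohort(spec)
  planted <- vapply(base$cluster_specs$SR,
                    function(cs) cs$treatment_log_or, numeric(1))
  names(planted) <- vapply(base$cluster_specs$SR,
                           function(cs) cs$cluster_id, character(1))
  for (cid in names(planted)) {
    sub <- tab[tab$true_cluster == cid, ]
    a <- sum(sub$death[sub$arm == "bb"]); b <- sum(sub$arm == "bb") - a
    c_ <- sum(sub$death[sub$arm == "placebo"])
    d <- sum(sub$arm == "placebo") - c_
    lor <- log((a / b) / (c_ / d))
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    expect_lt(abs(lor - planted[cid]), 3.5 * se)
    if (3.5 * se < log(1 + 0.03 / exp(planted[cid]))) {
      expect_lt(abs(exp(lor) - exp(planted[cid])), 0.03)
    }
  }
})

test_that("marginal medians of the default cohort match the calibrated locations", {
  tab <- generate_cohort(default_cohort_spec(seed = 7L))
  expect_equal(nrow(tab), 15659L)
  sr <- tab[tab$rhythm_raw == "SR", ]; af <- tab[tab$rhythm_raw == "AF", ]
  # tolerance IQR/10 per variable
  tol <- list(age = c(54, 71), bmi = c(24, 29.7), heart_rate = c(72, 88),
              sbp = c(110, 139), lvef = c(21, 33), creatinine = c(88, 124))
  target <- c(age = 64, bmi = 26.6, heart_rate = 80, sbp = 123, lvef = 27,
              creatinine = 104)
  for (v in names(target)) {
    expect_lt(abs(median(sr[[v]]) - target[[v]]), diff(tol[[v]]) / 10)
  }
  expect_lt(abs(median(af$age) - 69), (74 - 60) / 10)
  # binary marginals within 3 percentage points
  expect_lt(abs(mean(sr$gender == "female") - 0.248), 0.03)
  expect_lt(abs(mean(af$digoxin) - 0.839), 0.03)
})

test_that("randomisation is balanced within every generated trial", {
  for (seed in 1:20) {
    tab <- generate_cohort(default_cohort_spec(n_scale = 0.1, seed = seed))
    for (t in unique(tab$trial_id)) {
      sub <- tab[tab$trial_id == t, ]
      expect_lt(abs(mean(sub$arm == "bb") - 0.5), 3 / sqrt(nrow(sub)))
    }
  }
})

test_that("missingness injection is MCAR at the requested rates", {
  trials <- data.frame(trial_id = c("A", "B"), n_patients = c(7500L, 7500L),
                       af_prob = 0, followup_scale = 1)
  base <- default_cohort_spec()
  spec <- cohort_spec(trials, base$cluster_specs["SR"],
                      covariate_base = base$covariate_base, seed = 5L)
  tab <- generate_cohort(spec)
  expect_identical(inject_missingness(tab, c(bmi = 0), seed = 1L), tab)
  all_gone <- inject_missingness(tab, c(heart_rate = 1), seed = 1L)
  expect_true(all(is.na(all_gone$heart_rate)))
  expect_false(anyNA(all_gone$true_cluster))
  m <- inject_missingness(tab, c(bmi = 0.01), seed = 2L)
  cnt <- sum(is.na(m$bmi))
  bounds <- qbinom(c(0.005, 0.995), 15000L, 0.01)
  expect_gte(cnt, bounds[1]); expect_lte(cnt, bounds[2])
  expect_error(inject_missingness(tab, c(nope = 0.1)), "unknown")
})

test_that("cohort and spec round-trip through their file formats", {
  spec <- default_cohort_spec(n_scale = 0.02, seed = 3L)
  tab <- generate_cohort(spec)
  f <- tempfile(fileext = ".csv")
  write_cohort(tab, f)
  back <- read_cohort(f, drop_true_cluster = FALSE)
  expect_equal(back$age, tab$age, tolerance = 1e-12)
  expect_identical(back$true_cluster, tab$true_cluster)
  blind <- read_cohort(f)
  expect_false("true_cluster" %in% names(blind))
  y <- tempfile(fileext = ".yaml")
  write_cohort_spec(spec, y)
  spec2 <- read_cohort_spec(y)
  tab2 <- generate_cohort(spec2)
  expect_identical(tab2$true_cluster, tab$true_cluster)
  expect_identical(tab2$death, tab$death)
  expect_equal(tab2$age, tab$age, tolerance = 1e-6)
  expect_equal(tab2$creatinine, tab$creatinine, tolerance = 1e-6)
})
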