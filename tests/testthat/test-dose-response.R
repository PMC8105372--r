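test_that("responder fractions count per experiment and average across them", {
  resp <- matrix(FALSE, 10, 4)
  resp[1:4, 2] <- TRUE
  fr <- responder_fractions(make_calls(resp))
  expect_equal(fr$per_experiment$fraction_pct[fr$per_experiment$energy_density == 0.47],
               40)
  # three experiments at 10/20/30 % for one energy: mean 20, SEM sd/sqrt(3)
  calls <- rbind(
    make_calls(matrix(rep(c(TRUE, rep(FALSE, 9)), 1), 10, 1),
               energies = 0.5, experiment = "e1"),
    make_calls(matrix(c(rep(TRUE, 2), rep(FALSE, 8)), 10, 1),
               energies = 0.5, experiment = "e2"),
    make_calls(matrix(c(rep(TRUE, 3), rep(FALSE, 7)), 10, 1),
               energies = 0.5, experiment = "e3"))
  fr <- responder_fractions(calls)
  expect_equal(fr$summary$mean_pct, 20)
  expect_equal(fr$summary$sem_pct, sd(c(10, 20, 30)) / sqrt(3))
  expect_equal(fr$summary$sem_pct, 5.7735, tolerance = 1e-4)
  expect_error(responder_fractions(make_calls(resp)[0, ]))
})

test_that("fractions are invariant under relabeling of cells and experiments", {
  set.seed(21)
  resp <- matrix(runif(80) < 0.4, 20, 4)
  calls <- make_calls(resp)
  base <- responder_fractions(calls)$summary
  perm <- calls
  relab <- sample(sprintf("z%03d", 1:20))
  perm$roi_id <- relab[match(perm$roi_id, sprintf("c%03d", 1:20))]
  perm$experiment_id <- "renamed"
  shuf <- perm[sample(nrow(perm)), ]
  expect_equal(responder_fractions(shuf)$summary$mean_pct, base$mean_pct)
})

test_that("multiplicity partition is exact and per-energy sums match", {
  # definition cases
  resp <- rbind(c(FALSE, FALSE, TRUE, TRUE),   # 2x
                c(TRUE, TRUE, TRUE, TRUE),     # 3x+4x
                c(FALSE, FALSE, FALSE, TRUE),  # 1x
                c(FALSE, FALSE, FALSE, FALSE)) # 0
  mt <- multiplicity_categories(make_calls(resp))
  expect_equal(unname(mt$counts), c(1, 1, 1))
  expect_equal(mt$per_cell$class[2], "3x+4x")
  # the 2x cell is counted in both of its energies' decompositions
  expect_equal(mt$per_energy$n_2x[mt$per_energy$energy_density %in% c(0.58, 0.70)],
               c(1, 1))
  # brute-force partition property on random call sets
  set.seed(33)
  for (r in 1:5) {
    resp <- matrix(runif(400) < runif(1, 0.2, 0.6), 100, 4)
    mt <- multiplicity_categories(make_calls(resp))
    n_any <- sum(rowSums(resp) > 0)
    expect_equal(sum(mt$counts), n_any)
    # per-energy decomposition sums to the energy's responder count
    expect_equal(mt$per_energy$n_1x + mt$per_energy$n_2x + mt$per_energy$n_3x4x,
                 unname(colSums(resp)))
    expect_equal(mt$per_energy$n_responders, unname(colSums(resp)))
  }
})

test_that("cells with missing energy evaluations are excluded with a warning", {
  calls <- make_calls(matrix(TRUE, 3, 4))
  calls <- calls[!(calls$roi_id == "c001" & calls$energy_density == 0.35), ]
  expect_warning(mt <- multiplicity_categories(calls), "excluded")
  expect_equal(nrow(mt$per_cell), 2)
})

test_that("normalized dose-response reproduces ratio-of-means arithmetic", {
  # ratio oracle on the group means reported for the highly responsive
  # subset: 0.0148/0.0470/0.0654/0.0729 -> 20.3/64.5/89.7/100 %
  pct <- percent_of_reference(c(0.0148, 0.0470, 0.0654, 0.0729))
  expect_equal(pct, 100 * c(0.0148, 0.0470, 0.0654, 0.0729) / 0.0729)
  expect_equal(pct[4], 100)
  expect_equal(pct[2], 64.47, tolerance = 1e-3)
  expect_equal(pct[3], 89.71, tolerance = 1e-3)

  # full path: subset rule + normalisation on constructed calls
  resp <- cbind(rep(FALSE, 6), rep(TRUE, 6), rep(TRUE, 6), rep(TRUE, 6))
  peaks <- cbind(rep(0.01, 6), rep(0.02, 6), rep(0.04, 6), rep(0.05, 6))
  dr <- normalized_dose_response(make_calls(resp, peaks = peaks))
  expect_equal(dr$normalized_pct, c(20, 40, 80, 100))
  # all-equal means: all 100%
  dr <- normalized_dose_response(make_calls(resp,
                                            peaks = matrix(0.03, 6, 4)))
  expect_equal(dr$normalized_pct, rep(100, 4))
  # empty subset errors
  expect_error(normalized_dose_response(make_calls(matrix(FALSE, 6, 4))),
               "no cell")
})

test_that("normalized dose-response is scale invariant", {
  set.seed(8)
  resp <- cbind(runif(30) < 0.2, TRUE, TRUE, TRUE)
  peaks <- matrix(abs(rnorm(120, 0.05, 0.02)) + 0.001, 30, 4)
  c1 <- normalized_dose_response(make_calls(resp, peaks = peaks))
  c2 <- normalized_dose_response(make_calls(resp, peaks = peaks * 17))
  expect_equal(c2$normalized_pct, c1$normalized_pct, tolerance = 1e-12)
})

test_that("pooled two-sample t matches hand computation and handles degeneracy", {
  r <- two_sample_t(c(1, 2, 3), c(2, 3, 4))
  # pooled sd 1, se sqrt(2/3), t = -1/0.8165, df 4
  expect_equal(r$statistic, -1.2247, tolerance = 1e-4)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 0.2878, tolerance = 1e-3)
  r <- two_sample_t(c(5, 6, 7), c(5, 6, 7))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r <- two_sample_t(c(2, 2, 2), c(3, 3, 3))
  expect_true(is.infinite(r$statistic))
  expect_equal(r$p_value, 0)
})

test_that("two-sample t power matches the noncentral-t oracle", {
  # shifted-normal simulation: delta = 2 sigma, n = 20/20
  set.seed(14)
  n <- 20; reps <- 1000; delta <- 2
  rej <- replicate(reps,
    two_sample_t(rnorm(n), rnorm(n, delta))$p_value < 0.05)
  ncp <- delta / sqrt(2 / n)
  tc <- qt(0.975, 2 * n - 2)
  power <- 1 - pt(tc, 2 * n - 2, ncp) + pt(-tc, 2 * n - 2, ncp)
  expect_equal(mean(rej), power, tolerance = 0.03)
})

test_that("repeated-measures ANOVA has the within-subject df and k=2 equals paired t^2", {
  set.seed(19)
  for (r in 1:4) {
    m <- matrix(rnorm(14, mean = rep(c(0, 0.8), each = 7)), ncol = 2)
    rma <- rm_anova_bonferroni(m)
    tt <- t.test(m[, 2], m[, 1], paired = TRUE)
    expect_equal(rma$anova$statistic, unname(tt$statistic)^2,
                 tolerance = 1e-8)
    expect_equal(rma$anova$p_value, tt$p.value, tolerance = 1e-8)
    expect_equal(rma$anova$df, c(1, 6))
  }
  # k = 4 conditions: df (3, 3(n-1))
  m <- matrix(rnorm(40), ncol = 4)
  expect_equal(rm_anova_bonferroni(m)$anova$df, c(3, 27))
  # identical conditions: F = 0, p = 1
  m <- matrix(rep(rnorm(6), 3), ncol = 3)
  rma <- rm_anova_bonferroni(m)
  expect_equal(rma$anova$statistic, 0)
  expect_equal(rma$anova$p_value, 1)
  expect_error(rm_anova_bonferroni(matrix(c(1, NA, 2, 3), 2)), "complete")
})

test_that("Bonferroni multiplies by the number of comparisons, capped at one", {
  set.seed(4)
  m <- matrix(rnorm(30), ncol = 3)
  rma <- rm_anova_bonferroni(m)
  expect_equal(nrow(rma$pairwise), 2)  # adjacent pairs only
  expect_equal(rma$pairwise$p_adjusted,
               pmin(1, rma$pairwise$p_value * 2))
  rma <- rm_anova_bonferroni(m, pairs = "all")
  expect_equal(nrow(rma$pairwise), 3)
})

test_that("a strong monotone condition effect is detected at the study size", {
  # 98 cells x 4 energies with a graded amplitude effect, as in the
  # highly-responsive-subset analysis
  set.seed(27)
  n <- 98
  m <- sapply(c(0.015, 0.047, 0.065, 0.073), function(mu)
    rnorm(n, mu, 0.015))
  rma <- rm_anova_bonferroni(m)
  expect_lt(rma$anova$p_value, 0.001)
  expect_true(all(rma$pairwise$p_adjusted < 0.05))
})
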