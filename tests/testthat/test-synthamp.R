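test_that("generator is deterministic in the seed and validates its spec", {
  sp <- synth_spec(n_species = 40, seed = 7, n_outliers = 3)
  g1 <- generate_species_table(sp)
  g2 <- generate_species_table(sp)
  expect_identical(g1, g2)
  g3 <- generate_species_table(synth_spec(n_species = 40, seed = 8,
                                          n_outliers = 3))
  expect_false(identical(g1$table, g3$table))
  # the draw does not disturb the caller's RNG stream
  set.seed(123); before <- stats::rnorm(1)
  set.seed(123); invisible(generate_species_table(sp)); after <- stats::rnorm(1)
  expect_identical(before, after)
  expect_error(synth_spec(log_cor = 1), "log_cor")
  expect_error(synth_spec(n_outliers = 10, n_species = 5), "n_outliers")
  expect_error(synth_spec(frac_std = 2), "frac_std")
})

test_that("an empty spec yields an empty table and ground truth", {
  g <- generate_species_table(synth_spec(n_species = 0))
  expect_equal(nrow(g$table), 0)
  expect_length(g$ground_truth$outlier_ids, 0)
  expect_length(g$ground_truth$filter_fail_ids, 0)
})

test_that("generated marginals match the spec moments at Monte-Carlo scale", {
  n <- 10000
  sp <- synth_spec(n_species = n, seed = 31, log_pAm_mean = log(600),
                   log_pAm_sd = 1.1, log_v_mean = log(0.025), log_v_sd = 0.7,
                   log_cor = 0.5, n_outliers = 0)
  tab <- generate_species_table(sp)$table
  lx <- log(tab$p_Am_max); lv <- log(tab$v_dot)
  expect_lt(abs(mean(lx) - log(600)), 3 * 1.1 / sqrt(n))
  expect_lt(abs(mean(lv) - log(0.025)), 3 * 0.7 / sqrt(n))
  expect_lt(abs(stats::sd(lx) - 1.1), 3 * 1.1 / sqrt(2 * n))
  expect_lt(abs(stats::sd(lv) - 0.7), 3 * 0.7 / sqrt(2 * n))
  expect_lt(abs(stats::cor(lx, lv) - 0.5), 3 / sqrt(n))
  # allocation mixture: point mass plus spread in (0, 1)
  expect_gt(mean(tab$kappa == 0.8), 0.55)
  expect_true(all(tab$kappa > 0 & tab$kappa < 1))
  # scores live on the half-point 0-10 grid
  expect_true(all(tab$completeness %in% seq(0, 10, by = 0.5)))
})

test_that("curation recovers planted outliers and filter ground truth exactly", {
  # well-separated construction: tight base marginals, distant plants. The
  # separation is a verified property of the fixture, not an assumption:
  # the unplanted draw of the same seed must itself contain no row outside
  # the fences on the planted dimensions.
  base <- generate_species_table(synth_spec(n_species = 60, seed = 11,
                                            log_pAm_sd = 0.08,
                                            log_v_sd = 0.08,
                                            n_outliers = 0))$table
  for (cl in c("p_Am_max", "v_dot")) {
    q <- stats::quantile(base[[cl]], c(0.25, 0.75), type = 7)
    iqr <- q[2] - q[1]
    expect_true(all(base[[cl]] >= q[1] - 1.5 * iqr &
                      base[[cl]] <= q[2] + 1.5 * iqr))
  }
  sp <- synth_spec(n_species = 60, seed = 11, log_pAm_sd = 0.08,
                   log_v_sd = 0.08, n_outliers = 5, outlier_factor = 50)
  g <- generate_species_table(sp)
  expect_length(g$ground_truth$outlier_ids, 5)
  # the model/lifespan/completeness filter drops exactly the recorded rows
  kept <- filter_species(g$table)
  expect_setequal(setdiff(g$table$species_id, kept$species_id),
                  g$ground_truth$filter_fail_ids)
  # fences on the planted dimensions remove exactly the plants
  fenced <- iqr_outlier_filter(g$table, columns = c("p_Am_max", "v_dot"))
  removed <- setdiff(g$table$species_id, fenced$species_id)
  expect_setequal(removed, g$ground_truth$outlier_ids)
})

test_that("bundled fixture is stable and satisfies the table invariants", {
  tab <- bundled_fixture()
  expect_equal(nrow(tab), 300)
  expect_equal(names(tab),
               c("species_id", "model_type", "lifespan_y", "completeness",
                 "p_Am_max", "v_dot", "kappa", "p_M_vol"))
  expect_false(anyDuplicated(tab$species_id) > 0)
  num <- c("lifespan_y", "completeness", "p_Am_max", "v_dot", "kappa", "p_M_vol")
  expect_true(all(vapply(tab[num], function(x) all(is.finite(x)), TRUE)))
  expect_true(all(tab$p_Am_max > 0 & tab$v_dot > 0))
})

test_that("pipeline output on the bundled fixture reproduces the frozen combos", {
  combos <- curate_parameter_space(bundled_fixture())
  expect_equal(combos$pAm_bin, c(1, 1, 1, 2, 2, 2, 2, 3, 3, 4, 4))
  expect_equal(combos$v_bin, c(1, 2, 3, 1, 2, 3, 5, 2, 5, 2, 3))
  expect_equal(combos$frequency, c(27L, 16L, 4L, 6L, 8L, 4L, 2L, 3L, 3L, 2L, 2L))
  expect_equal(unique(combos$pAm_value),
               c(334.529164343525, 858.956040320219, 1383.382916296914,
                 1907.809792273608), tolerance = 1e-12)
  expect_equal(sort(unique(combos$v_value)),
               c(0.0135014491904746, 0.0255143415615641, 0.0375272339326535,
                 0.0615530186748325), tolerance = 1e-12)
  # byte-identical across repeated runs
  again <- curate_parameter_space(bundled_fixture())
  expect_identical(combos, again)
})
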