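species_row <- function(id, pAm = 500, v = 0.02, kappa = 0.8, pM = 50,
                        lifespan = 10, completeness = 3, model = "std") {
  data.frame(species_id = id, model_type = model, lifespan_y = lifespan,
             completeness = completeness, p_Am_max = pAm, v_dot = v,
             kappa = kappa, p_M_vol = pM, stringsAsFactors = FALSE)
}

test_that("species filter applies the exact inequality senses", {
  tab <- rbind(species_row("a", lifespan = 100, completeness = 5),
               species_row("b", lifespan = 20, completeness = 2.5),
               species_row("c", lifespan = 20, completeness = 2.0),
               species_row("d", lifespan = 20, completeness = 5, model = "abj"),
               species_row("e", lifespan = 99.9, completeness = 10))
  out <- filter_species(tab)
  expect_setequal(out$species_id, c("b", "e"))  # <100 strict, >=2.5 inclusive
  expect_equal(nrow(filter_species(tab[0, ])), 0)
  expect_error(filter_species(tab[, -2]), "missing column")
})

test_that("interquartile fences remove only outlying rows", {
  tab <- species_row(sprintf("r%d", 1:5))
  tab$p_Am_max <- c(1, 2, 3, 4, 100)
  out <- iqr_outlier_filter(tab, columns = "p_Am_max")
  # type-7 quartiles: Q1 = 2, Q3 = 4, upper fence 7
  expect_setequal(out$p_Am_max, c(1, 2, 3, 4))
  tab$p_Am_max <- rep(7, 5)
  expect_equal(nrow(iqr_outlier_filter(tab, "p_Am_max")), 5)
  tab$p_Am_max <- c(1, 2, 3, 4, 100)
  expect_equal(nrow(iqr_outlier_filter(tab, "p_Am_max", k = 1e9)), 5)
  expect_warning(out3 <- iqr_outlier_filter(tab[1:3, ], "p_Am_max"), "fewer than 4")
  expect_equal(nrow(out3), 3)
  expect_error(iqr_outlier_filter(tab, "p_Am_max", k = 0), "positive")
  # rows strictly inside both quartiles survive any fencing
  set.seed(21)
  for (i in 1:20) {
    t2 <- species_row(sprintf("s%d", 1:30))
    t2$p_Am_max <- stats::rlnorm(30, 6, 1.5)
    t2$v_dot <- stats::rlnorm(30, -3.5, 1)
    q1 <- stats::quantile(t2$p_Am_max, c(0.25, 0.75), type = 7)
    q2 <- stats::quantile(t2$v_dot, c(0.25, 0.75), type = 7)
    inside <- t2$p_Am_max > q1[1] & t2$p_Am_max < q1[2] &
      t2$v_dot > q2[1] & t2$v_dot < q2[2]
    kept <- iqr_outlier_filter(t2, c("p_Am_max", "v_dot"))
    expect_true(all(t2$species_id[inside] %in% kept$species_id))
  }
})

test_that("equal-width joint discretization with midpoint representatives", {
  tab <- species_row(sprintf("r%d", 1:4))
  tab$p_Am_max <- c(0, 10, 3.7, 9.1)
  tab$v_dot <- c(1, 1, 1, 1)
  cb <- joint_discretize(tab, n_bins = 5)
  expect_equal(sort(unique(cb$pAm_value)), c(1, 3, 9))  # midpoints of [0,2],[2,4],[8,10]
  expect_equal(cb$pAm_value[cb$pAm_bin == 2], 3)        # x = 3.7 maps to 3
  expect_equal(sum(cb$frequency), 4)
  expect_true(all(cb$v_bin == 1))                       # zero range: single bin
  one <- joint_discretize(tab[1, ], n_bins = 5)
  expect_equal(nrow(one), 1)
  expect_equal(one$frequency, 1L)
  # member-mean alternative uses the mean of the members, not the midpoint
  cbm <- joint_discretize(tab, n_bins = 5, representative = "member-mean")
  expect_equal(cbm$pAm_value[cbm$pAm_bin == 5], mean(c(10, 9.1)))
  expect_error(joint_discretize(tab[0, ]), "at least one row")
})

test_that("combo pruning: frequency, dedup and the 8-neighbour isolation rule", {
  cb <- data.frame(pAm_bin = c(1, 2), v_bin = c(1, 1), frequency = c(1, 5),
                   pAm_value = c(1, 3), v_value = c(1, 1))
  expect_equal(prune_combos(cb, drop_edge_outliers = FALSE)$pAm_bin, 2)
  dup <- rbind(cb[2, ], cb[2, ])
  expect_equal(nrow(prune_combos(dup, drop_edge_outliers = FALSE)), 1)
  # an isolated corner with no retained 8-neighbour is removed
  iso <- data.frame(pAm_bin = c(1, 1, 2, 5), v_bin = c(1, 2, 1, 5),
                    frequency = c(3, 3, 3, 3))
  expect_setequal(paste(prune_combos(iso)$pAm_bin, prune_combos(iso)$v_bin),
                  c("1 1", "1 2", "2 1"))
  # exhaustive check against a brute-force oracle on random 5x5 occupancies
  set.seed(99)
  for (rep in 1:25) {
    occ <- which(matrix(stats::runif(25) < 0.4, 5, 5), arr.ind = TRUE)
    if (nrow(occ) == 0) next
    cb2 <- data.frame(pAm_bin = occ[, 1], v_bin = occ[, 2],
                      frequency = sample(1:4, nrow(occ), replace = TRUE))
    got <- prune_combos(cb2, min_frequency = 2)
    keep <- cb2[cb2$frequency >= 2, ]
    ok <- vapply(seq_len(nrow(keep)), function(i) {
      any(abs(keep$pAm_bin - keep$pAm_bin[i]) <= 1 &
            abs(keep$v_bin - keep$v_bin[i]) <= 1 &
            (keep$pAm_bin != keep$pAm_bin[i] | keep$v_bin != keep$v_bin[i]))
    }, logical(1))
    oracle <- keep[ok, ]
    expect_setequal(paste(got$pAm_bin, got$v_bin),
                    paste(oracle$pAm_bin, oracle$v_bin))
  }
})

test_that("validation box uses closed bounds and never constrains kappa", {
  tab <- rbind(species_row("edge", pAm = 1500, v = 0.15, pM = 1600),
               species_row("highk", pAm = 5000, v = 0.3, pM = 1800, kappa = 0.95),
               species_row("fastv", pAm = 5000, v = 0.60, pM = 1800),
               species_row("out", pAm = 12000, v = 0.3, pM = 1800))
  out <- validation_box_query(tab)
  expect_setequal(out$species_id, c("edge", "highk"))
  expect_error(validation_box_query(tab, box = list(v_dot = c(1, 0))), "lower")
  expect_error(validation_box_query(tab[, -6]), "missing column")
})

test_that("coefficient of variation: value, degeneracy and scale invariance", {
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  expect_equal(coefficient_of_variation(rep(4, 10)), 0)
  x <- c(2, 5, 9, 11)
  expect_equal(coefficient_of_variation(3.7 * x), coefficient_of_variation(x))
  expect_error(coefficient_of_variation(1), "two values")
  expect_error(coefficient_of_variation(c(-2, 2)), "zero mean")
})

test_that("species-table CSV round-trip and column mapping", {
  tab <- rbind(species_row("a"), species_row("b", pAm = 900))
  path <- tempfile(fileext = ".csv")
  write_species_table(tab, path)
  back <- read_species_table(path)
  expect_equal(back, tab)
  names(tab)[names(tab) == "p_Am_max"] <- "pAm"
  path2 <- tempfile(fileext = ".csv")
  write_species_table(tab, path2)
  mapped <- read_species_table(path2, column_map = c(p_Am_max = "pAm"))
  expect_true("p_Am_max" %in% names(mapped))
  expect_error(read_species_table(path2, column_map = c(p_Am_max = "nope")),
               "not found")
})
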