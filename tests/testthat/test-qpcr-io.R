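test_that("read_cq_table parses, drops blank Cq cells and validates structure", {
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  df <- data.frame(gene = rep("ACTB", 6), sample = rep(c("s1", "s2"), each = 3),
                   group = "WT", replicate = rep(1:3, 2),
                   cq = c(20.1, 20.2, 20.15, 21.0, "", 21.1))
  write.csv(df, tf, row.names = FALSE)
  expect_message(cq <- read_cq_table(tf), "dropped 1 row")
  expect_equal(nrow(cq), 5L)
  expect_equal(attr(cq, "n_dropped"), 1L)
  expect_s3_class(cq, "cq_table")

  # custom column names
  tf2 <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf2), add = TRUE)
  df2 <- data.frame(Gene = "ACTB", Well = "s1", Condition = "WT",
                    Rep = 1:3, Ct = c(20, 20.1, 20.05))
  write.table(df2, tf2, sep = "\t", row.names = FALSE)
  cq2 <- read_cq_table(tf2, columns = c(gene = "Gene", sample = "Well",
                                        group = "Condition",
                                        replicate = "Rep", cq = "Ct"))
  expect_equal(cq2$cq, c(20, 20.1, 20.05))

  # missing column is a format error naming the column
  tf3 <- tempfile(fileext = ".csv")
  on.exit(unlink(tf3), add = TRUE)
  write.csv(df[, -5], tf3, row.names = FALSE)
  expect_error(read_cq_table(tf3), "cq", class = "refstab_format_error")
})

test_that("cq table invariants: unique replicates, one group per sample", {
  base <- data.frame(gene = "g", sample = "s1", group = "WT",
                     replicate = 1:3, cq = c(20, 20, 20))
  expect_s3_class(validate_cq_table(base), "cq_table")
  dup <- base; dup$replicate <- c(1, 1, 2)
  expect_error(validate_cq_table(dup), class = "refstab_validation_error")
  twogrp <- rbind(base, transform(base, group = "KO", replicate = 4:6))
  expect_error(validate_cq_table(twogrp), "more than one group",
               class = "refstab_validation_error")
  neg <- base; neg$cq[1] <- -1
  expect_error(validate_cq_table(neg), class = "refstab_validation_error")
})

test_that("replicate aggregation applies the SD > threshold outlier rule", {
  # consistent triplicate: plain mean, flag ok
  a <- aggregate_replicates(make_cq_df("g", "s", "WT", c(20.00, 20.05, 20.10)))
  expect_equal(a$cq[1, 1], 20.05)
  expect_equal(a$flag[1, 1], "ok")

  # one clear outlier: farthest from the median is dropped, SD recomputed
  b <- aggregate_replicates(make_cq_df("g", "s", "WT", c(20.00, 20.10, 20.90)))
  expect_equal(b$cq[1, 1], 20.05)
  expect_equal(b$sd[1, 1], sd(c(20.0, 20.1)), tolerance = 1e-12)
  expect_equal(b$flag[1, 1], "outlier_dropped")

  # irreducibly spread: flagged inconsistent, mean over all replicates kept
  c_ <- aggregate_replicates(make_cq_df("g", "s", "WT", c(19, 20, 21)))
  expect_equal(c_$cq[1, 1], 20)
  expect_equal(c_$flag[1, 1], "inconsistent")

  # fewer than 2 replicates is an error
  one <- data.frame(gene = "g", sample = "s", group = "WT",
                    replicate = 1L, cq = 20)
  expect_error(aggregate_replicates(validate_cq_table(one)),
               class = "refstab_validation_error")
})

test_that("aggregation is permutation-invariant and keeps retained SD below threshold", {
  set.seed(11)
  for (i in 1:25) {
    vals <- round(rnorm(3, 20, 0.4), 3)
    perm <- sample(3)
    a1 <- aggregate_replicates(make_cq_df("g", "s", "WT", vals))
    a2 <- aggregate_replicates(make_cq_df("g", "s", "WT", vals[perm],
                                          replicate = (1:3)[perm]))
    expect_equal(a1$cq[1, 1], a2$cq[1, 1])
    expect_equal(a1$flag[1, 1], a2$flag[1, 1])
    if (a1$flag[1, 1] != "inconsistent")
      expect_lt(a1$sd[1, 1], 0.20)
  }
  # documented tie-break: equidistant replicates drop the lowest index
  tie <- aggregate_replicates(make_cq_df("g", "s", "WT", c(19.75, 20.0, 20.25)))
  expect_equal(tie$flag[1, 1], "outlier_dropped")
  expect_equal(tie$cq[1, 1], mean(c(20.0, 20.25)))
})

test_that("standard-curve efficiency matches the dilution-series closed forms", {
  # perfect doubling: slope -3.3219 -> E = 2, R^2 = 1, pass
  eff <- efficiency_from_standard_curve(c(1, 0.1, 0.01),
                                        c(20.0000, 23.3219, 26.6439))
  expect_equal(eff$e_value, 2, tolerance = 1e-4)
  expect_equal(eff$r_squared, 1, tolerance = 1e-9)
  expect_true(eff$pass_qc)

  # flat curve: zero slope, E undefined, fail
  flat <- efficiency_from_standard_curve(c(1, 0.1, 0.01), c(20, 20, 20))
  expect_true(is.na(flat$e_value))
  expect_false(flat$pass_qc)

  # slope -3.9 -> E = 10^(1/3.9) ~ 1.805, outside the 1.9-2.1 band
  lc <- log10(c(1, 0.1, 0.01))
  low <- efficiency_from_standard_curve(c(1, 0.1, 0.01), 20 - 3.9 * lc)
  expect_equal(low$e_value, 10^(1 / 3.9), tolerance = 1e-9)
  expect_false(low$pass_qc)

  # scaling all concentrations only shifts the intercept
  sc <- efficiency_from_standard_curve(7 * c(1, 0.1, 0.01),
                                       c(20.0000, 23.3219, 26.6439))
  expect_equal(sc$slope, eff$slope, tolerance = 1e-9)
  expect_equal(sc$e_value, eff$e_value, tolerance = 1e-9)

  # the caller can mask the 4th dilution out
  four <- efficiency_from_standard_curve(c(1, 0.1, 0.01, 0.001),
                                         c(20, 23.3, 26.6, 35),
                                         use = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(four$n_points, 3L)

  expect_error(efficiency_from_standard_curve(c(1, 0.1), c(20, 23)),
               class = "refstab_validation_error")
  expect_error(efficiency_from_standard_curve(c(1, 1, 1), c(20, 21, 22)),
               class = "refstab_degenerate_design_error")
})

test_that("aggregated Cq round-trips through the wide CSV writer", {
  sim <- simulate_cq_dataset(panel_cfg(seed = 3, n_g = 3))
  agg <- aggregate_replicates(sim$cq)
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(c(tf, sub("\\.csv$", "_flags.csv", tf))))
  paths <- write_aggregated_cq(agg, tf)
  back <- as.matrix(read.csv(paths[1], row.names = 1, check.names = FALSE))
  expect_equal(back, agg$cq, tolerance = 1e-12)
  flags <- as.matrix(read.csv(paths[2], row.names = 1, check.names = FALSE))
  expect_equal(unname(flags), unname(agg$flag))
})
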