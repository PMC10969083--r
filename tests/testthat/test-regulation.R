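test_that("expression ratio is the signed fold-change", {
  expect_equal(expression_ratio(10, 10), 1)
  expect_equal(expression_ratio(10.5, 22), 22 / 10.5)
  # swapping conditions flips the sign, preserves the magnitude
  expect_equal(expression_ratio(22, 10.5), -expression_ratio(10.5, 22))
  expect_equal(expression_ratio(10, 5), -2)
  expect_true(abs(expression_ratio(3, 4)) >= 1)
})

test_that("Welch p matches an independent oracle and its invariances", {
  expect_equal(welch_p(c(10, 12, 11, 9), c(10, 12, 11, 9)), 1)
  a <- c(10, 12, 11, 9)
  b <- c(20, 22, 21, 25)
  expect_equal(welch_p(a, b), welch_oracle(a, b), tolerance = 1e-12)
  # invariant under common scaling
  expect_equal(welch_p(3 * a, 3 * b), welch_p(a, b), tolerance = 1e-12)
  # degenerate zero-variance groups
  expect_equal(welch_p(rep(5, 4), rep(5, 4)), 1)
})

test_that("CUT reproduces the printed per-gene thresholds", {
  expect_equal(compute_cut(0, 0), 1)
  # Aldh3a2: REVs 1.09% and 13.96% -> 1.198
  expect_equal(round(compute_cut(1.09, 13.96), 3), 1.198)
  # Pck2: REVs 101.47% and 26.41% -> 2.48
  expect_equal(round(compute_cut(101.47, 26.41), 2), 2.48)
  # symmetric and strictly increasing in each argument
  expect_equal(compute_cut(3, 7), compute_cut(7, 3))
  expect_gt(compute_cut(4, 7), compute_cut(3, 7))
  expect_gt(compute_cut(3, 8), compute_cut(3, 7))
})

# printed (x, p, CUT) triples of the four disagreement categories with the
# fixed 1.5x rule; all satisfy p < 0.05
table1 <- rbind(
  data.frame(category = "falsely_down",
             gene = c("Ifitm5", "Hinfp", "Prdm11", "Myl7", "Trim71",
                      "Usf1", "Chkb", "Cntnap5c", "Dnajb1", "Csrnp2"),
             x = c(-2.350, -2.164, -2.000, -1.887, -1.852, -1.837, -1.829,
                   -1.824, -1.812, -1.797),
             p = c(0.030, 0.039, 0.026, 0.022, 0.036, 0.023, 0.025, 0.025,
                   0.034, 0.032),
             cut = c(2.427, 2.639, 2.170, 2.468, 2.285, 1.928, 2.633,
                     1.922, 2.129, 2.176)),
  data.frame(category = "missed_down",
             gene = c("Gsk3b", "Aldh3a2", "Mapk10", "Myl2", "Tpm2",
                      "Atp5j", "Gmpr2", "Enpp4", "Chat", "Dbt"),
             x = c(-1.490, -1.462, -1.455, -1.431, -1.421, -1.401, -1.371,
                   -1.362, -1.353, -1.323),
             p = c(0.017, 0.007, 0.028, 0.007, 0.027, 0.013, 0.009, 0.028,
                   0.024, 0.024),
             cut = c(1.341, 1.198, 1.306, 1.329, 1.359, 1.272, 1.238,
                     1.316, 1.292, 1.274)),
  data.frame(category = "missed_up",
             gene = c("Lpin3", "Pde1a", "Gpam", "B4galt1", "Ncf4", "Bcl2",
                      "Ndufc1", "Ikbkg", "Atp6v1b2", "Gucy1b2"),
             x = c(1.372, 1.374, 1.374, 1.391, 1.397, 1.401, 1.410, 1.424,
                   1.438, 1.490),
             p = c(0.004, 0.008, 0.019, 0.005, 0.046, 0.005, 0.018, 0.005,
                   0.045, 0.034),
             cut = c(1.146, 1.219, 1.214, 1.334, 1.320, 1.164, 1.303,
                     1.233, 1.381, 1.426)),
  data.frame(category = "falsely_up",
             gene = c("Kif3c", "Nt5el", "Zfp362", "Ctsg", "Tmem231",
                      "Adam12", "Ftcd", "Ap1m1", "Lrrc71", "Gclc"),
             x = c(1.706, 1.720, 1.758, 1.887, 1.912, 1.966, 1.979, 2.063,
                   2.153, 2.330),
             p = c(0.009, 0.028, 0.024, 0.018, 0.027, 0.036, 0.033, 0.006,
                   0.034, 0.028),
             cut = c(1.832, 2.153, 1.852, 1.890, 2.196, 2.313, 2.214,
                     2.079, 2.559, 2.456))
)

test_that("the composite CUT criterion reproduces all four call categories", {
  for (i in seq_len(nrow(table1))) {
    row <- table1[i, ]
    call <- regulation_call(row$x, row$p, row$cut)
    expected_call <- switch(row$category,
      falsely_down = "none", falsely_up = "none",
      missed_down = "down", missed_up = "up")
    expect_equal(call, expected_call, label = row$gene)
  }
  # categorization against the fixed 1.5x rule recovers the table blocks
  reg <- data.frame(gene = table1$gene, x = table1$x, p = table1$p,
                    cut = table1$cut,
                    call = mapply(regulation_call, table1$x, table1$p,
                                  table1$cut),
                    stringsAsFactors = FALSE)
  cat_out <- compare_fixed_cutoff(reg)
  expect_equal(cat_out$category, as.character(table1$category))
})

test_that("category assignment agrees with a brute-force reimplementation", {
  set.seed(404)
  n <- 500
  reg <- data.frame(
    gene = paste0("g", 1:n),
    x = ifelse(runif(n) < 0.5, 1, -1) * exp(runif(n, 0, log(3))),
    p = runif(n, 0, 0.2),
    cut = 1 + runif(n, 0, 1.2),
    stringsAsFactors = FALSE
  )
  reg$call <- mapply(regulation_call, reg$x, reg$p, reg$cut)
  got <- compare_fixed_cutoff(reg)$category
  want <- vapply(seq_len(n), function(i) {
    sig <- reg$p[i] < 0.05
    fixed <- if (sig && reg$x[i] >= 1.5) "up"
      else if (sig && reg$x[i] <= -1.5) "down" else "none"
    ours <- reg$call[i]
    if (fixed == "up" && ours != "up") "falsely_up"
    else if (fixed == "down" && ours != "down") "falsely_down"
    else if (ours == "up" && fixed != "up") "missed_up"
    else if (ours == "down" && fixed != "down") "missed_down"
    else "concordant"
  }, character(1))
  expect_equal(got, want)
})

test_that("WIR brackets the printed purine-pathway values", {
  expect_equal(compute_wir(5, 1, 0.01), 0)
  # down-regulated adenylate cyclase: AVE 5.12, x = -1.66, p < 0.05
  lo <- compute_wir(5.12, -1.66, 0)
  hi <- compute_wir(5.12, -1.66, 0.05)
  expect_lt(lo, -3.36); expect_gt(hi, -3.36)
  # weakly expressed up-regulated gene: AVE 0.55, x = 1.24
  expect_gt(compute_wir(0.55, 1.24, 0), 0.13)
  expect_lt(compute_wir(0.55, 1.24, 0.05), 0.13)
  # |wir| <= ave * (|x| - 1), equality iff p = 0
  set.seed(99)
  for (k in 1:50) {
    ave <- runif(1, 0.1, 100)
    x <- sample(c(-1, 1), 1) * runif(1, 1, 10)
    p <- runif(1)
    expect_lte(abs(compute_wir(ave, x, p)), ave * (abs(x) - 1) + 1e-12)
  }
  expect_equal(abs(compute_wir(2, 3, 0)), 2 * 2)
})

test_that("coordination and control changes are simple signed differences", {
  expect_equal(compute_delta_coord(5, 5), 0)
  # a desynchronized gene: COORD 22% dropping to -4% -> -26 points
  expect_equal(compute_delta_coord(22, -4), -26)
  expect_equal(compute_delta_coord(-4, 22), 26)   # antisymmetric
  # control changes, in percent: REC 3.82 -> 27.93 is +2411%
  expect_equal(compute_delta_rec(3.82, 27.93), 2411)
  expect_equal(compute_delta_rec(11.08, 26.25), 1517)
})

test_that("the regulation table wires the pieces together", {
  sim <- generate_fabric(fabric_spec(
    25, fold = c(g1 = 5, g2 = 0.2),
    cv = stats::setNames(rep(0.05, 25), paste0("g", 1:25)),
    seed = 15))
  cfg <- fabric_config()
  reg <- regulation_table(sim$dataset, cfg)
  expect_setequal(reg$gene, paste0("g", 1:25))
  expect_true(all(abs(reg$x) >= 1))
  expect_true(all(reg$cut > 1))
  expect_equal(reg$call[reg$gene == "g1"], "up")
  expect_equal(reg$call[reg$gene == "g2"], "down")
  expect_equal(sign(reg$wir[reg$gene == "g2"]), -1)
  # calls respect the composite criterion row by row
  for (i in seq_len(nrow(reg))) {
    expect_equal(reg$call[i],
                 regulation_call(reg$x[i], reg$p[i], reg$cut[i]))
  }
})
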