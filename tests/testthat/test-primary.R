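test_that("AVE averages replicates over all redundant spots", {
  ds <- make_tiny_dataset()
  # single constant spot
  expect_equal(compute_ave(ds, "B", "N"), 2.5)
  # two spots with replicate means 2 and 10 -> grand mean 6
  expect_equal(compute_ave(ds, "A", "N"), 6)
  expect_error(compute_ave(ds, "ZZZ", "N"), "unknown gene")

  # generator-imposed AVE on the expression-level scale of a top gene
  spec <- fabric_spec(50, ave = c(g1 = 1134), cv = c(g1 = 0.02),
                      seed = 42)
  sim <- generate_fabric(spec)
  ave <- compute_ave(sim$dataset, "g1", "N")
  # CV 2%, 4 replicates: Monte-Carlo error ~ 1134*0.02/sqrt(4) ~ 11
  expect_lt(abs(ave - 1134) / 1134, 0.05)
})

test_that("REV matches the chi-square-corrected CV oracle", {
  ds <- make_tiny_dataset()
  expect_equal(compute_rev(ds, "B", "L", cv_correction = FALSE) > 0, TRUE)

  # constant replicates -> REV exactly 0
  const <- fabric_dataset("s1", "A",
                          list(N = matrix(5, 1, 4), L = matrix(7, 1, 4)))
  expect_equal(compute_rev(const, "A", "N"), 0)

  # single spot, n = 4, raw CV exactly 10%: nu = 3,
  # c = (sqrt(3/chisq_.975) + sqrt(3/chisq_.025)) / 2  (independent oracle)
  vals <- c(90, 110, 90, 110)           # mean 100, sd 11.547 -> scale to CV 10%
  vals <- 100 + (vals - 100) * (10 / stats::sd(vals))
  ds1 <- fabric_dataset("s1", "A",
                        list(N = matrix(vals, 1), L = matrix(vals, 1)))
  c_oracle <- 0.5 * (sqrt(3 / qchisq(0.975, 3)) + sqrt(3 / qchisq(0.025, 3)))
  expect_equal(compute_rev(ds1, "A", "N"), 10 * c_oracle, tolerance = 1e-12)
  expect_equal(compute_rev(ds1, "A", "N", cv_correction = FALSE), 10,
               tolerance = 1e-12)

  # pooled within-spot variance: a constant offset between spots does not
  # inflate REV (two spots, same within-spot variance, shifted means)
  base <- c(10, 12, 11, 9)
  ds2 <- fabric_dataset(c("s1", "s2"), c("A", "A"),
                        list(N = rbind(base, base + 100),
                             L = rbind(base, base)))
  naive_cv <- 100 * sd(c(base, base + 100)) / mean(c(base, base + 100))
  pooled <- compute_rev(ds2, "A", "N", cv_correction = FALSE)
  expect_equal(pooled, 100 * sd(base) / mean(c(base, base + 100)),
               tolerance = 1e-12)
  expect_lt(pooled, naive_cv)

  # generator recovery at the REV magnitude of a loosely controlled gene:
  # CV tuned so the corrected single-spot REV is ~101.5%
  target_cv <- 1.015 / (100 * rev_correction_factor(3) / 100)
  spec <- fabric_spec(40, n_replicates = 4, spot_probs = c(1, 0, 0),
                      cv = stats::setNames(rep(target_cv, 40),
                                           paste0("g", 1:40)),
                      seed = 5)
  sim <- generate_fabric(spec)
  revs <- vapply(paste0("g", 1:40), compute_rev, numeric(1),
                 dataset = sim$dataset, condition = "N")
  # per-gene REV is noisy at n = 4; the cross-gene mean recovers the target
  expect_lt(abs(mean(revs) - 101.5) / 101.5, 0.25)
})

test_that("correlation cut-offs reproduce the t closed form and known values", {
  # printed working values at n = 4
  expect_equal(round(correlation_cutoff(2, 2, 4), 2), 0.71)
  expect_equal(round(correlation_cutoff(3, 3, 4), 2), 0.58)
  expect_equal(round(correlation_cutoff(1, 1, 4), 4), 0.95)

  # brute-force oracle: invert the correlation-test p-value numerically
  r_oracle <- function(n_points, alpha = 0.05) {
    p_of_r <- function(r) {
      t <- r * sqrt((n_points - 2) / (1 - r^2))
      2 * stats::pt(-abs(t), n_points - 2)
    }
    stats::uniroot(function(r) p_of_r(r) - alpha, c(1e-9, 1 - 1e-9),
                   tol = 1e-12)$root
  }
  for (np in c(4, 8, 12, 20, 40)) {
    expect_equal(correlation_cutoff(np / 4, np / 4, 4), r_oracle(np),
                 tolerance = 1e-6)
  }

  # strictly decreasing in the number of points; min() generalization
  cuts <- vapply(1:6, function(s) correlation_cutoff(s, s, 4), numeric(1))
  expect_true(all(diff(cuts) < 0))
  expect_equal(correlation_cutoff(1, 3, 4), correlation_cutoff(1, 1, 4))
  expect_error(correlation_cutoff(1, 1, 2), "insufficient")
})

test_that("COR pairs spots in file order and handles degenerate vectors", {
  ds <- make_tiny_dataset()
  # gene against itself (restricting to a single spot) is exactly 1
  expect_equal(compute_cor(ds, "B", "B", "N")$cor, 1)
  # B = (1,2,3,4), C = (4,3,2,1): exact antisymmetry
  cc <- compute_cor(ds, "B", "C", "N")
  expect_equal(cc$cor, -1)
  expect_equal(cc$n_points, 4L)
  # multi-spot gene A vs single-spot B uses s_min = 1 spot -> 4 points
  expect_equal(compute_cor(ds, "A", "B", "N")$n_points, 4L)

  # zero variance -> undefined, classified as unclassified
  const <- fabric_dataset(c("s1", "s2"), c("A", "B"),
                          list(N = rbind(rep(5, 4), 1:4),
                               L = rbind(rep(5, 4), 1:4)))
  cc <- compute_cor(const, "A", "B", "N")
  expect_true(is.na(cc$cor))
  expect_equal(classify_pair(cc$cor, cc$n_points), "unclassified")
})

test_that("null pairs have near-zero mean correlation (simulation oracle)", {
  sim <- generate_fabric(fabric_spec(100, spot_probs = c(1, 0, 0),
                                     seed = 101))
  set.seed(202)
  pick <- replicate(1000, sample(100, 2), simplify = FALSE)
  cors <- vapply(pick, function(ij) {
    compute_cor(sim$dataset, paste0("g", ij[1]), paste0("g", ij[2]),
                "N")$cor
  }, numeric(1))
  se <- stats::sd(cors) / sqrt(length(cors))
  expect_lt(abs(mean(cors)), 3 * se + 1e-3)
  expect_lt(mean(abs(cors)), 0.6)   # wide null at n = 4
})

test_that("pair classification is exhaustive and mutually exclusive", {
  classes <- c("synergistic", "antagonistic", "independent", "unclassified")
  r_c <- correlation_cutoff(1, 1, 4)
  for (cor in c(-1, -0.99, -r_c, -0.5, -0.05, -0.03, 0, 0.03, 0.05,
                0.5, r_c, 0.99, 1)) {
    cls <- classify_pair(cor, 4)
    expect_true(cls %in% classes)
    # invariant re-derivation
    expected <- if (cor >= r_c) "synergistic"
      else if (cor <= -r_c) "antagonistic"
      else if (abs(cor) < 0.05) "independent"
      else "unclassified"
    expect_equal(cls, expected)
  }
  expect_equal(classify_pair(0.99, 4), "synergistic")
  expect_equal(classify_pair(0.03, 4), "independent")
  expect_equal(classify_pair(0.50, 4), "unclassified")
})

test_that("AVE and REV are blind to replicate permutation but COR is not", {
  sim <- generate_fabric(fabric_spec(10, spot_probs = c(1, 0, 0),
                                     blocks = list(list(genes = 1:4,
                                                        rho = 0.9)),
                                     seed = 33))
  ds <- sim$dataset
  perm <- ds
  i <- which(perm$gene == "g1")
  perm$values$N[i, ] <- perm$values$N[i, c(3, 1, 4, 2)]
  expect_equal(compute_ave(perm, "g1", "N"), compute_ave(ds, "g1", "N"))
  expect_equal(compute_rev(perm, "g1", "N"), compute_rev(ds, "g1", "N"))
  expect_false(isTRUE(all.equal(compute_cor(perm, "g1", "g2", "N")$cor,
                                compute_cor(ds, "g1", "g2", "N")$cor)))
})

test_that("pair tables enumerate distinct pairs within and between sets", {
  sim <- generate_fabric(fabric_spec(12, seed = 9))
  genes <- paste0("g", 1:12)
  cfg <- fabric_config()
  within <- pair_stats(sim$dataset, genes[1:6], condition = "N",
                       config = cfg)
  expect_equal(nrow(within), count_distinct_pairs(6))
  # overlapping cross sets: |A||B| - |shared| distinct pairs
  across <- pair_stats(sim$dataset, genes[1:5], genes[4:9],
                       condition = "N", config = cfg)
  expect_equal(nrow(across), 5 * 6 - 2 - 1)  # 2 shared self-pairs removed,
                                             # 1 duplicate unordered pair (g4,g5)
  expect_false(any(across$gene_i == across$gene_j))
  expect_warning(pair_stats(sim$dataset, c(genes[1:3], "ghost"),
                            condition = "N", config = cfg),
                 "absent")
})
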