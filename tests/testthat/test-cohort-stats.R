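test_that("paired_compare: degenerate, Gaussian and skewed branches", {
  a <- c(1, 2, 3, 4, 5)
  res <- paired_compare(a, a)
  expect_true(res$degenerate)
  expect_equal(res$estimate, 0)
  expect_equal(res$p_value, 1)

  set.seed(21)
  b <- rnorm(35)
  d <- rnorm(35, mean = 0.5, sd = 1)
  res_t <- paired_compare(b + d, b)
  expect_identical(res_t$test, "paired t")
  expect_true(res_t$conf_low <= 0.5 && 0.5 <= res_t$conf_high)
  expect_true(res_t$conf_low <= res_t$estimate &&
                res_t$estimate <= res_t$conf_high)
  expect_equal(res_t$estimate, mean(d), tolerance = 1e-9)

  set.seed(22)
  skew <- rexp(35)^2
  res_w <- paired_compare(b + skew, b)
  expect_identical(res_w$test, "wilcoxon")
})

test_that("paired_compare is antisymmetric and translation invariant", {
  set.seed(5)
  a <- rnorm(20, 1)
  b <- rnorm(20)
  r1 <- paired_compare(a, b)
  r2 <- paired_compare(b, a)
  expect_equal(r1$estimate, -r2$estimate)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$conf_low, -r2$conf_high)

  r3 <- paired_compare(a + 100, b + 100)
  expect_equal(r3$estimate, r1$estimate)
  expect_equal(r3$p_value, r1$p_value)
})

test_that("Spearman correlation: monotone extremes and the rank-formula oracle", {
  x <- c(1, 3, 5, 7, 11, 13)
  expect_equal(rank_correlation(x, x^3)$rho, 1)
  expect_equal(rank_correlation(x, -sqrt(x))$rho, -1)
  expect_error(rank_correlation(rep(1, 6), x), "constant")

  # exact rank formula on tie-free data, n <= 8
  for (seed in 1:6) {
    set.seed(seed)
    xx <- sample(100, 8)
    yy <- sample(100, 8)
    rho_formula <- 1 - 6 * sum((rank(xx) - rank(yy))^2) / (8 * (8^2 - 1))
    expect_equal(rank_correlation(xx, yy)$rho, rho_formula,
                 tolerance = 1e-12)
  }

  # invariant under strictly monotone transforms
  set.seed(9)
  u <- runif(12); v <- runif(12)
  expect_equal(rank_correlation(u, v)$rho,
               rank_correlation(exp(u), v^3)$rho)
})

test_that("per-variant best counts handle dominance, ties and label permutation", {
  tab <- cbind(A = c(1, 1, 1, 1), B = c(2, 3, 2, 2), C = c(3, 2, 4, 5))
  counts <- rank_by_variant(tab, "lower")
  expect_equal(as.vector(counts), c(4, 0, 0))

  # constructed 35-patient table with exactly 20 best at variant A
  set.seed(31)
  m <- matrix(runif(35 * 4, 1, 2), 35, 4,
              dimnames = list(NULL, c("A", "B", "C", "D")))
  best_at_A <- sample(35, 20)
  m[best_at_A, "A"] <- 0.5
  m[setdiff(1:35, best_at_A), "B"] <- 0.4
  counts2 <- rank_by_variant(m, "lower")
  expect_equal(unname(counts2["A"]), 20)
  expect_equal(unname(counts2["B"]), 15)

  # tied best is split and flagged
  tie <- cbind(A = c(1, 2), B = c(1, 3), C = c(5, 4))
  ct <- rank_by_variant(tie, "lower")
  expect_equal(as.vector(ct), c(1.5, 0.5, 0))
  expect_equal(attr(ct, "n_ties"), 1L)

  # permuting columns moves counts with their labels
  perm <- rank_by_variant(m[, c("C", "A", "D", "B")], "lower")
  expect_equal(perm[["A"]], counts2[["A"]])
})

# build a synthetic cohort table with controllable injected effects
make_cohort_table <- function(n = 20, seed = 1, mld_penalty_per_cm3 = 0.4) {
  set.seed(seed)
  v_ptv <- exp(runif(n, log(150), log(2600)))
  v_lung <- rnorm(n, 3500, 400)
  d_cord <- runif(n, 5, 60)
  psi_t <- runif(n, 0.4, 1)
  base <- data.frame(
    patient = seq_len(n), V_PTV_cm3 = v_ptv, V_lung_cm3 = v_lung,
    d_CTV_cord_mm = d_cord, d_CTV_skin_mm = runif(n, 2, 40),
    psi_tilde = psi_t, R_mm = runif(n, 0, 60))
  mk <- function(variant, mld_extra, v5_extra, cn_extra) {
    data.frame(base, variant = variant,
               CN = pmin(0.9, 0.55 + cn_extra + 0.1 * psi_t + rnorm(n, 0, 0.03)),
               HI = 0.15 - 0.03 * psi_t + rnorm(n, 0, 0.01),
               DHD = 0.03 + rnorm(n, 0, 0.004),
               MU = round(rnorm(n, 270, 30)) - (variant != "3DCRT") * 50,
               D1cc_cord_cGy = rnorm(n, 2900, 700),
               oeso_mean_cGy = rnorm(n, 1700, 700),
               V20Gy_pct = pmax(2, rnorm(n, 23, 9)),
               V5Gy_pct = pmax(5, rnorm(n, 54, 15) + v5_extra),
               MLD_cGy = rnorm(n, 1170, 400) + mld_extra)
  }
  rbind(mk("3DCRT", 0, 0, 0),
        mk("DCAT_00", mld_penalty_per_cm3 * (v_ptv - 800), 10, 0.09),
        mk("DCAT_30", mld_penalty_per_cm3 * (v_ptv - 800) + rnorm(n, 1, 4),
           10, 0.09),
        mk("DCAT_45", mld_penalty_per_cm3 * (v_ptv - 800) + rnorm(n, 2, 4),
           10, 0.09),
        mk("DCAT_90", mld_penalty_per_cm3 * (v_ptv - 800) + rnorm(n, 3, 4),
           10, 0.09))
}

test_that("cohort_report recovers an injected MLD penalty on large targets", {
  tab <- make_cohort_table(n = 24, seed = 7)
  rep <- cohort_report(tab)
  # arc plans were given an MLD penalty growing with PTV volume: the
  # correlation between the paired MLD difference and V_PTV must be
  # positive and strong
  cc <- rep$correlations$dMLD_vs_V_PTV
  expect_gt(cc$rho, 0.5)
  expect_lt(cc$p, 0.01)
  # injected V5 penalty shows up in the paired test direction
  expect_gt(rep$paired$V5Gy_pct$estimate, 0)
  # injected conformity advantage for the arc
  expect_gt(rep$paired$CN$estimate, 0)
})

test_that("cohort_report produces the full comparison shape", {
  tab <- make_cohort_table(n = 12, seed = 3)
  rep <- cohort_report(tab)
  expect_setequal(names(rep$paired),
                  c("CN", "HI", "DHD", "MU", "D1cc_cord_cGy",
                    "oeso_mean_cGy", "V20Gy_pct", "V5Gy_pct", "MLD_cGy"))
  expect_equal(nrow(rep$summary), 9)
  expect_true(all(c("3DCRT_mean", "DCAT_45_sd") %in% names(rep$summary)))
  expect_equal(sort(unique(rep$constraint_pass$variant)),
               sort(unique(tab$variant)))
  expect_length(rep$best_counts, 9)
  expect_equal(attr(rep$best_counts$HI, "n_patients"), 12)
  # constraint pass-percentage equals a hand count
  v20_pass <- with(tab[tab$variant == "3DCRT", ], mean(V20Gy_pct < 35))
  got <- rep$constraint_pass
  expect_equal(got$pass_pct[got$variant == "3DCRT" &
                              got$constraint == "lung V20Gy < 35%"],
               100 * v20_pass)
})

test_that("a cohort of identical paired plans is flagged degenerate", {
  tab <- make_cohort_table(n = 8, seed = 2)
  tab45 <- tab[tab$variant == "3DCRT", ]
  tab45$variant <- "DCAT_45"
  rep <- suppressWarnings(cohort_report(rbind(tab[tab$variant == "3DCRT", ],
                                              tab45)))
  for (m in names(rep$paired)) {
    expect_equal(rep$paired[[m]]$estimate, 0)
    expect_true(rep$paired[[m]]$degenerate)
  }
})
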