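# Build aligned mask + maps with prescribed LIV / OCDS_l values
quant_fixture <- function(liv, ocdsl, voxel_volume = 2e-6) {
  d <- dim(liv)
  mask <- structure(list(mask = array(TRUE, d), voxel_volume_mm3 = voxel_volume,
                         provenance = list()), class = "spheroid_mask")
  maps <- structure(list(liv = liv, ocds_l = ocdsl,
                         mean_intensity_db = array(0, d), provenance = list()),
                    class = "dynamics_maps")
  list(mask = mask, maps = maps)
}

test_that("quantification computes volume, means and strict-cutoff ratios", {
  d <- c(10, 10, 10)  # 1000 voxels
  liv <- array(rep(c(1, 5), each = 500), d)  # half below the 3 dB^2 cutoff
  ocdsl <- array(2e-4, d)                    # exactly at the cutoff
  fx <- quant_fixture(liv, ocdsl)
  q <- quantify_spheroid(fx$mask, fx$maps)
  expect_equal(q$volume_mm3, 1000 * 2e-6)
  expect_equal(q$mean_liv_db2, 3)
  expect_equal(q$mean_ocdsl_ms_inv, 2e-4)
  expect_equal(q$necrotic_ratio_liv, 0.5)
  # boundary voxels are viable: strict inequality
  expect_equal(q$necrotic_ratio_ocdsl, 0)
})

test_that("lowering a cutoff never increases the necrotic ratio", {
  set.seed(23)
  d <- c(6, 6, 6)
  fx <- quant_fixture(array(runif(216, 0, 8), d), array(runif(216, 0, 5e-4), d))
  cuts <- c(1, 2, 3, 4)
  ratios <- sapply(cuts, function(cv) {
    quantify_spheroid(fx$mask, fx$maps, liv_cutoff_db2 = cv)$necrotic_ratio_liv
  })
  expect_true(all(diff(ratios) >= 0))
  expect_true(all(ratios >= 0 & ratios <= 1))
})

test_that("quantification rejects empty or misaligned inputs", {
  fx <- quant_fixture(array(1, c(3, 3, 3)), array(1e-4, c(3, 3, 3)))
  fx$mask$mask[] <- FALSE
  expect_error(quantify_spheroid(fx$mask, fx$maps), "empty mask")
  fx2 <- quant_fixture(array(1, c(3, 3, 3)), array(1e-4, c(3, 3, 3)))
  fx2$mask$mask <- array(TRUE, c(2, 3, 3))
  expect_error(quantify_spheroid(fx2$mask, fx2$maps), "not aligned")
  fx3 <- quant_fixture(array(1, c(3, 3, 3)), array(1e-4, c(3, 3, 3)))
  expect_error(quantify_spheroid(fx3$mask, fx3$maps, liv_cutoff_db2 = -1),
               "positive")
})

test_that("exact Mann-Whitney matches enumeration landmarks", {
  expect_equal(as.numeric(compare_groups(1:5, 1:5)), 1)
  expect_equal(as.numeric(compare_groups(1:5, 6:10)), 2 / 252)
  expect_equal(as.numeric(compare_groups(1:4, 101:104)), 2 / 70)
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney agrees with wilcox.test on tie-free samples", {
  set.seed(33)
  for (i in 1:25) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)  # total n <= 12
    a <- rnorm(m); b <- rnorm(n, mean = sample(c(0, 2), 1))
    p_pkg <- as.numeric(compare_groups(a, b))
    p_ref <- suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value)
    expect_equal(p_pkg, p_ref, tolerance = 1e-12,
                 label = sprintf("case %d (m=%d, n=%d)", i, m, n))
  }
})

test_that("ties are handled by mid-ranks in the exact enumeration", {
  # hand-enumerable: a = (1, 2), b = (2, 3); mid-ranks 1, 2.5, 2.5, 4
  # U_obs = 3.5 - 3 = 0.5, |U - 2| = 1.5; assignments of 2 of 4 ranks:
  # rank sums 3.5, 3.5, 5, 3.5, 5, 6.5 -> U in {0.5, 0.5, 2, 0.5, 2, 3.5}
  # deviations {1.5, 1.5, 0, 1.5, 0, 1.5} -> 4/6 as or more extreme
  expect_equal(as.numeric(compare_groups(c(1, 2), c(2, 3))), 4 / 6)
  # symmetric call gives the same p
  expect_equal(as.numeric(compare_groups(c(2, 3), c(1, 2))), 4 / 6)
})

test_that("large groups fall back to the normal approximation", {
  set.seed(44)
  a <- rnorm(12); b <- rnorm(12, 1)
  p <- compare_groups(a, b)
  expect_identical(attr(p, "method"), "normal-approximation")
  expect_equal(as.numeric(p),
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
})

test_that("time-course table summarizes replicates and excludes outliers", {
  df <- data.frame(
    condition = rep("1uM", 6), day = c(1, 1, 1, 1, 1, 3),
    replicate = c(1:5, 1),
    mean_liv_db2 = c(1, 2, 3, 4, 5, 9)
  )
  tc <- time_course_table(df)
  s <- tc$summary[tc$summary$day == 1, ]
  expect_equal(s$mean, 3)
  expect_equal(s$sd, sd(1:5))          # 1.5811, n-1 divisor
  expect_equal(s$n, 5L)
  # single replicate: sd undefined
  expect_true(is.na(tc$summary$sd[tc$summary$day == 3]))

  # outlier exclusion: n decremented, stats recomputed on the rest
  df$outlier <- c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  tc2 <- time_course_table(df)
  s2 <- tc2$summary[tc2$summary$day == 1, ]
  expect_equal(s2$mean, mean(1:4))
  expect_equal(s2$n, 4L)
  expect_equal(s2$n_excluded, 1L)
})

test_that("time-course table computes pairwise day-to-day p-values", {
  set.seed(55)
  df <- expand.grid(condition = c("ctrl", "10uM"), day = c(1, 3, 6),
                    replicate = 1:5)
  df$necrotic_ratio_liv <- runif(nrow(df)) + df$day / 10
  tc <- time_course_table(df, metrics = "necrotic_ratio_liv")
  pw <- tc$pairwise
  expect_setequal(unique(pw$condition), c("ctrl", "10uM"))
  expect_equal(nrow(pw), 2 * 3)  # 2 conditions x choose(3, 2) day pairs
  expect_true(all(pw$p_value > 0 & pw$p_value <= 1))
  # p-values come from the same exact test
  a <- df$necrotic_ratio_liv[df$condition == "ctrl" & df$day == 1]
  b <- df$necrotic_ratio_liv[df$condition == "ctrl" & df$day == 3]
  expect_equal(pw$p_value[pw$condition == "ctrl" & pw$day_a == 1 & pw$day_b == 3],
               as.numeric(compare_groups(a, b)))
  # missing design cell is absent, not an error
  tc3 <- time_course_table(df[!(df$condition == "ctrl" & df$day == 6), ],
                           metrics = "necrotic_ratio_liv")
  expect_equal(nrow(tc3$summary), 5)
})
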