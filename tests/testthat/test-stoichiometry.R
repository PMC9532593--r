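test_that("acquisition sums map enzymes to their element cycles", {
  s <- acquisition_sums(data.frame(bg = 458.12, cbh = 159.11, nag = 114.38,
                                   lap = 24.9, ap = 200))
  expect_equal(s$c_acq, 617.23)
  expect_equal(s$n_acq, 139.28)
  expect_equal(s$p_acq, 200)

  z <- acquisition_sums(data.frame(bg = 0, cbh = 0, nag = 0, lap = 0, ap = 0))
  expect_equal(unlist(z[, c("c_acq", "n_acq", "p_acq")], use.names = FALSE),
               c(0, 0, 0))
  u <- acquisition_sums(data.frame(bg = 1, cbh = 1, nag = 1, lap = 1, ap = 1))
  expect_equal(unlist(u[, c("c_acq", "n_acq", "p_acq")], use.names = FALSE),
               c(2, 2, 1))
})

test_that("invalid enzyme profiles are rejected naming the enzyme", {
  expect_error(acquisition_sums(data.frame(bg = -1, cbh = 1, nag = 1, lap = 1, ap = 1)),
               "bg")
  expect_error(acquisition_sums(data.frame(bg = 1, cbh = 1, nag = 1, lap = 1)),
               "ap")
})

test_that("vector analysis reproduces hand-computed reference points", {
  # perfectly balanced N and P acquisition sits exactly on the 45-degree line
  b <- vector_limitation(data.frame(c_acq = 100, n_acq = 100, p_acq = 100))
  expect_equal(b$x, 0.5)
  expect_equal(b$y, 0.5)
  expect_equal(b$vector_length, sqrt(0.5))
  expect_equal(b$vector_angle_deg, 45)
  expect_equal(b$n_limitation, 45)
  expect_equal(as.character(b$limitation_class), "BALANCED")

  # values frozen from an independent brute-force trigonometry script
  v <- vector_limitation(data.frame(c_acq = 600, n_acq = 150, p_acq = 300))
  expect_equal(v$x, 2 / 3)
  expect_equal(v$y, 0.8)
  expect_equal(v$vector_length, 1.04137, tolerance = 1e-5)
  expect_equal(v$vector_angle_deg, 50.19443, tolerance = 1e-5)
  expect_equal(v$n_limitation, 39.80557, tolerance = 1e-5)
  expect_equal(as.character(v$limitation_class), "P_LIMITED")

  # with the field-survey mean C and N sums, the N-vs-P call is decided by
  # AP: P-acquisition above the N sum tips the angle past 45 (P-limited),
  # below it the site reads N-limited (oracle-computed 47.20959 / 43.86948)
  hi_ap <- vector_limitation(data.frame(c_acq = 617.23, n_acq = 139.28, p_acq = 200))
  expect_equal(hi_ap$vector_angle_deg, 47.20959, tolerance = 1e-5)
  expect_equal(as.character(hi_ap$limitation_class), "P_LIMITED")
  lo_ap <- vector_limitation(data.frame(c_acq = 617.23, n_acq = 139.28, p_acq = 110))
  expect_equal(lo_ap$vector_angle_deg, 43.86948, tolerance = 1e-5)
  expect_equal(as.character(lo_ap$limitation_class), "N_LIMITED")
})

test_that("degenerate acquisition sums are rejected", {
  expect_error(vector_limitation(data.frame(c_acq = 0, n_acq = 1, p_acq = 1)),
               "c_acq")
  expect_error(vector_limitation(data.frame(c_acq = 1, n_acq = 1, p_acq = -2)),
               "p_acq")
})

test_that("limitation indices are scale-invariant and bounded", {
  set.seed(11)
  for (rep in 1:25) {
    sums <- data.frame(c_acq = runif(1, 1, 1000), n_acq = runif(1, 1, 1000),
                       p_acq = runif(1, 1, 1000))
    base <- vector_limitation(sums)
    k <- 10^runif(1, -3, 3)
    scaled <- vector_limitation(sums * k)
    for (col in c("x", "y", "vector_length", "vector_angle_deg", "n_limitation")) {
      expect_equal(scaled[[col]], base[[col]], tolerance = 1e-12)
    }
    expect_identical(scaled$limitation_class, base$limitation_class)
    # bounds for strictly positive sums
    expect_gt(base$vector_length, 0)
    expect_lte(base$vector_length, sqrt(2))
    expect_gt(base$vector_angle_deg, 0)
    expect_lt(base$vector_angle_deg, 90)
    # complement identity to machine precision (one ulp of 90 degrees)
    expect_equal(base$n_limitation + base$vector_angle_deg, 90, tolerance = 1e-15)
  }
})

test_that("swapping the N and P axes reflects the angle about 45 degrees", {
  set.seed(12)
  for (rep in 1:25) {
    c_ <- runif(1, 1, 500); n_ <- runif(1, 1, 500); p_ <- runif(1, 1, 500)
    a <- vector_limitation(data.frame(c_acq = c_, n_acq = n_, p_acq = p_))
    b <- vector_limitation(data.frame(c_acq = c_, n_acq = p_, p_acq = n_))
    expect_equal(a$vector_angle_deg + b$vector_angle_deg, 90, tolerance = 1e-10)
  }
})

test_that("limitation indices respond monotonically to each acquisition sum", {
  set.seed(13)
  for (rep in 1:20) {
    c_ <- runif(1, 10, 500); n_ <- runif(1, 10, 500); p_ <- runif(1, 10, 500)
    base <- vector_limitation(data.frame(c_acq = c_, n_acq = n_, p_acq = p_))
    more_p <- vector_limitation(data.frame(c_acq = c_, n_acq = n_, p_acq = p_ * 1.3))
    expect_gt(more_p$vector_angle_deg, base$vector_angle_deg)
    more_n <- vector_limitation(data.frame(c_acq = c_, n_acq = n_ * 1.3, p_acq = p_))
    expect_lt(more_n$vector_angle_deg, base$vector_angle_deg)
    more_c <- vector_limitation(data.frame(c_acq = c_ * 1.3, n_acq = n_, p_acq = p_))
    expect_gt(more_c$vector_length, base$vector_length)
  }
})

test_that("water-column Redfield classification uses the molar 16:1 threshold", {
  # printed mean water TP of an oligotrophic saline lake: strongly P-limited
  hi <- water_limitation(tn = 1.0, tp = 0.04)
  expect_equal(hi$np_molar_ratio, 55.28307, tolerance = 1e-5)
  expect_equal(as.character(hi$water_limitation), "P_LIMITED")

  lo <- water_limitation(tn = 0.1, tp = 1.0)
  expect_equal(lo$np_molar_ratio, 0.2211323, tolerance = 1e-5)
  expect_equal(as.character(lo$water_limitation), "N_LIMITED")

  # the boundary ratio of exactly 16 is assigned to the N side
  tp <- 0.1
  tn_boundary <- 16 * (tp / 30.974) * 14.007
  at16 <- water_limitation(tn_boundary, tp)
  expect_equal(at16$np_molar_ratio, 16)
  expect_equal(as.character(at16$water_limitation), "N_LIMITED")

  expect_error(water_limitation(0, 1), "positive")
})

test_that("element-cycle distance matches hand geometry and the naive loop", {
  two <- data.frame(site_id = c("A", "B"),
                    bg = c(1, 4), cbh = c(2, 2), nag = c(3, 7),
                    lap = c(5, 5), ap = c(9, 9))
  d <- element_cycle_distance(two, standardize = FALSE)
  expect_equal(as.numeric(d), 5)  # 3-4-5 triangle in the bg/nag plane

  same <- random_profiles(1, seed = 3)
  dup <- rbind(same, same)
  dup$site_id <- c("A", "B")
  expect_equal(as.numeric(element_cycle_distance(dup, standardize = FALSE)), 0)

  prof <- random_profiles(4, seed = 4)
  m_raw <- as.matrix(prof[, c("bg", "cbh", "nag", "lap", "ap")])
  rownames(m_raw) <- prof$site_id
  expect_equal(as.matrix(element_cycle_distance(prof, standardize = FALSE)),
               naive_euclidean(m_raw), tolerance = 1e-12)
  expect_equal(as.matrix(element_cycle_distance(prof)),
               naive_euclidean(scale(m_raw)), tolerance = 1e-12)

  flat <- prof
  flat$ap <- 7
  expect_error(element_cycle_distance(flat), "ap")
  expect_silent(element_cycle_distance(flat, standardize = FALSE))
})

test_that("scalar difference matrices are absolute pairwise differences", {
  expect_true(all(as.matrix(scalar_difference_matrix(c(5, 5, 5))) == 0))
  expect_equal(as.numeric(scalar_difference_matrix(c(1, 4))), 3)
  d <- as.matrix(scalar_difference_matrix(c(0, 1, 3), labels = c("a", "b", "c")))
  expect_equal(d["a", "b"], 1)
  expect_equal(d["a", "c"], 3)
  expect_equal(d["b", "c"], 2)
  expect_error(scalar_difference_matrix(1), "2 sites")
})
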