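test_that("single-question 2x2 matrix: symmetric, identity and uninformative cases", {
  m <- rr_tm_single(0.8)
  expect_equal(unclass(m), matrix(c(.8, .2, .2, .8), 2,
                                  dimnames = list(c("n", "y"), c("n", "y"))),
               ignore_attr = TRUE)
  expect_equal(unclass(rr_tm_single(1)),
               diag(2), ignore_attr = TRUE)
  expect_warning(r5 <- rr_rand(0.5), "uninformative")
  expect_true(r5$uninformative)
  expect_equal(as.numeric(suppressWarnings(rr_tm_single(0.5))), rep(.5, 4))
  expect_error(rr_rand(0), "must be in")
  expect_error(rr_rand(1.2), "must be in")
})

test_that("asymmetric 2x2 form follows the general conditional-probability layout", {
  m <- rr_tm_single(0.9, p_nn = 0.7)   # p_{y|y} = .9, p_{n|n} = .7
  expect_equal(m["n", "n"], 0.7)
  expect_equal(m["y", "y"], 0.9)
  expect_equal(m["y", "n"], 0.3)
  expect_colsums_one(m)
})

test_that("Kronecker chain: entries, labels and shapes", {
  m2 <- rr_tm_single(0.8)
  m4 <- rr_kronecker(m2, m2)
  expect_identical(rownames(m4), c("nn", "ny", "yn", "yy"))
  expect_identical(colnames(m4), c("nn", "ny", "yn", "yy"))
  expect_equal(m4["nn", "nn"], 0.64)
  expect_equal(m4["yy", "nn"], 0.04)
  expect_colsums_one(m4)
  m86 <- rr_kronecker(rr_tm_ely(5/6), rr_tm_single(5/6))
  expect_equal(dim(m86), c(8L, 6L))
  expect_colsums_one(m86)
  ## identity factor leaves a variable unrandomized
  id <- diag(2); dimnames(id) <- list(c("n", "y"), c("n", "y"))
  mk <- rr_kronecker(m2, id)
  expect_colsums_one(mk)
  expect_equal(mk["ny", "ny"], 0.8)
  expect_equal(mk["ny", "nn"], 0)
  expect_error(rr_kronecker(list()), "at least one")
  expect_error(rr_kronecker(rr_tm_subsamples(.8), m2), "blocked")
})

test_that("sub-samples matrix has complementary blocks", {
  m <- rr_tm_subsamples(0.8)
  expect_identical(rownames(m), c("n|1", "y|1", "n|2", "y|2"))
  expect_equal(unname(m[1:2, ]), matrix(c(.8, .2, .2, .8), 2))
  expect_equal(unname(m[3:4, ]), matrix(c(.2, .8, .8, .2), 2))
  expect_identical(attr(m, "block"), c(1L, 1L, 2L, 2L))
  expect_colsums_one(m)
  m5 <- suppressWarnings(rr_tm_subsamples(0.5))
  expect_equal(unname(m5[1:2, ]), unname(m5[3:4, ]))  # degenerate at p = .5
})

test_that("ever/last-year 4x3 matrix matches direct substitution", {
  m <- rr_tm_ely(5/6)
  expect_equal(unname(m[, "yy"]), c(1, 5, 5, 25) / 36)
  expect_equal(unname(m[, "nn"]), c(25, 5, 5, 1) / 36)
  expect_equal(unname(m[, "yn"]), c(5, 1, 25, 5) / 36)
  expect_colsums_one(m)
  ## direct questioning: observed ny is impossible
  expect_equal(unname(rr_tm_ely(1)["ny", ]), c(0, 0, 0))
})

test_that("cheater column is the all-'no' indicator within each block", {
  mc <- rr_add_cheater(rr_tm_subsamples(0.8))
  expect_equal(unname(mc[, "c"]), c(1, 0, 1, 0))
  expect_colsums_one(mc)
  me <- rr_add_cheater(rr_tm_ely(5/6))
  expect_equal(unname(me[, "c"]), c(1, 0, 0, 0))
  expect_colsums_one(me)
})

test_that("SP(last-year) matrix reduces correctly and keeps column sums", {
  p <- 5/6
  expect_equal(unclass(rr_tm_sp_lastyear(p, 0, 0)), unclass(rr_tm_ely(p)))
  ## with no editing it is the plain SP-no mixture
  th <- 0.15
  mix <- (1 - th) * unclass(rr_tm_ely(p)) + th * c(1, 0, 0, 0) %o% rep(1, 3)
  expect_equal(unclass(rr_tm_sp_lastyear(p, th, 0)), mix)
  ## editing moves p^2 mass of the yy column from yy to yn responses
  m <- rr_tm_sp_lastyear(p, 0.1, 0.2)
  expect_colsums_one(m)
  expect_equal(m["yn", "yy"] - (1 - .1) * p * (1 - p), 0.2 * p^2)
  expect_error(rr_tm_sp_lastyear(p, 0.6, 0.5), "exceed 1")
  expect_error(rr_tm_sp_lastyear(p, -0.9, 0), "outside")
})

test_that("design-level matrix builder dispatches and keeps invariants", {
  d2 <- rr_design(rr_ely_pair(5/6), rr_ely_pair(5/6))
  expect_equal(dim(rr_design_matrix(d2)), c(16L, 9L))
  d1q <- rr_design(rr_ely_pair(5/6), rr_question(5/6))
  expect_equal(dim(rr_design_matrix(d1q, bias = "cdm")), c(8L, 7L))
  ## sp_no with theta = 0 is the null matrix
  expect_equal(unclass(rr_design_matrix(d1q, bias = "sp_no", theta = 0)),
               unclass(rr_design_matrix(d1q)))
  ## sp_last_year with one extra question: theta mass still lands on all-'no' only
  m <- rr_design_matrix(d1q, bias = "sp_last_year", theta = .1, theta_yy_yn = .2)
  expect_colsums_one(m)
  base <- unclass(rr_design_matrix(d1q))
  expect_equal(m["nnn", "nnn"], .9 * base["nnn", "nnn"] + .1)
  expect_equal(m["nny", "nnn"], .9 * base["nny", "nnn"])  # no theta off the all-no row
  expect_error(rr_design_matrix(rr_design(rr_question(.8)), bias = "sp_last_year",
                                theta = .1, theta_yy_yn = .1),
               "ever/last-year")
})

test_that("profile labels are lexicographic with the first block slowest", {
  d <- rr_design(rr_question(.8), rr_question(.8))
  expect_identical(d$profiles, c("nn", "ny", "yn", "yy"))
  d3 <- rr_design(rr_ely_pair(5/6), rr_question(5/6))
  expect_identical(d3$profiles,
                   c("nnn", "nny", "nyn", "nyy", "ynn", "yny", "yyn", "yyy"))
  expect_identical(d3$categories,
                   c("nnn", "nny", "ynn", "yny", "yyn", "yyy"))
})

test_that("column sums and entry ranges hold across random designs and parameters", {
  set.seed(42)
  for (i in 1:25) {
    p <- runif(1, 0.55, 0.99)
    d <- switch(sample(4, 1),
                rr_design(rr_ely_pair(p)),
                rr_design(rr_ely_pair(p), rr_question(runif(1, .55, .99))),
                rr_design(rr_ely_pair(p), rr_ely_pair(p)),
                rr_design(rr_question(p), subsamples = TRUE))
    th <- runif(1, 0, 0.5)
    for (bias in c("none", "cdm", "sp_no")) {
      m <- rr_design_matrix(d, bias = bias, theta = th)
      expect_colsums_one(m)
      expect_true(all(m >= 0 & m <= 1 + 1e-12))
    }
    if (length(rrbias:::ely_blocks(d)) > 0 && !d$subsamples) {
      m <- rr_design_matrix(d, bias = "sp_last_year", theta = th,
                            theta_yy_yn = runif(1, 0, 1 - th))
      expect_colsums_one(m)
      expect_true(all(m >= -1e-12 & m <= 1 + 1e-12))
    }
  }
})
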