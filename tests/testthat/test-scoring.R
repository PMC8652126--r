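test_that("correlation scores equal the brute-force Pearson oracle", {
  x <- random_standardized(5, 6, seed = 21)
  s <- score_correlation(x)
  expect_symmetric(s$scores)
  expect_lt(max(abs(s$scores - oracle_pearson(x$values))), 1e-12)
  expect_true(all(abs(upper_pairs(s$scores)) <= 1))

  # identical rows correlate at 1, a negated row at -1
  m <- x$values
  m[2, ] <- m[1, ]
  m[3, ] <- -m[1, ]
  s2 <- score_correlation(expression_matrix(m, standardized = TRUE))
  expect_equal(s2$scores[1, 2], 1, tolerance = 1e-12)
  expect_equal(s2$scores[1, 3], -1, tolerance = 1e-12)
})

test_that("correlation is invariant to positive rescaling of raw gene rows", {
  withr::with_seed(31, {
    m <- matrix(rnorm(5 * 8), 5, 8,
                dimnames = list(paste0("g", 1:5), paste0("c", 1:8)))
  })
  a <- score_correlation(standardize(expression_matrix(m)))
  b <- score_correlation(standardize(expression_matrix(m * rep(c(2, 17, 0.1, 5, 3), 8))))
  expect_equal(a$scores, b$scores, tolerance = 1e-12)
})

test_that("PCR with all components and ridge with no penalty reduce to OLS", {
  x <- random_standardized(6, 12, seed = 22)
  ols <- oracle_ols(x$values)
  pcr <- score_pcr(x, k = 5)
  ridge <- score_ridge(x, lambda = 0)
  expect_lt(max(abs(pcr$scores - ols)), 1e-8)
  expect_lt(max(abs(ridge$scores - ols)), 1e-8)
  expect_lt(max(abs(pcr$scores - ridge$scores)), 1e-8)
})

test_that("a near-duplicated gene dominates its partner's PCR row", {
  withr::with_seed(23, {
    m <- matrix(rnorm(6 * 10), 6, 10,
                dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
    m[2, ] <- m[1, ] + rnorm(10, sd = 0.01)
  })
  x <- standardize(expression_matrix(m))
  s <- score_pcr(x, k = 1)
  row1 <- abs(s$scores[1, -1])
  expect_identical(unname(which.max(row1)), 1L)  # g2 is the top partner of g1
})

test_that("ridge matches a direct penalized solve and shrinks to zero", {
  x <- random_standardized(8, 10, seed = 24)
  s <- score_ridge(x, lambda = 1)
  expect_lt(max(abs(s$scores - oracle_ridge(x$values, 1))), 1e-10)
  huge <- score_ridge(x, lambda = 1e9)
  expect_lt(max(abs(upper_pairs(huge$scores))), 1e-6)
})

test_that("PLS matches the literal-transcription oracle", {
  x <- random_standardized(6, 8, seed = 25)
  s <- score_pls(x, v = 2)
  expect_lt(max(abs(s$scores - oracle_pls(x$values, 2))), 1e-10)

  # duplicated pair attains the maximal |score| in the whole matrix
  withr::with_seed(26, {
    m <- matrix(rnorm(6 * 9), 6, 9,
                dimnames = list(paste0("g", 1:6), paste0("c", 1:9)))
    m[4, ] <- m[3, ] + rnorm(9, sd = 0.01)
  })
  xd <- standardize(expression_matrix(m))
  sd_ <- score_pls(xd, v = 2)
  off <- abs(sd_$scores); diag(off) <- 0
  top <- sort(unname(which(off == max(off), arr.ind = TRUE)[1, ]))
  expect_identical(top, c(3L, 4L))
})

test_that("mutually orthogonal genes score zero under every method", {
  x <- orthogonal_rows(5, 12)
  # PLS legitimately warns here: with no shared variance the weight norm
  # vanishes and the component loop caps below v
  pls <- suppressWarnings(score_pls(x, 2))
  for (s in list(score_correlation(x), score_pcr(x, 2), pls,
                 score_ridge(x, 1))) {
    expect_lt(max(abs(upper_pairs(s$scores))), 1e-10)
  }
})

test_that("all scorers are equivariant under gene permutation", {
  x <- random_standardized(7, 9, seed = 27)
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  xp <- expression_matrix(x$values[perm, ], standardized = TRUE)
  params <- list(correlation = list(), pcr = list(k = 3), pls = list(v = 3),
                 ridge = list(lambda = 1))
  fns <- list(correlation = score_correlation, pcr = score_pcr,
              pls = score_pls, ridge = score_ridge)
  for (m in names(fns)) {
    s <- do.call(fns[[m]], c(list(x), params[[m]]))$scores
    sp <- do.call(fns[[m]], c(list(xp), params[[m]]))$scores
    expect_equal(unname(sp), unname(s[perm, perm]), tolerance = 1e-10,
                 label = paste(m, "permuted scores"))
  }
})

test_that("symmetrize_scores averages directions and zeroes the diagonal", {
  m <- matrix(c(5, 1, 0, 5), 2, 2)       # m[1,2] = 0, m[2,1] = 1
  s <- symmetrize_scores(m)
  expect_equal(s[1, 2], 0.5)
  expect_symmetric(s)

  sym <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_equal(symmetrize_scores(sym), sym)

  anti <- matrix(c(0, -3, 3, 0), 2, 2)
  expect_true(all(symmetrize_scores(anti) == 0))

  expect_error(symmetrize_scores(matrix(1, 2, 3)), "square")
  expect_error(symmetrize_scores(matrix(c(1, NA, 1, 1), 2, 2)), "non-finite")
})

test_that("scorers demand standardized input and sane parameters", {
  m <- matrix(rnorm(20), 4, 5,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
  raw <- expression_matrix(m)
  expect_error(score_correlation(raw), "standardized")
  x <- standardize(raw)
  expect_error(score_pcr(x, k = 4), "at most p - 1")
  expect_error(score_pls(x, v = 5), "at most min")
  expect_error(score_ridge(x, lambda = -1), "non-negative")
})
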