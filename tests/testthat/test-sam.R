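sam_toy <- function() {
  m <- rbind(g1 = c(1, 2, 3, 2, 3, 4),
             g2 = c(5, 5, 5, 5, 5, 5) + c(0.1, -0.1, 0, 0.1, -0.1, 0))
  colnames(m) <- paste0("s", 1:6)
  list(matrix = m,
       labels = setNames(c(0L, 0L, 0L, 1L, 1L, 1L), colnames(m)))
}

test_that("sam_statistics matches the hand-computed formulas", {
  toy <- sam_toy()
  st <- sam_statistics(toy$matrix, toy$labels, s0 = 0)
  # group0 = {1,2,3}, group1 = {2,3,4}: r = 1, s = sqrt(4/6), d = r/s
  expect_equal(st$r[1], 1)
  expect_equal(st$s[1], sqrt(4 / 6), tolerance = 1e-12)
  expect_equal(st$d[1], 1 / sqrt(4 / 6), tolerance = 1e-12)
  # identical group means -> r = 0, d = 0
  expect_equal(st$r[2], 0)
  expect_equal(st$d[2], 0)
  # d strictly decreasing in s0 when r > 0
  d_s0 <- vapply(c(0, 0.5, 1, 2), function(s0)
    sam_statistics(toy$matrix, toy$labels, s0 = s0)$d[1], numeric(1))
  expect_true(all(diff(d_s0) < 0))
  expect_error(sam_statistics(toy$matrix, setNames(c(0L, 1L, 1L, 1L, 1L, 1L),
                                                   paste0("s", 1:6))),
               "at least 2")
})

test_that("shift and scale invariances hold exactly", {
  set.seed(9)
  m <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  lab <- setNames(rep(c(0L, 1L), each = 6), colnames(m))
  st <- sam_statistics(m, lab, s0 = 0.1)
  m_shift <- m; m_shift[7, ] <- m_shift[7, ] + 5
  st_shift <- sam_statistics(m_shift, lab, s0 = 0.1)
  expect_equal(st$r[7], st_shift$r[7], tolerance = 1e-12)
  expect_equal(st$s[7], st_shift$s[7], tolerance = 1e-12)
  expect_equal(st$d[7], st_shift$d[7], tolerance = 1e-12)
  # with s0 = 0, scaling one gene by c > 0 leaves d unchanged
  st0 <- sam_statistics(m, lab, s0 = 0)
  m_scale <- m; m_scale[3, ] <- 2.5 * m_scale[3, ]
  st_scale <- sam_statistics(m_scale, lab, s0 = 0)
  expect_equal(st_scale$d[3], st0$d[3], tolerance = 1e-12)
})

test_that("estimate_s0 honors the tie-break and improves the objective", {
  set.seed(4)
  r <- rnorm(200)
  s <- rep(0.7, 200)
  expect_equal(estimate_s0(r, s), 0)  # all candidates tie -> smallest
  expect_error(estimate_s0(r, rep(0, 200)), "zero")
  expect_error(estimate_s0(rnorm(10), runif(10)), "20 genes")
  # heteroscedastic null genes: selected s0 no worse than s0 = 0
  n <- 1000
  s_het <- sqrt(rchisq(n, 3) / 3) * runif(n, 0.2, 3)
  r_het <- rnorm(n, sd = s_het)
  s0 <- estimate_s0(r_het, s_het)
  cv_of <- function(s0v) {
    d <- r_het / (s_het + s0v)
    win <- cut(rank(s_het, ties.method = "first"), 100, labels = FALSE)
    mads <- tapply(d, win, mad)
    sd(mads) / mean(mads)
  }
  expect_lte(cv_of(s0), cv_of(0) + 1e-12)
})

test_that("permutation null is reproducible and calibrated", {
  set.seed(2)
  m <- matrix(rnorm(100 * 10), 100, 10,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:10)))
  lab <- setNames(rep(c(0L, 1L), each = 5), colnames(m))
  n1 <- sam_permutation_null(m, lab, n_perm = 50, seed = 7)
  n2 <- sam_permutation_null(m, lab, n_perm = 50, seed = 7)
  expect_identical(n1$d_bar, n2$d_bar)
  # identity-permutation hook: expected order stats = sorted observed d
  st <- sam_statistics(m, lab, s0 = 0)
  id <- sam_permutation_null(m, lab, identity_only = TRUE)
  expect_equal(id$d_bar, sort(st$d), tolerance = 1e-12)
  # pure noise: mean of expected order statistics near 0
  n3 <- sam_permutation_null(m, lab, n_perm = 100, seed = 1)
  se <- sd(colMeans(n3$d_perm)) / sqrt(ncol(n3$d_perm))
  expect_lt(abs(mean(n3$d_bar)), 3 * max(se, 0.05))
  # permuted statistics agree with direct recomputation on relabeled data
  set.seed(7)
  idx <- sample.int(10, 5)
  lab_p <- setNames(integer(10), colnames(m)); lab_p[idx] <- 1L
  expect_equal(sort(sam_statistics(m, lab_p, s0 = 0)$d), n1$d_perm[, 1],
               tolerance = 1e-12)
})

test_that("call_degs thresholds, monotonicity and empty-call path", {
  set.seed(3)
  m <- matrix(rnorm(200 * 12), 200, 12,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:12)))
  m[1:10, 7:12] <- m[1:10, 7:12] + 4
  lab <- setNames(rep(c(0L, 1L), each = 6), colnames(m))
  st <- sam_statistics(m, lab, s0 = 0.1)
  null <- sam_permutation_null(m, lab, n_perm = 50, seed = 1, s0 = 0.1)
  res1 <- sam_call_degs(st, null, delta = 0.8)
  expect_true(all(paste0("g", 1:10) %in% res1$deg_ids))
  expect_true(res1$fdr >= 0 && res1$fdr <= 1)
  # huge delta -> no calls, fdr NA, not an error
  res2 <- sam_call_degs(st, null, delta = 1e6)
  expect_length(res2$deg_ids, 0)
  expect_true(is.na(res2$fdr))
  # d identical to expectation -> no calls at delta 0.5
  st_eq <- st; st_eq$d <- null$d_bar[rank(st$d, ties.method = "first")]
  expect_length(sam_call_degs(st_eq, null, 0.5)$deg_ids, 0)
  # deg set monotone non-increasing in delta
  deltas <- c(0.2, 0.5, 1, 2)
  sets <- lapply(deltas, function(d) sam_call_degs(st, null, d)$deg_ids)
  for (k in seq_len(length(sets) - 1))
    expect_true(all(sets[[k + 1]] %in% sets[[k]]))
})
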