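test_that("label frequency and misclassification probabilities count votes", {
  rs <- rater_set(list(matrix(1, 1), matrix(1, 1), matrix(0, 1), matrix(1, 1)))
  expect_equal(as.vector(label_frequency(rs)), 0.75)

  # unanimous foreground
  rs1 <- rater_set(list(matrix(1, 1), matrix(1, 1)))
  expect_equal(as.vector(label_frequency(rs1)), 1)

  # a rater agreeing with everyone has zero misclassification probability;
  # a K = 2 disagreement gives 0.5 to both
  p <- rater_misclass_prob(rs1)
  expect_equal(as.vector(p), c(0, 0))
  rs2 <- rater_set(list(matrix(c(0, 1), 1), matrix(c(0, 0), 1)))
  p2 <- rater_misclass_prob(rs2)
  expect_equal(p2[2, ], c(0.5, 0.5))
  expect_equal(p2[1, ], c(0, 0))

  # random stacks against the direct-formula oracle
  set.seed(61)
  for (rep in 1:10) {
    rs <- rand_stack(6, c(3, 4))
    E <- sapply(rs$raters, as.integer)
    f1 <- rowSums(E) / 6
    expect_equal(as.vector(label_frequency(rs)), f1)
    p <- rater_misclass_prob(rs)
    for (k in 1:6) {
      fk <- ifelse(E[, k] == 1, f1, 1 - f1)
      expect_equal(p[, k], 1 - fk)
    }
  }
})

test_that("majority probability is the upper binomial tail with odd B", {
  expect_equal(majority_prob(0, 5), 0)
  expect_equal(majority_prob(1, 5), 1)
  for (B in c(1, 5, 99)) expect_equal(majority_prob(0.5, B), 0.5)
  expect_error(majority_prob(0.3, 4), "odd")
  expect_error(majority_prob(1.2, 5), "0, 1")

  # exhaustive enumeration over all 2^5 outcomes at B = 5
  enum_majority <- function(p) {
    tot <- 0
    for (bits in 0:31) {
      v <- as.integer(intToBits(bits))[1:5]
      if (sum(v) >= 3) tot <- tot + prod(ifelse(v == 1, p, 1 - p))
    }
    tot
  }
  for (p in c(0.1, 0.3, 0.62, 0.97)) {
    expect_equal(majority_prob(p, 5), enum_majority(p), tolerance = 1e-12)
  }

  # monotone in p, and complementary for odd B
  ps <- seq(0, 1, by = 0.05)
  vals <- majority_prob(ps, 9)
  expect_true(all(diff(vals) >= 0))
  expect_equal(majority_prob(ps, 9) + majority_prob(1 - ps, 9), rep(1, length(ps)))
})

test_that("estimated rater errors and truth size sum majority probabilities", {
  # rater identical to all others: v_k = 0
  img <- matrix(c(1, 0, 1), 1)
  rs <- rater_set(list(img, img, img))
  expect_equal(estimate_rater_error(rs), rep(0, 3))

  # single disputed element with p = 0.5: v_k = 0.5 by binomial symmetry
  rs2 <- rater_set(list(matrix(c(0, 1), 1), matrix(c(0, 0), 1)))
  expect_equal(estimate_rater_error(rs2, B = 99), c(0.5, 0.5))

  # truth size: unanimous foreground of 100 elements, empty stacks
  fg <- matrix(1, 10, 10)
  expect_equal(estimate_truth_size(rater_set(list(fg, fg))), 100)
  bg <- matrix(0, 10, 10)
  expect_equal(estimate_truth_size(rater_set(list(bg, bg))), 0)

  # brute-force summation oracle on small random stacks
  set.seed(71)
  for (rep in 1:5) {
    rs <- rand_stack(5, c(3, 3))
    p <- rater_misclass_prob(rs)
    vk_oracle <- colSums(apply(p, 2, majority_prob, B = 99))
    expect_equal(estimate_rater_error(rs, 99), vk_oracle, tolerance = 1e-10)
    f1 <- as.vector(label_frequency(rs))
    expect_equal(estimate_truth_size(rs, 99), sum(majority_prob(f1, 99)),
                 tolerance = 1e-10)
  }
})

test_that("dissimilarity factors match an end-to-end hand computation", {
  # 3 raters on 6 elements, worked through the frequency -> misclassification
  # -> majority -> moments chain with explicit loops
  e1 <- matrix(c(1, 1, 1, 0, 0, 0), 1)
  e2 <- matrix(c(1, 1, 0, 0, 0, 1), 1)
  e3 <- matrix(c(1, 0, 1, 0, 1, 1), 1)
  rs <- rater_set(list(e1, e2, e3))
  E <- cbind(as.vector(e1), as.vector(e2), as.vector(e3))
  B <- 99
  upper_tail <- function(p) {
    s <- 0
    for (i in 50:B) s <- s + choose(B, i) * p^i * (1 - p)^(B - i)
    s
  }
  vk <- numeric(3)
  for (k in 1:3) {
    for (x in 1:6) {
      f <- sum(E[x, ] == E[x, k]) / 3
      vk[k] <- vk[k] + upper_tail(1 - f)
    }
  }
  V <- 0
  for (x in 1:6) V <- V + upper_tail(sum(E[x, ]) / 3)
  fac <- dissimilarity_factors(rs, B = 99)
  expect_equal(fac$v_k, vk, tolerance = 1e-9)
  expect_equal(fac$V, V, tolerance = 1e-9)
  expect_equal(fac$d_c, sd(vk) / mean(vk), tolerance = 1e-9)
  expect_equal(fac$d_r, mean(vk) / V, tolerance = 1e-9)
  expect_false(fac$unanimous)
})

test_that("dissimilarity conventions: unanimity, rater order, tiling", {
  img <- matrix(c(1, 0, 1, 0), 2)
  fac <- dissimilarity_factors(rater_set(list(img, img, img)))
  expect_equal(c(fac$d_c, fac$d_r), c(0, 0))
  expect_true(fac$unanimous)
  expect_error(dissimilarity_factors(rater_set(list(img))), "K >= 2")

  set.seed(81)
  rs <- rand_stack(5, c(4, 4))
  fac1 <- dissimilarity_factors(rs)
  fac2 <- dissimilarity_factors(rater_set(rs$raters[c(4, 1, 5, 2, 3)]))
  expect_equal(sort(fac1$v_k), sort(fac2$v_k))
  expect_equal(fac1$d_c, fac2$d_c)
  expect_equal(fac1$d_r, fac2$d_r)

  # duplicating the scene (tiling twice) leaves both factors unchanged
  tile <- function(m) rbind(m, m)
  rs_t <- rater_set(lapply(rs$raters, function(r) tile(array(r, dim = dim(r)))))
  fac_t <- dissimilarity_factors(rs_t)
  expect_equal(fac_t$d_c, fac1$d_c, tolerance = 1e-12)
  expect_equal(fac_t$d_r, fac1$d_r, tolerance = 1e-12)

  # unanimous elements contribute 0 to v_k and 0/1 to V: the masked
  # computation agrees with the full-grid one
  dm <- compute_disputed_mask(rs)
  keep <- as.vector(dm$mask)
  p <- rater_misclass_prob(rs)
  vk_masked <- colSums(apply(p[keep, , drop = FALSE], 2, majority_prob, B = 99))
  expect_equal(estimate_rater_error(rs, 99), vk_masked, tolerance = 1e-10)
  f1 <- as.vector(label_frequency(rs))
  V_masked <- sum(majority_prob(f1[keep], 99)) + sum(f1[!keep] == 1)
  expect_equal(estimate_truth_size(rs, 99), V_masked, tolerance = 1e-10)
})
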