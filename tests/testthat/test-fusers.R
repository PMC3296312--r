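test_that("vote takes the per-element majority with foreground tie break", {
  # strict majority
  rs <- rater_set(list(matrix(1, 1), matrix(1, 1), matrix(0, 1)))
  expect_equal(as.integer(fuse_vote(rs)), 1L)
  # K = 2 tie goes to foreground by the documented global rule
  rs2 <- rater_set(list(matrix(1, 1), matrix(0, 1)))
  expect_equal(as.integer(fuse_vote(rs2)), 1L)

  # random stacks match the brute-force counting oracle
  set.seed(21)
  for (rep in 1:20) {
    rs <- rand_stack(7, c(4, 5))
    E <- sapply(rs$raters, as.integer)
    oracle <- apply(E, 1, function(v) {
      n1 <- sum(v); n0 <- 7 - n1
      if (n1 > n0) 1L else if (n0 > n1) 0L else 1L
    })
    expect_equal(as.vector(fuse_vote(rs)), oracle)
  }
})

test_that("signed distance is the exact EDT with negative interior", {
  row <- label_image(matrix(c(0, 0, 1, 0, 0), 1))
  expect_equal(as.vector(signed_distance(row)), c(2, 1, -1, 1, 2))

  # sign symmetry under label complement
  set.seed(31)
  m <- matrix(rbinom(63, 1, 0.4), 7, 9)
  m[1] <- 1L; m[2] <- 0L  # ensure non-empty, non-full
  d <- signed_distance(label_image(m))
  dc <- signed_distance(label_image(1L - m))
  expect_equal(as.vector(d), -as.vector(dc))

  # spacing metadata is ignored: distances are index-space
  d2 <- signed_distance(label_image(m, spacing = c(0.25, 3)))
  expect_equal(as.vector(d2), as.vector(d))

  # exhaustive pairwise oracle on random small images
  for (rep in 1:10) {
    m <- matrix(rbinom(30, 1, 0.5), 5, 6)
    if (sum(m) == 0 || sum(m) == 30) next
    expect_equal(as.vector(signed_distance(label_image(m))),
                 as.vector(brute_signed_distance(m)))
  }

  expect_error(signed_distance(matrix(0, 3, 3)), "non-empty")
  expect_error(signed_distance(matrix(1, 3, 3)), "non-full")
})

test_that("SBA averages signed distance maps and thresholds at zero", {
  # idempotence on identical inputs
  d <- disk_label(41, 21, 21, 8)
  expect_equal(as.vector(fuse_sba(rater_set(list(d, d, d)))), as.vector(d))

  # concentric disks: mean signed distance at radius rho is rho - mean(r),
  # so the fusion is the middle disk up to rasterization
  disks <- rater_set(lapply(c(10, 14, 18), function(r) disk_label(61, 31, 31, r)))
  fused <- fuse_sba(disks)
  r_eff <- sqrt(sum(fused) / pi)
  expect_lt(abs(r_eff - 14), 1)
  # nested convex inputs: result contains the intersection, stays in the union
  expect_true(all(fused[disks$raters[[1]] == 1L] == 1L))
  expect_true(all(fused[disks$raters[[3]] == 0L] == 0L))

  # two disjoint translated squares vs the brute-force exact-EDT oracle
  sq <- function(i0, j0) {
    m <- matrix(0L, 12, 12); m[i0:(i0 + 2), j0:(j0 + 2)] <- 1L; m
  }
  rs <- rater_set(list(sq(2, 2), sq(8, 8)))
  oracle <- (brute_signed_distance(sq(2, 2)) + brute_signed_distance(sq(8, 8))) / 2
  expect_equal(as.vector(fuse_sba(rs)), as.vector(as.integer(oracle <= 0)))

  # a boundary-free (empty) rater falls back to a constant map with warning
  rs2 <- rater_set(list(matrix(0L, 5, 5), disk_label(5, 3, 3, 1.2)))
  expect_warning(out <- fuse_sba(rs2), "empty foreground")
  expect_true(all(as.integer(out) %in% 0:1))
})

test_that("STAPLE returns unanimous input untouched and favors reliable raters", {
  img <- disk_label(15, 8, 8, 4)
  fit <- fuse_staple(rater_set(list(img, img, img)))
  expect_equal(as.vector(fit$label), as.vector(img))
  expect_equal(fit$performance$sensitivity, rep(1, 3))
  expect_equal(fit$n_iter, 0L)

  # rater 1 = truth, raters 2-3 carry heavy independent flip noise:
  # estimated performance of rater 1 must dominate
  set.seed(41)
  truth <- disk_label(40, 20, 20, 12)
  flip <- function(m, p) {
    v <- as.integer(m)
    sel <- rbinom(length(v), 1, p) == 1
    v[sel] <- 1L - v[sel]
    array(v, dim = dim(m))
  }
  rs <- rater_set(list(truth, flip(truth, 0.25), flip(truth, 0.25)))
  # parameter recovery is a property of the generative (full-grid) EM; the
  # disputed-only restriction conditions the estimates on disagreement
  fit <- fuse_staple(rs, restrict = "full")
  expect_gt(fit$performance$sensitivity[1], max(fit$performance$sensitivity[2:3]))
  expect_gt(fit$performance$specificity[1], max(fit$performance$specificity[2:3]))
  # the EM objective is monotone non-decreasing under either restriction
  expect_true(all(diff(fit$loglik) >= -1e-8))
  fit_d <- fuse_staple(rs)
  expect_true(all(diff(fit_d$loglik) >= -1e-8))
  expect_true(all(as.integer(fit_d$label) %in% 0:1))
  expect_error(fuse_staple(rater_set(list(truth))), "K >= 2")
})

test_that("fusers are invariant to rater order, and Vote/SBA to masking", {
  set.seed(51)
  rs <- rand_stack(5, c(8, 8), p = 0.45)
  perm <- rater_set(rs$raters[c(3, 5, 1, 4, 2)])
  expect_equal(as.vector(fuse_vote(rs)), as.vector(fuse_vote(perm)))
  expect_equal(as.vector(fuse_sba(rs)), as.vector(fuse_sba(perm)))
  expect_equal(as.vector(fuse_staple(rs)$label),
               as.vector(fuse_staple(perm)$label))

  # disputed-mask restriction is a no-op for Vote and SBA
  dm <- compute_disputed_mask(rs)
  v_full <- fuse_vote(rs)
  expect_equal(as.vector(assemble_fusion(dm, v_full[dm$mask])),
               as.vector(v_full))
  s_full <- fuse_sba(rs)
  expect_equal(as.vector(assemble_fusion(dm, s_full[dm$mask])),
               as.vector(s_full))
  # unanimous elements are never overturned by either fuser
  expect_true(all(v_full[!dm$mask] == dm$unanimous[!dm$mask]))
  expect_true(all(s_full[!dm$mask] == dm$unanimous[!dm$mask]))
})
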