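make_points <- function(n, f_staple, f_vote, f_sba, seed = 1) {
  set.seed(seed)
  d_c <- runif(n, 0, 1)
  d_r <- runif(n, 0, 0.5)
  data.frame(d_c = d_c, d_r = d_r,
             s_STAPLE = f_staple(d_c, d_r), s_VOTE = f_vote(d_c, d_r),
             s_SBA = f_sba(d_c, d_r), degenerate = FALSE, unanimous = FALSE)
}

test_that("scores rank fusion results 1/0 with linear interpolation", {
  tr <- label_image(matrix(0L, 10, 10))
  mk <- function(nwrong) {
    m <- matrix(0L, 10, 10); if (nwrong > 0) m[seq_len(nwrong)] <- 1L
    label_image(m)
  }
  sc <- score_test(mk(0), list(STAPLE = mk(10), VOTE = mk(20), SBA = mk(30)))
  expect_equal(unname(sc$s), c(1, 0.5, 0))
  expect_equal(unname(sc$v_m), c(10, 20, 30))
  expect_false(sc$degenerate)

  # all tied: every score 1, flagged degenerate
  sc2 <- score_test(mk(0), list(a = mk(5), b = mk(5), c = mk(5)))
  expect_equal(unname(sc2$s), c(1, 1, 1))
  expect_true(sc2$degenerate)

  # two-way worst tie: both get 0
  sc3 <- score_test(mk(0), list(a = mk(0), b = mk(7), c = mk(7)))
  expect_equal(unname(sc3$s), c(1, 0, 0))
})

test_that("meta fusion is a weighted vote with the foreground tie rule", {
  a <- label_image(matrix(c(1, 1, 0, 0), 2))
  expect_equal(as.vector(meta_fuse(list(a, a, a), c(0.2, 1, 3))), as.vector(a))
  b <- label_image(matrix(c(0, 1, 1, 0), 2))
  expect_equal(as.vector(meta_fuse(list(a, b, b), c(1, 0, 0))), as.vector(a))

  # weights (2, 1, 1): element-wise hand computation, ties to foreground
  c3 <- label_image(matrix(c(0, 0, 1, 1), 2))
  got <- meta_fuse(list(a, b, c3), c(2, 1, 1))
  # sums: x1: 2*1=2 >= 2 -> 1 ; x2: 2+1=3 -> 1 ; x3: 1+1=2 >= 2 -> 1 ; x4: 1 < 2 -> 0
  expect_equal(as.vector(got), c(1L, 1L, 1L, 0L))

  expect_warning(out <- meta_fuse(list(a, b), c(0, 0)), "zero")
  expect_equal(as.vector(out), as.vector(fuse_vote(rater_set(list(a, b)))))
  expect_error(meta_fuse(list(a), 1), "length")
})

test_that("surface fitting reproduces constants and separates clusters", {
  # constant scores fit constant surfaces
  pts <- make_points(60, function(c, r) rep(1, length(c)),
                     function(c, r) rep(0.5, length(c)),
                     function(c, r) rep(0, length(c)))
  model <- svs_train_points(pts)
  for (q in list(c(0.1, 0.1), c(0.9, 0.4), c(5, 5))) {  # inside and beyond box
    s <- svs_scores(model, q[1], q[2])
    expect_equal(unname(s), c(1, 0.5, 0), tolerance = 1e-6)
  }

  # two clusters with opposite winners: the argmax boundary separates them
  set.seed(3)
  n <- 40
  pts2 <- data.frame(
    d_c = c(runif(n, 0, 0.2), runif(n, 0.8, 1)),
    d_r = runif(2 * n, 0, 0.3),
    s_STAPLE = c(rep(0, n), rep(1, n)),
    s_VOTE = rep(0.4, 2 * n),
    s_SBA = c(rep(1, n), rep(0, n)),
    degenerate = FALSE, unanimous = FALSE)
  m2 <- svs_train_points(pts2)
  low <- svs_scores(m2, 0.1, 0.15)
  high <- svs_scores(m2, 0.9, 0.15)
  expect_equal(names(which.max(low)), "SBA")
  expect_equal(names(which.max(high)), "STAPLE")

  # all-degenerate training is rejected
  bad <- pts
  bad$degenerate <- TRUE
  expect_error(svs_train_points(bad), "degenerate")
})

test_that("serialized models round-trip with identical surface evaluations", {
  pts <- make_points(80, function(c, r) pmin(1, c + 0.1 * r),
                     function(c, r) rep(0.3, length(c)),
                     function(c, r) pmax(0, 1 - c), seed = 13)
  model <- svs_train_points(pts)
  path <- withr::local_tempfile(fileext = ".json")
  write_svs_model(model, path)
  back <- read_svs_model(path)
  expect_equal(back$methods, model$methods)
  set.seed(17)
  qc <- runif(1000, -0.2, 1.5)
  qr <- runif(1000, -0.1, 0.8)
  for (i in seq_len(1000)) {
    expect_equal(svs_scores(back, qc[i], qr[i]),
                 svs_scores(model, qc[i], qr[i]), tolerance = 1e-6)
  }
})

test_that("selection runs the top-scoring fuser and honors ties/unanimity", {
  set.seed(23)
  rs <- rand_stack(5, c(12, 12), p = 0.45)

  # model where STAPLE always wins: output must equal the STAPLE fusion
  pts <- make_points(60, function(c, r) rep(1, length(c)),
                     function(c, r) rep(0.2, length(c)),
                     function(c, r) rep(0.1, length(c)))
  model <- svs_train_points(pts)
  sel <- svs_select(rs, model)
  expect_equal(sel$report$method, "STAPLE")
  expect_equal(as.vector(sel$label), as.vector(fuse_staple(rs)$label))

  # exact tie between two surfaces exercises the meta-fusion path, and the
  # output is reproducible as the weighted vote of the three base results
  pts_tie <- make_points(60, function(c, r) rep(0.1, length(c)),
                         function(c, r) rep(0.9, length(c)),
                         function(c, r) rep(0.9, length(c)))
  m_tie <- svs_train_points(pts_tie)
  sel_tie <- svs_select(rs, m_tie)
  expect_equal(sel_tie$report$method, "META")
  base <- list(fuse_staple(rs)$label, fuse_vote(rs), fuse_sba(rs))
  expect_equal(as.vector(sel_tie$label),
               as.vector(meta_fuse(base, pmax(sel_tie$report$scores, 0))))

  # unanimity bypasses selection entirely
  img <- disk_label(9, 5, 5, 2)
  sel_u <- svs_select(rater_set(list(img, img, img)), model)
  expect_equal(sel_u$report$method, "UNANIMOUS")
  expect_equal(as.vector(sel_u$label), as.vector(img))

  # the SVS output is always one of the base results or their meta fusion
  for (rep in 1:5) {
    rs2 <- rand_stack(4, c(10, 10))
    out <- svs_select(rs2, model)
    candidates <- list(as.vector(fuse_staple(rs2)$label),
                       as.vector(fuse_vote(rs2)),
                       as.vector(fuse_sba(rs2)))
    expect_true(any(vapply(candidates, identical, logical(1),
                           y = as.vector(out$label))))
  }
})

test_that("training from whole test cases produces a usable model", {
  # small synthetic training run through the full pipeline
  spec <- small_spec_2d()
  sg <- small_sigma_2d()
  plan <- build_protocol("2d", n_grid = 4, raters_per_test = 6, seed = 12,
                         sigma_max = sg, spec = spec)
  tests <- lapply(seq_len(nrow(plan)), function(i) make_test_case(plan, i))
  # 16 tests: expect the under-populated-training warning (the LOESS span
  # widens too, which is the documented remedy)
  w <- capture_warnings(model <- svs_train(tests,
                                           provenance = list(set_id = "unit")))
  expect_true(any(grepl("fewer than 30", w)))
  expect_s3_class(model, "svs_model")
  expect_equal(nrow(model$training_points), 16L)
  s <- svs_scores(model, 0.3, 0.1)
  expect_true(all(s >= 0 & s <= 1))
})
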