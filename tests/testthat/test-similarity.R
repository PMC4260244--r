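test_that("best_window_match finds exact and near-threshold windows", {
  set.seed(101)
  a <- rand_seq(100)
  m <- best_window_match(a, a, 100, 0.70)
  expect_true(m$found)
  expect_identical(c(m$offset_a, m$offset_b), c(0L, 0L))
  expect_equal(m$identity, 1)

  # 31 mismatches in 100 -> identity 0.69, below threshold
  b31 <- mutate_at(a, sample(100, 31))
  expect_false(best_window_match(a, b31, 100, 0.70, scan_rc = FALSE)$found)
  # 30 mismatches -> exactly 0.70
  set.seed(102)
  b30 <- mutate_at(a, sample(100, 30))
  m30 <- best_window_match(a, b30, 100, 0.70, scan_rc = FALSE)
  expect_true(m30$found)
  expect_equal(m30$identity, 0.70)
})

test_that("best_window_match locates an embedded shared block", {
  set.seed(103)
  a <- rand_seq(200)
  b <- paste0(rand_seq(20), substr(a, 51, 150), rand_seq(30))
  m <- best_window_match(a, b, 100, 0.9)
  # the planted block sits on diagonal offset_a - offset_b = 30; the flank
  # may extend the perfect match by a base or two, which the smallest-offset
  # tie-break then prefers
  expect_equal(m$identity, 1)
  expect_identical(m$offset_a - m$offset_b, 30L)
  expect_lte(abs(m$offset_a - 50L), 5L)
  expect_identical(m$orientation, "forward")
  # same block presented reverse-complemented
  m2 <- best_window_match(a, revcomp_r(b), 100, 0.9)
  expect_true(m2$found)
  expect_identical(m2$orientation, "reverse-complement")
  expect_identical(m2$offset_a, m$offset_a)
})

test_that("best_window_match equals the exhaustive offset-pair scan", {
  set.seed(104)
  for (i in 1:8) {
    La <- sample(60:300, 1); Lb <- sample(60:300, 1)
    w <- sample(c(20L, 40L), 1)
    a <- rand_seq(La)
    # plant a corrupted copy of a block of a into b half the time
    b <- if (i %% 2 == 0) rand_seq(Lb) else {
      blk <- substr(a, 11, 10 + w)
      paste0(rand_seq(15), mutate_at(blk, sample(w, 2)), rand_seq(20))
    }
    got <- best_window_match(a, b, w, 0.75)
    want <- o_window_match(a, b, w, 0.75)
    if (is.null(want)) {
      expect_false(got$found)
    } else {
      expect_true(got$found)
      expect_equal(got$identity, want$identity, tolerance = 1e-12)
    }
  }
})

test_that("N bases never count as matches", {
  a <- strrep("N", 100)
  expect_false(best_window_match(a, a, 100, 0.1)$found)
  b <- paste0(strrep("A", 50), strrep("N", 50))
  m <- best_window_match(strrep("A", 100), b, 100, 0.5)
  expect_equal(m$identity, 0.5)
})

test_that("global_identity matches its frozen examples and the oracle", {
  set.seed(105)
  s <- rand_seq(400)
  expect_equal(global_identity(s, s), 1)
  expect_equal(global_identity("AAAA", "AAAT"), 0.75)
  big <- rand_seq(1000)
  big10 <- mutate_at(big, sample(1000, 10))
  expect_equal(global_identity(big, big10), 0.99)
  # symmetry
  expect_equal(global_identity(big, big10), global_identity(big10, big))
  # independent quadratic-alignment oracle on substitution-only cases:
  # no gaps are ever optimal, so identity is the hamming match fraction
  for (k in c(1, 25, 80)) {
    x <- mutate_at(s, sample(400, k))
    expect_equal(global_identity(s, x), o_matches(s, x) / 400)
  }
  # a clean truncation is not penalised (semi-global reading)
  expect_equal(global_identity(substr(s, 1, 300), s), 1)
})

test_that("global_identity agrees with a reference aligner on gapped cases", {
  set.seed(106)
  a <- rand_seq(300)
  # delete an internal block of 5 bases
  b <- paste0(substr(a, 1, 150), substr(a, 156, 300))
  al <- Biostrings::pairwiseAlignment(
    a, b, type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 0, gapExtension = 2)
  ref_id <- Biostrings::nmatch(al) / Biostrings::nchar(al)
  expect_equal(global_identity(a, b), ref_id, tolerance = 1e-9)
})
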