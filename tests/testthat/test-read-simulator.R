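test_that("allocate_reads is length-proportional with an exact total", {
  expect_identical(allocate_reads(c(1000, 2000), 300), c(100L, 200L))
  expect_identical(allocate_reads(500, 77), 77L)
  expect_identical(allocate_reads(rep(800, 4), 100), rep(25L, 4))
  set.seed(801)
  for (i in 1:10) {
    lens <- sample(300:3000, sample(2:20, 1))
    n <- sample(50:5000, 1)
    a <- allocate_reads(lens, n)
    expect_identical(sum(a), as.integer(n))
    expect_true(all(abs(a - n * lens / sum(lens)) <= 1))
  }
})

test_that("error-free simulation copies reads verbatim with true records", {
  set.seed(802)
  refs <- data.frame(id = c("t1", "t2"), seq = c(rand_seq(700), rand_seq(900)),
                     stringsAsFactors = FALSE)
  sim <- simulate_reads(refs, 200, read_len = 250, seed = 803)
  expect_identical(nrow(sim$reads), 400L) # 200 pairs
  expect_identical(sum(sim$reads$mate == "forward"), 200L)
  tr <- sim$truth
  expect_identical(nrow(tr), 400L)
  for (i in seq_len(nrow(tr))) {
    src <- refs$seq[match(tr$source[i], refs$id)]
    copied <- substr(src, tr$start[i] + 1, tr$start[i] + 250)
    if (tr$orientation[i] == "reverse-complement") copied <- revcomp_r(copied)
    expect_identical(sim$reads$seq[match(tr$read_id[i], sim$reads$id)], copied)
  }
})

test_that("mates fall inside the pair window anchored on the forward read", {
  set.seed(804)
  refs <- data.frame(id = "t1", seq = rand_seq(1200), stringsAsFactors = FALSE)
  sim <- simulate_reads(refs, 300, read_len = 250, pair_window = 500,
                        seed = 805)
  tr <- sim$truth
  fwd <- tr[tr$orientation == "forward", ]
  rev <- tr[tr$orientation == "reverse-complement", ]
  rev <- rev[match(sub("/1", "/2", fwd$read_id), rev$read_id), ]
  fwd_end <- fwd$start + 250
  expect_true(all(rev$start >= pmax(0, fwd_end - 500)))
  expect_true(all(rev$start + 250 <= pmin(nchar(refs$seq), fwd_end) + 500))
  expect_true(all(rev$start + 250 <= nchar(refs$seq)))
  # mate interval inside the 500-base window when not clipped by the start
  interior <- fwd_end >= 500
  expect_true(all(rev$start[interior] + 250 <= fwd_end[interior]))
})

test_that("substitution errors match the truth records exactly", {
  set.seed(806)
  refs <- data.frame(id = "t1", seq = rand_seq(800), stringsAsFactors = FALSE)
  sim <- simulate_reads(refs, 150, read_len = 250, error_rate = 0.02,
                        seed = 807)
  tr <- sim$truth
  ham <- integer(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    copied <- substr(refs$seq, tr$start[i] + 1, tr$start[i] + 250)
    if (tr$orientation[i] == "reverse-complement") copied <- revcomp_r(copied)
    rd <- sim$reads$seq[match(tr$read_id[i], sim$reads$id)]
    ham[i] <- 250L - o_matches(copied, rd)
  }
  expect_identical(ham, tr$n_errors)
  expect_gt(mean(tr$n_errors), 0)
})

test_that("references shorter than the read length are rejected", {
  set.seed(808)
  refs <- data.frame(id = c("ok", "short"),
                     seq = c(rand_seq(400), rand_seq(100)),
                     stringsAsFactors = FALSE)
  expect_warning(sim <- simulate_reads(refs, 50, read_len = 250, seed = 809),
                 "rejecting")
  expect_true(all(sim$truth$source == "ok"))
})

test_that("isoform families have the constructed divergence structure", {
  set.seed(810)
  fam0 <- make_isoform_families(1, 3, 500, divergence = 0, seed = 811)
  expect_identical(unique(fam0$seq), fam0$seq[1])

  fam <- make_isoform_families(1, 2, 1000, divergence = 0.04, seed = 812)
  d <- 1 - o_matches(fam$seq[1], fam$seq[2]) / 1000
  # two independent 4% substitution sets overlap by chance: expected
  # pairwise divergence ~2*0.04 - small correction; allow sampling slack
  expect_gt(d, 0.055)
  expect_lt(d, 0.085)

  far <- make_isoform_families(3, 1, 1500, divergence = 0, seed = 813)
  ids <- combn(3, 2, function(ix)
    o_matches(far$seq[ix[1]], far$seq[ix[2]]) / 1500)
  expect_true(all(ids > 0.15 & ids < 0.35)) # unrelated ~25%
})
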