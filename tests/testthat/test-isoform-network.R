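test_that("define_windows tiles the span per the trailing-remainder rule", {
  w <- define_windows(c(0L, 175L), 150L) # width 50, remainder 25 >= w/2
  expect_identical(w$start, c(0L, 50L, 100L, 150L))
  expect_identical(w$end, c(50L, 100L, 150L, 175L))

  w2 <- define_windows(c(0L, 170L), 150L) # remainder 20 < 25: widen last
  expect_identical(w2$start, c(0L, 50L, 100L))
  expect_identical(w2$end, c(50L, 100L, 170L))

  expect_identical(nrow(define_windows(c(0L, 49L), 150L)), 0L)
  # windows follow the span start, including negative overhang coordinates
  w3 <- define_windows(c(-30L, 120L), 150L)
  expect_identical(w3$start[1], -30L)
  expect_identical(sum(w3$end - w3$start), 150L)
})

test_that("collect_fragments keeps only reads fully spanning a window", {
  set.seed(501)
  g <- rand_seq(200)
  scaffold <- structure(list(
    guide_id = 1L, guide_seq = g,
    placements = data.frame(
      read_id = c("a", "b"), offset = c(0L, 25L),
      orientation = "forward", votes = 1L,
      oseq = c(substr(g, 1, 150), substr(g, 26, 175)),
      len = 150L, stringsAsFactors = FALSE),
    span = c(0L, 200L)), class = "scaffold_alignment")
  wins <- define_windows(c(0L, 200L), 150L)
  fr <- collect_fragments(scaffold, wins)
  expect_setequal(fr[[1]]$read_id, "a")         # [0,50): only read a
  expect_setequal(fr[[2]]$read_id, c("a", "b")) # [50,100)
  expect_setequal(fr[[3]]$read_id, c("a", "b")) # [100,150)
  expect_identical(nrow(fr[[4]]), 0L)           # [150,200): nobody spans
  expect_identical(fr[[2]]$frag[fr[[2]]$read_id == "b"], substr(g, 51, 100))
  expect_true(all(nchar(fr[[2]]$frag) == 50L))
})

test_that("cluster_fragments separates isoforms at the identity threshold", {
  set.seed(502)
  base <- rand_seq(50)
  ident <- data.frame(read_id = paste0("r", 1:20), frag = rep(base, 20))
  cl <- cluster_fragments(ident, 0.96)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$consensus, base)

  far <- mutate_at(base, sample(50, 5)) # identity 0.90 < 0.96
  fr2 <- data.frame(read_id = paste0("r", 1:20),
                    frag = rep(c(base, far), each = 10))
  cl2 <- cluster_fragments(fr2, 0.96)
  expect_length(cl2, 2L)
  expect_identical(max(o_hamming_components(fr2$frag, 0.96)), 2L)

  near <- mutate_at(base, sample(50, 2)) # identity 0.96: linked
  fr3 <- data.frame(read_id = paste0("r", 1:10),
                    frag = rep(c(base, near), each = 5))
  expect_length(cluster_fragments(fr3, 0.96), 1L)
})

test_that("clustering equals brute-force hamming components", {
  set.seed(503)
  for (i in 1:5) {
    anc <- rand_seq(50)
    frags <- vapply(1:40, function(j)
      mutate_at(anc, sample(50, sample(0:4, 1))), "")
    df <- data.frame(read_id = paste0("r", 1:40), frag = frags)
    got <- cluster_fragments(df, 0.96)
    want <- o_hamming_components(frags, 0.96)
    expect_identical(length(got), max(want))
    # conservation: every fragment lands in exactly one node
    expect_identical(sort(unname(unlist(lapply(got, `[[`, "members")))),
                     sort(df$read_id))
  }
})

test_that("consensus is the columnwise majority with lexicographic ties", {
  cl <- cluster_fragments(data.frame(
    read_id = c("a", "b", "c"),
    frag = c("AACGT", "AACGT", "TACGA")), min_isoform_sim = 0.5)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$consensus, "AACGT")
  tie <- cluster_fragments(data.frame(read_id = c("a", "b"),
                                      frag = c("AT", "AG")), 0.5)
  expect_length(tie, 1L)
  expect_identical(tie[[1]]$consensus, "AG") # G < T lexicographically
})

test_that("build_network forms a chain on a clean single-isoform scaffold", {
  set.seed(504)
  tx <- rand_seq(500)
  # duplicate tiling so even the terminal windows are spanned by two reads
  # (edges need two physically shared reads)
  rd <- rbind(tile_reads(tx, 200, 25, "a"), tile_reads(tx, 200, 25, "b"))
  sc <- build_scaffolds(rd, tx)
  nw <- build_network(sc$scaffolds[[1]])
  n_win <- nrow(nw$windows)
  expect_identical(lengths(nw$by_window), rep(1L, n_win))
  expect_identical(nrow(nw$edges), n_win - 1L)
  expect_identical(paste(vapply(nw$nodes, `[[`, "", "consensus"),
                         collapse = ""), tx)
})

test_that("edges require two shared reads in adjacent windows only", {
  nw <- hand_network(list(
    list(window = 1, members = c("x", "y", "z")),
    list(window = 2, members = c("x", "q")),   # shares 1 read with node 1
    list(window = 3, members = c("x", "y"))))  # adjacent only to window 2
  expect_identical(nrow(nw$edges), 0L)
  nw2 <- hand_network(list(
    list(window = 1, members = c("x", "y", "z")),
    list(window = 2, members = c("x", "y"))))
  expect_identical(nrow(nw2$edges), 1L)
  expect_identical(nw2$edges$shared, 2L)
})
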