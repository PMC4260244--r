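test_that("a chain network yields exactly one full-length path", {
  rr <- paste0("r", 1:6) # reads spanning all windows
  nw <- hand_network(list(
    list(window = 1, members = rr), list(window = 2, members = rr),
    list(window = 3, members = rr), list(window = 4, members = rr)))
  paths <- traverse_network(nw)
  expect_length(paths, 1L)
  expect_identical(paths[[1]]$nodes, 1:4)
  expect_setequal(paths[[1]]$support, rr)
})

test_that("the triplet rule blocks chimeric continuations at merged nodes", {
  # isoforms A and B differ in windows 1 and 3 but share window 2; reads
  # span windows 1-2-3 only within their own isoform
  a <- paste0("a", 1:4); b <- paste0("b", 1:4)
  nw <- hand_network(list(
    list(window = 1, members = a),        # node 1: A1
    list(window = 1, members = b),        # node 2: B1
    list(window = 2, members = c(a, b)),  # node 3: merged AB2
    list(window = 3, members = a),        # node 4: A3
    list(window = 3, members = b)))       # node 5: B3
  paths <- traverse_network(nw)
  expect_length(paths, 2L) # A1-AB2-A3 and B1-AB2-B3, not 4
  got <- lapply(paths, `[[`, "nodes")
  expect_true(list(c(1L, 3L, 4L)) %in% got)
  expect_true(list(c(2L, 3L, 5L)) %in% got)
})

test_that("paths start at window-0 nodes and at interior in-degree-0 nodes", {
  rr <- paste0("r", 1:4); ss <- paste0("s", 1:4)
  nw <- hand_network(list(
    list(window = 1, members = rr),
    list(window = 2, members = rr),
    list(window = 2, members = ss),   # isoform appearing mid-scaffold
    list(window = 3, members = c(rr, ss))))
  paths <- traverse_network(nw)
  nodesets <- lapply(paths, `[[`, "nodes")
  expect_true(list(c(3L, 4L)) %in% nodesets)

  # an isolated node can only seed a single-node path
  nw2 <- hand_network(list(list(window = 1, members = "x")))
  p2 <- traverse_network(nw2)
  expect_length(p2, 1L)
  expect_length(p2[[1]]$nodes, 1L)
})

test_that("pair confirmation keeps at exactly 30% and discards below", {
  set.seed(601)
  g <- rand_seq(200)
  n <- 10L
  fwd_ids <- paste0("f", 1:n)
  rev_ids <- paste0("m", 1:n)
  reads <- data.frame(
    id = c(fwd_ids, rev_ids), frag = rep(paste0("p", 1:n), 2),
    seq = substr(g, 1, 100),
    qual = NA_character_,
    mate = rep(c("forward", "reverse"), each = n),
    stringsAsFactors = FALSE)
  mk_scaffold <- function(k_mates_on) {
    ids <- c(fwd_ids, rev_ids[seq_len(k_mates_on)])
    structure(list(
      guide_id = 1L, guide_seq = g,
      placements = data.frame(
        read_id = ids, offset = 0L, orientation = "forward",
        votes = 1L, oseq = substr(g, 1, 100), len = 100L,
        stringsAsFactors = FALSE),
      span = c(0L, 150L)), class = "scaffold_alignment")
  }
  nw <- hand_network(list(list(window = 1, members = fwd_ids),
                          list(window = 2, members = fwd_ids),
                          list(window = 3, members = fwd_ids)))
  path <- list(nodes = 1:3, support = fwd_ids)
  expect_true(confirm_with_pairs(path, nw, mk_scaffold(10L), reads))
  expect_true(confirm_with_pairs(path, nw, mk_scaffold(3L), reads))  # 0.30
  expect_false(confirm_with_pairs(path, nw, mk_scaffold(2L), reads)) # 0.20
  expect_false(confirm_with_pairs(path, nw, mk_scaffold(0L), reads))
})

test_that("emit_transcripts enforces length, concatenation and dedup", {
  set.seed(602)
  cons <- vapply(1:5, function(i) rand_seq(50), "")
  mk_nw <- function(k) hand_network(lapply(seq_len(k), function(w)
    list(window = w, members = paste0("r", 1:3), consensus = cons[w])))
  nw5 <- mk_nw(5); nw4 <- mk_nw(4)
  p5 <- list(nodes = 1:5, support = paste0("r", 1:3))
  p4 <- list(nodes = 1:4, support = paste0("r", 1:3))
  tr <- emit_transcripts(list(p5, p4), list(nw5, nw4))
  expect_identical(nrow(tr), 1L) # 250 kept at the boundary, 200 dropped
  expect_identical(tr$seq, paste(cons, collapse = ""))
  expect_identical(tr$length, 250L)
  # identical sequences collapse to one
  tr2 <- emit_transcripts(list(p5, p5), list(nw5, nw5))
  expect_identical(nrow(tr2), 1L)
})
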