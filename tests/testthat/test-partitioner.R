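# union-find closure over all pairwise window matches: the partition
# structure the expansion search must reproduce when sampling is exhaustive
o_closure <- function(seqs, window, min_identity) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j &&
        !is.null(o_window_match(seqs[i], seqs[j], window, min_identity)))
      parent[find(j)] <- find(i)
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

test_that("empty input yields zero partitions", {
  expect_identical(partition_reads(reads_df(character())), list())
})

test_that("tiled reads from one transcript form a single partition", {
  set.seed(201)
  tx <- rand_seq(1000)
  rd <- tile_reads(tx, 250, 85)
  p <- assembly_params()
  set.seed(202)
  parts <- partition_reads(rd, p)
  expect_length(parts, 1L)
  expect_setequal(parts[[1]]$member_read_ids, rd$id)
  # equals the transitive closure when sampling is exhaustive (<= 12 adds)
  expect_identical(max(o_closure(rd$seq, 100, 0.70)), 1L)
})

test_that("reads from unrelated transcripts split into their components", {
  set.seed(203)
  tx1 <- rand_seq(1000); tx2 <- rand_seq(1000)
  rd <- rbind(tile_reads(tx1, 250, 85, "a"), tile_reads(tx2, 250, 85, "b"))
  closure <- o_closure(rd$seq, 100, 0.70)
  expect_identical(max(closure), 2L) # oracle: no cross-group match
  set.seed(204)
  parts <- partition_reads(rd, assembly_params())
  expect_length(parts, 2L)
  srcs <- lapply(parts, function(p) unique(substr(p$member_read_ids, 1, 1)))
  expect_true(all(lengths(srcs) == 1L))
})

test_that("partitions are disjoint, total, and never merge components", {
  set.seed(205)
  txs <- replicate(3, rand_seq(700))
  rd <- do.call(rbind, lapply(seq_along(txs), function(i)
    tile_reads(txs[i], 200, 150, letters[i])))
  set.seed(206)
  parts <- partition_reads(rd, assembly_params())
  members <- unlist(lapply(parts, `[[`, "member_read_ids"))
  expect_identical(sort(members), sort(rd$id)) # totality
  expect_identical(anyDuplicated(members), 0L) # disjointness
  expect_gte(length(parts), max(o_closure(rd$seq, 100, 0.70)))
})

test_that("reverse mates do not seed partitions but travel with partners", {
  set.seed(207)
  tx <- rand_seq(600)
  fwd <- tile_reads(tx, 250, 100, "p")
  fwd$mate <- "forward"
  rev <- fwd
  rev$id <- sub("p", "q", rev$id)
  rev$mate <- "reverse"
  rev$frag <- fwd$frag # same fragments
  rd <- rbind(fwd, rev)
  set.seed(208)
  parts <- partition_reads(rd, assembly_params())
  expect_false(any(grepl("^q", unlist(lapply(parts, `[[`,
                                             "member_read_ids")))))
  pool <- partition_pool(parts[[1]], rd)
  expect_setequal(pool$id, rd$id) # mates re-enter for guide building
})

test_that("select_assemblable keeps partitions of 3+ and defers the rest", {
  mk <- function(sizes) lapply(seq_along(sizes), function(i)
    list(id = i, seed_read_id = "s",
         member_read_ids = paste0("p", i, "_", seq_len(sizes[i]))))
  sel <- select_assemblable(mk(c(5, 2, 1)), assembly_params())
  expect_length(sel$kept, 1L)
  expect_length(sel$deferred, 3L)
  sel2 <- select_assemblable(mk(3), assembly_params())
  expect_length(sel2$kept, 1L)
  expect_length(sel2$deferred, 0L)
  sel3 <- select_assemblable(list(), assembly_params())
  expect_identical(sel3$kept, list())
  expect_identical(sel3$deferred, character())
})
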