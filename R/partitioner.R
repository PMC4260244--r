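# Stage (i): iterative seed-expansion partitioning of forward reads into
# protein-family-level groups.

#' Partition reads by windowed seed expansion
#'
#' A partition is seeded from a randomly selected unallocated forward read.
#' Every unallocated read sharing a region of similarity with the seed
#' (70% identity across a 100-base window by default, either orientation)
#' joins the partition. Each subsequent cycle draws up to
#' `expansion_sample` probe reads at random from the reads added in the
#' previous cycle and admits any unallocated read matching any probe; the
#' partition closes when a cycle adds nothing, and a new seed is drawn.
#' Partitioning finishes when no unallocated reads remain, so every forward
#' read belongs to exactly one partition.
#'
#' Only forward (or unpaired) reads seed, probe and join partitions;
#' reverse mates travel with their partner and become available to guide
#' building via [partition_pool()].
#'
#' @param reads Read data.frame from [load_reads()] (or any data.frame with
#'   `id`, `seq`, `mate` columns). Rows with `mate == "reverse"` are
#'   ignored here.
#' @param params [assembly_params()].
#' @return A list of partitions, each a list with `id`, `seed_read_id` and
#'   `member_read_ids`. Partitions are disjoint and cover all forward
#'   reads.
#' @export
partition_reads <- function(reads, params = assembly_params()) {
  fwd <- reads[reads$mate != "reverse", , drop = FALSE]
  if (nrow(fwd) == 0) return(list())
  seqs <- fwd$seq
  ids <- fwd$id
  unalloc <- seq_along(ids)
  partitions <- list()
  pid <- 0L
  while (length(unalloc) > 0) {
    pid <- pid + 1L
    seed <- unalloc[sample.int(length(unalloc), 1L)]
    unalloc <- setdiff(unalloc, seed)
    members <- seed
    last_added <- seed
    while (length(last_added) > 0 && length(unalloc) > 0) {
      k <- min(params$expansion_sample, length(last_added))
      probes <- last_added[sample.int(length(last_added), k)]
      hit <- cpp_any_window_match(seqs[unalloc], seqs[probes],
                                  params$partition_window,
                                  params$partition_identity, TRUE)
      added <- unalloc[hit]
      unalloc <- unalloc[!hit]
      members <- c(members, added)
      last_added <- added
    }
    partitions[[pid]] <- list(id = pid, seed_read_id = ids[seed],
                              member_read_ids = ids[members])
  }
  partitions
}

#' Split partitions into assemblable and deferred
#'
#' Partitions with at least `min_partition_size` members progress to guide
#' building; reads in smaller partitions are deferred -- they skip the de
#' novo stage but re-enter at mapping along with everything else, so no
#' read is permanently discarded.
#'
#' @param partitions Output of [partition_reads()].
#' @param params [assembly_params()].
#' @return A list with `kept` (list of partitions) and `deferred`
#'   (character vector of read ids).
#' @export
select_assemblable <- function(partitions, params = assembly_params()) {
  sizes <- vapply(partitions, function(p) length(p$member_read_ids), 0L)
  keep <- sizes >= params$min_partition_size
  list(kept = partitions[keep],
       deferred = unlist(lapply(partitions[!keep],
                                function(p) p$member_read_ids),
                         use.names = FALSE) %||% character())
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reads available to guide building for one partition
#'
#' Returns the partition's forward members plus the reverse mates that
#' travel with them (matched through the fragment id).
#'
#' @param partition One element of [partition_reads()] output.
#' @param reads The full read data.frame.
#' @return A data.frame subset of `reads`.
#' @export
partition_pool <- function(partition, reads) {
  sel <- reads$id %in% partition$member_read_ids
  frags <- reads$frag[sel]
  mates <- reads$mate == "reverse" & reads$frag %in% frags
  reads[sel | mates, , drop = FALSE]
}

#' Dump a read-to-partition assignment table
#'
#' @param partitions Output of [partition_reads()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_partition_table <- function(partitions, path) {
  df <- do.call(rbind, lapply(partitions, function(p)
    data.frame(read_id = p$member_read_ids, partition_id = p$id,
               stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(read_id = character(), partition_id = integer())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
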