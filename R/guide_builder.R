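# Stage (ii): greedy overlap assembly of guide sequences per partition,
# plus a final join pass over all guides.  Guides are approximate
# templates only -- per-site diversity is recovered later by mapping and
# networking.

#' Attempt to extend a growing guide sequence with one read
#'
#' If the read anchors to the guide (best window match at
#' `guide_identity` across `guide_window` bases, either orientation), it
#' is laid onto the guide at the anchored offset; bases overhanging either
#' end extend the guide, guide bases winning inside the overlap. A read
#' that anchors without overhang leaves the guide unchanged (`contained`).
#'
#' @param ggs Growing guide sequence (nucleotide string).
#' @param read_seq Read sequence (length at least `guide_window`).
#' @param params [assembly_params()].
#' @return List with `ggs` (possibly extended), `extended` and `contained`
#'   logicals.
#' @export
try_extend <- function(ggs, read_seq, params = assembly_params()) {
  res <- cpp_extend_guide(ggs, read_seq, params$guide_window,
                          params$guide_identity)
  list(ggs = res$ggs, extended = res$used[1], contained = res$satisfied[1])
}

.grow_guides <- function(seqs, params) {
  pool <- seq_along(seqs)
  guides <- character()
  consumed <- list()
  while (length(pool) > 0) {
    seed <- pool[sample.int(length(pool), 1L)]
    pool <- setdiff(pool, seed)
    res <- cpp_extend_guide(seqs[seed], seqs[pool], params$guide_window,
                            params$guide_identity)
    used <- pool[res$used]
    pool <- pool[!res$used]
    guides <- c(guides, res$ggs)
    consumed <- c(consumed, list(c(seed, used)))
  }
  list(guides = guides, consumed = consumed)
}

#' Build guide sequences from one partition
#'
#' Repeatedly seeds a growing guide sequence from a randomly selected
#' remaining read and extends it to exhaustion with [try_extend()]
#' semantics; extending reads are removed from the pool, contained reads
#' are not (they may seed later guides), so a single partition can yield
#' several guides. Finished guides shorter than `guide_window` are dropped
#' (their reads re-enter at mapping).
#'
#' @param pool_reads Data.frame of the partition's reads (see
#'   [partition_pool()]); only the `seq` column is used.
#' @param params [assembly_params()].
#' @return Character vector of guide sequences.
#' @export
build_guides <- function(pool_reads, params = assembly_params()) {
  seqs <- if (is.data.frame(pool_reads)) pool_reads$seq else pool_reads
  if (length(seqs) == 0) return(character())
  g <- .grow_guides(seqs, params)$guides
  # contained reads stay in the pool and may seed byte-identical guides;
  # exact duplicates are redundant templates and collapse here
  unique(g[nchar(g) >= params$guide_window])
}

#' Final join pass over all guides
#'
#' The same greedy extension applied with guides as both pool and seeds:
#' guides sharing a qualifying window (98% across 100 bases by default)
#' and an overhang are joined; a guide contained in another is kept as its
#' own output (absorbing it could silently delete a full-length isoform
#' that shares a single conserved window with a sibling). Iterates to a
#' fixed point, so the guide count never increases.
#'
#' @param guides Character vector of guide sequences.
#' @param params [assembly_params()].
#' @return Character vector of merged guide sequences.
#' @export
merge_guides <- function(guides, params = assembly_params()) {
  if (length(guides) <= 1) return(guides)
  repeat {
    n0 <- length(guides)
    guides <- unique(.grow_guides(guides, params)$guides)
    if (length(guides) >= n0) break
  }
  guides
}
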