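# Stage (v): traverse isoform networks under the triplet physical-linkage
# rule, confirm paths with mate pairs, emit consensus transcripts.

#' Traverse an isoform network into candidate transcript paths
#'
#' Paths are initiated at every node of the first window and additionally
#' at any later node with no incoming edge (isoforms need not have
#' coverage from window 0). The second node of a path must be
#' edge-connected to the first (edges already require
#' `edge_min_shared_reads` physically shared reads); every later node is
#' added only if at least one read is present in the candidate and in both
#' previously added nodes -- a single physical read spanning three
#' consecutive windows. Branching duplicates the path prefix; a path ends
#' when no candidate qualifies. Extension is breadth-first with a live
#' path cap against degenerate networks.
#'
#' @param network An `isoform_network` from [build_network()].
#' @param params [assembly_params()].
#' @return List of paths; each path is a list with `nodes` (integer node
#'   ids in window order) and `support` (union of member read ids).
#' @export
traverse_network <- function(network, params = assembly_params()) {
  nodes <- network$nodes
  if (length(nodes) == 0) return(list())
  succ <- split(network$edges$to, factor(network$edges$from,
                                         levels = seq_along(nodes)))
  indeg <- tabulate(network$edges$to, nbins = length(nodes))
  starts <- unique(c(network$by_window[[1]],
                     which(indeg == 0L)))
  starts <- sort(starts)
  frontier <- lapply(starts, function(s) s)
  done <- list()
  truncated <- FALSE
  while (length(frontier) > 0) {
    if (length(frontier) > params$max_live_paths) {
      truncated <- TRUE
      frontier <- frontier[seq_len(params$max_live_paths)]
    }
    nxt <- list()
    for (path in frontier) {
      last <- path[length(path)]
      cands <- succ[[last]]
      if (length(path) >= 2) {
        prev2 <- nodes[[path[length(path) - 1L]]]$members
        prev1 <- nodes[[last]]$members
        linked <- intersect(prev2, prev1)
        cands <- cands[vapply(cands, function(cd)
          length(intersect(linked, nodes[[cd]]$members)) >= 1L, logical(1))]
      }
      if (length(cands) == 0) {
        done[[length(done) + 1L]] <- path
      } else {
        for (cd in cands) nxt[[length(nxt) + 1L]] <- c(path, cd)
      }
    }
    frontier <- nxt
  }
  if (truncated)
    warning("traversal truncated at ", params$max_live_paths,
            " live paths on guide ", network$guide_id)
  lapply(done, function(p)
    list(nodes = p,
         support = unique(unlist(lapply(nodes[p], `[[`, "members")))))
}

#' Confirm a path with mate pairs
#'
#' For each supporting read of the path that has a mate, the mate counts
#' as mapped when it is placed on the same scaffold with an interval
#' overlapping the path's window span (either orientation). The path is
#' kept iff the mapped fraction is at least `pair_confirm_fraction`
#' (exactly 30% keeps; below discards). Supporting reads without mates are
#' ignored; a path with no paired supporting reads is kept vacuously.
#'
#' @param path One path from [traverse_network()].
#' @param network The `isoform_network` the path came from.
#' @param scaffold The corresponding `scaffold_alignment`.
#' @param reads Full read data.frame (for mate lookup via `frag`/`mate`).
#' @param params [assembly_params()].
#' @return Logical: keep the path?
#' @export
confirm_with_pairs <- function(path, network, scaffold, reads,
                               params = assembly_params()) {
  paired <- reads[reads$mate %in% c("forward", "reverse"), , drop = FALSE]
  if (nrow(paired) == 0) return(TRUE)
  mate_of <- function(ids) {
    i <- match(ids, paired$id)
    hit <- !is.na(i)
    out <- rep(NA_character_, length(ids))
    if (!any(hit)) return(out)
    key <- paste0(paired$frag[i[hit]], ":",
                  ifelse(paired$mate[i[hit]] == "forward", "reverse",
                         "forward"))
    lut <- paste0(paired$frag, ":", paired$mate)
    out[hit] <- paired$id[match(key, lut)]
    out
  }
  mates <- mate_of(path$support)
  mates <- mates[!is.na(mates)]
  if (length(mates) == 0) return(TRUE)
  win <- network$windows[path_window_range(path, network), , drop = FALSE]
  span <- c(min(win$start), max(win$end))
  pl <- scaffold$placements
  i <- match(mates, pl$read_id)
  on_scaffold <- !is.na(i)
  overlaps <- rep(FALSE, length(mates))
  overlaps[on_scaffold] <-
    pl$offset[i[on_scaffold]] < span[2] &
    pl$offset[i[on_scaffold]] + pl$len[i[on_scaffold]] > span[1]
  mean(overlaps) >= params$pair_confirm_fraction
}

path_window_range <- function(path, network) {
  vapply(network$nodes[path$nodes], `[[`, 0L, "window")
}

#' Emit transcripts from confirmed paths
#'
#' A transcript's sequence is the concatenation of its path's node
#' consensi in window order. Transcripts shorter than
#' `min_transcript_len` are dropped and exact duplicate sequences collapse
#' to one (the first occurrence wins).
#'
#' @param paths List of paths (each with `nodes`, `support` and a
#'   `network` attribute added by the pipeline, or pass `networks`).
#' @param networks List of `isoform_network` objects parallel to `paths`
#'   (i.e. `networks[[i]]` is the network `paths[[i]]` was traversed on).
#' @param params [assembly_params()].
#' @return Data.frame with `id`, `seq`, `length`, `guide_id`, `n_support`;
#'   the supporting read ids are kept in the `support` list column.
#' @export
emit_transcripts <- function(paths, networks, params = assembly_params()) {
  rows <- list()
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    nw <- networks[[i]]
    seqv <- paste(vapply(nw$nodes[p$nodes], `[[`, "", "consensus"),
                  collapse = "")
    if (nchar(seqv) < params$min_transcript_len) next
    rows[[length(rows) + 1L]] <- list(seq = seqv, guide_id = nw$guide_id,
                                      support = p$support)
  }
  if (length(rows) == 0)
    return(data.frame(id = character(), seq = character(),
                      length = integer(), guide_id = integer(),
                      n_support = integer(), stringsAsFactors = FALSE))
  seqs <- vapply(rows, `[[`, "", "seq")
  keep <- !duplicated(seqs)
  rows <- rows[keep]
  out <- data.frame(
    id = paste0("transcript_", seq_along(rows)),
    seq = vapply(rows, `[[`, "", "seq"),
    length = nchar(vapply(rows, `[[`, "", "seq")),
    guide_id = vapply(rows, `[[`, 0L, "guide_id"),
    n_support = vapply(rows, function(r) length(r$support), 0L),
    stringsAsFactors = FALSE)
  out$support <- lapply(rows, `[[`, "support")
  out
}
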