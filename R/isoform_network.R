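# Stage (iv): convert each scaffold alignment into an isoform network.
# Windows one third of the minimum read length tile the scaffold span;
# reads fully spanning a window contribute a truncated fragment; fragments
# are single-linkage clustered by hamming identity into nodes; edges join
# nodes in adjacent windows sharing at least two physical reads.

#' Define non-overlapping windows over a scaffold span
#'
#' Windows of width `floor(min_read_len / 3)` tile from the span start. A
#' trailing remainder of at least half a window becomes a final short
#' window; a smaller remainder is appended to the last full window, so no
#' terminal bases are discarded.
#'
#' @param span Integer pair `c(start, end)`, 0-based half-open scaffold
#'   coordinates.
#' @param min_read_len Minimum read length (>= 120).
#' @return Data.frame with columns `index` (1-based), `start`, `end`.
#'   Zero rows when the span is shorter than one window.
#' @export
define_windows <- function(span, min_read_len = 150L) {
  stopifnot(min_read_len >= 120L)
  w <- min_read_len %/% 3L
  L <- span[2] - span[1]
  if (L < w)
    return(data.frame(index = integer(), start = integer(), end = integer()))
  n_full <- L %/% w
  rem <- L %% w
  starts <- span[1] + w * (seq_len(n_full) - 1L)
  ends <- starts + w
  if (rem > 0) {
    if (rem >= w / 2) {
      starts <- c(starts, span[1] + n_full * w)
      ends <- c(ends, span[2])
    } else {
      ends[n_full] <- span[2]
    }
  }
  data.frame(index = seq_along(starts), start = as.integer(starts),
             end = as.integer(ends))
}

#' Collect window fragments from scaffold placements
#'
#' A read contributes a fragment to window i iff it fully covers
#' `[start_i, end_i)`; partial coverage contributes nothing. Fragments are
#' taken from the read oriented to scaffold coordinates, truncated to the
#' window interval.
#'
#' @param scaffold A `scaffold_alignment` from [build_scaffolds()].
#' @param windows Data.frame from [define_windows()].
#' @return A list (one element per window) of data.frames with `read_id`
#'   and `frag`.
#' @export
collect_fragments <- function(scaffold, windows) {
  pl <- scaffold$placements
  lapply(seq_len(nrow(windows)), function(i) {
    s <- windows$start[i]; e <- windows$end[i]
    cover <- pl$offset <= s & pl$offset + pl$len >= e
    if (!any(cover))
      return(data.frame(read_id = character(), frag = character(),
                        stringsAsFactors = FALSE))
    sub <- pl[cover, , drop = FALSE]
    data.frame(read_id = sub$read_id,
               frag = substr(sub$oseq, s - sub$offset + 1L, e - sub$offset),
               stringsAsFactors = FALSE)
  })
}

#' Cluster one window's fragments into network nodes
#'
#' Single-linkage agglomeration: two fragments link when their hamming
#' identity (matching columns over window width, `N` never matching) is at
#' least `min_isoform_sim`; nodes are the connected components, each with
#' a majority-vote consensus (column ties resolve to the lexicographically
#' smallest base).
#'
#' @param fragments Data.frame with `read_id`, `frag` (equal-length,
#'   equally anchored strings).
#' @param min_isoform_sim Link threshold (default 0.96).
#' @return List of nodes: `members` (read ids), `consensus`, `size`.
#' @export
cluster_fragments <- function(fragments, min_isoform_sim = 0.96) {
  if (nrow(fragments) == 0) return(list())
  lab <- cpp_hamming_components(fragments$frag, min_isoform_sim)
  lapply(split(seq_len(nrow(fragments)), lab), function(ix) {
    list(members = fragments$read_id[ix],
         consensus = as.character(cpp_consensus(fragments$frag[ix])),
         size = length(ix))
  })
}

#' Build the isoform network for one scaffold
#'
#' Runs [define_windows()], [collect_fragments()] and
#' [cluster_fragments()], then places an edge between nodes in adjacent
#' windows whenever their member sets share at least
#' `edge_min_shared_reads` read ids (physical linkage). Non-adjacent
#' windows are never connected.
#'
#' @param scaffold A `scaffold_alignment`.
#' @param params [assembly_params()].
#' @return An `isoform_network`: list with `guide_id`, `windows`, `nodes`
#'   (list of `id`, `window`, `members`, `consensus`, `size`) and `edges`
#'   (data.frame `from`, `to`, `shared`).
#' @export
build_network <- function(scaffold, params = assembly_params()) {
  windows <- define_windows(scaffold$span, params$min_read_len)
  nodes <- list()
  by_window <- vector("list", nrow(windows))
  if (nrow(windows) > 0) {
    frags <- collect_fragments(scaffold, windows)
    for (i in seq_len(nrow(windows))) {
      cl <- cluster_fragments(frags[[i]], params$min_isoform_sim)
      ids <- integer(0)
      for (nd in cl) {
        nid <- length(nodes) + 1L
        nodes[[nid]] <- list(id = nid, window = i, members = nd$members,
                             consensus = nd$consensus, size = nd$size)
        ids <- c(ids, nid)
      }
      by_window[[i]] <- ids
    }
  }
  edges <- list()
  if (nrow(windows) > 1) {
    for (i in seq_len(nrow(windows) - 1L)) {
      for (a in by_window[[i]]) {
        for (b in by_window[[i + 1L]]) {
          shared <- length(intersect(nodes[[a]]$members, nodes[[b]]$members))
          if (shared >= params$edge_min_shared_reads)
            edges[[length(edges) + 1L]] <-
              data.frame(from = a, to = b, shared = shared)
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(from = integer(), to = integer(),
                           shared = integer())
  structure(list(guide_id = scaffold$guide_id, windows = windows,
                 nodes = nodes, by_window = by_window, edges = edges),
            class = "isoform_network")
}

#' @export
print.isoform_network <- function(x, ...) {
  cat(sprintf("Isoform network on guide %d: %d windows, %d nodes, %d edges\n",
              x$guide_id, nrow(x$windows), length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Dump an isoform network as node and edge tables
#'
#' @param network An `isoform_network`.
#' @param node_path,edge_path Output TSV paths.
#' @return Invisibly, `c(node_path, edge_path)`.
#' @export
write_network_tables <- function(network, node_path, edge_path) {
  nd <- do.call(rbind, lapply(network$nodes, function(n)
    data.frame(node = n$id, window = n$window, size = n$size,
               consensus = n$consensus, stringsAsFactors = FALSE)))
  if (is.null(nd))
    nd <- data.frame(node = integer(), window = integer(), size = integer(),
                     consensus = character())
  write.table(nd, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(node_path, edge_path))
}
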