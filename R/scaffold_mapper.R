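# Stage (iii): k-mer vote mapping of all input reads (including deferred
# ones) onto the guide each is most similar to, producing scaffold
# alignments.  Offsets are 0-based and may be negative or exceed the guide
# end for overhanging reads.

#' Build a k-mer positional index over guide sequences
#'
#' Every k-mer occurrence of every guide is indexed with its (guide,
#' position) pair; k-mers containing `N` are skipped. This table form is
#' for inspection and testing; [map_reads()] builds the same index
#' internally in native code.
#'
#' @param guides Character vector of guide sequences.
#' @param k k-mer length in bases (default 10).
#' @return Data.frame with columns `kmer`, `guide` (1-based index into
#'   `guides`), `pos` (0-based).
#' @export
build_kmer_index <- function(guides, k = 10L) {
  stopifnot(k >= 1)
  if (length(guides) == 0)
    return(data.frame(kmer = character(), guide = integer(),
                      pos = integer(), stringsAsFactors = FALSE))
  cpp_kmer_table(guides, as.integer(k))
}

#' Map reads onto guides by k-mer voting
#'
#' Each k-mer of a read (in both orientations) votes for the
#' (guide, read-relative offset, orientation) bin implied by its indexed
#' positions; a read's placement is the bin with most votes. Ties break to
#' the lowest guide id, then the lowest offset, then forward orientation.
#' Reads sharing no k-mer with any guide in either orientation are
#' unmapped.
#'
#' @param read_seqs Character vector of read sequences.
#' @param guides Character vector of guide sequences.
#' @param params [assembly_params()].
#' @return Data.frame with one row per read: `read` (index), `guide`,
#'   `offset` (0-based position of the oriented read's first base on the
#'   guide), `orientation`, `votes`, `mapped`.
#' @export
map_reads <- function(read_seqs, guides, params = assembly_params()) {
  stopifnot(length(guides) > 0)
  cpp_map_reads(read_seqs, guides, params$kmer_length)
}

#' Build scaffold alignments from all reads
#'
#' Maps every input read (both mates, deferred reads included) onto its
#' winning guide and groups placements per guide. Guides that receive no
#' reads yield no scaffold; unmapped reads are reported.
#'
#' @param reads Read data.frame ([load_reads()]).
#' @param guides Character vector of guide sequences (non-empty).
#' @param params [assembly_params()].
#' @return List with `scaffolds` (list of `scaffold_alignment` objects:
#'   `guide_id`, `guide_seq`, `placements` data.frame with `read_id`,
#'   `offset`, `orientation`, `votes`, `oseq` (read oriented to scaffold
#'   coordinates), `len`, and `span = c(start, end)`) and `unmapped`
#'   (character vector of read ids).
#' @export
build_scaffolds <- function(reads, guides, params = assembly_params()) {
  if (length(guides) == 0)
    stop("configuration error: no guide sequences to map against")
  pl <- map_reads(reads$seq, guides, params)
  unmapped <- reads$id[!pl$mapped]
  scaffolds <- list()
  for (g in sort(unique(pl$guide[pl$mapped]))) {
    sel <- which(pl$mapped & pl$guide == g)
    rc <- pl$orientation[sel] == "reverse-complement"
    oseq <- reads$seq[sel]
    oseq[rc] <- reverse_complement(oseq[rc])
    placements <- data.frame(
      read_id = reads$id[sel],
      offset = pl$offset[sel],
      orientation = pl$orientation[sel],
      votes = pl$votes[sel],
      oseq = oseq,
      len = nchar(oseq),
      stringsAsFactors = FALSE)
    span <- c(min(placements$offset),
              max(placements$offset + placements$len))
    scaffolds[[length(scaffolds) + 1L]] <- structure(
      list(guide_id = g, guide_seq = guides[g], placements = placements,
           span = span),
      class = "scaffold_alignment")
  }
  list(scaffolds = scaffolds, unmapped = unmapped)
}

#' @export
print.scaffold_alignment <- function(x, ...) {
  cat(sprintf("Scaffold on guide %d: %d reads, span [%d, %d)\n",
              x$guide_id, nrow(x$placements), x$span[1], x$span[2]))
  invisible(x)
}

#' Dump scaffold placements to TSV
#'
#' @param scaffold A `scaffold_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scaffold_table <- function(scaffold, path) {
  df <- scaffold$placements[c("read_id", "offset", "orientation", "votes")]
  df$guide_id <- scaffold$guide_id
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
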