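# Stage (vi): remap all input reads to the finished transcripts and
# report length-normalised relative expression.

#' Quantify relative transcript expression
#'
#' Remaps all reads to the transcripts with the same k-mer vote mapper
#' used for scaffolding (transcripts acting as guides); each mapped read
#' counts once toward its winning transcript. Expression is the
#' length-normalised density `d = c / L`, reported as a percent of the sum
#' over all transcripts, so percents total 100 whenever at least one read
#' maps. Multi-mapping reads go entirely to the vote winner; for
#' near-identical isoforms this single-placement rule is a known bias
#' source.
#'
#' @param transcripts Data.frame with `id` and `seq` columns (e.g. from
#'   [emit_transcripts()]) or a character vector of sequences.
#' @param reads Read data.frame or character vector of read sequences.
#' @param params [assembly_params()].
#' @return Data.frame with `id`, `length`, `count`, `density`, `percent`.
#' @export
quantify_expression <- function(transcripts, reads,
                                params = assembly_params()) {
  if (is.character(transcripts))
    transcripts <- data.frame(id = paste0("transcript_",
                                          seq_along(transcripts)),
                              seq = transcripts, stringsAsFactors = FALSE)
  if (nrow(transcripts) == 0) stop("no transcripts to quantify")
  read_seqs <- if (is.data.frame(reads)) reads$seq else reads
  pl <- map_reads(read_seqs, transcripts$seq, params)
  counts <- tabulate(pl$guide[pl$mapped], nbins = nrow(transcripts))
  len <- nchar(transcripts$seq)
  density <- counts / len
  total <- sum(density)
  if (total == 0) {
    warning("no reads mapped to any transcript; all percents are 0")
    percent <- rep(0, length(counts))
  } else {
    percent <- 100 * density / total
  }
  data.frame(id = transcripts$id, length = len, count = counts,
             density = density, percent = percent, stringsAsFactors = FALSE)
}

#' Write an expression table to TSV
#'
#' @param expr Data.frame from [quantify_expression()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  write.table(expr[c("id", "length", "count", "percent")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
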