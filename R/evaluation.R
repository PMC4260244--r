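# Assembly evaluation: transcript/reference similarity summaries at
# thresholds, per-window source labelling for chimera detection, and
# length-distribution statistics.

.identity_matrix <- function(transcripts, references) {
  t_seq <- if (is.data.frame(transcripts)) transcripts$seq else transcripts
  r_seq <- if (is.data.frame(references)) references$seq else references
  m <- matrix(0, length(t_seq), length(r_seq))
  for (i in seq_along(t_seq)) {
    rc <- reverse_complement(t_seq[i])
    for (j in seq_along(r_seq)) {
      m[i, j] <- max(cpp_global_identity(t_seq[i], r_seq[j]),
                     cpp_global_identity(rc, r_seq[j]))
    }
  }
  m
}

#' Transcript-to-reference match summary at identity thresholds
#'
#' For each threshold, counts how many transcripts have at least one
#' reference at or above that global identity (either orientation) and
#' how many references are matched by at least one transcript. Both
#' counts are monotone non-increasing in the threshold.
#'
#' @param transcripts,references Character vectors of sequences or
#'   data.frames with a `seq` column (both non-empty).
#' @param thresholds Identity thresholds (default 0.90, 0.95, 0.99).
#' @return Data.frame with `threshold`, `transcripts_matched`,
#'   `references_matched`; the full identity matrix is attached as the
#'   `"identity"` attribute.
#' @export
match_summary <- function(transcripts, references,
                          thresholds = c(0.90, 0.95, 0.99)) {
  n_t <- if (is.data.frame(transcripts)) nrow(transcripts)
         else length(transcripts)
  n_r <- if (is.data.frame(references)) nrow(references)
         else length(references)
  stopifnot(n_t > 0, n_r > 0)
  m <- .identity_matrix(transcripts, references)
  out <- data.frame(
    threshold = thresholds,
    transcripts_matched = vapply(thresholds, function(th)
      sum(apply(m >= th, 1, any)), 0L),
    references_matched = vapply(thresholds, function(th)
      sum(apply(m >= th, 2, any)), 0L))
  attr(out, "identity") <- m
  out
}

#' Detect chimeric transcripts by per-window source labelling
#'
#' Each transcript is cut into non-overlapping windows; each full window
#' is labelled with the reference achieving the highest ungapped placement
#' identity (ties give no label). A transcript is called chimeric when its
#' label sequence switches between two sources that are each supported by
#' at least `min_run` consecutive windows -- the signature of an
#' artificial recombinant. References identical to each other produce
#' ties, hence no labels and a non-chimeric verdict by convention.
#'
#' @param transcripts Character vector or data.frame with `id`, `seq`.
#' @param references Named character vector or data.frame with `id`,
#'   `seq`; should include the true isoform set.
#' @param window Label window width in bases (default 50).
#' @param min_run Consecutive windows required to support a source
#'   (default 3).
#' @return A list with `verdicts` data.frame (`id`, `n_windows`,
#'   `n_switches`, `chimeric`) and `labels` (list of per-window label
#'   vectors, `NA` where tied).
#' @export
detect_chimeras <- function(transcripts, references, window = 50L,
                            min_run = 3L) {
  if (!is.data.frame(transcripts))
    transcripts <- data.frame(id = paste0("transcript_",
                                          seq_along(transcripts)),
                              seq = transcripts, stringsAsFactors = FALSE)
  if (is.data.frame(references)) {
    ref_seq <- references$seq
    ref_id <- references$id
  } else {
    ref_seq <- references
    ref_id <- names(references) %||% paste0("ref_", seq_along(references))
  }
  labels <- vector("list", nrow(transcripts))
  verdict <- data.frame(id = transcripts$id,
                        n_windows = 0L, n_switches = 0L, chimeric = FALSE,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(transcripts))) {
    s <- transcripts$seq[i]
    n_win <- nchar(s) %/% window
    lab <- rep(NA_character_, n_win)
    for (wdx in seq_len(n_win)) {
      frag <- substr(s, (wdx - 1L) * window + 1L, wdx * window)
      ids <- cpp_best_fragment_identity(frag, ref_seq, TRUE)
      best <- max(ids)
      hit <- which(ids >= best - 1e-12)
      if (length(hit) == 1) lab[wdx] <- ref_id[hit]
    }
    labels[[i]] <- lab
    runs <- rle(lab[!is.na(lab)])
    supported <- runs$values[runs$lengths >= min_run]
    supported <- rle(supported)$values # collapse repeats of the same source
    switches <- max(0L, length(supported) - 1L)
    verdict$n_windows[i] <- n_win
    verdict$n_switches[i] <- switches
    verdict$chimeric[i] <- switches >= 1L
  }
  list(verdicts = verdict, labels = labels)
}

#' Five-number length summary with boxplot outliers
#'
#' Quartiles use linear interpolation between closest ranks
#' (`stats::quantile` type 7). Outliers lie beyond the whiskers at
#' `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`.
#'
#' @param seqs Character vector of sequences, or a numeric vector of
#'   lengths.
#' @return List with `min`, `q1`, `median`, `q3`, `max`, `iqr` and
#'   `outliers` (the outlying lengths).
#' @export
length_stats <- function(seqs) {
  stopifnot(length(seqs) > 0)
  len <- if (is.character(seqs)) nchar(seqs) else as.numeric(seqs)
  q <- unname(quantile(len, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  iqr <- q[4] - q[2]
  out <- len[len < q[2] - 1.5 * iqr | len > q[4] + 1.5 * iqr]
  list(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
       iqr = iqr, outliers = out)
}
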