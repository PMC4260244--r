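# Benchmark read simulator: paired reads copied from reference transcripts
# at random positions, per-transcript counts normalised by length, the
# mate drawn from a 500-base window anchored on the forward read's last
# base and emitted reverse-complemented (FR geometry), with an optional
# per-site substitution error.

#' Length-normalised read allocation
#'
#' Distributes `n_reads` across the references proportionally to their
#' lengths using largest-remainder rounding, so the total is exact and
#' expected per-site coverage is uniform across transcripts.
#'
#' @param ref_lengths Integer vector of reference lengths.
#' @param n_reads Total forward reads to allocate.
#' @return Integer vector of per-reference counts summing to `n_reads`.
#' @export
allocate_reads <- function(ref_lengths, n_reads) {
  stopifnot(length(ref_lengths) >= 1, all(ref_lengths > 0))
  q <- n_reads * ref_lengths / sum(ref_lengths)
  base <- floor(q)
  rem <- n_reads - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

.mutate <- function(seqs, error_rate) {
  if (error_rate <= 0)
    return(list(seqs = seqs, n_errors = integer(length(seqs))))
  bases <- c("A", "C", "G", "T")
  n_err <- rbinom(length(seqs), nchar(seqs), error_rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      alt <- setdiff(bases, ch[p])
      ch[p] <- alt[sample.int(3L, 1L)]
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  list(seqs = seqs, n_errors = as.integer(n_err))
}

#' Simulate paired-end reads from reference transcripts
#'
#' For each reference, its length-proportional share of forward reads is
#' copied from uniformly random start positions. Each mate is copied from
#' a uniformly random position inside the `pair_window`-base window
#' anchored on the forward read's last base (clipped so the mate lies
#' fully inside the transcript) and emitted reverse-complemented. Each
#' base is independently substituted with probability `error_rate`
#' (uniform over the three alternatives). Qualities are a constant
#' placeholder -- the assembler never consults them.
#'
#' @param references Named character vector of reference transcript
#'   sequences, or a data.frame with `id` and `seq`.
#' @param n_reads Total forward reads (each yields one pair when
#'   `paired = TRUE`).
#' @param read_len Read length in bases (default 250).
#' @param pair_window Mate window width anchored on the forward read's
#'   last base (default 500; must be >= `read_len`).
#' @param error_rate Per-site substitution probability in \[0, 0.05\].
#' @param paired Emit mates (default TRUE).
#' @param seed Optional RNG seed; `NULL` uses the current RNG state.
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>_1.fastq`, `<prefix>_2.fastq` and `<prefix>_truth.tsv`.
#' @return List with `reads` (data.frame as from [load_reads()]) and
#'   `truth` (data.frame `read_id`, `source`, `start` (0-based),
#'   `orientation`, `n_errors`).
#' @export
simulate_reads <- function(references, n_reads, read_len = 250L,
                           pair_window = 500L, error_rate = 0,
                           paired = TRUE, seed = NULL, out_prefix = NULL) {
  if (is.data.frame(references)) {
    refs <- references$seq
    names(refs) <- references$id
  } else {
    refs <- references
    if (is.null(names(refs)))
      names(refs) <- paste0("ref_", seq_along(refs))
  }
  stopifnot(error_rate >= 0, error_rate <= 0.05, pair_window >= read_len)
  short <- nchar(refs) < read_len
  if (any(short)) {
    warning("rejecting ", sum(short), " reference(s) shorter than read_len")
    refs <- refs[!short]
  }
  stopifnot(length(refs) >= 1, n_reads >= length(refs))
  if (!is.null(seed)) set.seed(seed)
  counts <- allocate_reads(nchar(refs), n_reads)
  fid <- fsrc <- fseq <- character(0)
  fstart <- integer(0)
  rid <- rseq <- character(0)
  rstart <- integer(0)
  serial <- 0L
  for (r in seq_along(refs)) {
    L <- nchar(refs[r])
    cnt <- counts[r]
    if (cnt == 0) next
    s <- sample.int(L - read_len + 1L, cnt, replace = TRUE) - 1L
    ids <- paste0("r", serial + seq_len(cnt))
    serial <- serial + cnt
    fid <- c(fid, ids)
    fsrc <- c(fsrc, rep(names(refs)[r], cnt))
    fstart <- c(fstart, s)
    fseq <- c(fseq, substring(refs[r], s + 1L, s + read_len))
    if (paired) {
      ends <- s + read_len
      lo <- pmax(0L, ends - pair_window)
      hi <- pmin(L, ends) - read_len
      hi <- pmax(hi, lo)
      m <- lo + vapply(hi - lo + 1L, function(n) sample.int(n, 1L) - 1L, 0L)
      rid <- c(rid, ids)
      rstart <- c(rstart, m)
      rseq <- c(rseq, substring(refs[r], m + 1L, m + read_len))
    }
  }
  fm <- .mutate(fseq, error_rate)
  fwd <- data.frame(id = paste0(fid, "/1"), frag = fid, seq = fm$seqs,
                    qual = strrep("I", read_len),
                    mate = if (paired) "forward" else "unpaired",
                    stringsAsFactors = FALSE)
  truth <- data.frame(read_id = fwd$id, source = fsrc, start = fstart,
                      orientation = "forward", n_errors = fm$n_errors,
                      stringsAsFactors = FALSE)
  reads <- fwd
  if (paired) {
    rm_ <- .mutate(rseq, error_rate)
    rev <- data.frame(id = paste0(rid, "/2"), frag = rid,
                      seq = reverse_complement(rm_$seqs),
                      qual = strrep("I", read_len), mate = "reverse",
                      stringsAsFactors = FALSE)
    truth <- rbind(truth,
                   data.frame(read_id = rev$id, source = fsrc,
                              start = rstart,
                              orientation = "reverse-complement",
                              n_errors = rm_$n_errors,
                              stringsAsFactors = FALSE))
    reads <- rbind(fwd, rev)
  }
  if (!is.null(out_prefix)) {
    write_fastq(fwd$id, fwd$seq, paste0(out_prefix, "_1.fastq"), fwd$qual)
    if (paired)
      write_fastq(rev$id, rev$seq, paste0(out_prefix, "_2.fastq"), rev$qual)
    write.table(truth, paste0(out_prefix, "_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(reads = reads, truth = truth)
}

#' Generate synthetic isoform families
#'
#' A synthetic stand-in for a curated multi-isoform reference set: each
#' family derives its isoforms from one random ancestor by substituting a
#' `divergence` fraction of sites at positions drawn independently per
#' isoform; families are mutually independent random sequences (expected
#' inter-family identity ~25%).
#'
#' @param n_families Number of independent families.
#' @param isoforms_per_family Isoforms per family.
#' @param length Transcript length in bases.
#' @param divergence Per-isoform substitution fraction in \[0, 0.5\];
#'   recycled across families, so a vector gives each family its own
#'   divergence.
#' @param seed Optional RNG seed.
#' @return Data.frame with `id` (`fam<i>_iso<j>`), `family` and `seq`.
#' @export
make_isoform_families <- function(n_families, isoforms_per_family, length,
                                  divergence = 0.04, seed = NULL) {
  stopifnot(all(divergence >= 0), all(divergence <= 0.5))
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  divergence <- rep_len(divergence, n_families)
  rows <- list()
  for (f in seq_len(n_families)) {
    anc <- sample(bases, length, replace = TRUE)
    n_sub <- round(divergence[f] * length)
    for (k in seq_len(isoforms_per_family)) {
      iso <- anc
      if (n_sub > 0) {
        pos <- sample.int(length, n_sub)
        for (p in pos) iso[p] <- sample(setdiff(bases, iso[p]), 1L)
      }
      rows[[length(rows) + 1L]] <- list(
        id = sprintf("fam%d_iso%d", f, k), family = f,
        seq = paste(iso, collapse = ""))
    }
  }
  data.frame(id = vapply(rows, `[[`, "", "id"),
             family = vapply(rows, `[[`, 0, "family"),
             seq = vapply(rows, `[[`, "", "seq"), stringsAsFactors = FALSE)
}
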