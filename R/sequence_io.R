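# Sequence I/O: FASTQ/FASTA loading with mate-pair association, FASTA
# output with annotated headers.  Parsing is delegated to Biostrings; this
# layer normalises ids, enforces the pairing contract and presents reads as
# a plain data.frame (id, fragment, seq, qual, mate).

.detect_format <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  first <- ""
  while (TRUE) {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0) return("empty")
    if (nzchar(trimws(ln))) { first <- substr(trimws(ln), 1, 1); break }
  }
  if (first == "@") "fastq" else if (first == ">") "fasta"
  else stop("cannot determine sequence format of ", path,
            " (expected FASTA or FASTQ)")
}

.read_seq_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- .detect_format(path)
  if (fmt == "empty") {
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  res <- tryCatch(
    {
      if (fmt == "fastq") {
        x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                          with.qualities = TRUE)
        q <- as.character(S4Vectors::mcols(x)$qualities)
      } else {
        x <- Biostrings::readDNAStringSet(path, format = "fasta")
        q <- rep(NA_character_, length(x))
      }
      list(x = x, q = q)
    },
    error = function(e) {
      stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
  sq <- toupper(as.character(res$x))
  bad <- which(!is.na(res$q) & nchar(res$q) != nchar(sq))
  if (length(bad))
    stop("parse error in ", path, ": quality length differs from sequence ",
         "length at record ", bad[1], call. = FALSE)
  ids <- sub("\\s.*$", "", names(res$x))
  data.frame(id = ids, seq = sq, qual = res$q, stringsAsFactors = FALSE)
}

#' Strip mate suffixes from read ids
#'
#' Normalises the common Illumina mate-naming dialects (`/1`, `/2` and the
#' post-whitespace `1:...` / `2:...` comment, which is already removed with
#' the rest of the header comment) down to the shared fragment identifier.
#'
#' @param ids Character vector of read ids.
#' @return Character vector of fragment ids.
#' @export
strip_mate_suffix <- function(ids) {
  sub("/[12]$", "", sub("\\s.*$", "", ids))
}

#' Load reads from FASTQ or FASTA
#'
#' Reads one file (single-end) or two files (paired-end). Paired files are
#' associated positionally and checked by id: after mate-suffix
#' normalisation record i of both files must resolve to the same fragment
#' identifier. Qualities are carried along but never used by the assembly
#' algorithm.
#'
#' @param path Forward (or only) read file, FASTQ or FASTA.
#' @param paired_path Optional reverse-mate file.
#' @return A data.frame with columns `id`, `frag` (fragment id after
#'   suffix normalisation), `seq`, `qual` (`NA` for FASTA), and `mate`
#'   (`"unpaired"`, `"forward"` or `"reverse"`).
#' @export
load_reads <- function(path, paired_path = NULL) {
  fwd <- .read_seq_file(path)
  if (is.null(paired_path)) {
    fwd$frag <- strip_mate_suffix(fwd$id)
    fwd$mate <- rep("unpaired", nrow(fwd))
    if (anyDuplicated(fwd$id))
      stop("duplicate read ids in ", path)
    message(nrow(fwd), " reads loaded (single-end)")
    return(fwd[c("id", "frag", "seq", "qual", "mate")])
  }
  rev <- .read_seq_file(paired_path)
  if (nrow(fwd) != nrow(rev))
    stop("pairing error: ", path, " has ", nrow(fwd), " records but ",
         paired_path, " has ", nrow(rev))
  ff <- strip_mate_suffix(fwd$id)
  rf <- strip_mate_suffix(rev$id)
  bad <- which(ff != rf)
  if (length(bad))
    stop("pairing error: record ", bad[1], " ids do not resolve to the same ",
         "fragment (", fwd$id[bad[1]], " vs ", rev$id[bad[1]], ")")
  # make ids unique across the combined set when the two files reuse them
  if (any(fwd$id == rev$id)) {
    fwd$id <- paste0(ff, "/1")
    rev$id <- paste0(rf, "/2")
  }
  fwd$frag <- ff; fwd$mate <- rep("forward", nrow(fwd))
  rev$frag <- rf; rev$mate <- rep("reverse", nrow(rev))
  out <- rbind(fwd[c("id", "frag", "seq", "qual", "mate")],
               rev[c("id", "frag", "seq", "qual", "mate")])
  if (anyDuplicated(out$id))
    stop("duplicate read ids after mate-suffix normalization")
  rownames(out) <- NULL
  message(nrow(fwd), " read pairs loaded")
  out
}

#' Write sequences to FASTA
#'
#' Headers follow `"<id> <annotation>"`; the pipeline uses annotations of
#' the form `length=<L> expression=<p>%`.
#'
#' @param ids Character vector of sequence ids (non-empty).
#' @param seqs Character vector of nucleotide sequences.
#' @param path Output file.
#' @param annotations Optional character vector appended to each header.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, seqs, path, annotations = NULL) {
  stopifnot(length(ids) == length(seqs))
  if (length(ids) && any(!nzchar(ids))) stop("empty sequence id")
  headers <- ids
  if (!is.null(annotations)) {
    stopifnot(length(annotations) == length(ids))
    headers <- ifelse(nzchar(annotations), paste(ids, annotations), ids)
  }
  if (length(seqs) == 0) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- headers
  tryCatch(Biostrings::writeXStringSet(x, path, width = 70L),
           error = function(e) stop("I/O error writing ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Write reads to FASTQ
#'
#' @param ids,seqs,quals Parallel character vectors; `quals` defaults to a
#'   constant placeholder score.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, path, quals = NULL) {
  stopifnot(length(ids) == length(seqs))
  if (is.null(quals))
    quals <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(ids))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con, sep = "\n")
  invisible(path)
}
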