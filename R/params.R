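#' Assembly parameters
#'
#' Collects every tunable constant of the pipeline in one validated object.
#' Defaults are the algorithm's published operating point: partition
#' membership requires 70% identity across a 100-base window, guide
#' extension 98% across 100 bases, mapping uses 10-base k-mers, network
#' windows are one third of the minimum read length, edges require two
#' physically shared reads, and paths are discarded when fewer than 30% of
#' their mate pairs confirm.
#'
#' @param min_read_len Minimum read length in bases (default 150). The
#'   network window width is derived as `floor(min_read_len / 3)`. Hard
#'   floor 120: below that the windows carry too little sequence to
#'   cluster on diversity.
#' @param min_transcript_len Minimum emitted transcript length (default 250).
#' @param min_isoform_sim Hamming-identity threshold linking two window
#'   fragments into the same network node (default 0.96).
#' @param partition_window,partition_identity Window width and identity for
#'   partition membership (100 bases, 0.70).
#' @param expansion_sample Maximum probe reads drawn from the previous
#'   expansion cycle (12).
#' @param min_partition_size Partitions smaller than this are deferred to
#'   mapping (3).
#' @param guide_window,guide_identity Window width and identity anchoring a
#'   read onto a growing guide sequence (100 bases, 0.98).
#' @param kmer_length k-mer size for the mapping index (10).
#' @param edge_min_shared_reads Reads two adjacent network nodes must
#'   physically share for an edge (2).
#' @param pair_confirm_fraction A path is kept only if at least this
#'   fraction of its supporting reads' mates map back onto it (0.30).
#' @param max_live_paths Breadth-first traversal guard against degenerate
#'   networks (10000 live paths; truncation warns).
#' @param rng_seed Seed for every stochastic choice (partition seeding,
#'   probe sampling, guide seeding).
#'
#' @return A validated object of class `assembly_params`.
#' @seealso [validate_params()]
#' @examples
#' p <- assembly_params()
#' window_width(p) # 50
#' @export
assembly_params <- function(min_read_len = 150L,
                            min_transcript_len = 250L,
                            min_isoform_sim = 0.96,
                            partition_window = 100L,
                            partition_identity = 0.70,
                            expansion_sample = 12L,
                            min_partition_size = 3L,
                            guide_window = 100L,
                            guide_identity = 0.98,
                            kmer_length = 10L,
                            edge_min_shared_reads = 2L,
                            pair_confirm_fraction = 0.30,
                            max_live_paths = 10000L,
                            rng_seed = 1L) {
  p <- structure(list(
    min_read_len = as.integer(min_read_len),
    min_transcript_len = as.integer(min_transcript_len),
    min_isoform_sim = min_isoform_sim,
    partition_window = as.integer(partition_window),
    partition_identity = partition_identity,
    expansion_sample = as.integer(expansion_sample),
    min_partition_size = as.integer(min_partition_size),
    guide_window = as.integer(guide_window),
    guide_identity = guide_identity,
    kmer_length = as.integer(kmer_length),
    edge_min_shared_reads = as.integer(edge_min_shared_reads),
    pair_confirm_fraction = pair_confirm_fraction,
    max_live_paths = as.integer(max_live_paths),
    rng_seed = as.integer(rng_seed)
  ), class = "assembly_params")
  validate_params(p)
}

#' Validate assembly parameters
#'
#' Checks every invariant of an [assembly_params()] object and returns it
#' unchanged; any violation is an error. In particular the minimum read
#' length may not fall below 120 bases.
#'
#' @param p An `assembly_params` object (or a bare list with the same
#'   fields).
#' @return `p`, invisibly unchanged, with class `assembly_params`.
#' @export
validate_params <- function(p) {
  stopifnot(is.list(p))
  need <- c("min_read_len", "min_transcript_len", "min_isoform_sim",
            "partition_window", "partition_identity", "expansion_sample",
            "min_partition_size", "guide_window", "guide_identity",
            "kmer_length", "edge_min_shared_reads", "pair_confirm_fraction",
            "max_live_paths", "rng_seed")
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop("assembly_params is missing fields: ", paste(missing, collapse = ", "))
  chk_int <- function(x, nm, min = 1L) {
    if (length(x) != 1 || is.na(x) || x < min)
      stop("invalid assembly parameter '", nm, "': must be a single integer >= ",
           min, call. = FALSE)
  }
  chk_frac <- function(x, nm) {
    if (length(x) != 1 || is.na(x) || x <= 0 || x > 1)
      stop("invalid assembly parameter '", nm, "': must lie in (0, 1]",
           call. = FALSE)
  }
  if (p$min_read_len < 120L)
    stop("min_read_len must be at least 120 bases (window width would be too ",
         "small to cluster on diversity)", call. = FALSE)
  chk_int(p$min_read_len, "min_read_len", 120L)
  chk_int(p$min_transcript_len, "min_transcript_len")
  chk_int(p$partition_window, "partition_window")
  chk_int(p$expansion_sample, "expansion_sample")
  chk_int(p$min_partition_size, "min_partition_size")
  chk_int(p$guide_window, "guide_window")
  chk_int(p$kmer_length, "kmer_length")
  chk_int(p$edge_min_shared_reads, "edge_min_shared_reads", 1L)
  chk_int(p$max_live_paths, "max_live_paths")
  chk_frac(p$partition_identity, "partition_identity")
  chk_frac(p$guide_identity, "guide_identity")
  chk_frac(p$min_isoform_sim, "min_isoform_sim")
  chk_frac(p$pair_confirm_fraction, "pair_confirm_fraction")
  w <- p$min_read_len %/% 3L
  stopifnot(3L * w <= p$min_read_len) # any minimum-length read spans 3 windows
  class(p) <- "assembly_params"
  p
}

#' Network window width derived from the minimum read length
#'
#' One third of the minimum read length, so that a read of at least minimum
#' length can span three consecutive windows -- the precondition of the
#' triplet linkage rule used during traversal.
#'
#' @param p An `assembly_params` object.
#' @return Integer window width in bases.
#' @export
window_width <- function(p) p$min_read_len %/% 3L

#' @export
print.assembly_params <- function(x, ...) {
  cat("Assembly parameters\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read key=value parameter files
#'
#' Parses a plain `key=value` config file (one entry per line, `#`
#' comments) into an [assembly_params()] object; `overrides` (e.g. parsed
#' CLI flags) take precedence over file entries.
#'
#' @param path Config file path, or `NULL` for defaults only.
#' @param overrides Named list of parameter overrides.
#' @return A validated `assembly_params` object.
#' @export
read_params <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("malformed config line: ", ln)
      vals[[trimws(kv[1])]] <- type.convert(trimws(kv[2]), as.is = TRUE)
    }
  }
  vals[names(overrides)] <- overrides
  do.call(assembly_params, vals)
}
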