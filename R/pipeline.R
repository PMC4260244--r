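# End-to-end orchestration of the six assembly stages, plus the
# simulate -> assemble -> evaluate benchmark composition.

#' Run the full assembly pipeline
#'
#' Executes the six stages in order: (i) partition forward reads, (ii)
#' build and merge guide sequences per assemblable partition, (iii) map
#' ALL reads (deferred ones re-enter here) onto guides into scaffold
#' alignments, (iv) build one isoform network per scaffold, (v) traverse
#' under the triplet linkage rule, confirm with mate pairs when the input
#' is paired, and emit consensus transcripts, (vi) quantify relative
#' expression. All stochastic choices draw from one generator seeded with
#' `params$rng_seed`, so a fixed seed gives byte-identical outputs.
#'
#' @param reads Read data.frame from [load_reads()], or a file path
#'   (FASTQ/FASTA).
#' @param paired_path Optional mate file path when `reads` is a path.
#' @param params [assembly_params()].
#' @param out_dir Optional output directory; when given, writes
#'   `transcripts.fasta` (headers `<id> length=<L> expression=<p>%`),
#'   `expression.tsv` and `manifest.txt`.
#' @param keep_intermediates Also dump guides FASTA and per-scaffold
#'   placement/network TSVs under `out_dir`.
#' @param verbose Log per-stage record counts.
#' @return List of class `assembly_result`: `transcripts` (data.frame),
#'   `expression`, `guides`, `scaffolds`, `networks`, `manifest`.
#' @export
run_assembly <- function(reads, paired_path = NULL,
                         params = assembly_params(), out_dir = NULL,
                         keep_intermediates = FALSE, verbose = TRUE) {
  log_ <- function(...) if (verbose) message("[isoasm] ", sprintf(...))
  if (is.character(reads)) {
    reads <- tryCatch(load_reads(reads, paired_path),
                      error = function(e)
                        stop("stage load: ", conditionMessage(e),
                             call. = FALSE))
  }
  if (nrow(reads) == 0) stop("stage load: no reads in input")
  params <- validate_params(params)
  paired <- any(reads$mate == "reverse")
  set.seed(params$rng_seed)

  # (i) partitioning
  partitions <- partition_reads(reads, params)
  sel <- select_assemblable(partitions, params)
  log_("stage i: %d partitions (%d assemblable, %d reads deferred)",
       length(partitions), length(sel$kept), length(sel$deferred))

  # (ii) de novo guide construction
  guides <- character()
  for (p in sel$kept)
    guides <- c(guides, build_guides(partition_pool(p, reads), params))
  n_raw <- length(guides)
  guides <- merge_guides(guides, params)
  log_("stage ii: %d guides built, %d after final join", n_raw,
       length(guides))
  if (length(guides) == 0)
    stop("stage de-novo: no guide sequences could be assembled")

  # (iii) mapping
  sc <- build_scaffolds(reads, guides, params)
  log_("stage iii: %d scaffolds, %d reads unmapped", length(sc$scaffolds),
       length(sc$unmapped))

  # (iv) networking
  networks <- lapply(sc$scaffolds, build_network, params = params)
  log_("stage iv: %d networks, %d nodes total", length(networks),
       sum(vapply(networks, function(n) length(n$nodes), 0L)))

  # (v) traversal + pair confirmation
  paths <- list()
  path_networks <- list()
  n_paths <- 0L
  n_discarded <- 0L
  for (i in seq_along(networks)) {
    pp <- traverse_network(networks[[i]], params)
    n_paths <- n_paths + length(pp)
    for (p in pp) {
      ok <- !paired ||
        confirm_with_pairs(p, networks[[i]], sc$scaffolds[[i]], reads, params)
      if (ok) {
        paths[[length(paths) + 1L]] <- p
        path_networks[[length(path_networks) + 1L]] <- networks[[i]]
      } else {
        n_discarded <- n_discarded + 1L
      }
    }
  }
  transcripts <- emit_transcripts(paths, path_networks, params)
  log_("stage v: %d paths (%d discarded by pair confirmation), %d transcripts",
       n_paths, n_discarded, nrow(transcripts))

  # (vi) expression
  if (nrow(transcripts) > 0) {
    expr <- quantify_expression(transcripts, reads, params)
    transcripts$expression_percent <- expr$percent
  } else {
    expr <- data.frame(id = character(), length = integer(),
                       count = integer(), density = numeric(),
                       percent = numeric())
    transcripts$expression_percent <- numeric(0)
  }
  log_("stage vi: expression quantified over %d transcripts",
       nrow(transcripts))

  manifest <- list(
    params = params,
    paired = paired,
    pair_confirmation = if (paired) "applied" else "skipped (single-end)",
    n_reads = nrow(reads),
    n_forward = sum(reads$mate != "reverse"),
    n_partitions = length(partitions),
    n_assemblable = length(sel$kept),
    n_deferred = length(sel$deferred),
    n_guides = length(guides),
    n_scaffolds = length(sc$scaffolds),
    n_unmapped = length(sc$unmapped),
    n_paths = n_paths,
    n_paths_discarded = n_discarded,
    n_transcripts = nrow(transcripts))

  result <- structure(list(transcripts = transcripts, expression = expr,
                           guides = guides, scaffolds = sc$scaffolds,
                           networks = networks, unmapped = sc$unmapped,
                           manifest = manifest),
                      class = "assembly_result")
  if (!is.null(out_dir)) write_assembly(result, out_dir, keep_intermediates)
  result
}

#' Write assembly outputs to a directory
#'
#' @param result An `assembly_result`.
#' @param out_dir Output directory (created if needed).
#' @param keep_intermediates Also dump guides and per-scaffold tables.
#' @return `out_dir`, invisibly.
#' @export
write_assembly <- function(result, out_dir, keep_intermediates = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tr <- result$transcripts
  write_fasta(tr$id, tr$seq, file.path(out_dir, "transcripts.fasta"),
              annotations = sprintf("length=%d expression=%.2f%%",
                                    tr$length, tr$expression_percent))
  write_expression_table(result$expression,
                         file.path(out_dir, "expression.tsv"))
  mf <- result$manifest
  lines <- c("isoasm run manifest",
             vapply(setdiff(names(mf), "params"), function(nm)
               sprintf("%s\t%s", nm, paste(format(mf[[nm]]), collapse = " ")),
               ""),
             "params:",
             vapply(names(mf$params), function(nm)
               sprintf("  %s\t%s", nm, format(mf$params[[nm]])), ""))
  writeLines(lines, file.path(out_dir, "manifest.txt"))
  if (keep_intermediates) {
    write_fasta(paste0("guide_", seq_along(result$guides)), result$guides,
                file.path(out_dir, "guides.fasta"))
    for (i in seq_along(result$scaffolds)) {
      write_scaffold_table(result$scaffolds[[i]],
                           file.path(out_dir, sprintf("scaffold_%d.tsv", i)))
      write_network_tables(result$networks[[i]],
                           file.path(out_dir, sprintf("network_%d_nodes.tsv", i)),
                           file.path(out_dir, sprintf("network_%d_edges.tsv", i)))
    }
  }
  invisible(out_dir)
}

#' @export
print.assembly_result <- function(x, ...) {
  mf <- x$manifest
  cat(sprintf(paste0("Assembly of %d reads: %d partitions -> %d guides -> ",
                     "%d scaffolds -> %d transcripts\n"),
              mf$n_reads, mf$n_partitions, mf$n_guides, mf$n_scaffolds,
              mf$n_transcripts))
  invisible(x)
}

#' Simulate, assemble and evaluate in one call
#'
#' Chains [simulate_reads()], [run_assembly()] and the evaluation module:
#' the assembled transcripts are compared back to the simulating
#' references with [match_summary()] at the given thresholds and screened
#' with [detect_chimeras()].
#'
#' @param references Reference transcripts (named character vector or
#'   data.frame with `id`, `seq`).
#' @param n_reads,read_len,pair_window,error_rate,paired Simulator
#'   settings, see [simulate_reads()].
#' @param params [assembly_params()]; its `rng_seed` also seeds the
#'   simulator.
#' @param thresholds Match thresholds (default 0.90, 0.95, 0.99).
#' @param verbose Log stages.
#' @return List with `assembly` (an `assembly_result`), `match`
#'   (match_summary data.frame), `chimeras` (detect_chimeras report) and
#'   `sim` (the simulation truth).
#' @export
run_benchmark <- function(references, n_reads, read_len = 250L,
                          pair_window = 500L, error_rate = 0,
                          paired = TRUE, params = assembly_params(),
                          thresholds = c(0.90, 0.95, 0.99),
                          verbose = TRUE) {
  sim <- simulate_reads(references, n_reads, read_len = read_len,
                        pair_window = pair_window, error_rate = error_rate,
                        paired = paired, seed = params$rng_seed)
  assembly <- run_assembly(sim$reads, params = params, verbose = verbose)
  if (nrow(assembly$transcripts) == 0)
    return(list(assembly = assembly, match = NULL, chimeras = NULL,
                sim = sim))
  match <- match_summary(assembly$transcripts, references,
                         thresholds = thresholds)
  chim <- detect_chimeras(assembly$transcripts, references)
  list(assembly = assembly, match = match, chimeras = chim, sim = sim)
}
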