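# Shared fixtures and independent oracles.  Oracles are deliberately naive
# (exhaustive enumeration in plain R) and never call the code paths they
# check.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# substitute exactly k positions (guaranteed to change the base)
mutate_at <- function(s, pos) {
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in pos) x[p] <- sample(setdiff(BASES, x[p]), 1)
  paste(x, collapse = "")
}

revcomp_r <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

# error-free reads tiled over a transcript at fixed step
tile_reads <- function(transcript, read_len, step, prefix = "r") {
  L <- nchar(transcript)
  starts <- seq(1, L - read_len + 1, by = step)
  data.frame(id = paste0(prefix, seq_along(starts)),
             frag = paste0(prefix, seq_along(starts)),
             seq = substring(transcript, starts, starts + read_len - 1),
             qual = NA_character_, mate = "unpaired",
             stringsAsFactors = FALSE)
}

reads_df <- function(seqs, mate = "unpaired", prefix = "r") {
  data.frame(id = sprintf("%s%d", prefix, seq_along(seqs)),
             frag = sprintf("%s%d", prefix, seq_along(seqs)), seq = seqs,
             qual = rep(NA_character_, length(seqs)),
             mate = rep(mate, length.out = length(seqs)),
             stringsAsFactors = FALSE)
}

# ---- oracles -------------------------------------------------------------

# hamming matches between equal-length strings, N never matching
o_matches <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(x == y & x != "N")
}

# exhaustive best window match over every offset pair, forward orientation
# of b only (callers add the reverse complement themselves)
o_window_match_fwd <- function(a, b, window, min_identity) {
  La <- nchar(a); Lb <- nchar(b)
  best <- NULL
  if (La < window || Lb < window) return(best)
  for (oa in 0:(La - window)) {
    wa <- substr(a, oa + 1, oa + window)
    for (ob in 0:(Lb - window)) {
      id <- o_matches(wa, substr(b, ob + 1, ob + window)) / window
      if (id >= min_identity - 1e-12 &&
          (is.null(best) || id > best$identity + 1e-12))
        best <- list(offset_a = oa, offset_b = ob, identity = id)
    }
  }
  best
}

o_window_match <- function(a, b, window, min_identity) {
  f <- o_window_match_fwd(a, b, window, min_identity)
  r <- o_window_match_fwd(a, revcomp_r(b), window, min_identity)
  if (is.null(f)) return(r)
  if (is.null(r) || f$identity >= r$identity - 1e-12) return(f)
  r
}

# brute-force single-linkage components of the hamming-identity graph
o_hamming_components <- function(frags, min_identity) {
  n <- length(frags)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && o_matches(frags[i], frags[j]) / nchar(frags[i]) >=
        min_identity - 1e-12)
      parent[find(j)] <- find(i)
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

# per-offset ungapped scoring of a read against every guide/offset/strand:
# the score of a placement is the number of exactly matching k-length
# blocks, which is what k-mer voting counts
o_best_placement <- function(read, guides, k) {
  best <- NULL
  for (ori in c("forward", "reverse-complement")) {
    s <- if (ori == "forward") read else revcomp_r(read)
    Lr <- nchar(s)
    for (g in seq_along(guides)) {
      Lg <- nchar(guides[g])
      for (off in (-(Lr - k)):(Lg - k)) {
        votes <- 0L
        for (p in 0:(Lr - k)) {
          q <- off + p
          if (q < 0 || q + k > Lg) next
          if (substr(s, p + 1, p + k) == substr(guides[g], q + 1, q + k) &&
              !grepl("N", substr(s, p + 1, p + k), fixed = TRUE))
            votes <- votes + 1L
        }
        if (votes >= 1 &&
            (is.null(best) || votes > best$votes))
          best <- list(guide = g, offset = off, orientation = ori,
                       votes = votes)
      }
    }
  }
  best
}

# build a minimal isoform_network object by hand for traversal tests:
# `spec` is a list of nodes, each list(window =, members = character())
hand_network <- function(spec, width = 50L, edge_min = 2L) {
  n_win <- max(vapply(spec, `[[`, 0, "window"))
  windows <- data.frame(index = seq_len(n_win),
                        start = (seq_len(n_win) - 1L) * width,
                        end = seq_len(n_win) * width)
  nodes <- lapply(seq_along(spec), function(i)
    list(id = i, window = as.integer(spec[[i]]$window),
         members = spec[[i]]$members,
         consensus = spec[[i]]$consensus %||% strrep("A", width),
         size = length(spec[[i]]$members)))
  by_window <- lapply(seq_len(n_win), function(w)
    which(vapply(nodes, `[[`, 0, "window") == w))
  edges <- list()
  for (w in seq_len(n_win - 1)) {
    for (a in by_window[[w]]) for (b in by_window[[w + 1]]) {
      shared <- length(intersect(nodes[[a]]$members, nodes[[b]]$members))
      if (shared >= edge_min)
        edges[[length(edges) + 1]] <- data.frame(from = a, to = b,
                                                 shared = shared)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(from = integer(), to = integer(),
                           shared = integer())
  structure(list(guide_id = 1L, windows = windows, nodes = nodes,
                 by_window = by_window, edges = edges),
            class = "isoform_network")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
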