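# Independent oracles used across the suite. These deliberately share no
# code with the implementation: the window checker tests every candidate
# window against the position specs directly, and the PWM enumerator
# sums background probabilities over explicitly generated sequences.

# Expand a gapped pattern into per-window allowed-residue lists, one per
# fixed repeat combination, then test every (start, width) window of the
# sequence. Returns 0-based (start, end) pairs sorted like scan_pattern.
naive_window_scan <- function(sequence, pattern) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  combos <- expand.grid(lapply(pattern$positions, function(p) {
    seq.int(p$min_repeat, p$max_repeat)
  }), KEEP.OUT.ATTRS = FALSE)
  starts <- integer(0); ends <- integer(0)
  for (ci in seq_len(max(1L, nrow(combos)))) {
    specs <- list()
    for (j in seq_along(pattern$positions)) {
      reps <- combos[ci, j]
      specs <- c(specs, rep(list(pattern$positions[[j]]$residues), reps))
    }
    w <- length(specs)
    if (w > n) next
    for (s in seq_len(n - w + 1L)) {
      ok <- TRUE
      for (j in seq_len(w)) {
        res <- specs[[j]]
        ch <- chars[s + j - 1L]
        if (identical(res, "ANY")) {
          if (!grepl("^[A-Z]$", ch)) { ok <- FALSE; break }
        } else if (!(ch %in% res)) { ok <- FALSE; break }
      }
      if (ok) { starts <- c(starts, s - 1L); ends <- c(ends, s - 1L + w) }
    }
  }
  if (length(starts)) {
    keep <- !duplicated(paste(starts, ends))
    ord <- order(starts[keep], ends[keep])
    data.frame(start = starts[keep][ord], end = ends[keep][ord])
  } else {
    data.frame(start = integer(0), end = integer(0))
  }
}

# Exhaustive PWM p-values: enumerate all 20^k integer scores by
# column-wise outer sums, with matching background probabilities.
# Returns a function s -> P(score >= s).
enumerate_pwm_pvalue <- function(pwm) {
  si <- round(pwm$log_odds * 1000)
  b <- pwm$background
  scores <- 0; probs <- 1
  for (j in seq_len(ncol(si))) {
    scores <- as.vector(outer(scores, si[, j], "+"))
    probs <- as.vector(outer(probs, b, "*"))
  }
  function(s) vapply(s, function(x) sum(probs[scores >= x]), numeric(1))
}

random_protein <- function(n, alphabet = hepnmnt::AA_ALPHABET) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Tiny annotated-genome fixture written into `dir`: genes described by a
# data.frame (contig, start1, end1, strand, protein_id, genome_id) plus
# named protein sequences. Returns the two file paths.
write_toy_genome <- function(dir, genes, proteins) {
  gff <- file.path(dir, "toy.gff3")
  faa <- file.path(dir, "toy.faa")
  lines <- c("##gff-version 3", sprintf(
    "%s\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;genome_id=%s",
    genes$contig, genes$start1, genes$end1, genes$strand,
    genes$protein_id, genes$genome_id))
  writeLines(lines, gff)
  writeLines(as.vector(rbind(paste0(">", names(proteins)), proteins)), faa)
  list(gff3 = gff, fasta = faa)
}

# Independent re-statement of the greedy assignment rules (nearest rank
# first, ties toward the upstream antitoxin, then leftmost), written
# directly over the candidate edge list.
reference_greedy_pairs <- function(edges, ranks) {
  if (nrow(edges) == 0L) {
    return(data.frame(toxin_id = character(0), antitoxin_id = character(0)))
  }
  dist <- abs(ranks[edges$toxin_id] - ranks[edges$antitoxin_id])
  upstream <- ranks[edges$antitoxin_id] < ranks[edges$toxin_id]
  edges <- edges[order(dist, !upstream, ranks[edges$toxin_id],
                       ranks[edges$antitoxin_id]), , drop = FALSE]
  chosen <- list(); used <- character(0)
  for (i in seq_len(nrow(edges))) {
    if (!(edges$toxin_id[i] %in% used) &&
        !(edges$antitoxin_id[i] %in% used)) {
      chosen[[length(chosen) + 1L]] <- edges[i, ]
      used <- c(used, edges$toxin_id[i], edges$antitoxin_id[i])
    }
  }
  out <- do.call(rbind, chosen)
  out[order(ranks[out$toxin_id]), , drop = FALSE]
}
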