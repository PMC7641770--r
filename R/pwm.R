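# Position frequency / weight matrices and FIMO-style PWM scanning with
# exact p-values computed by dynamic programming over integer-discretized
# scores (scores scaled by 1000 and rounded).

.PWM_SCALE <- 1000

#' Build a position frequency matrix from matched sites
#'
#' @param sites Character vector of equal-length site strings, canonical
#'   residues only.
#' @return Object of class \code{"pfm"}: list with \code{counts} (20 x k
#'   integer matrix, rows named by residue, columns by position),
#'   \code{width}, and \code{n_sites}. Every column sums to
#'   \code{n_sites}.
#' @examples
#' build_pfm(c("RAY", "RAY", "RCY"))
#' @export
build_pfm <- function(sites) {
  if (length(sites) == 0L) stop("need at least one site")
  w <- unique(nchar(sites))
  if (length(w) != 1L) stop("sites have unequal lengths: ",
                            paste(w, collapse = ", "))
  mat <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  bad <- setdiff(unique(as.vector(mat)), AA_ALPHABET)
  if (length(bad)) stop("non-canonical residue(s) in sites: ",
                        paste(bad, collapse = ", "))
  counts <- vapply(seq_len(w), function(i) {
    tab <- table(factor(mat[, i], levels = AA_ALPHABET))
    as.integer(tab)
  }, integer(20))
  counts <- matrix(counts, nrow = 20,
                   dimnames = list(AA_ALPHABET, paste0("p", seq_len(w))))
  structure(list(counts = counts, width = w, n_sites = length(sites)),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("pfm: width", x$width, "from", x$n_sites, "sites\n")
  invisible(x)
}

# Pseudocounted column frequencies: (counts + pc * b) / (n + pc),
# background-weighted pseudocount as in standard PWM construction.
.pfm_frequencies <- function(pfm, background, pseudocount) {
  b <- .check_background(background)
  (pfm$counts + pseudocount * b) / (pfm$n_sites + pseudocount)
}

.check_background <- function(background) {
  stopifnot(length(background) == 20)
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  if (is.null(names(background))) names(background) <- AA_ALPHABET
  background <- background[AA_ALPHABET]
  if (anyNA(background)) stop("background must be named by canonical residues")
  background
}

#' Per-column information content of a PFM (bits)
#'
#' Kullback-Leibler information of each column relative to the background:
#' \eqn{\sum_a f_{ia} \log_2(f_{ia}/b_a)}, with \eqn{0 \log 0 = 0}.
#' Under a uniform background this is the usual sequence-logo column
#' height, at most \eqn{\log_2 20 \approx 4.32} bits.
#'
#' @param pfm A \code{pfm}.
#' @param background Length-20 probability vector (default uniform).
#' @param pseudocount Non-negative pseudocount added (background-weighted)
#'   to the counts; 0 uses raw frequencies.
#' @return Numeric vector, one value per column.
#' @export
information_content <- function(pfm, background = uniform_background(),
                                pseudocount = 0) {
  stopifnot(inherits(pfm, "pfm"), pseudocount >= 0)
  b <- .check_background(background)
  f <- .pfm_frequencies(pfm, b, pseudocount)
  if (any(f > 0 & b[row(f)] == 0)) stop("zero background with nonzero frequency")
  contrib <- ifelse(f > 0, f * log2(f / b), 0)
  colSums(contrib)
}

#' Convert a PFM to a log-odds position weight matrix
#'
#' \code{log_odds[a, i] = log2(((counts[a,i] + pc*b_a)/(n + pc)) / b_a)},
#' base 2.
#'
#' @inheritParams information_content
#' @param pseudocount Positive pseudocount (may be 0 only when all counts
#'   are nonzero).
#' @return Object of class \code{"pwm"}: list with \code{log_odds} (20 x k
#'   matrix), \code{width}, \code{background}.
#' @export
pwm_from_pfm <- function(pfm, background = uniform_background(),
                         pseudocount = 0.1) {
  stopifnot(inherits(pfm, "pfm"))
  b <- .check_background(background)
  if (pseudocount <= 0 && any(pfm$counts == 0)) {
    stop("pseudocount must be > 0 when the PFM has zero counts")
  }
  if (any(b <= 0)) stop("background entries must be > 0")
  f <- .pfm_frequencies(pfm, b, pseudocount)
  structure(list(log_odds = log2(f / b), width = pfm$width, background = b),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm: width", x$width, "| score range per column [",
      paste(sprintf("%.2f", range(x$log_odds)), collapse = ", "), "]\n")
  invisible(x)
}

# Integer-discretized score matrix (scores * 1000, rounded).
.pwm_int_scores <- function(pwm) {
  s <- round(pwm$log_odds * .PWM_SCALE)
  storage.mode(s) <- "integer"
  s
}

#' Exact score distribution of a PWM under its background
#'
#' Dynamic-programming convolution over integer-discretized column scores
#' (granularity 1/1000 bit): returns the exact null distribution of the
#' total score of a random width-k sequence drawn i.i.d. from the
#' background.
#'
#' @param pwm A \code{pwm}.
#' @return List with \code{score_int} (sorted integer scores) and
#'   \code{prob}; plus \code{pvalue}, a step function giving
#'   P(score >= s) for an integer score s.
#' @export
pwm_score_distribution <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  si <- .pwm_int_scores(pwm)
  b <- pwm$background
  lo <- sum(apply(si, 2, min))
  hi <- sum(apply(si, 2, max))
  # dist[j] = P(total integer score == lo_partial + j - 1)
  dist <- 1
  cur_lo <- 0L
  for (i in seq_len(ncol(si))) {
    col <- si[, i]
    new_lo <- cur_lo + min(col)
    new_len <- (cur_lo + max(col)) - new_lo + length(dist)
    new <- numeric(new_len)
    for (a in seq_len(20)) {
      off <- (cur_lo + col[a]) - new_lo
      idx <- seq_along(dist) + off
      new[idx] <- new[idx] + dist * b[a]
    }
    dist <- new
    cur_lo <- new_lo
  }
  score_int <- seq.int(lo, hi)
  keep <- dist > 0
  score_int <- score_int[keep]
  prob <- dist[keep]
  tail_prob <- pmin(rev(cumsum(rev(prob))), 1)  # guard accumulation round-off
  pvalue <- function(s) {
    # P(score >= s); 1 below the minimum, 0 above the maximum
    i <- findInterval(s - 1, score_int) + 1L
    ifelse(i > length(score_int), 0, tail_prob[pmin(i, length(score_int))])
  }
  list(score_int = score_int, prob = prob, pvalue = pvalue)
}

#' Scan a sequence with a PWM, reporting exact p-values
#'
#' Scores every offset; the reported score is the integer-discretized
#' score divided by 1000, and its p-value is the exact probability under
#' the i.i.d. background model that a random width-k sequence scores at
#' least as high (computed by \code{\link{pwm_score_distribution}}).
#' Windows containing non-canonical residues are skipped.
#'
#' @param sequence Protein string.
#' @param pwm A \code{pwm}.
#' @param p_threshold Report hits with p-value <= this (in (0, 1]).
#' @param protein_id Optional id copied into the hit table.
#' @return Hit data.frame as in \code{\link{scan_pattern}}, with
#'   \code{score} and \code{p_value} filled.
#' @export
pwm_scan <- function(sequence, pwm, p_threshold = 1e-4,
                     protein_id = NA_character_) {
  stopifnot(inherits(pwm, "pwm"))
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      p_threshold <= 0 || p_threshold > 1) {
    stop("p_threshold must be in (0, 1]")
  }
  if (is(sequence, "AAString")) sequence <- as.character(sequence)
  k <- pwm$width
  n <- nchar(sequence)
  empty <- data.frame(protein_id = character(0), pattern_id = character(0),
                      start = integer(0), end = integer(0),
                      matched_seq = character(0), score = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  if (n < k) return(empty)
  si <- .pwm_int_scores(pwm)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  ridx <- match(chars, AA_ALPHABET)  # NA for non-canonical
  n_win <- n - k + 1L
  scores_int <- rep(0L, n_win)
  ok <- rep(TRUE, n_win)
  for (j in seq_len(k)) {
    r <- ridx[j:(j + n_win - 1L)]
    ok <- ok & !is.na(r)
    col <- si[, j]
    scores_int <- scores_int + ifelse(is.na(r), 0L, col[ifelse(is.na(r), 1L, r)])
  }
  dist <- pwm_score_distribution(pwm)
  pvals <- dist$pvalue(scores_int)
  keep <- ok & pvals <= p_threshold
  starts <- which(keep) - 1L
  data.frame(
    protein_id = rep(protein_id, length(starts)),
    pattern_id = rep("pwm", length(starts)),
    start = starts,
    end = starts + k,
    matched_seq = if (length(starts)) substring(sequence, starts + 1L, starts + k)
                  else character(0),
    score = scores_int[keep] / .PWM_SCALE,
    p_value = pvals[keep],
    stringsAsFactors = FALSE
  )
}

#' Residue composition of a sequence set
#'
#' Empirical canonical-residue frequencies, the default scanning
#' background for real data.
#' @param proteins FASTA path, AAStringSet, or named character vector.
#' @return Named length-20 probability vector.
#' @export
sequence_background <- function(proteins) {
  seqs <- .as_protein_vector(proteins)
  chars <- unlist(strsplit(paste(seqs, collapse = ""), "", fixed = TRUE))
  tab <- table(factor(chars[chars %in% AA_ALPHABET], levels = AA_ALPHABET))
  if (sum(tab) == 0) return(uniform_background())
  as.numeric(tab) / sum(tab) -> f
  stats::setNames(f, AA_ALPHABET)
}

#' Write a PFM and its information content to TSV
#'
#' Emits the 20 x k count matrix followed by a per-column bits row.
#' @param pfm A \code{pfm}.
#' @param path Output file.
#' @inheritParams information_content
#' @return \code{path}, invisibly.
#' @export
write_pfm_tsv <- function(pfm, path, background = uniform_background(),
                          pseudocount = 0) {
  ic <- information_content(pfm, background, pseudocount)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# position frequency matrix; rows = residues, ",
                    "columns = motif positions; n_sites = ", pfm$n_sites), con)
  df <- data.frame(residue = rownames(pfm$counts), pfm$counts,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste(c("bits", sprintf("%.4f", ic)), collapse = "\t"), con)
  invisible(path)
}
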