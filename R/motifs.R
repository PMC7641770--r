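# Gapped protein motif patterns: parsing, canonical text form, and scanning.
#
# Grammar (PROSITE-flavoured, compact):
#   a single uppercase canonical residue letter  -> that residue only
#   X                                            -> any residue
#   [ACD]                                        -> any residue in the set
#   an integer suffix, e.g. X4                   -> fixed repeat count
#   a (min,max) suffix, e.g. X(4,6)              -> repeat range
# Examples: "RX4HXY" (toxin signature), "GSX10DXD" (antitoxin signature),
# "RX(4,6)H" (general HEPN RNase motif).

#' Parse a motif string into a gapped pattern
#'
#' Converts compact motif text such as \code{"RX4HXY"}, \code{"GSX10DXD"}
#' or \code{"RX(4,6)H"} into a structured gapped pattern: an ordered list
#' of position specs, each holding a set of allowed residues (or ANY) and
#' a repeat range.
#'
#' @param pattern_text Motif string. Uppercase one-letter residue codes;
#'   \code{X} matches any residue; \code{[ACD]} a residue set; an integer
#'   or \code{(min,max)} suffix repeats the preceding element.
#' @param pattern_id Label stored on the pattern; defaults to the
#'   canonical text form.
#' @return An object of class \code{"gapped_pattern"}: list with
#'   \code{pattern_id} and \code{positions}, each position a list with
#'   \code{residues} (character vector, or \code{"ANY"}), \code{min_repeat}
#'   and \code{max_repeat}.
#' @examples
#' p <- parse_pattern("RX4HXY")
#' pattern_min_length(p)  # 8
#' @export
parse_pattern <- function(pattern_text, pattern_id = NULL) {
  if (!is.character(pattern_text) || length(pattern_text) != 1L ||
      is.na(pattern_text) || nchar(pattern_text) == 0L) {
    stop("pattern_text must be a single non-empty string")
  }
  chars <- strsplit(pattern_text, "", fixed = TRUE)[[1]]
  i <- 1L
  n <- length(chars)
  positions <- list()
  while (i <= n) {
    ch <- chars[i]
    if (ch == "X") {
      residues <- "ANY"
      i <- i + 1L
    } else if (ch == "[") {
      close <- NULL
      for (j in seq(i + 1L, length.out = n - i)) {
        if (chars[j] == "]") { close <- j; break }
      }
      if (is.null(close) || close == i + 1L) {
        stop("malformed residue set starting at '",
             paste(chars[i:min(n, i + 4L)], collapse = ""), "'")
      }
      residues <- chars[(i + 1L):(close - 1L)]
      bad <- setdiff(residues, AA_ALPHABET)
      if (length(bad)) {
        stop("unknown residue letter '", bad[1], "' in set")
      }
      residues <- sort(unique(residues))
      i <- close + 1L
    } else if (ch %in% AA_ALPHABET) {
      residues <- ch
      i <- i + 1L
    } else {
      stop("unknown residue letter '", ch, "' at position ", i)
    }
    # optional repeat suffix: integer or (min,max)
    min_rep <- 1L
    max_rep <- 1L
    if (i <= n && grepl("^[0-9]$", chars[i])) {
      j <- i
      while (j <= n && grepl("^[0-9]$", chars[j])) j <- j + 1L
      rep_n <- as.integer(paste(chars[i:(j - 1L)], collapse = ""))
      if (rep_n < 1L) stop("repeat of 0 in '", pattern_text, "'")
      min_rep <- max_rep <- rep_n
      i <- j
    } else if (i <= n && chars[i] == "(") {
      close <- NULL
      for (j in seq(i + 1L, length.out = n - i)) {
        if (chars[j] == ")") { close <- j; break }
      }
      tok <- paste(chars[i:ifelse(is.null(close), n, close)], collapse = "")
      if (is.null(close) ||
          !grepl("^\\(([0-9]+),([0-9]+)\\)$", tok)) {
        stop("malformed range '", tok, "'")
      }
      parts <- as.integer(strsplit(gsub("[()]", "", tok), ",")[[1]])
      if (parts[1] < 1L) stop("repeat of 0 in range '", tok, "'")
      if (parts[2] < parts[1]) stop("malformed range '", tok, "': max < min")
      min_rep <- parts[1]
      max_rep <- parts[2]
      i <- close + 1L
    }
    positions[[length(positions) + 1L]] <-
      list(residues = residues, min_repeat = min_rep, max_repeat = max_rep)
  }
  pat <- structure(list(pattern_id = pattern_id, positions = positions),
                   class = "gapped_pattern")
  if (is.null(pattern_id)) pat$pattern_id <- pattern_to_string(pat)
  pat
}

#' Canonical text form of a gapped pattern
#'
#' Inverse of \code{\link{parse_pattern}}: re-parsing the returned string
#' yields an equivalent pattern.
#' @param pattern A \code{gapped_pattern}.
#' @return A single string.
#' @export
pattern_to_string <- function(pattern) {
  stopifnot(inherits(pattern, "gapped_pattern"))
  vapply(pattern$positions, function(p) {
    base <- if (identical(p$residues, "ANY")) {
      "X"
    } else if (length(p$residues) == 1L) {
      p$residues
    } else {
      paste0("[", paste(p$residues, collapse = ""), "]")
    }
    suf <- if (p$min_repeat == p$max_repeat) {
      if (p$min_repeat == 1L) "" else as.character(p$min_repeat)
    } else {
      sprintf("(%d,%d)", p$min_repeat, p$max_repeat)
    }
    paste0(base, suf)
  }, character(1)) |> paste(collapse = "")
}

#' Minimum and maximum match length of a pattern
#' @param pattern A \code{gapped_pattern}.
#' @return Integer.
#' @export
pattern_min_length <- function(pattern) {
  sum(vapply(pattern$positions, function(p) p$min_repeat, integer(1)))
}

#' @rdname pattern_min_length
#' @export
pattern_max_length <- function(pattern) {
  sum(vapply(pattern$positions, function(p) p$max_repeat, integer(1)))
}

#' @export
print.gapped_pattern <- function(x, ...) {
  cat("gapped_pattern <", x$pattern_id, ">: ", pattern_to_string(x),
      " (match length ", pattern_min_length(x),
      if (pattern_max_length(x) > pattern_min_length(x))
        paste0("-", pattern_max_length(x)) else "",
      ")\n", sep = "")
  invisible(x)
}

# Expand the repeat ranges of a pattern into every fixed-repeat
# combination; returns a list of integer vectors (one repeat count per
# position spec). Errors out on combinatorial explosion.
.pattern_repeat_combos <- function(pattern, max_combos = 10000L) {
  ranges <- lapply(pattern$positions,
                   function(p) seq.int(p$min_repeat, p$max_repeat))
  n_combo <- prod(vapply(ranges, length, integer(1)))
  if (n_combo > max_combos) {
    stop("pattern expands to ", n_combo, " repeat combinations (limit ",
         max_combos, ")")
  }
  grid <- expand.grid(rev(ranges), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(ranges)), drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}

# Character class for one position spec in a perl regex. ANY positions
# also match ambiguity codes (conservative: an ambiguous residue never
# satisfies a specific-residue position but cannot break a gap position).
.position_regex <- function(residues) {
  if (identical(residues, "ANY")) "[A-Z]"
  else paste0("[", paste(residues, collapse = ""), "]")
}

#' Scan a protein sequence with a gapped pattern
#'
#' Reports every distinct \code{(start, end)} window that satisfies the
#' pattern, including overlapping hits; for ranged repeats each distinct
#' window is reported once. Coordinates are 0-based half-open.
#'
#' Ambiguity codes (B, Z, J, U, O, X) in the sequence match ANY positions
#' but never a specific-residue position.
#'
#' @param sequence A protein string (one-letter codes).
#' @param pattern A \code{gapped_pattern} from \code{\link{parse_pattern}}.
#' @param protein_id Optional id copied into the hit table.
#' @return A data.frame of motif hits with columns \code{protein_id},
#'   \code{pattern_id}, \code{start}, \code{end}, \code{matched_seq},
#'   \code{score}, \code{p_value} (the last two \code{NA} in exact mode),
#'   sorted by \code{start} then \code{end}.
#' @examples
#' scan_pattern("MRAAAAHAYK", parse_pattern("RX4HXY"))
#' @export
scan_pattern <- function(sequence, pattern, protein_id = NA_character_) {
  stopifnot(inherits(pattern, "gapped_pattern"))
  if (is(sequence, "AAString")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  starts <- integer(0)
  ends <- integer(0)
  n <- nchar(sequence)
  if (!is.na(sequence) && n >= pattern_min_length(pattern)) {
    for (combo in .pattern_repeat_combos(pattern)) {
      pieces <- mapply(function(p, k) {
        if (k == 0L) return("")
        paste0(.position_regex(p$residues),
               if (k > 1L) paste0("{", k, "}") else "")
      }, pattern$positions, combo)
      width <- sum(combo)
      # lookahead finds overlapping matches
      rx <- paste0("(?=", paste(pieces, collapse = ""), ")")
      m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
      if (m[1] != -1L) {
        starts <- c(starts, as.integer(m) - 1L)  # 0-based
        ends <- c(ends, as.integer(m) - 1L + width)
      }
    }
  }
  if (length(starts)) {
    keep <- !duplicated(paste(starts, ends))
    starts <- starts[keep]; ends <- ends[keep]
    ord <- order(starts, ends)
    starts <- starts[ord]; ends <- ends[ord]
  }
  data.frame(
    protein_id = rep(protein_id, length(starts)),
    pattern_id = rep(pattern$pattern_id, length(starts)),
    start = starts,
    end = ends,
    matched_seq = if (length(starts)) substring(sequence, starts + 1L, ends)
                  else character(0),
    score = rep(NA_real_, length(starts)),
    p_value = rep(NA_real_, length(starts)),
    stringsAsFactors = FALSE
  )
}

#' Scan a set of proteins with a gapped pattern
#'
#' @param proteins An \code{AAStringSet}, a named character vector, or a
#'   path to a protein FASTA file (record id up to the first whitespace).
#' @param pattern A \code{gapped_pattern} or motif string.
#' @return Combined hit data.frame (see \code{\link{scan_pattern}}).
#' @export
scan_proteins <- function(proteins, pattern) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  seqs <- .as_protein_vector(proteins)
  if (length(seqs) == 0L) return(scan_pattern("", pattern))
  hits <- lapply(names(seqs), function(id) {
    scan_pattern(seqs[[id]], pattern, protein_id = id)
  })
  do.call(rbind, c(hits, list(make.row.names = FALSE)))
}

# Normalise FASTA path / AAStringSet / character vector to a named
# character vector of sequences.
.as_protein_vector <- function(proteins) {
  if (is.character(proteins) && length(proteins) == 1L &&
      file.exists(proteins)) {
    proteins <- Biostrings::readAAStringSet(proteins)
  }
  if (is(proteins, "AAStringSet")) {
    ids <- sub("\\s.*$", "", names(proteins))
    seqs <- as.character(proteins)
    names(seqs) <- ids
  } else if (is.character(proteins)) {
    if (is.null(names(proteins))) stop("protein vector must be named")
    seqs <- proteins
  } else {
    stop("unsupported protein input of class ", class(proteins)[1])
  }
  if (anyDuplicated(names(seqs))) stop("duplicate protein ids in input")
  seqs
}

#' Write motif hits to TSV
#'
#' Columns: protein_id, pattern_id, start (0-based), end (exclusive),
#' matched_seq, score, p_value (empty in exact-pattern mode).
#' @param hits Hit data.frame.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# motif hits; start 0-based, end exclusive; ",
                    "score/p_value empty for exact-pattern hits"), con)
  utils::write.table(hits, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
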