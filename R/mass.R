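# Molecular masses from elemental composition, PDE cleavage-product
# identification, and modification-stoichiometry inference from
# intact-protein mass shifts.

#' Parse a molecular formula
#'
#' @param formula String such as \code{"C10H14N5O7P"}; element symbols
#'   with optional counts.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula)) {
    stop("malformed formula '", formula, "'")
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(sub("^[A-Za-z]+", "", toks))
  ct[is.na(ct)] <- 1L
  counts <- tapply(ct, el, sum)
  stats::setNames(as.integer(counts), names(counts))
}

.composition_mass <- function(composition, kind) {
  if (is.character(composition) && length(composition) == 1L) {
    composition <- parse_formula(composition)
  }
  if (length(composition) == 0L || sum(composition) == 0L) {
    stop("empty composition")
  }
  if (any(composition < 0)) stop("negative element count")
  idx <- match(names(composition), .ELEMENT_MASS$element)
  if (anyNA(idx)) {
    stop("unknown element(s): ",
         paste(names(composition)[is.na(idx)], collapse = ", "))
  }
  sum(composition * .ELEMENT_MASS[[kind]][idx])
}

#' Molecular mass from elemental composition
#'
#' @param composition Named integer vector (element -> count) or a
#'   formula string such as \code{"C10H14N5O7P"}.
#' @return Mass in Da.
#' @examples
#' average_mass("H2O")            # 18.015
#' average_mass("C10H14N5O7P")    # free 5'-AMP, 347.22
#' @export
average_mass <- function(composition) .composition_mass(composition, "avg")

#' @rdname average_mass
#' @export
monoisotopic_mass <- function(composition) .composition_mass(composition, "mono")

#' Average mass of an intact protein
#'
#' Sum of residue average masses plus one water.
#' @param sequence Protein string, canonical residues only.
#' @param kind \code{"avg"} (default) or \code{"mono"}.
#' @return Mass in Da.
#' @examples
#' protein_average_mass("G")   # free glycine, 75.07
#' @export
protein_average_mass <- function(sequence, kind = c("avg", "mono")) {
  kind <- match.arg(kind)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad)) stop("non-canonical residue(s): ",
                        paste(bad, collapse = ", "))
  fn <- if (kind == "avg") average_mass else monoisotopic_mass
  res <- vapply(AA_ALPHABET, function(a) fn(.AA_COMPOSITION[[a]]), numeric(1))
  water <- fn(c(H = 2, O = 1))
  sum(res[chars]) + water
}

#' Residue mass of one AMP moiety
#'
#' Mass added per adenylyl group on the protein: free 5'-AMP
#' (C10H14N5O7P) minus one water lost in phosphodiester condensation,
#' i.e. C10H12N5O6P. Rounds to 329 Da at integer precision.
#'
#' @param kind \code{"avg"} (default, ~329.21) or \code{"mono"} (~329.05).
#' @return Mass in Da.
#' @export
amp_residue_mass <- function(kind = c("avg", "mono")) {
  kind <- match.arg(kind)
  fn <- if (kind == "avg") average_mass else monoisotopic_mass
  fn("C10H12N5O6P")
}

#' Built-in small-molecule candidate table
#'
#' The 5'-ribonucleoside monophosphates plus adenosine, with average
#' masses computed from their molecular formulas; the default table for
#' identifying PDE cleavage products.
#' @return data.frame with columns \code{name}, \code{formula},
#'   \code{mass_avg}.
#' @export
nucleotide_table <- function() {
  path <- system.file("extdata", "nucleotides.tsv", package = "hepnmnt")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Built-in modification (adduct) candidate table
#'
#' Residue masses (free molecule minus one water where condensation
#' applies) of common covalent modifications: AMP, phospho, acetyl.
#' @return data.frame with columns \code{name}, \code{formula},
#'   \code{residue_mass_avg}, \code{residue_mass_mono}.
#' @export
mod_candidate_table <- function() {
  path <- system.file("extdata", "mod_candidates.tsv", package = "hepnmnt")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Identify a small molecule by mass
#'
#' Matches an observed mass against a candidate table within a tolerance.
#' Returns \code{"ambiguous"} (listing all ties) whenever two or more
#' candidates fall within tolerance - it never silently picks one.
#'
#' @param observed_mass Observed mass in Da.
#' @param candidates data.frame with columns \code{name} and a mass
#'   column (\code{mass_avg}, \code{mass} or \code{residue_mass_avg});
#'   defaults to \code{\link{nucleotide_table}}.
#' @param tolerance Match tolerance in Da (> 0); default 0.5.
#' @return List of class \code{"mass_id"} with \code{status} one of
#'   \code{"match"}, \code{"no_match"}, \code{"ambiguous"};
#'   \code{matches}: data.frame of candidates within tolerance with
#'   signed \code{delta} (observed - candidate).
#' @examples
#' identify_small_molecule(347.6)  # the PDE cleavage product -> 5'-AMP
#' @export
identify_small_molecule <- function(observed_mass,
                                    candidates = nucleotide_table(),
                                    tolerance = 0.5) {
  stopifnot(is.numeric(observed_mass), length(observed_mass) == 1L,
            tolerance > 0)
  if (is.null(candidates) || nrow(candidates) == 0L) {
    stop("empty candidate table")
  }
  mass_col <- intersect(c("mass_avg", "mass", "residue_mass_avg"),
                        names(candidates))[1]
  if (is.na(mass_col)) stop("candidate table has no mass column")
  delta <- observed_mass - candidates[[mass_col]]
  hit <- abs(delta) <= tolerance
  matches <- data.frame(name = candidates$name[hit],
                        mass = candidates[[mass_col]][hit],
                        delta = delta[hit], stringsAsFactors = FALSE)
  matches <- matches[order(abs(matches$delta)), , drop = FALSE]
  status <- if (nrow(matches) == 0L) "no_match"
            else if (nrow(matches) == 1L) "match" else "ambiguous"
  structure(list(status = status, observed_mass = observed_mass,
                 tolerance = tolerance, matches = matches),
            class = "mass_id")
}

#' @export
print.mass_id <- function(x, ...) {
  cat("mass_id:", x$status, "for", x$observed_mass, "Da (tol",
      x$tolerance, "Da)\n")
  if (nrow(x$matches)) print(x$matches, row.names = FALSE)
  invisible(x)
}

#' Infer modification stoichiometry from a mass shift
#'
#' Exhaustively enumerates non-negative count vectors over the candidate
#' modifications with total count at most \code{max_total} and returns
#' the one explaining the observed shift within tolerance, preferring
#' (1) the smallest total number of additions (parsimony), then (2) the
#' smallest absolute residual, then (3) higher counts on
#' alphabetically-earlier candidate names (deterministic tie-break).
#'
#' @param mass_shift Observed mass difference in Da (modified minus
#'   unmodified).
#' @param candidates data.frame with columns \code{name} and
#'   \code{residue_mass_avg} (or \code{residue_mass_mono} with
#'   \code{kind = "mono"}); defaults to \code{\link{mod_candidate_table}}.
#' @param tolerance Acceptance tolerance in Da (> 0); default 1.5 for
#'   intact-protein shifts.
#' @param max_total Maximum total number of moieties (>= 1).
#' @param kind \code{"avg"} or \code{"mono"} residue masses.
#' @return List of class \code{"stoichiometry"} with \code{counts}
#'   (named integer vector), \code{predicted_shift}, \code{residual}
#'   (observed - predicted), or \code{NULL} if no combination fits.
#' @examples
#' infer_stoichiometry(987.45)  # -> three AMPs
#' @export
infer_stoichiometry <- function(mass_shift,
                                candidates = mod_candidate_table(),
                                tolerance = 1.5, max_total = 10L,
                                kind = c("avg", "mono")) {
  kind <- match.arg(kind)
  stopifnot(tolerance > 0, max_total >= 1)
  mass_col <- if (kind == "avg") "residue_mass_avg" else "residue_mass_mono"
  if (!mass_col %in% names(candidates)) {
    mass_col <- intersect(c("mass", "residue_mass"), names(candidates))[1]
    if (is.na(mass_col)) stop("candidate table has no residue mass column")
  }
  ord <- order(candidates$name)
  nm <- candidates$name[ord]
  ms <- candidates[[mass_col]][ord]
  k <- length(nm)
  # enumerate all count vectors with sum <= max_total
  grid <- expand.grid(rep(list(0:max_total), k), KEEP.OUT.ATTRS = FALSE)
  grid <- as.matrix(grid[rowSums(grid) <= max_total, , drop = FALSE])
  predicted <- as.numeric(grid %*% ms)
  residual <- mass_shift - predicted
  feasible <- abs(residual) <= tolerance
  if (!any(feasible)) return(NULL)
  g <- grid[feasible, , drop = FALSE]
  res <- residual[feasible]
  tot <- rowSums(g)
  # lexicographic preference for earlier-named candidates on ties
  ord2 <- do.call(order, c(list(tot, abs(res)),
                           lapply(seq_len(k), function(j) -g[, j])))
  best <- ord2[1]
  counts <- stats::setNames(as.integer(g[best, ]), nm)
  structure(list(counts = counts[counts > 0],
                 predicted_shift = sum(g[best, ] * ms),
                 residual = res[best],
                 observed_shift = mass_shift,
                 tolerance = tolerance),
            class = "stoichiometry")
}

#' @export
print.stoichiometry <- function(x, ...) {
  lab <- if (length(x$counts) == 0L) "no modification" else
    paste(sprintf("%d x %s", x$counts, names(x$counts)), collapse = " + ")
  cat(sprintf("stoichiometry: %s (predicted %.2f Da, residual %+.2f Da)\n",
              lab, x$predicted_shift, x$residual))
  invisible(x)
}
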