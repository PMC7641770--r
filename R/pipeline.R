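# End-to-end orchestration: mine a genome set for HEPN/MNT pairs, write
# the pair and census tables, and evaluate against a ground-truth
# manifest when one is available.

#' Mine a genome set for HEPN/MNT toxin-antitoxin pairs
#'
#' Runs the full discovery pipeline: load annotation and proteins, scan
#' every protein with the toxin (RX4HXY) and antitoxin (GSX10DXD)
#' signature patterns, admit PF05168-family proteins as additional
#' (motif-free, Class II) toxin candidates, pair neighboring candidate
#' genes, classify pairs into Class I/II, and compute the per-taxon
#' census. Writes \code{pairs.tsv} and \code{census.tsv} under
#' \code{out_dir} when given.
#'
#' @param fasta_path Protein FASTA.
#' @param gff3_path Genome annotation GFF3.
#' @param domains_path Domain-annotation TSV (protein_id, family, clan).
#' @param taxa_path Genome-to-taxon TSV.
#' @param out_dir Optional output directory for the TSVs.
#' @param toxin_pattern,antitoxin_pattern Motif strings (defaults are
#'   the two signature motifs).
#' @param adjacency A \code{\link{pair_config}}.
#' @return List of class \code{"run_report"}: \code{pairs} and
#'   \code{census} data.frames, a \code{counts} block (records per
#'   stage), the \code{config} echo, and file \code{paths} when written.
#' @export
run_mine <- function(fasta_path, gff3_path, domains_path, taxa_path,
                     out_dir = NULL,
                     toxin_pattern = TOXIN_MOTIF,
                     antitoxin_pattern = ANTITOXIN_MOTIF,
                     adjacency = pair_config()) {
  t0 <- Sys.time()
  genome <- .stage("read_annotation", read_annotation(gff3_path, fasta_path))
  domains <- .stage("read_domains", read_domains_tsv(domains_path))
  taxa <- .stage("read_taxa", read_taxa_tsv(taxa_path))
  missing_taxa <- setdiff(unique(genome$genes$genome_id), taxa$genome_id)
  if (length(missing_taxa)) {
    stop("run_mine/read_taxa: genome(s) missing from taxa table: ",
         paste(utils::head(missing_taxa, 5), collapse = ", "))
  }
  tox_hits <- .stage("scan_toxin",
                     scan_proteins(genome$proteins, toxin_pattern))
  anti_hits <- .stage("scan_antitoxin",
                      scan_proteins(genome$proteins, antitoxin_pattern))
  extra <- unique(domains$protein_id[domains$family == CLASS2_TOXIN_FAMILY])
  extra <- intersect(extra, genome$genes$protein_id)
  pairs <- .stage("find_candidate_pairs",
                  find_candidate_pairs(genome, tox_hits, anti_hits,
                                       adjacency = adjacency,
                                       extra_toxin_ids = extra))
  pairs <- .stage("classify_pairs", classify_pairs(pairs, domains))
  cens <- .stage("census",
                 census(pairs[pairs$class_label != "unclassified", ,
                              drop = FALSE], taxa))
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(pairs = file.path(out_dir, "pairs.tsv"),
                  census = file.path(out_dir, "census.tsv"))
    write_table_tsv(pairs, paths$pairs, paste(
      "candidate TA pairs; ranks 0-based along contig;",
      "intergenic_bp negative = overlap"))
    write_table_tsv(cens, paths$census,
                    "per-taxon census of classified pairs")
  }
  structure(list(
    pairs = pairs,
    census = cens,
    counts = list(n_genomes = length(unique(genome$genes$genome_id)),
                  n_genes = nrow(genome$genes),
                  n_toxin_hits = nrow(tox_hits),
                  n_antitoxin_hits = nrow(anti_hits),
                  n_extra_toxin_candidates = length(extra),
                  n_pairs = nrow(pairs),
                  n_class1 = sum(pairs$class_label == "ClassI"),
                  n_class2 = sum(pairs$class_label == "ClassII")),
    config = list(toxin_pattern = toxin_pattern,
                  antitoxin_pattern = antitoxin_pattern,
                  adjacency = unclass(adjacency),
                  version = as.character(utils::packageVersion("hepnmnt"))),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    paths = paths
  ), class = "run_report")
}

# Run a pipeline stage, prefixing its name onto any error.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("run_mine/", name, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", x$counts$n_genomes, "genomes,", x$counts$n_genes,
      "genes;", x$counts$n_pairs, "pairs (",
      x$counts$n_class1, "Class I,", x$counts$n_class2, "Class II )\n")
  invisible(x)
}

#' Evaluate mined pairs against a ground-truth manifest
#'
#' A planted pair counts as recovered when a reported pair has the same
#' unordered protein-id pair and the same class label. Sensitivity =
#' recovered / planted; precision = recovered / reported.
#'
#' @param pairs Classified pair data.frame, or a \code{pairs.tsv} path.
#' @param manifest Manifest list from \code{\link{generate_genomes}} /
#'   \code{\link{read_truth_manifest}}, or a \code{truth.json} path.
#' @return List: \code{sensitivity}, \code{precision}, \code{n_planted},
#'   \code{n_reported}, \code{n_recovered}, and a \code{per_class}
#'   data.frame (planted, reported, recovered per class).
#' @export
evaluate <- function(pairs, manifest) {
  if (is.character(pairs)) {
    pairs <- utils::read.delim(pairs, comment.char = "#",
                               stringsAsFactors = FALSE)
  }
  if (is.character(manifest)) manifest <- read_truth_manifest(manifest)
  truth <- manifest$pairs
  key <- function(a, b, cl) {
    paste(pmin(a, b), pmax(a, b), cl, sep = "|")
  }
  truth_keys <- key(truth$toxin_id, truth$antitoxin_id, truth$class_label)
  rep_keys <- if (nrow(pairs)) {
    key(pairs$toxin_id, pairs$antitoxin_id, pairs$class_label)
  } else character(0)
  recovered <- intersect(truth_keys, rep_keys)
  per_class <- do.call(rbind, lapply(c("ClassI", "ClassII"), function(cl) {
    tk <- truth_keys[truth$class_label == cl]
    rk <- rep_keys[pairs$class_label == cl]
    data.frame(class_label = cl, planted = length(tk), reported = length(rk),
               recovered = length(intersect(tk, rk)),
               stringsAsFactors = FALSE)
  }))
  list(
    sensitivity = if (length(truth_keys)) length(recovered) / length(truth_keys)
                  else NA_real_,
    precision = if (length(rep_keys)) length(recovered) / length(rep_keys)
                else NA_real_,
    n_planted = length(truth_keys),
    n_reported = length(rep_keys),
    n_recovered = length(recovered),
    per_class = per_class
  )
}
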