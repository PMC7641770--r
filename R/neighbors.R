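# Genome annotation loading, gene-neighborhood toxin-antitoxin pairing,
# Class I/II classification by Pfam family evidence, and the per-taxon
# census.
#
# Coordinates are GFF3 1-based inclusive at I/O and 0-based half-open
# internally. Locus ranks are assigned by ascending start within each
# (genome, contig) and are 0-based.

# Pfam families defining the two classes.
CLASS1_TOXIN_FAMILIES <- c("PF01934", "PF08780")
CLASS2_TOXIN_FAMILY <- "PF05168"
ANTITOXIN_FAMILY <- "PF01909"

#' Pairing (adjacency) configuration
#'
#' "Neighboring genes": same contig, locus-rank distance at most
#' \code{max_rank} (default 1 = immediately adjacent) and intergenic
#' distance at most \code{max_intergenic} bp; strand is ignored by
#' default, matching typical TA operon arrangements.
#'
#' @param max_rank Maximum locus-rank distance (>= 1).
#' @param max_intergenic Maximum intergenic gap in bp (overlapping genes
#'   have negative gaps and always pass).
#' @param require_same_strand Require both genes on one strand.
#' @return List of class \code{"pair_config"}.
#' @export
pair_config <- function(max_rank = 1L, max_intergenic = 500L,
                        require_same_strand = FALSE) {
  stopifnot(max_rank >= 1L)
  structure(list(max_rank = as.integer(max_rank),
                 max_intergenic = as.integer(max_intergenic),
                 require_same_strand = isTRUE(require_same_strand)),
            class = "pair_config")
}

#' Read genome annotation and protein sequences
#'
#' Loads a GFF3 of coding genes plus the matching protein FASTA into a
#' genome model. CDS/gene features must carry an \code{ID} (or
#' \code{protein_id}) attribute naming the FASTA record; an optional
#' \code{genome_id} attribute assigns features to genomes (defaults to
#' the seqid/contig).
#'
#' @param gff3_path GFF3 file.
#' @param fasta_path Protein FASTA file.
#' @return List of class \code{"genome_model"}: \code{genes} data.frame
#'   (genome_id, contig_id, start, end, strand, locus_rank, protein_id;
#'   0-based half-open coordinates), \code{proteins} named character
#'   vector of sequences.
#' @export
read_annotation <- function(gff3_path, fasta_path) {
  .validate_gff3_lines(gff3_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  gr <- gr[gr$type %in% c("CDS", "gene")]
  if (length(gr) == 0L) {
    return(structure(list(
      genes = data.frame(genome_id = character(0), contig_id = character(0),
                         start = integer(0), end = integer(0),
                         strand = character(0), protein_id = character(0),
                         locus_rank = integer(0)),
      proteins = stats::setNames(character(0), character(0))),
      class = "genome_model"))
  }
  meta <- S4Vectors::mcols(gr)
  pid <- if ("protein_id" %in% names(meta)) meta$protein_id else meta$ID
  if (is.null(pid) || anyNA(pid)) {
    stop("GFF3 features need an ID or protein_id attribute")
  }
  genome <- if ("genome_id" %in% names(meta)) as.character(meta$genome_id)
            else as.character(GenomicRanges::seqnames(gr))
  genes <- data.frame(
    genome_id = genome,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    protein_id = as.character(pid),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(genes$protein_id)) {
    stop("duplicate protein ids in GFF3: ",
         paste(unique(genes$protein_id[duplicated(genes$protein_id)]),
               collapse = ", "))
  }
  genes <- genes[order(genes$genome_id, genes$contig_id, genes$start), ]
  genes$locus_rank <- stats::ave(
    genes$start, genes$genome_id, genes$contig_id,
    FUN = function(x) seq_along(x) - 1L)
  rownames(genes) <- NULL
  proteins <- .as_protein_vector(fasta_path)
  missing <- setdiff(genes$protein_id, names(proteins))
  if (length(missing)) {
    stop("GFF3 ids absent from FASTA: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  structure(list(genes = genes, proteins = proteins[genes$protein_id]),
            class = "genome_model")
}

# Cheap structural check so malformed lines are reported with a line
# number before handing off to the rtracklayer parser.
.validate_gff3_lines <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nf != 9L]
  if (length(bad)) {
    stop("malformed GFF3 line ", bad[1], " in ", path,
         " (expected 9 tab-separated fields, got ", nf[which(body == bad[1])],
         ")")
  }
  invisible(TRUE)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(unique(x$genes$genome_id)), "genome(s),",
      nrow(x$genes), "genes\n")
  invisible(x)
}

#' Pair toxin-candidate and antitoxin-candidate neighboring genes
#'
#' Forms every (toxin gene, antitoxin gene) pair on the same contig
#' within the adjacency limits, then assigns greedily so that no gene
#' participates in two pairs: candidates are taken nearest-rank first,
#' ties broken toward the antitoxin lying upstream of the toxin (the
#' canonical TA operon arrangement), then by genomic position. The
#' result is independent of the input order of genes or hits.
#'
#' @param genome A \code{genome_model}.
#' @param toxin_hits,antitoxin_hits Motif-hit data.frames (as from
#'   \code{\link{scan_proteins}}) naming the candidate proteins.
#' @param adjacency A \code{\link{pair_config}}.
#' @param extra_toxin_ids Protein ids admitted as toxin candidates on
#'   non-motif evidence (e.g. PF05168 family membership, whose toxins
#'   lack the RX4HXY motif by definition).
#' @return data.frame of candidate pairs: genome_id, contig_id,
#'   toxin_id, antitoxin_id, toxin_rank, antitoxin_rank, rank_distance,
#'   intergenic_bp, strand_relation, toxin_motif_hits,
#'   antitoxin_motif_hits, class_label (\code{"unclassified"} until
#'   \code{\link{classify_pairs}}).
#' @export
find_candidate_pairs <- function(genome, toxin_hits, antitoxin_hits,
                                 adjacency = pair_config(),
                                 extra_toxin_ids = character()) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(adjacency, "pair_config"))
  genes <- genome$genes
  tox_count <- table(toxin_hits$protein_id)
  anti_count <- table(antitoxin_hits$protein_id)
  toxin_ids <- union(names(tox_count), extra_toxin_ids)
  antitoxin_ids <- names(anti_count)
  unknown <- setdiff(c(toxin_ids, antitoxin_ids), genes$protein_id)
  if (length(unknown)) {
    stop("hit proteins absent from genome model: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  empty <- data.frame(
    genome_id = character(0), contig_id = character(0),
    toxin_id = character(0), antitoxin_id = character(0),
    toxin_rank = integer(0), antitoxin_rank = integer(0),
    rank_distance = integer(0), intergenic_bp = integer(0),
    strand_relation = character(0), toxin_motif_hits = integer(0),
    antitoxin_motif_hits = integer(0), class_label = character(0),
    stringsAsFactors = FALSE)
  if (length(toxin_ids) == 0L || length(antitoxin_ids) == 0L) return(empty)
  tg <- genes[genes$protein_id %in% toxin_ids, , drop = FALSE]
  ag <- genes[genes$protein_id %in% antitoxin_ids, , drop = FALSE]
  cand <- merge(tg, ag, by = c("genome_id", "contig_id"),
                suffixes = c(".t", ".a"))
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[cand$protein_id.t != cand$protein_id.a, , drop = FALSE]
  cand$rank_distance <- abs(cand$locus_rank.t - cand$locus_rank.a)
  cand$intergenic_bp <- pmax(cand$start.t, cand$start.a) -
    pmin(cand$end.t, cand$end.a)
  keep <- cand$rank_distance <= adjacency$max_rank &
    cand$intergenic_bp <= adjacency$max_intergenic
  if (adjacency$require_same_strand) {
    keep <- keep & cand$strand.t == cand$strand.a
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  upstream <- as.integer(cand$start.a < cand$start.t)  # 1 if antitoxin upstream
  cand <- cand[order(cand$rank_distance, -upstream, cand$genome_id,
                     cand$contig_id, cand$locus_rank.t, cand$locus_rank.a), ,
               drop = FALSE]
  used <- character(0)
  take <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    t_id <- cand$protein_id.t[i]; a_id <- cand$protein_id.a[i]
    if (!(t_id %in% used) && !(a_id %in% used)) {
      take[i] <- TRUE
      used <- c(used, t_id, a_id)
    }
  }
  cand <- cand[take, , drop = FALSE]
  out <- data.frame(
    genome_id = cand$genome_id,
    contig_id = cand$contig_id,
    toxin_id = cand$protein_id.t,
    antitoxin_id = cand$protein_id.a,
    toxin_rank = cand$locus_rank.t,
    antitoxin_rank = cand$locus_rank.a,
    rank_distance = cand$rank_distance,
    intergenic_bp = cand$intergenic_bp,
    strand_relation = ifelse(cand$strand.t == cand$strand.a,
                             "same", "opposite"),
    toxin_motif_hits = as.integer(tox_count[cand$protein_id.t]),
    antitoxin_motif_hits = as.integer(anti_count[cand$protein_id.a]),
    class_label = "unclassified",
    stringsAsFactors = FALSE
  )
  out$toxin_motif_hits[is.na(out$toxin_motif_hits)] <- 0L
  out <- out[order(out$genome_id, out$contig_id, out$toxin_rank), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a domain-annotation table
#'
#' TSV with columns protein_id, family, clan (one row per label);
#' proteins may be absent (zero annotations).
#' @param path TSV file.
#' @return data.frame.
#' @export
read_domains_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("protein_id", "family", "clan")
  if (!all(need %in% names(df))) {
    stop("domains TSV needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Classify candidate pairs into Class I / Class II
#'
#' Class I: the toxin belongs to PF01934 or PF08780 and carries at least
#' one RX4HXY hit, and the antitoxin belongs to PF01909 and carries at
#' least one GSX10DXD hit. Class II: the toxin belongs to PF05168 and
#' has no RX4HXY hit, with the same antitoxin requirement. Everything
#' else stays unclassified; a PF05168 toxin that nevertheless carries an
#' RX4HXY hit is flagged (\code{flag_pf05168_with_motif}) rather than
#' assigned to either class.
#'
#' @param pairs data.frame from \code{\link{find_candidate_pairs}}.
#' @param domains Domain-annotation data.frame (protein_id, family, clan).
#' @return \code{pairs} with \code{class_label} filled and a logical
#'   \code{flag_pf05168_with_motif} column.
#' @export
classify_pairs <- function(pairs, domains) {
  fam_of <- split(domains$family, domains$protein_id)
  get_fams <- function(ids) fam_of[ids]
  tf <- get_fams(pairs$toxin_id)
  af <- get_fams(pairs$antitoxin_id)
  has <- function(fl, fams) {
    vapply(fl, function(f) !is.null(f) && any(f %in% fams), logical(1))
  }
  t_class1 <- has(tf, CLASS1_TOXIN_FAMILIES)
  t_class2 <- has(tf, CLASS2_TOXIN_FAMILY)
  a_ok <- has(af, ANTITOXIN_FAMILY) & pairs$antitoxin_motif_hits >= 1L
  cls <- rep("unclassified", nrow(pairs))
  cls[t_class1 & pairs$toxin_motif_hits >= 1L & a_ok] <- "ClassI"
  cls[t_class2 & pairs$toxin_motif_hits == 0L & a_ok] <- "ClassII"
  pairs$class_label <- cls
  pairs$flag_pf05168_with_motif <- t_class2 & pairs$toxin_motif_hits >= 1L
  pairs
}

#' Read a genome-to-taxon table
#' @param path TSV with columns genome_id, taxon.
#' @return data.frame.
#' @export
read_taxa_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("genome_id", "taxon") %in% names(df))) {
    stop("taxa TSV needs columns genome_id, taxon")
  }
  df
}

#' Per-taxon census of classified pairs
#'
#' For each taxon and each class (Class I, Class II): the total number
#' of pairs, the mean number per genome, and the percentage of genomes
#' carrying at least one pair. Genomes with zero pairs count in the
#' denominators.
#'
#' @param pairs Classified pair data.frame.
#' @param taxa data.frame (genome_id, taxon) covering every genome in
#'   the surveyed set, including pair-free genomes.
#' @return data.frame: taxon, class_label, n_genomes, total_pairs,
#'   mean_per_genome, pct_genomes_with_pair.
#' @export
census <- function(pairs, taxa) {
  stopifnot(all(c("genome_id", "taxon") %in% names(taxa)))
  missing <- setdiff(pairs$genome_id, taxa$genome_id)
  if (length(missing)) {
    stop("genome(s) missing from taxa table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  classes <- c("ClassI", "ClassII")
  taxa <- unique(taxa[, c("genome_id", "taxon")])
  taxons <- sort(unique(taxa$taxon))
  out <- expand.grid(taxon = taxons, class_label = classes,
                     stringsAsFactors = FALSE)
  out <- out[order(out$taxon, out$class_label), , drop = FALSE]
  pairs$taxon <- taxa$taxon[match(pairs$genome_id, taxa$genome_id)]
  res <- lapply(seq_len(nrow(out)), function(i) {
    tx <- out$taxon[i]; cl <- out$class_label[i]
    gset <- taxa$genome_id[taxa$taxon == tx]
    sub <- pairs[pairs$taxon == tx & pairs$class_label == cl, , drop = FALSE]
    n_gen <- length(gset)
    total <- nrow(sub)
    with_pair <- length(unique(sub$genome_id))
    data.frame(taxon = tx, class_label = cl, n_genomes = n_gen,
               total_pairs = total,
               mean_per_genome = if (n_gen) total / n_gen else 0,
               pct_genomes_with_pair = if (n_gen) 100 * with_pair / n_gen else 0,
               stringsAsFactors = FALSE)
  })
  if (length(res) == 0L) {
    return(data.frame(taxon = character(0), class_label = character(0),
                      n_genomes = integer(0), total_pairs = integer(0),
                      mean_per_genome = numeric(0),
                      pct_genomes_with_pair = numeric(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write pair / census tables to TSV
#'
#' @param x data.frame to write.
#' @param path Output file.
#' @param comment Header comment describing column semantics.
#' @return \code{path}, invisibly.
#' @export
write_table_tsv <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
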