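# Synthetic-data generation: annotated genomes with planted Class I/II
# HEPN/MNT pairs among decoy genes, and simulated ESI spectra - each with
# machine-readable ground truth, so the mining and mass pipelines can be
# validated end to end.

TOXIN_MOTIF <- "RX4HXY"
ANTITOXIN_MOTIF <- "GSX10DXD"

#' Genome-simulation configuration
#'
#' Defines the synthetic study conditions: how many genomes, their taxon
#' mix, genes per genome, how many Class I / Class II pairs to plant,
#' and the per-genome probability of each decoy kind. Decoys each
#' violate exactly one pairing rule: \code{lone_toxin} / \code{lone_antitoxin}
#' are motif genes with no motif-bearing neighbor; \code{distant_pair}
#' places both motifs two locus ranks apart; \code{toxin_no_y} plants an
#' RX4H motif lacking the terminal Y next to a real antitoxin.
#'
#' @param n_genomes Number of genomes.
#' @param taxa_proportions Named probability vector of taxon labels.
#' @param genes_per_genome Genes per genome (single contig).
#' @param class1_per_genome,class2_per_genome Planted pairs per genome.
#' @param decoy_rates Named vector of per-genome Bernoulli rates for
#'   \code{lone_toxin}, \code{lone_antitoxin}, \code{distant_pair},
#'   \code{toxin_no_y}.
#' @param intergenic_range Uniform range (bp) for intergenic gaps.
#' @param protein_length_range Uniform range (aa) for protein lengths.
#' @param background Length-20 residue probability vector used for all
#'   sequence draws (default proteome-like frequencies).
#' @param seed Mandatory integer seed; genome g uses the documented
#'   subseed \code{(seed * 1009 + g) mod (2^31 - 1)} so each genome is
#'   independently reproducible.
#' @return List of class \code{"genome_sim_config"}.
#' @export
genome_sim_config <- function(n_genomes = 50L,
                              taxa_proportions = c(Proteobacteria = 0.4,
                                                   Firmicutes = 0.2,
                                                   Actinobacteria = 0.2,
                                                   Euryarchaeota = 0.2),
                              genes_per_genome = 20L,
                              class1_per_genome = 1L,
                              class2_per_genome = 1L,
                              decoy_rates = c(lone_toxin = 0,
                                              lone_antitoxin = 0,
                                              distant_pair = 0,
                                              toxin_no_y = 0),
                              intergenic_range = c(20L, 200L),
                              protein_length_range = c(80L, 200L),
                              background = proteome_background(),
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_genomes >= 1, genes_per_genome >= 1,
            class1_per_genome >= 0, class2_per_genome >= 0,
            abs(sum(taxa_proportions) - 1) < 1e-9,
            all(decoy_rates >= 0), all(decoy_rates <= 1))
  need <- c("lone_toxin", "lone_antitoxin", "distant_pair", "toxin_no_y")
  rates <- stats::setNames(rep(0, 4), need)
  rates[names(decoy_rates)] <- decoy_rates
  structure(list(n_genomes = as.integer(n_genomes),
                 taxa_proportions = taxa_proportions,
                 genes_per_genome = as.integer(genes_per_genome),
                 class1_per_genome = as.integer(class1_per_genome),
                 class2_per_genome = as.integer(class2_per_genome),
                 decoy_rates = rates,
                 intergenic_range = as.integer(intergenic_range),
                 protein_length_range = as.integer(protein_length_range),
                 background = .check_background(background),
                 seed = as.integer(seed)),
            class = "genome_sim_config")
}

# One random background protein free of both signature motifs
# (rejection sampling).
.random_clean_protein <- function(len, background, patterns) {
  repeat {
    s <- paste(sample(AA_ALPHABET, len, replace = TRUE, prob = background),
               collapse = "")
    if (all(vapply(patterns,
                   function(p) nrow(scan_pattern(s, p)) == 0L, logical(1)))) {
      return(s)
    }
  }
}

# Sample a concrete instance of a gapped pattern, ANY positions filled
# from the background (planted sites vary rather than repeat one string).
.sample_motif_instance <- function(pattern, background) {
  paste(unlist(lapply(pattern$positions, function(p) {
    pool <- if (identical(p$residues, "ANY")) AA_ALPHABET else p$residues
    pr <- if (identical(p$residues, "ANY")) background else NULL
    sample(pool, p$min_repeat, replace = TRUE, prob = pr)
  })), collapse = "")
}

# Embed `instance` at a random offset of a clean background protein;
# re-sample until the protein contains the wanted motif (>= 1 hit) and
# none of the forbidden ones.
.plant_motif_protein <- function(len, background, instance_fn,
                                 want = NULL, forbid = list()) {
  patterns <- c(if (!is.null(want)) list(want), forbid)
  repeat {
    s <- .random_clean_protein(len, background, patterns)
    ins <- instance_fn()
    pos <- sample.int(nchar(s) - nchar(ins) + 1L, 1L)
    s2 <- paste0(substr(s, 1, pos - 1L), ins,
                 substr(s, pos + nchar(ins), nchar(s)))
    ok_want <- is.null(want) || nrow(scan_pattern(s2, want)) >= 1L
    ok_forbid <- all(vapply(forbid, function(p)
      nrow(scan_pattern(s2, p)) == 0L, logical(1)))
    if (ok_want && ok_forbid) {
      return(list(seq = s2, motif_start = pos - 1L))
    }
  }
}

#' Generate synthetic annotated genomes with planted TA pairs
#'
#' Emits, under \code{out_dir}: \code{proteins.faa}, \code{genes.gff3},
#' \code{domains.tsv}, \code{taxa.tsv} and \code{truth.json} (the ground
#' truth manifest). Background proteins are i.i.d. draws from the
#' background frequencies with both signature motifs rejected; planted
#' Class I toxins embed an RX4HXY instance (Pfam PF01934 or PF08780),
#' Class II toxins are motif-free PF05168 proteins, and all planted
#' antitoxins embed GSX10DXD (PF01909). Planted pairs occupy adjacent
#' locus ranks with the antitoxin upstream; every block is separated
#' from the next by at least one background gene, so each decoy violates
#' exactly one pairing rule. Outputs are byte-identical across runs with
#' the same config.
#'
#' @param config A \code{\link{genome_sim_config}}.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the five file \code{paths} and the
#'   in-memory \code{manifest} (see \code{\link{read_truth_manifest}}).
#' @export
generate_genomes <- function(config, out_dir) {
  stopifnot(inherits(config, "genome_sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tox_pat <- parse_pattern(TOXIN_MOTIF)
  anti_pat <- parse_pattern(ANTITOXIN_MOTIF)
  both <- list(tox_pat, anti_pat)
  bg <- config$background
  set.seed(config$seed)
  taxa_assign <- sample(names(config$taxa_proportions), config$n_genomes,
                        replace = TRUE, prob = config$taxa_proportions)
  fasta_ids <- character(0); fasta_seqs <- character(0)
  gff_lines <- "##gff-version 3"
  dom_rows <- list(); truth_pairs <- list(); truth_decoys <- list()

  rand_len <- function() sample(seq(config$protein_length_range[1],
                                    config$protein_length_range[2]), 1L)
  mk_bg <- function() list(kind = "background",
                           seq = .random_clean_protein(rand_len(), bg, both))
  mk_toxin1 <- function() {
    p <- .plant_motif_protein(rand_len(), bg,
                              function() .sample_motif_instance(tox_pat, bg),
                              want = tox_pat, forbid = list(anti_pat))
    c(list(kind = "toxin1", family = sample(CLASS1_TOXIN_FAMILIES, 1L),
           clan = "CL0291"), p)
  }
  mk_toxin2 <- function() {
    list(kind = "toxin2", family = CLASS2_TOXIN_FAMILY, clan = "CL0291",
         seq = .random_clean_protein(rand_len(), bg, both),
         motif_start = NA_integer_)
  }
  mk_anti <- function() {
    p <- .plant_motif_protein(rand_len(), bg,
                              function() .sample_motif_instance(anti_pat, bg),
                              want = anti_pat, forbid = list(tox_pat))
    c(list(kind = "antitoxin", family = ANTITOXIN_FAMILY, clan = "CL0260"), p)
  }
  mk_no_y <- function() {
    # RX4HX<not-Y>: satisfies RX4H but never the full toxin signature
    inst_fn <- function() {
      paste0("R",
             paste(sample(AA_ALPHABET, 4, TRUE, bg), collapse = ""), "H",
             sample(AA_ALPHABET, 1, prob = bg),
             sample(setdiff(AA_ALPHABET, "Y"), 1))
    }
    p <- .plant_motif_protein(rand_len(), bg, inst_fn,
                              want = NULL, forbid = both)
    c(list(kind = "toxin_no_y", family = CLASS1_TOXIN_FAMILIES[1],
           clan = "CL0291"), p)
  }

  for (g in seq_len(config$n_genomes)) {
    set.seed((config$seed * 1009 + g) %% 2147483647L)
    genome_id <- sprintf("G%04d", g)
    contig_id <- paste0(genome_id, "_c1")
    blocks <- list()
    for (i in seq_len(config$class1_per_genome)) {
      blocks <- c(blocks, list(list(type = "class1",
                                    genes = list(mk_anti(), mk_toxin1()))))
    }
    for (i in seq_len(config$class2_per_genome)) {
      blocks <- c(blocks, list(list(type = "class2",
                                    genes = list(mk_anti(), mk_toxin2()))))
    }
    for (kind in names(config$decoy_rates)) {
      if (stats::runif(1) < config$decoy_rates[[kind]]) {
        genes <- switch(kind,
          lone_toxin = list(mk_toxin1()),
          lone_antitoxin = list(mk_anti()),
          distant_pair = list(mk_anti(), mk_bg(), mk_toxin1()),
          toxin_no_y = list(mk_anti(), mk_no_y()))
        blocks <- c(blocks, list(list(type = kind, genes = genes)))
      }
    }
    if (length(blocks) > 1L) blocks <- blocks[sample.int(length(blocks))]
    n_block_genes <- sum(vapply(blocks, function(b) length(b$genes),
                                integer(1)))
    n_sep <- length(blocks) + 1L  # one background gene around every block
    n_fill <- config$genes_per_genome - n_block_genes - n_sep
    if (n_fill < 0L) {
      stop("infeasible config: ", n_block_genes + n_sep,
           " genes needed but genes_per_genome = ", config$genes_per_genome)
    }
    # distribute filler background genes among the separator slots
    extra <- if (n_fill > 0L) {
      tabulate(sample.int(n_sep, n_fill, replace = TRUE), nbins = n_sep)
    } else rep(0L, n_sep)
    gene_list <- list()
    slot_block <- c(lapply(blocks, function(b) b$genes), list(NULL))
    for (s in seq_len(n_sep)) {
      gene_list <- c(gene_list, replicate(1L + extra[s], mk_bg(),
                                          simplify = FALSE))
      if (!is.null(slot_block[[s]])) {
        gene_list <- c(gene_list, slot_block[[s]])
      }
    }
    # but blocks come after their separator: rebuild in order
    # (separator genes already interleaved above)
    pos <- 0L
    rows <- list()
    for (idx in seq_along(gene_list)) {
      gene <- gene_list[[idx]]
      pid <- sprintf("%s_p%03d", genome_id, idx)
      gap <- sample(seq(config$intergenic_range[1],
                        config$intergenic_range[2]), 1L)
      start0 <- pos + gap
      end0 <- start0 + 3L * nchar(gene$seq) + 3L
      pos <- end0
      strand <- if (gene$kind == "background") sample(c("+", "-"), 1L) else "+"
      gff_lines <- c(gff_lines, sprintf(
        "%s\thepnmnt_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;genome_id=%s",
        contig_id, start0 + 1L, end0, strand, pid, genome_id))
      fasta_ids <- c(fasta_ids, pid)
      fasta_seqs <- c(fasta_seqs, gene$seq)
      if (!is.null(gene$family)) {
        dom_rows[[length(dom_rows) + 1L]] <-
          data.frame(protein_id = pid, family = gene$family,
                     clan = gene$clan, stringsAsFactors = FALSE)
      }
      gene_list[[idx]]$protein_id <- pid
      rows[[idx]] <- gene_list[[idx]]
    }
    # record truth for planted pairs and decoys
    i <- 1L
    while (i <= length(rows)) {
      k <- rows[[i]]$kind
      if (k == "antitoxin" && i < length(rows) &&
          rows[[i + 1L]]$kind %in% c("toxin1", "toxin2")) {
        cls <- if (rows[[i + 1L]]$kind == "toxin1") "ClassI" else "ClassII"
        truth_pairs[[length(truth_pairs) + 1L]] <- data.frame(
          genome_id = genome_id,
          toxin_id = rows[[i + 1L]]$protein_id,
          antitoxin_id = rows[[i]]$protein_id,
          class_label = cls,
          toxin_motif_start = rows[[i + 1L]]$motif_start,
          antitoxin_motif_start = rows[[i]]$motif_start,
          stringsAsFactors = FALSE)
        i <- i + 2L
      } else if (k %in% c("toxin_no_y")) {
        truth_decoys[[length(truth_decoys) + 1L]] <- data.frame(
          genome_id = genome_id, kind = k,
          protein_id = rows[[i]]$protein_id, stringsAsFactors = FALSE)
        i <- i + 1L
      } else if (k %in% c("toxin1", "antitoxin")) {
        # lone or distant-pair members (no adjacent planted partner)
        truth_decoys[[length(truth_decoys) + 1L]] <- data.frame(
          genome_id = genome_id,
          kind = if (k == "toxin1") "decoy_toxin" else "decoy_antitoxin",
          protein_id = rows[[i]]$protein_id, stringsAsFactors = FALSE)
        i <- i + 1L
      } else {
        i <- i + 1L
      }
    }
  }

  paths <- list(
    fasta = file.path(out_dir, "proteins.faa"),
    gff3 = file.path(out_dir, "genes.gff3"),
    domains = file.path(out_dir, "domains.tsv"),
    taxa = file.path(out_dir, "taxa.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  aa <- Biostrings::AAStringSet(stats::setNames(fasta_seqs, fasta_ids))
  Biostrings::writeXStringSet(aa, paths$fasta)
  writeLines(gff_lines, paths$gff3)
  domains <- if (length(dom_rows)) do.call(rbind, dom_rows) else
    data.frame(protein_id = character(0), family = character(0),
               clan = character(0))
  write_table_tsv(domains, paths$domains,
                  "domain annotations: protein_id, Pfam family, clan")
  taxa <- data.frame(genome_id = sprintf("G%04d", seq_len(config$n_genomes)),
                     taxon = taxa_assign, stringsAsFactors = FALSE)
  write_table_tsv(taxa, paths$taxa, "genome_id -> taxon")
  pairs_df <- if (length(truth_pairs)) do.call(rbind, truth_pairs) else
    data.frame(genome_id = character(0), toxin_id = character(0),
               antitoxin_id = character(0), class_label = character(0),
               toxin_motif_start = integer(0),
               antitoxin_motif_start = integer(0))
  decoys_df <- if (length(truth_decoys)) do.call(rbind, truth_decoys) else
    data.frame(genome_id = character(0), kind = character(0),
               protein_id = character(0))
  manifest <- list(seed = config$seed, n_genomes = config$n_genomes,
                   pairs = pairs_df, decoys = decoys_df)
  jsonlite::write_json(manifest, paths$truth, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(paths = paths, manifest = manifest))
}

#' Read a ground-truth manifest
#' @param path \code{truth.json} written by \code{\link{generate_genomes}}.
#' @return List with \code{pairs} and \code{decoys} data.frames.
#' @export
read_truth_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(m$pairs) == 0L) {
    m$pairs <- data.frame(genome_id = character(0), toxin_id = character(0),
                          antitoxin_id = character(0),
                          class_label = character(0))
  }
  m
}

#' Simulate an ESI spectrum of one or more protein species
#'
#' Gaussian peaks at \eqn{(M + z m_p)/z} for every species and charge
#' state that falls inside the instrument m/z range; optional
#' multiplicative intensity noise. Deterministic for a given seed.
#'
#' @param masses Neutral masses (Da) of the species.
#' @param abundances Relative abundances (recycled; default equal).
#' @param z_min,z_max Charge-state range.
#' @param mz_range Instrument m/z range (default 600-2000).
#' @param peak_sd Gaussian peak width (s.d., m/z units; default 0.02).
#' @param grid_step Profile sampling step (m/z; default 0.005).
#' @param noise_level S.d. of multiplicative intensity noise (0 = none).
#' @param seed Optional seed (required when \code{noise_level > 0}).
#' @return Peak-list data.frame (\code{mz}, \code{intensity}).
#' @export
generate_spectrum <- function(masses, abundances = 1, z_min = 5L, z_max = 30L,
                              mz_range = c(600, 2000), peak_sd = 0.02,
                              grid_step = 0.005, noise_level = 0,
                              seed = NULL) {
  stopifnot(all(masses > 0), z_min >= 1L, z_max >= z_min,
            mz_range[1] < mz_range[2], peak_sd > 0, grid_step > 0)
  abundances <- rep_len(abundances, length(masses))
  mz <- seq(mz_range[1], mz_range[2], by = grid_step)
  intensity <- numeric(length(mz))
  n_in <- 0L
  for (i in seq_along(masses)) {
    for (z in seq.int(z_min, z_max)) {
      center <- (masses[i] + z * PROTON_MASS) / z
      if (center < mz_range[1] || center > mz_range[2]) next
      n_in <- n_in + 1L
      lo <- max(1L, floor((center - 8 * peak_sd - mz_range[1]) / grid_step))
      hi <- min(length(mz),
                ceiling((center + 8 * peak_sd - mz_range[1]) / grid_step) + 1L)
      idx <- lo:hi
      intensity[idx] <- intensity[idx] +
        abundances[i] * exp(-(mz[idx] - center)^2 / (2 * peak_sd^2))
    }
  }
  if (n_in == 0L) {
    stop("no (species, charge) combination lands inside the m/z range")
  }
  if (noise_level > 0) {
    if (is.null(seed)) stop("seed required when noise_level > 0")
    set.seed(seed)
    intensity <- pmax(0, intensity *
                        (1 + stats::rnorm(length(intensity), 0, noise_level)))
  }
  data.frame(mz = mz, intensity = intensity)
}
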