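# Synthetic proteogenome + PST simulator with ground truth. Generates
# multi-exon genes (splice-consistent, codon-aligned CDS pieces) on both
# strands with realistic feature-length statistics, then tryptic peptides
# and PSTs with configurable flank-mass noise and decoy tags, so every
# pipeline stage is testable without external data.

#' Configuration of the synthetic proteogenome and PST simulator
#'
#' Length samplers are log-normal, parameterized by their median (feature
#' length medians of a compact intron-rich eukaryotic genome: CDS pieces
#' 137 nt, introns 531 nt, intergenic spacers 2529 nt, about seven introns
#' per gene, which makes gene lengths come out near their 4.8 kb median).
#' Exons carry no UTRs here, so the exon sampler is the CDS sampler.
#'
#' @param n_genes Number of genes to simulate.
#' @param cds_median Median CDS-piece (exon) length, nt; rounded to codons.
#' @param intron_median Median intron length, nt.
#' @param intergenic_median Median intergenic spacer length, nt.
#' @param introns_per_gene Mean intron count per gene (Poisson).
#' @param length_sigma Log-space sd of all length samplers.
#' @param peptides_per_protein Tryptic peptides sampled per protein for PST
#'   emission.
#' @param psts_per_peptide PSTs emitted per sampled peptide.
#' @param tag_len Tag length, 3-5 residues.
#' @param flank_mass_error_sd Gaussian noise sd added to each flank mass
#'   (Da); 0 gives noise-free PSTs.
#' @param decoy_fraction Fraction of the emitted PST set that is decoy
#'   (random tag, random flank masses), in [0, 1].
#' @param missed_cleavages Missed cleavages allowed when sampling peptides.
#' @param constants [mass_constants()] used to form flank masses.
#' @param contig_id Name of the simulated contig.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_genes = 50L, cds_median = 137, intron_median = 531,
                         intergenic_median = 2529, introns_per_gene = 7,
                         length_sigma = 0.5, peptides_per_protein = 8L,
                         psts_per_peptide = 1L, tag_len = 5L,
                         flank_mass_error_sd = 0.1, decoy_fraction = 0,
                         missed_cleavages = 0L, constants = mass_constants(),
                         contig_id = "synth_contig_1", seed = 1L) {
  stopifnot(n_genes >= 1L, cds_median >= 9, intron_median >= 9,
            intergenic_median >= 9, tag_len >= 3L, tag_len <= 5L,
            flank_mass_error_sd >= 0, decoy_fraction >= 0,
            decoy_fraction <= 1, missed_cleavages >= 0L,
            psts_per_peptide >= 1L, peptides_per_protein >= 1L)
  structure(as.list(environment()), class = "synth_config")
}

# log-normal sampler parameterized by its median
.rlnorm_median <- function(n, median, sigma) {
  median * exp(stats::rnorm(n, 0, sigma))
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# inverse genetic code: residue -> codons (stops excluded)
.codons_for <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[CANONICAL_RESIDUES]
}

#' Simulate a proteogenome
#'
#' Builds one contig of alternating-strand multi-exon genes separated by
#' intergenic spacers. Each gene's protein is drawn uniformly over the 20
#' residues, back-translated through random synonymous codons, and split
#' into codon-aligned CDS pieces with random introns in between, so the
#' spliced CDS translates the protein exactly and no exon contains an
#' in-frame stop. Deterministic under `config$seed`.
#'
#' @param config [synth_config()].
#' @return List of class `synth_genome`: `contigs`
#'   ([Biostrings::DNAStringSet]), `genes` / `mrna` data.frames, `cds`
#'   (one row per CDS piece: `protein_id`, `gene_id`, `contig`, `strand`,
#'   `start`, `end`, `order`, `aa_from`, `aa_to`), `proteins`
#'   (`protein_id`, `gene_id`, `seq`), and `config`.
#' @export
synth_genome <- function(config = synth_config()) {
  set.seed(config$seed)
  codon_tab <- .codons_for()
  pieces <- character()
  genes <- list(); cds <- list(); proteins <- list()
  offset <- 0L  # bases already emitted

  emit <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    offset <<- offset + nchar(s)
  }

  for (g in seq_len(config$n_genes)) {
    gene_id <- sprintf("gene_%03d", g)
    mrna_id <- paste0(gene_id, ".t1")
    protein_id <- paste0(gene_id, ".p1")
    strand <- if (g %% 2L == 1L) "+" else "-"

    emit(.random_dna(max(9L, as.integer(round(
      .rlnorm_median(1, config$intergenic_median, config$length_sigma))))))

    n_exons <- 1L + stats::rpois(1L, config$introns_per_gene)
    exon_nt <- 3L * pmax(3L, as.integer(round(
      .rlnorm_median(n_exons, config$cds_median, config$length_sigma) / 3)))
    intron_nt <- if (n_exons > 1L) pmax(9L, as.integer(round(
      .rlnorm_median(n_exons - 1L, config$intron_median,
                     config$length_sigma)))) else integer()

    protein_len <- sum(exon_nt) %/% 3L
    protein <- paste(sample(CANONICAL_RESIDUES, protein_len, replace = TRUE),
                     collapse = "")
    codons <- vapply(strsplit(protein, "")[[1L]], function(r) {
      cs <- codon_tab[[r]]
      cs[sample.int(length(cs), 1L)]
    }, "")
    cds_nt <- paste(codons, collapse = "")

    # split CDS into exon chunks; interleave with introns
    ends <- cumsum(exon_nt)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    exon_seq <- substring(cds_nt, starts, ends)
    gene_parts <- character(2L * n_exons - 1L)
    gene_parts[seq(1L, by = 2L, length.out = n_exons)] <- exon_seq
    if (n_exons > 1L) {
      gene_parts[seq(2L, by = 2L, length.out = n_exons - 1L)] <-
        vapply(intron_nt, .random_dna, "")
    }
    gene_fwd <- paste(gene_parts, collapse = "")
    Lg <- nchar(gene_fwd)

    # relative exon coordinates within gene_fwd (1-based)
    part_len <- nchar(gene_parts)
    part_end <- cumsum(part_len)
    part_start <- c(1L, utils::head(part_end, -1L) + 1L)
    ex_idx <- seq(1L, by = 2L, length.out = n_exons)
    rel <- cbind(part_start[ex_idx], part_end[ex_idx])

    if (strand == "+") {
      abs_start <- offset + rel[, 1L]
      abs_end <- offset + rel[, 2L]
      emit(gene_fwd)
    } else {
      abs_start <- offset + Lg - rel[, 2L] + 1L
      abs_end <- offset + Lg - rel[, 1L] + 1L
      emit(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gene_fwd))))
    }
    aa_to <- cumsum(exon_nt) %/% 3L
    aa_from <- c(1L, utils::head(aa_to, -1L) + 1L)

    gene_start <- min(abs_start); gene_end <- max(abs_end)
    genes[[g]] <- data.frame(
      gene_id = gene_id, mrna_id = mrna_id, contig = config$contig_id,
      strand = strand, start = gene_start, end = gene_end,
      stringsAsFactors = FALSE)
    cds[[g]] <- data.frame(
      protein_id = protein_id, gene_id = gene_id, mrna_id = mrna_id,
      contig = config$contig_id, strand = strand,
      start = abs_start, end = abs_end, order = seq_len(n_exons),
      aa_from = aa_from, aa_to = aa_to, stringsAsFactors = FALSE)
    proteins[[g]] <- data.frame(
      protein_id = protein_id, gene_id = gene_id, seq = protein,
      stringsAsFactors = FALSE)
  }
  emit(.random_dna(max(9L, as.integer(round(
    .rlnorm_median(1, config$intergenic_median, config$length_sigma))))))

  contig <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
  names(contig) <- config$contig_id
  structure(list(contigs = contig,
                 genes = do.call(rbind, genes),
                 cds = do.call(rbind, cds),
                 proteins = do.call(rbind, proteins),
                 config = config),
            class = "synth_genome")
}

#' Write a simulated proteogenome to FASTA + GFF3 (+ protein TSV)
#'
#' @param genome [synth_genome()] output.
#' @param fasta_path,gff3_path,proteins_path Output paths
#'   (`proteins_path = NULL` skips the protein table).
#' @export
write_synth_genome <- function(genome, fasta_path, gff3_path,
                               proteins_path = NULL) {
  Biostrings::writeXStringSet(genome$contigs, fasta_path)
  g <- genome$genes
  cd <- genome$cds
  feats <- c(
    GenomicRanges::GRanges(g$contig, IRanges::IRanges(g$start, g$end),
                           strand = g$strand, type = "gene", ID = g$gene_id,
                           Parent = NA_character_),
    GenomicRanges::GRanges(g$contig, IRanges::IRanges(g$start, g$end),
                           strand = g$strand, type = "mRNA", ID = g$mrna_id,
                           Parent = g$gene_id),
    GenomicRanges::GRanges(cd$contig, IRanges::IRanges(cd$start, cd$end),
                           strand = cd$strand, type = "CDS",
                           ID = paste0(cd$mrna_id, ".cds", cd$order),
                           Parent = cd$mrna_id))
  S4Vectors::mcols(feats)$source <- "pstmap_synth"
  # CDS pieces are codon-aligned by construction
  S4Vectors::mcols(feats)$phase <-
    ifelse(S4Vectors::mcols(feats)$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(feats, gff3_path, format = "gff3")
  if (!is.null(proteins_path)) {
    utils::write.table(genome$proteins, proteins_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(list(fasta = fasta_path, gff3 = gff3_path))
}

# genomic interval of protein residue range [aa_s, aa_e] when it lies
# within one CDS piece `piece` (a 1-row data.frame)
.aa_range_to_genomic <- function(piece, aa_s, aa_e) {
  if (piece$strand == "+") {
    c(piece$start + 3L * (aa_s - piece$aa_from),
      piece$start + 3L * (aa_e - piece$aa_from + 1L) - 1L)
  } else {
    c(piece$end - 3L * (aa_e - piece$aa_from + 1L) + 1L,
      piece$end - 3L * (aa_s - piece$aa_from))
  }
}

#' Simulate PSTs (with ground truth) from a proteogenome
#'
#' Each protein is digested with trypsin; among its peptides, those fully
#' interior to a single CDS piece (one residue of context on each side
#' lies in the same piece and the peptide ends on K/R) and long enough to
#' hold the tag plus one flanking residue on each side are eligible, and up
#' to `peptides_per_protein` of them are sampled. For
#' each, a random interior tag window of `tag_len` residues is read and the two
#' flank masses computed from the flanking residue sums plus the
#' configured offsets, with Gaussian noise of sd `flank_mass_error_sd`.
#' Decoy PSTs (random tag, flank masses uniform over the plausible range)
#' are appended so they make up `decoy_fraction` of the set. Deterministic
#' under `config$seed`.
#'
#' @param genome [synth_genome()] output.
#' @param config [synth_config()]; defaults to the genome's own config.
#' @return List: `psts` (a [pst_table()]) and `truth` (one row per PST:
#'   `spectrum_id`, `gene_id`, `protein_id`, `peptide`, `tag`, `contig`,
#'   `strand`, `start`, `end`, `is_decoy`).
#' @export
synth_psts <- function(genome, config = genome$config) {
  set.seed(config$seed + 1L)
  co <- config$constants
  rm <- .RESIDUE_MASS
  rows <- list()
  n_skipped <- 0L

  for (p in seq_len(nrow(genome$proteins))) {
    prot <- genome$proteins[p, ]
    pieces <- genome$cds[genome$cds$protein_id == prot$protein_id, ,
                         drop = FALSE]
    dig <- tryptic_digest(prot$seq, config$missed_cleavages,
                          proline_rule = TRUE)
    chars <- strsplit(prot$seq, "", fixed = TRUE)[[1L]]
    ok <- logical(nrow(dig)); piece_idx <- integer(nrow(dig))
    for (i in seq_len(nrow(dig))) {
      s <- dig$start[i]; e <- dig$end[i]
      # a PST carries two flanking fragment ions, so its tag must be
      # interior to the peptide: at least one residue on each side
      if (e - s + 1L < config$tag_len + 2L) { n_skipped <- n_skipped + 1L; next }
      if (s < 2L) next                          # needs an interior N boundary
      if (!(chars[e] %in% c("K", "R"))) next    # tryptic C terminus
      # peptide plus one residue of context on each side must sit inside a
      # single CDS piece, so its genomic neighbourhood translates exactly
      # like the protein and the tryptic boundaries survive on the genome
      k <- which(pieces$aa_from <= s - 1L & pieces$aa_to >= e + 1L)
      if (!length(k)) next                      # spans an exon junction
      ok[i] <- TRUE; piece_idx[i] <- k[1L]
    }
    cand <- which(ok)
    if (!length(cand)) next
    take <- if (length(cand) > config$peptides_per_protein) {
      sample(cand, config$peptides_per_protein)
    } else cand
    for (i in take) {
      pep <- dig$peptide[i]
      plen <- nchar(pep)
      pchars <- chars[dig$start[i]:dig$end[i]]
      gi <- .aa_range_to_genomic(pieces[piece_idx[i], ], dig$start[i],
                                 dig$end[i])
      for (r in seq_len(config$psts_per_peptide)) {
        t0 <- 1L + sample.int(plen - config$tag_len - 1L, 1L)
        tag <- substr(pep, t0, t0 + config$tag_len - 1L)
        pre <- if (t0 > 1L) sum(rm[pchars[1:(t0 - 1L)]]) else 0
        post_from <- t0 + config$tag_len
        post <- if (post_from <= plen) sum(rm[pchars[post_from:plen]]) else 0
        mn <- pre + co$n_flank_offset
        mc <- post + co$c_flank_offset
        if (config$flank_mass_error_sd > 0) {
          mn <- mn + stats::rnorm(1, 0, config$flank_mass_error_sd)
          mc <- mc + stats::rnorm(1, 0, config$flank_mass_error_sd)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          spectrum_id = NA_character_, gene_id = prot$gene_id,
          protein_id = prot$protein_id, peptide = pep, tag = tag,
          contig = pieces$contig[1L], strand = pieces$strand[1L],
          start = gi[1L], end = gi[2L], mn = mn, mc = mc,
          is_decoy = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  if (n_skipped > 0L) {
    message(n_skipped, " peptide(s) too short to hold an interior tag skipped")
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spectrum_id = character(), gene_id = character(),
               protein_id = character(), peptide = character(),
               tag = character(), contig = character(), strand = character(),
               start = integer(), end = integer(), mn = numeric(),
               mc = numeric(), is_decoy = logical(),
               stringsAsFactors = FALSE)

  n_real <- nrow(truth)
  n_decoy <- if (config$decoy_fraction >= 1) max(n_real, 50L) else
    as.integer(round(config$decoy_fraction * n_real /
                       (1 - config$decoy_fraction)))
  if (config$decoy_fraction >= 1) truth <- truth[0L, , drop = FALSE]
  if (n_decoy > 0L) {
    dec <- data.frame(
      spectrum_id = NA_character_, gene_id = NA_character_,
      protein_id = NA_character_, peptide = NA_character_,
      tag = vapply(seq_len(n_decoy), function(i) {
        paste(sample(CANONICAL_RESIDUES, config$tag_len, replace = TRUE),
              collapse = "")
      }, ""),
      contig = NA_character_, strand = NA_character_,
      start = NA_integer_, end = NA_integer_,
      mn = co$n_flank_offset + stats::runif(n_decoy, 0, 800),
      mc = co$c_flank_offset + stats::runif(n_decoy, 0, 800),
      is_decoy = TRUE, stringsAsFactors = FALSE)
    truth <- rbind(truth, dec)
  }
  if (nrow(truth)) {
    truth$spectrum_id <- sprintf("spec_%05d", seq_len(nrow(truth)))
  }
  list(psts = pst_table(truth$spectrum_id, truth$tag, truth$mn, truth$mc),
       truth = truth)
}

#' Genes with enough simulated evidence to be recoverable
#'
#' The expected set for end-to-end evaluation: genes whose non-decoy PSTs
#' number at least `min_hits` and cover at least `min_peptides` distinct
#' (I/L-normalized) peptides.
#'
#' @param truth Truth table from [synth_psts()].
#' @param min_hits,min_peptides Evidence thresholds (defaults match the
#'   clustering defaults: 3 hits, 2 peptides).
#' @return Character vector of gene ids.
#' @export
expected_gene_set <- function(truth, min_hits = 3L, min_peptides = 2L) {
  t <- truth[!truth$is_decoy, , drop = FALSE]
  if (!nrow(t)) return(character())
  by_gene <- split(.il_norm(t$peptide), t$gene_id)
  names(by_gene)[vapply(by_gene, function(p) {
    length(p) >= min_hits && length(unique(p)) >= min_peptides
  }, TRUE)]
}

#' Write a complete synthetic dataset to a directory
#'
#' Convenience wrapper: genome FASTA, annotation GFF3, protein table, PST
#' TSV and ground-truth TSV.
#'
#' @param config [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisible list: `paths` plus the in-memory `genome`, `psts`,
#'   `truth`.
#' @export
synth_dataset <- function(config = synth_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- synth_genome(config)
  ps <- synth_psts(genome, config)
  paths <- list(fasta = file.path(dir, "genome.fasta"),
                gff3 = file.path(dir, "annotation.gff3"),
                proteins = file.path(dir, "proteins.tsv"),
                psts = file.path(dir, "psts.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_synth_genome(genome, paths$fasta, paths$gff3, paths$proteins)
  write_psts(ps$psts, paths$psts)
  utils::write.table(ps$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(paths = paths, genome = genome, psts = ps$psts,
                 truth = ps$truth))
}
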