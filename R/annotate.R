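# Qualification of clusters against an existing GFF3 annotation: the
# exon-mapping category (IN/OUT/CROSS relative to mRNA spans), annotation
# status (ANNOTATED/UNANNOTATED by CDS-included hits), confidence
# (DUBIOUS/POSSIBLE/SURE by typical spectra and distinct peptides), and
# consistency (OK/CHECK), plus GFF3 export for genome viewers.

#' Parse a GFF3 annotation into mRNA and CDS interval sets
#'
#' Keeps gene, mRNA and CDS features; other types are ignored with a
#' message. A CDS whose Parent cannot be resolved to an mRNA is kept as an
#' orphan with a warning.
#'
#' @param path Path to a GFF3 file with gene/mRNA/CDS features carrying
#'   ID/Parent attributes.
#' @return List of class `genome_annotation` with elements `mrna` (a
#'   [GenomicRanges::GRanges] with metadata columns `ID` and `gene`) and
#'   `cds` (a GRanges with metadata column `parent`).
#' @export
parse_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  other <- setdiff(unique(type), c("gene", "mRNA", "CDS"))
  if (length(other)) {
    message("ignoring feature type(s): ", paste(other, collapse = ", "))
  }
  first_chr <- function(x) {
    vapply(x, function(v) if (length(v)) as.character(v[[1L]]) else
      NA_character_, "")
  }
  genes <- gr[type == "gene"]
  mrna <- gr[type == "mRNA"]
  cds <- gr[type == "CDS"]
  mrna_parent <- if (length(mrna)) first_chr(mrna$Parent) else character()
  cds_parent <- if (length(cds)) first_chr(cds$Parent) else character()
  if (length(cds)) {
    orphan <- !(cds_parent %in% mrna$ID)
    if (any(orphan)) {
      warning(sum(orphan), " CDS feature(s) without resolvable mRNA parent",
              " kept as orphans")
    }
  }
  m <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(mrna), IRanges::ranges(mrna),
    strand = GenomicRanges::strand(mrna))
  m$ID <- if (length(mrna)) as.character(mrna$ID) else character()
  m$gene <- mrna_parent
  cc <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(cds), IRanges::ranges(cds),
    strand = GenomicRanges::strand(cds))
  cc$parent <- cds_parent
  structure(list(mrna = m, cds = cc, genes = genes), class = "genome_annotation")
}

.hits_granges <- function(hits) {
  GenomicRanges::GRanges(hits$contig,
                         IRanges::IRanges(hits$start, hits$end),
                         strand = hits$strand)
}

.clusters_granges <- function(clusters) {
  GenomicRanges::GRanges(clusters$contig,
                         IRanges::IRanges(clusters$start, clusters$end),
                         strand = clusters$strand)
}

#' Count spectra typical of (specific to) a cluster
#'
#' A spectrum is typical of a cluster when every one of its hits,
#' genome-wide, belongs to that cluster's member set.
#'
#' @param hit_rows Integer row indices of the cluster's member hits in
#'   `all_hits`.
#' @param all_hits The genome-wide hits the clusters were built from.
#' @return Number of typical spectra.
#' @export
count_typical_spectra <- function(hit_rows, all_hits) {
  specs <- unique(all_hits$spectrum_id[hit_rows])
  if (!length(specs)) return(0L)
  n_total <- table(all_hits$spectrum_id)[specs]
  n_inside <- table(factor(all_hits$spectrum_id[hit_rows], levels = specs))
  sum(n_inside == n_total)
}

#' Categorize clusters relative to annotated mRNA spans
#'
#' IN when the cluster span is fully contained in at least one mRNA
#' interval, OUT when it overlaps none, CROSS otherwise.
#'
#' @param clusters [cluster_hits()] output (or any data.frame with contig,
#'   strand, start, end).
#' @param annotation [parse_gff3()] output.
#' @param ignore_strand Compare irrespective of strand (default FALSE).
#' @return Character vector of "IN"/"OUT"/"CROSS", one per cluster.
#' @export
categorize_clusters <- function(clusters, annotation, ignore_strand = FALSE) {
  if (!nrow(clusters)) return(character())
  cl <- .clusters_granges(clusters)
  within <- GenomicRanges::countOverlaps(
    cl, annotation$mrna, type = "within", ignore.strand = ignore_strand)
  any_ov <- GenomicRanges::countOverlaps(
    cl, annotation$mrna, ignore.strand = ignore_strand)
  ifelse(within > 0L, "IN", ifelse(any_ov == 0L, "OUT", "CROSS"))
}

#' Qualify clusters against an annotation
#'
#' Assigns the three label families and the exon-mapping category:
#' \itemize{
#'   \item ANNOTATED if at least one hit is fully included in a CDS,
#'     UNANNOTATED otherwise;
#'   \item DUBIOUS with zero or one typical spectrum; POSSIBLE with two or
#'     more typical spectra but fewer than three distinct peptides; SURE
#'     with two or more typical spectra and three or more distinct
#'     peptides;
#'   \item OK if every hit is included in an annotated CDS, CHECK
#'     otherwise;
#'   \item IN/OUT/CROSS per [categorize_clusters()].
#' }
#' "Included in a CDS" means full containment of the hit interval in a
#' single CDS feature on the same contig and strand; hits overlapping a
#' CDS only partially count toward `cds_cross`.
#'
#' @param clusters [cluster_hits()] output.
#' @param all_hits The hits the clusters were built from (typicality is
#'   evaluated genome-wide).
#' @param annotation [parse_gff3()] output.
#' @param ignore_strand Passed to the mRNA category comparison.
#' @return `clusters` with added columns: `category`, `annotation_label`,
#'   `confidence_label`, `consistency_label`, `tot_hit`, `hit_in`,
#'   `cds_in`, `cds_cross`, `n_typical_spectra`.
#' @export
qualify_clusters <- function(clusters, all_hits, annotation,
                             ignore_strand = FALSE) {
  out <- clusters
  out$category <- categorize_clusters(clusters, annotation, ignore_strand)
  if (!nrow(clusters)) {
    for (col in c("annotation_label", "confidence_label",
                  "consistency_label")) out[[col]] <- character()
    for (col in c("tot_hit", "hit_in", "cds_in", "cds_cross",
                  "n_typical_spectra")) out[[col]] <- integer()
    return(out)
  }
  hg <- .hits_granges(all_hits)
  in_cds <- GenomicRanges::countOverlaps(hg, annotation$cds,
                                         type = "within") > 0L
  touch_cds <- GenomicRanges::countOverlaps(hg, annotation$cds) > 0L

  n <- nrow(clusters)
  ann <- conf <- cons <- character(n)
  tot <- hin <- cin <- ccr <- typ <- integer(n)
  for (i in seq_len(n)) {
    rows <- clusters$hit_rows[[i]]
    tot[i] <- length(rows)
    hin[i] <- sum(in_cds[rows])
    peps <- .il_norm(all_hits$peptide[rows])
    cin[i] <- length(unique(peps[in_cds[rows]]))
    ccr[i] <- length(unique(peps[touch_cds[rows] & !in_cds[rows]]))
    typ[i] <- count_typical_spectra(rows, all_hits)
    ann[i] <- if (hin[i] >= 1L) "ANNOTATED" else "UNANNOTATED"
    n_pep <- clusters$n_peptides[i]
    conf[i] <- if (typ[i] <= 1L) "DUBIOUS" else
      if (n_pep < 3L) "POSSIBLE" else "SURE"
    cons[i] <- if (hin[i] == tot[i]) "OK" else "CHECK"
  }
  out$annotation_label <- ann
  out$confidence_label <- conf
  out$consistency_label <- cons
  out$tot_hit <- tot
  out$hit_in <- hin
  out$cds_in <- cin
  out$cds_cross <- ccr
  out$n_typical_spectra <- typ
  out
}

#' Write the cluster qualification table
#'
#' Tab-separated report mirroring the cluster data sheets: id, location,
#' hit/peptide/spectrum tallies, CDS-inclusion counts, and the four labels.
#'
#' @param qualified [qualify_clusters()] output.
#' @param path File path.
#' @export
write_cluster_table <- function(qualified, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# cluster_id\tcontig\tstrand\tfrom\tto\ttot_hit\thit_in",
                    "\tcds_in\tcds_cross\tn_peptides\tn_spectra",
                    "\tn_typical_spectra\tcategory\tannotation\tconfidence",
                    "\tconsistency"), con)
  if (nrow(qualified)) {
    writeLines(sprintf(
      "%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s\t%s\t%s",
      qualified$cluster_id, qualified$contig, qualified$strand,
      qualified$start, qualified$end, qualified$tot_hit, qualified$hit_in,
      qualified$cds_in, qualified$cds_cross, qualified$n_peptides,
      qualified$n_spectra, qualified$n_typical_spectra, qualified$category,
      qualified$annotation_label, qualified$confidence_label,
      qualified$consistency_label), con)
  }
  invisible(path)
}

#' Export qualified clusters as GFF3
#'
#' One `match` feature per cluster carrying the labels and counts as
#' attributes, with one `match_part` child per member hit (peptide,
#' spectrum id, tag). The file loads in standard genome viewers alongside
#' the gene annotation.
#'
#' @param qualified [qualify_clusters()] output.
#' @param all_hits The hits the clusters were built from.
#' @param path Output file path.
#' @export
clusters_to_gff3 <- function(qualified, all_hits, path) {
  if (!nrow(qualified)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  parts <- lapply(seq_len(nrow(qualified)), function(i) {
    rows <- qualified$hit_rows[[i]]
    h <- all_hits[rows, , drop = FALSE]
    GenomicRanges::GRanges(
      h$contig, IRanges::IRanges(h$start, h$end), strand = h$strand,
      type = "match_part",
      ID = sprintf("%s.part%03d", qualified$cluster_id[i], seq_len(nrow(h))),
      Parent = qualified$cluster_id[i],
      peptide = h$peptide, spectrum = h$spectrum_id, tag = h$tag)
  })
  cl <- GenomicRanges::GRanges(
    qualified$contig, IRanges::IRanges(qualified$start, qualified$end),
    strand = qualified$strand,
    type = "match",
    ID = qualified$cluster_id,
    Parent = NA_character_,
    peptide = NA_character_, spectrum = NA_character_, tag = NA_character_)
  cl$category <- qualified$category
  cl$annotation <- qualified$annotation_label
  cl$confidence <- qualified$confidence_label
  cl$consistency <- qualified$consistency_label
  cl$tot_hit <- as.character(qualified$tot_hit)
  cl$hit_in <- as.character(qualified$hit_in)
  cl$n_typical_spectra <- as.character(qualified$n_typical_spectra)
  pp <- do.call(c, parts)
  for (col in c("category", "annotation", "confidence", "consistency",
                "tot_hit", "hit_in", "n_typical_spectra")) {
    S4Vectors::mcols(pp)[[col]] <- NA_character_
  }
  all <- c(cl, pp)
  S4Vectors::mcols(all)$source <- "pstmap"
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}
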