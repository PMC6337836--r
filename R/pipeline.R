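# End-to-end orchestration: translate -> map (per PST file) -> merge per
# group -> cluster -> qualify -> export. All intermediates are plain
# tab-separated / GFF3 files so every stage can also be run on its own.

#' Run the whole mapping/clustering/qualification pipeline
#'
#' PST files may be grouped (e.g. one group per strain); hit lists are
#' merged within each group before clustering, so polymorphic strains do
#' not chain each other's hits. Outputs per group: a hits TSV, a cluster
#' TSV, a qualification TSV and a cluster GFF3, written under `out_dir`.
#' All outputs are reproducible bit-for-bit from the inputs and
#' parameters.
#'
#' @param genome_fasta Path to the genomic FASTA.
#' @param annotation_gff3 Path to the GFF3 annotation (gene/mRNA/CDS).
#' @param pst_files Character vector of PST file paths, or a named list of
#'   such vectors (one element per group). Unnamed vectors form a single
#'   group `"all"`.
#' @param out_dir Output directory (created if needed).
#' @param params [map_params()].
#' @param cparams [cluster_params()].
#' @param ignore_strand Passed to cluster qualification.
#' @param expected_ids Optional character vector of expected gene ids; if
#'   given, an evaluation report (IN/CROSS cluster gene recovery) is
#'   computed and written.
#' @return Invisible list: `segments`, per-group `hits`, `clusters`,
#'   `qualified` (one combined data.frame with a `group` column), `eval`
#'   (or NULL), and all output `paths`. Per-stage counts are logged via
#'   `message()`.
#' @export
run_pipeline <- function(genome_fasta, annotation_gff3, pst_files, out_dir,
                         params = map_params(),
                         cparams = cluster_params(),
                         ignore_strand = FALSE,
                         expected_ids = NULL) {
  if (!is.list(pst_files)) pst_files <- list(all = pst_files)
  if (is.null(names(pst_files)) || any(names(pst_files) == "")) {
    stop("pst_files groups must be named")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  contigs <- stage("translate", read_genome_fasta(genome_fasta))
  segments <- stage("translate", six_frame_translate(contigs))
  message("translate: ", nrow(segments), " stop-free segments from ",
          length(contigs), " contig(s)")
  annotation <- stage("qualify", parse_gff3(annotation_gff3))

  paths <- list()
  qualified_all <- list()
  hits_by_group <- list()
  clusters_by_group <- list()
  for (grp in names(pst_files)) {
    hit_list <- lapply(pst_files[[grp]], function(f) {
      stage("map", map_psts(read_psts(f), segments, params))
    })
    hits <- do.call(rbind, hit_list)
    hits <- hits[order(hits$contig, hits$start, hits$end, hits$spectrum_id), ]
    rownames(hits) <- NULL
    message("map [", grp, "]: ", nrow(hits), " hits from ",
            length(hit_list), " PST file(s)")
    clusters <- stage("cluster", cluster_hits(hits, cparams))
    message("cluster [", grp, "]: ", nrow(clusters), " clusters")
    qual <- stage("qualify",
                  qualify_clusters(clusters, hits, annotation, ignore_strand))
    if (nrow(qual)) {
      message("qualify [", grp, "]: ",
              paste(names(table(qual$category)), table(qual$category),
                    sep = "=", collapse = " "), "; ",
              paste(names(table(qual$annotation_label)),
                    table(qual$annotation_label), sep = "=", collapse = " "))
    }
    p <- list(hits = file.path(out_dir, paste0("hits_", grp, ".tsv")),
              clusters = file.path(out_dir, paste0("clusters_", grp, ".tsv")),
              table = file.path(out_dir, paste0("qualified_", grp, ".tsv")),
              gff3 = file.path(out_dir, paste0("clusters_", grp, ".gff3")))
    write_hits(hits, p$hits)
    write_clusters(clusters, p$clusters)
    write_cluster_table(qual, p$table)
    clusters_to_gff3(qual, hits, p$gff3)
    paths[[grp]] <- p
    hits_by_group[[grp]] <- hits
    clusters_by_group[[grp]] <- clusters
    qual$group <- rep(grp, nrow(qual))
    qualified_all[[grp]] <- qual
  }
  qualified <- do.call(rbind, qualified_all)
  rownames(qualified) <- NULL

  ev <- NULL
  if (!is.null(expected_ids)) {
    found <- unique(unlist(lapply(qualified_all, function(q) {
      match_proteins_by_clusters(q, annotation, ignore_strand)
    })))
    ev <- evaluate(found, expected_ids)
    p_eval <- file.path(out_dir, "evaluation.tsv")
    write_eval_report(ev, p_eval)
    paths$evaluation <- p_eval
    message(sprintf("evaluate: sensitivity %.3f selectivity %.3f",
                    ev$sensitivity, ev$selectivity))
  }
  invisible(list(segments = segments, hits = hits_by_group,
                 clusters = clusters_by_group, qualified = qualified,
                 eval = ev, paths = paths))
}
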