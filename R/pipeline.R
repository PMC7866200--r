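# End-to-end orchestration. The synthetic mode runs the whole chain --
# simulate study tables -> filter/rank -> rank aggregation -> promoter
# corpus -> threshold calibration -> scanning -> enrichment -> TF collapse
# -> motif overlap -> interaction clustering -- writing every stage output
# under one directory together with a hashed manifest, byte-identical
# under a fixed seed. Real-data analyses compose the same stage functions
# (read_study_table, filter_and_rank, aggregate_ranks, select_tss,
# extract_promoters, parse_pwms, ...) directly.

#' Build a pipeline configuration
#'
#' All printed thresholds of the analysis live here so that every strict
#' `<` / `>` choice is auditable in one place: per-study inclusion
#' |FC| > 1.25 with platform-specific adjusted-p cutoffs, rank-aggregation
#' DEG call at `padj < 0.01`, enrichment scanning at site frequency
#' 1/2000 bp, overlap scanning at 1/50000 bp, significance at
#' `FE_adj > 1.25 & FDR < 0.05` (highly enriched `> 1.5`), expression
#' filter `FPKM >= 0.5`.
#'
#' @param seed global integer seed fanned out to all generators.
#' @param mode `"synthetic"` (default: simulate all inputs) or `"files"`
#'   (ingest + aggregation from user-supplied study tables).
#' @param studies for `mode = "files"`: list of `list(path=, platform=)`.
#' @param biotypes for `mode = "files"`: path of a biotype TSV
#'   (`gene_id, biotype`).
#' @param meta,promoter,pwm,ppi parameter lists forwarded to
#'   [meta_sim_config()], [promoter_sim_config()],
#'   [simulate_pwm_library()] and [simulate_ppi_edges()].
#' @param enrich_rate,overlap_rate site-frequency calibration targets
#'   (sites per bp).
#' @param rra_padj,fe_min,fe_high,fdr_max,fpkm_min,fc_min analysis
#'   thresholds.
#' @param min_studies minimum studies measuring a gene for eligibility.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, mode = c("synthetic", "files"),
                            studies = NULL, biotypes = NULL,
                            meta = list(), promoter = list(),
                            pwm = list(n_matrices = 6L), ppi = list(
                              cluster_sizes = c(4L, 3L), p_within = 0.95,
                              p_between = 0.02),
                            enrich_rate = 1 / 2000,
                            overlap_rate = 1 / 50000,
                            rra_padj = 0.01, fe_min = 1.25,
                            fe_high = 1.5, fdr_max = 0.05,
                            fpkm_min = 0.5, fc_min = 1.25,
                            min_studies = 2L) {
  mode <- match.arg(mode)
  stopifnot(rra_padj > 0, fe_min > 0, fe_high > 0, fdr_max > 0,
            enrich_rate > 0, overlap_rate > 0, fc_min > 1)
  structure(list(seed = as.integer(seed), mode = mode, studies = studies,
                 biotypes = biotypes, meta = meta, promoter = promoter,
                 pwm = pwm, ppi = ppi, enrich_rate = enrich_rate,
                 overlap_rate = overlap_rate, rra_padj = rra_padj,
                 fe_min = fe_min, fe_high = fe_high, fdr_max = fdr_max,
                 fpkm_min = fpkm_min, fc_min = fc_min,
                 min_studies = min_studies),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$mode == "files") {
    if (is.null(config$studies) || !length(config$studies))
      stop("mode 'files' requires at least one study entry", call. = FALSE)
    missing <- Filter(function(s) !file.exists(s$path), config$studies)
    if (length(missing))
      stop(sprintf("missing study file(s): %s",
                   paste(vapply(missing, `[[`, character(1), "path"),
                         collapse = ", ")), call. = FALSE)
    if (is.null(config$biotypes) || !file.exists(config$biotypes))
      stop("mode 'files' requires an existing biotype TSV", call. = FALSE)
  }
  invisible(config)
}

write_gene_set <- function(ids, path) {
  writeLines(sort(ids), path)
  invisible(path)
}

#' Run the pipeline end to end
#'
#' Stages run in order; any stage error aborts with the stage name. Every
#' written file is md5-hashed into `manifest.json`, which also embeds the
#' resolved configuration, so a run is reproducible from the manifest
#' alone and reruns under an identical config are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created; existing files overwritten).
#' @return Invisibly, the manifest list (`config`, `counts`, `files`).
#' @export
run_pipeline <- function(config, outdir) {
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stage <- "init"
  res <- tryCatch({
    # --- ingest -------------------------------------------------------
    stage <- "ingest"
    if (config$mode == "synthetic") {
      mc <- do.call(meta_sim_config, c(config$meta, seed = config$seed))
      sim <- simulate_meta_tables(mc)
      tables <- sim$tables
      write_study_tables(tables, file.path(outdir, "studies"))
      biotypes <- stats::setNames(
        rep("protein_coding", mc$n_genes),
        sprintf("gene%05d", seq_len(mc$n_genes)))
      write_tsv(data.frame(gene_id = names(biotypes), biotype = biotypes),
                file.path(outdir, "biotypes.tsv"))
      write_gene_set(sim$truth$true_up_genes,
                     file.path(outdir, "truth_up.txt"))
      write_gene_set(sim$truth$true_down_genes,
                     file.path(outdir, "truth_down.txt"))
    } else {
      tables <- lapply(config$studies, function(s)
        read_study_table(s$path, s$platform))
      bt <- read_tsv(config$biotypes)
      biotypes <- stats::setNames(bt$biotype, bt$gene_id)
    }
    counts$studies <- length(tables)

    stage <- "rank"
    ranked <- lapply(tables, filter_and_rank, gene_biotypes = biotypes,
                     fc_min = config$fc_min)
    rank_rows <- do.call(rbind, lapply(ranked, function(r)
      do.call(rbind, lapply(r, function(l) if (length(l$gene_id))
        data.frame(study_id = l$study_id, direction = l$direction,
                   gene_id = l$gene_id,
                   normalized_rank = sprintf("%.8g", l$normalized_rank),
                   stringsAsFactors = FALSE)))))
    write_tsv(rank_rows, file.path(outdir, "ranked_lists.tsv"))

    # --- aggregate ----------------------------------------------------
    stage <- "aggregate"
    agg <- lapply(c(up = "up", down = "down"), function(d) {
      a <- aggregate_ranks(lapply(ranked, `[[`, d),
                           min_studies = config$min_studies,
                           padj_threshold = config$rra_padj)
      out <- a
      for (col in c("rho", "p_bonf", "padj"))
        out[[col]] <- sprintf("%.8g", out[[col]])
      write_tsv(out, file.path(outdir, sprintf("aggregation_%s.tsv", d)))
      write_gene_set(a$gene_id[a$is_deg],
                     file.path(outdir, sprintf("degs_%s.txt", d)))
      a
    })
    deg_sets <- lapply(agg, function(a) a$gene_id[a$is_deg])
    counts$degs_up <- length(deg_sets$up)
    counts$degs_down <- length(deg_sets$down)
    cmp <- compare_deg_sets(deg_sets)
    counts$degs_shared <- unname(cmp$intersections["up", "down"])

    if (config$mode == "files") {
      manifest <- finish_manifest(config, counts, outdir)
      return(manifest)
    }

    # --- promoters ----------------------------------------------------
    stage <- "promoters"
    pwms <- do.call(simulate_pwm_library,
                    c(config$pwm, seed = config$seed))
    write_pwms(pwms, file.path(outdir, "pwms.transfac"), "transfac")
    write_pwms(pwms, file.path(outdir, "pwms.jaspar"), "jaspar")
    pc <- do.call(promoter_sim_config,
                  c(config$promoter,
                    list(planted_pwm_ids = pwms[[1]]$matrix_id,
                         seed = config$seed)))
    corpus <- simulate_promoter_corpus(pc, pwms)
    Biostrings::writeXStringSet(corpus$deg,
                                file.path(outdir, "promoters_deg.fasta"))
    Biostrings::writeXStringSet(corpus$ref,
                                file.path(outdir, "promoters_ref.fasta"))
    counts$deg_promoters <- length(corpus$deg)
    counts$ref_promoters <- length(corpus$ref)

    # --- scan ---------------------------------------------------------
    stage <- "scan"
    pwms <- lapply(pwms, log_odds_matrix)
    cals <- lapply(pwms, calibrate_threshold, background_seqs = corpus$ref,
                   target_rate = config$enrich_rate)
    cal_df <- data.frame(
      matrix_id = vapply(cals, `[[`, character(1), "matrix_id"),
      target_rate = config$enrich_rate,
      threshold = sprintf("%.6g", vapply(cals, `[[`, numeric(1),
                                         "threshold")),
      achieved_rate = sprintf("%.6g", vapply(cals, `[[`, numeric(1),
                                             "achieved_rate")))
    write_tsv(cal_df, file.path(outdir, "calibrations.tsv"))
    deg_hits <- scan_library(corpus$deg, pwms, cals)
    ref_hits <- scan_library(corpus$ref, pwms, cals)
    hit_out <- deg_hits
    hit_out$score <- sprintf("%.6g", hit_out$score)
    write_tsv(hit_out, file.path(outdir, "hits_deg.tsv"))
    counts$deg_hits <- nrow(deg_hits)

    # --- enrich -------------------------------------------------------
    stage <- "enrich"
    tf_map <- matrix_tf_map(pwms)
    enr <- enrich_library(deg_hits, ref_hits, names(corpus$deg),
                          names(corpus$ref), tf_map,
                          fe_min = config$fe_min, fe_high = config$fe_high,
                          fdr_max = config$fdr_max)
    enr_out <- enr
    for (col in c("odds_ratio", "fe_adj", "fisher_p", "fdr"))
      enr_out[[col]] <- sprintf("%.6g", enr_out[[col]])
    write_tsv(enr_out, file.path(outdir, "enrichment.tsv"))
    tf_sum <- collapse_to_tf(enr, tf_map, fe_min = config$fe_min,
                             fe_high = config$fe_high,
                             fdr_max = config$fdr_max)
    tf_out <- tf_sum
    for (col in c("fe_adj_max", "fdr_min"))
      tf_out[[col]] <- sprintf("%.6g", tf_out[[col]])
    write_tsv(tf_out, file.path(outdir, "tf_summary.tsv"))
    counts$significant_matrices <- sum(enr$significant)

    # --- overlap ------------------------------------------------------
    stage <- "overlap"
    ov_cals <- lapply(pwms, calibrate_threshold,
                      background_seqs = corpus$ref,
                      target_rate = config$overlap_rate)
    ov_hits <- scan_library(corpus$deg, pwms, ov_cals)
    ov_hits$tf <- unname(tf_map[ov_hits$matrix_id])
    ov <- overlap_percent(split(ov_hits, ov_hits$tf))
    ov_out <- ov
    ov_out$percent_overlapped <- sprintf("%.6g", ov_out$percent_overlapped)
    write_tsv(ov_out, file.path(outdir, "overlap.tsv"))

    # --- cluster ------------------------------------------------------
    stage <- "cluster"
    ppi <- do.call(simulate_ppi_edges, c(config$ppi, seed = config$seed))
    write_tsv(ppi$edges, file.path(outdir, "ppi_edges.tsv"))
    part <- mcl_cluster(ppi$edges,
                        nodes = names(ppi$truth$planted_clusters))
    write_tsv(data.frame(node = names(part$membership),
                         cluster = unname(part$membership)),
              file.path(outdir, "clusters.tsv"))
    counts$clusters <- part$n_clusters

    stage <- "manifest"
    finish_manifest(config, counts, outdir)
  }, error = function(e) {
    writeLines(sprintf("failed at stage '%s': %s", stage,
                       conditionMessage(e)),
               file.path(outdir, "failed"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

finish_manifest <- function(config, counts, outdir) {
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        c("manifest.json", "failed")))
  manifest <- list(
    config = unclass(config),
    counts = counts,
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(outdir, f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  stage_log("manifest", files = length(files))
  manifest
}

#' Intersect gene-class lists with DEG sets after an expression filter
#'
#' Each class is first restricted to genes expressed at or above
#' `fpkm_min` (genes absent from the FPKM table count as below the
#' cutoff and are logged), then intersected with each DEG set.
#'
#' @param deg_sets named list of DEG gene-id vectors.
#' @param class_lists named list of gene-class id vectors.
#' @param fpkm_table named numeric vector (gene id -> FPKM) or data.frame
#'   with columns `gene_id, fpkm`.
#' @param fpkm_min expression cutoff (default 0.5; genes with
#'   FPKM < 0.5 are removed).
#' @return data.frame `class, deg_set, class_size, deg_overlap, percent`
#'   (`percent` is `NA` for classes empty after filtering).
#' @export
class_intersections <- function(deg_sets, class_lists, fpkm_table,
                                fpkm_min = 0.5) {
  if (is.data.frame(fpkm_table))
    fpkm_table <- stats::setNames(fpkm_table$fpkm, fpkm_table$gene_id)
  rows <- list()
  for (cl in names(class_lists)) {
    genes <- unique(class_lists[[cl]])
    fpkm <- fpkm_table[genes]
    uncovered <- sum(is.na(fpkm))
    if (uncovered)
      stage_log("classes", class = cl, genes_without_fpkm = uncovered)
    kept <- genes[!is.na(fpkm) & fpkm >= fpkm_min]
    for (ds in names(deg_sets)) {
      ov <- length(intersect(kept, deg_sets[[ds]]))
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, deg_set = ds, class_size = length(kept),
        deg_overlap = ov,
        percent = if (length(kept)) 100 * ov / length(kept) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
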