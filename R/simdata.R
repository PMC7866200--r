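# Synthetic-data generators with planted ground truth. Every downstream
# stage of the pipeline (ingest -> rank aggregation -> promoter scanning ->
# enrichment -> overlap/clustering) can be exercised against these without
# any external download. All generators are deterministic under a fixed
# seed; one global seed fans out to per-generator seeds via derive_seed().

#' Adjusted-p cutoffs of the per-study inclusion filter, by platform
#'
#' RNA-seq and CAGE (both count-based sequencing assays) use 0.05; DNA
#' microarray uses the laxer 0.1.
#' @export
platform_padj_cutoffs <- c("rna-seq" = 0.05, "microarray" = 0.1,
                           "cage" = 0.05)

#' Configuration for the multi-study differential-expression simulator
#'
#' Describes a universe of genes measured across several studies with a
#' shared planted core of true up- and down-regulated genes. Null genes
#' carry Uniform(0,1) adjusted p-values and fold changes near 1 (the
#' simulator emulates post-adjustment result tables, not raw tests). A true
#' DEG "penetrates" any one study with probability `penetrance`: in a
#' penetrant cell its adjusted p is the platform cutoff times a
#' Beta(`true_p_scale`, 1) draw (hence guaranteed below the cutoff and
#' strongly concentrated near 0) and its |fold change| exceeds 1.25 with
#' the planted sign; in a non-penetrant cell it is drawn as a null.
#'
#' @param n_genes number of genes in the universe.
#' @param n_studies number of studies.
#' @param n_true_up,n_true_down planted true DEG counts per direction.
#' @param penetrance probability a true DEG passes the per-study inclusion
#'   filter in any one study.
#' @param true_p_scale shape `a < 1` of the Beta(a, 1) draw for penetrant
#'   adjusted p-values.
#' @param missing_rate fraction of gene-by-study cells left unmeasured.
#' @param platform_mix fraction of studies labelled `microarray`; the rest
#'   are `rna-seq`.
#' @param null_lfc_sd standard deviation of null log2 fold changes.
#' @param true_lfc_excess mean excess of |log2 fold change| beyond
#'   log2(1.25) in penetrant cells (exponential draw).
#' @param seed integer seed.
#' @return A list of class `meta_sim_config`.
#' @export
meta_sim_config <- function(n_genes = 5000, n_studies = 10,
                            n_true_up = 100, n_true_down = 100,
                            penetrance = 0.7, true_p_scale = 0.1,
                            missing_rate = 0.1, platform_mix = 0.5,
                            null_lfc_sd = 0.25, true_lfc_excess = 0.5,
                            seed = 1) {
  n_genes <- check_count(n_genes, "n_genes", 1L)
  n_studies <- check_count(n_studies, "n_studies", 1L)
  n_true_up <- check_count(n_true_up, "n_true_up")
  n_true_down <- check_count(n_true_down, "n_true_down")
  check_fraction(penetrance, "penetrance")
  check_fraction(missing_rate, "missing_rate")
  check_fraction(platform_mix, "platform_mix")
  if (n_true_up + n_true_down > n_genes)
    stop("n_true_up + n_true_down must not exceed n_genes", call. = FALSE)
  if (!is.numeric(true_p_scale) || true_p_scale <= 0)
    stop("true_p_scale must be positive", call. = FALSE)
  structure(list(n_genes = n_genes, n_studies = n_studies,
                 n_true_up = n_true_up, n_true_down = n_true_down,
                 penetrance = penetrance, true_p_scale = true_p_scale,
                 missing_rate = missing_rate, platform_mix = platform_mix,
                 null_lfc_sd = null_lfc_sd,
                 true_lfc_excess = true_lfc_excess,
                 seed = as.integer(seed)),
            class = "meta_sim_config")
}

#' Simulate per-study differential-expression result tables
#'
#' @param config a [meta_sim_config()].
#' @return A list with components `tables` (list of `study_table` objects,
#'   one per study) and `truth` (a `truth_set` with `true_up_genes` and
#'   `true_down_genes`).
#' @export
simulate_meta_tables <- function(config) {
  stopifnot(inherits(config, "meta_sim_config"))
  with_seed(derive_seed(config$seed, "meta"), {
    genes <- sprintf("gene%05d", seq_len(config$n_genes))
    tagged <- sample(genes, config$n_true_up + config$n_true_down)
    true_up <- sort(utils::head(tagged, config$n_true_up))
    true_down <- sort(utils::tail(tagged, config$n_true_down))
    sign_of <- stats::setNames(integer(config$n_genes), genes)
    sign_of[true_up] <- 1L
    sign_of[true_down] <- -1L

    n_micro <- round(config$n_studies * config$platform_mix)
    platforms <- rep(c("microarray", "rna-seq"),
                     c(n_micro, config$n_studies - n_micro))

    tables <- vector("list", config$n_studies)
    for (s in seq_len(config$n_studies)) {
      study_id <- sprintf("study%02d", s)
      platform <- platforms[s]
      cutoff <- platform_padj_cutoffs[[platform]]
      measured <- genes[stats::runif(config$n_genes) >= config$missing_rate]
      n <- length(measured)

      padj <- stats::runif(n)
      lfc <- stats::rnorm(n, 0, config$null_lfc_sd)
      sgn <- sign_of[measured]
      pen <- sgn != 0L & stats::runif(n) < config$penetrance
      k <- sum(pen)
      if (k > 0) {
        padj[pen] <- cutoff * stats::rbeta(k, config$true_p_scale, 1)
        lfc[pen] <- sgn[pen] *
          (log2(1.25) + stats::rexp(k, 1 / config$true_lfc_excess))
      }
      tables[[s]] <- study_table(
        data.frame(gene_id = measured, fold_change = 2^lfc, padj = padj,
                   stringsAsFactors = FALSE),
        study_id = study_id, platform = platform)
    }
    truth <- structure(list(true_up_genes = true_up,
                            true_down_genes = true_down),
                       class = "truth_set")
    list(tables = tables, truth = truth)
  })
}

#' Configuration for the synthetic promoter corpus
#'
#' Two groups of promoters are generated: a "DEG" group and a reference
#' group, both i.i.d. nucleotide backgrounds at a given GC content. For
#' each PWM named in `planted_pwm_ids`, each DEG-group promoter carries a
#' planted binding site with probability `planted_prevalence` (reference
#' promoters with probability `background_prevalence`). Planted sites are
#' sampled column-wise from the PWM base probabilities, placed on a random
#' strand at a random offset, and never overlap another planted site in
#' the same promoter.
#'
#' @param n_deg,n_ref promoter counts in the DEG and reference groups.
#' @param promoter_length promoter length in bp (default 2000, i.e. the
#'   -1500..+500 window around a TSS).
#' @param gc_content fraction of G+C in the background.
#' @param planted_pwm_ids character vector of matrix ids to plant.
#' @param planted_prevalence,background_prevalence per-promoter planting
#'   probabilities for the two groups.
#' @param seed integer seed.
#' @return A list of class `promoter_sim_config`.
#' @export
promoter_sim_config <- function(n_deg = 300, n_ref = 5000,
                                promoter_length = 2000, gc_content = 0.41,
                                planted_pwm_ids = character(),
                                planted_prevalence = 0.4,
                                background_prevalence = 0,
                                seed = 1) {
  n_deg <- check_count(n_deg, "n_deg", 1L)
  n_ref <- check_count(n_ref, "n_ref")
  promoter_length <- check_count(promoter_length, "promoter_length", 1L)
  check_fraction(gc_content, "gc_content")
  check_fraction(planted_prevalence, "planted_prevalence")
  check_fraction(background_prevalence, "background_prevalence")
  structure(list(n_deg = n_deg, n_ref = n_ref,
                 promoter_length = promoter_length,
                 gc_content = gc_content,
                 planted_pwm_ids = as.character(planted_pwm_ids),
                 planted_prevalence = planted_prevalence,
                 background_prevalence = background_prevalence,
                 seed = as.integer(seed)),
            class = "promoter_sim_config")
}

# Sample one site column-wise from PWM base probabilities, as base codes
# (A=1, C=2, G=3, T=4).
sample_site_codes <- function(pwm) {
  vapply(seq_len(pwm$length), function(i)
    sample.int(4L, 1L, prob = pwm$probabilities[i, ]), integer(1))
}

#' Simulate a promoter corpus with planted motif sites
#'
#' @param config a [promoter_sim_config()].
#' @param pwms list of `pwm` objects; must contain every id in
#'   `config$planted_pwm_ids`.
#' @return A list with `deg` and `ref` ([Biostrings::DNAStringSet]s named
#'   `degNNNN` / `refNNNN`) and `truth`, a `truth_set` whose
#'   `planted_site_coordinates` is a data.frame with columns
#'   `promoter_id, matrix_id, start, end, strand` (0-based half-open).
#' @export
simulate_promoter_corpus <- function(config, pwms) {
  stopifnot(inherits(config, "promoter_sim_config"))
  planted <- lapply(config$planted_pwm_ids, function(id) {
    hit <- Filter(function(p) p$matrix_id == id, pwms)
    if (!length(hit))
      stop(sprintf("planted PWM id '%s' not found in library", id),
           call. = FALSE)
    hit[[1]]
  })
  if (length(planted)) {
    max_len <- max(vapply(planted, function(p) p$length, integer(1)))
    if (max_len > config$promoter_length)
      stop("planted motif longer than promoter", call. = FALSE)
  }
  with_seed(derive_seed(config$seed, "promoters"), {
    base_probs <- c(A = (1 - config$gc_content) / 2,
                    C = config$gc_content / 2,
                    G = config$gc_content / 2,
                    T = (1 - config$gc_content) / 2)
    gen_group <- function(prefix, n, prevalence) {
      if (n == 0L)
        return(list(seqs = Biostrings::DNAStringSet(), rec = list()))
      ids <- sprintf("%s%04d", prefix, seq_len(n))
      len <- config$promoter_length
      # background drawn in bulk as base codes; promoter i occupies
      # positions (i-1)*len + 1 .. i*len
      v <- sample.int(4L, n * len, replace = TRUE, prob = base_probs)
      rec <- list()
      occupied <- vector("list", n)  # planted positions per promoter
      for (pwm in planted) {
        L <- pwm$length
        carriers <- which(stats::runif(n) < prevalence)
        for (i in carriers) {
          # rejection-sample an offset whose window is free of earlier plants
          start0 <- NA_integer_
          for (try in 1:50) {
            cand <- sample.int(len - L + 1L, 1L) - 1L
            win <- (cand + 1L):(cand + L)
            if (!any(win %in% occupied[[i]])) { start0 <- cand; break }
          }
          if (is.na(start0)) next
          win <- (start0 + 1L):(start0 + L)
          site <- sample_site_codes(pwm)
          strand <- sample(c("+", "-"), 1L)
          if (strand == "-") site <- rev(5L - site)  # reverse complement
          v[(i - 1L) * len + win] <- site
          occupied[[i]] <- c(occupied[[i]], win)
          rec[[length(rec) + 1L]] <- data.frame(
            promoter_id = ids[i], matrix_id = pwm$matrix_id,
            start = start0, end = start0 + L, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
      big <- intToUtf8(c(65L, 67L, 71L, 84L)[v])  # A C G T codepoints
      set <- Biostrings::DNAStringSet(
        substring(big, seq(1L, n * len, by = len),
                  seq(len, n * len, by = len)))
      names(set) <- ids
      list(seqs = set, rec = rec)
    }
    deg <- gen_group("deg", config$n_deg, config$planted_prevalence)
    ref <- gen_group("ref", config$n_ref, config$background_prevalence)
    coords <- do.call(rbind, c(deg$rec, ref$rec))
    if (is.null(coords))
      coords <- data.frame(promoter_id = character(), matrix_id = character(),
                           start = integer(), end = integer(),
                           strand = character(), stringsAsFactors = FALSE)
    truth <- structure(list(planted_site_coordinates = coords),
                       class = "truth_set")
    list(deg = deg$seqs, ref = ref$seqs, truth = truth)
  })
}

#' Simulate a library of position weight matrices
#'
#' The library always contains at least one near-consensus (low-entropy)
#' matrix (`*_M001`, dominant base count 97/100 per column) and, when
#' `n_matrices >= 2`, one fully degenerate matrix (last id, near-uniform
#' counts); the remainder have Dirichlet-like random columns of
#' intermediate information content.
#'
#' @param n_matrices number of matrices.
#' @param length_range integer range (min, max) of motif lengths in bp;
#'   all lengths must be >= 4.
#' @param seed integer seed.
#' @param id_prefix prefix of matrix ids (default `"SIM"`).
#' @return A list of `pwm` objects (see [parse_pwms()]), each annotated
#'   with a TF name `TF<k>`.
#' @export
simulate_pwm_library <- function(n_matrices, length_range = c(8L, 12L),
                                 seed = 1, id_prefix = "SIM") {
  n_matrices <- check_count(n_matrices, "n_matrices", 1L)
  if (min(length_range) < 4)
    stop("motif lengths must be >= 4", call. = FALSE)
  with_seed(derive_seed(seed, "pwmlib"), {
    rng <- seq(length_range[1], length_range[2])
    lens <- if (length(rng) == 1L) rep.int(rng, n_matrices)
            else sample(rng, n_matrices, replace = TRUE)
    lapply(seq_len(n_matrices), function(k) {
      L <- lens[k]
      counts <- matrix(0, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
      if (k == 1L) {                      # near-consensus
        cons <- sample.int(4L, L, replace = TRUE)
        for (i in seq_len(L)) {
          counts[i, ] <- 1
          counts[i, cons[i]] <- 97
        }
      } else if (k == n_matrices) {       # degenerate
        for (i in seq_len(L))
          counts[i, ] <- 22 + sample.int(6L, 4L, replace = TRUE)
      } else {                            # intermediate information
        for (i in seq_len(L)) {
          w <- stats::rgamma(4, shape = 0.8)
          counts[i, ] <- round(96 * w / sum(w)) + 1
        }
      }
      new_pwm(sprintf("%s_M%03d", id_prefix, k),
              tf_names = sprintf("TF%d", k), counts = counts)
    })
  })
}

#' Simulate a clustered TF interaction graph (planted partition)
#'
#' @param cluster_sizes integer vector of planted cluster sizes.
#' @param p_within,p_between edge probabilities inside and between planted
#'   clusters; `p_within` must exceed `p_between`.
#' @param seed integer seed.
#' @param node_prefix node name prefix (default `"TF"`).
#' @return A list with `edges` (data.frame `node_a, node_b, weight`) and
#'   `truth` (a `truth_set` with `planted_clusters`, a named integer map
#'   node -> cluster).
#' @export
simulate_ppi_edges <- function(cluster_sizes, p_within = 0.9,
                               p_between = 0.05, seed = 1,
                               node_prefix = "TF") {
  check_fraction(p_within, "p_within")
  check_fraction(p_between, "p_between")
  if (p_within <= p_between)
    stop("p_within must exceed p_between", call. = FALSE)
  with_seed(derive_seed(seed, "ppi"), {
    n <- sum(cluster_sizes)
    nodes <- sprintf("%s%02d", node_prefix, seq_len(n))
    membership <- stats::setNames(rep(seq_along(cluster_sizes),
                                      cluster_sizes), nodes)
    pairs <- utils::combn(n, 2L)
    same <- membership[pairs[1, ]] == membership[pairs[2, ]]
    p <- ifelse(same, p_within, p_between)
    keep <- stats::runif(ncol(pairs)) < p
    edges <- data.frame(node_a = nodes[pairs[1, keep]],
                        node_b = nodes[pairs[2, keep]],
                        weight = round(stats::runif(sum(keep), 0.4, 0.999), 3),
                        stringsAsFactors = FALSE)
    truth <- structure(list(planted_clusters = membership),
                       class = "truth_set")
    list(edges = edges, truth = truth)
  })
}

#' Write study tables as TSV files
#'
#' One file per study, header `gene_id, fold_change, padj, platform`,
#' named `<study_id>.tsv`.
#'
#' @param tables list of `study_table` objects.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_study_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(tables, function(st) {
    df <- st$table
    df$platform <- st$platform
    df$fold_change <- sprintf("%.6g", df$fold_change)
    df$padj <- sprintf("%.6g", df$padj)
    write_tsv(df, file.path(dir, paste0(st$study_id, ".tsv")))
  }, character(1))
  invisible(paths)
}
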