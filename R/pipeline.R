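#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow with defaults equal to
#' the values the analysis is built around: 6-nt indexes, 36-nt reads,
#' homopolymer threshold 0.80, minimum insert length 14, at most 2 alignment
#' mismatches, exact-test significance 0.05 without multiple-testing
#' selection, consensus target rule (Poisson p < 0.05 and >= 2 programs),
#' and the ordered-list weight decay beta = log(100)/100.
#'
#' @param seed master seed; every stage derives its own fixed offset seed.
#' @param n_mirnas,n_families,n_clusters,n_contaminants reference layout.
#' @param groups two group labels.
#' @param indexes named 6-nt index set (RNA).
#' @param n_reads reads per library.
#' @param error_rate per-base substitution rate on inserts.
#' @param contaminant_fractions see [simulate_library()].
#' @param dispersion common NB dispersion of the simulation.
#' @param sdlog abundance skew (see [simulate_abundances()]).
#' @param n_de_families,n_de_clusters number of planted differentially
#'   expressed families / clusters.
#' @param fc_range fold-change range for planted members (log-uniform).
#' @param de_alpha exact-test significance threshold.
#' @param array_replicates,compression,array_noise_sd,array_background
#'   array-arm parameters (see [simulate_array()]).
#' @param beta,n_perm ordered-list similarity parameters.
#' @param consensus_alpha,min_programs consensus target filter parameters.
#' @param n_genes,target_background_rate,target_q binding-site simulation.
#' @param out_dir optional output directory for artifacts + manifest.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            n_mirnas = 120, n_families = 24, n_clusters = 8,
                            n_contaminants = 6,
                            groups = c("FCx", "HP"),
                            indexes = default_indexes(),
                            n_reads = 20000, error_rate = 0.005,
                            contaminant_fractions = c(
                              adapter_dimer = 0.05, contaminant = 0.18,
                              homopolymer = 0.02, short_insert = 0.03,
                              unindexed = 0.08),
                            dispersion = 0.1, sdlog = 2.5,
                            n_de_families = 2, n_de_clusters = 2,
                            fc_range = c(2, 300),
                            de_alpha = 0.05,
                            array_replicates = 3, compression = 0.5,
                            array_noise_sd = 0.5, array_background = 2,
                            beta = log(100) / 100, n_perm = 1000,
                            consensus_alpha = 0.05, min_programs = 2,
                            n_genes = 150, target_background_rate = 1e-4,
                            target_q = 0.3,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$groups) == 2, cfg$de_alpha > 0, cfg$de_alpha < 1,
            cfg$n_reads > 0, all(nchar(as_dna(cfg$indexes)) == 6))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic workflow end to end
#'
#' Builds a reference, simulates group-wise abundances with fold changes
#' planted in designated families and clusters, generates one indexed
#' library per (group, index), preprocesses, aligns and counts, runs the
#' exact-test and moderated-t differential expression arms, compares the
#' platforms (Spearman, weighted ordered-list similarity, replicate
#' concordance, top-15 abundance shares), and applies the consensus target
#' filter to a simulated binding-site table for the differentially
#' expressed miRNAs. Fully deterministic given `config$seed`. If
#' `config$out_dir` is set, all tabular artifacts are written as TSV/JSON
#' together with a manifest of parameters and file hashes.
#'
#' @param config a `pipeline_config`.
#' @return list of class `mirseq_run` with elements `reference`, `profile`,
#'   `libraries`, `preprocess`, `count_table`, `dispersion`, `de_seq`,
#'   `array`, `de_array`, `family_cluster_report`, `crossplatform`,
#'   `targets`, `run_report`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  # stage seeds stay below .Machine$integer.max for any master seed
  seed <- as.integer(cfg$seed %% 2000000L)
  stage <- function(k) seed * 1000L + k

  ref <- build_reference(cfg$n_mirnas, cfg$n_families, cfg$n_clusters,
                         cfg$n_contaminants, seed = stage(1))
  fam_map <- stats::setNames(ref$mirnas$family_id, ref$mirnas$name)
  clu_map <- stats::setNames(ref$mirnas$cluster_id, ref$mirnas$name)

  ## plant fold changes in whole families / clusters, alternating direction.
  ## Groups are chosen among the mid/low-abundance tier and each member's
  ## post-change mass share is capped: in real libraries the large-fold-change
  ## miRNAs are never the dominant tier, and an uncapped change would shift
  ## the composition of every null miRNA.
  baseline <- simulate_abundances(ref, numeric(0), cfg$dispersion,
                                  seed = stage(3), sdlog = cfg$sdlog,
                                  groups = cfg$groups)$abundance[, 1]
  set.seed(stage(2))
  de_spec <- numeric(0)
  pick_groups <- function(map, n) {
    tab <- table(map)
    mass <- tapply(baseline[names(map)], map, max)
    ids <- names(tab)[tab >= 2 & mass[names(tab)] < 0.003]
    sample(ids, min(n, length(ids)))
  }
  chosen <- c(pick_groups(fam_map, cfg$n_de_families),
              pick_groups(clu_map, cfg$n_de_clusters))
  dir_up2 <- rep_len(c(TRUE, FALSE), length(chosen))
  for (i in seq_along(chosen)) {
    members <- names(fam_map)[fam_map == chosen[i] | clu_map == chosen[i]]
    fc_max <- pmax(pmin(cfg$fc_range[2], 0.003 / baseline[members]),
                   cfg$fc_range[1])
    fc <- exp(stats::runif(length(members), log(cfg$fc_range[1]), log(fc_max)))
    if (!dir_up2[i]) fc <- 1 / fc
    de_spec[members] <- fc
  }

  profile <- simulate_abundances(ref, de_spec, cfg$dispersion,
                                 seed = stage(3), sdlog = cfg$sdlog,
                                 groups = cfg$groups)

  libs <- list()
  k <- 0L
  for (g in cfg$groups) for (j in seq_along(cfg$indexes)) {
    k <- k + 1L
    lib <- simulate_library(ref, profile, g, cfg$indexes[[j]],
                            n_reads = cfg$n_reads,
                            error_rate = cfg$error_rate,
                            contaminant_fractions = cfg$contaminant_fractions,
                            seed = stage(10L + k),
                            sample_id = paste0(g, "-", names(cfg$indexes)[j]))
    libs[[lib$sample_id]] <- lib
  }
  group_of <- stats::setNames(vapply(libs, `[[`, character(1), "group"),
                              names(libs))

  pp <- run_preprocess(libs, ref, index_set = cfg$indexes)
  hits <- lapply(pp, function(x)
    align_inserts(x$inserts$insert, ref)$mirna)
  ct <- build_count_table(hits, group_of)
  disp <- estimate_common_dispersion(ct)
  de_seq <- de_table(ct, phi = disp$phi, alpha = cfg$de_alpha)
  report <- summarize_run(pp, hits, ct, group_of)

  am <- simulate_array(profile, cfg$array_replicates, cfg$compression,
                       cfg$array_noise_sd, cfg$array_background,
                       seed = stage(50))
  pc <- array_present_calls(am)
  det_union <- unique(unlist(pc$detected))
  am_det <- structure(unclass(am)[rownames(am) %in% det_union, , drop = FALSE],
                      groups = attr(am, "groups"),
                      background = attr(am, "background"),
                      noise_sd = attr(am, "noise_sd"),
                      class = class(am))
  de_arr <- array_de_moderated_t(am_det, alpha = cfg$de_alpha)

  fc_report <- group_de_by_family_cluster(de_seq, de_arr, fam_map, clu_map)

  ## cross-platform concordance on miRNAs detected by both platforms
  norm <- normalize_geometric(ct)
  cross <- list(replicate_concordance = replicate_concordance(ct))
  for (gi in seq_along(cfg$groups)) {
    g <- cfg$groups[gi]
    common <- intersect(ct$detected[[g]], pc$detected[[g]])
    seq_v <- rowMeans(norm$concentration[common, group_of[colnames(norm$concentration)] == g,
                                         drop = FALSE])
    arr_v <- rowMeans(unclass(am)[common, attr(am, "groups") == g, drop = FALSE])
    cross[[g]] <- list(
      n_common = length(common),
      spearman = spearman_rho(seq_v, arr_v),
      similarity = ordered_list_similarity(seq_v, arr_v, beta = cfg$beta,
                                           n_perm = cfg$n_perm,
                                           seed = stage(60L + gi)),
      top15_share_counts = abundance_share(ct, 15, g),
      top15_share_array = abundance_share(am, 15, g))
  }

  ## consensus target filter on the differentially expressed miRNAs
  sig <- fc_report$mirna[!fc_report$is_star]
  up_by_region <- split(fc_report$mirna[!fc_report$is_star],
                        fc_report$direction[!fc_report$is_star])
  targets <- NULL
  if (length(sig)) {
    set.seed(stage(70))
    planted <- do.call(rbind, lapply(sig, function(m) data.frame(
      mirna = m,
      gene = sprintf("gene-%04d", sample(cfg$n_genes, sample(3:8, 1))),
      n_sites = sample(2:4, 1), n_programs = sample(2:5, 1),
      stringsAsFactors = FALSE)))
    preds <- simulate_binding_sites(sig, n_genes = cfg$n_genes,
                                    background_rate = cfg$target_background_rate,
                                    q = cfg$target_q, planted = planted,
                                    seed = stage(71))
    calls <- consensus_filter(preds, alpha = cfg$consensus_alpha,
                              min_programs = cfg$min_programs,
                              background_rate = cfg$target_background_rate)
    targets <- list(predictions = preds, calls = calls,
                    summary = target_summary(calls, up_by_region))
  }

  run <- structure(list(
    reference = ref, profile = profile, libraries = libs, preprocess = pp,
    count_table = ct, dispersion = disp, de_seq = de_seq,
    array = am, present_calls = pc, de_array = de_arr,
    family_cluster_report = fc_report, crossplatform = cross,
    targets = targets, run_report = report, config = cfg),
    class = "mirseq_run")
  if (!is.null(cfg$out_dir)) write_run_artifacts(run, cfg$out_dir)
  run
}

#' @export
print.mirseq_run <- function(x, ...) {
  cat("mirseq_run (seed ", x$config$seed, ")\n", sep = "")
  print(x$run_report)
  cat("\nDE:", sum(x$de_seq$significant), "by sequencing,",
      sum(x$de_array$significant), "by array;",
      sum(x$family_cluster_report$family_highlighted |
            x$family_cluster_report$cluster_highlighted),
      "rows in highlighted families/clusters\n")
  invisible(x)
}

write_run_artifacts <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reference(run$reference, file.path(dir, "reference"))
  write_count_table(run$count_table, file.path(dir, "counts.tsv"))
  write_tsv(as.data.frame(run$de_seq), file.path(dir, "de_seq.tsv"))
  write_tsv(as.data.frame(run$de_array), file.path(dir, "de_array.tsv"))
  write_tsv(as.data.frame(run$family_cluster_report),
            file.path(dir, "de_families_clusters.tsv"))
  write_tsv(as.data.frame(run$run_report), file.path(dir, "run_report.tsv"))
  if (!is.null(run$targets)) {
    write_tsv(run$targets$calls, file.path(dir, "target_calls.tsv"))
  }
  sim <- lapply(run$config$groups, function(g) {
    s <- run$crossplatform[[g]]
    list(group = g, score = s$similarity$score, p = s$similarity$p_value,
         beta = s$similarity$beta, n_perm = s$similarity$n_perm,
         spearman = s$spearman)
  })
  jsonlite::write_json(sim, file.path(dir, "similarity.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(write_report(run), file.path(dir, "report.txt"))
  files <- setdiff(list.files(dir, recursive = TRUE, full.names = TRUE),
                   file.path(dir, "manifest.json"))
  cfg <- run$config
  cfg$indexes <- as.list(cfg$indexes)
  cfg$contaminant_fractions <- as.list(cfg$contaminant_fractions)
  manifest <- list(package = "mirseqpipe",
                   version = as.character(utils::packageVersion("mirseqpipe")),
                   parameters = unclass(cfg),
                   files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Human-readable run report
#'
#' Renders the run's headline results in four fixed sections: read
#' accounting, differentially expressed families/clusters, platform
#' concordance, and the consensus target summary. All numbers are taken
#' from the run's artifacts.
#'
#' @param run a `mirseq_run`.
#' @param path optional file to write to.
#' @return character vector of report lines, invisibly if `path` is given.
#' @export
write_report <- function(run, path = NULL) {
  g <- run$config$groups
  fmt_df <- function(df) utils::capture.output(print(df, row.names = FALSE))
  lines <- c("== Run accounting ==",
             fmt_df(as.data.frame(run$run_report)),
             "",
             "== Differentially expressed families and clusters ==")
  fr <- run$family_cluster_report
  hi <- fr[fr$family_highlighted | fr$cluster_highlighted, , drop = FALSE]
  lines <- c(lines,
             sprintf("significant miRNAs: %d (sequencing), %d (array)",
                     sum(run$de_seq$significant), sum(run$de_array$significant)),
             if (nrow(hi)) fmt_df(hi[, c("mirna", "family_id", "cluster_id",
                                         "detected_by", "direction")])
             else "no highlighted families or clusters",
             "",
             "== Platform concordance ==")
  for (gg in g) {
    s <- run$crossplatform[[gg]]
    lines <- c(lines, sprintf(
      "%s: %d miRNAs on both platforms; Spearman rho = %.3f; ordered-list p = %.4g; top-15 share %.1f%% (counts) vs %.1f%% (array)",
      gg, s$n_common, s$spearman, s$similarity$p_value,
      100 * s$top15_share_counts, 100 * s$top15_share_array))
  }
  off <- run$crossplatform$replicate_concordance
  off <- off[upper.tri(off)]
  lines <- c(lines,
             sprintf("replicate concordance (pairwise Spearman): %.3f - %.3f",
                     min(off), max(off)),
             "",
             "== Target summary ==")
  if (!is.null(run$targets)) {
    pm <- run$targets$summary$per_mirna
    sf <- run$targets$summary$shared_fraction
    lines <- c(lines,
               sprintf("consensus targets per miRNA: %d - %d (median %d)",
                       min(pm), max(pm), as.integer(stats::median(pm))),
               if (!is.null(sf)) sprintf("targets shared between regions: %s",
                                         paste(sprintf("%s %.1f%%", names(sf), 100 * sf),
                                               collapse = ", ")))
  } else lines <- c(lines, "no differentially expressed miRNAs; no target calls")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
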