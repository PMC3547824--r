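#' Simulate a complete discovery cohort
#'
#' Runs the genome, expression and screen generators under one
#' [sim_config()] and assembles their outputs with the planted ground truth.
#'
#' @param config a [sim_config()].
#' @return list with panel, cn, samples, expr, annotation, screen,
#'   screen_truth and truth (driver/DE-only/null ids plus the segment map).
#' @export
simulate_cohort <- function(config) {
  genomes <- generate_genomes(config)
  expression <- generate_expression(genomes, config)
  scr <- generate_screen(config)
  truth <- c(expression$truth,
             list(segment_map = config$segment_map,
                  differential_snp_ids =
                    genomes$panel$probe_id[genomes$truth$differential_snp]))
  list(panel = genomes$panel, cn = genomes$cn, samples = genomes$samples,
       expr = expression$expr, annotation = expression$annotation,
       screen = scr$screen, screen_truth = scr$truth, truth = truth,
       genome_truth = genomes$truth)
}

score_signature <- function(signature_ids, driver_ids) {
  tp <- length(intersect(signature_ids, driver_ids))
  precision <- if (length(signature_ids) > 0) tp / length(signature_ids) else NA_real_
  recall <- if (length(driver_ids) > 0) tp / length(driver_ids) else NA_real_
  list(precision = precision, recall = recall, true_positives = tp)
}

#' Run the full analysis pipeline on a simulated study
#'
#' Orchestrates every stage end to end: simulate a discovery cohort, segment
#' its copy-number profiles, run the three-gate cascade to derive the
#' signature, simulate an independent validation cohort whose two latent
#' clusters differ in signature expression, stratify its patients by PCA +
#' hierarchical clustering of the signature transcripts, evaluate the
#' clusters against overall and disease-specific mortality (Kaplan-Meier,
#' log-rank, cumulative incidence with Gray's test, multivariable Cox
#' adjusting for age, sex, HPV status and stage), and analyse the siRNA
#' screen (normalization, 30%-suppression hit calls, Fisher enrichment).
#' All randomness flows from the seeds inside the two config objects, so a
#' rerun with the same configs reproduces the report exactly.
#'
#' @param sim discovery-cohort [sim_config()].
#' @param config [pipeline_config()] of analysis constants.
#' @param validation_sim optional [sim_config()] for the validation cohort;
#'   by default the discovery config rerun under a shifted seed, with its
#'   groups reinterpreted as the two patient clusters.
#' @param dir optional output directory; when given, all stage TSV outputs
#'   and run_report.json are written there.
#' @return list of class \code{"run_report"}: stage counts, signature table,
#'   truth scores, cluster summary, survival summary, screen summary, config
#'   echo.
#' @export
run_pipeline <- function(sim = sim_config(), config = pipeline_config(),
                         validation_sim = NULL, dir = NULL) {
  stopifnot(inherits(sim, "sim_config"), inherits(config, "pipeline_config"))
  cohort <- simulate_cohort(sim)
  if (anyDuplicated(cohort$samples$sample_id))
    stop("inconsistent sample ids")

  profiles <- segment_profiles(cohort$cn, cohort$panel,
                               lam1 = config$lam1, lam2 = config$lam2)
  labels <- factor(cohort$samples$group, levels = c("primary", "met"))
  cascade <- run_cascade(cohort$expr, profiles, cohort$annotation,
                         cohort$panel, labels, config)
  scores <- score_signature(cascade$signature$transcript_id,
                            cohort$truth$driver_ids)

  # independent validation cohort: groups play the role of the two clusters
  if (is.null(validation_sim)) {
    validation_sim <- sim
    validation_sim$seed <- as.integer((sim$seed + 104729L) %% 2146489L)
  }
  vgen <- generate_genomes(validation_sim)
  vexpr <- generate_expression(vgen, validation_sim)
  true_cluster <- ifelse(vgen$samples$group == "met", 2L, 1L)

  cluster_summary <- NULL
  surv_summary <- NULL
  sig_ids <- cascade$signature$transcript_id
  if (length(sig_ids) >= config$n_pcs) {
    sub <- vexpr$expr[sig_ids, , drop = FALSE]
    pca <- pca_scores(sub, n_pcs = config$n_pcs)
    cl <- cluster_patients(pca, k = config$k_clusters, expr_subset = sub,
                           direction = cascade$signature$de_effect)
    agree <- max(mean(cl$cluster == true_cluster),
                 mean(cl$cluster == 3L - true_cluster))
    cluster_summary <- list(sizes = as.integer(table(cl$cluster)),
                            concordance = cl$concordance,
                            agreement_with_truth = agree,
                            cum_var_frac = pca$cum_var_frac)

    patients <- generate_survival(true_cluster, validation_sim)
    patients$assigned_cluster <- cl$cluster
    ev_all <- as.integer(patients$status > 0)
    lr <- logrank_test(patients$time, ev_all, patients$assigned_cluster)
    ci <- cuminc_fit(patients$time, patients$status, patients$assigned_cluster)
    gr <- gray_test(patients$time, patients$status, patients$assigned_cluster)
    covars <- data.frame(cluster2 = as.integer(patients$assigned_cluster == 2L),
                         age = patients$age,
                         sex = as.integer(patients$sex == "male"),
                         hpv = as.integer(patients$hpv == "high_risk"),
                         stage = as.integer(patients$stage == "III_IV"))
    cox <- cox_fit(covars, patients$time, ev_all)
    surv_summary <- list(logrank_p = lr$p, gray_p = gr$p,
                         cox = cox$table, cox_converged = cox$converged,
                         km = list(cluster1 = km_fit(
                           patients$time[patients$assigned_cluster == 1L],
                           ev_all[patients$assigned_cluster == 1L]),
                           cluster2 = km_fit(
                             patients$time[patients$assigned_cluster == 2L],
                             ev_all[patients$assigned_cluster == 2L])),
                         cuminc = ci)
  } else {
    patients <- NULL
  }

  viab <- normalize_viability(cohort$screen)
  hits <- call_hits(viab, threshold = config$suppression_threshold)
  sets <- cohort$screen[!cohort$screen$is_control,
                        c("gene", "set"), drop = FALSE]
  sets <- unique(sets)
  hits$set <- sets$set[match(hits$gene, sets$gene)]
  n_sig <- sum(hits$set == "signature")
  n_bg <- sum(hits$set == "background")
  h_sig <- sum(hits$hit & hits$set == "signature")
  h_bg <- sum(hits$hit & hits$set == "background")
  enr <- fisher_enrichment(h_sig, n_sig, h_bg, n_bg)
  screen_summary <- list(hits_signature = h_sig, n_signature = n_sig,
                         hits_background = h_bg, n_background = n_bg,
                         fisher_p = enr$p)

  report <- list(counts = cascade$counts,
                 signature = cascade$signature,
                 truth_scores = scores,
                 cluster = cluster_summary,
                 survival = surv_summary,
                 screen = screen_summary,
                 seed = sim$seed,
                 config = unclass(config))
  class(report) <- "run_report"

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cohort$patients <- patients
    write_cohort(cohort, dir)
    write_matrix_tsv(profiles, file.path(dir, "segmented.tsv"), "probe_id")
    calls <- call_cna(profiles, config$t_loss, config$t_gain)
    write_matrix_tsv(calls, file.path(dir, "cna_calls.tsv"), "probe_id")
    write_tsv(cascade$de, file.path(dir, "de_results.tsv"))
    write_tsv(cascade$records, file.path(dir, "integration.tsv"))
    write_tsv(cascade$signature[, c("transcript_id", "gene", "chrom",
                                    "direction")],
              file.path(dir, "signature.tsv"))
    write_tsv(hits, file.path(dir, "hits.tsv"))
    jsonlite::write_json(
      list(counts = as.list(cascade$counts),
           truth_scores = scores,
           cluster = cluster_summary[c("sizes", "agreement_with_truth",
                                       "cum_var_frac")],
           survival = if (!is.null(surv_summary))
             list(logrank_p = surv_summary$logrank_p,
                  gray_p = surv_summary$gray_p,
                  cox = surv_summary$cox),
           screen = screen_summary,
           seed = sim$seed,
           config = unclass(config)),
      file.path(dir, "run_report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report (seed ", x$seed, ")\n", sep = "")
  cat("  cascade: ", paste(names(x$counts), x$counts, sep = "=",
                           collapse = ", "), "\n")
  cat(sprintf("  signature precision %.3f, recall %.3f\n",
              x$truth_scores$precision, x$truth_scores$recall))
  if (!is.null(x$cluster))
    cat(sprintf("  clusters %s (agreement with truth %.3f)\n",
                paste(x$cluster$sizes, collapse = "/"),
                x$cluster$agreement_with_truth))
  if (!is.null(x$survival))
    cat(sprintf("  log-rank p %.3g, Gray p %.3g, cluster HR %.2f\n",
                x$survival$logrank_p, x$survival$gray_p,
                x$survival$cox$hr[x$survival$cox$term == "cluster2"]))
  cat(sprintf("  screen: %d/%d vs %d/%d hits, Fisher p %.3g\n",
              x$screen$hits_signature, x$screen$n_signature,
              x$screen$hits_background, x$screen$n_background,
              x$screen$fisher_p))
  invisible(x)
}
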