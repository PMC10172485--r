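# End-to-end pipeline: simulate -> preprocess -> connectivity -> metrics ->
# group statistics -> outcome prediction, with all parameters in one config.

#' Pipeline configuration
#'
#' Combines the cohort simulation config with the processing, statistics
#' and output parameters of a full run.
#'
#' @param sim A [sim_config()].
#' @param band Analysis frequency band, Hz.
#' @param window,overlap Welch parameters.
#' @param seg_len Segment length, seconds.
#' @param reject_uv Segment rejection threshold, uV.
#' @param artifact_removal Run ICA + wavelet ocular-artifact suppression.
#' @param filter_lo,filter_hi Band-pass edges, Hz.
#' @param alpha Significance level for property comparisons.
#' @param fdr_q FDR level for edge-wise comparisons.
#' @param aggregation Feature aggregation mode for prediction.
#' @param out_dir Output directory (`NULL` = do not write files).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(), band = sim$band,
                            window = sim$window, overlap = sim$overlap,
                            seg_len = sim$seg_len, reject_uv = 120,
                            artifact_removal = TRUE,
                            filter_lo = 0.1, filter_hi = 45,
                            alpha = 0.05, fdr_q = 0.05,
                            aggregation = "mean_over_tasks",
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Compare two samples with normality gating
#'
#' Dispatches to the test selected by [choose_test()] and returns a
#' uniform `"comparison_result"`.
#'
#' @param x,y Numeric samples.
#' @param paired Logical.
#' @return A `"comparison_result"`.
#' @export
compare_groups <- function(x, y, paired = FALSE) {
  test <- choose_test(x, y, paired)
  switch(test,
    pooled_t = {
      ht <- stats::t.test(x, y, var.equal = TRUE)
      comparison_result("pooled_t", ht$statistic, ht$parameter, ht$p.value,
                        sign(mean(x) - mean(y)))
    },
    welch_t = {
      ht <- stats::t.test(x, y)
      comparison_result("welch_t", ht$statistic, ht$parameter, ht$p.value,
                        sign(mean(x) - mean(y)))
    },
    paired_t = paired_t(x, y),
    mann_whitney_u = mann_whitney_u(x, y),
    wilcoxon_signed_rank = wilcoxon_signed_rank(x, y)
  )
}

preprocess_recording <- function(rec, cfg) {
  if (cfg$artifact_removal)
    rec <- remove_ocular_artifacts(rec)$recording
  rec <- bandpass_filter(rec, cfg$filter_lo, cfg$filter_hi)
  rec <- average_reference(rec)
  segs <- segment_recording(rec, cfg$seg_len)
  reject_segments(segs, cfg$reject_uv)
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a cohort, preprocesses every recording, builds
#' subject-level coherence networks, computes the four network properties,
#' compares groups (properties and edges, three contrasts: pre-treatment
#' vs control, pre vs post, post vs control), and fits the leave-one-out
#' cross-validated regression of the clinical change ratio on the change
#' features. When `cfg$out_dir` is set, stage outputs (metrics CSV,
#' comparison CSVs, prediction JSON, resolved config) are written there.
#'
#' @param cfg A [pipeline_config()].
#' @param cohort Optional pre-built `"cohort_bundle"`; by default the
#'   cohort is simulated from `cfg$sim`.
#' @return List with `metrics` (one row per network), `comparisons`
#'   (property-level tidy table), `edges` (named list of
#'   `"edge_comparison"`), `model` (a `"regression_model"`), `features`,
#'   `clinical`, `networks`, and `segment_counts`.
#' @export
run_pipeline <- function(cfg, cohort = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cohort)) {
    message("stage simulate: cohort of ", cfg$sim$n_sp, " sp + ",
            cfg$sim$n_hc, " hc subjects (seed ", cfg$sim$seed, ")")
    cohort <- simulate_cohort(cfg$sim)
  }
  idx <- cohort$index

  message("stage preprocess/connect: ", nrow(idx), " recordings")
  networks <- vector("list", nrow(idx))
  names(networks) <- idx$key
  kept <- integer(nrow(idx))
  rejected <- integer(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    segs <- preprocess_recording(cohort$recordings[[idx$key[i]]], cfg)
    kept[i] <- length(segs$segments)
    rejected[i] <- segs$rejected_count
    if (kept[i] == 0)
      stop("preprocess: all segments rejected for ", idx$key[i])
    networks[[i]] <- segments_coherence(segs, band = cfg$band,
                                        window = cfg$window,
                                        overlap = cfg$overlap)
  }
  message("stage preprocess: kept ", sum(kept), " segments, rejected ",
          sum(rejected))

  metrics <- do.call(rbind, lapply(seq_len(nrow(idx)), function(i) {
    nm <- network_properties(networks[[i]])
    data.frame(subject = idx$subject[i], task = idx$task[i],
               phase = idx$phase[i], clu = nm$clu, le = nm$le, ge = nm$ge,
               path_length = nm$path_length)
  }))

  message("stage stats: property and edge-wise comparisons")
  tasks <- unique(idx$task)
  props <- c("clu", "le", "ge", "path_length")
  contrasts <- list(before_vs_hc = c("before", "hc", FALSE),
                    before_vs_after = c("before", "after", TRUE),
                    after_vs_hc = c("after", "hc", FALSE))
  comp_rows <- list()
  for (tk in tasks) {
    for (cn in names(contrasts)) {
      ph <- contrasts[[cn]]
      m1 <- metrics[metrics$task == tk & metrics$phase == ph[1], ]
      m2 <- metrics[metrics$task == tk & metrics$phase == ph[2], ]
      if (nrow(m1) == 0 || nrow(m2) == 0) next
      paired <- as.logical(ph[3])
      if (paired) m2 <- m2[match(m1$subject, m2$subject), ]
      for (pr in props) {
        res <- compare_groups(m1[[pr]], m2[[pr]], paired = paired)
        comp_rows[[length(comp_rows) + 1]] <-
          data.frame(task = tk, contrast = cn, property = pr,
                     test = res$test_name, statistic = res$statistic,
                     p = res$p, direction = res$direction)
      }
    }
  }
  comparisons <- do.call(rbind, comp_rows)
  comparisons$significant <- comparisons$p < cfg$alpha

  edges <- list()
  for (tk in tasks) {
    grp <- function(ph) {
      keys <- idx$key[idx$task == tk & idx$phase == ph]
      networks[keys]
    }
    for (cn in names(contrasts)) {
      ph <- contrasts[[cn]]
      a <- grp(ph[1]); b <- grp(ph[2])
      if (length(a) >= 3 && length(b) >= 3)
        edges[[paste(tk, cn, sep = ".")]] <-
          edgewise_compare(a, b, alpha = cfg$fdr_q)
    }
  }

  message("stage predict: LOOCV regression of the change ratio")
  sp_metrics <- metrics[metrics$phase %in% c("before", "after"), ]
  before <- sp_metrics[sp_metrics$phase == "before", ]
  after <- sp_metrics[sp_metrics$phase == "after", ]
  clin <- cohort$clinical
  outcomes <- unique(clin[clin$group == "sp", c("subject", "change_ratio")])
  names(outcomes)[2] <- "y"
  features <- build_features(before, after, outcomes,
                             aggregation = cfg$aggregation)
  xcols <- setdiff(names(features), c("subject", "y"))
  xcols <- prune_collinear(features[xcols])
  message("stage predict: features after collinearity gate: ",
          paste(xcols, collapse = ", "))
  model <- loocv_regression(features[xcols], features$y)

  result <- list(metrics = metrics, comparisons = comparisons, edges = edges,
                 model = model, features = features, clinical = clin,
                 networks = networks,
                 segment_counts = data.frame(key = idx$key, kept = kept,
                                             rejected = rejected))
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(result, cfg)
  result
}

write_pipeline_outputs <- function(result, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$metrics, file.path(cfg$out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$comparisons,
                   file.path(cfg$out_dir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(result$segment_counts,
                   file.path(cfg$out_dir, "segment_counts.csv"),
                   row.names = FALSE)
  write_clinical(result$clinical, file.path(cfg$out_dir, "clinical.csv"))
  edge_summary <- do.call(rbind, lapply(names(result$edges), function(k) {
    e <- result$edges[[k]]
    data.frame(contrast = k,
               n_significant = sum(e$mask[upper.tri(e$mask)]))
  }))
  if (!is.null(edge_summary))
    utils::write.csv(edge_summary, file.path(cfg$out_dir, "edges.csv"),
                     row.names = FALSE)
  model <- result$model
  jsonlite::write_json(
    list(intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         vif = model$vif, tolerance = model$tolerance,
         loocv_r = model$r, loocv_p = model$p,
         rmse = model$rmse, rmse_pct = model$rmse_pct,
         predictions = model$loocv_predictions),
    file.path(cfg$out_dir, "prediction.json"), auto_unbox = TRUE, digits = NA)
  sim <- cfg$sim
  sim$dmn_edges <- apply(sim$dmn_edges, 1, paste, collapse = "-")
  cfg_out <- cfg
  cfg_out$sim <- sim
  jsonlite::write_json(lapply(unclass(cfg_out), unclass),
                       file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cfg$out_dir)
}
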