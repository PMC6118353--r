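# ---------------------------------------------------------------------------
# Whole-study orchestration: synthetic study (or a study directory on
# disk) -> metric panel -> random-removal ensemble -> mixed models + PCA,
# with seeded, reproducible outputs.
# ---------------------------------------------------------------------------

#' Write a study to a directory
#'
#' Writes `design.csv` plus one edge-list CSV and one species CSV per web,
#' and (when present) the true diet proportions as
#' `true_diets.csv` (`web, consumer, source, proportion`).
#'
#' @param study a `synth_study` or a list with `webs` (named list of
#'   `foodweb`) and optional `true_diets`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (lab in names(study$webs)) {
    w <- study$webs[[lab]]
    lf <- paste0(lab, "_links.csv")
    sf <- paste0(lab, "_species.csv")
    save_web(w, file.path(dir, lf), format = "edge_list",
             species_path = file.path(dir, sf))
    rows[[lab]] <- data.frame(ecosystem = w$ecosystem, web_type = w$web_type,
                              replicate = w$replicate, label = lab,
                              links_file = lf, species_file = sf,
                              stringsAsFactors = FALSE)
  }
  write.csv(do.call(rbind, rows), file.path(dir, "design.csv"),
            row.names = FALSE, quote = FALSE)
  if (!is.null(study$true_diets)) {
    td <- do.call(rbind, lapply(names(study$true_diets), function(lab) {
      diets <- study$true_diets[[lab]]
      if (length(diets) == 0) return(NULL)
      do.call(rbind, lapply(names(diets), function(cons) {
        data.frame(web = lab, consumer = cons, source = names(diets[[cons]]),
                   proportion = unname(diets[[cons]]),
                   stringsAsFactors = FALSE)
      }))
    }))
    if (!is.null(td)) {
      write.csv(td, file.path(dir, "true_diets.csv"), row.names = FALSE,
                quote = FALSE)
    }
  }
  invisible(dir)
}

#' Read a study from a directory written by [save_study()]
#'
#' @param dir study directory containing `design.csv`.
#' @return list with `webs`, `design` and (if stored) `true_diets`.
#' @export
load_study <- function(dir) {
  design <- read.csv(file.path(dir, "design.csv"), stringsAsFactors = FALSE)
  webs <- list()
  for (r in seq_len(nrow(design))) {
    webs[[design$label[r]]] <- load_web(
      file.path(dir, design$links_file[r]), format = "edge_list",
      species_path = file.path(dir, design$species_file[r]),
      ecosystem = design$ecosystem[r], web_type = design$web_type[r],
      replicate = design$replicate[r])
  }
  out <- list(webs = webs,
              design = design[, c("ecosystem", "web_type", "replicate",
                                  "label")])
  tdf <- file.path(dir, "true_diets.csv")
  if (file.exists(tdf)) {
    td <- read.csv(tdf, stringsAsFactors = FALSE)
    diets <- list()
    for (lab in unique(td$web)) {
      sub <- td[td$web == lab, ]
      diets[[lab]] <- lapply(split(sub, sub$consumer), function(d) {
        setNames(d$proportion, d$source)
      })
    }
    out$true_diets <- diets
  }
  out
}

#' Run the full comparison analysis on a study
#'
#' Computes the 19-metric panel of every FS and BA web, builds the
#' random-removal ensemble, fits the per-metric mixed models with Tukey
#' letters, the covariance PCA over all webs and the PC1 contrast.
#' Deterministic given (`study`, `seed`, `reps_per_fs_web`).
#'
#' @param study a `synth_study` or the result of [load_study()].
#' @param reps_per_fs_web pruned replicates per FS web (default 1).
#' @param seed integer seed for the null model.
#' @param rr_aggregate average the pruned replicates of each FS web into
#'   one RR row before the statistics (see [aggregate_rr_metrics()]);
#'   default `TRUE` (a no-op at 1 replicate per web).
#' @param standardize_pca passed to [pca_metrics()].
#' @param log_transform passed to [metric_panel_lme()].
#' @return list with `metrics` (study table over FS, BA and RR webs),
#'   `ensemble` (the [null_ensemble()] result), `lme` (per-metric panel),
#'   `pca`, `pc1` and `summary` (reporting table: per-type mean +/- SE,
#'   F, stars, letters).
#' @export
run_study <- function(study, reps_per_fs_web = 1, seed = 1,
                      rr_aggregate = TRUE, standardize_pca = FALSE,
                      log_transform = "auto") {
  webs <- study$webs
  real <- study_table(webs)
  ens <- null_ensemble(webs, reps_per_fs_web = reps_per_fs_web, seed = seed)
  rr <- if (rr_aggregate) aggregate_rr_metrics(ens$metrics) else ens$metrics
  metrics <- rbind(real, rr)
  panel <- metric_panel_lme(metrics, log_transform = log_transform)
  pca <- pca_metrics(metrics, standardize = standardize_pca)
  pc1 <- pc1_contrast(pca, metrics)
  list(metrics = metrics, ensemble = ens, lme = panel$results,
       pca = pca, pc1 = pc1, summary = panel$summary)
}

#' Write the result bundle of [run_study()] to CSV files
#'
#' Writes `metrics.csv`, `summary.csv`, `pca_scores.csv`,
#' `pca_loadings.csv` and a plain-text `manifest.txt` recording the seed
#' and package version.
#'
#' @param bundle a [run_study()] result.
#' @param dir output directory.
#' @param seed the seed the bundle was produced with (recorded in the
#'   manifest).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(bundle, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(bundle$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  write.csv(bundle$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  sc <- cbind(bundle$pca$table_meta, as.data.frame(bundle$pca$scores))
  write.csv(sc, file.path(dir, "pca_scores.csv"), row.names = FALSE)
  write.csv(as.data.frame(bundle$pca$loadings),
            file.path(dir, "pca_loadings.csv"), row.names = TRUE)
  writeLines(c(paste0("package: foundweb ",
                      as.character(utils::packageVersion("foundweb"))),
               paste0("seed: ", seed),
               paste0("pc1_variance_pct: ",
                      format(bundle$pca$variance_pct[1]))),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}
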