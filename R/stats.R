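# ---------------------------------------------------------------------------
# Comparison layer: one row per web (ecosystem, web type, replicate, the 19
# metrics), per-metric linear mixed models with web type fixed and
# ecosystem random, Satterthwaite F-tests and Tukey grouping letters, and
# a covariance PCA across webs with the PC1 contrast.
# ---------------------------------------------------------------------------

#' Build a study table from a list of webs
#'
#' @param webs list of `foodweb` objects with metadata set.
#' @return data frame: `ecosystem, web_type, replicate, label` plus one
#'   column per metric of [metric_names()].
#' @export
study_table <- function(webs) {
  rows <- lapply(webs, function(w) {
    m <- compute_all(w)
    cbind(data.frame(ecosystem = w$ecosystem, web_type = w$web_type,
                     replicate = w$replicate, label = web_label(w),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(m)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-type mean and standard error of every metric
#'
#' @param table a study table (see [study_table()]).
#' @return data frame with one row per metric: `metric`, then
#'   `<type>_mean` and `<type>_se` for each web type present.
#' @export
aggregate_table <- function(table) {
  types <- unique(table$web_type)
  out <- data.frame(metric = metric_names(), stringsAsFactors = FALSE)
  for (ty in types) {
    sub <- table[table$web_type == ty, metric_names(), drop = FALSE]
    out[[paste0(ty, "_mean")]] <- colMeans(sub)
    out[[paste0(ty, "_se")]] <- apply(sub, 2, sd) / sqrt(nrow(sub))
  }
  out
}

# Internal: grouping letters from a pairwise p-value matrix (insert-absorb
# via maximal cliques of the "not significantly different" graph).  Groups
# are lettered in order of increasing mean, so the lowest group is "a".
grouping_letters <- function(means, pmat, alpha = 0.05) {
  k <- length(means)
  g <- igraph::graph_from_adjacency_matrix(pmat >= alpha, mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g, min = 1)
  cl_min <- vapply(cliques, function(cl) min(means[as.integer(cl)]),
                   numeric(1))
  cliques <- cliques[order(cl_min)]
  letters_out <- rep("", k)
  for (i in seq_along(cliques)) {
    idx <- as.integer(cliques[[i]])
    letters_out[idx] <- paste0(letters_out[idx], letters[i])
  }
  setNames(letters_out, names(means))
}

#' Mixed-model comparison of one metric across web types
#'
#' Fits `metric ~ web_type + (1 | ecosystem)`, tests the web-type effect
#' with a one-way ANOVA F-test using the Satterthwaite denominator degrees
#' of freedom, and groups the web types with Tukey-adjusted pairwise
#' comparisons on the model's marginal means (letters in order of
#' increasing mean; types sharing a letter do not differ at `alpha`).
#' When the residuals fail a Shapiro-Wilk normality check (and all values
#' are positive) with `log_transform = "auto"`, the response is refit on
#' the log scale.  Designs where the random effect is unidentifiable (a
#' single ecosystem) or the fit is singular fall back to a fixed-effects
#' ANOVA, flagged in the result.
#'
#' @param table a study table.
#' @param metric metric column name.
#' @param log_transform `"auto"`, `"on"` or `"off"`.
#' @param alpha significance level used for the grouping letters.
#' @param posthoc compute Tukey letters (set `FALSE` to skip, e.g. in
#'   large simulation loops where only the F-test matters).
#' @return an object of class `lme_result`: list with `metric`, `F`,
#'   `num_df`, `den_df`, `p`, `letters` (named by web type, or `NULL`),
#'   `pairwise` (Tukey-adjusted p-values), `log_transformed`, `fallback`
#'   (`TRUE` when a fixed-effects ANOVA replaced the mixed model).
#' @export
fit_metric_lme <- function(table, metric, log_transform = c("auto", "on", "off"),
                           alpha = 0.05, posthoc = TRUE) {
  log_transform <- match.arg(log_transform)
  if (!metric %in% names(table)) stop("no such metric column: ", metric)
  dat <- data.frame(y = table[[metric]],
                    web_type = factor(table$web_type),
                    ecosystem = factor(table$ecosystem))
  if (anyNA(dat$y)) stop("missing values in metric ", metric)
  if (nlevels(dat$web_type) < 2) stop("need >= 2 web types")

  use_log <- log_transform == "on"
  if (use_log && any(dat$y <= 0)) {
    stop("log transform requested but metric has non-positive values")
  }

  fit_once <- function(dat) {
    fallback <- nlevels(dat$ecosystem) < 2
    m <- NULL
    if (!fallback) {
      m <- tryCatch(
        suppressMessages(lmerTest::lmer(y ~ web_type + (1 | ecosystem),
                                        data = dat)),
        error = function(e) NULL)
      if (is.null(m) || lme4::isSingular(m, tol = 1e-5)) fallback <- TRUE
    }
    if (fallback) m_fix <- lm(y ~ web_type, data = dat)
    list(model = if (fallback) m_fix else m, fallback = fallback)
  }

  transform_and_fit <- function(use_log) {
    d <- dat
    if (use_log) d$y <- log(d$y)
    c(fit_once(d), list(data = d))
  }

  fit <- transform_and_fit(use_log)
  if (log_transform == "auto" && all(dat$y > 0)) {
    res <- residuals(fit$model)
    swp <- tryCatch(shapiro.test(res)$p.value, error = function(e) NA_real_)
    if (!is.na(swp) && swp < 0.05) {
      fit <- transform_and_fit(TRUE)
      use_log <- TRUE
    }
  }
  model <- fit$model

  if (fit$fallback) {
    a <- anova(model)
    Fv <- a[["F value"]][1]
    ndf <- a[["Df"]][1]
    ddf <- a[["Df"]][2]
    p <- a[["Pr(>F)"]][1]
  } else {
    a <- anova(model, ddf = "Satterthwaite")
    Fv <- a[["F value"]][1]
    ndf <- a[["NumDF"]][1]
    ddf <- a[["DenDF"]][1]
    p <- a[["Pr(>F)"]][1]
  }

  letters_out <- NULL
  pw <- NULL
  if (posthoc) {
    emm <- emmeans::emmeans(model, "web_type",
                            lmer.df = "satterthwaite")
    ct <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                          adjust = "tukey"))
    emm_df <- as.data.frame(emm)
    means <- setNames(emm_df$emmean, as.character(emm_df$web_type))
    lv <- names(means)
    pmat <- matrix(1, length(lv), length(lv), dimnames = list(lv, lv))
    for (r in seq_len(nrow(ct))) {
      pair <- strsplit(ct$contrast[r], " - ", fixed = TRUE)[[1]]
      pair <- gsub("[()]", "", pair)
      pmat[pair[1], pair[2]] <- pmat[pair[2], pair[1]] <- ct$p.value[r]
    }
    letters_out <- grouping_letters(means, pmat, alpha = alpha)
    pw <- ct
  }

  structure(list(metric = metric, F = Fv, num_df = ndf, den_df = ddf, p = p,
                 letters = letters_out, pairwise = pw,
                 log_transformed = use_log, fallback = fit$fallback),
            class = "lme_result")
}

#' @export
print.lme_result <- function(x, ...) {
  cat(sprintf("<lme_result> %s: F(%s, %s) = %.3g, p = %.3g%s%s\n",
              x$metric, format(x$num_df, digits = 3),
              format(x$den_df, digits = 4), x$F, x$p,
              if (x$log_transformed) " [log]" else "",
              if (x$fallback) " [fixed-effects fallback]" else ""))
  if (!is.null(x$letters)) {
    cat("  letters:", paste(names(x$letters), x$letters, sep = "=",
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Significance stars for a p-value
#' @param p p-value.
#' @return `"***"`, `"**"`, `"*"`, `"."` or `"ns"`.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*",
         ifelse(p < 0.1, ".", "ns"))))
}

#' Principal component analysis of the metric panel
#'
#' Eigen-decomposition of the covariance matrix of the 19 metrics across
#' webs (correlation matrix when `standardize`); webs are samples, metrics
#' are variables.  On raw scales the covariance PCA is dominated by the
#' largest-variance metric (species number), which is why a single axis
#' carries almost all variation in studies shaped like this one.
#'
#' @param table a study table with >= 3 webs.
#' @param standardize use the correlation matrix instead of the covariance
#'   matrix.
#' @return an object of class `pca_result`: `total_variation` (sum of
#'   per-metric variances), `variance_pct` (per axis, sums to 100),
#'   `scores` (centred, one row per web), `loadings`, `table_meta`.
#' @export
pca_metrics <- function(table, standardize = FALSE) {
  if (nrow(table) < 3) stop("PCA needs at least 3 webs")
  X <- as.matrix(table[, metric_names(), drop = FALSE])
  v <- apply(X, 2, var)
  if (standardize && any(v == 0)) {
    stop("constant metric column(s) with standardize = TRUE: ",
         paste(metric_names()[v == 0], collapse = ", "))
  }
  pr <- prcomp(X, center = TRUE, scale. = standardize)
  var_ax <- pr$sdev^2
  structure(list(total_variation = sum(v),
                 variance_pct = 100 * var_ax / sum(var_ax),
                 scores = pr$x, loadings = pr$rotation,
                 standardize = standardize,
                 table_meta = table[, c("ecosystem", "web_type", "replicate",
                                        "label")]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> total variation %.4g; axis 1: %.1f%%, axis 2: %.1f%%\n",
              x$total_variation, x$variance_pct[1], x$variance_pct[2]))
  invisible(x)
}

#' Mixed-model contrast of web types on PC1
#'
#' Applies [fit_metric_lme()] to the first principal-component scores (web
#' type fixed, ecosystem random): the composite-structure test of whether
#' web types differ overall.
#'
#' @param pca a [pca_metrics()] result.
#' @param table the study table the PCA was fitted on (same row order).
#' @param ... passed to [fit_metric_lme()].
#' @return an `lme_result` for the PC1 scores.
#' @export
pc1_contrast <- function(pca, table, ...) {
  if (nrow(pca$scores) != nrow(table) ||
      !identical(pca$table_meta$label, table$label)) {
    stop("PCA scores are not aligned to the table rows")
  }
  tab <- table[, c("ecosystem", "web_type", "replicate", "label")]
  tab$PC1 <- pca$scores[, 1]
  fit_metric_lme(tab, "PC1", log_transform = "off", ...)
}

#' Per-metric mixed-model panel
#'
#' Runs [fit_metric_lme()] for every metric and assembles the reporting
#' table (per-type mean and SE, F, p, stars, letters).
#'
#' @param table a study table.
#' @param log_transform passed to [fit_metric_lme()].
#' @return list with `results` (named list of `lme_result`) and `summary`
#'   (data frame, one row per metric).
#' @export
metric_panel_lme <- function(table, log_transform = "auto") {
  agg <- aggregate_table(table)
  results <- list()
  rows <- list()
  types <- unique(table$web_type)
  for (m in metric_names()) {
    r <- fit_metric_lme(table, m, log_transform = log_transform)
    results[[m]] <- r
    rows[[m]] <- data.frame(
      F = r$F, p = r$p, stars = p_stars(r$p),
      letters = paste(r$letters[types], collapse = ", "),
      log_transformed = r$log_transformed, fallback = r$fallback,
      stringsAsFactors = FALSE)
  }
  summary <- cbind(agg, do.call(rbind, rows))
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}
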