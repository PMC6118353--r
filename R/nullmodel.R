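# ---------------------------------------------------------------------------
# Random-removal null model.
#
# A foundation-species web is pruned by uniformly random node removal; any
# species left trophically isolated (no remaining link to another species;
# a self-link alone does not count) is cascaded away after each removal.
# Pruning stops once the surviving species count falls inside the 95%
# confidence interval of the richness of the paired bare-area webs.  If the
# cascade overshoots below the interval the replicate restarts from the
# original web with a fresh draw from the same seeded stream.
# ---------------------------------------------------------------------------

#' Confidence interval for bare-web richness
#'
#' t-based confidence interval of the mean species count over the bare-area
#' replicate webs of one ecosystem, used as the stopping target for
#' [random_removal()].
#'
#' @param bare_webs list of at least two `foodweb` objects from one
#'   ecosystem.
#' @param level confidence level (default 0.95).
#' @return an object of class `target_interval`: list with `lo`, `hi`,
#'   `mean`, `se`, `n_bare`, `ecosystem`.
#' @export
bare_ci <- function(bare_webs, level = 0.95) {
  n <- length(bare_webs)
  if (n < 2) stop("need >= 2 bare webs for a confidence interval")
  counts <- vapply(bare_webs, n_species, integer(1))
  m <- mean(counts)
  se <- sd(counts) / sqrt(n)
  tq <- qt(1 - (1 - level) / 2, df = n - 1)
  structure(list(lo = m - tq * se, hi = m + tq * se, mean = m, se = se,
                 n_bare = n,
                 ecosystem = bare_webs[[1]]$ecosystem),
            class = "target_interval")
}

# Internal: ids with no link to another species (self-links ignored).
isolated_ids <- function(web) {
  lk <- web$links
  lk <- lk[lk$prey != lk$predator, , drop = FALSE]
  setdiff(species_ids(web), unique(c(lk$prey, lk$predator)))
}

#' Prune a foundation-species web by random removal
#'
#' Repeatedly removes one uniformly random species and cascades away any
#' species that becomes trophically isolated, until the species count falls
#' inside the target interval.  Each replicate draws its stopping point
#' uniformly within `[target$lo, target$hi]` (stopping at the interval's
#' first entry point would pile every pruned web against the upper bound
#' and bias the ensemble rich); the replicate succeeds if the final count
#' is at least `target$lo`, and otherwise restarts (up to `max_restarts`
#' times) with fresh randomness from the same seeded stream.  A web already
#' inside the interval is returned unchanged.  A pruned web must also keep
#' every surviving species trophically connected to a basal species (so
#' the metric panel is defined); replicates violating this restart too.
#'
#' @param fs_web the foundation-species `foodweb` to prune.
#' @param target a `target_interval` from [bare_ci()].
#' @param seed integer seed; the result is deterministic given the seed.
#' @param max_restarts restarts allowed when the cascade overshoots below
#'   `target$lo`.
#' @param exempt_foundation protect the foundation species from the random
#'   draw (it can still be cascaded away); default `FALSE` -- the removal
#'   is blind to identity.
#' @return an object of class `removal_result`: list with `web` (pruned
#'   web, `web_type` `"RR"`), `trace` (data frame `id, reason` with reason
#'   `"random"` or `"isolated"`, in removal order), `seed`, `restarts`.
#' @export
random_removal <- function(fs_web, target, seed, max_restarts = 100,
                           exempt_foundation = FALSE) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  as_rr <- function(web) {
    web$web_type <- "RR"
    web
  }
  empty_trace <- data.frame(id = character(), reason = character(),
                            stringsAsFactors = FALSE)
  if (n_species(fs_web) <= target$hi) {
    if (n_species(fs_web) < target$lo) {
      stop("web is already below the target interval")
    }
    return(structure(list(web = as_rr(fs_web), trace = empty_trace,
                          seed = seed, restarts = 0),
                     class = "removal_result"))
  }
  fs_id <- species_ids(fs_web)[fs_web$species$is_foundation]
  overshoots <- integer(0)
  for (r in seq_len(max_restarts)) {
    web <- fs_web
    trace <- list()
    stop_at <- runif(1, target$lo, target$hi)
    while (n_species(web) > stop_at) {
      pool <- species_ids(web)
      if (exempt_foundation) pool <- setdiff(pool, fs_id)
      if (length(pool) == 0) break
      victim <- pool[sample.int(length(pool), 1)]
      web <- induced_subweb(web, setdiff(species_ids(web), victim))
      trace[[length(trace) + 1]] <- data.frame(id = victim,
                                               reason = "random",
                                               stringsAsFactors = FALSE)
      repeat {
        iso <- isolated_ids(web)
        if (length(iso) == 0) break
        web <- induced_subweb(web, setdiff(species_ids(web), iso))
        for (s in iso) {
          trace[[length(trace) + 1]] <- data.frame(id = s,
                                                   reason = "isolated",
                                                   stringsAsFactors = FALSE)
        }
      }
    }
    if (n_species(web) >= target$lo &&
        length(basal_ids(web)) >= 1 &&
        all(is.finite(chain_length_values(web)))) {
      return(structure(list(web = as_rr(web),
                            trace = do.call(rbind, c(list(empty_trace), trace)),
                            seed = seed, restarts = r - 1),
                       class = "removal_result"))
    }
    overshoots <- c(overshoots, n_species(web))
  }
  stop("random_removal: ", max_restarts, " restarts exhausted; final sizes ",
       "all below target [", round(target$lo, 2), ", ",
       round(target$hi, 2), "]: ",
       paste(sort(unique(overshoots)), collapse = ", "))
}

#' Random-removal ensemble over a whole study
#'
#' Builds the per-ecosystem richness intervals from the bare webs, prunes
#' every foundation-species web `reps_per_fs_web` times with distinct
#' derived seeds, and computes the 19-metric panel of every pruned web.
#'
#' @param webs list of `foodweb` objects covering both `FS` and `BA` webs
#'   of the study (each with `ecosystem`, `web_type`, `replicate` set).
#' @param reps_per_fs_web pruned replicates per foundation web (default 1).
#' @param seed integer master seed.
#' @param level confidence level for [bare_ci()].
#' @param max_restarts per-replicate restart budget.
#' @param exempt_foundation passed to [random_removal()].
#' @return list with `results` (list of `removal_result`), `metrics` (one
#'   data-frame row per pruned web: `ecosystem, web_type, replicate` + the
#'   19 metrics) and `intervals` (named per-ecosystem list).
#' @export
null_ensemble <- function(webs, reps_per_fs_web = 1, seed = 1, level = 0.95,
                          max_restarts = 100, exempt_foundation = FALSE) {
  types <- vapply(webs, function(w) w$web_type, character(1))
  ecos <- vapply(webs, function(w) w$ecosystem, character(1))
  intervals <- list()
  for (e in unique(ecos)) {
    ba <- webs[types == "BA" & ecos == e]
    if (length(ba) < 2) stop("ecosystem ", e, " has fewer than 2 bare webs")
    intervals[[e]] <- bare_ci(ba, level = level)
  }
  fs_webs <- webs[types == "FS"]
  results <- list()
  k <- 0
  for (w in fs_webs) {
    for (rep in seq_len(reps_per_fs_web)) {
      k <- k + 1
      rr <- random_removal(w, intervals[[w$ecosystem]],
                           seed = derive_seed(seed, k),
                           max_restarts = max_restarts,
                           exempt_foundation = exempt_foundation)
      rr$web$replicate <- paste0(w$replicate, ".rr", rep)
      results[[k]] <- rr
    }
  }
  metrics <- study_table(lapply(results, function(r) r$web))
  list(results = results, metrics = metrics, intervals = intervals)
}

#' Average random-removal replicates per parent web
#'
#' When several pruned replicates are drawn per foundation web, the
#' replicates are draws from the same null distribution, not independent
#' webs; for the comparison statistics they are averaged into one row per
#' parent web (avoiding pseudo-replication while the extra replicates
#' stabilize the null expectation).
#'
#' @param metrics the `metrics` table of [null_ensemble()].
#' @return data frame with one row per parent FS web.
#' @export
aggregate_rr_metrics <- function(metrics) {
  parent <- sub("\\.rr[0-9]+$", "", metrics$replicate)
  key <- paste(metrics$ecosystem, parent, sep = "\r")
  rows <- lapply(split(seq_len(nrow(metrics)), key), function(idx) {
    first <- metrics[idx[1], c("ecosystem", "web_type", "replicate", "label")]
    first$replicate <- sub("\\.rr[0-9]+$", ".rr", first$replicate)
    first$label <- paste(first$ecosystem, "RR", first$replicate, sep = "_")
    cbind(first, as.data.frame(as.list(
      colMeans(metrics[idx, metric_names(), drop = FALSE]))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
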