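# ---------------------------------------------------------------------------
# Bayesian stable-isotope mixing model (SIAR-family).
#
# For a consumer with K diet sources and two isotope tracers (d13C, d15N),
# each consumer tissue sample X_j (isotope j) is modelled as
#
#     X_j = sum_k p_k * (s_jk + c_jk) + eps_j
#
# with p ~ Dirichlet(1, ..., 1) on the simplex, source signatures s_jk ~
# Normal(mu_jk, omega_jk), trophic enrichment c_jk ~ Normal(lambda_j,
# tau_j) and residual eps_j ~ Normal(0, sigma_j) with sigma_j inferred.
# Marginalizing the Normal source and enrichment terms gives the standard
# SIAR likelihood
#
#     X_j ~ Normal( sum_k p_k (mu_jk + lambda_j),
#                   sum_k p_k^2 (omega_jk^2 + tau_j^2) + sigma_j^2 )
#
# sampled here by an adaptive random-walk Metropolis sampler on the softmax
# parameterization of p (plus log sigma), single chain, first half
# discarded as burn-in.
# ---------------------------------------------------------------------------

#' Trophic enrichment factor
#'
#' Per-trophic-step isotopic shift applied to every source.  Defaults are
#' the conventional literature values: 3.4 permil (sd 1.0) for d15N and
#' 1.0 permil (sd 0.5) for d13C.
#'
#' @param delta_d13C,delta_d15N mean shift per trophic step (permil).
#' @param sd_d13C,sd_d15N standard deviations (permil, >= 0).
#' @return an object of class `trophic_enrichment`.
#' @export
trophic_enrichment <- function(delta_d13C = 1.0, sd_d13C = 0.5,
                               delta_d15N = 3.4, sd_d15N = 1.0) {
  if (sd_d13C < 0 || sd_d15N < 0) stop("enrichment sds must be >= 0")
  structure(list(delta_d13C = delta_d13C, sd_d13C = sd_d13C,
                 delta_d15N = delta_d15N, sd_d15N = sd_d15N),
            class = "trophic_enrichment")
}

#' Source signature table from per-sample isotope values
#'
#' Summarizes each source species' isotope samples into the mean/sd
#' signature the mixing model consumes.  Single-sample sources get sd 0.
#'
#' @param web a `foodweb` whose species carry isotope samples.
#' @param ids source species ids.
#' @return data frame `id, mean_d13C, sd_d13C, mean_d15N, sd_d15N`.
#' @export
source_signatures <- function(web, ids) {
  idx <- match(ids, species_ids(web))
  if (anyNA(idx)) stop("unknown species: ", paste(ids[is.na(idx)], collapse = ", "))
  one <- function(v, f) vapply(v, function(x) {
    if (length(x) == 0) NA_real_ else if (length(x) == 1 && identical(f, sd)) 0
    else f(x)
  }, numeric(1))
  data.frame(id = ids,
             mean_d13C = one(web$species$d13C[idx], mean),
             sd_d13C = one(web$species$d13C[idx], sd),
             mean_d15N = one(web$species$d15N[idx], mean),
             sd_d15N = one(web$species$d15N[idx], sd),
             stringsAsFactors = FALSE)
}

#' Fit the mixing model for one consumer
#'
#' @param consumer_samples matrix or data frame with columns `d13C` and
#'   `d15N`, one consumer tissue sample per row (>= 1 row).
#' @param sources data frame `id, mean_d13C, sd_d13C, mean_d15N, sd_d15N`
#'   with at least two rows.
#' @param tef a [trophic_enrichment()].
#' @param n_iter MCMC iterations (>= 1000); the first half is burn-in.
#' @param seed integer seed; the fit is deterministic given
#'   (inputs, seed, n_iter).
#' @param consumer optional consumer id stored in the result.
#' @return an object of class `diet_posterior`: data frame `summary` with
#'   per-source posterior `mean`, `sd`, `ci_low`, `ci_high` (95% credible
#'   interval), plus the retained `draws` matrix (one column per source).
#' @export
fit_mixing_model <- function(consumer_samples, sources, tef = trophic_enrichment(),
                             n_iter = 10000, seed = 1,
                             consumer = NA_character_) {
  x <- as.data.frame(consumer_samples)
  if (!all(c("d13C", "d15N") %in% names(x))) {
    stop("consumer_samples needs columns d13C and d15N")
  }
  x <- as.matrix(x[, c("d13C", "d15N")])
  if (nrow(x) < 1) stop("need at least one consumer sample")
  if (!all(is.finite(x))) stop("non-finite consumer sample values")
  K <- nrow(sources)
  if (K < 2) stop("mixing model needs at least 2 sources")
  if (n_iter < 1000) stop("n_iter must be >= 1000")
  mu <- rbind(sources$mean_d13C + tef$delta_d13C,
              sources$mean_d15N + tef$delta_d15N)           # 2 x K
  v <- rbind(sources$sd_d13C^2 + tef$sd_d13C^2,
             sources$sd_d15N^2 + tef$sd_d15N^2)             # 2 x K
  if (!all(is.finite(mu)) || !all(is.finite(v))) {
    stop("non-finite source signature (missing isotope samples?)")
  }
  n <- nrow(x)

  log_post <- function(w, logsig) {
    e <- exp(c(w, 0) - max(c(w, 0)))
    p <- e / sum(e)
    sig2 <- exp(2 * logsig)
    m <- drop(mu %*% p)                 # per-isotope mixture mean
    s2 <- drop(v %*% p^2) + sig2        # per-isotope mixture variance
    ll <- 0
    for (j in 1:2) {
      ll <- ll + sum(dnorm(x[, j], m[j], sqrt(s2[j]), log = TRUE))
    }
    # Dirichlet(1) prior via the softmax Jacobian, half-Normal(10) on sigma
    ll + sum(log(p)) + sum(dnorm(exp(logsig), 0, 10, log = TRUE) + logsig)
  }

  set.seed(as.integer(seed %% .Machine$integer.max))
  w <- rep(0, K - 1)
  logsig <- rep(log(max(apply(x, 2, sd), 0.5, na.rm = TRUE)), 2)
  cur <- log_post(w, logsig)
  step <- 0.5
  burn <- floor(n_iter / 2)
  keep <- matrix(NA_real_, n_iter - burn, K)
  for (t in seq_len(n_iter)) {
    w_new <- w + rnorm(K - 1, 0, step)
    ls_new <- logsig + rnorm(2, 0, 0.5 * step)
    cand <- log_post(w_new, ls_new)
    acc <- log(runif(1)) < cand - cur
    if (acc) {
      w <- w_new; logsig <- ls_new; cur <- cand
    }
    if (t <= burn) {   # Robbins-Monro adaptation toward ~30% acceptance
      step <- exp(log(step) + (as.numeric(acc) - 0.30) / sqrt(t))
      step <- min(max(step, 1e-3), 5)
    } else {
      e <- exp(c(w, 0) - max(c(w, 0)))
      keep[t - burn, ] <- e / sum(e)
    }
  }
  colnames(keep) <- sources$id
  qs <- apply(keep, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  structure(list(consumer = consumer,
                 summary = data.frame(source = sources$id,
                                      mean = colMeans(keep),
                                      sd = apply(keep, 2, sd),
                                      ci_low = qs[1, ], ci_high = qs[2, ],
                                      row.names = NULL,
                                      stringsAsFactors = FALSE),
                 draws = keep, n_iter = n_iter, seed = seed),
            class = "diet_posterior")
}

#' @export
print.diet_posterior <- function(x, ...) {
  cat("<diet_posterior>", if (!is.na(x$consumer)) x$consumer else "", "\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Fit mixing models for every multi-prey consumer of a web
#'
#' Consumers with two or more prey (self-links excluded; a species is not a
#' source in its own diet model) get a posterior over exactly their prey
#' set; single-prey consumers are skipped (their diet proportion is 1 by
#' construction).
#'
#' @param web a `foodweb` whose species carry isotope samples.
#' @param tef a [trophic_enrichment()].
#' @param n_iter,seed passed to [fit_mixing_model()]; each consumer gets a
#'   sub-seed derived deterministically from `seed`.
#' @return named list of `diet_posterior` objects, one per multi-prey
#'   consumer.
#' @export
fit_web_diets <- function(web, tef = trophic_enrichment(), n_iter = 10000,
                          seed = 1) {
  prey <- prey_sets(web, drop_self = TRUE)
  consumers <- names(prey)[vapply(prey, length, integer(1)) >= 2]
  out <- list()
  for (k in seq_along(consumers)) {
    cid <- consumers[k]
    idx <- match(cid, species_ids(web))
    samples <- data.frame(d13C = web$species$d13C[[idx]],
                          d15N = web$species$d15N[[idx]])
    if (nrow(samples) == 0) stop("consumer ", cid, " has no isotope samples")
    out[[cid]] <- fit_mixing_model(samples, source_signatures(web, prey[[cid]]),
                                   tef = tef, n_iter = n_iter,
                                   seed = derive_seed(seed, k),
                                   consumer = cid)
  }
  out
}

#' Remove weakly supported diet links
#'
#' Drops every link whose prey contributes less than `threshold` (strictly)
#' to the consumer's posterior mean diet.  Consumers with a single prey are
#' never filtered; self-links are never filtered.  The input web is not
#' modified.
#'
#' @param web a `foodweb`.
#' @param posteriors named list of `diet_posterior` objects (as from
#'   [fit_web_diets()]) covering every multi-prey consumer; each posterior's
#'   source set must equal the consumer's prey set exactly.
#' @param threshold diet-proportion cutoff (default 0.05).
#' @return a new `foodweb` with the weak links removed.
#' @export
diet_filter <- function(web, posteriors, threshold = 0.05) {
  prey <- prey_sets(web, drop_self = TRUE)
  multi <- names(prey)[vapply(prey, length, integer(1)) >= 2]
  drop <- matrix(character(0), ncol = 2)
  for (cid in multi) {
    post <- posteriors[[cid]]
    if (is.null(post)) stop("no posterior supplied for consumer ", cid)
    if (!setequal(post$summary$source, prey[[cid]])) {
      stop("posterior for consumer ", cid,
           " does not cover exactly its prey set")
    }
    weak <- post$summary$source[post$summary$mean < threshold]
    if (length(weak) > 0) drop <- rbind(drop, cbind(weak, cid))
  }
  if (nrow(drop) > 0) {
    key <- paste(web$links$prey, web$links$predator, sep = "\r")
    web$links <- web$links[!key %in% paste(drop[, 1], drop[, 2], sep = "\r"), ,
                           drop = FALSE]
    rownames(web$links) <- NULL
  }
  web
}

#' Posterior summary table for a set of consumers
#'
#' @param posteriors named list of `diet_posterior` objects.
#' @return data frame `consumer, source, mean, sd, ci_low, ci_high`.
#' @export
diet_summary_table <- function(posteriors) {
  do.call(rbind, lapply(posteriors, function(p) {
    cbind(consumer = p$consumer, p$summary)
  }))
}

# Internal: deterministic sub-seed stream (kept inside 32-bit range).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 104729) %%
               2147483647)
}
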