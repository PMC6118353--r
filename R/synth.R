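# ---------------------------------------------------------------------------
# Synthetic-study generator.
#
# Emulates the field design the pipeline is built for: several ecosystems,
# each with replicate pairs of a foundation-species-dominated (FS) web of
# ~25 species at connectance ~0.15 and a bare-area (BA) web of ~12
# species.  FS webs come from the classical niche model; one basal species
# is designated the foundation species and pruned to roughly half the
# web-average link count (foundation species are weakly linked food
# sources).  BA webs are induced subwebs of their paired FS web: the
# foundation species is always absent and the remaining species are
# subsampled uniformly ("random" facilitation) or with guild-dependent
# weights ("targeted" facilitation), followed by the same isolation cascade
# the null model uses.  Species counts and stable-isotope samples (with
# known true diet proportions) complete the study.
# ---------------------------------------------------------------------------

#' Configuration of a synthetic study
#'
#' @param n_ecosystems number of ecosystems (default 7).
#' @param reps replicate pairs per ecosystem: a vector of length
#'   `n_ecosystems` (values in 3..6) or a single value recycled.  The
#'   default `c(4, 4, 4, 4, 4, 4, 5)` yields 29 FS + 29 BA webs.
#' @param S_fs target species number of FS webs (default 25).
#' @param connectance target connectance of FS webs (default 0.15).
#' @param S_ba target species number of BA webs (default 12).
#' @param facilitation_mode `"random"` (uniform subsampling; the null
#'   hypothesis of the random-removal model holds by construction) or
#'   `"targeted"` (guild-weighted subsampling).
#' @param facilitation_weights named numeric vector over
#'   `basal, herbivore, omnivore, carnivore`: how strongly the foundation
#'   species facilitates each guild.  Retention probability in the bare
#'   web is proportional to `1 / weight`, so a strongly facilitated guild
#'   is depleted in bare areas.  Defaults: all 1 in random mode;
#'   `basal = 0.5, carnivore = 2` in targeted mode (foundation species
#'   suppress basal species by competing for space and disproportionately
#'   support carnivores).
#' @param eco_sd between-ecosystem sd of the species-number offset.
#' @param rep_sd between-replicate sd of the species-number offset.
#' @param rare_fraction fraction of species drawn with count below the
#'   rare-species threshold of 3 (default 0.1).
#' @param count_lambda Poisson mean of the abundance counts of common
#'   species (default 12).
#' @param d13C_range basal d13C spread (permil, default -32..-14).
#' @param d15N_base,d15N_sd basal d15N baseline mean/sd (permil).
#' @param tef [trophic_enrichment()] used to build consumer signatures.
#' @param noise_sd per-sample isotope measurement noise sd (permil).
#' @param n_samples isotope samples per species (default 5).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_ecosystems = 7, reps = c(4, 4, 4, 4, 4, 4, 5),
                         S_fs = 25, connectance = 0.15, S_ba = 12,
                         facilitation_mode = c("random", "targeted"),
                         facilitation_weights = NULL, eco_sd = 2,
                         rep_sd = 1.5, rare_fraction = 0.1,
                         count_lambda = 12, d13C_range = c(-32, -14),
                         d15N_base = 2, d15N_sd = 1,
                         tef = trophic_enrichment(), noise_sd = 0.5,
                         n_samples = 5) {
  facilitation_mode <- match.arg(facilitation_mode)
  if (length(reps) == 1) reps <- rep(reps, n_ecosystems)
  if (length(reps) != n_ecosystems) {
    stop("`reps` must have length 1 or n_ecosystems")
  }
  if (connectance <= 0 || connectance >= 0.5) {
    stop("connectance must be in (0, 0.5)")
  }
  if (S_ba >= S_fs) stop("S_ba must be smaller than S_fs")
  if (is.null(facilitation_weights)) {
    facilitation_weights <- if (facilitation_mode == "targeted") {
      c(basal = 0.5, herbivore = 1, omnivore = 1, carnivore = 2)
    } else {
      c(basal = 1, herbivore = 1, omnivore = 1, carnivore = 1)
    }
  }
  need <- c("basal", "herbivore", "omnivore", "carnivore")
  if (!all(need %in% names(facilitation_weights)) ||
      any(facilitation_weights <= 0)) {
    stop("facilitation_weights needs positive entries for ",
         paste(need, collapse = ", "))
  }
  structure(list(n_ecosystems = n_ecosystems, reps = reps, S_fs = S_fs,
                 connectance = connectance, S_ba = S_ba,
                 facilitation_mode = facilitation_mode,
                 facilitation_weights = facilitation_weights[need],
                 eco_sd = eco_sd, rep_sd = rep_sd,
                 rare_fraction = rare_fraction, count_lambda = count_lambda,
                 d13C_range = d13C_range, d15N_base = d15N_base,
                 d15N_sd = d15N_sd, tef = tef, noise_sd = noise_sd,
                 n_samples = n_samples),
            class = "synth_config")
}

#' Generate a niche-model food web
#'
#' Classical niche-model construction: each species receives a niche value
#' uniform on `[0, 1]` and consumes every species whose niche value falls
#' in a beta-distributed diet range centred below its own value; the
#' species with the smallest niche value gets an empty range so at least
#' one basal species exists.  Webs are redrawn until connected, free of
#' isolated species, with every species linked to a basal species through
#' its diet (so trophic levels are defined), and with realized connectance
#' within a relative tolerance of the target (the usual practice when
#' niche-model webs stand in for webs of a prescribed connectance).
#'
#' @param S species number (>= 3).
#' @param C target connectance in (0, 0.5); the beta shape is set to
#'   `1/(2C) - 1` so the expected realized connectance matches.
#' @param seed integer seed (same seed, same web).
#' @param max_tries redraw budget before giving up.
#' @param c_tol relative tolerance on realized connectance (default 0.05:
#'   accept webs with `|L/S^2 - C| <= 0.05 C`); set `Inf` to disable.
#' @return a `foodweb` with species ids `sp01, sp02, ...` in niche order.
#' @export
niche_model_web <- function(S, C, seed, max_tries = 2000, c_tol = 0.05) {
  if (S < 3) stop("niche model needs S >= 3")
  if (C <= 0 || C >= 0.5) stop("niche model needs 0 < C < 0.5")
  set.seed(as.integer(seed %% .Machine$integer.max))
  beta_shape <- 1 / (2 * C) - 1
  for (try in seq_len(max_tries)) {
    n <- sort(runif(S))
    r <- n * rbeta(S, 1, beta_shape)
    r[1] <- 0                       # smallest niche value is basal
    centre <- runif(S, r / 2, pmin(n, 1 - r / 2))
    ids <- sprintf("sp%02d", seq_len(S))
    links <- do.call(rbind, lapply(seq_len(S), function(i) {
      eats <- which(n >= centre[i] - r[i] / 2 & n <= centre[i] + r[i] / 2)
      if (length(eats) == 0) return(NULL)
      data.frame(prey = ids[eats], predator = ids[i],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(links) || nrow(links) == 0) next
    # tolerance in link units, never finer than the integer granularity
    if (abs(nrow(links) - C * S^2) > max(c_tol * C * S^2, 1)) next
    web <- tryCatch(foodweb(links, species = ids, allow_isolated = FALSE),
                    error = function(e) NULL)
    if (is.null(web)) next
    g <- as_igraph(web, directed = FALSE, drop_self = TRUE)
    if (igraph::components(g)$no != 1) next
    if (length(basal_ids(web)) < 1) next
    if (any(!is.finite(chain_length_values(web)))) next
    return(web)
  }
  stop("niche_model_web: no admissible web in ", max_tries, " draws ",
       "(S = ", S, ", C = ", C, ")")
}

# Internal: guild of every species of a web (basal/herbivore/omnivore/
# carnivore), self-links ignored.
species_guilds <- function(web) {
  basal <- basal_ids(web)
  prey <- prey_sets(web, drop_self = TRUE)
  vapply(species_ids(web), function(sp) {
    if (sp %in% basal) return("basal")
    p <- prey[[sp]]
    eats_basal <- any(p %in% basal)
    eats_nonbasal <- any(!p %in% basal)
    if (eats_basal && eats_nonbasal) "omnivore"
    else if (eats_basal) "herbivore" else "carnivore"
  }, character(1))
}

# Internal: designate a basal foundation species and prune its predator
# links to about half the web-average incident link count.  Links that are
# a predator's only prey are kept so no species loses its whole diet, and
# prunings that would strand a consumer cycle from its basal supply are
# skipped (trophic levels must stay defined).
add_foundation <- function(web, seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  basal <- basal_ids(web)
  lk <- web$links
  npred <- vapply(basal, function(b) sum(lk$prey == b & lk$predator != b),
                  numeric(1))
  fs <- basal[which.max(npred)]
  mean_inc <- degree_stats(web)$links
  target <- max(1, round(mean_inc / 2))
  prey <- prey_sets(web, drop_self = TRUE)
  n_prey <- vapply(prey, length, integer(1))
  is_fs_link <- lk$prey == fs & lk$predator != fs
  removable <- which(is_fs_link & n_prey[lk$predator] >= 2)
  excess <- sum(is_fs_link) - target
  if (excess > 0 && length(removable) > 0) {
    for (idx in sample(removable)) {
      if (excess <= 0) break
      cand <- web
      cand$links <- web$links[-match(paste(lk$prey[idx], lk$predator[idx]),
                                     paste(web$links$prey,
                                           web$links$predator)), ,
                              drop = FALSE]
      if (all(is.finite(chain_length_values(cand)))) {
        web <- cand
        excess <- excess - 1
      }
    }
    rownames(web$links) <- NULL
  }
  web$species$is_foundation <- web$species$id == fs
  web
}

# Internal: subsample a bare web from an FS web by sequential removal --
# the same mechanics as the null model, so that in random mode the bare
# webs satisfy the random-facilitation null by construction.  The
# foundation species is removed first (bare areas lack it); then species
# are removed one at a time with probability proportional to the
# facilitation weight of their guild (strongly facilitated guilds are the
# ones missing from bare areas; uniform in random mode), cascading away
# trophically isolated species after each removal, until `size` species
# remain.  Replicates that overshoot far below `size`, lose all basal
# species or strand a consumer cycle are restarted.
sample_bare_web <- function(fs_web, size, weights, seed, max_tries = 50) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  fs_id <- species_ids(fs_web)[fs_web$species$is_foundation]
  guild <- species_guilds(fs_web)
  size <- min(size, n_species(fs_web) - length(fs_id))
  cascade <- function(web) {
    repeat {
      iso <- isolated_ids(web)
      if (length(iso) == 0) return(web)
      web <- induced_subweb(web, setdiff(species_ids(web), iso))
    }
  }
  best <- NULL
  for (try in seq_len(max_tries)) {
    ba <- cascade(induced_subweb(fs_web, setdiff(species_ids(fs_web), fs_id)))
    while (n_species(ba) > size) {
      pool <- species_ids(ba)
      victim <- pool[sample.int(length(pool), 1,
                                prob = weights[guild[pool]])]
      ba <- cascade(induced_subweb(ba, setdiff(species_ids(ba), victim)))
    }
    if (n_species(ba) < max(3, size - 2)) next
    if (length(basal_ids(ba)) < 1) next
    if (any(!is.finite(chain_length_values(ba)))) next
    best <- ba
    break
  }
  if (is.null(best)) {
    stop("sample_bare_web: no usable bare web after ", max_tries, " tries")
  }
  best$web_type <- "BA"
  best$species$is_foundation <- FALSE
  best
}

# Internal: draw abundance counts (a rare_fraction of species get counts
# below the rare threshold of 3).
assign_counts <- function(web, cfg, seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  S <- n_species(web)
  rare <- runif(S) < cfg$rare_fraction
  counts <- 3L + rpois(S, cfg$count_lambda - 3)
  counts[rare] <- sample(1:2, sum(rare), replace = TRUE)
  web$species$count <- as.integer(counts)
  web
}

#' Simulate stable-isotope samples for a web
#'
#' Basal species get d13C means spread uniformly over `cfg$d13C_range` and
#' d15N means around the basal baseline.  Every consumer gets true diet
#' proportions drawn Dirichlet(1, ..., 1) over its prey (self-links
#' excluded); its tissue means solve the mixing identity
#' `mean_i = sum_k p_ik mean_k + enrichment` exactly, and per-sample
#' replicates add Gaussian noise of sd `cfg$noise_sd`.
#'
#' @param web a `foodweb` whose species all reach a basal species.
#' @param cfg a [synth_config()].
#' @param seed integer seed.
#' @return list with `web` (isotope samples filled in) and `true_diets`
#'   (named list: consumer id -> named proportion vector over its prey).
#' @export
simulate_isotopes <- function(web, cfg, seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  ids <- species_ids(web)
  S <- length(ids)
  basal <- basal_ids(web)
  if (length(basal) == 0) stop("web has no basal species")
  prey <- prey_sets(web, drop_self = TRUE)
  true_diets <- list()
  P <- matrix(0, S, S, dimnames = list(ids, ids))
  for (sp in setdiff(ids, basal)) {
    pr <- prey[[sp]]
    p <- rgamma(length(pr), 1)
    p <- p / sum(p)
    names(p) <- pr
    true_diets[[sp]] <- p
    P[sp, pr] <- p
  }
  b13 <- b15 <- setNames(rep(0, S), ids)
  nb <- length(basal)
  b13[basal] <- cfg$d13C_range[1] +
    (seq_len(nb) - 0.5) / nb * diff(cfg$d13C_range)
  b13[basal] <- sample(b13[basal])          # decouple spread from id order
  b15[basal] <- rnorm(nb, cfg$d15N_base, cfg$d15N_sd)
  rhs13 <- ifelse(ids %in% basal, b13, cfg$tef$delta_d13C)
  rhs15 <- ifelse(ids %in% basal, b15, cfg$tef$delta_d15N)
  A <- diag(S) - P
  m13 <- drop(solve(A, rhs13))
  m15 <- drop(solve(A, rhs15))
  web$species$d13C <- lapply(seq_len(S), function(i) {
    m13[i] + rnorm(cfg$n_samples, 0, cfg$noise_sd)
  })
  web$species$d15N <- lapply(seq_len(S), function(i) {
    m15[i] + rnorm(cfg$n_samples, 0, cfg$noise_sd)
  })
  list(web = web, true_diets = true_diets)
}

#' Generate all replicate web pairs of one ecosystem
#'
#' Each replicate pair consists of a foundation-species (FS) niche-model
#' web with a weakly linked basal foundation species, and a bare-area (BA)
#' web obtained by subsampling the FS web (foundation species removed,
#' guild weighting per the facilitation mode) followed by the isolation
#' cascade.  Counts and isotopes are attached to both webs.
#'
#' @param cfg a [synth_config()].
#' @param ecosystem ecosystem label.
#' @param n_reps number of replicate pairs.
#' @param seed integer seed.
#' @return list with `fs` (list of FS webs), `ba` (list of BA webs) and
#'   `true_diets` (named by web label).
#' @export
make_ecosystem_pair <- function(cfg, ecosystem, n_reps, seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  eco_off <- rnorm(1, 0, cfg$eco_sd)
  fs <- ba <- list()
  diets <- list()
  for (rep in seq_len(n_reps)) {
    s_fs <- max(10, round(cfg$S_fs + eco_off + rnorm(1, 0, cfg$rep_sd)))
    s_ba <- max(6, round(cfg$S_ba + eco_off * cfg$S_ba / cfg$S_fs +
                           rnorm(1, 0, cfg$rep_sd)))
    w <- niche_model_web(s_fs, cfg$connectance, derive_seed(seed, rep * 7 + 1))
    w <- add_foundation(w, derive_seed(seed, rep * 7 + 2))
    w$ecosystem <- ecosystem
    w$web_type <- "FS"
    w$replicate <- paste0("r", rep)
    w <- assign_counts(w, cfg, derive_seed(seed, rep * 7 + 3))
    sim <- simulate_isotopes(w, cfg, derive_seed(seed, rep * 7 + 4))
    w <- sim$web
    b <- sample_bare_web(w, s_ba, cfg$facilitation_weights,
                         derive_seed(seed, rep * 7 + 5))
    b$ecosystem <- ecosystem
    b$replicate <- paste0("r", rep)
    b <- assign_counts(b, cfg, derive_seed(seed, rep * 7 + 6))
    simb <- simulate_isotopes(b, cfg, derive_seed(seed, rep * 7 + 7))
    b <- simb$web
    fs[[rep]] <- w
    ba[[rep]] <- b
    diets[[web_label(w)]] <- sim$true_diets
    diets[[web_label(b)]] <- simb$true_diets
  }
  list(fs = fs, ba = ba, true_diets = diets)
}

#' Label of a web within a study
#' @param web a `foodweb`.
#' @return `"<ecosystem>_<web_type>_<replicate>"`.
#' @export
web_label <- function(web) {
  paste(web$ecosystem, web$web_type, web$replicate, sep = "_")
}

#' Generate a full synthetic study
#'
#' @param cfg a [synth_config()].
#' @param seed integer master seed; the whole study is deterministic given
#'   the seed.
#' @return an object of class `synth_study`: list with `webs` (named list
#'   of all FS and BA webs), `true_diets` (per web), `design` (data frame
#'   `ecosystem, web_type, replicate, label`), `cfg`, `seed`.
#' @export
generate_study <- function(cfg = synth_config(), seed = 1) {
  webs <- list()
  diets <- list()
  for (e in seq_len(cfg$n_ecosystems)) {
    eco <- sprintf("eco%d", e)
    part <- make_ecosystem_pair(cfg, eco, cfg$reps[e],
                                derive_seed(seed, 1000 + e))
    for (w in c(part$fs, part$ba)) webs[[web_label(w)]] <- w
    diets <- c(diets, part$true_diets)
  }
  design <- do.call(rbind, lapply(webs, function(w) {
    data.frame(ecosystem = w$ecosystem, web_type = w$web_type,
               replicate = w$replicate, label = web_label(w),
               stringsAsFactors = FALSE)
  }))
  rownames(design) <- NULL
  structure(list(webs = webs, true_diets = diets, design = design,
                 cfg = cfg, seed = seed),
            class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cat(sprintf("<synth_study> %d webs (%d FS, %d BA) over %d ecosystems, seed %s\n",
              length(x$webs), sum(x$design$web_type == "FS"),
              sum(x$design$web_type == "BA"),
              length(unique(x$design$ecosystem)), x$seed))
  invisible(x)
}
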