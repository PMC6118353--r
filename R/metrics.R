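# ---------------------------------------------------------------------------
# Food-web topology metrics.
#
# Conventions (stated once, applied everywhere):
#   * L counts every link including self-links; Z = L/S; C = L/S^2.
#   * generality  = mean number of prey per species, self-links counted,
#     so mean generality equals link density exactly.
#   * vulnerability = mean number of predators per species, self-links
#     excluded (a cannibal is not its own consumer in the predator count).
#   * basal/top/intermediate, guild membership, trophic levels, chain
#     lengths, similarity and the undirected graph metrics all ignore
#     self-links.
# ---------------------------------------------------------------------------

#' Names of the 19 topology metrics, in reporting order
#' @return character vector of length 19.
#' @export
metric_names <- function() {
  c("species_number", "link_density", "connectance", "vulnerability",
    "generality", "links", "top_fraction", "intermediate_fraction",
    "basal_fraction", "herbivore_fraction", "omnivore_fraction",
    "carnivore_fraction", "cannibal_fraction", "chain_length",
    "trophic_level", "max_similarity", "clustering", "path_length",
    "compartmentalization")
}

stop_if_empty <- function(web) {
  if (n_species(web) < 1) stop("empty web: no species")
}

# Internal: ids of basal species (no prey, self-links ignored).
basal_ids <- function(web) {
  lk <- web$links
  lk <- lk[lk$prey != lk$predator, , drop = FALSE]
  setdiff(species_ids(web), unique(lk$predator))
}

#' Degree statistics of a food web
#'
#' @param web a `foodweb` with at least one species.
#' @return named list: `S` (species number), `L` (links, self-links
#'   included), `link_density` (L/S), `connectance` (L/S^2),
#'   `vulnerability` (mean predators per species, self-links excluded),
#'   `generality` (mean prey per species, self-links included),
#'   `links` (mean distinct links incident to a species; a self-link
#'   counts once).
#' @export
degree_stats <- function(web) {
  stop_if_empty(web)
  S <- n_species(web)
  lk <- web$links
  L <- nrow(lk)
  self <- sum(lk$prey == lk$predator)
  ids <- species_ids(web)
  incident <- vapply(ids, function(i) sum(lk$prey == i | lk$predator == i),
                     integer(1))
  list(S = S, L = L, link_density = L / S, connectance = L / S^2,
       vulnerability = (L - self) / S, generality = L / S,
       links = mean(incident))
}

#' Trophic-position fractions
#'
#' Ignoring self-links: basal species have no prey, top species have prey
#' but no predators, intermediate species have both.
#'
#' @param web a `foodweb`.
#' @return named list `top`, `intermediate`, `basal`; fractions of S,
#'   summing to one.
#' @export
trophic_fractions <- function(web) {
  stop_if_empty(web)
  lk <- web$links
  lk <- lk[lk$prey != lk$predator, , drop = FALSE]
  ids <- species_ids(web)
  has_prey <- ids %in% lk$predator
  has_pred <- ids %in% lk$prey
  S <- length(ids)
  list(top = sum(has_prey & !has_pred) / S,
       intermediate = sum(has_prey & has_pred) / S,
       basal = sum(!has_prey) / S)
}

#' Feeding-guild fractions
#'
#' Consumers (non-basal species) are classified by their prey, self-links
#' ignored: herbivores eat only basal species, carnivores only non-basal
#' species, omnivores both.  The cannibal fraction is the fraction of all
#' species carrying a self-link.
#'
#' @param web a `foodweb`.
#' @return named list `herbivore`, `omnivore`, `carnivore`, `cannibal`
#'   (fractions of S; the first three sum to `1 - basal`).
#' @export
guild_fractions <- function(web) {
  stop_if_empty(web)
  S <- n_species(web)
  basal <- basal_ids(web)
  prey <- prey_sets(web, drop_self = TRUE)
  herb <- omn <- carn <- 0L
  for (sp in setdiff(species_ids(web), basal)) {
    p <- prey[[sp]]
    eats_basal <- any(p %in% basal)
    eats_nonbasal <- any(!p %in% basal)
    if (eats_basal && eats_nonbasal) omn <- omn + 1L
    else if (eats_basal) herb <- herb + 1L
    else carn <- carn + 1L
  }
  cann <- sum(web$links$prey == web$links$predator)
  list(herbivore = herb / S, omnivore = omn / S, carnivore = carn / S,
       cannibal = cann / S)
}

#' Prey-averaged trophic levels
#'
#' Basal species have trophic level 1; every consumer sits one level above
#' the mean of its prey: `TL_i = 1 + mean(TL_prey(i))`, self-links removed,
#' solved exactly as a linear system (feeding loops are fine as long as
#' every species is connected to a basal species through its diet).
#'
#' @param web a `foodweb`.
#' @return list with `tl` (named per-species vector) and `mean`.
#' @export
trophic_levels <- function(web) {
  stop_if_empty(web)
  ids <- species_ids(web)
  check_basal_reachability(web)
  prey <- prey_sets(web, drop_self = TRUE)
  S <- length(ids)
  D <- matrix(0, S, S, dimnames = list(ids, ids))
  for (i in seq_len(S)) {
    p <- prey[[ids[i]]]
    if (length(p) > 0) D[i, p] <- 1 / length(p)
  }
  tl <- drop(solve(diag(S) - D, rep(1, S)))
  names(tl) <- ids
  list(tl = tl, mean = mean(tl))
}

# Internal: every species must reach a basal species going down its prey
# links (self-links removed); otherwise trophic levels / chain lengths are
# undefined and the offending consumer cycle is reported.
check_basal_reachability <- function(web) {
  basal <- basal_ids(web)
  if (length(basal) == 0) {
    stop("no basal species: the web is one consumer cycle with no basal input")
  }
  ch <- chain_length_values(web, basal)
  stuck <- names(ch)[!is.finite(ch)]
  if (length(stuck) > 0) {
    stop("species with no feeding path to a basal species: ",
         paste(stuck, collapse = ", "))
  }
  invisible(ch)
}

# Internal: shortest number of feeding links down to a basal species (Inf
# where unreachable), computed by BFS from the basal set along reversed
# prey links.
chain_length_values <- function(web, basal = basal_ids(web)) {
  ids <- species_ids(web)
  prey <- prey_sets(web, drop_self = TRUE)
  dist <- setNames(rep(Inf, length(ids)), ids)
  dist[basal] <- 0
  frontier <- basal
  d <- 0
  preds <- predator_sets(web, drop_self = TRUE)
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- unique(unlist(preds[frontier], use.names = FALSE))
    nxt <- nxt[dist[nxt] == Inf]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Shortest chain lengths to a basal species
#'
#' The chain length of a species is the minimum number of feeding links
#' separating it from any basal species (basal species score 0); self-links
#' are ignored.
#'
#' @param web a `foodweb`.
#' @return list with `chain` (named per-species vector) and `mean`.
#' @export
chain_lengths <- function(web) {
  stop_if_empty(web)
  ch <- check_basal_reachability(web)
  list(chain = ch, mean = mean(ch))
}

#' Mean maximum trophic similarity
#'
#' The trophic similarity of a species pair is the number of prey and
#' predators they share divided by their total number of distinct prey and
#' predators (self-links excluded).  Each species takes the maximum over
#' all other species; the network value is the mean of these maxima.
#'
#' @param web a `foodweb` with at least two species.
#' @return list with `pairwise` (S x S symmetric matrix, diagonal NA),
#'   `max` (per-species maxima) and `mean`.
#' @export
max_similarity <- function(web) {
  if (n_species(web) < 2) stop("similarity needs at least 2 species")
  ids <- species_ids(web)
  prey <- prey_sets(web, drop_self = TRUE)
  pred <- predator_sets(web, drop_self = TRUE)
  S <- length(ids)
  sim <- matrix(NA_real_, S, S, dimnames = list(ids, ids))
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      a <- ids[i]; b <- ids[j]
      shared <- length(intersect(prey[[a]], prey[[b]])) +
        length(intersect(pred[[a]], pred[[b]]))
      total <- length(union(prey[[a]], prey[[b]])) +
        length(union(pred[[a]], pred[[b]]))
      sim[i, j] <- sim[j, i] <- if (total == 0) 0 else shared / total
    }
  }
  mx <- apply(sim, 1, max, na.rm = TRUE)
  list(pairwise = sim, max = mx, mean = mean(mx))
}

#' Undirected graph metrics
#'
#' Computed on the undirected simple projection of the web (self-links
#' dropped, link direction ignored): the mean local clustering coefficient
#' (species with fewer than two neighbours contribute 0), the mean shortest
#' path length over connected ordered pairs (unreachable pairs are
#' excluded, keeping the metric finite on fragmented webs), and
#' compartmentalization -- the mean, over unordered species pairs, of the
#' Jaccard overlap of their neighbourhoods with the pair itself removed
#' from both sets (pairs with an empty union contribute 0).
#'
#' @param web a `foodweb` with at least two species.
#' @return named list `clustering`, `path_length`, `compartmentalization`.
#' @export
graph_metrics <- function(web) {
  if (n_species(web) < 2) stop("graph metrics need at least 2 species")
  g <- as_igraph(web, directed = FALSE, drop_self = TRUE)
  cl <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  clustering <- mean(cl)
  dm <- igraph::distances(g)
  finite <- is.finite(dm) & dm > 0
  path_length <- if (any(finite)) mean(dm[finite]) else NaN
  ids <- species_ids(web)
  nb <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), function(v) {
    names(v)
  })
  names(nb) <- ids
  S <- length(ids)
  tot <- 0
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      ni <- setdiff(nb[[i]], c(ids[i], ids[j]))
      nj <- setdiff(nb[[j]], c(ids[i], ids[j]))
      u <- union(ni, nj)
      if (length(u) > 0) tot <- tot + length(intersect(ni, nj)) / length(u)
    }
  }
  list(clustering = clustering, path_length = path_length,
       compartmentalization = tot / (S * (S - 1) / 2))
}

#' Compute the full 19-metric panel of a web
#'
#' Runs every metric group and assembles the panel in reporting order; each
#' value is identical to what the individual metric function returns.
#'
#' @param web a `foodweb` satisfying all component preconditions (>= 2
#'   species, every species trophically connected to a basal species).
#' @return named numeric vector over [metric_names()].
#' @export
compute_all <- function(web) {
  wrap <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(what, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  d <- wrap("degree_stats", degree_stats(web))
  tf <- wrap("trophic_fractions", trophic_fractions(web))
  gf <- wrap("guild_fractions", guild_fractions(web))
  tl <- wrap("trophic_levels", trophic_levels(web))
  ch <- wrap("chain_lengths", chain_lengths(web))
  ms <- wrap("max_similarity", max_similarity(web))
  gm <- wrap("graph_metrics", graph_metrics(web))
  out <- c(species_number = d$S, link_density = d$link_density,
           connectance = d$connectance, vulnerability = d$vulnerability,
           generality = d$generality, links = d$links,
           top_fraction = tf$top, intermediate_fraction = tf$intermediate,
           basal_fraction = tf$basal, herbivore_fraction = gf$herbivore,
           omnivore_fraction = gf$omnivore, carnivore_fraction = gf$carnivore,
           cannibal_fraction = gf$cannibal, chain_length = ch$mean,
           trophic_level = tl$mean, max_similarity = ms$mean,
           clustering = gm$clustering, path_length = gm$path_length,
           compartmentalization = gm$compartmentalization)
  out[metric_names()]
}

#' Trophic importance of the foundation species
#'
#' Compares the foundation species' predator count (vulnerability) and
#' total link count against the mean over all other species and -- when the
#' foundation species is basal -- against the mean over the other basal
#' species.  Low ratios indicate the foundation species matters to the web
#' non-trophically rather than as a food source.
#'
#' @param web a `foodweb` with a flagged foundation species and at least
#'   one other species.
#' @return named list: `fs_vulnerability`, `other_mean_vulnerability`,
#'   `fs_links`, `other_mean_links`, and (if the foundation species is
#'   basal and other basal species exist) `fs_basal_links`,
#'   `other_basal_mean_links`, else `NA` for the basal pair.
#' @export
foundation_importance <- function(web) {
  stop_if_empty(web)
  fs <- species_ids(web)[web$species$is_foundation]
  if (length(fs) != 1) stop("web has no flagged foundation species")
  others <- setdiff(species_ids(web), fs)
  if (length(others) == 0) stop("no other species to compare against")
  lk <- web$links
  nonself <- lk[lk$prey != lk$predator, , drop = FALSE]
  vul <- vapply(species_ids(web), function(i) sum(nonself$prey == i),
                numeric(1))
  inc <- vapply(species_ids(web), function(i) sum(lk$prey == i | lk$predator == i),
                numeric(1))
  basal <- basal_ids(web)
  out <- list(fs_vulnerability = vul[[fs]],
              other_mean_vulnerability = mean(vul[others]),
              fs_links = inc[[fs]], other_mean_links = mean(inc[others]),
              fs_basal_links = NA_real_, other_basal_mean_links = NA_real_)
  ob <- setdiff(basal, fs)
  if (fs %in% basal && length(ob) > 0) {
    out$fs_basal_links <- inc[[fs]]
    out$other_basal_mean_links <- mean(inc[ob])
  }
  out
}
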