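# ---------------------------------------------------------------------------
# Web reconstruction: from a maximized, literature-based candidate web to
# the final constrained web.  Three filters run in a fixed order:
#   1. rare-species filter   (species with < min_count individuals)
#   2. forbidden-link filter (expert-flagged implausible interactions)
#   3. diet filter           (mixing-model contribution < threshold)
# Species left without any link afterwards are dropped, and every removal
# is recorded in a provenance log.
# ---------------------------------------------------------------------------

#' Remove rare species
#'
#' Drops every species observed fewer than `min_count` times (strict
#' inequality), together with all its links.
#'
#' @param web a `foodweb` whose species all carry counts.
#' @param min_count abundance threshold (default 3: species with fewer than
#'   three counted individuals are removed).
#' @return a new `foodweb`.
#' @export
rare_species_filter <- function(web, min_count = 3) {
  if (anyNA(web$species$count)) {
    stop("missing count for species: ",
         paste(web$species$id[is.na(web$species$count)], collapse = ", "))
  }
  keep <- web$species$id[web$species$count >= min_count]
  induced_subweb(web, keep)
}

#' Read a forbidden-link list
#'
#' @param path CSV with header `prey,predator,reason`.
#' @return data frame of forbidden links.
#' @export
load_forbidden <- function(path) {
  fb <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("prey", "predator") %in% names(fb))) {
    stop("forbidden-link file must have header `prey,predator[,reason]`: ",
         path)
  }
  if (is.null(fb$reason)) fb$reason <- ""
  fb
}

#' Remove expert-flagged implausible links
#'
#' Listed links are removed where present; listed links absent from the web
#' are ignored.
#'
#' @param web a `foodweb`.
#' @param forbidden data frame with columns `prey` and `predator` (and
#'   optionally `reason`), or `NULL`/empty for a no-op.
#' @return a new `foodweb`.
#' @export
apply_forbidden <- function(web, forbidden) {
  if (is.null(forbidden) || nrow(forbidden) == 0) return(web)
  key <- paste(web$links$prey, web$links$predator, sep = "\r")
  bad <- paste(forbidden$prey, forbidden$predator, sep = "\r")
  web$links <- web$links[!key %in% bad, , drop = FALSE]
  rownames(web$links) <- NULL
  web
}

#' Reconstruct a constrained web from a maximized candidate web
#'
#' Applies, in order, the rare-species filter, the forbidden-link filter
#' and the mixing-model diet filter, then drops species left without any
#' link.  Every removal is logged with its stage and reason; the pipeline
#' is deterministic given `seed`.
#'
#' @param maximized the literature-based candidate `foodweb` (species must
#'   carry counts, and isotope samples wherever a multi-prey diet must be
#'   resolved).
#' @param forbidden forbidden-link data frame (see [apply_forbidden()]), or
#'   `NULL`.
#' @param tef a [trophic_enrichment()].
#' @param threshold diet-proportion cutoff for [diet_filter()].
#' @param min_count rare-species threshold.
#' @param n_iter MCMC iterations per consumer.
#' @param seed integer seed for the mixing models.
#' @return list with `web` (the final `foodweb`), `log` (data frame
#'   `stage, kind, prey, predator, species, detail`) and `posteriors`.
#' @export
reconstruct_web <- function(maximized, forbidden = NULL,
                            tef = trophic_enrichment(), threshold = 0.05,
                            min_count = 3, n_iter = 10000, seed = 1) {
  log_rows <- list()
  note <- function(stage, kind, prey = NA, predator = NA, species = NA,
                   detail = "") {
    log_rows[[length(log_rows) + 1]] <<- data.frame(
      stage = stage, kind = kind, prey = prey, predator = predator,
      species = species, detail = detail, stringsAsFactors = FALSE)
  }
  link_diff <- function(before, after, stage, detail) {
    key_a <- paste(after$links$prey, after$links$predator, sep = "\r")
    gone <- before$links[!paste(before$links$prey, before$links$predator,
                                sep = "\r") %in% key_a, , drop = FALSE]
    for (r in seq_len(nrow(gone))) {
      note(stage, "link", prey = gone$prey[r], predator = gone$predator[r],
           detail = detail)
    }
  }

  w1 <- rare_species_filter(maximized, min_count = min_count)
  gone_sp <- setdiff(species_ids(maximized), species_ids(w1))
  for (s in gone_sp) {
    note("rare", "species", species = s,
         detail = paste0("count=", maximized$species$count[
           match(s, maximized$species$id)]))
  }
  link_diff(maximized, w1, "rare", "incident to rare species")

  w2 <- apply_forbidden(w1, forbidden)
  link_diff(w1, w2, "forbidden", "expert-flagged")

  posteriors <- fit_web_diets(w2, tef = tef, n_iter = n_iter, seed = seed)
  w3 <- diet_filter(w2, posteriors, threshold = threshold)
  link_diff(w2, w3, "diet", paste0("posterior mean < ", threshold))

  linked <- unique(c(w3$links$prey, w3$links$predator))
  iso <- setdiff(species_ids(w3), linked)
  final <- induced_subweb(w3, setdiff(species_ids(w3), iso))
  for (s in iso) note("isolated", "species", species = s,
                      detail = "isolated after reconstruction")

  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(stage = character(), kind = character(), prey = character(),
               predator = character(), species = character(),
               detail = character(), stringsAsFactors = FALSE)
  list(web = final, log = log, posteriors = posteriors)
}
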