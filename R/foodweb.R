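#' @import stats
#' @importFrom utils read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# Food-web data model
#
# A food web is a dichotomous (binary) directed network: a link (prey,
# predator) records only that the predator eats the prey.  Species carry the
# metadata the downstream filters need: an abundance count (rare-species
# filter), a foundation flag (at most one per web) and optional stable
# isotope samples (d13C / d15N, permil) used by the mixing model.
# ---------------------------------------------------------------------------

#' Construct a food web
#'
#' Builds a validated dichotomous food web from a link table and a species
#' table.  Links are directed prey -> predator; self-links (cannibalism) are
#' allowed, duplicates and links to unknown species are not.
#'
#' @param links data frame with character columns `prey` and `predator`, one
#'   directed feeding link per row, or `NULL` for a web with no links.
#' @param species either a character vector of species ids or a data frame
#'   with columns `id` and optionally `name`, `count`, `is_foundation`,
#'   `d13C`, `d15N`.  Isotope columns may be list columns of numeric sample
#'   vectors or semicolon-separated strings.  If `NULL`, the species set is
#'   taken from the link endpoints.
#' @param ecosystem,web_type,replicate metadata labels; `web_type` must be
#'   one of `"FS"` (foundation species-dominated), `"BA"` (bare area) or
#'   `"RR"` (random removal) when given.
#' @param allow_isolated keep species that participate in no link?  Defaults
#'   to `FALSE`: a sampled web only contains trophically connected taxa.
#' @return an object of class `foodweb`.
#' @export
foodweb <- function(links, species = NULL, ecosystem = NA_character_,
                    web_type = NA_character_, replicate = NA_character_,
                    allow_isolated = FALSE) {
  if (is.null(links)) {
    links <- data.frame(prey = character(), predator = character(),
                        stringsAsFactors = FALSE)
  }
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (!all(c("prey", "predator") %in% names(links))) {
    stop("`links` needs columns `prey` and `predator`")
  }
  links <- data.frame(prey = as.character(links$prey),
                      predator = as.character(links$predator),
                      stringsAsFactors = FALSE)

  if (is.null(species)) species <- sort(unique(c(links$prey, links$predator)))
  species <- normalize_species_table(species)

  if (!is.na(web_type) && !web_type %in% c("FS", "BA", "RR")) {
    stop("`web_type` must be one of FS, BA, RR")
  }

  web <- structure(list(species = species, links = links,
                        ecosystem = as.character(ecosystem),
                        web_type = as.character(web_type),
                        replicate = as.character(replicate)),
                   class = "foodweb")
  validate_foodweb(web, allow_isolated = allow_isolated)
}

normalize_species_table <- function(species) {
  if (is.character(species)) {
    species <- data.frame(id = species, stringsAsFactors = FALSE)
  }
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  if (!"id" %in% names(species)) stop("species table needs an `id` column")
  n <- nrow(species)
  species$id <- as.character(species$id)
  if (is.null(species$name)) species$name <- species$id
  if (is.null(species$count)) species$count <- rep(NA_integer_, n)
  if (is.null(species$is_foundation)) species$is_foundation <- rep(FALSE, n)
  species$is_foundation[is.na(species$is_foundation)] <- FALSE
  for (col in c("d13C", "d15N")) {
    if (is.null(species[[col]])) {
      species[[col]] <- replicate(nrow(species), numeric(0), simplify = FALSE)
    } else if (!is.list(species[[col]])) {
      species[[col]] <- parse_isotope_field(species[[col]])
    }
  }
  rownames(species) <- NULL
  species[c("id", "name", "count", "is_foundation", "d13C", "d15N")]
}

parse_isotope_field <- function(x) {
  lapply(as.character(x), function(v) {
    if (is.na(v) || !nzchar(trimws(v))) return(numeric(0))
    as.numeric(strsplit(v, ";", fixed = TRUE)[[1]])
  })
}

#' Validate a food web
#'
#' Checks the structural invariants: unique species ids, non-negative
#' counts, at most one foundation species, links referencing known species,
#' no duplicate links, and (unless `allow_isolated`) no species without any
#' link.
#'
#' @param web a `foodweb`.
#' @param allow_isolated permit species with no incident link.
#' @return the web, invisibly usable (returned unchanged).
#' @export
validate_foodweb <- function(web, allow_isolated = TRUE) {
  sp <- web$species
  if (anyDuplicated(sp$id)) {
    stop("duplicate species id(s): ",
         paste(unique(sp$id[duplicated(sp$id)]), collapse = ", "))
  }
  bad_count <- !is.na(sp$count) & sp$count < 0
  if (any(bad_count)) {
    stop("negative count for species: ",
         paste(sp$id[bad_count], collapse = ", "))
  }
  if (sum(sp$is_foundation) > 1) {
    stop("at most one foundation species per web (found ",
         sum(sp$is_foundation), ")")
  }
  lk <- web$links
  unknown <- setdiff(unique(c(lk$prey, lk$predator)), sp$id)
  if (length(unknown) > 0) {
    bad <- which(lk$prey %in% unknown | lk$predator %in% unknown)[1]
    stop("link ", bad, " (", lk$prey[bad], " -> ", lk$predator[bad],
         ") references unknown species: ", paste(unknown, collapse = ", "))
  }
  key <- paste(lk$prey, lk$predator, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop("duplicate link: ", lk$prey[d], " -> ", lk$predator[d])
  }
  if (!allow_isolated) {
    linked <- unique(c(lk$prey, lk$predator))
    iso <- setdiff(sp$id, linked)
    if (length(iso) > 0) {
      stop("isolated species not allowed: ", paste(iso, collapse = ", "),
           " (use allow_isolated = TRUE to keep them)")
    }
  }
  web
}

#' @export
print.foodweb <- function(x, ...) {
  cat(sprintf("<foodweb> %d species, %d links", nrow(x$species),
              nrow(x$links)))
  meta <- c(ecosystem = x$ecosystem, type = x$web_type, rep = x$replicate)
  meta <- meta[!is.na(meta)]
  if (length(meta)) {
    cat(" [", paste(names(meta), meta, sep = "=", collapse = ", "), "]",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Number of species / links in a web
#' @param web a `foodweb`.
#' @return integer count.
#' @export
n_species <- function(web) nrow(web$species)

#' @rdname n_species
#' @export
n_links <- function(web) nrow(web$links)

#' Species ids of a web
#' @param web a `foodweb`.
#' @return character vector in species-table order.
#' @export
species_ids <- function(web) web$species$id

#' Adjacency matrix of a web
#'
#' Rows are prey, columns are predators: `A[i, j] = 1` means species j eats
#' species i.
#'
#' @param web a `foodweb`.
#' @return an S x S 0/1 integer matrix with species ids as dimnames.
#' @export
adjacency_matrix <- function(web) {
  ids <- species_ids(web)
  a <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (n_links(web) > 0) {
    a[cbind(match(web$links$prey, ids), match(web$links$predator, ids))] <- 1L
  }
  a
}

#' Convert a web to an igraph graph
#'
#' @param web a `foodweb`.
#' @param directed directed prey -> predator edges, or undirected projection.
#' @param drop_self drop self-links (cannibalism) first.
#' @return an `igraph` graph whose vertices are the web's species.
#' @export
as_igraph <- function(web, directed = TRUE, drop_self = FALSE) {
  lk <- web$links
  if (drop_self) lk <- lk[lk$prey != lk$predator, , drop = FALSE]
  g <- igraph::graph_from_data_frame(lk, directed = directed,
                                     vertices = data.frame(name = species_ids(web)))
  if (!directed) g <- igraph::simplify(g)
  g
}

#' Induced sub-web
#'
#' Restricts a web to a subset of its species, keeping exactly the links
#' with both endpoints retained.  Metadata and per-species fields are
#' preserved.  Species that lose all their links are kept as isolated nodes
#' (pruning them is the null model's isolation cascade, not this
#' operation's job).
#'
#' @param web a `foodweb`.
#' @param keep character vector of species ids to retain.
#' @return a `foodweb` on the kept species.
#' @export
induced_subweb <- function(web, keep) {
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, species_ids(web))
  if (length(unknown) > 0) {
    stop("unknown species id(s) in `keep`: ", paste(unknown, collapse = ", "))
  }
  sp <- web$species[web$species$id %in% keep, , drop = FALSE]
  rownames(sp) <- NULL
  lk <- web$links
  lk <- lk[lk$prey %in% keep & lk$predator %in% keep, , drop = FALSE]
  rownames(lk) <- NULL
  structure(list(species = sp, links = lk, ecosystem = web$ecosystem,
                 web_type = web$web_type, replicate = web$replicate),
            class = "foodweb")
}

# ---------------------------------------------------------------------------
# File I/O: edge-list CSV ("prey,predator"), adjacency CSV (first row and
# column are species ids; cell (i, j) = 1 means species j eats species i)
# and the species CSV ("id,name,count,is_foundation,d13C,d15N" with
# semicolon-separated isotope replicates).
# ---------------------------------------------------------------------------

#' Read a food web from disk
#'
#' @param path path to an edge-list or adjacency CSV.
#' @param format `"edge_list"` (header `prey,predator`) or `"adjacency"`
#'   (square 0/1 matrix, rows prey / columns predators).
#' @param species_path optional species CSV
#'   (`id,name,count,is_foundation,d13C,d15N`); isotope fields hold
#'   semicolon-separated replicate values.  Without it a minimal species
#'   table is derived from the link endpoints.
#' @param allow_isolated keep species listed in the species table that have
#'   no link.  Default `FALSE` (such rows are rejected).
#' @param ecosystem,web_type,replicate metadata labels for the loaded web.
#' @return a `foodweb`.
#' @export
load_web <- function(path, format = c("edge_list", "adjacency"),
                     species_path = NULL, allow_isolated = FALSE,
                     ecosystem = NA_character_, web_type = NA_character_,
                     replicate = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "edge_list") {
    links <- read.csv(path, stringsAsFactors = FALSE,
                      colClasses = "character")
    if (!all(c("prey", "predator") %in% names(links))) {
      stop("edge-list file must have header `prey,predator`: ", path)
    }
  } else {
    m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
    if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
      stop("adjacency file must be square with matching row/column ids: ",
           path)
    }
    hit <- which(m != 0, arr.ind = TRUE)
    links <- data.frame(prey = rownames(m)[hit[, 1]],
                        predator = colnames(m)[hit[, 2]],
                        stringsAsFactors = FALSE)
  }
  species <- if (!is.null(species_path)) load_species(species_path) else NULL
  if (format == "adjacency" && is.null(species)) {
    species <- rownames(as.matrix(read.csv(path, row.names = 1,
                                           check.names = FALSE)))
  }
  foodweb(links, species = species, ecosystem = ecosystem,
          web_type = web_type, replicate = replicate,
          allow_isolated = allow_isolated)
}

#' Read a species table
#'
#' @param path species CSV with header `id,name,count,is_foundation,d13C,d15N`.
#' @return a species data frame suitable for [foodweb()].
#' @export
load_species <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sp <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(id = "character"))
  if (!"id" %in% names(sp)) stop("species file needs an `id` column: ", path)
  if (!is.null(sp$is_foundation)) {
    sp$is_foundation <- as.logical(sp$is_foundation)
  }
  normalize_species_table(sp)
}

#' Write a food web to disk
#'
#' `save_web()` followed by [load_web()] round-trips the web exactly
#' (species, links, flags, isotope samples).
#'
#' @param web a `foodweb`.
#' @param path output CSV path for the links.
#' @param format `"edge_list"` or `"adjacency"`.
#' @param species_path optional path for the companion species CSV.
#' @return `path`, invisibly.
#' @export
save_web <- function(web, path, format = c("edge_list", "adjacency"),
                     species_path = NULL) {
  format <- match.arg(format)
  if (format == "edge_list") {
    write.csv(web$links, path, row.names = FALSE, quote = FALSE)
  } else {
    write.csv(adjacency_matrix(web), path, quote = FALSE)
  }
  if (!is.null(species_path)) save_species(web$species, species_path)
  invisible(path)
}

#' @rdname save_web
#' @param species a species data frame (as held in `web$species`).
#' @export
save_species <- function(species, path) {
  out <- species
  for (col in c("d13C", "d15N")) {
    out[[col]] <- vapply(out[[col]], function(v) paste(v, collapse = ";"), "")
  }
  out$is_foundation <- ifelse(out$is_foundation, "TRUE", "FALSE")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Internal: replace the species table of `web` keeping class/metadata.
set_species <- function(web, species) {
  web$species <- species
  web
}

# Internal: per-species prey/predator id lists (self-links optionally kept).
prey_sets <- function(web, drop_self = FALSE) {
  lk <- web$links
  if (drop_self) lk <- lk[lk$prey != lk$predator, , drop = FALSE]
  ids <- species_ids(web)
  out <- split(lk$prey, factor(lk$predator, levels = ids))
  lapply(out, as.character)
}

predator_sets <- function(web, drop_self = FALSE) {
  lk <- web$links
  if (drop_self) lk <- lk[lk$prey != lk$predator, , drop = FALSE]
  ids <- species_ids(web)
  out <- split(lk$predator, factor(lk$prey, levels = ids))
  lapply(out, as.character)
}
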