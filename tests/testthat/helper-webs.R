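# Fixture webs and independent brute-force oracles used across the suite.

# 3-species chain A -> B -> C.
w3_chain <- function() {
  foodweb(data.frame(prey = c("A", "B"), predator = c("B", "C")))
}

# 4-link omnivory web with a cannibal: P -> H, P -> O, H -> O, O -> O.
w4_web <- function() {
  foodweb(data.frame(prey = c("P", "P", "H", "O"),
                     predator = c("H", "O", "O", "O")))
}

# Random Bernoulli web on S species (valid, possibly with self-links and
# isolated species kept); used for label-invariance / round-trip / oracle
# property checks.  Not a niche-model web on purpose.
random_web <- function(S, p = 0.3, seed = 1) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(S))
  a <- matrix(runif(S * S) < p, S, S)
  hit <- which(a, arr.ind = TRUE)
  if (nrow(hit) == 0) hit <- cbind(1, min(2, S))
  links <- data.frame(prey = ids[hit[, 1]], predator = ids[hit[, 2]],
                      stringsAsFactors = FALSE)
  foodweb(links, species = ids, allow_isolated = TRUE)
}

# Simulated study table with a known mixed-model structure: additive
# ecosystem effects, a per-type mean shift and iid residuals.
sim_table <- function(n_eco = 6, reps = 4, type_means = c(FS = 0, BA = 0, RR = 0),
                      eco_sd = 1, resid_sd = 1, seed = 1) {
  set.seed(seed)
  eco_eff <- rnorm(n_eco, 0, eco_sd)
  rows <- expand.grid(ecosystem = paste0("e", seq_len(n_eco)),
                      web_type = names(type_means),
                      replicate = paste0("r", seq_len(reps)),
                      stringsAsFactors = FALSE)
  rows$label <- paste(rows$ecosystem, rows$web_type, rows$replicate,
                      sep = "_")
  rows$y <- type_means[rows$web_type] +
    eco_eff[as.integer(sub("e", "", rows$ecosystem))] +
    rnorm(nrow(rows), 0, resid_sd)
  rows
}

# --- independent oracles (adjacency-matrix based, plain enumeration) -----

# Pairwise trophic similarity from the 0/1 adjacency matrix.
bf_similarity_mean <- function(web) {
  a <- adjacency_matrix(web)
  diag(a) <- 0L
  S <- nrow(a)
  mx <- numeric(S)
  for (i in seq_len(S)) {
    best <- 0
    for (j in seq_len(S)[-i]) {
      shared <- sum(a[, i] & a[, j]) + sum(a[i, ] & a[j, ])
      total <- sum(a[, i] | a[, j]) + sum(a[i, ] | a[j, ])
      s <- if (total == 0) 0 else shared / total
      best <- max(best, s)
    }
    mx[i] <- best
  }
  mean(mx)
}

# Mean shortest path over connected ordered pairs, by Floyd-Warshall on
# the undirected simple projection.
bf_path_length <- function(web) {
  a <- adjacency_matrix(web)
  diag(a) <- 0L
  u <- (a + t(a)) > 0
  S <- nrow(u)
  d <- matrix(Inf, S, S)
  d[u] <- 1
  diag(d) <- 0
  for (k in seq_len(S)) {
    for (i in seq_len(S)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  vals <- d[is.finite(d) & d > 0]
  if (length(vals) == 0) NaN else mean(vals)
}

# Mean pairwise neighbourhood overlap (focal pair removed from both
# neighbour sets), enumerated directly.
bf_compartmentalization <- function(web) {
  a <- adjacency_matrix(web)
  diag(a) <- 0L
  u <- (a + t(a)) > 0
  S <- nrow(u)
  tot <- 0
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      ni <- setdiff(which(u[i, ]), c(i, j))
      nj <- setdiff(which(u[j, ]), c(i, j))
      un <- union(ni, nj)
      if (length(un) > 0) tot <- tot + length(intersect(ni, nj)) / length(un)
    }
  }
  tot / (S * (S - 1) / 2)
}

# Mean local clustering coefficient (degree < 2 contributes 0).
bf_clustering <- function(web) {
  a <- adjacency_matrix(web)
  diag(a) <- 0L
  u <- (a + t(a)) > 0
  S <- nrow(u)
  cl <- numeric(S)
  for (i in seq_len(S)) {
    nb <- which(u[i, ])
    k <- length(nb)
    if (k < 2) next
    cl[i] <- sum(u[nb, nb]) / (k * (k - 1))
  }
  mean(cl)
}
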