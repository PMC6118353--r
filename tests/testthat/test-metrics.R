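# Hand-computed panels for the two toy webs:
#   W3: chain A -> B -> C
#   W4: P -> H, P -> O, H -> O, O -> O (omnivore O is also a cannibal)

test_that("degree statistics match hand counts", {
  d3 <- degree_stats(w3_chain())
  expect_equal(d3$S, 3L)
  expect_equal(d3$L, 2L)
  expect_equal(d3$link_density, 2 / 3)
  expect_equal(d3$connectance, 2 / 9)
  expect_equal(d3$vulnerability, 2 / 3)
  expect_equal(d3$generality, 2 / 3)
  expect_equal(d3$links, 4 / 3)

  d4 <- degree_stats(w4_web())
  expect_equal(d4$L, 4L)
  expect_equal(d4$connectance, 4 / 9)
  expect_equal(d4$generality, 4 / 3)
  expect_equal(d4$vulnerability, 1)
  expect_equal(d4$links, 7 / 3)

  # fully connected web without self-links, S = 4: C = 12/16
  ids <- c("a", "b", "c", "d")
  full <- expand.grid(prey = ids, predator = ids, stringsAsFactors = FALSE)
  full <- full[full$prey != full$predator, ]
  expect_equal(degree_stats(foodweb(full))$connectance, 0.75)

  expect_error(degree_stats(foodweb(NULL, species = character(0))), "empty")
})

test_that("trophic position fractions ignore self-links", {
  expect_equal(trophic_fractions(w3_chain()),
               list(top = 1 / 3, intermediate = 1 / 3, basal = 1 / 3))
  # O's only predator link is its self-link, so O is a top species
  expect_equal(trophic_fractions(w4_web()),
               list(top = 1 / 3, intermediate = 1 / 3, basal = 1 / 3))
  star <- foodweb(data.frame(prey = c("P", "P"), predator = c("H1", "H2")))
  f <- trophic_fractions(star)
  expect_equal(f$basal, 1 / 3)
  expect_equal(f$top, 2 / 3)
  expect_equal(f$intermediate, 0)
})

test_that("guild fractions classify consumers by their prey", {
  g3 <- guild_fractions(w3_chain())
  expect_equal(g3, list(herbivore = 1 / 3, omnivore = 0, carnivore = 1 / 3,
                        cannibal = 0))
  g4 <- guild_fractions(w4_web())
  expect_equal(g4, list(herbivore = 1 / 3, omnivore = 1 / 3, carnivore = 0,
                        cannibal = 1 / 3))
})

test_that("trophic levels solve the prey-averaging system exactly", {
  t3 <- trophic_levels(w3_chain())
  expect_equal(unname(t3$tl[c("A", "B", "C")]), c(1, 2, 3))
  expect_equal(t3$mean, 2)
  t4 <- trophic_levels(w4_web())
  expect_equal(unname(t4$tl[c("P", "H", "O")]), c(1, 2, 2.5))
  expect_equal(t4$mean, 11 / 6)
  # a two-species consumer loop with no basal input has no solution
  loop <- foodweb(data.frame(prey = c("H1", "H2"), predator = c("H2", "H1")))
  expect_error(trophic_levels(loop), "basal")
})

test_that("shortest chains to basal species match hand traces", {
  c3 <- chain_lengths(w3_chain())
  expect_equal(unname(c3$chain[c("A", "B", "C")]), c(0, 1, 2))
  expect_equal(c3$mean, 1)
  c4 <- chain_lengths(w4_web())
  expect_equal(unname(c4$chain[c("P", "H", "O")]), c(0, 1, 1))
  expect_equal(c4$mean, 2 / 3)
  # all consumers on the single basal species: mean = (S-1)/S
  S <- 6
  ids <- c("B0", paste0("c", 1:(S - 1)))
  star <- foodweb(data.frame(prey = "B0", predator = ids[-1]))
  expect_equal(chain_lengths(star)$mean, (S - 1) / S)
})

test_that("trophic similarity matches shared-partner counting", {
  expect_equal(max_similarity(w3_chain())$mean, 0)
  # two consumers with identical prey and predator sets have s = 1
  w <- foodweb(data.frame(prey = c("P", "P", "C1", "C2"),
                          predator = c("C1", "C2", "T", "T")))
  ms <- max_similarity(w)
  expect_equal(unname(ms$pairwise["C1", "C2"]), 1)
  expect_gte(ms$mean, 2 / n_species(w))
  expect_error(max_similarity(foodweb(NULL, species = "A",
                                      allow_isolated = TRUE)),
               "2 species")
})

test_that("similarity is symmetric, bounded, and matches the oracle", {
  for (seed in 1:25) {
    w <- random_web(sample(3:8, 1), p = runif(1, 0.15, 0.45), seed = seed)
    ms <- max_similarity(w)
    expect_true(all(ms$pairwise[!is.na(ms$pairwise)] >= 0))
    expect_true(all(ms$pairwise[!is.na(ms$pairwise)] <= 1))
    expect_equal(ms$pairwise, t(ms$pairwise))
    expect_equal(ms$mean, bf_similarity_mean(w))
  }
})

test_that("graph metrics match hand values and brute-force enumeration", {
  g3 <- graph_metrics(w3_chain())
  expect_equal(g3$clustering, 0)
  expect_equal(g3$path_length, 4 / 3)
  expect_equal(g3$compartmentalization, 1 / 3)
  tri <- foodweb(data.frame(prey = c("a", "b", "c"),
                            predator = c("b", "c", "a")))
  gt <- graph_metrics(tri)
  expect_equal(gt$clustering, 1)
  expect_equal(gt$path_length, 1)
  for (seed in 1:25) {
    w <- random_web(sample(3:8, 1), p = runif(1, 0.15, 0.45), seed = seed + 50)
    gm <- graph_metrics(w)
    expect_equal(gm$clustering, bf_clustering(w))
    expect_equal(gm$path_length, bf_path_length(w))
    expect_equal(gm$compartmentalization, bf_compartmentalization(w))
  }
})

test_that("compute_all agrees with the component metrics and is label-invariant", {
  w <- w4_web()
  m <- compute_all(w)
  expect_named(m, metric_names())
  expect_equal(unname(m["connectance"]), degree_stats(w)$connectance)
  expect_equal(unname(m["trophic_level"]), trophic_levels(w)$mean)
  expect_equal(unname(m["compartmentalization"]),
               graph_metrics(w)$compartmentalization)

  # relabelling species must not change any metric
  for (seed in 1:5) {
    w <- niche_model_web(12, 0.2, seed)
    m1 <- compute_all(w)
    set.seed(seed)
    perm <- sample(n_species(w))
    relab <- setNames(sprintf("q%02d", seq_along(perm)), species_ids(w)[perm])
    w2 <- w
    w2$species$id <- unname(relab[w$species$id])
    w2$links$prey <- unname(relab[w$links$prey])
    w2$links$predator <- unname(relab[w$links$predator])
    expect_equal(compute_all(w2), m1, tolerance = 1e-12)
  }
})

test_that("foundation importance compares against the other species", {
  # foundation F has 1 predator while the other four species are preyed
  # upon (2, 2, 1, 0) times -> mean 1.25, ratio 0.8
  w <- foodweb(data.frame(prey = c("F", "B", "B", "H1", "H2", "H1"),
                          predator = c("H1", "H1", "H2", "T", "T", "H2")),
               species = data.frame(id = c("F", "B", "H1", "H2", "T"),
                                    is_foundation = c(TRUE, FALSE, FALSE,
                                                      FALSE, FALSE)))
  fi <- foundation_importance(w)
  expect_equal(fi$fs_vulnerability, 1)
  expect_equal(fi$fs_links, 1)
  expect_equal(fi$fs_basal_links, 1)
  expect_equal(fi$other_basal_mean_links, 2)
  expect_equal(fi$fs_vulnerability / fi$other_mean_vulnerability, 1 / 1.25)

  lone <- foodweb(data.frame(prey = "F", predator = "F"),
                  species = data.frame(id = "F", is_foundation = TRUE))
  expect_error(foundation_importance(lone), "other species")
  expect_error(foundation_importance(w3_chain()), "foundation")
})

test_that("synthetic foundation species are weakly linked", {
  n_weak <- 0
  for (i in 1:60) {
    w <- foundweb:::add_foundation(niche_model_web(20, 0.15, 7000 + i),
                                   8000 + i)
    fi <- foundation_importance(w)
    if (fi$fs_links < fi$other_mean_links) n_weak <- n_weak + 1
  }
  expect_gte(n_weak / 60, 0.95)
})
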