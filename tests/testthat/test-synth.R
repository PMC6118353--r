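test_that("synth_config validates its inputs", {
  expect_error(synth_config(connectance = 0.6), "connectance")
  expect_error(synth_config(S_ba = 30), "S_ba")
  expect_error(synth_config(reps = c(3, 4)), "length")
  expect_error(synth_config(facilitation_weights = c(basal = -1)),
               "positive")
  cfg <- synth_config(facilitation_mode = "targeted")
  expect_equal(unname(cfg$facilitation_weights["basal"]), 0.5)
  expect_equal(unname(cfg$facilitation_weights["carnivore"]), 2)
})

test_that("niche-model webs are reproducible, connected and calibrated", {
  a <- niche_model_web(20, 0.15, 3)
  b <- niche_model_web(20, 0.15, 3)
  expect_identical(adjacency_matrix(a), adjacency_matrix(b))
  expect_false(identical(adjacency_matrix(a),
                         adjacency_matrix(niche_model_web(20, 0.15, 4))))
  cs <- numeric(60)
  for (i in seq_along(cs)) {
    w <- niche_model_web(25, 0.15, 400 + i)
    expect_gte(length(foundweb:::basal_ids(w)), 1)
    expect_length(foundweb:::isolated_ids(w), 0)
    expect_true(all(is.finite(foundweb:::chain_length_values(w))))
    cs[i] <- n_links(w) / n_species(w)^2
  }
  expect_equal(mean(cs), 0.15, tolerance = 0.02)
  expect_error(niche_model_web(2, 0.15, 1), "S >= 3")
})

test_that("ecosystem pairs nest bare webs inside their FS webs", {
  cfg <- synth_config()
  part <- make_ecosystem_pair(cfg, "ecoX", n_reps = 3, seed = 21)
  expect_length(part$fs, 3)
  expect_length(part$ba, 3)
  for (k in 1:3) {
    fs <- part$fs[[k]]
    ba <- part$ba[[k]]
    expect_equal(sum(fs$species$is_foundation), 1L)
    expect_equal(sum(ba$species$is_foundation), 0L)
    fs_id <- species_ids(fs)[fs$species$is_foundation]
    # bare webs are induced subwebs of the paired FS web, foundation absent
    expect_true(all(species_ids(ba) %in% setdiff(species_ids(fs), fs_id)))
    expect_equal(adjacency_matrix(ba),
                 adjacency_matrix(induced_subweb(fs, species_ids(ba))))
    expect_lt(n_species(ba), n_species(fs))
    # counts and isotopes attached everywhere
    expect_false(anyNA(fs$species$count))
    expect_true(all(lengths(ba$species$d13C) == cfg$n_samples))
  }
})

test_that("isotope simulation honours the mixing identity", {
  cfg <- synth_config(noise_sd = 0)
  w <- foodweb(data.frame(prey = "P", predator = "H"))
  sim <- simulate_isotopes(w, cfg, 5)
  p13 <- mean(sim$web$species$d13C[[match("P", species_ids(sim$web))]])
  h13 <- mean(sim$web$species$d13C[[match("H", species_ids(sim$web))]])
  p15 <- mean(sim$web$species$d15N[[match("P", species_ids(sim$web))]])
  h15 <- mean(sim$web$species$d15N[[match("H", species_ids(sim$web))]])
  # zero noise, single prey: consumer = prey + enrichment exactly
  expect_equal(h13, p13 + cfg$tef$delta_d13C)
  expect_equal(h15, p15 + cfg$tef$delta_d15N)

  # d15N climbs with trophic level at the configured enrichment per step
  cfg2 <- synth_config(noise_sd = 0.2)
  slopes <- sapply(1:10, function(i) {
    w <- niche_model_web(20, 0.15, 600 + i)
    sim <- simulate_isotopes(w, cfg2, 700 + i)
    tl <- trophic_levels(w)$tl
    n15 <- vapply(sim$web$species$d15N, mean, numeric(1))
    coef(lm(n15 ~ tl[species_ids(w)]))[2]
  })
  expect_equal(mean(slopes), cfg2$tef$delta_d15N, tolerance = 0.35)

  # true diets are simplex-distributed over each consumer's prey
  w <- niche_model_web(15, 0.2, 8)
  sim <- simulate_isotopes(w, synth_config(), 9)
  prey <- foundweb:::prey_sets(w, drop_self = TRUE)
  for (cons in names(sim$true_diets)) {
    p <- sim$true_diets[[cons]]
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
    expect_setequal(names(p), prey[[cons]])
  }
})

test_that("generate_study delivers the full design deterministically", {
  study <- generate_study(synth_config(), seed = 2)
  expect_equal(nrow(study$design), 58L)
  expect_equal(sum(study$design$web_type == "FS"), 29L)
  expect_equal(sum(study$design$web_type == "BA"), 29L)
  expect_equal(length(unique(study$design$ecosystem)), 7L)
  study2 <- generate_study(synth_config(), seed = 2)
  expect_identical(lapply(study2$webs, adjacency_matrix),
                   lapply(study$webs, adjacency_matrix))
  expect_identical(study2$true_diets, study$true_diets)

  sizes <- sapply(study$webs[study$design$label[study$design$web_type == "FS"]],
                  n_species)
  expect_equal(mean(sizes), 25, tolerance = 2.5)
})

test_that("random-mode subsampling does not bias the basal fraction", {
  # bare webs never hold the (basal) foundation species, so the unbiased
  # reference is uniform pruning of the foundation-free web to the same
  # size
  cfg <- synth_config()
  diffs <- numeric(40)
  for (i in seq_along(diffs)) {
    w <- foundweb:::add_foundation(niche_model_web(25, 0.15, 1200 + i),
                                   1300 + i)
    ba <- foundweb:::sample_bare_web(w, 12, cfg$facilitation_weights,
                                     1400 + i)
    nofs <- induced_subweb(w, species_ids(w)[!w$species$is_foundation])
    repeat {
      iso <- foundweb:::isolated_ids(nofs)
      if (length(iso) == 0) break
      nofs <- induced_subweb(nofs, setdiff(species_ids(nofs), iso))
    }
    rr <- random_removal(nofs, structure(list(lo = n_species(ba) - 0.4,
                                              hi = n_species(ba) + 0.4,
                                              mean = n_species(ba), se = 0,
                                              n_bare = 3, ecosystem = "e"),
                                         class = "target_interval"),
                         seed = 1500 + i)
    diffs[i] <- trophic_fractions(ba)$basal - trophic_fractions(rr$web)$basal
  }
  expect_lt(abs(mean(diffs)), 0.03)
})
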