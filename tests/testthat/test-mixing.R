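two_sources <- function() {
  data.frame(id = c("s1", "s2"), mean_d13C = c(-30, -20), sd_d13C = c(0.5, 0.5),
             mean_d15N = c(0, 10), sd_d15N = c(0.5, 0.5))
}
no_tef <- function() trophic_enrichment(0, 0, 0, 0)

test_that("mixing model input contracts are enforced", {
  src <- two_sources()
  cs <- data.frame(d13C = -25, d15N = 5)
  expect_error(fit_mixing_model(cs, src[1, ], no_tef()), "2 sources")
  expect_error(fit_mixing_model(data.frame(d13C = NA_real_, d15N = 5),
                                src, no_tef()), "non-finite")
  expect_error(fit_mixing_model(cs, src, no_tef(), n_iter = 10), "1000")
  expect_error(trophic_enrichment(1, -0.5), ">= 0")
})

test_that("a consumer midway between two sources gets a symmetric diet", {
  cs <- data.frame(d13C = rep(-25, 10), d15N = rep(5, 10))
  post <- fit_mixing_model(cs, two_sources(), no_tef(), n_iter = 8000,
                           seed = 11)
  expect_equal(post$summary$mean, c(0.5, 0.5), tolerance = 0.05)
  expect_equal(sum(post$summary$mean), 1, tolerance = 1e-9)
})

test_that("a consumer sitting on one source is assigned that source", {
  cs <- data.frame(d13C = rep(-30, 10), d15N = rep(0, 10))
  post <- fit_mixing_model(cs, two_sources(), no_tef(), n_iter = 8000,
                           seed = 12)
  expect_gte(post$summary$mean[post$summary$source == "s1"], 0.85)
})

test_that("posterior draws live on the simplex and fits are deterministic", {
  cs <- data.frame(d13C = c(-26, -24.5, -25.2), d15N = c(4.8, 5.6, 5.1))
  a <- fit_mixing_model(cs, two_sources(), no_tef(), n_iter = 5000, seed = 7)
  b <- fit_mixing_model(cs, two_sources(), no_tef(), n_iter = 5000, seed = 7)
  expect_identical(a$summary, b$summary)
  expect_true(all(a$draws >= 0 & a$draws <= 1))
  expect_equal(unname(rowSums(a$draws)), rep(1, nrow(a$draws)),
               tolerance = 1e-12)
  c2 <- fit_mixing_model(cs, two_sources(), no_tef(), n_iter = 5000, seed = 8)
  expect_false(identical(a$draws, c2$draws))
})

test_that("known diet proportions are recovered from simulated consumers", {
  set.seed(42)
  src <- data.frame(id = c("a", "b", "c"),
                    mean_d13C = c(-30, -22, -14), sd_d13C = rep(0.5, 3),
                    mean_d15N = c(0, 6, 2), sd_d15N = rep(0.5, 3))
  maes <- replicate(10, {
    p <- rgamma(3, 1)
    p <- p / sum(p)
    cs <- data.frame(d13C = sum(p * src$mean_d13C) + rnorm(8, 0, 0.4),
                     d15N = sum(p * src$mean_d15N) + rnorm(8, 0, 0.4))
    post <- fit_mixing_model(cs, src, no_tef(), n_iter = 10000,
                             seed = sample.int(1e6, 1))
    mean(abs(post$summary$mean - p))
  })
  expect_lt(mean(maes), 0.1)
})

test_that("diet_filter removes links strictly below the threshold", {
  w <- foodweb(data.frame(prey = c("s1", "s2"), predator = c("c", "c")),
               species = c("s1", "s2", "c"))
  fake_post <- function(means) {
    structure(list(consumer = "c",
                   summary = data.frame(source = names(means),
                                        mean = unname(means),
                                        sd = 0, ci_low = 0, ci_high = 1)),
              class = "diet_posterior")
  }
  out <- diet_filter(w, list(c = fake_post(c(s1 = 0.97, s2 = 0.03))))
  expect_equal(nrow(out$links), 1L)
  expect_equal(out$links$prey, "s1")
  expect_equal(n_species(out), 3L)           # species never removed
  expect_equal(n_links(w), 2L)               # input untouched

  # threshold 0 removes nothing
  same <- diet_filter(w, list(c = fake_post(c(s1 = 0.97, s2 = 0.03))),
                      threshold = 0)
  expect_equal(n_links(same), 2L)

  # boundary: exactly 5% is kept ("less than" is strict)
  w3 <- foodweb(data.frame(prey = c("s1", "s2", "s3"),
                           predator = c("c", "c", "c")),
                species = c("s1", "s2", "s3", "c"))
  kept <- diet_filter(w3, list(c = fake_post(c(s1 = 0.5, s2 = 0.45,
                                               s3 = 0.05))))
  expect_equal(n_links(kept), 3L)

  # single-prey consumers are never filtered
  w1 <- foodweb(data.frame(prey = "s1", predator = "c"),
                species = c("s1", "c"))
  expect_equal(n_links(diet_filter(w1, list())), 1L)

  # posterior must cover exactly the prey set
  expect_error(diet_filter(w, list(c = fake_post(c(s1 = 0.9, zz = 0.1)))),
               "consumer c")
  expect_error(diet_filter(w, list()), "consumer c")
})

test_that("fit_web_diets covers exactly the multi-prey consumers", {
  cfg <- synth_config()
  w <- niche_model_web(10, 0.2, 31)
  sim <- simulate_isotopes(w, cfg, 32)
  posts <- fit_web_diets(sim$web, cfg$tef, n_iter = 2000, seed = 5)
  prey <- foundweb:::prey_sets(sim$web, drop_self = TRUE)
  multi <- names(prey)[vapply(prey, length, integer(1)) >= 2]
  expect_setequal(names(posts), multi)
  for (cid in names(posts)) {
    expect_setequal(posts[[cid]]$summary$source, prey[[cid]])
    expect_equal(sum(posts[[cid]]$summary$mean), 1, tolerance = 1e-9)
  }
})
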