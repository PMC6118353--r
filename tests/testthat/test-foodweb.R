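test_that("construction validates structure", {
  w <- w3_chain()
  expect_s3_class(w, "foodweb")
  expect_equal(n_species(w), 3L)
  expect_equal(n_links(w), 2L)

  # links must reference listed species
  expect_error(
    foodweb(data.frame(prey = "A", predator = "X"), species = c("A", "B")),
    "unknown species")
  # duplicate links rejected
  expect_error(
    foodweb(data.frame(prey = c("A", "A"), predator = c("B", "B"))),
    "duplicate link")
  # at most one foundation species
  expect_error(
    foodweb(data.frame(prey = "A", predator = "B"),
            species = data.frame(id = c("A", "B"),
                                 is_foundation = c(TRUE, TRUE))),
    "foundation")
  # isolated species rejected unless allowed
  sp <- c("A", "B", "C")
  lk <- data.frame(prey = "A", predator = "B")
  expect_error(foodweb(lk, species = sp), "isolated")
  expect_equal(n_species(foodweb(lk, species = sp, allow_isolated = TRUE)), 3L)
  # negative counts rejected
  expect_error(
    foodweb(lk, species = data.frame(id = c("A", "B"), count = c(-1, 2))),
    "negative count")
})

test_that("edge-list and adjacency files load to the same web and round-trip", {
  w <- w3_chain()
  el <- withr::local_tempfile(fileext = ".csv")
  ad <- withr::local_tempfile(fileext = ".csv")
  save_web(w, el, format = "edge_list")
  save_web(w, ad, format = "adjacency")
  w_el <- load_web(el, format = "edge_list")
  w_ad <- load_web(ad, format = "adjacency")
  expect_equal(adjacency_matrix(w_el), adjacency_matrix(w_ad))
  expect_equal(sort(species_ids(w_el)), sort(species_ids(w_ad)))

  # round-trip identity on random webs, both formats, self-links included
  for (seed in 1:5) {
    w <- random_web(8, p = 0.35, seed = seed)
    sp <- withr::local_tempfile(fileext = ".csv")
    save_web(w, el, format = "edge_list", species_path = sp)
    back <- load_web(el, format = "edge_list", species_path = sp,
                     allow_isolated = TRUE)
    expect_equal(adjacency_matrix(back), adjacency_matrix(w))
    save_web(w, ad, format = "adjacency")
    back2 <- load_web(ad, format = "adjacency", allow_isolated = TRUE)
    expect_equal(adjacency_matrix(back2), adjacency_matrix(w))
  }
})

test_that("species table round-trips counts, flags and isotope samples", {
  sp <- data.frame(id = c("A", "B"), name = c("alga", "bug"),
                   count = c(5L, 12L), is_foundation = c(TRUE, FALSE))
  w <- foodweb(data.frame(prey = "A", predator = "B"), species = sp)
  w$species$d13C <- list(c(-21.5, -20.75), numeric(0))
  w$species$d15N <- list(c(4, 5), 8.25)
  f <- withr::local_tempfile(fileext = ".csv")
  save_species(w$species, f)
  back <- load_species(f)
  expect_equal(back$count, c(5L, 12L))
  expect_equal(back$is_foundation, c(TRUE, FALSE))
  expect_equal(back$d13C[[1]], c(-21.5, -20.75))
  expect_equal(back$d13C[[2]], numeric(0))
  expect_equal(back$d15N[[2]], 8.25)
})

test_that("missing species in the species table is a load error", {
  el <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("prey,predator", "A,B", "B,X"), el)
  sp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,name,count,is_foundation,d13C,d15N",
               "A,a,5,FALSE,,", "B,b,5,FALSE,,"), sp)
  expect_error(load_web(el, species_path = sp), "unknown species")
})

test_that("induced_subweb keeps exactly the induced links", {
  w <- w3_chain()
  s1 <- induced_subweb(w, c("A", "B"))
  expect_equal(n_links(s1), 1L)
  expect_equal(s1$links$prey, "A")
  # keep all -> identity
  expect_equal(adjacency_matrix(induced_subweb(w, c("A", "B", "C"))),
               adjacency_matrix(w))
  # endpoints dropped -> isolated survivors, zero links
  s2 <- induced_subweb(w, c("A", "C"))
  expect_equal(n_links(s2), 0L)
  expect_equal(n_species(s2), 2L)
  expect_error(induced_subweb(w, c("A", "Z")), "unknown species")
})

test_that("induced_subweb is idempotent and composes by intersection", {
  for (seed in 1:10) {
    w <- random_web(10, p = 0.3, seed = seed)
    set.seed(seed + 100)
    k1 <- sample(species_ids(w), 7)
    k2 <- sample(species_ids(w), 7)
    a <- induced_subweb(induced_subweb(w, k1), intersect(k1, k2))
    b <- induced_subweb(w, intersect(k1, k2))
    expect_equal(adjacency_matrix(a), adjacency_matrix(b))
    expect_equal(adjacency_matrix(induced_subweb(w, k1)),
                 adjacency_matrix(induced_subweb(induced_subweb(w, k1), k1)))
  }
})
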