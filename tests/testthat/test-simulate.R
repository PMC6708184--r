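test_that("zero mutation rate gives an empty population; seeds reproduce", {
  ly <- build_layout(1, 4, 4)
  tg <- reference_targets(c(g1 = strrep("ACGT", 100)))
  pop0 <- simulate_population(sim_config(mutation_rate = 0, seed = 1), tg, ly)
  expect_equal(nrow(pop0$mutations), 0)

  sc <- sim_config(mutation_rate = 1e-3, seed = 42)
  p1 <- simulate_population(sc, tg, ly)
  p2 <- simulate_population(sc, tg, ly)
  expect_identical(p1$mutations, p2$mutations)
  c1 <- simulate_pool_counts(p1, ly, tg, sc)
  c2 <- simulate_pool_counts(p2, ly, tg, sc)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("mutation totals follow the Poisson load and refs match the genome", {
  set.seed(7)
  tg <- random_targets(c(a = 100000, b = 150000))
  ly <- build_layout(1, 4, 5)  # 20 plants
  sc <- sim_config(mutation_rate = 1 / 154000, seed = 11)
  pop <- simulate_population(sc, tg, ly)
  lambda <- 20 * 250000 / 154000
  expect_lt(abs(nrow(pop$mutations) - lambda), 4 * sqrt(lambda) + 1)
  # every recorded ref matches the reference base at its site
  m <- pop$mutations
  obs <- mapply(function(t, p) substr(tg[[t]], p, p), m$target, m$position)
  expect_equal(unname(obs), m$ref)
  expect_true(all(m$alt != m$ref))
  # no plant carries two alts at one site
  expect_false(anyDuplicated(m[c("plant_id", "target", "position")]) > 0)
})

test_that("class placement respects eligible bases and recovers the spectrum", {
  set.seed(3)
  tg <- random_targets(c(g = 200000))
  ly <- build_layout(1, 8, 8)
  sc <- sim_config(mutation_rate = 5e-4, seed = 5)
  pop <- simulate_population(sc, tg, ly)
  m <- pop$mutations
  expect_gt(nrow(m), 4000)
  st <- spectrum_table(m)
  n <- sum(st$count)
  for (i in seq_len(nrow(st))) {
    p <- EMS_SPECTRUM[[st$class[i]]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(st$fraction[i] - p), 3 * se + 1e-12)
  }
  # a GC>AT event sits on G or C only
  gc_at <- (m$ref == "G" & m$alt == "A") | (m$ref == "C" & m$alt == "T")
  expect_true(all(m$ref[gc_at] %in% c("G", "C")))
})

test_that("pooled counts conserve depth and match expected carrier fractions", {
  ly <- build_layout(1, 16, 16)
  tg <- reference_targets(c(g1 = strrep("G", 400)))
  # one het carrier and one hom carrier at distinct sites
  mut <- data.frame(
    plant_id = c("B1R1C1", "B1R8C8"), target = "g1",
    position = c(100L, 300L), ref = "G", alt = "A",
    zygosity = c("het", "hom"), stringsAsFactors = FALSE)
  pop <- make_population(mut, ly$plants$plant_id, tg)
  sc <- sim_config(depth = 40000, error_rate = 0, imbalance = 0, seed = 9)
  cnt <- simulate_pool_counts(pop, ly, tg, sc)
  expect_true(all(cnt$A + cnt$C + cnt$G + cnt$T == cnt$depth))

  # expected fractions 1/32 (het) and 1/16 (hom) within 3 binomial SE
  for (cs in list(list(pos = 100L, pools = c("B1_R01", "B1_C01"), f = 1 / 32),
                  list(pos = 300L, pools = c("B1_R08", "B1_C08"), f = 1 / 16))) {
    rows <- cnt[cnt$position == cs$pos & cnt$pool_id %in% cs$pools, ]
    frac <- rows$A / rows$depth
    se <- sqrt(cs$f * (1 - cs$f) / rows$depth)
    expect_true(all(abs(frac - cs$f) < 3 * se))
  }
  # no carrier, no error => zero alternate everywhere else
  other <- cnt[!(cnt$position == 100 & cnt$pool_id %in% c("B1_R01", "B1_C01")) &
                 !(cnt$position == 300 & cnt$pool_id %in% c("B1_R08", "B1_C08")), ]
  expect_true(all(other$A == 0 & other$C == 0 & other$T == 0))
  expect_equal(pooled_alt_fraction("het", 16), 1 / 32)
  expect_equal(pooled_alt_fraction("hom", 16), 1 / 16)
})

test_that("library failure injection degrades only the listed pools", {
  ly <- build_layout(1, 4, 4)
  tg <- reference_targets(c(g1 = strrep("ACGT", 100)))
  sc <- sim_config(mutation_rate = 1e-4, depth = 2000, seed = 21)
  pop <- simulate_population(sc, tg, ly)
  cnt <- simulate_pool_counts(pop, ly, tg, sc)

  expect_identical(inject_pool_failure(cnt, character(0), 100), cnt)
  expect_error(inject_pool_failure(cnt, "B9_R01", 100), "unknown pool")

  set.seed(2)
  failed <- inject_pool_failure(cnt, c("B1_R02", "B1_C03"), 500)
  tot <- tapply(failed$depth, failed$pool_id, sum)
  expect_true(all(tot[c("B1_R02", "B1_C03")] < 1000))
  expect_equal(flag_failed_pools(failed, 1000), c("B1_C03", "B1_R02"))
  untouched <- setdiff(names(tot), c("B1_R02", "B1_C03"))
  orig <- tapply(cnt$depth, cnt$pool_id, sum)
  expect_equal(tot[untouched], orig[untouched])

  zero <- inject_pool_failure(cnt, "B1_R01", 0)
  expect_true(all(zero$depth[zero$pool_id == "B1_R01"] == 0))
})

test_that("sibling cloning duplicates a mutation set verbatim", {
  ly <- build_layout(1, 4, 4)
  tg <- reference_targets(c(g1 = strrep("G", 500)))
  mut <- data.frame(plant_id = "B1R1C1", target = "g1", position = 42L,
                    ref = "G", alt = "A", zygosity = "het",
                    stringsAsFactors = FALSE)
  pop <- make_population(mut, ly$plants$plant_id, tg)
  pop2 <- clone_siblings(pop, "B1R1C1", c("B1R2C2", "B1R3C3"))
  m <- pop2$mutations
  expect_equal(nrow(m), 3)
  expect_setequal(m$plant_id, c("B1R1C1", "B1R2C2", "B1R3C3"))
  expect_true(all(m$position == 42L & m$alt == "A"))
  expect_error(clone_siblings(pop, "nope", "B1R2C2"), "unknown plant")
})

test_that("spectrum class instantiation yields strand-consistent base pairs", {
  set.seed(8)
  inst <- instantiate_spectrum(rep(SPECTRUM_CLASSES, each = 50))
  st <- spectrum_table(inst)
  expect_equal(st$count, rep(50L, 5))
  expect_error(instantiate_spectrum("GC>XX"), "unknown spectrum class")
})
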