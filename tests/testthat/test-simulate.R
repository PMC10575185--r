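# Simulation tests run on reduced problem sizes (small proteomes, few spots);
# the full-scale defaults are exercised by the acceptance suite.

test_that("the default proteome calibration puts ~80% of mass above 10 kDa", {
  cfg <- sim_config(seed = 5, n_proteins = 10000)
  p <- sample_proteome(cfg)
  expect_equal(nrow(p), 10000)
  frac <- mean(p$mass > 10000)
  expect_gt(frac, 0.78)
  expect_lt(frac, 0.85)
  # truncation bounds respected
  expect_true(all(p$mass >= 3000 & p$mass <= 200000))
  # deterministic per seed
  expect_identical(p, sample_proteome(cfg))
  expect_false(identical(p$mass, sample_proteome(cfg, seed = 6)$mass))
})

test_that("the default noise model encodes 80% replicate RSD", {
  nm <- noise_model()
  expect_equal(noise_rsd(nm), 0.80, tolerance = 1e-3)
  x <- sample_intensity_noise(10000, nm, seed = 3)
  expect_equal(sd(x) / mean(x), 0.80, tolerance = 0.05)
  expect_error(noise_model(intensity_sigma_log = -1), ">= 0")
})

test_that("noise-model jitter defaults respect the bin-width principle", {
  nm <- noise_model()
  expect_true(all(check_jitter(intact_scheme(), nm$jitter_intact)$ok))
  expect_true(all(check_jitter(digested_scheme(), nm$jitter_digested)$ok))
})

test_that("digestion is deterministic, bounded and mass-conserving", {
  model <- digestion_model()
  f1 <- digest_protein(10000, "P00007", model, base_seed = 1)
  # identical across calls (fragment identity is a property of the protein)
  expect_identical(f1, digest_protein(10000, "P00007", model, base_seed = 1))
  # and stable regardless of surrounding RNG state
  set.seed(999); runif(5)
  expect_identical(f1, digest_protein(10000, "P00007", model, base_seed = 1))
  # 10 kDa protein: a handful of fragments in the clip band
  expect_gte(length(f1), 4)
  expect_lte(length(f1), 20)
  expect_true(all(f1 >= 200 & f1 <= 3000))
  expect_lte(sum(f1), 10000)

  # conservation and bounds over random proteins
  set.seed(17)
  for (mass in 10^runif(100, 3.5, 5.3)) {
    f <- digest_protein(mass, paste0("X", round(mass)), model, base_seed = 2)
    expect_lte(sum(f), mass)
    expect_true(all(f >= 200))
  }
  # different proteins digest differently
  expect_false(identical(digest_protein(10000, "A", model, 1),
                         digest_protein(10000, "B", model, 1)))
  expect_error(digest_protein(100, "tiny", model), "lighter")
})

test_that("class pairs respect preset constraints and disjointness", {
  cfg_easy <- sim_config(seed = 2, n_proteins = 400, preset = "easy")
  p <- sample_proteome(cfg_easy)
  pair <- make_class_pair(p, cfg_easy)
  expect_equal(nrow(pair$class_a), 50)
  expect_equal(nrow(pair$class_b), 50)
  expect_length(intersect(pair$class_a$id, pair$class_b$id), 0)
  expect_length(intersect(pair$shared$id,
                          c(pair$class_a$id, pair$class_b$id)), 0)
  expect_equal(nrow(pair$shared) + 100, 400)

  cfg_hard <- sim_config(seed = 2, n_proteins = 400, preset = "hard")
  ph <- make_class_pair(p, cfg_hard)
  markers <- rbind(ph$class_a, ph$class_b)
  expect_equal(nrow(markers), 10)
  expect_true(all(markers$mass > 20000))
  expect_true(all(markers$abundance < quantile(p$abundance, 0.25)))

  # infeasible constraint set errors
  expect_error(
    make_class_pair(sample_proteome(sim_config(seed = 1, n_proteins = 12)),
                    sim_config(seed = 1, n_proteins = 12, preset = "hard")),
    "not enough eligible")
})

test_that("rendered heights follow the attenuation power law exactly", {
  quiet <- noise_model(intensity_sigma_log = 0, jitter_intact = 0,
                       jitter_digested = 0, lod_intact = 0, lod_digested = 0)
  df <- data.frame(id = c("hi", "lo"), mass = c(10000, 1000),
                   abundance = c(2, 2))
  pair <- structure(list(shared = df, class_a = df[0, ], class_b = df[0, ],
                         preset = "easy"), class = "class_pair")
  cfg <- sim_config(seed = 1, noise = quiet)
  pl <- render_spot("a", "intact", pair, cfg, spot_seed = 1)
  h <- setNames(pl$peaks$intensity, round(pl$peaks$mz))
  # 10 kDa vs 1 kDa at equal abundance: two decades of signal lost
  expect_equal(unname(h["10000"] / h["1000"]), 1e-2, tolerance = 1e-10)

  # noise-free rendered peaks regress to exactly -slope_magnitude
  set.seed(8)
  df2 <- data.frame(id = sprintf("p%02d", 1:40),
                    mass = 10^runif(40, 3, 4.2),
                    abundance = 10^rnorm(40, 0, 0.5))
  pair2 <- structure(list(shared = df2, class_a = df2[0, ],
                          class_b = df2[0, ], preset = "easy"),
                     class = "class_pair")
  pl2 <- render_spot("a", "intact", pair2, cfg, spot_seed = 2)
  expect_equal(nrow(pl2$peaks), 40)
  y <- log10(pl2$peaks$intensity / df2$abundance[order(df2$mass)])
  slope <- coef(lm(y ~ log10(pl2$peaks$mz)))[2]
  expect_equal(unname(slope), -2, tolerance = 1e-12)

  # acquisition window filtering
  df3 <- data.frame(id = "big", mass = 30000, abundance = 5)
  pair3 <- structure(list(shared = df3, class_a = df3[0, ],
                          class_b = df3[0, ], preset = "easy"),
                     class = "class_pair")
  expect_equal(nrow(render_spot("a", "intact", pair3, cfg, 1)$peaks), 0)
})

test_that("replicate spots reproduce the 80% intensity RSD", {
  quiet_mz <- noise_model(jitter_intact = 0, lod_intact = 0)
  df <- data.frame(id = "p1", mass = 5000, abundance = 3)
  pair <- structure(list(shared = df, class_a = df[0, ], class_b = df[0, ],
                         preset = "easy"), class = "class_pair")
  cfg <- sim_config(seed = 1, noise = quiet_mz)
  h <- vapply(1:400, function(s)
    render_spot("a", "intact", pair, cfg, spot_seed = s)$peaks$intensity,
    numeric(1))
  expect_equal(sd(h) / mean(h), 0.80, tolerance = 0.15)
})

test_that("default intact spots keep at most ~10 peaks above 10 kDa", {
  cfg <- sim_config(seed = 3)
  pair <- make_class_pair(sample_proteome(cfg), cfg)
  high <- vapply(1:6, function(s) {
    pl <- render_spot("a", "intact", pair, cfg, spot_seed = s)
    sum(pl$peaks$mz > 10000)
  }, numeric(1))
  expect_true(all(high <= 10))
  expect_true(any(high >= 1))  # the high-mass region is sparse, not empty
})

test_that("datasets are pure functions of config and master seed", {
  cfg <- sim_config(seed = 9, n_proteins = 40, n_specific = 5,
                    spots_per_class = 2)
  d1 <- render_dataset(cfg)
  d2 <- render_dataset(cfg)
  expect_identical(d1$peaklists, d2$peaklists)
  expect_identical(d1$manifest, d2$manifest)
  expect_equal(length(d1$peaklists), 2 * 2 * 2 * 2)  # modes/roles/classes/i
  expect_false(identical(
    d1$peaklists, render_dataset(sim_config(seed = 10, n_proteins = 40,
                                            n_specific = 5,
                                            spots_per_class = 2))$peaklists))

  # on-disk generation is byte-identical across runs
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  m1 <- generate_dataset(cfg, dir1)
  m2 <- generate_dataset(cfg, dir2)
  expect_equal(nrow(m1), 16)
  expect_true(file.exists(file.path(dir1, "manifest.csv")))
  expect_true(file.exists(file.path(dir1, "sim_config.json")))
  for (f in basename(m1$file)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})

test_that("digestion separates classes that intact acquisition cannot", {
  # Operating regime: proteome small enough that the class-discriminating
  # fragments are mass-resolvable in the 0.5 Da digested bins. Here the
  # high-mass / low-abundance (hard) markers are invisible intact but their
  # tryptic fragments sort the classes; the unconstrained (easy) markers do
  # at least as well.
  run_one <- function(preset, seed, n_spec) {
    cfg <- sim_config(seed = seed, preset = preset, n_proteins = 60,
                      n_specific = n_spec, spots_per_class = 16)
    ds <- render_dataset(cfg)
    res <- suppressWarnings(suppressMessages(
      run_pipeline(ds, encoding = "binary", grid = "single", seed = 5)))
    vapply(res$trials, function(t) mean(t$J), numeric(1))
  }
  for (seed in 1:3) {
    easy <- run_one("easy", seed, n_spec = 10)
    hard <- run_one("hard", seed, n_spec = 3)
    # headline: digestion rescues the hard case from chance-level sorting
    expect_lt(hard[["intact"]], 0.3)
    expect_gt(hard[["digested"]], hard[["intact"]] + 0.5)
    expect_gt(easy[["digested"]], 0.8)
    # difficulty ordering within mode (intact Js are both chance-level
    # noise, so that comparison carries a noise tolerance)
    expect_gte(easy[["digested"]], hard[["digested"]] - 0.05)
    expect_gte(easy[["intact"]], hard[["intact"]] - 0.25)
  }
})
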