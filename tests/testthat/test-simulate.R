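test_that("explicit chronogram mode reproduces requested ages exactly", {
  ch <- simulate_chronogram(topology = "(A:10,B:10);")
  expect_equal(root_age(ch), 10)
  backbone <- papaver_chronogram()
  expect_equal(mrca_age(backbone, c("Pnu", "Pso")), 24.1)
  expect_equal(mrca_age(backbone, c("Pca", "Pso")), 16.8)
  expect_equal(mrca_age(backbone, c("Pbr", "Pso")), 9.7)
  expect_equal(mrca_age(backbone, c("Aquilegia", "Pso")), 110)
  expect_equal(mrca_age(backbone, c("Eschscholzia", "Pso")), 77)
})

test_that("non-ultrametric age specs are rejected naming the offender", {
  expect_error(simulate_chronogram(topology = "(A:10,B:7);"),
               "not ultrametric.*B")
})

test_that("birth-death mode is deterministic under a seed", {
  t1 <- simulate_chronogram(tips = 8, birth = 0.3, seed = 7)
  t2 <- simulate_chronogram(tips = 8, birth = 0.3, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_error(simulate_chronogram(tips = 8), "seed")
})

test_that("simulated chronograms are ultrametric by construction", {
  for (s in 1:5) {
    ch <- simulate_chronogram(tips = 10, birth = 0.4, death = 0.1, seed = s)
    ages <- node_ages(ch)[seq_len(ape::Ntip(ch))]
    expect_lt(max(abs(ages)), 1e-8)
  }
})

test_that("two-tip divergence matches the JC69 closed form", {
  # expected proportion of differing sites between two tips separated by
  # 2t: p = (3/4)(1 - exp(-8 r t / 3))
  r <- 1.396e-8
  t_my <- 10
  p_exp <- 0.75 * (1 - exp(-8 * r * t_my * 1e6 / 3))
  ch <- simulate_chronogram(topology = sprintf("(A:%g,B:%g);", t_my, t_my))
  set.seed(99)
  ps <- replicate(120, {
    aln <- simulate_alignment(ch, clock_model(rate = r, length = 500))
    mean(strsplit(aln[["A"]], "")[[1]] != strsplit(aln[["B"]], "")[[1]])
  })
  se <- sd(ps) / sqrt(length(ps))
  expect_lt(abs(mean(ps) - p_exp), 3 * se + 1e-12)
})

test_that("branch-wise JC distance matches 2rt within Monte Carlo error", {
  r <- 1e-8
  ch <- simulate_chronogram(topology = "(A:15,B:15);")
  set.seed(3)
  ds <- replicate(80, {
    aln <- simulate_alignment(ch, clock_model(rate = r, length = 800))
    jc69_distance(aln[["A"]], aln[["B"]])
  })
  expect_lt(abs(mean(ds) - 2 * r * 15e6), 3 * sd(ds) / sqrt(length(ds)))
})

test_that("fusion events concatenate modules in frame with the linker", {
  ch <- papaver_chronogram()
  b <- simulate_gene_family(ch, events = study_event_plan(linker_aa = 11),
                            clock = clock_model(rate = 3.4e-9), seed = 5)
  fused <- b$genes[b$genes$fused, ]
  expect_true(all(fused$linker_aa == 11))
  for (gid in fused$gene_id) {
    expect_equal(nchar(b$sequences[[gid]]), 900 + 33 + 600)
    expect_identical(b$module_bp[[gid]], c(900L, 600L))
  }
  # fusion carriers are clade 2 minus the configured losses
  expect_setequal(unique(fused$species), c("Pca", "Par", "Pbr", "Pso",
                                           "Pse"))
})

test_that("pairing places the gene pair at the configured distance", {
  ch <- papaver_chronogram()
  b <- simulate_gene_family(ch, clock = clock_model(rate = 3.4e-9),
                            seed = 2)
  lay <- b$layouts[b$layouts$contig == "ctg_Pnu", ]
  lay <- lay[order(lay$start), ]
  expect_equal(nrow(lay), 2)
  expect_equal(lay$start[2] - lay$end[1], 1000)
})

test_that("event times outside their branch interval are rejected", {
  ch <- papaver_chronogram()
  bad <- list(gf_event("pairing", c("Pnu", "Pso"), 20))  # inside Papaver crown
  expect_error(simulate_gene_family(ch, events = bad, seed = 1),
               "outside its branch")
  expect_error(gf_event("fusion", "Pca", 5, linker_aa = 0), "linker")
})

test_that("bundles regenerate byte-identically under one seed", {
  ch <- papaver_chronogram()
  b1 <- simulate_gene_family(ch, seed = 11,
                             clock = clock_model(rate = 3.4e-9))
  b2 <- simulate_gene_family(ch, seed = 11,
                             clock = clock_model(rate = 3.4e-9))
  expect_identical(b1$sequences, b2$sequences)
  expect_identical(b1$layouts, b2$layouts)
  d1 <- tempfile(); d2 <- tempfile()
  write_bundle(b1, d1); write_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("truth event history round-trips through JSON unchanged", {
  ch <- papaver_chronogram()
  b <- simulate_gene_family(ch, seed = 4,
                            clock = clock_model(rate = 3.4e-9))
  d <- tempfile()
  write_bundle(b, d)
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$events$kind, b$events$kind)
  expect_equal(truth$events$time_my, b$events$time_my)
  expect_equal(truth$genes$gene_id, b$genes$gene_id)
  expect_equal(truth$seed, b$seed)
})

test_that("dilution series: exact noiseless slope, determinism, guards", {
  conc <- 2^(0:9)
  noiseless <- simulate_dilution_series(conc, slope = 3.5)
  fit <- fit_lod(noiseless$calibration$conc, noiseless$calibration$response)
  expect_equal(fit$slope, 3.5, tolerance = 1e-12)
  expect_equal(fit$lod, 0, tolerance = 1e-9)
  a <- simulate_dilution_series(conc, slope = 2, noise_sd = 0.5, seed = 8)
  b <- simulate_dilution_series(conc, slope = 2, noise_sd = 0.5, seed = 8)
  expect_identical(a$calibration, b$calibration)
  expect_error(simulate_dilution_series(c(1, 2), slope = 1), "3")
})

test_that("samples at 50x LOD are called detected downstream", {
  conc <- 0.05 / 2^(0:19)
  sim <- simulate_dilution_series(conc, slope = 1000, noise_sd = 2,
                                  sample_multiples = c(hi = 50, lo = 2),
                                  seed = 21)
  fit <- fit_lod(sim$calibration$conc, sim$calibration$response)
  peaks <- data.frame(species = c("sp1", "sp1"),
                      compound = "thebaine",
                      area = sim$samples$response)
  m <- call_presence(peaks[1, ], list(thebaine = fit))
  expect_equal(unname(m["sp1", "thebaine"]), "detected")
  m2 <- call_presence(peaks[2, ], list(thebaine = fit))
  expect_equal(unname(m2["sp1", "thebaine"]), "ND")
})
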