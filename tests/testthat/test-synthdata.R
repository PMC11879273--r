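test_that("haplotype simulator is deterministic and matches closed-form truth", {
  cfg <- haplo_sim_config(L = 500L, lineage_sep = 20L,
                          pop_sizes = c(x = 6L, y = 6L), seed = 99)
  a <- simulate_haplotypes(cfg)
  b <- simulate_haplotypes(cfg)
  expect_identical(a$alignment$seqs, b$alignment$seqs)  # same seed, same bytes
  # two pure lineages, no private mutations: dA = 20/L exactly, Kst = 1
  r <- da_distance(a$alignment, "x", "y")
  expect_equal(r$da, 20 / 500, tolerance = 1e-12)
  k <- kst_test(a$alignment, "x", "y", n_perm = 50, seed = 1)
  expect_equal(k$kst, 1)
  # single lineage, no mutations: no diversity at all
  mono <- simulate_haplotypes(haplo_sim_config(
    L = 100L, lineage_sep = integer(), pop_sizes = c(z = 5L), seed = 3))
  st <- diversity_stats(mono$alignment)
  expect_equal(st$Hd, 0)
  expect_equal(st$pi_printed, 0)
  expect_equal(st$h, 1L)
})

test_that("private mutations give within-population K near 2 lambda", {
  lambda <- 3
  cfg <- haplo_sim_config(L = 5000L, lineage_sep = integer(),
                          pop_sizes = c(x = 40L), private_rate = lambda,
                          seed = 11)
  sim <- simulate_haplotypes(cfg)
  K <- nucleotide_diversity(sim$alignment)$K
  # each pair differs by the sum of two independent Poisson(lambda) counts
  expect_lt(abs(K - 2 * lambda), 3 * sqrt(2 * lambda / 40))
})

test_that("mutation placement beyond L is rejected", {
  expect_error(simulate_haplotypes(haplo_sim_config(
    L = 10L, lineage_sep = 50L, pop_sizes = c(x = 2L, y = 2L), seed = 1)),
    "exceeds")
})

test_that("landmark simulator is deterministic and honours its template", {
  cfg <- small_shape_sim(seed = 5)
  a <- simulate_landmarks(cfg)
  b <- simulate_landmarks(cfg)
  expect_identical(a$dataset$coords, b$dataset$coords)
  expect_equal(a$dataset$k, 11L)
  expect_error(shape_sim_config(noise_sd = 0, seed = 1), "noise_sd")
})

test_that("vanishing noise yields perfect group classification", {
  sim <- simulate_landmarks(small_shape_sim(
    seed = 61, group_sizes = c(A = 10L, B = 10L),
    group_offset_magnitude = 0.05, sex_vector_magnitude = 0,
    allometry_magnitude = 0, noise_sd = 1e-5))
  # no allometric signal simulated: classify the symmetric shapes directly
  sc <- symmetric_component(sim$dataset, sim$pairing)
  pc <- shape_pca(flatten_shapes(sc$shapes))
  cl <- jackknife_classify(pc$scores[, 1:5], sim$dataset$group)
  expect_equal(cl$overall, 1)
})

test_that("zero allometry is recovered as a near-zero slope", {
  sim <- simulate_landmarks(small_shape_sim(
    seed = 67, group_sizes = c(A = 15L), allometry_magnitude = 0,
    sex_vector_magnitude = 0, group_offset_magnitude = 0,
    noise_sd = 0.002))
  sc <- symmetric_component(sim$dataset, sim$pairing)
  fit <- allometry_residuals(sc$shapes, sc$cs)
  expect_lt(sqrt(sum(fit$slope^2)), 0.05)  # magnitude ~ noise, not signal
})

test_that("a sex vector built orthogonal to the group contrast is estimated near 90 degrees", {
  # explicit effect vectors: the sex vector is orthogonalized against the
  # group mean difference, so whitening by a near-isotropic within-group
  # covariance preserves the right angle
  tplp <- make_symmetric_template(6, 4)
  set.seed(70)
  tpl0 <- sweep(tplp$template, 2, colMeans(tplp$template))
  tpl0 <- tpl0 / sqrt(sum(tpl0^2))
  oA <- norppa:::random_symmetric_offset(tpl0, tplp$pairing, 0.04)
  oB <- norppa:::random_symmetric_offset(tpl0, tplp$pairing, 0.04)
  d <- oA - oB
  s <- norppa:::random_symmetric_offset(tpl0, tplp$pairing, 1)
  s <- s - sum(s * d) / sum(d * d) * d          # orthogonalize against d
  s <- s * (0.03 / sqrt(sum(s^2)))
  cfg <- shape_sim_config(template = tplp$template, pairing = tplp$pairing,
                          group_sizes = c(A = 30L, B = 30L),
                          group_offsets = list(A = oA, B = oB),
                          sex_vector = s, allometry_magnitude = 0,
                          prop_unknown = 0, prop_female = 0.5,
                          noise_sd = 0.003, seed = 71)
  sim <- simulate_landmarks(cfg)
  res <- morphometrics_analysis(sim$dataset, sim$pairing, n_pcs = 10)
  est <- res$angles$angle_deg[res$angles$pair == "A-B"]
  expect_lt(abs(est - 90), 15)
})
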