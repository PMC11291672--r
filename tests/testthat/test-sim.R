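test_that("initial pool construction is exact", {
  p <- ciona_panel()
  cfg <- sim_config(p, N = 100, p0 = 0.2, n_sample = 50, seed = 1)
  pool <- initialize_population(cfg)
  expect_equal(dim(pool), c(200, 10))
  expect_equal(sum(rowSums(pool) == 10), 40)  # 40 full-length alien tracts
  expect_equal(unname(colMeans(pool)), rep(0.2, 10))
  expect_error(initialize_population(sim_config(p, N = 100, p0 = 0, n_sample = 50)),
               "no introgressed haplotype")
})

test_that("the same seed reproduces a scenario exactly", {
  cfg <- small_config(seed = 9)
  s1 <- run_scenario(cfg)
  s2 <- run_scenario(cfg)
  expect_identical(s1, s2)
  f1 <- emit_fluorescence(s1)
  f2 <- emit_fluorescence(s2)
  expect_identical(f1, f2)
  s3 <- run_scenario(small_config(seed = 10))
  expect_false(identical(s1$cohorts, s3$cohorts))
})

test_that("haplotype count stays 2N and frequencies stay in [0, 1]", {
  cfg <- small_config(seed = 2)
  scen <- run_scenario(cfg)
  expect_true(all(scen$truth$freq >= 0 & scen$truth$freq <= 1))
  pool <- initialize_population(cfg)
  for (i in 1:3) {
    pool <- step_generation(pool, cfg)
    expect_equal(nrow(pool), 2 * cfg$N)
    expect_true(all(pool %in% c(0L, 1L)))
  }
})

test_that("neutral drift has zero mean change and p(1-p)/2N variance", {
  p <- ciona_panel()
  cfg <- sim_config(p, N = 50, s_core = 0, s_del = 0, m = 0,
                    rec_per_bp = 0, p0 = 0.3, n_sample = 20, seed = 123)
  set.seed(cfg$seed)
  pool0 <- matrix(0L, 100, 10, dimnames = list(NULL, cfg$markers))
  pool0[1:30, ] <- 1L
  delta <- replicate(2000, {
    colMeans(step_generation(pool0, cfg))[1] - 0.3
  })
  expect_lt(abs(mean(delta)), 0.005)           # se ~ 0.001
  v_expected <- 0.3 * 0.7 / (2 * 50)
  expect_gt(var(delta) / v_expected, 0.85)
  expect_lt(var(delta) / v_expected, 1.15)
})

test_that("directional selection drives the core up, m = 1 wipes aliens", {
  p <- ciona_panel()
  cfg <- sim_config(p, N = 200, s_core = 0.5, s_del = 0, m = 0,
                    rec_per_bp = 0, p0 = 0.2, burn_in = 10, gap = 0,
                    n_sample = 10, seed = 31)
  scen <- run_scenario(cfg)
  core_traj <- scen$truth$freq[, cfg$core_idx]
  expect_gt(core_traj[11], core_traj[1])
  cfg1 <- sim_config(p, N = 100, m = 1, n_sample = 50, seed = 5)
  pool <- initialize_population(cfg1)
  expect_equal(sum(step_generation(pool, cfg1)), 0)
})

test_that("without recombination core-shoulder association stays complete", {
  p <- ciona_panel()
  cfg <- sim_config(p, N = 150, s_core = 0.1, s_del = 0, m = 0.05,
                    rec_per_bp = 0, p0 = 0.3, burn_in = 8, gap = 0,
                    n_sample = 10, seed = 17)
  pool <- initialize_population(cfg)
  for (i in 1:8) pool <- step_generation(pool, cfg)
  # only the two parental haplotypes can exist: r2 = 1 while polymorphic
  f <- colMeans(pool)
  if (all(f > 0 & f < 1)) {
    r2 <- kaspop:::gametic_r2(pool)
    expect_equal(unname(r2[upper.tri(r2)]), rep(1, 45), tolerance = 1e-12)
  }
  expect_lte(length(unique(apply(pool, 1, paste, collapse = ""))), 2)
})

test_that("gap = 0 samples the same generation twice", {
  p <- ciona_panel()
  cfg <- sim_config(p, N = 80, n_sample = 80, burn_in = 4, gap = 0, seed = 3)
  scen <- run_scenario(cfg)
  # sampling the whole deme in both cohorts: identical allele counts
  expect_equal(colSums(scen$cohorts[["2012"]]),
               colSums(scen$cohorts[["2021"]]))
})

test_that("noiseless fluorescence gives exact VAFF values", {
  cfg <- small_config(noise_sd = 0, seed = 4)
  scen <- run_scenario(cfg)
  fl <- emit_fluorescence(scen)
  hi <- cfg$channel_high; lo <- cfg$channel_low
  smp <- fl[!fl$is_control & fl$assay_id == "SNP15", ]
  truth <- rbind(scen$cohorts[["2012"]], scen$cohorts[["2021"]])
  v <- compute_vaff(smp$f1, smp$f2)
  expect_equal(v[truth[, "SNP15"] == 2], rep(hi / (hi + lo),
               sum(truth[, "SNP15"] == 2)))
  expect_equal(v[truth[, "SNP15"] == 1], rep(0.5,
               sum(truth[, "SNP15"] == 1)))
  # multiplex of a pure native pools to the all-intestinalis corner
  mux <- fl[!fl$is_control & fl$assay_id == "multiplex", ]
  expect_equal(unique(compute_vaff(mux$f1, mux$f2)), lo / (hi + lo))
})
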