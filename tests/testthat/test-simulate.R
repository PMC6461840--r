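test_that("zero-noise chemistry equals the closed-form mean curves", {
  d <- sim_design(n_replicates = 2)
  p <- chem_params(noise_cv = 0)
  traj <- simulate_chemistry(d, p)
  mu <- chem_mean_curves(d$sampling_times, p)
  for (r in 1:2) {
    sub <- traj[traj$replicate == r, ]
    expect_equal(sub$glucose_C, mu$glucose_C)
    expect_equal(sub$ammonium_N, mu$ammonium_N)
    expect_equal(sub$total_N, mu$total_N)
    expect_equal(sub$biomass, mu$biomass)
  }
  expect_true(all(diff(mu$glucose_C) <= 0))
  expect_true(all(mu$glucose_C >= 0 & mu$ammonium_N >= 0 & mu$biomass >= 0))
})

test_that("ammonium depletion precedes glucose depletion by construction", {
  d <- sim_design(n_replicates = 2)
  traj <- simulate_chemistry(d, chem_params(noise_cv = 0))
  ph <- detect_phases(traj)
  expect_lt(ph$times[["t2"]], ph$times[["t3"]])
  # the generator refuses the reversed ordering outright
  expect_error(chem_params(ammonium_depletion = 500, glucose_depletion = 400),
               "ammonium must deplete before glucose")
})

test_that("replicate mean trajectories track the mean function within 3 SE", {
  n <- 1000
  d <- sim_design(n_replicates = n, seed = 101)
  p <- chem_params(noise_cv = 0.05)
  traj <- simulate_chemistry(d, p)
  mu <- chem_mean_curves(d$sampling_times, p)
  for (col in c("glucose_C", "ammonium_N", "biomass")) {
    obs <- tapply(traj[[col]], traj$time, mean)
    se <- 0.05 * mu[[col]] / sqrt(n)
    expect_true(all(abs(obs - mu[[col]]) <= 3 * se + 1e-9),
                info = col)
  }
})

test_that("count means follow the cumulative signed fold-change rule", {
  tpl <- data.frame(gene_id = c("flat", "up1"),
                    pattern = c("SSS", "USS"),
                    lfc_magnitude = c(3, 1),
                    base_mean = c(100, 100),
                    dispersion = 0.1,
                    category_path = "null")
  mu <- template_means(tpl)
  expect_equal(unname(mu["flat", ]), c(100, 100, 100, 100))
  expect_equal(unname(mu["up1", ]), c(100, 200, 200, 200))
  bad <- tpl
  bad$pattern[1] <- "US"
  expect_error(template_means(bad), "invalid template")
})

test_that("simulated counts match the NB moment formula", {
  n_rep <- 2500   # 4 time points x 2500 replicates = 1e4 draws per gene
  d <- sim_design(n_replicates = n_rep, seed = 5)
  tpl <- data.frame(gene_id = "g1", pattern = "SSS", lfc_magnitude = 0,
                    base_mean = 100, dispersion = 0.1, category_path = "null")
  sim <- simulate_counts(d, tpl, lib_size_range = c(1, 1), seed = 5)
  x <- as.numeric(sim$counts)
  expect_equal(length(x), 4 * n_rep)
  v_expected <- 100 + 0.1 * 100^2
  expect_lt(abs(stats::var(x) - v_expected) / v_expected, 0.10)
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
})

test_that("fixing the seed reproduces identical outputs", {
  d <- sim_design(seed = 3)
  expect_identical(simulate_chemistry(d), simulate_chemistry(d))
  tpl <- gene_templates(seed = 3)
  expect_identical(simulate_counts(d, tpl), simulate_counts(d, tpl))
  tr <- spectral_ground_truth()
  expect_identical(simulate_spectra(tr, seed = 3), simulate_spectra(tr, seed = 3))
  expect_identical(simulate_preedge(0.4, noise_sd = 1e-3, seed = 3),
                   simulate_preedge(0.4, noise_sd = 1e-3, seed = 3))
})

test_that("noiseless spectra equal the bilinear product exactly", {
  tr <- spectral_ground_truth(noise_sd = 0)
  sp <- simulate_spectra(tr, seed = 1)
  expect_equal(sp$intensities, tr$C_true %*% t(tr$S_true),
               ignore_attr = TRUE)
  # rank-1 structure: constant concentration makes all rows proportional
  tr1 <- tr
  tr1$S_true <- tr$S_true[, 1, drop = FALSE]
  tr1$C_true <- matrix(2, nrow(tr$C_true), 1)
  sp1 <- simulate_spectra(tr1, seed = 1)
  ratios <- sp1$intensities[2, ] / sp1$intensities[1, ]
  expect_true(all(abs(ratios[is.finite(ratios)] - 1) < 1e-12))
})

test_that("true factors explain at least 99% of a 1%-noise simulation", {
  tr <- spectral_ground_truth()
  tr$noise_sd <- 0.01 * max(tr$C_true %*% t(tr$S_true))
  sp <- simulate_spectra(tr, seed = 7)
  ev <- explained_variance(sp, tr$C_true, tr$S_true)
  expect_gte(ev, 99)
})

test_that("pre-edge generator has the analytic area-weighted centroid", {
  # oracle: numerical integration of the generated peak after removing the
  # known baseline
  num_centroid <- function(f) {
    s <- simulate_preedge(f, baseline_params = c(0.02, 0.001))
    base <- 0.02 + 0.001 * (s$energy - min(s$energy))
    net <- s$intensity - base
    sum(s$energy * net) / sum(net)
  }
  expect_equal(num_centroid(1), 7112.1, tolerance = 1e-6)
  expect_equal(num_centroid(0), 7113.5, tolerance = 1e-6)
  expect_equal(num_centroid(0.5), 7112.8, tolerance = 1e-6)
})

test_that("generator input validation rejects malformed designs", {
  expect_error(sim_design(sampling_times = c(100, 50)), "strictly increasing")
  expect_error(sim_design(n_replicates = 1), "n_replicates")
  expect_error(gene_templates(patterns = c("UXS")), "invalid template")
  expect_error(simulate_preedge(1.2), "must be in")
  expect_error(simulate_preedge(0.5, noise_sd = -1), "noise_sd")
  tr <- spectral_ground_truth()
  tr$noise_sd <- -1
  expect_error(simulate_spectra(tr), "noise_sd")
})
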