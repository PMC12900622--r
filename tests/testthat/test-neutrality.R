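test_that("Tajima's D is exactly zero when k_bar equals S/a1", {
  # n = 4: a1 = 11/6.  8 singleton columns contribute 3 pairwise diffs each,
  # 3 informative (2+2) columns contribute 4 each: k_bar = 36/6 = 6 = S/a1.
  cols <- c(rep(list(c("T", "A", "A", "A")), 8),
            rep(list(c("T", "T", "A", "A")), 3))
  m <- do.call(cbind, cols)
  seqs <- apply(m, 1, paste0, collapse = "")
  faln <- make_faln(seqs, rep("p", 4))
  expect_equal(classify_sites(faln)$S, 11L)
  expect_equal(tajimas_d(faln), 0, tolerance = 1e-12)
})

test_that("Tajima's D agrees with an independently coded constants oracle", {
  faln <- make_faln(c("AAAA", "AAAT", "ATAA", "AAAA"), rep("p", 4))
  S <- classify_sites(faln)$S
  expect_equal(S, 2L)
  k_bar <- mean_pairwise_differences(faln)
  expect_equal(tajimas_d(faln), oracle_tajima(4, S, k_bar), tolerance = 1e-12)
  # larger random cases
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(5:12, 1)
    seqs <- apply(matrix(sample(c("A", "G"), n * 30, replace = TRUE), n),
                  1, paste0, collapse = "")
    faln <- make_faln(seqs, rep("p", n))
    S <- classify_sites(faln)$S
    if (S == 0) next
    k_bar <- mean_pairwise_differences(faln)
    expect_equal(tajimas_d(faln), oracle_tajima(n, S, k_bar),
                 tolerance = 1e-12)
  }
  expect_error(tajimas_d(make_faln(rep("AAAA", 5), rep("p", 5))), "S = 0")
})

test_that("D is invariant under column permutation and relabeling, monotone in k_bar", {
  set.seed(17)
  seqs <- apply(matrix(sample(c("A", "C"), 6 * 20, replace = TRUE), 6),
                1, paste0, collapse = "")
  faln <- make_faln(seqs, rep("p", 6))
  d0 <- tajimas_d(faln)
  perm <- sample(20)
  seqs_p <- vapply(strsplit(seqs, ""), function(x) paste0(x[perm], collapse = ""), "")
  expect_equal(tajimas_d(make_faln(seqs_p, rep("p", 6))), d0, tolerance = 1e-12)
  expect_equal(tajimas_d(make_faln(rev(seqs), rep("p", 6))), d0,
               tolerance = 1e-12)
  # holding n and S fixed, D increases with k_bar (numerator affine)
  ks <- seq(0.5, 5, by = 0.5)
  ds <- vapply(ks, function(k) mtphylogeo:::tajima_d_from_summary(8, 10, k), 0)
  expect_true(all(diff(ds) > 0))
})

test_that("log-space Stirling numbers match exact integers (n <= 20)", {
  for (n in c(2, 5, 8, 13, 20)) {
    exact <- oracle_stirling_table(n)[n, 1:n]
    lg <- mtphylogeo:::log_stirling_row(n)
    expect_equal(lg, log(exact), tolerance = 1e-10)
  }
})

test_that("Fu's Fs: closed form at n = 2 and exact Ewens enumeration for n <= 8", {
  hs2 <- collapse_haplotypes(make_faln(c("AAAA", "AAAT"), rep("p", 2)))
  expect_equal(fus_fs(hs2, 1), 0, tolerance = 1e-12)        # ln(theta) at theta = 1
  expect_equal(fus_fs(hs2, 2.5), log(2.5), tolerance = 1e-12)
  # brute-force Ewens for a spread of (n, Nh, theta)
  for (case in list(c(4, 2, 1.7), c(5, 4, 0.8), c(8, 3, 2.2), c(8, 8, 5),
                    c(6, 2, 0.3))) {
    n <- case[1]; Nh <- case[2]; theta <- case[3]
    expect_equal(mtphylogeo:::fs_from_summary(n, Nh, theta),
                 oracle_fs(n, Nh, theta), tolerance = 1e-10)
  }
  # boundary: single haplotype
  hs1 <- collapse_haplotypes(make_faln(rep("AAAA", 3), rep("p", 3)))
  expect_warning(v <- fus_fs(hs1, 0.5), "boundary")
  expect_identical(v, Inf)
  expect_error(fus_fs(hs2, 0), "k_bar = 0")
})

test_that("Fs at survey scale (n = 97) stays finite in log space", {
  f <- mtphylogeo:::fs_from_summary(97, 79, 12.6)
  expect_true(is.finite(f))
  f2 <- mtphylogeo:::fs_from_summary(97, 2, 12.6)
  expect_true(is.finite(f2))
})

test_that("neutrality p-values behave under null and expansion simulations", {
  # observed data from a constant-size simulation should not look significant
  sim <- sim_coalescent(demography_config(samples_per_deme = 15, theta = 4,
                                          L = 2000), seed = 31)
  faln <- filter_sites(sim$alignment)
  res <- neutrality_pvalues(faln, n_sims = 200, seed = 7)
  expect_true(res$p_D > 0 && res$p_D <= 1)
  expect_true(res$p_Fs > 0 && res$p_Fs <= 1)
  # strong sudden expansion pushes D and Fs down and p_D low
  # recent expansion in coalescent time: T_exp = tau/theta = 0.1, so nearly
  # all lineages survive to the expansion and the genealogy is star-like
  sim_e <- sim_coalescent(demography_config(samples_per_deme = 25, theta = 40,
                                            expansion = list(tau = 4, growth = 1000),
                                            L = 5000), seed = 33)
  faln_e <- filter_sites(sim_e$alignment)
  res_e <- neutrality_pvalues(faln_e, n_sims = 200, seed = 8)
  expect_lt(res_e$D, 0)
  expect_lt(res_e$Fs, 0)
  expect_lt(res_e$p_D, 0.1)
  # S = 0 input propagates NA
  res0 <- neutrality_pvalues(make_faln(rep("AAAA", 5), rep("p", 5)),
                             n_sims = 10, seed = 1)
  expect_true(is.na(res0$D) && is.na(res0$Fs))
})

test_that("Fu's Fs is predominantly negative under expansion, centered under equilibrium", {
  set.seed(41)
  fs_exp <- replicate(30, {
    st <- mtphylogeo:::sim_neutral_stats(20, 5, 1,
                                         expansion = list(tau = 4, growth = 500))
    if (st$Nh > 1 && st$k_bar > 0)
      mtphylogeo:::fs_from_summary(20, st$Nh, st$k_bar) else NA
  })
  expect_gt(mean(fs_exp < 0, na.rm = TRUE), 0.7)
  fs_null <- replicate(30, {
    st <- mtphylogeo:::sim_neutral_stats(20, 5, 1)
    if (st$Nh > 1 && st$k_bar > 0)
      mtphylogeo:::fs_from_summary(20, st$Nh, st$k_bar) else NA
  })
  expect_lt(abs(median(fs_null, na.rm = TRUE)), 1.5)
})
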