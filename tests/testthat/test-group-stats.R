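# build a tidy directional-CMC table for profile assembly fixtures
cmc_fixture <- function(values_by_trial, n_trials = length(values_by_trial)) {
  tidyr::expand_grid(trial = seq_len(n_trials),
                     eeg = c("FC1", "Cz", "C3"), emg = c("ExO", "ES")) |>
    dplyr::mutate(participant = "p1", group = "amputee", task = "EO",
                  band = "alpha",
                  afferent_cmc = values_by_trial[trial],
                  efferent_cmc = values_by_trial[trial] / 2)
}

test_that("profiles average retained trials and flag all-masked records", {
  tab <- cmc_fixture(rep(0.4, 7))
  prof <- assemble_profiles(tab)
  expect_equal(nrow(prof), 2)  # afferent + efferent
  aff <- prof[prof$direction == "afferent", ]
  expect_true(all(as.numeric(aff[grep("^cmc_", names(aff))]) == 0.4))

  tab2 <- cmc_fixture(c(0.1, 0.2, 0.3, 0.9, 0.9, 0.9, 0.9))
  mask <- dplyr::distinct(tab2, participant, task, trial, band, eeg, emg) |>
    dplyr::mutate(retained = trial <= 3)
  prof2 <- assemble_profiles(tab2, mask)
  aff2 <- prof2[prof2$direction == "afferent", ]
  expect_true(all(abs(as.numeric(aff2[grep("^cmc_", names(aff2))]) - 0.2) < 1e-12))

  mask_none <- dplyr::mutate(mask, retained = FALSE)
  prof3 <- assemble_profiles(tab2, mask_none)
  expect_equal(nrow(prof3), 0)  # nothing retained anywhere
})

test_that("altGower distance equals the mean absolute difference (brute force)", {
  x <- c(0.2, 0.4, 0.6, 0.3, 0.5, 0.7)
  m <- rbind(x, x + 0.1)
  expect_equal(as.numeric(alt_gower_distance(m)), 0.1)
  expect_equal(as.matrix(alt_gower_distance(rbind(x, x)))[1, 2], 0)

  set.seed(31)
  r <- matrix(runif(60, 0.05, 0.95), 10, 6)
  d <- as.matrix(alt_gower_distance(r))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(d[i, j], mean(abs(r[i, ] - r[j, ])))
  }
  expect_true(all(d >= 0))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

# random complete profile set: n participants per group, 3 tasks, 2 bands
null_profiles <- function(n_per_group = 5, seed = 1) {
  withr::with_seed(seed, {
    tidyr::expand_grid(group = c("amputee", "control"),
                       subject = seq_len(n_per_group),
                       task = c("DT", "EC", "EO"), band = c("alpha", "beta")) |>
      dplyr::mutate(participant = paste0(group, subject),
                    direction = "efferent", missing = FALSE) |>
      dplyr::bind_cols(stats::setNames(
        as.data.frame(matrix(runif(2 * n_per_group * 6 * 6, 0.2, 0.8),
                             ncol = 6)),
        paste0("cmc_", 1:6)))
  })
}

test_that("PERMANOVA output has the seven design terms and a bounded p", {
  pf <- null_profiles(seed = 4)
  fit <- cmc_permanova(pf, n_perm = 199, seed = 1)
  td <- tidy(fit)
  expect_identical(td$term[1:7],
                   c("band", "task", "group", "band:task", "band:group",
                     "task:group", "band:task:group"))
  pv <- td$p_value[1:7]
  expect_true(all(pv >= 1 / 200 & pv <= 1, na.rm = TRUE))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 60)
  expect_equal(gl$strata, "participant")
})

test_that("PERMANOVA is invariant to a common reordering of observations", {
  pf <- null_profiles(seed = 6)
  fit1 <- cmc_permanova(pf, n_perm = 99, seed = 3)
  perm <- withr::with_seed(9, sample(nrow(pf)))
  fit2 <- cmc_permanova(pf[perm, ], n_perm = 99, seed = 3)
  expect_equal(tidy(fit1)$pseudo_f, tidy(fit2)$pseudo_f, tolerance = 1e-10)
})

test_that("free-permutation group test matches exhaustive enumeration on n = 6", {
  set.seed(40)
  m <- matrix(runif(36, 0.2, 0.8), 6, 6)
  grp <- rep(c("a", "b"), each = 3)
  d2 <- as.matrix(alt_gower_distance(m))^2
  pseudo_f <- function(g) {
    n <- length(g)
    ss_tot <- sum(d2[upper.tri(d2)]) / n
    ss_w <- sum(vapply(unique(g), function(lv) {
      i <- which(g == lv)
      sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
    }, numeric(1)))
    ((ss_tot - ss_w) / 1) / (ss_w / (n - 2))
  }
  f_obs <- pseudo_f(grp)
  # exhaustive oracle over all 720 relabelings
  perm_rec <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i) cbind(v[i], perm_rec(v[-i]))))
  }
  all_f <- apply(perm_rec(1:6), 1, function(ix) pseudo_f(grp[ix]))
  p_exact <- mean(all_f >= f_obs - 1e-12)

  pf <- tibble::tibble(participant = paste0("s", 1:6), group = grp,
                       task = "EO", band = "alpha", direction = "efferent",
                       missing = FALSE) |>
    dplyr::bind_cols(stats::setNames(as.data.frame(m), paste0("cmc_", 1:6)))
  res <- pairwise_group_by_task(pf, n_perm = 9999, seed = 5)
  expect_equal(res$p_value, p_exact, tolerance = 0.02)
  expect_equal(res$pseudo_f, f_obs, tolerance = 1e-8)
})

test_that("widely separated groups reach the permutation floor", {
  base <- null_profiles(n_per_group = 5, seed = 8)
  vals <- grep("^cmc_", names(base))
  base[base$group == "amputee", vals] <- base[base$group == "amputee", vals] + 10
  res <- pairwise_group_by_task(base, n_perm = 199, seed = 2)
  expect_true(all(res$p_value == 1 / 200))
  one_group <- base[base$group == "amputee", ]
  expect_error(pairwise_group_by_task(one_group, n_perm = 99), "one group")
})

test_that("NMDS recovers a planar configuration and embeds equal distances", {
  set.seed(12)
  pts <- matrix(rnorm(24), 12, 2)
  fit <- cmc_nmds(dist(pts), k = 2, n_restarts = 10, seed = 3)
  expect_lt(fit$stress, 1e-4)
  pr <- vegan::procrustes(pts, fit$points, symmetric = TRUE)
  expect_lt(pr$ss, 1e-3)
  expect_equal(dim(tidy(fit)), c(12L, 2L))
  expect_s3_class(glance(fit), "tbl_df")

  tri <- cmc_nmds(stats::as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)),
                  k = 2, n_restarts = 5, seed = 1)
  expect_lt(tri$stress, 1e-6)
})
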