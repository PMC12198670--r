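#' Assemble six-dimensional CMC profiles
#'
#' Averages trial-level directional CMC values over the trials retained by
#' the significance mask, per participant x task x band x direction, across
#' the 3 EEG x 2 EMG electrode pairs that form one profile. Pairs with zero
#' retained trials yield `NA`; profiles containing any `NA` are flagged
#' `missing` (and dropped by the distance computation).
#'
#' @param cmc_table Tidy tibble with columns `participant`, `group`, `task`,
#'   `trial`, `band`, `eeg`, `emg`, `afferent_cmc`, `efferent_cmc`.
#' @param mask Optional [significance_mask()] tibble with columns
#'   `participant`, `task`, `trial`, `band`, `eeg`, `emg`, `retained`; when
#'   `NULL` all trials are retained.
#' @return Tibble of class `cmc_profiles`: one row per participant x task x
#'   band x direction with columns `cmc_<EEG>_<EMG>` (6 values) and
#'   `missing`.
#' @export
assemble_profiles <- function(cmc_table, mask = NULL) {
  tab <- cmc_table |>
    tidyr::pivot_longer(c("afferent_cmc", "efferent_cmc"),
                        names_to = "direction", values_to = "cmc") |>
    mutate(direction = sub("_cmc$", "", .data$direction))
  if (!is.null(mask)) {
    keys <- intersect(names(tab), intersect(names(mask),
              c("participant", "group", "task", "trial", "band", "eeg", "emg")))
    tab <- tab |>
      left_join(select(mask, all_of(c(keys, "retained"))), by = keys) |>
      filter(.data$retained)
  }
  prof <- tab |>
    group_by(.data$participant, .data$group, .data$task, .data$band,
             .data$direction, .data$eeg, .data$emg) |>
    summarise(cmc = mean(.data$cmc), n_trials = n(), .groups = "drop") |>
    mutate(pair = paste0("cmc_", .data$eeg, "_", .data$emg)) |>
    select(-"eeg", -"emg", -"n_trials") |>
    tidyr::pivot_wider(names_from = "pair", values_from = "cmc")
  value_cols <- grep("^cmc_", names(prof), value = TRUE)
  prof$missing <- apply(prof[value_cols], 1, anyNA)
  class(prof) <- c("cmc_profiles", class(prof))
  prof
}

profile_matrix <- function(profiles) {
  value_cols <- grep("^cmc_", names(profiles), value = TRUE)
  m <- as.matrix(profiles[value_cols])
  rownames(m) <- NULL
  m
}

#' altGower distance between CMC profiles
#'
#' The altGower dissimilarity of two profiles is the mean absolute difference
#' across their dimensions, without range normalization (for strictly
#' positive coherence values no double-zero correction applies).
#'
#' @param profiles A `cmc_profiles` tibble (complete cases only) or a numeric
#'   matrix of profile rows.
#' @return A `dist` object.
#' @export
alt_gower_distance <- function(profiles) {
  m <- if (is.matrix(profiles)) profiles else {
    if (any(profiles$missing)) {
      abort("profiles contain missing records; drop them before computing distances",
            class = "cmcwave_validation_error")
    }
    profile_matrix(profiles)
  }
  if (anyNA(m)) {
    abort("profile matrix contains NA", class = "cmcwave_validation_error")
  }
  vegan::vegdist(m, method = "altGower")
}

#' PERMANOVA on CMC profiles
#'
#' Distance-based multivariate ANOVA with sequential (type-I) sums of squares
#' in the order frequency band, task, group, then all interactions --
#' `band * task * group`. Permutations are restricted to exchanges within
#' participant (the repeated-measures unit) by default; note that under this
#' restriction the purely between-participant `group` main effect is not
#' testable (its permutation distribution is degenerate), while task, band
#' and all interactions involving them are. Set `strata = NULL` for free
#' permutation.
#'
#' @param profiles A `cmc_profiles` tibble, typically restricted to one
#'   direction and one muscle set; missing records are dropped.
#' @param n_perm Number of permutations (study default 5000).
#' @param seed Integer seed for the permutation generator.
#' @param strata `"participant"` (default) or `NULL`.
#' @return Object of class `cmc_permanova`; use [tidy()] for the term table.
#' @export
cmc_permanova <- function(profiles, n_perm = 5000, seed = 1,
                          strata = "participant") {
  dat <- dplyr::as_tibble(profiles) |> filter(!.data$missing)
  check_balance(dat)
  d <- alt_gower_distance(profile_matrix(dat))
  meta <- data.frame(band = factor(dat$band), task = factor(dat$task),
                     group = factor(dat$group),
                     participant = factor(dat$participant))
  res <- with_seed_if(seed, {
    if (!is.null(strata)) {
      vegan::adonis2(d ~ band * task * group, data = meta,
                     permutations = n_perm, by = "terms",
                     strata = meta$participant)
    } else {
      vegan::adonis2(d ~ band * task * group, data = meta,
                     permutations = n_perm, by = "terms")
    }
  })
  structure(list(aov_table = res, n_perm = n_perm, n_obs = nrow(dat),
                 strata = strata, seed = seed),
            class = "cmc_permanova")
}

# unbalanced/empty design cells are a modelling error, not a silent drop
check_balance <- function(dat) {
  if (nrow(dat) == 0) {
    abort("no complete profiles to analyse", class = "cmcwave_validation_error")
  }
  cells <- dat |>
    group_by(.data$group, .data$task, .data$band) |>
    summarise(n = n(), .groups = "drop")
  full <- length(unique(dat$group)) * length(unique(dat$task)) *
    length(unique(dat$band))
  if (nrow(cells) < full) {
    have <- paste(cells$group, cells$task, cells$band, sep = ":")
    abort(sprintf("design has empty cells (present: %s)", paste(have, collapse = ", ")),
          class = "cmcwave_validation_error")
  }
  invisible(TRUE)
}

#' @export
print.cmc_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA on CMC profiles (%d observations, %d permutations%s)\n",
              x$n_obs, x$n_perm,
              if (!is.null(x$strata)) ", strata: participant" else ""))
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the PERMANOVA term table
#'
#' @param x A `cmc_permanova` object.
#' @param ... Unused.
#' @return Tibble with `term`, `df`, `sum_sq`, `r_squared`, `pseudo_f`,
#'   `p_value`.
#' @export
tidy.cmc_permanova <- function(x, ...) {
  tab <- as.data.frame(x$aov_table)
  tibble(
    term = rownames(tab),
    df = tab$Df,
    sum_sq = tab$SumOfSqs,
    r_squared = tab$R2,
    pseudo_f = tab$F,
    p_value = tab$`Pr(>F)`
  )
}

#' @rdname tidy.cmc_permanova
#' @return For `glance()`: one-row tibble with `n_obs`, `n_perm`, `strata`.
#' @export
glance.cmc_permanova <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_perm = x$n_perm,
         strata = x$strata %||% NA_character_)
}

#' Task-wise group contrasts
#'
#' For each task level, subsets the profiles and tests the group effect with
#' a free-permutation PERMANOVA (`group` is purely between-participant, so a
#' within-participant restriction would be degenerate here). No multiplicity
#' adjustment is applied, matching common reporting of such contrasts.
#'
#' @param profiles A `cmc_profiles` tibble (one direction / muscle set).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Tibble with `task`, `df`, `pseudo_f`, `p_value`.
#' @export
pairwise_group_by_task <- function(profiles, n_perm = 5000, seed = 1) {
  dat <- dplyr::as_tibble(profiles) |> filter(!.data$missing)
  seeds <- derive_seeds(seed, length(unique(dat$task)))
  purrr::map2_dfr(sort(unique(dat$task)), seeds, function(tk, sd_i) {
    sub <- filter(dat, .data$task == tk)
    if (length(unique(sub$group)) < 2) {
      abort(sprintf("task '%s' has only one group level", tk),
            class = "cmcwave_validation_error")
    }
    d <- alt_gower_distance(profile_matrix(sub))
    meta <- data.frame(group = factor(sub$group))
    res <- with_seed_if(sd_i, {
      vegan::adonis2(d ~ group, data = meta, permutations = n_perm, by = "terms")
    })
    tab <- as.data.frame(res)
    tibble(task = tk, df = tab$Df[1], pseudo_f = tab$F[1],
           p_value = tab$`Pr(>F)`[1])
  })
}

#' Nonmetric multidimensional scaling of CMC profiles
#'
#' Kruskal stress-1 minimization with monotone regression, best of
#' `n_restarts` random starts.
#'
#' @param x A `cmc_profiles` tibble, a numeric matrix, or a `dist`.
#' @param k Embedding dimension.
#' @param n_restarts Random restarts.
#' @param seed Integer seed.
#' @return Object of class `cmc_nmds` with `points` (n x k), `stress`
#'   (fraction in `[0, 1]`) and `converged`.
#' @export
cmc_nmds <- function(x, k = 2, n_restarts = 20, seed = 1) {
  d <- if (inherits(x, "dist")) x else alt_gower_distance(x)
  fit <- with_seed_if(seed, {
    suppressWarnings(suppressMessages(
      vegan::metaMDS(d, k = k, trymax = n_restarts, trace = 0,
                     autotransform = FALSE, wascores = FALSE)
    ))
  })
  structure(list(points = fit$points, stress = fit$stress,
                 converged = isTRUE(fit$converged > 0) || isTRUE(fit$converged),
                 engine = fit),
            class = "cmc_nmds")
}

#' @export
print.cmc_nmds <- function(x, ...) {
  cat(sprintf("NMDS embedding: %d points in %d dimensions, stress %.4f%s\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (!x$converged) " (no convergent solution found)" else ""))
  invisible(x)
}

#' Tidy NMDS coordinates
#'
#' @param x A `cmc_nmds` object.
#' @param ... Unused.
#' @return Tibble with one row per point and columns `NMDS1`, `NMDS2`, ...
#' @export
tidy.cmc_nmds <- function(x, ...) {
  as_tibble(as.data.frame(x$points))
}

#' @rdname tidy.cmc_nmds
#' @return For `glance()`: one-row tibble with `stress` and `converged`.
#' @export
glance.cmc_nmds <- function(x, ...) {
  tibble(stress = x$stress, converged = x$converged)
}
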