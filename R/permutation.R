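# Fast shared kernel used by both the real analysis and the permutation
# null: correlation -> thresholded network -> stiffness scale, impact,
# stability from the two cohort mean-abundance vectors. Kept free of
# messaging so the permutation loop stays quiet; the user-facing operations
# in R/stiffness.R wrap the same arithmetic with flags and notes, and a test
# asserts their equivalence.
correlate_matrix <- function(x, cfg) {
  corr <- switch(cfg$estimator,
    spearman = suppressWarnings(cor(t(x), method = "spearman")),
    pearson  = suppressWarnings(cor(t(x), method = "pearson")),
    sparcc   = sparcc_correlations(x, pseudocount = cfg$pseudocount,
                                   iterations = cfg$sparcc_iterations)
  )
  corr[!is.finite(corr)] <- 0
  corr <- (corr + t(corr)) / 2
  corr[corr > 1] <- 1
  corr[corr < -1] <- -1
  diag(corr) <- 1
  corr
}

stiffness_stats <- function(x, a_idx, cfg, pseudocount = 1e-6) {
  corr <- correlate_matrix(x[, a_idx, drop = FALSE], cfg)
  A <- (abs(corr) >= cfg$min_abs_corr) * 1
  diag(A) <- 0
  W <- abs(corr) * A
  diag(W) <- 1
  x_a <- rowMeans(x[, a_idx, drop = FALSE])
  x_b <- rowMeans(x[, -a_idx, drop = FALSE])

  denom <- drop(W %*% x_a)
  s <- ifelse(abs(denom) < 1e-12, NA_real_, x_b / denom)

  r <- (x_b - x_a) / pmax(x_a, pseudocount)
  ok <- abs(r) > 1e-12
  G <- abs(outer(r, r, "/"))
  G[, !ok] <- NA_real_

  def_cols <- matrix(ok, nrow = length(r), ncol = length(r), byrow = TRUE)
  n_def_imp <- rowSums(A * t(def_cols))   # defined terms of sum_j A_ij G_ji
  imp_sum <- rowSums(A * t(G), na.rm = TRUE)
  impact <- ifelse(n_def_imp == 0, NA_real_, imp_sum)

  n_def_st <- rowSums(A * def_cols)
  st_sum <- rowSums(A * G, na.rm = TRUE)
  stability <- ifelse(n_def_st == 0 | st_sum == 0, NA_real_, 1 / st_sum)

  list(stiffness_scale = s, impact = impact, stability = stability)
}

#' Randomly relabel the cohorts of a study
#'
#' Pools the `m + n` samples of both cohorts, permutes them uniformly at
#' random, and assigns the first `m` to cohort A and the remaining `n` to
#' cohort B. Abundances are untouched; only the cohort labels move, so the
#' permuted study realises the exchangeable null of no cohort effect.
#'
#' @param study An `sna_study`.
#' @param seed Optional integer seed (the global RNG state is preserved);
#'   omitted, the current RNG stream is used.
#' @return An `sna_study` with permuted cohort labels and unchanged cohort
#'   sizes.
#' @export
permute_cohorts <- function(study, seed = NULL) {
  stopifnot(inherits(study, "sna_study"))
  m <- sum(study$cohort == "A")
  N <- length(study$samples)
  ord <- if (is.null(seed)) sample.int(N) else {
    withr::with_seed(seed, sample.int(N))
  }
  out <- study
  lab <- rep("B", N)
  lab[ord[seq_len(m)]] <- "A"
  out$cohort <- setNames(lab, study$samples)
  out
}

#' Permutation null distributions of the stiffness parameters
#'
#' For each of `n_perm` random cohort relabelings, rebuilds the cohort-A
#' co-occurrence network and both cohort attribute vectors from the permuted
#' labels and recomputes stiffness scale, impact and stability — the full
#' network-construction-plus-stiffness algorithm, not just the attributes.
#' Undefined values are stored as `NA`, never as 0. The permutation index
#' matrix is drawn up front under `seed`, so results are reproducible and
#' independent of execution order.
#'
#' @param study An `sna_study` (already prevalence-filtered; filtering is
#'   label-free so it commutes with permutation).
#' @param net_cfg A [network_config()].
#' @param n_perm Number of permutations (the reference procedure uses 1000).
#' @param seed Integer seed.
#' @param pseudocount Baseline floor for relative changes.
#' @return A list with `stiffness_scale`, `impact`, `stability` (each a
#'   taxa-by-`n_perm` matrix of null values), and `n_failed` (permutations
#'   whose network construction failed; their columns are all-`NA`).
#' @export
null_distribution <- function(study, net_cfg = network_config(),
                              n_perm = 1000, seed = NULL,
                              pseudocount = 1e-6) {
  stopifnot(inherits(study, "sna_study"), n_perm >= 1)
  x <- study$abundance
  N <- ncol(x)
  m <- sum(study$cohort == "A")
  perms <- if (is.null(seed)) {
    matrix(replicate(n_perm, sample.int(N)), nrow = N)
  } else {
    withr::with_seed(seed, matrix(replicate(n_perm, sample.int(N)), nrow = N))
  }
  n <- nrow(x)
  out <- list(stiffness_scale = matrix(NA_real_, n, n_perm),
              impact = matrix(NA_real_, n, n_perm),
              stability = matrix(NA_real_, n, n_perm))
  n_failed <- 0L
  for (k in seq_len(n_perm)) {
    a_idx <- perms[seq_len(m), k]
    st <- tryCatch(stiffness_stats(x, a_idx, net_cfg, pseudocount),
                   error = function(e) NULL)
    if (is.null(st)) {
      n_failed <- n_failed + 1L
    } else {
      out$stiffness_scale[, k] <- st$stiffness_scale
      out$impact[, k] <- st$impact
      out$stability[, k] <- st$stability
    }
  }
  if (n_failed > 0L) {
    inform(paste0(n_failed, " of ", n_perm,
                  " permutations failed network construction"))
  }
  for (p in names(out)) rownames(out[[p]]) <- study$taxa
  out$n_failed <- n_failed
  out
}

#' Pseudo-P value pair from a permutation null
#'
#' `P1` is the fraction of valid null values strictly below the real value
#' `R`; `P2` the fraction at or above it (ties count towards `P2`), so
#' `P1 + P2 = 1`. A small `P2` marks a real value unusually high under the
#' null; a small `P1`, unusually low. With `smoothing = TRUE` the
#' `(N + 1) / (B + 1)` convention is used instead, which avoids exact zeros
#' at the cost of `P1 + P2` slightly exceeding 1.
#'
#' @param R Real (observed) value of the statistic.
#' @param null_values Numeric vector of permutation values (`NA`s dropped).
#' @param smoothing Use the add-one convention.
#' @return Named numeric vector `c(P1 = ..., P2 = ...)`; both `NA` when `R`
#'   is undefined or no valid null values remain.
#' @export
pseudo_p <- function(R, null_values, smoothing = FALSE) {
  valid <- null_values[!is.na(null_values)]
  if (!length(valid) || is.na(R)) return(c(P1 = NA_real_, P2 = NA_real_))
  n1 <- sum(valid < R)
  n2 <- sum(valid >= R)
  B <- length(valid)
  if (smoothing) {
    c(P1 = (n1 + 1) / (B + 1), P2 = (n2 + 1) / (B + 1))
  } else {
    c(P1 = n1 / B, P2 = n2 / B)
  }
}

#' Classify taxa from pseudo-P values with FDR control
#'
#' Benjamini-Hochberg adjustment is applied across taxa separately for the
#' increase tests (`P2` family) and the decrease tests (`P1` family), within
#' each parameter. A taxon is `sig_increased` when its adjusted `P2` falls
#' below `alpha` (real value significantly higher than the permutation
#' null), else `sig_decreased` when adjusted `P1` does, else `not_sig`;
#' taxa with undefined real values or empty nulls are `undefined`.
#'
#' @param report Tibble with columns `taxon`, `parameter`, `real`,
#'   `p_lower` (P1), `p_upper` (P2).
#' @param alpha FDR threshold (default 0.05).
#' @param fdr_method Method passed to [stats::p.adjust()] (default `"BH"`).
#' @return The report with columns `q_lower`, `q_upper`, `label` added;
#'   `label` is one of `sig_increased`, `sig_decreased`, `not_sig`,
#'   `undefined`.
#' @export
classify_taxa <- function(report, alpha = 0.05, fdr_method = "BH") {
  stopifnot(all(c("taxon", "parameter", "real", "p_lower", "p_upper")
                %in% names(report)))
  report |>
    group_by(.data$parameter) |>
    mutate(q_lower = p.adjust(.data$p_lower, method = fdr_method),
           q_upper = p.adjust(.data$p_upper, method = fdr_method)) |>
    ungroup() |>
    mutate(label = dplyr::case_when(
      is.na(.data$real) | is.na(.data$p_upper) ~ "undefined",
      .data$q_upper < alpha ~ "sig_increased",
      .data$q_lower < alpha ~ "sig_decreased",
      TRUE ~ "not_sig"))
}

#' Permutation test of stiffness parameters between two cohorts
#'
#' The full inference pipeline: prevalence-filter the study, compute the
#' real stiffness parameters (cohort-A network, cohort mean attributes),
#' generate the pooled-permutation null for stiffness scale, impact and
#' stability, convert to pseudo-P values and classify taxa under FDR
#' control. Force and displacement are computed for the profile but not
#' permutation-tested.
#'
#' @param study An `sna_study`.
#' @param net_cfg A [network_config()].
#' @param n_perm Number of permutations (default 1000).
#' @param alpha FDR threshold.
#' @param seed Integer seed making the whole run reproducible.
#' @param pseudocount Baseline floor for relative changes.
#' @param fdr_method Multiple-testing method for [stats::p.adjust()].
#' @param smoothing Use the add-one pseudo-P convention.
#' @return An `sna_permtest` object: the classified per-taxon report is in
#'   `$report` (also returned by [tidy()]), the real stiffness profile in
#'   `$profile`, the raw null matrices in `$nulls`.
#' @export
sna_permtest <- function(study, net_cfg = network_config(), n_perm = 1000,
                         alpha = 0.05, seed = NULL, pseudocount = 1e-6,
                         fdr_method = "BH", smoothing = FALSE) {
  stopifnot(inherits(study, "sna_study"))
  study <- filter_taxa(study, net_cfg)
  x <- study$abundance
  a_idx <- which(study$cohort == "A")

  real <- stiffness_stats(x, a_idx, net_cfg, pseudocount)
  net_a <- build_network(estimate_correlations(cohort_subset(study, "A"),
                                               net_cfg), net_cfg)
  profile <- suppressMessages(
    compute_profile(net_a, attr = cohort_means(study),
                    pseudocount = pseudocount))

  nulls <- null_distribution(study, net_cfg, n_perm = n_perm, seed = seed,
                             pseudocount = pseudocount)

  params <- c("stiffness_scale", "impact", "stability")
  report <- purrr::map_dfr(params, function(p) {
    pp <- t(vapply(seq_along(study$taxa), function(i) {
      pseudo_p(real[[p]][i], nulls[[p]][i, ], smoothing = smoothing)
    }, c(P1 = 0, P2 = 0)))
    tibble(taxon = study$taxa, parameter = p, real = real[[p]],
           p_lower = pp[, "P1"], p_upper = pp[, "P2"],
           n_valid = rowSums(!is.na(nulls[[p]])))
  })
  report <- classify_taxa(report, alpha = alpha, fdr_method = fdr_method)

  structure(list(report = report, profile = profile, nulls = nulls,
                 network_a = net_a, alpha = alpha, n_perm = n_perm,
                 seed = seed, taxa = study$taxa,
                 cohort_labels = study$cohort_labels),
            class = "sna_permtest")
}

#' Biomarker taxa from a permutation test
#'
#' @param test An `sna_permtest`.
#' @param parameter Which stiffness parameter's classification to use
#'   (default `"stability"`).
#' @return A list with character vectors `increased` and `decreased`.
#' @export
biomarkers <- function(test, parameter = "stability") {
  stopifnot(inherits(test, "sna_permtest"))
  rep <- test$report |> filter(.data$parameter == !!parameter)
  list(increased = rep$taxon[rep$label == "sig_increased"],
       decreased = rep$taxon[rep$label == "sig_decreased"])
}

#' @export
print.sna_permtest <- function(x, ...) {
  cat("<sna_permtest> ", length(x$taxa), " taxa, ", x$n_perm,
      " permutations, alpha = ", x$alpha, "\n", sep = "")
  tab <- x$report |>
    group_by(.data$parameter) |>
    summarise(increased = sum(.data$label == "sig_increased"),
              decreased = sum(.data$label == "sig_decreased"),
              .groups = "drop")
  print(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}

#' @method tidy sna_permtest
#' @export
tidy.sna_permtest <- function(x, ...) x$report

#' @method glance sna_permtest
#' @export
glance.sna_permtest <- function(x, ...) {
  x$report |>
    group_by(.data$parameter) |>
    summarise(n_taxa = n(),
              n_increased = sum(.data$label == "sig_increased"),
              n_decreased = sum(.data$label == "sig_decreased"),
              n_not_sig = sum(.data$label == "not_sig"),
              n_undefined = sum(.data$label == "undefined"),
              .groups = "drop") |>
    mutate(n_perm = x$n_perm, alpha = x$alpha)
}

format_pct <- function(k, n) paste0(round(100 * k / n, 1), "%")

#' Proportion-of-significant-taxa summary table
#'
#' Summarises one or several permutation tests into the
#' proportion-of-significant-species layout: per parameter the percentage
#' and `"k/n"` fraction of taxa classified as significantly increased
#' (real value above the null, column convention `R_i < R`), significantly
#' decreased (`R_i > R`) and not significant (`R_i = R`). Given several
#' reports, mean and standard error rows across studies are appended.
#'
#' @param tests An `sna_permtest` or a (optionally named) list of them.
#' @return A tibble with columns `study`, `parameter`, counts, numeric
#'   percentages (`pct_*`), and formatted cells (`cell_*` like `"25.9%"`,
#'   `frac_*` like `"22/85"`).
#' @export
significance_summary <- function(tests) {
  if (inherits(tests, "sna_permtest")) tests <- list(tests)
  stopifnot(length(tests) >= 1, all(vapply(tests, inherits, TRUE,
                                           "sna_permtest")))
  nms <- names(tests) %||% paste0("study", seq_along(tests))
  nms[nms == ""] <- paste0("study", which(nms == ""))

  per <- purrr::map2_dfr(tests, nms, function(tt, nm) {
    tt$report |>
      group_by(.data$parameter) |>
      summarise(
        n_taxa = n(),
        k_increased = sum(.data$label == "sig_increased"),
        k_decreased = sum(.data$label == "sig_decreased"),
        .groups = "drop") |>
      mutate(k_not_sig = .data$n_taxa - .data$k_increased - .data$k_decreased,
             study = nm)
  })
  per <- per |>
    mutate(pct_increased = 100 * .data$k_increased / .data$n_taxa,
           pct_decreased = 100 * .data$k_decreased / .data$n_taxa,
           pct_not_sig = 100 * .data$k_not_sig / .data$n_taxa,
           cell_increased = format_pct(.data$k_increased, .data$n_taxa),
           cell_decreased = format_pct(.data$k_decreased, .data$n_taxa),
           cell_not_sig = format_pct(.data$k_not_sig, .data$n_taxa),
           frac_increased = paste0(.data$k_increased, "/", .data$n_taxa),
           frac_decreased = paste0(.data$k_decreased, "/", .data$n_taxa),
           frac_not_sig = paste0(.data$k_not_sig, "/", .data$n_taxa)) |>
    select("study", dplyr::everything())

  if (length(tests) > 1L) {
    agg <- per |>
      group_by(.data$parameter) |>
      summarise(dplyr::across(dplyr::starts_with("pct_"),
                              list(mean = mean,
                                   se = ~ sd(.x) / sqrt(length(.x)))),
                .groups = "drop")
    mean_rows <- agg |>
      dplyr::transmute(study = "mean", .data$parameter,
                       pct_increased = .data$pct_increased_mean,
                       pct_decreased = .data$pct_decreased_mean,
                       pct_not_sig = .data$pct_not_sig_mean)
    se_rows <- agg |>
      dplyr::transmute(study = "std_err", .data$parameter,
                       pct_increased = .data$pct_increased_se,
                       pct_decreased = .data$pct_decreased_se,
                       pct_not_sig = .data$pct_not_sig_se)
    per <- bind_rows(per, mean_rows, se_rows)
  }
  per
}
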