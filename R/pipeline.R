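# Stage-tagged error propagation: any failure inside a pipeline stage
# surfaces as "[stage] message" so a caller (or the CLI wrapper) can report
# where the run died.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[", stage, "] ", conditionMessage(e)))
  })
}

default_run_config <- function() {
  list(
    io = list(abundance = NULL, metadata = NULL, cohort_column = "cohort",
              ref_label = NULL, outdir = "sna_results"),
    network = list(estimator = "spearman", min_abs_corr = 0.3,
                   min_prevalence = 0, pseudocount = 1e-6,
                   sparcc_iterations = 10),
    stiffness = list(pseudocount = 1e-6),
    permutation = list(n_perm = 1000, alpha = 0.05, seed = 1,
                       fdr = "BH", smoothing = FALSE),
    fon = list(parameter = "stability", cohort = "A",
               estimator = "sparcc", min_size = 3)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      merge_config(base[[nm]], override[[nm]])
    } else {
      override[[nm]]
    }
  }
  base
}

#' Run the full stiffness-network pipeline
#'
#' Executes, from a YAML configuration (or equivalent nested list):
#' abundance loading, per-cohort network construction, the stiffness
#' profile, the pooled-permutation significance test, biomarker FON-graph
#' extraction and all-positive subgroup mining — writing every result table
#' plus a JSON run manifest into the configured output directory. All
#' randomness flows from `permutation$seed`, so two runs with the same
#' configuration produce byte-identical result tables.
#'
#' @param config Path to a YAML config file, or a nested list with sections
#'   `io` (`abundance`, `metadata`, `cohort_column`, `ref_label`, `outdir`),
#'   `network`, `stiffness`, `permutation`, `fon` (missing entries take
#'   defaults).
#' @param study Optionally, an `sna_study` to use directly instead of
#'   reading `io$abundance` / `io$metadata`.
#' @return Invisibly, a list with the `sna_permtest`, the FON graph, the
#'   subgroups, and the written file paths.
#' @export
sna_run <- function(config, study = NULL) {
  cfg <- with_stage("config", {
    user <- if (is.character(config)) {
      if (!file.exists(config)) abort(paste0("no such config file: ", config))
      yaml::read_yaml(config)
    } else if (is.list(config)) config else {
      abort("config must be a path or a list")
    }
    merge_config(default_run_config(), user)
  })

  if (is.null(study)) {
    study <- with_stage("io", {
      if (is.null(cfg$io$abundance)) abort("io$abundance path not set")
      if (is.null(cfg$io$metadata)) abort("io$metadata path not set")
      read_abundance(cfg$io$abundance, cfg$io$metadata,
                     cohort_column = cfg$io$cohort_column,
                     ref_label = cfg$io$ref_label)
    })
  }
  outdir <- cfg$io$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  net_cfg <- with_stage("network", do.call(network_config, c(
    cfg$network[c("estimator", "min_abs_corr", "min_prevalence",
                  "pseudocount", "sparcc_iterations")])))

  test <- with_stage("permutation", sna_permtest(
    study, net_cfg = net_cfg,
    n_perm = cfg$permutation$n_perm, alpha = cfg$permutation$alpha,
    seed = cfg$permutation$seed,
    pseudocount = cfg$stiffness$pseudocount,
    fdr_method = cfg$permutation$fdr,
    smoothing = isTRUE(cfg$permutation$smoothing)))

  fstudy <- filter_taxa(study, net_cfg)
  with_stage("network", {
    net_b <- build_network(estimate_correlations(cohort_subset(fstudy, "B"),
                                                 net_cfg), net_cfg)
    paths$network_a <- file.path(outdir, "network_A.tsv")
    paths$network_b <- file.path(outdir, "network_B.tsv")
    write_network(test$network_a, paths$network_a)
    write_network(net_b, paths$network_b)
  })

  with_stage("stiffness", {
    paths$profile <- file.path(outdir, "profile.tsv")
    write_profile(test$profile, paths$profile)
  })

  with_stage("permutation", {
    paths$report <- file.path(outdir, "permutation_report.tsv")
    rep_out <- test$report |>
      select("taxon", "parameter", R = "real", P1 = "p_lower",
             P2 = "p_upper", q1 = "q_lower", q2 = "q_upper", "label")
    utils::write.table(as.data.frame(rep_out), paths$report, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$summary <- file.path(outdir, "significance_summary.tsv")
    utils::write.table(as.data.frame(significance_summary(test)),
                       paths$summary, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  fon_res <- with_stage("fon", {
    bm <- biomarkers(test, parameter = cfg$fon$parameter)
    fon_cfg <- network_config(
      estimator = cfg$fon$estimator,
      min_abs_corr = cfg$network$min_abs_corr,
      min_prevalence = cfg$network$min_prevalence,
      pseudocount = cfg$network$pseudocount,
      sparcc_iterations = cfg$network$sparcc_iterations)
    fon_net <- build_network(
      estimate_correlations(cohort_subset(fstudy, cfg$fon$cohort), fon_cfg),
      fon_cfg)
    fon <- suppressWarnings(
      extract_fon(fon_net, bm$increased, bm$decreased,
                  cohort_tag = cfg$fon$cohort))
    paths$fon <- file.path(outdir, "fon.graphml")
    write_fon_graphml(fon, paths$fon)
    paths$fon_pn <- file.path(outdir, "fon_pn.tsv")
    utils::write.table(as.data.frame(fon_pn_table(fon)), paths$fon_pn,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    subgroups <- mine_subgroups(fon_net, c(bm$increased, bm$decreased),
                                min_size = cfg$fon$min_size)
    paths$subgroups <- file.path(outdir, "subgroups.tsv")
    sg_df <- if (length(subgroups)) {
      purrr::imap_dfr(subgroups, function(sg, i) {
        tibble(subgroup = i, taxon = sg$taxa, size = sg$size,
               complete = sg$complete)
      })
    } else {
      tibble(subgroup = integer(), taxon = character(),
             size = integer(), complete = logical())
    }
    utils::write.table(as.data.frame(sg_df), paths$subgroups, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(fon = fon, subgroups = subgroups)
  })

  with_stage("manifest", {
    paths$manifest <- file.path(outdir, "manifest.json")
    manifest <- list(
      config = cfg,
      seed = cfg$permutation$seed,
      package_version = as.character(utils::packageVersion("stiffnet")),
      n_taxa = length(test$taxa),
      n_perm_failed = test$nulls$n_failed,
      n_undefined = sum(is.na(test$report$real)),
      regularized_solve = attr(test$profile, "regularized"),
      outputs = lapply(paths[names(paths) != "manifest"], basename))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, null = "null", digits = NA)
  })

  invisible(list(test = test, fon = fon_res$fon,
                 subgroups = fon_res$subgroups, paths = paths,
                 config = cfg))
}

#' Generate and write a synthetic study
#'
#' Wraps [generate_study()]: writes the abundance TSV, metadata TSV and a
#' ground-truth JSON into `outdir`. The written pair is directly loadable by
#' [sna_run()].
#'
#' @param spec A [synthetic_spec()], or a path to a YAML file whose keys are
#'   `synthetic_spec()` arguments (blocks as a list of `[size, rho]` pairs).
#' @param outdir Output directory.
#' @param seed Optional seed overriding the spec's.
#' @return Invisibly, a list with `study`, `truth`, and the written `paths`.
#' @export
sna_simulate <- function(spec = synthetic_spec(), outdir = "sna_sim",
                         seed = NULL) {
  spec <- with_stage("spec", {
    if (is.character(spec)) {
      if (!file.exists(spec)) abort(paste0("no such spec file: ", spec))
      raw <- yaml::read_yaml(spec)
      if (!is.null(raw$blocks)) {
        raw$blocks <- lapply(raw$blocks, function(b) c(b[[1]], b[[2]]))
      }
      do.call(synthetic_spec, raw)
    } else if (inherits(spec, "synthetic_spec")) spec else {
      abort("spec must be a synthetic_spec or a YAML path")
    }
  })
  gen <- with_stage("simulate", generate_study(spec, seed = seed))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(abundance = file.path(outdir, "abundance.tsv"),
                metadata = file.path(outdir, "metadata.tsv"),
                truth = file.path(outdir, "truth.json"))
  write_abundance(gen$study, paths$abundance, paths$metadata)
  jsonlite::write_json(
    list(planted = gen$truth$planted,
         rewire_mode = spec$rewire_mode,
         labels = truth_labels(gen$truth)),
    paths$truth, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(study = gen$study, truth = gen$truth, paths = paths))
}
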