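#' Default run configuration
#'
#' @param seed global seed for every stage.
#' @param genotype imaging/behavior genotype (default `"5xFAD"`, the study
#'   comparison; histology always simulates both genotypes for the region
#'   ratios).
#' @param odorants odorant panel.
#' @param stages named logical toggles: `imaging`, `histology`, `behavior`,
#'   `counts`, `correlate`.
#' @param n_per_group animals per genotype in the count tables.
#' @param ... overrides forwarded to [sim_config()].
#' @return list of class `"run_config"`.
#' @export
default_run_config <- function(seed = 1L, genotype = "5xFAD",
                               odorants = odorant_panel(),
                               stages = list(imaging = TRUE, histology = TRUE,
                                             behavior = TRUE, counts = TRUE,
                                             correlate = TRUE),
                               n_per_group = 6L, ...) {
  structure(list(seed = as.integer(seed), genotype = genotype,
                 odorants = odorants, stages = stages,
                 n_per_group = as.integer(n_per_group),
                 sim_overrides = list(...)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file.
#' @return a `"run_config"`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(default_run_config,
          c(list(seed = y$seed %||% 1L, genotype = y$genotype %||% "5xFAD",
                 odorants = y$odorants %||% odorant_panel(),
                 stages = utils::modifyList(
                   list(imaging = TRUE, histology = TRUE, behavior = TRUE,
                        counts = TRUE, correlate = TRUE),
                   y$stages %||% list()),
                 n_per_group = y$n_per_group %||% 6L),
            y$sim_overrides %||% list()))
}

#' Run the full synthetic-study pipeline
#'
#' Executes the enabled stages in dependency order -- simulate movies,
#' compute dF/F0 activity maps and angular profiles, simulate histology
#' and build A11 profiles, simulate behavior and compute performance
#' indices, generate count tables and group statistics, and correlate
#' modalities -- and aggregates a machine-readable report.  Rerunning with
#' the same config reproduces the report exactly.
#'
#' @param config a `"run_config"` ([default_run_config()]).
#' @param out_dir optional directory; when given, writes `report.json`,
#'   `correlations.csv` and `counts_summary.csv` there.
#' @return report list: `config_hash`, `seed`, `genotype`, `odorants`
#'   (per-odorant PI, peak dF/F0, angle-matched rho/p/n), `cluster`,
#'   `region_ratios`, `stats`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  st <- config$stages
  report <- list(config_hash = config_hash(config), seed = config$seed,
                 genotype = config$genotype)

  cfg <- do.call(sim_config,
                 c(list(seed = config$seed, genotype = config$genotype,
                        odorants = config$odorants),
                   config$sim_overrides))

  maps <- NULL
  if (isTRUE(st$imaging)) {
    geom <- ellipse_contour(cfg$fov_px, plane = "sagittal")
    maps <- lapply(cfg$odorants, function(od) {
      part <- generate_odorant_trialset(cfg, od, geom)
      compute_activity_map(part$trialset, geom)
    })
    names(maps) <- cfg$odorants
  }

  hist_wt <- hist_tg <- NULL
  if (isTRUE(st$histology)) {
    cfg_wt <- do.call(sim_config,
                      c(list(seed = config$seed, genotype = "WT",
                             odorants = config$odorants),
                        config$sim_overrides))
    cfg_tg <- do.call(sim_config,
                      c(list(seed = derive_seed(config$seed, 7),
                             genotype = "5xFAD",
                             odorants = config$odorants),
                        config$sim_overrides))
    hist_wt <- generate_histology_profile(cfg_wt, plane = "sagittal")
    hist_tg <- generate_histology_profile(cfg_tg, plane = "sagittal")
    report$region_ratios <- as.list(region_ratio(hist_wt$profile,
                                                 hist_tg$profile))
  }

  pis <- NULL
  if (isTRUE(st$behavior)) {
    pis <- vapply(seq_along(cfg$odorants), function(i) {
      od <- cfg$odorants[i]
      detects <- !(config$genotype == "5xFAD" && odorant_group(od) == "B")
      exp_s <- generate_trajectory(detects,
                                   seed = derive_seed(config$seed, 500 + i),
                                   condition = od)
      ctrl_s <- generate_trajectory(FALSE,
                                    seed = derive_seed(config$seed, 600 + i),
                                    condition = "MO")
      performance_index(100 * zone_occupancy(exp_s)$odor_fraction,
                        100 * zone_occupancy(ctrl_s)$odor_fraction)
    }, numeric(1))
    names(pis) <- cfg$odorants
  }

  if (isTRUE(st$correlate)) {
    if (is.null(maps)) stop("stage 'correlate' needs stage 'imaging'")
    if (is.null(hist_tg)) stop("stage 'correlate' needs stage 'histology'")
    cormat <- odor_map_correlation(lapply(maps, `[[`, "profile_abs"))
    cl <- cluster_odorants(cormat, k = 2L)
    report$cluster <- as.list(stats::setNames(as.integer(cl), names(cl)))
    report$correlations <- lapply(cfg$odorants, function(od) {
      am <- angle_matched_correlation(hist_tg$profile, maps[[od]]$profile)
      list(odorant = od, rho = am$cor$rho, p = am$cor$p,
           n_pairs = am$n_pairs, ci95 = am$cor$ci95, slope = am$slope)
    })
    names(report$correlations) <- cfg$odorants
  }

  if (isTRUE(st$counts)) {
    counts <- generate_count_tables(config$n_per_group,
                                    seed = derive_seed(config$seed, 900))
    report$counts_summary <- summarize_counts(counts)
    report$stats <- lapply(split(counts, counts$marker),
                           function(d) two_way_anova_bonferroni(d))
  }

  report$odorants <- lapply(cfg$odorants, function(od) {
    entry <- list(odorant = od, group = odorant_group(od))
    if (!is.null(pis)) entry$PI <- unname(pis[od])
    if (!is.null(maps)) entry$peak_dff <- maps[[od]]$peak_dff
    if (!is.null(report$correlations)) {
      entry$rho <- report$correlations[[od]]$rho
      entry$p <- report$correlations[[od]]$p
      entry$n_pairs <- report$correlations[[od]]$n_pairs
    }
    entry
  })
  names(report$odorants) <- cfg$odorants

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(strip_for_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(report$correlations)) {
      cors <- do.call(rbind, lapply(report$correlations, function(e) {
        data.frame(odorant = e$odorant, rho = e$rho, ci_low = e$ci95[1],
                   ci_high = e$ci95[2], p = e$p, n_pairs = e$n_pairs)
      }))
      utils::write.csv(cors, file.path(out_dir, "correlations.csv"),
                       row.names = FALSE)
    }
    if (!is.null(report$counts_summary)) {
      utils::write.csv(report$counts_summary,
                       file.path(out_dir, "counts_summary.csv"),
                       row.names = FALSE)
    }
  }
  report
}

# md5 of the canonical JSON serialization of the config
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

# drop heavy/recursive members before JSON serialization
strip_for_json <- function(report) {
  report$stats <- lapply(report$stats, function(s) {
    list(anova = s$anova, posthoc = s$posthoc)
  })
  report
}
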