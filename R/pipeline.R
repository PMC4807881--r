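# End-to-end experiment orchestration: simulate -> segment -> score -> test.
#
# A configuration (R list or YAML file) names the experiment kind, the
# groups with their generator parameters, the seed and the statistics plan;
# run_experiment() is deterministic given config + seed and writes tidy CSV,
# a JSON test report and a diagnostic plot.

experiment_kinds <- c("ovi", "oai", "aggregation", "ratio", "coloc",
                      "phagocytosis", "survival", "cfu")

#' Read an experiment configuration from YAML
#'
#' YAML 1.1 parses the bare keys `n` and `y` as booleans; since both are
#' legitimate configuration keys (group size, axis name) they are restored
#' after parsing.
#'
#' @param path YAML file; see [run_experiment()] for the expected fields.
#' @return the configuration list.
#' @export
read_experiment_config <- function(path) {
  fix_keys <- function(x) {
    if (!is.list(x)) return(x)
    nm <- names(x)
    if (!is.null(nm)) {
      nm[nm == "FALSE"] <- "n"
      nm[nm == "TRUE"] <- "y"
      names(x) <- nm
    }
    lapply(x, fix_keys)
  }
  fix_keys(yaml::read_yaml(path))
}

as_named_num <- function(x) {
  if (is.list(x)) unlist(x) else x
}

build_scene_spec <- function(overrides, seed) {
  args <- overrides %||% list()
  for (f in c("shape", "voxel", "center_offset"))
    if (!is.null(args[[f]])) args[[f]] <- as_named_num(args[[f]])
  args$seed <- seed
  do.call(scene_spec, args)
}

build_timelapse_spec <- function(overrides, seed) {
  args <- overrides %||% list()
  for (f in c("shape", "voxel")) if (!is.null(args[[f]])) args[[f]] <- as_named_num(args[[f]])
  args$seed <- seed
  do.call(timelapse_spec, args)
}

#' Validate an experiment configuration
#'
#' Checks the configuration without side effects and returns every finding
#' (missing seed, unknown kind, invalid geometry, comparisons naming
#' unknown groups, ...); an empty character vector means the configuration
#' is runnable.
#'
#' @param cfg configuration list (see [run_experiment()]).
#' @return character vector of findings.
#' @export
validate_config <- function(cfg) {
  findings <- character(0)
  say <- function(fmt, ...) findings <<- c(findings, sprintf(fmt, ...))
  if (is.null(cfg$seed)) say("missing seed: runs must be reproducible")
  if (is.null(cfg$kind) || !(cfg$kind %in% experiment_kinds))
    say("unknown experiment kind '%s'", cfg$kind %||% "<none>")
  if (is.null(cfg$groups) || length(cfg$groups) < 1L) {
    say("no groups defined")
    return(findings)
  }
  nms <- vapply(cfg$groups, function(g) g$name %||% NA_character_, character(1))
  if (anyNA(nms)) say("every group needs a name")
  if (anyDuplicated(nms)) say("duplicate group names")
  for (g in cfg$groups) {
    if ((g$n %||% 0) < 1) say("group '%s': n must be >= 1", g$name %||% "?")
    if (identical(cfg$kind, "coloc") && !is.null(g$rho) && abs(g$rho) > 1)
      say("group '%s': rho outside [-1, 1]", g$name)
    if (cfg$kind %in% c("ovi", "oai", "aggregation", "ratio")) {
      tryCatch({
        base <- build_scene_spec(g$scene, seed = cfg$seed %||% 1L)
        random_cell_spec(base,
                         n_vacuoles = g$n_vacuoles %||% 0,
                         vacuole_radius_range = as_named_num(g$vacuole_radius_range %||% c(1.6, 2.4)),
                         n_vesicles = g$n_vesicles %||% 0,
                         vesicle_diameter_range = as_named_num(g$vesicle_diameter_range %||% c(0.8, 1.6)),
                         seed = cfg$seed %||% 1L)
      }, error = function(e)
        say("group '%s': invalid geometry (%s)", g$name %||% "?", conditionMessage(e)))
    }
  }
  comps <- cfg$stats$comparisons
  if (!is.null(comps)) for (p in comps)
    if (!all(unlist(p) %in% nms))
      say("comparison names unknown group: %s", paste(unlist(p), collapse = " vs "))
  if (!is.null(cfg$reference) && !(cfg$reference %in% nms))
    say("reference '%s' is not a group", cfg$reference)
  findings
}

derive_seed <- function(seed, gi, i) {
  as.integer((as.numeric(seed) * 97 + gi * 10007 + i * 13) %% 2147483647)
}

morpho_values <- function(cfg) {
  rows <- list(); particle_sets <- list()
  for (gi in seq_along(cfg$groups)) {
    g <- cfg$groups[[gi]]
    psets <- vector("list", g$n)
    for (i in seq_len(g$n)) {
      sd <- derive_seed(cfg$seed, gi, i)
      base <- build_scene_spec(g$scene, seed = sd)
      spec <- random_cell_spec(base,
        n_vacuoles = g$n_vacuoles %||% 0,
        vacuole_radius_range = as_named_num(g$vacuole_radius_range %||% c(1.6, 2.4)),
        n_vesicles = g$n_vesicles %||% 0,
        vesicle_diameter_range = as_named_num(g$vesicle_diameter_range %||% c(0.8, 1.6)),
        seed = sd)
      sc <- make_cell_scene(spec)
      cell <- segment_cell_body(sc$stack)
      value <- switch(cfg$kind,
        ovi = {
          vac <- detect_vacuoles(sc$stack, cell)
          ovi(vac, cell)$value
        },
        oai = , aggregation = , ratio = {
          img <- max_project(sc$stack, 2L) * cell$mask2d
          ps <- detect_particles(img, pixel_size = unname(sc$stack$voxel["xy"]))
          psets[[i]] <- ps
          if (cfg$kind == "oai") oai(ps, cell$area)$value
          else if (cfg$kind == "aggregation") {
            if (nrow(ps) == 0L) NA_real_ else aggregation_index(ps)$value
          } else NA_real_  # ratio filled in after the reference mean is known
        })
      rows[[length(rows) + 1L]] <- data.frame(group = g$name, cell = i, value = value)
    }
    particle_sets[[g$name]] <- psets
  }
  values <- do.call(rbind, rows)
  if (cfg$kind == "ratio") {
    refg <- cfg$reference %||% cfg$groups[[1]]$name
    ref_mean <- diameter_reference(particle_sets[[refg]])
    values <- do.call(rbind, lapply(names(particle_sets), function(nm) {
      dr <- diameter_ratio(particle_sets[[nm]], ref_mean, group = nm)
      data.frame(group = nm, cell = seq_len(nrow(dr)), value = dr$value)
    }))
  }
  values
}

coloc_values <- function(cfg) {
  scene_groups <- list()
  for (gi in seq_along(cfg$groups)) {
    g <- cfg$groups[[gi]]
    scene_groups[[g$name]] <- lapply(seq_len(g$n), function(i) {
      sp <- build_scene_spec(g$scene, seed = derive_seed(cfg$seed, gi, i))
      make_coloc_scene(g$n_puncta %||% 60L, g$rho %||% 0, sp)$stack
    })
  }
  tab <- coloc_by_group(scene_groups)
  data.frame(group = tab$group, cell = tab$cell, value = tab$r)
}

phago_values <- function(cfg) {
  rows <- list()
  for (gi in seq_along(cfg$groups)) {
    g <- cfg$groups[[gi]]
    for (i in seq_len(g$n)) {
      sp <- build_timelapse_spec(g$timelapse, seed = derive_seed(cfg$seed, gi, i))
      mv <- make_timelapse(sp)
      cell <- segment_cell_body(mv$stack, channel = 1L, time = 1L)
      tr <- track_particle(mv$stack, cell = cell)
      value <- if (tr$docked)
        fyve_prevalence(mv$stack, tr, cell = cell)$prevalence_min else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(group = g$name, cell = i, value = value)
    }
  }
  do.call(rbind, rows)
}

run_stats <- function(cfg, values) {
  plan <- cfg$stats %||% list(test = "none")
  alpha <- plan$alpha %||% 0.05
  comps <- lapply(plan$comparisons %||% list(), unlist)
  vals <- values[!is.na(values$value), ]
  groups <- split(vals$value, vals$group)
  switch(plan$test %||% "none",
    none = NULL,
    anova_bonferroni = {
      an <- one_way_anova(groups)
      an$posthoc <- bonferroni_posthoc(groups,
        comparisons = if (length(comps)) comps else NULL, alpha = alpha)
      an
    },
    mann_whitney = {
      prs <- if (length(comps)) comps else list(names(groups)[1:2])
      ph <- do.call(rbind, lapply(prs, function(p) {
        mw <- mann_whitney(groups[[p[1]]], groups[[p[2]]], tails = "two")
        data.frame(group1 = p[1], group2 = p[2], U = mw$statistic,
                   p = mw$p_value, significant = mw$p_value < alpha)
      }))
      test_result("Mann-Whitney (two-tailed)", NA_real_, NA_real_, NA_real_, ph)
    },
    stop_hq("domain", "unknown stats test '%s'", plan$test))
}

#' Run a configured experiment end to end
#'
#' Generates the synthetic inputs for every group, runs the corresponding
#' quantification (index, correlation, prevalence, lifespan or CFU) and the
#' configured statistics, and (when `out` is given) writes `values.csv`,
#' `report.json`, `config_resolved.yaml` and a diagnostic `plot.pdf`.
#' Deterministic given the configuration and its seed.
#'
#' Configuration fields: `kind` (one of ovi, oai, aggregation, ratio,
#' coloc, phagocytosis, survival, cfu), `seed`, `groups` (list; each with
#' `name`, `n` and kind-specific generator fields: `scene` +
#' `n_vacuoles`/`vacuole_radius_range`/`n_vesicles`/`vesicle_diameter_range`
#' for the morphometric kinds, `rho`/`n_puncta` for coloc, `timelapse`
#' overrides for phagocytosis, `lifespan`/`replicates` for survival, `cfu`
#' for colony counts), optional `reference` group name, and `stats`
#' (`test` = anova_bonferroni | mann_whitney | none, `comparisons`,
#' `alpha`).
#'
#' @param cfg configuration list or path to a YAML file.
#' @param out output directory (created if needed), or `NULL` to skip
#'   writing.
#' @return list with `values` (tidy data.frame), `test` (`hq_test` or
#'   NULL), `summary` (kind-specific) and `findings`, invisibly.
#' @export
run_experiment <- function(cfg, out = NULL) {
  if (is.character(cfg)) cfg <- read_experiment_config(cfg)
  findings <- validate_config(cfg)
  if (length(findings))
    stop_hq("config", "invalid configuration:\n  %s", paste(findings, collapse = "\n  "))

  summary <- NULL
  values <- switch(cfg$kind,
    ovi = , oai = , aggregation = , ratio = morpho_values(cfg),
    coloc = coloc_values(cfg),
    phagocytosis = phago_values(cfg),
    survival = {
      cohort <- make_survival_cohort(cohort_spec(cfg$groups, seed = cfg$seed))
      ml <- median_lifespan(cohort)
      refg <- cfg$reference %||% cfg$groups[[1]]$name
      ml$relative_pct <- relative_lifespan(
        ml$median_days, ml$median_days[ml$group == refg])
      summary <- ml
      data.frame(group = cohort$group, cell = cohort$individual_id,
                 value = cohort$death_day)
    },
    cfu = {
      counts <- make_dilution_counts(cohort_spec(cfg$groups, seed = cfg$seed))
      est <- cfu_per_individual(counts)
      summary <- est
      data.frame(group = est$group, cell = est$individual_id, value = est$cfu)
    })

  test <- run_stats(cfg, values)
  bundle <- list(values = values, test = test, summary = summary,
                 findings = findings, kind = cfg$kind, seed = cfg$seed)

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(values, file.path(out, "values.csv"), row.names = FALSE)
    report <- list(kind = cfg$kind, seed = cfg$seed,
                   test = if (is.null(test)) NULL else
                     list(name = test$test, statistic = test$statistic,
                          df = test$df, p_value = test$p_value,
                          posthoc = test$posthoc),
                   summary = summary)
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows", force = TRUE)
    yaml::write_yaml(cfg, file.path(out, "config_resolved.yaml"))
    grDevices::pdf(file.path(out, "plot.pdf"), width = 5, height = 4)
    graphics::boxplot(value ~ group, data = values,
                      ylab = cfg$kind, main = sprintf("%s by group", cfg$kind))
    grDevices::dev.off()
  }
  invisible(bundle)
}
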