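# strict CSV dialect: comma, UTF-8, ".", "NA"
.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                  fileEncoding = "UTF-8")
}

.check_schema <- function(df, required, numeric_cols, path) {
  problems <- character(0)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    problems <- c(problems, paste0("missing column(s): ",
                                   paste(miss, collapse = ", ")))
  }
  for (cc in intersect(numeric_cols, names(df))) {
    if (!is.numeric(df[[cc]])) {
      problems <- c(problems, paste0("column '", cc, "' is not numeric"))
    }
  }
  list(df = df, problems = problems, path = path)
}

.fail_schema <- function(chk) {
  if (length(chk$problems)) {
    stop("invalid table '", chk$path, "':\n  - ",
         paste(chk$problems, collapse = "\n  - "), call. = FALSE)
  }
  chk$df
}

#' Read and validate an experiment-design table
#'
#' Required columns: \code{core_id}, \code{treatment},
#' \code{added_mmol_m2}, \code{label_atom_pct}.
#'
#' @param path CSV path (comma, UTF-8, NA for missing).
#' @return Validated data frame.
#' @export
read_design_table <- function(path) {
  chk <- .check_schema(.read_csv(path),
                       c("core_id", "treatment", "added_mmol_m2",
                         "label_atom_pct"),
                       c("added_mmol_m2", "label_atom_pct"), path)
  df <- chk$df
  if (!length(chk$problems)) {
    if (anyDuplicated(df$core_id)) {
      chk$problems <- c(chk$problems, "duplicate core_id values")
    }
    bad <- which(!is.na(df$added_mmol_m2) & df$added_mmol_m2 < 0)
    if (length(bad)) {
      chk$problems <- c(chk$problems,
                        paste0("negative added carbon in row(s): ",
                               paste(bad, collapse = ", ")))
    }
  }
  .fail_schema(chk)
}

#' Read and validate a water-chemistry table
#'
#' Required columns: \code{core_id}, \code{treatment}, \code{time_h},
#' \code{solute}, \code{conc_uM}, \code{delta13C} (nullable). All
#' violations are reported at once, with row numbers.
#'
#' @inheritParams read_design_table
#' @return Validated data frame.
#' @export
read_water_chemistry <- function(path) {
  chk <- .check_schema(.read_csv(path),
                       c("core_id", "treatment", "time_h", "solute",
                         "conc_uM", "delta13C"),
                       c("time_h", "conc_uM", "delta13C"), path)
  df <- chk$df
  if (!length(chk$problems)) {
    bad <- which(is.na(df$conc_uM) | df$conc_uM < 0)
    if (length(bad)) {
      chk$problems <- c(chk$problems,
                        paste0("missing or negative conc_uM in row(s): ",
                               paste(bad, collapse = ", ")))
    }
    bad <- which(!is.na(df$delta13C) & df$delta13C <= -1000)
    if (length(bad)) {
      chk$problems <- c(chk$problems,
                        paste0("delta13C <= -1000 in row(s): ",
                               paste(bad, collapse = ", ")))
    }
  }
  .fail_schema(chk)
}

#' Read and validate an end-point PLFA table
#'
#' Required columns: \code{core_id}, \code{plfa}, \code{carbon_mmol_m2},
#' \code{atom_pct_13C}. PLFA names are checked against
#' [plfa_vocabulary()]; unknown names are rejected with a nearest-match
#' hint.
#'
#' @inheritParams read_design_table
#' @param vocabulary accepted PLFA names.
#' @return Validated data frame.
#' @export
read_plfa_table <- function(path, vocabulary = plfa_vocabulary()) {
  chk <- .check_schema(.read_csv(path),
                       c("core_id", "plfa", "carbon_mmol_m2",
                         "atom_pct_13C"),
                       c("carbon_mmol_m2", "atom_pct_13C"), path)
  df <- chk$df
  if (!length(chk$problems)) {
    unknown <- setdiff(unique(df$plfa), vocabulary)
    for (u in unknown) {
      near <- vocabulary[which.min(utils::adist(u, vocabulary))]
      chk$problems <- c(chk$problems,
                        sprintf("unknown PLFA '%s' (did you mean %s?)",
                                u, near))
    }
    bad <- which(is.na(df$carbon_mmol_m2) | df$carbon_mmol_m2 < 0)
    if (length(bad)) {
      chk$problems <- c(chk$problems,
                        paste0("missing or negative carbon_mmol_m2 in row(s): ",
                               paste(bad, collapse = ", ")))
    }
    bad <- which(is.na(df$atom_pct_13C) | df$atom_pct_13C < 0 |
                   df$atom_pct_13C >= 100)
    if (length(bad)) {
      chk$problems <- c(chk$problems,
                        paste0("atom_pct_13C outside [0, 100) in row(s): ",
                               paste(bad, collapse = ", ")))
    }
  }
  .fail_schema(chk)
}

#' Write / read a generated experiment as plain CSV
#'
#' \code{write_experiment} writes \code{design.csv},
#' \code{water_chemistry.csv}, \code{plfa.csv} and \code{truth.yaml}
#' under \code{dir}; \code{read_experiment} reads and validates them
#' back.
#'
#' @param experiment an \code{isobudget_experiment}.
#' @param dir output directory (created if missing).
#' @return \code{write_experiment}: the directory, invisibly;
#'   \code{read_experiment}: a list with \code{design}, \code{water},
#'   \code{plfa} (and \code{truth} when present).
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "isobudget_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) utils::write.csv(
    df, file.path(dir, f), row.names = FALSE, na = "NA",
    fileEncoding = "UTF-8")
  wr(experiment$design, "design.csv")
  wr(experiment$water, "water_chemistry.csv")
  wr(experiment$plfa, "plfa.csv")
  tr <- experiment$truth
  tr$dic_tracer <- NULL
  tr$allocation <- lapply(tr$allocation, as.list)
  yaml::write_yaml(lapply(tr, function(x)
    if (is.numeric(x)) as.list(x) else x), file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(dir) {
  out <- list(design = read_design_table(file.path(dir, "design.csv")),
              water = read_water_chemistry(file.path(dir, "water_chemistry.csv")),
              plfa = read_plfa_table(file.path(dir, "plfa.csv")))
  ty <- file.path(dir, "truth.yaml")
  if (file.exists(ty)) out$truth <- yaml::read_yaml(ty)
  out
}

#' Serializable run configuration
#'
#' Collects every constant of a pipeline run (geometry, budget constants,
#' reference isotope ratio, seed) in one structure that round-trips
#' through YAML unchanged.
#'
#' @param geometry a [core_geometry()].
#' @param constants a [conversion_constants()].
#' @param r_std reference isotope ratio.
#' @param seed integer seed.
#' @param dic_background DIC background policy (\code{"t0"} or a number).
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(geometry = core_geometry(),
                       constants = conversion_constants(),
                       r_std = R_VPDB, seed = 1L,
                       dic_background = "t0") {
  structure(list(geometry = unclass(geometry)[c("inner_diameter",
                                                "water_volume",
                                                "sample_withdrawal")],
                 constants = unclass(constants)[c(
                   "biomarker_fraction", "plfa_c_per_biomass_c",
                   "label_atom_pct", "incubation_duration_d",
                   "biomarkers", "mixing_mode")],
                 r_std = r_std, seed = as.integer(seed),
                 dic_background = dic_background),
            class = "run_config")
}

#' @rdname run_config
#' @param config a \code{run_config}.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config(
    geometry = do.call(core_geometry, raw$geometry),
    constants = do.call(conversion_constants,
                        raw$constants[setdiff(names(raw$constants),
                                              "mixing_mode")]),
    r_std = raw$r_std, seed = raw$seed,
    dic_background = raw$dic_background)
  cfg$constants$mixing_mode <- raw$constants$mixing_mode
  cfg
}

#' Assemble the model frame for a solute's mixed-model analysis
#'
#' Areal pools (mmol m^-2) for one solute across all cores, with time in
#' days — the response/covariate layout [lme_varexp()] expects.
#'
#' @param water water-chemistry table.
#' @param solute solute name.
#' @param geometry a [core_geometry()].
#' @return Data frame: \code{core_id}, \code{treatment}, \code{time_d},
#'   \code{pool}.
#' @export
solute_model_frame <- function(water, solute, geometry = core_geometry()) {
  d <- water[water$solute == solute, ]
  if (!nrow(d)) stop("no rows for solute ", solute)
  d <- d[order(d$core_id, d$time_h), ]
  idx <- stats::ave(seq_len(nrow(d)), d$core_id, FUN = seq_along)
  data.frame(core_id = d$core_id, treatment = factor(d$treatment),
             time_d = d$time_h / 24,
             pool = areal_pool(d$conc_uM, geometry, idx),
             stringsAsFactors = FALSE)
}

#' Assemble the model frame for the substrate-derived DIC analysis
#'
#' Substrate-derived DIC pools of the labelled cores at the post-t0
#' timepoints (the t0 point defines each core's isotope background).
#'
#' @param water water-chemistry table.
#' @param design design table.
#' @param geometry a [core_geometry()].
#' @param constants a [conversion_constants()].
#' @param dic_background background policy, see [mineralization_series()].
#' @param control_label control treatment name.
#' @return Data frame: \code{core_id}, \code{treatment}, \code{time_d},
#'   \code{tracer}.
#' @export
mineralization_model_frame <- function(water, design,
                                       geometry = core_geometry(),
                                       constants = conversion_constants(),
                                       dic_background = "t0",
                                       control_label = "control") {
  labelled <- design[design$treatment != control_label, ]
  rows <- lapply(seq_len(nrow(labelled)), function(i) {
    cid <- labelled$core_id[i]
    dic <- water[water$core_id == cid & water$solute == "DIC", ]
    ser <- mineralization_series(dic$time_h, dic$conc_uM, dic$delta13C,
                                 geometry, constants, dic_background)
    ser <- ser[-1, , drop = FALSE]  # t0 is the background point
    data.frame(core_id = cid, treatment = labelled$treatment[i],
               time_d = ser$time_h / 24, tracer = ser$tracer_mmol_m2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$treatment <- factor(out$treatment)
  rownames(out) <- NULL
  out
}

#' Run the full carbon-budget analysis on an experiment
#'
#' End-to-end driver: per-core solute fluxes and their treatment
#' summaries, per-core tracer budgets and the treatment-level budget
#' report, Box-Cox/ANOVA/Tukey comparisons of uptake and BGE, the
#' proportional-uptake PCA fingerprint, and (optionally) mixed-model
#' backward selection for each solute and for the substrate-derived DIC
#' series.
#'
#' @param experiment an \code{isobudget_experiment} or a list with
#'   \code{design}, \code{water}, \code{plfa} (e.g. from
#'   [read_experiment()]).
#' @param config a [run_config()].
#' @param lme also fit the mixed models (slower).
#' @return A list of class \code{isobudget_report}: \code{rates},
#'   \code{flux_summary}, \code{budgets}, \code{budget_report},
#'   \code{group_stats}, \code{pca}, and \code{lme} when requested.
#' @export
run_report <- function(experiment, config = run_config(), lme = FALSE) {
  geom <- do.call(core_geometry, config$geometry)
  consts <- do.call(conversion_constants,
                    config$constants[setdiff(names(config$constants),
                                             "mixing_mode")])
  consts$mixing_mode <- config$constants$mixing_mode
  design <- experiment$design; water <- experiment$water
  plfa <- experiment$plfa

  rates <- per_core_rates(water, geom)
  flux_summary <- lapply(split(rates, rates$solute), summarize_rates,
                         design = design)
  budgets <- tracer_budget_table(water, plfa, design, geom, consts,
                                 config$dic_background)
  rep_tab <- budget_report(
    budgets, intersect(unique(design$treatment), unique(budgets$treatment)))

  gs <- list(uptake = group_comparison(budgets$I_B, budgets$treatment),
             bge = group_comparison(budgets$BGE, budgets$treatment))

  bg_plfa <- plfa_background(plfa, design)
  tracer <- do.call(rbind, lapply(budgets$core_id, function(cid) {
    tc <- plfa_tracer_carbon(plfa[plfa$core_id == cid, ], bg_plfa, consts)
    data.frame(core_id = cid, plfa = names(tc), tracer_mmol_m2 = unname(tc),
               stringsAsFactors = FALSE)
  }))
  pu <- proportional_uptake(tracer)
  pca <- correlation_pca(pu)

  out <- list(rates = rates, flux_summary = flux_summary,
              budgets = budgets, budget_report = rep_tab,
              group_stats = gs, proportional_uptake = pu, pca = pca,
              config = config)
  if (lme) {
    out$lme <- lapply(
      setdiff(unique(water$solute), "DIC"),
      function(s) backward_select(
        pool ~ time_d * treatment, solute_model_frame(water, s, geom),
        group = "core_id", var_time = "time_d"))
    names(out$lme) <- setdiff(unique(water$solute), "DIC")
    mm <- mineralization_model_frame(water, design, geom, consts,
                                     config$dic_background)
    out$lme$DIC_tracer <- backward_select(
      tracer ~ time_d * treatment, mm, group = "core_id",
      var_time = "time_d", var_strata = "treatment")
  }
  structure(out, class = "isobudget_report")
}

#' @export
print.isobudget_report <- function(x, ...) {
  print(x$budget_report)
  cat("\nBenthic solute fluxes (treatment mean ± SE, mmol m⁻² d⁻¹):\n")
  for (s in names(x$flux_summary)) {
    fs <- x$flux_summary[[s]]
    cat(sprintf("  %-4s %s\n", s, paste(
      sprintf("%s %.2f±%.2f", fs$treatment, fs$mean, fs$se),
      collapse = "  ")))
  }
  cat(sprintf("\nUptake ANOVA: F = %.2f, df %d,%d, p = %.4g (Box-Cox λ = %.2f)\n",
              x$group_stats$uptake$anova$F,
              x$group_stats$uptake$anova$df_between,
              x$group_stats$uptake$anova$df_within,
              x$group_stats$uptake$anova$p_value,
              x$group_stats$uptake$lambda))
  cat(sprintf("BGE    ANOVA: F = %.2f, df %d,%d, p = %.4g (Box-Cox λ = %.2f)\n",
              x$group_stats$bge$anova$F,
              x$group_stats$bge$anova$df_between,
              x$group_stats$bge$anova$df_within,
              x$group_stats$bge$anova$p_value,
              x$group_stats$bge$lambda))
  cat(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of fingerprint variance\n",
              100 * x$pca$prop_variance[1], 100 * x$pca$prop_variance[2]))
  invisible(x)
}
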