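#' Default PGLS model families for the air- and bone-volume analyses
#'
#' The air family explains log10 air volume by internal cavity volume with
#' or without body mass (only these are identifiable when nearly all divers
#' are apneumatic). The bone family crosses internal volume with body mass,
#' diving and pneumaticity up to the full model with both
#' internal-by-categorical interactions.
#'
#' @return Character vector of formula strings.
#' @export
default_air_models <- function() {
  c("air ~ internal",
    "air ~ internal + mass")
}

#' @rdname default_air_models
#' @export
default_bone_models <- function() {
  c("bone ~ internal",
    "bone ~ internal + mass",
    "bone ~ internal + diving",
    "bone ~ internal + pneumatic",
    "bone ~ internal + mass + diving",
    "bone ~ internal + mass + pneumatic",
    "bone ~ internal + diving + pneumatic",
    "bone ~ internal + mass + diving + pneumatic",
    "bone ~ internal + mass + diving + pneumatic + internal:pneumatic",
    "bone ~ internal + mass + diving + pneumatic + internal:diving",
    "bone ~ internal + mass + diving + pneumatic + internal:pneumatic + internal:diving")
}

#' Pipeline configuration
#'
#' Exactly one data source must be given: either the three input paths
#' (per-humerus volumes CSV, species side-table CSV, newick tree) or a
#' synthetic-generation block ([trait_gen_params()]).
#'
#' @param volumes_csv Path to per-humerus volumes CSV (columns
#'   `specimen_id`, `species`, `side`, `v_bone_mm3`, `v_marrow_mm3`,
#'   `v_air_mm3`).
#' @param traits_csv Path to the species side table (columns `species`,
#'   `body_mass_g`, `diving`).
#' @param tree_file Path to a newick tree.
#' @param synthetic A [trait_gen_params()] block; mutually exclusive with
#'   the input paths.
#' @param densities A [density_assumptions()].
#' @param epsilon Pneumaticity threshold on ASP_i.
#' @param air_exclude Character vector of species excluded from the
#'   air-volume model family (in addition to apneumatic species).
#' @param air_models,bone_models Formula strings for the two families.
#' @param seed Integer seed governing all randomness of a run.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(volumes_csv = NULL, traits_csv = NULL,
                            tree_file = NULL, synthetic = NULL,
                            densities = density_assumptions(),
                            epsilon = 0.001, air_exclude = character(),
                            air_models = default_air_models(),
                            bone_models = default_bone_models(),
                            seed = 1L) {
  has_paths <- !is.null(volumes_csv) || !is.null(traits_csv) ||
    !is.null(tree_file)
  has_syn <- !is.null(synthetic)
  if (has_paths == has_syn) {
    stop("exactly one of {input paths, synthetic block} must be given",
         call. = FALSE)
  }
  if (has_paths &&
      (is.null(volumes_csv) || is.null(traits_csv) || is.null(tree_file))) {
    stop("all three input paths (volumes_csv, traits_csv, tree_file) are required",
         call. = FALSE)
  }
  if (has_syn) stopifnot(inherits(synthetic, "trait_gen_params"))
  stopifnot(inherits(densities, "density_assumptions"))
  structure(list(volumes_csv = volumes_csv, traits_csv = traits_csv,
                 tree_file = tree_file, synthetic = synthetic,
                 densities = densities, epsilon = epsilon,
                 air_exclude = air_exclude, air_models = air_models,
                 bone_models = bone_models, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognized keys mirror the [pipeline_config()] arguments; a `synthetic`
#' mapping is passed to [trait_gen_params()] and a `densities` mapping to
#' [density_assumptions()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$synthetic)) {
    raw$synthetic <- do.call(trait_gen_params, raw$synthetic)
  }
  if (!is.null(raw$densities)) {
    raw$densities <- do.call(density_assumptions, raw$densities)
  }
  do.call(pipeline_config, raw)
}

# drop models whose categorical predictors are constant in the fitting
# subset (e.g. an all-apneumatic cohort): they would be rank deficient
.viable_formulas <- function(model_strings, data, say, family_name) {
  forms <- lapply(model_strings, stats::as.formula)
  keep <- vapply(forms, function(f) {
    vars <- all.vars(f)[-1]
    all(vapply(vars, function(v) {
      col <- data[[v]]
      is.numeric(col) || length(unique(col)) > 1L
    }, logical(1)))
  }, logical(1))
  if (any(!keep)) {
    say("%s: dropped %d of %d models with constant categorical predictors",
        family_name, sum(!keep), length(forms))
  }
  forms[keep]
}

# analysis table on the log10 scale from a species metrics table
.analysis_table <- function(sp) {
  data.frame(
    species = sp$species,
    internal = log10(sp$v_marrow_mm3 + sp$v_air_mm3),
    bone = log10(sp$v_bone_mm3),
    air = ifelse(sp$pneumatic & sp$v_air_mm3 > 0, log10(sp$v_air_mm3),
                 NA_real_),
    mass = log10(sp$body_mass_g),
    diving = sp$diving,
    pneumatic = sp$pneumatic,
    stringsAsFactors = FALSE
  )
}

#' Run the full pneumaticity pipeline
#'
#' Orchestrates one deterministic run: load (or simulate) per-humerus
#' volumes, a species side table and a tree; aggregate to species metrics;
#' fit the bone-volume model family on complete cases and the air-volume
#' family on pneumatic species minus the exclusion list; compute BTI from
#' the null bone model; summarize. Every filter is logged with
#' before/after counts, to stderr and to `run.log` in `out_dir`. All
#' tables are written as CSV, the summary and a provenance block (config
#' hash, package version, seed) as JSON.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides `config$seed` when non-`NULL`.
#' @return Invisibly, a list of class `"pneum_pipeline"` with elements
#'   `species`, `analysis`, `bone_table`, `air_table` (or `NULL` if the
#'   family was skipped), `bti`, `summary`, `tree`, `log`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    message("[pneumaticity] ", line)
    log_lines <<- c(log_lines, line)
  }

  if (!is.null(config$synthetic)) {
    params <- config$synthetic
    params$seed <- config$seed
    tree <- simulate_tree(params$n_tips, params$birth_rate,
                          seed = config$seed)
    sim <- simulate_traits(tree, params)
    rec <- traits_to_records(sim$traits)
    records <- rec$records
    side_table <- rec$side_table
    say("simulated %d species under seed %d", params$n_tips, config$seed)
  } else {
    records <- read.csv(config$volumes_csv, stringsAsFactors = FALSE)
    side_table <- read.csv(config$traits_csv, stringsAsFactors = FALSE)
    side_table$diving <- as.logical(side_table$diving)
    tree <- read_phylogeny(config$tree_file,
                           taxa = unique(records$species))
    say("read %d humerus records for %d species", nrow(records),
        length(unique(records$species)))
  }

  sp <- aggregate_species(records, side_table, d = config$densities,
                          epsilon = config$epsilon)
  say("aggregated %d records into %d species rows", nrow(records), nrow(sp))
  an <- .analysis_table(sp)

  # bone family: complete cases over the union of bone-model variables
  bone_vars <- unique(unlist(lapply(config$bone_models,
                                    function(s) all.vars(stats::as.formula(s)))))
  n_before <- nrow(an)
  bone_ok <- rep(TRUE, nrow(an))
  for (v in bone_vars) {
    col <- an[[v]]
    bone_ok <- bone_ok & (if (is.numeric(col)) is.finite(col) else !is.na(col))
  }
  say("bone family: %d -> %d complete-case species", n_before,
      sum(bone_ok))
  bone_forms <- .viable_formulas(config$bone_models, an[bone_ok, ],
                                 say, "bone family")
  bone_table <- compare_models(bone_forms, an[bone_ok, ], tree)

  # air family: pneumatic species with air, minus the exclusion list
  air_sub <- an[an$pneumatic & !is.na(an$air) &
                  !(an$species %in% config$air_exclude), , drop = FALSE]
  say("air family: %d pneumatic species retained of %d (%d excluded by list)",
      nrow(air_sub), sum(an$pneumatic),
      sum(an$species %in% config$air_exclude))
  air_table <- NULL
  if (nrow(air_sub) >= 5) {
    air_forms <- .viable_formulas(config$air_models, air_sub,
                                  say, "air family")
    air_table <- compare_models(air_forms, air_sub, tree)
  } else {
    say("air family skipped: only %d species with measurable air volume",
        nrow(air_sub))
  }

  bti <- compute_bti(an[bone_ok, ], tree)
  summ <- summarize_cohort(sp, bti = bti)

  # artifacts
  write.csv(sp, file.path(out_dir, "species_metrics.csv"), row.names = FALSE)
  write.csv(model_table_terms(bone_table),
            file.path(out_dir, "model_table_bone.csv"), row.names = FALSE)
  if (!is.null(air_table)) {
    write.csv(model_table_terms(air_table),
              file.path(out_dir, "model_table_air.csv"), row.names = FALSE)
  }
  bti_df <- data.frame(species = names(bti), bti = as.numeric(bti),
                       stringsAsFactors = FALSE)
  bti_df <- merge(bti_df, an[c("species", "diving", "pneumatic")],
                  by = "species", sort = TRUE)
  write.csv(bti_df, file.path(out_dir, "bti.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(summ), file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg_json <- jsonlite::toJSON(.config_fingerprint(config), auto_unbox = TRUE,
                               digits = NA)
  tmp <- file.path(out_dir, "config.json")
  writeLines(cfg_json, tmp)
  prov <- list(config_md5 = unname(tools::md5sum(tmp)),
               package_version = as.character(utils::packageVersion("pneumaticity")),
               seed = config$seed)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(structure(
    list(species = sp, analysis = an, bone_table = bone_table,
         air_table = air_table, bti = bti, summary = summ, tree = tree,
         log = log_lines),
    class = "pneum_pipeline"
  ))
}

.config_fingerprint <- function(config) {
  x <- unclass(config)
  x$synthetic <- if (!is.null(x$synthetic)) unclass(x$synthetic)
  x$densities <- unclass(x$densities)
  x
}

#' Summarize a species-level pneumaticity table
#'
#' Counts pneumatic and apneumatic species; reports ASP_i and ASP_t range
#' and mean over pneumatic species (whole percent, with the argmin/argmax
#' species), bulk density range and mean by pneumatic class (2 d.p.), and,
#' when BTI values are supplied, BTI means by pneumatic class and by diving
#' class.
#'
#' @param sp Species table from [aggregate_species()].
#' @param bti Optional named BTI vector from [compute_bti()].
#' @return A list of class `"cohort_summary"`.
#' @export
summarize_cohort <- function(sp, bti = NULL) {
  pn <- sp$pneumatic
  stat_pct <- function(v, names) {
    v <- v * 100
    list(min = round(min(v), 0), max = round(max(v), 0),
         mean = round(mean(v), 0),
         argmin = names[which.min(v)], argmax = names[which.max(v)])
  }
  stat_den <- function(v) {
    if (!length(v)) return(NULL)
    list(min = round(min(v), 2), max = round(max(v), 2),
         mean = round(mean(v), 2))
  }
  asp_sub <- pn & !is.na(sp$asp_i)
  out <- list(
    n_species = nrow(sp),
    n_pneumatic = sum(pn),
    n_apneumatic = sum(!pn),
    asp_i_pct = if (any(asp_sub)) stat_pct(sp$asp_i[asp_sub],
                                           sp$species[asp_sub]),
    asp_t_pct = if (any(asp_sub)) stat_pct(sp$asp_t[asp_sub],
                                           sp$species[asp_sub]),
    density_pneumatic = stat_den(sp$bulk_density_g_cm3[pn]),
    density_apneumatic = stat_den(sp$bulk_density_g_cm3[!pn])
  )
  if (!is.null(bti)) {
    idx <- match(names(bti), sp$species)
    bpn <- sp$pneumatic[idx]
    bdv <- sp$diving[idx]
    m <- function(v) if (length(v)) round(mean(v), 2) else NULL
    out$bti <- list(
      mean_pneumatic = m(bti[bpn]), mean_apneumatic = m(bti[!bpn]),
      mean_diving = m(bti[bdv]), mean_nondiving = m(bti[!bdv]),
      min = round(min(bti), 2), max = round(max(bti), 2)
    )
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d species (%d pneumatic, %d apneumatic)\n",
              x$n_species, x$n_pneumatic, x$n_apneumatic))
  if (!is.null(x$asp_i_pct)) {
    cat(sprintf("  ASP_i: %d%% (%s) to %d%% (%s), mean %d%%\n",
                x$asp_i_pct$min, x$asp_i_pct$argmin,
                x$asp_i_pct$max, x$asp_i_pct$argmax, x$asp_i_pct$mean))
    cat(sprintf("  ASP_t: %d%% to %d%%, mean %d%%\n",
                x$asp_t_pct$min, x$asp_t_pct$max, x$asp_t_pct$mean))
  }
  if (!is.null(x$density_pneumatic)) {
    cat(sprintf("  bulk density, pneumatic: %.2f-%.2f, mean %.2f g/cm^3\n",
                x$density_pneumatic$min, x$density_pneumatic$max,
                x$density_pneumatic$mean))
  }
  if (!is.null(x$density_apneumatic)) {
    cat(sprintf("  bulk density, apneumatic: %.2f-%.2f, mean %.2f g/cm^3\n",
                x$density_apneumatic$min, x$density_apneumatic$max,
                x$density_apneumatic$mean))
  }
  if (!is.null(x$bti)) {
    cat(sprintf("  BTI mean: pneumatic %.2f, apneumatic %.2f; diving %.2f, non-diving %.2f\n",
                x$bti$mean_pneumatic, x$bti$mean_apneumatic,
                x$bti$mean_diving, x$bti$mean_nondiving))
  }
  invisible(x)
}
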