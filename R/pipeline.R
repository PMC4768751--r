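#' Read a phenotype table from CSV
#'
#' Expects columns `id`, `environment`, `block`, and one column per trait.
#' Environment labels are validated against `env_labels`; unknown labels are
#' an error unless `normalize_case = TRUE`, in which case case-insensitive
#' matches are normalized.
#'
#' @param path Path to a CSV file.
#' @param env_labels Allowed environment labels, in display order.
#' @param traits Trait column names expected to be numeric.
#' @param normalize_case Normalize environment labels case-insensitively.
#' @return A tibble with `environment` as a factor over `env_labels`.
#' @export
read_phenotypes <- function(path,
                            env_labels = c("ripe", "unripe", "none"),
                            traits = c("body_mass_mg", "femur_area_mm2",
                                       "testis_mass_mg"),
                            normalize_case = FALSE) {
  header <- names(readr::read_csv(path, n_max = 0, comment = "#",
                                  show_col_types = FALSE))
  char_cols <- intersect(c("id", "environment", "block", "sire", "dam"), header)
  spec <- do.call(readr::cols,
                  c(stats::setNames(rep(list(readr::col_character()),
                                        length(char_cols)), char_cols),
                    list(.default = readr::col_double())))
  raw <- readr::read_csv(path, col_types = spec, comment = "#", progress = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    stop("malformed phenotype row(s) at line(s): ",
         paste(utils::head(unique(probs$row), 10), collapse = ", "),
         " in ", path, call. = FALSE)
  }
  need <- c("id", "environment")
  if (!all(need %in% names(raw))) {
    stop("phenotype file must have columns id, environment: ", path, call. = FALSE)
  }
  env <- raw$environment
  if (normalize_case) {
    hit <- match(tolower(env), tolower(env_labels))
    if (anyNA(hit)) {
      stop("unknown environment label(s): ",
           paste(unique(env[is.na(hit)]), collapse = ", "), call. = FALSE)
    }
    env <- env_labels[hit]
  } else if (!all(env %in% env_labels)) {
    stop("unknown environment label(s): ",
         paste(setdiff(unique(env), env_labels), collapse = ", "),
         "; expected ", paste(env_labels, collapse = ", "), call. = FALSE)
  }
  raw$environment <- factor(env, levels = env_labels)
  if ("block" %in% names(raw)) raw$block <- factor(raw$block)
  raw
}

#' Pipeline configuration
#'
#' A single configuration object driving [run_pipeline()]. In `synthetic`
#' mode a dataset is simulated from `design` and `truth`; in `analysis` mode
#' the pedigree and phenotype CSVs at `pedigree_path` / `phenotype_path` are
#' read.
#'
#' @param mode `"synthetic"` or `"analysis"`.
#' @param out_dir Output directory for the report bundle.
#' @param pedigree_path,phenotype_path Input CSVs (analysis mode).
#' @param traits Named trait columns (`body`, `femur`, `testis`).
#' @param env_labels Environment labels in display order.
#' @param seed Integer seed (required in synthetic mode).
#' @param design A [design_config()] (synthetic mode; defaults to the study
#'   design).
#' @param truth Named list of [true_params()] per trait (synthetic mode;
#'   defaults to [default_trait_params()]).
#' @param reml Options passed to [reml_fit()] (`max_iter`, `em_iters`,
#'   `tol_loglik`, `tol_grad`).
#' @param screening_threshold Interaction-retention threshold for the
#'   allometry ANCOVAs.
#' @param digits Rounding for the rendered report tables.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "analysis"),
                            out_dir,
                            pedigree_path = NULL, phenotype_path = NULL,
                            traits = c(body = "body_mass_mg",
                                       femur = "femur_area_mm2",
                                       testis = "testis_mass_mg"),
                            env_labels = c("ripe", "unripe", "none"),
                            seed = NULL,
                            design = NULL, truth = NULL,
                            reml = list(), screening_threshold = 0.20,
                            digits = 2) {
  mode <- match.arg(mode)
  if (mode == "synthetic") {
    if (is.null(seed)) stop("synthetic mode requires a seed", call. = FALSE)
    if (is.null(design)) design <- design_config(env_labels = env_labels)
    if (is.null(truth)) truth <- default_trait_params()
  } else {
    if (is.null(pedigree_path) || is.null(phenotype_path)) {
      stop("analysis mode requires pedigree_path and phenotype_path", call. = FALSE)
    }
    for (p in c(pedigree_path, phenotype_path)) {
      if (!file.exists(p)) stop("input file does not exist: ", p, call. = FALSE)
    }
  }
  structure(list(mode = mode, out_dir = out_dir,
                 pedigree_path = pedigree_path,
                 phenotype_path = phenotype_path,
                 traits = traits, env_labels = env_labels, seed = seed,
                 design = design, truth = truth, reml = reml,
                 screening_threshold = screening_threshold, digits = digits),
            class = "pipeline_config")
}

# hash only the scientific configuration, not filesystem locations, so that
# identical analyses produce identical (byte-comparable) outputs anywhere
config_hash <- function(cfg) {
  x <- unclass(cfg)
  x$out_dir <- NULL
  x$pedigree_path <- NULL
  x$phenotype_path <- NULL
  rlang::hash(x)
}

write_report_csv <- function(df, path, hash) {
  body <- readr::format_csv(df)
  writeLines(c(paste0("# config_hash: ", hash),
               sub("\n$", "", body)), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (optional) simulation of a half-sib split-brood
#' dataset; a REML animal-model fit per trait; the per-environment genetic
#' summary (means, V_A, V_P, CV_A, heritability with SE, I_A); and the
#' trait-expression/allometry battery on the log scale. Writes a report
#' bundle to `cfg$out_dir`: `genetic_summary.csv`, `scaling_tests.csv`,
#' `adjusted_means.csv`, `blups_<trait>.csv`, `fit_<trait>.json`,
#' `run_metadata.json`, and `run_log.txt`. All CSV outputs carry the config
#' hash in a header comment and are byte-identical across repeat runs with
#' the same configuration and seed.
#'
#' Individuals with a missing trait value are dropped from that trait's fit
#' only. Individuals with a non-positive trait value are excluded (with a
#' warning) from the log-scale battery only.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the simulated or loaded data, the fits, the
#'   genetic summary, the battery, and the output paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  t0 <- Sys.time()
  log_lines <- c(paste0("config_hash: ", hash),
                 paste0("mode: ", cfg$mode),
                 paste0("R version: ", R.version.string),
                 paste0("started: ", format(t0, usetz = TRUE)))
  stage <- function(msg) log_lines <<- c(log_lines, paste0("[", msg, "]"))

  if (cfg$mode == "synthetic") {
    stage("simulate")
    cfg$design$seed <- cfg$seed
    sim <- simulate_breeding_design(cfg$design, cfg$truth)
    ped <- sim$pedigree
    pheno <- sim$phenotypes
  } else {
    stage("load")
    ped <- read_pedigree(cfg$pedigree_path)
    pheno <- read_phenotypes(cfg$phenotype_path, env_labels = cfg$env_labels,
                             traits = unname(cfg$traits))
    orphan <- setdiff(pheno$id, ped$id)
    if (length(orphan)) {
      stop("phenotype id(s) absent from the pedigree: ",
           paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
    }
    sim <- NULL
  }
  log_lines <- c(log_lines,
                 paste0("individuals: ", nrow(pheno), "; pedigree: ", nrow(ped)))

  stage("fit")
  fits <- list()
  for (tr in unname(cfg$traits)) {
    args <- c(list(data = pheno, pedigree = ped, trait = tr), cfg$reml)
    fit <- do.call(reml_fit, args)
    fits[[tr]] <- fit
    log_lines <- c(log_lines,
                   paste0("  ", tr, ": logLik = ", format(fit$reml_loglik, digits = 10),
                          ", iterations = ", fit$convergence$iterations,
                          if (any(fit$boundary)) " [boundary]" else ""))
  }

  stage("summarize")
  gsum <- genetic_summary(fits, pheno)

  stage("scaling")
  pos <- rep(TRUE, nrow(pheno))
  for (tr in unname(cfg$traits)) {
    v <- pheno[[tr]]
    pos <- pos & (is.na(v) | v > 0)
  }
  if (any(!pos)) {
    warning(sum(!pos), " individual(s) with non-positive trait values ",
            "excluded from the log-scale scaling battery", call. = FALSE)
    log_lines <- c(log_lines, paste0("  excluded non-positive rows: ", sum(!pos)))
  }
  battery <- scaling_battery(pheno[pos, , drop = FALSE], traits = cfg$traits,
                             screening_threshold = cfg$screening_threshold)

  stage("write")
  paths <- list()
  paths$genetic_summary <- write_report_csv(
    format_genetic_summary(gsum, cfg$digits),
    file.path(cfg$out_dir, "genetic_summary.csv"), hash)
  paths$scaling_tests <- write_report_csv(
    dplyr::mutate(battery$table, dplyr::across(c(F, p), ~ signif(.x, 6))),
    file.path(cfg$out_dir, "scaling_tests.csv"), hash)
  adj <- purrr::imap_dfr(battery$ancovas, function(a, nm) {
    dplyr::mutate(dplyr::left_join(a$adjusted_means, a$letters, by = "group"),
                  model = nm, .before = 1)
  })
  paths$adjusted_means <- write_report_csv(
    dplyr::mutate(adj, dplyr::across(c(mean, se), ~ signif(.x, 6))),
    file.path(cfg$out_dir, "adjusted_means.csv"), hash)
  for (tr in unname(cfg$traits)) {
    fit <- fits[[tr]]
    paths[[paste0("blups_", tr)]] <- write_report_csv(
      dplyr::mutate(fit$blups, blup = signif(blup, 8)),
      file.path(cfg$out_dir, paste0("blups_", tr, ".csv")), hash)
    fitjson <- list(
      trait = tr,
      config_hash = hash,
      components = list(G = unclass(fit$components$G),
                        sigma2_e = fit$components$sigma2_e),
      reml_loglik = fit$reml_loglik,
      vcov_components = unclass(fit$vcov_components),
      fixed_effects = fit$fixed_effects,
      convergence = fit$convergence[c("iterations", "final_gradient_norm",
                                      "em_iterations")],
      boundary = as.list(fit$boundary)
    )
    jp <- file.path(cfg$out_dir, paste0("fit_", tr, ".json"))
    jsonlite::write_json(fitjson, jp, digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor")
    paths[[paste0("fit_", tr)]] <- jp
  }
  meta <- list(config_hash = hash, mode = cfg$mode, seed = cfg$seed,
               traits = as.list(cfg$traits), env_labels = cfg$env_labels,
               n_individuals = nrow(pheno), n_pedigree = nrow(ped))
  jsonlite::write_json(meta, file.path(cfg$out_dir, "run_metadata.json"),
                       digits = NA, auto_unbox = TRUE)
  log_lines <- c(log_lines,
                 paste0("finished: ", format(Sys.time(), usetz = TRUE)),
                 paste0("elapsed_s: ",
                        round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)))
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))

  invisible(list(pedigree = ped, phenotypes = pheno, simulation = sim,
                 fits = fits, genetic_summary = gsum, battery = battery,
                 paths = paths, config_hash = hash))
}

#' Write simulated data as the pipeline's CSV interchange files
#'
#' Writes `pedigree.csv` (`id,sire,dam`, unknown parents empty),
#' `phenotypes.csv`, and a `truth.json` sidecar recording the simulation's
#' true parameters for recovery tests.
#'
#' @param sim A [simulate_breeding_design()] result.
#' @param dir Output directory.
#' @return Invisibly, the file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pedp <- file.path(dir, "pedigree.csv")
  readr::write_csv(tibble::as_tibble(sim$pedigree), pedp, na = "")
  phenop <- file.path(dir, "phenotypes.csv")
  readr::write_csv(sim$phenotypes, phenop, na = "")
  truths <- if (inherits(sim$truth, "true_params")) list(value = sim$truth) else sim$truth
  truth_json <- purrr::map(truths, function(tp) {
    list(G = unclass(tp$G), sigma2_e = tp$sigma2_e,
         env_means = tp$env_means, block_effects = tp$block_effects)
  })
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(truth_json, tp, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(list(pedigree = pedp, phenotypes = phenop, truth = tp))
}
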