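# End-to-end orchestration: backbone -> intra-TAD models -> assembly ->
# evaluation, with all intermediates written as plain-text files so each
# stage can be re-run independently.

#' Build a run configuration
#'
#' @param seed Global seed; every stage derives its own seed from it, so
#'   one seed fully determines all outputs.
#' @param out_dir Output directory.
#' @param lambda_E_backbone,lambda_F,lambda_E_tad,lambda_R Term weights.
#'   The defaults are the published values for raw-count Hi-C input;
#'   they are scale-dependent and should be re-selected (see
#'   [tune_lambda()]) or set explicitly for inputs on other count
#'   scales, e.g. the unit-scale synthetic bundles.
#' @param resolution Intra-TAD bin size (bp).
#' @param opt Named list overriding [optimizer_config()] fields.
#' @param assembly Named list overriding [assembly_params()] fields
#'   (`c` and `beta` are always refit from the FISH data).
#' @param inputs Named list of input file paths: `tad_contacts`,
#'   `full_contacts`, `intra_contacts` (vector of paths in TAD order),
#'   `tads`, `fish`, optional `target_rg` (CSV with columns tad,rg) and
#'   `labels` (CSV with columns tad,label).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, out_dir = "chromfold_out",
                       lambda_E_backbone = lambda_defaults()$backbone[["lambda_E"]],
                       lambda_F = lambda_defaults()$backbone[["lambda_F"]],
                       lambda_E_tad = lambda_defaults()$tad[["lambda_E"]],
                       lambda_R = lambda_defaults()$tad[["lambda_R"]],
                       resolution = 5000, opt = list(),
                       assembly = list(), inputs = list()) {
  structure(list(seed = seed, out_dir = out_dir,
                 lambda_E_backbone = lambda_E_backbone,
                 lambda_F = lambda_F, lambda_E_tad = lambda_E_tad,
                 lambda_R = lambda_R, resolution = resolution,
                 opt = opt, assembly = assembly, inputs = inputs),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Write a resolved run configuration to YAML
#' @param config A `run_config`.
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Load the input bundle named by config$inputs from disk.
load_run_inputs <- function(config) {
  ip <- config$inputs
  need <- c("tad_contacts", "tads", "fish")
  missing <- setdiff(need, names(ip))
  if (length(missing) > 0) {
    abort(paste("missing input paths:", paste(missing, collapse = ", ")))
  }
  out <- list(
    tad_contacts = read_contact_map(ip$tad_contacts),
    tads = read_tads(ip$tads),
    fish = read_fish_matrix(ip$fish))
  if (!is.null(ip$full_contacts)) {
    out$full_contacts <- read_contact_map(ip$full_contacts,
                                          resolution = config$resolution)
  }
  if (!is.null(ip$intra_contacts)) {
    out$intra_contacts <- lapply(ip$intra_contacts, read_contact_map,
                                 resolution = config$resolution)
  }
  if (!is.null(ip$target_rg)) {
    df <- readr::read_csv(ip$target_rg, show_col_types = FALSE)
    out$target_rg <- df$rg[order(df$tad)]
  }
  if (!is.null(ip$labels)) {
    df <- readr::read_csv(ip$labels, show_col_types = FALSE)
    out$labels <- df$label[order(df$tad)]
  }
  out
}

#' Run the full reconstruction pipeline
#'
#' Stages: (1) TAD-level backbone embedding; (2) independent intra-TAD
#' models with radius-of-gyration targets from the FISH power law (or
#' user-supplied overrides); (3) rigid-body assembly; (4) evaluation.
#' All outputs (backbone CSV, per-TAD CSVs, final model CSV and PDB,
#' evaluation report, resolved configuration) are written under
#' `config$out_dir`.
#'
#' @param inputs A list as produced by [simulate_inputs()] or
#'   [load_run_inputs()]; when `NULL`, loaded from the paths in
#'   `config$inputs`.
#' @param config A [run_config()].
#' @return Invisibly, a list with the stage results: `backbone`,
#'   `tad_fits`, `assembly`, `report`, `powerlaw`.
#' @export
run_pipeline <- function(inputs = NULL, config = run_config()) {
  if (is.null(inputs)) inputs <- load_run_inputs(config)
  if (inherits(inputs$truth, "chromfold_truth") &&
      is.null(inputs$labels)) {
    inputs$labels <- inputs$truth$labels
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  opt <- do.call(optimizer_config,
                 modifyList(list(seed = config$seed), config$opt))

  # stage 1: backbone
  backbone <- fit_backbone(inputs$tad_contacts, inputs$fish,
                           lambda_E = config$lambda_E_backbone,
                           lambda_F = config$lambda_F,
                           opt = opt, tads = inputs$tads)
  write_conformation(backbone$conformation,
                     file.path(config$out_dir, "backbone.csv"))

  powerlaw <- fit_distance_powerlaw(inputs$fish, inputs$tads)
  result <- list(backbone = backbone, powerlaw = powerlaw)

  # stage 2: intra-TAD models
  if (!is.null(inputs$intra_contacts)) {
    lengths <- inputs$tads$end - inputs$tads$start
    target_rg <- if (!is.null(inputs$target_rg)) inputs$target_rg
                 else estimate_target_rg(lengths, powerlaw)
    tad_opt <- opt
    tad_opt$seed <- opt$seed + 1000L
    tad_fits <- fit_all_tads(inputs$intra_contacts, target_rg,
                             lambda_E = config$lambda_E_tad,
                             lambda_R = config$lambda_R, opt = tad_opt)
    for (i in seq_along(tad_fits)) {
      write_conformation(tad_fits[[i]]$conformation,
                         file.path(config$out_dir,
                                   sprintf("tad_%03d.csv", i)))
    }
    result$tad_fits <- tad_fits

    # stage 3: assembly
    ap <- do.call(assembly_params,
                  modifyList(list(c = powerlaw$c, beta = powerlaw$beta),
                             config$assembly))
    assembly <- assemble_chromosome(
      backbone, tad_fits, contacts = inputs$full_contacts,
      tads = inputs$tads, resolution = config$resolution, params = ap)
    write_conformation(assembly$conformation,
                       file.path(config$out_dir, "final_model.csv"))
    write_conformation(assembly$conformation,
                       file.path(config$out_dir, "final_model.pdb"),
                       format = "pdb")
    result$assembly <- assembly
    eval_conf <- assembly$conformation
  } else {
    eval_conf <- backbone$conformation
  }

  # stage 4: evaluation
  report <- evaluate_model(eval_conf, inputs$fish, tads = inputs$tads,
                           contacts = inputs$tad_contacts,
                           reference_labels = inputs$labels)
  readr::write_csv(report$summary,
                   file.path(config$out_dir, "report.csv"))
  re_out <- as.data.frame(report$re)
  names(re_out) <- paste0("tad_", seq_len(ncol(re_out)))
  readr::write_csv(re_out, file.path(config$out_dir, "re_matrix.csv"))
  result$report <- report

  write_run_config(config, file.path(config$out_dir, "config_used.yaml"))
  invisible(result)
}
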