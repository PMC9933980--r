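# End-to-end pipeline: simulate -> preprocess -> index -> select -> grid
# -> report, with a validated config, derived per-stage seeds and a run
# manifest carrying content digests.

pipeline_stages <- c("design", "biochemistry", "spectra", "preprocess",
                     "ltri", "select", "grid")

#' Pipeline configuration
#'
#' Nested stage configuration with validation-first semantics: unknown
#' keys anywhere in the structure are rejected before any stage runs. One
#' global seed deterministically derives independent per-stage seeds.
#'
#' @param seed global seed.
#' @param out_dir output directory for stage artifacts and the manifest.
#' @param simulate list: `n_plants_per_cell`, `cultivars`.
#' @param preprocess list passed to [preprocess_config()].
#' @param select list: `methods` (subset of NONE/SPA/CARS/UVE) and
#'   overrides for [selection_config()].
#' @param grid list: `indices`, `band_methods`, `families`, `k` folds,
#'   `selection` mode, `model_params` overrides.
#' @param verbosity 0 silent, 1 stage messages.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("frostspec_run_"),
                            simulate = list(), preprocess = list(),
                            select = list(), grid = list(), verbosity = 0L) {
  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown)) {
      stopf("config error: unknown key(s) in %s: %s", where,
            paste(unknown, collapse = ", "))
    }
  }
  check_keys(simulate, c("n_plants_per_cell", "cultivars"), "simulate")
  check_keys(preprocess, names(formals(preprocess_config)), "preprocess")
  check_keys(select, c("methods", names(formals(selection_config))), "select")
  check_keys(grid, c("indices", "band_methods", "families", "k",
                     "selection", "model_params"), "grid")
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulate = simulate, preprocess = preprocess,
                 select = select, grid = grid,
                 verbosity = as.integer(verbosity)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the seven stages in order (design, biochemistry, spectra,
#' preprocessing, index construction, band selection, model grid), writing
#' each intermediate artifact under the configured output directory plus a
#' manifest JSON recording per-stage seeds and MD5 digests of every output.
#' Reruns with the same config produce identical digests.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbosity > 0) message(sprintf(...))
  seeds <- vapply(pipeline_stages, function(s) derive_seed(config$seed, s), integer(1))
  artifacts <- list()
  add <- function(stage, path) {
    artifacts[[stage]] <<- c(artifacts[[stage]], path)
  }
  run_stage <- function(stage, fn) {
    say("stage %s", stage)
    tryCatch(fn(), error = function(e) {
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }

  gen <- generator_config(seed = seeds[["biochemistry"]])
  design <- run_stage("design", function() {
    d <- do.call(generate_design, config$simulate)
    f <- file.path(config$out_dir, "design.csv")
    write.csv(d, f, row.names = FALSE); add("design", f)
    d
  })
  records <- run_stage("biochemistry", function() {
    r <- simulate_biochemistry(design, gen, seed = seeds[["biochemistry"]])
    f <- file.path(config$out_dir, "biochemistry.csv")
    write.csv(r, f, row.names = FALSE); add("biochemistry", f)
    r
  })
  spectra <- run_stage("spectra", function() {
    s <- simulate_spectra(records, gen, seed = seeds[["spectra"]])
    f <- file.path(config$out_dir, "spectra.csv")
    write_spectra(s, f); add("spectra", f)
    s
  })
  pre <- run_stage("preprocess", function() {
    p <- preprocess_chain(spectra, do.call(preprocess_config, config$preprocess))
    f <- file.path(config$out_dir, "preprocessed.csv")
    write_spectra(p, f); add("preprocess", f)
    p
  })
  records <- run_stage("ltri", function() {
    model <- build_ltri(records[, biochem_vars])
    scored <- compute_ltri(records, model$weights, model$standardizer)
    f <- file.path(config$out_dir, "ltri_coefficients.csv")
    write.csv(data.frame(variable = names(model$weights) %||% biochem_vars,
                         composite = model$csc, weight = model$weights),
              f, row.names = FALSE)
    writeLines(ltri_equation(stats::setNames(model$weights, biochem_vars)),
               file.path(config$out_dir, "ltri_equation.txt"))
    add("ltri", f)
    add("ltri", file.path(config$out_dir, "ltri_equation.txt"))
    scored
  })
  sel_cfg <- do.call(selection_config,
                     config$select[setdiff(names(config$select), "methods")])
  methods <- config$select$methods %||% c("SPA", "CARS", "UVE")
  subsets <- run_stage("select", function() {
    out <- list()
    for (m in methods) {
      sub <- select_bands(pre, records$ltri, m, sel_cfg,
                          seed = derive_seed(seeds[["select"]], m))
      f <- file.path(config$out_dir, sprintf("subset_%s.json", tolower(m)))
      write_band_subset(sub, f); add("select", f)
      out[[m]] <- sub
    }
    out
  })
  grid <- run_stage("grid", function() {
    g <- config$grid
    targets <- cbind(records[, biochem_vars], LTRI = records$ltri)
    names(targets) <- c(unname(biochem_names), "LTRI")
    gr <- run_grid(pre, targets,
                   indices = g$indices %||% "LTRI",
                   band_methods = g$band_methods %||% c("NONE", "SPA"),
                   families = g$families %||% c("PLS", "SVM", "RF"),
                   cv_plan = make_cv_plan(nrow(pre), g$k %||% 5L,
                                          seed = seeds[["grid"]]),
                   sel_config = sel_cfg,
                   model_params = g$model_params %||% list(),
                   selection = g$selection %||% "per_fold",
                   seed = seeds[["grid"]])
    f <- file.path(config$out_dir, "grid_results.csv")
    write.csv(as.data.frame(gr), f, row.names = FALSE); add("grid", f)
    writeLines(grid_report(gr), file.path(config$out_dir, "report.md"))
    add("grid", file.path(config$out_dir, "report.md"))
    gr
  })

  manifest <- list(
    seed = config$seed,
    stage_seeds = as.list(seeds),
    stages = lapply(artifacts, function(paths) {
      lapply(paths, function(p) list(path = basename(p),
                                     md5 = unname(tools::md5sum(p))))
    })
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
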