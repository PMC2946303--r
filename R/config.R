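#' Default run configuration
#'
#' Single source of defaults for pipeline runs, mirroring the reference
#' analysis settings: map threshold P <= 0.001, vicinity and prediction
#' thresholds P <= 0.01 with a minimal overlap of 2, entity filters of
#' at least five causal genes per disease and five disease links per
#' gene, 200000 random gene sets for disease-side models and 100000 for
#' gene-side models, 20 cross-validation rounds removing 5 genes, and
#' restart probability 0.75 for the random walk.
#'
#' @param ... Named overrides, nested lists merged recursively (e.g.
#'   `thresholds = list(p_map = 0.01)`).
#' @return A `run_config` list with sections `paths`, `thresholds`,
#'   `sampling`, `cv`, `rwr`, `synthetic`.
#' @export
run_config <- function(...) {
  base <- list(
    paths = list(out_dir = ".", associations = NULL, go_map = NULL,
                 network = NULL, clusters = NULL, truth = NULL),
    thresholds = list(p_map = 0.001, p_vicinity = 0.01, p_predict = 0.01,
                      min_overlap = 2L, min_disease_genes = 5L,
                      min_gene_diseases = 5L),
    sampling = list(n_sets_disease = 200000L, n_sets_gene = 100000L,
                    seed = 1L, chunk_size = 20000L),
    cv = list(rounds = 20L, remove = 5L),
    rwr = list(restart = 0.75, tol = 1e-6, max_iter = 10000L),
    synthetic = list(n_diseases = 200L, n_genes = 1000L,
                     power_law_exponent = 1.8, max_degree = 78L,
                     background_edge_rate = 0, seed = 1L)
  )
  over <- list(...)
  cfg <- utils::modifyList(base, over)
  th <- cfg$thresholds
  stopifnot(th$p_map > 0, th$p_map <= 1, th$p_vicinity > 0, th$p_vicinity <= 1,
            th$p_predict > 0, th$p_predict <= 1, th$min_overlap >= 1,
            th$min_disease_genes >= 1, th$min_gene_diseases >= 1,
            cfg$rwr$restart > 0, cfg$rwr$restart < 1)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a YAML/JSON file with (a subset of) the
#'   [run_config()] sections; unspecified fields take the defaults.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Read fitted models back from their JSON serialization
#'
#' Reconstructs an `overlap_models` object (coefficients, valid ranges,
#' entity sets) from [write_models()] output plus the table the models
#' were fitted on; regression points and candidate tables are not
#' retained.
#'
#' @param path JSON path written by [write_models()].
#' @param table The `assoc_tbl` the models were fitted on (supplies the
#'   entity sets).
#' @return An `overlap_models` object.
#' @export
read_models <- function(path, table) {
  raw <- jsonlite::read_json(path)
  models <- list()
  sizes <- integer()
  for (rec in raw$models) {
    b <- unlist(rec$betas)
    models[[rec$entity]] <- structure(
      list(intercept = as.integer(rec$c), k_max = as.integer(rec$k_max),
           betas = b, aic = if (is.null(rec$aic)) NA_real_ else rec$aic,
           valid_range = as.integer(unlist(rec$valid_range)),
           fallback = isTRUE(rec$fallback), floor_epsilon = 1e-9,
           candidates = NULL, points = NULL),
      class = "overlap_model")
    sizes[rec$entity] <- as.integer(rec$set_size)
  }
  structure(
    list(models = models, sizes = sizes, sets = entity_sets(table),
         n_sets = as.integer(raw$n_sets), seed = as.integer(raw$seed),
         check_range = as.numeric(unlist(raw$check_range))),
    class = "overlap_models"
  )
}
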