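# Reproducible multi-stage runs: one config, named per-stage seed
# substreams, provenance JSON per artifact. A thin command-line wrapper
# over these functions ships in inst/cli/palynet.R.

#' Assemble a run configuration
#'
#' @param taxonomy Taxonomy config list (default [default_taxonomy()]).
#' @param generator List: `n_per_class`, `taphonomy` (a
#'   [taphonomy_config()] or `NULL`), `size`.
#' @param training List: `base_filters`, `dense_width`, `dropout`, `batch`,
#'   `lr`, `epochs` (NULL = per-node taxonomy epochs), `augment`.
#' @param policy List: `tau`.
#' @param paleo List: `marker_added`, `marker_dose`.
#' @param seed Global seed; every stage derives its own substream from it.
#' @param out_dir Output directory for artifacts.
#' @return A `run_config` object.
#' @export
run_config <- function(taxonomy = default_taxonomy(),
                       generator = list(n_per_class = 200, taphonomy = NULL,
                                        size = 128L),
                       training = list(base_filters = 8L, dense_width = 64L,
                                       dropout = 0.25, batch = 32L,
                                       lr = 1.5e-3, lr_decay = 0.95,
                                       epochs = c(main = 12L,
                                                  abies_picea = 8L,
                                                  pinus = 8L,
                                                  triporate = 40L,
                                                  tricolpate = 10L,
                                                  alnus = 16L, acer = 8L),
                                       augment = augmentation_config(
                                         rotation = 5, shear = 0.03,
                                         brightness_lowering = 0.03)),
                       policy = list(tau = 0.7),
                       paleo = list(marker_added = 15319, marker_dose = 0.1),
                       seed = 1L, out_dir = tempfile("palynet_run_")) {
  structure(list(taxonomy = taxonomy, generator = generator,
                 training = training, policy = policy, paleo = paleo,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

## named substream: deterministic child seed for a stage
stage_seed <- function(config, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((config$seed * 10007 + h) %% (.Machine$integer.max - 1L)) + 1L
}

provenance <- function(config, stage, extra = list()) {
  c(list(stage = stage, seed = stage_seed(config, stage),
         global_seed = config$seed,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra)
}

write_provenance <- function(config, stage, extra = list()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(config$out_dir, paste0(stage, ".json"))
  jsonlite::write_json(provenance(config, stage, extra), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Generate the configured dataset
#'
#' Renders the labelled image set for the configured taxonomy's terminal
#' classes, splits it and (optionally) writes the class-per-folder tree.
#'
#' @param config A [run_config()].
#' @param write Write PNG folders and manifest under `config$out_dir`.
#' @return List: `tree`, `dataset` (full `image_set`), `splits` (train /
#'   test / validation).
#' @export
cmd_generate <- function(config, write = FALSE) {
  tree <- build_hierarchy(config$taxonomy)
  specs <- default_class_specs()[terminal_labels(tree)]
  if (anyNA(names(specs))) {
    stop("no morphotype spec for some terminal classes", call. = FALSE)
  }
  dataset <- generate_dataset(specs, config$generator$n_per_class,
                              taphonomy = config$generator$taphonomy,
                              seed = stage_seed(config, "generate"),
                              size = config$generator$size %||% 128L)
  splits <- split_dataset(dataset, seed = stage_seed(config, "split"))
  if (write) {
    for (s in names(splits)) write_image_set(splits[[s]], config$out_dir, s)
    write_provenance(config, "generate",
                     list(n = length(dataset),
                          classes = dataset$classes))
  }
  list(tree = tree, dataset = dataset, splits = splits)
}

#' Train and calibrate the hierarchy for a config
#'
#' @param config A [run_config()].
#' @param data Output of [cmd_generate()] (regenerated if `NULL`).
#' @param verbose Print progress.
#' @return List: `tree`, `models` (calibrated), `calibration` (data frame),
#'   `splits`.
#' @export
cmd_train <- function(config, data = NULL, verbose = FALSE) {
  if (is.null(data)) data <- cmd_generate(config)
  tr <- config$training
  spec <- architecture_spec(base_filters = tr$base_filters %||% 8L,
                            dense_width = tr$dense_width %||% 64L,
                            dropout = tr$dropout %||% 0.5)
  models <- train_hierarchy(data$tree, data$splits, spec = spec,
                            epochs = tr$epochs, batch = tr$batch %||% 32L,
                            lr = tr$lr %||% 1e-3,
                            lr_decay = tr$lr_decay %||% 0.95,
                            augment = tr$augment,
                            seed = stage_seed(config, "train"),
                            restarts = tr$restarts %||% 1L,
                            verbose = verbose)
  cal <- calibrate_hierarchy(models, data$tree, data$splits$validation)
  list(tree = data$tree, models = cal$models, calibration = cal$results,
       splits = data$splits)
}

#' Classify a held-out split and report evaluation metrics
#'
#' @param config A [run_config()].
#' @param trained Output of [cmd_train()].
#' @param items Image set to classify (default: the test split).
#' @return List: `classified` (a `classified_set`), `confusion`
#'   (`confusion_apc` on terminal predictions vs truth), `under_threshold`.
#' @export
cmd_evaluate <- function(config, trained, items = NULL) {
  if (is.null(items)) items <- trained$splits$test
  pol <- threshold_policy(config$policy$tau %||% 0.7)
  cls <- classify_set(trained$tree, trained$models, items, pol)
  truth <- resolve_aliases(items$labels, trained$tree)
  conf <- confusion_and_apc(cls$labels, truth,
                            labels = enumerate_labels(trained$tree))
  list(classified = cls, confusion = conf,
       under_threshold = under_threshold_rate(cls))
}

#' Generate, classify and zone a synthetic fossil sequence
#'
#' @param config A [run_config()].
#' @param trained Output of [cmd_train()].
#' @param composition Per-depth composition data frame (see
#'   [generate_fossil_sequence()]).
#' @param n_objects Objects per sample.
#' @return List: `truth` (generating counts), `counts` (classified counts),
#'   `percent`, `zonation` (broken-stick selected).
#' @export
cmd_diagram <- function(config, trained, composition, n_objects = 100) {
  seq_seed <- stage_seed(config, "fossil")
  fs <- generate_fossil_sequence(composition, n_objects = n_objects,
                                 marker_dose = config$paleo$marker_dose,
                                 taphonomy = config$generator$taphonomy,
                                 seed = seq_seed)
  counts <- classify_sequence(trained$tree, trained$models, fs$samples,
                              composition$depth_cm,
                              threshold_policy(config$policy$tau %||% 0.7))
  pct <- percentages(counts)
  zon <- broken_stick_zones(coniss(counts[, setdiff(
    names(pct), c("sample_id", "depth_cm", "age_calBP", "pollen_sum",
                  grep("_of_total$", names(pct), value = TRUE)))],
    depths = counts$depth_cm))
  list(truth = fs$truth, counts = counts, percent = pct, zonation = zon)
}
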