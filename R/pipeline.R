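#' Run the full DTI prediction pipeline
#'
#' One-call orchestration of sample assembly, enclosing-subgraph
#' extraction, Palette-WL ordering, encoding, classifier training and
#' stratified cross-validation, with every artifact persisted to
#' `output_dir`: the sample table (`samples.tsv`), the embeddings
#' (`embeddings.tsv`), the cross-validation report (`report.json`) and,
#' when the network was simulated, the three network TSVs plus the
#' held-out true links. All randomness flows from the single root `seed`.
#'
#' @param config a named list (or path to a YAML/JSON file) with entries:
#'   * `network`: either paths `interactions`, `drug_sim`, `target_sim`,
#'     or a `simulate` list of [simulate_dti_network()] arguments;
#'   * `K` (subgraph size, default 10), `folds` (default 10),
#'     `seed` (default 1);
#'   * `sampling`: list with `n_positives`, `ratio_alpha`, `mode`;
#'   * `classifier`: overrides for [mlp_train()];
#'   * `output_dir`: where artifacts are written (optional).
#' @param quiet suppress progress messages.
#' @return The `dti_cv` report, invisibly also written to
#'   `output_dir/report.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- load_config(config)
  say <- function(...) if (!quiet) message(...)
  seed <- config$seed %||% 1L
  K <- config$K %||% 10L
  folds <- config$folds %||% 10L
  sampling <- config$sampling %||% list()
  out_dir <- config$output_dir

  nc <- config$network %||% list()
  if (!is.null(nc$simulate)) {
    say("simulating network (seed ", seed, ")")
    sim <- do.call(simulate_dti_network,
                   utils::modifyList(nc$simulate, list(seed = seed)))
    net <- sim$net
    if (!is.null(out_dir)) {
      write_dti_network(net, out_dir)
      readr::write_tsv(sim$held_out, file.path(out_dir, "held_out_links.tsv"))
    }
  } else {
    say("loading network from files")
    net <- read_dti_network(nc$interactions, nc$drug_sim, nc$target_sim)
  }
  say("network: ", net$m, " drugs, ", net$n, " targets, ",
      sum(net$Y), " interactions")

  cv <- cross_validate(
    net, K = K,
    n_positives = sampling$n_positives %||% "all",
    ratio_alpha = sampling$ratio_alpha %||% 1,
    mode = sampling$mode %||% "reliable",
    folds = folds,
    classifier = config$classifier %||% list(),
    seed = seed
  )
  say(sprintf("CV done: AUROC %.3f +/- %.3f, AUPR %.3f +/- %.3f",
              cv$mean_auroc, cv$sd_auroc, cv$mean_aupr, cv$sd_aupr))

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_samples(cv$samples, file.path(out_dir, "samples.tsv"))
    emb <- embed_pairs(net, cv$samples, K)
    write_embeddings(emb, file.path(out_dir, "embeddings.tsv"))
    report <- list(
      config = config[setdiff(names(config), "output_dir")],
      per_fold = cv$folds,
      mean_auroc = cv$mean_auroc, sd_auroc = cv$sd_auroc,
      mean_aupr = cv$mean_aupr, sd_aupr = cv$sd_aupr
    )
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("artifacts written to ", out_dir)
  }
  cv
}

# Accept a list, a YAML path or a JSON path.
load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON file path")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a
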