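# One-shot experimental pipeline on synthetic data: simulate -> encode ->
# priors (unimodal, supervised, unsupervised sweep) -> optional gating ->
# decode -> evaluate, emitting a comparison table across decoding variants.

#' Pipeline configuration
#'
#' @param synthetic A [synthetic_config()].
#' @param encoding An [encoding_config()].
#' @param unsupervised_C Cluster counts for the unsupervised sweep (can be
#'   empty).
#' @param unsupervised_repeats K-means repeats per cluster count (default 10;
#'   clusterings vary across repeats, so quality is reported per repeat).
#' @param supervised Decode under the supervised mixture prior? (default
#'   `TRUE`).
#' @param gating Fit and apply semantic gating? (default `TRUE`; requires
#'   `supervised`).
#' @param gating_folds CV folds for the gating penalty (default 10).
#' @param temperature Reconstruction temperature or `"hard"`.
#' @param seed Master seed for the pipeline stages.
#' @param output_dir Optional directory; when given, the comparison table,
#'   reports and reconstructions are written there.
#'
#' @return List of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       encoding = encoding_config(),
                       unsupervised_C = c(2L, 6L, 20L),
                       unsupervised_repeats = 10L,
                       supervised = TRUE,
                       gating = TRUE, gating_folds = 10L,
                       temperature = "hard", seed = 1L,
                       output_dir = NULL) {
  if (isTRUE(gating) && !isTRUE(supervised))
    stop("semantic gating requires the supervised decoding variant")
  structure(list(synthetic = synthetic, encoding = encoding,
                 unsupervised_C = as.integer(unsupervised_C),
                 unsupervised_repeats = as.integer(unsupervised_repeats),
                 supervised = isTRUE(supervised),
                 gating = isTRUE(gating), gating_folds = as.integer(gating_folds),
                 temperature = temperature, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

pipeline_log <- function(verbose, stage, t0) {
  if (verbose)
    message(sprintf("[%s] %s (%.1fs)", format(Sys.time(), "%H:%M:%S"), stage,
                    as.numeric(Sys.time()) - t0))
}

#' Run the full decoding comparison on synthetic data
#'
#' Generates a synthetic bundle, fits the encoding model, builds a unimodal
#' (single-Gaussian) prior, a supervised mixture prior and an unsupervised
#' K-means sweep, optionally fits semantic gating, decodes the test trials
#' under each variant and evaluates SSIM and classification accuracy.
#'
#' @param cfg A [run_config()].
#' @param verbose Log one line per stage (default `TRUE`).
#'
#' @return List of class `pipeline_result`: `table` (one row per decoding
#'   variant/repeat with SSIM sum/mean and accuracy), `reports` (per-variant
#'   `eval_report`s), `manifest` and the fitted `model`.
#' @export
run_pipeline <- function(cfg = run_config(), verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- as.numeric(Sys.time())
  seeds <- derive_seeds(cfg$seed, 3L + max(1L, length(cfg$unsupervised_C)) *
                          max(1L, cfg$unsupervised_repeats))
  bundle <- generate_dataset(cfg$synthetic)
  pipeline_log(verbose, "simulated dataset", t0)

  model <- fit_encoding_model(bundle$train_images, bundle$train_responses,
                              cfg$encoding)
  pipeline_log(verbose, sprintf("fitted encoding model (%d/%d voxels kept)",
                                sum(model$selected), length(model$selected)),
               t0)

  test_labels <- bundle$test_images$labels
  rows <- list()
  reports <- list()
  add_row <- function(variant, C, rep_id, decoded, predicted) {
    rep <- evaluate_reconstructions(decoded$reconstructions,
                                    bundle$test_images,
                                    predicted_labels = predicted,
                                    true_labels = if (!is.null(predicted))
                                      test_labels else NULL)
    key <- if (is.na(rep_id)) variant else sprintf("%s_C%d_r%d", variant, C, rep_id)
    reports[[key]] <<- rep
    rows[[length(rows) + 1L]] <<- data.frame(
      variant = variant, C = C, rep = rep_id,
      ssim_sum = rep$ssim_sum, ssim_mean = rep$ssim_mean,
      accuracy = if (is.null(rep$accuracy)) NA_real_ else rep$accuracy,
      stringsAsFactors = FALSE)
  }

  # unimodal: single-Gaussian prior over the whole prior set
  uni_prior <- build_unsupervised_prior(bundle$prior, C = 1L, restarts = 1L,
                                        seed = seeds[1])
  uni <- decode_batch(model, uni_prior, bundle$test_responses,
                      temperature = cfg$temperature)
  add_row("unimodal", 1L, NA_integer_, uni, NULL)
  pipeline_log(verbose, "unimodal decoding", t0)

  # supervised mixture
  if (cfg$supervised) {
    sup_prior <- build_supervised_prior(bundle$prior)
    sup <- decode_batch(model, sup_prior, bundle$test_responses,
                        temperature = cfg$temperature)
    add_row("supervised", n_components(sup_prior), NA_integer_, sup,
            sup$winner_names)
    pipeline_log(verbose, "supervised multimodal decoding", t0)
  }

  # semantic gating on the supervised categories
  if (cfg$gating) {
    sel <- select_gating_penalty(bundle$train_gating$data,
                                 bundle$train_images$labels,
                                 n_folds = cfg$gating_folds, seed = seeds[2])
    gmodel <- fit_gating(bundle$train_gating$data, bundle$train_images$labels,
                         sel$penalty)
    glw <- gated_log_weights(gmodel, bundle$test_gating$data, prior = sup_prior)
    gated <- decode_batch(model, sup_prior, bundle$test_responses,
                          gating_log_weights = glw,
                          temperature = cfg$temperature)
    add_row("gated", n_components(sup_prior), NA_integer_, gated,
            gated$winner_names)
    pipeline_log(verbose, "semantic gating", t0)
  }

  # unsupervised sweep
  si <- 3L
  for (C in cfg$unsupervised_C) {
    for (r in seq_len(cfg$unsupervised_repeats)) {
      prior_c <- build_unsupervised_prior(bundle$prior, C = C,
                                          seed = seeds[si])
      si <- si + 1L
      dec <- decode_batch(model, prior_c, bundle$test_responses,
                          temperature = cfg$temperature)
      predicted <- if (!is.null(dec$letter_probs))
        colnames(dec$letter_probs)[max.col(dec$letter_probs,
                                           ties.method = "first")] else NULL
      add_row("unsupervised", C, r, dec, predicted)
    }
    pipeline_log(verbose, sprintf("unsupervised decoding, C = %d", C), t0)
  }

  table <- do.call(rbind, rows)
  manifest <- list(config = list(synthetic = bundle$manifest,
                                 encoding = unclass(cfg$encoding),
                                 unsupervised_C = cfg$unsupervised_C,
                                 unsupervised_repeats = cfg$unsupervised_repeats,
                                 gating = cfg$gating,
                                 temperature = cfg$temperature,
                                 seed = cfg$seed),
                   n_selected_voxels = sum(model$selected))
  result <- structure(list(table = table, reports = reports,
                           manifest = manifest, model = model),
                      class = "pipeline_result")
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(table, file.path(cfg$output_dir, "comparison.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_report(manifest, file.path(cfg$output_dir, "manifest.json"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  agg <- stats::aggregate(cbind(ssim_mean, accuracy) ~ variant + C,
                          data = x$table, FUN = mean, na.action = stats::na.pass)
  print(agg, row.names = FALSE)
  invisible(x)
}
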