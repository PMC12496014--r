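#' End-to-end multiview denoising pipeline
#'
#' Convenience wrapper over the module functions: builds the spatial (and,
#' when morphology is present, the morphology) KNN affinity graph, low-pass
#' filters the expression view over the spatial graph, trains the
#' dual-encoder model, and returns the denoised expression together with the
#' fused latent features.  Operates on an already normalized (or simulated)
#' dataset; run [filter_genes()] / [normalize_log()] / [banksy_augment()]
#' beforehand for raw counts.
#'
#' @param ds a normalized [srt_dataset()].
#' @param config a [model_config()]; `k_spatial`, `k_morph`, `filter_order`,
#'   `alpha`, `beta` and the training hyperparameters are taken from it.
#' @param features optional spots x p matrix overriding the expression view
#'   (e.g. the output of [banksy_augment()]).
#' @param use_morphology use the morphology view when present (default TRUE).
#' @return List with `model`, `filtered` (the model input), `latent`
#'   (`latent_features`), `denoised` (spots x p matrix), `graph_spatial`,
#'   `graph_morphology` (or NULL).
#' @export
denoise_pipeline <- function(ds, config = model_config(), features = NULL,
                             use_morphology = TRUE) {
  stopifnot(inherits(ds, "srt_dataset"))
  X0 <- if (is.null(features)) expr_dense(ds) else as.matrix(features)
  As <- build_knn_affinity(ds$coords, k = config$k_spatial, view = "spatial")
  Am <- NULL
  if (use_morphology && !is.null(ds$morphology))
    Am <- build_knn_affinity(ds$morphology, k = min(config$k_morph,
                                                    nrow(ds$coords) - 1L),
                             view = "morphology")
  X <- laplacian_filter(X0, As, t = config$filter_order)
  model <- train_multiview(X, As, Am, config)
  latent <- encode_spots(model, X, perturb = FALSE)
  denoised <- denoise_expression(model, X)
  list(model = model, filtered = X, latent = latent, denoised = denoised,
       graph_spatial = As, graph_morphology = Am)
}
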