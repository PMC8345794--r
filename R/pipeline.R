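#' Pipeline configuration
#'
#' Builds the nested configuration list controlling every stage, with the
#' study defaults: 200x200 working resolution, 8-pixel CLAHE tiles with clip
#' limit 0.01, 3-level haar decomposition with mean-absolute detail fusion,
#' 8 gray levels at distance 1 over four angles for GLCM, four scan
#' directions for GLRLM, a 1..180 degree HOS angle grid with nfft 256 and 64
#' phase bins, ADASYN with k = 5 and full balancing in image space, all four
#' SVM kernels at C = 1 under 10-fold cross-validation with SFS
#' (max 50 features, patience 5). Serialises round-trip stably through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param ... Named overrides for nested entries, e.g.
#'   `hos = list(angles = seq(10, 180, by = 10))`; unnamed sub-entries keep
#'   their defaults.
#' @return Nested configuration list of class `stroke_config`.
#' @export
stroke_config <- function(...) {
  cfg <- list(
    preprocess = list(size = 200, tile_pixels = 8, clip_limit = 0.01),
    wavelets = list(family = "haar", levels = 3, fusion = "mean_abs"),
    glcm = list(levels = 8, distance = 1, angles = c(0, 45, 90, 135),
                feature_set = glcm_default_features()),
    glrlm = list(levels = 8, directions = c(0, 45, 90, 135)),
    hos = list(nfft = 256, phase_bins = 64, angles = 1:180),
    balance = list(k = 5, beta = 1, space = "images", enabled = TRUE),
    svm = list(kernels = c("linear", "poly2", "poly3", "rbf"), cost = 1,
               gamma = NULL, coef0 = 1),
    cv = list(folds = 10, collapse = "reference"),
    sfs = list(max_features = 50, patience = 5),
    seed = 42
  )
  mods <- list(...)
  for (nm in names(mods)) {
    if (is.list(mods[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(mods[[nm]])] <- mods[[nm]]
    } else {
      cfg[[nm]] <- mods[[nm]]
    }
  }
  structure(cfg, class = c("stroke_config", "list"))
}

#' @rdname stroke_config
#' @param config A `stroke_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname stroke_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(stroke_config, raw)
}

#' Run the full classification pipeline
#'
#' Executes preprocess -> balance (image space) -> wavelet decomposition and
#' fused feature extraction -> ANOVA ranking -> SFS + SVM under stratified
#' k-fold cross-validation for each configured kernel, and assembles a
#' kernel-comparison table. All randomness flows from `config$seed` through
#' named substreams (balance, cv, sfs).
#'
#' @param manifest Manifest tibble with `path` + `label` columns (or an
#'   `image` list-column for in-memory data).
#' @param config A [stroke_config()].
#' @param out_dir Optional directory: writes `features.csv`, `ranking.csv`,
#'   one `cv_<kernel>.json` per kernel and `kernel_comparison.csv`.
#' @param progress Print progress dots during extraction.
#' @return Object of class `stroke_run`: list with `features` (tibble),
#'   `ranking` (global ranking tibble), `reports` (per-kernel `cv_report`),
#'   `comparison` (tibble), `config`.
#' @export
run_pipeline <- function(manifest, config = stroke_config(), out_dir = NULL,
                         progress = FALSE) {
  pre <- preprocess_images(manifest, size = config$preprocess$size,
                           tile = config$preprocess$tile_pixels,
                           clip = config$preprocess$clip_limit)
  images <- pre$image
  labels <- as.character(pre$label)
  if (isTRUE(config$balance$enabled) &&
      identical(config$balance$space, "images") &&
      length(unique(table(labels))) > 1) {
    bal <- adasyn_images(images, labels, k = config$balance$k,
                         beta = config$balance$beta,
                         seed = derive_seed(config$seed, "balance"))
    images <- bal$images
    labels <- bal$labels
  }
  feats <- extract_features(images, labels, config = config,
                            progress = progress)
  if (isTRUE(config$balance$enabled) &&
      identical(config$balance$space, "features") &&
      length(unique(table(labels))) > 1) {
    feats <- adasyn(feats[setdiff(names(feats), "id")], label = "label",
                    k = config$balance$k, beta = config$balance$beta,
                    seed = derive_seed(config$seed, "balance"))
    feats$id <- seq_len(nrow(feats))
    feats <- feats[c("id", setdiff(names(feats), c("id", ".synthetic")))]
  }
  ranking <- rank_features(feats[setdiff(names(feats), "id")], label = "label")
  reports <- list()
  for (k in config$svm$kernels) {
    reports[[k]] <- cross_validate(
      feats[setdiff(names(feats), "id")], label = "label",
      kernel = kernel_spec(k, cost = config$svm$cost,
                           gamma = config$svm$gamma, coef0 = config$svm$coef0),
      folds = config$cv$folds, seed = derive_seed(config$seed, "cv"),
      max_features = config$sfs$max_features, patience = config$sfs$patience,
      collapse = config$cv$collapse)
  }
  comparison <- bind_rows(lapply(names(reports), function(k) {
    s <- reports[[k]]$summary
    tibble(kernel = k,
           sen = round_half_up(s$sen), spe = round_half_up(s$spe),
           ppv = round_half_up(s$ppv), acc = round_half_up(s$acc),
           dice = round_half_up(s$dice))
  }))
  run <- structure(list(features = feats, ranking = ranking,
                        reports = reports, comparison = comparison,
                        config = config),
                   class = "stroke_run")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(feats, file.path(out_dir, "features.csv"))
    readr::write_csv(ranking, file.path(out_dir, "ranking.csv"))
    readr::write_csv(comparison, file.path(out_dir, "kernel_comparison.csv"))
    for (k in names(reports)) {
      jsonlite::write_json(
        list(kernel = k,
             folds = reports[[k]]$folds,
             summary = reports[[k]]$summary,
             selected_features = reports[[k]]$selected),
        file.path(out_dir, sprintf("cv_%s.json", k)),
        auto_unbox = TRUE, digits = NA)
    }
  }
  run
}

#' @export
print.stroke_run <- function(x, ...) {
  cat(sprintf("<stroke_run> %d samples x %d features, %d kernel(s)\n",
              nrow(x$features), ncol(x$features) - 2, length(x$reports)))
  print(x$comparison)
  invisible(x)
}
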