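#' Analysis configuration for the end-to-end experiment
#'
#' Bundles every knob of the analysis graph: the synthetic input (or an
#' activations directory), permutation counts, the decoding setup, behavior
#' simulation, FDR families and the output directory. One global seed fans
#' out to per-stage seeds by a fixed counter scheme (stage k uses
#' seed + 104729 k mod 2^31 - 1), giving stage-level reproducibility without
#' cross-stage coupling.
#'
#' @param synthetic list of arguments for \code{\link{syntheticConfig}}, or
#'   NULL when \code{activationsDir} is given.
#' @param activationsDir directory readable by \code{\link{readActivations}}.
#' @param nPermMantel permutations for the per-layer Mantel tests.
#' @param nPermVariation permutations for the across-layer variation test.
#' @param decode list of arguments for \code{\link{decodeConfig}}.
#' @param behavior list: \code{nTrials} (NULL = exhaustive triplets),
#'   \code{choiceModel}, \code{temperature}.
#' @param mdsLayer layer for the super-RDM MDS (default: middle layer).
#' @param outDir output directory.
#' @param seed global seed.
#' @param figures write PNG figures (default TRUE).
#' @return a list of class \code{AnalysisConfig}.
#' @export
analysisConfig <- function(synthetic = list(), activationsDir = NULL,
                           nPermMantel = 1000, nPermVariation = 1000,
                           decode = list(), behavior = list(),
                           mdsLayer = NULL, outDir = tempfile("exp1_"),
                           seed = 1, figures = TRUE) {
  structure(list(synthetic = synthetic, activationsDir = activationsDir,
                 nPermMantel = as.integer(nPermMantel),
                 nPermVariation = as.integer(nPermVariation),
                 decode = decode, behavior = behavior, mdsLayer = mdsLayer,
                 outDir = outDir, seed = check_seed(seed),
                 figures = isTRUE(figures)),
            class = "AnalysisConfig")
}

#' Load an AnalysisConfig from a YAML file
#'
#' @param path YAML file whose top-level keys are the arguments of
#'   \code{\link{analysisConfig}}.
#' @param ... overrides (e.g. \code{seed}, \code{outDir}) taking precedence
#'   over the file.
#' @return an \code{AnalysisConfig}.
#' @export
loadAnalysisConfig <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  do.call(analysisConfig, vals)
}

validate_analysis_config <- function(config) {
  if (!inherits(config, "AnalysisConfig")) stop("not an AnalysisConfig")
  if (is.null(config$activationsDir)) {
    scfg <- do.call(syntheticConfig, config$synthetic)
    if (length(scfg$depictions) < 2)
      stop("validation error: at least two depiction types are required")
  } else if (!dir.exists(config$activationsDir)) {
    stop("validation error: activations directory does not exist: ",
         config$activationsDir)
  }
  invisible(TRUE)
}

write_csv_out <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full representational-generalization analysis
#'
#' Executes the analysis graph end to end on synthetic (or loaded)
#' activations: per-layer per-depiction RDMs, the cross-depiction Spearman
#' profile, Mantel tests per layer and depiction pair, the across-layer
#' variation test per pair, a super-RDM MDS embedding, intra- and
#' cross-depiction decoding, a triplet-behavior simulation with similarity
#' recovery and its fit to each layer's RDMs, and a consolidated
#' FDR-adjusted test table. All outputs are tidy CSVs, JSON test records and
#' (optionally) PNG figures under \code{config$outDir}; a manifest records
#' the config hash and seeds. Fully reproducible given the global seed.
#'
#' @param config an \code{\link{analysisConfig}}.
#' @return invisibly, a report list with the profile, RDMs, test table,
#'   decoding tables, behavior fit and file paths (consumed by
#'   \code{\link{runComparison}}).
#' @export
runExperiment1 <- function(config) {
  validate_analysis_config(config)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  stage <- function(k) derive_seed(seed, k)
  paths <- character(0)

  # --- stage 1: inputs -----------------------------------------------------
  if (is.null(config$activationsDir)) {
    sargs <- config$synthetic
    sargs$seed <- sargs$seed %||% stage(1)
    scfg <- do.call(syntheticConfig, sargs)
    multi <- generateActivations(scfg)
  } else {
    multi <- readActivations(config$activationsDir)
  }
  depictions <- unique(multi@meta$depiction)
  layers <- layerNames(multi)

  # --- stage 2: RDMs and cross-depiction profile ---------------------------
  rdms <- layerDepictionRDMs(multi)
  profile <- crossDepictionProfile(multi, depictions)
  paths <- c(paths, write_csv_out(profile, config$outDir, "profile.csv"))

  # --- stage 3: inference --------------------------------------------------
  tests <- list()
  pairs <- utils::combn(depictions, 2)
  for (k in seq_len(ncol(pairs))) {
    d1 <- pairs[1, k]; d2 <- pairs[2, k]
    pair_name <- paste(d1, d2, sep = "-")
    for (li in seq_along(layers)) {
      mt <- mantelTest(rdms[[layers[li]]][[d1]], rdms[[layers[li]]][[d2]],
                       nPerm = config$nPermMantel,
                       seed = stage(100 + 10 * k + li))
      rec <- permutationRecord(mt, family = "mantel")
      rec$layer <- layers[li]; rec$pair <- pair_name
      tests[[length(tests) + 1]] <- rec
    }
    vt <- acrossLayerVariationTest(
      lapply(layers, function(l) rdms[[l]][[d1]]),
      lapply(layers, function(l) rdms[[l]][[d2]]),
      nPerm = config$nPermVariation, seed = stage(200 + k))
    rec <- permutationRecord(vt, family = "layer_variation")
    rec$layer <- "all"; rec$pair <- pair_name
    tests[[length(tests) + 1]] <- rec
  }

  # --- stage 4: super-RDM and MDS ------------------------------------------
  mds_layer <- config$mdsLayer %||% layers[ceiling(length(layers) / 2)]
  srdm <- superRDM(multi, mds_layer)
  emb <- mdsEmbed(srdm, dims = 2, seed = stage(300), nRestarts = 4)
  mds_df <- data.frame(label = emb@labels, x = emb@coordinates[, 1],
                       y = emb@coordinates[, 2], stress = emb@stress)
  paths <- c(paths, write_csv_out(mds_df, config$outDir, "mds.csv"))

  # --- stage 5: decoding ---------------------------------------------------
  dargs <- config$decode
  by_dep <- lapply(layers, function(l)
    splitByDepiction(getLayer(multi, l)))
  names(by_dep) <- layers
  intra <- list(); cross <- list()
  for (li in seq_along(layers)) {
    for (d in depictions) {
      dargs$seed <- stage(400 + 20 * li + match(d, depictions))
      res <- cvDecode(by_dep[[layers[li]]][[d]],
                      config = do.call(decodeConfig, dargs))
      intra[[length(intra) + 1]] <- data.frame(
        layer = layers[li], depiction = d, mean = res@meanAccuracy,
        se = res@standardError)
    }
    for (d1 in depictions) for (d2 in setdiff(depictions, d1)) {
      dargs$seed <- stage(500 + 20 * li + 3 * match(d1, depictions) +
                            match(d2, depictions))
      res <- crossDecode(by_dep[[layers[li]]][[d1]],
                         by_dep[[layers[li]]][[d2]],
                         config = do.call(decodeConfig, dargs))
      cross[[length(cross) + 1]] <- data.frame(
        layer = layers[li], train = d1, test = d2, mean = res@meanAccuracy,
        se = res@standardError)
    }
  }
  intra <- do.call(rbind, intra)
  cross <- do.call(rbind, cross)
  paths <- c(paths, write_csv_out(intra, config$outDir,
                                  "decoding_intra.csv"),
             write_csv_out(cross, config$outDir, "decoding_cross.csv"))

  # --- stage 6: behavior ---------------------------------------------------
  bargs <- config$behavior
  planted <- attr(multi, "plantedSimilarity")
  if (is.null(planted)) {
    # no ground truth available: derive a reference similarity from the last
    # layer's first-depiction RDM (sim = 1 - d/2 maps [0,2] into [0,1])
    ref <- rdms[[layers[length(layers)]]][[depictions[1]]]
    planted <- 1 - rdmValues(ref) / 2
    diag(planted) <- 1
  }
  trials <- generateTripletTrials(
    planted,
    mode = if (is.null(bargs$nTrials)) "exhaustive" else "sampled",
    nTrials = bargs$nTrials,
    choiceModel = bargs$choiceModel %||% "deterministic",
    temperature = bargs$temperature %||% 0.1, seed = stage(600))
  paths <- c(paths, write_csv_out(trials, config$outDir, "triplets.csv"))
  est <- tripletSimilarity(trials, labels = rownames(planted))
  behav_rdm <- choiceSimilarityToRDM(est)
  fit <- do.call(rbind, lapply(layers, function(l) {
    data.frame(layer = l, depiction = depictions[1],
               rho = rdmSpearman(behav_rdm, rdms[[l]][[depictions[1]]]))
  }))
  paths <- c(paths, write_csv_out(fit, config$outDir, "behavior_fit.csv"))

  # --- stage 7: consolidated inference table -------------------------------
  test_df <- do.call(rbind, lapply(tests, function(r)
    data.frame(statistic = r$statistic, layer = r$layer, pair = r$pair,
               observed = r$observed, p = r$p, n_perm = r$n_perm,
               seed = r$seed, family = r$family)))
  test_df <- fdrWithinFamilies(test_df)
  paths <- c(paths, write_csv_out(test_df, config$outDir, "tests_fdr.csv"))
  jsonlite::write_json(tests, file.path(config$outDir, "tests.json"),
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, file.path(config$outDir, "tests.json"))

  # --- figures and manifest ------------------------------------------------
  if (config$figures) {
    plotMDS(emb, file.path(config$outDir, "mds.png"))
    plotProfile(profile, file.path(config$outDir, "profile.png"))
    plotRDM(srdm, file.path(config$outDir, "super_rdm.png"),
            main = paste("super-RDM", mds_layer))
  }
  cfg_yaml <- file.path(config$outDir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_yaml)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_yaml)),
    global_seed = seed,
    package_version = as.character(utils::packageVersion("depictRSA")),
    r_version = as.character(getRversion()),
    artifacts = basename(c(paths, cfg_yaml)))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(config = config, layers = layers, depictions = depictions,
                 rdms = rdms, profile = profile, tests = test_df,
                 decodingIntra = intra, decodingCross = cross,
                 behaviorFit = fit, mds = emb, paths = paths,
                 outDir = config$outDir))
}

#' Layerwise profile figure
#'
#' @param profile data.frame from \code{\link{crossDepictionProfile}}.
#' @param path output PNG path.
#' @export
plotProfile <- function(profile, path) {
  grDevices::png(path, width = 800, height = 500)
  on.exit(grDevices::dev.off())
  layers <- unique(profile$layer)
  prs <- unique(profile$pair)
  graphics::plot(NULL, xlim = c(1, length(layers)), ylim = range(profile$rho),
                 xaxt = "n", xlab = "layer", ylab = "Spearman rho",
                 main = "cross-depiction RDM correlation")
  graphics::axis(1, at = seq_along(layers), labels = layers)
  for (k in seq_along(prs)) {
    sub <- profile[profile$pair == prs[k], ]
    graphics::lines(match(sub$layer, layers), sub$rho, col = k, type = "b",
                    pch = k)
  }
  graphics::legend("bottomright", legend = prs, col = seq_along(prs),
                   pch = seq_along(prs))
  invisible(path)
}

#' Differential comparison of two completed runs
#'
#' For every layer and depiction pair present in both runs, tests whether the
#' cross-depiction RDM correlation differs between the two runs with the
#' generalized correlation-difference permutation test (one object
#' relabeling applied jointly to one side of both correlations), then adjusts
#' across the family with BH-FDR. Mirrors the structure of comparing a
#' standard network with a shape-biased or fine-tuned variant.
#'
#' @param runA,runB reports returned by \code{\link{runExperiment1}} with
#'   matching layers and depictions.
#' @param nPerm permutations per test (default 1000).
#' @param seed RNG seed.
#' @return data.frame with layer, pair, observed difference (run A minus
#'   run B), p, p_adj, n_perm, seed.
#' @export
runComparison <- function(runA, runB, nPerm = 1000, seed = 1) {
  if (!identical(runA$layers, runB$layers))
    stop("layer mismatch between runs: ",
         paste(runA$layers, collapse = ","), " vs ",
         paste(runB$layers, collapse = ","))
  if (!identical(sort(runA$depictions), sort(runB$depictions)))
    stop("depiction mismatch between runs")
  pairs <- utils::combn(runA$depictions, 2)
  out <- list()
  for (li in seq_along(runA$layers)) {
    l <- runA$layers[li]
    for (k in seq_len(ncol(pairs))) {
      d1 <- pairs[1, k]; d2 <- pairs[2, k]
      tst <- rdmPairDifferenceTest(
        runA$rdms[[l]][[d1]], runA$rdms[[l]][[d2]],
        runB$rdms[[l]][[d1]], runB$rdms[[l]][[d2]],
        nPerm = nPerm, seed = derive_seed(seed, 1000 + 50 * li + k))
      out[[length(out) + 1]] <- data.frame(
        layer = l, pair = paste(d1, d2, sep = "-"),
        observed = tst@observed, p = tst@p, n_perm = tst@nPerm,
        seed = tst@seed)
    }
  }
  res <- do.call(rbind, out)
  res$family <- "profile_difference"
  fdrWithinFamilies(res)
}
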