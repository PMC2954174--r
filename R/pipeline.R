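#' @include phantom.R pet.R atlas.R quant.R behavior.R
NULL

#' Run the full laterality pipeline on a phantom cohort
#'
#' Orchestrates every stage end to end: cohort simulation, the
#' standardize/smooth/flip-subtract/align activation analysis with
#' cluster-extent thresholding, the probabilistic atlas with fractional
#' overlap thresholds, per-subject tissue quantification with asymmetry
#' quotients, the bilateral-VOI structure correlation, and the behavioral
#' statistics (handedness index, population bias, GM-WM correlations,
#' handedness-by-threshold interaction). With a fixed seed and
#' configuration all written outputs are byte-identical across runs.
#'
#' @param config a [PhantomConfig].
#' @param seed integer master seed.
#' @param outDir optional directory; when given, writes `clusters.csv`,
#'   `atlas_volumes.csv`, `quant.csv`, `behavior.csv`, `stats.json` and a
#'   `manifest.json` recording the seed, thresholds and file hashes, plus
#'   the group t-map as NIfTI when `writeVolumes = TRUE`.
#' @param tThreshold,minExtentMM3,connectivity cluster-extent thresholding
#'   parameters (defaults t = 4.54, 72 mm^3, 26-connectivity).
#' @param fwhmMM smoothing kernel FWHM in mm (default 6).
#' @param fractions increasing overlap fractions in (0, 1).
#' @param writeVolumes also write the t-map and atlas count volume as
#'   NIfTI files.
#' @return Invisibly, a list with components `cohort`, `tmap`, `clusters`,
#'   `atlas`, `atlasVolumes`, `quant`, `voiCorrelation`, `stats`.
#' @examples
#' res <- runPipeline(phantomConfig(nAtlas = 8L), seed = 7)
#' clusterTable(res$clusters)
#' @export
runPipeline <- function(config = phantomConfig(), seed = 1L,
                        outDir = NULL, tThreshold = 4.54,
                        minExtentMM3 = 72, fwhmMM = 6,
                        fractions = c(0.3, 0.5, 0.7),
                        connectivity = 26L, writeVolumes = FALSE) {
  if (any(diff(fractions) <= 0) || any(fractions <= 0) || any(fractions >= 1))
    stop("fractions must be strictly increasing within (0, 1)", call. = FALSE)
  if (tThreshold <= 0 || minExtentMM3 <= 0 || fwhmMM < 0)
    stop("thresholds must be positive", call. = FALSE)

  cohort <- simulateCohort(config, seed)

  pet <- petAsymmetry(cohort@pet, cohort@hands, cohort@brainMask,
                      fwhmMM = fwhmMM, tThreshold = tThreshold,
                      minExtentMM3 = minExtentMM3,
                      connectivity = connectivity)

  atlas <- sumTracings(cohort@tracings)
  maps <- lapply(fractions, function(f) thresholdAtlas(atlas, f))
  names(maps) <- as.character(fractions)
  volumes <- atlasVolumeTable(atlas, fractions)

  quant <- quantifyCohort(cohort@segmentations, maps,
                          subjects = cohort@behavior$subject)

  voiCor <- NULL
  if (length(pet$clusters) >= 1L) {
    voi <- bilateralVOI(pet$clusters, 1L, reference = cohort@brainMask)
    voiCor <- voiStructureCorrelation(cohort@segmentations, voi, maps,
                                      tissue = "gm")
  }

  beh <- cohort@behavior
  beh$hi <- handednessIndex(beh$err_right, beh$err_left)
  beh$hand_class <- classifyHandedness(beh$hi)
  classified <- beh[beh$hand_class != "excluded", ]
  bias <- populationBiasTest(beh$hi)

  gmwm <- do.call(rbind, lapply(fractions, function(f) {
    sub <- quant[quant$fraction == f, ]
    agg <- stats::aggregate(cbind(pct_gm, pct_wm) ~ subject, sub, mean)
    pc <- pearsonCorrelation(agg$pct_gm, agg$pct_wm)
    data.frame(fraction = f, r = pc$r, p = pc$p, n = pc$n)
  }))

  aqTab <- unique(quant[, c("subject", "fraction", "aq_wm")])
  aqTab <- merge(aqTab, classified[, c("subject", "hand_class")],
                 by = "subject")
  interaction <- if (nrow(aqTab) &&
                     length(unique(aqTab$hand_class)) == 2L &&
                     all(table(unique(aqTab[c("subject", "hand_class")])$hand_class) >= 2L)) {
    mixedAnovaInteraction(data.frame(
      subject = aqTab$subject, threshold = aqTab$fraction,
      aq = aqTab$aq_wm, group = aqTab$hand_class))
  } else NULL

  stats <- list(
    seed = seed,
    n_clusters = length(pet$clusters),
    population_bias = bias,
    gm_wm_correlation = gmwm,
    voi_gm_correlation = voiCor,
    handedness_threshold_interaction = interaction
  )

  result <- list(cohort = cohort, tmap = pet$tmap, clusters = pet$clusters,
                 atlas = atlas, atlasMaps = maps, atlasVolumes = volumes,
                 quant = quant, behavior = beh, voiCorrelation = voiCor,
                 stats = stats)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      clusters = file.path(outDir, "clusters.csv"),
      atlas_volumes = file.path(outDir, "atlas_volumes.csv"),
      quant = file.path(outDir, "quant.csv"),
      behavior = file.path(outDir, "behavior.csv"),
      stats = file.path(outDir, "stats.json")
    )
    utils::write.csv(clusterTable(pet$clusters), paths[["clusters"]],
                     row.names = FALSE)
    utils::write.csv(volumes, paths[["atlas_volumes"]], row.names = FALSE)
    utils::write.csv(quant, paths[["quant"]], row.names = FALSE)
    utils::write.csv(beh, paths[["behavior"]], row.names = FALSE)
    jsonlite::write_json(stats, paths[["stats"]], auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", null = "null")
    if (writeVolumes) {
      writeVolume(ScalarVolume(pet$tmap@tvals, pet$tmap@voxelSize),
                  file.path(outDir, "tmap.nii.gz"))
      writeVolume(ScalarVolume(atlas@counts + 0, atlas@voxelSize),
                  file.path(outDir, "atlas_counts.nii.gz"))
    }
    manifest <- list(
      package = "latermap",
      version = as.character(utils::packageVersion("latermap")),
      seed = seed,
      t_threshold = tThreshold, min_extent_mm3 = minExtentMM3,
      smoothing_fwhm_mm = fwhmMM, fractions = fractions,
      connectivity = connectivity,
      n_pet_subjects = config@nPET, n_atlas_subjects = config@nAtlas,
      file_md5 = as.list(tools::md5sum(unname(paths)))
    )
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(result)
}
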