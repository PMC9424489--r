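#' Quantify one volume end to end
#'
#' Runs the full stage sequence on an in-memory volume: optional ROI
#' restriction (voxels outside the eroded slice-hull are zeroed before
#' thresholding), hysteresis thresholding (with the automatic limit rule
#' when limits are NA), connected component labelling, size/curation
#' filtering, skeletonization, graph building and iterative refinement,
#' and per-segment feature extraction.
#'
#' @param volume an \linkS4class{ImageVolume}
#' @param seg a [segmentationParams()] list
#' @param refine a [refineParams()] list
#' @param roi optional [roiParams()] list; NULL skips the ROI stage (the
#'   right choice when the tissue fills the grid, as for phantoms)
#' @param volumeId identifier used in the feature table
#' @return A list with elements \code{mask} (curated
#'   \linkS4class{VoxelMask}), \code{components} (the
#'   \linkS4class{LabeledMask}), \code{componentReport} (curation table),
#'   \code{graph} (refined \linkS4class{VesselGraph}), \code{features}
#'   (per-segment data.frame), and \code{thresholds} (the limits used).
#' @examples
#' ph <- generatePhantom(phantomSpec(volumeDim = c(80, 72, 72),
#'                                   axisLength = 120, initialLength = 20,
#'                                   initialLengthSd = 4, tipLength = 8,
#'                                   tipLengthSd = 2, seed = 5))
#' q <- quantifyVolume(ph$volume, segmentationParams(minSize = 200))
#' head(q$features)
#' @export
quantifyVolume <- function(volume, seg = segmentationParams(),
                           refine = refineParams(), roi = NULL,
                           volumeId = "volume") {
  stopifnot(is(volume, "ImageVolume"), inherits(seg, "SegmentationParams"),
            inherits(refine, "RefineParams"))
  rmask <- NULL
  if (!is.null(roi)) {
    rmask <- roiMask(volume, roi)
    v <- volume@values
    v[!rmask@values] <- 0
    volume <- imageVolume(v, volume@spacing)
  }
  thr <- c(low = seg$low, high = seg$high)
  if (is.na(thr["low"]) || is.na(thr["high"])) {
    auto <- suggestThresholds(volume, roi = rmask)
    if (is.na(thr["low"])) thr["low"] <- auto["low"]
    if (is.na(thr["high"])) thr["high"] <- auto["high"]
  }
  hyst <- hysteresisThreshold(volume, thr["low"], thr["high"],
                              seg$connectivity)
  comps <- labelComponents(hyst, seg$connectivity)
  curated <- filterComponents(comps, seg$minSize, seg$excludedLabels)
  graph <- refineGraph(buildGraph(skeletonize(curated)), refine)
  list(mask = curated, components = comps,
       componentReport = componentTable(comps), graph = graph,
       features = extractFeatures(graph, volumeId), thresholds = thr)
}

defaultConfig <- function() {
  list(seed = 1L, output_dir = "lymphnet_run",
       phantom = list(n = 2L, spec = list(), mutant = NULL),
       segmentation = list(low = NA, high = NA, min_size = 500L,
                           connectivity = 26L, excluded_labels = list()),
       roi = NULL,
       refine = list(spur_length = 10, node_merge_radius = 5,
                     max_iterations = 10L),
       analysis = list(features = c("length_um", "avg_cross_section_um2"),
                       unit = "segment", alpha = 0.05),
       volumes = NULL)
}

#' Read and complete a pipeline configuration
#'
#' Loads a YAML pipeline configuration (or takes a list) and fills missing
#' entries with the package defaults. The single \code{seed} drives all
#' randomness of a run.
#'
#' @param config path to a YAML file, or a named list
#' @return A completed configuration list.
#' @export
readPipelineConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  merged <- utils::modifyList(defaultConfig(), config)
  merged
}

configSpec <- function(cfg) {
  ov <- cfg$phantom$spec
  if (is.null(ov)) ov <- list()
  if (!is.null(ov$volumeDim)) ov$volumeDim <- as.integer(unlist(ov$volumeDim))
  if (!is.null(ov$spacing)) ov$spacing <- as.numeric(unlist(ov$spacing))
  do.call(phantomSpec, ov)
}

configSegParams <- function(cfg) {
  s <- cfg$segmentation
  segmentationParams(low = if (is.null(s$low) || is.na(s$low)) NA_real_ else s$low,
                     high = if (is.null(s$high) || is.na(s$high)) NA_real_ else s$high,
                     minSize = s$min_size, connectivity = s$connectivity,
                     excludedLabels = unlist(s$excluded_labels))
}

configRefineParams <- function(cfg) {
  r <- cfg$refine
  refineParams(spurLength = r$spur_length,
               nodeMergeRadius = r$node_merge_radius,
               maxIterations = r$max_iterations)
}

configRoiParams <- function(cfg) {
  if (is.null(cfg$roi)) return(NULL)
  roiParams(alpha = cfg$roi$alpha, erosionRadius = cfg$roi$erosion_radius,
            tissueThreshold = cfg$roi$tissue_threshold)
}

writeManifest <- function(cfg, dir, stage, extra = list()) {
  man <- c(list(stage = stage,
                package = "LymphNetQuant",
                version = as.character(packageVersion("LymphNetQuant")),
                seed = cfg$seed,
                config = cfg), extra)
  jsonlite::write_json(man, file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Simulate a phantom cohort to disk
#'
#' Generates a control cohort (and, when \code{phantom$mutant} is
#' configured, a matched rarefied cohort), writing each volume as TIFF, its
#' exact ground-truth graph as JSON, and a manifest. The volume list is
#' recorded in the configuration returned, ready for [runQuantify()].
#'
#' @param config a YAML path or configuration list (see
#'   [readPipelineConfig()]); uses \code{phantom$n}, \code{phantom$spec},
#'   \code{phantom$mutant} (\code{density_factor},
#'   \code{discontinuity_prob}), \code{seed}, \code{output_dir}
#' @return The completed configuration with the generated \code{volumes}
#'   entries, invisibly.
#' @export
runSimulate <- function(config) {
  cfg <- readPipelineConfig(config)
  dir.create(file.path(cfg$output_dir, "volumes"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(cfg$output_dir, "truth"), showWarnings = FALSE)
  spec <- configSpec(cfg)
  groups <- list(control = spec)
  if (!is.null(cfg$phantom$mutant))
    groups$mutant <- mutantSpec(spec,
                                cfg$phantom$mutant$density_factor,
                                cfg$phantom$mutant$discontinuity_prob)
  volumes <- list()
  for (gname in names(groups)) {
    seedOff <- if (gname == "control") 0L else 100L
    coh <- generateCohort(groups[[gname]], cfg$phantom$n,
                          seed = cfg$seed * 1000L + seedOff)
    for (k in seq_along(coh)) {
      id <- sprintf("%s_%d", gname, k)
      vp <- file.path(cfg$output_dir, "volumes", paste0(id, ".tif"))
      tp <- file.path(cfg$output_dir, "truth", paste0(id, ".json"))
      writeVolume(coh[[k]]$volume, vp)
      writeGraph(truthGraph(coh[[k]]$truth), tp)
      volumes[[length(volumes) + 1L]] <-
        list(id = id, path = vp, spacing = as.numeric(spacingVec(spec)),
             group = gname, truth = tp)
      message("simulated ", id)
    }
  }
  cfg$volumes <- volumes
  writeManifest(cfg, cfg$output_dir, "simulate")
  yaml::write_yaml(volumes, file.path(cfg$output_dir, "volumes.yaml"))
  invisible(cfg)
}

#' Quantify the configured volumes
#'
#' Runs [quantifyVolume()] on every configured volume (or the one named by
#' \code{volumeId}), writing per-volume curated masks, refined graphs
#' (JSON + GraphML), feature CSVs and a combined feature table. Any stage
#' error aborts with the stage and volume named.
#'
#' @param config a YAML path or configuration list; volume entries may come
#'   from [runSimulate()] (\code{<output_dir>/volumes.yaml} is consulted
#'   when the config lists none)
#' @param volumeId restrict the run to one volume id
#' @return Invisibly, a list with \code{features} (combined data.frame
#'   including the group column) and \code{summaries} (per-volume
#'   aggregates).
#' @export
runQuantify <- function(config, volumeId = NULL) {
  cfg <- readPipelineConfig(config)
  vols <- cfg$volumes
  if (is.null(vols)) {
    vf <- file.path(cfg$output_dir, "volumes.yaml")
    if (file.exists(vf)) vols <- yaml::read_yaml(vf)
  }
  if (is.null(vols) || !length(vols))
    stop("no volumes configured; run runSimulate() or list volumes in the config",
         call. = FALSE)
  if (!is.null(volumeId)) {
    vols <- Filter(function(v) v$id == volumeId, vols)
    if (!length(vols)) stop("no volume with id ", volumeId, call. = FALSE)
  }
  qdir <- file.path(cfg$output_dir, "quantified")
  dir.create(qdir, recursive = TRUE, showWarnings = FALSE)
  seg <- configSegParams(cfg)
  ref <- configRefineParams(cfg)
  roi <- configRoiParams(cfg)
  feats <- list(); sums <- list(); branchCounts <- c()
  for (v in vols) {
    t0 <- Sys.time()
    stage <- "read"
    res <- tryCatch({
      vol <- readVolume(v$path, as.numeric(unlist(v$spacing)))
      stage <- "quantify"
      q <- quantifyVolume(vol, seg = seg, refine = ref, roi = roi,
                          volumeId = v$id)
      stage <- "write"
      writeMask(q$mask, file.path(qdir, paste0(v$id, "_mask.tif")))
      writeGraph(q$graph, file.path(qdir, paste0(v$id, "_graph.json")))
      writeGraph(q$graph, file.path(qdir, paste0(v$id, "_graph.graphml")))
      write.csv(q$componentReport,
                file.path(qdir, paste0(v$id, "_components.csv")),
                row.names = FALSE)
      fe <- q$features
      fe$group <- if (is.null(v$group)) NA_character_ else v$group
      write.csv(fe, file.path(qdir, paste0(v$id, "_features.csv")),
                row.names = FALSE)
      list(features = fe, graph = q$graph)
    }, error = function(e)
      stop("stage '", stage, "' failed for volume '", v$id, "': ",
           conditionMessage(e), call. = FALSE))
    feats[[v$id]] <- res$features
    branchCounts[v$id] <- branchpointCount(res$graph)
    message(sprintf("quantified %s: %d segments in %.1f s", v$id,
                    nrow(res$features),
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  allFeat <- do.call(rbind, feats)
  rownames(allFeat) <- NULL
  write.csv(allFeat, file.path(qdir, "features_all.csv"), row.names = FALSE)
  summaries <- aggregatePerVolume(allFeat, branchCounts)
  write.csv(summaries, file.path(qdir, "summaries.csv"), row.names = FALSE)
  writeManifest(cfg, cfg$output_dir, "quantify")
  invisible(list(features = allFeat, summaries = summaries))
}

#' Compare two quantified groups
#'
#' Applies the Mann-Whitney U comparison to both configured features
#' (segment length and average cross-section area by default) between two
#' groups of quantified volumes, and writes the report as CSV + JSON.
#'
#' @param config a YAML path or configuration list
#' @param groupA,groupB group labels as recorded during quantification
#' @return Invisibly, a list of \code{GroupComparison} objects (one per
#'   feature).
#' @export
runCompare <- function(config, groupA = "control", groupB = "mutant") {
  cfg <- readPipelineConfig(config)
  fa <- file.path(cfg$output_dir, "quantified", "features_all.csv")
  if (!file.exists(fa))
    stop("no quantified features found; run runQuantify() first",
         call. = FALSE)
  feat <- read.csv(fa)
  ga <- feat[feat$group == groupA, ]
  gb <- feat[feat$group == groupB, ]
  if (!nrow(ga)) stop("missing group: ", groupA, call. = FALSE)
  if (!nrow(gb)) stop("missing group: ", groupB, call. = FALSE)
  cmps <- lapply(cfg$analysis$features, function(f)
    compareGroups(ga, gb, feature = f, unit = cfg$analysis$unit,
                  alpha = cfg$analysis$alpha, labels = c(groupA, groupB)))
  writeComparison(cmps, file.path(cfg$output_dir, "comparison"))
  writeManifest(cfg, cfg$output_dir, "compare")
  for (cmp in cmps) print(cmp)
  invisible(cmps)
}
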