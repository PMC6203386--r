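#' @include stats.R
NULL

#' Experiment configuration
#'
#' Bundles the cohort configuration with pipeline options for
#' \code{\link{runExperiment}}. The seed is mandatory: every number in
#' the results bundle is regenerable from (config, seed) alone.
#'
#' @param seed integer random seed.
#' @param nWT,nHET group sizes.
#' @param spec a PhantomSpec (default: the reduced-scale spec, suitable
#'   for simulation studies on a single CPU).
#' @param schedule dynamic frame schedule.
#' @param noise,psf image-degradation toggles.
#' @param iterations,cutoff,regWeight normalization warp settings.
#' @param ctThreshold CT threshold (default 500).
#' @param focalFraction inner-striatum erosion fraction (default 0.5).
#' @param hottestFrac hottest-voxel VOI fraction (default 0.2).
#' @param routes which normalization routes to run.
#' @param ... further arguments passed to \code{\link{cohortConfig}}.
#' @return a configuration list
#' @export
experimentConfig <- function(seed, nWT = 16, nHET = 15,
                             spec = coarsePhantomSpec(),
                             schedule = defaultFrameSchedule(),
                             noise = TRUE, psf = TRUE,
                             iterations = 16, cutoff = 3, regWeight = 1,
                             ctThreshold = 500, focalFraction = 0.5,
                             hottestFrac = 0.2,
                             routes = c("mri", "pet", "ct"), ...) {
  cohort <- cohortConfig(nWT = nWT, nHET = nHET, seed = seed, spec = spec,
                         schedule = schedule, noise = noise, psf = psf,
                         ...)
  list(cohort = cohort, iterations = iterations, cutoff = cutoff,
       regWeight = regWeight, ctThreshold = ctThreshold,
       focalFraction = focalFraction, hottestFrac = hottestFrac,
       routes = routes, seed = as.integer(seed))
}

.stageLog <- function(verbose, ...) if (verbose) message(...)

#' Run the full normalization-comparison experiment
#'
#' Generates a synthetic cohort, builds the MRI / tracer-PET / CT
#' templates from the WT subjects, runs every requested normalization
#' route on every subject, quantifies striatal BP_ND with the shared
#' template VOIs and with each subject's individual labels, and emits the
#' study's statistical surface: the group table, cross-route agreement
#' (Bland-Altman), accuracy correlations against individual-label
#' quantification, volumetrics, and focal-50% / hottest-20% VOI
#' re-quantifications.
#'
#' @param config a list from \code{\link{experimentConfig}}.
#' @param verbose log stage progress (default TRUE).
#' @return a results bundle: list(results, table1, volumetrics,
#'   agreement, accuracy, focal, hottest, exclusions, templates, cohort,
#'   config)
#' @export
runExperiment <- function(config, verbose = TRUE) {
  .stageLog(verbose, "[1/5] generating cohort (n=",
            config$cohort$nWT, "+", config$cohort$nHET, ")")
  cohort <- generateCohort(config$cohort)

  .stageLog(verbose, "[2/5] building templates from WT subjects")
  templates <- buildTemplates(cohort, iterations = config$iterations,
                              cutoff = config$cutoff,
                              regWeight = config$regWeight,
                              ctThreshold = config$ctThreshold)
  vois <- templates$voisPET  # quantification at PET resolution

  .stageLog(verbose, "[3/5] running normalization routes")
  rows <- list()
  exclusions <- list()
  routeDyn <- list()
  for (i in seq_along(cohort@subjects)) {
    s <- cohort@subjects[[i]]
    id <- s$truth@id
    # individual-label reference quantification (shared CT->MRI rigid)
    rigCT <- rigidRegister(thresholdCT(s$ct, config$ctThreshold), s$mri,
                           metric = "nmi")
    ind <- quantifyIndividual(s, ctRigid = rigCT,
                              ctThreshold = config$ctThreshold)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = id, genotype = s$truth@genotype, route = "individual",
      voi = "striatum", bp = ind$fit@bp, R1 = ind$fit@R1,
      k2 = ind$fit@k2, rss = ind$fit@rss,
      converged = ind$fit@converged, trueBP = s$truth@bp)
    for (r in config$routes) {
      res <- switch(r,
        mri = routeMRI(s, templates, ctThreshold = config$ctThreshold,
                       iterations = config$iterations,
                       cutoff = config$cutoff,
                       regWeight = config$regWeight),
        pet = routePET(s, templates, iterations = config$iterations,
                       cutoff = config$cutoff,
                       regWeight = config$regWeight),
        ct = routeCT(s, templates, ctThreshold = config$ctThreshold))
      if (is.null(res$dyn)) {
        exclusions[[length(exclusions) + 1L]] <- res$provenance
        next
      }
      routeDyn[[paste(id, r, sep = ".")]] <- res$dyn
      q <- quantifyVOI(res$dyn, vois)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = id, genotype = s$truth@genotype, route = r,
        voi = "striatum", bp = q$fit@bp, R1 = q$fit@R1, k2 = q$fit@k2,
        rss = q$fit@rss, converged = q$fit@converged,
        trueBP = s$truth@bp)
    }
  }
  results <- do.call(rbind, rows)

  .stageLog(verbose, "[4/5] focal and hottest-voxel VOI re-quantification")
  # focal VOI: erode at template (MRI) resolution, then transfer to the
  # quantification grid (direct erosion of the few-voxel PET-resolution
  # striatum would destroy it)
  focalVois <- tryCatch({
    v <- erodeToFraction(templates$vois, "striatumL",
                         config$focalFraction)
    v <- erodeToFraction(v, "striatumR", config$focalFraction)
    resampleLabelMap(v, NULL, templates$petGrid, threshold = 0.5)
  }, error = function(e) NULL)
  tplStatic <- templates$pet
  hotVois <- tryCatch({
    v <- hottestFraction(tplStatic, vois, "striatumL", config$hottestFrac)
    hottestFraction(tplStatic, v, "striatumR", config$hottestFrac)
  }, error = function(e) NULL)
  requant <- function(altVois, tag) {
    if (is.null(altVois)) return(NULL)
    do.call(rbind, lapply(names(routeDyn), function(key) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      q <- quantifyVOI(routeDyn[[key]], altVois)
      gt <- vapply(cohort@subjects, function(s) s$truth@id, character(1))
      s <- cohort@subjects[[match(parts[1], gt)]]
      data.frame(subject = parts[1], genotype = s$truth@genotype,
                 route = parts[2], voi = tag, bp = q$fit@bp,
                 converged = q$fit@converged, trueBP = s$truth@bp)
    }))
  }
  focal <- requant(focalVois, sprintf("focal%.0f", 100 *
                                        config$focalFraction))
  hottest <- requant(hotVois, sprintf("hottest%.0f", 100 *
                                        config$hottestFrac))

  .stageLog(verbose, "[5/5] statistics")
  table1 <- tryCatch(makeTable1(results[results$route != "individual", ],
                                routes = config$routes),
                     error = function(e) NULL)
  volumetrics <- volumetricsCompare(cohort)
  wide <- stats::reshape(
    results[, c("subject", "genotype", "route", "bp")],
    idvar = c("subject", "genotype"), timevar = "route",
    direction = "wide")
  names(wide) <- sub("^bp\\.", "", names(wide))
  agreement <- list()
  accuracy <- list()
  for (r in config$routes) {
    if (!(r %in% names(wide))) next
    for (g in c("WT", "HET")) {
      sel <- wide$genotype == g & stats::complete.cases(wide)
      if (sum(sel) >= 3) {
        if (r != "mri" && "mri" %in% names(wide))
          agreement[[paste(r, "vs.mri", g, sep = ".")]] <-
            blandAltman(wide[[r]][sel], wide$mri[sel])
        accuracy[[paste(r, "vs.individual", g, sep = ".")]] <-
          pearsonR(wide[[r]][sel], wide$individual[sel])
      }
    }
  }
  list(results = results, table1 = table1, volumetrics = volumetrics,
       agreement = agreement, accuracy = accuracy, focal = focal,
       hottest = hottest,
       exclusions = exclusions, templates = templates, cohort = cohort,
       wide = wide, config = config)
}

#' Write the main results of an experiment bundle as CSVs
#'
#' @param bundle result of \code{\link{runExperiment}}.
#' @param dir output directory (created if needed).
#' @return dir, invisibly
#' @export
writeResults <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$results, file.path(dir, "bp_by_route.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$table1)) {
    utils::write.csv(bundle$table1$groups,
                     file.path(dir, "group_table.csv"), row.names = FALSE)
    utils::write.csv(bundle$table1$crossRoutes,
                     file.path(dir, "cross_route_table.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(bundle$volumetrics$perSubject,
                   file.path(dir, "volumetrics.csv"), row.names = FALSE)
  invisible(dir)
}
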