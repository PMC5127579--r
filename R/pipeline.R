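# One-config orchestration of the full analysis: data -> diversity
# statistics -> network -> spatial PCA -> reduced datasets -> regional Fst
# -> correlograms -> coalescent migration sweep, with hierarchical seeding
# and a JSON run report.

pipelineDefaults <- function() {
  list(
    k = 12,
    q = 0.025,
    classBounds = c(200, 400, 800, 1200, 1600, 3200),
    fstPermutations = 999,
    globalPermutations = 499,
    correlogramPermutations = 999,
    seed = 1,
    coalescent = list(enabled = FALSE)
  )
}

#' Run the full spatial STR analysis pipeline
#'
#' Executes, in order: data input (Genepop + coordinates, or the synthetic
#' generator), Fis and global Fst with permutation test, k-nearest-
#' neighbour network, spatial PCA with the global-structure test, squared-
#' loading reduction on the first two components with the optimality
#' criteria, optional regional Fst on the reduced datasets, a Moran
#' correlogram for the top-ranked allele, and an optional coalescent
#' migration-rate sweep. Per-stage CSVs and a JSON report are written to
#' the output directory. Every stochastic stage is seeded from the master
#' seed via a stage-name hash, so identical configs reproduce identical
#' reports (timings aside).
#'
#' @param config a named list or the path of a YAML file. Recognised
#'   fields: `genepop` + `coords` (input paths) or `synthetic` (arguments
#'   for [syntheticSpec()]); `k`, `q`, `classBounds`, `fstPermutations`,
#'   `globalPermutations`, `correlogramPermutations`, `regions` (named
#'   location -> region map), `coalescent` (list: `enabled`, `model`
#'   ("model1"/"model2"), `mGrid`, `R`, `observedFst`, `sampleSizes`,
#'   `mu`, `K`, `nLoci`), `seed`, `outDir`.
#' @return the run report (list), invisibly written as
#'   `file.path(outDir, "report.json")`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipelineDefaults(), config)

  # ---- pre-flight: collect every config violation before any compute ----
  problems <- character(0)
  if (is.null(cfg$outDir)) problems <- c(problems, "outDir is required")
  hasFiles <- !is.null(cfg$genepop) || !is.null(cfg$coords)
  if (hasFiles) {
    for (f in c("genepop", "coords")) {
      if (is.null(cfg[[f]])) problems <- c(problems, paste(f, "path missing"))
      else if (!file.exists(cfg[[f]]))
        problems <- c(problems, sprintf("%s file not found: %s", f, cfg[[f]]))
    }
    if (!is.null(cfg$synthetic))
      problems <- c(problems, "give either input files or a synthetic spec, not both")
  } else if (is.null(cfg$synthetic)) {
    problems <- c(problems, "either genepop+coords or a synthetic spec is required")
  }
  if (!is.numeric(cfg$k) || cfg$k < 1) problems <- c(problems, "k must be >= 1")
  if (!is.numeric(cfg$q) || cfg$q <= 0 || cfg$q > 1)
    problems <- c(problems, "q must lie in (0, 1]")
  if (any(diff(cfg$classBounds) <= 0))
    problems <- c(problems, "classBounds must be strictly increasing")
  if (length(problems))
    stop("invalid pipeline config:\n  - ", paste(problems, collapse = "\n  - "))

  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package = "strscape",
                 version = as.character(utils::packageVersion("strscape")),
                 rVersion = R.version.string,
                 seed = cfg$seed, stages = list(), timings = list())
  tic <- function() proc.time()[["elapsed"]]
  runStage <- function(name, fun) {
    t0 <- tic()
    out <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    report$timings[[name]] <<- round(tic() - t0, 3)
    out
  }

  dataset <- runStage("data", function() {
    if (hasFiles) {
      readGenepop(cfg$genepop, readCoordinates(cfg$coords))
    } else {
      spArgs <- cfg$synthetic
      spArgs$seed <- spArgs$seed %||% deriveSeed(cfg$seed, "synthetic")
      sp <- do.call(syntheticSpec, spArgs)
      sim <- simulateSTRData(sp)
      writeGroundTruth(sp, sim$truth, file.path(cfg$outDir, "ground_truth.json"))
      sim$dataset
    }
  })
  report$stages$data <- list(subjects = nSubjects(dataset),
                             loci = length(locusNames(dataset)),
                             locations = nLocations(dataset))

  stats <- runStage("stats", function() {
    fis <- estimateFis(dataset)
    utils::write.csv(fis$table, file.path(cfg$outDir, "fis.csv"),
                     row.names = FALSE)
    fst <- fstPermutationTest(dataset, B = cfg$fstPermutations,
                              seed = deriveSeed(cfg$seed, "fst"))
    list(fis = fis, fst = fst)
  })
  report$stages$stats <- list(meanFis = stats$fis$mean,
                              globalFst = stats$fst$fst,
                              fstP = stats$fst$p)

  freqs <- alleleFrequencies(dataset)
  network <- runStage("network", function()
    knnNetwork(locationInfo(dataset), k = cfg$k))

  spca <- runStage("spca", function() {
    res <- spatialPCA(freqs, network)
    utils::write.csv(data.frame(component = seq_along(eigenvalues(res)),
                                eigenvalue = eigenvalues(res),
                                variance = res@varScores,
                                moranI = res@moranScores),
                     file.path(cfg$outDir, "spca_eigenvalues.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(locationInfo(dataset), scores(res)),
                     file.path(cfg$outDir, "spca_scores.csv"),
                     row.names = FALSE)
    res
  })
  gtest <- runStage("globalTest", function()
    globalStructureTest(freqs, network, B = cfg$globalPermutations,
                        seed = deriveSeed(cfg$seed, "global")))
  ev <- eigenvalues(spca)
  report$stages$spca <- list(
    eigenvalues123 = ev[seq_len(min(3, length(ev)))],
    nPositive = sum(ev > 0), nNegative = sum(ev < 0),
    globalStructureP = gtest$p)

  red <- runStage("reduction", function() {
    sel1 <- selectTopQuantile(squaredLoadings(spca, 1), cfg$q)
    sel2 <- selectTopQuantile(squaredLoadings(spca, 2), cfg$q)
    crit <- validateReductionCriteria(sel1, sel2, dataset)
    utils::write.csv(rbind(cbind(component = "sPC1", sel1),
                           cbind(component = "sPC2", sel2)),
                     file.path(cfg$outDir, "selected_alleles.csv"),
                     row.names = FALSE)
    list(sel1 = sel1, sel2 = sel2, crit = crit,
         red1 = recodeDataset(dataset, sel1, "sPC1", cfg$q),
         red2 = recodeDataset(dataset, sel2, "sPC2", cfg$q))
  })
  report$stages$reduction <- list(
    q = cfg$q,
    selected = list(sPC1 = paste(red$sel1$locus, red$sel1$allele, sep = ":"),
                    sPC2 = paste(red$sel2$locus, red$sel2$allele, sep = ":")),
    sharedAlleles = red$crit$sharedAlleles,
    multiAlleleLoci = red$crit$multiAlleleLoci,
    fst = as.list(red$crit$fst),
    pass = as.list(red$crit$pass))

  if (!is.null(cfg$regions)) {
    regional <- runStage("regionalFst", function() {
      regions <- unlist(cfg$regions)
      out <- list()
      for (rg in unique(regions)) {
        locs <- names(regions)[regions == rg]
        keep <- locationOf(dataset) %in% locs
        if (length(locs) < 2) next
        for (nm in c("red1", "red2")) {
          rd <- red[[nm]]
          sub <- new("ReducedDataset", component = rd@component, q = rd@q,
                     selection = rd@selection,
                     dosage = rd@dosage[keep, , drop = FALSE],
                     subjectIds = rd@subjectIds[keep],
                     locationId = rd@locationId[keep],
                     locations = rd@locations[rd@locations$id %in% locs, ])
          out[[length(out) + 1L]] <- data.frame(
            region = rg, component = rd@component,
            fst = weirCockerhamFst(sub)$fst)
        }
      }
      tab <- do.call(rbind, out)
      utils::write.csv(tab, file.path(cfg$outDir, "regional_fst.csv"),
                       row.names = FALSE)
      tab
    })
    report$stages$regionalFst <- regional
  }

  corr <- runStage("correlogram", function() {
    top <- red$sel1[1, ]
    col <- which(freqs@locusCol == top$locus &
                 freqs@alleleCol == parseAllele(top$allele))
    cg <- moranCorrelogram(freqs@freq[, col], locationInfo(dataset),
                           classBounds = cfg$classBounds,
                           B = cfg$correlogramPermutations,
                           seed = deriveSeed(cfg$seed, "correlogram"))
    utils::write.csv(cg$table, file.path(cfg$outDir, "correlogram.csv"),
                     row.names = FALSE)
    list(allele = paste(top$locus, top$allele, sep = ":"), cg = cg)
  })
  report$stages$correlogram <- list(allele = corr$allele,
                                    clinal = corr$cg$clinal,
                                    moranI = corr$cg$table$moranI)

  if (isTRUE(cfg$coalescent$enabled)) {
    co <- cfg$coalescent
    sweep <- runStage("coalescent", function() {
      model <- if (identical(co$model, "model2"))
        model2Demography(m = co$m %||% 0.01) else model1Demography()
      mut <- mutationModel(mu = co$mu %||% 5e-4, K = co$K %||% 20,
                           nLoci = co$nLoci %||% 8)
      sw <- sweepMigration(model, mut,
                           sampleSizes = co$sampleSizes %||% 30,
                           mGrid = co$mGrid %||% c(0, 0.0005, 0.001, 0.0025,
                                                   0.005, 0.01, 0.02),
                           R = co$R %||% 2000,
                           observedFst = co$observedFst %||% stats$fst$fst,
                           seed = deriveSeed(cfg$seed, "coalescent"),
                           vary = if (identical(co$model, "model2"))
                             "joinerM" else "m")
      utils::write.csv(sw$table, file.path(cfg$outDir, "migration_sweep.csv"),
                       row.names = FALSE)
      sw
    })
    report$stages$coalescent <- list(best = sweep$best,
                                     table = sweep$table)
  }

  jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
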