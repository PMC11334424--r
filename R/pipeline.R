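# End-to-end pipeline driver: QC -> ecosystem labels -> prevalence filter ->
# CLR -> bootstrap k selection -> final half-sample fit -> markers
# (+ permutation FDR, pathway roll-up, top-N) -> sub-clustering -> GC
# regression -> taxonomy comparison. Every stage writes its result table plus
# a provenance record (parameters, derived seed, input-file hashes); a stage
# whose provenance matches and whose outputs exist is skipped, which makes
# runs resumable from intermediates. Stage values are always reloaded from
# the stage's own output files, so a resumed run is byte-identical to a fresh
# one. Stage seeds derive from the master seed and the stage name.

.CONFIG_DEFAULTS <- list(
  counts = NULL, samples = NULL, pathways = NULL, taxonomy = NULL,
  orientation = "samples_as_rows", outDir = "koclust_run",
  minGenes = 100000, minPctAnnotated = 30, minEcosystemCount = 100,
  minPrevalence = 0.10, clrPrior = 0.5,
  kMin = 2, kMax = 6, bootstrapB = 100, subsampleFraction = 0.8, nInit = 10,
  methods = c("kmeans", "ward"), fixedK = NA,
  trainFraction = 0.5, kSub = 2,
  alpha = 0.001, minLfc = 2, nPerm = 100, nTop = 15,
  seed = 1)

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys, and checks every parameter against
#' its documented domain. `config` may be a named list or the path of a flat
#' YAML document.
#'
#' @param config named list or YAML file path.
#' @return the completed, checked configuration list.
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path",
                             call. = FALSE)
  unknown <- setdiff(names(config), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  cfg <- modifyList(.CONFIG_DEFAULTS, config, keep.null = TRUE)
  .assertScalarNumber(cfg$minGenes, "minGenes", lower = 0)
  .assertScalarNumber(cfg$minPctAnnotated, "minPctAnnotated", lower = 0, upper = 100)
  .assertCount(cfg$minEcosystemCount, "minEcosystemCount")
  .assertScalarNumber(cfg$minPrevalence, "minPrevalence", lower = 0, upper = 1)
  .assertScalarNumber(cfg$clrPrior, "clrPrior", lower = 0)
  cfg$kMin <- .assertCount(cfg$kMin, "kMin", min = 2L)
  cfg$kMax <- .assertCount(cfg$kMax, "kMax", min = 2L)
  if (cfg$kMin > cfg$kMax) stop("kMin must not exceed kMax", call. = FALSE)
  .assertCount(cfg$bootstrapB, "bootstrapB", min = 2L)
  .assertScalarNumber(cfg$subsampleFraction, "subsampleFraction",
                      lower = 0, upper = 1, strict_lower = TRUE)
  .assertCount(cfg$nInit, "nInit", min = 1L)
  cfg$methods <- match.arg(cfg$methods, c("kmeans", "ward"), several.ok = TRUE)
  if (!is.na(cfg$fixedK)) cfg$fixedK <- .assertCount(cfg$fixedK, "fixedK", min = 2L)
  .assertScalarNumber(cfg$trainFraction, "trainFraction", lower = 0, upper = 1,
                      strict_lower = TRUE)
  .assertCount(cfg$kSub, "kSub", min = 1L)
  .assertScalarNumber(cfg$alpha, "alpha", lower = 0, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  .assertScalarNumber(cfg$minLfc, "minLfc", lower = 0)
  .assertCount(cfg$nPerm, "nPerm", min = 1L)
  .assertCount(cfg$nTop, "nTop", min = 1L)
  cfg$seed <- .assertCount(cfg$seed, "seed", min = 0L)
  if (is.null(cfg$counts) || is.null(cfg$samples))
    stop("config must name 'counts' and 'samples' input files", call. = FALSE)
  cfg
}

#' @noRd
.stageLog <- function(name, msg) message(sprintf("[%s] %s", name, msg))

# Run one stage with provenance-based skipping. `compute` must write every
# file in `outputs`; `reload` rebuilds the stage value from those files and
# is used for fresh and resumed runs alike.
#' @noRd
.runStage <- function(dir, name, params, inputFiles, outputs, compute, reload) {
  provPath <- file.path(dir, paste0("provenance_", name, ".json"))
  key <- list(stage = name, params = params,
              inputs = as.list(md5sum(inputFiles)))
  hash <- .md5String(as.character(jsonlite::toJSON(key, auto_unbox = TRUE,
                                                   digits = NA)))
  if (file.exists(provPath) && all(file.exists(outputs))) {
    prov <- try(jsonlite::read_json(provPath), silent = TRUE)
    if (!inherits(prov, "try-error") && identical(prov$hash, hash)) {
      .stageLog(name, "up to date; skipping")
      return(reload())
    }
  }
  .stageLog(name, "running")
  ok <- tryCatch({ compute(); TRUE },
                 error = function(e) stop(sprintf("stage '%s' failed: %s",
                                                  name, conditionMessage(e)),
                                          call. = FALSE))
  jsonlite::write_json(c(key, list(hash = hash, outputs = as.list(outputs),
                                   timestamp = format(Sys.time(), tz = "UTC"))),
                       provPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  reload()
}

#' @noRd
.writeDF <- function(df, path) {
  write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  path
}

#' @noRd
.readDF <- function(path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)

#' Run the full pipeline
#'
#' Executes every stage on the configured inputs, writing one table and one
#' provenance record per stage into `config$outDir`. Stages whose provenance
#' matches an earlier run are skipped (resumable). Any stage error aborts
#' with the stage name.
#'
#' @param config named list or YAML path, see [validateConfig()].
#' @return invisibly, a list with the run directory and the main stage
#'   values (chosen k/method, cluster labels, marker table, FDR estimate,
#'   GC regression, taxonomy comparisons).
#' @export
runPipeline <- function(config) {
  cfg <- validateConfig(config)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  dir <- cfg$outDir
  inFiles <- c(cfg$counts, cfg$samples)

  counts0 <- readCountMatrix(cfg$counts, orientation = cfg$orientation)
  samples0 <- readSampleTable(cfg$samples)

  # -- qc ---------------------------------------------------------------
  qcOut <- file.path(dir, c("qc_report.tsv", "counts_qc.tsv"))
  kset <- .runStage(dir, "qc",
    params = cfg[c("minGenes", "minPctAnnotated", "orientation")],
    inputFiles = inFiles, outputs = qcOut,
    compute = function() {
      qc <- applySampleQC(counts0, samples = samples0, minGenes = cfg$minGenes,
                          minPctAnnotated = cfg$minPctAnnotated)
      .writeDF(qc$report, qcOut[1L])
      writeCountMatrix(qc$kset, qcOut[2L])
    },
    reload = function() {
      ks <- readCountMatrix(qcOut[2L])
      addSampleData(ks, samples0[match(sampleIds(ks), samples0$sample_id), ,
                                 drop = FALSE])
    })

  # -- ecosystem labels -------------------------------------------------
  labOut <- file.path(dir, "sample_labels.tsv")
  kset <- .runStage(dir, "labels",
    params = cfg["minEcosystemCount"], inputFiles = inFiles, outputs = labOut,
    compute = function() {
      lab <- assignEcosystemLabels(colData(kset), minCount = cfg$minEcosystemCount)
      .writeDF(data.frame(sample_id = rownames(lab),
                          ecosystem_label = lab$ecosystem_label), labOut)
    },
    reload = function() {
      lab <- .readDF(labOut)
      cd <- colData(kset)
      cd$ecosystem_label <- lab$ecosystem_label[match(rownames(cd), lab$sample_id)]
      colData(kset) <- cd
      kset
    })

  # -- prevalence filter + CLR ------------------------------------------
  clrOut <- file.path(dir, c("counts_filtered.tsv", "clr.tsv"))
  kset <- .runStage(dir, "normalize",
    params = cfg[c("minPrevalence", "clrPrior")], inputFiles = inFiles,
    outputs = clrOut,
    compute = function() {
      kf <- filterRareKOs(kset, minPrevalence = cfg$minPrevalence)
      kf <- clrNormalize(kf, prior = cfg$clrPrior)
      writeCountMatrix(kf, clrOut[1L])
      writeCountMatrix(clrValues(kf), clrOut[2L])
    },
    reload = function() {
      kf <- readCountMatrix(clrOut[1L])
      kf <- addSampleData(kf, colData(kset)[match(sampleIds(kf), sampleIds(kset)), ,
                                            drop = FALSE])
      clr <- t(as.matrix(.readDF(clrOut[2L])[, -1L]))
      dimnames(clr) <- dimnames(koCounts(kf))
      assay(kf, "clr") <- clr
      metadata(kf)$clr_prior <- cfg$clrPrior
      kf
    })

  # -- bootstrap model selection ----------------------------------------
  selOut <- file.path(dir, c("bootstrap_scores.tsv", "chosen_model.json"))
  chosen <- .runStage(dir, "select_k",
    params = cfg[c("kMin", "kMax", "bootstrapB", "subsampleFraction",
                   "nInit", "methods", "fixedK", "minPrevalence", "clrPrior",
                   "seed")],
    inputFiles = inFiles, outputs = selOut,
    compute = function() {
      if (!is.na(cfg$fixedK)) {
        .writeDF(data.frame(method = character(), k = integer()), selOut[1L])
        jsonlite::write_json(list(k = cfg$fixedK, method = "kmeans",
                                  source = "fixedK"),
                             selOut[2L], auto_unbox = TRUE)
      } else {
        rep <- bootstrapSelect(kset, kRange = cfg$kMin:cfg$kMax,
                               methods = cfg$methods, B = cfg$bootstrapB,
                               subsampleFraction = cfg$subsampleFraction,
                               seed = .deriveSeed(cfg$seed, "select_k"),
                               nInit = cfg$nInit)
        .writeDF(summary(rep), selOut[1L])
        jsonlite::write_json(list(k = chosenK(rep), method = chosenMethod(rep),
                                  source = "bootstrap"),
                             selOut[2L], auto_unbox = TRUE)
      }
    },
    reload = function() jsonlite::read_json(selOut[2L]))

  # -- final fit ---------------------------------------------------------
  fitOut <- file.path(dir, "cluster_labels.tsv")
  labels <- .runStage(dir, "fit",
    params = c(cfg[c("trainFraction", "nInit", "seed")], k = chosen$k),
    inputFiles = inFiles, outputs = fitOut,
    compute = function() {
      model <- fitFinal(kset, k = chosen$k, trainFraction = cfg$trainFraction,
                        seed = .deriveSeed(cfg$seed, "fit"), nInit = cfg$nInit)
      .writeDF(data.frame(sample_id = names(clusterLabels(model)),
                          cluster = clusterLabels(model),
                          training = names(clusterLabels(model)) %in%
                            trainingSamples(model)), fitOut)
    },
    reload = function() {
      tab <- .readDF(fitOut)
      setNames(tab$cluster, tab$sample_id)[sampleIds(kset)]
    })

  # -- markers -----------------------------------------------------------
  mkOut <- file.path(dir, "marker_table.tsv")
  markers <- .runStage(dir, "markers",
    params = c(cfg[c("alpha", "minLfc", "seed")], k = chosen$k),
    inputFiles = inFiles, outputs = mkOut,
    compute = function() {
      mk <- callMarkers(kset, labels, alpha = cfg$alpha, minLfc = cfg$minLfc)
      .writeDF(mk, mkOut)
    },
    reload = function() {
      tab <- .readDF(mkOut)
      out <- DataFrame(tab)
      metadata(out) <- list(alpha = cfg$alpha, min_lfc = cfg$minLfc,
                            lfc_method = "difference_of_medians",
                            clusters = sub("^lfc_min_", "",
                                           grep("^lfc_min_", names(tab),
                                                value = TRUE)))
      out
    })

  # -- permutation FDR ---------------------------------------------------
  fdrOut <- file.path(dir, "permutation_fdr.json")
  fdr <- .runStage(dir, "fdr",
    params = c(cfg[c("alpha", "minLfc", "nPerm", "seed")], k = chosen$k),
    inputFiles = inFiles, outputs = fdrOut,
    compute = function() {
      pf <- permutationFDR(kset, labels, alpha = cfg$alpha,
                           minLfc = cfg$minLfc, nPerm = cfg$nPerm,
                           seed = .deriveSeed(cfg$seed, "fdr"))
      jsonlite::write_json(list(observed_markers = pf@observedMarkers,
                                perm_counts = pf@permCounts,
                                fdr_estimate = fdrEstimate(pf),
                                no_observed_markers = pf@noObservedMarkers),
                           fdrOut, auto_unbox = TRUE, digits = NA)
    },
    reload = function() jsonlite::read_json(fdrOut))

  # -- pathway roll-up (optional) ---------------------------------------
  rollup <- NULL
  if (!is.null(cfg$pathways)) {
    pwOut <- file.path(dir, c("pathway_counts.tsv", "category_counts.tsv",
                              "unmapped_markers.tsv"))
    rollup <- .runStage(dir, "pathways",
      params = cfg[c("alpha", "minLfc")],
      inputFiles = c(inFiles, cfg$pathways), outputs = pwOut,
      compute = function() {
        ru <- mapMarkersToPathways(markers, readPathwayMap(cfg$pathways))
        .writeDF(ru$pathways, pwOut[1L])
        .writeDF(ru$categories, pwOut[2L])
        .writeDF(ru$unmapped, pwOut[3L])
      },
      reload = function() list(pathways = .readDF(pwOut[1L]),
                               categories = .readDF(pwOut[2L]),
                               unmapped = .readDF(pwOut[3L])))
  }

  # -- top markers -------------------------------------------------------
  topOut <- file.path(dir, "top_markers.tsv")
  top <- .runStage(dir, "top_markers",
    params = cfg[c("alpha", "minLfc", "nTop")], inputFiles = inFiles,
    outputs = topOut,
    compute = function() {
      tm <- topMarkers(markers, n = cfg$nTop)
      if (is.null(tm)) tm <- data.frame(cluster = character(), rank = integer(),
                                        ko = character(), lfc_min = numeric(),
                                        H = numeric())
      .writeDF(tm, topOut)
    },
    reload = function() .readDF(topOut))

  # -- sub-clustering ----------------------------------------------------
  subOut <- file.path(dir, "subclusters.tsv")
  .runStage(dir, "subcluster",
    params = c(cfg[c("kSub", "nInit", "seed")], k = chosen$k),
    inputFiles = inFiles, outputs = subOut,
    compute = function() {
      model <- new("ClusterModel", method = "kmeans",
                   k = as.integer(chosen$k),
                   labels = setNames(as.integer(labels), sampleIds(kset)),
                   centers = matrix(0, 0, 0),
                   trainingSamples = sampleIds(kset),
                   seed = NA_integer_, diagnostics = list())
      subs <- subcluster(kset, model, kSub = cfg$kSub,
                         seed = .deriveSeed(cfg$seed, "subcluster"),
                         nInit = cfg$nInit)
      rows <- do.call(rbind, lapply(names(subs), function(p) {
        data.frame(sample_id = names(clusterLabels(subs[[p]])),
                   parent_cluster = as.integer(p),
                   subcluster = clusterLabels(subs[[p]]),
                   stringsAsFactors = FALSE)
      }))
      .writeDF(rows[order(rows$sample_id), ], subOut)
    },
    reload = function() .readDF(subOut))

  # -- GC analyses -------------------------------------------------------
  gcOut <- file.path(dir, c("gc_regression.tsv", "gc_cluster_comparison.tsv"))
  gcReg <- .runStage(dir, "gc",
    params = cfg[c("minPrevalence", "clrPrior")], inputFiles = inFiles,
    outputs = gcOut,
    compute = function() {
      .writeDF(gcKORegression(kset), gcOut[1L])
      cmp <- compareAcrossClusters(colData(kset)$gc_content, labels,
                                   variable = "gc_content")
      .writeDF(cbind(variable = "gc_content", H = cmp@H, p = cmp@p, cmp@dunn),
               gcOut[2L])
    },
    reload = function() .readDF(gcOut[1L]))

  # -- taxonomy comparison (optional) -----------------------------------
  taxCmp <- NULL
  if (!is.null(cfg$taxonomy)) {
    taxOut <- file.path(dir, c("taxonomy_proportions.tsv",
                               "taxonomy_comparison.tsv"))
    taxCmp <- .runStage(dir, "taxonomy",
      params = list(), inputFiles = c(inFiles, cfg$taxonomy), outputs = taxOut,
      compute = function() {
        tax <- readTaxonomyTable(cfg$taxonomy)
        prop <- taxonomyProportions(tax)
        .writeDF(prop, taxOut[1L])
        shared <- intersect(prop$sample_id, sampleIds(kset))
        rows <- do.call(rbind, lapply(.TAX_DOMAINS, function(d) {
          cmp <- compareAcrossClusters(
            prop[[d]][match(shared, prop$sample_id)],
            labels[match(shared, sampleIds(kset))], variable = d)
          cbind(variable = d, H = cmp@H, p = cmp@p, cmp@dunn)
        }))
        .writeDF(rows, taxOut[2L])
      },
      reload = function() .readDF(taxOut[2L]))
  }

  invisible(list(dir = dir, chosen = chosen, labels = labels,
                 markers = markers, fdr = fdr, pathways = rollup,
                 topMarkers = top, gcRegression = gcReg,
                 taxonomyComparison = taxCmp))
}
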