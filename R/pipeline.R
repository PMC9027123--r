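#' @include simulate.R
NULL

#' Default peak-calling mode and cut-off for an antibody
#'
#' Transcription factors (Smarca4, Ezh2) are called in narrow mode;
#' histone marks in broad mode with the island p-value cut-off 1e-10,
#' except H3K27ac-like acetylation marks which use 1e-5.
#'
#' @param antibody antibody name.
#' @return A [peakCallingConfig()].
#' @export
defaultPeakConfig <- function(antibody) {
  if (antibody %in% c("Smarca4", "Ezh2"))
    peakCallingConfig("narrow")
  else if (grepl("ac$", antibody))
    peakCallingConfig("broad", pCutoff = 1e-5)
  else
    peakCallingConfig("broad")
}

#' Pipeline configuration
#'
#' A flat configuration for [runPipeline()]. The defaults are the study's
#' printed parameters: broad islands at 200/600 with cut-offs 1e-10
#' (1e-5 for acetylation marks), DE thresholds padj < 0.05 and |log2FC| >
#' 0.58, TSS flank and upstream pad of 1 kb, enhancer extension to 3001 bp
#' with a 100 kb nearest-gene cap, and a two-sided permutation test at
#' 2.5% per tail with Bonferroni correction.
#'
#' @param outdir output directory for all stage results.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param simulate list of arguments for [simulateStudy()] /
#'   [syntheticGenomeSpec()] (the generator seed is derived from `seed`).
#' @param peakConfigs optional named list of [peakCallingConfig()] per
#'   antibody; missing antibodies fall back to [defaultPeakConfig()].
#' @param refAntibody antibody defining the basic-set partition
#'   (default `"Smarca4"`).
#' @param deAlpha,deLfcMin DE filter thresholds.
#' @param annotation an [annotationConfig()].
#' @param nPermutations,tailAlpha permutation-test settings.
#' @param enhancerLength,enhancerCap enhancer extension length and
#'   nearest-gene distance cap (bp).
#' @param profileHalfwidth,profileSpan binding-profile window half-width
#'   and LOESS span.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(outdir = tempfile("chipshift_run_"), seed = 1L,
                           simulate = list(),
                           peakConfigs = list(),
                           refAntibody = "Smarca4",
                           deAlpha = 0.05, deLfcMin = 0.58,
                           annotation = annotationConfig(),
                           nPermutations = 1e6, tailAlpha = 0.025,
                           enhancerLength = 3001L, enhancerCap = 100000L,
                           profileHalfwidth = 2500L, profileSpan = 0.3) {
  structure(list(outdir = outdir, seed = as.integer(seed),
                 simulate = simulate, peakConfigs = peakConfigs,
                 refAntibody = refAntibody, deAlpha = deAlpha,
                 deLfcMin = deLfcMin, annotation = annotation,
                 nPermutations = nPermutations, tailAlpha = tailAlpha,
                 enhancerLength = as.integer(enhancerLength),
                 enhancerCap = as.integer(enhancerCap),
                 profileHalfwidth = as.integer(profileHalfwidth),
                 profileSpan = profileSpan),
            class = "PipelineConfig")
}

.stageLog <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[chipshift] %s", sprintf(fmt, ...)))
}

#' Run the full pipeline on a synthetic study
#'
#' Orchestrates simulate, peak calling (standard and condition-swapped
#' differential), classification, gene annotation, expression integration,
#' binding-pattern permutation tests, enhancer analysis and binding
#' profiles into one reproducible run. Every stage's output is written
#' under `cfg$outdir`, along with a `manifest.json` recording package
#' version, seeds and parameters, and a machine-readable `summary.json`.
#' Re-running with the same configuration reproduces the outputs byte for
#' byte (no timestamps are recorded).
#'
#' @param cfg a [pipelineConfig()].
#' @param study optional pre-built [SyntheticStudy-class]; by default one
#'   is simulated from `cfg$simulate` with a seed derived from `cfg$seed`.
#' @param quiet suppress per-stage progress messages.
#' @return Invisibly, a list with all in-memory stage results: `study`,
#'   `classified` (per antibody), `membership`, `deFilter`, `merged`,
#'   `basicSet`, `permutation`, `enhancer`, `profiles`, `summary`.
#' @export
runPipeline <- function(cfg = pipelineConfig(), study = NULL,
                        quiet = FALSE) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  # stage 1: simulate ------------------------------------------------------
  if (is.null(study)) {
    simArgs <- cfg$simulate
    specArgs <- simArgs[intersect(names(simArgs),
                                  names(formals(syntheticGenomeSpec)))]
    specArgs$seed <- cfg$seed
    spec <- do.call(syntheticGenomeSpec, specArgs)
    restArgs <- simArgs[intersect(names(simArgs),
                                  setdiff(names(formals(simulateStudy)),
                                          c("spec", "archetypes")))]
    study <- do.call(simulateStudy, c(list(spec = spec), restArgs))
    .stageLog(quiet, "simulate: %d genes, %d enhancers, %d tracks",
              length(geneModels(study)), length(enhancerAnchors(study)),
              length(tagTracks(study)))
  }
  writeStudy(study, file.path(cfg$outdir, "study"))
  tracks <- tagTracks(study)
  input <- tracks[["input"]]
  antibodies <- unique(sub("\\.(control|kd)$", "",
                           setdiff(names(tracks), "input")))

  # stage 2: peak calling + classification ---------------------------------
  classified <- list()
  peakDir <- file.path(cfg$outdir, "peaks")
  dir.create(peakDir, showWarnings = FALSE)
  for (ab in antibodies) {
    pcfg <- if (!is.null(cfg$peakConfigs[[ab]])) cfg$peakConfigs[[ab]]
            else defaultPeakConfig(ab)
    ctrlT <- tracks[[paste0(ab, ".control")]]
    kdT <- tracks[[paste0(ab, ".kd")]]
    ctrlP <- callIslands(ctrlT, input, pcfg)
    kdP <- callIslands(kdT, input, pcfg)
    dCK <- callDifferential(ctrlT, kdT, pcfg)
    dKC <- callDifferential(kdT, ctrlT, pcfg)
    cp <- classifyPeaks(ctrlP, kdP, dCK, dKC, antibody = ab)
    classified[[ab]] <- cp
    for (cls in .PEAK_CLASSES) {
      pk <- peakClass(cp, cls)
      writeBed(pk, file.path(peakDir, sprintf("%s_%s.bed", ab, cls)),
               name = rep(cls, length(pk)),
               score = if (length(pk) && !is.null(pk$pvalue))
                 round(-log10(pmax(pk$pvalue, 1e-300)), 3) else NULL)
    }
    .stageLog(quiet,
              "callpeaks %s (%s): ctrl=%d kd=%d COM=%d INC=%d DEC=%d",
              ab, pcfg$mode, length(ctrlP), length(kdP),
              length(peakClass(cp, "COMMON")),
              length(peakClass(cp, "INCREASE")),
              length(peakClass(cp, "DECREASE")))
  }

  # stage 3: annotation -----------------------------------------------------
  membership <- assignPeaks(classified, geneModels(study), cfg$annotation)
  write.table(membership, file.path(cfg$outdir, "membership.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  .stageLog(quiet, "annotate: %d membership rows", nrow(membership))

  # stage 4: expression integration ----------------------------------------
  de <- deTable(study)
  deFilter <- filterDE(de, cfg$deAlpha, cfg$deLfcMin)
  merged <- mergeExpressionBinding(de, membership, cfg$deAlpha,
                                   cfg$deLfcMin)
  write.table(merged, file.path(cfg$outdir, "expression_binding.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  .stageLog(quiet, "integrate: %d up, %d down of %d genes",
            nrow(deFilter$up), nrow(deFilter$down), nrow(de))

  # stage 5: permutation tests ---------------------------------------------
  basicSet <- buildBasicSet(deFilter$down, membership,
                            refAntibody = cfg$refAntibody)
  otherAbs <- setdiff(antibodies, cfg$refAntibody)
  permutation <- NULL
  if ((length(basicSet$D) + length(basicSet$I)) > 0 && length(otherAbs)) {
    permutation <- runPermutationTests(
      basicSet, membership, antibodies = otherAbs,
      nPermutations = cfg$nPermutations, tailAlpha = cfg$tailAlpha,
      seed = cfg$seed + 1000L)
    write.table(permutation, file.path(cfg$outdir, "permutation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    .stageLog(quiet, "permtest: %d tests (m=%d), basic set D=%d I=%d",
              nrow(permutation), attr(permutation, "m"),
              length(basicSet$D), length(basicSet$I))
  }

  # stage 6: enhancer analysis ----------------------------------------------
  enhancer <- NULL
  if (length(enhancerAnchors(study)) &&
      cfg$refAntibody %in% names(classified)) {
    ext <- extendEnhancers(enhancerAnchors(study), cfg$enhancerLength)
    cp <- classified[[cfg$refAntibody]]
    fractions <- enhancerBindingFractions(
      ext, list(control = peakClass(cp, "ctrl"), kd = peakClass(cp, "kd"),
                COMMON = peakClass(cp, "COMMON"),
                INCREASE = peakClass(cp, "INCREASE"),
                DECREASE = peakClass(cp, "DECREASE")))
    linked <- linkAndSummarise(ext, geneModels(study), de, cp,
                               cap = cfg$enhancerCap,
                               membership = membership,
                               alpha = cfg$deAlpha, lfcMin = cfg$deLfcMin)
    enhancer <- list(extended = ext, fractions = fractions,
                     links = linked$links, summary = linked$summary)
    write.table(fractions, file.path(cfg$outdir,
                                     "enhancer_fractions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(linked$summary, file.path(cfg$outdir,
                                          "enhancer_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    .stageLog(quiet, "enhancers: %.0f%% bound in control, %.0f%% in kd",
              100 * fractions$fraction[fractions$set == "control"],
              100 * fractions$fraction[fractions$set == "kd"])
  }

  # stage 7: binding profiles -----------------------------------------------
  profiles <- list()
  for (ab in antibodies) {
    pk <- peakClass(classified[[ab]], "ctrl")
    if (!length(pk)) next
    prof <- bindingProfile(tracks[[paste0(ab, ".control")]], pk,
                           halfwidth = cfg$profileHalfwidth,
                           span = cfg$profileSpan)
    profiles[[ab]] <- prof
    write.table(as.data.frame(prof),
                file.path(cfg$outdir, sprintf("profile_%s.tsv", ab)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # summary + manifest -------------------------------------------------------
  summary <- list(
    seed = cfg$seed,
    genes = length(geneModels(study)),
    enhancers = length(enhancerAnchors(study)),
    peaks = lapply(classified, function(cp)
      lapply(setNames(.PEAK_CLASSES, .PEAK_CLASSES),
             function(cl) length(peakClass(cp, cl)))),
    de = list(up = nrow(deFilter$up), down = nrow(deFilter$down),
              total = nrow(de)),
    basic_set = list(D = length(basicSet$D), I = length(basicSet$I)),
    permutation = if (!is.null(permutation))
      permutation[c("antibody", "category", "partition", "observed",
                    "expected", "p_value", "direction", "tier")],
    enhancer_fractions = if (!is.null(enhancer)) enhancer$fractions,
    enhancer_summary = if (!is.null(enhancer)) enhancer$summary,
    profile_peak_offset = lapply(profiles, function(p)
      p$offset[which.max(p$smoothed)]))
  write_json(summary, file.path(cfg$outdir, "summary.json"),
             auto_unbox = TRUE, digits = 10, pretty = TRUE, na = "null")
  manifest <- list(package = "chipshift",
                   version = as.character(packageVersion("chipshift")),
                   seed = cfg$seed,
                   parameters = cfg[setdiff(names(cfg), "outdir")])
  write_json(manifest, file.path(cfg$outdir, "manifest.json"),
             auto_unbox = TRUE, digits = 10, pretty = TRUE, force = TRUE,
             na = "null")
  invisible(list(study = study, classified = classified,
                 membership = membership, deFilter = deFilter,
                 merged = merged, basicSet = basicSet,
                 permutation = permutation, enhancer = enhancer,
                 profiles = profiles, summary = summary))
}
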