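#' Full run configuration
#'
#' Bundles the feature, selection, IEL and ANEL settings plus the seed.
#' Defaults equal the pipeline's canonical settings: k = 1..5,
#' mismatch pairs (3,1)/(4,1)/(5,1), the per-variant (lambda, w)
#' quintuple, lag = 7, 18 maximum stacking rounds, learning rate 5e-3,
#' batch 32, 23 epochs, dropout 0.5.
#'
#' @param feature a \code{\link{featureConfig}}
#' @param selection a \code{\link{selectionControl}}
#' @param iel an \code{\link{ielControl}}
#' @param anel an \code{\link{anelControl}}
#' @param seed integer seed
#' @return a list of class \code{runConfig}
#' @export
runConfig <- function(feature = featureConfig(),
                      selection = selectionControl(),
                      iel = ielControl(), anel = anelControl(), seed = 1L) {
  structure(list(feature = feature, selection = selection, iel = iel,
                 anel = anel, seed = as.integer(seed)), class = "runConfig")
}

#' Write / read a run configuration as YAML
#'
#' The round trip \code{readRunConfig(writeRunConfig(cfg, p))} restores an
#' equal configuration.
#'
#' @param config a \code{\link{runConfig}}
#' @param path YAML file path
#' @return \code{writeRunConfig}: the path, invisibly;
#'   \code{readRunConfig}: a \code{runConfig}
#' @export
writeRunConfig <- function(config, path) {
  plain <- rapply(unclass(config), function(x) x, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  fc <- raw$feature
  mp <- lapply(fc$mismatchPairs, as.integer)
  runConfig(
    feature = featureConfig(ks = as.integer(fc$ks), mismatchPairs = mp,
                            pseNcSpecs = fc$pseNcSpecs,
                            lagMax = fc$lagMax,
                            hexamerPseudocount = fc$hexamerPseudocount),
    selection = do.call(selectionControl, raw$selection),
    iel = do.call(ielControl, raw$iel),
    anel = do.call(anelControl, raw$anel),
    seed = raw$seed)
}

#' Run one pipeline command
#'
#' The programmatic surface behind the command-line script: dispatches one
#' of the pipeline stages and writes its artifacts under \code{outDir}
#' (\code{features/}, \code{models/}, \code{reports/}), together with the
#' resolved configuration.
#'
#' \describe{
#'   \item{simulate}{writes \code{pos.fa}/\code{neg.fa} from
#'     \code{\link{generateDataset}} plus a config sidecar}
#'   \item{extract}{reads the FASTA pair and writes one TSV per block}
#'   \item{train-iel / train-anel}{fits the model on the FASTA pair (with
#'     an internal stratified 80/20 train/validation split) and persists
#'     it under \code{models/}}
#'   \item{predict}{loads a persisted model and scores a FASTA}
#'   \item{evaluate}{runs \code{\link{crossValidate}} and writes the
#'     report as JSON + TSV}
#' }
#'
#' @param command one of \code{simulate}, \code{extract}, \code{train-iel},
#'   \code{train-anel}, \code{predict}, \code{evaluate}
#' @param config a \code{\link{runConfig}}
#' @param outDir artifact directory
#' @param posFasta,negFasta labeled input FASTA pair (all commands except
#'   simulate/predict)
#' @param inputFasta FASTA to score (predict)
#' @param modelDir persisted model directory (predict)
#' @param synth a \code{\link{synthConfig}} (simulate)
#' @param method \code{"IEL"} or \code{"ANEL"} (evaluate)
#' @return invisibly, a list of the written artifact paths
#' @export
runPipeline <- function(command, config = runConfig(), outDir = ".",
                        posFasta = NULL, negFasta = NULL, inputFasta = NULL,
                        modelDir = NULL, synth = synthConfig(),
                        method = "IEL") {
  command <- match.arg(command, c("simulate", "extract", "train-iel",
                                  "train-anel", "predict", "evaluate"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeRunConfig(config, file.path(outDir, "run-config.yaml"))
  artifacts <- list(config = file.path(outDir, "run-config.yaml"))

  needPair <- function() {
    if (is.null(posFasta) || is.null(negFasta))
      stop(sprintf("'%s' needs posFasta and negFasta", command))
    readTranscriptPair(posFasta, negFasta)
  }

  if (command == "simulate") {
    ts <- generateDataset(synth)
    lab <- transcriptLabels(ts)
    posPath <- file.path(outDir, "pos.fa"); negPath <- file.path(outDir, "neg.fa")
    writeTranscripts(ts[lab == 1L], posPath)
    writeTranscripts(ts[lab == 0L], negPath)
    jsonlite::write_json(unclass(synth), file.path(outDir, "synth-config.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, list(pos = posPath, neg = negPath))
  } else if (command == "extract") {
    ts <- needPair()
    fbs <- extractFeatures(ts, config$feature)
    paths <- writeFeatureTSV(fbs, file.path(outDir, "features"))
    artifacts <- c(artifacts, list(features = paths))
  } else if (command %in% c("train-iel", "train-anel")) {
    ts <- needPair()
    lab <- transcriptLabels(ts)
    hex <- buildHexamerTable(transcriptSeqs(ts)[lab == 0L],
                             transcriptSeqs(ts)[lab == 1L],
                             config$feature$hexamerPseudocount)
    fbs <- extractFeatures(ts, config$feature, hexTable = hex)
    sp <- .stratifiedSplit(lab, 0.2, seed = config$seed)
    trainB <- .subsetBlocks(fbs, sp$train)
    valB <- .subsetBlocks(fbs, sp$val)
    selections <- fitSelections(fbs, trainIdx = sp$train, valIdx = sp$val,
                                control = config$selection, seed = config$seed)
    model <- if (command == "train-iel")
      ielFit(trainB, valB, selections, config$iel, seed = config$seed)
    else
      anelFit(trainB, valB, selections, config$anel, seed = config$seed)
    mdir <- file.path(outDir, "models",
                      if (command == "train-iel") "iel" else "anel")
    dir.create(mdir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(model, file.path(mdir, "model.rds"))
    saveRDS(hex, file.path(mdir, "hexamer-table.rds"))
    writeRunConfig(config, file.path(mdir, "config.yaml"))
    jsonlite::write_json(
      list(type = class(model)[1L], seed = config$seed,
           blocks = blockTags(fbs)),
      file.path(mdir, "manifest.json"), auto_unbox = TRUE)
    artifacts <- c(artifacts, list(model = mdir))
  } else if (command == "predict") {
    if (is.null(inputFasta) || is.null(modelDir))
      stop("'predict' needs inputFasta and modelDir")
    model <- readRDS(file.path(modelDir, "model.rds"))
    hex <- readRDS(file.path(modelDir, "hexamer-table.rds"))
    mcfg <- readRunConfig(file.path(modelDir, "config.yaml"))
    ts <- readTranscripts(inputFasta)
    fbs <- extractFeatures(ts, mcfg$feature, hexTable = hex)
    p <- predictProb(model, fbs)
    rpt <- file.path(outDir, "reports")
    dir.create(rpt, showWarnings = FALSE, recursive = TRUE)
    out <- file.path(rpt, "predictions.tsv")
    utils::write.table(
      data.frame(id = transcriptIds(ts), prob = p,
                 label = as.integer(p >= 0.5)),
      out, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, list(predictions = out))
  } else if (command == "evaluate") {
    ts <- needPair()
    report <- crossValidate(ts, method = method, config = config,
                            seed = config$seed)
    rpt <- file.path(outDir, "reports")
    dir.create(rpt, showWarnings = FALSE, recursive = TRUE)
    writeCVReport(report, file.path(rpt, "cv-report.json"),
                  file.path(rpt, "cv-report.tsv"))
    artifacts <- c(artifacts, list(report = file.path(rpt, "cv-report.json")))
  }
  invisible(artifacts)
}
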