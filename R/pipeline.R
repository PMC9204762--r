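## End-to-end pipeline: configuration, staging, provenance. Each analysis
## stage is an exported function; runPipeline() chains them:
## featurize/load -> filter -> train across splits -> align states ->
## validate -> observables -> dynamics -> contacts.

#' Build and validate a pipeline configuration
#'
#' Either pass a YAML file path or named arguments. Recognized fields:
#' `input` (directory with `features.csv` etc., or `"synthetic"`),
#' `outDir`, `k`, `lagNs`, `preset` (`"desk"`/`"paper"`), `nModels`,
#' `testFraction`, `boundCutoffNm`, `contactCutoffNm`, `errorMode`
#' (`"percentile"`/`"sd"`), `seed`, `stages` (character subset of
#' `c("validate", "observables", "dynamics", "contacts")`).
#'
#' @param file optional YAML config path.
#' @param ... fields overriding the file/defaults.
#' @return validated config list (class `"softmsmConfig"`).
#' @export
pipelineConfig <- function(file = NULL, ...) {
  cfg <- list(
    input = "synthetic", outDir = NULL, k = 2L, lagNs = 5,
    preset = "desk", nModels = 3L, testFraction = 0.1,
    boundCutoffNm = 0.5, contactCutoffNm = 0.45,
    errorMode = "percentile", seed = 1L,
    stages = c("validate", "observables", "dynamics", "contacts")
  )
  if (!is.null(file)) {
    cfg <- utils::modifyList(cfg, yaml::read_yaml(file))
  }
  cfg <- utils::modifyList(cfg, list(...))
  stopifnot(cfg$lagNs > 0, cfg$boundCutoffNm > 0, cfg$contactCutoffNm > 0,
            cfg$k >= 1, cfg$nModels >= 1)
  if (!cfg$preset %in% c("desk", "paper")) {
    stop("preset must be 'desk' or 'paper'")
  }
  if (!cfg$errorMode %in% c("percentile", "sd")) {
    stop("errorMode must be 'percentile' or 'sd'")
  }
  bad <- setdiff(cfg$stages, c("validate", "observables", "dynamics", "contacts"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if ("contacts" %in% cfg$stages && !identical(cfg$input, "synthetic")) {
    if (!file.exists(file.path(cfg$input, "contacts.csv"))) {
      stop("contact stage enabled but no contact input: ",
           file.path(cfg$input, "contacts.csv"))
    }
  }
  structure(cfg, class = "softmsmConfig")
}

configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Loads (or generates) a feature/contact data set, trains `nModels`
#' soft-assignment models on randomized train/validation splits (three
#' trials each, best kept by test-set VAMP-2), aligns states across
#' models, and runs the validation, observables, dynamics and contacts
#' stages. When `outDir` is set, every table is written as CSV/JSON with
#' a provenance stamp (config hash, seed, package version).
#'
#' @param config a config from [pipelineConfig()].
#' @param bench optional pre-generated benchmark list from
#'   [makeBenchmarkEnsemble()] (used when `input = "synthetic"`).
#' @return list with `models`, `assignments`, `koopman` (per model),
#'   `permutations`, and one entry per executed stage.
#' @export
runPipeline <- function(config = pipelineConfig(), bench = NULL) {
  stopifnot(inherits(config, "softmsmConfig"))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  ## ---- load / generate ----
  dat <- stage("input", {
    if (identical(config$input, "synthetic")) {
      if (is.null(bench)) {
        bench <- makeBenchmarkEnsemble(groundTruthSpec(seed = config$seed))
      }
      list(features = bench$features, contacts = bench$contacts,
           distances = NULL)
    } else {
      feat <- readFeatureCSV(file.path(config$input, "features.csv"))
      contacts <- NULL
      cf <- file.path(config$input, "contacts.csv")
      if (file.exists(cf)) contacts <- readFeatureCSV(cf)
      distances <- NULL
      df <- file.path(config$input, "distances.csv")
      if (file.exists(df)) distances <- readFeatureCSV(df)
      list(features = feat, contacts = contacts, distances = distances)
    }
  })
  netInput <- stage("featurize", expandCircular(dat$features))

  ## ---- unbound-frame filter (holo ensembles with distance input) ----
  mask <- rep(TRUE, nrow(featureValues(netInput)))
  if (!is.null(dat$distances)) {
    mask <- stage("filter", filterBoundFrames(dat$distances,
                                              config$boundCutoffNm))
    netInput <- newFeatureSeries(featureValues(netInput)[mask, , drop = FALSE],
                                 featureLabels(netInput),
                                 trajIds(netInput)[mask],
                                 frameInterval(netInput))
  }

  ## ---- training across splits ----
  n <- nrow(featureValues(netInput))
  plan <- makeSplits(n, testFraction = config$testFraction,
                     nSplits = config$nModels, seed = config$seed)
  hp <- presetHyperparams(config$preset)
  hp$lagNs <- config$lagNs
  fits <- stage("train", lapply(seq_len(config$nModels), function(m) {
    split <- c(plan@splits[[m]], list(test = plan@test))
    trainAssignmentModel(netInput, k = config$k, hyperparams = hp,
                         split = split, seed = deriveSeed(config$seed, m))
  }))

  ## ---- align states across models ----
  ## state-averaged feature maps, one row per state (k x p)
  maps <- lapply(fits, function(f) {
    m <- stateAverage(featureValues(dat$features)[mask, , drop = FALSE],
                      f$assignment)
    if (!is.matrix(m)) m <- matrix(m, nrow = config$k)
    m
  })
  perms <- if (config$nModels >= 2) {
    alignStatesAcrossModels(maps,
                            populations = lapply(fits, function(f)
                              equilibriumDistribution(f$koopman)))
  } else list(seq_len(config$k))
  aligned <- Map(function(f, p) permuteStates(f$assignment, f$koopman, p),
                 fits, perms)
  chis <- lapply(aligned, `[[`, "chi")
  models <- lapply(aligned, `[[`, "model")

  out <- list(models = lapply(fits, `[[`, "model"), assignments = chis,
              koopman = models, permutations = perms, splitPlan = plan,
              config = config)

  maxLag <- config$lagNs * 4
  if ("validate" %in% config$stages) {
    out$validation <- stage("validate", list(
      impliedTimescales = impliedTimescales(
        chis[[1]], lagGrid = config$lagNs * c(0.25, 0.5, 1, 2, 4)),
      ck = chapmanKolmogorov(chis[[1]], config$lagNs, nMax = 5,
                             seed = config$seed)
    ))
  }
  if ("observables" %in% config$stages) {
    out$observables <- stage("observables", {
      ts <- do.call(rbind, lapply(models, relaxationTimescales))
      lt <- do.call(rbind, lapply(models, stateLifetimes))
      pop <- do.call(rbind, lapply(models, statePopulations))
      list(
        timescales = modelEnsembleStats(ts, mode = config$errorMode,
                                        seed = config$seed),
        lifetimes = modelEnsembleStats(lt, mode = config$errorMode,
                                       seed = config$seed),
        populations = modelEnsembleStats(pop, mode = config$errorMode,
                                         seed = config$seed),
        rates = lapply(models, transitionRates)
      )
    })
  }
  if ("dynamics" %in% config$stages) {
    out$dynamics <- stage("dynamics", {
      feats <- dat$features
      fv <- featureValues(feats)[mask, , drop = FALSE]
      sub <- newFeatureSeries(fv, featureLabels(feats),
                              trajIds(feats)[mask], frameInterval(feats))
      w <- frameWeights(chis[[1]], models[[1]])
      chiCols <- grep("^chi1_", featureLabels(sub))
      list(
        ramachandran = ramachandranEntropy(sub, weights = w),
        stateEntropy = stateEntropy(chis[[1]], weights = w),
        chi1Autocorrelation = if (length(chiCols)) {
          circularAutocorrelation(
            newFeatureSeries(featureValues(sub)[, chiCols, drop = FALSE],
                             featureLabels(sub)[chiCols], trajIds(sub),
                             frameInterval(sub)),
            lagNs = config$lagNs)
        } else NULL
      )
    })
  }
  if ("contacts" %in% config$stages && !is.null(dat$contacts)) {
    out$contacts <- stage("contacts", {
      list(kinetics = contactLifetime(dat$contacts, lagNs = config$lagNs))
    })
  }
  out$elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  if (!is.null(config$outDir)) {
    stage("write", writePipelineReport(out, config))
  }
  out
}

writePipelineReport <- function(out, config) {
  dir <- config$outDir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prov <- list(configHash = configHash(config), seed = config$seed,
               package = as.character(utils::packageVersion("softmsm")),
               date = format(Sys.time(), "%Y-%m-%d"))
  jsonlite::write_json(c(prov, unclass(config)[c("k", "lagNs", "preset",
                                                 "nModels", "errorMode")]),
                       file.path(dir, "provenance.json"), auto_unbox = TRUE,
                       digits = NA)
  statNames <- c("timescales", "lifetimes", "populations")
  if (!is.null(out$observables)) {
    tabs <- lapply(statNames, function(nm) {
      s <- out$observables[[nm]]
      data.frame(quantity = nm, index = seq_along(s@mean), mean = s@mean,
                 lower = s@lower, upper = s@upper)
    })
    utils::write.csv(do.call(rbind, tabs),
                     file.path(dir, "observables.csv"), row.names = FALSE)
  }
  if (!is.null(out$validation)) {
    utils::write.csv(out$validation$impliedTimescales,
                     file.path(dir, "implied_timescales.csv"),
                     row.names = FALSE)
    ck <- out$validation$ck
    jsonlite::write_json(list(tau = ck@tau, n = ck@n,
                              maxDeviation = ck@maxDeviation,
                              pass = ck@pass),
                         file.path(dir, "ck_report.json"),
                         auto_unbox = FALSE, digits = NA)
  }
  if (!is.null(out$dynamics)) {
    ram <- out$dynamics$ramachandran
    utils::write.csv(data.frame(residue = names(ram$perResidue),
                                entropy = ram$perResidue),
                     file.path(dir, "ramachandran_entropy.csv"),
                     row.names = FALSE)
    extra <- list(stateEntropy = out$dynamics$stateEntropy,
                  totalRamachandran = ram$total)
    if (!is.null(out$dynamics$chi1Autocorrelation)) {
      extra$chi1Autocorrelation <- as.list(out$dynamics$chi1Autocorrelation)
    }
    jsonlite::write_json(extra, file.path(dir, "dynamics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(out$contacts)) {
    utils::write.csv(out$contacts$kinetics,
                     file.path(dir, "contact_kinetics.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
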