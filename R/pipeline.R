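## End-to-end pipeline: synth -> tag -> evaluate -> network -> classeffect,
## with JSON/TSV reports and a run manifest. Also the engine behind the
## command-line wrapper in inst/scripts/adrminer.R.

.defaultPipelineConfig <- function() {
  list(seed = 1L,
       synth = list(),                     # overrides for synthConfig()
       fraction = 0.5,
       min_class_size = 2L,
       stages = c("synth", "tag", "evaluate", "network", "classeffect"))
}

#' Tag a directory of labels and build per-drug profiles
#'
#' Reads every `*.xml` label under `labelsDir`, tags it with the compiled
#' dictionary, removes header matches, and collapses mentions per drug
#' (unioning over a drug's labels).
#'
#' @param labelsDir directory of label XML files.
#' @param dict compiled [TermDictionary-class].
#' @return list with `mentions` (named per label id, each a mention
#'   data.frame), `profiles` (list of [DrugAdrProfile-class]), `table`
#'   (a [DrugAdrTable-class]) and `gold` (named list of gold reaction sets
#'   for labels that carry them).
#' @export
tagLabelDirectory <- function(labelsDir, dict) {
  files <- sort(list.files(labelsDir, pattern = "\\.xml$", full.names = TRUE))
  if (!length(files)) stop(sprintf("no label XML files under '%s'", labelsDir))
  mentionsByLabel <- list()
  byDrug <- list()
  goldByDrug <- list()
  for (f in files) {
    doc <- readLabelXml(f)
    m <- tagDocument(doc, dict)
    m <- filterHeaders(m, detectHeaders(doc))
    mentionsByLabel[[labelId(doc)]] <- m
    d <- drugName(doc)
    byDrug[[d]] <- c(byDrug[[d]], list(m))
    if (!is.null(goldReactions(doc)))
      goldByDrug[[d]] <- sort(unique(c(goldByDrug[[d]], goldReactions(doc))))
  }
  profiles <- lapply(names(byDrug), function(d)
    normalizeToProfile(d, byDrug[[d]]))
  names(profiles) <- names(byDrug)
  list(mentions = mentionsByLabel, profiles = profiles,
       table = profilesToTable(profiles), gold = goldByDrug)
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  path
}

#' Run the full analysis pipeline
#'
#' Chains synthetic-universe generation, tagging, evaluation, network
#' construction and class-effect analysis, writing each stage's report
#' under `outDir` plus a run manifest. Stage selection allows partial
#' runs; later stages require the outputs of earlier ones in `outDir`.
#'
#' @param config either a path to a YAML config file or a config list;
#'   recognized keys: `seed`, `synth` (overrides for [synthConfig()]),
#'   `fraction`, `min_class_size`, `stages`.
#' @param outDir output directory.
#' @return invisibly, a list of stage results.
#' @export
runPipeline <- function(config = list(), outDir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(.defaultPipelineConfig(), config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  t0 <- Sys.time()

  uniDir <- file.path(outDir, "universe")
  if ("synth" %in% cfg$stages) {
    scfg <- do.call(synthConfig, utils::modifyList(list(seed = cfg$seed),
                                                   cfg$synth))
    res$synth <- generateUniverse(scfg, uniDir)
  }
  if (!dir.exists(uniDir))
    stop("stage error [tag]: no universe directory; run the synth stage or point outDir at one")

  dict <- compileDictionary(loadTermTable(file.path(uniDir, "dictionary.tsv")))

  if ("tag" %in% cfg$stages) {
    tg <- tagLabelDirectory(file.path(uniDir, "labels"), dict)
    res$tag <- tg
    mentionReport <- lapply(tg$mentions, function(m) {
      m$term_ids <- vapply(m$term_ids, paste, "", collapse = "|")
      m
    })
    .writeJson(mentionReport, file.path(outDir, "mentions.json"))
    .writeJson(lapply(tg$profiles, function(p)
      list(drug = drugName(p), counts = as.list(mentionCounts(p)))),
      file.path(outDir, "profiles.json"))
  }

  if ("evaluate" %in% cfg$stages) {
    if (is.null(res$tag)) stop("stage error [evaluate]: tag stage required")
    tg <- res$tag
    perDrug <- lapply(names(tg$gold), function(d) {
      pred <- if (d %in% names(tg$profiles)) adrTerms(tg$profiles[[d]])
              else character()
      evaluateDrug(pred, tg$gold[[d]])
    })
    names(perDrug) <- names(tg$gold)
    res$evaluate <- list(per_drug = perDrug,
                         micro = aggregateResults(perDrug, "micro"),
                         macro = aggregateResults(perDrug, "macro"))
    .writeJson(list(mode_note = "micro pools counts; macro averages per-drug metrics",
                    micro = unclass(res$evaluate$micro),
                    macro = unclass(res$evaluate$macro),
                    per_drug = lapply(perDrug, unclass)),
               file.path(outDir, "evaluation.json"))
  }

  if ("network" %in% cfg$stages) {
    if (is.null(res$tag)) stop("stage error [network]: tag stage required")
    net <- buildCooccurrenceNetwork(res$tag$table, cfg$fraction)
    res$network <- net
    nm <- setNames(termEntries(dict)$preferred_name, termEntries(dict)$term_id)
    exportNetwork(net, file.path(outDir, "network"), termNames = nm)
  }

  if ("classeffect" %in% cfg$stages) {
    if (is.null(res$tag)) stop("stage error [classeffect]: tag stage required")
    ontology <- loadObo(file.path(uniDir, "ontology.obo"))
    dt <- read.delim(file.path(uniDir, "drug_terms.tsv"), sep = "\t",
                     colClasses = "character")
    drugTerms <- setNames(dt$term_id, dt$drug)
    drugTerms <- drugTerms[names(drugTerms) %in% tableDrugs(res$tag$table)]
    assignment <- assignClasses(drugTerms, ontology)
    pcr <- pcrTable(assignment, res$tag$table,
                    minClassSize = cfg$min_class_size)
    write.table(pcr, file.path(outDir, "pcr.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    effects <- pcr[pcr$class_effect, , drop = FALSE]
    shared <- split(effects$adr_term_id, effects$class_id)
    subs <- lapply(shared, function(adrs) {
      adrs <- intersect(adrs, oboTerms(ontology)$id)
      if (!length(adrs)) return(NULL)
      extractSubtree(ontology, adrs, "computed_intermediate")
    })
    for (cl in names(subs)) {
      if (is.null(subs[[cl]])) next
      writeObo(subs[[cl]], file.path(outDir, sprintf(
        "shared_adrs_%s.obo", gsub("[^A-Za-z0-9]+", "_", cl))))
    }
    res$classeffect <- list(pcr = pcr, shared = shared, subtrees = subs)
  }

  cfgPath <- file.path(outDir, "config_used.json")
  .writeJson(cfg, cfgPath)
  manifest <- list(command = "runPipeline",
                   config_hash = unname(tools::md5sum(cfgPath)),
                   inputs = list(universe = uniDir),
                   seed = cfg$seed,
                   tool_version = as.character(utils::packageVersion("adrminer")),
                   started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  .writeJson(manifest, file.path(outDir, "manifest.json"))
  invisible(res)
}
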