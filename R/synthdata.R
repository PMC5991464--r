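## Synthetic test universe with planted ground truth. Real ADR
## vocabularies are license-restricted and curated label corpora are
## access-restricted, so every input artifact (dictionary, is-a ontology,
## structured labels with gold annotations, drug-class mapping) is
## synthesized from a closed vocabulary, fully determined by one seed.

.SYN_ADJECTIVES <- c("acute", "chronic", "peripheral", "transient", "severe",
                     "persistent", "recurrent", "focal", "diffuse",
                     "nocturnal", "episodic", "generalized")
.SYN_NOUNS <- c("neuropathy", "dermatitis", "cephalalgia", "myalgia",
                "vertigo", "pruritus", "emesis", "pyrexia", "tremor",
                "insomnia", "anaemia", "alopecia", "dyspnoea", "arthralgia",
                "gastritis", "oedema", "tachycardia", "leukopenia",
                "somnolence", "paraesthesia")
.SYN_ANALYTES <- c("serum creatinine" = "SCR", "blood glucose" = "BGL",
                   "alkaline reductase" = "AKR", "plasma ferritin" = "PFR",
                   "serum amylase" = "SAM", "blood urea" = "BUR")
.SYN_CATEGORIES <- c("behavioral and neurological AE", "digestive system AE",
                     "skin and subcutaneous AE", "immune system AE",
                     "hematopoietic system AE", "muscular system AE")

#' Configuration of the synthetic universe
#'
#' @param n_drugs number of drugs.
#' @param n_adr_terms number of ADR vocabulary terms.
#' @param n_labels_per_drug labels (brands) per drug.
#' @param mentions_per_label target ADR-profile size of a non-class drug
#'   (every profile ADR is mentioned in each of the drug's labels).
#' @param fraction_variant_forms probability that a planted mention is
#'   rendered through an expansion-rule variant (plural form or
#'   laboratory-finding reordering) instead of the preferred name.
#' @param planted_class_specs list of planted drug classes, each a list
#'   with `size` (member drugs), `n_shared` (ADRs shared by all members)
#'   and `n_extra` (additional ADRs private to each member).
#' @param distractor_rate expected density of distractor sentences per
#'   label (including acronym traps such as the bare word "all"); 0
#'   disables distractors.
#' @param seed integer seed; fully determines every generated byte.
#' @return validated config list of class `SynthConfig`.
#' @export
synthConfig <- function(n_drugs = 20L, n_adr_terms = 60L,
                        n_labels_per_drug = 1L, mentions_per_label = 12L,
                        fraction_variant_forms = 0.3,
                        planted_class_specs = list(
                          list(size = 3L, n_shared = 43L, n_extra = 5L)),
                        distractor_rate = 0.1, seed = 1L) {
  cfg <- list(n_drugs = as.integer(n_drugs),
              n_adr_terms = as.integer(n_adr_terms),
              n_labels_per_drug = as.integer(n_labels_per_drug),
              mentions_per_label = as.integer(mentions_per_label),
              fraction_variant_forms = fraction_variant_forms,
              planted_class_specs = planted_class_specs,
              distractor_rate = distractor_rate,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_drugs >= 1L, n_adr_terms >= 1L, n_labels_per_drug >= 1L,
              mentions_per_label >= 1L,
              fraction_variant_forms >= 0, fraction_variant_forms <= 1,
              distractor_rate >= 0)
    if (n_adr_terms > length(.SYN_ADJECTIVES) * length(.SYN_NOUNS))
      stop("n_adr_terms exceeds the closed synthetic vocabulary")
  })
  cfg$planted_class_specs <- lapply(cfg$planted_class_specs, function(s)
    list(size = as.integer(s$size), n_shared = as.integer(s$n_shared),
         n_extra = as.integer(s$n_extra)))
  sizes <- vapply(cfg$planted_class_specs, `[[`, 0L, "size")
  shared <- vapply(cfg$planted_class_specs, `[[`, 0L, "n_shared")
  extra <- vapply(cfg$planted_class_specs, `[[`, 0L, "n_extra")
  if (any(sizes < 1L) || any(shared < 0L) || any(extra < 0L))
    stop("invalid planted class spec")
  if (any(sizes == 1L & extra > 0L))
    stop("config error: a single-drug class with private extras would share its whole profile")
  if (sum(sizes) + 2L > cfg$n_drugs)
    stop("config error: planted classes leave fewer than 2 unplanted drugs")
  if (any(shared + sizes * extra > cfg$n_adr_terms))
    stop("config error: more planted ADRs than ADR terms")
  structure(cfg, class = "SynthConfig")
}

.sentenceTemplates <- c(
  "Subjects frequently experienced %s during the trial.",
  "Episodes of %s were documented by the investigators.",
  "Treatment was interrupted after %s in several participants.",
  "Clinicians additionally noted %s at follow up visits.")

.distractorSentences <- c(
  "Overall, all patients completed the scheduled follow up.",
  "Support from aids agencies was documented for some subjects.",
  "Not all subjects returned for the final review visit.")

## Pick the rendered surface for a planted mention of `entry` (a row of the
## dictionary entries data.frame), honouring fraction_variant_forms.
.renderSurface <- function(entry, useVariant, config) {
  pref <- entry$preferred_name
  if (!useVariant) return(pref)
  if (length(entry$abbreviations[[1L]])) {
    v <- setdiff(generateLabVariants(pref, entry$abbreviations[[1L]],
                                     dictConfig()), pref)
  } else {
    v <- setdiff(expandNumber(pref), pref)
  }
  v <- v[nchar(surfaceKey(v)) >= dictConfig()$minAcronymLen]
  if (!length(v)) pref else v[sample.int(length(v), 1L)]
}

#' Generate the complete synthetic universe
#'
#' Writes, under `outDir`: `dictionary.tsv` (the term dictionary),
#' `ontology.obo` (one is-a DAG holding both the chemical classification
#' of the drugs and an adverse-event hierarchy over the ADR terms),
#' `drug_terms.tsv` (drug to chemical term mapping), `labels/` (one label
#' XML per drug brand, with gold mentions and gold normalized reactions)
#' and `ground_truth.json` (planted profiles, expected network edges at
#' fraction 0.5 computed by exhaustive pair counting, and the planted
#' shared-ADR set of every planted class).
#'
#' Labels embed each profile ADR once per label, a configured fraction
#' rendered through the dictionary's own expansion-rule variants; one ADR
#' not in the drug's profile is planted inside a markup-flagged table
#' header row (a correct tagger must exclude it); distractor sentences
#' contain acronym traps. Non-planted drug classes are adjusted so that no
#' class other than the planted ones fully shares any ADR.
#'
#' @param config a [synthConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the file paths and the in-memory ground
#'   truth.
#' @export
generateUniverse <- function(config, outDir) {
  stopifnot(inherits(config, "SynthConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "labels"), showWarnings = FALSE)
  set.seed(config$seed)

  ## ---- vocabulary -------------------------------------------------------
  combos <- expand.grid(adj = .SYN_ADJECTIVES, noun = .SYN_NOUNS,
                        stringsAsFactors = FALSE)
  combos <- combos[sample.int(nrow(combos)), , drop = FALSE]
  nLab <- min(length(.SYN_ANALYTES), max(0L, config$n_adr_terms %/% 12L))
  nCombo <- config$n_adr_terms - nLab
  prefNames <- paste(combos$adj[seq_len(nCombo)], combos$noun[seq_len(nCombo)])
  if (nLab > 0L) {
    analytes <- .SYN_ANALYTES[seq_len(nLab)]
    dirWords <- rep_len(c("increased", "decreased"), nLab)
    labNames <- paste(names(analytes), dirWords)
    prefNames <- c(prefNames, labNames)
  }
  ids <- sprintf("ADR%04d", seq_len(config$n_adr_terms))
  entries <- data.frame(term_id = ids, preferred_name = prefNames,
                        stringsAsFactors = FALSE)
  entries$synonyms <- rep(list(character()), nrow(entries))
  entries$abbreviations <- rep(list(setNames(character(), character())),
                               nrow(entries))
  if (nLab > 0L) {
    for (k in seq_len(nLab)) {
      i <- nCombo + k
      entries$abbreviations[[i]] <- setNames(unname(analytes[k]),
                                             names(analytes)[k])
    }
  }
  ## a few synonyms, plus the acronym-trap entries (never planted in text)
  synIdx <- seq_len(min(5L, nCombo))
  for (i in synIdx)
    entries$synonyms[[i]] <- paste(entries$preferred_name[i], "disorder")
  trap <- data.frame(term_id = c("ADRTRAP1", "ADRTRAP2"),
                     preferred_name = c("acute lymphocytic leukaemia",
                                        "immune deficiency syndrome"),
                     stringsAsFactors = FALSE)
  trap$synonyms <- list(character(), character())
  trap$abbreviations <- list(
    c("acute lymphocytic leukaemia" = "ALL"),
    c("immune deficiency syndrome" = "AIDS"))
  entries <- rbind(entries, trap)

  ## ---- drugs, classes and ontology --------------------------------------
  drugs <- sprintf("drug%02d", seq_len(config$n_drugs))
  chemIds <- sprintf("SYN:CHM%03d", seq_len(config$n_drugs))
  classOf <- character(config$n_drugs)
  plantedClassIds <- character(0)
  nextDrug <- 1L
  for (k in seq_along(config$planted_class_specs)) {
    sz <- config$planted_class_specs[[k]]$size
    cid <- sprintf("SYN:CLS%02d", k)
    plantedClassIds <- c(plantedClassIds, cid)
    classOf[nextDrug:(nextDrug + sz - 1L)] <- cid
    nextDrug <- nextDrug + sz
  }
  rest <- seq(nextDrug, config$n_drugs)
  grpSizes <- integer(0)
  remaining <- length(rest)
  while (remaining > 0L) {
    s <- if (remaining %% 3L == 0L || remaining > 4L) 3L else 2L
    s <- min(s, remaining)
    grpSizes <- c(grpSizes, s); remaining <- remaining - s
  }
  nonClassIds <- sprintf("SYN:NCL%02d", seq_along(grpSizes))
  classOf[rest] <- rep(nonClassIds, times = grpSizes)

  rootChem <- "SYN:ROOT1"; rootAe <- "SYN:AE000"
  ontoIds <- c(rootChem, rootAe, unique(classOf), chemIds)
  ontoNames <- c("chemical entity", "adverse event",
                 paste("drug class", unique(classOf)),
                 paste("compound of", drugs))
  parents <- c(list(character(), character()),
               rep(list(rootChem), length(unique(classOf))),
               as.list(classOf))
  names(parents) <- ontoIds
  catIds <- sprintf("SYN:CAT%02d", seq_along(.SYN_CATEGORIES))
  ontoIds <- c(ontoIds, catIds)
  ontoNames <- c(ontoNames, .SYN_CATEGORIES)
  parents <- c(parents, setNames(rep(list(rootAe), length(catIds)), catIds))
  for (i in seq_len(config$n_adr_terms)) {
    cat1 <- catIds[(i - 1L) %% length(catIds) + 1L]
    ps <- cat1
    if (i %% 7L == 0L)                      # occasional multi-parent term
      ps <- c(ps, catIds[i %% length(catIds) + 1L])
    ontoIds <- c(ontoIds, ids[i])
    ontoNames <- c(ontoNames, prefNames[i])
    parents[[ids[i]]] <- ps
  }
  ontology <- new("Ontology",
                  terms = data.frame(id = ontoIds, name = ontoNames,
                                     stringsAsFactors = FALSE),
                  parents = parents)
  drugTerms <- setNames(chemIds, drugs)

  ## ---- profiles ----------------------------------------------------------
  profiles <- setNames(vector("list", config$n_drugs), drugs)
  pool <- ids
  plantedShared <- list()
  usedExtra <- character(0)
  nextDrug <- 1L
  for (k in seq_along(config$planted_class_specs)) {
    spec <- config$planted_class_specs[[k]]
    shared <- sort(sample(pool, spec$n_shared))
    plantedShared[[plantedClassIds[k]]] <- shared
    nonshared <- setdiff(pool, c(shared, usedExtra))
    for (m in seq_len(spec$size)) {
      extra <- if (spec$n_extra > 0L) sort(sample(nonshared, spec$n_extra))
               else character(0)
      nonshared <- setdiff(nonshared, extra)
      usedExtra <- c(usedExtra, extra)
      profiles[[nextDrug]] <- sort(c(shared, extra))
      nextDrug <- nextDrug + 1L
    }
  }
  core <- if (length(plantedShared))
            plantedShared[[1L]][seq_len(min(6L, length(plantedShared[[1L]])))]
          else sort(sample(pool, min(6L, length(pool))))
  for (d in seq(nextDrug, config$n_drugs)) {
    base <- core[runif(length(core)) < 0.9]
    nMore <- max(0L, config$mentions_per_label - length(base))
    more <- sample(setdiff(pool, base), min(nMore, length(setdiff(pool, base))))
    profiles[[d]] <- sort(unique(c(base, more)))
  }

  ## ---- fix-up: no non-planted class may fully share an ADR ---------------
  assignment <- assignClasses(drugTerms, ontology)
  plantedDrugs <- drugs[seq_len(sum(vapply(config$planted_class_specs,
                                           function(s) s$size, 0L)))]
  allClasses <- sort(unique(unlist(assignment, use.names = FALSE)))
  for (cl in setdiff(allClasses, plantedClassIds)) {
    members <- names(assignment)[vapply(assignment, function(x) cl %in% x,
                                        logical(1L))]
    if (length(members) < 2L) next
    sharedHere <- Reduce(intersect, profiles[members])
    for (adr in sharedHere) {
      victim <- rev(setdiff(members, plantedDrugs))[1L]
      if (is.na(victim)) next   # cannot happen: >=2 unplanted drugs enforced
      profiles[[victim]] <- setdiff(profiles[[victim]], adr)
    }
  }

  ## ---- labels ------------------------------------------------------------
  entryByIdx <- setNames(seq_len(nrow(entries)), entries$term_id)
  labelPaths <- character(0)
  mentionTruth <- list()
  for (d in seq_len(config$n_drugs)) {
    for (lb in seq_len(config$n_labels_per_drug)) {
      lid <- sprintf("%s_L%d", drugs[d], lb)
      lines <- c("ADVERSE REACTIONS",
                 sprintf("Clinical experience with %s is summarized below.",
                         drugs[d]))
      mentions <- list()
      headerRows <- list()
      offsetOf <- function(ls) if (length(ls)) sum(nchar(ls)) + length(ls) else 0L

      ## markup-flagged table with an out-of-profile ADR in its header row
      trapPool <- setdiff(ids, profiles[[d]])
      if (length(trapPool)) {
        trapAdr <- sort(trapPool)[1L + (d + lb) %% length(trapPool)]
        trapSurface <- entries$preferred_name[entryByIdx[[trapAdr]]]
        lines <- c(lines, "TABLE 1 COMMON EVENTS")
        hdrLine <- sprintf("%s incidence and severity", trapSurface)
        headerRows[[length(headerRows) + 1L]] <- data.frame(
          section_id = "S1", start = offsetOf(lines),
          length = nchar(hdrLine), stringsAsFactors = FALSE)
        lines <- c(lines, hdrLine,
                   "events were recorded in a minority of subjects")
      }

      for (j in seq_along(profiles[[d]])) {
        adr <- profiles[[d]][j]
        entry <- entries[entryByIdx[[adr]], , drop = FALSE]
        useVariant <- runif(1L) < config$fraction_variant_forms
        surf <- .renderSurface(entry, useVariant, config)
        tmpl <- .sentenceTemplates[(j - 1L) %% length(.sentenceTemplates) + 1L]
        sent <- sprintf(tmpl, surf)
        at <- offsetOf(lines) + regexpr(surf, sent, fixed = TRUE) - 1L
        mentions[[length(mentions) + 1L]] <- data.frame(
          section_id = "S1", start = as.integer(at), length = nchar(surf),
          mention_type = "AdverseReaction", surface = surf,
          term_id = adr, stringsAsFactors = FALSE)
        lines <- c(lines, sent)
      }

      if (config$distractor_rate > 0) {
        nd <- stats::rpois(1L, config$distractor_rate * 10)
        if (nd > 0L)
          lines <- c(lines, rep_len(.distractorSentences, nd))
      }

      text <- paste(lines, collapse = "\n")
      gm <- if (length(mentions)) do.call(rbind, mentions) else NULL
      hr <- if (length(headerRows)) do.call(rbind, headerRows)
            else data.frame(section_id = character(), start = integer(),
                            length = integer(), stringsAsFactors = FALSE)
      doc <- labelDocument(
        drugName = drugs[d], labelId = lid,
        sections = data.frame(section_id = "S1", title = "adverse reactions",
                              text = text, stringsAsFactors = FALSE),
        goldMentions = if (is.null(gm)) NULL
                       else gm[, c("section_id", "start", "length",
                                   "mention_type", "surface")],
        goldReactions = profiles[[d]],
        headerRows = hr)
      path <- file.path(outDir, "labels", paste0(lid, ".xml"))
      writeLabelXml(doc, path)
      labelPaths <- c(labelPaths, path)
      if (!is.null(gm)) mentionTruth[[lid]] <- gm
    }
  }

  ## ---- artifacts ---------------------------------------------------------
  dictPath <- file.path(outDir, "dictionary.tsv")
  dictTab <- data.frame(
    term_id = entries$term_id, preferred_name = entries$preferred_name,
    synonyms = vapply(entries$synonyms, paste, "", collapse = "|"),
    abbreviations = vapply(entries$abbreviations, function(a)
      paste(sprintf("%s=%s", names(a), unname(a)), collapse = "|"), ""),
    stringsAsFactors = FALSE)
  write.table(dictTab, dictPath, sep = "\t", quote = FALSE, row.names = FALSE)

  oboPath <- file.path(outDir, "ontology.obo")
  writeObo(ontology, oboPath)

  drugTermPath <- file.path(outDir, "drug_terms.tsv")
  write.table(data.frame(drug = drugs, term_id = chemIds,
                         stringsAsFactors = FALSE),
              drugTermPath, sep = "\t", quote = FALSE, row.names = FALSE)

  ## expected network by exhaustive pair counting over planted profiles
  thr <- minEdgeCount(config$n_drugs, 0.5)
  allAdr <- sort(unique(unlist(profiles, use.names = FALSE)))
  gtEdges <- list()
  for (i in seq_along(allAdr)) for (j in seq_len(i - 1L)) {
    a <- allAdr[j]; b <- allAdr[i]
    w <- sum(vapply(profiles, function(p) a %in% p && b %in% p, logical(1L)))
    if (w >= thr)
      gtEdges[[length(gtEdges) + 1L]] <- data.frame(
        a = a, b = b, weight = as.integer(w), stringsAsFactors = FALSE)
  }
  gtEdges <- if (length(gtEdges)) do.call(rbind, gtEdges)
             else data.frame(a = character(), b = character(),
                             weight = integer(), stringsAsFactors = FALSE)
  gtEdges <- gtEdges[order(gtEdges$a, gtEdges$b), , drop = FALSE]
  rownames(gtEdges) <- NULL

  truth <- list(
    seed = config$seed,
    drugs = drugs,
    adr_term_ids = ids,
    profiles = profiles,
    planted_classes = lapply(seq_along(plantedClassIds), function(k) list(
      class_id = plantedClassIds[k],
      drugs = drugs[classOf == plantedClassIds[k]],
      shared_adrs = plantedShared[[plantedClassIds[k]]])),
    expected_network = list(fraction = 0.5, min_count = thr,
                            edges = gtEdges),
    mentions = lapply(mentionTruth, function(m)
      m[, c("section_id", "start", "length", "surface", "term_id")]))
  gtPath <- file.path(outDir, "ground_truth.json")
  jsonlite::write_json(truth, gtPath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  invisible(list(dictionary = dictPath, ontology = oboPath,
                 drug_terms = drugTermPath, labels = labelPaths,
                 ground_truth = gtPath, truth = truth, entries = entries))
}
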