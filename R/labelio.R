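## Drug-label XML I/O. The dialect mirrors public structured-label corpora:
## a <Label drug= id=> root with <Text>/<Section>, optional <Mentions> with
## curated ADR spans, optional <Reactions> with normalized preferred-term
## ids, and (our extension) <HeaderRows> flagging table-header rows in the
## source markup. Offsets are 0-based, half-open, in characters.

.SECTION_STD <- c("id", "name")
.MENTION_STD <- c("id", "section", "type", "start", "len", "str")

#' Read a drug label from XML
#'
#' @param path path to a label XML file.
#' @return a [LabelDocument-class]. `goldMentions`/`goldReactions` are
#'   `NULL` (absent, not empty) when the corresponding XML sections are
#'   missing. Unknown attributes are preserved for round-tripping.
#' @export
readLabelXml <- function(path) {
  stopifnot(file.exists(path))
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf(
                    "malformed XML in '%s': %s", path, conditionMessage(e))))
  root <- xml2::xml_root(doc)
  rattrs <- xml2::xml_attrs(root)
  drug <- if ("drug" %in% names(rattrs)) rattrs[["drug"]] else ""
  lid <- if ("id" %in% names(rattrs)) rattrs[["id"]] else drug
  extra <- rattrs[setdiff(names(rattrs), c("drug", "id"))]

  secs <- xml2::xml_find_all(doc, "./Text/Section")
  sections <- data.frame(
    section_id = vapply(secs, xml2::xml_attr, "", attr = "id"),
    title = vapply(secs, xml2::xml_attr, "", attr = "name"),
    text = vapply(secs, xml2::xml_text, ""),
    stringsAsFactors = FALSE)
  sections$title[is.na(sections$title)] <- ""
  for (s in secs) {
    at <- xml2::xml_attrs(s)
    for (nm in setdiff(names(at), .SECTION_STD)) {
      col <- paste0("attr_", nm)
      if (!col %in% names(sections)) sections[[col]] <- NA_character_
      sections[[col]][match(xml2::xml_attr(s, "id"), sections$section_id)] <- at[[nm]]
    }
  }

  gm <- NULL
  mnode <- xml2::xml_find_first(doc, "./Mentions")
  if (!inherits(mnode, "xml_missing")) {
    ms <- xml2::xml_find_all(mnode, "./Mention")
    gm <- data.frame(
      section_id = vapply(ms, xml2::xml_attr, "", attr = "section"),
      start = as.integer(vapply(ms, xml2::xml_attr, "", attr = "start")),
      length = as.integer(vapply(ms, xml2::xml_attr, "", attr = "len")),
      mention_type = vapply(ms, xml2::xml_attr, "", attr = "type"),
      surface = vapply(ms, xml2::xml_attr, "", attr = "str"),
      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(gm))) {
      sec <- match(gm$section_id[i], sections$section_id)
      if (is.na(sec))
        stop(sprintf("mention %d in '%s' references unknown section '%s'",
                     i, path, gm$section_id[i]))
      got <- sliceText(sections$text[sec], gm$start[i], gm$length[i])
      if (!identical(got, gm$surface[i]))
        stop(sprintf(
          "offset error for mention %d in '%s': slice '%s' != str '%s'",
          i, path, got, gm$surface[i]))
    }
  }

  gr <- NULL
  rnode <- xml2::xml_find_first(doc, "./Reactions")
  if (!inherits(rnode, "xml_missing")) {
    norm <- xml2::xml_find_all(rnode, "./Reaction/Normalization")
    ids <- vapply(norm, xml2::xml_attr, "", attr = "meddra_pt_id")
    gr <- sort(unique(ids[!is.na(ids) & nzchar(ids)]))
  }

  hr <- xml2::xml_find_all(doc, "./HeaderRows/HeaderRow")
  headerRows <- data.frame(
    section_id = vapply(hr, xml2::xml_attr, "", attr = "section"),
    start = as.integer(vapply(hr, xml2::xml_attr, "", attr = "start")),
    length = as.integer(vapply(hr, xml2::xml_attr, "", attr = "len")),
    stringsAsFactors = FALSE)

  new("LabelDocument", drugName = drug, labelId = lid, sections = sections,
      goldMentions = gm, goldReactions = gr, headerRows = headerRows,
      extraAttrs = extra)
}

#' Write a drug label to XML
#'
#' Inverse of [readLabelXml()]: reading the written file reproduces the
#' document field-for-field (including non-ASCII text and any preserved
#' unknown attributes).
#'
#' @param doc a [LabelDocument-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeLabelXml <- function(doc, path) {
  stopifnot(is(doc, "LabelDocument"))
  validObject(doc)
  root <- xml2::xml_new_root("Label", drug = doc@drugName, id = doc@labelId)
  for (nm in names(doc@extraAttrs)) xml2::xml_set_attr(root, nm, doc@extraAttrs[[nm]])
  txt <- xml2::xml_add_child(root, "Text")
  s <- doc@sections
  extraCols <- grep("^attr_", names(s), value = TRUE)
  for (i in seq_len(nrow(s))) {
    node <- xml2::xml_add_child(txt, "Section", id = s$section_id[i],
                                name = s$title[i])
    for (col in extraCols) {
      if (!is.na(s[[col]][i]))
        xml2::xml_set_attr(node, sub("^attr_", "", col), s[[col]][i])
    }
    xml2::xml_set_text(node, s$text[i])
  }
  if (nrow(doc@headerRows)) {
    hr <- xml2::xml_add_child(root, "HeaderRows")
    for (i in seq_len(nrow(doc@headerRows))) {
      xml2::xml_add_child(hr, "HeaderRow",
                          section = doc@headerRows$section_id[i],
                          start = as.character(doc@headerRows$start[i]),
                          len = as.character(doc@headerRows$length[i]))
    }
  }
  if (!is.null(doc@goldMentions)) {
    mn <- xml2::xml_add_child(root, "Mentions")
    gm <- doc@goldMentions
    for (i in seq_len(nrow(gm))) {
      xml2::xml_add_child(mn, "Mention", id = sprintf("M%d", i),
                          section = gm$section_id[i],
                          type = gm$mention_type[i],
                          start = as.character(gm$start[i]),
                          len = as.character(gm$length[i]),
                          str = gm$surface[i])
    }
  }
  if (!is.null(doc@goldReactions)) {
    rn <- xml2::xml_add_child(root, "Reactions")
    for (i in seq_along(doc@goldReactions)) {
      r <- xml2::xml_add_child(rn, "Reaction", id = sprintf("AR%d", i))
      xml2::xml_add_child(r, "Normalization", id = sprintf("AR%d.N1", i),
                          meddra_pt_id = doc@goldReactions[i])
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Construct a LabelDocument in memory
#'
#' @param drugName,labelId identifying strings.
#' @param sections data.frame with `section_id`, `title`, `text`.
#' @param goldMentions optional mention data.frame (`section_id`, `start`,
#'   `length`, `mention_type`, `surface`); `NULL` for unannotated labels.
#' @param goldReactions optional character vector of normalized term ids.
#' @param headerRows optional data.frame of markup-flagged table-header
#'   spans (`section_id`, `start`, `length`).
#' @return a validated [LabelDocument-class].
#' @export
labelDocument <- function(drugName, labelId, sections, goldMentions = NULL,
                          goldReactions = NULL,
                          headerRows = data.frame(section_id = character(),
                                                  start = integer(),
                                                  length = integer(),
                                                  stringsAsFactors = FALSE)) {
  new("LabelDocument", drugName = drugName, labelId = labelId,
      sections = sections, goldMentions = goldMentions,
      goldReactions = goldReactions, headerRows = headerRows,
      extraAttrs = setNames(character(), character()))
}

#' Detect section and table headers in a label
#'
#' Returns spans that the tagger must ignore: (i) lines equal to the
#' section's own title (case-insensitive, after trimming), (ii) lines
#' matching the header regex (by default fully upper-case lines, the usual
#' rendering of section/table headings in label text), and (iii) rows
#' flagged as table headers in the source markup.
#'
#' @param doc a [LabelDocument-class].
#' @param headerRegex regular expression a whole (trimmed) line must match
#'   to count as a header line.
#' @return data.frame with columns `section_id`, `start`, `length`.
#' @export
detectHeaders <- function(doc, headerRegex = "^[A-Z][A-Z0-9 ,:()/-]*$") {
  stopifnot(is(doc, "LabelDocument"))
  out <- list()
  s <- doc@sections
  for (i in seq_len(nrow(s))) {
    text <- s$text[i]
    if (!nzchar(text)) next
    lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
    offs <- c(0L, cumsum(nchar(lines) + 1L))[seq_along(lines)]
    for (j in seq_along(lines)) {
      ln <- trimws(lines[j])
      if (!nzchar(ln)) next
      isTitle <- nzchar(s$title[i]) && tolower(ln) == tolower(trimws(s$title[i]))
      isCaps <- grepl(headerRegex, ln, perl = TRUE)
      if (isTitle || isCaps) {
        out[[length(out) + 1L]] <- data.frame(
          section_id = s$section_id[i], start = offs[j],
          length = nchar(lines[j]), stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(section_id = character(), start = integer(),
                         length = integer(), stringsAsFactors = FALSE)
  res <- rbind(res, doc@headerRows)
  res <- unique(res)
  res[order(match(res$section_id, s$section_id), res$start), , drop = FALSE]
}
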