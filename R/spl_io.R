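# SPL label input/output: a simplified dialect of the FDA Structured Product
# Labeling XML.  Documents are reduced to an ordered list of LOINC-coded
# narrative sections with stable 0-based character offsets over the
# concatenated plain text (sections joined by single newlines).

#' The eight medical-condition-related LOINC sections
#'
#' FDA drug labels carry 80 LOINC-coded section types; only eight of them
#' contain medical-condition narrative relevant to indication,
#' contraindication, overdosage and adverse-reaction mining.  This returns
#' the default whitelist mapping those eight LOINC codes to their canonical
#' singular headers.
#'
#' @param codes Character vector of LOINC codes to include. Defaults to the
#'   eight medical-condition sections.
#' @return An object of class `section_whitelist`: a named character vector
#'   mapping LOINC code to canonical header.
#' @examples
#' section_whitelist()
#' @export
section_whitelist <- function(codes = NULL) {
  full <- c(
    "34066-1" = "BOXED WARNING",
    "42232-9" = "PRECAUTION",
    "43685-7" = "WARNING AND PRECAUTION",
    "34071-1" = "WARNING",
    "34070-3" = "CONTRAINDICATION",
    "34088-5" = "OVERDOSAGE",
    "34067-9" = "INDICATION",
    "34084-4" = "ADVERSE REACTION"
  )
  if (!is.null(codes)) {
    bad <- setdiff(codes, names(full))
    if (length(bad) > 0) {
      stop("unknown LOINC code(s): ", paste(bad, collapse = ", "))
    }
    full <- full[codes]
  }
  structure(full, class = "section_whitelist")
}

loinc_code_valid <- function(x) grepl("^[0-9]{5}-[0-9]$", x)

collapse_ws <- function(x) {
  gsub("[[:space:]]+", " ", trimws(x))
}

# Recompute char_start/char_end so that section texts tile the concatenated
# document text with single-newline separators.
recompute_offsets <- function(sections) {
  n <- nrow(sections)
  if (n == 0) {
    sections$char_start <- integer(0)
    sections$char_end <- integer(0)
    return(sections)
  }
  lens <- nchar(sections$text)
  starts <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    starts[i] <- pos
    pos <- pos + lens[i] + 1L # +1 for the newline separator
  }
  sections$char_start <- starts
  sections$char_end <- starts + lens
  sections
}

new_label_document <- function(doc_id, drug_name, ndc, category, sections) {
  stopifnot(is.data.frame(sections))
  sections <- recompute_offsets(sections)
  structure(
    list(doc_id = doc_id, drug_name = drug_name, ndc = ndc,
         category = category, sections = sections),
    class = "label_document"
  )
}

#' Parse a drug label in simplified SPL XML
#'
#' Reads one drug label in the simplified SPL dialect:
#' \preformatted{
#' <label id="..." category="OTC|Rx_Top200|Rx_Other">
#'   <drug name="..." ndc="..."/>
#'   <section code="NNNNN-N" title="...">mixed narrative content</section>
#'   ...
#' </label>
#' }
#' All inline markup inside `<section>` is stripped, whitespace runs are
#' collapsed to single spaces and section edges trimmed, so offsets are
#' independent of XML pretty-printing.  Unknown elements are ignored.  No
#' section filtering happens here; see [filter_sections()].
#'
#' @param xml_text A length-1 character string of XML, or a file path.
#' @return A `label_document`: list with `doc_id`, `drug_name`, `ndc`,
#'   `category` and a `sections` data frame (`loinc_code`, `header`, `text`,
#'   `char_start`, `char_end`; offsets 0-based half-open over the
#'   concatenated document text, sections separated by single newlines).
#' @seealso [filter_sections()], [document_text()], [serialize_spl()]
#' @export
parse_spl <- function(xml_text) {
  doc <- tryCatch(
    xml2::read_xml(xml_text),
    error = function(e) stop("malformed SPL XML: ", conditionMessage(e),
                             call. = FALSE)
  )
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "label") {
    stop("structural error: root element must be <label>, found <",
         xml2::xml_name(root), ">", call. = FALSE)
  }
  doc_id <- xml2::xml_attr(root, "id")
  if (is.na(doc_id)) doc_id <- ""
  category <- xml2::xml_attr(root, "category")
  if (is.na(category) || !category %in% c("OTC", "Rx_Top200", "Rx_Other")) {
    category <- "unknown"
  }
  drug <- xml2::xml_find_first(root, "./drug")
  if (inherits(drug, "xml_missing")) {
    stop("structural error: missing <drug> element", call. = FALSE)
  }
  drug_name <- xml2::xml_attr(drug, "name")
  if (is.na(drug_name) || !nzchar(drug_name)) {
    stop("structural error: <drug> element has no non-empty name attribute",
         call. = FALSE)
  }
  ndc <- xml2::xml_attr(drug, "ndc")
  if (is.na(ndc)) ndc <- ""

  secs <- xml2::xml_find_all(root, "./section")
  n <- length(secs)
  codes <- character(n); headers <- character(n); texts <- character(n)
  for (i in seq_len(n)) {
    code <- xml2::xml_attr(secs[[i]], "code")
    if (is.na(code)) {
      stop("structural error: section ", i - 1L,
           " has no LOINC code attribute", call. = FALSE)
    }
    if (!loinc_code_valid(code)) {
      stop("structural error: section ", i - 1L,
           " has syntactically invalid LOINC code '", code, "'",
           call. = FALSE)
    }
    title <- xml2::xml_attr(secs[[i]], "title")
    codes[i] <- code
    headers[i] <- if (is.na(title)) "" else title
    texts[i] <- collapse_ws(xml2::xml_text(secs[[i]]))
  }
  sections <- data.frame(loinc_code = codes, header = headers, text = texts,
                         stringsAsFactors = FALSE)
  new_label_document(doc_id, drug_name, ndc, category, sections)
}

#' Serialize a label document back to simplified SPL XML
#'
#' Inverse of [parse_spl()] on the simplified dialect: parse, serialize and
#' re-parse yield identical section codes, headers and texts.
#'
#' @param doc A `label_document`.
#' @return A length-1 character string of XML.
#' @export
serialize_spl <- function(doc) {
  stopifnot(inherits(doc, "label_document"))
  root <- xml2::xml_new_root("label")
  xml2::xml_set_attr(root, "id", doc$doc_id)
  if (doc$category != "unknown") xml2::xml_set_attr(root, "category", doc$category)
  drug <- xml2::xml_add_child(root, "drug")
  xml2::xml_set_attr(drug, "name", doc$drug_name)
  if (nzchar(doc$ndc)) xml2::xml_set_attr(drug, "ndc", doc$ndc)
  for (i in seq_len(nrow(doc$sections))) {
    sec <- xml2::xml_add_child(root, "section")
    xml2::xml_set_attr(sec, "code", doc$sections$loinc_code[i])
    if (nzchar(doc$sections$header[i])) {
      xml2::xml_set_attr(sec, "title", doc$sections$header[i])
    }
    xml2::xml_set_text(sec, doc$sections$text[i])
  }
  as.character(root)
}

#' @export
print.label_document <- function(x, ...) {
  cat("<label_document> ", x$doc_id, ": ", x$drug_name, sep = "")
  if (nzchar(x$ndc)) cat(" (NDC ", x$ndc, ")", sep = "")
  cat(" [", x$category, "]\n", sep = "")
  cat(nrow(x$sections), "section(s)\n")
  if (nrow(x$sections) > 0) {
    for (i in seq_len(nrow(x$sections))) {
      cat(sprintf("  [%d] %s %s (%d chars)\n", i - 1L,
                  x$sections$loinc_code[i], x$sections$header[i],
                  nchar(x$sections$text[i])))
    }
  }
  invisible(x)
}

#' Keep only whitelisted LOINC sections
#'
#' Returns a new document whose sections are exactly those whose LOINC code
#' is in the whitelist, in original order, with offsets recomputed and each
#' retained section's header replaced by the whitelist's canonical header.
#' A document with no retained sections is a valid empty result.
#'
#' @param doc A `label_document`.
#' @param whitelist A [section_whitelist()].
#' @return A `label_document`.
#' @export
filter_sections <- function(doc, whitelist = section_whitelist()) {
  stopifnot(inherits(doc, "label_document"))
  if (length(whitelist) == 0) stop("whitelist must be non-empty")
  keep <- doc$sections$loinc_code %in% names(whitelist)
  sections <- doc$sections[keep, , drop = FALSE]
  rownames(sections) <- NULL
  sections$header <- unname(whitelist[sections$loinc_code])
  new_label_document(doc$doc_id, doc$drug_name, doc$ndc, doc$category,
                     sections)
}

#' Concatenated plain text of a label document
#'
#' @param doc A `label_document`.
#' @return The document plain text: section texts joined by single newlines
#'   (empty string for a document with no sections).
#' @export
document_text <- function(doc) {
  stopifnot(inherits(doc, "label_document"))
  paste(doc$sections$text, collapse = "\n")
}

#' Map a document-level character offset to a section-local offset
#'
#' @param doc A `label_document`.
#' @param offset 0-based document-level character offset; must fall strictly
#'   inside the document text (half-open convention — the total length is
#'   out of range).  Offsets on a newline separator map to the following
#'   section with a local offset of -1 flagged as an error instead.
#' @return A list with `section_index` (0-based) and `local` (0-based offset
#'   within that section's text).
#' @export
offset_to_section <- function(doc, offset) {
  stopifnot(inherits(doc, "label_document"))
  total <- nchar(document_text(doc))
  if (length(offset) != 1 || is.na(offset) || offset < 0 || offset >= total) {
    stop("offset ", offset, " out of range [0, ", total, ")", call. = FALSE)
  }
  s <- doc$sections
  i <- which(offset >= s$char_start & offset < s$char_end)
  if (length(i) == 0) {
    stop("offset ", offset, " falls on a section separator", call. = FALSE)
  }
  list(section_index = i - 1L, local = as.integer(offset - s$char_start[i]))
}

#' Write parsed labels as plain text plus a JSON section index
#'
#' One `.txt` file (the concatenated plain text) and one `.json` section
#' index (`doc_id`, `drug_name`, `sections` with code/header/start/end) per
#' document.
#'
#' @param docs A list of `label_document`s.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_plaintext <- function(docs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (doc in docs) {
    base <- file.path(dir, doc$doc_id)
    writeLines(document_text(doc), paste0(base, ".txt"), useBytes = TRUE)
    idx <- list(
      doc_id = doc$doc_id, drug_name = doc$drug_name,
      sections = lapply(seq_len(nrow(doc$sections)), function(i) {
        list(code = doc$sections$loinc_code[i],
             header = doc$sections$header[i],
             start = doc$sections$char_start[i],
             end = doc$sections$char_end[i])
      })
    )
    jsonlite::write_json(idx, paste0(base, ".json"), auto_unbox = TRUE)
    paths <- c(paths, paste0(base, ".txt"), paste0(base, ".json"))
  }
  invisible(paths)
}
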