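# Span annotations over label sections, BIO label conversion, fold building
# and the standoff TSV format.
#
# A set of annotations is a plain data frame with the columns
#   doc_id, section_index (0-based), char_start, char_end (0-based,
#   half-open, in section text), category (DD/SS/MC), surface.
# DD/SS categories are kept in gold files but collapsed to a single MC class
# for tagging and scoring.  Only continuous spans are representable;
# overlapping spans are allowed (needed for gold standards where two
# mentions share tokens).

bio_labels <- c("MC_B", "MC_I", "O")

#' Construct a span-annotation data frame
#'
#' @param doc_id,section_index,char_start,char_end,category,surface Vectors
#'   of equal length (recycled where length 1).  Offsets are 0-based
#'   half-open within the section text; `section_index` is 0-based.
#' @return A data frame of annotations.
#' @export
span_annotations <- function(doc_id = character(0),
                             section_index = integer(0),
                             char_start = integer(0),
                             char_end = integer(0),
                             category = character(0),
                             surface = character(0)) {
  ann <- data.frame(doc_id = as.character(doc_id),
                    section_index = as.integer(section_index),
                    char_start = as.integer(char_start),
                    char_end = as.integer(char_end),
                    category = as.character(category),
                    surface = as.character(surface),
                    stringsAsFactors = FALSE)
  bad <- !ann$category %in% c("DD", "SS", "MC")
  if (any(bad)) stop("invalid category: ", paste(unique(ann$category[bad]), collapse = ", "))
  if (any(ann$char_start < 0) || any(ann$char_end <= ann$char_start)) {
    stop("invalid span offsets: need 0 <= char_start < char_end")
  }
  ann
}

section_text_at <- function(doc, section_index) {
  i <- section_index + 1L
  if (i < 1L || i > nrow(doc$sections)) {
    stop("doc ", doc$doc_id, ": no section with index ", section_index,
         call. = FALSE)
  }
  doc$sections$text[i]
}

#' Validate annotations against their documents
#'
#' Checks that every annotation's offsets lie inside its section text and
#' that its surface equals the text slice.  Used by the standoff reader and
#' by the synthetic generator's self-checks.
#'
#' @param ann Annotation data frame (see [span_annotations()]).
#' @param docs Named list of `label_document`s (names = doc_id), or an
#'   unnamed list (doc_ids are read from the documents).
#' @return Invisibly `ann`; stops with a validation error otherwise.
#' @export
validate_annotations <- function(ann, docs) {
  if (is.null(names(docs))) {
    names(docs) <- vapply(docs, function(d) d$doc_id, character(1))
  }
  for (i in seq_len(nrow(ann))) {
    d <- docs[[ann$doc_id[i]]]
    if (is.null(d)) stop("validation error: unknown doc_id ", ann$doc_id[i])
    txt <- section_text_at(d, ann$section_index[i])
    if (ann$char_end[i] > nchar(txt)) {
      stop("validation error: doc ", ann$doc_id[i], " section ",
           ann$section_index[i], " span [", ann$char_start[i], ",",
           ann$char_end[i], ") exceeds section length ", nchar(txt))
    }
    slice <- substr(txt, ann$char_start[i] + 1L, ann$char_end[i])
    if (slice != ann$surface[i]) {
      stop("validation error: doc ", ann$doc_id[i], " section ",
           ann$section_index[i], " offsets [", ann$char_start[i], ",",
           ann$char_end[i], "): surface '", ann$surface[i],
           "' != text slice '", slice, "'")
    }
  }
  invisible(ann)
}

#' Encode spans as BIO token labels
#'
#' Maps character spans onto one label per token: a token that begins at
#' least one span is `MC_B`, a token covered by at least one span (but
#' beginning none) is `MC_I`, all others are `O`.  Overlapping spans are
#' collapsed to this token-level union, so a token shared as the start of
#' two mentions yields a single `MC_B` — the convention used by token-level
#' scoring of overlapping gold entities.  The DD/SS distinction is erased.
#'
#' @param tokens Token data frame from [tokenize()] (columns `text`,
#'   `char_start`, `char_end`), sorted and non-overlapping.
#' @param spans Annotation data frame for the same text region; offsets in
#'   the same coordinate system as `tokens`.
#' @return Character vector of labels, one per token.
#' @export
encode_bio <- function(tokens, spans) {
  n <- nrow(tokens)
  labels <- rep("O", n)
  if (is.null(spans) || nrow(spans) == 0) return(labels)
  in_mention <- rep(FALSE, n)
  begins <- rep(FALSE, n)
  for (i in seq_len(nrow(spans))) {
    s <- spans$char_start[i]; e <- spans$char_end[i]
    cov <- which(tokens$char_start < e & tokens$char_end > s)
    if (length(cov) == 0) {
      stop("alignment error: span [", s, ",", e,
           ") covers no token", call. = FALSE)
    }
    if (tokens$char_start[cov[1]] != s ||
        tokens$char_end[cov[length(cov)]] != e) {
      stop("alignment error: span [", s, ",", e, ") '",
           if ("surface" %in% names(spans)) spans$surface[i] else "",
           "' boundary falls strictly inside a token", call. = FALSE)
    }
    in_mention[cov] <- TRUE
    begins[cov[1]] <- TRUE
  }
  labels[in_mention] <- "MC_I"
  labels[begins] <- "MC_B"
  labels
}

#' Decode BIO token labels into spans
#'
#' Maximal label runs starting at `MC_B` become spans; an orphan `MC_I`
#' (directly after `O` or at sequence start, as raw CRF output may produce)
#' leniently starts a new span.  Category is always `MC`.
#'
#' @param tokens Token data frame (columns `text`, `char_start`,
#'   `char_end`).
#' @param labels Character vector of BIO labels, same length as `tokens`.
#' @param text Optional section text used to recover exact surfaces
#'   (including inter-token whitespace); if `NULL`, token texts are joined
#'   with single spaces.
#' @param doc_id,section_index Metadata copied onto the result.
#' @return Annotation data frame, sorted, non-overlapping.
#' @export
decode_bio <- function(tokens, labels, text = NULL, doc_id = "",
                       section_index = 0L) {
  stopifnot(nrow(tokens) == length(labels))
  starts <- integer(0); ends <- integer(0)
  i <- 1L; n <- length(labels)
  while (i <= n) {
    if (labels[i] %in% c("MC_B", "MC_I")) {
      j <- i
      while (j + 1L <= n && labels[j + 1L] == "MC_I") j <- j + 1L
      starts <- c(starts, tokens$char_start[i])
      ends <- c(ends, tokens$char_end[j])
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  surface <- if (length(starts) == 0) {
    character(0)
  } else if (is.null(text)) {
    vapply(seq_along(starts), function(k) {
      idx <- which(tokens$char_start >= starts[k] & tokens$char_end <= ends[k])
      paste(tokens$text[idx], collapse = " ")
    }, character(1))
  } else {
    substring(text, starts + 1L, ends)
  }
  span_annotations(doc_id = rep(doc_id, length(starts)),
                   section_index = rep(as.integer(section_index), length(starts)),
                   char_start = starts, char_end = ends,
                   category = rep("MC", length(starts)),
                   surface = surface)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Assign documents to cross-validation folds
#'
#' Greedy balanced assignment: documents are taken in descending
#' `balance_counts` order (entity counts, token counts, ...) and each is
#' placed in the currently lightest eligible fold, where eligibility keeps
#' fold sizes within one document of each other.  Ties are broken by a
#' seeded shuffle, so the assignment is deterministic given the seed.
#'
#' @param doc_ids Character vector of unique document ids.
#' @param k Number of folds (>= 2).
#' @param balance_counts Named numeric vector (names = doc_ids) used to
#'   balance fold totals; defaults to 1 per document.
#' @param seed Integer seed.
#' @return Object of class `fold_assignment`: list with `k` and `mapping`
#'   (named integer vector of fold indices in `[0, k)`).
#' @export
split_folds <- function(doc_ids, k, balance_counts = NULL, seed = 1L) {
  if (k < 2) stop("configuration error: k must be >= 2")
  n <- length(doc_ids)
  if (anyDuplicated(doc_ids)) stop("doc_ids must be unique")
  if (k > n) stop("configuration error: k (", k, ") exceeds number of documents (", n, ")")
  if (is.null(balance_counts)) {
    balance_counts <- setNames(rep(1, n), doc_ids)
  }
  counts <- balance_counts[doc_ids]
  counts[is.na(counts)] <- 0
  fl <- n %/% k
  r <- n %% k
  mapping <- with_seed(seed, {
    ord <- sample.int(n)                # seeded shuffle breaks count ties
    ord <- ord[order(-counts[ord])]     # stable sort: descending counts
    sizes <- integer(k)
    totals <- numeric(k)
    fold_pref <- sample.int(k)          # seeded tie-break among equal totals
    m <- setNames(integer(n), doc_ids)
    for (d in ord) {
      cap_ok <- sizes < fl |
        (sizes == fl & r > 0 & sum(sizes > fl) < r)
      elig <- which(cap_ok)
      best <- elig[order(totals[elig], match(elig, fold_pref))][1]
      m[d] <- best - 1L
      sizes[best] <- sizes[best] + 1L
      totals[best] <- totals[best] + counts[d]
    }
    m
  })
  structure(list(k = as.integer(k), mapping = mapping),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat("<fold_assignment> k =", x$k, "\n")
  sizes <- tabulate(x$mapping + 1L, nbins = x$k)
  cat("fold sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Read and write the standoff annotation TSV
#'
#' One annotation per row, UTF-8, with the mandatory header
#' `doc_id  section_index  char_start  char_end  category  surface`.
#' On read, annotations are validated against `docs` when supplied
#' (surface must equal the section-text slice).
#'
#' @param path File path.
#' @param docs Optional list of `label_document`s for validation.
#' @return `read_standoff`: an annotation data frame.
#' @export
read_standoff <- function(path, docs = NULL) {
  cols <- c("doc_id", "section_index", "char_start", "char_end",
            "category", "surface")
  ann <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = c("character", "integer", "integer",
                                   "integer", "character", "character"),
                    fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  if (!identical(names(ann), cols)) {
    stop("standoff file ", path, " must have header: ",
         paste(cols, collapse = "\t"))
  }
  ann <- span_annotations(ann$doc_id, ann$section_index, ann$char_start,
                          ann$char_end, ann$category, ann$surface)
  if (!is.null(docs)) validate_annotations(ann, docs)
  ann
}

#' @param ann Annotation data frame to write.
#' @rdname read_standoff
#' @return `write_standoff`: invisibly, `path`.
#' @export
write_standoff <- function(ann, path) {
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
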