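# Porter (1980) suffix-stripping stemmer.  Implemented from the published
# algorithm: five rule steps applied in order, longest matching suffix per
# step, conditions expressed over the measure m (number of VC sequences in
# the stem).  Words of length <= 2 are left unchanged, following the
# reference implementation.

.p_is_cons <- function(ch, i) {
  l <- ch[i]
  if (l %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (l == "y") {
    if (i == 1L) return(TRUE)
    return(!.p_is_cons(ch, i - 1L))
  }
  TRUE
}

.p_cons_vec <- function(word) {
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  out <- logical(length(ch))
  for (i in seq_along(ch)) {
    l <- ch[i]
    out[i] <- if (l %in% c("a", "e", "i", "o", "u")) FALSE
              else if (l == "y") (i == 1L || !out[i - 1L])
              else TRUE
  }
  out
}

# measure m of a stem: number of VC sequences in [C](VC)^m[V]
.p_measure <- function(stem) {
  if (!nzchar(stem)) return(0L)
  cons <- .p_cons_vec(stem)
  m <- 0L
  prev_v <- FALSE
  for (c in cons) {
    if (c && prev_v) m <- m + 1L
    prev_v <- !c
  }
  m
}

.p_has_vowel <- function(stem) {
  if (!nzchar(stem)) return(FALSE)
  any(!.p_cons_vec(stem))
}

.p_ends_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2) return(FALSE)
  a <- substr(word, n - 1, n - 1); b <- substr(word, n, n)
  if (a != b) return(FALSE)
  cons <- .p_cons_vec(word)
  cons[n]
}

# *o: stem ends cvc where the final c is not w, x or y
.p_ends_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3) return(FALSE)
  cons <- .p_cons_vec(stem)
  if (!(cons[n - 2] && !cons[n - 1] && cons[n])) return(FALSE)
  !substr(stem, n, n) %in% c("w", "x", "y")
}

.p_ends <- function(word, suffix) {
  n <- nchar(word); s <- nchar(suffix)
  n > s && substr(word, n - s + 1, n) == suffix
}

# Apply the first (longest) matching rule of a step; rules is a list of
# c(suffix, replacement, condition) where condition is a function of the
# stem (word minus suffix) or NULL for unconditional.
.p_step <- function(word, rules) {
  for (r in rules) {
    suf <- r$s
    n <- nchar(word); sn <- nchar(suf)
    if (n > sn && substr(word, n - sn + 1, n) == suf) {
      stem <- substr(word, 1, n - sn)
      if (is.null(r$cond) || r$cond(stem)) {
        return(paste0(stem, r$r))
      }
      return(word) # longest match found; condition failed -> step done
    }
  }
  word
}

.p_m_gt0 <- function(stem) .p_measure(stem) > 0L
.p_m_gt1 <- function(stem) .p_measure(stem) > 1L

.p_step1a <- function(w) {
  .p_step(w, list(
    list(s = "sses", r = "ss", cond = NULL),
    list(s = "ies",  r = "i",  cond = NULL),
    list(s = "ss",   r = "ss", cond = NULL),
    list(s = "s",    r = "",   cond = NULL)
  ))
}

.p_step1b <- function(w) {
  n <- nchar(w)
  if (.p_ends(w, "eed")) {
    stem <- substr(w, 1, n - 3)
    if (.p_m_gt0(stem)) return(paste0(stem, "ee"))
    return(w)
  }
  fired <- FALSE
  if (.p_ends(w, "ed")) {
    stem <- substr(w, 1, n - 2)
    if (.p_has_vowel(stem)) { w <- stem; fired <- TRUE }
  } else if (.p_ends(w, "ing")) {
    stem <- substr(w, 1, n - 3)
    if (.p_has_vowel(stem)) { w <- stem; fired <- TRUE }
  }
  if (fired) {
    if (.p_ends(w, "at") || .p_ends(w, "bl") || .p_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.p_ends_double_cons(w) &&
               !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
      w <- substr(w, 1, nchar(w) - 1)
    } else if (.p_measure(w) == 1L && .p_ends_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

.p_step1c <- function(w) {
  n <- nchar(w)
  if (n > 1 && substr(w, n, n) == "y" && .p_has_vowel(substr(w, 1, n - 1))) {
    w <- paste0(substr(w, 1, n - 1), "i")
  }
  w
}

.p_step2 <- function(w) {
  .p_step(w, list(
    list(s = "ational", r = "ate",  cond = .p_m_gt0),
    list(s = "ization", r = "ize",  cond = .p_m_gt0),
    list(s = "iveness", r = "ive",  cond = .p_m_gt0),
    list(s = "fulness", r = "ful",  cond = .p_m_gt0),
    list(s = "ousness", r = "ous",  cond = .p_m_gt0),
    list(s = "tional",  r = "tion", cond = .p_m_gt0),
    list(s = "biliti",  r = "ble",  cond = .p_m_gt0),
    list(s = "ousli",   r = "ous",  cond = .p_m_gt0),
    list(s = "entli",   r = "ent",  cond = .p_m_gt0),
    list(s = "ation",   r = "ate",  cond = .p_m_gt0),
    list(s = "alism",   r = "al",   cond = .p_m_gt0),
    list(s = "aliti",   r = "al",   cond = .p_m_gt0),
    list(s = "iviti",   r = "ive",  cond = .p_m_gt0),
    list(s = "enci",    r = "ence", cond = .p_m_gt0),
    list(s = "anci",    r = "ance", cond = .p_m_gt0),
    list(s = "izer",    r = "ize",  cond = .p_m_gt0),
    list(s = "abli",    r = "able", cond = .p_m_gt0),
    list(s = "alli",    r = "al",   cond = .p_m_gt0),
    list(s = "ator",    r = "ate",  cond = .p_m_gt0),
    list(s = "eli",     r = "e",    cond = .p_m_gt0)
  ))
}

.p_step3 <- function(w) {
  .p_step(w, list(
    list(s = "icate", r = "ic", cond = .p_m_gt0),
    list(s = "ative", r = "",   cond = .p_m_gt0),
    list(s = "alize", r = "al", cond = .p_m_gt0),
    list(s = "iciti", r = "ic", cond = .p_m_gt0),
    list(s = "ical",  r = "ic", cond = .p_m_gt0),
    list(s = "ful",   r = "",   cond = .p_m_gt0),
    list(s = "ness",  r = "",   cond = .p_m_gt0)
  ))
}

.p_step4 <- function(w) {
  ion_cond <- function(stem) {
    .p_m_gt1(stem) && nzchar(stem) &&
      substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")
  }
  .p_step(w, list(
    list(s = "ement", r = "", cond = .p_m_gt1),
    list(s = "ance",  r = "", cond = .p_m_gt1),
    list(s = "ence",  r = "", cond = .p_m_gt1),
    list(s = "able",  r = "", cond = .p_m_gt1),
    list(s = "ible",  r = "", cond = .p_m_gt1),
    list(s = "ment",  r = "", cond = .p_m_gt1),
    list(s = "ent",   r = "", cond = .p_m_gt1),
    list(s = "ion",   r = "", cond = ion_cond),
    list(s = "ism",   r = "", cond = .p_m_gt1),
    list(s = "ate",   r = "", cond = .p_m_gt1),
    list(s = "iti",   r = "", cond = .p_m_gt1),
    list(s = "ous",   r = "", cond = .p_m_gt1),
    list(s = "ive",   r = "", cond = .p_m_gt1),
    list(s = "ize",   r = "", cond = .p_m_gt1),
    list(s = "ant",   r = "", cond = .p_m_gt1),
    list(s = "al",    r = "", cond = .p_m_gt1),
    list(s = "er",    r = "", cond = .p_m_gt1),
    list(s = "ic",    r = "", cond = .p_m_gt1),
    list(s = "ou",    r = "", cond = .p_m_gt1)
  ))
}

.p_step5a <- function(w) {
  n <- nchar(w)
  if (n > 1 && substr(w, n, n) == "e") {
    stem <- substr(w, 1, n - 1)
    m <- .p_measure(stem)
    if (m > 1L || (m == 1L && !.p_ends_cvc(stem))) return(stem)
  }
  w
}

.p_step5b <- function(w) {
  n <- nchar(w)
  if (substr(w, n, n) == "l" && .p_ends_double_cons(w) &&
      .p_m_gt1(substr(w, 1, n - 1))) {
    return(substr(w, 1, n - 1))
  }
  w
}

porter_one <- function(word) {
  w <- tolower(word)
  if (nchar(w) <= 2 || grepl("[^a-z]", w)) return(w)
  w <- .p_step1a(w)
  w <- .p_step1b(w)
  w <- .p_step1c(w)
  w <- .p_step2(w)
  w <- .p_step3(w)
  w <- .p_step4(w)
  w <- .p_step5a(w)
  w <- .p_step5b(w)
  w
}

#' Porter stem of a token
#'
#' Classic Porter (1980) suffix stripping, lowercased.  Tokens of length
#' two or less, and tokens containing non-letter characters (numbers,
#' punctuation), are returned lowercased but otherwise unchanged.
#'
#' @param tokens Character vector.
#' @return Character vector of stems, same length.
#' @examples
#' stem(c("lesions", "burning", "rash"))
#' @export
stem <- function(tokens) {
  vapply(tokens, porter_one, character(1), USE.NAMES = FALSE)
}
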