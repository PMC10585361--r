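#' English Snowball (Porter2) stemming
#'
#' A native implementation of the English Snowball stemmer (Porter2). The
#' algorithm reduces inflected word forms to a common stem so that, e.g.,
#' "induce", "induced" and "inducing" all map to "induc", which standardizes
#' the vocabulary of a corpus before topic modeling.
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' snowball_stem(c("induced", "injury", "reports"))
#' @export
snowball_stem <- function(words) {
  if (length(words) == 0) return(character(0))
  u <- unique(words)
  stems <- vapply(u, .sb_stem_word, character(1), USE.NAMES = FALSE)
  stems[match(words, u)]
}

.sb_vowels <- c("a", "e", "i", "o", "u", "y")

.sb_is_vowel <- function(ch) ch %in% .sb_vowels

# region start (1-based index of first char of R1/R2), length+1 when null
.sb_region_start <- function(ch, from) {
  n <- length(ch)
  i <- from
  while (i <= n && !.sb_is_vowel(ch[i])) i <- i + 1L
  while (i <= n && .sb_is_vowel(ch[i])) i <- i + 1L
  if (i > n) return(n + 1L)
  i + 1L
}

# suffix occupies positions (nchar(w)-nchar(suf)+1)..nchar(w); in-region test
.sb_in_region <- function(w, suf, rstart) {
  nchar(w) - nchar(suf) + 1L >= rstart
}

.sb_chars <- function(w) strsplit(w, "", fixed = TRUE)[[1]]

# short syllable at end of word: vowel followed by a non-vowel other than
# w/x/Y with a non-vowel before the vowel; or word-initial vowel + non-vowel
.sb_ends_short_syllable <- function(w) {
  ch <- .sb_chars(w)
  n <- length(ch)
  if (n == 2L) {
    return(.sb_is_vowel(ch[1]) && !.sb_is_vowel(ch[2]))
  }
  if (n >= 3L) {
    c3 <- ch[n]; c2 <- ch[n - 1L]; c1 <- ch[n - 2L]
    return(!.sb_is_vowel(c3) && !(c3 %in% c("w", "x", "Y")) &&
             .sb_is_vowel(c2) && !.sb_is_vowel(c1))
  }
  FALSE
}

.sb_has_vowel <- function(w) {
  if (!nzchar(w)) return(FALSE)
  any(.sb_is_vowel(.sb_chars(w)))
}

.sb_exceptions1 <- c(
  skis = "ski", skies = "sky", dying = "die", lying = "lie", tying = "tie",
  idly = "idl", gently = "gentl", ugly = "ugli", early = "earli",
  only = "onli", singly = "singl",
  sky = "sky", news = "news", howe = "howe", atlas = "atlas",
  cosmos = "cosmos", bias = "bias", andes = "andes"
)

.sb_exceptions2 <- c("inning", "outing", "canning", "herring", "earring",
                     "proceed", "exceed", "succeed")

.sb_doubles <- c("bb", "dd", "ff", "gg", "mm", "nn", "pp", "rr", "tt")

.sb_li_ending <- c("c", "d", "e", "g", "h", "k", "m", "n", "r", "t")

.sb_step2_rules <- list(
  c("ational", "ate"), c("fulness", "ful"), c("iveness", "ive"),
  c("ization", "ize"), c("ousness", "ous"),
  c("biliti", "ble"), c("lessli", "less"), c("tional", "tion"),
  c("alism", "al"), c("aliti", "al"), c("ation", "ate"),
  c("entli", "ent"), c("fulli", "ful"), c("ousli", "ous"),
  c("anci", "ance"), c("abli", "able"), c("alli", "al"),
  c("ator", "ate"), c("enci", "ence"), c("izer", "ize"),
  c("bli", "ble"), c("ogi", "@ogi"), c("li", "@li")
)

.sb_step3_rules <- list(
  c("ational", "ate"), c("tional", "tion"), c("alize", "al"),
  c("icate", "ic"), c("iciti", "ic"), c("ative", "@ative"),
  c("ical", "ic"), c("ness", ""), c("ful", "")
)

.sb_step4_suffixes <- c("ement", "ance", "ence", "able", "ible", "ment",
                        "ant", "ent", "ism", "ate", "iti", "ous", "ive",
                        "ize", "ion", "al", "er", "ic")

.sb_stem_word <- function(word) {
  if (nchar(word) <= 2L) return(word)
  if (word %in% names(.sb_exceptions1)) return(unname(.sb_exceptions1[word]))

  w <- word
  if (startsWith(w, "'")) w <- substr(w, 2L, nchar(w))

  # mark consonant-y as Y (word-initial y, or y following a vowel)
  ch <- .sb_chars(w)
  if (ch[1] == "y") ch[1] <- "Y"
  if (length(ch) > 1L) {
    for (i in 2:length(ch)) {
      if (ch[i] == "y" && .sb_is_vowel(ch[i - 1L])) ch[i] <- "Y"
    }
  }
  w <- paste(ch, collapse = "")

  # R1/R2 as fixed left positions; special prefixes fix R1 directly
  r1 <- if (any(startsWith(w, c("gener", "commun", "arsen")))) {
    6L
  } else {
    .sb_region_start(ch, 1L)
  }
  r2 <- .sb_region_start(ch, r1)

  # step 0: strip apostrophe suffixes
  for (suf in c("'s'", "'s", "'")) {
    if (endsWith(w, suf)) { w <- substr(w, 1L, nchar(w) - nchar(suf)); break }
  }

  # step 1a
  if (endsWith(w, "sses")) {
    w <- paste0(substr(w, 1L, nchar(w) - 4L), "ss")
  } else if (endsWith(w, "ied") || endsWith(w, "ies")) {
    base <- substr(w, 1L, nchar(w) - 3L)
    w <- paste0(base, if (nchar(base) > 1L) "i" else "ie")
  } else if (endsWith(w, "ss") || endsWith(w, "us")) {
    # no action
  } else if (endsWith(w, "s")) {
    if (nchar(w) >= 3L && .sb_has_vowel(substr(w, 1L, nchar(w) - 2L))) {
      w <- substr(w, 1L, nchar(w) - 1L)
    }
  }

  if (w %in% .sb_exceptions2) return(chartr("Y", "y", w))

  # step 1b
  if (endsWith(w, "eedly") || endsWith(w, "eed")) {
    suf <- if (endsWith(w, "eedly")) "eedly" else "eed"
    if (.sb_in_region(w, suf, r1)) {
      w <- paste0(substr(w, 1L, nchar(w) - nchar(suf)), "ee")
    }
  } else {
    suf <- NULL
    for (s in c("ingly", "edly", "ing", "ed")) {
      if (endsWith(w, s)) { suf <- s; break }
    }
    if (!is.null(suf)) {
      base <- substr(w, 1L, nchar(w) - nchar(suf))
      if (.sb_has_vowel(base)) {
        w <- base
        last2 <- if (nchar(w) >= 2L) substr(w, nchar(w) - 1L, nchar(w)) else ""
        if (last2 %in% c("at", "bl", "iz")) {
          w <- paste0(w, "e")
        } else if (last2 %in% .sb_doubles) {
          w <- substr(w, 1L, nchar(w) - 1L)
        } else if (nchar(w) < r1 && .sb_ends_short_syllable(w)) {
          # word is "short": R1 null and ends in a short syllable
          w <- paste0(w, "e")
        }
      }
    }
  }

  # step 1c: y -> i after a non-vowel that is not word-initial
  n <- nchar(w)
  if (n > 2L && substr(w, n, n) %in% c("y", "Y") &&
      !.sb_is_vowel(substr(w, n - 1L, n - 1L))) {
    w <- paste0(substr(w, 1L, n - 1L), "i")
  }

  # step 2: longest matching suffix; apply only if in R1
  for (rule in .sb_step2_rules) {
    suf <- rule[1]
    if (endsWith(w, suf)) {
      if (.sb_in_region(w, suf, r1)) {
        base <- substr(w, 1L, nchar(w) - nchar(suf))
        rep <- rule[2]
        if (rep == "@ogi") {
          if (endsWith(base, "l")) w <- paste0(base, "og")
        } else if (rep == "@li") {
          if (nzchar(base) && substr(base, nchar(base), nchar(base)) %in% .sb_li_ending) {
            w <- base
          }
        } else {
          w <- paste0(base, rep)
        }
      }
      break
    }
  }

  # step 3: longest matching suffix; apply only if in R1
  for (rule in .sb_step3_rules) {
    suf <- rule[1]
    if (endsWith(w, suf)) {
      if (.sb_in_region(w, suf, r1)) {
        base <- substr(w, 1L, nchar(w) - nchar(suf))
        rep <- rule[2]
        if (rep == "@ative") {
          if (.sb_in_region(w, suf, r2)) w <- base
        } else {
          w <- paste0(base, rep)
        }
      }
      break
    }
  }

  # step 4: longest matching suffix; delete if in R2
  for (suf in .sb_step4_suffixes) {
    if (endsWith(w, suf)) {
      if (.sb_in_region(w, suf, r2)) {
        base <- substr(w, 1L, nchar(w) - nchar(suf))
        if (suf == "ion") {
          if (nzchar(base) && substr(base, nchar(base), nchar(base)) %in% c("s", "t")) {
            w <- base
          }
        } else {
          w <- base
        }
      }
      break
    }
  }

  # step 5
  n <- nchar(w)
  if (n >= 1L && substr(w, n, n) == "e") {
    del <- if (n >= r2) TRUE
           else if (n >= r1) !.sb_ends_short_syllable(substr(w, 1L, n - 1L))
           else FALSE
    if (del) w <- substr(w, 1L, n - 1L)
  } else if (n >= 2L && substr(w, n, n) == "l") {
    if (n >= r2 && substr(w, n - 1L, n - 1L) == "l") w <- substr(w, 1L, n - 1L)
  }

  chartr("Y", "y", w)
}
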