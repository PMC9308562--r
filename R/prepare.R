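# WHO ICD-10 chapter blocks (3-character code ranges).  Embedded as a
# versioned constant; note that chapter IX is circulatory and XI digestive
# in this (WHO) scheme.
icd10_chapter_table <- data.frame(
  chapter = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X",
              "XI", "XII", "XIII", "XIV", "XV", "XVI", "XVII", "XVIII",
              "XIX", "XX", "XXI", "XXII"),
  start = c("A00", "C00", "D50", "E00", "F00", "G00", "H00", "H60", "I00",
            "J00", "K00", "L00", "M00", "N00", "O00", "P00", "Q00", "R00",
            "S00", "V01", "Z00", "U00"),
  end   = c("B99", "D48", "D89", "E90", "F99", "G99", "H59", "H95", "I99",
            "J99", "K93", "L99", "M99", "N99", "O99", "P96", "Q99", "R99",
            "T98", "Y98", "Z99", "U99"),
  stringsAsFactors = FALSE)

icd10_stem <- function(code) {
  stem <- toupper(substr(gsub("[. ]", "", code), 1L, 3L))
  ok <- grepl("^[A-Z][0-9]{2}$", stem)
  if (any(!ok))
    stop("not a valid ICD-10 code: ", paste(unique(code[!ok]), collapse = ", "))
  stem
}

#' Map ICD-10 codes to their chapter
#'
#' Uses the WHO chapter table (I Infectious ... XXII Special purposes); the
#' 3-character stem of each code is located in the chapter block ranges.
#' Letter-then-digits codes compare correctly as fixed-width strings.
#'
#' @param code character vector of ICD-10 codes (e.g. `"I25.1"`, `"C34"`).
#' @return character vector of chapter numerals (`"I"`..`"XXII"`).
#' @examples
#' icd10_chapter(c("C34", "D12", "K52", "I21"))  # "II" "II" "XI" "IX"
#' @export
icd10_chapter <- function(code) {
  stem <- icd10_stem(code)
  tab <- icd10_chapter_table
  idx <- vapply(stem, function(s) {
    hit <- which(s >= tab$start & s <= tab$end)
    if (length(hit) != 1L) stop("ICD-10 stem not in any chapter: ", s)
    hit
  }, 0L)
  unname(tab$chapter[idx])
}

is_counted_cancer <- function(code) {
  # cancers C00-C97 except non-melanoma skin cancer C44
  stem <- icd10_stem(code)
  grepl("^C", stem) & stem <= "C97" & stem != "C44"
}

#' Exclude subjects with a pre-entry cancer
#'
#' Removes subjects who had any cancer other than non-melanoma skin cancer
#' (C00--C97 except C44) strictly before their entry age.  Cancers at or
#' after entry are retained here and handled by censoring downstream.
#'
#' @param subjects data.frame with `id` and `entry_age`.
#' @param episodes data.frame with `id`, `age`, `code`.
#' @return filtered subjects; excluded ids attached as
#'   `attr(, "excluded_ids")`.
#' @export
apply_baseline_exclusions <- function(subjects, episodes) {
  stopifnot(all(c("id", "entry_age") %in% names(subjects)),
            all(c("id", "age", "code") %in% names(episodes)))
  if (anyNA(subjects$entry_age)) stop("missing entry ages")
  entry <- subjects$entry_age[match(episodes$id, subjects$id)]
  bad <- is_counted_cancer(episodes$code) & episodes$age < entry &
    !is.na(entry)
  excluded <- unique(episodes$id[bad])
  out <- subjects[!subjects$id %in% excluded, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_ids") <- excluded
  out
}

#' First primary admission per subject and ICD-10 chapter
#'
#' For each subject and chapter, keeps the earliest primary-diagnosis episode
#' at or after the subject's entry age; later same-chapter episodes and all
#' non-primary episodes are dropped.  Same-age ties within a chapter are
#' broken deterministically by code sort order and reported via
#' `attr(, "ties")`.
#'
#' @param subjects data.frame with `id`, `entry_age` (exclusions already
#'   applied).
#' @param episodes data.frame with `id`, `age`, `code`, `primary` (logical).
#' @return data.frame `id`, `chapter`, `age`, `code`, one row per
#'   (subject, chapter) with an event.
#' @export
first_event_per_chapter <- function(subjects, episodes) {
  stopifnot(all(c("id", "age", "code", "primary") %in% names(episodes)))
  ep <- episodes[episodes$id %in% subjects$id & as.logical(episodes$primary), ,
                 drop = FALSE]
  entry <- subjects$entry_age[match(ep$id, subjects$id)]
  ep <- ep[ep$age >= entry, , drop = FALSE]
  if (nrow(ep) == 0L) {
    out <- data.frame(id = integer(0), chapter = character(0),
                      age = numeric(0), code = character(0))
    attr(out, "ties") <- out
    return(out)
  }
  ep$chapter <- icd10_chapter(ep$code)
  ord <- order(ep$id, ep$chapter, ep$age, ep$code)
  ep <- ep[ord, , drop = FALSE]
  key <- paste(ep$id, ep$chapter)
  first <- !duplicated(key)
  out <- ep[first, c("id", "chapter", "age", "code"), drop = FALSE]
  # a tie: another episode in the same (subject, chapter) at the same age
  firsts <- out[match(key, paste(out$id, out$chapter)), ]
  tied <- !first & ep$age == firsts$age & ep$code != firsts$code
  ties <- ep[tied, c("id", "chapter", "age", "code"), drop = FALSE]
  rownames(out) <- rownames(ties) <- NULL
  if (nrow(ties) > 0L)
    message(nrow(ties), " same-age tie(s) broken by code order")
  attr(out, "ties") <- ties
  out
}

disease_code_match <- function(code, code_set) {
  # prefix match on dot-stripped codes: "I25.1" covers I25.1x; "I21" covers I21.x
  norm <- function(x) toupper(gsub("[. ]", "", x))
  code <- norm(code); code_set <- norm(code_set)
  Reduce(`|`, lapply(code_set, function(cs) startsWith(code, cs)))
}

#' Build the left-truncated, right-censored dataset for one disease
#'
#' A disease is one or more ICD-10 codes inside a single chapter.  Per
#' subject: the event age is their chapter-first event when its code falls in
#' the code-set; otherwise they are censored at the earliest of study end,
#' first counted cancer (C00--C97 except C44) at or after entry, and the
#' chapter-first event age when that event was a *different* disease in the
#' same chapter (the chapter is then "used up" under the
#' first-disease-per-chapter design, so the subject leaves the risk set).
#'
#' @param code_set character vector of ICD-10 codes defining the disease.
#' @param subjects data.frame with `id`, `entry_age`, `exit_age` (study-end
#'   age) and any covariate columns (carried through).
#' @param first_events output of [first_event_per_chapter()].
#' @param episodes full episode table (used to locate censoring cancers);
#'   optional, omit if cancers cannot occur.
#' @return `cohort` data.frame: `id`, `entry_age`, `exit_age`, `status`,
#'   covariate columns.
#' @export
build_disease_dataset <- function(code_set, subjects, first_events,
                                  episodes = NULL) {
  if (length(code_set) == 0L) stop("empty code-set")
  chap <- unique(icd10_chapter(code_set))
  if (length(chap) != 1L)
    stop("disease code-set spans several chapters: ",
         paste(chap, collapse = ", "))
  stopifnot(all(c("id", "entry_age", "exit_age") %in% names(subjects)))

  fe <- first_events[first_events$chapter == chap, , drop = FALSE]
  fe_age <- fe$age[match(subjects$id, fe$id)]
  fe_code <- fe$code[match(subjects$id, fe$id)]
  is_event <- !is.na(fe_age) & disease_code_match(fe_code, code_set)

  censor <- subjects$exit_age
  if (!is.null(episodes)) {
    ca <- episodes[is_counted_cancer(episodes$code), , drop = FALSE]
    entry <- subjects$entry_age[match(ca$id, subjects$id)]
    ca <- ca[!is.na(entry) & ca$age >= entry, , drop = FALSE]
    if (nrow(ca) > 0L) {
      ca <- ca[order(ca$id, ca$age), , drop = FALSE]
      ca <- ca[!duplicated(ca$id), , drop = FALSE]
      cancer_age <- ca$age[match(subjects$id, ca$id)]
      censor <- pmin(censor, cancer_age, na.rm = TRUE)
    }
  }
  # a different disease's first event in this chapter censors the subject
  other <- !is.na(fe_age) & !is_event
  censor[other] <- pmin(censor[other], fe_age[other])

  status <- as.integer(is_event & fe_age <= censor)
  exit <- ifelse(status == 1L, fe_age, censor)

  keep <- setdiff(names(subjects), c("exit_age"))
  out <- subjects[, keep, drop = FALSE]
  out$exit_age <- pmax(exit, out$entry_age)
  out$status <- status
  out <- out[, c("id", setdiff(keep, "id"), "exit_age", "status"), drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort", "data.frame")
  out
}
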