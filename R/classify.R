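#' Morbidity group catalogue
#'
#' The twelve WHO-adapted maternal morbidity groups used throughout the
#' package, some split into subgroups. Labels follow the field's numbering
#' (there is no group 6; group 13 is the residual "others" group).
#'
#' @return Character vector of the twenty item labels.
#' @export
item_catalogue <- function() {
  c("1a", "1b", "2a", "2b", "3", "4a", "4b", "5", "7a", "7b",
    "8a", "8b", "8c", "8d", "8e", "9", "10", "11", "12", "13")
}

#' Display names for morbidity groups and subgroups
#'
#' @return Named character vector mapping item labels (and bare group
#'   numbers) to human-readable names.
#' @export
item_display_names <- function() {
  c("1"  = "Abortion",
    "1a" = "Abortion without complications",
    "1b" = "Abortion with complications",
    "2"  = "Hypertensive disorders",
    "2a" = "Pregnancy-specific hypertension",
    "2b" = "Chronic hypertension",
    "3"  = "Obstetric haemorrhages",
    "4"  = "Infections",
    "4a" = "Pregnancy-related infections",
    "4b" = "Infections not related to pregnancy",
    "5"  = "Other obstetric complications",
    "7"  = "Diabetes",
    "7a" = "Gestational diabetes",
    "7b" = "Non-gestational diabetes",
    "8"  = "Non-obstetric complications",
    "8a" = "Respiratory system diseases",
    "8b" = "Digestive system diseases",
    "8c" = "Circulatory system diseases",
    "8d" = "Anaemia",
    "8e" = "Other non-obstetric diseases",
    "9"  = "Unknown causes",
    "10" = "Childbirth",
    "11" = "Other obstetric conditions",
    "12" = "External causes",
    "13" = "Others")
}

#' The residual morbidity group label
#' @keywords internal
RESIDUAL_GROUP <- "13"

#' Outcome item labels attached to every transaction
#' @keywords internal
OUTCOME_ITEMS <- c("DEATH", "ALIVE")

#' Build a validated ICD-10 prefix to morbidity-group mapping
#'
#' A mapping is an ordered table of `(icd_prefix, item_label)` entries.
#' Classification uses longest-prefix match on dot-less upper-case codes,
#' so a four-character entry (e.g. `O244`) overrides the three-character
#' entry (`O24`) which in turn overrides a chapter-letter entry (`O`).
#'
#' @param entries Data frame with character columns `icd_prefix` and
#'   `item_label`.
#' @return A `group_mapping` tibble.
#' @export
group_mapping <- function(entries) {
  entries <- tibble::as_tibble(entries)
  if (!all(c("icd_prefix", "item_label") %in% names(entries))) {
    stop("mapping must have columns 'icd_prefix' and 'item_label'", call. = FALSE)
  }
  entries$icd_prefix <- toupper(gsub(".", "", entries$icd_prefix, fixed = TRUE))
  entries$item_label <- as.character(entries$item_label)
  if (any(!nzchar(entries$icd_prefix)) || any(nchar(entries$icd_prefix) > 4L)) {
    stop("icd_prefix entries must be 1-4 characters", call. = FALSE)
  }
  # unambiguity: a prefix may not point at two different labels
  amb <- tapply(entries$item_label, entries$icd_prefix,
                function(x) length(unique(x)))
  if (any(amb > 1L)) {
    stop("ambiguous mapping: prefix(es) ",
         paste(names(amb)[amb > 1L], collapse = ", "),
         " map to more than one item label", call. = FALSE)
  }
  bad <- setdiff(unique(entries$item_label), item_catalogue())
  if (length(bad)) {
    stop("unknown item label(s) in mapping: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  entries <- dplyr::distinct(entries, .data$icd_prefix, .keep_all = TRUE)
  class(entries) <- c("group_mapping", class(entries))
  entries
}

#' Load a morbidity mapping from CSV
#'
#' @param path CSV file with columns `icd_prefix,item_label`.
#' @return A `group_mapping`.
#' @export
load_group_mapping <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path, call. = FALSE)
  group_mapping(utils::read.csv(path, colClasses = "character"))
}

#' The shipped default morbidity mapping
#'
#' An adaptation of the WHO ICD-10 maternal-death grouping to morbidity
#' coding: obstetric chapter-XV codes are assigned to the abortion,
#' hypertensive, haemorrhage, infection, childbirth and complication groups;
#' whole non-obstetric chapters feed the non-obstetric complication
#' subgroups (respiratory, digestive, circulatory, anaemia, other); injuries
#' and external causes form group 12; R95-R99 form the unknown-cause group.
#' Codes matching no entry fall into the residual group 13 ("others").
#' The mapping is a versioned CSV and fully user-replaceable; pipeline
#' correctness does not depend on any particular entry.
#'
#' @return A `group_mapping`.
#' @export
default_group_mapping <- function() {
  load_group_mapping(system.file("extdata", "morbidity_groups.csv",
                                 package = "morbrules", mustWork = TRUE))
}

icd_shape_ok <- function(codes) {
  grepl("^[A-Z][0-9]{2}[0-9A-Z]{0,2}$", codes)
}

normalize_icd <- function(codes) {
  toupper(gsub(".", "", trimws(codes), fixed = TRUE))
}

#' Classify ICD-10 codes into morbidity groups
#'
#' Longest-prefix match against the mapping; codes that match no entry are
#' assigned to the residual group ("13"). Vectorised.
#'
#' @param codes Character vector of ICD-10 codes (dots optional).
#' @param mapping A [group_mapping()]; default [default_group_mapping()].
#' @return Character vector of item labels, same length as `codes`.
#' @export
#' @examples
#' classify_code(c("O14", "O80", "Z999"))
classify_code <- function(codes, mapping = default_group_mapping()) {
  codes <- normalize_icd(codes)
  bad <- !is.na(codes) & !icd_shape_ok(codes)
  if (any(bad)) {
    stop("malformed ICD-10 code(s): ",
         paste(unique(codes[bad]), collapse = ", "), call. = FALSE)
  }
  lookup <- setNames(mapping$item_label, mapping$icd_prefix)
  out <- rep(RESIDUAL_GROUP, length(codes))
  unresolved <- !is.na(codes)
  for (k in 4:1) {
    if (!any(unresolved)) break
    hit <- lookup[substr(codes, 1L, k)]
    take <- unresolved & !is.na(hit)
    out[take] <- hit[take]
    unresolved <- unresolved & is.na(hit)
  }
  out[is.na(codes)] <- NA_character_
  out
}

#' Representative ICD-10 code for each morbidity item
#'
#' One concrete code per item label that the shipped default mapping
#' resolves back to that item; used by the synthetic claims generator to
#' emit diagnoses with a known classification.
#'
#' @return Named character vector, names are item labels.
#' @export
representative_codes <- function() {
  c("1a" = "O034", "1b" = "O06",  "2a" = "O14",  "2b" = "O10",
    "3"  = "O72",  "4a" = "O85",  "4b" = "A41",  "5"  = "O26",
    "7a" = "O244", "7b" = "E11",  "8a" = "J18",  "8b" = "K92",
    "8c" = "I26",  "8d" = "D62",  "8e" = "N17",  "9"  = "R99",
    "10" = "O80",  "11" = "Z34",  "12" = "T81",  "13" = "R50")
}

#' Convert episodes to morbidity transactions
#'
#' Each episode becomes one transaction: the deduplicated set of morbidity
#' group labels obtained by classifying every diagnosis of every claim in
#' the episode, plus a single outcome item (`DEATH` for in-hospital death,
#' `ALIVE` otherwise). Classification is independent of diagnosis and claim
#' order.
#'
#' @param episodes Episode table from [episodes()] (needs the `diagnoses`
#'   list-column and `outcome`).
#' @param mapping A [group_mapping()].
#' @return Tibble with `episode_id`, `items` (list of sorted labels) and
#'   `outcome_item`.
#' @export
episodes_to_transactions <- function(episodes, mapping = default_group_mapping()) {
  stopifnot(is.data.frame(episodes), "diagnoses" %in% names(episodes))
  codes <- unlist(episodes$diagnoses, use.names = FALSE)
  lens <- lengths(episodes$diagnoses)
  labels <- classify_code(codes, mapping)
  idx <- rep(seq_len(nrow(episodes)), lens)
  keep <- !duplicated(paste(idx, labels, sep = "\x1f"))
  idx <- idx[keep]; labels <- labels[keep]
  o <- order(idx, labels, method = "radix")
  items <- unname(split(labels[o], factor(idx[o], levels = seq_len(nrow(episodes)))))
  tibble::tibble(
    episode_id = episodes$episode_id,
    items = items,
    outcome_item = ifelse(episodes$outcome == "in_hospital_death", "DEATH", "ALIVE")
  )
}

#' Classify one episode into a transaction
#'
#' Convenience wrapper over [episodes_to_transactions()] for a single
#' episode row.
#'
#' @inheritParams episodes_to_transactions
#' @param episode One-row episode table.
#' @return One-row transaction tibble.
#' @export
episode_to_transaction <- function(episode, mapping = default_group_mapping()) {
  episodes_to_transactions(episode[1, , drop = FALSE], mapping)
}
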