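#' Clinical entity inventory for the IBD domain
#'
#' The nine entity types extracted from inflammatory bowel disease (IBD)
#' clinical notes: the diagnosis (Crohn's disease / ulcerative colitis and
#' variants), its date, the Montreal-classification axes (disease location
#' L1--L3, behaviour B1--B3, extent E1--E3), history of peri-anal disease,
#' previous surgery, and the patient's length (height) and body weight.
#'
#' @return character vector of the nine canonical entity type names.
#' @export
ibd_entity_types <- function() {
  c("diagnosis", "diagnosis_date", "disease_location", "disease_behavior",
    "peri_anal_disease", "previous_surgery", "disease_extent",
    "length", "body_weight")
}

#' Build a BIO label scheme from an entity inventory
#'
#' Derives the token-level tag set used throughout the package: one \code{O}
#' tag plus \code{B-}/\code{I-} tags per entity type, and the special sequence
#' markers inserted at batch-assembly time.
#'
#' @param entity_types character vector of entity type names; defaults to the
#'   IBD inventory of [ibd_entity_types()].
#' @return an object of class \code{"label_scheme"}: a list with
#'   \code{entity_types}, \code{bio_labels} (length \code{2 * n + 1}, `O`
#'   first), and \code{special_tokens} (begin/end/pad/mask/unknown markers).
#' @examples
#' sch <- label_scheme()
#' length(sch$bio_labels)  # 19 for the nine IBD entity types
#' @export
label_scheme <- function(entity_types = ibd_entity_types()) {
  entity_types <- as.character(entity_types)
  if (length(entity_types) == 0L) stopf("entity inventory is empty")
  if (anyDuplicated(entity_types)) stopf("duplicated entity type names")
  if (any(!nzchar(entity_types))) stopf("empty entity type name")
  bio <- c("O", as.vector(rbind(paste0("B-", entity_types),
                                paste0("I-", entity_types))))
  structure(
    list(
      entity_types = entity_types,
      bio_labels = bio,
      special_tokens = c(cls = "[CLS]", sep = "[SEP]", pad = "[PAD]",
                         mask = "[MASK]", unk = "[UNK]", sec = "[SEC]")
    ),
    class = "label_scheme"
  )
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("BIO label scheme:", length(x$entity_types), "entity types,",
      length(x$bio_labels), "tags\n")
  cat("  types:", paste(x$entity_types, collapse = ", "), "\n")
  invisible(x)
}

# Tag helpers ---------------------------------------------------------------

tag_type <- function(tags) {
  out <- rep(NA_character_, length(tags))
  ent <- tags != "O"
  out[ent] <- substring(tags[ent], 3L)
  out
}

tag_prefix <- function(tags) {
  out <- rep("O", length(tags))
  ent <- tags != "O"
  out[ent] <- substring(tags[ent], 1L, 1L)
  out
}

check_tags <- function(tags, scheme) {
  bad <- setdiff(unique(tags), scheme$bio_labels)
  if (length(bad)) stopf("tags outside the label scheme: %s",
                         paste(bad, collapse = ", "))
  invisible(TRUE)
}

# Reserved label-token surfaces for entity MLM, e.g. "<B-diagnosis>".
label_token_surfaces <- function(scheme) {
  paste0("<", setdiff(scheme$bio_labels, "O"), ">")
}
label_token_for_tag <- function(tag) paste0("<", tag, ">")
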