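#' Sign of a drug effect on a disease-shared lncRNA
#'
#' A drug effect is *therapeutic* when it pushes the lncRNA against its
#' shared disease direction (inhibiting an lncRNA upregulated in both
#' diseases, or raising one that is downregulated in both) and
#' *exacerbating* when it pushes further in the disease direction.
#'
#' @param direction the lncRNA's shared regulation direction, `"up"` or
#'   `"down"` (vectorized).
#' @param effect the drug's effect on it, `"increase"` or `"decrease"`.
#' @return A character vector, `"therapeutic"` or `"exacerbating"`.
#' @export
#' @examples
#' effect_sign("up", "decrease")   # therapeutic
#' effect_sign("up", "increase")   # exacerbating
effect_sign <- function(direction, effect) {
  direction <- match_enum(direction, c("up", "down"), "direction")
  effect <- match_enum(effect, c("increase", "decrease"), "effect")
  push <- ifelse(effect == "increase", "up", "down")
  ifelse(push == direction, "exacerbating", "therapeutic")
}

# internal: vectorized enum check
match_enum <- function(x, levels, what) {
  x <- as.character(x)
  bad <- !(x %in% levels)
  if (any(bad)) {
    stop("invalid ", what, " value(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  x
}

#' Map free-text effect verbs to increase/decrease
#'
#' Source databases describe drug effects with free-text verbs
#' ("inhibits", "overexpresses", ...). This maps them onto the binary
#' effect through the packaged controlled vocabulary (see
#' [load_fixture()]`("effect_verbs")`), which can be extended.
#'
#' @param verbs character vector of effect verbs (case-insensitive).
#' @param vocabulary data frame with columns `verb` and `effect`; defaults to
#'   the packaged vocabulary.
#' @return Character vector of `"increase"`/`"decrease"`.
#' @export
normalize_effect <- function(verbs, vocabulary = load_fixture("effect_verbs")) {
  key <- norm_id(verbs)
  idx <- match(key, norm_id(vocabulary$verb))
  if (anyNA(idx)) {
    stop("unrecognized effect verb(s): ",
         paste(unique(verbs[is.na(idx)]), collapse = ", "),
         "; extend the effect vocabulary to map them")
  }
  vocabulary$effect[idx]
}

# internal: attach signs to effect records; returns list(signed, skipped)
sign_effect_records <- function(effects, directions) {
  stopifnot(is.data.frame(effects), is.data.frame(directions))
  eff <- data.frame(drug = as.character(effects[[1L]]),
                    lncrna = as.character(effects[[2L]]),
                    effect = match_enum(effects[[3L]], c("increase", "decrease"),
                                        "effect"),
                    stringsAsFactors = FALSE)
  # refuse duplicate (drug, lncRNA) pairs with opposite verbs: conflicting
  # source reports need manual curation, not silent resolution
  key <- paste(norm_id(eff$drug), norm_id(eff$lncrna), sep = "\r")
  conflict <- tapply(eff$effect, key, function(v) length(unique(v)) > 1L)
  if (any(conflict)) {
    pairs <- unique(eff[key %in% names(conflict)[conflict], c("drug", "lncrna")])
    stop("conflicting effect records for pair(s): ",
         paste(paste(pairs$drug, pairs$lncrna, sep = "/"), collapse = ", "),
         "; resolve before labeling")
  }
  eff <- eff[!duplicated(key), , drop = FALSE]
  dir_dm <- as.character(directions$direction_dm)
  dir_ad <- as.character(directions$direction_ad)
  consistent <- dir_dm == dir_ad & dir_dm %in% c("up", "down")
  dir_map <- ifelse(consistent, dir_dm, NA_character_)
  names(dir_map) <- norm_id(directions$lncrna)
  eff$direction <- unname(dir_map[norm_id(eff$lncrna)])
  signable <- !is.na(eff$direction)
  skipped <- eff[!signable, c("drug", "lncrna", "effect"), drop = FALSE]
  if (nrow(skipped)) {
    warning(nrow(skipped), " effect record(s) skipped: lncRNA direction ",
            "unknown or discordant between the two diseases", call. = FALSE)
  }
  eff <- eff[signable, , drop = FALSE]
  eff$sign <- effect_sign(eff$direction, eff$effect)
  list(signed = eff, skipped = skipped)
}

#' Remove drugs with contradictory lncRNA effect signs
#'
#' Signs every (drug, lncRNA) effect record against the shared disease
#' direction table, then removes drugs carrying both a therapeutic and an
#' exacerbating edge. Edges to lncRNAs with unknown or disease-discordant
#' direction are ignored for signing (with a warning), and drugs whose every
#' edge is unsignable are set aside rather than classified.
#'
#' @param effects data frame whose first three columns are drug id, lncRNA id
#'   and effect (`"increase"`/`"decrease"`; free verbs can be mapped first
#'   with [normalize_effect()]).
#' @param directions data frame with columns `lncrna`, `direction_dm`,
#'   `direction_ad` (values `up`/`down`/`unknown`), e.g.
#'   [load_fixture()]`("table4_directions")`.
#' @return A list of class `signed_effects`: `signed` (uniform-sign records
#'   of retained drugs), `removed_contradictory`, `removed_unsignable`
#'   (drug id vectors) and `skipped_records`.
#' @export
remove_contradictory <- function(effects, directions) {
  res <- sign_effect_records(effects, directions)
  eff <- res$signed
  all_drugs <- unique(as.character(effects[[1L]]))
  if (!nrow(eff)) stop("no signable effect record; check the direction table")
  signs_by_drug <- tapply(eff$sign, norm_id(eff$drug),
                          function(s) length(unique(s)))
  mixed <- names(signs_by_drug)[signs_by_drug > 1L]
  removed <- unique(eff$drug[norm_id(eff$drug) %in% mixed])
  kept <- eff[!(norm_id(eff$drug) %in% mixed), , drop = FALSE]
  unsignable <- setdiff(all_drugs[!(norm_id(all_drugs) %in% norm_id(eff$drug))],
                        removed)
  out <- list(signed = kept,
              removed_contradictory = removed,
              removed_unsignable = unsignable,
              skipped_records = res$skipped)
  class(out) <- "signed_effects"
  out
}

#' Partition uniformly signed drugs into therapeutic and exacerbating sets
#'
#' @param signed a `signed_effects` object from [remove_contradictory()], or
#'   a data frame with columns `drug` and `sign` in which every drug must
#'   already be uniform-signed (a mixed-sign drug here is an invariant breach
#'   and raises an error).
#' @return An object of class `labeled_drugs`: `positives` (uniformly
#'   therapeutic drug ids), `negatives` (uniformly exacerbating),
#'   `removed_contradictory`, `removed_unsignable`.
#' @export
#' @examples
#' tab4 <- load_fixture("table4_directions")
#' eff <- data.frame(drug = c("A", "A", "B"),
#'                   lncrna = c("NEAT1", "MALAT1", "H19"),
#'                   effect = c("decrease", "increase", "increase"))
#' partition_drugs(remove_contradictory(eff, tab4))
partition_drugs <- function(signed) {
  if (inherits(signed, "signed_effects")) {
    eff <- signed$signed
    removed_c <- signed$removed_contradictory
    removed_u <- signed$removed_unsignable
  } else {
    eff <- signed
    removed_c <- character()
    removed_u <- character()
  }
  stopifnot(is.data.frame(eff), all(c("drug", "sign") %in% names(eff)))
  if (nrow(eff)) {
    n_signs <- tapply(eff$sign, norm_id(eff$drug), function(s) length(unique(s)))
    if (any(n_signs > 1L)) {
      stop("mixed-sign drug reached partitioning; run remove_contradictory() first")
    }
  }
  first <- eff[!duplicated(norm_id(eff$drug)), , drop = FALSE]
  out <- list(
    positives = first$drug[first$sign == "therapeutic"],
    negatives = first$drug[first$sign == "exacerbating"],
    removed_contradictory = removed_c,
    removed_unsignable = removed_u
  )
  class(out) <- "labeled_drugs"
  out
}

#' Label drugs from effect records and disease directions
#'
#' Convenience composition of [remove_contradictory()] and
#' [partition_drugs()].
#'
#' @inheritParams remove_contradictory
#' @return A `labeled_drugs` object.
#' @export
label_drugs <- function(effects, directions) {
  partition_drugs(remove_contradictory(effects, directions))
}

#' Class label vector of a labeled drug set
#'
#' @param labels a `labeled_drugs` object.
#' @return A named factor (`negative`/`positive`) over all classified drugs.
#' @export
drug_classes <- function(labels) {
  stopifnot(inherits(labels, "labeled_drugs"))
  out <- factor(c(rep("positive", length(labels$positives)),
                  rep("negative", length(labels$negatives))),
                levels = c("negative", "positive"))
  names(out) <- c(labels$positives, labels$negatives)
  out
}

#' @export
print.labeled_drugs <- function(x, ...) {
  cat(sprintf(paste0("Labeled drug set: %d positive (therapeutic), ",
                     "%d negative (exacerbating)\n"),
              length(x$positives), length(x$negatives)))
  if (length(x$removed_contradictory)) {
    cat("  removed (contradictory signs):",
        paste(x$removed_contradictory, collapse = ", "), "\n")
  }
  if (length(x$removed_unsignable)) {
    cat("  set aside (no signable edge):",
        paste(x$removed_unsignable, collapse = ", "), "\n")
  }
  invisible(x)
}
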