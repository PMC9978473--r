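#' Level taxonomy
#'
#' A `level_taxonomy` describes the set of lymph node level structures a label
#' volume may contain: for each level a name, an integer label value and a
#' laterality (`"left"`, `"right"` or `"midline"`), plus the left/right mirror
#' pairing used by the mirroring augmentation and the craniocaudal exclusivity
#' chains used by slice-plane adjustment. Background is a dedicated value
#' (0 in the shipped default) that is never a level.
#'
#' The shipped default (see [default_taxonomy()]) contains the 20 head-and-neck
#' levels commonly delineated for nodal target volumes — midline Ia, VIa, VIb
#' and VIIa and bilateral Ib, II, III, IVa, IVb, V, VIIb and VIII — i.e. 21
#' prediction classes including background. Exclusivity chains default to the
#' per-side jugular chain II -> III -> IVa -> IVb (cranial to caudal); which
#' levels are treated as craniocaudally adjacent is a configurable convention,
#' not an anatomical invariant, and can be overridden in the JSON file.
#'
#' @param entries data.frame with columns `name`, `label_value`, `laterality`.
#' @param background_value integer background label (default 0).
#' @param mirror_pairs list of length-2 character vectors `(left, right)`.
#' @param exclusivity_chains list of character vectors, each ordered cranial
#'   to caudal.
#' @return An object of class `level_taxonomy`.
#' @seealso [load_taxonomy()], [default_taxonomy()]
#' @export
level_taxonomy <- function(entries, background_value = 0L,
                           mirror_pairs = list(),
                           exclusivity_chains = list()) {
  stopifnot(is.data.frame(entries),
            all(c("name", "label_value", "laterality") %in% names(entries)))
  entries <- data.frame(
    name = as.character(entries$name),
    label_value = as.integer(entries$label_value),
    laterality = as.character(entries$laterality),
    stringsAsFactors = FALSE
  )
  tax <- structure(
    list(entries = entries,
         background_value = as.integer(background_value),
         mirror_pairs = lapply(mirror_pairs, as.character),
         exclusivity_chains = lapply(exclusivity_chains, as.character)),
    class = "level_taxonomy"
  )
  validate_taxonomy(tax)
  tax
}

validate_taxonomy <- function(tax) {
  e <- tax$entries
  if (anyDuplicated(e$name))
    stop("duplicate level name(s): ",
         paste(unique(e$name[duplicated(e$name)]), collapse = ", "))
  if (anyDuplicated(e$label_value))
    stop("duplicate label value(s): ",
         paste(unique(e$label_value[duplicated(e$label_value)]), collapse = ", "))
  if (any(e$label_value <= 0L))
    stop("label values must be positive: ",
         paste(e$name[e$label_value <= 0L], collapse = ", "))
  if (any(e$label_value == tax$background_value))
    stop("label value equals background value for: ",
         paste(e$name[e$label_value == tax$background_value], collapse = ", "))
  bad_lat <- !e$laterality %in% c("left", "right", "midline")
  if (any(bad_lat))
    stop("invalid laterality for: ", paste(e$name[bad_lat], collapse = ", "))

  pair_members <- unlist(tax$mirror_pairs)
  if (anyDuplicated(pair_members))
    stop("level appears in more than one mirror pair: ",
         paste(unique(pair_members[duplicated(pair_members)]), collapse = ", "))
  for (p in tax$mirror_pairs) {
    if (length(p) != 2L) stop("mirror pair must have exactly two members")
    miss <- setdiff(p, e$name)
    if (length(miss))
      stop("mirror pair references unknown level(s): ",
           paste(miss, collapse = ", "))
    lat <- e$laterality[match(p, e$name)]
    if (!identical(lat, c("left", "right")))
      stop("mirror pair (", paste(p, collapse = ", "),
           ") must pair a left level with a right level")
  }
  lateral <- e$name[e$laterality %in% c("left", "right")]
  unpaired <- setdiff(lateral, pair_members)
  if (length(unpaired))
    stop("lateral level(s) missing from mirror pairs: ",
         paste(unpaired, collapse = ", "))
  midline_paired <- intersect(e$name[e$laterality == "midline"], pair_members)
  if (length(midline_paired))
    stop("midline level(s) may not appear in mirror pairs: ",
         paste(midline_paired, collapse = ", "))

  for (ch in tax$exclusivity_chains) {
    miss <- setdiff(ch, e$name)
    if (length(miss))
      stop("exclusivity chain references unknown level(s): ",
           paste(miss, collapse = ", "))
    if (anyDuplicated(ch))
      stop("level repeated within an exclusivity chain: ",
           paste(unique(ch[duplicated(ch)]), collapse = ", "))
  }
  invisible(tax)
}

#' Load a level taxonomy from a JSON file
#'
#' Reads and validates a taxonomy JSON file (schema as in the file shipped at
#' `system.file("extdata", "taxonomy.json", package = "levelpost")`).
#' Validation enforces unique positive label values distinct from background,
#' complete left/right mirror pairing of lateral levels, and exclusivity
#' chains that only reference declared levels.
#'
#' @param path path to a taxonomy JSON file.
#' @return A [level_taxonomy()] object.
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$entries)) stop("taxonomy JSON has no 'entries' field")
  entries <- do.call(rbind, lapply(j$entries, function(en) {
    if (is.null(en$name) || is.null(en$label_value) || is.null(en$laterality))
      stop("taxonomy entry missing name/label_value/laterality")
    data.frame(name = en$name, label_value = en$label_value,
               laterality = en$laterality, stringsAsFactors = FALSE)
  }))
  level_taxonomy(
    entries = entries,
    background_value = if (is.null(j$background_value)) 0L else j$background_value,
    mirror_pairs = lapply(j$mirror_pairs, unlist),
    exclusivity_chains = lapply(j$exclusivity_chains, unlist)
  )
}

#' The shipped default 20-level taxonomy
#'
#' @return The default `level_taxonomy` (20 levels, 21 classes including
#'   background).
#' @export
default_taxonomy <- function() {
  load_taxonomy(system.file("extdata", "taxonomy.json", package = "levelpost",
                            mustWork = TRUE))
}

#' @export
print.level_taxonomy <- function(x, ...) {
  e <- x$entries
  cat("Level taxonomy:", nrow(e), "level structures (",
      nrow(e) + 1L, "classes incl. background", x$background_value, ")\n")
  cat("  midline:", paste(e$name[e$laterality == "midline"], collapse = ", "), "\n")
  cat("  mirror pairs:", length(x$mirror_pairs),
      " exclusivity chains:", length(x$exclusivity_chains), "\n")
  for (ch in x$exclusivity_chains)
    cat("    ", paste(ch, collapse = " -> "), "\n")
  invisible(x)
}

#' Map level names to label values
#'
#' @param tax a `level_taxonomy`.
#' @param names character vector of level names.
#' @return integer label values.
#' @export
taxonomy_labels <- function(tax, names = NULL) {
  e <- tax$entries
  if (is.null(names)) return(e$label_value)
  idx <- match(names, e$name)
  if (anyNA(idx))
    stop("unknown level name(s): ", paste(names[is.na(idx)], collapse = ", "))
  e$label_value[idx]
}
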