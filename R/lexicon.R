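#' Load a hierarchical emotion lexicon
#'
#' The lexicon is a three-tier Parrot-style taxonomy: six fixed primary
#' emotions (surprise, anger, love, joy, sadness, fear), each branching into
#' secondary and tertiary classes, every class carrying an optional synonym
#' list. The file format is tab-separated text with columns `label`, `tier`,
#' `parent`, `synonyms` (pipe-separated, possibly empty); lines starting with
#' `#` are comments, and the header may declare its own counts as
#' `# n_subclasses: N` and `# n_synonyms: M` for self-verification.
#'
#' All class labels and synonyms are normalized (lowercased,
#' whitespace-collapsed, lemmatized with [lemmatize_tokens()]) into the term
#' index, so that dictionary and cleaned review text meet in one canonical
#' space. Loading validates the lexicon and fails on any structural defect.
#'
#' @param path Path to a lexicon file.
#' @return An object of class `emotion_lexicon`: a list with `classes`
#'   (tibble: label, tier, parent, synonyms list-column), `term_index`
#'   (tibble: term, n_tokens, class_label, tertiary, secondary, primary),
#'   `primaries`, and `declared` (counts declared in the file header, if any).
#' @seealso [validate_lexicon()], [primary_of()], [demo_lexicon()]
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Lexicon file not found: ", path), class = "emospect_schema_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  declared <- parse_declared_counts(lines)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(body)) {
    abort("Lexicon file has no entries.", class = "emospect_schema_error")
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  header <- trimws(fields[[1]])
  if (!identical(header[1:3], c("label", "tier", "parent"))) {
    abort(
      "Lexicon header must be: label, tier, parent, synonyms (tab-separated).",
      class = "emospect_schema_error"
    )
  }
  rows <- fields[-1]
  bad <- which(lengths(rows) < 3L)
  if (length(bad)) {
    abort(paste0("Malformed lexicon entry at data line ", bad[1], ": fewer than 3 fields."),
          class = "emospect_schema_error")
  }
  classes <- tibble::tibble(
    label = vapply(rows, function(r) trimws(r[1]), character(1)),
    tier = vapply(rows, function(r) trimws(r[2]), character(1)),
    parent = vapply(rows, function(r) {
      p <- trimws(r[3]); if (nzchar(p)) p else NA_character_
    }, character(1)),
    synonyms = lapply(rows, function(r) {
      if (length(r) < 4L || !nzchar(trimws(r[4]))) return(character(0))
      syn <- trimws(strsplit(r[4], "|", fixed = TRUE)[[1]])
      syn[nzchar(syn)]
    })
  )
  lex <- build_lexicon(classes, declared = declared)
  validate_lexicon(lex)
  lex
}

parse_declared_counts <- function(lines) {
  get1 <- function(key) {
    m <- regmatches(lines, regexec(paste0("^\\s*#\\s*", key, "\\s*:\\s*([0-9]+)"), lines))
    v <- vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
    v <- v[!is.na(v)]
    if (length(v)) as.integer(v[1]) else NA_integer_
  }
  c(n_subclasses = get1("n_subclasses"), n_synonyms = get1("n_synonyms"))
}

# Assemble an emotion_lexicon from a classes tibble; structural validation
# (unique labels, tier/parent consistency, tree shape) happens here because
# the term index cannot be built from a malformed tree.
build_lexicon <- function(classes, declared = c(n_subclasses = NA_integer_,
                                                n_synonyms = NA_integer_)) {
  if (anyDuplicated(classes$label)) {
    dup <- classes$label[duplicated(classes$label)][1]
    abort(paste0("Duplicate class label: '", dup, "'."),
          class = "emospect_structure_error")
  }
  if (!all(classes$tier %in% c("primary", "secondary", "tertiary"))) {
    abort("Class tier must be one of primary/secondary/tertiary.",
          class = "emospect_schema_error")
  }
  prim <- classes$label[classes$tier == "primary"]
  if (!setequal(prim, PRIMARY_EMOTIONS) || length(prim) != 6L) {
    abort(paste0("Primary classes must be exactly: ",
                 paste(PRIMARY_EMOTIONS, collapse = ", "), "."),
          class = "emospect_structure_error")
  }
  if (any(!is.na(classes$parent[classes$tier == "primary"]))) {
    abort("Primary classes must not declare a parent.",
          class = "emospect_structure_error")
  }
  nonprim <- classes[classes$tier != "primary", ]
  if (any(is.na(nonprim$parent))) {
    abort(paste0("Class '", nonprim$label[is.na(nonprim$parent)][1],
                 "' has no parent."), class = "emospect_structure_error")
  }
  missing_parent <- setdiff(nonprim$parent, classes$label)
  if (length(missing_parent)) {
    abort(paste0("Orphan class: parent '", missing_parent[1], "' does not exist."),
          class = "emospect_structure_error")
  }
  tier_of <- setNames(classes$tier, classes$label)
  bad_sec <- nonprim$label[nonprim$tier == "secondary" &
                             tier_of[nonprim$parent] != "primary"]
  if (length(bad_sec)) {
    abort(paste0("Secondary class '", bad_sec[1], "' must have a primary parent."),
          class = "emospect_structure_error")
  }
  bad_ter <- nonprim$label[nonprim$tier == "tertiary" &
                             tier_of[nonprim$parent] != "secondary"]
  if (length(bad_ter)) {
    abort(paste0("Tertiary class '", bad_ter[1], "' must have a secondary parent."),
          class = "emospect_structure_error")
  }

  parent_of <- setNames(classes$parent, classes$label)
  lineage <- lapply(classes$label, function(lab) {
    tier <- tier_of[[lab]]
    if (tier == "primary") {
      c(tertiary = lab, secondary = lab, primary = lab)
    } else if (tier == "secondary") {
      c(tertiary = lab, secondary = lab, primary = parent_of[[lab]])
    } else {
      sec <- parent_of[[lab]]
      c(tertiary = lab, secondary = sec, primary = parent_of[[sec]])
    }
  })
  lineage <- do.call(rbind, lineage)

  idx <- purrr::map2_dfr(seq_len(nrow(classes)), classes$synonyms, function(i, syn) {
    terms <- unique(vapply(c(classes$label[i], syn), normalize_term, character(1),
                           USE.NAMES = FALSE))
    if (any(!nzchar(terms))) {
      abort(paste0("Class '", classes$label[i],
                   "' has a label or synonym that normalizes to nothing."),
            class = "emospect_schema_error")
    }
    tibble::tibble(
      term = terms,
      n_tokens = lengths(strsplit(terms, " ", fixed = TRUE)),
      class_label = classes$label[i],
      tertiary = unname(lineage[i, "tertiary"]),
      secondary = unname(lineage[i, "secondary"]),
      primary = unname(lineage[i, "primary"])
    )
  })

  structure(
    list(
      classes = classes,
      term_index = idx,
      primaries = PRIMARY_EMOTIONS,
      declared = declared
    ),
    class = "emotion_lexicon"
  )
}

#' Validate an emotion lexicon and recompute its manifest
#'
#' Checks the invariants the matching pipeline depends on — six fixed
#' primaries, a strict two-level tree below them, and an unambiguous term
#' index (no surface form mapping to two classes) — and returns the lexicon
#' manifest with recomputed class and synonym counts, overall and per
#' primary emotion. Ambiguity is a hard error: the pipeline has no
#' disambiguation rule, so failing loudly preserves determinism.
#'
#' @param lex An `emotion_lexicon`.
#' @return A list of class `lexicon_manifest` with `n_subclasses`,
#'   `n_synonyms`, `declared`, and `per_primary` (tibble of counts).
#' @export
validate_lexicon <- function(lex) {
  stopifnot(inherits(lex, "emotion_lexicon"))
  idx <- lex$term_index
  dup_terms <- unique(idx$term[duplicated(idx$term)])
  if (length(dup_terms)) {
    t1 <- dup_terms[1]
    cls <- sort(unique(idx$class_label[idx$term == t1]))
    abort(
      paste0("Ambiguous term '", t1, "' maps to multiple classes: ",
             paste(cls, collapse = ", "), "."),
      class = "emospect_ambiguity_error"
    )
  }
  # every term resolves to a primary in at most 2 parent hops
  stopifnot(all(idx$primary %in% PRIMARY_EMOTIONS))

  n_subclasses <- sum(lex$classes$tier != "primary")
  n_synonyms <- sum(lengths(lex$classes$synonyms))
  prim_of_class <- setNames(
    idx$primary[!duplicated(idx$class_label)],
    idx$class_label[!duplicated(idx$class_label)]
  )
  per_primary <- lex$classes |>
    dplyr::mutate(
      primary = unname(prim_of_class[.data$label]),
      n_syn = lengths(.data$synonyms)
    ) |>
    dplyr::group_by(.data$primary) |>
    dplyr::summarise(
      n_subclasses = sum(.data$tier != "primary"),
      n_synonyms = sum(.data$n_syn),
      .groups = "drop"
    )

  structure(
    list(
      n_subclasses = n_subclasses,
      n_synonyms = n_synonyms,
      declared = lex$declared,
      per_primary = per_primary
    ),
    class = "lexicon_manifest"
  )
}

#' @export
print.lexicon_manifest <- function(x, ...) {
  cat("<lexicon_manifest> ", x$n_subclasses, " subclasses, ",
      x$n_synonyms, " synonyms\n", sep = "")
  if (!all(is.na(x$declared))) {
    cat("  declared in file: ", x$declared[["n_subclasses"]], " subclasses, ",
        x$declared[["n_synonyms"]], " synonyms\n", sep = "")
  }
  print(x$per_primary)
  invisible(x)
}

#' @export
print.emotion_lexicon <- function(x, ...) {
  cat("<emotion_lexicon> ", nrow(x$classes), " classes, ",
      nrow(x$term_index), " indexed terms\n", sep = "")
  invisible(x)
}

#' Primary ancestor of an emotion class
#'
#' Walks the class tree upward to the unique primary emotion; the identity
#' for primary labels themselves.
#'
#' @param lex An `emotion_lexicon`.
#' @param class_label A class label present in the lexicon.
#' @return The primary emotion label.
#' @examples
#' lex <- demo_lexicon()
#' primary_of(lex, "joy")
#' primary_of(lex, "heartbroken")
#' @export
primary_of <- function(lex, class_label) {
  stopifnot(inherits(lex, "emotion_lexicon"))
  hit <- match(class_label, lex$classes$label)
  if (is.na(hit)) {
    abort(paste0("Unknown class label: '", class_label, "'."),
          class = "emospect_lookup_error")
  }
  row <- lex$term_index[lex$term_index$class_label == class_label, ]
  row$primary[1]
}

#' Write an emotion lexicon back to its file format
#'
#' @param lex An `emotion_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "emotion_lexicon"))
  man <- validate_lexicon(lex)
  hdr <- c(
    "# emospect emotion lexicon",
    paste0("# n_subclasses: ", man$n_subclasses),
    paste0("# n_synonyms: ", man$n_synonyms),
    "label\ttier\tparent\tsynonyms"
  )
  body <- vapply(seq_len(nrow(lex$classes)), function(i) {
    paste(
      lex$classes$label[i], lex$classes$tier[i],
      ifelse(is.na(lex$classes$parent[i]), "", lex$classes$parent[i]),
      paste(lex$classes$synonyms[[i]], collapse = "|"),
      sep = "\t"
    )
  }, character(1))
  writeLines(c(hdr, body), path, useBytes = TRUE)
  invisible(path)
}

#' The demonstration emotion lexicon shipped with emospect
#'
#' A compact three-tier lexicon in the six-primary Parrot taxonomy, intended
#' for tests, examples and synthetic corpora. It is illustrative, not a
#' reconstruction of any published resource.
#'
#' @return An `emotion_lexicon`.
#' @export
demo_lexicon <- function() {
  load_lexicon(system.file("extdata", "demo_emotion_lexicon.tsv",
                           package = "emospect"))
}
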