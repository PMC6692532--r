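# Controlled vocabularies (gene, disease, drug, variant, population):
# loading, surface-form indexing, and orthographic variant generation.

GREEK_MAP <- c(
  "α" = "alpha", "β" = "beta", "γ" = "gamma",
  "δ" = "delta", "ε" = "epsilon", "κ" = "kappa",
  "λ" = "lambda", "μ" = "mu", "σ" = "sigma",
  "ω" = "omega"
)

ROMAN_MAP <- c(i = "1", ii = "2", iii = "3", iv = "4", v = "5",
               vi = "6", vii = "7", viii = "8", ix = "9", x = "10")

GENE_HEAD_WORDS <- c("gene", "protein", "receptor")

#' Normalize a surface form for dictionary matching
#'
#' Case-folds, maps Unicode dashes and apostrophes to their ASCII forms,
#' collapses runs of whitespace, and strips leading/trailing punctuation.
#' The function is idempotent; all lexicon index keys and all lookups use
#' this normal form.
#'
#' @param name Character vector of surface strings.
#' @return Character vector of normalized forms.
#' @examples
#' normalize_surface("  IL–2  ")   # "il-2"
#' @export
normalize_surface <- function(name) {
  x <- tolower(name)
  x <- gsub("[‐‑‒–—―−]", "-", x, perl = TRUE)
  x <- gsub("[‘’ʼ]", "'", x, perl = TRUE)
  x <- gsub("\\s+", " ", x, perl = TRUE)
  # strip leading/trailing punctuation (but keep internal structure)
  x <- gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", x, perl = TRUE)
  x
}

# Cheap applicability pre-checks keep the closure fast on plain words.
GREEK_ANY_RE <- paste0("[", paste(names(GREEK_MAP), collapse = ""), "]|",
                       paste(GREEK_MAP, collapse = "|"))
ROMAN_ANY_RE <- "(?:^| )(?:i{1,3}|iv|v|vi{1,3}|ix|x|[1-9]|10)(?: |$)"

# Hyphen/space/fused alternation. Up to three separators every assignment is
# enumerated (so mixed forms like "tgf-beta 1" ~ "tgf beta-1" are reachable
# from either side); beyond that only the uniform replacements are generated
# to keep the closure small.
apply_hyphen_rule <- function(form) {
  if (!grepl("[ -]", form)) return(character())
  parts <- strsplit(form, "[ -]")[[1]]
  k <- length(parts) - 1L
  if (k >= 1L && k <= 3L) {
    combos <- expand.grid(rep(list(c("-", " ", "")), k),
                          stringsAsFactors = FALSE)
    out <- apply(combos, 1L, function(seps) {
      paste0(paste0(parts[-length(parts)], seps, collapse = ""),
             parts[length(parts)])
    })
    setdiff(out, form)
  } else {
    setdiff(c(gsub("-", " ", form, fixed = TRUE),
              gsub("-", "", form, fixed = TRUE),
              gsub(" ", "-", form, fixed = TRUE),
              gsub(" ", "", form, fixed = TRUE)), form)
  }
}

apply_greek_rule <- function(form) {
  if (!grepl(GREEK_ANY_RE, form, perl = TRUE)) return(character())
  out <- character()
  for (ch in names(GREEK_MAP)) {
    if (grepl(ch, form, fixed = TRUE)) {
      out <- c(out, gsub(ch, GREEK_MAP[[ch]], form, fixed = TRUE))
    }
  }
  for (ch in names(GREEK_MAP)) {
    pat <- paste0("(?<![a-z])", GREEK_MAP[[ch]], "(?![a-z])")
    if (grepl(pat, form, perl = TRUE)) {
      out <- c(out, gsub(pat, ch, form, perl = TRUE))
    }
  }
  out
}

apply_roman_rule <- function(form) {
  if (!grepl(ROMAN_ANY_RE, form, perl = TRUE)) return(character())
  words <- strsplit(form, " ", fixed = TRUE)[[1]]
  out <- character()
  for (k in seq_along(words)) {
    w <- words[k]
    if (w %in% names(ROMAN_MAP)) {
      alt <- words
      alt[k] <- ROMAN_MAP[[w]]
      out <- c(out, paste(alt, collapse = " "))
    } else if (w %in% ROMAN_MAP) {
      alt <- words
      alt[k] <- names(ROMAN_MAP)[match(w, ROMAN_MAP)]
      out <- c(out, paste(alt, collapse = " "))
    }
  }
  out
}

apply_headword_rule <- function(form) {
  if (!grepl("gene|protein|receptor", form)) return(character())
  words <- strsplit(form, " ", fixed = TRUE)[[1]]
  keep <- !(words %in% GENE_HEAD_WORDS)
  if (all(keep) || !any(keep)) return(character())
  paste(words[keep], collapse = " ")
}

#' Generate orthographic variants of an entity name
#'
#' Returns the closure (capped at three rounds, which terminates and is
#' exhaustive in practice) of four switchable rule families over the
#' normalized name:
#' \itemize{
#'   \item `hyphen`: hyphen/space/fused alternation ("TGF-beta 1" ~
#'     "tgf beta 1" ~ "tgfbeta1");
#'   \item `greek`: Greek letters and their spelled forms ("α" ~ "alpha");
#'   \item `roman`: whole-token Roman/Arabic numeral swaps ("II" ~ "2");
#'   \item `headword` (gene class only): dropping the head words "gene",
#'     "protein", "receptor".
#' }
#' The result always contains `normalize_surface(name)`.
#'
#' @param name A single surface string.
#' @param entity_class Entity class; the head-word rule only fires for
#'   `"gene"`.
#' @param rules Character vector of enabled rule families.
#' @return Character vector (a set) of normalized variant forms.
#' @export
expand_variants <- function(name, entity_class = "gene",
                            rules = c("hyphen", "greek", "roman", "headword")) {
  if (length(name) != 1 || is.na(name) || name == "") {
    abort_invalid("`name` must be a single non-empty string.")
  }
  base <- normalize_surface(name)
  if (base == "") return(character())
  forms <- base
  use_headword <- "headword" %in% rules && identical(entity_class, "gene")
  for (round in 1:3) {
    new_forms <- character()
    for (f in forms) {
      if ("hyphen" %in% rules) new_forms <- c(new_forms, apply_hyphen_rule(f))
      if ("greek" %in% rules) new_forms <- c(new_forms, apply_greek_rule(f))
      if ("roman" %in% rules) new_forms <- c(new_forms, apply_roman_rule(f))
      if (use_headword) new_forms <- c(new_forms, apply_headword_rule(f))
    }
    new_forms <- setdiff(unique(normalize_surface(new_forms)), forms)
    new_forms <- new_forms[new_forms != ""]
    if (length(new_forms) == 0) break
    forms <- c(forms, new_forms)
  }
  forms
}

# ---- Lexicon container ------------------------------------------------------

#' Construct a lexicon from an entries table
#'
#' @param entries Tibble with columns `id`, `name`, `synonyms` (list column
#'   of character vectors), and optionally `parent_id` and `flags`.
#' @param entity_class One of `r paste(PGX_CLASSES, collapse = ", ")`.
#' @return An object of class `pgx_lexicon`: the entries plus a hashed
#'   surface index mapping each normalized name/synonym to the ids that use
#'   it (ambiguity preserved).
#' @export
new_lexicon <- function(entries, entity_class) {
  entity_class <- match.arg(entity_class, PGX_CLASSES)
  if (!"parent_id" %in% names(entries)) entries$parent_id <- NA_character_
  if (!"flags" %in% names(entries)) entries$flags <- ""
  if (anyDuplicated(entries$id)) {
    abort_format(sprintf("Duplicate canonical id in %s lexicon: %s",
                         entity_class,
                         entries$id[duplicated(entries$id)][1]))
  }
  dangling <- setdiff(stats::na.omit(entries$parent_id[entries$parent_id != ""]),
                      entries$id)
  if (length(dangling) > 0) {
    abort_format(sprintf("Dangling parent_id in %s lexicon: %s",
                         entity_class, dangling[1]))
  }

  index <- new.env(parent = emptyenv(), hash = TRUE)
  max_tokens <- 1L
  plain_surfaces <- TRUE
  for (k in seq_len(nrow(entries))) {
    surfaces <- unique(normalize_surface(c(entries$name[k], entries$synonyms[[k]])))
    surfaces <- surfaces[surfaces != ""]
    for (s in surfaces) {
      cur <- get0(s, envir = index, ifnotfound = NULL)
      assign(s, unique(c(cur, entries$id[k])), envir = index)
      max_tokens <- max(max_tokens, length(strsplit(s, "[^a-z0-9]+")[[1]]))
      if (grepl(WINDOW_SPECIAL_RE, s, perl = TRUE)) plain_surfaces <- FALSE
    }
  }
  structure(
    list(entity_class = entity_class, entries = entries,
         surface_index = index, max_tokens = max_tokens,
         # whether every surface stays within the letter/digit/hyphen/space/
         # Greek alphabet; when TRUE the recognizer may skip text windows
         # containing other characters (commas, parentheses, ...) unseen
         plain_surfaces = plain_surfaces,
         window_cache = new.env(parent = emptyenv(), hash = TRUE)),
    class = "pgx_lexicon"
  )
}

# Characters outside the set that orthographic expansion can ever remove or
# introduce; a text window containing one of these can only match a lexicon
# whose surfaces also use them.
WINDOW_SPECIAL_RE <- paste0("[^a-z0-9 '‐‑‒–—―−’‘ʼ",
                            paste(names(GREEK_MAP), collapse = ""), "-]")

#' @export
print.pgx_lexicon <- function(x, ...) {
  cat(sprintf("<pgx_lexicon: %s, %d entries, %d surface forms>\n",
              x$entity_class, nrow(x$entries),
              length(ls(x$surface_index, all.names = TRUE))))
  invisible(x)
}

#' Load a lexicon TSV
#'
#' Expected columns: `id`, `name`, `synonyms` (pipe-separated, may be empty),
#' optional `parent_id` (e.g. an ICD chapter for diseases, an owner gene for
#' variants) and optional `flags` (e.g. `metabolite` for drug entries).
#' Duplicate surface forms across entries are preserved as ambiguity — they
#' are resolved, or rejected, at normalization time, not here.
#'
#' @param path Path to the TSV.
#' @param entity_class Entity class of the vocabulary.
#' @return A `pgx_lexicon`.
#' @export
load_lexicon <- function(path, entity_class) {
  if (!file.exists(path)) {
    abort_io(sprintf("Lexicon file does not exist: %s", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("id", "name")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort_format(sprintf("Lexicon %s is missing column(s): %s", path,
                         paste(missing_cols, collapse = ", ")))
  }
  entries <- tibble(
    id = raw$id,
    name = raw$name,
    synonyms = map(raw$synonyms %||% rep("", nrow(raw)), function(x) {
      if (is.na(x) || x == "") character()
      else strsplit(x, "|", fixed = TRUE)[[1]]
    }),
    parent_id = if ("parent_id" %in% names(raw)) {
      ifelse(is.na(raw$parent_id), NA_character_, raw$parent_id)
    } else NA_character_,
    flags = if ("flags" %in% names(raw)) dplyr::coalesce(raw$flags, "") else ""
  )
  new_lexicon(entries, entity_class)
}

#' Load a population word list (one term per line)
#'
#' @param path Path to the text file.
#' @return A `pgx_lexicon` of class `population` whose ids are the terms.
#' @export
load_population_list <- function(path) {
  terms <- readr::read_lines(path, progress = FALSE)
  terms <- trimws(terms)
  terms <- terms[terms != ""]
  new_lexicon(tibble(id = terms, name = terms,
                     synonyms = rep(list(character()), length(terms))),
              "population")
}

#' Look up a normalized surface form in a lexicon
#'
#' @param lexicon A `pgx_lexicon`.
#' @param surface Already-normalized surface form(s).
#' @return For a single surface, the character vector of matching canonical
#'   ids (possibly empty).
#' @export
lexicon_lookup <- function(lexicon, surface) {
  out <- unique(unlist(lapply(surface, function(s) {
    get0(s, envir = lexicon$surface_index, ifnotfound = NULL)
  })))
  if (is.null(out)) character() else out
}

lexicon_entry <- function(lexicon, id) {
  lexicon$entries[match(id, lexicon$entries$id), ]
}

lexicon_surfaces <- function(lexicon) {
  ls(lexicon$surface_index, all.names = TRUE)
}
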