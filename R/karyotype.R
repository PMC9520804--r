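#' Parse a simplified ISCN karyotype string
#'
#' Covers the grammar of routine CML cytogenetics reports: clones separated
#' by `/`; within a clone a leading chromosome count (single value or
#' range, hyphen or en-dash), a sex designation, abnormality tokens
#' (`t()`, `del()`, `add()`, `der()`, `i()`/`iso()`, gains `+N`, losses
#' `-N`) and an optional trailing cell count in brackets. Typographic
#' variants are normalised: whitespace is stripped, commas between
#' chromosomes inside `t(...)` become semicolons, and en-dashes become
#' hyphens. Not a full ISCN 2020 parser.
#'
#' @param text Karyotype string, e.g. `"46,XY,t(9;22)(q34;q11.2)[20]"`.
#' @return A `karyotype` object: `clones` tibble (`count_min`, `count_max`,
#'   `sex`, `abnormalities` list-column of normalised tokens, `n_cells`)
#'   and the original string in `raw`.
#' @export
parse_karyotype <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text))) {
    abort("karyotype must be a single non-empty string")
  }
  raw <- text
  s <- gsub("–", "-", text)      # en-dash
  s <- gsub("[[:space:]]+", "", s)
  clone_strings <- strsplit(s, "/", fixed = TRUE)[[1]]
  clones <- lapply(seq_along(clone_strings), function(ci) {
    parse_clone(clone_strings[ci], ci)
  })
  structure(list(clones = bind_rows(clones), raw = raw), class = "karyotype")
}

parse_clone <- function(s, clone_index) {
  orig <- s
  # leading chromosome count or range
  m <- regmatches(s, regexec("^([0-9]+)(?:-([0-9]+))?,", s))[[1]]
  if (length(m) == 0) {
    abort(sprintf("clone %d: expected a leading chromosome count in '%s'",
                  clone_index, orig))
  }
  count_min <- as.integer(m[2])
  count_max <- if (nzchar(m[3])) as.integer(m[3]) else count_min
  s <- substring(s, nchar(m[1]) + 1)
  # sex designation
  sm <- regmatches(s, regexec("^(X[XY]?Y*)", s))[[1]]
  if (length(sm) == 0) {
    abort(sprintf("clone %d: expected a sex designation after the count in '%s'",
                  clone_index, orig))
  }
  sex <- sm[2]
  s <- substring(s, nchar(sex) + 1)
  # trailing clone-level cell count
  n_cells <- NA_integer_
  bm <- regmatches(s, regexec("\\[([0-9]+)\\]$", s))[[1]]
  if (length(bm) > 0) {
    n_cells <- as.integer(bm[2])
    s <- substring(s, 1, nchar(s) - nchar(bm[1]))
  }
  # abnormality tokens: split on commas outside parentheses/brackets
  tokens <- character(0)
  if (nzchar(s)) {
    if (!startsWith(s, ",")) {
      abort(sprintf("clone %d: unparseable text '%s' after the sex designation",
                    clone_index, s))
    }
    tokens <- split_top_level(substring(s, 2))
    tokens <- vapply(tokens, normalize_abnormality,
                     character(1), clone_index = clone_index)
  }
  tibble(count_min = count_min, count_max = count_max, sex = sex,
         abnormalities = list(unname(tokens)), n_cells = n_cells)
}

split_top_level <- function(s) {
  depth <- 0
  out <- character(0)
  cur <- ""
  for (ch in strsplit(s, "")[[1]]) {
    if (ch %in% c("(", "[")) depth <- depth + 1
    if (ch %in% c(")", "]")) depth <- depth - 1
    if (ch == "," && depth == 0) {
      out <- c(out, cur)
      cur <- ""
    } else cur <- paste0(cur, ch)
  }
  c(out, cur)
}

normalize_abnormality <- function(tok, clone_index) {
  tok <- sub("\\[[0-9]+\\]$", "", tok)  # per-token cell counts
  if (!nzchar(tok)) return(NA_character_)
  # commas between chromosome designators inside the first group of a
  # rearrangement become semicolons: t(9,22) -> t(9;22)
  if (grepl("^(t|der|dic)\\(", tok)) {
    first <- regmatches(tok, regexec("^[a-z]+\\(([^)]*)\\)", tok))[[1]]
    if (length(first) > 0) {
      fixed <- gsub(",", ";", first[2], fixed = TRUE)
      tok <- sub(first[2], fixed, tok, fixed = TRUE)
    }
  }
  ok <- grepl("^\\+?(t|del|add|der|dic|i|iso|ins|inv)\\(", tok) ||
    grepl("^[+-][0-9XY]+$", tok) || grepl("^\\+?i\\(", tok)
  if (!ok) {
    abort(sprintf("clone %d: unrecognised abnormality token '%s'",
                  clone_index, tok))
  }
  tok
}

#' @export
print.karyotype <- function(x, ...) {
  cat("<karyotype>", format_karyotype(x), "\n")
  invisible(x)
}

#' Format a parsed karyotype back to its normalised ISCN string
#'
#' @param k A [parse_karyotype()] result.
#' @return Single string; `parse -> format -> parse` is idempotent.
#' @export
format_karyotype <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  cl <- k$clones
  parts <- vapply(seq_len(nrow(cl)), function(i) {
    count <- if (cl$count_max[i] > cl$count_min[i]) {
      sprintf("%d-%d", cl$count_min[i], cl$count_max[i])
    } else as.character(cl$count_min[i])
    ab <- cl$abnormalities[[i]]
    body <- paste(c(count, cl$sex[i], ab), collapse = ",")
    if (!is.na(cl$n_cells[i])) body <- sprintf("%s[%d]", body, cl$n_cells[i])
    body
  }, character(1))
  paste(parts, collapse = "/")
}

# chromosomes named in the first parenthesised group of a rearrangement
rearrangement_chromosomes <- function(tok) {
  m <- regmatches(tok, regexec("^\\+?[a-z]+\\(([^)]*)\\)", tok))[[1]]
  if (length(m) == 0) return(character(0))
  strsplit(m[2], ";", fixed = TRUE)[[1]]
}

is_ph_token <- function(tok) {
  grepl("^\\+?t\\(", tok) &&
    all(c("9", "22") %in% rearrangement_chromosomes(tok))
}

#' Does a karyotype carry the Philadelphia chromosome?
#'
#' True iff any clone carries a translocation involving both chromosome 9
#' and chromosome 22; breakpoints are not required to match the canonical
#' t(9;22)(q34;q11.2) exactly.
#'
#' @param k A [parse_karyotype()] result.
#' @return Logical flag.
#' @export
has_philadelphia <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  any(vapply(unlist(k$clones$abnormalities), is_ph_token, logical(1)))
}

#' Additional chromosomal abnormalities acquired in the blast phase
#'
#' Normalised abnormality tokens present in any blast-phase clone but in no
#' chronic-phase clone of the same patient. Philadelphia-translocation
#' tokens are excluded from the comparison when both phases are
#' Ph-positive, so breakpoint typos in the Ph token itself do not count as
#' clonal evolution.
#'
#' @param chronic,blast Parsed karyotypes of the two phases.
#' @return Character vector of acquired abnormality tokens (possibly empty).
#' @export
additional_abnormalities <- function(chronic, blast) {
  stopifnot(inherits(chronic, "karyotype"), inherits(blast, "karyotype"))
  ab_c <- unique(unlist(chronic$clones$abnormalities))
  ab_b <- unique(unlist(blast$clones$abnormalities))
  ab_c <- ab_c[!is.na(ab_c)]
  ab_b <- ab_b[!is.na(ab_b)]
  extra <- setdiff(ab_b, ab_c)
  if (has_philadelphia(chronic) && has_philadelphia(blast)) {
    extra <- extra[!vapply(extra, is_ph_token, logical(1))]
  }
  unname(extra)
}

#' Cohort-level cytogenetic summary
#'
#' Counts, over patient pairs of chronic/blast karyotypes, how many
#' patients acquired at least one additional abnormality in the blast
#' phase and how many blast-phase karyotypes lack the Philadelphia
#' chromosome.
#'
#' @param pairs Tibble/data frame with `chronic_karyotype` and
#'   `blast_karyotype` string columns (one row per patient).
#' @return List: `n_patients`, `n_with_additional_abnormalities`,
#'   `n_ph_negative_blast`, and a per-patient tibble `details`.
#' @export
cytogenetic_summary <- function(pairs) {
  if (nrow(pairs) == 0) abort("no karyotype pairs supplied")
  details <- lapply(seq_len(nrow(pairs)), function(i) {
    kc <- parse_karyotype(pairs$chronic_karyotype[i])
    kb <- parse_karyotype(pairs$blast_karyotype[i])
    extra <- additional_abnormalities(kc, kb)
    tibble(patient = if ("patient" %in% names(pairs)) pairs$patient[i] else
             as.character(i),
           n_additional = length(extra),
           additional = paste(extra, collapse = ";"),
           ph_chronic = has_philadelphia(kc),
           ph_blast = has_philadelphia(kb))
  })
  details <- bind_rows(details)
  list(n_patients = nrow(details),
       n_with_additional_abnormalities = sum(details$n_additional > 0),
       n_ph_negative_blast = sum(!details$ph_blast),
       details = details)
}

#' Packaged CML cytogenetic table
#'
#' The cytogenetic profiles of the 18 CML patients in both disease phases,
#' as printed in the study (including its typographic variants, which the
#' parser normalises).
#'
#' @return Tibble with `patient`, `chronic_karyotype`, `blast_karyotype`.
#' @export
cml_karyotype_table <- function() {
  path <- system.file("extdata", "cml_karyotypes.csv", package = "telarch")
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
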